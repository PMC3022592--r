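test_that("baseline distance summarizes single-gene accuracy", {
  m <- hky_params(kappa = 2, gamma_shape = 1)
  sp <- yule_tree(8, seed = 1, height = 0.1)
  alns <- lapply(1:3, function(g) simulate_alignment(sp, 300, m, seed = g,
                                                     gene = paste0("g", g)))
  rec <- function(a) nj_tree(impute_distances(ml_pairwise_distances(a, m)))
  b <- baseline_distance(sp, alns, rec)
  expect_gte(b, 0); expect_lte(b, 1)
  # star-returning reconstructor: RF(binary, star) = 0.5 per gene
  star <- parse_newick(paste0("(", paste(sp$tip.label, collapse = ","), ");"))
  expect_equal(baseline_distance(sp, alns, function(a) star), 0.5)
  # single gene: baseline equals that gene's distance
  expect_equal(baseline_distance(sp, alns[1], rec),
               rf_distance(rec(alns[[1]]), sp))
  # incomplete alignments are refused
  short <- gene_alignment(alns[[1]]$seqs[-1, ], gene = "bad")
  expect_error(baseline_distance(sp, list(short), rec), "complete")
})

test_that("wilcoxon_signed_rank follows the exact and approximate regimes", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(wilcoxon_signed_rank(x, x)$p.value, 1)
  expect_true(wilcoxon_signed_rank(x, x)$degenerate)
  # all six differences positive: exact two-sided p = 2/2^6
  w <- wilcoxon_signed_rank(x + c(1, 2, 1.5, 0.5, 2.5, 3), x)
  expect_equal(w$p.value, 2 / 64)
  expect_false(w$degenerate)
  expect_equal(w$n_nonzero, 6L)
  # n = 30: approximate p close to the exact one
  set.seed(99)
  a <- rnorm(30, 0.4); b <- rnorm(30)
  mine <- wilcoxon_signed_rank(a, b)  # n > 25 -> approximation
  exact <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
  expect_lt(abs(mine$p.value - exact), 0.01)
  expect_error(wilcoxon_signed_rank(1:3, 4:6), "at least 5")
})

test_that("run_benchmark keeps the paired design and is reproducible", {
  cfg <- sim_config(regime = "custom", coverage = "complete", genetrees = "E",
                    n_taxa = 10, n_genes = 4, total_sites = 1200, seed = 5)
  b1 <- suppressWarnings(run_benchmark(cfg, methods = c("sa", "mrp_br", "consensus"),
                                       reps = 5))
  expect_s3_class(b1, "benchmark_result")
  expect_setequal(names(b1$results), c("replicate", "method", "rf", "seed"))
  expect_equal(nrow(b1$results), 15L)
  expect_true(all(b1$results$rf >= 0 & b1$results$rf <= 1))
  expect_equal(nrow(b1$gene_rf), 5L)
  # bit-identical rerun under the same config seed
  b2 <- suppressWarnings(run_benchmark(cfg, methods = c("sa", "mrp_br", "consensus"),
                                       reps = 5))
  expect_identical(b1$results, b2$results)
  s <- summary(b1)
  expect_true(all(c("method", "mean_rf", "median_rf") %in% names(s)))
  expect_type(attr(s, "baseline"), "double")
  md <- format_markdown(b1)
  expect_true(any(grepl("Baseline", md)))
  # paired comparison runs on matched replicates
  cmp <- compare_methods(b1, "sa", "mrp_br")
  expect_s3_class(cmp, "paired_signrank")
})

test_that("inapplicable methods are skipped with a reason", {
  cfg <- sim_config(regime = "custom", coverage = "missing", genetrees = "E",
                    n_taxa = 10, n_genes = 4, total_sites = 1200,
                    mean_coverage = 0.7, seed = 6)
  b <- suppressWarnings(run_benchmark(cfg, methods = c("consensus", "mrp_br"),
                                      reps = 2))
  expect_true(!is.null(b$skipped))
  expect_true(all(b$skipped$method == "consensus"))
  expect_match(b$skipped$reason[1], "complete")
  expect_true(all(b$results$method == "mrp_br"))
})
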