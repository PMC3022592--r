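test_that("yule_tree draws seeded ultrametric trees at the target height", {
  tr <- yule_tree(25, seed = 4, height = 0.3)
  expect_equal(length(tr$tip.label), 25L)
  expect_equal(tr$Nnode, 24L)
  expect_equal(max(ape::node.depth.edgelength(tr)), 0.3, tolerance = 1e-12)
  expect_identical(write_newick(yule_tree(10, seed = 7)),
                   write_newick(yule_tree(10, seed = 7)))
  expect_length(splits_of(ape::unroot(tr)), 22L)
  expect_error(yule_tree(3), ">= 4")
})

test_that("coalescent gene trees collapse onto the species tree as theta -> 0", {
  sp <- yule_tree(8, seed = 2, height = 0.2)
  gt <- coalescent_gene_trees(sp, 1e-8, 5, seed = 3)
  for (g in gt) expect_equal(rf_distance(ape::unroot(g), ape::unroot(sp)), 0)
  gt0 <- coalescent_gene_trees(sp, 0, 3)
  expect_identical(gt0[[1]], sp)
  sp2 <- sp; sp2$edge.length <- NULL
  expect_error(coalescent_gene_trees(sp2, 0.01, 2), "branch lengths")
})

test_that("pairwise coalescence time matches theta/2 below the root", {
  sp <- parse_newick("(A:1,B:1);")
  gt <- coalescent_gene_trees(sp, 0.005, 3000, seed = 11)
  extra <- vapply(gt, function(t) max(ape::node.depth.edgelength(t)) - 1, 0)
  se <- sd(extra) / sqrt(length(extra))
  expect_lt(abs(mean(extra) - 0.0025), 4 * se + 1e-5)
})

test_that("gene-tree incongruence increases with theta", {
  sp <- yule_tree(15, seed = 5, height = 0.1)
  means <- vapply(c(0.002, 0.01, 0.05), function(th) {
    g <- coalescent_gene_trees(sp, th, 40, seed = 6)
    mean(vapply(g, function(t) rf_distance(ape::unroot(t), ape::unroot(sp)), 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
  expect_gt(means[3], means[1])
})

test_that("rate-scaled gene trees keep topology and calibrated factors", {
  sp <- yule_tree(10, seed = 8, height = 0.2)
  gt <- rate_scaled_gene_trees(sp, 1e6, 5, seed = 9)
  for (g in gt) {
    expect_equal(rf_distance(ape::unroot(g), ape::unroot(sp)), 0)
    expect_equal(g$edge.length, sp$edge.length, tolerance = 0.01)
  }
  f <- attr(rate_scaled_gene_trees(sp, 3, 10000, seed = 10), "factors")
  expect_equal(mean(f), 1, tolerance = 3 * sqrt(1 / 3 / 10000) * 3)
  expect_equal(var(f), 1 / 3, tolerance = 0.03)
})

test_that("sequence simulation respects the model", {
  m <- hky_params(kappa = 4, pi = c(A = .4, C = .1, G = .1, T = .4),
                  gamma_shape = 1)
  # zero branch lengths: identical sequences
  sp <- parse_newick("((A:0,B:0):0,(C:0,D:0):0);")
  aln <- simulate_alignment(sp, 50, m, seed = 1)
  expect_true(all(aln$seqs == rep(aln$seqs[1, ], each = 4)))
  # base composition follows pi
  tr <- parse_newick("(A:0.05,B:0.05);")
  big <- simulate_alignment(tr, 20000, m, seed = 2)
  freq <- tabulate(big$seqs, 4) / length(big$seqs)
  expect_equal(freq, unname(m$pi), tolerance = 0.02)
  # deterministic under seed
  expect_identical(simulate_alignment(tr, 100, m, seed = 3)$seqs,
                   simulate_alignment(tr, 100, m, seed = 3)$seqs)
  expect_error(simulate_alignment(tr, 0, m), "positive")
})

test_that("occupancy sampling hits the regime statistics", {
  occ <- sample_occupancy("small", seed = 13)
  expect_equal(dim(occ$occ), c(25L, 10L))
  expect_gte(mean(occ$occ), 0.632)
  expect_lte(mean(occ$occ), 0.672)
  expect_true(all(colSums(occ$occ) >= 4L))
  expect_true(any(rowSums(occ$occ) == 10L))  # a fully covered taxon
  expect_true(all(rowSums(occ$occ) >= 1L))
  expect_equal(sum(occ$lengths), 6681, tolerance = 0.01)
  occ2 <- sample_occupancy("large", seed = 14)
  expect_equal(dim(occ2$occ), c(69L, 254L))
  expect_gte(mean(occ2$occ), 0.148)
  expect_lte(mean(occ2$occ), 0.168)
  expect_true(all(colSums(occ2$occ) >= 4L))
})

test_that("apply_occupancy prunes taxa per gene", {
  m <- hky_params()
  sp <- yule_tree(6, seed = 15, height = 0.1)
  alns <- lapply(1:3, function(g) simulate_alignment(sp, 50, m, seed = g,
                                                     gene = paste0("g", g)))
  occ <- matrix(1L, 6, 3, dimnames = list(sp$tip.label, paste0("g", 1:3)))
  same <- apply_occupancy(alns, occ)
  expect_equal(same[[2]]$seqs, alns[[2]]$seqs)
  occ[1:2, 2] <- 0L
  pruned <- apply_occupancy(alns, occ)
  expect_equal(nrow(pruned[[2]]$seqs), 4L)
  expect_equal(ncol(pruned[[2]]$seqs), 50L)
  expect_equal(vapply(pruned, function(a) nrow(a$seqs), 0L),
               unname(colSums(occ)))
})

test_that("bootstrap consensus gene trees behave at the extremes", {
  m <- hky_params(kappa = 2, gamma_shape = 1)
  set.seed(16)
  tr <- ape::rtree(6); tr$edge.length <- tr$edge.length * 0.05
  rec <- function(a) nj_tree(impute_distances(ml_pairwise_distances(a, m)))
  aln <- simulate_alignment(tr, 400, m, seed = 17)
  single <- bootstrap_consensus_gene_tree(aln, 1, rec, seed = 18)
  expect_s3_class(single, "phylo")
  # strong signal: consensus of 10 replicates equals the single-shot tree
  long <- simulate_alignment(tr, 4000, m, seed = 19)
  cons <- bootstrap_consensus_gene_tree(long, 10, rec, seed = 20)
  expect_equal(rf_distance(cons, rec(long)), 0)
})

test_that("the simulation pipeline is a pure function of its seed", {
  cfg <- sim_config(regime = "custom", coverage = "missing", genetrees = "T",
                    theta = 0.01, n_taxa = 10, n_genes = 4,
                    total_sites = 800, seed = 21)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(write_newick(d1$species_tree), write_newick(d2$species_tree))
  expect_identical(d1$alignments[[3]]$seqs, d2$alignments[[3]]$seqs)
  expect_identical(d1$occupancy$occ, d2$occupancy$occ)
  # occupancy governs the pruned alignments
  expect_equal(vapply(d1$alignments, function(a) nrow(a$seqs), 0L),
               unname(colSums(d1$occupancy$occ)))
  # setting E returns copies of the species tree
  cfgE <- sim_config(regime = "custom", coverage = "complete", genetrees = "E",
                     n_taxa = 8, n_genes = 3, total_sites = 500, seed = 22)
  dE <- simulate_dataset(cfgE)
  for (g in dE$gene_trees) expect_identical(write_newick(g),
                                            write_newick(dE$species_tree))
})

test_that("run directories contain the dataset as plain text", {
  cfg <- sim_config(regime = "custom", coverage = "complete", genetrees = "E",
                    n_taxa = 6, n_genes = 2, total_sites = 200, seed = 23)
  ds <- simulate_dataset(cfg)
  dir <- file.path(tempdir(), "run1")
  write_run_dir(ds, dir)
  expect_true(file.exists(file.path(dir, "species_tree.nwk")))
  expect_true(file.exists(file.path(dir, "occupancy.tsv")))
  fa <- list.files(dir, pattern = "\\.fasta$")
  expect_length(fa, 2L)
  back <- read_alignment(file.path(dir, fa[1]))
  expect_equal(dim(back$seqs), dim(ds$alignments[[1]]$seqs))
})
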