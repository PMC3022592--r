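# Accuracy evaluation: baseline distance, paired Wilcoxon signed-rank
# comparison, and the benchmark grid runner applying the combination methods
# to simulated replicates under a paired design.

#' Baseline distance
#'
#' The mean normalized Robinson-Foulds distance between the true species
#' tree and the gene trees reconstructed from the *complete* single-gene
#' alignments: the accuracy obtainable from one gene alone, and hence the
#' bar a data-combination method must beat to be useful.
#'
#' @param species The true species tree (`phylo`).
#' @param complete_alns List of complete [gene_alignment()] objects (every
#'   alignment must cover all species-tree taxa).
#' @param reconstructor Function `gene_alignment -> phylo`.
#' @return Mean normalized RF over genes.
#' @export
baseline_distance <- function(species, complete_alns, reconstructor) {
  .check_phylo(species, "species")
  taxa <- sort(species$tip.label)
  for (k in seq_along(complete_alns)) {
    if (!setequal(rownames(complete_alns[[k]]$seqs), taxa)) {
      .stopf("alignment %d is incomplete; the baseline distance is defined on complete data", k)
    }
  }
  mean(vapply(complete_alns,
              function(a) rf_distance(reconstructor(a), species), 0))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of zero median paired difference between two equal-length
#' samples (e.g. per-replicate accuracies of two methods). Zero differences
#' are dropped before ranking and ties get midranks; the exact distribution
#' is used for up to 25 non-zero differences without ties, otherwise the
#' normal approximation with continuity correction. The point estimate and
#' confidence interval are the Hodges-Lehmann pseudomedian and its
#' signed-rank interval.
#'
#' @param x,y Paired numeric vectors of equal length (>= 5).
#' @return An object of class `paired_signrank`: `p.value`, `estimate`
#'   (pseudomedian of x - y), `conf.int`, `n` (pairs), `n_nonzero`,
#'   `degenerate` (all differences zero).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) .stopf("'x' and 'y' must have equal length")
  if (length(x) < 5L) .stopf("need at least 5 pairs")
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0L) {
    out <- list(p.value = 1, estimate = 0, conf.int = c(0, 0),
                n = length(x), n_nonzero = 0L, degenerate = TRUE)
    return(structure(out, class = "paired_signrank"))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, exact = nz <= 25L, correct = TRUE,
    conf.int = TRUE))
  structure(list(p.value = wt$p.value,
                 estimate = unname(wt$estimate),
                 conf.int = as.numeric(wt$conf.int),
                 n = length(x), n_nonzero = nz, degenerate = FALSE),
            class = "paired_signrank")
}

#' @export
print.paired_signrank <- function(x, ...) {
  cat(sprintf("Paired Wilcoxon signed-rank: p = %.3g, pseudomedian diff = %.4g [%.4g, %.4g], n = %d (%d non-zero)\n",
              x$p.value, x$estimate, x$conf.int[1L], x$conf.int[2L],
              x$n, x$n_nonzero))
  if (x$degenerate) cat("  (all paired differences are zero)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Benchmark runner

.BENCH_METHODS <- c("sa", "avcon", "sdm", "consensus", "mrp_br", "mrp_pu",
                    "mrp_i", "mrf_br", "mrf_pu", "mrc", "mincut", "modmincut")

# default per-gene reconstructor: ML distances + NJ (fast)
.gene_tree_nj <- function(aln, model) {
  dm <- ml_pairwise_distances(aln, model)
  if (anyNA(dm[upper.tri(dm)])) dm <- impute_distances(dm)
  nj_tree(dm)
}

# one method applied to one replicate context; returns phylo or NULL(+reason)
.apply_method <- function(method, ctx) {
  root_taxon <- ctx$root_taxon
  need_rooted <- method %in% c("mrp_pu", "mrp_i", "mincut", "modmincut")
  if (need_rooted && is.null(root_taxon)) {
    return(structure(list(), reason = "no fully covered taxon for rooting"))
  }
  if (method == "consensus" && !ctx$complete) {
    return(structure(list(), reason = "consensus needs complete coverage"))
  }
  cfg <- search_config(n_restarts = ctx$n_restarts, seed = ctx$seed)
  # Purvis matrices have flatter search landscapes; double the restarts
  cfg_pu <- search_config(n_restarts = max(2L, 2L * ctx$n_restarts),
                          seed = ctx$seed)
  switch(method,
    sa = superalignment_tree(ctx$alignments, ctx$model, cfg),
    avcon = fm_tree(average_consensus(ctx$gene_dists), cfg),
    sdm = fm_tree(sdm_combine(ctx$gene_dists)$X, cfg),
    consensus = majority_consensus(ctx$gene_trees),
    mrp_br = mr_supertree(encode_br(ctx$gene_trees), "fitch", cfg),
    mrp_pu = mr_supertree(encode_pu(ctx$rooted_gene_trees), "fitch", cfg_pu,
                          root = TRUE),
    mrp_i = mr_supertree(encode_br(ctx$rooted_gene_trees), "camin_sokal", cfg),
    mrf_br = mr_supertree(encode_br(ctx$gene_trees), "flip", cfg),
    mrf_pu = mr_supertree(encode_pu(ctx$rooted_gene_trees), "flip", cfg_pu,
                          root = TRUE),
    mrc = mr_supertree(encode_br(ctx$gene_trees), "compat", cfg),
    mincut = cut_supertree(ctx$rooted_gene_trees, "mincut"),
    modmincut = cut_supertree(ctx$rooted_gene_trees, "modmincut"),
    .stopf("unknown method '%s'", method))
}

#' Run the simulation benchmark
#'
#' For each replicate: simulate a data set under `config` (all methods see
#' the same alignments -- a paired design), reconstruct per-gene trees by ML
#' distances + neighbor joining, apply every requested combination method,
#' and score each result by the normalized RF distance to the true species
#' tree. Methods inapplicable to a setting (consensus without complete
#' coverage; rooted methods without a fully covered taxon) are skipped with a
#' logged reason. Per-replicate complete-data gene-tree distances (for the
#' baseline) and true-gene-tree distances are recorded as well.
#'
#' @param config A [sim_config()].
#' @param methods Character vector of method names (subset of
#'   `c("sa","avcon","sdm","consensus","mrp_br","mrp_pu","mrp_i","mrf_br",
#'   "mrf_pu","mrc","mincut","modmincut")`).
#' @param reps Number of replicates.
#' @param species Optional fixed species tree used for every replicate; by
#'   default each replicate draws a fresh Yule species tree (and occupancy
#'   pattern), so results average over tree space as in the classic
#'   supertree simulation scheme.
#' @param occupancy Optional fixed `occupancy_matrix` reused across
#'   replicates.
#' @param n_restarts Search restarts for the heuristic methods.
#' @return An object of class `benchmark_result`: `results` (long data frame
#'   with replicate, method, rf, seed), `gene_rf` (per replicate: mean
#'   reconstructed and true gene-tree RF), `skipped`, `species`, `config`.
#' @export
run_benchmark <- function(config, methods = c("sa", "avcon", "mrp_br"),
                          reps = 10L, species = NULL, occupancy = NULL,
                          n_restarts = 1L) {
  if (!inherits(config, "sim_config")) .stopf("'config' must be a 'sim_config'")
  methods <- match.arg(methods, .BENCH_METHODS, several.ok = TRUE)
  fixed_species <- species; fixed_occ <- occupancy
  res <- with_seed(config$seed, {
    rep_seeds <- sample.int(2^31 - 2, reps)
    rows <- list(); generf <- list(); skipped <- list()
    for (r in seq_len(reps)) {
      ds <- simulate_dataset(config, species = fixed_species,
                             occupancy = fixed_occ, seed = rep_seeds[r])
      species <- ds$species_tree
      occupancy <- ds$occupancy
      full_taxa <- rownames(occupancy$occ)[
        rowSums(occupancy$occ) == ncol(occupancy$occ)]
      root_taxon <- if (length(full_taxa)) sort(full_taxa)[1L] else NULL
      ctx <- with_seed(rep_seeds[r] + 1L, {
        gene_dists <- lapply(ds$alignments, ml_pairwise_distances,
                             model = config$model)
        gene_trees <- lapply(gene_dists, function(dm) {
          if (anyNA(dm[upper.tri(dm)])) dm <- impute_distances(dm)
          nj_tree(dm)
        })
        rooted <- if (!is.null(root_taxon)) {
          lapply(gene_trees, function(tr) {
            if (root_taxon %in% tr$tip.label) root_at(tr, root_taxon) else NULL
          })
        } else NULL
        if (!is.null(rooted)) rooted <- Filter(Negate(is.null), rooted)
        list(alignments = ds$alignments, gene_trees = gene_trees,
             rooted_gene_trees = rooted, gene_dists = gene_dists,
             model = config$model, complete = config$coverage == "complete",
             root_taxon = root_taxon, seed = rep_seeds[r] + 2L,
             n_restarts = n_restarts)
      })
      # baseline ingredients: complete-alignment gene trees + true gene trees
      # gene trees from user-supplied sources (mode G) may not cover the
      # full taxon set; the baseline is then undefined for those genes
      crf <- with_seed(rep_seeds[r] + 3L, vapply(ds$complete_alignments,
        function(a) tryCatch(
          rf_distance(.gene_tree_nj(a, config$model), species),
          error = function(e) NA_real_), 0))
      trf <- vapply(ds$gene_trees, function(gt) {
        if (setequal(gt$tip.label, species$tip.label) &&
            length(gt$tip.label) >= 4L) rf_distance(gt, species) else NA_real_
      }, 0)
      generf[[r]] <- data.frame(replicate = r, mean_gene_rf = mean(crf, na.rm = TRUE),
                                mean_true_gene_rf = mean(trf, na.rm = TRUE))
      for (m in methods) {
        out <- with_seed(rep_seeds[r] + 4L,
                         tryCatch(.apply_method(m, ctx), error = function(e) {
                           structure(list(), reason = conditionMessage(e))
                         }))
        if (.is_phylo(out)) {
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = r, method = m,
            rf = rf_distance(out, species), seed = rep_seeds[r])
        } else {
          skipped[[length(skipped) + 1L]] <- data.frame(
            replicate = r, method = m, reason = attr(out, "reason"))
        }
      }
    }
    list(results = do.call(rbind, rows),
         gene_rf = do.call(rbind, generf),
         skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
         species = species, occupancy = occupancy)
  })
  structure(c(res, list(config = config, methods = methods, reps = reps)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d replicates, coverage '%s', gene-tree mode '%s'\n",
              x$reps, x$config$coverage, x$config$genetrees))
  print(summary(x))
  invisible(x)
}

#' Summarize a benchmark result
#'
#' Per-method mean, median and quartiles of the normalized RF distance, plus
#' the baseline distance (mean complete-data gene-tree RF).
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A data frame, one row per method, with the baseline in
#'   `attr(, "baseline")`.
#' @export
summary.benchmark_result <- function(object, ...) {
  sp <- split(object$results$rf, object$results$method)
  out <- data.frame(
    method = names(sp),
    n = vapply(sp, length, 0L),
    mean_rf = vapply(sp, mean, 0),
    median_rf = vapply(sp, stats::median, 0),
    q25 = vapply(sp, function(v) unname(stats::quantile(v, 0.25)), 0),
    q75 = vapply(sp, function(v) unname(stats::quantile(v, 0.75)), 0),
    row.names = NULL)
  out <- out[order(out$mean_rf), ]
  attr(out, "baseline") <- mean(object$gene_rf$mean_gene_rf)
  out
}

#' Benchmark summary as a Markdown table
#'
#' @param x A `benchmark_result`.
#' @return Character vector of Markdown lines.
#' @export
format_markdown <- function(x) {
  s <- summary(x)
  lines <- c("| method | n | mean RF | median RF | q25 | q75 |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %d | %.3f | %.3f | %.3f | %.3f |",
                     s$method, s$n, s$mean_rf, s$median_rf, s$q25, s$q75),
             "",
             sprintf("Baseline distance (mean single-gene RF): %.3f",
                     attr(s, "baseline")))
  lines
}

#' Paired comparison of two methods in a benchmark result
#'
#' Convenience wrapper extracting the per-replicate RF distances of two
#' methods (paired by replicate) and running [wilcoxon_signed_rank()].
#'
#' @param x A `benchmark_result`.
#' @param m1,m2 Method names present in `x$results`.
#' @return A `paired_signrank` object for RF(m1) - RF(m2).
#' @export
compare_methods <- function(x, m1, m2) {
  r <- x$results
  a <- r[r$method == m1, c("replicate", "rf")]
  b <- r[r$method == m2, c("replicate", "rf")]
  common <- intersect(a$replicate, b$replicate)
  wilcoxon_signed_rank(a$rf[match(common, a$replicate)],
                       b$rf[match(common, b$replicate)])
}
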