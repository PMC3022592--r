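# Simulation engine: Yule species trees, true gene trees (identical,
# Gamma-rate-scaled, or multispecies-coalescent), HKY+Gamma sequence
# evolution with continuous Gamma site rates, empirical-style occupancy
# patterns, and bootstrap-consensus gene trees. Every stochastic operation is
# a pure function of (inputs, seed).

#' Yule species tree
#'
#' Draws a pure-birth (Yule) tree conditioned on `n_taxa` extant taxa and
#' rescales the branch lengths so the maximum root-to-tip height equals
#' `height` (expected substitutions per site). The default height places
#' single-gene signal in the regime where a few hundred sites leave an
#' appreciable fraction of internal edges unresolved while thousands of
#' sites resolve nearly all of them, as in empirical multi-gene data sets.
#' Optionally `edge_sd` superimposes independent log-normal rate factors on
#' the clock-like Yule branches for an even more non-uniform branch-length
#' distribution. Leaves are labelled `t01, t02, ...`.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param seed Integer seed or `NULL`.
#' @param height Maximum root-to-tip height in substitutions/site.
#' @param edge_sd Log-SD of the per-branch rate factors; 0 gives an
#'   ultrametric tree.
#' @return A rooted binary `phylo`.
#' @export
yule_tree <- function(n_taxa, seed = NULL, height = 0.08, edge_sd = 0) {
  if (n_taxa < 4L) .stopf("'n_taxa' must be >= 4")
  tr <- with_seed(seed, {
    x <- ape::rphylo(n_taxa, birth = 1, death = 0)
    if (edge_sd > 0) {
      x$edge.length <- x$edge.length *
        stats::rlnorm(length(x$edge.length), 0, edge_sd)
    }
    x
  })
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / h)
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr
}

#' Gene trees from a multispecies coalescent
#'
#' Samples `k` gene trees from the rooted species tree under a multispecies
#' coalescent with one lineage per species. Species-tree branch lengths are
#' read directly as coalescent-time units: within a branch of duration t,
#' every pair of extant gene lineages coalesces at rate \eqn{2/\theta};
#' lineages not coalesced at the top of a branch continue into the parent
#' branch, and the root branch extends to infinity. Larger \eqn{\theta}
#' yields more incomplete lineage sorting; \eqn{\theta \to 0} collapses every
#' gene tree onto the species tree (the `theta = 0` limit returns copies of
#' it). Gene-tree branch lengths are in the same units as the species tree.
#'
#' @param species A rooted `phylo` with branch lengths.
#' @param theta Coalescent intensity parameter (>= 0).
#' @param k Number of gene trees.
#' @param seed Integer seed or `NULL`.
#' @return A list of `k` rooted `phylo` objects.
#' @export
coalescent_gene_trees <- function(species, theta, k, seed = NULL) {
  .check_phylo(species, "species")
  if (!ape::is.rooted(species)) .stopf("species tree must be rooted")
  if (is.null(species$edge.length)) .stopf("species tree needs branch lengths")
  if (theta < 0) .stopf("'theta' must be >= 0")
  if (theta == 0) return(replicate(k, species, simplify = FALSE))
  nt <- length(species$tip.label)
  depth <- ape::node.depth.edgelength(species)
  H <- max(depth)
  age <- H - depth  # age above the youngest tip, per node
  children <- split(species$edge[, 2L], species$edge[, 1L])
  rate2 <- 2 / theta
  sim_one <- function() {
    # lineage: list(node = newick fragment, age)
    run_branch <- function(lins, from_age, to_age) {
      t_now <- from_age
      while (length(lins) > 1L) {
        np <- length(lins) * (length(lins) - 1L) / 2
        wait <- stats::rexp(1L, rate = np * rate2)
        if (t_now + wait > to_age) break
        t_now <- t_now + wait
        ij <- sample.int(length(lins), 2L)
        a <- lins[[ij[1L]]]; b <- lins[[ij[2L]]]
        merged <- list(
          node = sprintf("(%s:%.10g,%s:%.10g)", a$node, t_now - a$age,
                         b$node, t_now - b$age),
          age = t_now)
        lins <- c(lins[-ij], list(merged))
      }
      lins
    }
    recurse <- function(v) {
      if (v <= nt) {
        lins <- list(list(node = species$tip.label[v], age = age[v]))
      } else {
        lins <- unlist(lapply(children[[as.character(v)]], recurse),
                       recursive = FALSE)
      }
      # run the coalescent on the branch above v (root: to infinity)
      par_edge <- match(v, species$edge[, 2L])
      top <- if (is.na(par_edge)) Inf else age[species$edge[par_edge, 1L]]
      run_branch(lins, age[v], top)
    }
    res <- recurse(nt + 1L)
    stopifnot(length(res) == 1L)
    parse_newick(paste0(res[[1L]]$node, ";"))
  }
  with_seed(seed, replicate(k, sim_one(), simplify = FALSE))
}

#' Gene trees with Gamma-scaled rates
#'
#' Each gene tree is the species tree with all branch lengths multiplied by
#' an independent Gamma(`alpha_rate`, mean 1) draw (variance `1/alpha_rate`):
#' gene-specific evolutionary rates without topological change.
#'
#' @param species A `phylo` with branch lengths.
#' @param alpha_rate Gamma shape of the per-gene rate factors (> 0).
#' @param k Number of gene trees.
#' @param seed Integer seed or `NULL`.
#' @return A list of `k` `phylo` objects; `attr(, "factors")` holds the
#'   drawn rate factors.
#' @export
rate_scaled_gene_trees <- function(species, alpha_rate, k, seed = NULL) {
  .check_phylo(species, "species")
  if (is.null(species$edge.length)) .stopf("species tree needs branch lengths")
  if (alpha_rate <= 0) .stopf("'alpha_rate' must be > 0")
  f <- with_seed(seed, stats::rgamma(k, shape = alpha_rate, rate = alpha_rate))
  out <- lapply(f, function(fac) {
    tr <- species
    tr$edge.length <- tr$edge.length * fac
    tr
  })
  attr(out, "factors") <- f
  out
}

#' Simulate a DNA alignment along a tree
#'
#' Evolves sequences under HKY85 with continuous Gamma(mean 1) site rates:
#' the root sequence is drawn from the stationary frequencies and each branch
#' applies the HKY transition probabilities at the site's rate times the
#' branch length (expected substitutions/site).
#'
#' @param tree A `phylo` with branch lengths.
#' @param length Number of sites (> 0).
#' @param model An [hky_params()].
#' @param seed Integer seed or `NULL`.
#' @param gene Gene id for the resulting alignment.
#' @return A [gene_alignment()] over the tree's leaves.
#' @export
simulate_alignment <- function(tree, length, model = hky_params(), seed = NULL,
                               gene = "gene") {
  .check_phylo(tree)
  if (is.null(tree$edge.length)) .stopf("tree needs branch lengths")
  if (length < 1L) .stopf("'length' must be positive")
  eig <- .hky_eigen(model)
  nt <- base::length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  run <- function() {
    rates <- if (is.infinite(model$gamma_shape)) rep(1, length) else
      stats::rgamma(length, shape = model$gamma_shape, rate = model$gamma_shape)
    states <- matrix(0L, nt + tr$Nnode, length)
    root <- nt + 1L
    states[root, ] <- sample.int(4L, length, replace = TRUE, prob = model$pi)
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
      t_e <- tr$edge.length[k]
      ps <- states[p, ]
      if (t_e <= 0) { states[ch, ] <- ps; next }
      E <- exp(outer(rates * t_e, eig$lambda))  # sites x 4
      u <- stats::runif(length)
      new <- integer(length)
      for (a in 1:4) {
        idx <- which(ps == a)
        if (!base::length(idx)) next
        Pr <- E[idx, , drop = FALSE] %*% t(eig$A[a, , ])  # sites_a x 4
        Pr[Pr < 0] <- 0
        cp <- Pr / rowSums(Pr)
        cum <- t(apply(cp, 1L, cumsum))
        new[idx] <- 1L + rowSums(u[idx] > cum)
      }
      new[new > 4L] <- 4L
      states[ch, ] <- new
    }
    states[seq_len(nt), , drop = FALSE]
  }
  S <- with_seed(seed, run())
  rownames(S) <- tr$tip.label
  gene_alignment(S, gene = gene)
}

#' Sample a taxon-occupancy pattern
#'
#' Draws a taxa x genes presence/absence matrix emulating the coverage
#' statistics of the two empirical regimes: `"small"` (25 taxa x 10 genes,
#' mean per-taxon gene coverage 65.2%, one taxon carrying every gene) and
#' `"large"` (69 taxa x 254 genes, mean coverage 15.8%). Per-taxon coverage
#' probabilities come from a Beta distribution with the regime's mean, then
#' the draw is repaired to satisfy the structural constraints: every gene
#' present in >= 4 taxa, every taxon in >= 1 gene, the gene-overlap graph
#' connected, and (small/custom) at least one fully covered taxon for
#' rooting. Draws are retried until the realized mean coverage is within the
#' regime tolerance (+-2 points small/custom, +-1 large).
#'
#' Per-gene sequence lengths are drawn log-normally and scaled to the
#' regime's total alignment length (6,681 sites for small; for custom
#' regimes, `total_sites`).
#'
#' @param regime `"small"`, `"large"` or `"custom"`.
#' @param seed Integer seed or `NULL`.
#' @param n_taxa,n_genes,mean_coverage,total_sites Custom-regime settings
#'   (ignored for the named regimes).
#' @param require_full Require a fully covered taxon? Default: yes except
#'   for `"large"`.
#' @return An object of class `occupancy_matrix`: list with the 0/1 matrix
#'   `occ` (taxa x genes) and integer `lengths` per gene.
#' @export
sample_occupancy <- function(regime = c("small", "large", "custom"), seed = NULL,
                             n_taxa = 25L, n_genes = 10L, mean_coverage = 0.652,
                             total_sites = 6681L, require_full = NULL) {
  regime <- match.arg(regime)
  if (regime == "small") {
    n_taxa <- 25L; n_genes <- 10L; mean_coverage <- 0.652; total_sites <- 6681L
    tol <- 0.02
  } else if (regime == "large") {
    n_taxa <- 69L; n_genes <- 254L; mean_coverage <- 0.158; total_sites <- 96698L
    tol <- 0.01
  } else tol <- 0.02
  if (is.null(require_full)) require_full <- regime != "large"
  # empirical occupancy patterns are heterogeneous in both directions: taxa
  # differ in sampling depth and genes range from a handful of taxa to
  # nearly all, so presence combines a per-taxon and a per-gene propensity
  conc_taxa <- 3
  conc_gene <- 2.5
  draw <- function() {
    u <- stats::rbeta(n_taxa, mean_coverage * conc_taxa,
                      (1 - mean_coverage) * conc_taxa)
    q <- stats::rbeta(n_genes, mean_coverage * conc_gene,
                      (1 - mean_coverage) * conc_gene)
    p <- pmin(outer(u, q) / mean_coverage, 1)
    occ <- matrix(stats::rbinom(n_taxa * n_genes, 1L, p), n_taxa, n_genes)
    if (require_full) occ[which.max(u), ] <- 1L
    # repair: each gene in >= 4 taxa
    for (j in seq_len(n_genes)) {
      need <- 4L - sum(occ[, j])
      if (need > 0L) {
        zero <- which(occ[, j] == 0L)
        occ[zero[sample.int(length(zero), need)], j] <- 1L
      }
    }
    # repair: each taxon in >= 1 gene
    for (i in which(rowSums(occ) == 0L)) occ[i, sample.int(n_genes, 1L)] <- 1L
    occ
  }
  connected <- function(occ) {
    # genes connected through shared taxa
    if (ncol(occ) == 1L) return(TRUE)
    adj <- crossprod(occ) > 0
    grp <- .merge_groups(as.character(seq_len(ncol(occ))),
                         as.character(row(adj)[adj & upper.tri(adj)]),
                         as.character(col(adj)[adj & upper.tri(adj)]))
    length(unique(grp)) == 1L
  }
  res <- with_seed(seed, {
    occ <- NULL
    for (try in seq_len(500L)) {
      cand <- draw()
      if (abs(mean(cand) - mean_coverage) <= tol && connected(cand)) {
        occ <- cand; break
      }
    }
    if (is.null(occ)) {
      .stopf("could not satisfy occupancy constraints for mean coverage %.3f; adjust parameters",
             mean_coverage)
    }
    lens <- exp(stats::rnorm(n_genes, 0, 0.8))
    lens <- pmax(50L, as.integer(round(lens / sum(lens) * total_sites)))
    list(occ = occ, lengths = lens)
  })
  dimnames(res$occ) <- list(sprintf("t%02d", seq_len(n_taxa)),
                            sprintf("g%03d", seq_len(n_genes)))
  names(res$lengths) <- colnames(res$occ)
  structure(list(occ = res$occ, lengths = res$lengths, regime = regime),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("Occupancy (%s): %d taxa x %d genes, mean coverage %.1f%%, %d total sites\n",
              x$regime, nrow(x$occ), ncol(x$occ), 100 * mean(x$occ),
              sum(x$lengths)))
  invisible(x)
}

#' Apply an occupancy pattern to gene alignments
#'
#' Deletes each taxon from each gene alignment wherever the occupancy matrix
#' marks it absent; gene lengths are unchanged.
#'
#' @param alns List of [gene_alignment()] objects, one per occupancy column,
#'   in column order.
#' @param occ An `occupancy_matrix` (or plain 0/1 matrix) with rownames
#'   matching the alignments' taxa.
#' @return A list of pruned [gene_alignment()] objects.
#' @export
apply_occupancy <- function(alns, occ) {
  m <- if (inherits(occ, "occupancy_matrix")) occ$occ else occ
  if (length(alns) != ncol(m)) {
    .stopf("got %d alignments for %d occupancy columns", length(alns), ncol(m))
  }
  out <- vector("list", length(alns))
  for (j in seq_along(alns)) {
    a <- alns[[j]]
    bad <- setdiff(rownames(a$seqs), rownames(m))
    if (length(bad)) .stopf("alignment %d has taxa missing from occupancy: %s",
                            j, paste(bad, collapse = ", "))
    keep <- rownames(a$seqs)[m[rownames(a$seqs), j] == 1L]
    out[[j]] <- gene_alignment(a$seqs[keep, , drop = FALSE], gene = a$gene)
  }
  out
}

#' Bootstrap majority-rule consensus gene tree
#'
#' Reconstructs a gene tree as the majority-rule consensus of trees
#' estimated from `B` column-resampled replicates of the alignment. Splits in
#' the output have, by construction, more than 50% replicate support; the
#' result may be polytomous.
#'
#' @param aln A [gene_alignment()].
#' @param B Number of bootstrap replicates (>= 1; `B = 1` returns the single
#'   resampled-tree estimate).
#' @param reconstructor Function `gene_alignment -> phylo`.
#' @param seed Integer seed or `NULL`.
#' @return A `phylo` (possibly polytomous).
#' @export
bootstrap_consensus_gene_tree <- function(aln, B, reconstructor, seed = NULL) {
  if (B < 1L) .stopf("'B' must be >= 1")
  trees <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(ncol(aln$seqs), replace = TRUE)
      reconstructor(gene_alignment(aln$seqs[, idx, drop = FALSE], gene = aln$gene))
    })
  })
  if (B == 1L) return(trees[[1L]])
  majority_consensus(trees)
}

#' Simulation configuration
#'
#' Bundles the settings of one simulation scenario, mirroring the benchmark
#' shorthand: data-set regime (S/L/custom sizes), taxon coverage (`c`
#' complete / `m` missing), true-gene-tree mode (`E` identical to the
#' species tree, `R` Gamma-rate-scaled, `T` coalescent, `G` user-supplied),
#' and sequence length mode (`n` normal / `l` ten-fold).
#'
#' @param regime `"small"`, `"large"` or `"custom"`.
#' @param coverage `"complete"` or `"missing"`.
#' @param genetrees `"E"`, `"R"`, `"T"` or `"G"`.
#' @param seqlen `"normal"` or `"long"` (ten times longer).
#' @param n_taxa,n_genes,mean_coverage,total_sites Custom-regime sizes.
#' @param theta Coalescent parameter for mode `"T"`.
#' @param alpha_rate Gamma shape of gene rate factors for mode `"R"`.
#' @param user_gene_trees List of rooted `phylo` for mode `"G"`.
#' @param model An [hky_params()].
#' @param tree_height Species-tree root-to-tip height (substitutions/site).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(regime = c("custom", "small", "large"),
                       coverage = c("complete", "missing"),
                       genetrees = c("E", "R", "T", "G"),
                       seqlen = c("normal", "long"),
                       n_taxa = 24L, n_genes = 10L, mean_coverage = 0.652,
                       total_sites = 6681L, theta = 0.005, alpha_rate = 3,
                       user_gene_trees = NULL,
                       model = hky_params(kappa = 4,
                                          pi = c(A = 0.3, C = 0.2,
                                                 G = 0.2, T = 0.3),
                                          gamma_shape = 1),
                       tree_height = 0.08, seed = 1L) {
  cfg <- list(regime = match.arg(regime), coverage = match.arg(coverage),
              genetrees = match.arg(genetrees), seqlen = match.arg(seqlen),
              n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
              mean_coverage = mean_coverage, total_sites = as.integer(total_sites),
              theta = theta, alpha_rate = alpha_rate,
              user_gene_trees = user_gene_trees, model = model,
              tree_height = tree_height, seed = as.integer(seed))
  if (cfg$regime == "small") { cfg$n_taxa <- 25L; cfg$n_genes <- 10L
    cfg$mean_coverage <- 0.652; cfg$total_sites <- 6681L }
  if (cfg$regime == "large") { cfg$n_taxa <- 69L; cfg$n_genes <- 254L
    cfg$mean_coverage <- 0.158; cfg$total_sites <- 96698L }
  if (cfg$genetrees == "G" && is.null(cfg$user_gene_trees)) {
    .stopf("mode 'G' needs 'user_gene_trees'")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate one replicate data set
#'
#' Runs the full generative pipeline for one replicate: species tree (drawn
#' or supplied), true gene trees according to the configured mode, per-gene
#' occupancy and lengths, and HKY+Gamma alignments (pruned to the occupancy
#' pattern when coverage is `"missing"`).
#'
#' @param config A [sim_config()].
#' @param species Optional fixed species tree (rooted, with branch lengths);
#'   drawn by [yule_tree()] from the config seed when omitted.
#' @param occupancy Optional fixed `occupancy_matrix` to reuse across
#'   replicates.
#' @param seed Overrides `config$seed` for this replicate.
#' @return A list: `species_tree`, `gene_trees` (true), `alignments`
#'   (occupancy applied), `complete_alignments`, `occupancy`.
#' @export
simulate_dataset <- function(config, species = NULL, occupancy = NULL,
                             seed = NULL) {
  if (!inherits(config, "sim_config")) .stopf("'config' must be a 'sim_config'")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  with_seed(seed, {
    if (is.null(species)) {
      species <- yule_tree(config$n_taxa, height = config$tree_height)
    }
    if (is.null(occupancy)) {
      occupancy <- sample_occupancy(
        config$regime, n_taxa = config$n_taxa, n_genes = config$n_genes,
        mean_coverage = config$mean_coverage, total_sites = config$total_sites)
    }
    k <- ncol(occupancy$occ)
    gene_trees <- switch(config$genetrees,
      E = replicate(k, species, simplify = FALSE),
      R = rate_scaled_gene_trees(species, config$alpha_rate, k),
      T = coalescent_gene_trees(species, config$theta, k),
      G = {
        if (length(config$user_gene_trees) != k) {
          .stopf("mode 'G': need %d user gene trees", k)
        }
        config$user_gene_trees
      })
    lens <- occupancy$lengths
    if (config$seqlen == "long") lens <- lens * 10L
    complete <- vector("list", k)
    for (g in seq_len(k)) {
      complete[[g]] <- simulate_alignment(gene_trees[[g]], lens[g],
                                          model = config$model,
                                          gene = names(lens)[g])
    }
    alns <- if (config$coverage == "missing") {
      apply_occupancy(complete, occupancy)
    } else complete
    list(species_tree = species, gene_trees = gene_trees, alignments = alns,
         complete_alignments = complete, occupancy = occupancy, seed = seed)
  })
}
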