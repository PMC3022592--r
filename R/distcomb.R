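# Early- and medium-level combination: per-gene pairwise ML distances under
# HKY+Gamma, average-consensus and SDM (super distance matrix) combination of
# partial matrices, missing-data-aware Fitch-Margoliash least-squares tree
# fitting, neighbor joining, and superalignment by concatenation.
#
# A partial distance matrix is a plain symmetric numeric matrix with taxon
# dimnames, zero diagonal and NA for pairs sharing no data; the gene id (if
# any) is kept in attr(dm, "gene").

.check_pdm <- function(dm, arg = "dm") {
  if (!is.matrix(dm) || is.null(rownames(dm)) ||
      !identical(rownames(dm), colnames(dm))) {
    .stopf("'%s' must be a square matrix with matching taxon dimnames", arg)
  }
  if (any(dm < 0, na.rm = TRUE)) .stopf("'%s' has negative distances", arg)
  invisible(dm)
}

# ---------------------------------------------------------------------------
# Pairwise ML distances

# per-pair 16-cell site-pattern counts over mutually determined sites
.pair_counts <- function(seqs) {
  n <- nrow(seqs)
  pairs <- utils::combn(n, 2L)
  storage.mode(seqs) <- "integer"
  counts <- .pair_counts_cpp(seqs)
  list(pairs = pairs, counts = counts)
}

#' Pairwise maximum-likelihood distances under HKY+Gamma
#'
#' Estimates, for every pair of sequences with overlapping determined sites,
#' the evolutionary distance maximizing the pairwise likelihood under the
#' HKY85 model with 4 discrete Gamma rate categories. Distances are searched
#' on \eqn{[0, d_{max}]}; saturated pairs are clamped at `d_max` with a
#' warning. Pairs with no overlapping sites get an absent (`NA`) entry.
#'
#' @param aln A [gene_alignment()].
#' @param model An [hky_params()]. With `kappa = 1` and uniform frequencies
#'   and `gamma_shape = Inf` the estimate coincides with the Jukes-Cantor
#'   closed form.
#' @param d_max Upper bound for distances (substitutions/site).
#' @return A symmetric matrix of distances with `NA` for absent pairs;
#'   `attr(, "gene")` carries the gene id.
#' @export
ml_pairwise_distances <- function(aln, model = hky_params(), d_max = 10) {
  if (!inherits(aln, "gene_alignment")) .stopf("'aln' must be a 'gene_alignment'")
  seqs <- aln$seqs
  n <- nrow(seqs)
  if (n < 2L) .stopf("need at least 2 sequences")
  taxa <- rownames(seqs)
  eig <- .hky_eigen(model)
  rates <- discrete_gamma_rates(model$gamma_shape, 4L)
  pc <- .pair_counts(seqs)
  # coarse log-spaced grid, then 1-D refinement per pair
  dgrid <- c(0, exp(seq(log(1e-5), log(d_max), length.out = 160L)))
  logJ <- log(.hky_joint_grid(eig, dgrid, rates))          # 16 x G
  LL <- pc$counts %*% logJ                                 # P x G
  best <- max.col(LL, ties.method = "first")
  dm <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  diag(dm) <- 0
  nsite <- matrix(0, n, n, dimnames = list(taxa, taxa))
  saturated <- FALSE
  for (p in seq_len(ncol(pc$pairs))) {
    cnt <- pc$counts[p, ]
    if (sum(cnt) == 0) next  # no overlap: absent entry
    i <- pc$pairs[1L, p]; j <- pc$pairs[2L, p]
    nsite[i, j] <- nsite[j, i] <- sum(cnt)
    b <- best[p]
    if (b == 1L && sum(cnt[c(1, 6, 11, 16)]) == sum(cnt)) {
      d <- 0  # identical over overlap
    } else {
      lo <- dgrid[max(b - 1L, 2L)] * 0.5
      hi <- min(dgrid[min(b + 1L, length(dgrid))] * 1.5, d_max)
      opt <- stats::optimize(function(d) .hky_pair_ll(cnt, eig, d, rates),
                             c(lo, hi), maximum = TRUE, tol = 1e-8)
      d <- opt$maximum
      if (d > d_max * 0.99) { d <- d_max; saturated <- TRUE }
    }
    dm[i, j] <- dm[j, i] <- d
  }
  if (saturated) .warnf("gene '%s': saturated pair(s) clamped at d_max = %g",
                        aln$gene, d_max)
  attr(dm, "gene") <- aln$gene
  attr(dm, "n_sites") <- nsite  # pairwise overlap lengths (replicate counts)
  dm
}

#' Estimate the HKY transition/transversion ratio for a gene
#'
#' Maximizes the sum over sequence pairs of the pairwise HKY+Gamma
#' log-likelihoods (each profiled over its distance) as a function of kappa.
#' Base frequencies are taken empirically from the alignment.
#'
#' @inheritParams ml_pairwise_distances
#' @param gamma_shape Gamma shape used during estimation.
#' @return An [hky_params()] with the estimated kappa and empirical
#'   frequencies.
#' @export
estimate_hky <- function(aln, gamma_shape = 1, d_max = 10) {
  if (!inherits(aln, "gene_alignment")) .stopf("'aln' must be a 'gene_alignment'")
  tab <- tabulate(aln$seqs[!is.na(aln$seqs)], nbins = 4L)
  pi <- stats::setNames(pmax(tab, 1) / sum(pmax(tab, 1)), .NUC)
  pc <- .pair_counts(aln$seqs)
  dgrid <- c(0, exp(seq(log(1e-5), log(d_max), length.out = 120L)))
  profll <- function(logk) {
    m <- hky_params(exp(logk), pi, gamma_shape)
    eig <- .hky_eigen(m)
    rates <- discrete_gamma_rates(gamma_shape, 4L)
    LL <- pc$counts %*% log(.hky_joint_grid(eig, dgrid, rates))
    sum(apply(LL, 1L, max))
  }
  opt <- stats::optimize(profll, log(c(0.2, 100)), maximum = TRUE, tol = 1e-3)
  hky_params(exp(opt$maximum), pi, gamma_shape)
}

# ---------------------------------------------------------------------------
# Matrix combination

# align a list of partial matrices to the union taxon set
.expand_to_union <- function(coll) {
  taxa <- sort(unique(unlist(lapply(coll, rownames))))
  lapply(coll, function(dm) {
    out <- matrix(NA_real_, length(taxa), length(taxa),
                  dimnames = list(taxa, taxa))
    out[rownames(dm), colnames(dm)] <- dm
    diag(out) <- 0
    attr(out, "gene") <- attr(dm, "gene")
    out
  })
}

#' Average-consensus combination of distance matrices
#'
#' Combines per-gene partial distance matrices by averaging, for each taxon
#' pair, the distances of all genes covering that pair. Pairs covered by no
#' gene stay absent (`NA`).
#'
#' @param coll List of partial distance matrices (symmetric, `NA` for absent
#'   pairs, taxon dimnames).
#' @return A partial distance matrix on the union taxon set.
#' @export
average_consensus <- function(coll) {
  if (!length(coll)) .stopf("empty collection")
  lapply(coll, .check_pdm)
  ex <- .expand_to_union(coll)
  n <- nrow(ex[[1L]])
  sum_ <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (dm in ex) {
    ok <- !is.na(dm)
    sum_[ok] <- sum_[ok] + dm[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- sum_ / cnt
  out[cnt == 0L] <- NA_real_
  dimnames(out) <- dimnames(ex[[1L]])
  diag(out) <- 0
  out
}

#' Super-distance-matrix (SDM) combination
#'
#' Combines per-gene partial distance matrices by jointly fitting a scale
#' factor \eqn{\alpha_g} per gene and (optionally) an additive constant
#' \eqn{a_{g,i}} per taxon per gene, minimizing the dispersion
#' \deqn{\sum_g \sum_{i<j \in g} (\alpha_g D^g_{ij} + a_{g,i} + a_{g,j} - X_{ij})^2}
#' over the scalings, shifts and the consensus matrix X, subject to the
#' normalization \eqn{\sum_g w_g \alpha_g = \sum_g w_g} with \eqn{w_g} the
#' number of available pairs in gene g (fixing the overall scale). The
#' problem is linear least squares and is solved exactly; rank-deficient
#' systems fall back to the minimum-norm solution with a warning. The
#' average-consensus solution (\eqn{\alpha = 1}, \eqn{a = 0}) is feasible, so
#' the SDM objective is never worse than the AvCon objective.
#'
#' @inheritParams average_consensus
#' @param shifts Fit the per-taxon additive constants as well? Default
#'   `TRUE`; `FALSE` fits scale factors only.
#' @return An object of class `sdm_solution`: list with the combined partial
#'   matrix `X`, per-gene `alpha`, per-gene-per-taxon `shifts`, the attained
#'   `objective` and the `objective_avcon` of the plain-average solution.
#' @export
sdm_combine <- function(coll, shifts = TRUE) {
  if (!length(coll)) .stopf("empty collection")
  lapply(coll, .check_pdm)
  ex <- .expand_to_union(coll)
  taxa <- rownames(ex[[1L]])
  n <- length(taxa)
  G <- length(ex)
  ut <- upper.tri(ex[[1L]])
  # observation rows: one per (gene, available pair)
  obs <- list()
  for (g in seq_len(G)) {
    dm <- ex[[g]]
    av <- which(ut & !is.na(dm), arr.ind = TRUE)
    if (!nrow(av)) .stopf("gene %d has no available pairs", g)
    obs[[g]] <- cbind(g = g, i = av[, 1L], j = av[, 2L],
                      d = dm[av], pair = (av[, 1L] - 1L) * n + av[, 2L])
  }
  O <- do.call(rbind, obs)
  m <- nrow(O)
  w_g <- tabulate(O[, "g"], nbins = G)
  # parameters: alpha (G) then, if shifts, a_{g,i} for taxa present in gene g
  par_a <- integer(0)
  if (shifts) {
    pres <- unique(rbind(cbind(O[, "g"], O[, "i"]), cbind(O[, "g"], O[, "j"])))
    pres <- pres[order(pres[, 1L], pres[, 2L]), , drop = FALSE]
    a_index <- stats::setNames(G + seq_len(nrow(pres)),
                               paste(pres[, 1L], pres[, 2L]))
  } else {
    pres <- matrix(0L, 0L, 2L)
    a_index <- stats::setNames(integer(0), character(0))
  }
  npar <- G + nrow(pres)
  B <- matrix(0, m, npar)
  B[cbind(seq_len(m), O[, "g"])] <- O[, "d"]
  if (shifts) {
    B[cbind(seq_len(m), a_index[paste(O[, "g"], O[, "i"])])] <-
      B[cbind(seq_len(m), a_index[paste(O[, "g"], O[, "i"])])] + 1
    B[cbind(seq_len(m), a_index[paste(O[, "g"], O[, "j"])])] <-
      B[cbind(seq_len(m), a_index[paste(O[, "g"], O[, "j"])])] + 1
  }
  # residual projector: objective = || (I - H) B theta ||^2 where H averages
  # observations of the same pair (X is profiled out)
  pair_f <- match(O[, "pair"], unique(O[, "pair"]))
  k_pair <- tabulate(pair_f)
  center <- function(M) {
    M - apply(M, 2L, function(col) (rowsum(col, pair_f) / k_pair)[pair_f])
  }
  Bc <- center(B)
  Q <- crossprod(Bc)
  cvec <- c(w_g, rep(0, npar - G))
  KKT <- rbind(cbind(2 * Q, cvec), c(cvec, 0))
  rhs <- c(rep(0, npar), sum(w_g))
  theta <- tryCatch(solve(KKT, rhs)[seq_len(npar)],
                    error = function(e) {
                      .warnf("rank-deficient SDM system: using minimum-norm solution")
                      (MASS::ginv(KKT) %*% rhs)[seq_len(npar)]
                    })
  alpha <- theta[seq_len(G)]
  yhat <- as.vector(B %*% theta)
  xbar <- (rowsum(yhat, pair_f) / k_pair)[pair_f]
  objective <- sum((yhat - xbar)^2)
  # AvCon reference objective under the same constraint set
  y0 <- O[, "d"]
  x0 <- (rowsum(y0, pair_f) / k_pair)[pair_f]
  objective_avcon <- sum((y0 - x0)^2)
  X <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  diag(X) <- 0
  xb_pair <- rowsum(yhat, pair_f) / k_pair
  up <- unique(O[, "pair"])
  X[up] <- xb_pair  # linear indices fall in the lower triangle
  X[X < 0] <- 0     # shifts can push tiny distances below zero
  X[upper.tri(X)] <- t(X)[upper.tri(X)]
  shifts_m <- matrix(0, G, n, dimnames = list(NULL, taxa))
  if (shifts && nrow(pres)) {
    shifts_m[pres] <- theta[-seq_len(G)]
  }
  structure(list(X = X, alpha = alpha, shifts = shifts_m,
                 objective = objective, objective_avcon = objective_avcon),
            class = "sdm_solution")
}

#' @export
print.sdm_solution <- function(x, ...) {
  cat(sprintf("SDM combination of %d matrices: objective %.6g (plain average: %.6g)\n",
              length(x$alpha), x$objective, x$objective_avcon))
  cat("  scale factors:", paste(sprintf("%.3f", x$alpha), collapse = " "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tree fitting from (partial) distances

.coverage_components <- function(dm) {
  n <- nrow(dm)
  av <- which(upper.tri(dm) & !is.na(dm), arr.ind = TRUE)
  grp <- .merge_groups(rownames(dm), rownames(dm)[av[, 1L]], rownames(dm)[av[, 2L]])
  split(rownames(dm), grp)
}

#' Complete a partial distance matrix by shortest paths
#'
#' Fills absent entries with the shortest-path distance through available
#' entries (used to obtain starting trees; imputed entries carry no weight
#' in the Fitch-Margoliash objective itself).
#'
#' @param dm Partial distance matrix.
#' @return A complete distance matrix.
#' @export
impute_distances <- function(dm) {
  .check_pdm(dm)
  if (!anyNA(dm)) return(dm)
  comp <- .coverage_components(dm)
  if (length(comp) > 1L) {
    .stopf("coverage graph is disconnected: components {%s}",
           paste(vapply(comp, function(c) paste(c, collapse = ","), ""),
                 collapse = "} {"))
  }
  av <- which(upper.tri(dm) & !is.na(dm), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(dm)[av[, 1L]], to = rownames(dm)[av[, 2L]],
               weight = dm[av]),
    directed = FALSE, vertices = rownames(dm))
  sp <- igraph::distances(g)
  out <- sp[rownames(dm), colnames(dm)]
  keep <- !is.na(dm)
  out[keep] <- dm[keep]
  attr(out, "gene") <- attr(dm, "gene")
  out
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining ([ape::nj()]) with negative branch lengths
#' clamped to zero. The matrix must be complete; impute absent entries first
#' (see [impute_distances()]).
#'
#' @param dm Complete distance matrix with taxon dimnames.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(dm) {
  .check_pdm(dm)
  if (anyNA(dm[upper.tri(dm)])) {
    .stopf("distance matrix has missing entries; impute them first (impute_distances)")
  }
  n <- nrow(dm)
  if (n < 3L) .stopf("need at least 3 taxa")
  if (n == 3L) {
    lab <- rownames(dm)
    e <- c((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2,
           (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2,
           (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
    tr <- parse_newick(sprintf("(%s:%g,%s:%g,%s:%g);",
                               lab[1], max(e[1], 0), lab[2], max(e[2], 0),
                               lab[3], max(e[3], 0)))
    return(tr)
  }
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Weighted least-squares branch fit of a fixed topology to available entries.
# Returns list(objective, lengths, edge_split) with negative lengths clamped.
.fm_fit <- function(topo, dm, w) {
  labs <- rownames(dm)
  tr <- ape::reorder.phylo(topo, "postorder")
  nt <- length(tr$tip.label)
  ne <- nrow(tr$edge)
  # tips below each edge (matrix ne x nt over dm's taxon order)
  below <- matrix(FALSE, nt + tr$Nnode, nt)
  ord <- match(tr$tip.label, labs)
  for (v in seq_len(nt)) below[v, ord[v]] <- TRUE
  for (k in seq_len(ne)) {
    below[tr$edge[k, 1L], ] <- below[tr$edge[k, 1L], ] | below[tr$edge[k, 2L], ]
  }
  Bt <- below[tr$edge[, 2L], , drop = FALSE] * 1  # ne x nt
  av <- which(upper.tri(dm) & !is.na(dm), arr.ind = TRUE)
  A <- t(abs(Bt[, av[, 1L], drop = FALSE] - Bt[, av[, 2L], drop = FALSE]))
  d <- dm[av]
  wv <- w[av]
  M <- crossprod(A * sqrt(wv))
  rhs <- crossprod(A, wv * d)
  b <- tryCatch(as.vector(solve(M, rhs)),
                error = function(e) as.vector(MASS::ginv(M) %*% rhs))
  b[b < 0] <- 0
  r <- d - as.vector(A %*% b)
  list(objective = sum(wv * r * r), lengths = b, tree = tr)
}

#' Fitch-Margoliash least-squares tree from a partial distance matrix
#'
#' Finds a tree minimizing the weighted least-squares criterion
#' \deqn{\sum_{ij\ available} (D_{ij} - d_{ij}(T))^2 / D_{ij}^2}
#' over topologies (seeded NNI hill climbing from a neighbor-joining start on
#' the shortest-path-completed matrix) and branch lengths (weighted least
#' squares per topology, negative lengths clamped to zero). Only available
#' entries enter the objective; imputed entries only seed the start tree.
#' Entries with \eqn{D_{ij} = 0} get their squared-distance weight floored at
#' \eqn{10^{-6}}.
#'
#' When the distances carry unequal amounts of data (e.g. pairwise overlap
#' lengths in a gappy superalignment), a matrix of relative replicate
#' `weights` can be supplied; each pair's weight becomes
#' \eqn{w_{ij} / D_{ij}^2} (the replicate-weighted criterion of classic
#' least-squares fitters).
#'
#' @param dm Partial distance matrix (coverage graph must be connected).
#' @param config A [search_config()]; restarts beyond the first use random
#'   starting topologies.
#' @param weights Optional nonnegative matrix of relative replicate weights,
#'   same shape as `dm`; default all-1.
#' @param power Exponent of the denominator \eqn{D_{ij}^{power}} (the
#'   classic least-squares Power option): 2 is the Fitch-Margoliash
#'   criterion, 1 approximates inverse-variance weighting of ML distances,
#'   0 is ordinary least squares.
#' @return An unrooted `phylo` with fitted branch lengths;
#'   `attr(, "objective")` holds the attained criterion value.
#' @export
fm_tree <- function(dm, config = search_config(n_restarts = 1L),
                    weights = NULL, power = 2) {
  .check_pdm(dm)
  n <- nrow(dm)
  if (n < 4L) .stopf("need at least 4 taxa")
  w <- 1 / pmax(dm^power, 1e-6)
  if (!is.null(weights)) {
    if (!identical(dim(weights), dim(dm))) .stopf("'weights' shape mismatch")
    w <- w * weights
  }
  full <- impute_distances(dm)  # also errors on disconnected coverage
  run <- function() {
    starts <- list(nj_tree(full))
    if (config$n_restarts > 1L) {
      for (r in seq_len(config$n_restarts - 1L)) {
        starts[[length(starts) + 1L]] <- .random_topology(rownames(dm))
      }
    }
    best <- NULL
    for (st in starts) {
      st$edge.length <- NULL
      res <- .nni_hillclimb(st, function(tr) .fm_fit(tr, dm, w)$objective)
      if (is.null(best) || res$score < best$score - 1e-12) best <- res
    }
    best
  }
  best <- with_seed(config$seed, run())
  fit <- .fm_fit(best$tree, dm, w)
  out <- fit$tree
  out$edge.length <- fit$lengths
  attr(out, "objective") <- fit$objective
  out
}

# ---------------------------------------------------------------------------
# Superalignment

#' Concatenate gene alignments into a superalignment
#'
#' Builds one alignment over the union taxon set; gene x taxon blocks with no
#' sequence are filled with missing states (gaps). The per-gene coordinate
#' map is retained in `attr(, "gene_map")` for gene-aware column resampling.
#'
#' @param alns List of [gene_alignment()] objects with unique gene ids.
#' @param taxa Optional taxon set to use; must be covered by at least one
#'   gene each. Defaults to the union of the genes' taxa.
#' @return A [gene_alignment()] of total length equal to the summed gene
#'   lengths.
#' @export
concatenate <- function(alns, taxa = NULL) {
  if (!length(alns)) .stopf("empty alignment list")
  ids <- vapply(alns, `[[`, character(1L), "gene")
  if (anyDuplicated(ids)) {
    .stopf("duplicate gene ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  union_taxa <- sort(unique(unlist(lapply(alns, function(a) rownames(a$seqs)))))
  if (is.null(taxa)) taxa <- union_taxa else {
    bad <- setdiff(taxa, union_taxa)
    if (length(bad)) .stopf("taxa present in no gene: %s", paste(bad, collapse = ", "))
    taxa <- sort(taxa)
  }
  lens <- vapply(alns, function(a) ncol(a$seqs), 0L)
  total <- sum(lens)
  m <- matrix(NA_integer_, length(taxa), total, dimnames = list(taxa, NULL))
  at <- 0L
  map <- data.frame(gene = ids, start = integer(length(alns)), end = integer(length(alns)))
  for (k in seq_along(alns)) {
    a <- alns[[k]]
    rows <- intersect(rownames(a$seqs), taxa)
    m[rows, at + seq_len(lens[k])] <- a$seqs[rows, , drop = FALSE]
    map$start[k] <- at + 1L; map$end[k] <- at + lens[k]
    at <- at + lens[k]
  }
  out <- gene_alignment(m, gene = "superalignment")
  attr(out, "gene_map") <- map
  out
}

#' Superalignment tree (early-level combination)
#'
#' Concatenates the gene alignments, computes pairwise ML distances on the
#' superalignment (each pair scored over its mutually determined sites) and
#' fits the tree by weighted least squares. Each distance is weighted by its
#' pairwise overlap length (its replicate count) divided by the distance
#' (Power option 1), approximating inverse-variance weighting of ML
#' distances, so that well-supported long-overlap distances dominate sparse
#' ones.
#'
#' @inheritParams concatenate
#' @param model An [hky_params()] for the distance estimation.
#' @param config A [search_config()] for the tree search.
#' @return An unrooted `phylo`.
#' @export
superalignment_tree <- function(alns, model = hky_params(),
                                config = search_config(n_restarts = 1L)) {
  sa <- concatenate(alns)
  dm <- ml_pairwise_distances(sa, model)
  fm_tree(dm, config, weights = attr(dm, "n_sites"), power = 1)
}
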