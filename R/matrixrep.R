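# Matrix representation of source trees (Baum/Ragan and Purvis coding) and
# supertree estimation by optimizing parsimony (Fitch), irreversible
# Camin-Sokal parsimony, flip distance (MRF) or column compatibility (MRC)
# over tree space with seeded NNI hill climbing.

#' Matrix representation of a set of source trees
#'
#' An `mr_matrix` holds the binary coding of a collection of source trees:
#' one row per taxon (union of all source-tree leaf sets), one column per
#' coded edge/node, states 0/1 with `NA` for `?` (taxon absent from the
#' source tree). Constructed by [encode_br()] or [encode_pu()].
#'
#' @param mat Integer matrix (taxa x columns) with entries 0, 1 or `NA`;
#'   rownames are taxon labels.
#' @param provenance Data frame with one row per column: source-tree index
#'   and coded node number.
#' @return An object of class `mr_matrix`.
#' @export
mr_matrix <- function(mat, provenance = NULL) {
  if (!is.matrix(mat) || is.null(rownames(mat))) {
    .stopf("'mat' must be a matrix with taxon rownames")
  }
  storage.mode(mat) <- "integer"
  ok <- mat %in% c(0L, 1L, NA)
  if (!all(ok)) .stopf("matrix entries must be 0, 1 or NA ('?')")
  structure(list(taxa = rownames(mat), mat = mat, provenance = provenance),
            class = "mr_matrix")
}

#' @export
print.mr_matrix <- function(x, ...) {
  cat(sprintf("Matrix representation: %d taxa x %d columns (%.1f%% '?')\n",
              nrow(x$mat), ncol(x$mat), 100 * mean(is.na(x$mat))))
  invisible(x)
}

#' @export
dim.mr_matrix <- function(x) dim(x$mat)

# keep only informative columns: >= 2 definite 1s and >= 1 definite 0
.mr_filter <- function(mat, prov) {
  if (!ncol(mat)) return(list(mat = mat, prov = prov))
  ones <- colSums(mat == 1L, na.rm = TRUE)
  zeros <- colSums(mat == 0L, na.rm = TRUE)
  keep <- ones >= 2L & zeros >= 1L
  list(mat = mat[, keep, drop = FALSE], prov = prov[keep, , drop = FALSE])
}

.mr_assemble <- function(cols) {
  taxa <- sort(unique(unlist(lapply(cols, function(c) names(c$states)))))
  mat <- matrix(NA_integer_, length(taxa), length(cols),
                dimnames = list(taxa, NULL))
  prov <- data.frame(tree = integer(length(cols)), node = integer(length(cols)))
  for (j in seq_along(cols)) {
    mat[names(cols[[j]]$states), j] <- cols[[j]]$states
    prov$tree[j] <- cols[[j]]$tree
    prov$node[j] <- cols[[j]]$node
  }
  f <- .mr_filter(mat, prov)
  mr_matrix(f$mat, f$prov)
}

#' Baum/Ragan matrix representation
#'
#' Codes every interior edge of every source tree as one binary column: taxa
#' on one side of the edge get 1, taxa on the other side 0, and taxa absent
#' from that source tree get `?` (`NA`). For rooted trees the root side is
#' always coded 0, so each column is the cluster below the edge. For unrooted
#' trees the orientation is canonicalized: the block not containing the
#' lexicographically smallest leaf of the tree is coded 1 (Fitch parsimony is
#' orientation-invariant). Uninformative columns are dropped.
#'
#' @param trees A list of `phylo` objects (rooted or unrooted) with
#'   overlapping leaf sets.
#' @return An [mr_matrix()].
#' @examples
#' m <- encode_br(list(parse_newick("(B,(C,(A,D)));")))
#' m$mat   # rows A=1,1  B=0,0  C=1,0  D=1,1
#' @export
encode_br <- function(trees) {
  trees <- .as_treelist(trees)
  cols <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    .check_phylo(tr)
    labs <- tr$tip.label
    n <- length(labs)
    n_before <- length(cols)
    if (n >= 3L) {
      rooted <- ape::is.rooted(tr)
      pp <- ape::prop.part(tr)
      node_ids <- seq.int(n + 1L, n + tr$Nnode)
      ref <- min(labs)
      seen <- character(0L)
      for (k in seq_along(pp)) {
        cl <- labs[pp[[k]]]
        sz <- length(cl)
        if (sz >= n) next                      # root cluster: no edge above
        if (rooted) {
          if (sz < 2L) next                    # leaf edges are uninformative
          states <- stats::setNames(integer(n), labs)
          states[cl] <- 1L
        } else {
          if (sz <= 1L || sz >= n - 1L) next   # trivial split
          blk <- if (ref %in% cl) setdiff(labs, cl) else cl
          key <- .key(blk)
          if (key %in% seen) next              # both root children give one split
          seen <- c(seen, key)
          states <- stats::setNames(integer(n), labs)
          states[blk] <- 1L
        }
        cols[[length(cols) + 1L]] <- list(states = states, tree = i,
                                          node = node_ids[k])
      }
    }
    if (length(cols) == n_before) {
      .warnf("source tree %d contributes no informative columns", i)
    }
  }
  .mr_assemble(cols)
}

#' Purvis matrix representation
#'
#' Codes every interior node of every rooted source tree as one column: the
#' descendants of the node get 1, the node's sister group gets 0 and all
#' other taxa of the tree get `?`, aiming to remove the redundancy of the
#' Baum/Ragan coding. Taxa absent from a source tree are `?` as always.
#' Uninformative columns (such as the root's, which has no sister) are
#' dropped. A Purvis matrix never has fewer `?` entries than the Baum/Ragan
#' matrix of the same trees.
#'
#' @param trees A list of rooted `phylo` objects.
#' @return An [mr_matrix()].
#' @examples
#' m <- encode_pu(list(parse_newick("(B,(C,(A,D)));")))
#' m$mat   # rows A=1,1  B=0,NA  C=1,0  D=1,1
#' @export
encode_pu <- function(trees) {
  trees <- .as_treelist(trees)
  cols <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    .check_phylo(tr)
    if (!ape::is.rooted(tr)) .stopf("Purvis coding requires rooted trees (tree %d)", i)
    labs <- tr$tip.label
    n <- length(labs)
    if (n < 3L) { .warnf("source tree %d contributes no informative columns", i); next }
    tr2 <- ape::reorder.phylo(tr, "postorder")
    # leaf descendants per node
    desc <- vector("list", n + tr2$Nnode)
    for (v in seq_len(n)) desc[[v]] <- labs[v]
    for (e in seq_len(nrow(tr2$edge))) {
      p <- tr2$edge[e, 1L]; ch <- tr2$edge[e, 2L]
      desc[[p]] <- c(desc[[p]], desc[[ch]])
    }
    children <- split(tr2$edge[, 2L], tr2$edge[, 1L])
    for (v in seq.int(n + 1L, n + tr2$Nnode)) {
      par <- tr2$edge[match(v, tr2$edge[, 2L]), 1L]
      if (is.na(par)) next  # root: no sister group -> uninformative column
      sibs <- setdiff(children[[as.character(par)]], v)
      states <- stats::setNames(rep(NA_integer_, n), labs)
      states[desc[[v]]] <- 1L
      states[unlist(desc[sibs])] <- 0L
      cols[[length(cols) + 1L]] <- list(states = states, tree = i, node = v)
    }
  }
  .mr_assemble(cols)
}

# ---------------------------------------------------------------------------
# Column scoring against a tree. All scorers are vectorized across columns.

# Fitch parsimony length per column; '?' is the full state set. Exact for
# binary trees (the only trees the search visits).
.score_fitch <- function(tree, mat) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  m <- mat[tr$tip.label, , drop = FALSE]
  s <- m + 1L
  s[is.na(s)] <- 3L
  .fitch_counts_cpp(tr$edge, nt, tr$Nnode, s)
}

# Camin-Sokal irreversible parsimony per column on a rooted tree: the root is
# in state 0 and only 0 -> 1 changes are allowed; '?' is free.
.score_camin_sokal <- function(tree, mat) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  m <- mat[tr$tip.label, , drop = FALSE]
  .cs_counts_cpp(tr$edge, nt, tr$Nnode, m)
}

# Non-trivial split blocks of a tree (both orientations) for flip/compat
# scoring; the trivial candidate sets are handled in closed form by the C
# kernel. Rows follow tree$tip.label order.
.flip_candidates <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  pp <- ape::prop.part(tree)
  keep <- list()
  for (cl in pp) {
    sz <- length(cl)
    if (sz <= 1L || sz >= n - 1L) next
    v <- logical(n); v[cl] <- TRUE
    keep[[length(keep) + 1L]] <- v
  }
  B <- if (length(keep)) do.call(cbind, keep) else matrix(FALSE, n, 0L)
  if (ncol(B)) B <- B[, !duplicated(t(B)), drop = FALSE]
  Cl <- cbind(B, !B)
  rownames(Cl) <- labs
  storage.mode(Cl) <- "integer"
  Cl
}

# Minimum definite-entry flips per column so its 1-set ('?' free) becomes a
# split block of the tree or a trivial set.
.score_flip <- function(tree, mat) {
  Cl <- .flip_candidates(tree)
  m <- mat[rownames(Cl), , drop = FALSE]
  ones <- matrix(as.integer((!is.na(m)) & m == 1L), nrow(m))
  zeros <- matrix(as.integer((!is.na(m)) & m == 0L), nrow(m))
  .flip_counts_cpp(Cl, ones, zeros)
}

#' Score a matrix representation against a tree
#'
#' Evaluates how well a candidate supertree explains an [mr_matrix()] under
#' one of four objectives:
#' \describe{
#'   \item{`fitch`}{total Fitch parsimony length over columns, with `?`
#'     treated as the full state set (minimized by MRP with Baum/Ragan or
#'     Purvis coding);}
#'   \item{`camin_sokal`}{total irreversible parsimony length: only 0 to 1
#'     changes, the all-0 state at the root (requires a rooted tree; the MRP
#'     variant exploiting root information);}
#'   \item{`flip`}{total minimum number of definite-entry flips making each
#'     column's 1-set (with `?` assigned freely) a split block of the tree or
#'     a trivial set (MRF);}
#'   \item{`compat`}{number of columns requiring zero flips, i.e. congruent
#'     with the tree (MRC; maximized).}
#' }
#' `flip` is 0 exactly when `compat` equals the column count. Scores are
#' invariant under taxon reordering and column permutation.
#'
#' @param matrix An [mr_matrix()].
#' @param tree A `phylo` whose leaf set equals the matrix taxa; binary trees
#'   give exact Fitch scores. Must be rooted for `camin_sokal`.
#' @param objective One of `"fitch"`, `"camin_sokal"`, `"flip"`, `"compat"`.
#' @param per_column Return the per-column vector instead of the total?
#' @return A single number (or per-column vector).
#' @export
mr_score <- function(matrix, tree,
                     objective = c("fitch", "camin_sokal", "flip", "compat"),
                     per_column = FALSE) {
  objective <- match.arg(objective)
  if (!inherits(matrix, "mr_matrix")) .stopf("'matrix' must be an 'mr_matrix'")
  .check_phylo(tree)
  if (!setequal(tree$tip.label, matrix$taxa)) {
    .stopf("tree leaf set does not match matrix taxa")
  }
  if (objective == "camin_sokal" && !ape::is.rooted(tree)) {
    .stopf("camin_sokal scoring requires a rooted tree")
  }
  v <- switch(objective,
    fitch = .score_fitch(tree, matrix$mat),
    camin_sokal = .score_camin_sokal(tree, matrix$mat),
    flip = .score_flip(tree, matrix$mat),
    compat = as.numeric(.score_flip(tree, matrix$mat) == 0)
  )
  if (per_column) v else sum(v)
}

#' Heuristic search configuration
#'
#' Settings for the seeded NNI hill-climbing searches used by
#' [mr_supertree()] and [fm_tree()]: number of random restarts, RNG seed and
#' the move set (NNI only).
#'
#' @param n_restarts Number of random starting trees (>= 1).
#' @param seed Integer seed making the search deterministic, or `NULL`.
#' @param move_set Currently only `"NNI"` (plus single-taxon repositioning
#'   sweeps).
#' @param n_ratchet Weight-perturbation (ratchet) rounds per restart in
#'   [mr_supertree()]; 0 disables.
#' @param max_no_improve Unused placeholder (search stops at a local
#'   optimum); kept for forward compatibility.
#' @return An object of class `search_config`.
#' @export
search_config <- function(n_restarts = 2L, seed = NULL, move_set = "NNI",
                          n_ratchet = 3L, max_no_improve = 0L) {
  if (n_restarts < 1L) .stopf("'n_restarts' must be >= 1")
  move_set <- match.arg(move_set, "NNI")
  structure(list(n_restarts = as.integer(n_restarts), seed = seed,
                 move_set = move_set, n_ratchet = as.integer(n_ratchet),
                 max_no_improve = as.integer(max_no_improve)),
            class = "search_config")
}

# random unrooted binary topology on a label set
.random_topology <- function(taxa) {
  tr <- ape::rtree(length(taxa), rooted = FALSE, br = NULL)
  tr$tip.label <- sample(taxa)
  tr
}

# First-improvement NNI hill climbing from `start`, minimizing score_fun.
.nni_hillclimb <- function(start, score_fun) {
  cur <- start
  cur_score <- score_fun(cur)
  repeat {
    nbs <- phangorn::nni(cur)
    improved <- FALSE
    for (k in seq_along(nbs)) {
      nb <- nbs[[k]]  # [[ restores tip labels of compressed multiPhylo
      s <- score_fun(nb)
      if (s < cur_score - 1e-12) {
        cur <- nb; cur_score <- s; improved <- TRUE
        break  # first improvement
      }
    }
    if (!improved) break
  }
  list(tree = cur, score = cur_score)
}

# Insert a new tip in the middle of edge k of a (topology-only) phylo,
# keeping ape's node-numbering convention. Much cheaper than bind.tree.
.insert_tip <- function(base, k, label) {
  n <- length(base$tip.label)
  e <- base$edge
  e[e > n] <- e[e > n] + 1L           # shift internal ids for the new tip
  w <- n + base$Nnode + 2L            # the new internal node
  u <- e[k, 1L]; v <- e[k, 2L]
  e[k, ] <- c(u, w)
  e <- rbind(e, c(w, v), c(w, n + 1L))
  structure(list(edge = e, tip.label = c(base$tip.label, label),
                 Nnode = base$Nnode + 1L),
            class = "phylo")
}

# One sweep of single-taxon repositioning: each leaf is pruned and re-grafted
# on the best edge (tip-restricted SPR). Escapes the shallow local optima NNI
# alone leaves on '?'-rich matrices.
.reinsert_sweep <- function(cur, cur_score, score_fun) {
  for (tip in sort(cur$tip.label)) {
    if (length(cur$tip.label) <= 4L) break
    base <- ape::drop.tip(cur, tip)
    base$edge.length <- NULL
    best <- cur; best_score <- cur_score
    for (k in seq_len(nrow(base$edge))) {
      cand <- .insert_tip(base, k, tip)
      s <- score_fun(cand)
      if (s < best_score - 1e-12) { best <- cand; best_score <- s }
    }
    cur <- best; cur_score <- best_score
  }
  list(tree = cur, score = cur_score)
}

# Full climb: alternate NNI descent and reinsertion sweeps to convergence.
.mr_climb <- function(start, score_fun) {
  res <- .nni_hillclimb(start, score_fun)
  repeat {
    swept <- .reinsert_sweep(res$tree, res$score, score_fun)
    if (swept$score >= res$score - 1e-12) break
    res <- .nni_hillclimb(swept$tree, score_fun)
    if (res$score >= swept$score - 1e-12) { res <- swept; break }
  }
  res
}

#' Matrix-representation supertree
#'
#' Estimates the supertree optimizing [mr_score()] (minimizing `fitch`,
#' `camin_sokal` or `flip`; maximizing `compat`) by seeded heuristic search:
#' each restart builds a stepwise random-addition parsimony starting tree
#' (classic random addition sequence) and polishes it by first-improvement
#' NNI hill climbing under the target objective. If several distinct best
#' topologies are found across restarts, their strict consensus is returned
#' (the usual co-optimum rule).
#'
#' With `root = TRUE` an all-0 hypothetical ancestor row (the `R` row of the
#' classic worked example) is appended and attached as outgroup, the search
#' runs over rooted topologies, and the result is rooted. This polarizes the
#' columns and is essential for Purvis-coded matrices, whose `?`-rich
#' columns constrain little in a purely unrooted analysis; `camin_sokal`
#' implies it.
#'
#' @inheritParams mr_score
#' @param config A [search_config()].
#' @param root Append the all-0 ancestral row and return a rooted tree?
#'   Forced `TRUE` for `camin_sokal`; recommended for Purvis-coded matrices.
#' @return A `phylo` on the matrix taxa (rooted if `root = TRUE`).
#' @export
mr_supertree <- function(matrix,
                         objective = c("fitch", "camin_sokal", "flip", "compat"),
                         config = search_config(), root = FALSE) {
  objective <- match.arg(objective)
  if (!inherits(matrix, "mr_matrix")) .stopf("'matrix' must be an 'mr_matrix'")
  taxa <- matrix$taxa
  if (length(taxa) < 4L) .stopf("need at least 4 taxa")
  if (ncol(matrix$mat) == 0L) {
    .warnf("empty matrix representation: returning the star tree")
    return(.tree_from_clusters(taxa, character(0L)))
  }
  rooted_search <- root || objective == "camin_sokal"
  ROOT <- ".mr.root."
  mat <- matrix$mat
  if (rooted_search) {
    mat <- rbind(mat, rep(0L, ncol(mat)))
    rownames(mat)[nrow(mat)] <- ROOT
    search_taxa <- c(taxa, ROOT)
  } else {
    search_taxa <- taxa
  }
  # compress duplicate columns; score sums are weighted by multiplicity
  key <- apply(mat, 2L, paste, collapse = ".")
  first <- !duplicated(key)
  wc <- as.vector(table(key)[key[first]])
  matc <- mat[, first, drop = FALSE]
  # per-column contribution, oriented so that smaller is always better; the
  # flip objectives reuse precomputed definite-entry masks across evaluations
  if (objective %in% c("flip", "compat")) {
    taxa_order <- rownames(matc)
    onesI <- matrix(as.integer((!is.na(matc)) & matc == 1L), nrow(matc))
    zerosI <- matrix(as.integer((!is.na(matc)) & matc == 0L), nrow(matc))
    flipcol <- function(tr) {
      Cl <- .flip_candidates(tr)[taxa_order, , drop = FALSE]
      .flip_counts_cpp(Cl, onesI, zerosI)
    }
  }
  percol <- switch(objective,
    fitch = function(tr) .score_fitch(tr, matc),
    camin_sokal = function(tr) .score_camin_sokal(root_at(tr, ROOT), matc),
    flip = flipcol,
    compat = function(tr) -(flipcol(tr) == 0))
  mkscore <- function(w) function(tr) sum(w * percol(tr))
  score_fun <- mkscore(wc)
  ch <- ifelse(is.na(mat), "?", as.character(mat))
  pd <- phangorn::phyDat(ch, type = "USER", levels = c("0", "1"),
                         ambiguity = "?")
  run <- function() {
    best <- NULL
    for (r in seq_len(config$n_restarts)) {
      start <- phangorn::random.addition(pd)
      start$edge.length <- NULL
      res <- .mr_climb(start, score_fun)
      # ratchet rounds: NNI-climb under perturbed column weights, then
      # re-climb under the true weights; keep improvements. The expensive
      # repositioning sweeps run only at the start and as a final polish.
      for (i in seq_len(config$n_ratchet)) {
        w2 <- wc * (1 + (stats::runif(length(wc)) < 0.25))
        pert <- .nni_hillclimb(res$tree, mkscore(w2))
        back <- .nni_hillclimb(pert$tree, score_fun)
        if (back$score < res$score - 1e-12) res <- back
      }
      res <- .mr_climb(res$tree, score_fun)
      if (is.null(best) || res$score < best$score - 1e-12) {
        best <- res
        best$trees <- list(res$tree)
      } else if (abs(res$score - best$score) <= 1e-12) {
        best$trees <- c(best$trees, list(res$tree))
      }
    }
    best
  }
  best <- with_seed(config$seed, run())
  finalize <- function(tr) {
    if (rooted_search) {
      tr <- root_at(tr, ROOT)
      tr <- ape::drop.tip(tr, ROOT)
    }
    tr
  }
  trees <- lapply(best$trees, finalize)
  keys <- vapply(trees, canonical_newick, character(1L), rooted = rooted_search)
  trees <- trees[!duplicated(keys)]
  out <- if (length(trees) == 1L) trees[[1L]] else strict_consensus(trees)
  # attained objective value (on the objective's natural scale) and the
  # number of distinct co-optimal topologies found
  attr(out, "score") <- if (objective == "compat") -best$score else best$score
  attr(out, "n_optima") <- length(trees)
  out
}

# ---------------------------------------------------------------------------
# Import/export

#' Export a matrix representation
#'
#' `write_mr_nexus()` writes a NEXUS data block (`datatype=standard`,
#' `symbols="01"`, `missing=?`); `write_mr_tsv()` writes a plain
#' tab-separated table with `?` for missing entries, and `read_mr_tsv()`
#' reads it back.
#'
#' @param x An [mr_matrix()].
#' @param file Output path.
#' @export
write_mr_nexus <- function(x, file) {
  if (!inherits(x, "mr_matrix")) .stopf("'x' must be an 'mr_matrix'")
  m <- x$mat
  rows <- apply(m, 1L, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX"), con)
  writeLines(sprintf("    %s %s", format(rownames(m)), rows), con)
  writeLines(c("  ;", "END;"), con)
  invisible(file)
}

#' @rdname write_mr_nexus
#' @export
write_mr_tsv <- function(x, file) {
  if (!inherits(x, "mr_matrix")) .stopf("'x' must be an 'mr_matrix'")
  m <- x$mat
  out <- ifelse(is.na(m), "?", as.character(m))
  utils::write.table(out, file, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_mr_nexus
#' @export
read_mr_tsv <- function(file) {
  tab <- utils::read.table(file, sep = "\t", row.names = 1L,
                           colClasses = "character")
  m <- as.matrix(tab)
  m[m == "?"] <- NA
  storage.mode(m) <- "integer"
  colnames(m) <- NULL
  mr_matrix(m)
}
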