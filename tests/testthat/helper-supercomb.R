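# Shared helpers: small fixtures and independent brute-force oracles used to
# validate the package's scorers and searches.

# random unrooted binary topology with given labels
rand_topology <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = FALSE, br = NULL)
  tr$tip.label <- sample(labels)
  tr
}

# random rooted binary topology
rand_rooted <- function(labels) {
  tr <- ape::rtree(length(labels))
  tr$edge.length <- NULL
  tr$tip.label <- sample(labels)
  tr
}

# random MR-style matrix over `taxa` with given fraction of '?'
rand_mr_matrix <- function(taxa, ncols, na_frac = 0.2) {
  n <- length(taxa)
  repeat {
    m <- matrix(sample(0:1, n * ncols, replace = TRUE), n, ncols,
                dimnames = list(taxa, NULL))
    m[matrix(stats::runif(n * ncols) < na_frac, n, ncols)] <- NA_integer_
    ones <- colSums(m == 1L, na.rm = TRUE)
    zeros <- colSums(m == 0L, na.rm = TRUE)
    if (all(ones >= 2L & zeros >= 1L)) return(mr_matrix(m))
  }
}

# Fitch oracle via phangorn parsimony (independent implementation)
oracle_fitch <- function(tree, mat) {
  ch <- ifelse(is.na(mat), "?", as.character(mat))
  pd <- phangorn::phyDat(ch, type = "USER", levels = c("0", "1"),
                         ambiguity = "?")
  phangorn::parsimony(tree, pd)
}

# Camin-Sokal oracle: enumerate all internal-node 0/1 assignments of a rooted
# binary tree (root fixed at 0) and count 0->1 edges, with 1->0 forbidden.
oracle_camin_sokal <- function(tree, mat) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  root <- nt + 1L
  m <- mat[tr$tip.label, , drop = FALSE]
  internal <- seq.int(nt + 1L, nt + nn)
  free <- setdiff(internal, root)
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  best <- rep(Inf, ncol(m))
  for (g in seq_len(max(nrow(grid), 1L))) {
    st <- integer(nt + nn)
    st[root] <- 0L
    if (length(free)) st[free] <- grid[g, ]
    for (col in seq_len(ncol(m))) {
      obs <- m[, col]
      # leaf states: enumerate '?' implicitly by taking cheapest compatible
      cost <- 0
      ok <- TRUE
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
        sp <- st[p]
        if (ch <= nt) {
          o <- obs[ch]
          sch <- if (is.na(o)) sp else o  # '?' leaf: copy parent (free)
        } else sch <- st[ch]
        if (sp == 1L && sch == 0L) { ok <- FALSE; break }
        if (sp == 0L && sch == 1L) cost <- cost + 1
      }
      if (ok && cost < best[col]) best[col] <- cost
    }
  }
  sum(best)
}

# Flip oracle: direct definition via subset enumeration. Every subset of
# taxa that is a split block of the tree or trivial is an admissible
# completed 1-set; the cost of a column is the minimal number of definite
# entries disagreeing with the nearest admissible set. Subsets are bitmasks
# over the sorted taxon labels.
.popcount <- vapply(0:4095, function(b) sum(bitwAnd(b, 2^(0:11)) > 0), 0L)

oracle_flip_sets <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  mask_of <- function(set) sum(2^(match(set, labs) - 1L))
  masks <- c(0, 2^n - 1, 2^(0:(n - 1)), (2^n - 1) - 2^(0:(n - 1)))  # trivial
  for (s in splits_of(tree)) {
    m <- mask_of(s)
    masks <- c(masks, m, (2^n - 1) - m)
  }
  unique(masks)
}

oracle_flip <- function(tree, mat, compat = FALSE, sets = NULL) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  if (is.null(sets)) sets <- oracle_flip_sets(tree)
  m <- mat[labs, , drop = FALSE]
  full <- 2^n - 1
  total <- 0
  for (col in seq_len(ncol(m))) {
    obs <- m[, col]
    ones <- sum(2^(which(!is.na(obs) & obs == 1L) - 1L))
    zeros <- sum(2^(which(!is.na(obs) & obs == 0L) - 1L))
    cost <- min(.popcount[bitwAnd(ones, bitwXor(sets, full)) + 1L] +
                  .popcount[bitwAnd(zeros, sets) + 1L])
    total <- total + (if (compat) as.numeric(cost == 0) else cost)
  }
  total
}

# does a tree display a rooted triplet string "a,b|c"? (the tree is taken
# as rooted even when its root is a polytomy)
displays_triplet <- function(tree, trip) {
  all(trip %in% extract_triplets(tree, rooted = TRUE))
}
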