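# Aho's Build algorithm and its conflict-resolving MinCut / modified MinCut
# extensions for rooted source trees. At each recursion level a weighted
# graph on the current taxon subset connects two taxa when a restricted
# source tree places them together in a proper cluster below its root; the
# connected components of that graph become the child subtrees. Build fails
# on a connected (conflicting) graph; the cut variants disconnect it by
# removing a global minimum-weight edge cut (after contracting edges that
# must, or should, be preserved).

# Restrict rooted trees to `taxa`, keeping those with >= 2 surviving leaves.
.restricted_trees <- function(trees, taxa) {
  out <- list()
  for (tr in trees) {
    keep <- intersect(tr$tip.label, taxa)
    if (length(keep) >= 2L) {
      out[[length(out) + 1L]] <-
        if (length(keep) == length(tr$tip.label)) tr else ape::keep.tip(tr, keep)
    }
  }
  out
}

# Proper clusters below the root of a rooted tree: leaf sets of the root's
# child subtrees and everything below, each of size >= 2 and < n.
.proper_clusters <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 2L) return(list())
  pp <- ape::prop.part(tree)
  cls <- lapply(pp, function(i) labs[i])
  Filter(function(cl) length(cl) >= 2L && length(cl) < n, cls)
}

# Pair bookkeeping at one recursion level. Returns a data frame of edges
# (a, b, weight, cooccur) where weight = number of restricted trees placing
# a,b together in a proper cluster and cooccur = number of restricted trees
# (with >= 3 leaves) containing both.
.build_graph <- function(rtrees, taxa) {
  w <- new.env(parent = emptyenv())
  cooc <- new.env(parent = emptyenv())
  bump <- function(env, k) assign(k, (if (exists(k, env)) get(k, env) else 0L) + 1L, env)
  for (tr in rtrees) {
    labs <- tr$tip.label
    if (length(labs) >= 3L) {
      cb <- utils::combn(sort(labs), 2L)
      for (j in seq_len(ncol(cb))) bump(cooc, paste(cb[, j], collapse = .SEP))
    }
    # taxa are "together" iff they share a root-child subtree
    root <- length(labs) + 1L
    kids <- tr$edge[tr$edge[, 1L] == root, 2L]
    pp <- ape::prop.part(tr)
    for (k in kids) {
      members <- if (k <= length(labs)) labs[k] else labs[pp[[k - length(labs)]]]
      if (length(members) >= 2L) {
        cb <- utils::combn(sort(members), 2L)
        for (j in seq_len(ncol(cb))) bump(w, paste(cb[, j], collapse = .SEP))
      }
    }
  }
  keys <- ls(w)
  if (!length(keys)) {
    return(data.frame(a = character(), b = character(),
                      weight = integer(), cooccur = integer()))
  }
  ab <- do.call(rbind, strsplit(keys, .SEP, fixed = TRUE))
  data.frame(a = ab[, 1L], b = ab[, 2L],
             weight = vapply(keys, function(k) get(k, w), 0L),
             cooccur = vapply(keys, function(k)
               if (exists(k, cooc)) get(k, cooc) else 0L, 0L),
             row.names = NULL)
}

# Does rooted tree `tr` contradict cluster `cl`? Yes iff tr displays a
# triplet xz|y with x, y in cl and z outside it, i.e. some cluster D of tr
# mixes members and non-members of cl while excluding another member.
.contradicts <- function(tr, cl) {
  inside <- intersect(tr$tip.label, cl)
  if (length(inside) < 2L) return(FALSE)
  if (!length(setdiff(tr$tip.label, cl))) return(FALSE)
  for (D in .proper_clusters(tr)) {
    din <- D %in% cl
    if (any(din) && any(!din) && !all(inside %in% D)) return(TRUE)
  }
  FALSE
}

# Decompose the current taxon set. Returns a list of components (character
# vectors) or signals incompatibility when `cut = NULL` and the graph is
# connected.
.decompose <- function(rtrees, taxa, cut) {
  edges <- .build_graph(rtrees, taxa)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(taxa))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
    igraph::E(g)$weight <- edges$weight
  }
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    return(split(names(comp$membership), comp$membership))
  }
  if (length(taxa) <= 1L) return(list(taxa))
  if (is.null(cut)) {
    .stopf("incompatible source trees: conflicting placements among {%s}",
           paste(sort(taxa), collapse = ", "))
  }
  # --- cut variants: contract protected edges, then min cut ---------------
  protect <- edges$weight == edges$cooccur & edges$cooccur > 0L  # mandatory
  if (cut == "modmincut") {
    # additionally protect pairs inside clusters uncontradicted by any tree
    prot_pairs <- character(0L)
    for (tr in rtrees) {
      for (cl in .proper_clusters(tr)) {
        ok <- !any(vapply(rtrees, .contradicts, TRUE, cl = cl))
        if (ok && length(cl) >= 2L) {
          cb <- utils::combn(sort(cl), 2L)
          prot_pairs <- c(prot_pairs, apply(cb, 2L, paste, collapse = .SEP))
        }
      }
    }
    if (length(prot_pairs)) {
      key <- paste(edges$a, edges$b, sep = .SEP)
      protect <- protect | key %in% prot_pairs
    }
  }
  # contract; if protection merges everything, progressively relax
  for (level in c("full", "mandatory", "none")) {
    pr <- switch(level,
                 full = protect,
                 mandatory = edges$weight == edges$cooccur & edges$cooccur > 0L,
                 none = rep(FALSE, nrow(edges)))
    grp <- .merge_groups(sort(taxa), edges$a[pr], edges$b[pr])
    if (length(unique(grp)) >= 2L) break
  }
  super <- split(sort(taxa), grp)
  cg <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(as.character(seq_along(super)))
  idx <- stats::setNames(rep(seq_along(super), lengths(super)), unlist(super))
  ga <- idx[edges$a]; gb <- idx[edges$b]
  keep <- ga != gb
  if (any(keep)) {
    cg <- igraph::add_edges(cg, rbind(as.character(ga[keep]), as.character(gb[keep])))
    igraph::E(cg)$weight <- edges$weight[keep]
  }
  mc <- igraph::min_cut(cg, capacity = igraph::E(cg)$weight, value.only = FALSE)
  side1 <- unlist(super[as.integer(igraph::as_ids(mc$partition1))])
  side2 <- setdiff(taxa, side1)
  # delete original edges crossing the cut, then take components
  cross <- (edges$a %in% side1) != (edges$b %in% side1)
  grp2 <- .merge_groups(sort(taxa), edges$a[!cross], edges$b[!cross])
  split(sort(taxa), grp2)
}

# union-find grouping of `items` under links a[i]-b[i]
.merge_groups <- function(items, a, b) {
  parent <- stats::setNames(seq_along(items), items)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(a)) {
    ra <- find(match(a[k], items)); rb <- find(match(b[k], items))
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_along(items), find, 0L)
}

# warn when the source trees themselves do not overlap through shared taxa
.check_tree_overlap <- function(trees) {
  if (length(trees) < 2L) return(invisible())
  ids <- as.character(seq_along(trees))
  links_a <- character(0L); links_b <- character(0L)
  for (i in seq_len(length(trees) - 1L)) {
    for (j in seq.int(i + 1L, length(trees))) {
      if (length(intersect(trees[[i]]$tip.label, trees[[j]]$tip.label))) {
        links_a <- c(links_a, ids[i]); links_b <- c(links_b, ids[j])
      }
    }
  }
  grp <- .merge_groups(ids, links_a, links_b)
  if (length(unique(grp)) > 1L) {
    .warnf("source trees fall into %d groups sharing no taxa; the groups attach at the root",
           length(unique(grp)))
  }
  invisible()
}

.build_recurse <- function(trees, taxa, cut) {
  taxa <- sort(taxa)
  if (length(taxa) == 1L) return(taxa)
  if (length(taxa) == 2L) {
    return(paste0("(", taxa[1L], ",", taxa[2L], ")"))
  }
  rtrees <- .restricted_trees(trees, taxa)
  comps <- .decompose(rtrees, taxa, cut)
  if (length(comps) == 1L) {
    # cut variants always disconnect; reaching here means <= 2 taxa handled above
    .stopf("internal error: undecomposable taxon set")
  }
  parts <- vapply(comps, function(cc) .build_recurse(trees, cc, cut), character(1L))
  parts <- parts[order(vapply(parts, function(p) min(.first_labels(p)), character(1L)))]
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Build supertree of compatible rooted trees
#'
#' Aho's Build algorithm: if the rooted source trees are compatible, returns
#' a rooted supertree on the union of their leaf sets that displays every
#' input; otherwise an incompatibility error names the offending taxon
#' subset.
#'
#' @param trees A list of rooted `phylo` objects with overlapping leaf sets.
#' @return A rooted `phylo` on the union taxon set.
#' @examples
#' tt <- lapply(c("((a,b),c);", "((c,d),e);"), parse_newick)
#' write_newick(build_supertree(tt))
#' @export
build_supertree <- function(trees) {
  trees <- .as_treelist(trees)
  for (i in seq_along(trees)) {
    if (!ape::is.rooted(trees[[i]])) .stopf("tree %d is not rooted", i)
  }
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  if (length(taxa) < 2L) .stopf("need at least 2 taxa")
  .check_tree_overlap(trees)
  nwk <- paste0(.build_recurse(trees, taxa, cut = NULL), ";")
  parse_newick(nwk)
}

#' MinCut and modified MinCut supertrees
#'
#' Conflict-tolerant extensions of Build: whenever the proper-cluster graph
#' at a recursion level is connected, edges present in every source tree
#' containing both endpoints are contracted (for `modmincut`, additionally
#' all edges inside clusters uncontradicted by any source tree), a global
#' minimum-weight edge cut of the contracted graph is removed, and the
#' recursion continues on the resulting components. The output is always a
#' rooted tree on the union taxon set; on compatible inputs it equals
#' [build_supertree()]. Deterministic given the input order (cut ties are
#' resolved by the deterministic min-cut routine).
#'
#' MinCut tends to place poorly-supported taxa near the root of subtrees
#' (Adams-consensus-like behavior); `modmincut` mitigates this by preserving
#' uncontradicted subtrees.
#'
#' @param trees A list of rooted `phylo` objects.
#' @param variant `"mincut"` or `"modmincut"`.
#' @return A rooted `phylo` on the union taxon set.
#' @export
cut_supertree <- function(trees, variant = c("mincut", "modmincut")) {
  variant <- match.arg(variant)
  trees <- .as_treelist(trees)
  for (i in seq_along(trees)) {
    if (!ape::is.rooted(trees[[i]])) .stopf("tree %d is not rooted", i)
  }
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  if (length(taxa) < 3L) {
    return(parse_newick(paste0("(", paste(taxa, collapse = ","), ");")))
  }
  .check_tree_overlap(trees)
  nwk <- paste0(.build_recurse(trees, taxa, cut = variant), ";")
  parse_newick(nwk)
}
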