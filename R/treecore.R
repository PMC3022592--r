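# Tree data model: Newick I/O, splits, Robinson-Foulds distance, consensus,
# rooting, restriction and rooted triplets. Trees are ape "phylo" objects
# throughout; a tree is treated as rooted iff ape::is.rooted() says so.

#' Parse a Newick string into a tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Quoted labels and
#' bracketed comments are accepted (comments are discarded); zero-length
#' branches are permitted. A tree is rooted iff its root has exactly two
#' children.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return A `phylo` object.
#' @examples
#' parse_newick("((A,D),C,B);")
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    .stopf("'text' must be a single Newick string")
  }
  # cheap structural check so we can report a character offset
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) .stopf("Newick parse error at character %d: unmatched ')'", i)
    }
  }
  if (depth != 0L) {
    .stopf("Newick parse error at character %d: %d unclosed '('",
           length(chars), depth)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) .stopf("Newick parse error: %s", text)
  .check_phylo(tr)
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @return A Newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  .check_phylo(tree)
  ape::write.tree(tree)
}

#' Read / write Newick tree files
#'
#' Files may contain several semicolon-terminated trees, one per line.
#'
#' @param file Path to a Newick file.
#' @return `read_newick_file()`: a list of `phylo` objects.
#' @export
read_newick_file <- function(file) {
  tr <- ape::read.tree(file)
  if (is.null(tr)) .stopf("no trees found in '%s'", file)
  .as_treelist(tr)
}

#' @rdname read_newick_file
#' @param trees A `phylo`, `multiPhylo` or list of `phylo` objects.
#' @export
write_newick_file <- function(trees, file) {
  trees <- .as_treelist(trees)
  writeLines(vapply(trees, ape::write.tree, character(1L)), file)
  invisible(file)
}

# Internal: canonical split keys of a tree (non-trivial splits only).
# Each split is represented by the block NOT containing the reference taxon
# (default: lexicographically smallest leaf), sorted and joined.
.split_keys <- function(tree, ref = NULL) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(character(0L))
  if (is.null(ref)) ref <- min(labs)
  pp <- ape::prop.part(tree)
  keys <- character(0L)
  for (cl in pp) {
    sz <- length(cl)
    if (sz <= 1L || sz >= n - 1L) next  # trivial (incl. full set at root)
    blk <- labs[cl]
    if (ref %in% blk) blk <- setdiff(labs, blk)
    keys <- c(keys, .key(blk))
  }
  unique(keys)
}

#' Non-trivial splits of a tree
#'
#' Returns the non-trivial bipartitions (splits) of the leaf set induced by
#' the internal edges of `tree`, as a list of taxon-label vectors; each
#' split is reported as its smaller block (ties broken towards the
#' lexicographically smaller block). A binary unrooted tree on n leaves has
#' exactly n - 3 such splits; polytomies yield fewer; trees with fewer than
#' 4 leaves have none.
#'
#' @param tree A `phylo` object (rooted or unrooted; rooting is ignored).
#' @return A list of character vectors, one per split.
#' @examples
#' splits_of(parse_newick("((A,D),C,B);"))
#' @export
splits_of <- function(tree) {
  .check_phylo(tree)
  labs <- sort(tree$tip.label)
  lapply(.split_keys(tree), function(k) {
    blk <- .unkey(k)
    other <- setdiff(labs, blk)
    if (length(other) < length(blk) ||
        (length(other) == length(blk) && other[1L] < blk[1L])) other else blk
  })
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count of the non-trivial split sets of two trees
#' on the same leaf set, optionally normalized by its maximum 2(n - 3) so the
#' result lies in \eqn{[0, 1]} and reads as the fraction of false or missing
#' splits. Rooting is ignored; polytomous trees are compared as-is (a fully
#' resolved tree accrues distance against a polytomous one), with the same
#' 2(n - 3) denominator.
#'
#' Trees on unequal leaf sets are refused; restrict both to the shared taxa
#' with [restrict_to()] first.
#'
#' @param t1,t2 `phylo` objects on the same leaf set (n >= 4).
#' @param normalized Divide by 2(n - 3)? Default `TRUE`.
#' @return A single number: the raw count or the normalized distance.
#' @examples
#' a <- parse_newick("((A,B),(C,D),E);")
#' b <- parse_newick("((A,C),(B,D),E);")
#' rf_distance(a, b)            # 1: all splits disagree
#' rf_distance(a, b, FALSE)     # raw count 4
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  .check_phylo(t1, "t1"); .check_phylo(t2, "t2")
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    d <- c(setdiff(l1, l2), setdiff(l2, l1))
    .stopf("leaf sets differ (symmetric difference: %s); restrict both trees first",
           paste(d, collapse = ", "))
  }
  n <- length(l1)
  if (n < 4L) .stopf("Robinson-Foulds distance needs at least 4 shared leaves")
  ref <- min(l1)
  s1 <- .split_keys(t1, ref); s2 <- .split_keys(t2, ref)
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) raw / (2 * (n - 3)) else raw
}

# Internal: build an unrooted phylo from a set of pairwise-compatible splits.
# `clusters` are keys of blocks not containing `ref`; nesting them under the
# full leaf set yields the unique most-resolved tree displaying all splits.
.tree_from_clusters <- function(taxa, cluster_keys) {
  taxa <- sort(taxa)
  cls <- lapply(unique(cluster_keys), .unkey)
  sizes <- vapply(cls, length, 1L)
  ord <- order(sizes, decreasing = TRUE)
  cls <- cls[ord]
  build <- function(members, sub) {
    # sub: clusters strictly inside `members`, in decreasing size order
    children <- list()
    used <- character(0L)
    while (length(sub)) {
      top <- sub[[1L]]
      inner <- Filter(function(c2) all(c2 %in% top), sub[-1L])
      children[[length(children) + 1L]] <- build(top, inner)
      used <- c(used, top)
      sub <- Filter(function(c2) !all(c2 %in% top), sub[-1L])
    }
    singles <- setdiff(members, used)
    parts <- c(sort(singles), unlist(lapply(children, identity)))
    # deterministic child order: by smallest contained label
    minlab <- vapply(parts, function(p) min(.first_labels(p)), character(1L))
    parts <- parts[order(minlab)]
    if (length(parts) == 1L) parts[[1L]] else paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, cls), ";")
  ape::read.tree(text = nwk)
}

# labels occurring in a newick fragment (for deterministic ordering)
.first_labels <- function(frag) {
  strsplit(gsub("[(),;]", " ", frag), "\\s+")[[1L]] |>
    (\(x) x[nzchar(x)])()
}

# Internal consensus engine: keep splits whose count satisfies `keep(count, k)`.
.consensus_engine <- function(trees, keep) {
  trees <- .as_treelist(trees)
  k <- length(trees)
  labsets <- lapply(trees, function(t) sort(t$tip.label))
  if (k > 1L && !all(vapply(labsets[-1L], identical, TRUE, labsets[[1L]]))) {
    .stopf("consensus requires identical leaf sets in all trees (complete data)")
  }
  taxa <- labsets[[1L]]
  ref <- min(taxa)
  tab <- table(unlist(lapply(trees, .split_keys, ref = ref)))
  kept <- names(tab)[keep(as.integer(tab), k)]
  .tree_from_clusters(taxa, kept)
}

#' Majority-rule consensus tree
#'
#' Returns the tree containing exactly the splits present in strictly more
#' than `threshold` of the input trees (default: more than half). A split
#' occurring in exactly the threshold fraction is excluded. All input trees
#' must share the same leaf set. The output may be polytomous.
#'
#' @param trees A list of `phylo` objects (or `multiPhylo`) on one leaf set.
#' @param threshold Fraction in `[0.5, 1)`; splits with frequency strictly
#'   above it are retained.
#' @return An unrooted `phylo`, possibly polytomous.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (threshold < 0.5 || threshold >= 1) .stopf("'threshold' must be in [0.5, 1)")
  .consensus_engine(trees, function(cnt, k) cnt / k > threshold)
}

#' Strict consensus tree
#'
#' The tree whose splits are exactly those present in every input tree.
#'
#' @inheritParams majority_consensus
#' @return An unrooted `phylo`, possibly polytomous.
#' @export
strict_consensus <- function(trees) {
  .consensus_engine(trees, function(cnt, k) cnt == k)
}

#' Root a tree at an outgroup taxon
#'
#' Returns a rooted tree whose root separates `outgroup` from all remaining
#' taxa. The unrooted split set is unchanged.
#'
#' @param tree A `phylo` object.
#' @param outgroup A leaf label of `tree`.
#' @return A rooted `phylo`.
#' @export
root_at <- function(tree, outgroup) {
  .check_phylo(tree)
  if (!is.character(outgroup) || length(outgroup) != 1L ||
      !(outgroup %in% tree$tip.label)) {
    .stopf("outgroup '%s' is not a leaf of the tree", as.character(outgroup)[1L])
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Restrict a tree to a taxon subset
#'
#' Induced subtree on `taxa`: other leaves are dropped, degree-2 nodes are
#' suppressed and their branch lengths summed, so patristic distances among
#' surviving leaves are preserved.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of leaf labels, a subset of the tree's leaves
#'   of size at least 2.
#' @return A `phylo` on `taxa`.
#' @export
restrict_to <- function(tree, taxa) {
  .check_phylo(tree)
  taxa <- unique(as.character(taxa))
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad)) .stopf("taxa not in tree: %s", paste(bad, collapse = ", "))
  if (length(taxa) < 2L) .stopf("need at least 2 taxa to restrict to")
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Rooted triplets displayed by a tree
#'
#' For every 3-leaf subset whose restriction in the rooted input is resolved,
#' returns one triplet `ab|c` (a and b joined against c). A binary rooted tree
#' on n leaves displays all `choose(n, 3)` triplets.
#'
#' @param tree A rooted `phylo`.
#' @param rooted Interpret the tree as rooted even when its root is a
#'   polytomy (which ape cannot distinguish from an unrooted basal node);
#'   needed for rooted supertrees with unresolved roots.
#' @return Character vector of triplets, each formatted `"a,b|c"` with
#'   `a < b` lexicographically.
#' @examples
#' extract_triplets(parse_newick("(B,(C,(A,D)));"))
#' @export
extract_triplets <- function(tree, rooted = ape::is.rooted(tree)) {
  .check_phylo(tree)
  if (!rooted) .stopf("triplets are defined only for rooted trees")
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 3L) return(character(0L))
  pp <- ape::prop.part(tree)
  # membership matrix: clusters x taxa
  memb <- do.call(rbind, lapply(pp, function(cl) {
    v <- logical(n); v[cl] <- TRUE; v
  }))
  sizes <- rowSums(memb)
  out <- character(0L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- which(memb[, i] & memb[, j])
      lca <- both[which.min(sizes[both])]
      outside <- labs[!memb[lca, ]]
      if (length(outside)) {
        pair <- sort(c(labs[i], labs[j]))
        out <- c(out, paste0(pair[1L], ",", pair[2L], "|", outside))
      }
    }
  }
  sort(out)
}

#' Canonical Newick string of a tree topology
#'
#' A rotation-invariant Newick serialization of the topology (branch lengths
#' dropped): children are ordered by their smallest leaf label. Two trees have
#' the same canonical string iff they have the same split set (unrooted
#' comparison) or cluster set (rooted comparison).
#'
#' @param tree A `phylo` object.
#' @param rooted Compare as rooted (clusters) or unrooted (splits)? Defaults
#'   to the tree's own rooting.
#' @return A single Newick string.
#' @export
canonical_newick <- function(tree, rooted = ape::is.rooted(tree)) {
  .check_phylo(tree)
  labs <- sort(tree$tip.label)
  n <- length(labs)
  if (rooted) {
    pp <- ape::prop.part(tree)
    keys <- unique(vapply(pp, function(cl) .key(tree$tip.label[cl]), character(1L)))
    keys <- keys[vapply(keys, function(k) length(.unkey(k)) < n, TRUE)]
    tr <- .tree_from_clusters(labs, keys)
    # re-rooting information is in the cluster set; serialize the nested form
    return(ape::write.tree(tr))
  }
  tr <- .tree_from_clusters(labs, .split_keys(tree))
  ape::write.tree(tr)
}
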