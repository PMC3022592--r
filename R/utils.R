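# Internal helpers shared across modules.

# Separator used when flattening taxon sets into keys; taxon labels must not
# contain it (enforced at tree validation time).
.SEP <- "\x1f"

.key <- function(x) paste(sort(x), collapse = .SEP)

.unkey <- function(k) strsplit(k, .SEP, fixed = TRUE)[[1L]]

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations do not disturb an enclosing simulation
#' stream. With `seed = NULL` the expression simply uses the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_phylo <- function(x) inherits(x, "phylo")

.check_phylo <- function(x, arg = "tree") {
  if (!.is_phylo(x)) .stopf("'%s' must be a 'phylo' object", arg)
  if (anyDuplicated(x$tip.label)) {
    .stopf("duplicate leaf labels: %s",
           paste(unique(x$tip.label[duplicated(x$tip.label)]), collapse = ", "))
  }
  if (any(grepl(.SEP, x$tip.label, fixed = TRUE))) {
    .stopf("leaf labels must not contain control characters")
  }
  invisible(x)
}

.as_treelist <- function(trees) {
  if (.is_phylo(trees)) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  if (!is.list(trees) || !length(trees) || !all(vapply(trees, .is_phylo, TRUE))) {
    .stopf("expected a 'phylo', 'multiPhylo' or list of 'phylo' objects")
  }
  trees
}
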