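# Alignment container and file I/O: FASTA / relaxed PHYLIP alignments,
# PHYLIP-style square distance matrices with "NA" for absent entries, and
# occupancy tables.

.NUC <- c("A", "C", "G", "T")

#' Gene alignment container
#'
#' A `gene_alignment` is a gap-free-by-construction DNA alignment for one
#' gene: a taxa x sites matrix of nucleotide codes (1 = A, 2 = C, 3 = G,
#' 4 = T, `NA` = gap/ambiguity) plus the gene id. All sequences of a gene
#' have equal length.
#'
#' @param seqs Either a character matrix of nucleotides (rows = taxa) or an
#'   integer matrix of codes 1..4 / `NA`; rownames are taxon labels.
#' @param gene Gene identifier.
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(seqs, gene = "gene") {
  if (!is.matrix(seqs) || is.null(rownames(seqs))) {
    .stopf("'seqs' must be a matrix with taxon rownames")
  }
  if (is.character(seqs)) {
    up <- toupper(seqs)
    codes <- match(up, .NUC)  # '-', 'N', etc. -> NA
    seqs <- matrix(codes, nrow(seqs), ncol(seqs), dimnames = dimnames(seqs))
  }
  storage.mode(seqs) <- "integer"
  if (any(!is.na(seqs) & (seqs < 1L | seqs > 4L))) .stopf("invalid nucleotide codes")
  structure(list(gene = gene, seqs = seqs), class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("Gene alignment '%s': %d taxa x %d sites (%.1f%% missing)\n",
              x$gene, nrow(x$seqs), ncol(x$seqs), 100 * mean(is.na(x$seqs))))
  invisible(x)
}

#' @export
dim.gene_alignment <- function(x) dim(x$seqs)

# character-matrix view; missing as '-'
.aln_chars <- function(aln) {
  m <- matrix("-", nrow(aln$seqs), ncol(aln$seqs), dimnames = dimnames(aln$seqs))
  m[!is.na(aln$seqs)] <- .NUC[aln$seqs[!is.na(aln$seqs)]]
  m
}

#' Read and write gene alignments
#'
#' FASTA and (relaxed, sequential) PHYLIP are supported through
#' [ape::read.dna()]/[ape::write.dna()]. Gaps and ambiguity codes become
#' missing states.
#'
#' @param file Path to the alignment file.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @param gene Gene id to record; defaults to the file name.
#' @return `read_alignment()`: a [gene_alignment()].
#' @export
read_alignment <- function(file, format = c("fasta", "phylip"), gene = NULL) {
  format <- match.arg(format)
  d <- ape::read.dna(file, format = if (format == "fasta") "fasta" else "sequential",
                     as.character = TRUE, as.matrix = TRUE)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(file))
  gene_alignment(toupper(d), gene = gene)
}

#' @rdname read_alignment
#' @param aln A [gene_alignment()].
#' @export
write_alignment <- function(aln, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  m <- .aln_chars(aln)
  if (format == "fasta") {
    con <- file(file, "w"); on.exit(close(con))
    for (i in seq_len(nrow(m))) {
      writeLines(c(paste0(">", rownames(m)[i]), paste(m[i, ], collapse = "")), con)
    }
  } else {
    ape::write.dna(m, file, format = "sequential", colsep = "", nbcol = -1)
  }
  invisible(file)
}

#' Read and write partial distance matrices
#'
#' PHYLIP-style square matrices: first line the number of taxa, then one row
#' per taxon (label followed by the distances). Absent entries are written as
#' the literal string `NA` (a documented extension of the format for
#' distances between taxa sharing no data).
#'
#' @param file Path.
#' @return `read_distmatrix()`: a numeric matrix with taxon dimnames and
#'   `NA` for absent entries.
#' @export
read_distmatrix <- function(file) {
  ln <- readLines(file)
  n <- as.integer(strsplit(trimws(ln[1L]), "\\s+")[[1L]][1L])
  rows <- strsplit(trimws(ln[seq.int(2L, 1L + n)]), "\\s+")
  labs <- vapply(rows, `[[`, character(1L), 1L)
  m <- t(vapply(rows, function(r) {
    v <- r[-1L]
    v[v == "NA"] <- NA
    as.numeric(v)
  }, numeric(n)))
  dimnames(m) <- list(labs, labs)
  m
}

#' @rdname read_distmatrix
#' @param dm Numeric matrix with taxon dimnames; `NA` allowed off-diagonal.
#' @export
write_distmatrix <- function(dm, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(format(rownames(dm)[i]),
                       formatC(dm[i, ], format = "g", digits = 8)),
                     collapse = "  "), con)
  }
  invisible(file)
}

#' Write a simulated data set to a run directory
#'
#' Emits one FASTA per gene, the true species and gene trees as Newick, and
#' the occupancy pattern as TSV.
#'
#' @param dataset A simulated data set from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_dir <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick_file(dataset$species_tree, file.path(dir, "species_tree.nwk"))
  write_newick_file(dataset$gene_trees, file.path(dir, "gene_trees.nwk"))
  for (aln in dataset$alignments) {
    write_alignment(aln, file.path(dir, paste0(aln$gene, ".fasta")))
  }
  occ <- dataset$occupancy
  utils::write.table(occ$occ, file.path(dir, "occupancy.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}
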