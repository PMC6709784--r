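#' Codon alignment container
#'
#' A light S3 container for gap-aware codon alignments: a character matrix
#' with one row per gene and one column per nucleotide position, whose
#' number of columns is divisible by three, plus an optional per-codon
#' domain annotation produced by [annotate_columns()].
#'
#' @param seqs character matrix of single characters (A/C/G/T/-), rows
#'   named by gene id, or a character vector of equal-length strings.
#' @param domains optional character vector of per-codon-column domain
#'   labels (length `ncol(seqs) / 3`).
#' @return an object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, domains = NULL) {
  m <- as_aln_matrix(seqs)
  if (ncol(m) %% 3L != 0L)
    stop("alignment length (", ncol(m), ") is not divisible by 3")
  if (!is.null(domains) && length(domains) != ncol(m) / 3L)
    stop("domain annotation must have one label per codon column")
  structure(list(seqs = m, domains = domains), class = "codon_alignment")
}

# Coerce strings / matrices / codon_alignment to a character matrix of
# single characters with row names.
as_aln_matrix <- function(x) {
  if (inherits(x, "codon_alignment")) return(x$seqs)
  if (is.matrix(x)) {
    storage.mode(x) <- "character"
    return(x)
  }
  if (is.character(x)) {
    if (length(unique(nchar(x))) != 1L)
      stop("aligned sequences must all have the same length")
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
    return(m)
  }
  stop("cannot interpret input as an alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x$seqs), "sequences x",
      ncol(x$seqs) / 3L, "codons",
      if (!is.null(x$domains)) "(domain-annotated)" else "", "\n")
  invisible(x)
}

#' @export
as.matrix.codon_alignment <- function(x, ...) x$seqs

#' @export
dim.codon_alignment <- function(x) dim(x$seqs)

# collapse matrix rows back to strings
aln_strings <- function(x) {
  m <- as_aln_matrix(x)
  setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}
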