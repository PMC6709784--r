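# ---- sequence and annotation file I/O -----------------------------------

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `gene` features from a GFF3 file (1-based inclusive coordinates)
#' into the package's gene-model table; curation flags are read from the
#' comma-separated `note` attribute.
#'
#' @param path GFF3 file.
#' @param accession accession id stored alongside the models (default:
#'   file name without extension).
#' @return data.frame: gene_id, accession, contig, start, end, strand,
#'   flags.
#' @export
read_gff3 <- function(path, accession = NULL) {
  if (is.null(accession))
    accession <- sub("\\.gff3?$", "", basename(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  flags <- if (!is.null(gr$note)) {
    unname(vapply(as.list(gr$note), function(x) {
      x <- x[!is.na(x)]
      paste(x, collapse = ",")
    }, ""))
  } else rep("", length(gr))
  data.frame(
    gene_id = gr$ID, accession = accession,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)), flags = flags)
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features per gene model (single-exon
#' models; 1-based inclusive), with flags carried in the `note` attribute.
#'
#' @param genes gene-model data.frame (see [read_gff3()]).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  n <- nrow(genes)
  feat <- function(type, id, parent) {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$contig,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand)
    gr$type <- type
    gr$ID <- id
    if (!is.null(parent)) gr$Parent <- parent
    gr
  }
  g <- feat("gene", genes$gene_id, NULL)
  g$note <- ifelse(nzchar(genes$flags), genes$flags, NA_character_)
  m <- feat("mRNA", paste0(genes$gene_id, ".1"), genes$gene_id)
  cds <- feat("CDS", paste0(genes$gene_id, ".1.cds"),
              paste0(genes$gene_id, ".1"))
  cds$phase <- 0L
  all <- c(g, m, cds)
  all <- all[order(as.character(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all), all$type)]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read a domain interval table
#'
#' @param path TSV with columns gene_id, label, start, end, source.
#' @return data.frame.
#' @export
read_domains <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "label", "start", "end", "source")
  if (!all(need %in% names(d)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Write and read trees in Newick format
#'
#' Thin wrappers around the ape readers/writers; internal node labels
#' (bootstrap supports) and branch lengths round-trip.
#'
#' @param tree an [ape::phylo].
#' @param path file path.
#' @return `read_newick` returns an [ape::phylo].
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Coordinate convention converters
#'
#' The package stores coordinates 1-based inclusive end to end (the
#' GFF3/GRanges convention). These converters translate to and from
#' 0-based half-open (BED-style) coordinates at interchange boundaries.
#'
#' @param start,end interval coordinates.
#' @return two-column matrix `start`, `end` in the other convention.
#' @export
to_zero_based <- function(start, end) {
  cbind(start = start - 1L, end = end)
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  cbind(start = start + 1L, end = end)
}

#' Read a simulated or external pan-NLRome panel from disk
#'
#' Counterpart of [write_pannlrome()]: reads per-accession GFF3 and
#' FASTA files plus the panel-wide domain table.
#'
#' @param dir directory containing `<accession>.gff3`,
#'   `<accession>.protein.fasta`, `<accession>.cds.fasta` and
#'   `domains.tsv`.
#' @return list with `genes`, `proteins`, `cds`, `domains`.
#' @export
read_panel <- function(dir) {
  gffs <- sort(list.files(dir, pattern = "\\.gff3$", full.names = TRUE))
  if (!length(gffs)) stop("no GFF3 files found in ", dir)
  genes <- list(); proteins <- character(); cds <- character()
  for (p in gffs) {
    acc <- sub("\\.gff3$", "", basename(p))
    genes[[acc]] <- read_gff3(p, accession = acc)
    proteins <- c(proteins,
                  read_fasta(file.path(dir, paste0(acc, ".protein.fasta"))))
    cds <- c(cds, read_fasta(file.path(dir, paste0(acc, ".cds.fasta"))))
  }
  list(genes = do.call(rbind, c(genes, make.row.names = FALSE)),
       proteins = proteins, cds = cds,
       domains = read_domains(file.path(dir, "domains.tsv")))
}
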