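#' Build the orthogroup co-occurrence graph over contigs
#'
#' For every accession, every unordered pair of orthogroups found on the
#' same contig gains one unit of edge weight — counted once per accession
#' even when the pair co-occurs on several contigs or through multiple
#' gene copies, so edge weights are accession-support counts.
#'
#' @param assignments data.frame with columns `gene_id`, `accession`,
#'   `contig`, `og_id` (NA rows = singletons, ignored); include non-NLR
#'   orthogroups to maximize anchoring power.
#' @param og_attrs optional data.frame with columns `og_id` and any of
#'   `size`, `is_nlr`, `reference_interval` (NA when the orthogroup has no
#'   reference allele); attached as node attributes.
#' @return an undirected [igraph::graph] with edge attribute `weight` and
#'   node attributes from `og_attrs` (plus `has_reference_allele`).
#' @export
build_cooccurrence <- function(assignments, og_attrs = NULL) {
  a <- assignments[!is.na(assignments$og_id), , drop = FALSE]
  pair_keys <- unique(unlist(lapply(
    split(a, a$accession), function(x) {
      keys <- character()
      for (ctg in split(x$og_id, x$contig)) {
        ogs <- sort(unique(ctg))
        if (length(ogs) < 2L) next
        pr <- combn(ogs, 2L)
        keys <- c(keys, paste0(pr[1L, ], "\r", pr[2L, ]))
      }
      if (!length(keys)) return(character(0))
      paste0(x$accession[1L], "\r", unique(keys))
    }), use.names = FALSE))
  nodes <- sort(unique(a$og_id))
  if (length(pair_keys)) {
    parts <- do.call(rbind, strsplit(pair_keys, "\r"))
    tb <- table(paste0(parts[, 2L], "\r", parts[, 3L]))
    ep <- do.call(rbind, strsplit(names(tb), "\r"))
    edges <- data.frame(from = ep[, 1L], to = ep[, 2L],
                        weight = as.integer(tb))
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(og_attrs)) {
    ix <- match(nodes, og_attrs$og_id)
    for (col in setdiff(names(og_attrs), "og_id"))
      g <- igraph::set_vertex_attr(g, col, value = og_attrs[[col]][ix])
    if ("reference_interval" %in% names(og_attrs))
      g <- igraph::set_vertex_attr(
        g, "has_reference_allele",
        value = !is.na(og_attrs$reference_interval[ix]))
  }
  g
}

#' Thresholded co-occurrence subnetworks
#'
#' Drops edges supported by fewer than `min_accessions` accessions and
#' returns the connected components with at least two nodes.
#'
#' @param graph graph from [build_cooccurrence()].
#' @param min_accessions minimum accession support per edge (default 10).
#' @return list of igraph subgraphs.
#' @export
subnetworks <- function(graph, min_accessions = 10L) {
  if (min_accessions < 1L) stop("threshold must be >= 1")
  keep <- igraph::E(graph)[igraph::E(graph)$weight >= min_accessions]
  g2 <- igraph::subgraph_from_edges(graph, keep, delete.vertices = TRUE)
  comp <- igraph::components(g2)
  out <- lapply(seq_len(comp$no), function(i) {
    igraph::induced_subgraph(g2, which(comp$membership == i))
  })
  out[vapply(out, igraph::vcount, numeric(1L)) >= 2L]
}

#' Anchor non-reference orthogroups to reference intervals
#'
#' Within each subnetwork, every orthogroup lacking a reference allele
#' receives the reference interval of its highest-weight anchored direct
#' neighbor (ties resolve to the smallest genomic coordinate).
#' Orthogroups with no anchored neighbor stay unanchored.
#'
#' @param subnets list of subgraphs from [subnetworks()]; nodes need
#'   attributes `reference_interval` / `has_reference_allele`.
#' @return data.frame: og_id, reference_interval, via (anchoring
#'   neighbor), weight.
#' @export
anchor_nonreference <- function(subnets) {
  rows <- list()
  for (g in subnets) {
    has_ref <- igraph::vertex_attr(g, "has_reference_allele")
    if (is.null(has_ref) || !any(has_ref, na.rm = TRUE)) next
    refint <- igraph::vertex_attr(g, "reference_interval")
    nm <- igraph::V(g)$name
    for (v in which(!has_ref)) {
      nb <- as.integer(igraph::neighbors(g, v))
      nb <- nb[has_ref[nb]]
      if (!length(nb)) next
      w <- vapply(nb, function(u)
        igraph::E(g)[v %--% u]$weight[1L], numeric(1L))
      best <- nb[w == max(w)]
      if (length(best) > 1L) {
        coord <- vapply(refint[best], interval_start, numeric(1L))
        best <- best[order(coord)][1L]
      } else best <- best[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = nm[v], reference_interval = refint[best],
        via = nm[best], weight = max(w))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(og_id = character(),
                      reference_interval = character(),
                      via = character(), weight = numeric())
  rownames(out) <- NULL
  out
}

# parse "chr1:100-200" style intervals; NA-safe
interval_start <- function(x) {
  if (is.na(x)) return(Inf)
  part <- strsplit(sub("^[^:]*:", "", x), "-")[[1L]]
  suppressWarnings(as.numeric(part[1L]))
}
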