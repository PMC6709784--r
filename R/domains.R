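#' Identify NLR genes from their domain content
#'
#' A gene is an NLR iff it carries at least one NB, TIR or RPW8 domain;
#' LRR or CC motifs alone are not sufficient.
#'
#' @param labels character vector of (canonicalized) domain labels for one
#'   gene, or a data.frame with a `label` column.
#' @return logical scalar.
#' @export
identify_nlr <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  any(canonicalize_domain(labels) %in% c("NB", "TIR", "RPW8"))
}

#' Consensus coiled-coil intervals by two-of-three vote
#'
#' Returns the maximal protein intervals in which at least `min_votes`
#' distinct predictors (of coils, paircoil and nlrparser) report a
#' coiled-coil. The vote is residue-wise: a residue counts as supported if
#' it is covered by intervals from two or more distinct predictors.
#'
#' @param cc_calls data.frame with columns `start`, `end` (1-based
#'   inclusive protein coordinates) and `source` (predictor tag), or a
#'   named list of two-column start/end matrices/data.frames per predictor.
#' @param min_votes minimum number of distinct supporting predictors
#'   (default 2).
#' @return data.frame with columns `start`, `end`; zero rows if no residue
#'   reaches the vote threshold.
#' @export
vote_cc <- function(cc_calls, min_votes = 2L) {
  if (is.list(cc_calls) && !is.data.frame(cc_calls)) {
    cc_calls <- do.call(rbind, lapply(names(cc_calls), function(src) {
      x <- as.data.frame(cc_calls[[src]])
      if (!nrow(x)) return(NULL)
      names(x)[1:2] <- c("start", "end")
      x$source <- src
      x[, c("start", "end", "source")]
    }))
  }
  if (is.null(cc_calls) || !nrow(cc_calls))
    return(data.frame(start = integer(), end = integer()))
  stopifnot(all(cc_calls$start <= cc_calls$end))
  maxpos <- max(cc_calls$end)
  votes <- matrix(FALSE, nrow = length(unique(cc_calls$source)),
                  ncol = maxpos,
                  dimnames = list(unique(cc_calls$source), NULL))
  for (i in seq_len(nrow(cc_calls)))
    votes[cc_calls$source[i], cc_calls$start[i]:cc_calls$end[i]] <- TRUE
  support <- colSums(votes) >= min_votes
  if (!any(support)) return(data.frame(start = integer(), end = integer()))
  r <- rle(support)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Assign the NLR class from the collapsed domain set
#'
#' Applies the class rules as a precedence-ordered partition: a TIR domain
#' makes a TNL; else an RPW8 domain makes an RNL; else CC together with NB
#' makes a CNL; else NB alone makes an NL.
#'
#' @param collapsed_set character vector of distinct canonical domain
#'   labels for one gene.
#' @return one of `"TNL"`, `"CNL"`, `"RNL"`, `"NL"`.
#' @export
assign_class <- function(collapsed_set) {
  s <- unique(canonicalize_domain(collapsed_set))
  if ("TIR" %in% s) return("TNL")
  if ("RPW8" %in% s) return("RNL")
  if (all(c("CC", "NB") %in% s)) return("CNL")
  if ("NB" %in% s) return("NL")
  stop("domain set {", paste(s, collapse = ", "),
       "} matches no NLR class; did the gene pass identify_nlr()?")
}

#' Collapse an ordered domain sequence into an architecture key
#'
#' The architecture is the collapsed protein domain set: repeated and
#' consecutive copies of a domain are not distinguished, and the key is
#' order-independent (a sorted, de-duplicated label string).
#'
#' @param ordered_domains character vector of domain labels sorted by start
#'   coordinate.
#' @return single string key, labels sorted and joined with `"+"`.
#' @export
collapse_architecture <- function(ordered_domains) {
  if (!length(ordered_domains)) return("")
  paste(sort(unique(canonicalize_domain(ordered_domains))), collapse = "+")
}

#' Tabulate integrated domains across the panel
#'
#' Every non-canonical domain label found in an NLR gene is an integrated
#' domain (ID). IDs seen in exactly one gene model of exactly one accession
#' are flagged as singletons and excluded from architecture-novelty
#' analyses downstream.
#'
#' @param domains data.frame with columns `gene_id`, `label` (and
#'   optionally `source`).
#' @param accession_of_gene named character vector mapping gene id to
#'   accession.
#' @param nlr_genes character vector of gene ids that passed
#'   [identify_nlr()]; rows of other genes are ignored.
#' @return data.frame with columns `label`, `n_genes`, `n_accessions`,
#'   `singleton`; zero rows when no ID exists.
#' @export
find_integrated_domains <- function(domains, accession_of_gene, nlr_genes) {
  d <- domains[domains$gene_id %in% nlr_genes, , drop = FALSE]
  d$label <- canonicalize_domain(d$label)
  d <- d[!(d$label %in% CANONICAL_DOMAINS), , drop = FALSE]
  if (!nrow(d))
    return(data.frame(label = character(), n_genes = integer(),
                      n_accessions = integer(), singleton = logical()))
  d <- unique(d[, c("gene_id", "label")])
  d$accession <- accession_of_gene[d$gene_id]
  agg <- lapply(split(d, d$label), function(x)
    data.frame(label = x$label[1L], n_genes = length(unique(x$gene_id)),
               n_accessions = length(unique(x$accession))))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out$singleton <- out$n_genes == 1L & out$n_accessions == 1L
  out[order(out$label), , drop = FALSE]
}

#' Architecture membership across three panels (UpSet-style)
#'
#' Tabulates each distinct architecture key's presence across three input
#' sets (e.g. reference accession, pan-NLRome, related species).
#'
#' @param set_a,set_b,set_c character vectors of architecture keys,
#'   canonicalized identically (see [collapse_architecture()]).
#' @param names_abc length-3 character vector of set names.
#' @return data.frame with one row per distinct key and one logical column
#'   per set; attribute `"intersections"` carries the per-cell counts.
#' @export
architecture_intersections <- function(set_a, set_b, set_c,
                                       names_abc = c("A", "B", "C")) {
  keys <- sort(unique(c(set_a, set_b, set_c)))
  out <- data.frame(architecture = keys,
                    a = keys %in% set_a,
                    b = keys %in% set_b,
                    c = keys %in% set_c)
  names(out)[2:4] <- names_abc
  if (nrow(out)) {
    cell <- apply(out[, 2:4, drop = FALSE], 1L, function(v)
      paste(names_abc[v], collapse = "&"))
    attr(out, "intersections") <- table(cell)
  } else {
    attr(out, "intersections") <- table(character())
  }
  out
}

#' Classify every gene of a panel
#'
#' Convenience wrapper applying the CC vote, NLR identification, class
#' assignment and architecture collapsing to a full domain table.
#'
#' @param domains data.frame with columns `gene_id`, `label`, `start`,
#'   `end`, `source`; CC predictor rows carry sources `coils`, `paircoil`,
#'   `nlrparser`.
#' @param cc_min_votes predictors required for a consensus CC (default 2).
#' @return data.frame with columns `gene_id`, `is_nlr`, `class`,
#'   `architecture` (collapsed key), `ordered_architecture`
#'   (order-preserving metadata), `has_id`.
#' @export
classify_genes <- function(domains, cc_min_votes = 2L) {
  domains$label <- canonicalize_domain(domains$label)
  cc_sources <- c("coils", "paircoil", "nlrparser")
  res <- lapply(split(domains, domains$gene_id), function(d) {
    cc <- d[d$label == "CC" & d$source %in% cc_sources, , drop = FALSE]
    rest <- d[!(d$label == "CC" & d$source %in% cc_sources), , drop = FALSE]
    cons <- vote_cc(cc, min_votes = cc_min_votes)
    if (nrow(cons))
      rest <- rbind(rest[, c("gene_id", "label", "start", "end")],
                    data.frame(gene_id = d$gene_id[1L], label = "CC",
                               start = cons$start, end = cons$end))
    else rest <- rest[, c("gene_id", "label", "start", "end")]
    rest <- rest[order(rest$start), , drop = FALSE]
    is_nlr <- identify_nlr(rest$label)
    cls <- if (is_nlr) assign_class(unique(rest$label)) else NA_character_
    data.frame(gene_id = d$gene_id[1L], is_nlr = is_nlr, class = cls,
               architecture = collapse_architecture(rest$label),
               ordered_architecture = paste(rest$label, collapse = ";"),
               has_id = any(!(rest$label %in% CANONICAL_DOMAINS)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
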