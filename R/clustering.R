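#' Smith-Waterman local alignment score
#'
#' Scores one pair of protein sequences with BLOSUM62 and affine gaps; a
#' gap of length L costs `gap_open + L * gap_ext`.
#'
#' @param a,b protein sequence strings.
#' @param gap_open,gap_ext affine gap penalties (defaults 11 and 1).
#' @return numeric local alignment score.
#' @export
sw_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_ext, scoreOnly = TRUE)
}

# sum of BLOSUM62 diagonal entries: the optimal local self-alignment score
# (every diagonal entry is positive)
self_scores <- function(proteins) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  vapply(strsplit(proteins, ""), function(ch)
    sum(B[cbind(ch, ch)]), numeric(1L))
}

# candidate pair prefilter: pairs sharing >= min_shared distinct k-mers.
# Unrelated proteins essentially never share several 4-mers, while
# within-family pairs share many; this stands in for a seed-and-filter
# search stage ahead of exact local alignment.
kmer_candidates <- function(proteins, k = 4L, min_shared = 3L) {
  n <- length(proteins)
  kms <- lapply(proteins, function(s) {
    l <- nchar(s)
    if (l < k) return(character())
    unique(substring(s, 1:(l - k + 1L), k:l))
  })
  all_k <- unique(unlist(kms, use.names = FALSE))
  if (!length(all_k)) return(matrix(integer(), ncol = 2L))
  X <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(kms)),
    j = match(unlist(kms, use.names = FALSE), all_k),
    x = 1, dims = c(n, length(all_k)))
  S <- as(Matrix::tcrossprod(X), "TsparseMatrix")  # shared k-mer counts
  keep <- S@x >= min_shared & S@i < S@j
  cbind(S@i[keep] + 1L, S@j[keep] + 1L)
}

#' All-against-all protein similarity edges
#'
#' Computes Smith-Waterman local alignment scores (BLOSUM62, gap open 11,
#' extend 1) for every candidate pair of proteins and returns edges above a
#' score floor, with scores also normalized to [0, 1] by the smaller
#' self-score. A k-mer prefilter skips pairs with no detectable seed
#' similarity; set `prefilter = FALSE` to force the full quadratic scan.
#'
#' @param proteins named character vector of protein sequences.
#' @param score_floor minimum retained score (default 50).
#' @param prefilter use the k-mer candidate filter (default `TRUE`).
#' @param batch_size alignments per vectorized call.
#' @return data.frame with columns `gene_a`, `gene_b`, `score`,
#'   `normalized_score` (one row per unordered pair, gene_a < gene_b).
#' @export
pairwise_similarity <- function(proteins, score_floor = 50,
                                prefilter = TRUE, batch_size = 20000L) {
  if (any(!nzchar(proteins))) stop("empty sequence in input")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("g", seq_along(proteins))
  n <- length(proteins)
  if (n < 2L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), normalized_score = numeric()))
  if (prefilter) {
    cand <- kmer_candidates(proteins)
  } else {
    cand <- t(combn(n, 2L))
  }
  if (!nrow(cand))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), normalized_score = numeric()))
  selfs <- self_scores(proteins)
  aa <- Biostrings::AAStringSet(proteins)
  scores <- numeric(nrow(cand))
  for (off in seq(1L, nrow(cand), by = batch_size)) {
    ix <- off:min(off + batch_size - 1L, nrow(cand))
    scores[ix] <- Biostrings::pairwiseAlignment(
      aa[cand[ix, 1L]], aa[cand[ix, 2L]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
  }
  keep <- scores >= score_floor
  cand <- cand[keep, , drop = FALSE]; scores <- scores[keep]
  norm <- pmin(1, pmax(0, scores / pmin(selfs[cand[, 1L]],
                                        selfs[cand[, 2L]])))
  swap <- names(proteins)[cand[, 1L]] > names(proteins)[cand[, 2L]]
  ga <- ifelse(swap, names(proteins)[cand[, 2L]], names(proteins)[cand[, 1L]])
  gb <- ifelse(swap, names(proteins)[cand[, 1L]], names(proteins)[cand[, 2L]])
  out <- data.frame(gene_a = ga, gene_b = gb, score = scores,
                    normalized_score = norm)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Type similarity edges as ortholog, co-ortholog or inparalog
#'
#' Between-accession edges are orthologs iff they are reciprocal best hits
#' (ties retained as co-best). A within-accession edge is an inparalog iff
#' its score is at least both members' best between-accession scores (genes
#' with no between-accession hit qualify). Co-ortholog edges connect the
#' inparalogs of reciprocal-best partners. Edges matching no rule are
#' dropped.
#'
#' @param edges data.frame from [pairwise_similarity()].
#' @param accession_of_gene named character vector gene id -> accession.
#' @return the edge data.frame restricted to typed edges, with a `type`
#'   column (`ortholog`, `co-ortholog`, `inparalog`).
#' @export
classify_edges <- function(edges, accession_of_gene) {
  genes <- unique(c(edges$gene_a, edges$gene_b))
  if (any(is.na(accession_of_gene[genes])))
    stop("every gene must have an accession")
  if (!nrow(edges)) return(cbind(edges, type = character()))
  acc_a <- accession_of_gene[edges$gene_a]
  acc_b <- accession_of_gene[edges$gene_b]
  between <- acc_a != acc_b
  # best between-accession score per gene
  bg <- c(edges$gene_a[between], edges$gene_b[between])
  bs <- c(edges$score[between], edges$score[between])
  best_between <- setNames(rep(-Inf, length(genes)), genes)
  if (length(bg)) {
    mx <- tapply(bs, bg, max)
    best_between[names(mx)] <- mx
  }
  # reciprocal best between accessions: best score per (gene, other
  # accession) pair, directional
  dir_g <- c(edges$gene_a[between], edges$gene_b[between])
  dir_acc <- c(acc_b[between], acc_a[between])
  dir_s <- c(edges$score[between], edges$score[between])
  key <- paste0(dir_g, "\r", dir_acc)
  best_dir <- tapply(dir_s, key, max)
  type <- rep(NA_character_, nrow(edges))
  bidx <- which(between)
  if (length(bidx)) {
    ka <- paste0(edges$gene_a[bidx], "\r", acc_b[bidx])
    kb <- paste0(edges$gene_b[bidx], "\r", acc_a[bidx])
    recip <- edges$score[bidx] >= best_dir[ka] - 1e-9 &
      edges$score[bidx] >= best_dir[kb] - 1e-9
    type[bidx[recip]] <- "ortholog"
  }
  widx <- which(!between)
  if (length(widx)) {
    inp <- edges$score[widx] >= best_between[edges$gene_a[widx]] &
      edges$score[widx] >= best_between[edges$gene_b[widx]]
    type[widx[inp]] <- "inparalog"
  }
  # co-orthologs: between-accession untyped edge (x, y) where x is an
  # inparalog partner of some gene with an ortholog edge to y (or
  # symmetrically)
  inpar <- edges[which(type == "inparalog"), , drop = FALSE]
  orth <- edges[which(type == "ortholog"), , drop = FALSE]
  if (nrow(inpar) && nrow(orth)) {
    partner <- split(c(inpar$gene_b, inpar$gene_a),
                     c(inpar$gene_a, inpar$gene_b))
    orth_of <- split(c(orth$gene_b, orth$gene_a),
                     c(orth$gene_a, orth$gene_b))
    untyped_b <- bidx[is.na(type[bidx])]
    for (i in untyped_b) {
      x <- edges$gene_a[i]; y <- edges$gene_b[i]
      hit <- any(unlist(partner[x]) %in% unlist(orth_of[y])) ||
        any(unlist(partner[y]) %in% unlist(orth_of[x]))
      if (isTRUE(hit)) type[i] <- "co-ortholog"
    }
  }
  out <- edges[!is.na(type), , drop = FALSE]
  out$type <- type[!is.na(type)]
  rownames(out) <- NULL
  out
}

#' Markov clustering of a weighted gene graph
#'
#' Runs MCL on the typed-edge graph: a column-stochastic transition matrix
#' with self-loops (weight = maximal incident edge weight) is alternately
#' expanded (matrix squared) and inflated (entry-wise power, columns
#' renormalized) with pruning of small entries, until the maximum column
#' change falls below the tolerance. Clusters are the connected components
#' of the converged attractor matrix.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and a weight
#'   column (`normalized_score`, or `weight`, or `score`, in that order of
#'   preference).
#' @param inflation inflation exponent (> 1, default 1.5).
#' @param prune_threshold matrix entries below this are dropped each
#'   iteration (default 1e-5).
#' @param max_iterations iteration cap (default 100); non-convergence
#'   raises a warning and returns the current interpretation.
#' @param tolerance convergence threshold on the max absolute entry change
#'   (default 1e-6).
#' @return list of character vectors (clusters), each sorted, ordered by
#'   decreasing size then lexically.
#' @export
mcl_cluster <- function(edges, inflation = 1.5, prune_threshold = 1e-5,
                        max_iterations = 100L, tolerance = 1e-6) {
  if (!nrow(edges)) stop("graph is empty")
  if (inflation <= 1) stop("inflation must exceed 1")
  wcol <- intersect(c("normalized_score", "weight", "score"), names(edges))[1L]
  if (is.na(wcol)) stop("edges need a weight column")
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(genes)
  ia <- match(edges$gene_a, genes); ib <- match(edges$gene_b, genes)
  w <- edges[[wcol]]
  M <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(w, w),
                            dims = c(n, n))
  # self-loops at the maximal incident weight (standard MCL practice)
  loops <- apply(M, 2L, max)
  loops[loops == 0] <- 1
  Matrix::diag(M) <- loops
  normalize <- function(X) {
    cs <- Matrix::colSums(X)
    X %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    M2 <- M %*% M                      # expansion
    M2@x <- M2@x ^ inflation           # inflation
    M2 <- Matrix::drop0(M2 * (M2 > prune_threshold))
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iterations,
            " iterations; returning current interpretation")
  A <- as(M > prune_threshold, "TsparseMatrix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = genes[A@i + 1L], to = genes[A@j + 1L]),
    directed = FALSE, vertices = genes)
  comp <- igraph::components(g)$membership
  cl <- lapply(split(names(comp), comp), sort)
  names(cl) <- NULL
  cl[order(-lengths(cl), vapply(cl, `[`, "", 1L))]
}

#' Form orthogroups from clusters
#'
#' Clusters with at least `min_og_size` genes become orthogroups with
#' stable ids (sorted by decreasing size, then by lexically smallest
#' member); smaller clusters and unclustered genes are singletons.
#'
#' @param clusters list of character vectors of gene ids.
#' @param all_genes character vector of the full gene universe (default:
#'   the union of the clusters).
#' @param min_og_size minimum orthogroup size (default 2).
#' @return list with `ogs` (named list of member vectors, names
#'   `OG0001...`) and `singletons` (character vector).
#' @export
form_ogs <- function(clusters, all_genes = NULL, min_og_size = 2L) {
  if (min_og_size < 2L) stop("min_og_size must be >= 2")
  if (is.null(all_genes)) all_genes <- unlist(clusters, use.names = FALSE)
  clustered <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(clustered))
    stop("clusters must partition the genes (duplicate member found)")
  keep <- clusters[lengths(clusters) >= min_og_size]
  keep <- lapply(keep, sort)
  keep <- keep[order(-lengths(keep), vapply(keep, `[`, "", 1L))]
  names(keep) <- sprintf("OG%04d", seq_along(keep))
  singles <- setdiff(all_genes, unlist(keep, use.names = FALSE))
  list(ogs = keep, singletons = sort(singles))
}
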