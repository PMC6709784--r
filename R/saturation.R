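#' Bootstrap rarefaction of orthogroup discovery
#'
#' For every subset size k from 2 to the panel size, draws k accessions
#' uniformly without replacement (each replicate draws one random
#' accession ordering; its k-prefixes are uniform k-subsets) and records
#' the fraction of orthogroups with at least one member among them, and
#' the mean total membership of the orthogroups not yet discovered.
#'
#' @param matrix orthogroup x accession member-count matrix (a
#'   `PresenceMatrix`).
#' @param reps replicates (default 1000).
#' @param seed optional seed.
#' @param ci percentile interval width (default 0.95).
#' @return data.frame: size, mean_fraction, lo, hi,
#'   mean_undiscovered_size (`NA` once everything is discovered).
#' @export
rarefy_ogs <- function(matrix, reps = 1000L, seed = NULL, ci = 0.95) {
  if (reps < 1L) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  M <- matrix > 0
  n_og <- nrow(M); n_acc <- ncol(M)
  if (n_acc < 2L) stop("need at least 2 accessions")
  sizes <- 2L:n_acc
  og_size <- rowSums(matrix)
  frac <- matrix(0, reps, length(sizes))
  undisc <- matrix(NA_real_, reps, length(sizes))
  for (r in seq_len(reps)) {
    perm <- sample.int(n_acc)
    cum <- t(apply(M[, perm, drop = FALSE], 1L, cummax))  # discovered yet?
    for (ki in seq_along(sizes)) {
      disc <- cum[, sizes[ki]] > 0
      frac[r, ki] <- mean(disc)
      if (any(!disc)) undisc[r, ki] <- mean(og_size[!disc])
    }
  }
  alpha <- (1 - ci) / 2
  data.frame(
    size = sizes,
    mean_fraction = colMeans(frac),
    lo = apply(frac, 2L, quantile, probs = alpha),
    hi = apply(frac, 2L, quantile, probs = 1 - alpha),
    mean_undiscovered_size = colMeans(undisc, na.rm = TRUE))
}

#' Smallest panel size reaching a discovery target
#'
#' @param curve data.frame from [rarefy_ogs()] (columns `size`,
#'   `mean_fraction`), or a named numeric vector size -> mean fraction.
#' @param target discovery fraction to reach (default 0.95).
#' @return the minimal size whose mean fraction is at least the target,
#'   or `NA` if it is never reached.
#' @export
saturation_point <- function(curve, target = 0.95) {
  if (is.data.frame(curve)) {
    sizes <- curve$size; means <- curve$mean_fraction
  } else {
    sizes <- as.integer(names(curve)); means <- as.numeric(curve)
  }
  ord <- order(sizes)
  hit <- which(means[ord] >= target)
  if (!length(hit)) return(NA_integer_)
  sizes[ord][hit[1L]]
}

#' Bootstrap rarefaction of nucleotide and haplotype diversity
#'
#' For every subset size k, subsamples accessions, recomputes mean
#' nucleotide diversity and mean haplotype diversity over orthogroups with
#' at least 2 sampled members, and expresses them as fractions of the
#' full-panel values, averaged over replicates.
#'
#' @param alignments named list of codon alignments (one per orthogroup;
#'   rows named by gene id).
#' @param accession_of_gene named character vector gene id -> accession.
#' @param reps replicates (default 100).
#' @param seed optional seed.
#' @return data.frame: size, pi_fraction, hap_fraction.
#' @export
rarefy_diversity <- function(alignments, accession_of_gene, reps = 100L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  accs <- sort(unique(accession_of_gene[unlist(
    lapply(alignments, function(a) rownames(as_aln_matrix(a))),
    use.names = FALSE)]))
  n_acc <- length(accs)
  # precompute per orthogroup: pairwise difference counts, usable length,
  # haplotype ids, member accessions
  pre <- lapply(alignments, function(a) {
    m <- as_aln_matrix(a)
    keep <- !apply(m == "-", 2L, any)
    mc <- m[, keep, drop = FALSE]
    nn <- nrow(mc)
    D <- matrix(0, nn, nn)
    if (nn >= 2L) for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn)
      D[i, j] <- D[j, i] <- sum(mc[i, ] != mc[j, ])
    list(D = D, L = ncol(mc),
         hap = as.integer(factor(apply(mc, 1L, paste0, collapse = ""))),
         acc = match(accession_of_gene[rownames(mc)], accs))
  })
  stat_for <- function(p, idx) {
    k <- length(idx)
    if (k < 2L) return(c(NA_real_, NA_real_))
    pi <- mean(p$D[idx, idx][upper.tri(diag(k))]) / max(1L, p$L)
    tb <- table(p$hap[idx])
    hd <- k * (1 - sum((as.numeric(tb) / k)^2)) / (k - 1L)
    c(pi, hd)
  }
  full <- vapply(pre, function(p) stat_for(p, seq_len(nrow(p$D))),
                 numeric(2L))
  full_pi <- mean(full[1L, ], na.rm = TRUE)
  full_hd <- mean(full[2L, ], na.rm = TRUE)
  sizes <- 2L:n_acc
  acc_pi <- matrix(NA_real_, reps, length(sizes))
  acc_hd <- matrix(NA_real_, reps, length(sizes))
  for (r in seq_len(reps)) {
    perm <- sample.int(n_acc)
    rank_of <- integer(n_acc); rank_of[perm] <- seq_len(n_acc)
    for (ki in seq_along(sizes)) {
      k <- sizes[ki]
      st <- vapply(pre, function(p)
        stat_for(p, which(rank_of[p$acc] <= k)), numeric(2L))
      acc_pi[r, ki] <- mean(st[1L, ], na.rm = TRUE)
      acc_hd[r, ki] <- mean(st[2L, ], na.rm = TRUE)
    }
  }
  data.frame(size = sizes,
             pi_fraction = colMeans(acc_pi, na.rm = TRUE) / full_pi,
             hap_fraction = colMeans(acc_hd, na.rm = TRUE) / full_hd)
}
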