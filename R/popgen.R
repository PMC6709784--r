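# ---- diversity and neutrality statistics --------------------------------

harmonic <- function(n, p = 1) sum(1 / seq_len(n - 1L)^p)

#' Diversity and neutrality statistics for a codon alignment
#'
#' Computes, on the gap-filtered column set, the segregating site count S,
#' nucleotide diversity pi (average pairwise differences per site),
#' Watterson's theta, haplotype count and diversity, Tajima's D, Fu and
#' Li's D* and F* (the star variants, no outgroup), Ramos-Onsins and
#' Rozas' R2, and Strobeck's S (the Ewens-sampling probability of at most
#' the observed number of haplotypes given Watterson's theta).
#'
#' Under complete deletion (the default) every column containing a gap in
#' any row is excluded throughout; under pairwise deletion pi is averaged
#' over pairwise comparisons excluding only the columns gapped in that
#' pair, while the site-frequency statistics still use the complete-column
#' set.
#'
#' Statistics that are undefined (e.g. Tajima's D when S = 0, or any
#' statistic for too-small n) are reported as `NA`, never as zero.
#'
#' @param aln a [codon_alignment()] or character matrix / named strings.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return object of class `neutrality_stats`: a list with fields `n`,
#'   `L`, `S`, `eta`, `eta_s`, `pi`, `pi_count`, `theta_w`, `K`,
#'   `hap_div`, `tajima_d`, `fu_li_d_star`, `fu_li_f_star`, `r2`,
#'   `strobeck_s`.
#' @export
neutrality_stats <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- as_aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  gap <- m == "-" | m == "N" | m == "n"
  keep <- !apply(gap, 2L, any)
  if (!any(keep)) stop("no gap-free columns remain")
  mc <- m[, keep, drop = FALSE]
  L <- ncol(mc)

  # site summaries on the complete-deletion column set
  states <- apply(mc, 2L, function(col) table(col))
  n_states <- vapply(states, length, integer(1L))
  S <- sum(n_states > 1L)
  eta <- sum(n_states - 1L)
  # singleton mutations: states carried by exactly one sequence
  U <- integer(n)
  for (j in which(n_states > 1L)) {
    tb <- states[[j]]
    sing <- names(tb)[tb == 1L]
    for (s2 in sing) U[which(mc[, j] == s2)] <- U[which(mc[, j] == s2)] + 1L
  }
  eta_s <- sum(U)

  # pairwise differences
  pairs <- combn(n, 2L)
  if (deletion == "complete") {
    diffs <- apply(pairs, 2L, function(p) sum(mc[p[1L], ] != mc[p[2L], ]))
    pi_count <- mean(diffs)
    pi <- pi_count / L
  } else {
    per_site <- apply(pairs, 2L, function(p) {
      ok <- !(gap[p[1L], ] | gap[p[2L], ])
      if (!any(ok)) return(NA_real_)
      sum(m[p[1L], ok] != m[p[2L], ok]) / sum(ok)
    })
    pi <- mean(per_site, na.rm = TRUE)
    diffs <- apply(pairs, 2L, function(p) sum(mc[p[1L], ] != mc[p[2L], ]))
    pi_count <- mean(diffs)
  }

  # haplotypes on the complete-deletion column set
  haps <- apply(mc, 1L, paste0, collapse = "")
  tb <- table(haps)
  K <- length(tb)
  p_i <- as.numeric(tb) / n
  hap_div <- n * (1 - sum(p_i^2)) / (n - 1L)

  a1 <- harmonic(n)
  theta_w <- S / (a1 * L)

  tajima_d <- tajima_d_stat(n, S, pi_count)
  fl <- fu_li_star(n, eta, eta_s, pi_count)
  r2 <- r2_stat(U, pi_count, S, n)
  strobeck_s <- ewens_prob_at_most(n, K, S / a1)

  structure(list(
    n = n, L = L, S = S, eta = eta, eta_s = eta_s, pi = pi,
    pi_count = pi_count, theta_w = theta_w, K = K, hap_div = hap_div,
    tajima_d = tajima_d, fu_li_d_star = fl$d_star,
    fu_li_f_star = fl$f_star, r2 = r2, strobeck_s = strobeck_s,
    deletion = deletion), class = "neutrality_stats")
}

#' @export
print.neutrality_stats <- function(x, ...) {
  cat(sprintf(
    "neutrality_stats: n=%d L=%d S=%d pi=%.5f theta_w=%.5f K=%d\n",
    x$n, x$L, x$S, x$pi, x$theta_w, x$K))
  cat(sprintf(
    "  hap_div=%.4f  Tajima's D=%s  D*=%s  F*=%s  R2=%s  Strobeck=%s\n",
    x$hap_div, fmt_na(x$tajima_d), fmt_na(x$fu_li_d_star),
    fmt_na(x$fu_li_f_star), fmt_na(x$r2), fmt_na(x$strobeck_s)))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

tajima_d_stat <- function(n, S, pi_count) {
  if (S == 0L || n < 3L) return(NA_real_)
  a1 <- harmonic(n); a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_count - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li's D* and F* (star variants, no outgroup), with the corrected
# variance constants of Simonsen, Churchill & Aquadro (1995)
fu_li_star <- function(n, eta, eta_s, pi_count) {
  if (eta == 0L || n < 4L) return(list(d_star = NA_real_, f_star = NA_real_))
  a <- harmonic(n); b <- harmonic(n, 2)
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  d_star <- ((n / (n - 1)) * eta - a * eta_s) /
    sqrt(uD * eta + vD * eta^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * a) / n^2 - 8 * b / n) / (a^2 + b)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / a - vF
  f_star <- (pi_count - ((n - 1) / n) * eta_s) /
    sqrt(uF * eta + vF * eta^2)
  list(d_star = d_star, f_star = f_star)
}

# Ramos-Onsins & Rozas' R2 from per-sequence singleton counts
r2_stat <- function(U, pi_count, S, n) {
  if (S == 0L) return(NA_real_)
  sqrt(sum((U - pi_count / 2)^2) / n) / S
}

# P(K' <= K) under the Ewens sampling formula at theta (per locus),
# computed with log-space unsigned-Stirling-number recursion
ewens_prob_at_most <- function(n, K, theta) {
  if (theta <= 0) return(1)
  # log |s(n, k)| for k = 1..n by the triangular recursion
  logs <- c(0)                      # row n = 1: |s(1,1)| = 1
  if (n > 1L) for (i in 2L:n) {
    prev <- c(-Inf, logs, -Inf)     # pad k = 0 and k = i
    logs <- vapply(seq_len(i), function(k) {
      x <- prev[k]                  # |s(i-1, k-1)|
      y <- log(i - 1) + prev[k + 1L]  # (i-1) |s(i-1, k)|
      mx <- max(x, y)
      if (is.infinite(mx)) -Inf else mx + log(exp(x - mx) + exp(y - mx))
    }, numeric(1L))
  }
  log_denom <- sum(log(theta + 0:(n - 1L)))
  logp <- logs + seq_len(n) * log(theta) - log_denom
  min(1, sum(exp(logp[seq_len(min(K, n))])))
}

#' Empirical null moments of Tajima's D under neutrality
#'
#' Simulates neutral coalescent alignments and returns the mean and
#' standard deviation of Tajima's D over the replicates (a validation
#' harness for the statistic; the neutral expectation is near zero and
#' slightly negative).
#'
#' @param n sequences per replicate.
#' @param theta per-site scaled mutation rate.
#' @param length alignment length in bases (divisible by 3).
#' @param reps number of replicates (>= 200 recommended).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `n_defined` and the vector `values`
#'   (replicates where D is undefined are `NA` and excluded from the
#'   moments; with theta = 0 the mean is reported as `NA`).
#' @export
tajima_d_null <- function(n, theta, length = 999L, reps = 1000L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    a <- simulate_neutral_alignment(n, length, theta)
    st <- neutrality_stats(a)
    st$tajima_d
  }, numeric(1L))
  ok <- !is.na(vals)
  list(mean = if (any(ok)) mean(vals[ok]) else NA_real_,
       sd = if (sum(ok) > 1L) sd(vals[ok]) else NA_real_,
       n_defined = sum(ok), values = vals)
}

# ---- per-domain statistics ----------------------------------------------

#' Annotate alignment codon columns with domains by majority vote
#'
#' Maps each gene's domain intervals (ungapped protein coordinates) onto
#' the alignment and labels every codon column with the domain claimed by
#' the plurality of its non-gap residues; residues claimed by no interval
#' vote for `none`, and ties resolve to `none`.
#'
#' @param aln a [codon_alignment()].
#' @param domains data.frame with columns `gene_id`, `label`, `start`,
#'   `end` in protein coordinates (predictor CC rows should already be
#'   replaced by consensus intervals).
#' @return character vector with one label per codon column.
#' @export
annotate_columns <- function(aln, domains) {
  m <- as_aln_matrix(aln)
  ncodon <- ncol(m) %/% 3L
  votes <- matrix(NA_character_, nrow(m), ncodon,
                  dimnames = list(rownames(m), NULL))
  for (g in rownames(m)) {
    res_cols <- which(m[g, seq(1L, ncol(m), 3L)] != "-")
    nres <- length(res_cols)
    lab <- rep("none", nres)
    d <- domains[domains$gene_id == g, , drop = FALSE]
    if (nrow(d)) {
      if (any(d$end > nres))
        stop("gene ", g, ": domain interval beyond protein length (",
             nres, " residues)")
      d <- d[order(d$start), , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        span <- d$start[i]:d$end[i]
        lab[span][lab[span] == "none"] <- d$label[i]  # first claim wins
      }
    }
    votes[g, res_cols] <- lab
  }
  vapply(seq_len(ncodon), function(j) {
    v <- votes[, j]
    v <- v[!is.na(v)]
    if (!length(v)) return("none")
    tb <- sort(table(v), decreasing = TRUE)
    if (length(tb) > 1L && tb[1L] == tb[2L]) return("none")
    names(tb)[1L]
  }, character(1L))
}

#' Neutrality statistics restricted to one domain's columns
#'
#' Concatenates the codon columns labeled with the requested domain and
#' computes [neutrality_stats()] on the sub-alignment.
#'
#' @param aln a [codon_alignment()].
#' @param labels per-codon-column labels from [annotate_columns()].
#' @param domain domain label to keep.
#' @param deletion gap handling, as in [neutrality_stats()].
#' @return a `neutrality_stats` object, or an all-`NA` sentinel of the
#'   same class when no column carries the label.
#' @export
domain_subset_stats <- function(aln, labels, domain,
                                deletion = "complete") {
  m <- as_aln_matrix(aln)
  cod <- which(labels == domain)
  if (!length(cod)) {
    return(structure(list(
      n = nrow(m), L = 0L, S = NA_integer_, eta = NA_integer_,
      eta_s = NA_integer_, pi = NA_real_, pi_count = NA_real_,
      theta_w = NA_real_, K = NA_integer_, hap_div = NA_real_,
      tajima_d = NA_real_, fu_li_d_star = NA_real_,
      fu_li_f_star = NA_real_, r2 = NA_real_, strobeck_s = NA_real_,
      deletion = deletion), class = "neutrality_stats"))
  }
  cols <- c(rbind(3L * cod - 2L, 3L * cod - 1L, 3L * cod))
  neutrality_stats(m[, cols, drop = FALSE], deletion = deletion)
}

#' Invariable codon columns
#'
#' A codon column is invariable iff no row is gapped there and all rows
#' carry the identical codon.
#'
#' @param aln a [codon_alignment()].
#' @return list with `count` and integer `positions` (codon indices).
#' @export
invariable_codons <- function(aln) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  ncodon <- ncol(m) %/% 3L
  inv <- vapply(seq_len(ncodon), function(j) {
    block <- m[, (3L * j - 2L):(3L * j), drop = FALSE]
    if (any(block == "-")) return(FALSE)
    codons <- apply(block, 1L, paste0, collapse = "")
    length(unique(codons)) == 1L
  }, logical(1L))
  list(count = sum(inv), positions = which(inv))
}

# ---- enrichment, correlation, expression --------------------------------

#' Hypergeometric flag enrichment across orthogroups
#'
#' For every orthogroup x flag combination, the upper-tail hypergeometric
#' probability of drawing at least the observed number of flagged members
#' in a draw of the orthogroup's size from the gene universe, with
#' Benjamini-Hochberg correction across all combinations.
#'
#' @param og_members named list: orthogroup id -> member gene ids.
#' @param gene_flags data.frame with columns `gene_id`, `flag` (one row
#'   per flag on a gene), or a named list flag -> gene ids.
#' @param universe character vector of all genes (default: union of the
#'   orthogroup members).
#' @param q_max significance threshold on the BH q-value (default 0.1).
#' @return data.frame: og_id, flag, k, og_size, flag_total, p, q,
#'   significant.
#' @export
flag_enrichment <- function(og_members, gene_flags, universe = NULL,
                            q_max = 0.1) {
  if (is.data.frame(gene_flags))
    gene_flags <- split(gene_flags$gene_id, gene_flags$flag)
  if (is.null(universe))
    universe <- unique(unlist(og_members, use.names = FALSE))
  N <- length(universe)
  bad <- vapply(gene_flags, function(g) any(!(g %in% universe)),
                logical(1L))
  if (any(bad))
    stop("flagged genes outside the universe for flag(s): ",
         paste(names(gene_flags)[bad], collapse = ", "))
  rows <- list()
  for (og in names(og_members)) {
    mem <- og_members[[og]]
    for (fl in names(gene_flags)) {
      flagged <- unique(gene_flags[[fl]])
      k <- sum(mem %in% flagged)
      p <- phyper(k - 1L, length(flagged), N - length(flagged),
                  length(mem), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og, flag = fl, k = k, og_size = length(mem),
        flag_total = length(flagged), p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_max
  out[order(out$q, out$p), , drop = FALSE]
}

#' Pearson correlation and least-squares fit of paired statistics
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 3), e.g.
#'   Tajima's D of sensor and executor partners across pairs.
#' @return list with `r`, `slope`, `intercept`, `n`; all-`NA` sentinel
#'   when either vector has zero variance.
#' @export
pair_correlation <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("unequal lengths")
  ok <- !(is.na(values_a) | is.na(values_b))
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = length(a)))
  fit <- lm(b ~ a)
  list(r = cor(a, b), slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]), n = length(a))
}

#' Per-accession minimum expression threshold from intron background
#'
#' Estimates kernel densities of NLR expression counts and of intronic
#' background counts on a shared log10(count + 1) grid, subtracts the
#' background density from the NLR density, and returns the lowest
#' expression level at which the difference becomes positive.
#'
#' @param nlr_counts normalized NLR expression counts.
#' @param intron_counts normalized intronic background counts.
#' @param grid_n grid resolution (default 512).
#' @return the threshold on the count scale, or `NA` when no level has a
#'   positive density excess (e.g. identical distributions) or all counts
#'   are zero.
#' @export
expression_threshold <- function(nlr_counts, intron_counts,
                                 grid_n = 512L) {
  if (!length(nlr_counts) || !length(intron_counts))
    stop("both count vectors must be non-empty")
  if (all(nlr_counts == 0) && all(intron_counts == 0)) return(NA_real_)
  la <- log10(nlr_counts + 1)
  lb <- log10(intron_counts + 1)
  rng <- range(c(la, lb))
  da <- density(la, from = rng[1L], to = rng[2L], n = grid_n)
  db <- density(lb, from = rng[1L], to = rng[2L], n = grid_n)
  diff <- da$y - db$y
  idx <- which(diff > 1e-12)
  if (!length(idx)) return(NA_real_)
  10^da$x[idx[1L]] - 1
}
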