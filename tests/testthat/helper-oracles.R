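# Independent brute-force oracles used across the suite. These
# deliberately re-derive every quantity from first principles with naive
# loops, sharing no code with the package internals.

# naive popgen statistics from a character matrix (no gaps expected)
oracle_stats <- function(m) {
  n <- nrow(m); L <- ncol(m)
  # segregating sites by direct column scan
  S <- 0L
  for (j in seq_len(L)) if (length(unique(m[, j])) > 1L) S <- S + 1L
  # pairwise differences by double loop
  total <- 0; npair <- 0L
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    total <- total + sum(m[i, ] != m[k, ])
    npair <- npair + 1L
  }
  pi_count <- total / npair
  pi <- pi_count / L
  # haplotype diversity
  haps <- apply(m, 1L, paste0, collapse = "")
  cnt <- as.numeric(table(haps))
  hap_div <- n * (1 - sum((cnt / n)^2)) / (n - 1)
  # Tajima's D from the published constants
  tajima <- NA_real_
  if (S > 0L && n >= 3L) {
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    tajima <- (pi_count - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  # R2: per-sequence singleton counts by direct scanning
  U <- integer(n)
  for (j in seq_len(L)) {
    tb <- table(m[, j])
    if (length(tb) < 2L) next
    for (state in names(tb)[tb == 1L]) {
      i <- which(m[, j] == state)
      U[i] <- U[i] + 1L
    }
  }
  r2 <- if (S > 0L) sqrt(sum((U - pi_count / 2)^2) / n) / S else NA_real_
  list(S = S, pi = pi, pi_count = pi_count, hap_div = hap_div,
       K = length(cnt), tajima_d = tajima, r2 = r2, U = U)
}

# brute-force local (Smith-Waterman) alignment score with affine gaps;
# gap of length l costs open + l * ext
oracle_sw <- function(a, b, open = 11, ext = 1) {
  B <- get_blosum()
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                          Y[i - 1, j - 1]) + B[x[i - 1], y[j - 1]])
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

# brute-force global (Needleman-Wunsch) optimum score, same conventions
oracle_nw <- function(a, b, open = 11, ext = 1) {
  B <- get_blosum()
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      B[x[i - 1], y[j - 1]]
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

get_blosum <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# score a given pairwise alignment (two gapped rows) under the same model
score_pair_alignment <- function(ra, rb, open = 11, ext = 1) {
  B <- get_blosum()
  a <- strsplit(ra, "")[[1]]; b <- strsplit(rb, "")[[1]]
  sc <- 0; in_gap <- 0L
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") {
      side <- if (a[i] == "-") 1L else 2L
      sc <- sc - ext - (if (in_gap != side) open else 0)
      in_gap <- side
    } else {
      sc <- sc + B[a[i], b[i]]
      in_gap <- 0L
    }
  }
  sc
}

# minimal independent Markov clustering on a dense adjacency matrix
oracle_mcl <- function(A, inflation = 1.5, iters = 200, tol = 1e-8) {
  n <- nrow(A)
  diag(A) <- apply(A, 2, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(iters)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  adj <- (M > 1e-6) | t(M > 1e-6)
  # connected components by BFS
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# best 4-taxon topology by the four-point criterion: the true split
# minimizes the sum of within-pair distances
oracle_quartet <- function(D) {
  stopifnot(nrow(D) == 4)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  sums <- vapply(splits, function(s) {
    o <- setdiff(1:4, s)
    D[s[1], s[2]] + D[o[1], o[2]]
  }, numeric(1))
  splits[[which.min(sums)]]
}

# the split {x, y} induced on a 4-leaf unrooted tree (partner of leaf 1)
tree_quartet_split <- function(tree, labels) {
  stopifnot(length(tree$tip.label) == 4)
  ints <- (length(tree$tip.label) + 1):(length(tree$tip.label) + tree$Nnode)
  for (nd in ints) {
    tips <- phangorn::Descendants(tree, nd, "tips")[[1]]
    if (length(tips) == 2) {
      pair <- sort(match(tree$tip.label[tips], labels))
      if (1 %in% pair) return(pair)
      return(sort(match(tree$tip.label[setdiff(1:4, tips)], labels)))
    }
  }
  stop("no cherry found")
}

# random ungapped alignment with realistic sharing: a few haplotypes plus
# scattered mutations
rand_aln <- function(n, L, seed) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  k <- sample(2:max(2, n %/% 2), 1)
  haps <- replicate(k, {
    h <- base
    nm <- rpois(1, L / 30)
    if (nm > 0) {
      pos <- sample(L, min(nm, L))
      for (p in pos) h[p] <- sample(setdiff(c("A", "C", "G", "T"), h[p]), 1)
    }
    h
  })
  m <- t(haps[, sample(k, n, replace = TRUE), drop = FALSE])
  rownames(m) <- paste0("s", seq_len(n))
  m
}

# shared small simulated panel, built once per test run
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_pannlrome(simulation_config(
        n_accessions = 12,
        og_spectrum = data.frame(p = c(0.9, 0.5, 0.2), n = c(6, 6, 8)),
        seed = 42))
    cache
  }
})
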