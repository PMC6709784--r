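test_that("hand-enumerable alignments give the documented statistics", {
  m <- do.call(rbind, strsplit(c("AAA", "AAT", "ATT"), ""))
  rownames(m) <- paste0("s", 1:3)
  st <- neutrality_stats(m)
  expect_equal(st$pi, (4 / 3) / 3, tolerance = 1e-12)
  expect_equal(st$S, 2L)
  expect_equal(st$K, 3L)
  expect_equal(st$hap_div, 1.0)

  ident <- matrix("A", 4, 9, dimnames = list(paste0("s", 1:4), NULL))
  st0 <- neutrality_stats(ident)
  expect_equal(st0$S, 0L)
  expect_equal(st0$pi, 0)
  expect_equal(st0$hap_div, 0)
  expect_true(is.na(st0$tajima_d))
  expect_true(is.na(st0$r2))

  # n = 4, one singleton site: R2 = sqrt(0.75/4)/1
  m4 <- do.call(rbind, strsplit(c("AAT", "AAA", "AAA", "AAA"), ""))
  rownames(m4) <- paste0("s", 1:4)
  st4 <- neutrality_stats(m4)
  expect_equal(st4$pi_count, 0.5)
  expect_equal(st4$r2, sqrt(0.75 / 4), tolerance = 1e-12)

  expect_error(neutrality_stats(m[1, , drop = FALSE]), "at least 2")
  allgap <- matrix("-", 3, 3)
  expect_error(neutrality_stats(allgap), "gap-free")
})

test_that("statistics equal the brute-force oracle on random alignments", {
  for (i in 1:30) {
    m <- rand_aln(n = sample(4:20, 1), L = 3 * sample(10:100, 1),
                  seed = 1000 + i)
    st <- neutrality_stats(m)
    or <- oracle_stats(m)
    expect_equal(st$S, or$S)
    expect_equal(st$pi, or$pi, tolerance = 1e-12)
    expect_equal(st$hap_div, or$hap_div, tolerance = 1e-12)
    expect_equal(st$K, or$K)
    if (is.na(or$tajima_d)) expect_true(is.na(st$tajima_d))
    else expect_equal(st$tajima_d, or$tajima_d, tolerance = 1e-12)
    if (is.na(or$r2)) expect_true(is.na(st$r2))
    else expect_equal(st$r2, or$r2, tolerance = 1e-12)
    expect_true(st$hap_div >= 0 && st$hap_div <= 1)
    expect_true((st$hap_div == 0) == (st$K == 1))
  }
})

test_that("Tajima's D and Fu & Li's D* respond to genealogy shape", {
  # star genealogy: every sequence carries private singletons -> D < 0
  n <- 12; L <- 300
  star <- matrix("A", n, L, dimnames = list(paste0("s", 1:n), NULL))
  set.seed(5)
  for (i in seq_len(n)) star[i, sample(L, 6)] <- "T"
  st <- neutrality_stats(star)
  expect_lt(st$tajima_d, 0)
  expect_lt(st$fu_li_d_star, 0)
  expect_lt(st$fu_li_f_star, 0)
  # deep balanced split: two diverged haplogroups -> D > 0
  deep <- matrix("A", n, L, dimnames = list(paste0("s", 1:n), NULL))
  deep[1:(n / 2), 1:40] <- "G"
  std <- neutrality_stats(deep)
  expect_gt(std$tajima_d, 0)
  expect_gt(std$fu_li_f_star, 0)
})

test_that("Strobeck's S matches exact Ewens enumeration and its bounds", {
  # exact oracle: coefficients of the rising factorial give |s(n, k)|
  ewens_oracle <- function(n, K, theta) {
    coefs <- 1
    for (i in 0:(n - 1)) coefs <- c(0, coefs) + c(coefs * i, 0)
    # coefs[k + 1] = coefficient of theta^k, i.e. |s(n, k)|
    probs <- vapply(1:n, function(k)
      coefs[k + 1] * theta^k / prod(theta + 0:(n - 1)), numeric(1))
    sum(probs[1:K])
  }
  for (n in c(4, 7, 10)) for (K in c(1, 2, n)) for (theta in c(0.5, 2, 7)) {
    got <- pannlrome:::ewens_prob_at_most(n, K, theta)
    expect_equal(got, ewens_oracle(n, K, theta), tolerance = 1e-10)
    expect_true(got >= 0 && got <= 1)
  }
  expect_equal(pannlrome:::ewens_prob_at_most(8, 3, 0), 1)
  # S = 0 (theta_hat = 0) gives Strobeck's S = 1 through the public API
  ident <- matrix("A", 4, 9, dimnames = list(paste0("s", 1:4), NULL))
  expect_equal(neutrality_stats(ident)$strobeck_s, 1)
})

test_that("the Tajima null harness is seeded and handles theta = 0", {
  h <- tajima_d_null(8, 0.01, length = 300, reps = 25, seed = 3)
  h2 <- tajima_d_null(8, 0.01, length = 300, reps = 25, seed = 3)
  expect_identical(h$values, h2$values)
  h0 <- tajima_d_null(8, 0, length = 300, reps = 5, seed = 3)
  expect_true(all(is.na(h0$values)))
  expect_true(is.na(h0$mean))
})

test_that("column domain annotation votes over non-gap residues", {
  m <- matrix("A", 5, 30, dimnames = list(paste0("g", 1:5), NULL))
  aln <- codon_alignment(m)
  dom <- data.frame(gene_id = paste0("g", 1:5), label = "NB",
                    start = 1, end = 10)
  expect_true(all(annotate_columns(aln, dom) == "NB"))
  # 3 NB vs 2 LRR at every column -> NB
  dom2 <- data.frame(gene_id = paste0("g", 1:5),
                     label = c("NB", "NB", "NB", "LRR", "LRR"),
                     start = 1, end = 10)
  expect_true(all(annotate_columns(aln, dom2) == "NB"))
  # 2 vs 2 tie (fifth gene unannotated votes none) -> depends on counts:
  # with 2 NB, 2 LRR and 1 none every label ties at 2 -> none
  dom3 <- data.frame(gene_id = paste0("g", 1:4),
                     label = c("NB", "NB", "LRR", "LRR"),
                     start = 1, end = 10)
  expect_true(all(annotate_columns(aln, dom3) == "none"))
  bad <- data.frame(gene_id = "g1", label = "NB", start = 1, end = 99)
  expect_error(annotate_columns(aln, bad), "beyond protein length")
})

test_that("domain-restricted statistics isolate the labeled columns", {
  set.seed(21)
  aln <- simulate_neutral_alignment(6, 60, 0.1, seed = 13)
  labs <- rep("NB", 20)
  full <- neutrality_stats(aln)
  nb <- domain_subset_stats(aln, labs, "NB")
  expect_equal(nb$pi, full$pi)
  expect_equal(nb$S, full$S)
  absent <- domain_subset_stats(aln, labs, "LRR")
  expect_true(is.na(absent$pi))
  expect_equal(absent$L, 0L)
  # variable LRR columns, constant NB columns: pi(LRR) > pi(NB) = 0
  m <- matrix("A", 6, 60, dimnames = list(paste0("g", 1:6), NULL))
  for (i in 1:6) m[i, sample(31:60, 8)] <- "C"
  labs2 <- rep(c("NB", "LRR"), each = 10)
  pin <- domain_subset_stats(m, labs2, "NB")
  pil <- domain_subset_stats(m, labs2, "LRR")
  expect_equal(pin$pi, 0)
  expect_gt(pil$pi, 0)
})

test_that("invariable codons require identity and no gaps", {
  m <- matrix(rep(strsplit("ATGAAATTTGGG", "")[[1]], 4), 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), NULL))
  iv <- invariable_codons(codon_alignment(m))
  expect_equal(iv$count, 4L)
  m2 <- m; m2[2, 10] <- "C"      # codon 4 now variable
  expect_equal(invariable_codons(codon_alignment(m2))$count, 3L)
  m3 <- m; m3[1, 1] <- "-"       # gap kills codon 1
  expect_equal(invariable_codons(codon_alignment(m3))$positions,
               c(2L, 3L, 4L))
})

test_that("flag enrichment matches exact hypergeometric probabilities", {
  universe <- paste0("g", 1:20)
  flagged <- paste0("g", 1:5)
  ogs <- list(OG1 = paste0("g", 1:5))
  out <- flag_enrichment(ogs, list(rare = flagged), universe = universe)
  expect_equal(out$p, 1 / choose(20, 5), tolerance = 1e-12)
  # an orthogroup spanning the whole universe: p = 1 for every flag
  all_og <- list(OG1 = universe)
  out2 <- flag_enrichment(all_og, list(rare = flagged), universe = universe)
  expect_equal(out2$p, 1)
  expect_error(flag_enrichment(ogs, list(rare = "zz"), universe = universe),
               "outside the universe")
})

test_that("BH q-values reproduce the reference step-up procedure", {
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))
    # independent step-up implementation
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    qref <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
    expect_equal(p.adjust(p, "BH"), qref, tolerance = 1e-12)
    ogs <- setNames(lapply(seq_along(p), function(j) paste0("g", j)),
                    paste0("OG", seq_along(p)))
  }
  # q-values are monotone in p within the ranked list
  out <- flag_enrichment(
    list(OG1 = paste0("g", 1:3), OG2 = paste0("g", 4:10)),
    list(f1 = paste0("g", 1:3), f2 = paste0("g", c(1, 5))),
    universe = paste0("g", 1:10))
  expect_true(all(diff(out$q[order(out$p)]) >= -1e-12))
})

test_that("pair correlation returns Pearson r, slope and sentinels", {
  expect_equal(pair_correlation(1:5, 1:5)$r, 1)
  expect_equal(pair_correlation(1:5, -(1:5))$r, -1)
  a <- c(1, 2, 3); b <- c(2, 4, 6.5)
  pc <- pair_correlation(a, b)
  r_brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pc$r, r_brute, tolerance = 1e-12)
  expect_equal(pc$slope, cov(a, b) / var(a), tolerance = 1e-12)
  expect_true(is.na(pair_correlation(c(1, 1, 1), 1:3)$r))
})

test_that("expression threshold falls between background and signal", {
  set.seed(33)
  intron <- rexp(500, 1 / 5)            # all small
  nlr <- 1000 + rexp(500, 1 / 200)      # all large
  thr <- expression_threshold(nlr, intron)
  expect_gt(thr, 10)
  expect_lte(thr, 1000)
  # identical distributions: no positive excess
  x <- rexp(300, 1 / 50)
  expect_true(is.na(expression_threshold(x, x)))
  expect_true(is.na(expression_threshold(rep(0, 10), rep(0, 10))))
  # bimodal mixture: threshold between the modes
  bg <- exp(rnorm(800, log(20), 0.4))
  sig <- exp(rnorm(800, log(500), 0.4))
  thr2 <- expression_threshold(sig, bg)
  expect_gt(thr2, 20)
  expect_lt(thr2, 500)
})
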