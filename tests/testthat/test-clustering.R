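test_that("local alignment scores match the brute-force DP oracle", {
  expect_equal(sw_score("HEAGAWGHEE", "PAWHEAE"),
               oracle_sw("HEAGAWGHEE", "PAWHEAE"))
  set.seed(31)
  aas <- rownames(get_blosum())[1:20]
  for (i in 1:15) {
    a <- paste0(sample(aas, sample(5:15, 1), replace = TRUE), collapse = "")
    b <- paste0(sample(aas, sample(5:15, 1), replace = TRUE), collapse = "")
    expect_equal(sw_score(a, b), oracle_sw(a, b))
  }
})

test_that("similarity edges are normalized and floored", {
  prot <- c(p1 = "MKVAGHWLLRTESNKV", p2 = "MKVAGHWLLRTESNKV",
            p3 = "MKVAGHWLLRTESDKV")
  ed <- pairwise_similarity(prot, score_floor = 10, prefilter = FALSE)
  id_edge <- ed[ed$gene_a == "p1" & ed$gene_b == "p2", ]
  expect_equal(id_edge$normalized_score, 1.0)
  expect_true(all(ed$normalized_score <= 1 & ed$normalized_score >= 0))
  # dissimilar short sequences fall below the floor
  ed2 <- pairwise_similarity(c(a = "MKVAGH", b = "WTRESP"),
                             score_floor = 50, prefilter = FALSE)
  expect_equal(nrow(ed2), 0)
  expect_error(pairwise_similarity(c(a = "", b = "MKV")), "empty")
})

test_that("edge typing follows the ortholog/inparalog rules", {
  # 2 accessions x 1 gene each: mutual best edge is an ortholog
  acc <- c(a1 = "A", b1 = "B")
  ed <- data.frame(gene_a = "a1", gene_b = "b1", score = 100,
                   normalized_score = 1)
  ty <- classify_edges(ed, acc)
  expect_equal(ty$type, "ortholog")

  # a1, a2 near-identical in A, both hitting b1: inparalog + co-ortholog
  acc <- c(a1 = "A", a2 = "A", b1 = "B")
  ed <- data.frame(gene_a = c("a1", "a1", "a2"),
                   gene_b = c("a2", "b1", "b1"),
                   score = c(200, 150, 140),
                   normalized_score = c(1, 0.8, 0.7))
  ty <- classify_edges(ed, acc)
  tt <- setNames(ty$type, paste(ty$gene_a, ty$gene_b))
  expect_equal(tt[["a1 a2"]], "inparalog")
  expect_equal(tt[["a1 b1"]], "ortholog")
  expect_equal(tt[["a2 b1"]], "co-ortholog")

  # within-accession edge below a member's best cross score is dropped
  ed$score <- c(120, 150, 140)   # a1-a2 < a1's best between (150)
  ty2 <- classify_edges(ed, acc)
  expect_false("inparalog" %in% ty2$type)
})

test_that("MCL separates components and splits the weak barbell", {
  tri <- function(v) t(combn(v, 2))
  e <- rbind(tri(c("a", "b", "c")), tri(c("x", "y", "z")))
  ed <- data.frame(gene_a = e[, 1], gene_b = e[, 2], weight = 1)
  cl <- mcl_cluster(ed)
  expect_equal(lengths(cl), c(3L, 3L))
  expect_setequal(cl[[1]], c("a", "b", "c"))

  single <- mcl_cluster(data.frame(gene_a = "a", gene_b = "b", weight = 1))
  expect_equal(single, list(c("a", "b")))

  # barbell: two 4-cliques joined by one weak edge
  k4a <- tri(c("a1", "a2", "a3", "a4")); k4b <- tri(c("b1", "b2", "b3", "b4"))
  ed <- data.frame(gene_a = c(k4a[, 1], k4b[, 1], "a1"),
                   gene_b = c(k4a[, 2], k4b[, 2], "b1"),
                   weight = c(rep(1, 12), 0.1))
  cl <- mcl_cluster(ed, inflation = 1.5)
  expect_equal(lengths(cl), c(4L, 4L))
  # reference Markov clustering on the same dense matrix
  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(ed))) {
    A[ed$gene_a[i], ed$gene_b[i]] <- ed$weight[i]
    A[ed$gene_b[i], ed$gene_a[i]] <- ed$weight[i]
  }
  comp <- oracle_mcl(A, inflation = 1.5)
  ref <- lapply(split(nodes, comp), sort)
  expect_setequal(lapply(cl, identity), unname(ref))
})

test_that("clustering is invariant under gene relabeling", {
  set.seed(4)
  e <- t(combn(6, 2))
  ed <- data.frame(gene_a = paste0("g", e[, 1]),
                   gene_b = paste0("g", e[, 2]),
                   weight = round(runif(nrow(e)), 2))
  base <- mcl_cluster(ed)
  perm <- setNames(paste0("h", sample(6)), paste0("g", 1:6))
  ed2 <- data.frame(gene_a = perm[ed$gene_a], gene_b = perm[ed$gene_b],
                    weight = ed$weight)
  remapped <- lapply(mcl_cluster(ed2), function(cl)
    sort(names(perm)[match(cl, perm)]))
  expect_setequal(lapply(base, identity), remapped)
})

test_that("orthogroup formation partitions the gene universe", {
  res <- form_ogs(list(c("a", "b"), "c"), all_genes = c("a", "b", "c", "d"))
  expect_equal(length(res$ogs), 1)
  expect_setequal(res$singletons, c("c", "d"))

  res2 <- form_ogs(list(letters[1:5]))
  expect_equal(lengths(res2$ogs), c(OG0001 = 5L))
  expect_equal(length(res2$singletons), 0)

  cl12 <- split(paste0("g", 1:24), rep(1:12, each = 2))
  res3 <- form_ogs(cl12)
  expect_equal(length(res3$ogs), 12)
  # no gene lost or duplicated
  all3 <- c(unlist(res3$ogs), res3$singletons)
  expect_setequal(all3, paste0("g", 1:24))
  expect_false(anyDuplicated(all3) > 0)
  expect_error(form_ogs(list(c("a", "b"), c("b", "c"))), "partition")
})
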