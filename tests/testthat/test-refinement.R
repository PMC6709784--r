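test_that("progressive alignment is optimal for pairs and keeps order", {
  # identical sequences: gap-free
  m <- align_og(c(a = "MKVLLAGH", b = "MKVLLAGH", c = "MKVLLAGH"))
  expect_false(any(m == "-"))
  expect_equal(rownames(m), c("a", "b", "c"))
  # two sequences: the alignment attains the brute-force global optimum
  m2 <- align_og(c(x = "MKV", y = "MV"))
  expect_equal(sum(m2 == "-"), 1)
  got <- score_pair_alignment(paste0(m2["x", ], collapse = ""),
                              paste0(m2["y", ], collapse = ""))
  expect_equal(got, oracle_nw("MKV", "MV"))
  set.seed(12)
  aas <- rownames(get_blosum())[1:20]
  for (i in 1:10) {
    a <- paste0(sample(aas, sample(6:12, 1), replace = TRUE), collapse = "")
    b <- paste0(sample(aas, sample(6:12, 1), replace = TRUE), collapse = "")
    mm <- align_og(c(p = a, q = b))
    sc <- score_pair_alignment(paste0(mm["p", ], collapse = ""),
                               paste0(mm["q", ], collapse = ""))
    expect_equal(sc, oracle_nw(a, b))
  }
  expect_error(align_og(c(a = "MKV")), "at least 2")
})

test_that("codon back-translation expands residues and reports mismatches", {
  out <- protein_to_codon(c(g = "M-K"), c(g = "ATGAAA"))
  expect_equal(paste0(as.matrix(out)["g", ], collapse = ""), "ATG---AAA")
  # trailing stop codon excluded
  out2 <- protein_to_codon(c(g = "MK"), c(g = "ATGAAATAA"))
  expect_equal(paste0(as.matrix(out2)["g", ], collapse = ""), "ATGAAA")
  # mismatch reported at the right residue
  expect_error(protein_to_codon(c(g = "MW"), c(g = "ATGAAA")),
               "residue 2")
})

test_that("outlier detection flags the alien row and is deterministic", {
  set.seed(77)
  fam <- as.matrix(simulate_neutral_alignment(9, 150, 0.05, seed = 5))
  alien <- sample(c("A", "C", "G", "T"), 150, replace = TRUE)
  m <- rbind(fam, alien = alien)
  out <- detect_outliers(m, seed = 1)
  expect_equal(out, "alien")
  expect_identical(detect_outliers(m, seed = 9), detect_outliers(m, seed = 9))
  # identical rows: nothing flagged
  ident <- matrix("A", 10, 30, dimnames = list(paste0("r", 1:10), NULL))
  expect_equal(length(detect_outliers(ident, seed = 1)), 0)
  # fewer than 5 rows: no-op
  expect_equal(length(detect_outliers(m[1:4, ], seed = 1)), 0)
})

test_that("NJ recovers star trees and additive quartets", {
  ident <- matrix("A", 3, 30, dimnames = list(c("a", "b", "c"), NULL))
  tr <- build_tree(ident, bootstrap_reps = 0)
  expect_true(all(tr$edge.length == 0))

  # additive quartet: d(a,b)=2, d(c,d)=4, all cross distances 6 (per 99
  # sites); mutations on disjoint site sets realize the tree exactly
  L <- 99
  base <- rep("A", L)
  mut <- function(s, pos) { s[pos] <- "G"; s }
  a <- mut(base, 1); b <- mut(base, 2)
  core <- mut(base, 3:5)
  c_ <- mut(core, 6:7); d_ <- mut(core, 8:9)
  m <- rbind(a = a, b = b, c = c_, d = d_)
  # hamming distances by direct count
  D <- matrix(0, 4, 4, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:3) for (j in (i + 1):4)
    D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
  expect_equal(unname(D["a", "b"]), 2)
  tr <- build_tree(m, bootstrap_reps = 50, seed = 3)
  expect_equal(tree_quartet_split(tr, rownames(m)), oracle_quartet(D))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("duplication nodes are typed simple or complex", {
  acc <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,c1:1):1);")
  d1 <- detect_duplications(t1, acc)$duplications
  expect_equal(nrow(d1), 1)
  expect_equal(d1$type, "simple")

  t2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,c1:1):1);")
  d2 <- detect_duplications(t2, acc)$duplications
  expect_equal(d2$type, "complex")

  t3 <- ape::read.tree(text = "((a1:1,b1:1):1,c1:2);")
  d3 <- detect_duplications(t3, c(a1 = "A", b1 = "B", c1 = "C"))
  expect_equal(nrow(d3$duplications), 0)
})

test_that("the 5% rule prunes rare paralogs and splits pervasive ones", {
  # 40 occupied accessions, 1 duplicated: f = 0.025 -> prune
  tips <- paste0("g", 1:40)
  nwk <- paste0("((g1:0.05,g41:0.25):0.1,",
                paste0(tips[-1], ":0.1", collapse = ","), ");")
  tr <- ape::read.tree(text = nwk)
  acc <- setNames(paste0("A", 1:40), tips)
  acc["g41"] <- "A1"
  res <- refine_og("OG1", c(tips, "g41"), tr, acc)
  expect_equal(names(res$ogs), "OG1")
  expect_equal(length(res$ogs$OG1), 40)
  pruned <- res$log$gene_id[res$log$status == "pruned_paralog"]
  expect_equal(pruned, "g41")  # the longer-branch copy goes

  # 40 occupied, 5 duplicated: f = 0.125 -> split at the duplication node
  dups <- paste0("d", 1:5)
  nwk2 <- paste0("((", paste0(tips, ":0.1", collapse = ","), "):2,(",
                 paste0(dups, ":0.1", collapse = ","), "):2);")
  tr2 <- ape::read.tree(text = nwk2)
  acc2 <- c(setNames(paste0("A", 1:40), tips),
            setNames(paste0("A", 1:5), dups))
  res2 <- refine_og("OG2", c(tips, dups), tr2, acc2)
  expect_equal(sort(lengths(res2$ogs)), c(5L, 40L), ignore_attr = TRUE)
  expect_setequal(res2$ogs[["OG2.1"]], tips)
  expect_setequal(res2$ogs[["OG2.2"]], dups)
  expect_true(all(grepl("^split_to:OG2\\.", res2$log$status)))

  # no duplications: unchanged
  res3 <- refine_og("OG3", c("x", "y", "z"),
                    ape::read.tree(text = "((x:1,y:1):1,z:1);"),
                    c(x = "A1", y = "A2", z = "A3"))
  expect_equal(res3$ogs$OG3, c("x", "y", "z"))
  expect_true(all(res3$log$status == "kept"))
})

test_that("size thresholds partition orthogroups into cloud/shell/core", {
  expect_equal(classify_og_type(c(12, 13, 51, 52)),
               c("cloud", "shell", "shell", "core"))
  expect_equal(classify_og_type(30), "shell")
  expect_error(classify_og_type(1), "at least 2")
  sizes <- sample(2:80, 50, replace = TRUE)
  expect_equal(sum(table(classify_og_type(sizes))), 50)
})

test_that("physical clusters chain by single linkage within 200 kb", {
  g <- data.frame(gene_id = c("x", "y"), accession = "a", contig = "c1",
                  start = c(1000, 150000))
  expect_true(all(detect_physical_clusters(g)$clustered))
  g2 <- data.frame(gene_id = c("x", "y"), accession = "a", contig = "c1",
                   start = c(1000, 250000))
  expect_false(any(detect_physical_clusters(g2)$clustered))
  g3 <- data.frame(gene_id = c("x", "y", "z"), accession = "a",
                   contig = "c1", start = c(0, 150000, 300000))
  r3 <- detect_physical_clusters(g3)
  expect_true(all(r3$clustered))
  expect_equal(length(unique(r3$cluster_id)), 1)
})

test_that("head-to-head pairs require divergent orientation within 10 kb", {
  g <- data.frame(gene_id = c("A", "B"), accession = "a", contig = "c1",
                  start = c(1000, 3500), end = c(3000, 6000),
                  strand = c("-", "+"))
  expect_equal(nrow(detect_pairs(g)), 1)
  g$strand <- c("+", "-")    # convergent
  expect_equal(nrow(detect_pairs(g)), 0)
  g$strand <- c("-", "+"); g$start[2] <- 53000; g$end[2] <- 56000
  expect_equal(nrow(detect_pairs(g)), 0)
  g$strand <- c(NA, "+")
  expect_warning(out <- detect_pairs(g), "missing strand")
  expect_equal(nrow(out), 0)
})

test_that("orthogroup annotation votes over member metadata", {
  meta <- data.frame(gene_id = paste0("g", 1:12),
                     class = c(rep("TNL", 10), rep("NL", 2)),
                     clustered = c(rep(TRUE, 7), rep(FALSE, 5)),
                     paired = FALSE,
                     has_id = c(TRUE, rep(FALSE, 11)))
  star <- ape::read.tree(text = paste0("(", paste0("g", 1:12, ":0",
                                                   collapse = ","), ");"))
  out <- annotate_og("OG9", paste0("g", 1:12), meta, star)
  expect_equal(out$class, "TNL")
  expect_true(out$id_flag)          # one member with an ID is enough
  expect_true(out$clustered_flag)
  expect_equal(out$mean_branch_length, 0)
  expect_equal(out$og_type, "cloud")
})
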