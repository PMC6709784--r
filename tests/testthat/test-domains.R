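test_that("NLR identification requires NB, TIR or RPW8", {
  expect_false(identify_nlr(c("LRR", "CC")))
  expect_true(identify_nlr("NB"))
  expect_true(identify_nlr("PF01582"))      # TIR by Pfam accession
  expect_true(identify_nlr(c("RPW8", "LRR")))
  expect_false(identify_nlr(character()))
})

test_that("coiled-coil vote takes residues supported by two predictors", {
  out <- vote_cc(data.frame(start = c(10, 15), end = c(40, 45),
                            source = c("coils", "paircoil")))
  expect_equal(out, data.frame(start = 15L, end = 40L))
  # a single predictor can never reach two votes
  expect_equal(nrow(vote_cc(data.frame(start = c(1, 50), end = c(30, 80),
                                       source = "coils"))), 0)
  # unanimous agreement
  out3 <- vote_cc(data.frame(start = c(1, 1, 1), end = c(30, 30, 30),
                             source = c("coils", "paircoil", "nlrparser")))
  expect_equal(out3, data.frame(start = 1L, end = 30L))
})

test_that("vote_cc is monotone in added predictor intervals", {
  set.seed(8)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    calls <- data.frame(
      start = sample(1:80, k, replace = TRUE),
      source = sample(c("coils", "paircoil", "nlrparser"), k,
                      replace = TRUE))
    calls$end <- calls$start + sample(5:40, k, replace = TRUE)
    base <- vote_cc(calls)
    extra <- rbind(calls, data.frame(start = 20, end = 60,
                                     source = "nlrparser"))
    more <- vote_cc(extra)
    cover <- function(v) {
      if (!nrow(v)) return(integer())
      unlist(Map(seq, v$start, v$end))
    }
    expect_true(all(cover(base) %in% cover(more)))
  }
})

test_that("class assignment follows the TIR > RPW8 > CC+NB > NB precedence", {
  expect_equal(assign_class(c("TIR", "NB", "LRR")), "TNL")
  expect_equal(assign_class(c("CC", "NB", "LRR")), "CNL")
  expect_equal(assign_class(c("NB", "LRR")), "NL")
  expect_equal(assign_class(c("RPW8", "NB")), "RNL")
  expect_equal(assign_class(c("TIR", "RPW8", "CC", "NB")), "TNL")
  expect_error(assign_class(c("LRR", "CC")), "no NLR class")
})

test_that("architectures collapse repeats and ignore order", {
  expect_equal(collapse_architecture(c("TIR", "NB", "LRR", "LRR", "LRR")),
               "LRR+NB+TIR")
  expect_equal(collapse_architecture("NB"), "NB")
  expect_equal(collapse_architecture(c("WRKY", "TIR", "NB", "LRR")),
               collapse_architecture(c("TIR", "NB", "LRR", "WRKY")))
  expect_equal(collapse_architecture(character()), "")
})

test_that("integrated domains are tabulated with the singleton filter", {
  acc <- c(g1 = "a1", g2 = "a1", g3 = "a2", g4 = "a2")
  dom <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1", "g4"),
    label = c("WRKY", "WRKY", "WRKY", "kinase", "NB"))
  out <- find_integrated_domains(dom, acc, c("g1", "g2", "g3", "g4"))
  wrky <- out[out$label == "WRKY", ]
  expect_equal(wrky$n_genes, 3L)
  expect_equal(wrky$n_accessions, 2L)
  expect_false(wrky$singleton)
  kin <- out[out$label == "kinase", ]
  expect_true(kin$singleton)
  expect_false("NB" %in% out$label)
  # no non-canonical labels: empty table
  none <- find_integrated_domains(
    data.frame(gene_id = "g1", label = "NB"), acc, "g1")
  expect_equal(nrow(none), 0)
})

test_that("architecture intersections enumerate UpSet cells", {
  one <- architecture_intersections("x", "x", "x")
  expect_equal(nrow(one), 1)
  expect_equal(as.integer(attr(one, "intersections")["A&B&C"]), 1L)
  two <- architecture_intersections(c("x", "y"), "y", character())
  ix <- attr(two, "intersections")
  expect_equal(as.integer(ix["A"]), 1L)
  expect_equal(as.integer(ix["A&B"]), 1L)
  expect_equal(sum(ix), nrow(two))
  empty <- architecture_intersections(character(), character(), character())
  expect_equal(nrow(empty), 0)
})

test_that("classification recovers the simulator's truth exactly", {
  sim <- small_panel()
  cls <- classify_genes(sim$domains)
  expect_true(all(cls$is_nlr))
  # exactly one class per NLR; counts sum to the NLR count
  expect_false(any(is.na(cls$class)))
  expect_equal(sum(table(cls$class)), nrow(cls))
  truth <- sim$truth$architecture[cls$gene_id]
  expect_identical(unname(cls$ordered_architecture), unname(truth))
  truth_class <- vapply(strsplit(truth, ";"), function(x)
    assign_class(unique(x)), character(1))
  expect_identical(unname(cls$class), unname(truth_class))
})
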