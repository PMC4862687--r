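test_that("progressive alignment matches pairwise DP oracles", {
  # identical pair aligns gap-free
  al <- progressive_align(c(a = "MKTAYIAK", b = "MKTAYIAK"))
  expect_equal(unname(al$aligned), c("MKTAYIAK", "MKTAYIAK"))

  # one-gap case, cross-checked against Needleman-Wunsch in Biostrings
  al2 <- progressive_align(c(a = "ACDEFG", b = "ACEFG"))
  expect_equal(al2$aligned[["a"]], "ACDEFG")
  expect_equal(al2$aligned[["b"]], "AC-EFG")
  ora <- Biostrings::pairwiseAlignment(
    Biostrings::AAString("ACDEFG"), Biostrings::AAString("ACEFG"),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 0, gapExtension = 8)
  expect_equal(as.character(Biostrings::alignedSubject(ora)), "AC-EFG")

  # identical sequences stay identical rows in a 3-way alignment
  al3 <- progressive_align(c(x = "MKTAYIAK", y = "MKTAYIAK", z = "MKTAYIK"))
  expect_equal(al3$aligned[["x"]], al3$aligned[["y"]])
  expect_equal(al3$length, nchar(al3$aligned[["x"]]))
  expect_error(progressive_align(c(a = "MKT")), ">= 2")
})

test_that("Jukes-Cantor distances follow the closed form and saturate", {
  m <- c(s1 = strrep("A", 10), s2 = strrep("A", 10))
  expect_equal(jc_distance(m)[1, 2], 0)
  # p = 0.1, k = 20: frozen from direct evaluation of the closed form
  m2 <- c(s1 = strrep("A", 10), s2 = paste0(strrep("A", 9), "C"))
  expect_equal(jc_distance(m2)[1, 2], 0.1056644, tolerance = 1e-6)
  # p at the domain boundary returns the cap with a warning
  m3 <- c(s1 = paste(rep(c("A", "C", "D", "E", "F"), 5), collapse = ""),
          s2 = paste(rep(c("G", "H", "I", "K", "L"), 5), collapse = ""))
  expect_warning(d3 <- jc_distance(m3), "saturated")
  expect_equal(d3[1, 2], 10)
  # monotone increasing in p on the valid domain
  ds <- vapply(1:17, function(k) {
    a <- strrep("A", 20)
    b <- paste0(strrep("C", k), strrep("A", 20 - k))
    jc_distance(c(x = a, y = b))[1, 2]
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
  # pairwise deletion: gapped columns are ignored
  m4 <- c(s1 = "AAAA--", s2 = "AAAACC")
  expect_equal(jc_distance(m4)[1, 2], 0)
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("neighbor joining is exact on additive matrices", {
  # 4-taxon: recovers the generating topology and branch lengths; oracle =
  # check the tree metric reproduces the input path lengths
  d4 <- matrix(c(0, 3, 7, 8, 3, 0, 6, 7, 7, 6, 0, 5, 8, 7, 5, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- neighbor_joining(d4)
  expect_equal(ape::cophenetic.phylo(t4)[LETTERS[1:4], LETTERS[1:4]], d4,
               tolerance = 1e-12)
  # ((A,B),(C,D)) split present
  expect_true(ape::is.monophyletic(t4, c("A", "B")))

  # 100 random additive matrices, 5-12 taxa: path lengths within 1e-9 and
  # topology identical to an independent NJ implementation
  worst <- 0
  for (s in 1:100) {
    sz <- 5L + (s %% 8L)
    fix <- random_additive_matrix(sz, seed = 1000 + s)
    tr <- neighbor_joining(fix$d)
    err <- max(abs(ape::cophenetic.phylo(tr)[rownames(fix$d),
                                             rownames(fix$d)] - fix$d))
    worst <- max(worst, err)
    if (s %% 10 == 0) {
      td <- ape::dist.topo(ape::unroot(tr),
                           ape::unroot(ape::nj(stats::as.dist(fix$d))))
      expect_equal(as.numeric(td), 0)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("bootstrap supports behave under resampling and permutation", {
  # two well-separated cherries: near-certain support
  aln <- c(a = paste0(strrep("A", 30), strrep("C", 5)),
           b = paste0(strrep("A", 30), strrep("C", 4), "T"),
           c = paste0(strrep("T", 30), strrep("C", 5)),
           d = paste0(strrep("T", 30), strrep("C", 4), "G"))
  bs <- bootstrap_support(aln, n_replicates = 100, seed = 4,
                          alphabet_size = 4)
  sup <- attr(bs, "supports")
  expect_length(sup, 1L)
  expect_gte(unname(sup), 95)

  # a single replicate can only produce 0 or 100
  bs1 <- bootstrap_support(aln, n_replicates = 1, seed = 9,
                           alphabet_size = 4)
  expect_true(all(attr(bs1, "supports") %in% c(0, 100)))

  # same seed, same supports; leaf order never matters
  bs2 <- bootstrap_support(aln, n_replicates = 50, seed = 13,
                           alphabet_size = 4)
  bs3 <- bootstrap_support(aln[c(3, 1, 4, 2)], n_replicates = 50, seed = 13,
                           alphabet_size = 4)
  expect_equal(unname(attr(bs2, "supports")), unname(attr(bs3, "supports")))
})

test_that("outgroup rooting splits on the separating edge or refuses", {
  tr <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:2):1);"))
  r1 <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(r1))
  kids <- ape::cophenetic.phylo(r1)
  expect_equal(unname(kids["A", "D"]), unname(ape::cophenetic.phylo(tr)["A", "D"]))

  r2 <- root_with_outgroup(tr, c("C", "D"))
  expect_true(ape::is.rooted(r2))
  expect_true(ape::is.monophyletic(r2, c("C", "D")))
  expect_true(ape::is.monophyletic(r2, c("A", "B")))

  expect_error(root_with_outgroup(tr, c("A", "C")), "monophyletic")
  expect_error(root_with_outgroup(tr, c("A", "Z")), "not in tree")
})
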