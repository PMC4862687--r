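test_that("find_orfs locates a minimal forward ORF with its stop", {
  orfs <- find_orfs(c(t1 = "ATGAAATAA"), min_aa_len = 2L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$frame, 1L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$aa_len, 2L)
})

test_that("find_orfs agrees with a brute-force six-frame scan", {
  # oracle: translate every frame with Biostrings and regex maximal
  # M-to-stop stretches
  brute_count <- function(seq, min_aa) {
    n <- 0L
    for (strand in 1:2) {
      s <- if (strand == 1) Biostrings::DNAString(seq) else
        Biostrings::reverseComplement(Biostrings::DNAString(seq))
      for (off in 0:2) {
        len <- (length(s) - off) %/% 3 * 3
        if (len < 3) next
        aa <- as.character(suppressWarnings(Biostrings::translate(
          Biostrings::subseq(s, off + 1, off + len),
          if.fuzzy.codon = "X")))
        # segments between stops; a trailing open segment has no stop
    n_stops <- lengths(regmatches(aa, gregexpr("*", aa, fixed = TRUE)))
        segs <- strsplit(paste0(aa, "#"), "*", fixed = TRUE)[[1]]
        segs[length(segs)] <- sub("#$", "", segs[length(segs)])
        for (k in seq_along(segs)) {
          seg <- segs[k]
          closed <- k <= n_stops
          if (k == 1 && closed) {
            body <- seg                       # edge-anchored, stop-closed
          } else {
            body <- sub("^[^M]*", "", seg)    # needs an ATG
            if (!grepl("M", seg)) next
          }
          if (nchar(body) >= min_aa) n <- n + 1L
        }
      }
    }
    n
  }
  set.seed(11)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(60:240, 1),
                        replace = TRUE), collapse = "")
    mine <- find_orfs(c(x = seq), min_aa_len = 8L)
    expect_equal(nrow(mine), brute_count(seq, 8L), info = seq)
  }
})

test_that("a reverse-strand ORF is found on a negative frame", {
  core <- "ATGAAACCCGGGTTTTAA"   # M K P G F *
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core)))
  tx <- c(t1 = paste0("CCTCC", rc, "GGAGG"))
  orfs <- find_orfs(tx, min_aa_len = 5L)
  expect_true(any(orfs$frame < 0))
  neg <- orfs[orfs$frame < 0, ][1, ]
  # the 5'-truncated ORF is edge-anchored, so it may carry leading codons
  expect_match(orf_protein(tx, neg), "MKPGF$")
})

test_that("all-N transcripts yield no ORFs and protein input errors", {
  expect_equal(nrow(find_orfs(c(x = paste(rep("N", 90), collapse = "")),
                              min_aa_len = 5L)), 0L)
  expect_error(find_orfs(c(x = "MKTAYIAK"), 2L), "alphabet")
})

test_that("end flags follow the stop-then-start curation rule", {
  # in-frame TAA directly before ATG, stop at the 3' end
  tx <- c(t1 = paste0("CCGTAA", "ATGAAACCCGGGTTTTTGAAATAA"))
  orfs <- find_orfs(tx, min_aa_len = 5L)
  o <- flag_orf_ends(tx, orfs[1, ])
  expect_true(o$n_term_ok)
  expect_true(o$c_term_ok)
  expect_true(o$orf_confident)

  # ORF truncated by the contig edge at 3'
  tx2 <- c(t1 = paste0("CCGTAA", "ATGAAACCCGGGTTTTTGAAA"))
  o2 <- flag_orf_ends(tx2, find_orfs(tx2, min_aa_len = 5L)[1, ])
  expect_false(o2$c_term_ok)
  expect_false(o2$orf_confident)

  # upstream stop far beyond the window does not rescue the 5' end
  spacer <- paste(rep("GCA", 100), collapse = "")  # 300 nt, stop-free
  tx3 <- c(t1 = paste0("TAA", spacer, "ATGAAACCCGGGTTTTTGAAATAA"))
  orfs3 <- find_orfs(tx3, min_aa_len = 5L)
  atg <- orfs3[orfs3$start == 303 & orfs3$frame == 1, ]
  o3 <- flag_orf_ends(tx3, atg[1, ], upstream_window_nt = 90L)
  expect_false(o3$n_term_ok)

  expect_error(flag_orf_ends(tx, orfs[1, ], upstream_window_nt = -1L), ">= 0")
})

test_that("end flags ignore appended 3'-UTR sequence beyond the stop", {
  base <- c(t1 = paste0("CCGTAA", "ATGAAACCCGGGTTTTTGAAATAA"))
  o_base <- flag_orf_ends(base, find_orfs(base, 5L)[1, ])
  set.seed(3)
  for (rep in 1:10) {
    utr <- paste(sample(c("A", "C", "G", "T"), sample(1:60, 1),
                        replace = TRUE), collapse = "")
    ext <- stats::setNames(paste0(base, utr), "t1")
    orfs <- find_orfs(ext, 5L)
    o <- flag_orf_ends(ext, orfs[orfs$start == 6 & orfs$frame == 1, ][1, ])
    expect_equal(o[c("n_term_ok", "c_term_ok", "orf_confident")],
                 o_base[c("n_term_ok", "c_term_ok", "orf_confident")])
  }
})
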