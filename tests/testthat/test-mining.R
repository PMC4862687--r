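test_that("mining retains planted receptors and rejects decoys exactly", {
  sim <- make_transcriptome(12, 8, 50, seed = 7)
  res <- mine_receptors(sim$transcripts, sim$seeds, sim$seed_classes)
  ret <- unique(res$candidates$transcript_id[res$candidates$status ==
                                               "retained"])
  receptors <- sim$truth$id[sim$truth$class == "receptor"]
  decoys <- sim$truth$id[sim$truth$class == "decoy"]
  expect_setequal(ret, receptors)                     # sensitivity 1.0
  expect_length(intersect(ret, decoys), 0L)           # specificity 1.0
  expect_true(all(decoys %in% res$candidates$transcript_id))
  expect_true(all(res$candidates$status[res$candidates$transcript_id %in%
                                          decoys] != "retained"))
  # retained receptors carry the expected 7TM annotation
  kept <- res$candidates[res$candidates$status == "retained", ]
  expect_true(all(kept$n_tm_domains == 7L))
  expect_true(all(kept$n_terminus_side == "out"))
})

test_that("mining is idempotent on its own output", {
  sim <- make_transcriptome(6, 3, 10, seed = 21)
  res1 <- mine_receptors(sim$transcripts, sim$seeds, sim$seed_classes)
  kept_tx <- unique(res1$candidates$transcript_id[res1$candidates$status ==
                                                    "retained"])
  res2 <- mine_receptors(sim$transcripts[kept_tx], sim$seeds,
                         sim$seed_classes)
  ret2 <- unique(res2$candidates$transcript_id[res2$candidates$status ==
                                                 "retained"])
  expect_setequal(ret2, kept_tx)
})

test_that("a second round admits receptors reachable only via round-1 hits", {
  # family A seeds are basic/aromatic; the chain candidate c1 is half
  # A-like, half from a disjoint polar alphabet; c2 matches only c1's far
  # half, so it cannot be admitted until c1 joins the database
  set.seed(9)
  alpha_a <- c("K", "R", "H", "Y", "W", "F")
  alpha_b <- c("G", "S", "T", "N", "Q", "D", "E", "P")
  seed_a <- paste(sample(alpha_a, 220, replace = TRUE), collapse = "")
  far_half <- paste(sample(alpha_b, 110, replace = TRUE), collapse = "")
  c1 <- paste0(substr(seed_a, 1, 110), far_half)
  c2 <- paste0(paste(sample(alpha_b, 110, replace = TRUE), collapse = ""),
               far_half)
  tx <- c(chain1 = protein_to_transcript(c1, complete_5p = FALSE, seed = 1),
          chain2 = protein_to_transcript(c2, complete_5p = FALSE, seed = 2))
  res <- mine_receptors(tx, c(seedA = seed_a),
                        c(seedA = "gpcr_seed"),
                        params = list(min_aa_len = 150L))
  kept <- res$candidates[res$candidates$status == "retained", ]
  expect_setequal(unique(kept$transcript_id), c("chain1", "chain2"))
  expect_equal(kept$round_admitted[kept$transcript_id == "chain1"], 1L)
  expect_equal(kept$round_admitted[kept$transcript_id == "chain2"], 2L)
})

test_that("degenerate mining inputs return empty results", {
  empty <- mine_receptors(character(0), c(s = toy_7tm()))
  expect_equal(nrow(empty$candidates), 0L)
  sim0 <- make_transcriptome(0, 0, 5, seed = 3)
  res0 <- mine_receptors(sim0$transcripts, sim0$seeds, sim0$seed_classes)
  expect_equal(sum(res0$candidates$status == "retained"), 0L)
})

test_that("completeness mix drives the curation flag space", {
  sim5 <- make_transcriptome(6, 0, 0,
                             orf_completeness_mix = c(complete = 0, no5 = 1,
                                                      no3 = 0), seed = 5)
  res <- mine_receptors(sim5$transcripts, sim5$seeds, sim5$seed_classes)
  expect_true(all(!res$candidates$n_term_ok))
  expect_true(all(res$candidates$c_term_ok))
  expect_true(all(res$candidates$status == "retained"))
})
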