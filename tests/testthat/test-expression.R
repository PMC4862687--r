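test_that("read mapping enforces inclusive 0.9 similarity and coverage", {
  set.seed(31)
  refs <- c(gene1 = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                          collapse = ""),
            gene2 = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                          collapse = ""))
  exact <- substr(refs[["gene1"]], 101, 200)
  flip <- function(read, k) {
    ch <- strsplit(read, "")[[1]]
    ch[seq_len(k)] <- chartr("ACGT", "TGCA", ch[seq_len(k)])
    paste(ch, collapse = "")
  }
  ct <- map_reads(list(s1 = c(r1 = exact, r2 = flip(exact, 10),
                              r3 = flip(exact, 11))), refs)
  expect_equal(unname(ct$counts["gene1", "s1"]), 2)   # exact + 10 mismatches
  expect_equal(unname(ct$counts["gene2", "s1"]), 0)
  expect_equal(unname(ct$total_mapped["s1"]), 3L)     # library size counts all

  # reverse-complement reads map to the same gene
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(exact)))
  ct2 <- map_reads(c(r1 = rc), refs)
  expect_equal(unname(ct2$counts["gene1", 1]), 1)

  # a read matching two references equally splits fractionally
  refs_dup <- c(g1 = refs[["gene1"]], g2 = refs[["gene1"]])
  ct3 <- map_reads(c(r1 = exact), refs_dup)
  expect_equal(unname(ct3$counts[, 1]), c(0.5, 0.5))
  expect_error(map_reads(c(r1 = exact), character(0)), "empty reference")
})

test_that("rpkm is the unit-cancelling scale with proportionality", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(7, 500, 2e6), rpkm(7, 500, 1e6) / 2)
  # duplicating every read and doubling totals changes nothing
  expect_equal(rpkm(2 * 7, 500, 2 * 1e6), rpkm(7, 500, 1e6))
  expect_error(rpkm(1, 1000, 0), "total")
})

test_that("fold change applies the division-by-zero sentinel", {
  expect_equal(fold_change(8, 2), 2)
  expect_equal(fold_change(5, 0), log2(10000))
  expect_equal(round(fold_change(5, 0), 2), 13.29)
  expect_equal(fold_change(0, 5), -log2(10000))
  expect_true(is.na(fold_change(0, 0)))
  expect_equal(fold_change(c(8, 5, 0), c(2, 0, 0)),
               c(2, log2(10000), NA))
})

test_that("the proportions test matches an exact permutation oracle", {
  mk_table <- function(counts, totals) {
    structure(list(genes = "g", lengths = 1000L,
                   samples = sprintf("s%d", seq_along(counts)),
                   group = rep(c("sexual", "asexual"), each = 6),
                   counts = matrix(counts, 1, dimnames = list("g", NULL)),
                   total_mapped = totals), class = "count_table")
  }
  totals <- rep(30000L, 12)
  # identical proportion vectors: no signal
  same <- mk_table(rep(c(40, 42, 38, 41, 40, 39), 2), totals)
  expect_equal(de_test(same)$p_value, 1)

  # planted 16-fold gene at high counts: decisive in both tests
  strong <- mk_table(c(800, 820, 790, 812, 805, 795,
                       50, 52, 48, 51, 49, 50), totals)
  expect_lt(de_test(strong)$p_value, 1e-4)
  expect_equal(perm_test_gene(strong$counts[1, ], totals, strong$group),
               2 / choose(12, 6), tolerance = 1e-12)

  # a null gene: the parametric p and the exact permutation p agree
  set.seed(17)
  null_counts <- rpois(12, 60)
  weak <- mk_table(null_counts, totals)
  p_param <- de_test(weak)$p_value
  p_perm <- perm_test_gene(null_counts, totals, weak$group)
  expect_lt(abs(p_param - p_perm), 0.2)

  zero <- mk_table(rep(0L, 12), totals)
  res0 <- de_test(zero)
  expect_equal(res0$p_value, 1)
  expect_true(res0$all_zero)
})

test_that("BH correction reproduces the step-up rule and equivariance", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("trend trimming retains the documented middle counts", {
  set.seed(23)
  expect_equal(fit_trend(rnorm(376), rnorm(376))$n_used, 282L)
  expect_equal(fit_trend(rnorm(8), rnorm(8))$n_used, 6L)
  x <- seq(-2, 2, length.out = 40)
  ft <- fit_trend(x, 2 * x + 1)
  expect_equal(ft$slope, 2)
  expect_equal(ft$intercept, 1)
  expect_error(fit_trend(1:3, 1:3, middle_fraction = 0.3), "fewer than 3")
})

test_that("normalization applies the published coefficients exactly", {
  expect_equal(normalize_fc(0, 1), 2.29)
  expect_equal(normalize_fc(3.0, 100), 4.468)
  expect_equal(normalize_fc(1.5, 10, slope = 0, intercept = 0), 1.5)
  expect_error(normalize_fc(1, 0), "> 0")
  # fitted coefficients produce residuals around zero
  x <- runif(50, 0, 3); y <- 0.5 * x - 1 + rnorm(50, 0, 0.01)
  tc <- trend_coefficients(fit_trend(x, y, middle_fraction = 1))
  expect_equal(median(normalize_fc(y, 10^x, tc$slope, tc$intercept)), 0,
               tolerance = 0.02)
})

test_that("enrichment selection is inclusive on fold, strict on alpha", {
  rows <- data.frame(gene_id = c("a", "b", "c", "d"),
                     q_value = c(0.01, 0.01, 0.05, 0.04),
                     log2fc_normalized = c(2.0, 1.99, 4, 2.5),
                     stringsAsFactors = FALSE)
  expect_setequal(select_enriched(rows), c("a", "d"))  # b under fold, c at alpha
})

test_that("trend recovery: the planted abundance bias is re-estimated", {
  # informative recovery conditions: deep libraries, moderate abundance
  # spread, no biological noise, no planted enrichment
  mc <- make_counts(n_genes = 1000, baseline_law = c(log(100), 0.9),
                    enriched_ids = integer(0), fold = 1,
                    biol_sd = 0, dispersion = 0.005,
                    library_size = 330000L, seed = 5)
  ct <- mc$count_table
  R <- rpkm(ct$counts, ct$lengths,
            matrix(ct$total_mapped, nrow = nrow(ct$counts),
                   ncol = ncol(ct$counts), byrow = TRUE))
  y <- fold_change(rowMeans(R[, ct$group == "sexual"]),
                   rowMeans(R[, ct$group == "asexual"]))
  x <- log10(mc$truth$baseline)
  ok <- is.finite(y) & abs(y) < log2(10000)
  expect_equal(fit_trend(x[ok], y[ok])$slope, 0.411, tolerance = 0.05)
})

test_that("trend normalization centres null genes on generator output", {
  # bias-removal check: planted abundance bias only, no enrichment outliers
  meds <- vapply(1:5, function(s) {
    mc <- make_counts(enriched_ids = integer(0), fold = 1, seed = s)
    scr <- analyze_expression(mc$count_table)
    tb <- scr$table
    ok <- is.finite(tb$log2fc_raw) & abs(tb$log2fc_raw) < log2(10000) &
      tb$max_control_rpkm > 0
    tc <- trend_coefficients(fit_trend(log10(tb$max_control_rpkm[ok]),
                                       tb$log2fc_raw[ok]))
    nrm <- normalize_fc(tb$log2fc_raw[ok], tb$max_control_rpkm[ok],
                        tc$slope, tc$intercept)
    median(nrm[!mc$truth$enriched[ok]])
  }, numeric(1))
  expect_lt(median(abs(meds)), 0.1)
})

test_that("the screen controls FDR and retains power on planted tables", {
  # full-pipeline simulation: planted 8-fold genes among biased nulls
  reps <- 15
  stats <- sapply(1:reps, function(s) {
    mc <- make_counts(seed = 100 + s)
    scr <- analyze_expression(mc$count_table)
    planted <- mc$truth$gene[mc$truth$enriched]
    bc <- rowMeans(mc$count_table$counts)
    elig <- mc$truth$gene[mc$truth$enriched & bc >= 50]
    sel <- scr$enriched
    c(fdp = if (length(sel)) mean(!sel %in% planted) else 0,
      power = if (length(elig)) mean(elig %in% sel) else NA)
  })
  expect_lte(mean(stats["fdp", ]), 1.5 * 0.05)
  expect_gte(mean(stats["power", ], na.rm = TRUE), 0.9)
})
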