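#' Map reads to a reference gene set
#'
#' K-mer seeded ungapped mapping: each read (both strands) is anchored to
#' candidate reference offsets through shared k-mers and compared without
#' gaps over the full overlap. A read counts toward a gene iff
#' `similarity = identities / aligned length` and
#' `coverage = aligned length / read length` both reach the thresholds
#' (inclusive). A read qualifying for several genes is assigned to the gene
#' with the best similarity; exact ties are split as fractional counts.
#'
#' @param reads A `DNAStringSet`/named character vector (one sample), or a
#'   named list of them (one element per sample).
#' @param references Named reference sequences (`DNAStringSet` or character).
#' @param min_similarity,min_coverage Inclusive thresholds (defaults 0.9).
#' @param groups Character vector of group labels per sample (e.g.
#'   `"sexual"` / `"asexual"`); recycled `NA` if missing.
#' @param k Seed k-mer length.
#' @param seed_stride Distance between consecutive seed positions on a read.
#' @return List of class `count_table`: `genes`, `lengths`, `samples`,
#'   `group`, `counts` (gene x sample), `total_mapped` (reads per sample —
#'   all reads in the sample, mapped or not, i.e. the library size).
#' @export
map_reads <- function(reads, references, min_similarity = 0.9,
                      min_coverage = 0.9, groups = NULL, k = 15L,
                      seed_stride = 10L) {
  refs <- as_named_chr(references)
  if (!length(refs)) stop("empty reference set")
  if (!is.list(reads)) reads <- list(sample1 = reads)
  if (is.null(names(reads))) {
    names(reads) <- sprintf("sample%d", seq_along(reads))
  }
  index <- kmer_index(refs, k)
  counts <- matrix(0, nrow = length(refs), ncol = length(reads),
                   dimnames = list(names(refs), names(reads)))
  totals <- stats::setNames(integer(length(reads)), names(reads))
  for (s in names(reads)) {
    rv <- as_named_chr_reads(reads[[s]])
    totals[s] <- length(rv)
    for (rd in rv) {
      hit <- best_gene_hits(rd, refs, index, k, seed_stride,
                            min_similarity, min_coverage)
      if (length(hit)) counts[hit, s] <- counts[hit, s] + 1 / length(hit)
    }
  }
  structure(list(genes = names(refs), lengths = nchar(refs),
                 samples = names(reads),
                 group = if (is.null(groups)) rep(NA_character_,
                                                  length(reads)) else groups,
                 counts = counts, total_mapped = totals),
            class = "count_table")
}

as_named_chr_reads <- function(x) {
  if (methods::is(x, "XStringSet")) return(as.character(x))
  as.character(x)
}

kmer_index <- function(refs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (gi in seq_along(refs)) {
    s <- refs[[gi]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    for (p in seq_len(n)) {
      key <- kmers[p]
      env[[key]] <- rbind(if (!is.null(env[[key]])) env[[key]],
                          c(gi, p))
    }
  }
  env
}

best_gene_hits <- function(read, refs, index, k, stride, min_sim, min_cov) {
  best_sim <- -1
  best <- integer(0)
  len <- nchar(read)
  for (strand in 1:2) {
    rd <- if (strand == 1L) read else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    seed_pos <- unique(c(seq(1L, max(1L, len - k + 1L), by = stride),
                         max(1L, len - k + 1L)))
    cand <- list()
    for (sp in seed_pos) {
      key <- substr(rd, sp, sp + k - 1L)
      hits <- index[[key]]
      if (is.null(hits)) next
      for (h in seq_len(nrow(hits))) {
        cand[[paste(hits[h, 1], hits[h, 2] - sp, sep = "_")]] <-
          c(hits[h, 1], hits[h, 2] - sp)
      }
    }
    rchars <- strsplit(rd, "")[[1]]
    for (cv in cand) {
      gi <- cv[1]; off <- cv[2]
      ref <- refs[[gi]]
      a <- max(1L, 1L - off)            # read coordinate window
      b <- min(len, nchar(ref) - off)
      if (b < a) next
      aligned <- b - a + 1L
      if (aligned / len < min_cov) next
      refseg <- strsplit(substr(ref, a + off, b + off), "")[[1]]
      ident <- sum(rchars[a:b] == refseg)
      sim <- ident / aligned
      if (sim < min_sim) next
      if (sim > best_sim + 1e-12) {
        best_sim <- sim; best <- gi
      } else if (abs(sim - best_sim) <= 1e-12 && !(gi %in% best)) {
        best <- c(best, gi)
      }
    }
  }
  best
}

#' Reads per kilobase per million mapped reads
#'
#' `1e9 * counts / (length * total)`.
#'
#' @param counts Read counts (vectorized).
#' @param gene_length_nt Gene length in nucleotides (> 0).
#' @param total_mapped Library size (> 0).
#' @return Non-negative RPKM values.
#' @export
rpkm <- function(counts, gene_length_nt, total_mapped) {
  if (any(total_mapped == 0)) stop("total_mapped must be > 0")
  if (any(gene_length_nt <= 0)) stop("gene lengths must be > 0")
  1e9 * counts / (gene_length_nt * total_mapped)
}

#' Log2 fold change with a division-by-zero sentinel
#'
#' `log2(sexual / asexual)` group-mean ratio. A zero denominator with a
#' positive numerator maps to `log2(sentinel_ratio)` (13.29 at the default
#' sentinel of 10,000); the symmetric case maps to its negative; both means
#' zero yields `NA` (undefined, excluded downstream).
#'
#' @param mean_rpkm_sex,mean_rpkm_asex Group mean RPKM (vectorized).
#' @param sentinel_ratio Ratio substituted for division by zero.
#' @return Numeric log2 fold changes (`NA` = undefined).
#' @export
fold_change <- function(mean_rpkm_sex, mean_rpkm_asex,
                        sentinel_ratio = 10000) {
  n <- max(length(mean_rpkm_sex), length(mean_rpkm_asex))
  sx <- rep_len(mean_rpkm_sex, n); ax <- rep_len(mean_rpkm_asex, n)
  out <- rep(NA_real_, n)
  both <- sx > 0 & ax > 0
  out[both] <- log2(sx[both] / ax[both])
  out[sx > 0 & ax == 0] <- log2(sentinel_ratio)
  out[sx == 0 & ax > 0] <- -log2(sentinel_ratio)
  out
}

#' Two-group differential test on read proportions
#'
#' Weighted two-sample t-test on per-replicate mapped proportions
#' (`count / total_mapped`), in the style of Baggerly's beta-binomial
#' proportions test: replicates are weighted by library size, each group's
#' variance is the library-size-weighted replicate variance floored by the
#' binomial sampling variance of the pooled proportion, and the statistic is
#' referred to a t distribution with Satterthwaite degrees of freedom.
#'
#' @param count_table A `count_table` whose `group` has exactly two levels
#'   with >= 2 replicates each.
#' @return Data frame `gene_id`, `statistic`, `df`, `p_value`, `all_zero`.
#' @export
de_test <- function(count_table) {
  ct <- count_table
  gl <- unique(ct$group[!is.na(ct$group)])
  if (length(gl) != 2L) stop("need exactly two groups")
  i1 <- which(ct$group == gl[1]); i2 <- which(ct$group == gl[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("need >= 2 replicates per group")
  }
  N1 <- ct$total_mapped[i1]; N2 <- ct$total_mapped[i2]
  if (sum(N1) == 0 || sum(N2) == 0) stop("a group has zero total reads")
  P1 <- sweep(ct$counts[, i1, drop = FALSE], 2, N1, "/")
  P2 <- sweep(ct$counts[, i2, drop = FALSE], 2, N2, "/")
  grp_stats <- function(P, N) {
    W <- sum(N)
    phat <- as.vector(P %*% N) / W
    neff <- W^2 / sum(N^2)
    dev2 <- sweep(P, 1, phat, "-")^2
    s2 <- as.vector(dev2 %*% N) / W * neff / (neff - 1)
    list(phat = phat, var = s2 / neff, n = length(N), W = W)
  }
  g1 <- grp_stats(P1, N1); g2 <- grp_stats(P2, N2)
  pool <- (as.vector(ct$counts[, i1, drop = FALSE] %*% rep(1, g1$n)) +
             as.vector(ct$counts[, i2, drop = FALSE] %*% rep(1, g2$n))) /
    (g1$W + g2$W)
  v1 <- pmax(g1$var, pool * (1 - pool) / g1$W)
  v2 <- pmax(g2$var, pool * (1 - pool) / g2$W)
  delta <- g1$phat - g2$phat
  tt <- delta / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  all_zero <- rowSums(ct$counts) == 0
  zero_stat <- is.nan(tt) | delta == 0
  p[zero_stat] <- 1
  tt[is.nan(tt)] <- 0
  p[all_zero] <- 1
  data.frame(gene_id = ct$genes, statistic = tt, df = df, p_value = p,
             all_zero = all_zero, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fit the abundance trend of fold changes
#'
#' Sorts points by abundance (`x = log10 RPKM`), symmetrically discards
#' `(1 - middle_fraction)/2` of the points from each end (count rounded down
#' per side), and fits ordinary least squares to the retained middle points.
#' With 376 input points and the default fraction this retains exactly the
#' middle 282.
#'
#' @param x `log10(RPKM)` values (the regression abscissa).
#' @param y `log2(fold change)` values.
#' @param middle_fraction Fraction of points retained (default 0.75).
#' @return List of class `trend_fit`: `slope`, `intercept`, `n_used`,
#'   `x_range_used`.
#' @export
fit_trend <- function(x, y, middle_fraction = 0.75) {
  stopifnot(length(x) == length(y))
  if (middle_fraction <= 0 || middle_fraction > 1) {
    stop("middle_fraction must lie in (0, 1]")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  drop_per_side <- floor(n * (1 - middle_fraction) / 2)
  ord <- order(x)
  keep <- ord[seq.int(drop_per_side + 1L, n - drop_per_side)]
  if (length(keep) < 3L) stop("fewer than 3 points retained for the trend")
  fit <- stats::lm(y[keep] ~ x[keep])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_used = length(keep),
                 x_range_used = range(x[keep])),
            class = "trend_fit")
}

#' Trend coefficients in the normalization's sign convention
#'
#' The normalization subtracts `slope * log10(RPKM)` and then adds a
#' constant; relative to the fitted line `y = a + b x` that constant is
#' `-a`. This helper converts a [fit_trend()] result into the
#' `(slope, intercept)` pair [normalize_fc()] expects, so that normalized
#' fold changes are the regression residuals.
#'
#' @param fit A `trend_fit`.
#' @return List with `slope` and `intercept`.
#' @export
trend_coefficients <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  list(slope = fit$slope, intercept = -fit$intercept)
}

#' Trend-normalized log2 fold change
#'
#' `normalized = log2fc - slope * log10(rpkm) + intercept`. The published
#' coefficients (slope 0.411, intercept 2.29) are the defaults; pass the
#' output of [trend_coefficients()] to use a freshly fitted trend.
#'
#' @param log2fc Raw log2 fold changes.
#' @param rpkm Abundance (> 0; use the maximum control RPKM).
#' @param slope,intercept Trend coefficients.
#' @return Normalized log2 fold changes.
#' @export
normalize_fc <- function(log2fc, rpkm, slope = 0.411, intercept = 2.29) {
  if (any(rpkm <= 0, na.rm = TRUE)) stop("rpkm must be > 0")
  log2fc - slope * log10(rpkm) + intercept
}

#' Select sexually enriched genes
#'
#' Genes with `q_value < alpha` (strict) and normalized log2 fold change at
#' least `log2(min_fold)` (inclusive).
#'
#' @param rows Data frame with `gene_id`, `q_value`, `log2fc_normalized`.
#' @param min_fold Minimum fold enrichment (default 4).
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector of selected gene ids.
#' @export
select_enriched <- function(rows, min_fold = 4, alpha = 0.05) {
  sel <- !is.na(rows$q_value) & rows$q_value < alpha &
    !is.na(rows$log2fc_normalized) &
    rows$log2fc_normalized >= log2(min_fold)
  rows$gene_id[sel]
}

#' Full biotype-comparison expression screen
#'
#' Runs the whole expression stage on a count table: per-sample RPKM, group
#' means, raw fold change with the division-by-zero sentinel, the weighted
#' proportions test, BH correction, the abundance-trend fit over the
#' significant genes (`q < alpha`), trend normalization against the maximum
#' control RPKM, and enriched-gene selection.
#'
#' @param count_table A `count_table` with two groups; the group named
#'   `"sexual"` (or the first group) is the fold-change numerator.
#' @param min_fold,alpha Selection thresholds (defaults 4 and 0.05).
#' @param middle_fraction Trend-fit trimming fraction (default 0.75).
#' @param sentinel_ratio Division-by-zero sentinel (default 10,000).
#' @param preset_trend If non-`NULL`, a `list(slope=, intercept=)` used
#'   instead of fitting (e.g. the published `0.411` / `2.29`).
#' @return List of class `expression_screen`: `table` (per-gene rows:
#'   RPKM means, `max_control_rpkm`, `log2fc_raw`, `p_value`, `q_value`,
#'   `log2fc_normalized`), `trend` (the `trend_fit` or preset), `enriched`.
#' @export
analyze_expression <- function(count_table, min_fold = 4, alpha = 0.05,
                               middle_fraction = 0.75, sentinel_ratio = 10000,
                               preset_trend = NULL) {
  ct <- count_table
  R <- rpkm(ct$counts, ct$lengths,
            matrix(ct$total_mapped, nrow = nrow(ct$counts),
                   ncol = length(ct$total_mapped), byrow = TRUE))
  gl <- unique(ct$group)
  sex <- if ("sexual" %in% gl) "sexual" else gl[1]
  asex <- setdiff(gl, sex)[1]
  mean_sex <- rowMeans(R[, ct$group == sex, drop = FALSE])
  mean_asex <- rowMeans(R[, ct$group == asex, drop = FALSE])
  max_rpkm <- apply(R, 1, max)
  lfc <- fold_change(mean_sex, mean_asex, sentinel_ratio)
  de <- de_test(ct)
  q <- bh_fdr(de$p_value)
  sig <- !is.na(q) & q < alpha & !is.na(lfc) & max_rpkm > 0
  # sentinel-derived fold changes are division-by-zero placeholders, not
  # measurements; they are normalized and selectable but never fitted
  measured <- sig & abs(lfc) < log2(sentinel_ratio)
  trend <- preset_trend
  fit <- NULL
  if (is.null(trend)) {
    fit <- fit_trend(log10(max_rpkm[measured]), lfc[measured],
                     middle_fraction)
    trend <- trend_coefficients(fit)
  }
  norm <- rep(NA_real_, length(lfc))
  pos <- max_rpkm > 0 & !is.na(lfc)
  norm[pos] <- normalize_fc(lfc[pos], max_rpkm[pos],
                            trend$slope, trend$intercept)
  tab <- data.frame(gene_id = ct$genes,
                    mean_rpkm_sex = mean_sex, mean_rpkm_asex = mean_asex,
                    max_control_rpkm = max_rpkm, log2fc_raw = lfc,
                    p_value = de$p_value, q_value = q,
                    log2fc_normalized = norm, stringsAsFactors = FALSE)
  enriched <- select_enriched(tab, min_fold = min_fold, alpha = alpha)
  structure(list(table = tab, trend = trend, trend_fit = fit,
                 n_significant = sum(sig), enriched = enriched),
            class = "expression_screen")
}
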