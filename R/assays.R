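#' Normalize a luminescence response to the total calcium response
#'
#' Fraction of the total response attributable to the peptide:
#' `peptide / (peptide + triton)`, where the Triton reading releases the
#' remaining calcium after the peptide challenge.
#'
#' @param peptide_lum,triton_lum Non-negative luminescence readings
#'   (vectorized; sums must be positive).
#' @return Fractions in \[0, 1\].
#' @export
normalize_response <- function(peptide_lum, triton_lum) {
  if (any(peptide_lum < 0 | triton_lum < 0)) {
    stop("luminescence readings must be >= 0")
  }
  tot <- peptide_lum + triton_lum
  if (any(tot == 0)) stop("peptide + triton must be > 0")
  peptide_lum / tot
}

#' Scale a response series to percent of its maximum
#'
#' @param series Numeric vector of normalized responses (max > 0).
#' @return The series scaled so its maximum is exactly 100.
#' @export
percent_of_max <- function(series) {
  if (!length(series)) stop("empty series")
  m <- max(series)
  if (m <= 0) stop("series maximum must be > 0")
  series / m * 100
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(EC50) - log10(x))))`
#' on log10 concentration, via Levenberg-Marquardt. Initialization takes
#' `bottom`/`top` from the data extremes, the EC50 start from the
#' concentration whose mean response is nearest half-range, and tries three
#' Hill starts (1, -1, 3), keeping the best-RSS convergent fit. The top is
#' bounded by 1.5x the observed maximum; the bottom is unconstrained (assay
#' baselines drift). All replicate points are fitted jointly by default.
#'
#' @param concentration Positive molar concentrations (>= 4 distinct).
#' @param response Responses (same length).
#' @param fit_means Fit per-concentration means instead of all points.
#' @return List of class `fourpl_fit`: `ec50`, `hill`, `top`, `bottom`,
#'   `converged`, `reliable` (falls when the fitted span or slope is too
#'   small to identify an EC50), `rss`, `n`, and `fitted(x)` closure.
#'   Never throws on non-convergence: `converged = FALSE` with diagnostics.
#' @export
fit_4pl <- function(concentration, response, fit_means = FALSE) {
  stopifnot(length(concentration) == length(response))
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  if (length(unique(concentration)) < 4L) {
    stop("need >= 4 distinct concentrations")
  }
  if (fit_means) {
    agg <- stats::aggregate(response, list(conc = concentration), mean)
    concentration <- agg$conc; response <- agg$x
  }
  lx <- log10(concentration)
  y <- response
  bottom0 <- min(y); top0 <- max(y)
  mean_by_conc <- tapply(y, lx, mean)
  half <- (max(y) + min(y)) / 2
  lec50_0 <- as.numeric(names(mean_by_conc))[
    which.min(abs(mean_by_conc - half))]
  best <- NULL
  for (hill0 in c(1, -1, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lx))),
        start = list(bottom = bottom0, top = top0, lec50 = lec50_0,
                     hill = hill0),
        lower = c(bottom = -Inf, top = -Inf, lec50 = min(lx) - 6,
                  hill = -50),
        upper = c(bottom = Inf, top = 1.5 * max(abs(y)),
                  lec50 = max(lx) + 6, hill = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, converged = FALSE,
                          reliable = FALSE, rss = NA_real_, n = length(y),
                          fitted = NULL),
                     class = "fourpl_fit"))
  }
  cf <- stats::coef(best$fit)
  span <- cf[["top"]] - cf[["bottom"]]
  reliable <- abs(span) > 0.1 * max(abs(y), 1e-12) && abs(cf[["hill"]]) > 0.1
  f <- function(x) {
    cf[["bottom"]] + span / (1 + 10^(cf[["hill"]] * (cf[["lec50"]] -
                                                       log10(x))))
  }
  structure(list(ec50 = 10^cf[["lec50"]], hill = cf[["hill"]],
                 top = cf[["top"]], bottom = cf[["bottom"]],
                 converged = TRUE, reliable = reliable, rss = best$rss,
                 n = length(y), fitted = f),
            class = "fourpl_fit")
}

#' Bootstrap confidence interval for a fitted EC50
#'
#' Nonparametric bootstrap over replicates (or over points when replicate
#' ids are absent): resample, refit, and report percentile bounds of the
#' EC50. Deterministic given `seed`.
#'
#' @param concentration,response As in [fit_4pl()].
#' @param replicate Optional replicate id per point.
#' @param n_boot Resamples (default 1000).
#' @param seed Integer RNG seed.
#' @param level Confidence level (default 0.95).
#' @return List `ec50`, `lower`, `upper`, `n_effective` (successful refits).
#' @export
ec50_bootstrap_ci <- function(concentration, response, replicate = NULL,
                              n_boot = 1000L, seed = 1L, level = 0.95) {
  base_fit <- fit_4pl(concentration, response)
  units <- if (is.null(replicate)) seq_along(concentration) else replicate
  uu <- unique(units)
  est <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(uu, length(uu), replace = TRUE)
      idx <- unlist(lapply(pick, function(u) which(units == u)))
      ft <- tryCatch(fit_4pl(concentration[idx], response[idx]),
                     error = function(e) NULL)
      if (is.null(ft) || !ft$converged) NA_real_ else ft$ec50
    }, numeric(1))
  })
  qs <- stats::quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(ec50 = base_fit$ec50, lower = qs[1], upper = qs[2],
       n_effective = sum(!is.na(est)))
}

#' Relative quantification by delta-delta-Ct
#'
#' Per sample, `dCt = Ct(gene) - Ct(reference gene)`;
#' `ddCt = mean dCt(test) - mean dCt(reference condition)`;
#' `RQ = 2^-ddCt`. The error range follows the asymmetric convention
#' `[2^-(ddCt + SEM), 2^-(ddCt - SEM)]`, where the SEM is computed over the
#' test-condition dCt replicates only (never the reference condition).
#'
#' @param ct_table Data frame with columns `sample`, `condition`, `gene`,
#'   `ct`.
#' @param gene Gene of interest.
#' @param test_condition,reference_condition Condition labels.
#' @param reference_gene Internal-control gene (must be measured in every
#'   sample).
#' @return List `ddct`, `rq`, `sem`, `range` (`c(low, high)`, `NA` when the
#'   test condition has a single replicate), `n_test`, `n_reference`.
#' @export
delta_delta_ct <- function(ct_table, gene, test_condition,
                           reference_condition,
                           reference_gene = "beta-tubulin") {
  tb <- ct_table
  stopifnot(all(c("sample", "condition", "gene", "ct") %in% names(tb)))
  dct_for <- function(cond) {
    samples <- unique(tb$sample[tb$condition == cond])
    if (!length(samples)) stop("no samples in condition: ", cond)
    vapply(samples, function(s) {
      g <- tb$ct[tb$sample == s & tb$gene == gene]
      r <- tb$ct[tb$sample == s & tb$gene == reference_gene]
      if (!length(r)) stop("reference gene '", reference_gene,
                           "' missing for sample ", s)
      if (!length(g)) stop("gene '", gene, "' missing for sample ", s)
      mean(g) - mean(r)
    }, numeric(1))
  }
  dct_test <- dct_for(test_condition)
  dct_ref <- dct_for(reference_condition)
  ddct <- mean(dct_test) - mean(dct_ref)
  rq <- 2^(-ddct)
  sem <- if (length(dct_test) >= 2L) {
    stats::sd(dct_test) / sqrt(length(dct_test))
  } else NA_real_
  rng <- if (is.na(sem)) c(NA_real_, NA_real_) else
    c(2^(-(ddct + sem)), 2^(-(ddct - sem)))
  list(ddct = ddct, rq = rq, sem = sem, range = rng,
       n_test = length(dct_test), n_reference = length(dct_ref))
}
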