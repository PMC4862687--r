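# Karlin-Altschul parameters for gapped local alignment, from the published
# tables for the corresponding BLAST matrices (gap open 11 / extend 1 for
# BLOSUM62, 10/1 for BLOSUM80).
KA_PARAMS <- list(
  BLOSUM62 = list(lambda = 0.267, K = 0.041),
  BLOSUM80 = list(lambda = 0.299, K = 0.071)
)

#' Local-alignment similarity search against a seed database
#'
#' Smith-Waterman local alignments (via [Biostrings::pairwiseAlignment()])
#' of each query against every seed, scored with the named substitution
#' matrix. Raw scores are converted to bit scores with the Karlin-Altschul
#' formula and E-values use an effective search space equal to the product of
#' the query length and the total database length.
#'
#' @param query_proteins Named character vector or `AAStringSet`.
#' @param seed_proteins Named character vector or `AAStringSet`.
#' @param seed_classes Named character vector mapping seed id to a class tag
#'   (`"gpcr_seed"`, `"non_gpcr_tm"`, `"other"`); defaults to `"gpcr_seed"`
#'   for every seed.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @param matrix_name Substitution matrix name (`"BLOSUM62"` or `"BLOSUM80"`).
#' @param max_e Hits with E-value above this are dropped (default `Inf`,
#'   keep all).
#' @return Data frame `query_id`, `target_id`, `target_class`, `bit_score`,
#'   `e_value`, sorted per query by ascending E-value then target id.
#' @export
search_seeds <- function(query_proteins, seed_proteins, seed_classes = NULL,
                         gap_open = 11, gap_extend = 1,
                         matrix_name = "BLOSUM62", max_e = Inf) {
  if (!matrix_name %in% names(KA_PARAMS)) {
    stop("unknown substitution matrix: ", matrix_name)
  }
  queries <- as_named_chr(query_proteins)
  empty <- data.frame(query_id = character(), target_id = character(),
                      target_class = character(), bit_score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE)
  if (length(seed_proteins) == 0L || length(queries) == 0L) return(empty)
  seeds <- as_named_chr(seed_proteins)
  if (is.null(seed_classes)) {
    seed_classes <- stats::setNames(rep("gpcr_seed", length(seeds)),
                                    names(seeds))
  }
  ka <- KA_PARAMS[[matrix_name]]
  db_len <- sum(nchar(seeds))
  qset <- Biostrings::AAStringSet(queries)
  rows <- vector("list", length(seeds))
  for (j in seq_along(seeds)) {
    sc <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(seeds[[j]]), type = "local",
      substitutionMatrix = matrix_name,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    bits <- (ka$lambda * sc - log(ka$K)) / log(2)
    rows[[j]] <- data.frame(
      query_id = names(queries), target_id = names(seeds)[j],
      target_class = unname(seed_classes[names(seeds)[j]]),
      bit_score = bits,
      e_value = nchar(queries) * db_len * 2^(-bits),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  hits <- hits[hits$e_value <= max_e, , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$e_value, hits$target_id), ]
  rownames(hits) <- NULL
  hits
}

#' Non-GPCR exclusion rule
#'
#' A candidate is excluded when, among its `top_k` best hits (all hits if
#' fewer), the fraction that are non-GPCR transmembrane proteins with
#' E-value below `e_cut` reaches `min_fraction`. Ties at the `top_k`
#' truncation boundary are broken by ascending `(e_value, target_id)`.
#'
#' @param hits Hit data frame for one query, as from [search_seeds()].
#' @param top_k Number of best hits considered (default 50).
#' @param e_cut Significance cutoff (default 1e-10).
#' @param min_fraction Exclusion threshold on the fraction (default 0.5).
#' @return `"exclude"` or `"keep"`.
#' @export
exclusion_filter <- function(hits, top_k = 50L, e_cut = 1e-10,
                             min_fraction = 0.5) {
  if (min_fraction < 0 || min_fraction > 1) {
    stop("min_fraction must lie in [0, 1]")
  }
  if (is.null(hits) || nrow(hits) == 0L) return("keep")
  hits <- hits[order(hits$e_value, hits$target_id), , drop = FALSE]
  top <- utils::head(hits, top_k)
  frac <- mean(top$target_class == "non_gpcr_tm" & top$e_value < e_cut)
  if (frac >= min_fraction) "exclude" else "keep"
}
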