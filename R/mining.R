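#' Default mining parameters
#'
#' @return Named list of every threshold the mining loop uses: minimum ORF
#'   length (`min_aa_len`, 200 residues — a repo convention surfaced here),
#'   upstream stop-to-ATG window (`upstream_window_nt`, 90 nt), seed-search
#'   admission E-value (`admit_e`, 1e-4), exclusion-rule settings (`top_k`
#'   50, `e_cut` 1e-10, `min_fraction` 0.5), hydropathy topology settings
#'   (`tm_window` 19, `tm_cut` 1.6), alignment settings, and `max_rounds`.
#' @export
mining_params <- function() {
  list(min_aa_len = 200L, upstream_window_nt = 90L, admit_e = 1e-4,
       top_k = 50L, e_cut = 1e-10, min_fraction = 0.5,
       tm_window = 19L, tm_cut = 1.6,
       gap_open = 11, gap_extend = 1, matrix_name = "BLOSUM62",
       max_rounds = 10L)
}

#' Recursive receptor mining
#'
#' One pass of the receptor-discovery workflow, iterated to a fixpoint: ORF
#' discovery in all six frames, end-curation flags, similarity search of each
#' candidate protein against the seed set plus every receptor retained in
#' earlier rounds, the non-GPCR exclusion rule, and the seven-transmembrane
#' topology filter. Rounds repeat (seeding each round with the previously
#' retained receptors) until the retained set stops changing. Decisions are
#' monotone: a candidate excluded in one round is never re-admitted.
#'
#' @param transcriptome `DNAStringSet` or named character vector.
#' @param seeds Named protein sequences (`AAStringSet` or character).
#' @param seed_classes Named character vector of class tags per seed
#'   (`"gpcr_seed"` / `"non_gpcr_tm"` / `"other"`); defaults to all
#'   `"gpcr_seed"`.
#' @param params List as from [mining_params()]; entries may be overridden.
#' @return List of class `mining_result`: `candidates` (one row per candidate
#'   ORF that was ever admitted, with ORF coordinates, end flags, topology
#'   summary, best seed E-value, `status`
#'   (`retained` / `excluded_similarity` / `excluded_topology`) and
#'   `round_admitted`), `proteins` (named character of retained proteins),
#'   `rounds` (retained-set size per round).
#' @export
mine_receptors <- function(transcriptome, seeds, seed_classes = NULL,
                           params = mining_params()) {
  params <- utils::modifyList(mining_params(), params)
  tx <- as_named_chr(transcriptome)
  seeds <- if (length(seeds)) as_named_chr(seeds) else character(0)
  if (is.null(seed_classes)) {
    seed_classes <- stats::setNames(rep("gpcr_seed", length(seeds)),
                                    names(seeds))
  }
  empty <- data.frame(
    candidate_id = character(), transcript_id = character(), frame = integer(),
    start = integer(), end = integer(), aa_len = integer(),
    n_term_ok = logical(), c_term_ok = logical(), orf_confident = logical(),
    n_tm_domains = integer(), n_terminus_side = character(),
    c_terminus_side = character(), best_gpcr_e = numeric(),
    status = character(), round_admitted = integer(), stringsAsFactors = FALSE)
  if (length(tx) == 0L) {
    return(structure(list(candidates = empty, proteins = character(0),
                          rounds = integer(0)), class = "mining_result"))
  }

  # ORF discovery + flags + translation, once up front
  orfs <- list(); prots <- character(0)
  for (id in names(tx)) {
    t1 <- stats::setNames(tx[id], id)
    found <- find_orfs(t1, min_aa_len = params$min_aa_len)
    for (i in seq_len(nrow(found))) {
      orf <- flag_orf_ends(t1, found[i, ], params$upstream_window_nt)
      cid <- sprintf("%s|f%+d|%d", id, orf$frame, orf$start)
      orf$candidate_id <- cid
      orfs[[cid]] <- orf
      prots[cid] <- orf_protein(t1, orf)
    }
  }
  if (!length(orfs)) {
    return(structure(list(candidates = empty, proteins = character(0),
                          rounds = integer(0)), class = "mining_result"))
  }

  status <- stats::setNames(rep("unseen", length(prots)), names(prots))
  round_admitted <- stats::setNames(rep(NA_integer_, length(prots)),
                                    names(prots))
  best_e <- stats::setNames(rep(NA_real_, length(prots)), names(prots))
  rounds <- integer(0)

  for (round in seq_len(params$max_rounds)) {
    retained_ids <- names(status)[status == "retained"]
    db <- c(seeds, prots[retained_ids])
    db_classes <- c(seed_classes,
                    stats::setNames(rep("gpcr_seed", length(retained_ids)),
                                    retained_ids))
    fresh <- names(status)[status == "unseen"]
    new_retained <- character(0)
    if (length(fresh) && length(db)) {
      hits <- search_seeds(prots[fresh], db, db_classes,
                           gap_open = params$gap_open,
                           gap_extend = params$gap_extend,
                           matrix_name = params$matrix_name)
      for (cid in fresh) {
        h <- hits[hits$query_id == cid & hits$target_id != cid, , drop = FALSE]
        g <- h[h$target_class == "gpcr_seed", , drop = FALSE]
        e <- if (nrow(g)) min(g$e_value) else Inf
        if (e > params$admit_e) next  # not a candidate this round
        best_e[cid] <- e
        round_admitted[cid] <- round
        if (exclusion_filter(h, params$top_k, params$e_cut,
                             params$min_fraction) == "exclude") {
          status[cid] <- "excluded_similarity"
          next
        }
        cand <- list(orf = orfs[[cid]],
                     topology = predict_topology(
                       stats::setNames(prots[cid], cid),
                       window = params$tm_window,
                       hydropathy_cut = params$tm_cut),
                     status = "retained")
        cand <- topology_filter(cand)
        status[cid] <- cand$status
        if (cand$status == "retained") new_retained <- c(new_retained, cid)
      }
    }
    rounds <- c(rounds, sum(status == "retained"))
    if (!length(new_retained)) break
    if (round == params$max_rounds && length(new_retained)) {
      stop("mining did not converge after ", params$max_rounds,
           " rounds; retained per round: ", paste(rounds, collapse = ", "))
    }
  }

  admitted <- names(status)[status != "unseen"]
  cand_rows <- lapply(admitted, function(cid) {
    orf <- orfs[[cid]]
    top <- predict_topology(stats::setNames(prots[cid], cid),
                            window = params$tm_window,
                            hydropathy_cut = params$tm_cut)
    data.frame(candidate_id = cid, transcript_id = orf$transcript_id,
               frame = orf$frame, start = orf$start, end = orf$end,
               aa_len = orf$aa_len, n_term_ok = orf$n_term_ok,
               c_term_ok = orf$c_term_ok, orf_confident = orf$orf_confident,
               n_tm_domains = top$n_segments,
               n_terminus_side = top$n_terminus_side,
               c_terminus_side = top$c_terminus_side,
               best_gpcr_e = best_e[cid], status = status[cid],
               round_admitted = round_admitted[cid], stringsAsFactors = FALSE)
  })
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else empty
  rownames(candidates) <- NULL
  retained <- candidates$candidate_id[candidates$status == "retained"]
  structure(list(candidates = candidates, proteins = prots[retained],
                 rounds = rounds), class = "mining_result")
}
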