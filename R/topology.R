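# Kyte-Doolittle hydropathy scale; X (unknown) scored neutral.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

#' Transmembrane topology prediction by sliding-window hydropathy
#'
#' A hydropathy stand-in for an HMM-based membrane-topology predictor:
#' transmembrane (TM) segments are maximal runs of residues whose centred
#' sliding-window mean Kyte-Doolittle hydropathy exceeds `hydropathy_cut`;
#' runs separated by fewer than 4 residues are merged, and each segment is
#' symmetrically trimmed or padded toward the canonical 21-residue helix
#' length (bounded by the protein ends and neighbouring segments). The side
#' of the N-terminus is assigned by the positive-inside rule: loop regions
#' (tails and inter-segment loops) are split into the two alternating sides
#' and the side with greater summed lysine + arginine content is called
#' intracellular; ties fall to an intracellular N-terminus. The C-terminal
#' side follows from the N-terminal side and segment-count parity.
#'
#' @param protein Named character of length 1 or an `AAStringSet` element.
#' @param window Odd sliding-window width (default 19).
#' @param hydropathy_cut Mean-hydropathy threshold (default 1.6).
#' @return List of class `topology_prediction`: `protein_id`, `tm_segments`
#'   (two-column matrix of 0-based half-open residue intervals),
#'   `n_segments`, `n_terminus_side`, `c_terminus_side` (`"out"`/`"in"`).
#' @export
predict_topology <- function(protein, window = 19L, hydropathy_cut = 1.6) {
  if (window %% 2L == 0L) stop("window must be odd")
  p <- as_named_chr(if (length(protein) == 1L && is.null(names(protein)))
    stats::setNames(protein, "protein") else protein)
  id <- names(p)[1]
  aa <- strsplit(p[[1]], "")[[1]]
  n <- length(aa)
  segs <- matrix(integer(0), ncol = 2)
  if (n >= window) {
    h <- KD_SCALE[aa]
    h[is.na(h)] <- 0
    means <- stats::filter(h, rep(1 / window, window), sides = 2)
    centers <- which(!is.na(means) & means > hydropathy_cut)
    if (length(centers)) {
      runs <- split(centers, cumsum(c(1L, diff(centers) > 1L)))
      segs <- do.call(rbind, lapply(runs, function(r) c(min(r), max(r))))
      # merge segments separated by < 4 residues
      if (nrow(segs) > 1L) {
        merged <- segs[1, , drop = FALSE]
        for (i in 2:nrow(segs)) {
          if (segs[i, 1] - merged[nrow(merged), 2] - 1L < 4L) {
            merged[nrow(merged), 2] <- segs[i, 2]
          } else {
            merged <- rbind(merged, segs[i, ])
          }
        }
        segs <- merged
      }
      segs <- resize_segments(segs, n, target = 21L)
      segs <- cbind(segs[, 1] - 1L, segs[, 2])  # 0-based half-open
    }
  }
  n_seg <- nrow(segs)
  n_side <- positive_inside_side(aa, segs)
  c_side <- if (n_seg %% 2L == 0L) n_side else setdiff(c("out", "in"), n_side)
  structure(list(protein_id = id, tm_segments = segs, n_segments = n_seg,
                 n_terminus_side = n_side, c_terminus_side = c_side),
            class = "topology_prediction")
}

# Symmetric trim/pad toward 21 residues on 1-based inclusive intervals,
# clamped to [1, n] and kept non-overlapping with >= 1 residue gaps.
resize_segments <- function(segs, n, target = 21L) {
  for (i in seq_len(nrow(segs))) {
    len <- segs[i, 2] - segs[i, 1] + 1L
    delta <- target - len
    grow_l <- delta %/% 2L + delta %% 2L
    grow_r <- delta %/% 2L
    lo <- if (i > 1L) segs[i - 1L, 2] + 2L else 1L
    hi <- if (i < nrow(segs)) segs[i + 1L, 1] - 2L else n
    segs[i, 1] <- max(lo, segs[i, 1] - grow_l)
    segs[i, 2] <- min(hi, segs[i, 2] + grow_r)
  }
  segs
}

positive_inside_side <- function(aa, segs) {
  n <- length(aa)
  pos <- as.integer(aa %in% c("K", "R"))
  # loops: 0 = N-tail, k = loop after segment k (last = C-tail)
  bounds <- rbind(c(0L, if (nrow(segs)) segs[1, 1] else n),
                  if (nrow(segs) > 0L)
                    cbind(segs[, 2], c(segs[-1, 1], n)))
  charge <- vapply(seq_len(nrow(bounds)), function(k) {
    a <- bounds[k, 1] + 1L; b <- bounds[k, 2]
    if (a > b) 0L else sum(pos[a:b])
  }, integer(1))
  odd_loops <- sum(charge[seq_along(charge) %% 2L == 0L])   # loops 1, 3, ...
  even_loops <- sum(charge[seq_along(charge) %% 2L == 1L])  # N-tail, 2, 4, ...
  # N out => loops 1,3,... are inside; N in => N-tail, 2,4,... are inside
  if (odd_loops > even_loops) "out" else "in"
}

#' Seven-transmembrane topology filter
#'
#' Removes candidates that look complete but are not built like a GPCR: a
#' candidate whose ORF is confident is excluded unless its predicted topology
#' shows exactly seven TM segments with an extracellular N-terminus and an
#' intracellular C-terminus. Candidates without a confident ORF are never
#' excluded on topology (their ends, and hence their segment count, may be
#' missing).
#'
#' @param candidate List with elements `orf` (flagged ORF row) and `topology`
#'   (a `topology_prediction`), plus an optional `status`.
#' @return The candidate with `status` set to `"excluded_topology"` or left
#'   as-is (`"retained"` if unset).
#' @export
topology_filter <- function(candidate) {
  if (is.null(candidate$status)) candidate$status <- "retained"
  if (candidate$status != "retained") return(candidate)  # monotone transitions
  top <- candidate$topology
  ok7tm <- top$n_segments == 7L && top$n_terminus_side == "out" &&
    top$c_terminus_side == "in"
  if (isTRUE(candidate$orf$orf_confident) && !ok7tm) {
    candidate$status <- "excluded_topology"
  }
  candidate
}
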