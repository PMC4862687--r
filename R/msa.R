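# Minimal deterministic progressive aligner: pairwise global alignments give
# identity distances, average-linkage clustering gives the guide tree, and
# profiles are merged in guide-tree order with a sum-of-pairs Needleman-
# Wunsch (linear gap penalty). Small receptor families only; not a
# general-purpose MSA engine.

GAP_SCORE <- -8     # residue vs gap, and per-column indel penalty
GAP_GAP_SCORE <- 0

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Profile = character matrix (sequences x columns, '-' for gaps).
profile_align <- function(A, B, sub) {
  la <- ncol(A); lb <- ncol(B)
  col_score <- function(ca, cb) {
    s <- 0
    for (x in ca) for (y in cb) {
      s <- s + if (x == "-" && y == "-") GAP_GAP_SCORE
      else if (x == "-" || y == "-") GAP_SCORE
      else sub[x, y]
    }
    s / (length(ca) * length(cb))
  }
  S <- matrix(0, la + 1L, lb + 1L)
  P <- matrix(0L, la + 1L, lb + 1L)  # 1 diag, 2 up (gap in B), 3 left
  S[, 1] <- GAP_SCORE * (0:la)
  S[1, ] <- GAP_SCORE * (0:lb)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  M <- matrix(0, la, lb)
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    M[i, j] <- col_score(A[, i], B[, j])
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      diag_s <- S[i, j] + M[i, j]
      up_s <- S[i, j + 1L] + GAP_SCORE
      left_s <- S[i + 1L, j] + GAP_SCORE
      best <- max(diag_s, up_s, left_s)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (best == diag_s) 1L
      else if (best == up_s) 2L else 3L
    }
  }
  # traceback
  i <- la; j <- lb
  cols_a <- integer(0); cols_b <- integer(0)
  while (i > 0L || j > 0L) {
    mv <- P[i + 1L, j + 1L]
    if (mv == 1L) {
      cols_a <- c(i, cols_a); cols_b <- c(j, cols_b); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b); i <- i - 1L
    } else {
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b); j <- j - 1L
    }
  }
  gap_a <- matrix("-", nrow(A), length(cols_a))
  gap_b <- matrix("-", nrow(B), length(cols_b))
  gap_a[, cols_a > 0L] <- A[, cols_a[cols_a > 0L], drop = FALSE]
  gap_b[, cols_b > 0L] <- B[, cols_b[cols_b > 0L], drop = FALSE]
  rbind(gap_a, gap_b)
}

#' Progressive multiple alignment
#'
#' Aligns protein sequences progressively: all pairwise global alignment
#' scores (BLOSUM62, linear gap penalty) give identity-based distances, an
#' average-linkage guide tree orders the merges, and profiles are merged with
#' a sum-of-pairs Needleman-Wunsch whose traceback prefers match over
#' deletion over insertion, making the result deterministic.
#'
#' @param proteins Named character vector or `AAStringSet`, length >= 2.
#' @return List of class `msa`: `ids`, `aligned` (named character vector of
#'   equal-length gapped rows, input order), `length`.
#' @export
progressive_align <- function(proteins) {
  seqs <- as_named_chr(proteins)
  if (length(seqs) < 2L) stop("progressive alignment needs >= 2 sequences")
  sub <- blosum62_matrix()
  n <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  # pairwise identity distances from two-sequence profile alignments
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  pair_aln <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ali <- profile_align(matrix(chars[[i]], nrow = 1L),
                         matrix(chars[[j]], nrow = 1L), sub)
    idn <- mean(ali[1, ] == ali[2, ] & ali[1, ] != "-")
    D[i, j] <- D[j, i] <- 1 - idn
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- lapply(chars, function(x) matrix(x, nrow = 1L))
  rows <- lapply(seq_len(n), function(i) i)
  merged <- vector("list", n - 1L)
  merged_rows <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    pick <- function(v) if (v < 0L) list(profiles[[-v]], rows[[-v]])
    else list(merged[[v]], merged_rows[[v]])
    a <- pick(hc$merge[k, 1]); b <- pick(hc$merge[k, 2])
    merged[[k]] <- profile_align(a[[1]], b[[1]], sub)
    merged_rows[[k]] <- c(a[[2]], b[[2]])
  }
  final <- merged[[n - 1L]]
  ord <- order(merged_rows[[n - 1L]])
  final <- final[ord, , drop = FALSE]
  aligned <- stats::setNames(apply(final, 1, paste, collapse = ""),
                             names(seqs))
  structure(list(ids = names(seqs), aligned = aligned, length = ncol(final)),
            class = "msa")
}

#' Alignment as a character matrix
#'
#' @param alignment An `msa`, or a named character vector of equal-length
#'   gapped sequences.
#' @return Character matrix, sequences in rows.
#' @export
msa_matrix <- function(alignment) {
  rows <- if (inherits(alignment, "msa")) alignment$aligned else alignment
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows must have equal length")
  }
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  m
}
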