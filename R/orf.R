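#' Six-frame ORF discovery
#'
#' Scans all six reading frames of a nucleotide sequence for maximal open
#' reading frames. Within each frame, stop codons partition the sequence into
#' segments; a segment yields an ORF running from its first ATG to the stop
#' codon that closes it (the stop is included in the interval) or to the
#' contig edge. A 5'-most segment that is closed by a stop but has no ATG is
#' reported as a 5'-truncated, edge-anchored ORF; an open stretch with
#' neither a start nor a stop is not an ORF.
#'
#' Coordinates are 0-based half-open nucleotide offsets on the scanned strand:
#' for frames -1..-3 they index into the reverse complement of the transcript.
#'
#' @param transcript Named character of length 1, or a single-element
#'   `DNAStringSet` entry; DNA alphabet (ambiguity `N` allowed).
#' @param min_aa_len Minimum translated length in residues (stop excluded).
#' @return Data frame with columns `transcript_id`, `frame`, `start`, `end`,
#'   `n_term_ok`, `c_term_ok`, `orf_confident` (flags all `NA` until
#'   [flag_orf_ends()] is applied), plus `aa_len`.
#' @export
find_orfs <- function(transcript, min_aa_len = 200L) {
  rec <- single_dna_record(transcript)
  if (min_aa_len < 1L) stop("min_aa_len must be >= 1")
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- strand_seq(rec$seq, frame)
    off <- abs(frame) - 1L
    n_codons <- (nchar(s) - off) %/% 3L
    if (n_codons < 1L) next
    aa <- translate_codons(s, off, n_codons)
    stops <- which(aa == "*")
    seg_start <- c(1L, stops + 1L)           # codon index starting each segment
    seg_end <- c(stops, n_codons)            # last codon index (incl. stop)
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]; b <- seg_end[k]
      if (a > b) next
      has_stop <- length(stops) >= k && b %in% stops
      if (a == 1L && has_stop) {
        start_codon <- 1L                    # 5'-truncated, edge-anchored
      } else {
        # an open stretch with neither start nor stop is a window, not an
        # ORF: require an ATG when the 3' stop is absent or a >= 2 segment
        atg <- which(aa[a:b] == "M")
        if (!length(atg)) next
        start_codon <- a + atg[1L] - 1L
      }
      aa_len <- (b - start_codon + 1L) - as.integer(has_stop)
      if (aa_len < min_aa_len) next
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = rec$id, frame = frame,
        start = off + (start_codon - 1L) * 3L,
        end = off + b * 3L,
        n_term_ok = NA, c_term_ok = NA, orf_confident = NA,
        aa_len = aa_len, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), frame = integer(),
                      start = integer(), end = integer(), n_term_ok = logical(),
                      c_term_ok = logical(), orf_confident = logical(),
                      aa_len = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Curation flags for ORF ends
#'
#' Applies the end-curation rule: the amino terminus is trusted
#' (`n_term_ok`) when the ORF begins at an ATG preceded by an in-frame stop
#' codon within `upstream_window_nt` nucleotides (a stop closely followed by a
#' start); the carboxy terminus is trusted (`c_term_ok`) when the ORF ends at
#' a stop codon inside the transcript. `orf_confident` is the conjunction.
#' Sequence appended downstream of the stop never changes the flags.
#'
#' @param transcript As in [find_orfs()].
#' @param orf One row of the data frame returned by [find_orfs()].
#' @param upstream_window_nt Maximum gap (nt) between the upstream stop's end
#'   and the ORF's ATG; default 90.
#' @return The ORF row with `n_term_ok`, `c_term_ok`, `orf_confident` filled.
#' @export
flag_orf_ends <- function(transcript, orf, upstream_window_nt = 90L) {
  if (upstream_window_nt < 0L) stop("upstream_window_nt must be >= 0")
  rec <- single_dna_record(transcript)
  s <- strand_seq(rec$seq, orf$frame)
  if (orf$end > nchar(s) || orf$start < 0L) stop("ORF lies outside transcript")
  starts_atg <- substr(s, orf$start + 1L, orf$start + 3L) == "ATG"
  n_ok <- FALSE
  if (starts_atg) {
    pos <- orf$start - 3L
    while (pos >= 0L && (orf$start - (pos + 3L)) <= upstream_window_nt) {
      if (substr(s, pos + 1L, pos + 3L) %in% STOP_CODONS) {
        n_ok <- TRUE
        break
      }
      pos <- pos - 3L
    }
  }
  last_codon <- substr(s, orf$end - 2L, orf$end)
  c_ok <- last_codon %in% STOP_CODONS
  orf$n_term_ok <- n_ok
  orf$c_term_ok <- c_ok
  orf$orf_confident <- n_ok && c_ok
  orf
}

#' Extract and translate an ORF
#'
#' @param transcript As in [find_orfs()].
#' @param orf One ORF row.
#' @return Single protein string (terminal stop stripped; ambiguous codons
#'   translate to `X`).
#' @export
orf_protein <- function(transcript, orf) {
  rec <- single_dna_record(transcript)
  s <- strand_seq(rec$seq, orf$frame)
  nt <- substr(s, orf$start + 1L, orf$end)
  aa <- translate_codons(nt, 0L, nchar(nt) %/% 3L)
  sub("\\*$", "", paste(aa, collapse = ""))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

strand_seq <- function(seq, frame) {
  if (frame > 0L) seq
  else as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_codons <- function(s, offset, n_codons) {
  if (n_codons < 1L) return(character(0))
  starts <- offset + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  unname(aa)
}

single_dna_record <- function(transcript) {
  if (methods::is(transcript, "XStringSet")) {
    if (methods::is(transcript, "AAStringSet")) {
      stop("expected a DNA sequence, got protein")
    }
    stopifnot(length(transcript) == 1L)
    return(list(id = names(transcript)[1], seq = as.character(transcript[[1]])))
  }
  stopifnot(is.character(transcript), length(transcript) == 1L)
  id <- if (is.null(names(transcript))) "transcript" else names(transcript)
  seq <- toupper(transcript[[1]])
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), ALPHABET_CHARS$dna)
  if (length(bad)) {
    stop("not a DNA sequence (alphabet mismatch): ", paste(bad, collapse = ""))
  }
  list(id = id, seq = seq)
}
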