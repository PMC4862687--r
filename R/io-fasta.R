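#' Read a FASTA file into a sequence set
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' conventions the rest of the pipeline relies on: unique, non-empty record
#' identifiers; non-empty sequences; and characters restricted to the declared
#' alphabet (ambiguity codes allowed: `N` for DNA, `X` for protein).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet], one
#'   element per record, in file order; names are the first whitespace-
#'   delimited token of each header.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(Biostrings::width(raw) == 0L)) {
    bad <- ids[Biostrings::width(raw) == 0L]
    stop("FASTA record(s) with empty sequence: ", paste(bad, collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids
  check_alphabet(seqs, alphabet)
  if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
  else Biostrings::AAStringSet(seqs)
}

#' Write a sequence set to FASTA
#'
#' @param x A named character vector or `XStringSet`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- as_named_chr(x)
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = width)
  invisible(path)
}

ALPHABET_CHARS <- list(
  dna = c("A", "C", "G", "T", "N"),
  protein = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
)

check_alphabet <- function(seqs, alphabet) {
  ok <- ALPHABET_CHARS[[alphabet]]
  for (i in seq_along(seqs)) {
    ch <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(ch, ok)
    if (length(bad)) {
      stop("sequence ", names(seqs)[i], " contains character(s) outside the ",
           alphabet, " alphabet: ", paste(bad, collapse = ""))
    }
  }
  invisible(TRUE)
}

# Accept XStringSet or named character; return named character vector.
as_named_chr <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else {
    out <- x
  }
  if (length(out) == 0L) return(stats::setNames(character(0), character(0)))
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("sequences must carry non-empty names")
  }
  out
}
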