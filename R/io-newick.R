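#' Newick tree serialization
#'
#' Writes an [ape::phylo] tree as standard Newick, with bootstrap supports (if
#' present in `node.label`) emitted as internal node labels. Leaf labels
#' containing Newick metacharacters (`(){}[]:;,` quotes or whitespace) are
#' emitted single-quoted, and [read_newick()] restores them, so write + read
#' round-trips any labeled tree.
#'
#' @param tree An `ape::phylo` object with labeled leaves and branch lengths.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (is.null(labs) || any(is.na(labs)) || any(!nzchar(labs))) {
    stop("every leaf must carry a non-empty label")
  }
  if (anyDuplicated(labs)) stop("leaf labels must be unique")
  needs_quote <- grepl("[]();:,{}'\" \t[]", labs)
  placeholder <- sprintf("gpcrmineTIP%06d", seq_along(labs))
  tr2 <- tree
  tr2$tip.label <- ifelse(needs_quote, placeholder, labs)
  txt <- ape::write.tree(tr2)
  for (i in which(needs_quote)) {
    quoted <- paste0("'", gsub("'", "''", labs[i]), "'")
    txt <- sub(placeholder[i], quoted, txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Counterpart of [write_newick()]; single-quoted labels (including escaped
#' quotes) are restored verbatim.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object; internal node labels (e.g. bootstrap
#'   supports) are kept in `node.label`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # replace quoted labels with parse-safe placeholders, then restore
  m <- gregexpr("'(?:[^']|'')*'", txt)[[1]]
  restored <- character(0)
  if (m[1] != -1L) {
    pieces <- regmatches(txt, gregexpr("'(?:[^']|'')*'", txt))[[1]]
    restored <- gsub("''", "'", substr(pieces, 2, nchar(pieces) - 1))
    for (i in seq_along(pieces)) {
      txt <- sub(pieces[i], sprintf("gpcrmineTIP%06d", i), txt, fixed = TRUE)
    }
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  for (i in seq_along(restored)) {
    ph <- sprintf("gpcrmineTIP%06d", i)
    tree$tip.label[tree$tip.label == ph] <- restored[i]
    if (!is.null(tree$node.label)) {
      tree$node.label[tree$node.label == ph] <- restored[i]
    }
  }
  tree
}
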