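#' @name annotation_table
#' @title Receptor annotation table I/O
#'
#' @description
#' The curated receptor database is serialized as a UTF-8 tab-separated table
#' with a fixed column order (a repo convention mirroring the published
#' spreadsheet legend): `clone_id`, `gene_name`, `cluster`, `orf_confident`,
#' `n_term_ok`, `c_term_ok`, `n_tm_domains`, `max_control_rpkm`,
#' `norm_log2fc`, `insitu_pattern`. Missing optional fields are written as
#' `NA`. The in-situ pattern cell is a comma-separated list of codes from the
#' legend set (BR, INT, TE, OV, OVD, VIT, SPD, CO, NE). A fold change whose
#' denominator was zero is stored as its numeric sentinel value
#' (`log2(10000)`, printed 13.29), never as a symbol.
NULL

ANNOTATION_COLUMNS <- c(
  "clone_id", "gene_name", "cluster", "orf_confident", "n_term_ok",
  "c_term_ok", "n_tm_domains", "max_control_rpkm", "norm_log2fc",
  "insitu_pattern"
)

INSITU_CODES <- c("BR", "INT", "TE", "OV", "OVD", "VIT", "SPD", "CO", "NE")

validate_annotation <- function(rows) {
  stopifnot(is.data.frame(rows))
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(rows))
  if (length(missing_cols)) {
    stop("annotation table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(rows) == 0L) return(rows[ANNOTATION_COLUMNS])
  for (fl in c("orf_confident", "n_term_ok", "c_term_ok")) {
    if (!is.logical(rows[[fl]])) stop("column ", fl, " must be logical")
  }
  if (any(rows$n_tm_domains < 0, na.rm = TRUE)) {
    stop("n_tm_domains must be >= 0")
  }
  if (any(rows$max_control_rpkm < 0, na.rm = TRUE)) {
    stop("max_control_rpkm must be non-negative")
  }
  pats <- rows$insitu_pattern[!is.na(rows$insitu_pattern)]
  if (length(pats)) {
    codes <- unique(unlist(strsplit(pats, ",", fixed = TRUE)))
    bad <- setdiff(trimws(codes), INSITU_CODES)
    if (length(bad)) {
      stop("unknown in-situ code(s): ", paste(bad, collapse = ", "))
    }
  }
  rows[ANNOTATION_COLUMNS]
}

#' Write the receptor annotation table
#'
#' @param rows Data frame with the columns listed under [annotation_table].
#' @param path Output path (TSV).
#' @export
write_annotation_table <- function(rows, path) {
  rows <- validate_annotation(rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the receptor annotation table
#'
#' @param path TSV path written by [write_annotation_table()].
#' @return Data frame with the documented columns and types.
#' @export
read_annotation_table <- function(path) {
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = "NA",
                            colClasses = c(
                              clone_id = "character", gene_name = "character",
                              cluster = "character", orf_confident = "logical",
                              n_term_ok = "logical", c_term_ok = "logical",
                              n_tm_domains = "integer",
                              max_control_rpkm = "numeric",
                              norm_log2fc = "numeric",
                              insitu_pattern = "character"),
                            fileEncoding = "UTF-8")
  validate_annotation(rows)
}

#' Read a three-column similarity edge list
#'
#' Parses whitespace-delimited lines `node_i node_j p_value`. Self-edges are
#' dropped; a pair listed more than once keeps its smallest p-value (edges
#' are undirected). P-values outside (0, 1] or non-numeric raise an error
#' naming the offending line.
#'
#' @param path Path to the edge-list file.
#' @return Data frame with columns `node_i`, `node_j`, `p_value`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  keep[1] <- keep[1] && !grepl("node_i", lines[1], fixed = TRUE)  # header
  edges <- list()
  for (ln in which(keep)) {
    parts <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(parts) != 3L) {
      stop("edge list line ", ln, ": expected 3 fields, got ", length(parts))
    }
    p <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(p)) stop("edge list line ", ln, ": non-numeric p-value '",
                       parts[3], "'")
    if (p <= 0 || p > 1) stop("edge list line ", ln, ": p-value ", p,
                              " outside (0, 1]")
    if (parts[1] == parts[2]) next  # self-edge
    edges[[length(edges) + 1L]] <- data.frame(
      node_i = parts[1], node_j = parts[2], p_value = p,
      stringsAsFactors = FALSE)
  }
  if (!length(edges)) {
    return(data.frame(node_i = character(), node_j = character(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, edges)
  # canonical unordered pair, keep min p across duplicates
  a <- pmin(df$node_i, df$node_j)
  b <- pmax(df$node_i, df$node_j)
  key <- paste(a, b, sep = "\r")
  df <- data.frame(node_i = a, node_j = b, p_value = df$p_value,
                   stringsAsFactors = FALSE)
  df <- df[order(key, df$p_value), ]
  df <- df[!duplicated(paste(df$node_i, df$node_j, sep = "\r")), ]
  rownames(df) <- NULL
  df
}

#' Write a three-column similarity edge list
#'
#' @param edges Data frame with `node_i`, `node_j`, `p_value`.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("node_i", "node_j", "p_value") %in% names(edges)))
  if (any(edges$p_value <= 0 | edges$p_value > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  utils::write.table(edges[c("node_i", "node_j", "p_value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
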