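#' Read and write delimited matrices and label files
#'
#' The on-disk formats used by the command-line interface: numeric matrices
#' are delimited text with a header row and sample identifiers in the first
#' column; labelings are two-column delimited text (`sample_id`, `label`).
#' The delimiter is inferred from the file extension (`.csv` comma,
#' anything else tab) unless given explicitly.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) infers from the
#'   extension.
#' @return `read_matrix()`: a numeric matrix with row names.
#'   `read_labels()`: a named character vector. The writers return their
#'   input invisibly.
#' @name io
NULL

.infer_delim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' @rdname io
#' @export
read_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("cannot read matrix file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .infer_delim(path, delim),
                          row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname io
#' @param x Numeric matrix with row names (written in the first column).
#' @export
write_matrix <- function(x, path, delim = NULL) {
  x <- as.matrix(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .infer_delim(path, delim),
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname io
#' @export
read_labels <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("cannot read labels file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .infer_delim(path, delim),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("labels file needs two columns: sample_id, label")
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' @rdname io
#' @param labels Named label vector (names are sample identifiers).
#' @export
write_labels <- function(labels, path, delim = NULL) {
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("S", seq_along(labels))
  df <- data.frame(sample_id = ids, label = as.character(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .infer_delim(path, delim),
                     quote = FALSE, row.names = FALSE)
  invisible(labels)
}
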