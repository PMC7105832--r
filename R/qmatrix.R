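#' Validate and coerce a Q-matrix
#'
#' A Q-matrix is a binary items-by-attributes loading matrix: entry
#' \eqn{q_{jk} = 1} when item j requires attribute k. Validity requires all
#' entries in \{0, 1\}, at least one nonzero entry in every row (each item
#' measures something) and in every column (each attribute is measured by
#' some item).
#'
#' @param x Matrix or data frame of 0/1 entries, items in rows.
#' @return Integer matrix of class `qmatrix`.
#' @export
as_qmatrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "integer")
  }
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    bad <- which(apply(m, 1, function(r) anyNA(r) || !all(r %in% c(0, 1))))
    stop("Q-matrix entries must all be 0 or 1; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  zr <- which(rowSums(m) == 0)
  if (length(zr)) {
    stop("every Q-matrix row needs at least one 1; offending row(s): ",
         paste(zr, collapse = ", "), call. = FALSE)
  }
  zc <- which(colSums(m) == 0)
  if (length(zc)) {
    stop("every Q-matrix column needs at least one 1; offending column(s): ",
         paste(zc, collapse = ", "), call. = FALSE)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("A", seq_len(ncol(m)))
  rownames(m) <- NULL
  class(m) <- c("qmatrix", class(m))
  m
}

#' Read a Q-matrix from CSV
#'
#' Expects a header row of attribute names and one row per item with 0/1
#' cells. Validation failures name the offending rows or columns.
#'
#' @param path Path to the CSV file.
#' @return A `qmatrix` (see [as_qmatrix()]).
#' @export
read_qmatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_qmatrix(df)
}

#' Write a Q-matrix to CSV
#'
#' @param q A `qmatrix` or binary matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qmatrix <- function(q, path) {
  utils::write.csv(as.data.frame(unclass(q)), path, row.names = FALSE)
  invisible(path)
}
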