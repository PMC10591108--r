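# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_usage(...)
  invisible(TRUE)
}

# HC1 heteroskedasticity-robust covariance for a linear fit.
# X: n x k design, e: residual vector. Returns k x k matrix.
hc1_cov <- function(X, e) {
  n <- nrow(X)
  k <- ncol(X)
  xtx_inv <- chol2inv(qr.R(qr(X)))
  meat <- crossprod(X * e, X * e)
  (n / (n - k)) * xtx_inv %*% meat %*% xtx_inv
}

# Deterministic child seed: keeps derived seeds inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

#' Write a data frame as tab-separated text
#'
#' Plain TSV writer used by every pipeline stage: no quoting, no row names.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a numeric matrix as TSV with a leading id column
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_name name for the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_tsv(df, path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path file path.
#' @return numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
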