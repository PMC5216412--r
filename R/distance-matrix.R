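#' Construct a labelled distance matrix
#'
#' Symmetric, non-negative matrix with zero diagonal, used for R_ST and
#' F_ST distances fed to ordination and clustering. Raw (possibly negative)
#' estimates, where they exist, travel in the `raw` attribute.
#'
#' @param m Square numeric matrix with identical row/column labels.
#' @param raw Optional matrix of raw signed estimates, same shape.
#' @return An object of class `dist_matrix` (a plain labelled matrix).
#' @export
dist_matrix <- function(m, raw = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) rownames(m) <- paste0("L", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels must agree")
  }
  if (any(!is.finite(m))) stop("distances must be finite")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 0)) stop("diagonal must be exactly zero")
  if (any(m < 0)) stop("distances must be non-negative")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (!is.null(raw)) attr(m, "raw") <- as.matrix(raw)
  class(m) <- c("dist_matrix", class(matrix()))
  m
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line holds the matrix order; each following line a label and its
#' full row, preserving at least 9 decimal digits.
#'
#' @param D A `dist_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  n <- nrow(D)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste(c(rownames(D)[i],
                       sprintf("%.10g", unclass(D)[i, ])), collapse = "  "),
               con)
  }
  invisible(path)
}

#' Read a distance matrix in PHYLIP square format
#'
#' @param path File path.
#' @return A [dist_matrix()].
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP matrix")
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(parts) != n + 1L) {
      stop("malformed PHYLIP row at line ", i + 1L)
    }
    labels[i] <- parts[1L]
    m[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(m) <- list(labels, labels)
  dist_matrix(m)
}

#' Upper-triangle values of a distance matrix
#' @param D A square matrix.
#' @return Numeric vector of strictly-upper-triangle entries.
#' @export
upper_tri_vec <- function(D) {
  D <- as.matrix(D)
  D[upper.tri(D)]
}
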