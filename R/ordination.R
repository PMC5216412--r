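#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: double-center `-1/2 * J D^2 J`, eigendecompose, and
#' return the top-`k` coordinate axes scaled by the square root of their
#' eigenvalues. Negative eigenvalues are reported but never used for
#' coordinates.
#'
#' @param D A [dist_matrix()] (or symmetric matrix with labels).
#' @param k Number of dimensions, `k < nrow(D)`.
#' @return An object of class `ordination_result`: `coordinates`
#'   (labels x k), `eigenvalues` (all, decreasing), and `residual` (sum of
#'   absolute omitted eigenvalues over sum of absolute eigenvalues).
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("distances must be finite")
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of labels")
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  eig <- fit$eig
  used <- sum(abs(eig[seq_len(k)]))
  resid <- if (sum(abs(eig)) > 0) 1 - used / sum(abs(eig)) else 0
  structure(list(coordinates = coords, eigenvalues = eig,
                 residual = resid),
            class = "ordination_result")
}

#' PCA of relative haplogroup frequencies per population
#'
#' Haplogroup labels are collapsed to ancestors at a chosen depth of the
#' haplogroup tree, relative frequencies are computed per population
#' (rows sum to 1), and a column-centred PCA is taken via
#' eigendecomposition of the covariance matrix.
#'
#' @param table A [haplotype_table()].
#' @param tree A [haplogroup_tree()].
#' @param depth Tree depth at which to pool haplogroups (default 1).
#' @param k Number of components to return.
#' @return An `ordination_result` with population scores; the frequency
#'   matrix is attached as attribute `frequencies`.
#' @export
haplogroup_frequency_pca <- function(table, tree, depth = 1L, k = 2L) {
  pops <- unique(table$population)
  hg <- haplogroup_at_depth(tree, table$haplogroup, depth)
  levels_hg <- sort(unique(hg))
  freq <- t(vapply(pops, function(p) {
    v <- table(factor(hg[table$population == p], levels = levels_hg))
    as.numeric(v) / sum(v)
  }, numeric(length(levels_hg))))
  dimnames(freq) <- list(pops, levels_hg)
  centred <- scale(freq, center = TRUE, scale = FALSE)
  cv <- stats::cov(freq)
  ed <- eigen(cv, symmetric = TRUE)
  eig <- pmax(ed$values, 0)
  k <- min(k, ncol(freq))
  scores <- centred %*% ed$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- structure(
    list(coordinates = scores, eigenvalues = eig,
         residual = if (sum(eig) > 0) 1 - sum(eig[seq_len(k)]) / sum(eig) else 0),
    class = "ordination_result")
  attr(out, "frequencies") <- freq
  out
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination: %d labels x %d dimensions, residual %.3g\n",
              nrow(x$coordinates), ncol(x$coordinates), x$residual))
  invisible(x)
}
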