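#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}), followed by a clean-up pass
#' that clamps negative branch lengths to zero and transfers the deficit
#' to the sibling edge so path lengths through the node are preserved.
#'
#' @param D A [dist_matrix()] (n >= 2).
#' @return An unrooted `phylo` object.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D))) stop("NaN distance")
  n <- nrow(D)
  if (n < 2L) stop("need at least two labels")
  if (n == 2L) {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(D)[1L], D[1, 2] / 2,
                   rownames(D)[2L], D[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  phy <- ape::nj(stats::as.dist(D))
  clamp_negative_branches(phy)
}

# set negative edges to zero, moving the deficit onto the sibling edge;
# passes are bounded (a deficit can bounce between siblings), any
# residual negative is clamped at the end
clamp_negative_branches <- function(phy) {
  for (pass in seq_len(2L * nrow(phy$edge))) {
    neg <- which(phy$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(phy$edge.length[neg])]
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    par <- phy$edge[e, 1L]
    sibs <- which(phy$edge[, 1L] == par & seq_len(nrow(phy$edge)) != e)
    if (length(sibs)) {
      s <- sibs[1L]
      phy$edge.length[s] <- phy$edge.length[s] + deficit
    }
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Ward clustering of a distance matrix via its MDS embedding
#'
#' Coordinates are reconstructed from the leading dimensions of a
#' classical MDS (default 3, fewer when the matrix is small) and
#' agglomerated with Ward's minimum-variance method on their Euclidean
#' distances (`hclust`, `ward.D2`).
#'
#' @param D A [dist_matrix()].
#' @param k_mds Number of MDS dimensions used for reconstruction.
#' @return An `hclust` dendrogram.
#' @export
ward_cluster <- function(D, k_mds = 3L) {
  D <- as.matrix(D)
  if (any(is.na(D))) stop("NaN distance")
  n <- nrow(D)
  if (n < 2L) stop("need at least two labels")
  k <- min(k_mds, n - 1L)
  ord <- classical_mds(D, k = k)
  stats::hclust(stats::dist(ord$coordinates), method = "ward.D2")
}
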