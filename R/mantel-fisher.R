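#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-upper triangles; significance by
#' permuting the label order of the second matrix. The p-value uses the
#' `(count >= observed + 1) / (n_perm + 1)` convention and is one-sided
#' for positive association, as is standard for distance concordance.
#'
#' @param D1,D2 Square symmetric matrices with identical labels in the
#'   same order.
#' @param n_perm Number of random permutations, or `"exhaustive"` to
#'   enumerate all `n!` label orders (exact test; `n <= 8` recommended).
#' @param seed RNG seed for random permutations.
#' @return A list with `r`, `p` and `n_perm`.
#' @export
mantel <- function(D1, D2, n_perm = 999L, seed = 1L) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("matrices must agree in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2))) {
    stop("matrix labels must agree in order")
  }
  n <- nrow(D1)
  if (n < 4L) stop("need at least 4 labels")
  v1 <- upper_tri_vec(D1)
  if (stats::sd(v1) == 0 || stats::sd(upper_tri_vec(D2)) == 0) {
    stop("zero variance in a distance triangle")
  }
  r_obs <- stats::cor(v1, upper_tri_vec(D2))
  stat <- function(perm) stats::cor(v1, upper_tri_vec(D2[perm, perm]))
  if (identical(n_perm, "exhaustive")) {
    perms <- all_perms(n)
    r_perm <- vapply(perms, stat, numeric(1))
    # exact rank fraction over the full permutation group
    p <- sum(r_perm >= r_obs - 1e-12) / length(perms)
    n_eff <- length(perms)
  } else {
    set.seed(as.integer(seed))
    r_perm <- vapply(seq_len(n_perm), function(i) stat(sample(n)), numeric(1))
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_eff <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_eff)
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Fisher exact test of geographic concordance
#'
#' Two-sided Fisher exact test on a 2x2 contingency table of
#' correctly/incorrectly classified populations on the two sides of an
#' inferred split (probability-mass ordering, ties included), as used to
#' ask whether an inferred population-tree split could match geography by
#' chance.
#'
#' @param k1_correct,k1_wrong,k2_wrong,k2_correct Non-negative integer
#'   cell counts of the 2x2 table, row-wise.
#' @return Two-sided p-value.
#' @export
fisher_geo_test <- function(k1_correct, k1_wrong, k2_wrong, k2_correct) {
  tab <- matrix(c(k1_correct, k1_wrong, k2_wrong, k2_correct), 2L, 2L,
                byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (sum(tab) == 0L) stop("all-zero table")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}
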