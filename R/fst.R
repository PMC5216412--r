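#' Hudson's F_ST between two populations
#'
#' Per site, with sample allele frequencies `p1`, `p2` and allele counts
#' `n1`, `n2`, the numerator is
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`. The genome-wide estimate is the ratio of
#' averages `sum(num) / sum(den)`. Sites monomorphic in the pooled sample
#' are excluded and their count reported.
#'
#' @param geno A [genotype_matrix()].
#' @param popA,popB Population labels present in `geno`.
#' @return A list with `per_site` (data frame: site, num, den, fst),
#'   `estimate` (ratio of averages), and `n_excluded` (monomorphic or
#'   under-covered sites).
#' @export
hudson_fst <- function(geno, popA, popB) {
  pops <- attr(geno, "population")
  a <- unclass(geno)[, pops == popA, drop = FALSE]
  b <- unclass(geno)[, pops == popB, drop = FALSE]
  if (ncol(a) == 0L || ncol(b) == 0L) stop("population absent from matrix")
  n1 <- 2 * rowSums(!is.na(a))
  n2 <- 2 * rowSums(!is.na(b))
  p1 <- rowSums(a, na.rm = TRUE) / n1
  p2 <- rowSums(b, na.rm = TRUE) / n2
  usable <- n1 >= 2 & n2 >= 2
  pooled_poly <- (rowSums(a, na.rm = TRUE) + rowSums(b, na.rm = TRUE)) > 0 &
    (rowSums(a, na.rm = TRUE) + rowSums(b, na.rm = TRUE)) < (n1 + n2)
  keep <- usable & pooled_poly
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  per_site <- data.frame(site = rownames(geno)[keep],
                         num = num[keep], den = den[keep],
                         fst = num[keep] / den[keep])
  list(per_site = per_site,
       estimate = sum(per_site$num) / sum(per_site$den),
       n_excluded = sum(!keep))
}

#' Pairwise Hudson-type F_ST between individual samples
#'
#' Each diploid individual is treated as a population of two allele copies
#' and the Hudson form is aggregated over sites as a ratio of averages.
#' Sites missing in either member of a pair are skipped; pairs with fewer
#' than `min_sites` usable sites are flagged unreliable.
#'
#' @param geno A [genotype_matrix()].
#' @param min_sites Minimum usable sites per pair (default 50).
#' @return A [dist_matrix()] over samples (entries clamped at 0; raw
#'   signed estimates in `attr(,"raw")`, unreliable pairs flagged in
#'   `attr(,"unreliable")`).
#' @export
pairwise_individual_fst <- function(geno, min_sites = 50L) {
  g <- unclass(geno)
  n <- ncol(g)
  labs <- colnames(g)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  raw <- m
  unreliable <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      p1 <- g[ok, i] / 2
      p2 <- g[ok, j] / 2
      poly <- (p1 + p2) > 0 & (p1 + p2) < 2
      p1 <- p1[poly]; p2 <- p2[poly]
      # n1 = n2 = 2 allele copies per individual
      num <- (p1 - p2)^2 - p1 * (1 - p1) - p2 * (1 - p2)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      est <- if (sum(den) > 0) sum(num) / sum(den) else 0
      raw[i, j] <- raw[j, i] <- est
      m[i, j] <- m[j, i] <- max(est, 0)
      if (sum(ok) < min_sites) unreliable[i, j] <- unreliable[j, i] <- TRUE
    }
  }
  out <- dist_matrix(m, raw = raw)
  attr(out, "unreliable") <- unreliable
  out
}
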