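# small fixtures built in code, shared across test files

make_table <- function(reps, population, haplogroup = NULL,
                       loci = paste0("L", seq_len(ncol(reps)))) {
  reps <- as.matrix(reps)
  colnames(reps) <- loci
  haplotype_table(
    sample_id = paste0("s", seq_len(nrow(reps))),
    population = population,
    haplogroup = if (is.null(haplogroup)) rep("J", nrow(reps)) else haplogroup,
    repeats = reps
  )
}

# naive O(n^2 L) R_ST oracle: averages of squared differences computed by
# explicit double loops
rst_brute <- function(reps_a, reps_b) {
  num <- 0; den <- 0
  pair_mean <- function(m) {
    n <- nrow(m)
    if (n < 2) return(NA_real_)
    tot <- 0; cnt <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      tot <- tot + (m[i, 1] - m[j, 1])^2; cnt <- cnt + 1
    }
    tot / cnt
  }
  for (l in seq_len(ncol(reps_a))) {
    a <- reps_a[!is.na(reps_a[, l]), l, drop = FALSE]
    b <- reps_b[!is.na(reps_b[, l]), l, drop = FALSE]
    sw <- mean(c(pair_mean(a), pair_mean(b)), na.rm = TRUE)
    sbar <- pair_mean(rbind(a, b))
    if (is.na(sbar)) next
    if (is.nan(sw) || is.na(sw)) sw <- 0
    num <- num + (sbar - sw)
    den <- den + sbar
  }
  if (den == 0) 0 else num / den
}

# truncated Poisson-mixture oracle for the SMM net-change probability
smm_brute <- function(k, theta, mmax = 400) {
  k <- abs(k)
  total <- 0
  for (m in seq(k, mmax, by = 2)) {
    # m steps, net k: choose (m+k)/2 ups
    total <- total + stats::dpois(m, theta) *
      stats::dbinom((m + k) / 2, m, 0.5)
  }
  total
}

# two-sided Fisher p by exhaustive enumeration of tables with fixed margins
fisher_brute <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    stats::dhyper(x, r1, r2, c1)
  }, numeric(1))
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs + 1e-7 * obs])
}
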