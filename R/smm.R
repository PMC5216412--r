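#' Single-step mutation model transition probability
#'
#' Probability that a STR locus changes by a net `k` repeats after an
#' expected number `theta = mu * t` of mutations, each +1 or -1 with
#' probability 1/2. Mutation counts are Poisson, so the net change is
#' symmetric Skellam: `P(k) = exp(-theta) * I_|k|(theta)` with `I` the
#' modified Bessel function of the first kind. Computed with the
#' exponentially-scaled Bessel function, stable for `theta` up to 1e4.
#'
#' @param k Integer net repeat change (vectorised).
#' @param theta Expected mutation count, `>= 0`.
#' @return Log-probability (`-Inf` where the probability is 0).
#' @export
smm_transition_logprob <- function(k, theta) {
  if (any(theta < 0)) stop("theta must be non-negative")
  k <- abs(as.integer(k))
  n <- max(length(k), length(theta))
  k <- rep_len(k, n)
  theta <- rep_len(theta, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- smm_probs_cpp(theta[i], k[i])[k[i] + 1L]
    out[i] <- if (p > 0) log(p) else -Inf
  }
  out
}
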