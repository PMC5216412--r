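#' Prior specification for the STR coalescent MCMC
#'
#' Defaults (all overridable): per-locus mutation rate
#' `mu ~ Gamma(shape 2, mean 6.9e-4)`; present total size
#' `N0 ~ Gamma(shape 1, mean 5000)`; growth rate
#' `growth ~ Gamma(shape 1, mean 0.002)` per generation; growth onset
#' `beta ~ Uniform(0, 5000)` generations; split proportion
#' `p_split ~ Beta(1, 1)`; split times `~ Uniform(0, 1500)` generations
#' (subject to root-ward ordering; the range spans post-glacial and
#' Holocene divergence scales with a wide margin). Each component is a list with a
#' `dist` field (`"gamma"`, `"uniform"`, `"beta"`, `"lognormal"`) and its
#' parameters.
#'
#' @param mu,N0,growth,beta,p_split,split_time Distribution specs.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu = list(dist = "gamma", shape = 2, rate = 2 / 6.9e-4),
                       N0 = list(dist = "gamma", shape = 1, rate = 1 / 5000),
                       growth = list(dist = "gamma", shape = 1, rate = 1 / 0.002),
                       beta = list(dist = "uniform", min = 0, max = 5000),
                       p_split = list(dist = "beta", shape1 = 1, shape2 = 1),
                       split_time = list(dist = "uniform", min = 0, max = 1500)) {
  out <- list(mu = mu, N0 = N0, growth = growth, beta = beta,
              p_split = p_split, split_time = split_time)
  for (nm in names(out)) check_dist_spec(out[[nm]], nm)
  structure(out, class = "prior_spec")
}

check_dist_spec <- function(sp, name) {
  if (!is.list(sp) || is.null(sp$dist)) {
    stop("prior component '", name, "' must be a list with a dist field")
  }
  pars <- unlist(sp[setdiff(names(sp), "dist")])
  switch(sp$dist,
    gamma = if (sp$shape <= 0 || sp$rate <= 0)
      stop("gamma hyperparameters must be positive (", name, ")"),
    beta = if (sp$shape1 <= 0 || sp$shape2 <= 0)
      stop("beta hyperparameters must be positive (", name, ")"),
    uniform = if (sp$max <= sp$min)
      stop("uniform prior needs max > min (", name, ")"),
    lognormal = if (sp$sdlog <= 0)
      stop("lognormal sdlog must be positive (", name, ")"),
    stop("unsupported prior distribution: ", sp$dist)
  )
  invisible(sp)
}

d_prior <- function(sp, x) {
  switch(sp$dist,
    gamma = stats::dgamma(x, shape = sp$shape, rate = sp$rate, log = TRUE),
    beta = stats::dbeta(x, sp$shape1, sp$shape2, log = TRUE),
    uniform = stats::dunif(x, sp$min, sp$max, log = TRUE),
    lognormal = stats::dlnorm(x, sp$meanlog, sp$sdlog, log = TRUE))
}

r_prior <- function(sp, n = 1L) {
  switch(sp$dist,
    gamma = stats::rgamma(n, shape = sp$shape, rate = sp$rate),
    beta = stats::rbeta(n, sp$shape1, sp$shape2),
    uniform = stats::runif(n, sp$min, sp$max),
    lognormal = stats::rlnorm(n, sp$meanlog, sp$sdlog))
}

q_prior <- function(sp, p) {
  switch(sp$dist,
    gamma = stats::qgamma(p, shape = sp$shape, rate = sp$rate),
    beta = stats::qbeta(p, sp$shape1, sp$shape2),
    uniform = sp$min + p * (sp$max - sp$min),
    lognormal = stats::qlnorm(p, sp$meanlog, sp$sdlog))
}

p_prior <- function(sp, q) {
  switch(sp$dist,
    gamma = stats::pgamma(q, shape = sp$shape, rate = sp$rate),
    beta = stats::pbeta(q, sp$shape1, sp$shape2),
    uniform = stats::punif(q, sp$min, sp$max),
    lognormal = stats::plnorm(q, sp$meanlog, sp$sdlog))
}

prior_support <- function(sp) {
  switch(sp$dist,
    gamma = c(0, Inf),
    beta = c(0, 1),
    uniform = c(sp$min, sp$max),
    lognormal = c(0, Inf))
}
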