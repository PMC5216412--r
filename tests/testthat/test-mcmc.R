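test_that("SMM transition probabilities match the Poisson-mixture oracle", {
  expect_equal(exp(smm_transition_logprob(0, 0)), 1)
  expect_equal(exp(smm_transition_logprob(2, 0)), 0)
  # theta = 1, k = 0: e^-1 I_0(1), frozen from the truncated Poisson sum
  expect_equal(exp(smm_transition_logprob(0, 1)), 0.46575961, tolerance = 1e-7)
  for (theta in c(0.1, 1, 10)) {
    for (k in 0:6) {
      expect_equal(exp(smm_transition_logprob(k, theta)),
                   smm_brute(k, theta), tolerance = 1e-10)
    }
    # probabilities over all net changes sum to 1
    ks <- 0:60
    p <- exp(smm_transition_logprob(ks, theta))
    expect_equal(p[1] + 2 * sum(p[-1]), 1, tolerance = 1e-12)
  }
  expect_error(smm_transition_logprob(0, -1), "non-negative")
})

test_that("pruning likelihood equals closed forms on tiny trees", {
  # zero-length tree with identical haplotypes: root prior only
  tr <- genealogy(parent = c(3L, 3L, NA), time = c(0, 0, 0),
                  tip_pop = c("A", "A"))
  tab <- make_table(matrix(c(14L, 14L, 12L, 12L), 2, 2), c("A", "A"))
  pad <- 5L
  W <- 2 * pad + 1
  expect_equal(tree_log_likelihood(tr, tab, mu = 1e-3, window_pad = pad),
               2 * log(1 / W))
  # two tips, one locus, net difference k over total path t:
  # equals the SMM transition probability plus the root term
  t_half <- 400
  tr2 <- genealogy(parent = c(3L, 3L, NA), time = c(0, 0, t_half),
                   tip_pop = c("A", "A"))
  tab2 <- make_table(matrix(c(13L, 16L), 2, 1), c("A", "A"))
  mu <- 2e-3
  pad <- 30L
  ll <- tree_log_likelihood(tr2, tab2, mu, window_pad = pad)
  W2 <- (16 - 13) + 2 * pad + 1
  want <- smm_transition_logprob(3, mu * 2 * t_half) - log(W2)
  expect_equal(ll, want, tolerance = 1e-8)
  # mu = 0 with differing haplotypes is impossible
  expect_equal(tree_log_likelihood(tr2, tab2, 0, window_pad = 10), -Inf)
})

test_that("likelihood is invariant to locus relabeling and tip order", {
  mod <- demography_model("A;", N0 = 800)
  sim <- simulate_str_sample(mod, c(A = 6), n_loci = 4, seed = 2)
  gen <- sim$truth$genealogy
  tr <- genealogy(gen$parent, gen$time, gen$tip_pop)
  reps <- loci_matrix(sim$table)
  base <- tree_log_likelihood(tr, reps, 6.9e-4, window_pad = 15)
  expect_equal(tree_log_likelihood(tr, reps[, c(3, 1, 4, 2)], 6.9e-4,
                                   window_pad = 15), base)
  # swap two tips and their data rows consistently
  perm <- c(2L, 1L, 3L, 4L, 5L, 6L)
  inv <- order(perm)
  parent2 <- gen$parent
  n_all <- length(parent2)
  map <- c(inv, seq.int(7L, n_all))
  new_parent <- rep(NA_integer_, n_all)
  for (v in seq_len(n_all)) {
    if (!is.na(parent2[v])) new_parent[map[v]] <- map[parent2[v]]
  }
  new_time <- numeric(n_all); new_time[map] <- gen$time
  tr_perm <- genealogy(new_parent, new_time, gen$tip_pop[perm])
  expect_equal(tree_log_likelihood(tr_perm, reps[perm, ], 6.9e-4,
                                   window_pad = 15), base)
})

test_that("coalescent prior matches closed forms and rejects violations", {
  mod <- demography_model("A;", N0 = 1000)
  t_obs <- 700
  tr <- genealogy(c(3L, 3L, NA), c(0, 0, t_obs), c("A", "A"))
  expect_equal(coalescent_log_prior(tr, mod),
               -t_obs / 1000 - log(1000), tolerance = 1e-12)
  # density integrates to 1 over coalescence time (quadrature)
  ts <- seq(0.25, 30000, by = 0.5)  # midpoint rule
  dens <- vapply(ts, function(t) {
    exp(coalescent_log_prior(genealogy(c(3L, 3L, NA), c(0, 0, t),
                                       c("A", "A")), mod))
  }, numeric(1))
  expect_equal(sum(dens) * 0.5, 1, tolerance = 1e-4)
  # cross-population coalescence below the split time has zero density
  mod2 <- demography_model("(A,B)root;", N0 = 2000,
                           split_times = c(root = 500))
  tr_bad <- genealogy(c(3L, 3L, NA), c(0, 0, 300), c("A", "B"))
  expect_equal(coalescent_log_prior(tr_bad, mod2), -Inf)
  tr_ok <- genealogy(c(3L, 3L, NA), c(0, 0, 800), c("A", "B"))
  expect_true(is.finite(coalescent_log_prior(tr_ok, mod2)))
})

test_that("growth-phase coalescent prior matches quadrature", {
  # n = 2 with growth: density f(t) = lambda(t) exp(-integral lambda),
  # lambda = 1 / N(t); checked against numeric quadrature normalisation
  mod <- demography_model("A;", N0 = 5000, N_a = 500, beta = 200)
  ts <- seq(0.125, 20000, by = 0.25)  # midpoint rule
  dens <- vapply(ts, function(t) {
    exp(coalescent_log_prior(genealogy(c(3L, 3L, NA), c(0, 0, t),
                                       c("A", "A")), mod))
  }, numeric(1))
  expect_equal(sum(dens) * 0.25, 1, tolerance = 1e-4)
  # hand value at t < beta
  t1 <- 100
  lam <- 1 / (5000 * exp(-mod$growth_rate * t1))
  cum <- refugium:::inv_size_integral(mod, 0, t1)
  expect_equal(coalescent_log_prior(genealogy(c(3L, 3L, NA), c(0, 0, t1),
                                              c("A", "A")), mod),
               log(lam) - cum, tolerance = 1e-10)
})

test_that("identical seeds give identical traces", {
  mod <- demography_model("(A,B)root;", N0 = 1500,
                          split_times = c(root = 250))
  sim <- simulate_str_sample(mod, c(A = 5, B = 5), n_loci = 4, seed = 8)
  f1 <- suppressWarnings(run_mcmc(sim$table, topology = "(A,B)root;",
                                  n_iter = 120, burn_in = 40, seed = 77))
  f2 <- suppressWarnings(run_mcmc(sim$table, topology = "(A,B)root;",
                                  n_iter = 120, burn_in = 40, seed = 77))
  expect_identical(f1$trace, f2$trace)
  expect_error(run_mcmc(sim$table, n_iter = 100, burn_in = 100), "exceed")
})

test_that("fixed-parameter no-data chains reproduce the coalescent", {
  # the sampler over genealogies alone matches the independent simulator
  reps0 <- matrix(14L, 6, 0)
  tab <- haplotype_table(paste0("s", 1:6), rep("A", 6), rep("J", 6), reps0)
  fit <- suppressWarnings(run_mcmc(
    tab, topology = NULL, n_iter = 6000, burn_in = 500, thin = 4, seed = 2,
    fixed = list(mu = 1e-3, N0 = 1000, growth = 0, beta = 0)))
  mod <- demography_model("A;", N0 = 1000)
  set.seed(5)
  sim <- replicate(3000, refugium:::simulate_genealogy(mod, c(A = 6))$tmrca)
  expect_gt(stats::ks.test(fit$trace$tmrca, sim)$p.value, 0.01)
})

test_that("UEP carrier TMRCA runs collapse to the carrier subset", {
  mod <- demography_model("A;", N0 = 800)
  sim <- simulate_str_sample(mod, c(A = 8), n_loci = 6, seed = 12)
  fit_all <- suppressWarnings(run_mcmc(sim$table, n_iter = 150, burn_in = 50,
                                       seed = 5))
  tab1 <- sim$table
  tab1$population <- rep("carriers", nrow(tab1))
  fit_uep <- suppressWarnings(uep_tmrca(sim$table, seq_len(nrow(sim$table)),
                                        n_iter = 150, burn_in = 50, seed = 5))
  expect_equal(fit_uep$trace$tmrca, fit_all$trace$tmrca)
  expect_warning(uep_tmrca(sim$table, 1L), "single carrier")
})
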