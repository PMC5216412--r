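test_that("degenerate simulations hit their closed-form corners", {
  mod <- demography_model("A;", N0 = 500)
  one <- simulate_str_sample(mod, c(A = 1), n_loci = 5, seed = 3)
  expect_equal(one$truth$tmrca, 0)
  expect_true(all(loci_matrix(one$table) == 14L))

  mod0 <- demography_model("A;", N0 = 500, mu = 0)
  many <- simulate_str_sample(mod0, c(A = 8), n_loci = 5, seed = 4)
  expect_true(all(loci_matrix(many$table) == 14L))

  expect_error(simulate_str_sample(mod, c(A = 0)), "sample sizes")
  expect_error(simulate_str_sample(mod, c(B = 2)), "match model populations")
})

test_that("pair coalescence times match the constant-size closed form", {
  mod <- demography_model("A;", N0 = 1000)
  set.seed(11)
  tm <- replicate(10000, refugium:::simulate_genealogy(mod, c(A = 2))$tmrca)
  # mean TMRCA for n = 2 is N (haploid scaling), within 3 standard errors
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1000), 3 * se)
  # full distribution is Exp(1/N): KS not rejecting at alpha = 0.01
  ks <- stats::ks.test(tm, stats::pexp, rate = 1 / 1000)
  expect_gt(ks$p.value, 0.01)
})

test_that("growth and splits shape the genealogy as specified", {
  # beta > 0 with N_a << N0: ancestral coalescence much faster
  modg <- demography_model("A;", N0 = 10000, N_a = 100, beta = 50)
  set.seed(21)
  tmg <- replicate(2000, refugium:::simulate_genealogy(modg, c(A = 2))$tmrca)
  # expected: survive the 50 growth generations (rate ~1/N0 there), then
  # coalesce at rate 1/100
  expect_lt(mean(tmg), 400)
  expect_gt(mean(tmg), 50)

  # lineages from two populations never coalesce below the split time
  mod2 <- demography_model("(A,B)root;", N0 = 1000,
                           split_times = c(root = 400))
  for (s in 1:20) {
    gen <- refugium:::simulate_genealogy(mod2, c(A = 3, B = 3))
    expect_gte(gen$tmrca, 400)
  }
})

test_that("pairwise repeat variance accumulates as 2 mu t under the SMM", {
  mod <- demography_model("A;", N0 = 800, mu = 2e-3)
  set.seed(31)
  diffs <- t(replicate(4000, {
    sim <- simulate_str_sample(mod, c(A = 2), n_loci = 4,
                               seed = sample.int(1e7, 1))
    reps <- loci_matrix(sim$table)
    c(mean((reps[1, ] - reps[2, ])^2), sim$truth$tmrca)
  }))
  # E[(x1 - x2)^2 | T] = 2 mu T per locus (Skellam variance of the path)
  resid <- diffs[, 1] - 2 * 2e-3 * diffs[, 2]
  se <- stats::sd(resid) / sqrt(nrow(diffs))
  expect_lt(abs(mean(resid)), 3 * se)
})

test_that("simulations are bitwise reproducible from the seed", {
  mod <- demography_model("(A,B)root;", N0 = 2000,
                          split_times = c(root = 300))
  a <- simulate_str_sample(mod, c(A = 6, B = 6), seed = 99, uep = c(M1 = 0.5))
  b <- simulate_str_sample(mod, c(A = 6, B = 6), seed = 99, uep = c(M1 = 0.5))
  expect_identical(a$table, b$table)
  expect_identical(a$truth$tmrca, b$truth$tmrca)
  expect_identical(a$truth$uep_tmrca, b$truth$uep_tmrca)
  g1 <- simulate_divergent_genotypes(100, c(10, 10), N = 200, t_split = 20,
                                     seed = 7)
  g2 <- simulate_divergent_genotypes(100, c(10, 10), N = 200, t_split = 20,
                                     seed = 7)
  expect_identical(unclass(g1), unclass(g2))
})

test_that("UEP placement marks a clade with a recorded TMRCA", {
  mod <- demography_model("A;", N0 = 1500)
  sim <- simulate_str_sample(mod, c(A = 20), seed = 5, uep = c(M1 = 0.4))
  carriers <- sim$table$haplogroup == "M1"
  expect_gt(sum(carriers), 0)
  expect_lt(sum(carriers), 20)
  expect_lte(sim$truth$uep_tmrca[["M1"]], sim$truth$tmrca)
})

test_that("drifted genotypes reach the expected Hudson F_ST", {
  g0 <- simulate_divergent_genotypes(2000, c(30, 30), N = 300, t_split = 0,
                                     seed = 13)
  f0 <- hudson_fst(g0, "pop1", "pop2")
  expect_lt(abs(f0$estimate), 0.02)

  N <- 300
  g <- simulate_divergent_genotypes(6000, c(40, 40), N = N,
                                    t_split = round(0.1 * 2 * N), seed = 17)
  f <- hudson_fst(g, "pop1", "pop2")
  target <- 1 - exp(-0.1)
  # bootstrap over sites for the SE of the ratio-of-averages estimate
  set.seed(1)
  boot <- replicate(200, {
    i <- sample.int(nrow(f$per_site), replace = TRUE)
    sum(f$per_site$num[i]) / sum(f$per_site$den[i])
  })
  expect_lt(abs(f$estimate - target), 3 * stats::sd(boot) + 0.005)
  expect_error(simulate_divergent_genotypes(10, c(5, 5), 100, -1), "t_split")
})
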