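test_that("harmonic-mean Ne follows the closed form", {
  expect_equal(signif(harmonic_mean_ne(c(7000, 9500)), 3), 8060)
  expect_equal(harmonic_mean_ne(c(4200, 4200)), 4200)
  expect_equal(harmonic_mean_ne(5000), 5000)
  expect_error(harmonic_mean_ne(numeric(0)), "empty")
  expect_error(harmonic_mean_ne(c(100, -5)), "positive")
  # harmonic <= geometric <= arithmetic on random positive inputs
  set.seed(2)
  for (i in 1:20) {
    v <- stats::rlnorm(sample(2:6, 1), 8, 1)
    h <- harmonic_mean_ne(v)
    g <- exp(mean(log(v)))
    expect_lte(h, g + 1e-9)
    expect_lte(g, mean(v) + 1e-9)
  }
})

test_that("F_ST dating is log-form, increasing, and linear in the limit", {
  cfg <- dating_config(c(7000, 9500), 28.96)
  expect_equal(signif(fst_to_time(0.075, cfg)$generations, 3), 1260)
  expect_equal(signif(fst_to_time(0.057, cfg)$generations, 3), 946)
  expect_equal(fst_to_time(0, cfg)$generations, 0)
  # strictly increasing in F_ST and in Ne
  f <- seq(0.01, 0.5, by = 0.01)
  g <- vapply(f, function(x) fst_to_time(x, cfg)$generations, numeric(1))
  expect_true(all(diff(g) > 0))
  cfg_big <- dating_config(20000, 28.96)
  expect_gt(fst_to_time(0.075, cfg_big)$generations,
            fst_to_time(0.075, cfg)$generations)
  # small-F_ST limit agrees with the linear approximation
  tiny <- fst_to_time(1e-6, cfg)
  expect_equal(tiny$generations / tiny$generations_linear, 1,
               tolerance = 1e-5)
  expect_error(fst_to_time(1, cfg), "< 1")
  expect_warning(fst_to_time(-0.01, cfg), "clamped")
  expect_error(dating_config(generation_time = 50), "20, 35")
})

test_that("split trees assemble, convert to ka, and flag inversions", {
  cfg <- dating_config(c(7000, 9500), 28.96)
  reports <- list(root = list(median = 800, q025 = 400, q975 = 1500))
  st <- assemble_split_tree(reports, "(A,B)root;", cfg)
  expect_equal(st$nodes$age_ka, 800 * 28.96 / 1000)
  expect_length(st$inversions, 0)
  phy <- ape::read.tree(text = st$newick)
  expect_setequal(phy$tip.label, c("A", "B"))
  # contradictory child-older-than-parent reports are flagged, not fixed
  reports2 <- list(root = list(median = 500, q025 = 300, q975 = 900),
                   inner = list(median = 900, q025 = 600, q975 = 1200))
  st2 <- assemble_split_tree(reports2, "((A,B)inner,C)root;", cfg)
  expect_equal(st2$inversions, "inner>root")
  expect_error(assemble_split_tree(reports, "((A,B)inner,C)root;", cfg),
               "no report")
})

test_that("double-conformation runs are deterministic and structured", {
  mod <- demography_model("((A,B)i1,(C,D)i2)root;", N0 = 4000,
                          split_times = c(root = 800, i1 = 250, i2 = 250))
  sim <- simulate_str_sample(mod, c(A = 6, B = 6, C = 6, D = 6),
                             n_loci = 6, seed = 21)
  plan <- list(A = "A", B = "B", C = "C", D = "D")
  r1 <- suppressWarnings(run_double_conformation(
    sim$table, plan, seed = 31, n_iter = 150, burn_in = 50))
  r2 <- suppressWarnings(run_double_conformation(
    sim$table, plan, seed = 31, n_iter = 150, burn_in = 50))
  expect_identical(r1$fit_ab_cd$trace, r2$fit_ab_cd$trace)
  expect_identical(r1$consistency, r2$consistency)
  expect_true(is.finite(r1$root_ab_cd$median))
  expect_true(is.finite(r1$root_a_b_cd$median))
  expect_error(run_double_conformation(sim$table, list(A = "A", B = "B",
                                                       C = "C", D = "Z")),
               "absent")
  expect_error(run_double_conformation(sim$table, list(A = "A", B = "A",
                                                       C = "C", D = "D")),
               "disjoint")
})
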