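test_that("analytic PMF kinds evaluate to their stated forms", {
  expect_equal(evaluate_pmf(analytic_pmf("uniform"), c(-3, 0, 17)), c(0, 0, 0))

  nw <- analytic_pmf("neutral_well", depth = 6, z_mid = 15, steepness = 2)
  expect_equal(evaluate_pmf(nw, 0), -6 / (1 + exp(-7.5)), tolerance = 1e-10)
  expect_equal(evaluate_pmf(nw, 0), -5.9966, tolerance = 1e-4)
  expect_equal(evaluate_pmf(nw, 15), -3)          # half depth at the wall
  expect_equal(evaluate_pmf(nw, -15), -3)         # symmetric in |z|
  expect_lt(abs(evaluate_pmf(nw, 60)), 1e-6)      # bulk reference

  ch <- analytic_pmf("charged_interfacial", depth = 4, z0 = 22, sigma = 3,
                     barrier = 3, sigma_b = 6)
  expect_equal(evaluate_pmf(ch, 22), -4 + 3 * exp(-22^2 / 72), tolerance = 1e-10)
  expect_equal(evaluate_pmf(ch, 22), -4, tolerance = 0.01)  # B-term negligible
  expect_gt(evaluate_pmf(ch, 0), 0)               # interior penalty above bulk

  tab <- analytic_pmf("custom_table", table = list(z = c(0, 1, 2), w = c(0, 2, 2)))
  expect_equal(evaluate_pmf(tab, 0.25), 0.5)      # linear interpolation
  expect_error(evaluate_pmf(tab, 2.5), "outside")
})

test_that("a biased trajectory equipartitions in a harmonic window", {
  plan <- build_plan(0, 20, 1, k_parallel = 2)
  cfg <- sampler_config(n_steps = 1e6, stride = 100, seed = 424242)
  ts <- simulate_window(analytic_pmf("uniform"), plan, 10L, cfg)
  kT <- KB_KCAL_MOL_K * plan$temperature
  # OU stationary moments: mean = center, var = kBT / k; bounds ~3 standard
  # errors at this correlation-adjusted effective sample size
  expect_lt(abs(mean(ts$values) - 10), 0.15)
  expect_lt(abs(var(ts$values) - kT / 2), 0.12)
})

test_that("trajectories are reproducible from the seed", {
  plan <- build_plan(0, 10, 1)
  cfg <- sampler_config(n_steps = 2e4, stride = 10, seed = 99L)
  a <- simulate_window(analytic_pmf("uniform"), plan, 5L, cfg)
  b <- simulate_window(analytic_pmf("uniform"), plan, 5L, cfg)
  expect_identical(a$values, b$values)
  cfg2 <- cfg; cfg2$seed <- 100L
  c2 <- simulate_window(analytic_pmf("uniform"), plan, 5L, cfg2)
  expect_false(identical(a$values, c2$values))
})

test_that("unbiased drift on a linear PMF matches -D*slope/kBT", {
  slope <- 0.5
  lin <- analytic_pmf("custom_table",
                      table = list(z = c(-60, 60), w = slope * c(-60, 60)))
  plan <- build_plan(-40, 40, 1, k_parallel = 0)
  kT <- KB_KCAL_MOL_K * plan$temperature
  t_total <- 0.5
  expected_drift <- -10 * slope / kT * t_total   # A after t_total ns
  finals <- vapply(1:30, function(s) {
    cfg <- sampler_config(dt = 1e-5, diffusion = 10, n_steps = t_total / 1e-5,
                          stride = t_total / 1e-5, seed = 7000L + s,
                          initial_z = 0)
    tail(simulate_window(lin, plan, 40L, cfg)$values, 1L)
  }, 0.0)
  se <- sqrt(2 * 10 * t_total / 30)
  expect_lt(abs(mean(finals) - expected_drift), 3 * se)
})

test_that("long biased runs reproduce the Boltzmann distribution", {
  plan <- build_plan(0, 20, 1, k_parallel = 2)
  # stride past the window correlation time so samples are near-independent
  cfg <- sampler_config(n_steps = 1e7, stride = 1e4, seed = 31415)
  ts <- simulate_window(analytic_pmf("uniform"), plan, 10L, cfg)
  kT <- KB_KCAL_MOL_K * plan$temperature
  sdv <- sqrt(kT / 2)
  breaks <- c(-Inf, 10 + sdv * seq(-2, 2, by = 0.5), Inf)
  obs <- table(cut(ts$values, breaks))
  probs <- diff(pnorm(breaks, 10, sdv))
  pval <- suppressWarnings(chisq.test(as.vector(obs), p = probs)$p.value)
  expect_gt(pval, 0.001)
})

test_that("dataset generation is deterministic with a ground-truth manifest", {
  pre <- synthetic_preset("alc0315_like")
  cfg <- sampler_config(n_steps = 2000, stride = 100)
  ds1 <- generate_dataset(pre$plan_charged, pre$plan_neutral, pre$pmf_charged,
                          pre$pmf_neutral, cfg = cfg, base_seed = 5L,
                          z_hi = pre$z_hi)
  ds2 <- generate_dataset(pre$plan_charged, pre$plan_neutral, pre$pmf_charged,
                          pre$pmf_neutral, cfg = cfg, base_seed = 5L,
                          z_hi = pre$z_hi)
  expect_identical(ds1$series_charged[[20]]$values,
                   ds2$series_charged[[20]]$values)
  expect_identical(ds1$manifest, ds2$manifest)

  # per-window seeds are distinct across windows and states
  seeds <- c(ds1$manifest$seeds_charged, ds1$manifest$seeds_neutral)
  expect_equal(anyDuplicated(seeds), 0L)

  # the manifest's truth equals an independent quadrature of the analytic pair
  z <- seq(0.01, pre$z_hi, by = 0.02)
  kT <- KB_KCAL_MOL_K * 310.15
  brute <- log10(mean(exp(-evaluate_pmf(pre$pmf_charged, z) / kT)) /
                 mean(exp(-evaluate_pmf(pre$pmf_neutral, z) / kT)))
  expect_equal(ds1$manifest$true_delta_pka, brute, tolerance = 1e-10)

  # identical charged/neutral profiles give exactly zero true shift
  null <- synthetic_preset("null")
  expect_equal(true_delta_pka(null$pmf_charged, null$pmf_neutral, 0, 45.5), 0)
})

test_that("presets have the membrane-like shape of the two lipid forms", {
  for (name in c("alc0315_like", "mc3_like")) {
    pre <- synthetic_preset(name)
    zi <- pre$pmf_charged$params[2]
    expect_gte(zi, 18); expect_lte(zi, 28)     # interfacial minimum position
    expect_gt(evaluate_pmf(pre$pmf_charged, 0), -0.5)  # interior near/above bulk
    expect_lt(evaluate_pmf(pre$pmf_neutral, 5), -5)    # broad deep interior well
    expect_lt(abs(evaluate_pmf(pre$pmf_neutral, pre$z_hi)), 0.05)  # flat tail
    expect_lt(true_delta_pka(pre$pmf_charged, pre$pmf_neutral, 0, pre$z_hi), 0)
  }
})
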