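test_that("binning follows the left-closed convention on the anchored grid", {
  plan <- build_plan(0, 1, 1)
  ts <- window_timeseries(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.3))
  h <- histogram_windows(list(ts), plan, bin_width = 0.2, z_range = c(0, 0.4))
  expect_equal(as.vector(h$counts), c(2L, 1L))
  expect_equal(h$bin_centers, c(0.1, 0.3))

  # a sample exactly on an interior edge goes to the right bin
  ts_edge <- window_timeseries(0.1, 0.2)
  h2 <- histogram_windows(list(ts_edge), plan, bin_width = 0.2,
                          z_range = c(0, 0.4))
  expect_equal(as.vector(h2$counts), c(0L, 1L))

  # protocol-style grid: [-2, 50] at 0.2 A gives 260 bins
  plan_alc <- build_plan(-2, 50, 1)
  ts3 <- window_timeseries(1:3, c(-1, 0, 25))
  h3 <- histogram_windows(list(ts3), plan_alc, bin_width = 0.2)
  expect_equal(length(h3$bin_centers), 260L)

  # out-of-range samples are reported, not folded into edge bins
  ts4 <- window_timeseries(1:3, c(-5, 0.1, 9))
  expect_message(
    h4 <- histogram_windows(list(ts4), plan, bin_width = 0.2,
                            z_range = c(0, 0.4)),
    "outside")
  expect_equal(sum(h4$counts), 1L)
  expect_equal(h4$n_outside, 2L)
})

test_that("a single unbiased window reproduces the histogram closed form", {
  plan <- build_plan(0, 1, 1, k_parallel = 0)
  ts <- window_timeseries(1:10 / 10, c(0.1, 0.1, 0.1, 0.1, 0.1, 0.3, 0.3, 0.3,
                                       0.5, 0.7))
  h <- histogram_windows(list(ts), plan, bin_width = 0.2, z_range = c(0, 0.8))
  res <- solve_wham(h)
  kT <- KB_KCAL_MOL_K * plan$temperature
  expected <- -kT * log(c(5, 3, 1, 1) / 10)
  expect_equal(res$pmf$energies, expected, tolerance = 1e-12)
  expect_true(res$converged)
  # normalization of the recovered distribution
  expect_lt(abs(sum(res$probabilities) - 1), 1e-10)
})

test_that("two overlapping windows recover a known linear PMF", {
  plan <- build_plan(0, 1, 1, k_parallel = 2)
  edges <- seq(-1, 2, by = 0.1)
  slope <- 1.5  # kcal/mol/A
  counts <- expected_counts(function(z) slope * z, plan, edges, N = 1e6)
  h <- histogram_from_counts(counts, plan, edges)
  res <- solve_wham(h, tolerance = 1e-10)
  expect_true(res$converged)
  pop <- !is.na(res$pmf$energies)
  W <- res$pmf$energies[pop]
  truth <- slope * res$pmf$bin_centers[pop]
  expect_lt(max(abs((W - mean(W)) - (truth - mean(truth)))), 0.05)
})

test_that("WHAM is gauge invariant and deterministic", {
  plan <- build_plan(0, 2, 1, k_parallel = 2)
  edges <- seq(-0.5, 2.5, by = 0.1)
  counts <- expected_counts(function(z) -1.2 * cos(z), plan, edges, N = 1e5)
  h <- histogram_from_counts(counts, plan, edges)
  res1 <- solve_wham(h)
  res2 <- solve_wham(h)
  expect_identical(res1$pmf$energies, res2$pmf$energies)  # bit-identical

  # adding a constant to every bias leaves the PMF shape unchanged:
  # emulate by a plan whose bias differs by a constant via half_factor trick
  # on a shifted-count check instead: scale all counts by 3 (same densities)
  h3 <- histogram_from_counts(counts * 3L, plan, edges)
  res3 <- solve_wham(h3)
  pop <- !is.na(res1$pmf$energies)
  expect_equal(res1$pmf$energies[pop] - mean(res1$pmf$energies[pop]),
               res3$pmf$energies[pop] - mean(res3$pmf$energies[pop]),
               tolerance = 1e-8)
})

test_that("solver PMF matches the independent maximum-likelihood oracle", {
  plan5 <- build_plan(0, 4, 1, k_parallel = 2)
  edges <- seq(-0.5, 4.5, by = 0.1)  # 50 bins
  shapes <- list(
    function(z) 0.8 * z,
    function(z) -2 / (1 + exp((abs(z) - 2) / 0.5)),
    function(z) 1.5 * sin(z)
  )
  for (W_fun in shapes) {
    counts <- expected_counts(W_fun, plan5, edges, N = 1e6)
    h <- histogram_from_counts(counts, plan5, edges)
    res <- solve_wham(h, tolerance = 1e-10)
    oracle <- wham_ml_oracle(h)
    mine <- centred_on(res$pmf, oracle$bin_centers)
    expect_lt(max(abs(mine - oracle$energies)), 0.02)
  }
})

test_that("non-convergence warns and flags, all-empty histograms error", {
  plan <- build_plan(0, 1, 1, k_parallel = 2)
  edges <- seq(-0.5, 1.5, by = 0.1)
  counts <- expected_counts(function(z) 2 * z, plan, edges, N = 1e4)
  h <- histogram_from_counts(counts, plan, edges)
  expect_warning(res <- solve_wham(h, tolerance = 1e-12, max_iter = 3),
                 "did not converge")
  expect_false(res$converged)
  expect_equal(res$iterations, 3L)

  h0 <- histogram_from_counts(matrix(0L, 2, length(edges) - 1), plan, edges)
  expect_error(solve_wham(h0), "empty")
})

test_that("adjacent-window overlap matches analytic values", {
  plan <- build_plan(0, 1, 1)
  edges <- seq(-6, 7, by = 0.05)
  centers <- edges[-length(edges)] + 0.025

  # identical histograms overlap fully
  n1 <- as.integer(round(1e6 * dnorm(centers, 0, 1) * 0.05))
  h_same <- histogram_from_counts(rbind(n1, n1), plan, edges)
  ov <- window_overlap(h_same)
  expect_equal(ov$overlap, 1.0, tolerance = 1e-3)
  expect_false(ov$flagged)

  # unit-variance Gaussians 1 A apart: overlap = 2*Phi(-0.5) ~ 0.617
  n2 <- as.integer(round(1e6 * dnorm(centers, 1, 1) * 0.05))
  h_shift <- histogram_from_counts(rbind(n1, n2), plan, edges)
  expect_equal(window_overlap(h_shift)$overlap, 2 * pnorm(-0.5),
               tolerance = 0.02)

  # disjoint histograms overlap 0 and get flagged
  a <- integer(length(centers)); b <- a
  a[10] <- 100L; b[200] <- 100L
  h_disj <- histogram_from_counts(rbind(a, b), plan, edges)
  expect_warning(ov3 <- window_overlap(h_disj), "overlap")
  expect_equal(ov3$overlap, 0)
  expect_true(ov3$flagged)
})

test_that("PMF text round-trip preserves energies, NA bins and temperature", {
  z <- seq(0.1, 5, by = 0.2)
  w <- sin(z); w[c(3, 10)] <- NA
  pmf <- pmf_profile(z, w, temperature = 300, provenance = "unit test")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf(pmf, path)
  back <- read_pmf(path)
  expect_equal(back$bin_centers, z, tolerance = 1e-9)
  expect_equal(back$energies, w, tolerance = 1e-9)
  expect_equal(back$temperature, 300)
  expect_equal(back$provenance, "unit test")
})
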