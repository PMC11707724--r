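kT310 <- KB_KCAL_MOL_K * 310.15
grid_pmf <- function(w, z = seq(0.1, 45.5, by = 0.2))
  pmf_profile(z, w, temperature = 310.15)

test_that("pKa shift closed forms hold", {
  z <- seq(0.1, 45.5, by = 0.2)
  w <- -3 * exp(-(z - 20)^2 / 50)
  same <- delta_pka(grid_pmf(w), grid_pmf(w), z_lo = 0, z_hi = 45.5)
  expect_equal(same, 0)

  # uniform offset c: delta = -c / (kB T ln 10); c = 1.41917 gives -1.000
  expect_equal(kT310 * log(10), 1.41917, tolerance = 1e-4)
  c0 <- 1.41917
  d <- delta_pka(grid_pmf(w + c0), grid_pmf(w), z_lo = 0, z_hi = 45.5)
  expect_equal(d, -c0 / (kT310 * log(10)), tolerance = 1e-12)
  expect_equal(d, -1.0, tolerance = 1e-4)
})

test_that("square-well pair matches the brute-force bin sum", {
  z <- seq(0.1, 44.9, by = 0.2)
  w_neutral <- ifelse(z <= 20, -4, 0)
  w_charged <- rep(0, length(z))
  mine <- delta_pka(grid_pmf(w_charged, z), grid_pmf(w_neutral, z),
                    z_lo = 0, z_hi = 45)
  brute <- brute_delta_pka(z, w_charged, w_neutral, 0, 45, 310.15)
  expect_equal(mine, brute, tolerance = 1e-10)
  expect_lt(mine, 0)  # stronger neutral binding lowers the apparent pKa
})

test_that("shift is invariant, antisymmetric, and monotone in the PMFs", {
  set.seed(5)
  z <- seq(0.1, 40, by = 0.2)
  wA <- -5 * exp(-(z - 22)^2 / 18) + 2 * exp(-z^2 / 60)
  wB <- -7 / (1 + exp((z - 14) / 2))

  d <- delta_pka(grid_pmf(wA, z), grid_pmf(wB, z), z_lo = 0, z_hi = 40)
  # common constant cancels
  dsh <- delta_pka(grid_pmf(wA + 2.2, z), grid_pmf(wB + 2.2, z),
                   z_lo = 0, z_hi = 40)
  expect_equal(d, dsh, tolerance = 1e-10)
  # antisymmetry
  expect_equal(delta_pka(grid_pmf(wB, z), grid_pmf(wA, z), 0, 40), -d,
               tolerance = 1e-12)
  # deepening the neutral PMF anywhere strictly lowers the shift
  wB2 <- wB; wB2[50] <- wB2[50] - 1
  expect_lt(delta_pka(grid_pmf(wA, z), grid_pmf(wB2, z), 0, 40), d)

  # Riemann consistency: halving the bin width moves the value < 1e-3
  z_f <- seq(0.05, 40, by = 0.1)
  wA_f <- -5 * exp(-(z_f - 22)^2 / 18) + 2 * exp(-z_f^2 / 60)
  wB_f <- -7 / (1 + exp((z_f - 14) / 2))
  d_f <- delta_pka(grid_pmf(wA_f, z_f), grid_pmf(wB_f, z_f), 0, 40)
  expect_lt(abs(d_f - d), 1e-3)
})

test_that("undefined bins or mismatched grids abort the shift integral", {
  z <- seq(0.1, 10, by = 0.2)
  w <- rep(0, length(z)); w[25] <- NA
  expect_error(delta_pka(grid_pmf(w, z), grid_pmf(rep(0, length(z)), z),
                         0, 10), "undefined")
  z2 <- z + 0.05
  expect_error(delta_pka(grid_pmf(rep(0, length(z)), z),
                         grid_pmf(rep(0, length(z)), z2), 0, 10), "grids")
})

test_that("apparent pKa reproduces the reference table rows exactly", {
  tab <- table1_reference()
  expect_equal(apparent_pka(tab$pka_s, tab$delta_pka), tab$pka_a_calc,
               tolerance = 1e-12)
  # identity at zero shift
  expect_equal(apparent_pka(8.3, 0), 8.3)
})

test_that("replicate statistics use the sample (n-1) standard deviation", {
  s <- replicate_stats(c(-2.5, -2.5, -2.5))
  expect_equal(s$mean, -2.5)
  expect_equal(s$sd, 0)

  s2 <- replicate_stats(c(-2, -3))
  expect_equal(s2$mean, -2.5)
  expect_equal(s2$sd, 1 / sqrt(2), tolerance = 1e-12)

  # single replicate: sd undefined, not zero
  s1 <- replicate_stats(-2.1)
  expect_true(is.na(s1$sd))
  expect_equal(s1$mean, -2.1)
})

test_that("calculated-vs-experimental regression matches the reference data", {
  tab <- table1_reference()
  three <- tab$lipid %in% c("ALC-0315", "MC3", "SM-102")
  expect_equal(round(rsquared(tab$pka_a_calc[three], tab$pka_a_expt[three]), 3),
               0.971)
  expect_equal(round(rsquared(tab$pka_a_calc, tab$pka_a_expt), 3), 0.998)

  # brute-force Pearson formula as an independent check on all four rows
  x <- tab$pka_a_calc; y <- tab$pka_a_expt
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
       sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(rsquared(x, y), r^2, tolerance = 1e-12)

  # affine pairs are perfectly correlated
  expect_equal(rsquared(c(1, 2, 5), 3 - 2 * c(1, 2, 5)), 1)
  expect_error(rsquared(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(rsquared(1:3, 1:4), "length")
})

test_that("bulk cutoff finder locates the plateau without overriding inputs", {
  z <- seq(0.1, 50, by = 0.2)
  w <- -6 / (1 + exp((z - 15) / 1.5))
  pmf <- grid_pmf(w, z)
  zc <- suggest_bulk_cutoff(pmf, flat_tol = 0.1)
  # sigmoid reaches |W| < 0.1 around z = 15 + 1.5*ln(59) ~ 21.1
  expect_gt(zc, 19); expect_lt(zc, 23)
  # a never-flat profile has no cutoff
  expect_true(is.na(suggest_bulk_cutoff(grid_pmf(z, z))))
})

test_that("pka_result ties the pieces together consistently", {
  res <- pka_result(pka_s = 9.26, per_replicate_deltas = c(-2.5, -2.6, -2.55),
                    z_lo = 0, z_hi = 45.5, label = "demo")
  expect_equal(res$pka_a, res$pka_s + res$delta_pka, tolerance = 1e-12)
  expect_equal(res$delta_mean, mean(c(-2.5, -2.6, -2.55)))
  expect_gte(res$delta_sd, 0)
  lines <- format_summary_table(list(res))
  expect_match(lines[2], "^demo\t9.26\t")
})
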