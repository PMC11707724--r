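# Independent oracles used to cross-check the package's estimators.
# These deliberately take different algorithmic routes than the
# implementation (direct likelihood optimisation instead of fixed-point
# iteration; brute-force loops instead of vectorised formulas).

KBT_REF <- 0.0019872041 * 310.15

# Maximum-likelihood WHAM oracle: minimise the convex objective
#   L(g) = sum_i N_i ln( sum_b exp(-g_b - beta U_ib) ) + sum_b n_b g_b
# over per-bin reduced free energies g_b (populated bins only), with
# analytic gradient, via stats::optim BFGS. Returns PMF energies
# (kcal/mol) at populated bin centers, mean-centred over those bins.
wham_ml_oracle <- function(hist) {
  plan <- hist$plan
  beta <- 1 / (0.0019872041 * plan$temperature)
  pref <- if (plan$half_factor) 0.5 else 1.0
  centers0 <- plan$windows$center[match(hist$window_index, plan$windows$index)]
  U <- outer(centers0, hist$bin_centers,
             function(c0, z) pref * plan$k_parallel * (z - c0)^2)
  pop <- colSums(hist$counts) > 0
  Up <- U[, pop, drop = FALSE]
  n_b <- colSums(hist$counts)[pop]
  N_i <- hist$totals

  obj <- function(g) {
    M <- sweep(-beta * Up, 2, g, "-")      # windows x bins: -g_b - beta U_ib
    m <- apply(M, 1, max)
    lse <- m + log(rowSums(exp(M - m)))
    sum(N_i * lse) + sum(n_b * g)
  }
  grad <- function(g) {
    M <- sweep(-beta * Up, 2, g, "-")
    m <- apply(M, 1, max)
    P <- exp(M - m) / rowSums(exp(M - m))  # row-softmax
    n_b - colSums(N_i * P)
  }
  fit <- optim(rep(0, sum(pop)), obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  W <- fit$par / beta
  list(bin_centers = hist$bin_centers[pop], energies = W - mean(W))
}

# mean-centred defined energies of a pmf_profile restricted to given centers
centred_on <- function(pmf, centers) {
  idx <- match(round(centers, 9), round(pmf$bin_centers, 9))
  w <- pmf$energies[idx]
  w - mean(w)
}

# Expected (rounded) per-window counts for sampling density
# p_i(z) proportional to exp(-(W(z)+U_i(z))/kBT), by fine numeric
# quadrature within each histogram bin. W given as a function of z.
expected_counts <- function(W_fun, plan, bin_edges, N = 1e6, nq = 50) {
  beta <- 1 / (0.0019872041 * plan$temperature)
  pref <- if (plan$half_factor) 0.5 else 1.0
  n_bins <- length(bin_edges) - 1L
  counts <- matrix(0L, nrow = nrow(plan$windows), ncol = n_bins)
  for (i in seq_len(nrow(plan$windows))) {
    c0 <- plan$windows$center[i]
    dens <- function(z) exp(-beta * (W_fun(z) + pref * plan$k_parallel * (z - c0)^2))
    mass <- vapply(seq_len(n_bins), function(b) {
      zq <- seq(bin_edges[b], bin_edges[b + 1L], length.out = nq)
      sum(dens(zq)) - (dens(zq[1]) + dens(zq[nq])) / 2   # trapezoid, un-normalised
    }, 0.0)
    counts[i, ] <- as.integer(round(N * mass / sum(mass)))
  }
  counts
}

# Build a histogram_set directly from a count matrix (bypasses sampling)
histogram_from_counts <- function(counts, plan, bin_edges,
                                  window_index = plan$windows$index[seq_len(nrow(counts))]) {
  width <- diff(bin_edges)[1]
  structure(list(
    counts = counts, totals = rowSums(counts),
    bin_edges = bin_edges,
    bin_centers = bin_edges[-length(bin_edges)] + width / 2,
    bin_width = width,
    window_index = window_index, plan = plan,
    n_outside = integer(nrow(counts))
  ), class = "histogram_set")
}

# brute-force delta-pKa: explicit loop over bins, no vectorisation
brute_delta_pka <- function(z, w_charged, w_neutral, z_lo, z_hi, temperature) {
  kT <- 0.0019872041 * temperature
  num <- 0; den <- 0; n <- 0
  for (i in seq_along(z)) {
    if (z[i] >= z_lo && z[i] <= z_hi) {
      num <- num + exp(-w_charged[i] / kT)
      den <- den + exp(-w_neutral[i] / kT)
      n <- n + 1
    }
  }
  log10((num / n) / (den / n))
}

# brute-force centered moving average with shrinking symmetric edge window
brute_moving_average <- function(w, width) {
  n <- length(w); half <- width %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(w[i])) next
    h <- min(half, i - 1, n - i)
    seg <- w[(i - h):(i + h)]
    out[i] <- mean(seg, na.rm = TRUE)
  }
  out
}
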