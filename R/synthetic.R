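#' Analytic membrane-like free-energy profile
#'
#' Ground-truth PMFs for the synthetic sampler, shaped like the profiles of
#' ionizable lipids in a bilayer. \code{neutral_well} is a broad, deep
#' interior well, \eqn{W(z) = -D / (1 + e^{(|z| - z_m)/w})};
#' \code{charged_interfacial} is an interfacial minimum plus an interior
#' penalty, \eqn{W(z) = -A e^{-(|z|-z_0)^2/2\sigma^2} + B e^{-z^2/2\sigma_b^2}};
#' \code{uniform} is identically zero (bulk everywhere); \code{custom_table}
#' interpolates a user table linearly. All kinds tend to 0 at large z, the
#' bulk reference.
#'
#' @param kind One of \code{"uniform"}, \code{"neutral_well"},
#'   \code{"charged_interfacial"}, \code{"custom_table"}.
#' @param depth Well depth D or A (kcal/mol).
#' @param z_mid Half-width z_m of the interior well (Angstrom).
#' @param steepness Softness w of the well wall (Angstrom).
#' @param z0 Position of the interfacial minimum (Angstrom).
#' @param sigma Width of the interfacial minimum (Angstrom).
#' @param barrier Interior penalty height B at z = 0 (kcal/mol).
#' @param sigma_b Width of the interior penalty (Angstrom).
#' @param table Data frame / list with \code{z} and \code{w} for
#'   \code{custom_table}.
#' @return An object of class \code{analytic_pmf}.
#' @export
analytic_pmf <- function(kind = c("uniform", "neutral_well",
                                  "charged_interfacial", "custom_table"),
                         depth = NULL, z_mid = NULL, steepness = NULL,
                         z0 = NULL, sigma = NULL,
                         barrier = NULL, sigma_b = NULL, table = NULL) {
  kind <- match.arg(kind)
  obj <- switch(kind,
    uniform = list(kind = kind, code = 0L, params = numeric()),
    neutral_well = {
      stopifnot(!is.null(depth), !is.null(z_mid), !is.null(steepness))
      list(kind = kind, code = 1L, params = c(depth, z_mid, steepness))
    },
    charged_interfacial = {
      stopifnot(!is.null(depth), !is.null(z0), !is.null(sigma),
                !is.null(barrier), !is.null(sigma_b))
      list(kind = kind, code = 2L, params = c(depth, z0, sigma, barrier, sigma_b))
    },
    custom_table = {
      stopifnot(!is.null(table), !is.null(table$z), !is.null(table$w))
      if (is.unsorted(table$z, strictly = TRUE))
        stop("'table$z' must be strictly increasing", call. = FALSE)
      list(kind = kind, code = 3L, params = numeric(),
           table_z = as.numeric(table$z), table_w = as.numeric(table$w))
    })
  if (is.null(obj$table_z)) { obj$table_z <- numeric(); obj$table_w <- numeric() }
  structure(obj, class = "analytic_pmf")
}

#' Evaluate an analytic PMF
#'
#' @param pmf An \code{analytic_pmf}.
#' @param z Position(s) in Angstrom; vectorized.
#' @return Free energy in kcal/mol. Querying a \code{custom_table} outside
#'   its tabulated range is an error.
#' @export
evaluate_pmf <- function(pmf, z) {
  stopifnot(inherits(pmf, "analytic_pmf"))
  vapply(z, function(zz)
    cpp_pmf_eval(pmf$code, pmf$params, pmf$table_z, pmf$table_w, zz), 0.0)
}

#' Sampler configuration
#'
#' Numerical settings of the overdamped Langevin integrator. The defaults —
#' 1e6 steps of 1e-5 ns with diffusion coefficient 10 A^2/ns, recording
#' every 100th position — equilibrate and sample each 1-A-spaced window
#' stably under the standard 2.0 kcal/mol/A^2 restraint.
#'
#' @param dt Time step (ns).
#' @param diffusion Diffusion coefficient (A^2/ns).
#' @param n_steps Number of integration steps.
#' @param stride Record every \code{stride}-th position.
#' @param seed RNG seed applied before each trajectory.
#' @param initial_z Starting position (Angstrom); \code{NA} means start at
#'   the window center.
#' @return An object of class \code{sampler_config}.
#' @export
sampler_config <- function(dt = 1e-5, diffusion = 10, n_steps = 1e6,
                           stride = 100L, seed = 1L, initial_z = NA_real_) {
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (diffusion <= 0) stop("'diffusion' must be > 0", call. = FALSE)
  n_steps <- as.integer(n_steps); stride <- as.integer(stride)
  if (n_steps < stride || stride < 1L)
    stop("'n_steps' >= 'stride' >= 1 required", call. = FALSE)
  structure(list(dt = dt, diffusion = diffusion, n_steps = n_steps,
                 stride = stride, seed = as.integer(seed),
                 initial_z = initial_z),
            class = "sampler_config")
}

#' Simulate one umbrella window by overdamped Langevin dynamics
#'
#' Integrates \eqn{z_{t+dt} = z_t - \frac{D_c\,dt}{k_BT}\,
#' \frac{d(W + U_i)}{dz} + \sqrt{2 D_c\,dt}\,\xi} with standard-normal
#' \eqn{\xi} and the total-energy gradient taken by central difference
#' (h = 1e-4 A). Reflecting walls sit 2 A outside the plan range; a
#' trajectory escaping the plan range by more than 10 A aborts with a
#' divergence error. Fully reproducible from \code{cfg$seed}.
#'
#' @param pmf An \code{analytic_pmf} (the ground truth being sampled).
#' @param plan The \code{umbrella_plan} supplying restraint and temperature.
#' @param index Window index within the plan.
#' @param cfg A \code{sampler_config}.
#' @return A \code{window_timeseries} with times in ns.
#' @export
simulate_window <- function(pmf, plan, index, cfg) {
  stopifnot(inherits(pmf, "analytic_pmf"), inherits(plan, "umbrella_plan"),
            inherits(cfg, "sampler_config"))
  row <- match(index, plan$windows$index)
  if (is.na(row)) stop("no window with index ", index, call. = FALSE)
  center <- plan$windows$center[row]
  z0 <- if (is.na(cfg$initial_z)) center else cfg$initial_z
  set.seed(cfg$seed)
  z <- cpp_langevin(pmf$code, pmf$params, pmf$table_z, pmf$table_w,
                    center, plan$k_parallel,
                    if (plan$half_factor) 0.5 else 1.0,
                    kBT(plan$temperature), cfg$diffusion, cfg$dt,
                    cfg$n_steps, cfg$stride, z0,
                    plan$z_min - 2, plan$z_max + 2,
                    plan$z_min, plan$z_max)
  times <- seq.int(cfg$stride, cfg$n_steps, by = cfg$stride) * cfg$dt
  window_timeseries(times, z, window_index = index, plan_ref = plan$label)
}

# deterministic per-window seed: base + index + large prime * state slot
# (charged = 0, neutral = 1); stays far below .Machine$integer.max for
# base seeds < 2^27
window_seed <- function(base_seed, window_index, state) {
  state_code <- match(state, c("charged", "neutral")) - 1L
  as.integer(base_seed + window_index + 104729L * state_code)
}

#' Generate a paired synthetic umbrella dataset with ground truth
#'
#' Runs the Langevin sampler over every window of a charged and a neutral
#' plan against their analytic PMFs, deriving each window's seed
#' deterministically from \code{base_seed} (seed = base + window index +
#' 104729 * state slot). The manifest records the analytic profiles
#' tabulated at \code{bin_width}, the per-window seeds, and the true pKa
#' shift obtained from the analytic PMFs by direct quadrature over
#' \code{[z_lo, z_hi]}.
#'
#' @param plan_charged,plan_neutral Umbrella plans for the two protonation
#'   states.
#' @param pmf_charged,pmf_neutral Their \code{analytic_pmf} ground truths.
#' @param cfg A \code{sampler_config}; its \code{seed} field is ignored in
#'   favour of derived per-window seeds.
#' @param base_seed Integer master seed.
#' @param z_lo,z_hi Averaging range (Angstrom) for the recorded true shift.
#' @param bin_width Tabulation resolution of the manifest profiles (A).
#' @return List with \code{series_charged}, \code{series_neutral} (lists of
#'   \code{window_timeseries}) and \code{manifest}.
#' @export
generate_dataset <- function(plan_charged, plan_neutral,
                             pmf_charged, pmf_neutral,
                             cfg = sampler_config(), base_seed = 1L,
                             z_lo = 0, z_hi, bin_width = 0.2) {
  stopifnot(inherits(plan_charged, "umbrella_plan"),
            inherits(plan_neutral, "umbrella_plan"))
  if (missing(z_hi)) z_hi <- min(plan_charged$z_max, plan_neutral$z_max) - 3

  run_state <- function(plan, pmf, state) {
    lapply(plan$windows$index, function(i) {
      wcfg <- cfg
      wcfg$seed <- window_seed(base_seed, i, state)
      simulate_window(pmf, plan, i, wcfg)
    })
  }
  series_charged <- run_state(plan_charged, pmf_charged, "charged")
  series_neutral <- run_state(plan_neutral, pmf_neutral, "neutral")

  true_delta <- true_delta_pka(pmf_charged, pmf_neutral,
                               z_lo = z_lo, z_hi = z_hi,
                               temperature = plan_charged$temperature)
  grid <- seq(plan_charged$z_min, max(plan_charged$z_max, plan_neutral$z_max),
              by = bin_width)
  manifest <- list(
    base_seed = as.integer(base_seed),
    seeds_charged = vapply(plan_charged$windows$index,
                           window_seed, 0L, base_seed = base_seed,
                           state = "charged"),
    seeds_neutral = vapply(plan_neutral$windows$index,
                           window_seed, 0L, base_seed = base_seed,
                           state = "neutral"),
    true_delta_pka = true_delta,
    z_lo = z_lo, z_hi = z_hi,
    temperature = plan_charged$temperature,
    true_pmf_grid = grid,
    true_pmf_charged = evaluate_pmf(pmf_charged, grid),
    true_pmf_neutral = evaluate_pmf(pmf_neutral, grid),
    sampler = unclass(cfg)
  )
  list(series_charged = series_charged, series_neutral = series_neutral,
       manifest = manifest)
}

#' True pKa shift of an analytic PMF pair by direct quadrature
#'
#' Evaluates the shift formula on a fine grid (0.02 A) over
#' \code{[z_lo, z_hi]} directly from the analytic profiles — the ground
#' truth that the simulate/WHAM/postprocess pipeline should recover.
#'
#' @inheritParams generate_dataset
#' @param temperature Temperature (K).
#' @param dz Quadrature grid spacing (Angstrom).
#' @return The true shift in pKa units.
#' @export
true_delta_pka <- function(pmf_charged, pmf_neutral, z_lo = 0, z_hi,
                           temperature = DEFAULT_TEMPERATURE_K, dz = 0.02) {
  z <- seq(z_lo + dz / 2, z_hi, by = dz)
  beta <- 1 / kBT(temperature)
  log10(mean(exp(-beta * evaluate_pmf(pmf_charged, z))) /
        mean(exp(-beta * evaluate_pmf(pmf_neutral, z))))
}

#' Built-in synthetic system presets
#'
#' Ready-made plan/profile pairs emulating the qualitative PMF structure of
#' ionizable lipids in a bilayer: a broad, deep interior well for the
#' neutral form and an interfacial minimum in the headgroup region
#' (z0 between 18 and 28 A) with an interior penalty rising to or above the
#' bulk level for the charged form.
#' \describe{
#'   \item{alc0315_like}{53 windows over -2..50 A; neutral well 8 kcal/mol
#'     deep to ~15 A; charged minimum 4 kcal/mol at 22 A with a 3 kcal/mol
#'     center penalty; bulk cutoff 45.5 A.}
#'   \item{mc3_like}{58 windows over -2..55 A; deeper wells (10 and
#'     6 kcal/mol) with the interfacial minimum at 25 A; cutoff 52 A.}
#'   \item{null}{both forms uniform (zero) profiles over -2..50 A; the true
#'     shift is exactly 0.}
#' }
#'
#' @param name Preset name.
#' @param temperature Temperature (K).
#' @return List with \code{plan_charged}, \code{plan_neutral},
#'   \code{pmf_charged}, \code{pmf_neutral}, \code{z_hi}, \code{label}.
#' @export
synthetic_preset <- function(name = c("alc0315_like", "mc3_like", "null"),
                             temperature = DEFAULT_TEMPERATURE_K) {
  name <- match.arg(name)
  mkplans <- function(z_max, label)
    list(charged = build_plan(-2, z_max, 1, temperature = temperature,
                              state = "charged", label = label),
         neutral = build_plan(-2, z_max, 1, temperature = temperature,
                              state = "neutral", label = label))
  out <- switch(name,
    alc0315_like = {
      p <- mkplans(50, "alc0315_like")
      list(plan_charged = p$charged, plan_neutral = p$neutral,
           pmf_charged = analytic_pmf("charged_interfacial", depth = 4,
                                      z0 = 22, sigma = 3, barrier = 3,
                                      sigma_b = 6),
           pmf_neutral = analytic_pmf("neutral_well", depth = 8, z_mid = 15,
                                      steepness = 2),
           z_hi = 45.5, label = "alc0315_like")
    },
    mc3_like = {
      p <- mkplans(55, "mc3_like")
      list(plan_charged = p$charged, plan_neutral = p$neutral,
           pmf_charged = analytic_pmf("charged_interfacial", depth = 6,
                                      z0 = 25, sigma = 3, barrier = 2,
                                      sigma_b = 6),
           pmf_neutral = analytic_pmf("neutral_well", depth = 10, z_mid = 17,
                                      steepness = 2),
           z_hi = 52, label = "mc3_like")
    },
    null = {
      p <- mkplans(50, "null")
      list(plan_charged = p$charged, plan_neutral = p$neutral,
           pmf_charged = analytic_pmf("uniform"),
           pmf_neutral = analytic_pmf("uniform"),
           z_hi = 45.5, label = "null")
    })
  out
}
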