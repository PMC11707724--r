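#' Estimate a post-processed PMF from one state's window series
#'
#' The per-state estimator chain: discard equilibration, histogram the
#' windows at \code{bin_width}, solve WHAM, smooth over \code{smooth_width}
#' bins and shift to zero in the bulk tail.
#'
#' @param series List of \code{window_timeseries} for one protonation state.
#' @param plan Their \code{umbrella_plan}.
#' @param burn_in_ns Equilibration cut (ns); \code{NULL} means
#'   \code{burn_in_fraction} of each window's last time stamp.
#' @param burn_in_fraction Fallback fractional burn-in (default 0.3, the
#'   30/100 ns protocol ratio).
#' @param bin_width Histogram resolution (A), default 0.2.
#' @param smooth_width Moving-average width in bins, default 11.
#' @param tail_start Baseline tail start (A); \code{NULL} = 5 A short of
#'   the profile end.
#' @param tolerance,max_iter WHAM convergence settings.
#' @return List with \code{pmf} (post-processed \code{pmf_profile}),
#'   \code{wham} (the raw \code{wham_result}) and \code{overlap} (the
#'   adjacent-window overlap table).
#' @export
estimate_state_pmf <- function(series, plan, burn_in_ns = NULL,
                               burn_in_fraction = 0.3, bin_width = 0.2,
                               smooth_width = 11L, tail_start = NULL,
                               tolerance = 1e-7, max_iter = 1e5) {
  trimmed <- lapply(series, function(ts) {
    t0 <- if (is.null(burn_in_ns)) burn_in_fraction * max(ts$times)
          else burn_in_ns
    discard_equilibration(ts, t0)
  })
  hist <- histogram_windows(trimmed, plan, bin_width = bin_width)
  ov <- if (nrow(hist$counts) >= 2L) window_overlap(hist) else NULL
  wr <- solve_wham(hist, tolerance = tolerance, max_iter = max_iter)
  pmf <- postprocess_pmf(wr$pmf, width = smooth_width, tail_start = tail_start)
  list(pmf = pmf, wham = wr, overlap = ov)
}

#' Recover the pKa shift from a synthetic dataset
#'
#' Runs the full estimator (histogram, WHAM, smoothing, baselining, shift
#' integral) on the output of [generate_dataset()] and compares with the
#' manifest's ground truth.
#'
#' @param dataset Output of [generate_dataset()].
#' @param plan_charged,plan_neutral The plans the dataset was generated
#'   under.
#' @param z_lo,z_hi Averaging bounds; default to the manifest values.
#' @inheritParams estimate_state_pmf
#' @return List with \code{delta} (recovered shift), \code{true_delta},
#'   \code{error}, and the two post-processed profiles.
#' @export
recover_delta_pka <- function(dataset, plan_charged, plan_neutral,
                              z_lo = NULL, z_hi = NULL,
                              burn_in_fraction = 0.3, bin_width = 0.2,
                              smooth_width = 11L, tail_start = NULL,
                              tolerance = 1e-7, max_iter = 1e5) {
  man <- dataset$manifest
  if (is.null(z_lo)) z_lo <- man$z_lo
  if (is.null(z_hi)) z_hi <- man$z_hi
  est_c <- estimate_state_pmf(dataset$series_charged, plan_charged,
                              burn_in_fraction = burn_in_fraction,
                              bin_width = bin_width,
                              smooth_width = smooth_width,
                              tail_start = tail_start,
                              tolerance = tolerance, max_iter = max_iter)
  est_n <- estimate_state_pmf(dataset$series_neutral, plan_neutral,
                              burn_in_fraction = burn_in_fraction,
                              bin_width = bin_width,
                              smooth_width = smooth_width,
                              tail_start = tail_start,
                              tolerance = tolerance, max_iter = max_iter)
  d <- delta_pka(est_c$pmf, est_n$pmf, z_lo = z_lo, z_hi = z_hi)
  list(delta = d, true_delta = man$true_delta_pka,
       error = d - man$true_delta_pka,
       pmf_charged = est_c$pmf, pmf_neutral = est_n$pmf)
}

# full default config; unknown user keys are rejected against this template
default_run_config <- function() {
  list(
    label = "",
    pka_s = NA_real_,
    temperature = DEFAULT_TEMPERATURE_K,
    z_lo = 0,
    z_hi = NA_real_,
    bin_width = 0.2,
    smooth_width = 11L,
    tail_start = NULL,
    burn_in_ns = NULL,
    burn_in_fraction = 0.3,
    tolerance = 1e-7,
    max_iter = 1e5,
    dialect = "two_column",
    field = "z",
    plan_charged = NULL,
    plan_neutral = NULL,
    replicates = NULL,
    out_dir = NULL,
    log_level = "info"
  )
}

#' Validate and complete a run configuration
#'
#' Merges a user configuration (named list, or path to a JSON/YAML
#' document) over the package defaults. Unknown keys are rejected before
#' any computation.
#'
#' @param config Named list or file path.
#' @return The completed configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package", call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) stop("'config' must be a named list or a file path",
                             call. = FALSE)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  merged <- defaults
  merged[names(config)] <- config
  merged
}

log_line <- function(level, fmt, ..., min_level = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3)
  if (ranks[[level]] >= ranks[[min_level]])
    message(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    level, sprintf(fmt, ...)))
}

#' Run the full apparent-pKa pipeline
#'
#' Ingest per-replicate window series for both protonation states, solve
#' WHAM, post-process the PMFs, compute the per-replicate pKa shift, and
#' combine into replicate statistics and the apparent pKa. With
#' \code{out_dir} set, writes per-replicate post-processed PMFs
#' (\code{pmf_<state>_rep<k>.tsv}), a per-replicate delta table
#' (\code{deltas.tsv}) and a one-row summary (\code{summary.tsv}).
#'
#' @param config A configuration list or file path (see
#'   [read_run_config()]). Required keys: \code{plan_charged} /
#'   \code{plan_neutral} (plan file paths or \code{umbrella_plan} objects),
#'   \code{replicates} (a list; each element has \code{charged} and
#'   \code{neutral}, each a character vector of series file paths or a list
#'   of \code{window_timeseries}), \code{z_hi}, and \code{pka_s} for an
#'   apparent-pKa result.
#' @return A \code{pka_result} (invisibly when \code{out_dir} is set), with
#'   the per-replicate post-processed profiles in
#'   \code{attr(, "profiles")}.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  lvl <- cfg$log_level

  get_plan <- function(p, what) {
    if (inherits(p, "umbrella_plan")) return(p)
    if (is.character(p) && length(p) == 1L) return(load_plan(p))
    stop("config '", what, "' must be an umbrella_plan or a plan file path",
         call. = FALSE)
  }
  plan_c <- get_plan(cfg$plan_charged, "plan_charged")
  plan_n <- get_plan(cfg$plan_neutral, "plan_neutral")
  if (is.null(cfg$replicates) || !length(cfg$replicates))
    stop("config 'replicates' must list at least one replicate", call. = FALSE)
  if (!is.finite(cfg$z_hi)) stop("config 'z_hi' is required", call. = FALSE)

  load_series <- function(x, plan) {
    if (is.list(x) && all(vapply(x, inherits, TRUE, "window_timeseries")))
      return(x)
    if (!is.character(x))
      stop("replicate series must be file paths or window_timeseries",
           call. = FALSE)
    lapply(seq_along(x), function(i)
      read_timeseries(x[i], dialect = cfg$dialect, field = cfg$field,
                      window_index = plan$windows$index[i],
                      plan_ref = plan$label))
  }

  deltas <- numeric(0)
  profiles <- list()
  for (r in seq_along(cfg$replicates)) {
    rep_cfg <- cfg$replicates[[r]]
    if (is.null(rep_cfg$charged) || is.null(rep_cfg$neutral))
      stop(sprintf("replicate %d: needs 'charged' and 'neutral' series", r),
           call. = FALSE)
    log_line("info", "replicate %d: ingesting series", r, min_level = lvl)
    sc <- load_series(rep_cfg$charged, plan_c)
    sn <- load_series(rep_cfg$neutral, plan_n)
    est_c <- tryCatch(
      estimate_state_pmf(sc, plan_c, burn_in_ns = cfg$burn_in_ns,
                         burn_in_fraction = cfg$burn_in_fraction,
                         bin_width = cfg$bin_width,
                         smooth_width = cfg$smooth_width,
                         tail_start = cfg$tail_start,
                         tolerance = cfg$tolerance, max_iter = cfg$max_iter),
      error = function(e) stop(sprintf("replicate %d, charged state: %s", r,
                                       conditionMessage(e)), call. = FALSE))
    est_n <- tryCatch(
      estimate_state_pmf(sn, plan_n, burn_in_ns = cfg$burn_in_ns,
                         burn_in_fraction = cfg$burn_in_fraction,
                         bin_width = cfg$bin_width,
                         smooth_width = cfg$smooth_width,
                         tail_start = cfg$tail_start,
                         tolerance = cfg$tolerance, max_iter = cfg$max_iter),
      error = function(e) stop(sprintf("replicate %d, neutral state: %s", r,
                                       conditionMessage(e)), call. = FALSE))
    d <- delta_pka(est_c$pmf, est_n$pmf, z_lo = cfg$z_lo, z_hi = cfg$z_hi,
                   temperature = cfg$temperature)
    log_line("info", "replicate %d: delta pKa = %.3f", r, d, min_level = lvl)
    deltas <- c(deltas, d)
    profiles[[r]] <- list(charged = est_c$pmf, neutral = est_n$pmf)
  }

  res <- pka_result(pka_s = cfg$pka_s, per_replicate_deltas = deltas,
                    z_lo = cfg$z_lo, z_hi = cfg$z_hi,
                    temperature = cfg$temperature, label = cfg$label)
  attr(res, "profiles") <- profiles

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_along(profiles)) {
      write_pmf(profiles[[r]]$charged,
                file.path(cfg$out_dir, sprintf("pmf_charged_rep%d.tsv", r)))
      write_pmf(profiles[[r]]$neutral,
                file.path(cfg$out_dir, sprintf("pmf_neutral_rep%d.tsv", r)))
    }
    writeLines(c("# replicate\tdelta_pka",
                 sprintf("%d\t%.6f", seq_along(deltas), deltas)),
               file.path(cfg$out_dir, "deltas.tsv"))
    writeLines(format_summary_table(list(res)),
               file.path(cfg$out_dir, "summary.tsv"))
    log_line("info", "wrote results to %s", cfg$out_dir, min_level = lvl)
    return(invisible(res))
  }
  res
}

#' Format pKa results as a summary table
#'
#' Tab-separated table with columns lipid, pKa^S, delta pKa (mean +/- sd)
#' and pKa^A — the layout used to report apparent-pKa predictions per
#' formulation.
#'
#' @param results List of \code{pka_result} objects.
#' @param markdown If TRUE, emit a Markdown pipe table instead.
#' @return Character vector of lines.
#' @export
format_summary_table <- function(results, markdown = FALSE) {
  stopifnot(is.list(results), all(vapply(results, inherits, TRUE, "pka_result")))
  rows <- vapply(results, function(x) {
    sd_txt <- if (is.na(x$delta_sd)) "NA" else sprintf("%.2f", x$delta_sd)
    c(if (nzchar(x$label)) x$label else "(unnamed)",
      sprintf("%.2f", x$pka_s),
      sprintf("%.2f ± %s", x$delta_mean, sd_txt),
      sprintf("%.2f", x$pka_a))
  }, character(4))
  header <- c("lipid", "pKa_S", "delta_pKa", "pKa_A")
  if (markdown) {
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", 4), collapse = "|"), "|"),
      apply(rows, 2, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  } else {
    c(paste(header, collapse = "\t"),
      apply(rows, 2, function(r) paste(r, collapse = "\t")))
  }
}
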