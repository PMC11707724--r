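#' Histogram umbrella windows onto a common grid
#'
#' Bins every window's retained z samples onto one uniform grid. Bins are
#' left-closed, right-open \code{[edge, edge + width)}, anchored at
#' \code{z_range[1]}; a sample falling exactly on an interior edge goes to
#' the bin on its right. Samples outside \code{z_range} are counted and
#' reported via the \code{n_outside} field (and a message), never folded
#' into edge bins.
#'
#' @param series List of \code{window_timeseries}, one per plan window to
#'   include (matched to the plan by \code{window_index}).
#' @param plan The \code{umbrella_plan} the series were sampled under
#'   (supplies bias constants and temperature).
#' @param bin_width Bin width in Angstrom; the protocol resolution is 0.2 A.
#' @param z_range Length-2 numeric, histogram range (defaults to the plan
#'   range).
#' @return An object of class \code{histogram_set}: counts matrix
#'   (windows x bins), per-window totals, bin edges/centers, the plan, and
#'   per-window out-of-range counts.
#' @export
histogram_windows <- function(series, plan, bin_width = 0.2,
                              z_range = c(plan$z_min, plan$z_max)) {
  stopifnot(inherits(plan, "umbrella_plan"))
  if (!is.list(series) || !length(series))
    stop("'series' must be a non-empty list of window_timeseries", call. = FALSE)
  if (!all(vapply(series, inherits, TRUE, "window_timeseries")))
    stop("'series' must contain window_timeseries objects", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("'bin_width' must be > 0", call. = FALSE)
  if (z_range[2L] <= z_range[1L]) stop("invalid 'z_range'", call. = FALSE)

  widx <- vapply(series, function(s) s$window_index, 0L)
  miss <- setdiff(widx, plan$windows$index)
  if (length(miss))
    stop("series window index not in plan: ", paste(miss, collapse = ", "),
         call. = FALSE)

  n_bins <- floor((z_range[2L] - z_range[1L]) / bin_width + 1e-9)
  edges <- z_range[1L] + (0:n_bins) * bin_width
  centers <- edges[-(n_bins + 1L)] + bin_width / 2

  counts <- matrix(0L, nrow = length(series), ncol = n_bins)
  n_outside <- integer(length(series))
  for (i in seq_along(series)) {
    z <- series[[i]]$values
    if (length(z) == 0L)
      stop("window ", widx[i], " has no retained samples", call. = FALSE)
    b <- floor((z - z_range[1L]) / bin_width) + 1L
    inside <- b >= 1L & b <= n_bins & z >= z_range[1L]
    n_outside[i] <- sum(!inside)
    counts[i, ] <- tabulate(b[inside], nbins = n_bins)
  }
  if (any(n_outside > 0L))
    message(sprintf("histogram_windows: %d sample(s) outside [%g, %g] in window(s) %s",
                    sum(n_outside), z_range[1L], z_range[2L],
                    paste(widx[n_outside > 0L], collapse = ", ")))

  structure(list(
    counts = counts, totals = rowSums(counts),
    bin_edges = edges, bin_centers = centers, bin_width = bin_width,
    window_index = widx, plan = plan, n_outside = n_outside
  ), class = "histogram_set")
}

#' PMF profile container
#'
#' A binned free-energy curve W(z) on a uniform grid. Undefined entries
#' (empty histogram bins) are \code{NA}, never sentinel infinities.
#'
#' @param bin_centers Uniform, increasing bin centers (Angstrom).
#' @param energies Free energies at the centers (kcal/mol), \code{NA} where
#'   undefined.
#' @param temperature Temperature (K) the profile refers to.
#' @param provenance Character vector describing how the profile was made;
#'   each transform appends a line.
#' @return An object of class \code{pmf_profile}.
#' @export
pmf_profile <- function(bin_centers, energies,
                        temperature = DEFAULT_TEMPERATURE_K,
                        provenance = character()) {
  if (length(bin_centers) != length(energies))
    stop("'bin_centers' and 'energies' must have equal length", call. = FALSE)
  if (length(bin_centers) > 1L) {
    d <- diff(bin_centers)
    if (any(d <= 0) || max(abs(d - d[1L])) > 1e-9)
      stop("'bin_centers' must be uniform and increasing", call. = FALSE)
  }
  if (any(!is.finite(energies) & !is.na(energies)))
    stop("'energies' must be finite or NA", call. = FALSE)
  structure(list(bin_centers = as.numeric(bin_centers),
                 energies = as.numeric(energies),
                 temperature = temperature,
                 provenance = as.character(provenance)),
            class = "pmf_profile")
}

#' Solve 1-D WHAM by self-consistent iteration
#'
#' Combines the biased window histograms into one unbiased distribution by
#' iterating the standard pair of self-consistency equations:
#' \deqn{p(b) = \frac{\sum_i n_i(b)}{\sum_i N_i e^{(F_i - U_i(z_b))/k_BT}},
#'       \qquad
#'       F_i = -k_BT \ln \sum_b p(b)\, e^{-U_i(z_b)/k_BT},}
#' until the largest per-iteration change in any \eqn{F_i} is at most
#' \code{tolerance}. The PMF is \eqn{W(z_b) = -k_BT \ln p(b)}, reported up to
#' an additive constant with the first window's offset pinned to zero. Bias
#' energies are evaluated at bin centers. Empty bins give \code{NA} energies.
#' The iteration is deterministic: identical inputs give identical results.
#'
#' @param hist A \code{histogram_set}.
#' @param tolerance Convergence threshold on \eqn{\max_i |\Delta F_i|}
#'   (kcal/mol), default 1e-7.
#' @param max_iter Iteration cap, default 1e5. Reaching it yields a result
#'   with \code{converged = FALSE} and a warning, not an error.
#' @return An object of class \code{wham_result}: \code{$pmf}
#'   (a \code{pmf_profile}), \code{$window_offsets} (F_i, kcal/mol),
#'   \code{$probabilities} (normalized p(b)), \code{$iterations},
#'   \code{$final_residual}, \code{$converged}.
#' @export
solve_wham <- function(hist, tolerance = 1e-7, max_iter = 1e5) {
  stopifnot(inherits(hist, "histogram_set"))
  if (all(hist$counts == 0L)) stop("all histogram bins are empty", call. = FALSE)
  plan <- hist$plan
  beta <- 1 / kBT(plan$temperature)

  n_w <- nrow(hist$counts)
  # bias of each contributing window at each bin center
  U <- bias_matrix(plan, hist$bin_centers)[match(hist$window_index,
                                                 plan$windows$index), ,
                                           drop = FALSE]
  expU <- exp(-beta * U)                    # windows x bins, underflow -> 0
  nsum <- colSums(hist$counts)              # total counts per bin
  N <- hist$totals

  F_off <- numeric(n_w)
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(crossprod(expU, N * exp(beta * F_off)))
    p <- ifelse(denom > 0, nsum / denom, 0)
    s <- sum(p)
    p <- p / s
    F_new <- -log(as.numeric(expU %*% p)) / beta
    F_new <- F_new - F_new[1L]              # gauge: pin first window to 0
    resid <- max(abs(F_new - F_off))
    F_off <- F_new
    if (resid <= tolerance || iter >= max_iter) break
  }
  converged <- resid <= tolerance
  if (!converged)
    warning(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                    iter, resid), call. = FALSE)

  W <- ifelse(p > 0, -log(p) / beta, NA_real_)
  pmf <- pmf_profile(hist$bin_centers, W, temperature = plan$temperature,
                     provenance = c(sprintf("wham: %d windows, %d bins, tol %g, %d iterations",
                                            n_w, length(p), tolerance, iter)))
  structure(list(pmf = pmf, window_offsets = F_off, probabilities = p,
                 iterations = iter, final_residual = resid,
                 converged = converged),
            class = "wham_result")
}

#' Adjacent-window histogram overlap
#'
#' Shared probability mass between the normalized histograms of adjacent
#' windows, \eqn{\sum_b \min(n_i(b)/N_i,\; n_{i+1}(b)/N_{i+1})}. Values near
#' zero mean the biased distributions barely touch and the WHAM stitching
#' across that pair is unreliable.
#'
#' @param hist A \code{histogram_set} with at least two windows.
#' @param threshold Pairs with overlap below this are flagged (default 0.03).
#' @return A data frame with columns \code{window_a}, \code{window_b},
#'   \code{overlap}, \code{flagged}.
#' @export
window_overlap <- function(hist, threshold = 0.03) {
  stopifnot(inherits(hist, "histogram_set"))
  n_w <- nrow(hist$counts)
  if (n_w < 2L) stop("need at least two windows for overlap", call. = FALSE)
  ord <- order(hist$window_index)
  P <- hist$counts[ord, , drop = FALSE] / hist$totals[ord]
  ov <- vapply(seq_len(n_w - 1L), function(i)
    sum(pmin(P[i, ], P[i + 1L, ])), 0.0)
  out <- data.frame(window_a = hist$window_index[ord][-n_w],
                    window_b = hist$window_index[ord][-1L],
                    overlap = ov, flagged = ov < threshold)
  if (any(out$flagged))
    warning(sprintf("%d adjacent window pair(s) with overlap < %g",
                    sum(out$flagged), threshold), call. = FALSE)
  out
}

#' Write / read a PMF profile as tab-separated text
#'
#' Columns \code{bin_center_A} and \code{pmf_kcal_mol}; '#' header lines
#' carry temperature and provenance. Undefined bins are written as NA.
#'
#' @param pmf A \code{pmf_profile}.
#' @param path Output (input) path.
#' @return \code{path} invisibly (\code{write_pmf}); a \code{pmf_profile}
#'   (\code{read_pmf}).
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  hdr <- c(sprintf("# temperature_K\t%.10g", pmf$temperature),
           paste0("# provenance\t", pmf$provenance),
           "# bin_center_A\tpmf_kcal_mol")
  body <- sprintf("%.10g\t%.10g", pmf$bin_centers, pmf$energies)
  body <- sub("\tNA$", "\tNA", body)  # NA printed literally by sprintf
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  temp <- DEFAULT_TEMPERATURE_K
  prov <- character()
  th <- grep("^# temperature_K\t", hdr, value = TRUE)
  if (length(th)) temp <- as.numeric(sub("^# temperature_K\t", "", th[1L]))
  prov <- sub("^# provenance\t", "", grep("^# provenance\t", hdr, value = TRUE))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  parts <- strsplit(body, "\t")
  z <- as.numeric(vapply(parts, `[`, "", 1L))
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  pmf_profile(z, w, temperature = temp, provenance = prov)
}

#' @export
print.pmf_profile <- function(x, ...) {
  def <- !is.na(x$energies)
  cat(sprintf("PMF profile: %d bins (%d defined), z = %g..%g A, T = %g K\n",
              length(x$bin_centers), sum(def),
              min(x$bin_centers), max(x$bin_centers), x$temperature))
  if (any(def))
    cat(sprintf("  W range [%.3f, %.3f] kcal/mol\n",
                min(x$energies[def]), max(x$energies[def])))
  for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("WHAM result: %s after %d iterations (residual %.3g kcal/mol)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_residual))
  print(x$pmf)
  invisible(x)
}
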