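#' Smooth a PMF with a centered moving average
#'
#' Replaces every defined bin by the mean of the defined energies inside a
#' centered window of \code{width} bins (default 11, the protocol value).
#' Near the profile edges the window shrinks symmetrically to the largest
#' odd width that fits (\code{edge = "shrink"}, default); with
#' \code{edge = "truncate"} the full window is kept and simply clipped at
#' the edges (an asymmetric average). Undefined (\code{NA}) bins are left
#' undefined and are excluded from their neighbours' averages, so smoothing
#' never extends the defined support.
#'
#' @param pmf A \code{pmf_profile}.
#' @param width Odd integer >= 1, number of adjacent bins averaged.
#' @param edge Edge policy, \code{"shrink"} or \code{"truncate"}.
#' @return The smoothed \code{pmf_profile}.
#' @export
smooth_pmf <- function(pmf, width = 11L, edge = c("shrink", "truncate")) {
  stopifnot(inherits(pmf, "pmf_profile"))
  edge <- match.arg(edge)
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L)
    stop("'width' must be an odd integer >= 1", call. = FALSE)
  w <- pmf$energies
  n <- length(w)
  if (all(is.na(w))) stop("profile has no defined bins", call. = FALSE)
  half <- width %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(w[i])) next
    h <- if (edge == "shrink") min(half, i - 1L, n - i) else half
    lo <- max(1L, i - h); hi <- min(n, i + h)
    seg <- w[lo:hi]
    out[i] <- mean(seg[!is.na(seg)])
  }
  res <- pmf
  res$energies <- out
  res$provenance <- c(pmf$provenance,
                      sprintf("smooth: moving average width %d (%s edges)",
                              width, edge))
  res
}

#' Shift a PMF to zero in the bulk tail
#'
#' Subtracts the mean of the defined energies at bin centers at or beyond
#' \code{tail_start} so the profile reads 0 kcal/mol in bulk solution, the
#' reference state of the shift calculation.
#'
#' @param pmf A \code{pmf_profile}.
#' @param tail_start Start of the bulk tail (Angstrom). Default: 5 A short
#'   of the last bin center.
#' @param min_bins Minimum number of defined tail bins required (default 5).
#' @return The baselined \code{pmf_profile}; the applied shift is recorded
#'   in provenance.
#' @export
zero_baseline <- function(pmf, tail_start = NULL, min_bins = 5L) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(tail_start))
    tail_start <- max(pmf$bin_centers) - 5
  if (tail_start < min(pmf$bin_centers) || tail_start > max(pmf$bin_centers))
    stop("'tail_start' outside the profile range", call. = FALSE)
  tail_mask <- pmf$bin_centers >= tail_start & !is.na(pmf$energies)
  if (sum(tail_mask) < min_bins)
    stop(sprintf("only %d defined bin(s) beyond tail_start = %g A (need >= %d)",
                 sum(tail_mask), tail_start, min_bins), call. = FALSE)
  shift <- mean(pmf$energies[tail_mask])
  res <- pmf
  res$energies <- pmf$energies - shift
  res$provenance <- c(pmf$provenance,
                      sprintf("baseline: shifted by %.6g kcal/mol (tail z >= %g A, %d bins)",
                              -shift, tail_start, sum(tail_mask)))
  res
}

#' Average replicate PMFs bin by bin
#'
#' Per-bin arithmetic mean over replicate profiles sharing one grid and
#' temperature. A bin is defined in the output only where it is defined in
#' every replicate.
#'
#' @param pmfs List of \code{pmf_profile} objects on identical grids.
#' @return The replicate-mean \code{pmf_profile}.
#' @export
average_replicates <- function(pmfs) {
  if (!is.list(pmfs) || length(pmfs) < 1L ||
      !all(vapply(pmfs, inherits, TRUE, "pmf_profile")))
    stop("'pmfs' must be a non-empty list of pmf_profile objects", call. = FALSE)
  ref <- pmfs[[1L]]
  for (k in seq_along(pmfs)[-1L]) {
    p <- pmfs[[k]]
    if (length(p$bin_centers) != length(ref$bin_centers) ||
        any(abs(p$bin_centers - ref$bin_centers) > 1e-9)) {
      d <- if (length(p$bin_centers) != length(ref$bin_centers)) 1L
           else which(abs(p$bin_centers - ref$bin_centers) > 1e-9)[1L]
      stop(sprintf("replicate %d grid differs from replicate 1 starting at bin %d",
                   k, d), call. = FALSE)
    }
    if (abs(p$temperature - ref$temperature) > 1e-9)
      stop("replicate temperatures differ", call. = FALSE)
  }
  E <- do.call(rbind, lapply(pmfs, `[[`, "energies"))
  mean_e <- colMeans(E)                     # NA wherever any replicate is NA
  pmf_profile(ref$bin_centers, mean_e, temperature = ref$temperature,
              provenance = sprintf("average of %d replicate profiles",
                                   length(pmfs)))
}

#' Standard PMF post-processing chain
#'
#' Applies the protocol order: smooth over \code{width} adjacent bins, then
#' shift to zero in the bulk tail.
#'
#' @inheritParams smooth_pmf
#' @inheritParams zero_baseline
#' @return The post-processed \code{pmf_profile}.
#' @export
postprocess_pmf <- function(pmf, width = 11L, tail_start = NULL,
                            edge = c("shrink", "truncate"), min_bins = 5L) {
  zero_baseline(smooth_pmf(pmf, width = width, edge = edge),
                tail_start = tail_start, min_bins = min_bins)
}
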