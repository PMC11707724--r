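#' Window time series container
#'
#' One umbrella window's sampled reaction coordinate: times in ns and z
#' values in Angstrom (position of the tracked amine nitrogen relative to
#' the bilayer center).
#'
#' @param times Numeric vector of time stamps (ns).
#' @param values Numeric vector of z values (Angstrom), same length.
#' @param window_index Integer window identity within its plan.
#' @param plan_ref Label tying the series to an umbrella plan (free text).
#' @param field Column name used in the COLVAR dialect (default "z").
#' @return An object of class \code{window_timeseries}.
#' @export
window_timeseries <- function(times, values, window_index = 0L,
                              plan_ref = "", field = "z") {
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (length(times) < 1L)
    stop("a window time series needs at least one sample", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    warning("time stamps are not strictly increasing; keeping input order",
            call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 window_index = as.integer(window_index),
                 plan_ref = plan_ref, field = field),
            class = "window_timeseries")
}

#' Read a reaction-coordinate time series
#'
#' Two dialects are supported: \code{two_column} (whitespace-separated
#' "time value" rows, '#' comment lines) and \code{colvar} (first line
#' \code{#! FIELDS time <name> ...}; the caller names the column to
#' extract via \code{field}).
#'
#' @param path Input file path.
#' @param dialect \code{"two_column"} or \code{"colvar"}.
#' @param field Column to extract in the colvar dialect (default \code{"z"}).
#' @param window_index,plan_ref Identity attached to the returned series.
#' @return A \code{window_timeseries}.
#' @export
read_timeseries <- function(path, dialect = c("two_column", "colvar"),
                            field = "z", window_index = 0L, plan_ref = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)

  tcol <- 1L; vcol <- 2L
  start <- 1L
  if (dialect == "colvar") {
    if (!grepl("^#!\\s*FIELDS\\s+", lines[1L]))
      stop("colvar file must start with '#! FIELDS ...': ", path, call. = FALSE)
    fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[1L]), "\\s+")[[1L]]
    tcol <- match("time", fields)
    vcol <- match(field, fields)
    if (is.na(tcol)) stop("colvar header has no 'time' field: ", path, call. = FALSE)
    if (is.na(vcol)) stop("colvar header has no '", field, "' field: ", path,
                          call. = FALSE)
    start <- 2L
  }

  lineno <- seq_along(lines)
  body <- trimws(lines[seq.int(start, length(lines))])
  blno <- lineno[seq.int(start, length(lines))]
  data <- nzchar(body) & !startsWith(body, "#")
  body <- body[data]; blno <- blno[data]
  if (length(body) == 0L)
    stop("no data rows in ", path, call. = FALSE)
  tok <- strsplit(body, "\\s+")
  ncols <- lengths(tok)
  need <- max(tcol, vcol)
  if (any(ncols < need)) {
    bad <- which(ncols < need)[1L]
    stop(sprintf("line %d of %s: expected at least %d columns", blno[bad],
                 path, need), call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(vapply(tok, `[`, "", tcol)))
  values <- suppressWarnings(as.numeric(vapply(tok, `[`, "", vcol)))
  if (anyNA(times) || anyNA(values)) {
    bad <- which(is.na(times) | is.na(values))[1L]
    badtok <- tok[[bad]][c(tcol, vcol)]
    stop(sprintf("line %d of %s: non-numeric value '%s'", blno[bad], path,
                 badtok[which(is.na(suppressWarnings(as.numeric(badtok))))[1L]]),
         call. = FALSE)
  }
  window_timeseries(times, values, window_index = window_index,
                    plan_ref = plan_ref, field = field)
}

#' Write a time series to disk
#'
#' Values are printed with 12 significant digits so a read-back round-trip
#' reproduces them.
#'
#' @param ts A \code{window_timeseries}.
#' @param path Output file path.
#' @param dialect \code{"two_column"} or \code{"colvar"}.
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(ts, path, dialect = c("two_column", "colvar")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ts, "window_timeseries"))
  body <- sprintf("%.12g %.12g", ts$times, ts$values)
  header <- if (dialect == "colvar") sprintf("#! FIELDS time %s", ts$field)
            else sprintf("# window %d time_ns z_A", ts$window_index)
  tryCatch(writeLines(c(header, body), path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Discard the equilibration part of a series
#'
#' Keeps samples with time >= \code{t_start} (ns), preserving order. The
#' standard protocol samples each window for 100 ns and analyses times
#' between 30 and 100 ns; this is that 30 ns cut.
#'
#' @param ts A \code{window_timeseries}.
#' @param t_start Burn-in end time (ns), >= 0.
#' @return The filtered \code{window_timeseries}; may have zero samples, in
#'   which case a warning is emitted (WHAM will refuse such a window later).
#' @export
discard_equilibration <- function(ts, t_start) {
  stopifnot(inherits(ts, "window_timeseries"))
  if (!is.numeric(t_start) || length(t_start) != 1L || t_start < 0)
    stop("'t_start' must be a single non-negative number", call. = FALSE)
  keep <- ts$times >= t_start
  out <- ts
  out$times <- ts$times[keep]
  out$values <- ts$values[keep]
  if (length(out$times) == 0L)
    warning(sprintf("window %d: no samples at t >= %g ns", ts$window_index,
                    t_start), call. = FALSE)
  out
}

#' @export
print.window_timeseries <- function(x, ...) {
  cat(sprintf("Window %d time series (%s): %d samples",
              x$window_index,
              if (nzchar(x$plan_ref)) x$plan_ref else "unlabelled",
              length(x$times)))
  if (length(x$times))
    cat(sprintf(", t = %g..%g ns, z mean %.2f A", min(x$times), max(x$times),
                mean(x$values)))
  cat("\n")
  invisible(x)
}
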