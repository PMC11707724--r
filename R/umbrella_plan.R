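#' Construct an umbrella-sampling plan
#'
#' Builds the ladder of harmonically restrained windows used to sample the
#' distance z between the ionizable-lipid amine nitrogen and the bilayer
#' center. Windows are placed at \code{z_min, z_min + spacing, ...}, up to and
#' including \code{z_max} whenever \code{z_max - z_min} is an integer multiple
#' of \code{spacing}. Centers are computed as \code{z_min + i * spacing} from
#' integer indices so the grid carries no floating-point accumulation.
#'
#' @param z_min,z_max Range of window centers (Angstrom). The standard
#'   protocol spans -2 to 50 A (to 55 A for MC3), covering bilayer center to
#'   bulk water.
#' @param spacing Distance between adjacent window centers (Angstrom),
#'   default 1.0.
#' @param k_parallel Harmonic force constant along z (kcal/mol/A^2),
#'   default 2.0. Zero is permitted and means an unbiased window.
#' @param k_perpendicular Lateral (x,y) force constant (kcal/mol/A^2),
#'   default 1.0. Metadata for MD export; the 1-D machinery never uses it.
#' @param temperature Simulation temperature in kelvin, default 310.15.
#' @param state Protonation state of the tagged lipid, \code{"charged"} or
#'   \code{"neutral"}.
#' @param label Free-text system label (e.g. lipid name).
#' @param sampling_time_ns,burn_in_ns Nominal per-window production length
#'   and equilibration discard (ns); protocol metadata, defaults 100 and 30.
#' @param metadata Named list of additional inert protocol metadata (e.g.
#'   per-window relaxation time, seeding order, membrane net-z restraint).
#' @param half_factor Logical; if \code{TRUE} (default) the bias convention
#'   is U = 1/2 k (z - z0)^2. Set \code{FALSE} for engines using U = k x^2.
#' @return An object of class \code{umbrella_plan}: a list with the window
#'   table (\code{$windows}: index, center), restraint constants, range,
#'   temperature, state and metadata.
#' @examples
#' plan <- build_plan(-2, 50, 1, state = "charged", label = "ALC-0315")
#' nrow(plan$windows)  # 53
#' @export
build_plan <- function(z_min, z_max, spacing = 1.0,
                       k_parallel = 2.0, k_perpendicular = 1.0,
                       temperature = DEFAULT_TEMPERATURE_K,
                       state = c("charged", "neutral"),
                       label = "",
                       sampling_time_ns = 100, burn_in_ns = 30,
                       metadata = list(), half_factor = TRUE) {
  state <- match.arg(state)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("invalid 'spacing': must be a single positive number", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("invalid 'temperature': must be a single positive number", call. = FALSE)
  if (!is.numeric(k_parallel) || k_parallel < 0)
    stop("invalid 'k_parallel': must be >= 0", call. = FALSE)
  if (!is.numeric(k_perpendicular) || k_perpendicular <= 0)
    stop("invalid 'k_perpendicular': must be > 0", call. = FALSE)
  if (!(z_max > z_min))
    stop("invalid range: 'z_max' must exceed 'z_min'", call. = FALSE)

  n <- floor((z_max - z_min) / spacing + 1e-9) + 1L
  idx <- seq_len(n) - 1L
  windows <- data.frame(index = idx, center = z_min + idx * spacing)

  structure(list(
    windows = windows,
    z_min = z_min, z_max = z_max, spacing = spacing,
    k_parallel = k_parallel, k_perpendicular = k_perpendicular,
    temperature = temperature,
    state = state, label = label,
    sampling_time_ns = sampling_time_ns, burn_in_ns = burn_in_ns,
    half_factor = isTRUE(half_factor),
    metadata = metadata
  ), class = "umbrella_plan")
}

#' Harmonic bias energy of an umbrella window
#'
#' Restraint energy \eqn{U_i(z) = \tfrac{1}{2} k_\parallel (z - z_i)^2} (or
#' \eqn{k_\parallel (z - z_i)^2} when the plan was built with
#' \code{half_factor = FALSE}).
#'
#' @param plan An \code{umbrella_plan}.
#' @param index Window index (0-based, as stored in \code{plan$windows}).
#' @param z Position(s) along the bilayer normal (Angstrom); vectorized.
#' @return Bias energy in kcal/mol, same length as \code{z}.
#' @examples
#' p <- build_plan(0, 20, 1)
#' bias_energy(p, 10, 11)  # 0.5 * 2 * 1^2 = 1 kcal/mol
#' @export
bias_energy <- function(plan, index, z) {
  stopifnot(inherits(plan, "umbrella_plan"))
  row <- match(index, plan$windows$index)
  if (is.na(row)) stop("no window with index ", index, call. = FALSE)
  pref <- if (plan$half_factor) 0.5 else 1.0
  pref * plan$k_parallel * (z - plan$windows$center[row])^2
}

# bias energies for all windows at a vector of positions:
# returns a length(windows) x length(z) matrix
bias_matrix <- function(plan, z) {
  pref <- if (plan$half_factor) 0.5 else 1.0
  outer(plan$windows$center, z, function(c0, zz) pref * plan$k_parallel * (zz - c0)^2)
}

#' Serialize an umbrella plan to JSON
#'
#' @param plan An \code{umbrella_plan}.
#' @param path File path to write; with \code{path = NULL} the JSON text is
#'   returned instead.
#' @return \code{path} invisibly, or the JSON string when \code{path} is NULL.
#' @seealso [load_plan()]
#' @export
save_plan <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "umbrella_plan"))
  doc <- list(
    label = plan$label,
    state = plan$state,
    temperature_K = plan$temperature,
    z_min_A = plan$z_min, z_max_A = plan$z_max, spacing_A = plan$spacing,
    k_parallel = plan$k_parallel, k_perpendicular = plan$k_perpendicular,
    half_factor = plan$half_factor,
    sampling_time_ns = plan$sampling_time_ns, burn_in_ns = plan$burn_in_ns,
    windows = data.frame(index = plan$windows$index,
                         center_A = plan$windows$center),
    metadata = plan$metadata
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Load an umbrella plan from JSON
#'
#' Validates required fields and window ordering. Windows out of center order
#' are re-sorted with a warning.
#'
#' @param path Path to a JSON plan document, or a JSON string.
#' @return An \code{umbrella_plan}.
#' @export
load_plan <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse plan document: ",
                                           conditionMessage(e), call. = FALSE))
  req <- c("state", "temperature_K", "z_min_A", "z_max_A", "spacing_A",
           "k_parallel", "k_perpendicular", "windows")
  missing <- setdiff(req, names(doc))
  if (length(missing))
    stop("plan document missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  w <- doc$windows
  if (!all(c("index", "center_A") %in% names(w)))
    stop("plan document field 'windows' must have 'index' and 'center_A'",
         call. = FALSE)
  if (is.unsorted(w$center_A, strictly = TRUE)) {
    warning("plan windows not ordered by center; re-sorting", call. = FALSE)
    w <- w[order(w$center_A), , drop = FALSE]
    w$index <- seq_len(nrow(w)) - 1L
  }
  plan <- build_plan(
    z_min = doc$z_min_A, z_max = doc$z_max_A, spacing = doc$spacing_A,
    k_parallel = doc$k_parallel, k_perpendicular = doc$k_perpendicular,
    temperature = doc$temperature_K, state = doc$state,
    label = if (is.null(doc$label)) "" else doc$label,
    sampling_time_ns = if (is.null(doc$sampling_time_ns)) 100 else doc$sampling_time_ns,
    burn_in_ns = if (is.null(doc$burn_in_ns)) 30 else doc$burn_in_ns,
    metadata = if (is.null(doc$metadata)) list() else doc$metadata,
    half_factor = if (is.null(doc$half_factor)) TRUE else doc$half_factor
  )
  # the serialized window list is authoritative (it may be a subset grid)
  if (nrow(plan$windows) != nrow(w) ||
      max(abs(plan$windows$center - w$center_A)) > 1e-9) {
    plan$windows <- data.frame(index = as.integer(w$index), center = w$center_A)
  }
  plan
}

#' @export
print.umbrella_plan <- function(x, ...) {
  cat(sprintf("Umbrella plan%s [%s]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$state))
  cat(sprintf("  %d windows, z = %g..%g A, spacing %g A\n",
              nrow(x$windows), x$z_min, x$z_max, x$spacing))
  cat(sprintf("  k_par %g, k_perp %g kcal/mol/A^2 (U = %sk dz^2), T = %g K\n",
              x$k_parallel, x$k_perpendicular,
              if (x$half_factor) "1/2 " else "", x$temperature))
  invisible(x)
}
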