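#' Physical growth environment
#'
#' Bundles the two constants that define the diffusion-limited growth
#' medium: the calcium diffusion coefficient `D` and the far-field
#' concentration of free (uncomplexed) calcium `c0`. Defaults are the
#' literature values for muscle-like soft tissue: `D = 1.65e-6` cm^2/s and
#' `c0 = 4.2e-5` g/cm^3 (42 mg/l, about half of total extracellular
#' calcium). All model functions work in CGS units (cm, g, s); unit
#' conversions happen only at input/output boundaries.
#'
#' @param D Calcium diffusion coefficient, cm^2/s. Must be positive.
#' @param c0 Free calcium concentration far from the grain, g/cm^3.
#'   Must be positive.
#' @param year_days Days per year used by the time converters. The model
#'   itself is calendar-free; 365.25 shifts multi-year results by under
#'   0.3 percent relative to other conventions.
#'
#' @return An object of class `growth_env`: a list with elements `D`,
#'   `c0` and `year_days`.
#' @examples
#' env <- growth_env()
#' env$D * env$c0 # the Dc0 product that sets every rate in the model
#' @export
growth_env <- function(D = 1.65e-6, c0 = 4.2e-5, year_days = 365.25) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(c0), length(c0) == 1L, is.finite(c0),
            is.numeric(year_days), length(year_days) == 1L)
  if (D <= 0) stop("`D` must be positive (cm^2/s)", call. = FALSE)
  if (c0 <= 0) stop("`c0` must be positive (g/cm^3)", call. = FALSE)
  if (year_days <= 0) stop("`year_days` must be positive", call. = FALSE)
  structure(list(D = D, c0 = c0, year_days = year_days),
            class = "growth_env")
}

#' @export
print.growth_env <- function(x, ...) {
  cat("<growth_env>\n")
  cat(sprintf("  D  = %g cm^2/s (calcium diffusion coefficient)\n", x$D))
  cat(sprintf("  c0 = %g g/cm^3 (free calcium far-field concentration)\n", x$c0))
  cat(sprintf("  year = %g days\n", x$year_days))
  invisible(x)
}

as_growth_env <- function(env) {
  if (inherits(env, "growth_env")) return(env)
  stop("`env` must be created with growth_env()", call. = FALSE)
}

#' Time-unit conversions
#'
#' The model computes times in seconds; these helpers convert to and from
#' the units the results are usually reported in. The calendar convention
#' is one year = `year_days` days (default 365.25) and one month = a
#' twelfth of a year.
#'
#' @param t_s Time in seconds (vectorized).
#' @param t_years Time in years (vectorized).
#' @param env A [growth_env()] carrying the `year_days` convention.
#' @return Numeric vector in the requested unit.
#' @examples
#' seconds_to_years(1.883e8) # about 6 years
#' @export
seconds_to_years <- function(t_s, env = growth_env()) {
  t_s / (as_growth_env(env)$year_days * 86400)
}

#' @rdname seconds_to_years
#' @export
years_to_seconds <- function(t_years, env = growth_env()) {
  t_years * as_growth_env(env)$year_days * 86400
}

#' @rdname seconds_to_years
#' @export
seconds_to_days <- function(t_s, env = growth_env()) t_s / 86400

#' @rdname seconds_to_years
#' @export
seconds_to_months <- function(t_s, env = growth_env()) {
  seconds_to_years(t_s, env) * 12
}

#' Read a run configuration file
#'
#' Loads a YAML configuration overriding the physical constants and the
#' analysis conventions. Recognized keys: `D_cm2_per_s`, `c0_g_per_cm3`,
#' `year_days`, `density_policy` (one of `"midpoint"`, `"min"`, `"max"`,
#' `"explicit"`) and `default_voxel_um`. Unknown keys are rejected with a
#' warning listing them, so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `env` (a [growth_env()]), `density_policy`
#'   and `default_voxel_um`.
#' @export
read_growth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("D_cm2_per_s", "c0_g_per_cm3", "year_days",
             "density_policy", "default_voxel_um")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  policy <- raw$density_policy %||% "midpoint"
  policy <- match.arg(policy, c("midpoint", "min", "max", "explicit"))
  voxel_um <- raw$default_voxel_um %||% 13.5
  stopifnot(is.numeric(voxel_um), voxel_um > 0)
  list(
    env = growth_env(D = raw$D_cm2_per_s %||% 1.65e-6,
                     c0 = raw$c0_g_per_cm3 %||% 4.2e-5,
                     year_days = raw$year_days %||% 365.25),
    density_policy = policy,
    default_voxel_um = voxel_um
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
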