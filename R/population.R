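#' The published ligament case table
#'
#' Per-case density ranges of the mineral grains measured in yellow
#' ligament (ligamentum flavum) samples by micro-CT: two CPPD cases and
#' four HAP cases (two young controls, two elderly stenosis patients),
#' all with grain radii spanning 0.02-0.1 cm. This is the case-level
#' input to [rate_table()] and the template the synthetic generator
#' emulates.
#'
#' @return A tibble with columns `case_id`, `age_years`, `group`
#'   (`control`/`stenosis`), `phase` (`CPPD`/`HAP`), `rho_min`,
#'   `rho_max` (g/cm^3), `a_min_cm`, `a_max_cm`.
#' @examples
#' ligament_cases()
#' @export
ligament_cases <- function() {
  tibble::tibble(
    case_id = c("CPPD-72", "CPPD-81", "HAP-control-35", "HAP-control-36",
                "HAP-stenosis-59", "HAP-stenosis-60"),
    age_years = c(72, 81, 35, 36, 59, 60),
    group = c("stenosis", "stenosis", "control", "control",
              "stenosis", "stenosis"),
    phase = c("CPPD", "CPPD", "HAP", "HAP", "HAP", "HAP"),
    rho_min = c(2.15, 2.40, 1.78, 1.85, 1.85, 1.87),
    rho_max = c(2.25, 2.61, 1.95, 2.00, 2.00, 2.20),
    a_min_cm = 0.02,
    a_max_cm = 0.1
  )
}

grain_table_required <- c("case_id", "age_years", "group", "phase",
                          "density_g_cm3")

#' Read a per-grain measurement table
#'
#' Reads a comma-separated grain table (UTF-8, header mandatory) with
#' unit-suffixed column names: `case_id`, `age_years`, `group`, `phase`,
#' `radius_cm` (or `radius_um`), `density_g_cm3`, `voxel_um` (or
#' `voxel_cm`). Micron-suffixed columns are converted to cm on read.
#' Rows violating the record invariants (positive radius, density, voxel
#' and age; known phase and group) are not silently dropped: they are
#' collected into a rejection report attached as the `"rejections"`
#' attribute (a tibble with a `reason` column).
#'
#' @param source Path to a CSV file, or a data frame already in memory.
#' @return A tibble of valid grain records with standardized columns
#'   `case_id`, `age_years`, `group`, `phase`, `radius_cm`,
#'   `density_g_cm3`, `voxel_um`; rejected rows in
#'   `attr(, "rejections")`.
#' @seealso [write_grain_table()]
#' @export
read_grain_table <- function(source) {
  if (is.data.frame(source)) {
    raw <- tibble::as_tibble(source)
  } else {
    raw <- readr::read_csv(source, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  }
  nm <- names(raw)
  if (!("radius_cm" %in% nm) && !("radius_um" %in% nm)) {
    stop("grain table must have a `radius_cm` or `radius_um` column", call. = FALSE)
  }
  if (!("voxel_um" %in% nm) && !("voxel_cm" %in% nm)) {
    stop("grain table must have a `voxel_um` or `voxel_cm` column", call. = FALSE)
  }
  missing <- setdiff(grain_table_required, nm)
  if (length(missing) > 0) {
    stop("grain table missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  parsed <- tibble::tibble(
    case_id = as.character(raw$case_id),
    age_years = num(raw$age_years),
    group = as.character(raw$group),
    phase = as.character(raw$phase),
    radius_cm = if ("radius_cm" %in% nm) num(raw$radius_cm) else num(raw$radius_um) * 1e-4,
    density_g_cm3 = num(raw$density_g_cm3),
    voxel_um = if ("voxel_um" %in% nm) num(raw$voxel_um) else num(raw$voxel_cm) * 1e4
  )

  reason <- dplyr::case_when(
    is.na(parsed$radius_cm) ~ "radius not numeric",
    parsed$radius_cm <= 0 ~ "radius must be positive",
    is.na(parsed$density_g_cm3) ~ "density not numeric",
    parsed$density_g_cm3 <= 0 ~ "density must be positive",
    is.na(parsed$voxel_um) ~ "voxel size not numeric",
    parsed$voxel_um <= 0 ~ "voxel size must be positive",
    is.na(parsed$age_years) | parsed$age_years <= 0 ~ "age must be positive",
    !(parsed$phase %in% c("HAP", "CPPD", "unknown")) ~ "phase must be HAP, CPPD or unknown",
    !(parsed$group %in% c("control", "stenosis")) ~ "group must be control or stenosis",
    TRUE ~ NA_character_
  )
  ok <- is.na(reason)
  records <- parsed[ok, , drop = FALSE]
  rejections <- dplyr::bind_cols(parsed[!ok, , drop = FALSE],
                                 tibble::tibble(reason = reason[!ok]))
  attr(records, "rejections") <- rejections
  records
}

#' Write a per-grain measurement table
#'
#' Writes the standardized grain-table CSV consumed by
#' [read_grain_table()] (columns `case_id`, `age_years`, `group`,
#' `phase`, `radius_cm`, `density_g_cm3`, `voxel_um`).
#'
#' @param records A grain-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grain_table <- function(records, path) {
  cols <- c("case_id", "age_years", "group", "phase",
            "radius_cm", "density_g_cm3", "voxel_um")
  stopifnot(all(cols %in% names(records)))
  readr::write_csv(records[, cols], path)
  invisible(path)
}

#' Per-case summaries of grain measurements
#'
#' Collapses grain records to one row per case: density and radius
#' ranges, grain count and phase — the case-level view published for
#' the ligament data.
#'
#' @param records A grain-record tibble (see [read_grain_table()]).
#' @return A tibble with columns `case_id`, `age_years`, `group`,
#'   `phase`, `rho_min`, `rho_max`, `a_min_cm`, `a_max_cm`, `n_grains`.
#' @export
summarize_cases <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(case_id = character(), age_years = numeric(),
                          group = character(), phase = character(),
                          rho_min = numeric(), rho_max = numeric(),
                          a_min_cm = numeric(), a_max_cm = numeric(),
                          n_grains = integer()))
  }
  records |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      age_years = .data$age_years[1],
      group = .data$group[1],
      phase = .data$phase[1],
      rho_min = min(.data$density_g_cm3),
      rho_max = max(.data$density_g_cm3),
      a_min_cm = min(.data$radius_cm),
      a_max_cm = max(.data$radius_cm),
      n_grains = dplyr::n(),
      .groups = "drop"
    )
}

resolve_density <- function(rho_min, rho_max, policy, rho_explicit = NULL) {
  switch(policy,
    midpoint = (rho_min + rho_max) / 2,
    min = rho_min,
    max = rho_max,
    explicit = {
      if (is.null(rho_explicit)) {
        stop("density policy `explicit` requires `rho_explicit`", call. = FALSE)
      }
      rep(rho_explicit, length.out = length(rho_min))
    },
    stop("unknown density policy: ", policy, call. = FALSE)
  )
}

#' Growth-rate table at the extreme radii of each case
#'
#' For each case, evaluates the growth rate `da/dt = D c0 / (a rho)` at
#' the case's minimum and maximum grain radius, using one density per
#' case resolved from its published range by `policy`. Because the rate
#' scales as `1/a`, each row satisfies
#' `rate_a_min / rate_a_max = a_max / a_min` exactly.
#'
#' @param summaries Case summaries ([summarize_cases()] output or
#'   [ligament_cases()]).
#' @param policy How to pick a density from the case's `[rho_min,
#'   rho_max]` range: `"midpoint"` (default), `"min"`, `"max"`, or
#'   `"explicit"` (then give `rho_explicit`). The published rate cells
#'   imply grain-specific densities that were not individually printed,
#'   so the choice is explicit and recorded in the output.
#' @param rho_explicit Density in g/cm^3 used when `policy =
#'   "explicit"` (scalar, recycled).
#' @param env A [growth_env()].
#' @return A tibble with columns `case_id`, `age_years`, `phase`,
#'   `rho_used`, `density_policy`, `a_min_cm`, `a_max_cm`,
#'   `rate_a_min_cm_s`, `rate_a_max_cm_s`.
#' @examples
#' rate_table(ligament_cases(), policy = "explicit", rho_explicit = 1.95)
#' @export
rate_table <- function(summaries, policy = c("midpoint", "min", "max", "explicit"),
                       rho_explicit = NULL, env = growth_env()) {
  policy <- match.arg(policy)
  env <- as_growth_env(env)
  if (nrow(summaries) == 0) {
    return(tibble::tibble(case_id = character(), age_years = numeric(),
                          phase = character(), rho_used = numeric(),
                          density_policy = character(),
                          a_min_cm = numeric(), a_max_cm = numeric(),
                          rate_a_min_cm_s = numeric(),
                          rate_a_max_cm_s = numeric()))
  }
  rho <- resolve_density(summaries$rho_min, summaries$rho_max, policy, rho_explicit)
  tibble::tibble(
    case_id = summaries$case_id,
    age_years = summaries$age_years,
    phase = summaries$phase,
    rho_used = rho,
    density_policy = policy,
    a_min_cm = summaries$a_min_cm,
    a_max_cm = summaries$a_max_cm,
    rate_a_min_cm_s = growth_rate(summaries$a_min_cm, rho, env),
    rate_a_max_cm_s = growth_rate(summaries$a_max_cm, rho, env)
  )
}

#' Density implied by a published growth-rate cell
#'
#' Inverts the growth law for the density a printed `da/dt` cell would
#' require: `rho = D c0 / (a * rate)`. Used to audit published rate
#' tables against published density ranges instead of guessing which
#' grain the cell refers to.
#'
#' @param a Radius the cell was evaluated at, cm.
#' @param rate Printed growth rate, cm/s.
#' @param env A [growth_env()].
#' @return Implied density, g/cm^3.
#' @examples
#' implied_density(0.02, 1.75e-9) # ~1.98
#' @export
implied_density <- function(a, rate, env = growth_env()) {
  env <- as_growth_env(env)
  check_radius_positive(a)
  stopifnot(is.numeric(rate), all(rate > 0))
  env$D * env$c0 / (a * rate)
}

#' Per-grain growth times with half-voxel error bars
#'
#' Applies the closed-form growth time to every measured grain and
#' propagates the micro-CT radius uncertainty (half the voxel edge)
#' into a growth-time error bar: `dt = 2 t (voxel/2) / a`, so
#' `dt / t = voxel / a`. Nucleation is dated relative to
#' `observation_time` (default 0 = extraction/surgery), giving negative
#' offsets into the past. Grains smaller than one voxel are flagged
#' `sub_voxel` and their times set to `NA` rather than computed from an
#' unreliable radius.
#'
#' @param records Grain-record tibble ([read_grain_table()] layout).
#' @param observation_time Reference epoch in seconds (default 0).
#' @param env A [growth_env()].
#' @return The records with added columns `growth_time_s`,
#'   `growth_time_years`, `nucleation_offset_s` (= observation_time -
#'   growth time), `dt_s`, `dt_years` (half-voxel error bar) and
#'   `sub_voxel` (logical).
#' @export
growth_time_table <- function(records, observation_time = 0, env = growth_env()) {
  env <- as_growth_env(env)
  voxel_cm <- records$voxel_um * 1e-4
  sub <- records$radius_cm < voxel_cm
  t_s <- growth_time(records$radius_cm, records$density_g_cm3, env)
  dt_s <- propagate_radius_error(records$radius_cm, records$density_g_cm3,
                                 voxel_cm / 2, env)
  t_s[sub] <- NA_real_
  dt_s[sub] <- NA_real_
  records |>
    dplyr::mutate(
      growth_time_s = t_s,
      growth_time_years = seconds_to_years(t_s, env),
      nucleation_offset_s = observation_time - t_s,
      dt_s = dt_s,
      dt_years = seconds_to_years(dt_s, env),
      sub_voxel = sub
    )
}

#' Density histogram of a grain population
#'
#' Histogram of grain densities with bins of width `bin_width` aligned
#' to a fixed origin at 0, reporting `C`, the percentage contribution of
#' each density bin per `reference_volume` of tissue. Contribution is by
#' grain count by default; `weight = "volume"` weights each grain by its
#' spherical volume instead (the published histogram does not state its
#' weighting).
#'
#' @param records Grain-record tibble.
#' @param bin_width Bin width in g/cm^3 (default 0.05).
#' @param reference_volume Tissue reference volume in mm^3 the
#'   percentages refer to (default 100, metadata only).
#' @param weight `"count"` or `"volume"`.
#' @return A tibble of non-empty bins: `bin_lo`, `bin_hi`, `phase`-blind
#'   `C_percent` summing to 100, `n_grains`; attribute
#'   `reference_volume_mm3`.
#' @export
density_histogram <- function(records, bin_width = 0.05,
                              reference_volume = 100,
                              weight = c("count", "volume")) {
  weight <- match.arg(weight)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  if (nrow(records) == 0) {
    out <- tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                          C_percent = numeric(), n_grains = integer())
    attr(out, "reference_volume_mm3") <- reference_volume
    return(out)
  }
  w <- if (weight == "count") rep(1, nrow(records)) else sphere_volume(records$radius_cm)
  bin <- floor(records$density_g_cm3 / bin_width)
  out <- tibble::tibble(bin = bin, w = w) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(C_percent = sum(.data$w), n_grains = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(
      bin_lo = .data$bin * bin_width,
      bin_hi = (.data$bin + 1) * bin_width,
      C_percent = 100 * .data$C_percent / sum(.data$C_percent)
    ) |>
    dplyr::select("bin_lo", "bin_hi", "C_percent", "n_grains")
  attr(out, "reference_volume_mm3") <- reference_volume
  out
}
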