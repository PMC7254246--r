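#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for oracle and recovery objects
#'
#' `tidy()` returns the per-sample (or per-grain) detail as a tibble;
#' `glance()` returns a one-row summary, broom-style.
#'
#' @param x A `grain_ode`, `grain_diffusion` or `grain_recovery` object.
#' @param ... Unused.
#' @return A tibble.
#' @name grainclock-tidiers
NULL

#' @rdname grainclock-tidiers
#' @method tidy grain_ode
#' @export
tidy.grain_ode <- function(x, ...) x$samples

#' @rdname grainclock-tidiers
#' @method glance grain_ode
#' @export
glance.grain_ode <- function(x, ...) {
  tibble::tibble(
    rho = x$settings$rho,
    a0_cm = x$settings$a0,
    t_end_s = x$settings$t_end,
    tol = x$settings$tol,
    max_rel_dev = x$max_rel_dev
  )
}

#' @rdname grainclock-tidiers
#' @method tidy grain_diffusion
#' @export
tidy.grain_diffusion <- function(x, ...) x$profile

#' @rdname grainclock-tidiers
#' @method glance grain_diffusion
#' @export
glance.grain_diffusion <- function(x, ...) {
  tibble::tibble(
    a_cm = x$settings$a,
    R_cm = x$settings$R,
    t_end_s = x$settings$t_end,
    n_grid = x$settings$n_grid,
    n_steps = x$settings$n_steps,
    scheme = x$settings$scheme,
    final_surface_flux = x$final_surface_flux,
    quasistatic_flux = x$quasistatic_flux,
    flux_ratio = x$final_surface_flux / x$quasistatic_flux,
    mass_balance_rel_error = x$mass_balance$rel_error
  )
}

#' @rdname grainclock-tidiers
#' @method tidy grain_recovery
#' @export
tidy.grain_recovery <- function(x, ...) x$per_grain

#' @rdname grainclock-tidiers
#' @method glance grain_recovery
#' @export
glance.grain_recovery <- function(x, ...) {
  tibble::tibble(
    n_grains = x$n_grains,
    n_sub_voxel = x$n_sub_voxel,
    voxel_um = x$spec$voxel_um,
    seed = x$seed,
    max_abs_error_s = x$max_abs_error_s,
    mean_abs_error_s = x$mean_abs_error_s,
    max_bound_s = x$max_bound_s,
    all_within_bound = x$all_within_bound
  )
}

#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: the
#' radius-versus-time trajectory of a [growth_curve()], the
#' concentration profile of a [solve_radial_diffusion()] field against
#' its steady form, and the error-versus-bound scatter of a
#' [recovery_experiment()].
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name grainclock-autoplot
NULL

#' @rdname grainclock-autoplot
#' @method autoplot growth_curve
#' @export
autoplot.growth_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_years, y = .data$a_um)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "growth time (years)", y = "grain radius (µm)",
      title = sprintf("Diffusion-limited growth, ρ = %g g/cm³",
                      attr(object, "rho"))
    )
}

#' @rdname grainclock-autoplot
#' @method autoplot grain_diffusion
#' @export
autoplot.grain_diffusion <- function(object, ...) {
  prof <- tidyr::pivot_longer(object$profile, -"r_cm",
                              names_to = "which", values_to = "c")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$r_cm, y = .data$c,
                                     linetype = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (cm)", y = "calcium concentration (g/cm³)",
                  linetype = NULL)
}

#' @rdname grainclock-autoplot
#' @method autoplot grain_recovery
#' @export
autoplot.grain_recovery <- function(object, ...) {
  d <- dplyr::filter(object$per_grain, !.data$sub_voxel)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a_measured_cm)) +
    ggplot2::geom_point(ggplot2::aes(y = seconds_to_years(.data$abs_error_s)),
                        alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = seconds_to_years(.data$bound_exact_s)),
                       colour = "red") +
    ggplot2::labs(x = "measured radius (cm)",
                  y = "|nucleation-time error| (years)",
                  title = "Recovery errors vs half-voxel bound")
}

#' Plot a density histogram
#'
#' Bar chart of a [density_histogram()] result: percentage contribution
#' per density bin.
#'
#' @param hist A [density_histogram()] tibble.
#' @return A ggplot object.
#' @export
plot_density_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                     y = .data$C_percent)) +
    ggplot2::geom_col(width = (hist$bin_hi - hist$bin_lo)[1] * 0.9) +
    ggplot2::labs(x = "grain density (g/cm³)", y = "C (%)")
}

#' @importFrom rlang .data
NULL
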