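# broom-style accessors and ggplot2 graphics for fitted objects.

#' Tidy a kinetic fit
#'
#' One row per fitted quantity (`k`, `c_max`, `t30`) with bootstrap
#' standard errors where available, in broom's `term`/`estimate` layout.
#'
#' @param x a `kinetic_fit`
#' @param ... unused
#' @return a tibble with columns `term`, `estimate`, `std.error`
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "c_max", "t30"),
    estimate = c(x$k, x$c_max, x$t30$time_min),
    std.error = c(NA_real_, x$se_cmax, x$se_t30)
  )
}

#' Glance at a kinetic fit
#'
#' @param x a `kinetic_fit`
#' @param ... unused
#' @return a one-row tibble: `n_steps`, `k`, `c_max`, `chi2`, `t30`,
#'   `t30_censored`, `converged`
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    n_steps = x$n_steps, k = x$k, c_max = x$c_max, chi2 = x$chi2,
    t30 = x$t30$time_min, t30_censored = x$t30$censored,
    converged = x$converged
  )
}

#' Plot a fitted assembly time course
#'
#' Per-timepoint mean colocalization fractions with replicate-SD error
#' bars, overlaid with the best-fit multi-step assembly curve.
#'
#' @param object a `kinetic_fit`
#' @param n_curve number of curve sample points
#' @param ... unused
#' @return a ggplot
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, n_curve = 200, ...) {
  summ <- object$data
  tc <- seq(0, max(summ$time_min), length.out = n_curve)
  curve <- tibble::tibble(
    time_min = tc,
    fraction = assembly_curve(tc, object$n_steps, object$k, object$c_max)
  )
  lab <- if (!is.na(object$protein)) object$protein else "fit"
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sd_fraction,
                   ymax = .data$mean_fraction + .data$sd_fraction),
      width = 2
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_fraction)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fraction),
                       colour = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = "Incubation time (min)", y = "Colocalized DNAs",
      title = lab,
      subtitle = sprintf("%d-step fit: Cmax = %.0f%%, T%d %s",
                         object$n_steps, 100 * object$c_max,
                         round(100 * object$threshold), format(object$t30))
    ) +
    ggplot2::theme_minimal()
}

#' Overlay several assembly series and their fits
#'
#' @param fits a named list of `kinetic_fit` objects
#' @param n_curve number of curve sample points
#' @return a ggplot
#' @export
plot_assembly_comparison <- function(fits, n_curve = 200) {
  labels <- names(fits)
  if (is.null(labels)) labels <- paste0("fit", seq_along(fits))
  pts <- purrr::map2_dfr(fits, labels, function(f, lab) {
    dplyr::mutate(f$data, label = lab)
  })
  crv <- purrr::map2_dfr(fits, labels, function(f, lab) {
    tc <- seq(0, max(f$data$time_min), length.out = n_curve)
    tibble::tibble(time_min = tc, label = lab,
                   fraction = assembly_curve(tc, f$n_steps, f$k, f$c_max))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_min,
                                    colour = .data$label)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sd_fraction,
                   ymax = .data$mean_fraction + .data$sd_fraction),
      width = 2
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_fraction)) +
    ggplot2::geom_line(data = crv, ggplot2::aes(y = .data$fraction)) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Incubation time (min)", y = "Colocalized DNAs",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
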