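#' Plot a radial density profile
#'
#' Rescaled density versus `ln(r/R)` on a log scale, with optional theory
#' overlays.
#'
#' @param object A [radial_profile()] tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.radial_profile <- function(object, ...) {
  d <- dplyr::filter(object, .data$rho_tilde > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ln_r_over_R_mid,
                                  y = .data$rho_tilde)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$rho_tilde - .data$stderr, .Machine$double.xmin),
      ymax = .data$rho_tilde + .data$stderr), size = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ln(r / R)",
                  y = expression(tilde(rho)(r)),
                  title = "Rescaled counterion density profile")
}

#' Plot chain traces
#'
#' Energy and condensed-count traces of a Monte Carlo chain.
#'
#' @param object A [run_chain()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cylcond_chain <- function(object, ...) {
  d <- tidyr::pivot_longer(object$samples, c("energy", "n_condensed"),
                           names_to = "series")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sweep, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "sweep", y = NULL, title = "Chain traces")
}

#' Plot a data collapse
#'
#' Transformed order-parameter data `Delta^(beta/nu) m` against the scaling
#' variable `Delta^(1/nu) zeta`, coloured by system size, with the fitted
#' master curve.
#'
#' @param object A [data_collapse()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.collapse_result <- function(object, ...) {
  mc <- object$master_curve
  ggplot2::ggplot(mc, ggplot2::aes(x = .data$u, y = .data$w,
                                   colour = factor(.data$delta))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$w - .data$w_err,
                                          ymax = .data$w + .data$w_err),
                             size = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey30",
                       linewidth = 0.3) +
    ggplot2::labs(
      x = expression(Delta^{1 / nu} * zeta),
      y = expression(Delta^{beta / nu} * m),
      colour = expression(Delta),
      title = sprintf("Data collapse: beta = %.3f, nu = %.3f",
                      object$beta, object$nu))
}

#' Condensation summary plot for a Manning-parameter sweep
#'
#' Condensed fraction and heat capacity versus the Manning parameter from a
#' [run_experiment_grid()] table, with the Manning threshold and (when
#' `alpha` is given) the complete-condensation onset marked.
#'
#' @param grid A [run_experiment_grid()] result tibble.
#' @param alpha Optional radius-shrinking exponent for the `xi_2` mark.
#' @return A ggplot object.
#' @export
plot_condensation <- function(grid, alpha = NULL) {
  d <- tidyr::pivot_longer(
    dplyr::transmute(grid, xi = .data$xi, f = .data$f,
                     C_scaled = .data$C_tilde / max(.data$C_tilde, na.rm = TRUE)),
    c("f", "C_scaled"), names_to = "observable")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$xi, y = .data$value,
                                       colour = .data$observable)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = expression(xi), y = NULL,
                  title = "Condensed fraction and scaled heat capacity")
  if (!is.null(alpha))
    p <- p + ggplot2::geom_vline(xintercept = xi2_of_alpha(alpha),
                                 linetype = "dashed")
  p
}

#' @importFrom rlang .data
NULL
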