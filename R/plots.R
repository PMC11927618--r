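#' Plot a splitting solution
#'
#' Post-first-passage mean trajectories \eqn{\mu_1}, \eqn{\mu_2} against
#' lag (log scale), with the targets as dashed references.  Flat lines at
#' the targets are the Markovian signature; any structure is a memory
#' effect.
#'
#' @param object a [solve_splitting()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.splitting_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$tau, .data$mu,
                                   colour = factor(.data$target))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0, object$L), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag after first passage", y = "mean position",
                  colour = "target",
                  title = sprintf("%s: pi2 = %.4f (Markovian %.4f)",
                                  object$model$name, object$pi2,
                                  object$x0 / object$L)) +
    ggplot2::theme_minimal()
}

#' Plot an estimated MSD curve
#'
#' Log-log MSD with error bars; if a fit is supplied its curve is overlaid.
#'
#' @param object an [estimate_msd()] tibble.
#' @param fit optional [fit_msd_viscoelastic()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msd_estimate <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$msd)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$msd - 2 * .data$se,
                                          ymax = .data$msd + 2 * .data$se),
                             size = 0.2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time", y = "MSD") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- exp(seq(log(min(object$t)), log(max(object$t)), length.out = 100))
    df <- tibble::tibble(t = tt,
                         msd = fit$amplitude * visc_f(tt / fit$tau0, fit$alpha) + fit$offset)
    p <- p + ggplot2::geom_line(data = df, colour = "firebrick")
  }
  p
}

#' Plot empirical splitting probabilities
#'
#' \eqn{\hat\pi_2(x_0)} with 2-SE error bars against the Markovian line
#' \eqn{x_0/L}; optionally overlays theory points.
#'
#' @param object an [empirical_splitting()] result.
#' @param theory optional tibble with columns `x0`, `pi2`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.empirical_splitting <- function(object, theory = NULL, ...) {
  df <- object$by_x0
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x0, .data$pi2_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$pi2_hat - .data$ci_halfwidth,
                                          ymax = .data$pi2_hat + .data$ci_halfwidth)) +
    ggplot2::geom_abline(slope = 1 / object$L, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "start position x0", y = "empirical pi2") +
    ggplot2::theme_minimal()
  if (!is.null(theory))
    p <- p + ggplot2::geom_line(data = theory, ggplot2::aes(.data$x0, .data$pi2),
                                colour = "forestgreen")
  p
}
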