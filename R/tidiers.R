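#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a splitting solution
#'
#' @param x a [solve_splitting()] result.
#' @param ... unused.
#' @return a long tibble: `tau`, `target`, `mu` (the post-first-passage
#'   mean trajectories on the solver grid).
#' @export
tidy.splitting_solution <- function(x, ...) {
  tibble::tibble(
    tau = rep(x$tau_grid, 2),
    target = rep(1:2, each = length(x$tau_grid)),
    mu = c(x$mu1, x$mu2)
  )
}

#' @rdname tidy.splitting_solution
#' @return `glance()`: a one-row tibble with `pi1`, `pi2`, `pi_markovian`,
#'   `residual_norm`, `pi_drift`, `iterations`, `converged`.
#' @export
glance.splitting_solution <- function(x, ...) {
  tibble::tibble(pi1 = x$pi1, pi2 = x$pi2, pi_markovian = x$x0 / x$L,
                 residual_norm = x$residual_norm, pi_drift = x$pi_drift,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy an MSD fit
#'
#' @param x an [fit_msd_viscoelastic()] result.
#' @param ... unused.
#' @return a tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.msd_fit <- function(x, ...) {
  terms <- c("amplitude", "tau0", "alpha")
  est <- c(x$amplitude, x$tau0, x$alpha)
  if (x$offset > 0) { terms <- c(terms, "offset"); est <- c(est, x$offset) }
  tibble::tibble(term = terms, estimate = est,
                 std.error = x$se[seq_along(terms)])
}

#' @rdname tidy.msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, tau0 = x$tau0, alpha = x$alpha,
                 crossover_in_range = x$crossover_in_range,
                 deviance = tryCatch(stats::deviance(x$fit), error = function(e) NA_real_))
}

#' Tidy Monte Carlo hitting statistics
#'
#' @param x an `hitting_stats` object.
#' @param ... unused.
#' @return the per-lag conditional mean tibble (empty when post-hit curves
#'   were not recorded).
#' @export
tidy.hitting_stats <- function(x, ...) {
  if (is.null(x$mu)) tibble::tibble() else x$mu
}

#' @rdname tidy.hitting_stats
#' @export
glance.hitting_stats <- function(x, ...) {
  tibble::tibble(pi2_hat = x$pi2_hat, se = x$se, n_events = x$n_events,
                 censored_fraction = x$censored_fraction)
}
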