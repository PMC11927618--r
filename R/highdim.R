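#' Two-target splitting problem in d dimensions
#'
#' Describes two absorbing spherical targets of radius `a` centred at `r1`
#' and `r2`, a start position `r0`, and an isotropic process whose
#' independent coordinates each follow `model`.  The confinement radius `R`
#' is carried for bookkeeping: the large-volume theory itself is
#' confinement-free.
#'
#' @param d spatial dimension (1 or 2 supported by the propagator tools).
#' @param r0,r1,r2 numeric vectors of length `d`.
#' @param a target radius (>= 0; 0 is allowed for d = 1 point targets).
#' @param model per-coordinate [msd_model()].
#' @param R confinement radius (optional metadata).
#' @return an object of class `highdim_problem`.
#' @export
highdim_problem <- function(d, r0, r1, r2, a, model, R = Inf) {
  stopifnot(length(r0) == d, length(r1) == d, length(r2) == d,
            inherits(model, "msd_model"), a >= 0)
  L <- sqrt(sum((r1 - r2)^2))
  if (L <= 2 * a) stop("targets overlap: need |r1 - r2| > 2a", call. = FALSE)
  if (sqrt(sum((r0 - r1)^2)) <= a || sqrt(sum((r0 - r2)^2)) <= a)
    stop("start position lies inside a target", call. = FALSE)
  structure(list(d = d, r0 = r0, r1 = r1, r2 = r2, a = a, L = L,
                 model = model, R = R),
            class = "highdim_problem")
}

#' Free isotropic Gaussian propagator
#'
#' Density of the unconfined process at position `r` and time `t`, given a
#' start at `r_start`: a product of `d` identical 1D Gaussians with
#' variance \eqn{\psi(t)} per coordinate.
#'
#' @param model per-coordinate [msd_model()].
#' @param r,r_start positions (equal length).
#' @param t times (> 0).
#' @return density values.
#' @export
free_propagator <- function(model, r, r_start, t) {
  stopifnot(length(r) == length(r_start))
  if (any(t <= 0)) stop("`t` must be strictly positive", call. = FALSE)
  d <- length(r)
  v <- msd_eval(model, t)
  rho2 <- sum((r - r_start)^2)
  exp(-rho2 / (2 * v)) / (2 * pi * v)^(d / 2)
}

#' Propagator models for the post-hit density
#'
#' The large-volume splitting formula needs the density \eqn{q_j(r, t)} of
#' the walker a time `t` after first hitting target `j`.  Two modes are
#' provided.  The Markovian baseline takes the post-hit state to be
#' memory-free: a Gaussian re-centred on the target surface with uniform
#' hit direction (`m_j == 0`, no angular concentration).  The
#' semi-empirical mode uses measured single-target statistics under the
#' decoupling approximation: a radial mean-displacement curve
#' \eqn{m_j(t)} (signed overshoot beyond the target radius along the hit
#' direction; `m_j(0) = 0`) and an exponential-cosine (von Mises) hit-angle
#' distribution \eqn{\Pi(\theta) \propto e^{\kappa_\theta \cos(\theta - \theta_0)}}
#' about the axis from the target towards the start.
#'
#' @param m1,m2 functions of lag returning the signed radial mean
#'   displacement for targets 1 and 2 (default 0).
#' @param kappa_angle angular concentration (>= 0; 0 = uniform).
#' @param theta0 reference angle (radians) relative to the target-to-start
#'   axis.
#' @return an object of class `propagator_model`.
#' @export
propagator_semi_empirical <- function(m1 = function(t) rep(0, length(t)),
                                      m2 = m1, kappa_angle = 0, theta0 = 0) {
  stopifnot(is.function(m1), is.function(m2), kappa_angle >= 0)
  structure(list(mode = "semi_empirical", m = list(m1, m2),
                 kappa_angle = kappa_angle, theta0 = theta0),
            class = "propagator_model")
}

#' @describeIn propagator_semi_empirical the memory-free baseline.
#' @export
propagator_markovian <- function() {
  out <- propagator_semi_empirical()
  out$mode <- "markovian_baseline"
  out
}

# Post-hit density q_j at position r, times t (vectorised over t).
# The mean position is c_j + (a + m_j(t)) u(theta) averaged over the hit
# angle theta ~ Pi(theta); u is measured from the axis c_j -> r0.
post_hit_density <- function(problem, propagator, j, r, t) {
  v <- msd_eval(problem$model, t)
  cj <- if (j == 1) problem$r1 else problem$r2
  mj <- propagator$m[[j]](t)
  rad <- problem$a + mj
  if (problem$d == 1) {
    # the hit direction is the axis towards the start (point targets)
    u <- sign(problem$r0 - cj)
    mu <- cj + rad * u
    return(stats::dnorm(r, mu, sqrt(v)))
  }
  # d == 2: average over theta with von Mises weights (trapezoid on the circle)
  nth <- 64
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  wvm <- exp(propagator$kappa_angle * cos(th - propagator$theta0))
  wvm <- wvm / sum(wvm)
  axis <- problem$r0 - cj
  phi0 <- atan2(axis[2], axis[1])
  ux <- cos(phi0 + th); uy <- sin(phi0 + th)
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    mx <- cj[1] + rad[i] * ux; my <- cj[2] + rad[i] * uy
    g <- exp(-((r[1] - mx)^2 + (r[2] - my)^2) / (2 * v[i])) / (2 * pi * v[i])
    out[i] <- sum(wvm * g)
  }
  out
}

#' Time-integrated propagator differences
#'
#' \eqn{h_{ij} = \int_0^\infty [q_j(r_i, t) - p(r_i, t)]\,dt}: the excess
#' occupation of target position \eqn{r_i} by a walker conditioned to have
#' hit target `j` first, relative to the free process.  Integrated on a
#' log-time grid with an algebraic tail extrapolation fitted to the last
#' decade; integration aborts if the integrand has not entered a decaying
#' algebraic regime by the cutoff.
#'
#' @param problem a [highdim_problem()].
#' @param propagator a `propagator_model`.
#' @param t_span integration range in units of the characteristic time
#'   \eqn{\psi(t_c) = L^2}.
#' @param per_decade quadrature nodes per decade.
#' @return a 2 x 2 matrix `h[i, j]`.
#' @export
h_matrix <- function(problem, propagator, t_span = c(1e-6, 1e6), per_decade = 48) {
  stopifnot(inherits(problem, "highdim_problem"),
            inherits(propagator, "propagator_model"))
  tc <- characteristic_time(problem$model, problem$L)
  nq <- ceiling(log10(t_span[2] / t_span[1]) * per_decade) + 1
  u <- seq(log(t_span[1] * tc), log(t_span[2] * tc), length.out = nq)
  tq <- exp(u); du <- u[2] - u[1]
  w <- tq * du; w[c(1, nq)] <- w[c(1, nq)] / 2
  h <- matrix(0, 2, 2)
  for (i in 1:2) {
    ri <- if (i == 1) problem$r1 else problem$r2
    p_i <- vapply(tq, function(tt) free_propagator(problem$model, ri, problem$r0, tt),
                  numeric(1))
    for (j in 1:2) {
      q_ij <- post_hit_density(problem, propagator, j, ri, tq)
      f <- q_ij - p_i
      I <- sum(w * f)
      sel <- tq >= tq[nq] / 10
      fs <- f[sel]
      if (all(fs > 0) || all(fs < 0)) {
        b <- stats::lm.fit(cbind(1, log(tq[sel])), log(abs(fs)))$coefficients[2]
        if (b < -1.01) {
          I <- I + fs[length(fs)] * tq[nq] / (-b - 1)
        } else if (abs(fs[length(fs)]) * tq[nq] > 1e-6 * max(abs(I), 1e-12)) {
          stop(sprintf(
            "h integrand tail decays like t^%.2f at the cutoff; integral not convergent",
            b), call. = FALSE)
        }
      }
      h[i, j] <- I
    }
  }
  h
}

#' Splitting probabilities from the h matrix
#'
#' In the large-volume limit
#' \eqn{\pi_1 = (h_{22} - h_{12}) / (h_{22} + h_{11} - h_{21} - h_{12})},
#' \eqn{\pi_2 = 1 - \pi_1}.
#'
#' @param h a 2 x 2 matrix from [h_matrix()] (or four scalars via `...`).
#' @return a list with `pi1`, `pi2`.
#' @export
splitting_from_h <- function(h) {
  stopifnot(is.matrix(h), all(dim(h) == c(2, 2)))
  den <- h[2, 2] + h[1, 1] - h[2, 1] - h[1, 2]
  if (abs(den) < 1e-12 * max(abs(h)))
    stop("degenerate geometry: h denominator vanishes", call. = FALSE)
  pi1 <- (h[2, 2] - h[1, 2]) / den
  list(pi1 = pi1, pi2 = 1 - pi1)
}

#' Large-volume splitting probability in d dimensions
#'
#' Convenience wrapper: [h_matrix()] followed by [splitting_from_h()].
#'
#' @inheritParams h_matrix
#' @return a list with `pi1`, `pi2`, `h`, `mode`.
#' @export
splitting_highdim <- function(problem, propagator = propagator_markovian(),
                              t_span = c(1e-6, 1e6), per_decade = 48) {
  h <- h_matrix(problem, propagator, t_span, per_decade)
  out <- splitting_from_h(h)
  c(out, list(h = h, mode = propagator$mode))
}

#' Fit the exponential-cosine hit-angle distribution
#'
#' Maximum-likelihood fit of \eqn{\Pi(\theta) \propto e^{\kappa\cos(\theta-\theta_0)}}
#' (the von Mises family) to a sample of hit angles.  \eqn{\theta_0} is the
#' circular mean; the concentration solves
#' \eqn{I_1(\kappa)/I_0(\kappa) = \bar R} (mean resultant length), by
#' bracketed root-finding, capped at 50 for degenerate samples.
#'
#' @param theta angles in radians (>= 200 values recommended).
#' @return a list with `kappa_angle`, `theta0`, `R_bar`, `n`.
#' @export
fit_angle_distribution <- function(theta) {
  n <- length(theta)
  if (n < 200) warning("fewer than 200 angles; concentration estimate is unstable")
  C <- mean(cos(theta)); S <- mean(sin(theta))
  theta0 <- atan2(S, C)
  Rbar <- sqrt(C^2 + S^2)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  if (Rbar >= A(50)) {
    warning("sample nearly degenerate; concentration capped at 50")
    kappa <- 50
  } else if (Rbar < 1e-12) {
    kappa <- 0
  } else {
    kappa <- stats::uniroot(function(k) A(k) - Rbar, c(1e-8, 50), tol = 1e-10)$root
  }
  list(kappa_angle = kappa, theta0 = theta0, R_bar = Rbar, n = n)
}

#' Calibrate the semi-empirical propagator from single-target runs
#'
#' Under the decoupling approximation, post-hit statistics in the two-target
#' problem are taken from the single-target problem: the radial
#' mean-displacement curve comes from
#' [single_target_post_hit_2d()] run towards each target, and the angular
#' law from [fit_angle_distribution()] on the recorded hit angles.
#'
#' @param problem a [highdim_problem()].
#' @param single1,single2 outputs of [single_target_post_hit_2d()] for
#'   approaches to target 1 and 2 (target 2 defaults to the same
#'   statistics, appropriate for equal radii and a start on the axis).
#' @param min_events minimum hit count per calibration.
#' @return a `propagator_model` in semi-empirical mode.
#' @export
calibrate_semi_empirical <- function(problem, single1, single2 = single1,
                                     min_events = 500) {
  for (s in list(single1, single2))
    if (s$n_events < min_events)
      stop(sprintf("calibration needs >= %d events, got %d", min_events, s$n_events),
           call. = FALSE)
  ang <- fit_angle_distribution(c(single1$theta, single2$theta))
  mk <- function(s) {
    tt <- s$m_curve$t; mm <- s$m_curve$mean
    mm[1] <- 0   # the trajectory starts on the target surface
    af <- stats::approxfun(tt, mm, rule = 2)
    function(t) af(t)
  }
  out <- propagator_semi_empirical(m1 = mk(single1), m2 = mk(single2),
                                   kappa_angle = ang$kappa_angle,
                                   theta0 = ang$theta0)
  out$angle_fit <- ang
  out
}
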