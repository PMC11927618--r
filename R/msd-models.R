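#' Mean-squared-displacement models
#'
#' A centered Gaussian process with stationary increments is fully
#' characterised by its mean squared displacement (MSD)
#' \eqn{\psi(t) = \langle [x(t) - x(0)]^2 \rangle}.  An `msd_model` bundles
#' the function \eqn{\psi} with the exponent \eqn{H} and amplitude
#' \eqn{\kappa} of its long-time power law \eqn{\psi(t) \simeq \kappa
#' t^{2H}}, \eqn{0 < H < 1}.  Every other tool in the package (the
#' splitting-probability solver, the exact samplers, the trajectory
#' pipeline) takes one of these objects as the sole description of the
#' process.
#'
#' @param name short label for printing.
#' @param psi vectorised function of time returning length^2 values;
#'   must satisfy `psi(0) == 0` and be strictly increasing.
#' @param H_inf long-time exponent in (0, 1).
#' @param kappa amplitude of the long-time law, length^2 / time^(2H).
#' @param params named list of model parameters (kept for provenance).
#'
#' @return an object of class `msd_model`.
#' @seealso [msd_powerlaw()], [msd_bidiffusive()], [msd_viscoelastic()],
#'   [msd_rouse()], [msd_tabulated()]
#' @export
msd_model <- function(name, psi, H_inf, kappa, params = list()) {
  stopifnot(is.function(psi))
  if (!is.numeric(H_inf) || length(H_inf) != 1 || H_inf <= 0 || H_inf >= 1)
    stop("`H_inf` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(kappa) || kappa <= 0)
    stop("`kappa` must be positive", call. = FALSE)
  structure(
    list(name = name, psi = psi, H_inf = H_inf, kappa = kappa, params = params),
    class = "msd_model"
  )
}

#' @export
print.msd_model <- function(x, ...) {
  cat(sprintf("<msd_model: %s>\n", x$name))
  cat(sprintf("  long-time law  kappa t^(2H): kappa = %g, H = %g\n", x$kappa, x$H_inf))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the MSD of a model
#'
#' @param model an [msd_model()].
#' @param t non-negative times.
#' @return numeric vector \eqn{\psi(t)}.
#' @export
msd_eval <- function(model, t) {
  stopifnot(inherits(model, "msd_model"))
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  model$psi(t)
}

#' MSD values on a time grid, as a tibble
#'
#' @inheritParams msd_eval
#' @return a tibble with columns `t` and `psi`.
#' @export
msd_curve <- function(model, t) {
  tibble::tibble(t = t, psi = msd_eval(model, t))
}

#' Scale-invariant (fractional Brownian motion) MSD
#'
#' \eqn{\psi(t) = \kappa t^{2H}}.  `H = 1/2` is ordinary diffusion with
#' \eqn{\kappa = 2D}; `H < 1/2` is subdiffusive (anti-persistent), `H > 1/2`
#' superdiffusive (persistent).
#'
#' @param kappa amplitude (length^2 / time^(2H)), positive.
#' @param H Hurst exponent in (0, 1).
#' @return an [msd_model()].
#' @export
msd_powerlaw <- function(kappa = 1, H = 0.5) {
  if (!is.numeric(H) || length(H) != 1 || H <= 0 || H >= 1)
    stop("`H` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("`kappa` must be positive", call. = FALSE)
  force(kappa); force(H)
  msd_model(
    name = sprintf("powerlaw(kappa=%g, H=%g)", kappa, H),
    psi = function(t) kappa * t^(2 * H),
    H_inf = H, kappa = kappa,
    params = list(kappa = kappa, H = H)
  )
}

#' Bidiffusive MSD
#'
#' \eqn{\psi(t) = t + B (1 - e^{-t})} in dimensionless units: the sum of a
#' white noise and a single-relaxation-time colored noise (Brownian motion
#' plus an equilibrium Ornstein-Uhlenbeck component), as for a tracer in a
#' Maxwell fluid.  Short-time diffusivity is `1 + B`, long-time diffusivity 1.
#'
#' @param B non-negative amplitude of the transient component.
#' @return an [msd_model()] with `H_inf = 1/2`, `kappa = 1`.
#' @export
msd_bidiffusive <- function(B) {
  if (!is.numeric(B) || length(B) != 1 || B < 0)
    stop("`B` must be non-negative", call. = FALSE)
  force(B)
  msd_model(
    name = sprintf("bidiffusive(B=%g)", B),
    psi = function(t) t + B * (1 - exp(-t)),
    H_inf = 0.5, kappa = 1,
    params = list(B = B)
  )
}

#' Viscoelastic MSD (incomplete-gamma crossover model)
#'
#' \eqn{\psi(t) = A f(t/\tau_0)} with
#' \deqn{f(y) = [(y - \alpha + 1)\,\gamma(\alpha, y) + y^\alpha e^{-y}] / \Gamma(\alpha),}
#' where \eqn{\gamma} is the lower incomplete gamma function.  This is the
#' MSD induced by a generalized Langevin equation whose friction kernel is a
#' power law cut off exponentially at the relaxation time \eqn{\tau_0}: the
#' motion is subdiffusive with exponent \eqn{\alpha} for \eqn{t \ll \tau_0}
#' and diffusive for \eqn{t \gg \tau_0}.  The prefactor (a combination of
#' temperature and friction) is carried as the single fitted `amplitude`.
#'
#' @param amplitude overall MSD scale (length^2), positive.
#' @param tau0 crossover (memory) time, positive.
#' @param alpha short-time subdiffusion exponent in (0, 1].  `alpha = 1`
#'   reduces exactly to simple diffusion, \eqn{f(y) = y}.
#' @return an [msd_model()] with `H_inf = 1/2`, `kappa = amplitude/tau0`.
#' @export
msd_viscoelastic <- function(amplitude, tau0, alpha) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude <= 0)
    stop("`amplitude` must be positive", call. = FALSE)
  if (!is.numeric(tau0) || length(tau0) != 1 || tau0 <= 0)
    stop("`tau0` must be positive", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  force(amplitude); force(tau0); force(alpha)
  msd_model(
    name = sprintf("viscoelastic(A=%g, tau0=%g, alpha=%g)", amplitude, tau0, alpha),
    psi = function(t) amplitude * visc_f(t / tau0, alpha),
    H_inf = 0.5, kappa = amplitude / tau0,
    params = list(amplitude = amplitude, tau0 = tau0, alpha = alpha)
  )
}

#' Crossover scaling function of the viscoelastic MSD
#'
#' \eqn{f(y) = [(y - \alpha + 1)\gamma(\alpha, y) + y^\alpha e^{-y}]/\Gamma(\alpha)}.
#' The regularised incomplete gamma \eqn{P(\alpha, y) = \gamma(\alpha, y)/\Gamma(\alpha)}
#' is evaluated by `pgamma()`, whose series/continued-fraction branches keep
#' the relative error at machine precision over the whole range; the
#' \eqn{y^\alpha e^{-y}} term is computed on the log scale.
#'
#' @param y non-negative scaled time `t / tau0`.
#' @param alpha exponent in (0, 1].
#' @return dimensionless values, `f(0) = 0`, `f(y) ~ y` for large `y`.
#' @export
visc_f <- function(y, alpha) {
  out <- numeric(length(y))
  pos <- y > 0
  yp <- y[pos]
  out[pos] <- (yp - alpha + 1) * stats::pgamma(yp, alpha) +
    exp(alpha * log(yp) - yp - lgamma(alpha))
  out
}

#' Rouse-chain first-monomer MSD
#'
#' Per-coordinate MSD of the first bead of a discrete Rouse chain of `N`
#' beads obeying \eqn{\partial_t x_i = x_{i+1} - 2 x_i + x_{i-1} + f_i(t)}
#' with free ends (ghost-bead prescription \eqn{x_0 = x_1},
#' \eqn{x_{N+1} = x_N}) and thermal noise of variance 2 per coordinate.
#' Decomposing onto the cosine normal modes of the free chain,
#' \deqn{\psi(t) = \frac{2t}{N} + \sum_{p=1}^{N-1} \frac{2}{N}
#'   \cos^2\!\Big(\frac{p\pi}{2N}\Big) \frac{2}{\lambda_p}
#'   \big(1 - e^{-\lambda_p t}\big), \qquad
#'   \lambda_p = 4 \sin^2\!\Big(\frac{p\pi}{2N}\Big).}
#' The first term is centre-of-mass diffusion; the internal modes produce a
#' transient subdiffusive regime with apparent exponent near 1/2.
#'
#' @param N number of beads (>= 1).
#' @return an [msd_model()] with `H_inf = 1/2`, `kappa = 2/N`.
#' @export
msd_rouse <- function(N) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    stop("`N` must be a positive integer", call. = FALSE)
  N <- as.integer(N)
  if (N == 1L) {
    return(msd_model("rouse(N=1)", function(t) 2 * t, H_inf = 0.5, kappa = 2,
                     params = list(N = 1L)))
  }
  p <- seq_len(N - 1)
  lam <- 4 * sin(p * pi / (2 * N))^2
  w1 <- (2 / N) * cos(p * pi / (2 * N))^2   # squared first-bead mode weight
  force(lam); force(w1)
  msd_model(
    name = sprintf("rouse(N=%d)", N),
    psi = function(t) {
      com <- 2 * t / N
      internal <- vapply(t, function(tt) sum(w1 * 2 / lam * (1 - exp(-lam * tt))), numeric(1))
      com + internal
    },
    H_inf = 0.5, kappa = 2 / N,
    params = list(N = N)
  )
}

#' Tabulated MSD
#'
#' Builds an `msd_model` from measured `(t, psi)` pairs, e.g. an MSD curve
#' estimated from tracking data.  Interpolation is monotone in log-log
#' space; beyond the table the declared `(kappa, H)` power-law tail is used
#' (defaults: fitted to the last decade of the table), and below the table
#' the local power law of the first two points.
#'
#' @param data a data frame with columns `t` and `psi`, both positive and
#'   strictly increasing.
#' @param kappa,H optional long-time tail; fitted to the last decade of the
#'   table when omitted.
#' @return an [msd_model()].
#' @export
msd_tabulated <- function(data, kappa = NULL, H = NULL) {
  stopifnot(is.data.frame(data), all(c("t", "psi") %in% names(data)))
  tt <- data$t; pp <- data$psi
  if (any(tt <= 0) || any(pp <= 0)) stop("table must be positive", call. = FALSE)
  if (is.unsorted(tt, strictly = TRUE) || is.unsorted(pp, strictly = TRUE))
    stop("table must be strictly increasing in both t and psi", call. = FALSE)
  lt <- log(tt); lp <- log(pp)
  if (is.null(H) || is.null(kappa)) {
    sel <- tt >= max(tt) / 10
    if (sum(sel) < 2) sel <- seq(max(1, length(tt) - 2), length(tt))
    fit <- stats::lm.fit(cbind(1, lt[sel]), lp[sel])
    if (is.null(H)) H <- max(min(fit$coefficients[2] / 2, 0.99), 0.01)
    if (is.null(kappa)) kappa <- exp(fit$coefficients[1])
  }
  slope0 <- (lp[2] - lp[1]) / (lt[2] - lt[1])
  af <- stats::approxfun(lt, lp)
  force(slope0); force(af)
  msd_model(
    name = "tabulated",
    psi = function(t) {
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      res <- numeric(length(tp))
      lo <- tp < tt[1]; hi <- tp > tt[length(tt)]; mid <- !lo & !hi
      res[lo] <- exp(lp[1] + slope0 * (log(tp[lo]) - lt[1]))
      res[mid] <- exp(af(log(tp[mid])))
      res[hi] <- kappa * tp[hi]^(2 * H)
      out[pos] <- res
      out
    },
    H_inf = H, kappa = kappa,
    params = list(n_points = length(tt), t_min = tt[1], t_max = tt[length(tt)])
  )
}

#' Conditional-mean weight of a Gaussian stationary-increment process
#'
#' \eqn{M(t, \tau) = [\psi(t+\tau) + \psi(t) - \psi(\tau)] / [2\psi(t)]}:
#' the coefficient with which the present displacement enters the
#' conditional mean of the future position.  For Brownian motion
#' \eqn{M \equiv 1} (independent increments).
#'
#' @param model an [msd_model()].
#' @param t conditioning times, strictly positive.
#' @param tau lags, non-negative.  `t` and `tau` are recycled.
#' @return dimensionless values.
#' @export
correlation_M <- function(model, t, tau) {
  stopifnot(inherits(model, "msd_model"))
  if (any(t <= 0)) stop("`t` must be strictly positive (M is singular at t = 0)", call. = FALSE)
  if (any(tau < 0)) stop("`tau` must be non-negative", call. = FALSE)
  (msd_eval(model, t + tau) + msd_eval(model, t) - msd_eval(model, tau)) /
    (2 * msd_eval(model, t))
}

#' Autocovariance of discrete increments
#'
#' For sampling step `dt`, the stationary increment sequence
#' \eqn{\Delta_n = x((n+1)dt) - x(n\,dt)} has autocovariance
#' \eqn{c(k) = \tfrac12[\psi((k+1)dt) - 2\psi(k\,dt) + \psi(|k-1|dt)]},
#' the second difference of the MSD.  `c(0) = psi(dt)`.
#'
#' @param model an [msd_model()].
#' @param dt sampling step, positive.
#' @param lags integer lags (>= 0).
#' @return numeric vector of covariances (length^2).
#' @export
increment_autocov <- function(model, dt, lags) {
  stopifnot(inherits(model, "msd_model"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (any(lags < 0) || any(lags != round(lags))) stop("`lags` must be non-negative integers", call. = FALSE)
  0.5 * (msd_eval(model, (lags + 1) * dt) - 2 * msd_eval(model, lags * dt) +
           msd_eval(model, abs(lags - 1) * dt))
}

#' Time for the process to span a distance
#'
#' Returns \eqn{t_c} solving \eqn{\psi(t_c) = L^2}: the natural time unit of
#' a two-target problem with separation `L`, used to scale all solver grids.
#'
#' @param model an [msd_model()].
#' @param L distance, positive.
#' @return a single time.
#' @export
characteristic_time <- function(model, L) {
  stopifnot(inherits(model, "msd_model"))
  if (L <= 0) stop("`L` must be positive", call. = FALSE)
  guess <- (L^2 / model$kappa)^(1 / (2 * model$H_inf))
  lo <- guess * 1e-9; hi <- guess * 1e9
  f <- function(t) msd_eval(model, t) - L^2
  if (f(lo) > 0 || f(hi) < 0) stop("could not bracket psi(t) = L^2", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = guess * 1e-12)$root
}

#' Read an MSD model specification from YAML
#'
#' The file must contain `type` (one of `powerlaw`, `bidiffusive`,
#' `viscoelastic`, `rouse`, `table`) plus that constructor's parameters; for
#' `table`, a `file` entry naming a two-column CSV `(t, psi)` resolved
#' relative to the YAML file.
#'
#' @param path path to a YAML file.
#' @return an [msd_model()].
#' @export
read_msd_model <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$type)) stop("model spec needs a `type` field", call. = FALSE)
  switch(spec$type,
    powerlaw = msd_powerlaw(kappa = spec$kappa %||% 1, H = spec$H),
    bidiffusive = msd_bidiffusive(B = spec$B),
    viscoelastic = msd_viscoelastic(spec$amplitude, spec$tau0, spec$alpha),
    rouse = msd_rouse(spec$N),
    table = {
      f <- spec$file
      if (!file.exists(f)) f <- file.path(dirname(path), spec$file)
      msd_tabulated(utils::read.csv(f), kappa = spec$kappa, H = spec$H)
    },
    stop(sprintf("unknown model type '%s'", spec$type), call. = FALSE)
  )
}
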