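#' Single-particle trajectories
#'
#' The analysis pipeline works on plain tibbles with columns `t` (uniform
#' sampling) and `x` (1D position, e.g. the x-axis projection of a tracked
#' bead).  `as_trajectory()` validates the sampling; [read_trajectory()]
#' reads CSV/TSV with columns `t`, `x` (a leading `time` column is also
#' accepted).
#'
#' @param data a data frame with columns `t` and `x`.
#' @param dt_rel_tol allowed relative jitter of the frame interval.
#' @return a tibble of class `trajectory` with attribute `dt`.
#' @export
as_trajectory <- function(data, dt_rel_tol = 1e-6) {
  stopifnot(is.data.frame(data))
  nm <- names(data)
  if ("time" %in% nm && !("t" %in% nm)) names(data)[nm == "time"] <- "t"
  stopifnot(all(c("t", "x") %in% names(data)))
  tt <- data$t
  if (is.unsorted(tt, strictly = TRUE)) stop("`t` must be strictly increasing", call. = FALSE)
  dts <- diff(tt)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > dt_rel_tol * dt)
    stop("frame interval is not uniform; split the trajectory at the gaps", call. = FALSE)
  out <- tibble::as_tibble(data)
  class(out) <- c("trajectory", class(out))
  attr(out, "dt") <- dt
  out
}

#' @describeIn as_trajectory read a trajectory table from CSV/TSV.
#' @param path file path; the delimiter is sniffed from the header line.
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  as_trajectory(utils::read.table(path, header = TRUE, sep = sep,
                                  comment.char = "#"))
}

trajectory_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- stats::median(diff(traj$t))
  dt
}

#' Time-averaged mean squared displacement
#'
#' The standard overlapping-window estimator
#' \eqn{\widehat\psi(k\,dt) = \mathrm{mean}_n [x_{n+k} - x_n]^2}, with a
#' per-lag variance computed from the spread of the squared displacements
#' and an effective sample size `n_pairs / (2k)` that discounts window
#' overlap (a conservative standard replacement for exact estimator
#' covariances).
#'
#' @param traj a [as_trajectory()] tibble.
#' @param max_lag largest lag in steps (truncated with a warning if beyond
#'   a tenth of the trajectory).
#' @param lags optional explicit integer lags (default: log-spaced).
#' @param n_lags number of log-spaced lags when `lags` is omitted.
#' @return a tibble of class `msd_estimate` with `lag`, `t`, `msd`, `se`,
#'   `n_pairs`, `n_eff`.
#' @export
estimate_msd <- function(traj, max_lag = NULL, lags = NULL, n_lags = 40) {
  dt <- trajectory_dt(traj)
  n <- nrow(traj)
  if (is.null(max_lag)) max_lag <- floor(n / 10)
  if (max_lag > floor(n / 10)) {
    warning("max_lag longer than a tenth of the trajectory; truncated")
    max_lag <- floor(n / 10)
  }
  if (is.null(lags))
    lags <- sort(unique(pmax(1, round(exp(seq(0, log(max_lag), length.out = n_lags))))))
  x <- traj$x
  out <- purrr::map_dfr(lags, function(k) {
    d2 <- (x[(1 + k):n] - x[1:(n - k)])^2
    np <- length(d2)
    n_eff <- max(np / (2 * k), 2)
    tibble::tibble(lag = k, t = k * dt, msd = mean(d2),
                   se = stats::sd(d2) / sqrt(n_eff),
                   n_pairs = np, n_eff = n_eff)
  })
  class(out) <- c("msd_estimate", class(out))
  out
}

#' Pooled MSD over an ensemble of trajectories
#'
#' Averages per-trajectory time-averaged MSD curves at common lags, with
#' standard errors taken across the independent trajectories.  A single
#' record of this MSD family leaves the crossover time poorly identified
#' (the amplitude and `tau0` are nearly degenerate); pooling independent
#' beads is the standard remedy and is what the crossover fit expects.
#'
#' @param trajs a list of [as_trajectory()] tibbles with a common frame
#'   interval.
#' @inheritParams estimate_msd
#' @return a tibble of class `msd_estimate` (per-lag `se` across
#'   trajectories).
#' @export
estimate_msd_ensemble <- function(trajs, max_lag = NULL, lags = NULL, n_lags = 40) {
  stopifnot(is.list(trajs), length(trajs) >= 2)
  curves <- lapply(trajs, estimate_msd, max_lag = max_lag, lags = lags, n_lags = n_lags)
  pooled <- dplyr::bind_rows(curves) |>
    dplyr::group_by(.data$lag, .data$t) |>
    dplyr::summarise(se = stats::sd(.data$msd) / sqrt(dplyr::n()),
                     msd = mean(.data$msd),
                     n_pairs = sum(.data$n_pairs), n_eff = sum(.data$n_eff),
                     .groups = "drop") |>
    dplyr::select("lag", "t", "msd", "se", "n_pairs", "n_eff")
  class(pooled) <- c("msd_estimate", class(pooled))
  pooled
}

#' Fit the viscoelastic crossover MSD to an estimated curve
#'
#' Weighted least squares of \eqn{\log \widehat\psi} against
#' \eqn{\log[A f(t/\tau_0)]} ([visc_f()]) with weights from the per-lag
#' relative standard errors, via Levenberg-Marquardt.  Starting values:
#' `alpha` from the small-lag log-slope, `tau0` from the crossover of the
#' two asymptotes, `A` from the largest lags.  An optional constant
#' `offset` absorbs a localisation-noise plateau.
#'
#' @param curve an [estimate_msd()] result.
#' @param offset include a constant offset term (default FALSE).
#' @return an object of class `msd_fit`: list with `amplitude`, `tau0`,
#'   `alpha`, standard errors, the `nls` object, and flags:
#'   `crossover_in_range` is FALSE (with a warning) when the largest lag
#'   does not reach `10 * tau0` or the smallest decade does not probe below
#'   `tau0`.
#' @export
fit_msd_viscoelastic <- function(curve, offset = FALSE) {
  stopifnot(inherits(curve, "msd_estimate") || all(c("t", "msd", "se") %in% names(curve)))
  tt <- curve$t; yy <- curve$msd
  wls <- 1 / pmax(curve$se / yy, 1e-3)^2
  ns <- max(3, floor(nrow(curve) / 4))
  alpha0 <- min(max(stats::coef(stats::lm(log(yy[1:ns]) ~ log(tt[1:ns])))[2], 0.05), 1)
  slope_end <- stats::coef(stats::lm(log(utils::tail(yy, ns)) ~ log(utils::tail(tt, ns))))[2]
  D_end <- utils::tail(yy, 1) / utils::tail(tt, 1)
  # crossover guess: where the early power law meets the late linear law
  c_early <- yy[1] / tt[1]^alpha0
  tau0_0 <- if (abs(1 - alpha0) > 0.05) (D_end / c_early)^(1 / (alpha0 - 1)) else stats::median(tt)
  tau0_0 <- min(max(tau0_0, min(tt)), max(tt))
  A0 <- D_end * tau0_0
  df <- data.frame(t = tt, ly = log(yy), w = wls)
  # near alpha = 1 the model degenerates (f = y for every tau0); keep the
  # starting point in the interior so the gradient stays full rank
  if (alpha0 > 0.95) { alpha0 <- 0.9; tau0_0 <- stats::median(tt) }
  run_nls <- function(start) {
    if (offset) {
      minpack.lm::nlsLM(ly ~ log(A * visc_f(t / tau0, alpha) + off), data = df,
                        start = c(start, list(off = yy[1] / 10)),
                        lower = c(1e-12, min(tt) / 100, 0.01, 0),
                        upper = c(Inf, max(tt) * 100, 1, Inf),
                        weights = df$w, control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(ly ~ log(A * visc_f(t / tau0, alpha)), data = df,
                        start = start,
                        lower = c(1e-12, min(tt) / 100, 0.01),
                        upper = c(Inf, max(tt) * 100, 1),
                        weights = df$w, control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  grid_start <- function() {
    # profile A analytically on a (tau0, alpha) grid; robust when the data
    # are close to a pure power law and the gradient degenerates
    taus <- exp(seq(log(min(tt) / 2), log(max(tt) * 5), length.out = 25))
    alphas <- seq(0.1, 1, by = 0.05)
    best <- NULL; best_ss <- Inf
    for (ta in taus) for (al in alphas) {
      lf <- log(visc_f(tt / ta, al))
      la <- sum(wls * (log(yy) - lf)) / sum(wls)
      ss <- sum(wls * (log(yy) - la - lf)^2)
      if (ss < best_ss) { best_ss <- ss; best <- list(A = exp(la), tau0 = ta, alpha = al) }
    }
    best
  }
  fit <- tryCatch(run_nls(list(A = A0, tau0 = tau0_0, alpha = alpha0)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    gs <- grid_start()
    gs$alpha <- min(gs$alpha, 0.97)
    fit <- tryCatch(run_nls(gs), error = function(e) NULL)
  }
  if (is.null(fit)) {
    gs <- grid_start()
    cf <- c(A = gs$A, tau0 = gs$tau0, alpha = gs$alpha)
    ses <- rep(NA_real_, 3)
  } else {
    cf <- stats::coef(fit)
    ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  }
  crossover_ok <- (max(tt) >= 10 * cf[["tau0"]]) && (min(tt) <= cf[["tau0"]])
  if (!crossover_ok)
    warning("crossover time lies at the edge of the fitted range; fit flagged unreliable")
  structure(list(amplitude = cf[["A"]], tau0 = cf[["tau0"]], alpha = cf[["alpha"]],
                 offset = if (offset) cf[["off"]] else 0,
                 se = ses, fit = fit, crossover_in_range = crossover_ok,
                 curve = curve),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit: A = %.4g, tau0 = %.4g, alpha = %.4g%s>\n",
              x$amplitude, x$tau0, x$alpha,
              if (!x$crossover_in_range) " [crossover at range edge]" else ""))
  invisible(x)
}

#' Gaussianity check of trajectory increments
#'
#' Standardises the increments \eqn{x(t+\tau) - x(t)} at each probe lag by
#' their empirical standard deviation and compares them to a standard
#' normal: Kolmogorov-Smirnov distance with p-value and excess kurtosis.
#' Default probe lags follow the bead-tracking convention of the memory
#' time and half of it when `tau0` is supplied.
#'
#' @param traj a trajectory tibble.
#' @param taus probe lags (times); default `c(tau0, tau0/2)` or `10 dt`.
#' @param tau0 optional memory time used for the default lags.
#' @param alpha_level significance level for the pass flag.
#' @return a tibble with one row per lag: `tau`, `n`, `ks_stat`, `p_value`,
#'   `excess_kurtosis`, `pass`.
#' @export
check_gaussian_increments <- function(traj, taus = NULL, tau0 = NULL,
                                      alpha_level = 0.01) {
  dt <- trajectory_dt(traj)
  if (is.null(taus))
    taus <- if (!is.null(tau0)) c(tau0, tau0 / 2) else 10 * dt
  x <- traj$x
  purrr::map_dfr(taus, function(tau) {
    k <- max(1, round(tau / dt))
    inc <- x[(1 + k):length(x)] - x[1:(length(x) - k)]
    # thin to independent increments for a calibrated test
    inc <- inc[seq(1, length(inc), by = k)]
    if (length(inc) < 1e3)
      stop(sprintf("need >= 1000 increments at lag %g (have %d)", tau, length(inc)),
           call. = FALSE)
    z <- (inc - mean(inc)) / stats::sd(inc)
    ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
    kur <- mean(z^4) - 3
    tibble::tibble(tau = k * dt, n = length(inc), ks_stat = unname(ks$statistic),
                   p_value = ks$p.value, excess_kurtosis = kur,
                   pass = ks$p.value > alpha_level)
  })
}

#' Drift check with autocorrelation-aware errors
#'
#' Mean one-frame displacement with a confidence interval from a block
#' bootstrap whose block length should exceed twice the memory time, so
#' that correlated increments do not fool the error bar.
#'
#' @param traj a trajectory tibble.
#' @param block_length block size in frames (default `2 tau0 / dt` when
#'   `tau0` is given, else 50).
#' @param tau0 optional memory time.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @return a one-row tibble: `mean_increment`, `se_naive`, `se_block`,
#'   `ci_lo`, `ci_hi`, `unbiased` (does the CI cover 0).
#' @export
check_drift <- function(traj, block_length = NULL, tau0 = NULL,
                        n_boot = 400, conf = 0.95) {
  dt <- trajectory_dt(traj)
  inc <- diff(traj$x)
  n <- length(inc)
  if (n < 1e3) stop("need >= 1000 increments", call. = FALSE)
  if (is.null(block_length))
    block_length <- if (!is.null(tau0)) max(ceiling(2 * tau0 / dt), 10) else 50
  nb <- floor(n / block_length)
  bm <- colMeans(matrix(inc[1:(nb * block_length)], block_length, nb))
  boot <- replicate(n_boot, mean(sample(bm, nb, replace = TRUE)))
  se_block <- stats::sd(boot)
  m <- mean(inc)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  tibble::tibble(mean_increment = m,
                 se_naive = stats::sd(inc) / sqrt(n),
                 se_block = se_block,
                 ci_lo = m - zq * se_block, ci_hi = m + zq * se_block,
                 unbiased = (m - zq * se_block) < 0 & 0 < (m + zq * se_block))
}

#' Empirical splitting probabilities from a long trajectory
#'
#' Implements the fictitious-target protocol of bead-tracking experiments:
#' the trajectory is scanned for admissible starting instants; from each
#' start at position `p`, targets are placed at `p - x0` and `p - x0 + L`
#' (the start sits at relative coordinate `x0`), the trajectory is followed
#' to its first crossing, the indicator \eqn{\eta} (1 when the far target
#' at relative `L` is hit first) is recorded, and the next admitted start
#' must lie at least `spacing` after the crossing, so that successive
#' events are effectively independent (the `2 tau0` rule).
#'
#' @param traj a trajectory tibble.
#' @param L target separation.
#' @param x0s start offsets (each scanned in its own pass).
#' @param spacing minimum time between a crossing and the next start;
#'   use at least twice the memory time.
#' @param follow_duration post-crossing time retained for
#'   [post_fpt_mean()].
#' @return an object of class `empirical_splitting`: tibble `by_x0`
#'   (`x0`, `pi2_hat`, `ci_halfwidth` = 2 SE, `n_events`), tibble `events`
#'   (`x0`, `start_index`, `eta`, `hit_index`), and the post-crossing
#'   segments (relative coordinates) needed for mean curves.
#' @export
empirical_splitting <- function(traj, L, x0s, spacing, follow_duration = 0) {
  dt <- trajectory_dt(traj)
  x <- traj$x
  n <- length(x)
  rms1 <- stats::sd(diff(x))
  if (rms1 > L / 10)
    stop(sprintf(
      "one-frame RMS displacement %.3g exceeds L/10 = %.3g: frame rate too low for this L",
      rms1, L / 10), call. = FALSE)
  sp_steps <- max(1L, ceiling(spacing / dt))
  follow_steps <- if (follow_duration > 0) floor(follow_duration / dt) + 1L else 0L
  all_events <- list(); all_post <- list()
  for (x0 in x0s) {
    stopifnot(x0 > 0, x0 < L)
    idx <- 1L
    ev <- list(); post <- list()
    while (idx <= n - 1L) {
      p <- x[idx]
      sc <- scan_crossing_cpp(x, idx - 1L, p - x0, p - x0 + L)
      if (sc$idx == 0) break
      k <- sc$idx
      ev[[length(ev) + 1L]] <- tibble::tibble(
        x0 = x0, start_index = idx, eta = as.integer(sc$side == 2), hit_index = k)
      if (follow_steps > 0 && k + follow_steps - 1L <= n) {
        seg <- x[k:(k + follow_steps - 1L)] - (p - x0)   # relative frame: targets at 0, L
        post[[length(post) + 1L]] <- list(target = sc$side, seg = seg)
      }
      idx <- k + sp_steps
    }
    all_events[[as.character(x0)]] <- dplyr::bind_rows(ev)
    all_post[[as.character(x0)]] <- post
  }
  events <- dplyr::bind_rows(all_events)
  by_x0 <- events |>
    dplyr::group_by(x0) |>
    dplyr::summarise(pi2_hat = mean(eta),
                     n_events = dplyr::n(),
                     ci_halfwidth = 2 * sqrt(pi2_hat * (1 - pi2_hat) / n_events),
                     .groups = "drop")
  structure(list(by_x0 = by_x0, events = events, post = all_post,
                 dt = dt, L = L, follow_steps = follow_steps),
            class = "empirical_splitting")
}

#' @export
print.empirical_splitting <- function(x, ...) {
  cat("<empirical_splitting>\n")
  print(x$by_x0)
  invisible(x)
}

#' Post-first-passage mean trajectories from empirical events
#'
#' Conditional ensemble means of the post-crossing relative positions
#' (targets at 0 and `L`), per target, with 2-SD-of-the-mean confidence
#' bands.
#'
#' @param es an [empirical_splitting()] result with `follow_duration > 0`.
#' @param x0 which start offset's events to use (default: first).
#' @param min_events per-target minimum; under-sampled targets are flagged
#'   with a warning and dropped.
#' @return a tibble: `target`, `t`, `mean`, `ci_halfwidth`, `n`.
#' @export
post_fpt_mean <- function(es, x0 = NULL, min_events = 50) {
  stopifnot(inherits(es, "empirical_splitting"))
  if (es$follow_steps == 0) stop("empirical_splitting was run without follow_duration", call. = FALSE)
  key <- if (is.null(x0)) names(es$post)[1] else as.character(x0)
  post <- es$post[[key]]
  purrr::map_dfr(1:2, function(tg) {
    segs <- purrr::keep(post, ~ .x$target == tg)
    if (length(segs) < min_events) {
      warning(sprintf("target %d has only %d complete post segments", tg, length(segs)))
      if (length(segs) == 0) return(tibble::tibble())
    }
    M <- do.call(cbind, purrr::map(segs, "seg"))
    tibble::tibble(target = tg, t = (seq_len(nrow(M)) - 1) * es$dt,
                   mean = rowMeans(M),
                   ci_halfwidth = 2 * apply(M, 1, stats::sd) / sqrt(ncol(M)),
                   n = ncol(M))
  })
}

#' Synthetic bead trajectory generator
#'
#' Generates a single long trajectory emulating a tracer bead in a
#' viscoelastic polymer solution: Gaussian, unbiased, stationary
#' increments with the crossover MSD of [msd_viscoelastic()], sampled
#' exactly by circulant embedding, plus optional additive white
#' localisation noise.  Defaults mirror a mid-concentration solution
#' (memory time a few seconds, subdiffusion exponent 1/2).
#'
#' @param amplitude,tau0,alpha viscoelastic MSD parameters.
#' @param duration total time.
#' @param dt frame interval.
#' @param seed integer seed.
#' @param localization_sigma standard deviation of additive i.i.d.
#'   position noise (0 disables; adds a `2 sigma^2` MSD plateau).
#' @return a [as_trajectory()] tibble.
#' @export
gen_synthetic_bead_trajectory <- function(amplitude = 0.02, tau0 = 3, alpha = 0.5,
                                          duration, dt = 0.05, seed = NULL,
                                          localization_sigma = 0) {
  stopifnot(duration > 10 * tau0)
  model <- msd_viscoelastic(amplitude, tau0, alpha)
  n_steps <- ceiling(duration / dt)
  pe <- sample_increment_process(model, n_steps, dt, n_paths = 1, seed = seed)
  x <- pe$positions[, 1]
  if (localization_sigma > 0) x <- x + stats::rnorm(length(x), 0, localization_sigma)
  as_trajectory(tibble::tibble(t = seq(0, by = dt, length.out = length(x)), x = x))
}
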