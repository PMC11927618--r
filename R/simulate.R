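#' Exact sampling of stationary-increment Gaussian paths
#'
#' Samples discrete paths of any [msd_model()] by circulant embedding of the
#' increment autocovariance ([increment_autocov()]): the covariance sequence
#' is embedded in a circulant matrix, diagonalised by FFT, and complex
#' Gaussian noise is coloured by the eigenvalue square roots, giving two
#' independent exact samples per transform.  No discretisation bias: the
#' sampled increments have exactly the requested covariance.
#'
#' @param model an [msd_model()].
#' @param n_steps number of increments per path.
#' @param dt sampling step.
#' @param n_paths number of paths.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param eig_tol relative tolerance on negative circulant eigenvalues:
#'   values below `-eig_tol * max(eig)` abort; small negatives (roundoff)
#'   are clipped to zero with a warning above `1e-12` relative mass.
#' @return a `path_ensemble`: positions matrix of dimension
#'   `(n_steps + 1) x n_paths` (paths start at 0), with attributes `dt`,
#'   `model`, `seed`.
#' @export
sample_increment_process <- function(model, n_steps, dt, n_paths, seed = NULL,
                                     eig_tol = 1e-8) {
  stopifnot(inherits(model, "msd_model"), n_steps >= 2, dt > 0, n_paths >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- increment_autocov(model, dt, 0:n_steps)
  m <- stats::nextn(2 * n_steps, c(2, 3, 5))
  half <- m %/% 2
  r <- numeric(m)
  r[1:(half + 1)] <- g[1:(half + 1)]
  r[(half + 2):m] <- g[half:2]
  lam <- Re(stats::fft(r))
  mx <- max(lam)
  if (min(lam) < -eig_tol * mx)
    stop(sprintf("circulant embedding failed: eigenvalue %.3e of max %.3e",
                 min(lam), mx), call. = FALSE)
  if (min(lam) < -1e-12 * mx)
    warning(sprintf("clipping small negative circulant eigenvalues (min %.2e rel)",
                    min(lam) / mx))
  lam[lam < 0] <- 0
  nb <- ceiling(n_paths / 2)
  E <- matrix(stats::rnorm(m * nb), m, nb) + 1i * matrix(stats::rnorm(m * nb), m, nb)
  Y <- stats::mvfft(sqrt(lam / m) * E)[seq_len(n_steps), , drop = FALSE]
  inc <- cbind(Re(Y), Im(Y))[, seq_len(n_paths), drop = FALSE]
  X <- rbind(0, col_cumsum(inc))
  new_path_ensemble(X, dt, model$name, seed)
}

col_cumsum <- function(m) apply(m, 2, cumsum)

new_path_ensemble <- function(X, dt, model_name, seed) {
  structure(list(positions = X, dt = dt, n_steps = nrow(X) - 1L,
                 n_paths = ncol(X), model = model_name, seed = seed),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("<path_ensemble: %d paths x %d steps, dt = %g, model %s, seed %s>\n",
              x$n_paths, x$n_steps, x$dt, x$model,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' @describeIn sample_increment_process fractional Gaussian noise /
#'   fractional Brownian motion paths (`psi = kappa t^(2H)`) via the same
#'   circulant embedding, which is exact for fGN.
#' @param H,kappa power-law MSD parameters.
#' @export
sample_fgn <- function(H, kappa = 1, n_steps, dt, n_paths, seed = NULL) {
  sample_increment_process(msd_powerlaw(kappa, H), n_steps, dt, n_paths, seed)
}

#' Exact bidiffusive paths by Markovian embedding
#'
#' Samples \eqn{x(t) = W(t) + y(t) - y(0)} with `W` Brownian and `y` a
#' stationary Ornstein-Uhlenbeck process of variance `B/2` and unit
#' relaxation time, using exact discrete updates (no Euler bias), so the
#' MSD is exactly \eqn{t + B(1 - e^{-t})}.  Serves as an independent
#' cross-check of the circulant sampler.
#'
#' @param B transient amplitude (>= 0).
#' @inheritParams sample_increment_process
#' @return a `path_ensemble`.
#' @export
sample_bidiffusive <- function(B, n_steps, dt, n_paths, seed = NULL) {
  stopifnot(B >= 0, n_steps >= 1, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  X <- bidiffusive_paths_cpp(B, as.integer(n_steps), dt, as.integer(n_paths))
  new_path_ensemble(X, dt, sprintf("bidiffusive(B=%g) [exact]", B), seed)
}

#' Rouse-chain first-monomer paths
#'
#' Simulates the first bead of a free Rouse chain by exact normal-mode
#' Ornstein-Uhlenbeck updates (internal modes initialised in equilibrium,
#' centre of mass diffusing), per coordinate.  Returns one `path_ensemble`
#' per coordinate; the monomer MSD per coordinate is [msd_rouse()]'s.
#'
#' @param N number of beads.
#' @param d spatial dimension (1-3); coordinates are independent.
#' @inheritParams sample_increment_process
#' @return for `d = 1` a `path_ensemble`, otherwise a list of `d` of them.
#' @export
sample_rouse <- function(N, d = 1, n_steps, dt, n_paths, seed = NULL) {
  stopifnot(N >= 1, d %in% 1:3)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(d), function(j) {
    X <- rouse_paths_cpp(as.integer(N), as.integer(n_steps), dt, as.integer(n_paths))
    new_path_ensemble(X, dt, sprintf("rouse(N=%d) coord %d [exact modes]", N, j), seed)
  })
  if (d == 1) out[[1]] else out
}

#' Tidy a path ensemble
#'
#' @param x a `path_ensemble`.
#' @param ... unused.
#' @return a long tibble with columns `path`, `t`, `x`.
#' @export
tidy.path_ensemble <- function(x, ...) {
  tibble::tibble(
    path = rep(seq_len(x$n_paths), each = x$n_steps + 1L),
    t = rep(seq(0, by = x$dt, length.out = x$n_steps + 1L), times = x$n_paths),
    x = as.vector(x$positions)
  )
}

#' Empirical MSD of an ensemble
#'
#' Ensemble-averaged squared displacement from the start, with standard
#' errors, at the requested step lags; the master calibration check of
#' every sampler.
#'
#' @param paths a `path_ensemble`.
#' @param lags integer step lags.
#' @param time_average also average over time origins (valid because the
#'   increments are stationary); the standard error then uses an effective
#'   sample size `n_paths * n_steps / (2 lag)` discounting window overlap.
#' @return a tibble with `lag`, `t`, `msd`, `se`.
#' @export
ensemble_msd <- function(paths, lags, time_average = FALSE) {
  stopifnot(inherits(paths, "path_ensemble"), all(lags >= 1), all(lags <= paths$n_steps))
  X <- paths$positions
  purrr::map_dfr(lags, function(k) {
    if (time_average) {
      D2 <- (X[(1 + k):nrow(X), , drop = FALSE] - X[1:(nrow(X) - k), , drop = FALSE])^2
      n_eff <- max(ncol(X) * paths$n_steps / (2 * k), ncol(X))
      tibble::tibble(lag = k, t = k * paths$dt, msd = mean(D2),
                     se = stats::sd(D2) / sqrt(n_eff))
    } else {
      d2 <- (X[k + 1, ] - X[1, ])^2
      tibble::tibble(lag = k, t = k * paths$dt, msd = mean(d2),
                     se = stats::sd(d2) / sqrt(length(d2)))
    }
  })
}

#' First-passage events between two targets
#'
#' Shifts the ensemble so paths start at `x0`, finds for each path the
#' first sampled position at or beyond 0 or `L`, interpolates the crossing
#' time linearly, and (optionally) keeps the post-hit path segment.  Paths
#' reaching neither target within the horizon are reported censored.
#'
#' @param paths a `path_ensemble` (paths starting at 0).
#' @param x0 start position, `0 < x0 < L`.
#' @param L target separation.
#' @param follow_duration time after the hit over which to keep the
#'   trajectory (`0` to skip); only events with a complete post segment
#'   contribute curves.
#' @param censor_warn,censor_max censored-fraction thresholds for a warning
#'   and a hard error.
#' @return an object of class `fp_events`: a list with a tibble `events`
#'   (`path`, `target` (0 = censored), `hit_time`), per-target post-hit
#'   mean accumulators, `dt`, and counts.
#' @export
first_passage_events <- function(paths, x0, L, follow_duration = 0,
                                 censor_warn = 0.01, censor_max = 0.2) {
  stopifnot(inherits(paths, "path_ensemble"), x0 > 0, x0 < L)
  follow_steps <- if (follow_duration > 0) floor(follow_duration / paths$dt) + 1L else 0L
  X <- paths$positions + x0
  res <- fp_batch_cpp(X, 0, L, as.integer(follow_steps))
  events <- tibble::tibble(
    path = seq_len(paths$n_paths),
    target = res$side,
    hit_time = ifelse(res$side > 0, (res$khit - 2 + res$frac) * paths$dt, NA_real_)
  )
  cens <- mean(res$side == 0)
  if (cens > censor_max)
    stop(sprintf("censored fraction %.1f%% exceeds %.0f%%: horizon too short",
                 100 * cens, 100 * censor_max), call. = FALSE)
  if (cens > censor_warn)
    warning(sprintf("censored fraction %.2f%% (horizon may be short)", 100 * cens))
  structure(
    list(events = events, dt = paths$dt, x0 = x0, L = L,
         follow_steps = follow_steps, censored_fraction = cens,
         post = list(
           list(sum = res$post1_sum, sq = res$post1_sq, n = res$post1_n),
           list(sum = res$post2_sum, sq = res$post2_sq, n = res$post2_n))),
    class = "fp_events"
  )
}

#' @export
print.fp_events <- function(x, ...) {
  n_ev <- sum(x$events$target > 0)
  cat(sprintf("<fp_events: %d events (%d censored), x0 = %g, L = %g>\n",
              n_ev, sum(x$events$target == 0), x$x0, x$L))
  invisible(x)
}

#' Monte Carlo splitting statistics
#'
#' Aggregates first-passage events into the splitting-probability estimate
#' \eqn{\hat\pi_2 = \langle \eta \rangle} (the fraction of uncensored paths
#' that reached the far target), its binomial standard error, and the
#' conditional post-hit mean trajectories with per-lag standard errors.
#'
#' @param events an `fp_events` object, or a list of them to pool.
#' @return a `hitting_stats` list: `pi2_hat`, `se`, `n_events`,
#'   `censored_fraction`, and a tibble `mu` with columns `target`, `t`,
#'   `mean`, `se`, `n`.
#' @export
estimate_splitting_mc <- function(events) {
  evs <- if (inherits(events, "fp_events")) list(events) else events
  stopifnot(all(vapply(evs, inherits, logical(1), "fp_events")))
  n2 <- sum(vapply(evs, function(e) sum(e$events$target == 2), numeric(1)))
  n_ev <- sum(vapply(evs, function(e) sum(e$events$target > 0), numeric(1)))
  n_tot <- sum(vapply(evs, function(e) nrow(e$events), numeric(1)))
  if (n_ev < 100) warning("fewer than 100 events; estimates will be noisy")
  pi2 <- n2 / n_ev
  mu <- NULL
  fs <- evs[[1]]$follow_steps
  if (fs > 0) {
    dt <- evs[[1]]$dt
    mu <- purrr::map_dfr(1:2, function(tg) {
      s <- Reduce(`+`, lapply(evs, function(e) e$post[[tg]]$sum))
      q <- Reduce(`+`, lapply(evs, function(e) e$post[[tg]]$sq))
      n <- sum(vapply(evs, function(e) e$post[[tg]]$n, numeric(1)))
      if (n == 0)
        return(tibble::tibble(target = tg, t = numeric(0), mean = numeric(0),
                              se = numeric(0), n = integer(0)))
      m <- s / n
      tibble::tibble(target = tg, t = (seq_len(fs) - 1) * dt, mean = m,
                     se = sqrt(pmax(q / n - m^2, 0) / n), n = as.integer(n))
    })
  }
  structure(list(pi2_hat = pi2, se = sqrt(pi2 * (1 - pi2) / n_ev),
                 n_events = n_ev,
                 censored_fraction = 1 - n_ev / n_tot, mu = mu),
            class = "hitting_stats")
}

#' @export
print.hitting_stats <- function(x, ...) {
  cat(sprintf("<hitting_stats: pi2_hat = %.4f (se %.4f), %d events>\n",
              x$pi2_hat, x$se, x$n_events))
  invisible(x)
}

#' One-call Monte Carlo splitting estimate
#'
#' Streams path generation in batches (to bound memory), detects first
#' passages and pools the statistics.  The sampler is chosen from the
#' model: the exact Markovian embedding for a bidiffusive model, circulant
#' embedding otherwise; `sampler` overrides.
#'
#' @inheritParams sample_increment_process
#' @inheritParams first_passage_events
#' @param sampler `"auto"`, `"circulant"` or `"exact-bidiffusive"`.
#' @param batch_size paths per generation batch.
#' @param censor_warn,censor_max forwarded to [first_passage_events()].
#' @return a `hitting_stats` object.
#' @export
mc_splitting <- function(model, x0, L, n_steps, dt, n_paths, seed = NULL,
                         follow_duration = 0, sampler = c("auto", "circulant",
                                                          "exact-bidiffusive"),
                         batch_size = 500, censor_warn = 0.01, censor_max = 0.2) {
  sampler <- match.arg(sampler)
  if (sampler == "auto")
    sampler <- if (grepl("^bidiffusive", model$name)) "exact-bidiffusive" else "circulant"
  if (!is.null(seed)) set.seed(seed)
  n_batches <- ceiling(n_paths / batch_size)
  evs <- vector("list", n_batches)
  left <- n_paths
  for (b in seq_len(n_batches)) {
    nb <- min(batch_size, left); left <- left - nb
    pe <- if (sampler == "exact-bidiffusive")
      sample_bidiffusive(model$params$B, n_steps, dt, nb)
    else sample_increment_process(model, n_steps, dt, nb)
    evs[[b]] <- withCallingHandlers(
      first_passage_events(pe, x0, L, follow_duration,
                           censor_warn = 1, censor_max = 1),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  out <- estimate_splitting_mc(evs)
  if (out$censored_fraction > censor_max)
    stop(sprintf("censored fraction %.1f%%: horizon too short", 100 * out$censored_fraction),
         call. = FALSE)
  if (out$censored_fraction > censor_warn)
    warning(sprintf("censored fraction %.2f%%", 100 * out$censored_fraction))
  out
}

#' Confined two-target Monte Carlo in two dimensions
#'
#' Walkers start at `(x0, 0)`; absorbing disks of radius `a` sit at the
#' origin and at `(L, 0)`; the motion is reflected specularly at radius `R`
#' about the first target.  Processes: `"bidiffusive"` (per-coordinate MSD
#' \eqn{t + B(1 - e^{-t})}; `B = 0` gives Brownian motion with
#' per-coordinate MSD `t`) or `"rouse"` (first monomer of an `N`-bead
#' chain).  Crossing resolution is guarded: the RMS step must not exceed
#' `a / 3`.
#'
#' @param process `"bidiffusive"` or `"rouse"`.
#' @param x0 start abscissa.
#' @param L target separation.
#' @param a target radius.
#' @param R confinement radius.
#' @param dt time step.
#' @param n_paths number of walkers.
#' @param horizon maximum simulated time before censoring.
#' @param B,N process parameters.
#' @param follow_duration post-hit recording time (projection of the mean
#'   trajectory on the target axis).
#' @param seed optional seed.
#' @return a `hitting_stats` object (post-hit curves carry the mean of the
#'   x-coordinate; `pi1_hat = 1 - pi2_hat`).
#' @export
simulate_confined_fp_2d <- function(process = c("bidiffusive", "rouse"),
                                    x0, L, a, R, dt, n_paths, horizon,
                                    B = 0, N = 1, follow_duration = 0,
                                    seed = NULL) {
  process <- match.arg(process)
  stopifnot(a > 0, L > 2 * a, R > L + a, x0 > a, x0 < L - a)
  step_model <- if (process == "bidiffusive") msd_bidiffusive(B) else msd_rouse(N)
  rms_step <- sqrt(2 * msd_eval(step_model, dt))   # two coordinates
  if (rms_step > a / 3)
    stop(sprintf("RMS step %.3g exceeds a/3 = %.3g: reduce dt", rms_step, a / 3),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  follow_steps <- if (follow_duration > 0) floor(follow_duration / dt) + 1L else 0L
  res <- confined2d_cpp(if (process == "bidiffusive") 0L else 1L,
                        B, as.integer(N), x0, L, a, R, dt,
                        as.integer(ceiling(horizon / dt)),
                        as.integer(n_paths), as.integer(follow_steps))
  n_ev <- sum(res$side > 0)
  pi2 <- sum(res$side == 2) / n_ev
  mu <- NULL
  if (follow_steps > 0) {
    mu <- purrr::map_dfr(1:2, function(tg) {
      n <- if (tg == 1) res$post1_n else res$post2_n
      s <- if (tg == 1) res$post1_x_sum else res$post2_x_sum
      if (n == 0)
        return(tibble::tibble(target = tg, t = numeric(0), mean = numeric(0), n = integer(0)))
      tibble::tibble(target = tg, t = (seq_len(follow_steps) - 1) * dt,
                     mean = s / n, n = as.integer(n))
    })
  }
  structure(list(pi2_hat = pi2, se = sqrt(pi2 * (1 - pi2) / n_ev),
                 n_events = n_ev, censored_fraction = 1 - n_ev / length(res$side),
                 mu = mu, hit_time = res$hit_time),
            class = "hitting_stats")
}

#' Single-target post-hit statistics in two dimensions
#'
#' Runs walkers from distance `L0` towards one absorbing disk (radius `a`
#' at the origin, reflecting circle `R`), recording for each hit the hit
#' angle relative to the approach axis and the subsequent displacement
#' projected on the hit direction.  This is the measurement behind the
#' semi-empirical propagator calibration ([calibrate_semi_empirical()]).
#'
#' @inheritParams simulate_confined_fp_2d
#' @param L0 start distance from the target centre.
#' @return a list with `theta` (hit angles), a tibble `m_curve`
#'   (`t`, `mean`, `se`: mean radial overshoot \eqn{m(t)} beyond the target
#'   radius), `n_events`, `censored`.
#' @export
single_target_post_hit_2d <- function(process = c("bidiffusive", "rouse"),
                                      L0, a, R, dt, n_paths, horizon,
                                      B = 0, N = 1, follow_duration,
                                      seed = NULL) {
  process <- match.arg(process)
  stopifnot(a > 0, L0 > a, R > L0)
  if (!is.null(seed)) set.seed(seed)
  follow_steps <- floor(follow_duration / dt) + 1L
  res <- single_target2d_cpp(if (process == "bidiffusive") 0L else 1L,
                             B, as.integer(N), L0, a, R, dt,
                             as.integer(ceiling(horizon / dt)),
                             as.integer(n_paths), as.integer(follow_steps))
  n <- res$n_events
  if (n == 0) stop("no hits recorded; extend horizon", call. = FALSE)
  m <- res$proj_sum / n - a
  se <- sqrt(pmax(res$proj_sq / n - (res$proj_sum / n)^2, 0) / n)
  list(theta = res$theta,
       m_curve = tibble::tibble(t = (seq_len(follow_steps) - 1) * dt,
                                mean = m, se = se),
       n_events = n, censored = res$n_censored)
}
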