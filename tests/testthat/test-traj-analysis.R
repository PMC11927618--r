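make_traj <- function(x, dt = 0.05) {
  as_trajectory(tibble::tibble(t = seq(0, by = dt, length.out = length(x)), x = x))
}

test_that("trajectory validation enforces uniform sampling", {
  expect_error(as_trajectory(data.frame(t = c(0, 1, 1.5), x = 0:2)), "uniform")
  expect_error(as_trajectory(data.frame(t = c(0, 0, 1), x = 0:2)), "increasing")
  tr <- as_trajectory(data.frame(time = seq(0, 1, by = 0.1), x = rnorm(11)))
  expect_true("t" %in% names(tr))
})

test_that("CSV/TSV round trip preserves the trajectory", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = seq(0, 5, by = 0.05), x = cumsum(rnorm(101)))
  utils::write.csv(df, f, row.names = FALSE)
  tr <- read_trajectory(f)
  expect_equal(tr$x, df$x)
})

test_that("MSD estimator is exact on a ballistic fixture and plateaus on noise", {
  v <- 0.7; dt <- 0.05
  tr <- make_traj(v * seq(0, by = dt, length.out = 4000), dt)
  cv <- estimate_msd(tr, max_lag = 100, lags = c(1, 5, 20, 100))
  expect_equal(cv$msd, (v * cv$t)^2, tolerance = 1e-12)
  # i.i.d. localisation noise: MSD plateau at 2 sigma^2
  set.seed(8)
  sig <- 0.3
  trn <- make_traj(rnorm(20000, 0, sig), dt)
  cvn <- estimate_msd(trn, lags = c(2, 10, 50))
  expect_true(all(abs(cvn$msd - 2 * sig^2) < 4 * cvn$se))
  expect_warning(estimate_msd(make_traj(rnorm(100)), max_lag = 90), "truncated")
})

test_that("MSD of a synthetic diffusive trajectory is recovered with honest errors", {
  tr <- gen_synthetic_bead_trajectory(amplitude = 1, tau0 = 1, alpha = 1,
                                      duration = 2500, dt = 0.05, seed = 9)
  cv <- estimate_msd(tr, lags = c(1, 10, 100))
  expect_true(all(abs(cv$msd - cv$t) < 3 * cv$se))
})

test_that("crossover fit recovers generator parameters from an ensemble", {
  trs <- lapply(1:6, function(i)
    gen_synthetic_bead_trajectory(1, 3, 0.5, duration = 3000, dt = 0.1, seed = 30 + i))
  cv <- estimate_msd_ensemble(trs, max_lag = 600)
  ft <- fit_msd_viscoelastic(cv)
  expect_equal(ft$alpha, 0.5, tolerance = 0.05)
  expect_equal(ft$tau0, 3, tolerance = 0.35)
  expect_equal(ft$amplitude, 1, tolerance = 0.35)
  expect_true(ft$crossover_in_range)
  expect_s3_class(tidy(ft), "tbl_df")
  # alpha ~ 1 degeneracy: Brownian input fits back the diffusive line
  trb <- lapply(1:3, function(i)
    gen_synthetic_bead_trajectory(1, 1, 1, duration = 1500, dt = 0.05, seed = 50 + i))
  ftb <- suppressWarnings(fit_msd_viscoelastic(estimate_msd_ensemble(trb, max_lag = 300)))
  expect_gt(ftb$alpha, 0.9)
})

test_that("a too-short lag range flags the crossover fit", {
  trs <- lapply(1:3, function(i)
    gen_synthetic_bead_trajectory(1, 3, 0.5, duration = 1200, dt = 0.1, seed = 60 + i))
  expect_warning(fit_msd_viscoelastic(estimate_msd_ensemble(trs, max_lag = 150)),
                 "edge of the fitted range")
})

test_that("Gaussianity diagnostics pass Gaussian input and reject Laplace", {
  tr <- gen_synthetic_bead_trajectory(1, 3, 0.5, duration = 4000, dt = 0.05, seed = 10)
  g <- check_gaussian_increments(tr, tau0 = 3)
  expect_identical(nrow(g), 2L)            # probe lags tau0 and tau0/2
  expect_equal(g$tau, c(3, 1.5))
  expect_true(all(g$pass))
  # power: Laplace-increment walk is rejected
  set.seed(11)
  lap <- cumsum(rexp(20000) * sign(runif(20000) - 0.5))
  gl <- check_gaussian_increments(make_traj(lap), taus = 0.05)
  expect_false(any(gl$pass))
  expect_gt(gl$excess_kurtosis[1], 1)
  expect_error(check_gaussian_increments(make_traj(rnorm(100))), "1000")
})

test_that("drift diagnostics cover zero drift and detect imposed drift", {
  tr <- gen_synthetic_bead_trajectory(1, 3, 0.5, duration = 4000, dt = 0.05, seed = 12)
  d0 <- check_drift(tr, tau0 = 3)
  expect_true(d0$unbiased)
  v <- 10 * d0$se_block / 0.05    # drift well above the detection floor
  trd <- make_traj(tr$x + v * tr$t)
  dd <- check_drift(trd, tau0 = 3)
  expect_false(dd$unbiased)
  # correlated increments: blocked and naive errors disagree materially
  trc <- make_traj(sample_bidiffusive(20, 20000, 0.05, 1, seed = 13)$positions[, 1])
  dc <- check_drift(trc, block_length = 200)
  expect_gt(abs(dc$se_block / dc$se_naive - 1), 0.2)
})

test_that("the fictitious-target scan records hand-checkable events", {
  # one upward crossing of p - x0 + L, then too little room for a second event
  x <- c(0, 0.02, 0.05, 0.12, 0.22, 0.35, 0.33, 0.36, 0.38, 0.40)
  tr <- make_traj(x, dt = 1)
  es <- empirical_splitting(tr, L = 0.5, x0s = 0.2, spacing = 2)
  expect_identical(nrow(es$events), 1L)
  expect_identical(es$events$eta, 1L)       # upper target hit first
  expect_identical(es$by_x0$pi2_hat, 1)
  expect_identical(es$by_x0$n_events, 1L)
  # resolution guard
  expect_error(empirical_splitting(make_traj(c(0, 1, 0, 1, 0, 1)), L = 2, x0s = 1,
                                   spacing = 1), "frame rate")
})

test_that("empirical splitting on synthetic diffusive data matches x0/L", {
  tr <- gen_synthetic_bead_trajectory(1, 1, 1, duration = 6000, dt = 0.05, seed = 14)
  L <- 3
  es <- empirical_splitting(tr, L = L, x0s = c(0.75, 1.5), spacing = 2,
                            follow_duration = 3)
  for (i in seq_len(nrow(es$by_x0))) {
    row <- es$by_x0[i, ]
    expect_lt(abs(row$pi2_hat - row$x0 / L), 1.5 * row$ci_halfwidth + 0.02)
  }
  pm <- suppressWarnings(post_fpt_mean(es, x0 = 0.75))
  flat1 <- pm[pm$target == 1 & pm$t > 0.2, ]
  expect_true(all(abs(flat1$mean) < 1.5 * flat1$ci_halfwidth + 0.05 * L))
})

test_that("the generator produces unbiased Gaussian data with the requested MSD", {
  pe <- sample_increment_process(msd_viscoelastic(1, 3, 0.5), 3000, 0.05, 200, seed = 15)
  em <- ensemble_msd(pe, c(5, 50, 500), time_average = TRUE)
  th <- msd_eval(msd_viscoelastic(1, 3, 0.5), em$t)
  expect_true(all(abs(em$msd - th) < 3 * em$se + 0.01 * th))
  # localisation noise adds a 2 sigma^2 plateau
  trn <- gen_synthetic_bead_trajectory(1, 3, 0.5, duration = 2000, dt = 0.05,
                                       seed = 16, localization_sigma = 0.5)
  cv <- estimate_msd(trn, lags = 1)
  expect_equal(cv$msd, msd_eval(msd_viscoelastic(1, 3, 0.5), 0.05) + 2 * 0.25,
               tolerance = 0.1)
})
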