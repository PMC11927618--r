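# Sampler exactness is checked against closed-form moments (3-standard-error
# bands under fixed seeds); first-passage bookkeeping against hand-built
# fixture paths.

fixture_ensemble <- function(rows, dt = 1) {
  X <- do.call(cbind, rows)
  memfp:::new_path_ensemble(X, dt, "fixture", seed = NULL)
}

test_that("fGN increments have the exact autocovariance", {
  pe <- sample_fgn(H = 0.75, kappa = 1, n_steps = 3000, dt = 0.01, n_paths = 60, seed = 1)
  inc <- diff(pe$positions)
  r1 <- cor(as.vector(inc[-nrow(inc), ]), as.vector(inc[-1, ]))
  n_eff <- length(inc) / 2   # conservative for correlated series
  expect_lt(abs(r1 - (2^(2 * 0.75) - 2) / 2), 3 / sqrt(n_eff))
  # H = 1/2: independent increments
  pe2 <- sample_fgn(H = 0.5, kappa = 1, n_steps = 3000, dt = 0.01, n_paths = 40, seed = 2)
  inc2 <- diff(pe2$positions)
  r0 <- cor(as.vector(inc2[-nrow(inc2), ]), as.vector(inc2[-1, ]))
  expect_lt(abs(r0), 3 / sqrt(length(inc2)))
})

test_that("every sampler reproduces its model MSD over three decades", {
  cases <- list(
    list(pe = sample_fgn(0.4, 1, 4000, 0.01, 300, seed = 3), m = msd_powerlaw(H = 0.4)),
    list(pe = sample_increment_process(msd_bidiffusive(10), 4000, 0.01, 300, seed = 4),
         m = msd_bidiffusive(10)),
    list(pe = sample_bidiffusive(10, 4000, 0.01, 300, seed = 5), m = msd_bidiffusive(10)),
    list(pe = sample_increment_process(msd_viscoelastic(1, 3, 0.5), 4000, 0.01, 300, seed = 6),
         m = msd_viscoelastic(1, 3, 0.5)),
    list(pe = sample_rouse(80, 1, 4000, 0.01, 300, seed = 7), m = msd_rouse(80))
  )
  for (cs in cases) {
    em <- ensemble_msd(cs$pe, c(4, 40, 400, 4000), time_average = TRUE)
    th <- msd_eval(cs$m, em$t)
    expect_true(all(abs(em$msd - th) < 3 * em$se + 0.01 * th), info = cs$m$name)
  }
})

test_that("sampling is bit-reproducible under a seed", {
  a <- sample_fgn(0.6, 1, 500, 0.01, 20, seed = 99)
  b <- sample_fgn(0.6, 1, 500, 0.01, 20, seed = 99)
  expect_identical(a$positions, b$positions)
  r1 <- sample_rouse(20, 1, 200, 0.05, 10, seed = 7)
  r2 <- sample_rouse(20, 1, 200, 0.05, 10, seed = 7)
  expect_identical(r1$positions, r2$positions)
})

test_that("exact and circulant bidiffusive samplers agree on splitting", {
  m <- msd_bidiffusive(10)
  s1 <- mc_splitting(m, 0.208 * 20, 20, n_steps = 4000, dt = 0.1, n_paths = 1500,
                     seed = 11, sampler = "exact-bidiffusive")
  s2 <- mc_splitting(m, 0.208 * 20, 20, n_steps = 4000, dt = 0.1, n_paths = 1500,
                     seed = 12, sampler = "circulant")
  z <- abs(s1$pi2_hat - s2$pi2_hat) / sqrt(s1$se^2 + s2$se^2)
  expect_lt(z, 3)
})

test_that("first-passage detection interpolates hand-checkable crossings", {
  # path crossing the upper target between steps 2 and 3 (positions relative to 0)
  up <- c(0.208, 0.4, 1.02, 1.1) - 0.208      # ensemble paths start at 0
  lo <- c(0, -0.1, -0.25, 0.1)
  stay <- c(0, 0.05, 0.1, 0.15)
  pe <- fixture_ensemble(list(up, lo, stay), dt = 1)
  ev <- suppressWarnings(first_passage_events(pe, x0 = 0.208, L = 1, censor_max = 0.5))
  expect_identical(ev$events$target, c(2L, 1L, 0L))
  # linear interpolation between x = 0.4 and 1.02 (started at 0.208 + path)
  frac <- (1 - (0.4)) / (1.02 - 0.4)
  expect_equal(ev$events$hit_time[1], 1 + frac)
  frac1 <- (0 - (0.208 - 0.1)) / ((0.208 - 0.25) - (0.208 - 0.1))
  expect_equal(ev$events$hit_time[2], 1 + frac1)
  expect_equal(ev$censored_fraction, 1 / 3)
})

test_that("censoring thresholds warn and abort", {
  slow <- replicate(20, c(0, cumsum(rep(1e-4, 30))), simplify = FALSE)
  pe <- fixture_ensemble(slow)
  expect_error(first_passage_events(pe, 0.5, 1), "censored")
  one_fast <- c(list(c(0, rep(0.6, 30))), replicate(15, c(0, cumsum(rep(1e-4, 30))),
                                                    simplify = FALSE))
  expect_error(first_passage_events(fixture_ensemble(one_fast), 0.5, 1, censor_max = 0.2),
               "censored")
})

test_that("Brownian Monte Carlo recovers pi2 = x0/L and flat post-hit means", {
  m <- msd_powerlaw(kappa = 1, H = 0.5)
  st <- mc_splitting(m, 0.3, 1, n_steps = 4000, dt = 0.005, n_paths = 3000,
                     seed = 21, follow_duration = 2)
  expect_lt(abs(st$pi2_hat - 0.3), 3 * st$se)
  # the sampled hit position overshoots the target by O(one RMS step), so the
  # flatness band allows that discretisation offset
  over <- sqrt(0.005)
  mu <- st$mu
  m1 <- mu[mu$target == 1 & mu$t > 0.1, ]
  m2 <- mu[mu$target == 2 & mu$t > 0.1, ]
  expect_true(all(abs(m1$mean) < 3 * m1$se + over))
  expect_true(all(abs(m2$mean - 1) < 3 * m2$se + over))
})

test_that("splitting statistics validate inputs and flag empty targets", {
  skinny <- fixture_ensemble(list(c(0, 0.9), c(0, 0.85)))
  ev <- suppressWarnings(first_passage_events(skinny, 0.208, 1, follow_duration = 0))
  st <- suppressWarnings(estimate_splitting_mc(ev))
  expect_identical(st$pi2_hat, 1)
  expect_identical(st$n_events, 2)
})

test_that("confined 2D runs respect symmetry and the step-resolution guard", {
  expect_error(
    simulate_confined_fp_2d("bidiffusive", x0 = 10, L = 40, a = 1, R = 90,
                            dt = 1, n_paths = 10, horizon = 10, B = 0),
    "RMS step")
  st <- simulate_confined_fp_2d("bidiffusive", x0 = 6, L = 12, a = 1, R = 25,
                                dt = 0.05, n_paths = 300, horizon = 4e4, B = 0,
                                seed = 5)
  expect_lt(abs(st$pi2_hat - 0.5), 3 * st$se)
})

test_that("single-target calibration runs recover the memory-free baseline", {
  s <- single_target_post_hit_2d("bidiffusive", L0 = 10, a = 1, R = 22, dt = 0.05,
                                 n_paths = 600, horizon = 4e4, B = 0,
                                 follow_duration = 10, seed = 6)
  expect_gte(s$n_events, 500)
  late <- s$m_curve[s$m_curve$t > 2, ]
  expect_true(all(abs(late$mean) < 3 * late$se + 0.1))
  ang <- fit_angle_distribution(s$theta)
  expect_lt(ang$kappa_angle, 0.6)  # weak geometric concentration only
})
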