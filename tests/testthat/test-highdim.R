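test_that("the free propagator is a normalised Gaussian product", {
  m <- msd_powerlaw(kappa = 2, H = 0.5)   # psi = 2Dt with D = 1
  # peak value in d = 2
  expect_equal(free_propagator(m, c(0, 0), c(0, 0), 3), 1 / (2 * pi * 6))
  # heat kernel comparison at a probe point
  r <- c(1, -2); t <- 0.7
  expect_equal(free_propagator(m, r, c(0, 0), t),
               exp(-sum(r^2) / (4 * t)) / (4 * pi * t), tolerance = 1e-12)
  # normalisation over the plane by polar quadrature
  rr <- seq(0, 60, length.out = 4000)
  dens <- vapply(rr, function(q) free_propagator(m, c(q, 0), c(0, 0), 5), numeric(1))
  I <- 2 * pi * sum(rr * dens) * (rr[2] - rr[1])
  expect_equal(I, 1, tolerance = 1e-5)
  expect_error(free_propagator(m, r, c(0, 0), 0), "positive")
})

test_that("splitting_from_h reduces algebraically", {
  h <- matrix(c(1.3, 0.2, 0.2, 1.3), 2, 2)
  expect_equal(splitting_from_h(h)$pi1, 0.5)
  h2 <- matrix(c(2, 0, 0, 1), 2, 2)    # h11 = 2, h22 = 1, off-diagonals 0
  expect_equal(splitting_from_h(h2)$pi1, 1 / 3)
  expect_equal(splitting_from_h(h2)$pi2, 2 / 3)
  expect_error(splitting_from_h(matrix(c(1, 1, 1, 1), 2, 2)), "degenerate")
})

test_that("h matrix has exchange symmetry for symmetric problems", {
  pb <- highdim_problem(2, r0 = c(20, 0), r1 = c(0, 0), r2 = c(40, 0), a = 1,
                        model = msd_bidiffusive(0))
  h <- h_matrix(pb, propagator_markovian())
  expect_equal(h[1, 1], h[2, 2], tolerance = 1e-10)
  expect_equal(h[1, 2], h[2, 1], tolerance = 1e-10)
  expect_equal(splitting_from_h(h)$pi1, 0.5, tolerance = 1e-10)
  # swapping the targets swaps the probabilities
  pb2 <- highdim_problem(2, r0 = c(10, 0), r1 = c(0, 0), r2 = c(40, 0), a = 1,
                         model = msd_bidiffusive(0))
  pb2s <- highdim_problem(2, r0 = c(10, 0), r1 = c(40, 0), r2 = c(0, 0), a = 1,
                          model = msd_bidiffusive(0))
  s <- splitting_highdim(pb2); ss <- splitting_highdim(pb2s)
  expect_equal(s$pi1, ss$pi2, tolerance = 1e-9)
})

test_that("the 1D h-matrix route agrees with the self-consistent solver", {
  sol <- solve_splitting(msd_powerlaw(H = 0.4), 0.208, 1)
  pb <- highdim_problem(1, r0 = 0.208, r1 = 0, r2 = 1, a = 0,
                        model = msd_powerlaw(H = 0.4))
  prop <- propagator_semi_empirical(
    m1 = function(t) mu_at(sol, t, 1),
    m2 = function(t) -(mu_at(sol, t, 2) - 1))
  out <- splitting_highdim(pb, prop)
  expect_lt(abs(out$pi2 - sol$pi2), 1e-2)
  # Brownian 1D: the h route recovers x0/L
  pbb <- highdim_problem(1, r0 = 0.3, r1 = 0, r2 = 1, a = 0,
                         model = msd_powerlaw(kappa = 2, H = 0.5))
  outb <- splitting_highdim(pbb, propagator_semi_empirical())
  expect_lt(abs(outb$pi2 - 0.3), 1e-2)
})

test_that("the angle-distribution MLE recovers known samples", {
  set.seed(42)
  # uniform angles: concentration compatible with zero
  u <- runif(5000, -pi, pi)
  fu <- fit_angle_distribution(u)
  expect_lt(fu$kappa_angle, 3 / sqrt(5000 / 2))
  # von Mises sample with kappa = 2 via rejection sampling (independent oracle)
  rvm <- function(n, kappa, mu = 0.7) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- runif(2 * n, -pi, pi)
      keep <- runif(2 * n) < exp(kappa * (cos(x - mu) - 1))
      out <- c(out, x[keep])
    }
    out[1:n]
  }
  sm <- rvm(10000, 2)
  fv <- fit_angle_distribution(sm)
  expect_lt(abs(fv$kappa_angle - 2) / 2, 0.15)
  expect_lt(abs(fv$theta0 - 0.7), 0.1)
  # mirror-symmetric sample: location at the symmetry axis
  th <- c(rvm(4000, 1.5, 0.3), 0.6 - rvm(4000, 1.5, 0.3))
  ft <- fit_angle_distribution(th)
  expect_lt(abs(ft$theta0 - 0.3), 0.05)
  # degenerate sample: capped with warning
  expect_warning(fd <- fit_angle_distribution(rep(1, 300)), "capped")
  expect_equal(fd$kappa_angle, 50)
})

test_that("semi-empirical calibration beats the baseline for a recoiling process", {
  s <- single_target_post_hit_2d("bidiffusive", L0 = 12, a = 1, R = 25, dt = 0.004,
                                 n_paths = 800, horizon = 2e4, B = 10,
                                 follow_duration = 20, seed = 42)
  expect_gte(s$n_events, 500)
  # recoil toward the start: positive projection overshoot at intermediate lags
  mid <- s$m_curve[s$m_curve$t > 2 & s$m_curve$t < 15, ]
  expect_true(all(mid$mean > 0))
  pb <- highdim_problem(2, r0 = c(5, 0), r1 = c(0, 0), r2 = c(12, 0), a = 1,
                        model = msd_bidiffusive(10))
  prop <- calibrate_semi_empirical(pb, s)
  expect_identical(prop$mode, "semi_empirical")
  expect_equal(prop$m[[1]](0), 0)
  se_pi <- splitting_highdim(pb, prop)
  bl_pi <- splitting_highdim(pb)
  mc <- simulate_confined_fp_2d("bidiffusive", x0 = 5, L = 12, a = 1, R = 25,
                                dt = 0.004, n_paths = 500, horizon = 2e4, B = 10,
                                seed = 43)
  expect_lt(abs(se_pi$pi2 - mc$pi2_hat), 3 * mc$se + 0.03)
  # memory pulls the walker back to the closer target: pi2 below the baseline
  expect_lt(mc$pi2_hat, bl_pi$pi2)
  expect_error(calibrate_semi_empirical(pb, list(n_events = 10)), ">= 500")
})

test_that("problem construction rejects invalid geometry", {
  m <- msd_bidiffusive(0)
  expect_error(highdim_problem(2, c(1, 0), c(0, 0), c(1.5, 0), a = 1, model = m),
               "overlap")
  expect_error(highdim_problem(2, c(0.5, 0), c(0, 0), c(40, 0), a = 1, model = m),
               "inside a target")
})
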