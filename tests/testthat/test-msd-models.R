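test_that("power-law MSD evaluates and validates", {
  m <- msd_powerlaw(kappa = 1, H = 0.4)
  expect_equal(msd_eval(m, 4), 4^0.8)
  expect_equal(msd_powerlaw(kappa = 2, H = 0.5)$psi(3), 2 * 3)  # 2Dt
  expect_equal(msd_powerlaw(H = 0.6)$H_inf, 0.6)
  expect_error(msd_powerlaw(H = 1.2), "between 0 and 1")
  expect_error(msd_powerlaw(kappa = -1, H = 0.5), "positive")
})

test_that("bidiffusive MSD has the stated limits", {
  m <- msd_bidiffusive(10)
  expect_equal(msd_eval(m, 20), 20 + 10 * (1 - exp(-20)), tolerance = 1e-12)
  # short-time diffusivity 1 + B
  expect_equal(msd_eval(m, 1e-8) / 1e-8, 11, tolerance = 1e-6)
  expect_equal(msd_eval(msd_bidiffusive(0), 3.7), 3.7)
  expect_error(msd_bidiffusive(-1), "non-negative")
})

test_that("viscoelastic crossover function reduces and scales correctly", {
  # alpha = 1 is exactly simple diffusion: f(y) = y
  y <- 10^seq(-6, 6, length.out = 40)
  expect_equal(visc_f(y, 1), y, tolerance = 1e-12)
  m1 <- msd_viscoelastic(2, 5, 1)
  m2 <- msd_powerlaw(kappa = 2 / 5, H = 0.5)
  tt <- 10^seq(-4, 5, length.out = 30)
  expect_equal(msd_eval(m1, tt), msd_eval(m2, tt), tolerance = 1e-10)
  # small-y branch: expanding the lower incomplete gamma, f ~ y^alpha / Gamma(1 + alpha)
  a <- 0.5
  ysm <- 1e-6
  expect_equal(visc_f(ysm, a), ysm^a / gamma(1 + a), tolerance = 1e-4)
  slope <- (log(visc_f(2e-5, a)) - log(visc_f(1e-5, a))) / log(2)
  expect_equal(slope, a, tolerance = 1e-3)
  expect_identical(visc_f(0, 0.5), 0)
  expect_error(msd_viscoelastic(1, 1, 1.5), "0, 1")
})

test_that("Rouse monomer MSD has free-monomer, subdiffusive and diffusive regimes", {
  expect_equal(msd_eval(msd_rouse(1), 2.5), 5)
  m <- msd_rouse(80)
  # long-time: centre-of-mass diffusion 2t/N dominates
  expect_equal(msd_eval(m, 1e7) / (2 * 1e7 / 80), 1, tolerance = 1e-3)
  # intermediate-time exponent: minimum local log-slope near 1/2
  tt <- exp(seq(log(0.05), log(650), length.out = 150))
  sl <- diff(log(msd_eval(m, tt))) / diff(log(tt))
  expect_lt(abs(min(sl) - 0.5), 0.05)
  expect_error(msd_rouse(0), "positive integer")
})

test_that("all shipped models satisfy psi(0) = 0, strict increase and the declared tail", {
  models <- list(msd_powerlaw(H = 0.34), msd_powerlaw(H = 0.6),
                 msd_bidiffusive(10), msd_viscoelastic(1, 3, 0.5), msd_rouse(20))
  for (m in models) {
    expect_identical(msd_eval(m, 0), 0)
    tc <- characteristic_time(m, 1)
    tt <- tc * 10^seq(-6, 6, length.out = 120)
    ps <- msd_eval(m, tt)
    expect_true(all(diff(ps) > 0), info = m$name)
    # psi(t) / (kappa t^{2H}) -> 1 at 1e3-1e6 characteristic times
    tail_ratio <- msd_eval(m, 1e6 * tc) / (m$kappa * (1e6 * tc)^(2 * m$H_inf))
    expect_equal(tail_ratio, 1, tolerance = 0.05, info = m$name)
  }
})

test_that("conditional-mean weight M matches closed forms", {
  bro <- msd_powerlaw(kappa = 2, H = 0.5)
  tt <- 10^seq(-3, 3, length.out = 11)
  expect_equal(correlation_M(bro, tt, rep(1.3, 11)), rep(1, 11), tolerance = 1e-12)
  fbm <- msd_powerlaw(H = 0.4)
  expect_equal(correlation_M(fbm, 5, 5), 2^(2 * 0.4 - 1), tolerance = 1e-12)
  expect_equal(correlation_M(msd_bidiffusive(3), 2, 1e-12), 1, tolerance = 1e-9)
  expect_error(correlation_M(bro, 0, 1), "singular")
})

test_that("increment autocovariance telescopes back to the MSD", {
  models <- list(msd_powerlaw(H = 0.34), msd_powerlaw(kappa = 2, H = 0.5),
                 msd_bidiffusive(10), msd_viscoelastic(1, 3, 0.5), msd_rouse(20))
  for (m in models) {
    dt <- characteristic_time(m, 1) / 50
    n <- 64
    cc <- increment_autocov(m, dt, 0:n)
    expect_equal(cc[1], msd_eval(m, dt), info = m$name)
    # Var(sum of n increments) = sum over pairs of c(|j-k|) must equal psi(n dt)
    var_sum <- n * cc[1] + 2 * sum((n - 1:(n - 1)) * cc[2:n])
    expect_equal(var_sum, msd_eval(m, n * dt), tolerance = 1e-8, info = m$name)
  }
  # closed forms: Brownian increments independent, fGN second difference
  expect_equal(increment_autocov(msd_powerlaw(kappa = 2, H = 0.5), 0.1, 1:5),
               rep(0, 5), tolerance = 1e-14)
  H <- 0.7; dt <- 0.2; k <- 3
  expect_equal(increment_autocov(msd_powerlaw(H = H), dt, k),
               dt^(2 * H) / 2 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + (k - 1)^(2 * H)))
})

test_that("characteristic time inverts the MSD", {
  expect_equal(characteristic_time(msd_powerlaw(kappa = 2, H = 0.5), 3), 9 / 2)
  H <- 0.4
  expect_equal(characteristic_time(msd_powerlaw(H = H), 2), (4)^(1 / (2 * H)),
               tolerance = 1e-9)
  # bidiffusive B = 10, L = 20: root of t + 10(1 - e^-t) = 400
  oracle <- uniroot(function(t) t + 10 * (1 - exp(-t)) - 400, c(1, 1000), tol = 1e-10)$root
  expect_equal(characteristic_time(msd_bidiffusive(10), 20), oracle, tolerance = 1e-6)
})

test_that("tabulated models interpolate and extrapolate with the declared tail", {
  src <- msd_viscoelastic(1, 3, 0.5)
  tt <- 10^seq(-2, 3, length.out = 60)
  tab <- msd_tabulated(data.frame(t = tt, psi = msd_eval(src, tt)))
  probe <- 10^seq(-1.7, 2.7, length.out = 17)
  expect_equal(msd_eval(tab, probe), msd_eval(src, probe), tolerance = 5e-3)
  expect_equal(tab$H_inf, 0.5, tolerance = 0.02)
  expect_error(msd_tabulated(data.frame(t = c(1, 1), psi = c(1, 2))), "increasing")
})

test_that("YAML model specs round-trip", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("type: viscoelastic\namplitude: 2\ntau0: 1.5\nalpha: 0.7", f)
  m <- read_msd_model(f)
  expect_equal(msd_eval(m, 4), 2 * visc_f(4 / 1.5, 0.7))
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("type: powerlaw\nH: 0.6", f2)
  expect_equal(read_msd_model(f2)$H_inf, 0.6)
})
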