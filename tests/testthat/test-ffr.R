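test_that("moving cycle average matches closed forms and an oversampled oracle", {
  t <- seq(0, 10, by = 0.02)
  const <- waveform_record(t, rep(3.7, length(t)), "Pa")
  expect_equal(cycle_average(const, 0.8, c(0, 1.234, 9.2)), rep(3.7, 3))
  # sinusoid of period tau averages to its mean from any start
  tau <- 0.833
  dense_t <- seq(0, 10, by = 0.0005)
  sine <- waveform_record(dense_t, 5 + 2 * sin(2 * pi * dense_t / tau), "Pa")
  starts <- c(0, 0.1, 0.37, 4.2, 9.1)
  expect_equal(cycle_average(sine, tau, starts), rep(5, length(starts)),
               tolerance = 1e-6)
  # random piecewise-linear record versus 10x-oversampled Riemann sums
  set.seed(31)
  rec <- waveform_record(t, 100 + cumsum(rnorm(length(t))), "Pa")
  for (t0 in c(0, 1.01, 5.003)) {
    tg <- seq(t0, t0 + 0.8, length.out = 4001)
    oracle <- mean(stats::approx(rec$t, rec$x, tg)$y[-1] / 2 +
                     stats::approx(rec$t, rec$x, tg)$y[-4001] / 2)
    expect_equal(cycle_average(rec, 0.8, t0), oracle, tolerance = 1e-6)
  }
  expect_error(cycle_average(const, 0.8, 9.5), "exceeds")
})

test_that("FFR equals the designed ratio for proportional records", {
  pr <- gen_paired_record(0.83, jitter = 0.02, seed = 8)
  res <- compute_ffr(pr$P0, pr$P1, tau = 1 / 1.2)
  expect_equal(res$ffr, 0.83, tolerance = 1e-6)
  # identical records give FFR = 1 regardless of waveform shape
  res1 <- compute_ffr(pr$P0, pr$P0, tau = 1 / 1.2)
  expect_equal(res1$ffr, 1, tolerance = 1e-12)
  # auto period estimation gives the same statistic
  res_auto <- compute_ffr(pr$P0, pr$P1, tau = "auto")
  expect_equal(res_auto$ffr, 0.83, tolerance = 1e-3)
})

test_that("windowed minimum agrees with a brute-force dense-grid oracle", {
  # time-varying designed ratio dipping once
  dip <- function(t) 0.9 - 0.15 * exp(-((t - 8) / 1.2)^2)
  pr <- gen_paired_record(dip, n_cycles = 20L, seed = 12)
  tau <- 1 / 1.2
  res <- compute_ffr(pr$P0, pr$P1, tau)
  expect_equal(res$ffr, brute_force_ffr(pr$P0, pr$P1, tau),
               tolerance = 1e-4)
  # the minimum is attained near the dip
  expect_lt(abs(res$t_min + tau / 2 - 8), 1.5)
})

test_that("FFR is invariant to units, common rescaling, shift and resampling", {
  pr <- gen_paired_record(0.74, seed = 21)
  tau <- 1 / 1.2
  f0 <- compute_ffr(pr$P0, pr$P1, tau)$ffr
  # common positive rescaling (equivalently mmHg vs Pa ingestion)
  P0s <- waveform_record(pr$P0$t, pr$P0$x / 133.322, "mmHg")
  P1s <- waveform_record(pr$P1$t, pr$P1$x / 133.322, "mmHg")
  expect_equal(compute_ffr(P0s, P1s, tau)$ffr, f0, tolerance = 1e-12)
  # common time shift
  P0t <- waveform_record(pr$P0$t + 11.3, pr$P0$x, "Pa")
  P1t <- waveform_record(pr$P1$t + 11.3, pr$P1$x, "Pa")
  expect_equal(compute_ffr(P0t, P1t, tau)$ffr, f0, tolerance = 1e-12)
  # resampling onto a 2x-finer grid
  resample <- function(rec) {
    tg <- seq(rec$t[1], rec$t[length(rec$t)],
              by = min(diff(rec$t)) / 2)
    waveform_record(tg, stats::approx(rec$t, rec$x, tg)$y, "Pa")
  }
  f2 <- compute_ffr(resample(pr$P0), resample(pr$P1), tau)$ffr
  expect_equal(f2, f0, tolerance = 1e-4)
})

test_that("FFR recovery on noisy jittered records is unbiased within 0.01", {
  for (f in c(0.6, 0.8, 0.95)) {
    est <- vapply(1:50, function(s) {
      pr <- gen_paired_record(f, n_cycles = 25L, jitter = 0.03,
                              noise_sd = 0.6, seed = 5000 + s)
      compute_ffr(pr$P0, pr$P1, tau = 1 / 1.2)$ffr
    }, numeric(1))
    expect_lt(abs(stats::median(est) - f), 0.01)
  }
})

test_that("pressure ratio evaluates both algebraic forms", {
  expect_equal(pressure_ratio(0, 120), 1)
  expect_equal(pressure_ratio(0, 120, printed_form = TRUE), 1)
  expect_equal(pressure_ratio(4, 100), 0.96)
  expect_equal(pressure_ratio(4, 100, printed_form = TRUE), 100 / 96)
  # exact algebraic identity of the default form
  expect_equal(pressure_ratio(4, 100) * 100 + 4, 100)
  expect_error(pressure_ratio(100, 100), "beta > pi_star")
  expect_error(pressure_ratio(120, 100), "beta > pi_star")
})

test_that("first-order error propagation matches finite differences", {
  expect_equal(propagate_error(0, 4, 100), 0)
  # frozen direct evaluation at the order-of-magnitude reference inputs
  expect_equal(propagate_error(1, 4, 100, R = 1), 400 / 9216)
  expect_equal(400 / 9216, 0.0434, tolerance = 1e-3)
  # attenuation limit for beta >> pi_star: eps_R ~ eps_pi * pi/beta
  expect_equal(propagate_error(1, 4, 1e4, R = 1), 4 / 1e4,
               tolerance = 1e-3)
  # finite-difference check against direct recomputation of R
  beta <- 100; pi0 <- 4
  R0 <- pressure_ratio(pi0, beta, printed_form = TRUE)
  fd_resid <- vapply(c(1e-3, 5e-4), function(eps) {
    R1 <- pressure_ratio(pi0 * (1 + eps), beta, printed_form = TRUE)
    fd <- (R1 - R0) / R0
    abs(fd - propagate_error(eps, pi0, beta, R = R0))
  }, numeric(1))
  # residual is O(eps^2): halving eps quarters it
  expect_lt(fd_resid[1], 1e-3^2 * 10)
  expect_gt(fd_resid[1] / fd_resid[2], 3)
  expect_error(propagate_error(1e-4, 4, 4), "differ")
})
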