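test_that("anchor calibration solves the correlation coefficients exactly", {
  anchors <- data.frame(severity = c(0.583, 0.63), reynolds = 1268,
                        pi = c(4.03, 4.93))
  m <- calibrate_anchors(anchors)
  # independent 2x2 linear solve
  cf <- solve_two_anchors(anchors)
  expect_equal(m$Kv, cf[1], tolerance = 1e-12)
  expect_equal(m$kt, cf[2], tolerance = 1e-12)
  # anchors reproduced exactly by construction
  expect_equal(pi_steady(0.583, 1268, m), 4.03, tolerance = 1e-12)
  expect_equal(pi_steady(0.63, 1268, m), 4.93, tolerance = 1e-12)
  expect_equal(attr(m, "residual_rms"), 0, tolerance = 1e-12)
  # viscous/expansion decomposition of the fitted drop
  expect_equal(m$Kv / 1268 +
                 (m$kt / 2) * (0.583 / (1 - 0.583))^2, 4.03,
               tolerance = 1e-12)
  # degenerate and underdetermined anchor sets are refused
  expect_error(calibrate_anchors(anchors[1, ]), "at least 2")
  same_s <- data.frame(severity = 0.6, reynolds = c(1000, 2000),
                       pi = c(4, 5))
  expect_error(calibrate_anchors(same_s), "distinct severities")
})

test_that("calibration recovers known coefficients from redundant anchors", {
  true_m <- pressure_drop_model(Kv = 2100, kt = 1.4)
  S <- c(0.45, 0.5, 0.583, 0.63, 0.7)
  Re <- c(900, 1268, 1268, 1500, 1800)
  anchors <- data.frame(severity = S, reynolds = Re,
                        pi = pi_steady(S, Re, true_m))
  m <- calibrate_anchors(anchors)
  expect_equal(m$Kv, 2100, tolerance = 1e-9)
  expect_equal(m$kt, 1.4, tolerance = 1e-9)
  expect_lt(attr(m, "residual_rms"), 1e-10)
})

test_that("steady drop is monotone and decays slower than Poiseuille", {
  m <- pressure_drop_model()
  # S = 0: pure viscous term
  expect_equal(pi_steady(0, 1268, m), m$Kv / 1268)
  # strictly increasing in severity
  S <- seq(0, 0.9, by = 0.05)
  expect_true(all(diff(pi_steady(S, 1268, m)) > 0))
  expect_gt(pi_steady(0.7, 1268, m), pi_steady(0.63, 1268, m))
  # strictly decreasing in Reynolds
  Re <- seq(300, 2500, by = 100)
  expect_true(all(diff(pi_steady(0.583, Re, m)) < 0))
  # far weaker than the Poiseuille prediction between Re 500 and 2000:
  # pure Pi ~ 1/Re would give a ratio of 0.25
  expect_gt(pi_steady(0.583, 2000, m) / pi_steady(0.583, 500, m), 0.4)
  expect_error(pi_steady(1, 1268, m), "\\[0, 1\\)")
  expect_error(pi_steady(0.5, -10, m), "positive")
})

test_that("table mode interpolates its grid and guards its hull", {
  grid <- expand.grid(severity = c(0.4, 0.5, 0.6, 0.7),
                      reynolds = c(500, 1000, 2000))
  ref <- pressure_drop_model(Kv = 2748, kt = 1.9)
  tab <- data.frame(grid, pi = pi_steady(grid$severity, grid$reynolds, ref))
  tm <- pressure_drop_model(mode = "table", table = tab)
  # nodes reproduced exactly
  expect_equal(pi_steady(0.5, 1000, tm), pi_steady(0.5, 1000, ref))
  # interpolated value lies between its bracketing nodes
  mid <- pi_steady(0.55, 1500, tm)
  expect_gt(mid, pi_steady(0.5, 2000, ref))
  expect_lt(mid, pi_steady(0.6, 500, ref))
  # a bilinear function is reproduced exactly between nodes
  tab2 <- data.frame(grid, pi = 1 + 2 * grid$severity +
                       0.001 * grid$reynolds)
  tm2 <- pressure_drop_model(mode = "table", table = tab2)
  expect_equal(pi_steady(0.47, 1234, tm2), 1 + 2 * 0.47 + 0.001 * 1234,
               tolerance = 1e-12)
  expect_error(pi_steady(0.9, 1000, tm), "hull")
  expect_equal(pi_steady(0.9, 1000, tm, extrapolate = TRUE),
               pi_steady(0.7, 1000, tm))  # clamped
})

test_that("unsteady drop reduces to steady at zero acceleration and orders phases", {
  props <- fluid_properties()
  m <- pressure_drop_model()
  D <- 5.15e-3
  # constant waveform: zero acceleration everywhere
  flat <- inlet_waveform(v0m = 0.7, Omega = 1.2)
  tt <- seq(0, 0.8, length.out = 7)
  expect_equal(pi_unsteady(tt, flat, 0.583, props, m, D),
               rep(pi_steady(0.583, reynolds(props, 0.7, D), m), 7))
  # single-harmonic waveform: t and T/2 - t have equal v0, opposite dv0/dt
  w <- inlet_waveform(v0m = 0.7, Omega = 1.2, a = c(0.2))
  t_acc <- 0.05                 # dv0/dt > 0
  t_dec <- 1 / 2.4 - 0.05       # same v0, dv0/dt < 0
  expect_equal(eval_waveform(t_acc, w), eval_waveform(t_dec, w))
  pi_acc <- pi_unsteady(t_acc, w, 0.583, props, m, D)
  pi_dec <- pi_unsteady(t_dec, w, 0.583, props, m, D)
  pi_mid <- pi_steady(0.583, reynolds_inst(props, eval_waveform(t_acc, w), D), m)
  expect_gt(pi_acc, pi_mid)
  expect_lt(pi_dec, pi_mid)
  # reversing flow is out of the modelled regime
  rev <- inlet_waveform(v0m = 0.1, Omega = 1.2, a = c(0.5))
  expect_error(pi_unsteady(0.1, rev, 0.5, props, m, D), "reverses")
})

test_that("cycle-averaged pulsatile drop stays near the steady value at mean Re", {
  props <- fluid_properties()
  m <- pressure_drop_model()
  D <- 5.15e-3
  w <- gen_velocity_waveform(seed = 5)$truth
  tt <- seq(0, 1 / 1.2, length.out = 2001)[-2001]
  pi_bar <- mean(pi_unsteady(tt, w, 0.583, props, m, D))
  pi_mean_re <- pi_steady(0.583, reynolds(props, 0.7, D), m)
  expect_lt(abs(pi_bar - pi_mean_re) / pi_mean_re, 0.10)
})

test_that("distal pressure subtracts the modelled drop and orders severities", {
  props <- fluid_properties()
  D <- 5.15e-3
  t <- seq(0, 5, by = 0.01)
  P0 <- waveform_record(t, 13000 + 1500 * sin(2 * pi * 1.2 * t), "Pa")
  w <- gen_velocity_waveform(seed = 2)$truth
  # zero model: P1 equals P0
  zero <- pressure_drop_model(Kv = 0, kt = 0, Ku_Leff_over_D = 0)
  expect_equal(distal_pressure(P0, w, 0.583, props, zero, D)$x, P0$x)
  # constant velocity and drop: constant offset rho v0^2 Pi
  m <- pressure_drop_model()
  flat <- inlet_waveform(v0m = 0.7, Omega = 1.2)
  P1c <- distal_pressure(P0, flat, 0.583, props, m, D)
  drop <- props$rho * 0.7^2 *
    pi_steady(0.583, reynolds(props, 0.7, D), m)
  expect_equal(P0$x - P1c$x, rep(drop, length(t)))
  # deeper stenosis: larger drop at every instant
  P1_nom <- distal_pressure(P0, w, 0.583, props, m, D)
  P1_pert <- distal_pressure(P0, w, 0.6219, props, m, D)
  expect_true(all(P1_pert$x < P1_nom$x))
  expect_true(all(P1_nom$x <= P0$x + 1e-9))
})
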