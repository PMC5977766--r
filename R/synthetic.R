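# Seeded generators for synthetic coronary waveforms and FFR histograms.
#
# The templates are fixed published-morphology approximations (diastolic-
# dominant coronary inflow; aortic pressure with a dicrotic-notch-like
# feature). They emulate the shape class of hyperaemic recordings, not any
# particular patient.

# Periodic raised-cosine bump centred at `c` with total width `w`, on
# phase in [0, 1).
phase_bump <- function(phi, centre, width) {
  d <- (phi - centre) %% 1
  d <- pmin(d, 1 - d)
  ifelse(d < width / 2, cos(pi * d / width)^2, 0)
}

# Coronary inflow template on phase [0, 1): small systolic bump, dominant
# diastolic bump over a positive baseline. Mean is O(1); callers rescale.
velocity_template <- function(phi) {
  0.35 + 0.35 * phase_bump(phi, 0.18, 0.30) +
    0.50 * phase_bump(phi, 0.68, 0.55)
}

# Aortic pressure template on phase [0, 1): systolic upstroke, dicrotic
# notch, secondary (reflected) bump, diastolic decay. Normalized to
# exactly [0, 1] over the sampled phase grid by the caller.
pressure_template <- function(phi) {
  0.80 * phase_bump(phi, 0.16, 0.52) +
    0.22 * phase_bump(phi, 0.47, 0.22) +
    0.25 * exp(-2.0 * ((phi + 0.05) %% 1))
}

# Project a periodic template onto the six-harmonic Fourier basis on a
# dense uniform phase grid (exact for trigonometric polynomials).
project_six_harmonics <- function(template) {
  m <- 4096L
  phi <- (seq_len(m) - 1L) / m
  g <- template(phi)
  a <- vapply(1:6, function(n) 2 * mean(g * sin(2 * pi * n * phi)),
              numeric(1))
  b <- vapply(1:6, function(n) 2 * mean(g * cos(2 * pi * n * phi)),
              numeric(1))
  list(mean = mean(g), a = a, b = b)
}

# Per-cycle sample times and phases under multiplicative lognormal
# cycle-length jitter (median cycle length 1/Omega).
jittered_cycles <- function(Omega, n_cycles, samples_per_cycle, jitter) {
  periods <- (1 / Omega) * exp(stats::rnorm(n_cycles, 0, jitter))
  starts <- c(0, cumsum(periods))
  phi <- (seq_len(samples_per_cycle) - 1L) / samples_per_cycle
  t <- unlist(lapply(seq_len(n_cycles),
                     function(k) starts[k] + phi * periods[k]))
  list(t = t, phi = rep(phi, n_cycles), periods = periods)
}

#' Generate a synthetic coronary velocity waveform
#'
#' A six-harmonic, diastolic-dominant coronary inflow waveform: strictly
#' positive, with section-averaged mean exactly `v0m` before noise. The
#' exact Fourier ground truth is returned alongside the sampled record, so
#' fitting and FFR pipelines can be validated against known coefficients.
#'
#' @param v0m mean velocity over the cycle (m/s).
#' @param Omega cycle frequency (1/s).
#' @param n_cycles number of cardiac cycles.
#' @param samples_per_cycle samples per cycle.
#' @param jitter relative s.d. of the per-cycle period (lognormal
#'   multiplicative jitter, median 1).
#' @param noise_sd additive Gaussian noise s.d. (m/s).
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @return A list with `record` (a [waveform_record()] in m/s), `truth`
#'   (the exact [inlet_waveform()]), and `periods` (the realized cycle
#'   lengths, s).
#' @export
gen_velocity_waveform <- function(v0m = 0.7, Omega = 1.2, n_cycles = 25L,
                                  samples_per_cycle = 100L, jitter = 0,
                                  noise_sd = 0, seed = NULL) {
  assert_scalar_num(v0m, "v0m", lower = .Machine$double.eps)
  assert_scalar_num(Omega, "Omega", lower = .Machine$double.eps)
  assert_scalar_num(jitter, "jitter", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stopf("n_cycles must be >= 1")
  pr <- project_six_harmonics(velocity_template)
  scale <- v0m / pr$mean
  truth <- inlet_waveform(v0m = v0m, Omega = Omega,
                          a = pr$a * scale, b = pr$b * scale)
  check_no_reversal(truth)
  with_seed(seed, {
    cyc <- jittered_cycles(Omega, n_cycles, as.integer(samples_per_cycle),
                           jitter)
    x <- eval_waveform(cyc$phi / Omega, truth)  # template is phase-periodic
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
    list(record = waveform_record(cyc$t, x, unit = "m/s"),
         truth = truth, periods = cyc$periods)
  })
}

#' Generate a synthetic aortic pressure waveform
#'
#' A periodic arterial pressure trace oscillating between `P_dia` and
#' `P_sys` with a dicrotic-notch-like feature; the noiseless trace attains
#' both extremes exactly on the sampled phase grid.
#'
#' @param P_sys,P_dia systolic and diastolic pressure (mmHg);
#'   `P_sys > P_dia`.
#' @param Omega cycle frequency (1/s).
#' @param n_cycles number of cardiac cycles.
#' @param samples_per_cycle samples per cycle.
#' @param jitter relative s.d. of the per-cycle period.
#' @param noise_sd additive Gaussian noise s.d. (mmHg).
#' @param seed RNG seed.
#' @return A [waveform_record()] in Pa (converted from mmHg on ingest).
#' @export
gen_pressure_waveform <- function(P_sys = 130, P_dia = 70, Omega = 1.2,
                                  n_cycles = 25L,
                                  samples_per_cycle = 100L, jitter = 0,
                                  noise_sd = 0, seed = NULL) {
  assert_scalar_num(P_sys, "P_sys")
  assert_scalar_num(P_dia, "P_dia")
  if (P_sys <= P_dia) stopf("need P_sys > P_dia")
  assert_scalar_num(jitter, "jitter", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stopf("n_cycles must be >= 1")
  spc <- as.integer(samples_per_cycle)
  phi_grid <- (seq_len(spc) - 1L) / spc
  g <- pressure_template(phi_grid)
  g <- (g - min(g)) / (max(g) - min(g))   # exact [0, 1] on this grid
  with_seed(seed, {
    cyc <- jittered_cycles(Omega, n_cycles, spc, jitter)
    x <- P_dia + (P_sys - P_dia) * rep(g, n_cycles)
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
    waveform_record(cyc$t, x, unit = "mmHg")
  })
}

#' Generate a paired proximal/distal pressure record with known FFR
#'
#' Builds `P0` with [gen_pressure_waveform()] and sets
#' `P1(t) = r(t) * P0(t)` for a designed smooth ratio profile `r(t)`, so
#' the windowed-minimum FFR statistic has an analytically known target.
#'
#' @param true_ffr_profile either a single ratio in (0, 1] or a function
#'   of time returning ratios in (0, 1].
#' @param noise_sd additive noise s.d. applied independently to both
#'   records (mmHg).
#' @param seed RNG seed.
#' @inheritParams gen_pressure_waveform
#' @return A list with `P0`, `P1` ([waveform_record()]s in Pa) and
#'   `ratio` (the designed `r(t)` samples).
#' @export
gen_paired_record <- function(true_ffr_profile = 0.83, P_sys = 130,
                              P_dia = 70, Omega = 1.2, n_cycles = 25L,
                              samples_per_cycle = 100L, jitter = 0,
                              noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    P0 <- gen_pressure_waveform(P_sys, P_dia, Omega, n_cycles,
                                samples_per_cycle, jitter, noise_sd = 0,
                                seed = NULL)
    r <- if (is.function(true_ffr_profile)) {
      true_ffr_profile(P0$t)
    } else {
      rep(true_ffr_profile, length(P0$t))
    }
    if (any(!is.finite(r)) || any(r <= 0) || any(r > 1)) {
      stopf("true_ffr_profile must yield ratios in (0, 1]")
    }
    x1 <- r * P0$x
    if (noise_sd > 0) {
      sd_pa <- to_pascal(noise_sd, "mmHg")
      P0$x <- P0$x + stats::rnorm(length(P0$x), 0, sd_pa)
      x1 <- x1 + stats::rnorm(length(x1), 0, sd_pa)
    }
    list(P0 = P0, P1 = waveform_record(P0$t, x1, unit = "Pa"), ratio = r)
  })
}

#' Generate a peaked synthetic FFR population histogram
#'
#' Patient FFR values are drawn from a beta distribution parameterized by
#' its mode and concentration (mode `~0.85` matches published FFR registry
#' distributions), then binned; the total count equals `n_patients`
#' exactly.
#'
#' @param n_patients total number of patients.
#' @param mode modal FFR value, strictly in (0, 1).
#' @param concentration beta concentration (> 2); larger is narrower.
#' @param bin_width histogram bin width on (0, 1].
#' @param seed RNG seed.
#' @return An [ffr_histogram()] on bins `seq(0, 1, bin_width)`.
#' @export
gen_ffr_histogram <- function(n_patients = 1944L, mode = 0.85,
                              concentration = 25, bin_width = 0.05,
                              seed = NULL) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 0L) stopf("n_patients must be >= 0")
  if (!is.numeric(mode) || length(mode) != 1L || mode <= 0 || mode >= 1) {
    stopf("mode must lie strictly in (0, 1)")
  }
  assert_scalar_num(concentration, "concentration", lower = 2 + 1e-9)
  edges <- seq(0, 1, by = bin_width)
  if (abs(edges[length(edges)] - 1) > 1e-12) {
    stopf("bin_width must divide 1")
  }
  shape1 <- mode * (concentration - 2) + 1
  shape2 <- (1 - mode) * (concentration - 2) + 1
  with_seed(seed, {
    draws <- stats::rbeta(n_patients, shape1, shape2)
    counts <- tabulate(findInterval(draws, edges, rightmost.closed = TRUE),
                       nbins = length(edges) - 1L)
    ffr_histogram(edges, counts)
  })
}
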