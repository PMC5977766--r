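#' Sampled waveform record
#'
#' A time series of pressure or velocity samples over one or more cardiac
#' cycles. Times must be strictly increasing; pressures are converted to
#' pascals on ingest (`mmHg` factor 133.322).
#'
#' @param t sample times (s), strictly increasing, length >= 2.
#' @param x sample values; finite.
#' @param unit `"Pa"`, `"mmHg"` or `"m/s"`.
#' @return An object of class `waveform_record` with fields `t`, `x` and
#'   `unit` (`"Pa"` or `"m/s"` after conversion).
#' @export
waveform_record <- function(t, x, unit = c("Pa", "mmHg", "m/s")) {
  unit <- match.arg(unit)
  if (length(t) < 2L || length(t) != length(x)) {
    stopf("need >= 2 samples with matching `t` and `x` lengths")
  }
  if (any(!is.finite(t)) || any(!is.finite(x))) {
    stopf("waveform samples must be finite")
  }
  if (any(diff(t) <= 0)) stopf("sample times must be strictly increasing")
  if (unit == "mmHg") {
    x <- to_pascal(x, "mmHg")
    unit <- "Pa"
  }
  structure(list(t = as.numeric(t), x = as.numeric(x), unit = unit),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf(
    "Waveform record: %d samples over [%.3f, %.3f] s, unit %s\n",
    length(x$t), min(x$t), max(x$t), x$unit))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$x), max(x$x), mean(x$x)))
  invisible(x)
}

#' Read / write waveform records as two-column CSV
#'
#' The CSV format is `time_s,value`, one sample per row.
#'
#' @param path file path.
#' @param unit unit of the value column (see [waveform_record()]).
#' @param rec a [waveform_record()].
#' @return `read_waveform()` returns a [waveform_record()];
#'   `write_waveform()` returns `path` invisibly.
#' @export
read_waveform <- function(path, unit = "Pa") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stopf("waveform CSV must have columns `time_s,value`: %s", path)
  }
  waveform_record(df$time_s, df$value, unit)
}

#' @rdname read_waveform
#' @export
write_waveform <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_record"))
  utils::write.csv(data.frame(time_s = rec$t, value = rec$x), path,
                   row.names = FALSE)
  invisible(path)
}

#' Six-harmonic inlet waveform
#'
#' Truncated Fourier representation of the section-averaged inlet velocity
#' over the cardiac cycle,
#' \eqn{v_0(t) = v_{0m} + \sum_{n=1}^{6} [a_n \sin(2\pi n \Omega t) +
#' b_n \cos(2\pi n \Omega t)]}. Typical hyperaemic values are
#' `v0m = 0.7` m/s and `Omega = 1.2` 1/s.
#'
#' @param v0m mean velocity over the cycle (m/s).
#' @param Omega cycle frequency (1/s).
#' @param a,b sine and cosine coefficient vectors (m/s), length 6 (shorter
#'   vectors are zero-padded).
#' @return An object of class `inlet_waveform`.
#' @export
inlet_waveform <- function(v0m = 0.7, Omega = 1.2, a = numeric(6),
                           b = numeric(6)) {
  assert_scalar_num(v0m, "v0m")
  assert_scalar_num(Omega, "Omega", lower = .Machine$double.eps)
  if (length(a) > 6L || length(b) > 6L) {
    stopf("at most 6 harmonics are supported")
  }
  a <- c(a, numeric(6L - length(a)))
  b <- c(b, numeric(6L - length(b)))
  structure(list(v0m = v0m, Omega = Omega, a = a, b = b),
            class = "inlet_waveform")
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat(sprintf(
    "Inlet waveform: v0m = %.4g m/s, Omega = %.4g 1/s (period %.4g s)\n",
    x$v0m, x$Omega, 1 / x$Omega))
  cat("  a:", paste(signif(x$a, 4), collapse = " "), "\n")
  cat("  b:", paste(signif(x$b, 4), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a six-harmonic inlet waveform
#'
#' @param t times (s); vectorised.
#' @param w an [inlet_waveform()].
#' @return `eval_waveform()`: velocity `v0(t)` (m/s);
#'   `eval_waveform_derivative()`: the analytic `dv0/dt` (m/s^2).
#' @export
eval_waveform <- function(t, w) {
  stopifnot(inherits(w, "inlet_waveform"))
  out <- rep(w$v0m, length(t))
  for (n in 1:6) {
    ph <- 2 * pi * n * w$Omega * t
    out <- out + w$a[n] * sin(ph) + w$b[n] * cos(ph)
  }
  out
}

#' @rdname eval_waveform
#' @export
eval_waveform_derivative <- function(t, w) {
  stopifnot(inherits(w, "inlet_waveform"))
  out <- numeric(length(t))
  for (n in 1:6) {
    cn <- 2 * pi * n * w$Omega
    ph <- cn * t
    out <- out + cn * (w$a[n] * cos(ph) - w$b[n] * sin(ph))
  }
  out
}

#' Fit a six-harmonic Fourier series to a sampled waveform
#'
#' Least-squares fit of the [inlet_waveform()] model to a sampled record.
#' The cycle period is either supplied or estimated from the record by
#' [estimate_period()].
#'
#' @param rec a [waveform_record()].
#' @param n_harmonics number of harmonics (<= 6).
#' @param period cycle period (s), or `NULL` to estimate.
#' @return An [inlet_waveform()] with an attribute `residual_rms`, the
#'   root-mean-square reconstruction error.
#' @export
fit_fourier <- function(rec, n_harmonics = 6L, period = NULL) {
  stopifnot(inherits(rec, "waveform_record"))
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L || n_harmonics > 6L) {
    stopf("n_harmonics must be in 1..6")
  }
  if (length(rec$t) < 2L * n_harmonics + 1L) {
    stopf("underdetermined fit: need >= %d samples, have %d",
          2L * n_harmonics + 1L, length(rec$t))
  }
  if (is.null(period)) period <- estimate_period(rec)$tau
  Omega <- 1 / period
  X <- matrix(1, nrow = length(rec$t), ncol = 1L + 2L * n_harmonics)
  for (n in seq_len(n_harmonics)) {
    ph <- 2 * pi * n * Omega * rec$t
    X[, 2L * n] <- sin(ph)
    X[, 2L * n + 1L] <- cos(ph)
  }
  fit <- stats::lm.fit(X, rec$x)
  cf <- unname(fit$coefficients)
  a <- numeric(6); b <- numeric(6)
  a[seq_len(n_harmonics)] <- cf[2L * seq_len(n_harmonics)]
  b[seq_len(n_harmonics)] <- cf[2L * seq_len(n_harmonics) + 1L]
  w <- inlet_waveform(v0m = cf[1L], Omega = Omega, a = a, b = b)
  attr(w, "residual_rms") <- sqrt(mean(fit$residuals^2))
  w
}

#' Estimate the mean cardiac cycle period of a record
#'
#' Two-stage estimate: (1) a coarse period from the first autocorrelation
#' peak whose normalized height exceeds 0.5; (2) refinement as the mean
#' interval between systolic peaks, peaks being local maxima separated by
#' at least 60% of the coarse period.
#'
#' @param rec a [waveform_record()] spanning at least 3 cycles, sampled
#'   on a (near-)uniform grid.
#' @return A list with `tau` (mean period, s), `tau_sd` (inter-peak
#'   dispersion, s) and `n_peaks`.
#' @export
estimate_period <- function(rec) {
  stopifnot(inherits(rec, "waveform_record"))
  dt <- stats::median(diff(rec$t))
  x <- rec$x - mean(rec$x)
  if (max(abs(x)) < .Machine$double.eps^0.5 * max(abs(rec$x), 1)) {
    stopf("no periodicity detected: record is constant")
  }
  n <- length(x)
  ac <- stats::acf(x, lag.max = floor(n * 0.8), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  ac <- ac / ac[1]
  # first local maximum of the acf above 0.5, skipping lag 0
  lag <- NA_integer_
  for (k in 2:(length(ac) - 1L)) {
    if (ac[k] > 0.5 && ac[k] >= ac[k - 1L] && ac[k] >= ac[k + 1L]) {
      lag <- k - 1L
      break
    }
  }
  if (is.na(lag)) stopf("no periodicity detected in record")
  tau0 <- lag * dt
  # systolic peaks: local maxima above the 60th percentile, separated by
  # at least 0.6 * tau0
  thr <- stats::quantile(rec$x, 0.6, names = FALSE)
  is_peak <- c(FALSE, diff(sign(diff(rec$x))) < 0, FALSE) & rec$x > thr
  pk_t <- rec$t[is_peak]
  if (length(pk_t) >= 2L) {
    keep <- c(TRUE, diff(pk_t) > 0.6 * tau0)
    # greedy thinning: drop peaks too close to the previously kept one
    kept <- pk_t[1]
    for (tt in pk_t[-1]) {
      if (tt - kept[length(kept)] > 0.6 * tau0) kept <- c(kept, tt)
    }
    pk_t <- kept
  }
  if (length(pk_t) >= 3L) {
    gaps <- diff(pk_t)
    list(tau = mean(gaps), tau_sd = stats::sd(gaps),
         n_peaks = length(pk_t))
  } else {
    list(tau = tau0, tau_sd = NA_real_, n_peaks = length(pk_t))
  }
}
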