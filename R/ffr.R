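# Cumulative trapezoidal integral of the piecewise-linear interpolant of a
# record, evaluated at arbitrary query times (vectorised).
cumulative_integral <- function(rec, q) {
  t <- rec$t; x <- rec$x
  I <- c(0, cumsum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2))
  j <- findInterval(q, t, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(t) - 1L)
  xq <- x[j] + (x[j + 1L] - x[j]) * (q - t[j]) / (t[j + 1L] - t[j])
  I[j] + (q - t[j]) * (x[j] + xq) / 2
}

#' Moving cycle average of a waveform record
#'
#' \eqn{\bar P(t) = (1/\tau)\int_t^{t+\tau} P(t')\,dt'} by trapezoidal
#' quadrature on the sample grid with linear interpolation at the window
#' endpoints. The normalization by \eqn{\tau} is a convention; it cancels
#' in the FFR ratio.
#'
#' @param rec a [waveform_record()].
#' @param tau averaging window: the mean cardiac cycle period (s).
#' @param t window start times (s); vectorised. Every `[t, t + tau]` must
#'   lie within the record span.
#' @return The windowed averages, same units as the record.
#' @export
cycle_average <- function(rec, tau, t) {
  stopifnot(inherits(rec, "waveform_record"))
  assert_scalar_num(tau, "tau", lower = .Machine$double.eps)
  if (any(t < rec$t[1] - 1e-12) ||
      any(t + tau > rec$t[length(rec$t)] + 1e-12)) {
    stopf("averaging window [t, t + tau] exceeds the record span")
  }
  (cumulative_integral(rec, t + tau) - cumulative_integral(rec, t)) / tau
}

#' Compute the fractional flow reserve from paired pressure records
#'
#' Forms the moving cycle averages \eqn{\bar P_0(t)} and \eqn{\bar P_1(t)}
#' with window `tau`, evaluates their ratio at every proximal sample time
#' whose window fits inside both records, and returns the minimum of that
#' ratio: the clinical FFR statistic.
#'
#' @param P0,P1 proximal and distal pressure [waveform_record()]s with a
#'   common span of at least `2 * tau`.
#' @param tau cycle period (s), or `"auto"` to estimate it from `P0` via
#'   [estimate_period()].
#' @return An object of class `ffr_result`: a list with `ffr`, `tau`,
#'   `t_min` (argmin window start), `t` (window starts), `Pbar0`, `Pbar1`
#'   and `ratio` curves, and `n_windows`.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' p0 <- waveform_record(t, 100 + 15 * sin(2 * pi * 1.2 * t), "mmHg")
#' p1 <- waveform_record(t, 0.8 * p0$x, "Pa")
#' compute_ffr(p0, p1, tau = 1 / 1.2)$ffr   # 0.8
#' @export
compute_ffr <- function(P0, P1, tau = "auto") {
  stopifnot(inherits(P0, "waveform_record"),
            inherits(P1, "waveform_record"))
  if (identical(tau, "auto")) tau <- estimate_period(P0)$tau
  assert_scalar_num(tau, "tau", lower = .Machine$double.eps)
  lo <- max(P0$t[1], P1$t[1])
  hi <- min(P0$t[length(P0$t)], P1$t[length(P1$t)])
  if (hi - lo < 2 * tau) {
    stopf("common record span (%.3g s) is shorter than 2 * tau = %.3g s",
          hi - lo, 2 * tau)
  }
  starts <- P0$t[P0$t >= lo & P0$t + tau <= hi]
  pbar0 <- cycle_average(P0, tau, starts)
  pbar1 <- cycle_average(P1, tau, starts)
  if (any(pbar0 <= 0)) {
    stopf("cycle-averaged proximal pressure is not strictly positive")
  }
  ratio <- pbar1 / pbar0
  k <- which.min(ratio)
  structure(list(ffr = ratio[k], tau = tau, t_min = starts[k],
                 t = starts, Pbar0 = pbar0, Pbar1 = pbar1,
                 ratio = ratio, n_windows = length(starts)),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("FFR = %.4f (tau = %.4g s, argmin window start t = %.4g s,\n",
              x$ffr, x$tau, x$t_min))
  cat(sprintf("       %d windows evaluated)\n", x$n_windows))
  invisible(x)
}

#' Instantaneous pressure ratio from the dimensionless drop
#'
#' Relates the instantaneous distal-to-proximal pressure ratio
#' \eqn{R = P_1/P_0} to the drop \eqn{\Pi^*} through the proximal
#' static-to-dynamic pressure ratio \eqn{\beta = P_0/(\rho v_0^2)}. The
#' default is the algebraically consistent form
#' \eqn{R = (\beta - \Pi^*)/\beta = 1 - \Pi^*/\beta}; with
#' `printed_form = TRUE` the reciprocal form \eqn{R = \beta/(\beta -
#' \Pi^*)} is evaluated instead (which exceeds 1 for a positive drop;
#' both are exposed, neither silently corrected).
#'
#' @param pi_star instantaneous dimensionless pressure drop; vectorised.
#' @param beta proximal static-to-dynamic pressure ratio, typically of
#'   order 100; must exceed `pi_star`.
#' @param printed_form evaluate the reciprocal form.
#' @return The pressure ratio `R` (dimensionless).
#' @export
pressure_ratio <- function(pi_star, beta, printed_form = FALSE) {
  if (any(!is.finite(pi_star)) || any(!is.finite(beta))) {
    stopf("pi_star and beta must be finite")
  }
  if (any(beta <= pi_star)) {
    stopf("need beta > pi_star (dynamic pressure must not exhaust P0)")
  }
  if (printed_form) beta / (beta - pi_star) else 1 - pi_star / beta
}

#' First-order propagation of pressure-drop errors into the ratio
#'
#' A small relative error \eqn{\epsilon_{\Pi^*}} in the computed pressure
#' drop produces a relative error in the pressure ratio
#' \deqn{\epsilon_R = \frac{\epsilon_{\Pi^*}\,\beta\,\Pi^*}
#'   {R\,(\beta - \Pi^*)^2} + O(\epsilon_{\Pi^*}^2),}
#' which for \eqn{\beta \gg \Pi^*} and \eqn{R \approx 1} reduces to
#' \eqn{\epsilon_{\Pi^*}\,\Pi^*/\beta}: drop errors are attenuated by the
#' large static-to-dynamic pressure ratio.
#'
#' @param eps_pi relative error of `pi_star` (small).
#' @param pi_star dimensionless pressure drop.
#' @param beta proximal static-to-dynamic pressure ratio; `> pi_star`.
#' @param R the pressure ratio at which the sensitivity is evaluated
#'   (default: recomputed from `pi_star` and `beta`).
#' @return Relative error \eqn{\epsilon_R} of the pressure ratio.
#' @export
propagate_error <- function(eps_pi, pi_star, beta,
                            R = pressure_ratio(pi_star, beta)) {
  if (any(beta == pi_star)) stopf("beta must differ from pi_star")
  if (any(beta < pi_star)) stopf("need beta > pi_star")
  eps_pi * beta * pi_star / (R * (beta - pi_star)^2)
}
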