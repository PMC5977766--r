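#' Reduced-order trans-stenotic pressure-drop model
#'
#' A calibratable surrogate for the dimensionless pressure drop
#' \eqn{\Pi = (P_0 - P_1)/(\rho v_{0m}^2)} across the stenosis, standing
#' in for a full 3D flow computation. In `"correlation"` mode it uses a
#' Young-Tsai-type viscous-plus-expansion-loss form
#' \deqn{\Pi(S, Re) = K_v/Re + (k_t/2)\,[S/(1-S)]^2,}
#' strictly increasing in severity `S` and decreasing in Reynolds number,
#' plus an inertial (acceleration) term for pulsatile flow (see
#' [pi_unsteady()]). In `"table"` mode it bilinearly interpolates a
#' user-supplied `(S, Re, Pi)` table (e.g. from CFD or bench data).
#'
#' The default coefficients reproduce the two anchor points
#' `(S = 0.583, Re = 1268, Pi = 4.03)` and `(S = 0.63, Re = 1268,
#' Pi = 4.93)` exactly (see [calibrate_anchors()]).
#'
#' @param Kv viscous coefficient (dimensionless), >= 0.
#' @param kt expansion-loss coefficient (dimensionless), >= 0.
#' @param Ku_Leff_over_D inertial coefficient: the effective length of the
#'   measured segment in lumen diameters. The default `2 * 1.92 + 1.94`
#'   is the pressure-tap span of the reference geometry (taps one `Ls`
#'   either side of the neck).
#' @param mode `"correlation"` or `"table"`.
#' @param table for table mode, a data frame with columns
#'   `severity`, `reynolds`, `pi` forming a complete regular grid.
#' @param provenance optional list describing the calibration source.
#' @return An object of class `pressure_drop_model`.
#' @export
pressure_drop_model <- function(Kv = NULL, kt = NULL,
                                Ku_Leff_over_D = 2 * 1.92 + 1.94,
                                mode = c("correlation", "table"),
                                table = NULL, provenance = list()) {
  mode <- match.arg(mode)
  assert_scalar_num(Ku_Leff_over_D, "Ku_Leff_over_D", lower = 0)
  if (mode == "correlation") {
    if (is.null(Kv) || is.null(kt)) {
      m <- calibrate_anchors(default_anchors(),
                             Ku_Leff_over_D = Ku_Leff_over_D)
      if (is.null(Kv)) Kv <- m$Kv
      if (is.null(kt)) kt <- m$kt
    }
    assert_scalar_num(Kv, "Kv", lower = 0)
    assert_scalar_num(kt, "kt", lower = 0)
  } else {
    if (is.null(table)) stopf("table mode requires a calibration table")
    need <- c("severity", "reynolds", "pi")
    if (!all(need %in% names(table))) {
      stopf("calibration table must have columns %s",
            paste(need, collapse = ", "))
    }
    Kv <- NA_real_; kt <- NA_real_
  }
  structure(list(Kv = Kv, kt = kt, Ku_Leff_over_D = Ku_Leff_over_D,
                 mode = mode, table = table, provenance = provenance),
            class = "pressure_drop_model")
}

# Anchor points of the reference calibration: dimensionless pressure drops
# of the smooth eccentric-stenosis model at Re = 1268 for the nominal and
# +300 um perturbed severities.
default_anchors <- function() {
  data.frame(severity = c(0.583, 0.63),
             reynolds = c(1268, 1268),
             pi = c(4.03, 4.93))
}

#' @export
print.pressure_drop_model <- function(x, ...) {
  cat("Reduced-order pressure-drop model\n")
  if (x$mode == "correlation") {
    cat(sprintf("  Pi = %.5g/Re + (%.5g/2) * (S/(1-S))^2\n", x$Kv, x$kt))
  } else {
    cat(sprintf("  table mode: %d rows\n", nrow(x$table)))
  }
  cat(sprintf("  inertial coefficient Ku*Leff/D = %.4g\n",
              x$Ku_Leff_over_D))
  invisible(x)
}

#' Steady dimensionless pressure drop
#'
#' @param S severity in `[0, 1)`; vectorised.
#' @param Re Reynolds number, > 0; vectorised (recycled against `S`).
#' @param model a [pressure_drop_model()].
#' @param extrapolate in table mode, allow queries outside the table hull.
#' @return Dimensionless pressure drop \eqn{\Pi}.
#' @export
pi_steady <- function(S, Re, model = pressure_drop_model(),
                      extrapolate = FALSE) {
  stopifnot(inherits(model, "pressure_drop_model"))
  if (any(!is.finite(S)) || any(S < 0) || any(S >= 1)) {
    stopf("severity must lie in [0, 1)")
  }
  if (any(!is.finite(Re)) || any(Re <= 0)) {
    stopf("Reynolds number must be positive")
  }
  if (model$mode == "correlation") {
    model$Kv / Re + (model$kt / 2) * (S / (1 - S))^2
  } else {
    table_interp(model$table, S, Re, extrapolate)
  }
}

# Bilinear interpolation on the regular (severity, reynolds) grid of a
# calibration table.
table_interp <- function(tab, S, Re, extrapolate) {
  Sg <- sort(unique(tab$severity))
  Rg <- sort(unique(tab$reynolds))
  if (nrow(tab) != length(Sg) * length(Rg)) {
    stopf("calibration table is not a complete regular grid")
  }
  Z <- matrix(NA_real_, length(Sg), length(Rg))
  Z[cbind(match(tab$severity, Sg), match(tab$reynolds, Rg))] <- tab$pi
  n <- max(length(S), length(Re))
  S <- rep_len(S, n); Re <- rep_len(Re, n)
  out_hull <- S < Sg[1] | S > Sg[length(Sg)] |
    Re < Rg[1] | Re > Rg[length(Rg)]
  if (any(out_hull) && !extrapolate) {
    stopf("table query outside calibration hull (S in [%g, %g], Re in [%g, %g])",
          Sg[1], Sg[length(Sg)], Rg[1], Rg[length(Rg)])
  }
  Sq <- pmin(pmax(S, Sg[1]), Sg[length(Sg)])
  Rq <- pmin(pmax(Re, Rg[1]), Rg[length(Rg)])
  i <- pmin(pmax(findInterval(Sq, Sg), 1L), length(Sg) - 1L)
  j <- pmin(pmax(findInterval(Rq, Rg), 1L), length(Rg) - 1L)
  u <- (Sq - Sg[i]) / (Sg[i + 1L] - Sg[i])
  v <- (Rq - Rg[j]) / (Rg[j + 1L] - Rg[j])
  (1 - u) * (1 - v) * Z[cbind(i, j)] + u * (1 - v) * Z[cbind(i + 1L, j)] +
    (1 - u) * v * Z[cbind(i, j + 1L)] + u * v * Z[cbind(i + 1L, j + 1L)]
}

#' Calibrate the correlation model to pressure-drop anchors
#'
#' Solves for `(Kv, kt)` of the correlation shape from a set of
#' `(S, Re, Pi)` anchor points: exactly for two anchors, by least squares
#' for more. Anchors may come from printed results, CFD runs or bench
#' measurements.
#'
#' @param anchors data frame with columns `severity`, `reynolds`, `pi`;
#'   at least two rows with distinct severities.
#' @param Ku_Leff_over_D inertial coefficient passed through to the model.
#' @return A [pressure_drop_model()] whose attribute `residual_rms` is the
#'   root-mean-square anchor reproduction error (0 for two anchors).
#' @examples
#' calibrate_anchors(data.frame(severity = c(0.583, 0.63),
#'                              reynolds = 1268, pi = c(4.03, 4.93)))
#' @export
calibrate_anchors <- function(anchors, Ku_Leff_over_D = 2 * 1.92 + 1.94) {
  need <- c("severity", "reynolds", "pi")
  if (!all(need %in% names(anchors))) {
    stopf("anchors must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(anchors) < 2L) {
    stopf("need at least 2 anchors for the 2-parameter shape")
  }
  if (length(unique(anchors$severity)) < 2L) {
    stopf("anchors must span at least 2 distinct severities")
  }
  X <- cbind(1 / anchors$reynolds, 0.5 * (anchors$severity /
                                            (1 - anchors$severity))^2)
  fit <- stats::lm.fit(X, anchors$pi)
  cf <- unname(fit$coefficients)
  if (any(is.na(cf)) || abs(det(crossprod(X))) < 1e-300) {
    stopf("degenerate anchor set: cannot identify (Kv, kt)")
  }
  if (any(cf < 0)) {
    stopf(paste0("anchor fit gives a negative coefficient (Kv = %.4g, ",
                 "kt = %.4g); use table mode for such data"),
          cf[1], cf[2])
  }
  m <- pressure_drop_model(Kv = cf[1], kt = cf[2],
                           Ku_Leff_over_D = Ku_Leff_over_D,
                           provenance = list(anchors = anchors))
  attr(m, "residual_rms") <- sqrt(mean(fit$residuals^2))
  m
}

#' Instantaneous dimensionless pressure drop under pulsatile flow
#'
#' \deqn{\Pi^*(t) = \Pi(S, Re^*(t)) + K_u L_{eff}/D \cdot
#'   D\,\dot v_0(t)/v_0(t)^2,}
#' the quasi-steady drop at the instantaneous Reynolds number plus an
#' inertial term proportional to the inlet acceleration. At the zero
#' acceleration instants \eqn{\Pi^*} coincides exactly with the steady
#' value at the same \eqn{Re^*}; the drop is larger during acceleration
#' than deceleration at matched \eqn{Re^*}.
#'
#' @param t times (s); vectorised.
#' @param w an [inlet_waveform()]; must be strictly positive over the
#'   cycle (no flow reversal).
#' @param S severity in `[0, 1)`.
#' @param props a [fluid_properties()].
#' @param model a [pressure_drop_model()].
#' @param D lumen diameter (m).
#' @return \eqn{\Pi^*(t)}, dimensionless.
#' @export
pi_unsteady <- function(t, w, S, props = fluid_properties(),
                        model = pressure_drop_model(), D = 5.15e-3) {
  stopifnot(inherits(w, "inlet_waveform"),
            inherits(props, "fluid_properties"),
            inherits(model, "pressure_drop_model"))
  check_no_reversal(w)
  v0 <- eval_waveform(t, w)
  dv0 <- eval_waveform_derivative(t, w)
  re_star <- reynolds_inst(props, v0, D)
  pi_steady(S, re_star, model) +
    model$Ku_Leff_over_D * D * dv0 / v0^2
}

check_no_reversal <- function(w) {
  tt <- seq(0, 1 / w$Omega, length.out = 2048L)
  if (min(eval_waveform(tt, w)) <= 0) {
    stopf("inlet waveform reverses (v0 <= 0 within the cycle): outside the modelled regime")
  }
  invisible(TRUE)
}

#' Synthesize the distal pressure waveform
#'
#' \eqn{P_1(t) = P_0(t) - \rho\,v_0(t)^2\,\Pi^*(t)}: the post-stenotic
#' pressure given the proximal pressure record, the inlet waveform and
#' the pressure-drop surrogate.
#'
#' @param P0 proximal pressure [waveform_record()] in Pa.
#' @param w an [inlet_waveform()].
#' @param S severity in `[0, 1)`.
#' @param props a [fluid_properties()].
#' @param model a [pressure_drop_model()].
#' @param D lumen diameter (m).
#' @return A [waveform_record()] for `P1` on the same time grid.
#' @export
distal_pressure <- function(P0, w, S, props = fluid_properties(),
                            model = pressure_drop_model(), D = 5.15e-3) {
  stopifnot(inherits(P0, "waveform_record"))
  if (P0$unit != "Pa") stopf("P0 must be in Pa (got %s)", P0$unit)
  pis <- pi_unsteady(P0$t, w, S, props, model, D)
  v0 <- eval_waveform(P0$t, w)
  waveform_record(P0$t, P0$x - props$rho * v0^2 * pis, unit = "Pa")
}
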