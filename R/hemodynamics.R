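#' Blood fluid properties
#'
#' Density plus the constants of the Carreau-type shear-thinning viscosity
#' law \eqn{\mu = \mu_\infty \{1 + 15.2\,\omega\,[1 + (\lambda
#' \dot\gamma)^2]^{(n-1)/2}\}}. The switch `omega` selects the Newtonian
#' approximation at infinite-shear viscosity (`omega = 0`) or the full
#' shear-thinning law (`omega = 1`).
#'
#' Defaults are standard values for blood: density 1060 kg/m^3,
#' \eqn{\mu_\infty = 0.00350} Pa s, \eqn{\lambda = 3.31} s,
#' \eqn{n = 0.357}.
#'
#' @param rho density (kg/m^3).
#' @param mu_inf infinite-shear viscosity (Pa s).
#' @param lam shear-thinning time constant (s).
#' @param n_exp shear-thinning exponent, in (0, 1).
#' @param omega non-Newtonian switch, 0 (Newtonian) or 1 (Carreau).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1060, mu_inf = 0.00350, lam = 3.31,
                             n_exp = 0.357, omega = 0) {
  assert_scalar_num(rho, "rho", lower = .Machine$double.eps)
  assert_scalar_num(mu_inf, "mu_inf", lower = .Machine$double.eps)
  assert_scalar_num(lam, "lam", lower = 0)
  if (!is.numeric(n_exp) || length(n_exp) != 1L || n_exp <= 0 ||
      n_exp >= 1) {
    stopf("n_exp must lie strictly in (0, 1)")
  }
  if (!omega %in% c(0, 1)) stopf("omega must be 0 or 1")
  structure(list(rho = rho, mu_inf = mu_inf, lam = lam, n_exp = n_exp,
                 omega = omega),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf(
    "Fluid: rho = %g kg/m^3, mu_inf = %g Pa s, lambda = %g s, n = %g, %s\n",
    x$rho, x$mu_inf, x$lam, x$n_exp,
    if (x$omega == 1) "Carreau (omega = 1)" else "Newtonian (omega = 0)"))
  invisible(x)
}

#' Carreau-type apparent blood viscosity
#'
#' @param gamma_dot shear rate (1/s), >= 0; vectorised.
#' @param props a [fluid_properties()].
#' @return Apparent viscosity (Pa s). Constant `mu_inf` for `omega = 0`;
#'   for `omega = 1` a monotone non-increasing function of shear rate
#'   bounded in `[mu_inf, 16.2 * mu_inf]`.
#' @examples
#' carreau_viscosity(0, fluid_properties(omega = 1))     # 16.2 * mu_inf
#' carreau_viscosity(1000, fluid_properties(omega = 1))  # close to mu_inf
#' @export
carreau_viscosity <- function(gamma_dot, props = fluid_properties()) {
  stopifnot(inherits(props, "fluid_properties"))
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0)) {
    stopf("shear rate must be finite and >= 0")
  }
  props$mu_inf * (1 + 15.2 * props$omega *
    (1 + (props$lam * gamma_dot)^2)^((props$n_exp - 1) / 2))
}

# eta range where the exact Bessel expression is evaluated; outside it the
# analytic limits (uniform / parabolic) are returned. The lower switch
# coincides with the series/asymptotic split of the Bessel evaluation
# (|z| = 1/eta = BESSEL_SPLIT); branch agreement there is tested.
ETA_PARABOLIC <- 1e3
ETA_UNIFORM <- 2e-3

#' Womersley-family inlet velocity profile
#'
#' One-parameter family of axisymmetric velocity profiles
#' \eqn{v(r) = v_0\,\Re\{N\,[1 - J_0(k\,2r/D)/J_0(k)]\}} with
#' \eqn{k = \eta^{-1} i^{3/2}} and normalization
#' \eqn{N = [1 - 2\eta\,i^{-3/2} J_1(k)/J_0(k)]^{-1}}, the oscillatory
#' pipe-flow solution at Womersley number \eqn{1/\eta}. It is used purely
#' as a shape family interpolating between the uniform profile
#' (\eqn{\eta = 0}) and the parabolic Poiseuille profile
#' (\eqn{\eta = \infty}); the normalization makes the section average
#' equal `v0` exactly for every `eta`.
#'
#' @param r radial positions, `0 <= r <= D/2` (m); vectorised.
#' @param D lumen diameter (m).
#' @param eta profile-shape parameter, `>= 0`, `Inf` allowed.
#' @param v0 instantaneous section-averaged velocity (m/s).
#' @return Axial velocity at each `r` (m/s).
#' @examples
#' womersley_profile(0, D = 5.15e-3, eta = Inf, v0 = 0.7)  # 2 * v0
#' @export
womersley_profile <- function(r, D, eta, v0 = 1) {
  assert_scalar_num(D, "D", lower = .Machine$double.eps)
  assert_scalar_num(eta, "eta", lower = 0, allow_inf = TRUE)
  assert_scalar_num(v0, "v0")
  if (any(!is.finite(r)) || any(r < 0) || any(r > D / 2 * (1 + 1e-12))) {
    stopf("radial positions must lie in [0, D/2]")
  }
  s <- pmin(1, 2 * r / D)   # normalized radius
  if (eta == 0) return(rep(v0, length(s)))
  if (eta >= ETA_PARABOLIC) return(2 * v0 * (1 - s^2))
  if (eta < ETA_UNIFORM) {
    # Stokes-layer asymptotic: uniform core with an exponential wall layer
    # of thickness ~ eta * D. Avoids overflow of the Bessel expressions.
    norm <- 1 / (1 - 2 * eta * complex(real = sqrt(0.5),
                                       imaginary = -sqrt(0.5)))
    decay <- -(1 - s) * complex(real = 1, imaginary = 1) / (eta * sqrt(2))
    layer <- ifelse(s > 0, exp(decay - 0.5 * log(s)), 0 + 0i)
    return(v0 * Re(norm * (1 - layer)))
  }
  k <- (1 / eta) * complex(real = -sqrt(0.5), imaginary = sqrt(0.5)) # i^{3/2}/eta
  J0k <- besselJ_complex(k, 0)
  J1k <- besselJ_complex(k, 1)
  i_m32 <- complex(real = -sqrt(0.5), imaginary = -sqrt(0.5))  # i^{-3/2}
  norm <- 1 / (1 - 2 * eta * i_m32 * J1k / J0k)
  prof <- norm * (1 - besselJ_complex(k * s, 0) / J0k)
  v0 * Re(prof)
}

#' Reynolds number \eqn{Re = \rho v_{0m} D / \mu_\infty}
#'
#' @param props a [fluid_properties()].
#' @param v0m mean (cycle-averaged) section velocity (m/s).
#' @param D lumen diameter (m).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(props, v0m, D) {
  stopifnot(inherits(props, "fluid_properties"))
  assert_scalar_num(v0m, "v0m", lower = 0)
  assert_scalar_num(D, "D", lower = .Machine$double.eps)
  props$rho * v0m * D / props$mu_inf
}

#' Instantaneous Reynolds number \eqn{Re^* = \rho v_0(t) D / \mu_\infty}
#'
#' @param props a [fluid_properties()].
#' @param v0_t instantaneous section velocity values (m/s); vectorised.
#' @param D lumen diameter (m).
#' @return Dimensionless instantaneous Reynolds numbers.
#' @export
reynolds_inst <- function(props, v0_t, D) {
  stopifnot(inherits(props, "fluid_properties"))
  assert_scalar_num(D, "D", lower = .Machine$double.eps)
  props$rho * v0_t * D / props$mu_inf
}

#' Womersley number \eqn{\alpha = D (2\pi\Omega\rho/\mu_\infty)^{1/2}}
#'
#' @param props a [fluid_properties()].
#' @param Omega cardiac cycle frequency (1/s).
#' @param D lumen diameter (m).
#' @return Dimensionless Womersley number.
#' @examples
#' womersley_number(fluid_properties(), Omega = 1.2, D = 5.15e-3)  # 7.78
#' @export
womersley_number <- function(props, Omega, D) {
  stopifnot(inherits(props, "fluid_properties"))
  assert_scalar_num(Omega, "Omega", lower = 0)
  assert_scalar_num(D, "D", lower = .Machine$double.eps)
  D * sqrt(2 * pi * Omega * props$rho / props$mu_inf)
}
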