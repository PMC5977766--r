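#' Parametric eccentric stenosis geometry
#'
#' The idealized lumen is a straight cylinder of diameter `D` and length `L`
#' from which a sphere of diameter `Ds` is subtracted, its centre placed at
#' axial position `Ls` from the inlet and at transverse distance `d` from
#' the cylinder axis. With `d` between `(Ds - D)/2` and `(Ds + D)/2` the
#' sphere carves an eccentric, partially occluding plaque whose severity is
#' strictly between 0 and 1. Default aspect ratios are `Ds/D = 1.94`,
#' `L/D = 11.6`, `Ls/D = 1.92`.
#'
#' Exactly one of `d` and `severity` must be supplied (or neither, in which
#' case `severity = 0.583`, a stenosis near the clinical decision
#' threshold). When `severity` is supplied the offset is obtained by
#' [calibrate_offset()].
#'
#' @param D lumen diameter (m).
#' @param Ds carving-sphere diameter (m). Default `1.94 * D`.
#' @param L vessel length (m). Default `11.6 * D`.
#' @param Ls axial position of the sphere centre from the inlet (m).
#'   Default `1.92 * D`.
#' @param d transverse distance from the cylinder axis to the sphere
#'   centre (m), or `NULL` to calibrate from `severity`.
#' @param severity target severity in (0, 1) used to calibrate `d`, or
#'   `NULL` when `d` is given.
#' @return An object of class `stenosis_geometry`: a list with fields
#'   `D`, `Ds`, `L`, `Ls`, `d` (all metres).
#' @examples
#' g <- stenosis_geometry(D = 5.15e-3, Ds = 10e-3, severity = 0.583)
#' severity(g)
#' @export
stenosis_geometry <- function(D, Ds = 1.94 * D, L = 11.6 * D,
                              Ls = 1.92 * D, d = NULL, severity = NULL) {
  assert_scalar_num(D, "D", lower = .Machine$double.eps)
  assert_scalar_num(Ds, "Ds", lower = .Machine$double.eps)
  assert_scalar_num(L, "L", lower = .Machine$double.eps)
  assert_scalar_num(Ls, "Ls", lower = .Machine$double.eps)
  if (L <= Ls) stopf("need L > Ls > 0 (got L = %g, Ls = %g)", L, Ls)
  if (!is.null(d) && !is.null(severity)) {
    stopf("supply only one of `d` and `severity`")
  }
  if (is.null(d)) {
    if (is.null(severity)) severity <- 0.583
    d <- calibrate_offset(D, Ds, severity)
  }
  assert_scalar_num(d, "d", lower = 0)
  geom <- structure(list(D = D, Ds = Ds, L = L, Ls = Ls, d = d),
                    class = "stenosis_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  with(geom, {
    if (d <= (Ds - D) / 2 || d >= (Ds + D) / 2) {
      stopf(paste0(
        "offset d = %g m outside the partial-occlusion regime ",
        "(%g, %g): severity would not lie strictly in (0, 1)"),
        d, (Ds - D) / 2, (Ds + D) / 2)
    }
  })
  invisible(geom)
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat("Eccentric stenosis geometry (cylinder minus sphere)\n")
  cat(sprintf("  D  = %.4g mm   Ds = %.4g mm\n", x$D * 1e3, x$Ds * 1e3))
  cat(sprintf("  L  = %.4g mm   Ls = %.4g mm\n", x$L * 1e3, x$Ls * 1e3))
  cat(sprintf("  d  = %.4g mm (transverse sphere-centre offset)\n",
              x$d * 1e3))
  cat(sprintf("  severity S = %.4f   A_min = %.4g mm^2\n",
              severity(x), min_area(x) * 1e6))
  invisible(x)
}

#' Area of intersection of two coplanar discs (circular lens)
#'
#' Closed-form lens area of two discs of radii `rA` and `rB` whose centres
#' are a distance `d` apart. Continuous in all arguments; returns 0 for
#' disjoint discs and the full area of the smaller disc when it is
#' contained in the larger one.
#'
#' @param rA,rB disc radii (> 0), same length units.
#' @param d centre-to-centre distance (>= 0). Vectorised over `d`.
#' @return Intersection area, in squared input units.
#' @examples
#' lens_area(1, 1, 3)            # disjoint: 0
#' lens_area(1, 3, 0) / pi       # engulfed: rA^2
#' @export
lens_area <- function(rA, rB, d) {
  assert_scalar_num(rA, "rA", lower = .Machine$double.eps)
  assert_scalar_num(rB, "rB", lower = .Machine$double.eps)
  if (any(!is.finite(d)) || any(d < 0)) {
    stopf("centre distance `d` must be finite and >= 0")
  }
  out <- numeric(length(d))
  full <- d <= abs(rA - rB)
  out[full] <- pi * min(rA, rB)^2
  mid <- !full & d < rA + rB
  if (any(mid)) {
    dm <- d[mid]
    # clamp acos arguments against roundoff at the tangency limits
    c1 <- pmin(1, pmax(-1, (dm^2 + rA^2 - rB^2) / (2 * dm * rA)))
    c2 <- pmin(1, pmax(-1, (dm^2 + rB^2 - rA^2) / (2 * dm * rB)))
    s <- (-dm + rA + rB) * (dm + rA - rB) * (dm - rA + rB) * (dm + rA + rB)
    out[mid] <- rA^2 * acos(c1) + rB^2 * acos(c2) -
      0.5 * sqrt(pmax(0, s))
  }
  out
}

# Cross-sectional radius of the carving sphere at axial position z,
# NA outside the carved span.
sphere_cross_radius <- function(geom, z) {
  rs2 <- (geom$Ds / 2)^2 - (z - geom$Ls)^2
  ifelse(rs2 > 0, sqrt(pmax(0, rs2)), NA_real_)
}

#' Lumen cross-sectional area profile
#'
#' Area of the lumen cross section at axial position `z`:
#' \eqn{A(z) = \pi D^2/4 - \mathrm{lens}(D/2, r_s(z), d)}, where
#' \eqn{r_s(z)} is the sphere's cross-sectional radius, which vanishes
#' outside the carved span `|z - Ls| >= Ds/2`. The minimum is attained at
#' the neck plane `z = Ls`.
#'
#' @param geom a [stenosis_geometry()].
#' @param z axial positions in `[0, L]` (m); vectorised.
#' @return Lumen areas (m^2).
#' @export
area_profile <- function(geom, z) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (any(!is.finite(z)) || any(z < 0) || any(z > geom$L)) {
    stopf("z must lie within [0, L] = [0, %g]", geom$L)
  }
  a_full <- pi * geom$D^2 / 4
  rs <- sphere_cross_radius(geom, z)
  out <- rep(a_full, length(z))
  carved <- !is.na(rs) & rs > 0
  if (any(carved)) {
    out[carved] <- a_full -
      vapply(rs[carved], function(r) lens_area(geom$D / 2, r, geom$d),
             numeric(1))
  }
  out
}

# Minimum lumen area, evaluated in closed form on the neck plane z = Ls.
min_area <- function(geom) {
  pi * geom$D^2 / 4 - lens_area(geom$D / 2, geom$Ds / 2, geom$d)
}

#' Stenosis severity
#'
#' \eqn{S = 1 - 4 A_{\min} / (\pi D^2)}: the fractional reduction of the
#' minimum lumen cross-section area relative to the healthy artery.
#'
#' @param geom a [stenosis_geometry()].
#' @return Severity in `[0, 1)` (dimensionless).
#' @export
severity <- function(geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  1 - 4 * min_area(geom) / (pi * geom$D^2)
}

#' Calibrate the sphere-centre offset for a target severity
#'
#' The transverse offset `d` is never part of published stenosis
#' descriptions; severities are. Severity is strictly decreasing in `d` at
#' fixed `(D, Ds)`, so the offset reproducing a stated severity is found by
#' root bracketing on the closed-form lens area.
#'
#' @param D lumen diameter (m).
#' @param Ds carving-sphere diameter (m).
#' @param S_target severity strictly in (0, 1).
#' @param tol relative convergence tolerance on `d`.
#' @return Offset `d` (m) such that the resulting severity equals
#'   `S_target` to within `tol`.
#' @examples
#' d <- calibrate_offset(5.15e-3, 10e-3, 0.583)   # ~ 4.434 mm
#' @export
calibrate_offset <- function(D, Ds, S_target, tol = 1e-12) {
  assert_scalar_num(D, "D", lower = .Machine$double.eps)
  assert_scalar_num(Ds, "Ds", lower = .Machine$double.eps)
  if (!is.numeric(S_target) || length(S_target) != 1L ||
      is.na(S_target) || S_target <= 0 || S_target >= 1) {
    stopf("S_target must lie strictly in (0, 1); got %s",
          format(S_target))
  }
  lo <- max(0, (Ds - D) / 2)   # engulfment limit, S -> 1 (when Ds > D)
  hi <- (Ds + D) / 2           # tangency limit,   S -> 0
  f <- function(d) 4 * lens_area(D / 2, Ds / 2, d) / (pi * D^2) - S_target
  res <- tryCatch(
    stats::uniroot(f, c(lo, hi), tol = tol * hi, maxiter = 200L,
                   extendInt = "no"),
    error = function(e) {
      stopf("offset calibration failed for S_target = %g: %s",
            S_target, conditionMessage(e))
    }
  )
  res$root
}

#' Apply a segmentation-error perturbation to a geometry
#'
#' A contour-detection error of one pixel in the angiographic image maps to
#' a signed error `delta_Ds` in the carving-sphere diameter. The sphere
#' centre `(Ls, d)` is held fixed, so severity increases for
#' `delta_Ds > 0` and decreases for `delta_Ds < 0`.
#'
#' @param geom a [stenosis_geometry()].
#' @param delta_Ds signed sphere-diameter error (m); `|delta_Ds| < Ds`.
#' @return A new `stenosis_geometry` with `Ds + delta_Ds`.
#' @examples
#' g <- stenosis_geometry(D = 5.15e-3, Ds = 10e-3, severity = 0.583)
#' severity(perturb(g, 300e-6))   # ~ 0.62
#' severity(perturb(g, -300e-6))  # ~ 0.54
#' @export
perturb <- function(geom, delta_Ds) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  assert_scalar_num(delta_Ds, "delta_Ds")
  if (abs(delta_Ds) >= geom$Ds) {
    stopf("|delta_Ds| = %g must be smaller than Ds = %g",
          abs(delta_Ds), geom$Ds)
  }
  out <- geom
  out$Ds <- geom$Ds + delta_Ds
  validate_geometry(out)
  out
}
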