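# Independent oracles used across the suite. Each re-derives a quantity by
# a route disjoint from the implementation it checks.

# Reference nominal stenosis used throughout.
nominal_geometry <- function() {
  stenosis_geometry(D = 5.15e-3, Ds = 10e-3, severity = 0.583)
}

# Grid point-counting oracle for the circle-circle intersection area:
# cell-centre counting over the bounding box of disc A (origin), disc B at
# (d, 0). Accuracy ~2e-4 relative at n = 1500 for non-degenerate overlaps.
grid_lens_oracle <- function(rA, rB, d, n = 1500L) {
  h <- 2 * rA / n
  xs <- seq(-rA + h / 2, rA - h / 2, length.out = n)
  inA <- outer(xs^2, xs^2, "+") <= rA^2
  inB <- outer((xs - d)^2, xs^2, "+") <= rB^2
  sum(inA & inB) * h^2
}

# Voxel-slab oracle for the lumen area at axial position z: fraction of a
# fine grid over the lumen disc lying outside the sphere's cross circle.
voxel_area_oracle <- function(geom, z, n = 1200L) {
  R <- geom$D / 2
  h <- 2 * R / n
  xs <- seq(-R + h / 2, R - h / 2, length.out = n)
  rs2 <- (geom$Ds / 2)^2 - (z - geom$Ls)^2
  in_lumen <- outer(xs^2, xs^2, "+") <= R^2
  if (rs2 <= 0) return(sum(in_lumen) * h^2)
  in_sphere <- outer((xs - geom$d)^2, xs^2, "+") <= rs2
  sum(in_lumen & !in_sphere) * h^2
}

# Quadrature oracle for J_nu(z), complex z: Gauss-Legendre integration of
# the integral representations
#   J0(z) = (1/pi) int_0^pi cos(z sin(th)) dth
#   J1(z) = (1/pi) int_0^pi cos(th - z sin(th)) dth
bessel_quadrature_oracle <- function(z, nu, n_nodes = 600L) {
  gl <- pracma::gaussLegendre(n_nodes, 0, pi)
  f <- if (nu == 0) {
    function(th) cos(z * sin(th))
  } else {
    function(th) cos(th - z * sin(th))
  }
  sum(gl$w * vapply(gl$x, f, complex(1))) / pi
}

# Smooth-surface area of the tessellation's parametric patch by tensor
# Gauss-Legendre quadrature of |r_theta x r_z| (central-difference partials).
smooth_patch_area_oracle <- function(geom, margin = 1, n_nodes = 160L) {
  span <- ffrsens:::stenotic_patch_span(geom, margin)
  gth <- pracma::gaussLegendre(n_nodes, 0, 2 * pi)
  gz <- pracma::gaussLegendre(n_nodes, span[1], span[2])
  grid <- expand.grid(theta = gth$x, z = gz$x)
  h_th <- 1e-6
  h_z <- 1e-6 * geom$D
  p_t1 <- ffrsens:::wall_points(geom, grid$theta + h_th, grid$z)
  p_t0 <- ffrsens:::wall_points(geom, grid$theta - h_th, grid$z)
  p_z1 <- ffrsens:::wall_points(geom, grid$theta, grid$z + h_z)
  p_z0 <- ffrsens:::wall_points(geom, grid$theta, grid$z - h_z)
  rt <- (p_t1 - p_t0) / (2 * h_th)
  rz <- (p_z1 - p_z0) / (2 * h_z)
  cr <- cbind(rt[, 2] * rz[, 3] - rt[, 3] * rz[, 2],
              rt[, 3] * rz[, 1] - rt[, 1] * rz[, 3],
              rt[, 1] * rz[, 2] - rt[, 2] * rz[, 1])
  jac <- sqrt(rowSums(cr^2))
  w <- as.vector(outer(gth$w, gz$w))
  sum(w * jac)
}

# Brute-force windowed-minimum FFR: resample both records onto a common
# dense grid and scan every window start by direct trapezoidal averaging.
brute_force_ffr <- function(P0, P1, tau, oversample = 10L) {
  lo <- max(P0$t[1], P1$t[1])
  hi <- min(P0$t[length(P0$t)], P1$t[length(P1$t)])
  dt <- min(diff(P0$t)) / oversample
  tg <- seq(lo, hi, by = dt)
  x0 <- stats::approx(P0$t, P0$x, tg)$y
  x1 <- stats::approx(P1$t, P1$x, tg)$y
  nw <- max(which(tg + tau <= hi + 1e-12))
  k <- round(tau / dt)
  trapz_mean <- function(x, i) {
    idx <- i:(i + k)
    sum((x[idx[-length(idx)]] + x[idx[-1]]) / 2) * dt / (k * dt)
  }
  ratios <- vapply(seq_len(nw), function(i) {
    trapz_mean(x1, i) / trapz_mean(x0, i)
  }, numeric(1))
  min(ratios)
}

# Direct 2x2 solve for the correlation-model coefficients from two anchors.
solve_two_anchors <- function(anchors) {
  A <- cbind(1 / anchors$reynolds,
             0.5 * (anchors$severity / (1 - anchors$severity))^2)
  as.numeric(solve(A, anchors$pi))
}
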