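#' FFR versus severity under a segmentation perturbation
#'
#' For each target severity: calibrate the sphere-centre offset, apply the
#' carving-sphere diameter error `delta_Ds` with the centre held fixed,
#' recompute the (perturbed) severity, synthesize the distal pressure with
#' the reduced-order drop model, and evaluate the clinical FFR statistic.
#' A positive `delta_Ds` deepens every stenosis, so its curve lies below
#' the nominal one pointwise; a negative `delta_Ds` lies above.
#'
#' @param severities strictly increasing grid of nominal severities in
#'   (0, 1).
#' @param delta_Ds signed carving-sphere diameter error (m).
#' @param P0 proximal pressure [waveform_record()] (Pa).
#' @param w an [inlet_waveform()].
#' @param props a [fluid_properties()].
#' @param model a [pressure_drop_model()].
#' @param D lumen diameter (m).
#' @param Ds carving-sphere diameter (m).
#' @param tau cycle period passed to [compute_ffr()] (`"auto"` to
#'   estimate from `P0`).
#' @return An object of class `ffr_curve`: a list with `severities` (the
#'   nominal grid), `severities_actual` (after perturbation), `ffr`,
#'   `delta_Ds` and a `provenance` list.
#' @export
ffr_vs_severity <- function(severities, delta_Ds, P0, w,
                            props = fluid_properties(),
                            model = pressure_drop_model(),
                            D = 5.15e-3, Ds = 1.94 * D, tau = "auto") {
  if (length(severities) < 1L || any(!is.finite(severities)) ||
      any(severities <= 0) || any(severities >= 1)) {
    stopf("severities must lie strictly in (0, 1)")
  }
  if (is.unsorted(severities, strictly = TRUE)) {
    stopf("severities must be strictly increasing")
  }
  if (identical(tau, "auto")) tau <- estimate_period(P0)$tau
  ffr <- numeric(length(severities))
  s_act <- numeric(length(severities))
  for (i in seq_along(severities)) {
    res <- tryCatch({
      geom <- stenosis_geometry(D = D, Ds = Ds,
                                severity = severities[i])
      if (delta_Ds != 0) geom <- perturb(geom, delta_Ds)
      s_i <- severity(geom)
      P1 <- distal_pressure(P0, w, s_i, props, model, D)
      list(s = s_i, ffr = compute_ffr(P0, P1, tau)$ffr)
    }, error = function(e) {
      stopf("FFR evaluation failed at severity %.4g: %s",
            severities[i], conditionMessage(e))
    })
    s_act[i] <- res$s
    ffr[i] <- res$ffr
  }
  structure(list(severities = severities, severities_actual = s_act,
                 ffr = ffr, delta_Ds = delta_Ds,
                 provenance = list(D = D, Ds = Ds, tau = tau)),
            class = "ffr_curve")
}

#' @export
print.ffr_curve <- function(x, ...) {
  cat(sprintf(
    "FFR curve: %d severities in [%.3g, %.3g], delta_Ds = %+g um\n",
    length(x$severities), min(x$severities), max(x$severities),
    x$delta_Ds * 1e6))
  cat(sprintf("  FFR range [%.4f, %.4f]\n", min(x$ffr), max(x$ffr)))
  invisible(x)
}

#' Critical severity: where an FFR curve crosses the decision threshold
#'
#' Monotone piecewise-linear interpolation of the first downward crossing
#' of `threshold` along the curve. Returns `NA` (with a message attribute)
#' when the curve never crosses.
#'
#' @param curve an [ffr_vs_severity()] result, or any list with
#'   `severities` and `ffr` fields.
#' @param threshold FFR decision threshold (default 0.8).
#' @return The interpolated severity `S*` at the crossing, or `NA_real_`
#'   if there is none.
#' @examples
#' toy <- list(severities = seq(0, 0.9, 0.1),
#'             ffr = 1 - 0.5 * seq(0, 0.9, 0.1))
#' critical_severity(toy)   # 0.4
#' @export
critical_severity <- function(curve, threshold = 0.8) {
  s <- curve$severities
  f <- curve$ffr
  assert_scalar_num(threshold, "threshold")
  below <- which(f < threshold)
  if (length(below) == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "curve never falls below the threshold"
    return(out)
  }
  k <- below[1]
  if (k == 1L) return(s[1])
  # linear interpolation between the bracketing grid points
  s[k - 1L] + (threshold - f[k - 1L]) * (s[k] - s[k - 1L]) /
    (f[k] - f[k - 1L])
}

#' FFR population histogram
#'
#' Bin edges and patient counts of a population FFR distribution, as
#' published in large FFR registries.
#'
#' @param bin_edges strictly increasing FFR bin edges, length
#'   `length(counts) + 1`.
#' @param counts non-negative patient counts per bin.
#' @return An object of class `ffr_histogram`.
#' @export
ffr_histogram <- function(bin_edges, counts) {
  if (length(bin_edges) != length(counts) + 1L) {
    stopf("need length(bin_edges) == length(counts) + 1")
  }
  if (any(diff(bin_edges) <= 0)) {
    stopf("bin edges must be strictly increasing")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stopf("counts must be finite and >= 0")
  }
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts)),
            class = "ffr_histogram")
}

#' @export
print.ffr_histogram <- function(x, ...) {
  cat(sprintf("FFR histogram: %d bins on [%.3g, %.3g], %g patients\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$counts)))
  invisible(x)
}

#' Read / write FFR histograms as CSV
#'
#' Format: columns `bin_lo,bin_hi,count`, contiguous bins.
#'
#' @param path file path.
#' @param hist an [ffr_histogram()].
#' @return `read_histogram()` returns an [ffr_histogram()];
#'   `write_histogram()` returns `path` invisibly.
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_lo", "bin_hi", "count")
  if (!all(need %in% names(df))) {
    stopf("histogram CSV must have columns %s", paste(need, collapse = ","))
  }
  if (any(abs(utils::head(df$bin_hi, -1) - utils::tail(df$bin_lo, -1)) >
          1e-9)) {
    stopf("histogram bins must be contiguous")
  }
  ffr_histogram(c(df$bin_lo, df$bin_hi[nrow(df)]), df$count)
}

#' @rdname read_histogram
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "ffr_histogram"))
  n <- length(hist$counts)
  utils::write.csv(data.frame(bin_lo = hist$bin_edges[seq_len(n)],
                              bin_hi = hist$bin_edges[seq_len(n) + 1L],
                              count = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Remap an FFR histogram through a geometry-perturbation error
#'
#' Clinical-impact remapping: treat each histogram bin centre within
#' `range` as a "true" FFR value, invert the nominal FFR-versus-severity
#' curve to find the underlying severity, look up the FFR the perturbed
#' geometry would have produced at that severity, and move the bin's
#' patient count to the bin containing that wrong FFR value. Bins outside
#' `range` are untouched; the total count is conserved exactly.
#'
#' @param hist an [ffr_histogram()].
#' @param nominal an [ffr_vs_severity()] curve for `delta_Ds = 0`; must be
#'   monotone over the severities mapped from `range`.
#' @param perturbed an [ffr_vs_severity()] curve for the perturbed
#'   geometry.
#' @param range FFR interval whose bins are remapped (default
#'   `c(0.7, 0.9)`).
#' @return A new [ffr_histogram()] on the same bins.
#' @export
histogram_remap <- function(hist, nominal, perturbed,
                            range = c(0.7, 0.9)) {
  stopifnot(inherits(hist, "ffr_histogram"))
  if (length(range) != 2L || range[1] >= range[2]) {
    stopf("range must be an increasing length-2 interval")
  }
  f_nom <- nominal$ffr
  s_nom <- nominal$severities
  if (any(diff(f_nom) >= 0)) {
    # the nominal curve must be invertible (strictly decreasing) on its grid
    stopf("nominal FFR curve is not strictly monotone over its severity grid")
  }
  n <- length(hist$counts)
  centres <- (hist$bin_edges[seq_len(n)] + hist$bin_edges[seq_len(n) + 1L]) / 2
  counts <- hist$counts
  out <- counts
  in_range <- centres >= range[1] & centres <= range[2] & counts > 0
  for (i in which(in_range)) {
    f <- centres[i]
    if (f > max(f_nom) || f < min(f_nom)) next  # outside curve coverage
    # f_nom is strictly decreasing in severity; approx() needs ascending x
    S <- stats::approx(rev(f_nom), rev(s_nom), xout = f,
                       ties = "ordered")$y
    f_wrong <- stats::approx(perturbed$severities, perturbed$ffr, xout = S,
                             rule = 2, ties = "ordered")$y
    j <- findInterval(f_wrong, hist$bin_edges, rightmost.closed = TRUE)
    j <- min(max(j, 1L), n)
    out[i] <- out[i] - counts[i]
    out[j] <- out[j] + counts[i]
  }
  ffr_histogram(hist$bin_edges, out)
}

#' Patients below an FFR threshold
#'
#' Sum of the counts in bins entirely below `threshold`, plus a pro-rata
#' fraction of a bin the threshold straddles (uniform-within-bin
#' assumption).
#'
#' @param hist an [ffr_histogram()].
#' @param threshold FFR decision threshold (default 0.8).
#' @return Number of patients with FFR below the threshold.
#' @export
count_below <- function(hist, threshold = 0.8) {
  stopifnot(inherits(hist, "ffr_histogram"))
  n <- length(hist$counts)
  lo <- hist$bin_edges[seq_len(n)]
  hi <- hist$bin_edges[seq_len(n) + 1L]
  frac <- pmin(pmax((threshold - lo) / (hi - lo), 0), 1)
  sum(hist$counts * frac)
}
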