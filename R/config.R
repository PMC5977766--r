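# Configuration and the end-to-end pipeline driver.

# Full default configuration. Geometry and fluid defaults are the nominal
# reference stenosis (D = 5.15 mm, Ds/D = 1.94, L/D = 11.6, Ls/D = 1.92,
# severity 0.583) and standard blood properties.
default_config <- function() {
  list(
    geometry = list(D_mm = 5.15, Ds_mm = 1.94 * 5.15, L_mm = 11.6 * 5.15,
                    Ls_mm = 1.92 * 5.15, severity = 0.583,
                    offset_mm = NULL),
    fluid = list(rho = 1060, mu_inf = 0.0035, lam = 3.31, n_exp = 0.357,
                 omega = 0),
    waveform = list(v0m = 0.7, Omega = 1.2, n_cycles = 25L,
                    samples_per_cycle = 100L, jitter = 0.03,
                    noise_sd = 0.007, file = NULL),
    pressure = list(P_sys_mmHg = 130, P_dia_mmHg = 70, noise_sd_mmHg = 0.6,
                    file = NULL),
    model = list(Kv = NULL, kt = NULL, Ku_Leff_over_D = 2 * 1.92 + 1.94,
                 anchors_file = NULL),
    sweep = list(severities = seq(0.40, 0.70, by = 0.05),
                 delta_Ds_um = c(-300, 0, 300)),
    remap = list(range = c(0.7, 0.9), n_patients = 1944L, mode = 0.85,
                 concentration = 25, bin_width = 0.05),
    seed = 1L,
    out_dir = NULL
  )
}

# Merge user values over defaults, rejecting unknown keys at both levels.
merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stopf("unknown config key%s: %s",
          if (length(unknown) > 1L) "s" else "",
          paste0(path, unknown, collapse = ", "))
  }
  out <- defaults
  for (nm in names(user)) {
    val <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      merge_config(user[[nm]], defaults[[nm]], paste0(path, nm, "."))
    } else {
      user[[nm]]
    }
    out[nm] <- list(val)   # keeps explicit NULLs instead of dropping keys
  }
  out
}

#' Load, validate and complete a pipeline configuration
#'
#' Reads a JSON configuration, validates every key against the schema
#' (unknown keys are rejected by name) and fills omitted values with the
#' package defaults: the nominal reference stenosis (`D = 5.15` mm,
#' `Ds/D = 1.94`, `L/D = 11.6`, `Ls/D = 1.92`, severity 0.583), standard
#' blood properties (`rho = 1060`, `mu_inf = 0.0035`, `lam = 3.31`,
#' `n_exp = 0.357`), and the typical hyperaemic waveform parameters
#' (`v0m = 0.7` m/s, `Omega = 1.2` 1/s).
#'
#' @param path JSON file path, or `NULL` for the pure defaults.
#' @return An object of class `run_config` (a nested named list).
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- merge_config(user, default_config())
  # light type checks on the values that feed computations directly
  with(cfg$geometry, {
    assert_scalar_num(D_mm, "geometry.D_mm", lower = 1e-6)
    assert_scalar_num(Ds_mm, "geometry.Ds_mm", lower = 1e-6)
  })
  if (!is.null(cfg$geometry$severity) && !is.null(cfg$geometry$offset_mm)) {
    stopf("config may set only one of geometry.severity and geometry.offset_mm")
  }
  structure(cfg, class = "run_config")
}

#' Save a configuration as JSON
#'
#' @param cfg a `run_config` (or plain list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# Stable hash of a configuration for provenance stamping. Output paths do
# not influence the computation, so they are excluded from the hash.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full FFR sensitivity pipeline
#'
#' End-to-end composition of the package's stages: synthesize (or load)
#' the inlet velocity and proximal pressure waveforms, fit the
#' six-harmonic inlet model, calibrate the pressure-drop surrogate, sweep
#' FFR versus severity for each requested carving-sphere diameter error,
#' extract critical severities, and remap a population FFR histogram
#' through the perturbation. Deterministic for a fixed config and seed;
#' all randomness flows from `cfg$seed` through named substreams.
#'
#' @param cfg a [load_config()] result (default: all package defaults).
#' @return An object of class `ffr_pipeline_result`: a list with
#'   `curves` (one [ffr_vs_severity()] curve per `delta_Ds`),
#'   `critical` (named critical severities), `histogram`,
#'   `histogram_remapped`, `revascularized` (counts below 0.8 before and
#'   after remapping), `waveform` (fitted [inlet_waveform()]), `model`,
#'   and `provenance` (config hash, seed, package version). If
#'   `cfg$out_dir` is set, curves, histograms and a result summary JSON
#'   are written there.
#' @export
run_pipeline <- function(cfg = load_config()) {
  if (!inherits(cfg, "run_config")) stopf("cfg must come from load_config()")
  props <- with(cfg$fluid,
                fluid_properties(rho, mu_inf, lam, n_exp, omega))
  D <- cfg$geometry$D_mm * 1e-3
  Ds <- cfg$geometry$Ds_mm * 1e-3

  # --- input waveforms ------------------------------------------------
  wf <- cfg$waveform
  if (!is.null(wf$file)) {
    if (!file.exists(wf$file)) {
      stopf("waveform file not found: %s", wf$file)
    }
    vrec <- read_waveform(wf$file, unit = "m/s")
  } else {
    vrec <- gen_velocity_waveform(
      v0m = wf$v0m, Omega = wf$Omega, n_cycles = wf$n_cycles,
      samples_per_cycle = wf$samples_per_cycle, jitter = wf$jitter,
      noise_sd = wf$noise_sd,
      seed = substream_seed(cfg$seed, "velocity"))$record
  }
  pf <- cfg$pressure
  if (!is.null(pf$file)) {
    if (!file.exists(pf$file)) {
      stopf("pressure file not found: %s", pf$file)
    }
    P0 <- read_waveform(pf$file, unit = "mmHg")
  } else {
    P0 <- gen_pressure_waveform(
      P_sys = pf$P_sys_mmHg, P_dia = pf$P_dia_mmHg, Omega = wf$Omega,
      n_cycles = wf$n_cycles, samples_per_cycle = wf$samples_per_cycle,
      jitter = wf$jitter, noise_sd = pf$noise_sd_mmHg,
      seed = substream_seed(cfg$seed, "pressure"))
  }
  w <- fit_fourier(vrec, n_harmonics = 6L)

  # --- pressure-drop surrogate ----------------------------------------
  model <- if (!is.null(cfg$model$anchors_file)) {
    calibrate_anchors(utils::read.csv(cfg$model$anchors_file),
                      Ku_Leff_over_D = cfg$model$Ku_Leff_over_D)
  } else {
    pressure_drop_model(Kv = cfg$model$Kv, kt = cfg$model$kt,
                        Ku_Leff_over_D = cfg$model$Ku_Leff_over_D)
  }

  # --- severity sweep under each perturbation -------------------------
  tau <- estimate_period(P0)$tau
  dds <- cfg$sweep$delta_Ds_um * 1e-6
  curves <- lapply(dds, function(dd) {
    ffr_vs_severity(cfg$sweep$severities, dd, P0, w, props, model,
                    D = D, Ds = Ds, tau = tau)
  })
  names(curves) <- sprintf("delta_Ds_%+g_um", cfg$sweep$delta_Ds_um)
  critical <- vapply(curves, function(cu) {
    as.numeric(critical_severity(cu, 0.8))
  }, numeric(1))

  # --- histogram clinical-impact remap --------------------------------
  nominal <- curves[[which(cfg$sweep$delta_Ds_um == 0)[1]]]
  worst <- curves[[which.max(cfg$sweep$delta_Ds_um)]]
  hist0 <- gen_ffr_histogram(
    n_patients = cfg$remap$n_patients, mode = cfg$remap$mode,
    concentration = cfg$remap$concentration,
    bin_width = cfg$remap$bin_width,
    seed = substream_seed(cfg$seed, "histogram"))
  hist1 <- histogram_remap(hist0, nominal, worst,
                           range = cfg$remap$range)

  res <- structure(list(
    curves = curves,
    critical = critical,
    histogram = hist0,
    histogram_remapped = hist1,
    revascularized = c(original = count_below(hist0, 0.8),
                       remapped = count_below(hist1, 0.8)),
    waveform = w,
    model = model,
    tau = tau,
    provenance = list(config_hash = config_hash(cfg),
                      seed = cfg$seed,
                      package_version =
                        as.character(utils::packageVersion("ffrsens")))
  ), class = "ffr_pipeline_result")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg)
  res
}

write_pipeline_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  curve_df <- do.call(rbind, lapply(names(res$curves), function(nm) {
    cu <- res$curves[[nm]]
    data.frame(delta_Ds_um = cu$delta_Ds * 1e6,
               severity_nominal = cu$severities,
               severity_actual = cu$severities_actual, ffr = cu$ffr)
  }))
  utils::write.csv(curve_df, file.path(cfg$out_dir, "curves.csv"),
                   row.names = FALSE)
  write_histogram(res$histogram,
                  file.path(cfg$out_dir, "histogram_original.csv"))
  write_histogram(res$histogram_remapped,
                  file.path(cfg$out_dir, "histogram_remapped.csv"))
  summary <- list(
    critical_severity = as.list(res$critical),
    revascularized = as.list(res$revascularized),
    tau_s = res$tau,
    model = list(Kv = res$model$Kv, kt = res$model$kt,
                 Ku_Leff_over_D = res$model$Ku_Leff_over_D),
    provenance = res$provenance
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.ffr_pipeline_result <- function(x, ...) {
  cat("FFR sensitivity pipeline result\n")
  cat(sprintf("  cycle period tau = %.4g s\n", x$tau))
  for (nm in names(x$curves)) {
    cat(sprintf("  %s: FFR in [%.3f, %.3f], critical severity %s\n",
                nm, min(x$curves[[nm]]$ffr), max(x$curves[[nm]]$ffr),
                ifelse(is.na(x$critical[[nm]]), "none",
                       sprintf("%.3f", x$critical[[nm]]))))
  }
  cat(sprintf("  revascularized (FFR < 0.8): %.0f -> %.0f of %g patients\n",
              x$revascularized["original"], x$revascularized["remapped"],
              sum(x$histogram$counts)))
  invisible(x)
}
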