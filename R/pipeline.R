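#' Pipeline run configuration
#'
#' Validates and normalizes a configuration for [run_pipeline()].  All
#' randomness of a run derives from the single `seed`, fanned out to
#' per-stage child seeds by a stable derivation, so stages are
#' independently reproducible.
#'
#' @param stenosis a [stenosis_spec()] (or list of its arguments).
#' @param inlet an [inlet_spec()] (or argument list); use
#'   `pulsatile = TRUE` to attach the default [aortic_waveform()].
#' @param grid a [grid3d()] (or argument list).
#' @param turb a [turb_params()] (or argument list).
#' @param conditions data.frame with columns `delta_L` (mm) and `delta_t`
#'   (ms), one row per acquisition condition.
#' @param scheme an [encoding_scheme()].
#' @param alpha scan-time-budget noise scaling factor.
#' @param snr optional fixed SNR overriding the budget law (recycled over
#'   conditions); `NA` entries fall back to the budget law.
#' @param seed master RNG seed.
#' @param pulsatile attach the default aortic waveform when `inlet` has
#'   none.
#' @param roi_threshold envelope-ROI TKE threshold.
#' @param out_dir optional directory for intermediate HDF5 artifacts.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(stenosis = stenosis_spec(), inlet = inlet_spec(),
                       grid, turb = turb_params(),
                       conditions = data.frame(delta_L = c(1.5, 2.5),
                                               delta_t = 5),
                       scheme = encoding_scheme(), alpha = 1.68,
                       snr = NULL, seed = 1L, pulsatile = FALSE,
                       roi_threshold = 0.05, out_dir = NULL) {
  as_spec <- function(x, ctor) if (is.list(x) && !inherits(x, class(ctor()))) {
    do.call(ctor, x)
  } else x
  stenosis <- as_spec(stenosis, stenosis_spec)
  inlet <- as_spec(inlet, inlet_spec)
  turb <- as_spec(turb, turb_params)
  if (is.list(grid) && !inherits(grid, "grid3d")) grid <- do.call(grid3d, grid)
  if (pulsatile && is.null(inlet$waveform)) {
    period <- grid$period_ms
    inlet$waveform <- aortic_waveform(
      period_ms = if (is.finite(period)) period else 1000,
      peak_ratio = inlet$peak_Re / inlet$mean_Re)
  }
  conditions <- as.data.frame(conditions)
  if (!all(c("delta_L", "delta_t") %in% names(conditions)))
    stop_domain("run_config: conditions needs columns delta_L, delta_t")
  if (any(conditions$delta_L < grid$spacing[1]))
    stop_domain("run_config: delta_L < source spacing L is invalid")
  if (any(conditions$delta_t < 0))
    stop_domain("run_config: delta_t must be >= 0")
  if (!is.null(snr)) snr <- rep_len(snr, nrow(conditions))
  cfg <- structure(list(stenosis = stenosis, inlet = inlet, grid = grid,
                        turb = turb, conditions = conditions,
                        scheme = scheme, alpha = alpha, snr = snr,
                        seed = as.integer(seed),
                        roi_threshold = roi_threshold, out_dir = out_dir),
                   class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

# Order-stable fingerprint of the numeric content of a config (no
# external hashing dependency; collisions are irrelevant for provenance).
config_hash <- function(cfg) {
  s <- paste(capture_numbers(cfg), collapse = ",")
  h <- 5381
  for (x in utf8ToInt(s)) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", as.integer(h))
}

capture_numbers <- function(x) {
  if (is.function(x)) return(paste(deparse(attributes(x) %||% "fn"), collapse = ""))
  if (is.list(x)) return(unlist(lapply(x, capture_numbers)))
  as.character(x)
}

#' Run the full synthesis / reconstruction pipeline
#'
#' For every `(delta_L, delta_t)` condition: temporal window averaging of
#' the ground truth at each frame, band-limiting to `delta_L`, multipoint
#' signal encoding, scan-time-budget noise, Bayesian multipoint
#' reconstruction, and ROI error analysis.  Bit-reproducible given the
#' config seed.
#'
#' @param config a [run_config()].
#' @param verbose print per-condition progress.
#' @return object of class `"pipeline_result"`: the ground-truth field
#'   `gt`, a per-condition list `runs` (each with the condition, the
#'   [error_report()], QC counters and the reconstructions), and a
#'   summary data.frame `summary`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  gt <- make_phantom_flow(config$stenosis, config$inlet, config$grid,
                          turb = config$turb)
  rois <- list(ROI1 = roi_envelope(gt, threshold = config$roi_threshold),
               ROI2 = gt$mask)
  if (!any(rois$ROI1)) rois$ROI1 <- NULL
  runs <- vector("list", nrow(config$conditions))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gridded_fields(gt, file.path(config$out_dir, "ground_truth.h5"))
  }
  for (ci in seq_len(nrow(config$conditions))) {
    dl <- config$conditions$delta_L[ci]
    dt <- config$conditions$delta_t[ci]
    spec <- mtf_spec(config$grid$spacing[1], dl)
    snr_i <- if (!is.null(config$snr) && is.finite(config$snr[ci]))
      config$snr[ci] else NULL
    nspec <- noise_spec(dl^3, dt, alpha = config$alpha, snr = snr_i,
                        seed = derive_seed(config$seed,
                                           sprintf("noise-%d", ci)))
    n_clamped <- 0L
    n_neg_eigen <- 0L
    recons <- vector("list", n_frames(gt$grid))
    for (t in seq_len(n_frames(gt$grid))) {
      fr <- temporal_window_average(gt, gt$grid$time_ms[t], dt)
      ds <- downsample_field(fr, spec)
      n_neg_eigen <- n_neg_eigen + attr(ds, "n_negative_eigen")
      sig <- encode_signal(frame_u(ds, 1L), frame_rst(ds, 1L),
                           config$scheme, rho = ds$rho, grid = ds$grid,
                           mask = ds$mask)
      nspec_t <- nspec
      nspec_t$seed <- derive_seed(config$seed,
                                  sprintf("noise-%d-%d", ci, t))
      sig <- add_noise(sig, nspec_t)
      rec <- reconstruct(sig)
      n_clamped <- n_clamped + rec$qc$n_clamped
      recons[[t]] <- rec
    }
    rep <- error_report(recons, gt, rois = rois)
    runs[[ci]] <- list(delta_L = dl, delta_t = dt, snr = nspec$snr,
                       report = rep, recons = recons,
                       qc = list(n_clamped = n_clamped,
                                 n_negative_eigen = n_neg_eigen))
    if (verbose)
      message(sprintf("condition %d/%d: delta_L = %.2g mm, delta_t = %g ms, SNR = %.3g",
                      ci, nrow(config$conditions), dl, dt, nspec$snr))
  }
  summary <- do.call(rbind, lapply(seq_along(runs), function(ci) {
    r <- runs[[ci]]
    cyc <- r$report$cycle
    data.frame(condition = ci, delta_L = r$delta_L, delta_t = r$delta_t,
               snr = r$snr, roi = cyc$roi, pct_error_tke = cyc$pct_error_tke)
  }))
  structure(list(gt = gt, runs = runs, summary = summary,
                 config_hash = config$hash, seed = config$seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (config %s, seed %d):\n", x$config_hash,
              x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Deterministic test fixtures
#'
#' Writes small phantom ground-truth fields used by the test suite:
#' `tiny` is a 16-voxel-cube steady field, `small` a 24 x 24 x 40
#' five-frame pulsatile field.  Regeneration is idempotent (same bytes
#' for the same size).
#'
#' @param size `"tiny"` or `"small"`.
#' @param dir output directory.
#' @return path of the written HDF5 file, invisibly.
#' @export
make_fixtures <- function(size = c("tiny", "small"), dir = tempdir()) {
  size <- match.arg(size)
  f <- fixture_field(size)
  path <- file.path(dir, sprintf("phantom_%s.h5", size))
  write_gridded_fields(f, path)
  invisible(path)
}

# In-memory fixture fields (also used directly by the tests).
fixture_field <- function(size = c("tiny", "small")) {
  size <- match.arg(size)
  if (size == "tiny") {
    grid <- grid3d(c(16, 16, 16), spacing = 1)
    spec <- stenosis_spec(severity = 0.75, eccentricity = 0.05,
                          diameter = 10, throat_position = 0.5,
                          downstream_length = 0.9)
    inlet <- inlet_spec()
    make_phantom_flow(spec, inlet, grid, turb_params(tke_peak = 50))
  } else {
    grid <- grid3d(c(24, 24, 40), spacing = 1,
                   time_ms = seq(0, 800, by = 200), period_ms = 1000)
    spec <- stenosis_spec(severity = 0.75, eccentricity = 0.05,
                          diameter = 14, throat_position = 0.8,
                          downstream_length = 1.9)
    inlet <- inlet_spec(waveform = aortic_waveform())
    make_phantom_flow(spec, inlet, grid, turb_params(tke_peak = 100,
                                                     lag_ms = 100))
  }
}
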