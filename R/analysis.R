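#' Turbulent-region envelope ROI
#'
#' Operationalizes the "envelope of the turbulent region" as the set of
#' voxels whose ground-truth TKE reaches at least `threshold` times its
#' spatiotemporal peak, morphologically closed (6-neighborhood dilation
#' then erosion).
#'
#' @param field ground-truth [gt_field()].
#' @param threshold TKE fraction of the spatiotemporal peak.
#' @param close apply one morphological closing pass.
#' @return logical array `c(shape)`; a subset of the fluid mask.
#' @export
roi_envelope <- function(field, threshold = 0.05, close = TRUE) {
  nt <- n_frames(field$grid)
  peak <- array(0, field$grid$shape)
  for (t in seq_len(nt)) peak <- pmax(peak, tke_map(frame_rst(field, t)))
  mx <- max(peak)
  if (mx <= 0) return(array(FALSE, field$grid$shape))
  env <- peak >= threshold * mx
  if (close) env <- erode6(dilate6(env))
  env & field$mask
}

shift_or <- function(m, combine = `|`) {
  d <- dim(m)
  out <- m
  ix <- function(n, s) pmin(pmax(seq_len(n) + s, 1L), n)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- ix(d[ax], s)
    out <- combine(out, m[idx[[1]], idx[[2]], idx[[3]]])
  }
  out
}

dilate6 <- function(m) shift_or(m, `|`)
erode6 <- function(m) shift_or(m, `&`)

#' Volume-integrated total of an energy-density map
#'
#' Sums the field over the ROI and multiplies by voxel volume, converting
#' J/m^3 to mJ (`1 mm^3 = 1e-9 m^3`, `1 J = 1e3 mJ`).
#'
#' @param field 3-D array in J/m^3.
#' @param roi logical array on the same grid.
#' @param grid the [grid3d()].
#' @return total in mJ.
#' @export
total_in_roi <- function(field, roi, grid) {
  if (!any(roi)) stop_domain("total_in_roi: empty ROI")
  sum(field[roi]) * voxel_volume_mm3(grid) * 1e-6
}

#' Signed percent error
#'
#' `100 * (measured - truth) / truth`; overestimation is positive.
#'
#' @param measured,truth totals (same units); `truth` must be > 0, else
#'   the error is undefined and `NA` is returned.
#' @return percent error (or `NA_real_`).
#' @export
percent_error <- function(measured, truth) {
  if (!is.finite(truth) || truth <= 0) return(NA_real_)
  100 * (measured - truth) / truth
}

# Sub-frame peak time by 3-point quadratic interpolation around argmax.
peak_time <- function(t, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(t[i])
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(t[i])
  dt <- (t[i + 1] - t[i - 1]) / 2
  t[i] + dt * 0.5 * (y0 - y2) / den
}

#' Temporal lag between peak flow rate and peak total TKE
#'
#' `delta = argmax-time(total TKE) - argmax-time(flow rate)`, each peak
#' located with quadratic sub-frame interpolation.
#'
#' @param time_ms frame times (>= 5 frames).
#' @param flow_rate flow-rate series (e.g. inlet slice flux).
#' @param total_tke total-TKE series (mJ).
#' @return lag in ms; `NA` with a warning for flat series.
#' @export
peak_delay <- function(time_ms, flow_rate, total_tke) {
  if (length(time_ms) < 5L)
    stop_domain("peak_delay: need at least 5 frames")
  if (diff(range(flow_rate)) == 0 || diff(range(total_tke)) == 0) {
    warning("peak_delay: flat series, delay undefined")
    return(NA_real_)
  }
  peak_time(time_ms, total_tke) - peak_time(time_ms, flow_rate)
}

#' Mean and standard deviation of peak voxel-wise TKE
#'
#' Per-voxel temporal maximum of the TKE series, then mean and SD over
#' the ROI.
#'
#' @param tke_series array `c(shape, n_frames)` in J/m^3 (a single 3-D
#'   frame is accepted).
#' @param roi logical array `c(shape)`.
#' @return named vector `c(mu, sigma)` in J/m^3.
#' @export
voxelwise_peak_stats <- function(tke_series, roi) {
  if (!any(roi)) stop_domain("voxelwise_peak_stats: empty ROI")
  d <- dim(tke_series)
  if (length(d) == 3L) dim(tke_series) <- d <- c(d, 1L)
  pk <- array(-Inf, d[1:3])
  for (t in seq_len(d[4])) pk <- pmax(pk, array(tke_series[, , , t], d[1:3]))
  v <- pk[roi]
  c(mu = mean(v), sigma = if (length(v) > 1L) sd(v) else 0)
}

#' Inlet-plane flow rate
#'
#' Slice-integrated axial flux at the first axial plane of the mask, per
#' frame, in ml/s.
#'
#' @param field a [gt_field()].
#' @return numeric vector, one value per frame.
#' @export
inlet_flow_rate <- function(field) {
  a_mm2 <- field$grid$spacing[1] * field$grid$spacing[2]
  vapply(seq_len(n_frames(field$grid)), function(t) {
    uz <- frame_u(field, t)[, , 1L, 3L]
    sum(uz[field$mask[, , 1L]]) * a_mm2 * 1e-6 * 1e6   # m/s*mm^2 -> ml/s
  }, 0)
}

#' ROI error report against ground truth
#'
#' Per-frame, per-ROI totals and percent errors of TKE and KE, comparing
#' a list of reconstructions against the ground-truth field, plus
#' cycle-integrated errors (trapezoidal over the frame times).
#'
#' @param recons list of [recon_result][reconstruct()]s, one per frame of
#'   `gt` (their grids may be coarser than the ground-truth grid).
#' @param gt ground-truth [gt_field()] on the source grid.
#' @param rois named list of ground-truth-grid logical ROIs; default
#'   `ROI1` = [roi_envelope()] and `ROI2` = whole fluid mask.
#' @return object of class `"error_report"`: `frames` data.frame
#'   (frame, time_ms, roi, measured/truth totals in mJ, percent errors)
#'   and `cycle` data.frame of cycle-integrated percent errors.
#' @export
error_report <- function(recons, gt, rois = NULL) {
  nt <- n_frames(gt$grid)
  stopifnot(length(recons) == nt)
  if (is.null(rois))
    rois <- list(ROI1 = roi_envelope(gt), ROI2 = gt$mask)
  rows <- list()
  for (t in seq_len(nt)) {
    rec <- recons[[t]]
    tke_t <- tke_map(frame_rst(gt, t))
    ke_t <- ke_map(frame_u(gt, t), gt$rho)
    for (rn in names(rois)) {
      roi <- rois[[rn]]
      if (!any(roi)) next
      roi_m <- map_roi(roi, gt$grid, rec$grid)
      tke_meas <- total_in_roi(rec$tke, roi_m & rec$mask, rec$grid)
      ke_meas <- total_in_roi(rec$ke, roi_m & rec$mask, rec$grid)
      tke_true <- total_in_roi(tke_t, roi, gt$grid)
      ke_true <- total_in_roi(ke_t, roi, gt$grid)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, time_ms = gt$grid$time_ms[t], roi = rn,
        total_tke_mJ = tke_meas, total_tke_truth_mJ = tke_true,
        pct_error_tke = percent_error(tke_meas, tke_true),
        total_ke_mJ = ke_meas, total_ke_truth_mJ = ke_true,
        pct_error_ke = percent_error(ke_meas, ke_true))
    }
  }
  frames <- do.call(rbind, rows)
  cyc <- do.call(rbind, lapply(split(frames, frames$roi), function(df) {
    data.frame(roi = df$roi[1],
               cycle_tke_meas = trapz(df$time_ms, df$total_tke_mJ),
               cycle_tke_truth = trapz(df$time_ms, df$total_tke_truth_mJ))
  }))
  cyc$pct_error_tke <- mapply(percent_error, cyc$cycle_tke_meas,
                              cyc$cycle_tke_truth)
  structure(list(frames = frames, cycle = cyc), class = "error_report")
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(y[1])
  sum(diff(x) * (head_(y) + tail_(y)) / 2)
}
head_ <- function(y) y[-length(y)]
tail_ <- function(y) y[-1]

# Map a source-grid ROI to a (possibly coarser) reconstruction grid.
map_roi <- function(roi, src_grid, dst_grid) {
  if (is.null(dst_grid) || identical(dst_grid$shape, src_grid$shape))
    return(roi)
  ix <- lapply(1:3, function(a) {
    (axis_coords(dst_grid, a) - src_grid$origin[a]) / src_grid$spacing[a] + 1
  })
  ex <- expand.grid(x = ix[[1]], y = ix[[2]], z = ix[[3]])
  array(interp3(array(as.numeric(roi), dim(roi)), ex$x, ex$y, ex$z) >= 0.5,
        dst_grid$shape)
}

#' @export
print.error_report <- function(x, ...) {
  cat("error_report:\n")
  print(x$cycle, row.names = FALSE)
  invisible(x)
}
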