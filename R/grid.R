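#' Regular Cartesian grid
#'
#' Voxel-center sampling with 0-based voxel indices: the center of voxel
#' `(i, j, k)` sits at `origin + c(i, j, k) * spacing` (mm).  The axial
#' (tube) direction of the phantom is the third axis.
#'
#' @param shape integer triple `(n_x, n_y, n_z)`, all components >= 4.
#' @param spacing voxel edge length per axis in mm (scalar recycled to 3);
#'   the default `0.65` mm is the source-grid resolution used for CFD
#'   projection.
#' @param origin mm offset of the first voxel center.
#' @param time_ms frame times in ms, strictly increasing (singleton for
#'   steady flow).
#' @param period_ms cardiac-cycle length in ms for periodic temporal
#'   operations; defaults to `max(time_ms) + mean frame spacing` for
#'   multi-frame grids and `NA` for steady grids.
#' @return object of class `"grid3d"`.
#' @export
grid3d <- function(shape, spacing = 0.65, origin = c(0, 0, 0),
                   time_ms = 0, period_ms = NULL) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  time_ms <- as.numeric(time_ms)
  if (length(shape) != 3L || any(shape < 4L))
    stop_domain("grid3d: shape must be 3 integers, all >= 4")
  if (any(spacing <= 0))
    stop_domain("grid3d: spacing must be > 0 on all axes")
  if (length(time_ms) > 1L && any(diff(time_ms) <= 0))
    stop_domain("grid3d: time_ms must be strictly increasing")
  if (is.null(period_ms)) {
    period_ms <- if (length(time_ms) > 1L)
      max(time_ms) + mean(diff(time_ms)) else NA_real_
  }
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 time_ms = time_ms, period_ms = period_ms),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing %s mm, %d frame(s)\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              length(x$time_ms)))
  invisible(x)
}

n_frames <- function(grid) length(grid$time_ms)

voxel_volume_mm3 <- function(grid) prod(grid$spacing)

# Voxel-center coordinates along one axis (mm).
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}
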