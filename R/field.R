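#' Ground-truth flow field container
#'
#' Holds a mean-velocity vector field and a symmetric Reynolds stress tensor
#' (RST) field on a regular grid, per time frame, together with the fluid
#' lumen mask and fluid properties.  Velocity is in m/s, the RST in Pa
#' (density-scaled velocity covariance), spacing in mm.
#'
#' @param grid a [grid3d()].
#' @param u numeric array `c(shape, 3, n_frames)` (trailing frame dimension
#'   may be dropped for steady fields), mean velocity in m/s.
#' @param rst numeric array `c(shape, 6, n_frames)` with components ordered
#'   `xx, yy, zz, xy, xz, yz`, in Pa.
#' @param mask logical array `c(shape)`, TRUE inside the fluid lumen.
#' @param rho fluid density in kg/m^3 (blood: 1060).
#' @param mu dynamic viscosity in Pa s (blood: 3.5e-3).
#' @param validate run invariant checks (symmetric storage is implicit in
#'   the 6-component form; checks cover shapes, zero fields outside the
#'   mask, and positive semidefiniteness at masked voxels).
#' @return object of class `"gt_field"`.
#' @export
gt_field <- function(grid, u, rst, mask, rho = 1060, mu = 3.5e-3,
                     validate = TRUE) {
  stopifnot(inherits(grid, "grid3d"))
  nt <- n_frames(grid)
  sp <- grid$shape
  if (length(dim(u)) == 4L) dim(u) <- c(dim(u), 1L)
  if (length(dim(rst)) == 4L) dim(rst) <- c(dim(rst), 1L)
  f <- structure(list(grid = grid, u = u, rst = rst,
                      mask = array(as.logical(mask), sp),
                      rho = as.numeric(rho), mu = as.numeric(mu)),
                 class = "gt_field")
  if (validate) validate_gt_field(f)
  f
}

#' Validate a ground-truth field's invariants
#'
#' Checks array shapes, positivity of `rho`, zero velocity/RST outside the
#' mask, and positive semidefiniteness of the RST at masked voxels
#' (eigenvalues >= -1e-9 * trace).
#'
#' @param f a [gt_field()].
#' @param psd_tol relative eigenvalue tolerance.
#' @return `f`, invisibly; errors on violation.
#' @export
validate_gt_field <- function(f, psd_tol = 1e-9) {
  sp <- f$grid$shape
  nt <- n_frames(f$grid)
  if (!identical(dim(f$u), c(sp, 3L, nt)))
    stop_domain("gt_field: u must have dim c(shape, 3, n_frames)")
  if (!identical(dim(f$rst), c(sp, 6L, nt)))
    stop_domain("gt_field: rst must have dim c(shape, 6, n_frames)")
  if (!identical(dim(f$mask), sp))
    stop_domain("gt_field: mask must have dim = shape")
  if (f$rho <= 0) stop_domain("gt_field: rho must be > 0")
  nvox <- prod(sp)
  um <- array(f$u, c(nvox, 3L * nt))
  rm6 <- array(f$rst, c(nvox, 6L * nt))
  out <- !f$mask
  if (any(abs(um[out, ]) > 0) || any(abs(rm6[out, ]) > 0))
    stop_domain("gt_field: u and rst must be zero outside the mask")
  for (t in seq_len(nt)) {
    r6 <- array(f$rst[, , , , t], c(nvox, 6L))[f$mask, , drop = FALSE]
    if (nrow(r6) == 0L) next
    ev <- sym3_eigenvalues(r6)
    tr <- rowSums(r6[, 1:3, drop = FALSE])
    if (any(ev[, 3L] < -psd_tol * pmax(tr, .Machine$double.eps)))
      stop_domain("gt_field: RST not positive semidefinite at frame %d", t)
  }
  invisible(f)
}

#' @export
print.gt_field <- function(x, ...) {
  print(x$grid)
  tke <- tke_map(frame_rst(x, 1L))
  cat(sprintf("fluid voxels: %d (%.1f%%), rho = %g kg/m^3, peak TKE frame 1: %.3g J/m^3\n",
              sum(x$mask), 100 * mean(x$mask), x$rho, max(tke)))
  invisible(x)
}

# Extract one frame's velocity / RST as c(shape, 3) / c(shape, 6) arrays.
frame_u <- function(f, t) {
  sp <- f$grid$shape
  array(f$u[, , , , t], c(sp, 3L))
}

frame_rst <- function(f, t) {
  sp <- f$grid$shape
  array(f$rst[, , , , t], c(sp, 6L))
}

# Single-frame gt_field at frame t (time axis collapsed to that frame).
extract_frame <- function(f, t) {
  g <- f$grid
  g1 <- grid3d(g$shape, g$spacing, g$origin, time_ms = g$time_ms[t],
               period_ms = g$period_ms)
  gt_field(g1, frame_u(f, t), frame_rst(f, t), f$mask,
           rho = f$rho, mu = f$mu, validate = FALSE)
}
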