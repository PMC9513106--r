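#' Truncated Gaussian MTF specification
#'
#' Models finite imaging resolution as k-space apodization with a separable
#' 3-D Gaussian of standard deviation `sigma_G = sqrt(8 ln 2) * L /
#' Delta_L` per axis, truncated by a box window where each 1-D Gaussian
#' falls to amplitude 0.5.  Frequencies are measured on the per-axis
#' normalized grid (cycles per source sample, Nyquist = 0.5), so the
#' `Delta_L = L` case is near-identity; `sigma_G` is always recomputed
#' from the spacings, never stored.
#'
#' @param source_spacing source-grid voxel size `L` in mm (isotropic).
#' @param target_spacing target MR resolution `Delta_L` in mm, `>= L`.
#' @return object of class `"mtf_spec"`.
#' @export
mtf_spec <- function(source_spacing, target_spacing) {
  if (target_spacing < source_spacing)
    stop_domain("mtf_spec: target_spacing (%.3g) must be >= source_spacing (%.3g)",
                target_spacing, source_spacing)
  structure(list(source_spacing = as.numeric(source_spacing),
                 target_spacing = as.numeric(target_spacing)),
            class = "mtf_spec")
}

mtf_sigma <- function(spec) {
  sqrt(8 * log(2)) * spec$source_spacing / spec$target_spacing
}

# Signed normalized frequencies in FFT layout (DC first), cycles/sample.
fft_freq <- function(n) {
  k <- c(seq(0L, floor(n / 2)), seq(-ceiling(n / 2) + 1L, -1L))
  k / n
}

mtf_weights_1d <- function(spec, n) {
  s <- mtf_sigma(spec)
  f <- fft_freq(n)
  w <- exp(-f^2 / (2 * s^2))
  w[abs(f) > s * sqrt(2 * log(2))] <- 0   # cut where amplitude < 0.5
  w
}

#' k-space weights of the truncated Gaussian MTF
#'
#' @param spec an [mtf_spec()].
#' @param dims integer triple of array dimensions.
#' @return 3-D weight array in FFT layout (DC at `[1, 1, 1]`, weight 1).
#' @export
gaussian_mtf <- function(spec, dims) {
  dims <- as.integer(dims)
  w1 <- mtf_weights_1d(spec, dims[1])
  w2 <- mtf_weights_1d(spec, dims[2])
  w3 <- mtf_weights_1d(spec, dims[3])
  array(outer(outer(w1, w2), w3), dims)
}

# Zero-pad a 3-D array by `pad` voxels per side, apply the MTF in k-space,
# crop back.  Padding suppresses periodic wrap-around of the FFT.
apply_mtf <- function(x, spec, pad = 8L) {
  d0 <- dim(x)
  if (pad > 0L) {
    dp <- d0 + 2L * pad
    xp <- array(0, dp)
    xp[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <- x
  } else {
    dp <- d0
    xp <- x
  }
  w <- gaussian_mtf(spec, dp)
  y <- Re(fft(fft(xp) * w, inverse = TRUE)) / prod(dp)
  if (pad > 0L)
    y <- y[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])]
  y
}

# Target grid for decimation: same origin, isotropic target spacing,
# voxel centers sampled inside the source extent.
target_grid <- function(grid, spec) {
  L <- spec$source_spacing
  DL <- spec$target_spacing
  sp <- vapply(1:3, function(a) {
    as.integer(floor((grid$shape[a] - 1) * grid$spacing[a] / DL)) + 1L
  }, 0L)
  grid3d(sp, spacing = DL, origin = grid$origin,
         time_ms = grid$time_ms, period_ms = grid$period_ms)
}

# Fractional source-array indices (1-based) of target voxel centers.
target_indices <- function(grid, tgrid) {
  ix <- lapply(1:3, function(a) {
    (axis_coords(tgrid, a) - grid$origin[a]) / grid$spacing[a] + 1
  })
  ex <- expand.grid(x = ix[[1]], y = ix[[2]], z = ix[[3]])
  ex
}

decimate_to <- function(x, grid, tgrid, idx) {
  array(interp3(x, idx$x, idx$y, idx$z), tgrid$shape)
}

#' Band-limit a velocity field (componentwise MTF apodization)
#'
#' Inverse FT of the Fourier transform multiplied by the truncated
#' Gaussian MTF, per component, on the source grid.
#'
#' @param u velocity array `c(shape, 3)`.
#' @param spec an [mtf_spec()].
#' @param pad zero-padding in source voxels per side.
#' @return filtered array of the same shape.
#' @export
downsample_velocity <- function(u, spec, pad = 8L) {
  sp <- dim(u)[1:3]
  out <- array(0, dim(u))
  for (c3 in 1:3)
    out[, , , c3] <- apply_mtf(array(u[, , , c3], sp), spec, pad = pad)
  out
}

#' Band-limit a Reynolds-stress field with the partial-volume term
#'
#' `R_filt = MTF(R) + rho * MTF(u u^T) - rho * u_filt u_filt^T`: the
#' difference of the last two terms is the covariance of the mean velocity
#' within the point-spread function, which converts unresolved mean-flow
#' gradients (shear layers, walls) into apparent turbulence.
#'
#' @param rst RST array `c(shape, 6)` in Pa.
#' @param u paired mean-velocity array `c(shape, 3)` on the same grid
#'   (required by the partial-volume term).
#' @param spec an [mtf_spec()].
#' @param rho fluid density kg/m^3.
#' @param pad zero-padding in source voxels per side.
#' @return filtered RST array `c(shape, 6)`; attribute
#'   `"n_negative_eigen"` counts voxels whose smallest eigenvalue fell
#'   below `-1e-6 * trace`.
#' @export
downsample_rst <- function(rst, u, spec, rho = 1060, pad = 8L) {
  if (is.null(u)) stop_domain("downsample_rst: paired velocity field required")
  sp <- dim(rst)[1:3]
  u_f <- downsample_velocity(u, spec, pad = pad)
  uu <- vel_outer6(u)
  uu_f <- vel_outer6(u_f)
  out <- array(0, dim(rst))
  for (c6 in 1:6) {
    out[, , , c6] <- apply_mtf(array(rst[, , , c6], sp), spec, pad = pad) +
      rho * (apply_mtf(array(uu[, , , c6], sp), spec, pad = pad) -
               array(uu_f[, , , c6], sp))
  }
  nv <- prod(sp)
  r6 <- matrix(out, nv, 6L)
  ev <- sym3_eigenvalues(r6)
  tr <- pmax(rowSums(r6[, 1:3, drop = FALSE]), .Machine$double.eps)
  attr(out, "n_negative_eigen") <- sum(ev[, 3L] < -1e-6 * tr)
  out
}

#' Band-limit and decimate a ground-truth field to MR resolution
#'
#' Applies [downsample_velocity()] and [downsample_rst()] per frame, then
#' (optionally) samples the filtered fields at target-voxel centers by
#' trilinear interpolation; the MTF itself encodes the acquisition blur, so
#' no extra box averaging is applied.  The mask is decimated by
#' interpolating its indicator and thresholding at 0.5.
#'
#' @param field a [gt_field()] on the source grid.
#' @param spec an [mtf_spec()]; `source_spacing` must match the grid.
#' @param pad zero-padding in source voxels per side.
#' @param decimate sample onto the coarser target grid (default) or stay
#'   on the source grid.
#' @return a [gt_field()] on the target (or source) grid; attribute
#'   `"n_negative_eigen"` as in [downsample_rst()].
#' @export
downsample_field <- function(field, spec, pad = 8L, decimate = TRUE) {
  g <- field$grid
  if (abs(g$spacing[1] - spec$source_spacing) > 1e-9)
    stop_domain("downsample_field: spec source_spacing %.3g != grid spacing %.3g",
                spec$source_spacing, g$spacing[1])
  nt <- n_frames(g)
  sp <- g$shape
  same <- !decimate || spec$target_spacing <= spec$source_spacing
  tg <- if (same) g else target_grid(g, spec)
  idx <- if (same) NULL else target_indices(g, tg)
  u_out <- array(0, c(tg$shape, 3L, nt))
  r_out <- array(0, c(tg$shape, 6L, nt))
  nneg <- 0L
  for (t in seq_len(nt)) {
    u_f <- downsample_velocity(frame_u(field, t), spec, pad = pad)
    r_f <- downsample_rst(frame_rst(field, t), frame_u(field, t), spec,
                          rho = field$rho, pad = pad)
    nneg <- nneg + attr(r_f, "n_negative_eigen")
    if (same) {
      u_out[, , , , t] <- u_f
      r_out[, , , , t] <- r_f
    } else {
      for (c3 in 1:3)
        u_out[, , , c3, t] <- decimate_to(array(u_f[, , , c3], sp), g, tg, idx)
      for (c6 in 1:6)
        r_out[, , , c6, t] <- decimate_to(array(r_f[, , , c6], sp), g, tg, idx)
    }
  }
  mask_t <- if (same) field$mask else
    array(decimate_to(array(as.numeric(field$mask), sp), g, tg, idx) >= 0.5,
          tg$shape)
  out <- gt_field(tg, u_out, r_out, mask_t, rho = field$rho, mu = field$mu,
                  validate = FALSE)
  attr(out, "n_negative_eigen") <- nneg
  out
}
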