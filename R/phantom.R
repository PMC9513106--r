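#' Eccentric cosine-stenosis geometry
#'
#' A straight tube whose cross-sectional area follows a cosine constriction
#' over an axial extent of two diameters centered on the throat, reaching
#' `1 - severity` of the inlet area at the throat; the lumen center is
#' offset laterally (first axis) by a cosine bump peaking at
#' `eccentricity * diameter` at the throat.
#'
#' @param severity fractional area reduction at the throat, in `[0, 1)`.
#' @param eccentricity lateral throat offset as a fraction of the diameter,
#'   in `[0, 0.5)`.
#' @param diameter nominal (unstenosed) tube diameter in mm.
#' @param throat_position throat distance from the inlet, in diameters.
#' @param downstream_length tube length beyond the throat, in diameters.
#' @return object of class `"stenosis_spec"`.
#' @export
stenosis_spec <- function(severity = 0.75, eccentricity = 0.05,
                          diameter = 25, throat_position = 3,
                          downstream_length = 20) {
  if (severity < 0 || severity >= 1)
    stop_domain("stenosis_spec: severity must be in [0, 1)")
  if (eccentricity < 0 || eccentricity >= 0.5)
    stop_domain("stenosis_spec: eccentricity must be in [0, 0.5)")
  if (diameter <= 0) stop_domain("stenosis_spec: diameter must be > 0")
  structure(list(severity = severity, eccentricity = eccentricity,
                 diameter = diameter, throat_position = throat_position,
                 downstream_length = downstream_length),
            class = "stenosis_spec")
}

# Local lumen radius (mm) and lateral center offset (mm) at axial position
# z (mm, measured from the inlet plane).
stenosis_profile <- function(spec, z) {
  D <- spec$diameter
  z0 <- spec$throat_position * D
  r0 <- D / 2
  s <- rep(0, length(z))
  in_sten <- abs(z - z0) <= D
  s[in_sten] <- (1 + cos(pi * (z[in_sten] - z0) / D)) / 2
  area_frac <- 1 - spec$severity * s
  list(radius = r0 * sqrt(area_frac),
       offset = spec$eccentricity * D * s)
}

#' Lumen mask for the stenotic tube
#'
#' @param spec a [stenosis_spec()].
#' @param grid a [grid3d()]; its axial (third-axis) span must cover
#'   `throat_position + downstream_length` diameters and its cross-section
#'   must fit the tube diameter.
#' @return logical array `c(grid$shape)`.
#' @export
make_stenosis_mask <- function(spec, grid) {
  D <- spec$diameter
  z <- axis_coords(grid, 3L) - grid$origin[3]
  span_z <- (grid$shape[3] - 1) * grid$spacing[3]
  need_z <- (spec$throat_position + spec$downstream_length) * D
  if (span_z < need_z - 1e-9)
    stop_domain("make_stenosis_mask: grid axial span %.1f mm < %.1f mm required by spec",
                span_z, need_z)
  for (ax in 1:2) {
    if ((grid$shape[ax] - 1) * grid$spacing[ax] < D - 1e-9)
      stop_domain("make_stenosis_mask: grid axis %d too narrow for diameter %.1f mm",
                  ax, D)
  }
  prof <- stenosis_profile(spec, z)
  x <- axis_coords(grid, 1L)
  y <- axis_coords(grid, 2L)
  cx <- (x[1] + x[length(x)]) / 2
  cy <- (y[1] + y[length(y)]) / 2
  mask <- array(FALSE, grid$shape)
  dy2 <- (y - cy)^2
  for (k in seq_along(z)) {
    dx <- x - cx - prof$offset[k]
    mask[, , k] <- outer(dx^2, dy2, `+`) <= prof$radius[k]^2
  }
  mask
}

#' Inlet boundary specification
#'
#' @param mean_Re cycle-mean inlet Reynolds number.
#' @param peak_Re peak inlet Reynolds number (pulsatile waveforms).
#' @param waveform `NULL` for steady flow, or a function of time (ms)
#'   returning the flow-rate scale factor; must average to 1 over the cycle
#'   so the mean scales to `mean_Re`.  See [aortic_waveform()].
#' @param inlet_area_fraction fraction of the inlet cross-section carrying
#'   flow (stenotic-inlet projection at constant flow rate), in `(0, 1]`.
#' @return object of class `"inlet_spec"`.
#' @export
inlet_spec <- function(mean_Re = 1000, peak_Re = 4000, waveform = NULL,
                       inlet_area_fraction = 1) {
  if (inlet_area_fraction <= 0 || inlet_area_fraction > 1)
    stop_domain("inlet_spec: inlet_area_fraction must be in (0, 1]")
  structure(list(mean_Re = mean_Re, peak_Re = peak_Re, waveform = waveform,
                 inlet_area_fraction = inlet_area_fraction),
            class = "inlet_spec")
}

#' Idealized aortic flow-rate waveform
#'
#' A raised-cosine systolic bump on a constant diastolic baseline, periodic
#' over the cardiac cycle, normalized so the cycle mean is exactly 1 and the
#' peak is `peak_ratio` (so a `mean_Re = 1000` inlet reaches
#' `peak_ratio * 1000` at peak systole).
#'
#' @param period_ms cycle length in ms.
#' @param peak_ratio peak-to-mean flow-rate ratio.
#' @param systole_ms systolic bump duration in ms.
#' @param t_peak_ms time of peak flow in ms.
#' @return a function of time (ms); attributes carry the parameters.
#' @export
aortic_waveform <- function(period_ms = 1000, peak_ratio = 4,
                            systole_ms = 300, t_peak_ms = 150) {
  frac <- systole_ms / (2 * period_ms)   # cycle mean of the cos^2 bump
  a <- (peak_ratio - 1) / (1 - frac)
  b <- peak_ratio - a
  if (b < 0)
    stop_domain("aortic_waveform: parameters give negative diastolic flow")
  f <- function(t_ms) {
    tau <- (t_ms - t_peak_ms) %% period_ms
    tau <- ifelse(tau > period_ms / 2, tau - period_ms, tau)
    p <- ifelse(abs(tau) < systole_ms / 2,
                cos(pi * tau / systole_ms)^2, 0)
    b + a * p
  }
  attr(f, "period_ms") <- period_ms
  attr(f, "t_peak_ms") <- t_peak_ms
  f
}

waveform_at <- function(inlet, t_ms) {
  if (is.null(inlet$waveform)) 1 else inlet$waveform(t_ms)
}

#' Hagen-Poiseuille inlet profile on a masked slice
#'
#' Axial parabolic profile on the masked inlet cross-section, scaled so the
#' slice-mean velocity gives Reynolds number
#' `waveform(frame_time) * mean_Re` with `Re = rho * U * D / mu`, `D` taken
#' from the masked slice area.  Velocity is zero outside the mask and falls
#' to zero at the lumen radius (no-slip).
#'
#' @param inlet an [inlet_spec()].
#' @param mask_slice logical `n_x x n_y` inlet lumen mask.
#' @param grid the [grid3d()] the slice belongs to.
#' @param frame_time time in ms at which to evaluate the waveform.
#' @param rho,mu fluid density (kg/m^3) and dynamic viscosity (Pa s).
#' @return `n_x x n_y x 3` array, axial component in slot 3, in m/s.
#' @export
hagen_poiseuille_profile <- function(inlet, mask_slice, grid,
                                     frame_time = 0, rho = 1060,
                                     mu = 3.5e-3) {
  mask_slice <- as.matrix(mask_slice)
  n <- sum(mask_slice)
  if (n == 0L) stop_domain("hagen_poiseuille_profile: empty inlet slice")
  area_mm2 <- n * grid$spacing[1] * grid$spacing[2]
  D_m <- 2 * sqrt(area_mm2 / pi) * 1e-3
  x <- axis_coords(grid, 1L); y <- axis_coords(grid, 2L)
  idx <- which(mask_slice, arr.ind = TRUE)
  cx <- mean(x[idx[, 1]]); cy <- mean(y[idx[, 2]])
  R_mm <- sqrt(area_mm2 / pi)
  r2 <- outer((x - cx)^2, (y - cy)^2, `+`) / R_mm^2
  shape <- pmax(1 - r2, 0) * mask_slice
  Re_t <- waveform_at(inlet, frame_time) * inlet$mean_Re
  U <- Re_t * mu / (rho * D_m)          # target slice-mean velocity, m/s
  sc <- U / mean(shape[mask_slice])
  out <- array(0, c(dim(mask_slice), 3L))
  out[, , 3L] <- shape * sc
  out
}

#' Turbulence parameters for the analytic phantom
#'
#' The phantom RST is axisymmetric about the tube axis: axial normal stress
#' `rho * sigma_ax^2` and radial normal stresses `rho * anisotropy *
#' sigma_ax^2`, zero shear components, modulated by a smooth envelope that
#' is zero upstream of the throat, peaks `peak_position` diameters
#' downstream and decays axially; the radial profile follows the jet and
#' vanishes at the walls.  Positive semidefiniteness holds by construction
#' (`anisotropy >= 0`).
#'
#' @param tke_peak peak voxel TKE in J/m^3 (0 gives a laminar field).
#' @param anisotropy radial-to-axial variance ratio, >= 0 (1 = isotropic).
#' @param peak_position envelope peak, in diameters downstream of the
#'   throat.
#' @param lag_ms temporal lag of turbulence behind the flow waveform for
#'   pulsatile runs (ms).
#' @return object of class `"turb_params"`.
#' @export
turb_params <- function(tke_peak = 100, anisotropy = 0.5,
                        peak_position = 4, lag_ms = 0) {
  if (tke_peak < 0) stop_domain("turb_params: tke_peak must be >= 0")
  if (anisotropy < 0)
    stop_domain("turb_params: anisotropy must be >= 0 (PSD by construction)")
  structure(list(tke_peak = tke_peak, anisotropy = anisotropy,
                 peak_position = peak_position, lag_ms = lag_ms),
            class = "turb_params")
}

#' Analytic stenotic-jet ground-truth field
#'
#' Deterministic stand-in for a resolved CFD solution of post-stenotic
#' turbulent flow: a mass-consistent axial jet (each slice is normalized to
#' the instantaneous flow rate, so slice-integrated flux is constant along
#' the tube) with an axisymmetric RST envelope downstream of the throat.
#' For pulsatile inlets the jet scales with the waveform and the turbulence
#' amplitude follows the squared waveform delayed by `turb$lag_ms`.
#'
#' @param spec a [stenosis_spec()].
#' @param inlet an [inlet_spec()].
#' @param grid a [grid3d()]; its `time_ms` defines the frames.
#' @param turb a [turb_params()].
#' @param rho,mu fluid properties.
#' @return a validated [gt_field()].
#' @export
make_phantom_flow <- function(spec, inlet, grid, turb = turb_params(),
                              rho = 1060, mu = 3.5e-3) {
  mask <- make_stenosis_mask(spec, grid)
  sp <- grid$shape
  nt <- n_frames(grid)
  D <- spec$diameter
  z <- axis_coords(grid, 3L) - grid$origin[3]
  z0 <- spec$throat_position * D
  prof <- stenosis_profile(spec, z)
  x <- axis_coords(grid, 1L); y <- axis_coords(grid, 2L)
  cx <- (x[1] + x[length(x)]) / 2
  cy <- (y[1] + y[length(y)]) / 2
  dy2 <- outer(rep(1, sp[1]), (y - cy)^2)

  # Jet effective radius: lumen radius through the stenosis, linear
  # recovery to the full radius over `recovery` diameters downstream.
  recovery <- 8
  r_throat <- (D / 2) * sqrt(1 - spec$severity)
  zeta <- (z - z0) / D
  r_jet <- prof$radius
  dn <- zeta > 0
  r_jet[dn] <- r_throat + (D / 2 - r_throat) * pmin(zeta[dn] / recovery, 1)

  # Per-slice jet shape and wall factor (zero at the local lumen radius).
  shape_sl <- vector("list", sp[3])
  wall2_sl <- vector("list", sp[3])
  for (k in seq_len(sp[3])) {
    dx2 <- (x - cx - prof$offset[k])^2
    rr2 <- outer(dx2, rep(1, sp[2])) + dy2
    wall <- pmax(1 - rr2 / prof$radius[k]^2, 0)
    s <- exp(-rr2 / r_jet[k]^2) * wall
    s[!mask[, , k]] <- 0
    shape_sl[[k]] <- s
    wall2_sl[[k]] <- wall^2 * exp(-rr2 / r_jet[k]^2)
  }

  # Mean inlet speed (m/s) at unit waveform; flow rate in m^3/s uses the
  # discrete masked inlet area.
  D_m <- D * 1e-3
  U_mean <- inlet$mean_Re * mu / (rho * D_m)
  A_in_m2 <- sum(mask[, , 1]) * grid$spacing[1] * grid$spacing[2] * 1e-6
  Q_mean <- U_mean * A_in_m2 / inlet$inlet_area_fraction
  vox_a_m2 <- grid$spacing[1] * grid$spacing[2] * 1e-6

  # Turbulence axial envelope g(zeta): zero upstream, peak 1 at
  # `peak_position` diameters downstream of the throat.
  zp <- turb$peak_position
  g_ax <- ifelse(zeta > 0, (zeta / zp) * exp(1 - zeta / zp), 0)

  u <- array(0, c(sp, 3L, nt))
  rst <- array(0, c(sp, 6L, nt))
  wf <- vapply(grid$time_ms, function(t) waveform_at(inlet, t), 0)
  wf_lag <- vapply(grid$time_ms - turb$lag_ms, function(t) {
    if (is.null(inlet$waveform)) 1 else inlet$waveform(t)
  }, 0)
  amp_t <- wf_lag^2 / max(wf_lag^2)

  base_tke <- array(0, sp)
  for (k in seq_len(sp[3]))
    base_tke[, , k] <- g_ax[k] * wall2_sl[[k]]
  peak_base <- max(base_tke)
  sig_ax2 <- if (turb$tke_peak > 0 && peak_base > 0) {
    # TKE = rho/2 * (sigma_ax^2 + 2 * beta * sigma_ax^2)
    turb$tke_peak / (peak_base * (rho / 2) * (1 + 2 * turb$anisotropy))
  } else 0

  for (t in seq_len(nt)) {
    Q_t <- Q_mean * wf[t]
    for (k in seq_len(sp[3])) {
      s <- shape_sl[[k]]
      tot <- sum(s)
      if (tot > 0) u[, , k, 3L, t] <- s * (Q_t / (tot * vox_a_m2))
    }
    a2 <- sig_ax2 * amp_t[t] * base_tke
    rst[, , , 3L, t] <- rho * a2                       # zz (axial)
    rst[, , , 1L, t] <- rho * turb$anisotropy * a2     # xx
    rst[, , , 2L, t] <- rho * turb$anisotropy * a2     # yy
  }

  # Exact peak-TKE calibration (max over voxels and frames).
  if (turb$tke_peak > 0) {
    tke_max <- max((rst[, , , 1L, ] + rst[, , , 2L, ] + rst[, , , 3L, ]) / 2)
    if (tke_max > 0) rst <- rst * (turb$tke_peak / tke_max)
  }
  gt_field(grid, u, rst, mask, rho = rho, mu = mu)
}

#' Ensemble mean and Reynolds stress from velocity snapshots
#'
#' `R = rho * Cov(u)` with the `1/N`-normalized covariance of velocity
#' fluctuations about the ensemble mean.
#'
#' @param snapshots list of `N >= 2` velocity arrays `c(shape, 3)` on the
#'   same grid.
#' @param rho fluid density in kg/m^3.
#' @return list with `u_mean` (`c(shape, 3)`, m/s) and `rst`
#'   (`c(shape, 6)`, Pa).
#' @export
ensemble_covariance <- function(snapshots, rho = 1060) {
  N <- length(snapshots)
  if (N < 2L) stop_domain("ensemble_covariance: need at least 2 snapshots")
  d <- dim(snapshots[[1]])
  sp <- d[-length(d)]
  nv <- prod(sp)
  um <- matrix(0, nv, 3L)
  for (s in snapshots) {
    if (!identical(dim(s), d))
      stop_domain("ensemble_covariance: snapshots must share one grid")
    um <- um + matrix(s, nv, 3L)
  }
  um <- um / N
  acc <- matrix(0, nv, 6L)
  for (s in snapshots) {
    f <- matrix(s, nv, 3L) - um
    acc <- acc + cbind(f[, 1]^2, f[, 2]^2, f[, 3]^2,
                       f[, 1] * f[, 2], f[, 1] * f[, 3], f[, 2] * f[, 3])
  }
  list(u_mean = array(um, c(sp, 3L)),
       rst = array(rho * acc / N, c(sp, 6L)))
}

#' Temporal window averaging of a pulsatile field series
#'
#' Models the finite temporal footprint of the acquisition: all frames
#' whose centers fall in the closed window `[t0 - delta_t/2, t0 +
#' delta_t/2]` (periodic over the cardiac cycle) form the measurement
#' ensemble.  The output mean velocity is the window mean of per-frame
#' means; the output RST is the window mean of per-frame RSTs **plus**
#' `rho` times the covariance of the per-frame mean velocities, so
#' temporal mean-flow variation appears as apparent turbulence.
#'
#' @param field a multi-frame [gt_field()].
#' @param t0 window center in ms.
#' @param delta_t window width in ms; `0` returns the frame nearest `t0`
#'   unchanged (instantaneous encoding).
#' @return a single-frame [gt_field()] at time `t0`.
#' @export
temporal_window_average <- function(field, t0, delta_t) {
  if (delta_t < 0) stop_domain("temporal_window_average: delta_t must be >= 0")
  g <- field$grid
  tms <- g$time_ms
  if (length(tms) == 1L) {
    sel <- 1L
  } else {
    Tc <- g$period_ms
    d <- tms - t0
    if (is.finite(Tc)) d <- ((d + Tc / 2) %% Tc) - Tc / 2
    sel <- which(abs(d) <= delta_t / 2 + 1e-9)
    if (length(sel) == 0L) sel <- which.min(abs(d))
  }
  sp <- g$shape
  nv <- prod(sp)
  N <- length(sel)
  um <- matrix(0, nv, 3L)
  rm6 <- matrix(0, nv, 6L)
  for (t in sel) {
    um <- um + matrix(frame_u(field, t), nv, 3L)
    rm6 <- rm6 + matrix(frame_rst(field, t), nv, 6L)
  }
  um <- um / N
  rm6 <- rm6 / N
  if (N > 1L) {
    acc <- matrix(0, nv, 6L)
    for (t in sel) {
      f <- matrix(frame_u(field, t), nv, 3L) - um
      acc <- acc + cbind(f[, 1]^2, f[, 2]^2, f[, 3]^2,
                         f[, 1] * f[, 2], f[, 1] * f[, 3], f[, 2] * f[, 3])
    }
    rm6 <- rm6 + field$rho * acc / N
  }
  g1 <- grid3d(sp, g$spacing, g$origin, time_ms = t0, period_ms = g$period_ms)
  gt_field(g1, array(um, c(sp, 3L)), array(rm6, c(sp, 6L)), field$mask,
           rho = field$rho, mu = field$mu, validate = FALSE)
}
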