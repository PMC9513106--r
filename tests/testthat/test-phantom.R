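test_that("stenosis mask reproduces severity and eccentricity geometry", {
  grid <- tiny_grid(20L, spacing = 0.75)
  specs <- list(none = tiny_stenosis(severity = 0, eccentricity = 0),
                conc = tiny_stenosis(severity = 0.75, eccentricity = 0),
                ecc = tiny_stenosis(severity = 0.75, eccentricity = 0.05))
  masks <- lapply(specs, make_stenosis_mask, grid = grid)

  # severity 0: uniform cylinder, same voxel count in every slice
  counts <- apply(masks$none, 3, sum)
  expect_true(all(counts == counts[1]))

  # throat area = (1 - severity) * inlet area by brute-force voxel
  # counting, at the source resolution the tube is meant for (L = 0.65 mm,
  # D = 25 mm); tolerance is the lattice counting error of the two circles
  gbig <- grid3d(c(42, 42, 100), spacing = 0.65)
  sbig <- stenosis_spec(severity = 0.75, eccentricity = 0, diameter = 25,
                        throat_position = 1.28, downstream_length = 1.28)
  mbig <- make_stenosis_mask(sbig, gbig)
  zbig <- (seq_len(100) - 1) * 0.65
  kth <- which.min(abs(zbig - 1.28 * 25))
  a_in <- sum(mbig[, , 1]) * 0.65^2          # unstenosed inlet slice
  a_th <- sum(mbig[, , kth]) * 0.65^2
  # lattice counting error is of order perimeter * L
  expect_lt(abs(a_in - pi * 12.5^2), 2 * pi * 12.5 * 0.65)
  expect_lt(abs(a_th - 0.25 * a_in), 2 * pi * 6.25 * 0.65)

  # throat centroid displaced by eccentricity * diameter (brute-force
  # voxel-count centroid; discretization tolerance ~ half a voxel)
  z <- (seq_len(20) - 1) * 0.75
  kthroat <- which.min(abs(z - specs$conc$throat_position * 10))
  cen <- function(m, k) {
    idx <- which(m[, , k], arr.ind = TRUE)
    mean((idx[, 1] - 1) * 0.75)
  }
  shift <- cen(masks$ecc, kthroat) - cen(masks$conc, kthroat)
  expect_lt(abs(shift - 0.05 * 10), 0.75 / 2)

  # too-short grid rejected
  expect_error(make_stenosis_mask(stenosis_spec(diameter = 10), grid),
               "axial span")
})

test_that("Hagen-Poiseuille inlet profile hits the target Reynolds number", {
  grid <- tiny_grid(20L, spacing = 0.75)
  mask <- make_stenosis_mask(tiny_stenosis(severity = 0), grid)[, , 1]
  rho <- 1060; mu <- 3.5e-3

  for (re in c(1000, 4000)) {
    inlet <- inlet_spec(mean_Re = re)
    u <- hagen_poiseuille_profile(inlet, mask, grid, rho = rho, mu = mu)
    D_m <- 2 * sqrt(sum(mask) * 0.75^2 / pi) * 1e-3
    re_meas <- mean(u[, , 3][mask]) * D_m * rho / mu
    expect_lt(abs(re_meas / re - 1), 0.01)
  }
  # no-slip: zero outside the lumen
  u <- hagen_poiseuille_profile(inlet_spec(), mask, grid)
  expect_true(all(u[, , 3][!mask] == 0))
  # pulsatile peak: waveform peak scales slice Re to peak_Re within 1%
  wf <- aortic_waveform(peak_ratio = 4)
  up <- hagen_poiseuille_profile(inlet_spec(waveform = wf), mask, grid,
                                 frame_time = attr(wf, "t_peak_ms"))
  D_m <- 2 * sqrt(sum(mask) * 0.75^2 / pi) * 1e-3
  expect_lt(abs(mean(up[, , 3][mask]) * D_m * 1060 / 3.5e-3 / 4000 - 1), 0.01)
  expect_error(hagen_poiseuille_profile(inlet_spec(), mask & FALSE, grid),
               "empty")
})

test_that("phantom flow is mass-consistent, calibrated and reproducible", {
  f <- tiny_field()
  uz <- turbmri:::frame_u(f, 1)[, , , 3]
  flux <- apply(uz, 3, sum)
  expect_lt(diff(range(flux)) / mean(flux), 0.02)

  # peak TKE calibration is exact
  expect_lt(abs(max(tke_map(turbmri:::frame_rst(f, 1))) - 50), 50 * 1e-6)

  # laminar limit: tke_peak = 0 gives rst == 0
  lam <- make_phantom_flow(tiny_stenosis(), inlet_spec(), tiny_grid(),
                           turb_params(tke_peak = 0))
  expect_true(all(lam$rst == 0))

  # isotropic parameters: max half-trace equals tke_peak within 1e-6
  iso <- make_phantom_flow(tiny_stenosis(), inlet_spec(), tiny_grid(),
                           turb_params(tke_peak = 100, anisotropy = 1))
  expect_lt(abs(max(tke_map(turbmri:::frame_rst(iso, 1))) - 100), 1e-4)

  # RST zero upstream of the throat, nonzero downstream
  r <- turbmri:::frame_rst(f, 1)
  z_throat <- 0.5 * 10
  kup <- which((seq_len(16) - 1) * 1 <= z_throat)
  expect_true(all(r[, , kup, ] == 0))
  expect_gt(max(abs(r)), 0)

  # deterministic: regeneration is bit-identical
  f2 <- turbmri:::fixture_field("tiny")
  expect_identical(f$u, f2$u)
  expect_identical(f$rst, f2$rst)

  # field invariants hold
  expect_silent(validate_gt_field(f))
  expect_silent(validate_gt_field(small_field()))
})

test_that("ensemble_covariance matches Eq.-style hand and oracle values", {
  sp <- c(4L, 4L, 4L)
  rho <- 1060
  mk <- function(vx) {
    u <- array(0, c(sp, 3L)); u[, , , 1] <- vx; u
  }
  # two snapshots +/- a: mean 0, R_xx = rho a^2
  a <- 0.3
  r <- ensemble_covariance(list(mk(a), mk(-a)), rho = rho)
  expect_equal(max(abs(r$u_mean)), 0)
  expect_equal(r$rst[1, 1, 1, 1], rho * a^2, tolerance = 1e-12)
  expect_true(all(abs(r$rst[, , , 2:6]) == 0))

  # identical snapshots: R == 0
  r0 <- ensemble_covariance(list(mk(a), mk(a), mk(a)), rho = rho)
  expect_true(all(r0$rst == 0))
  expect_error(ensemble_covariance(list(mk(a))), "at least 2")

  # brute-force double-loop covariance oracle on a <= 100-voxel field
  set.seed(7)
  snaps <- lapply(1:6, function(i) array(rnorm(prod(sp) * 3), c(sp, 3L)))
  r <- ensemble_covariance(snaps, rho = rho)
  N <- length(snaps)
  comp <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (v in list(c(1, 1, 1), c(2, 3, 4), c(4, 4, 4))) {
    um <- sapply(1:3, function(c3)
      mean(sapply(snaps, function(s) s[v[1], v[2], v[3], c3])))
    for (ci in 1:6) {
      acc <- 0
      for (n in 1:N) {
        fi <- snaps[[n]][v[1], v[2], v[3], comp[ci, 1]] - um[comp[ci, 1]]
        fj <- snaps[[n]][v[1], v[2], v[3], comp[ci, 2]] - um[comp[ci, 2]]
        acc <- acc + fi * fj
      }
      expect_equal(r$rst[v[1], v[2], v[3], ci], rho * acc / N,
                   tolerance = 1e-12)
    }
  }

  # sampling oracle: known diagonal covariance sigma^2 I recovered within
  # 3 Monte-Carlo standard errors (per component, averaged over voxels)
  set.seed(11)
  n_mc <- 20000L
  sig <- 0.25
  sp1 <- c(2L, 2L, 2L)
  nvox <- prod(sp1)
  snaps <- lapply(seq_len(n_mc), function(i)
    array(rnorm(nvox * 3, sd = sig), c(sp1, 3L)))
  r <- ensemble_covariance(snaps, rho = 1)
  se_var <- sig^2 * sqrt(2 / n_mc) / sqrt(nvox)  # SE of voxel-avg variance
  se_cov <- sig^2 * sqrt(1 / n_mc) / sqrt(nvox)  # SE of voxel-avg covariance
  for (ci in 1:3)
    expect_lt(abs(mean(r$rst[, , , ci]) - sig^2), 3 * se_var)
  for (ci in 4:6)
    expect_lt(abs(mean(r$rst[, , , ci])), 3 * se_cov)
})

test_that("temporal window averaging reproduces the ensemble mechanism", {
  f <- small_field()
  # delta_t = 0: frame at t0 unchanged (instantaneous encoding)
  w0 <- temporal_window_average(f, f$grid$time_ms[2], 0)
  expect_equal(turbmri:::frame_u(w0, 1), turbmri:::frame_u(f, 2))
  expect_equal(turbmri:::frame_rst(w0, 1), turbmri:::frame_rst(f, 2))

  # steady flow: any delta_t leaves the field unchanged
  s <- tiny_field()
  ws <- temporal_window_average(s, 0, 50)
  expect_equal(turbmri:::frame_u(ws, 1), turbmri:::frame_u(s, 1))
  expect_equal(turbmri:::frame_rst(ws, 1), turbmri:::frame_rst(s, 1))

  # idempotent for steady series
  ws2 <- temporal_window_average(ws, 0, 50)
  expect_equal(ws2$u, ws$u)
  expect_equal(ws2$rst, ws$rst)

  # two frames with u = +/- a, R = 0: window R_xx = rho a^2 (Eq. 1 on the
  # 2-frame ensemble)
  sp <- c(4L, 4L, 4L)
  g2 <- grid3d(sp, time_ms = c(0, 10), period_ms = 20)
  a <- 0.4
  u2 <- array(0, c(sp, 3L, 2L))
  u2[, , , 1, 1] <- a; u2[, , , 1, 2] <- -a
  f2 <- gt_field(g2, u2, array(0, c(sp, 6L, 2L)), array(TRUE, sp))
  w2 <- temporal_window_average(f2, 5, 10)
  expect_equal(max(abs(turbmri:::frame_u(w2, 1))), 0)
  expect_equal(turbmri:::frame_rst(w2, 1)[1, 1, 1, 1], 1060 * a^2,
               tolerance = 1e-12)
  expect_error(temporal_window_average(f2, 5, -1), "delta_t")
})
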