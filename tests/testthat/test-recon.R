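test_that("single-point IVSD inverts the magnitude ratio", {
  # |s_ref|/|s_enc| = e with |k_v| = 1 -> sigma^2 = 2
  s2 <- ivsd_single_point(complex(real = exp(1)), complex(real = 1), 1)
  expect_equal(as.vector(s2), 2, tolerance = 1e-14)
  # equal magnitudes -> 0
  expect_equal(as.vector(ivsd_single_point(1 + 0i, 1i, 2)), 0)
  # noise-inflated encoded magnitude clamped to 0 with a counter
  s2 <- ivsd_single_point(complex(real = c(1, 1)),
                          complex(real = c(1.2, 0.5)), 1)
  expect_equal(as.vector(s2), c(0, 2 * log(2)))
  expect_equal(attr(s2, "n_clamped"), 1L)
  # zero reference flagged
  s2 <- ivsd_single_point(0 + 0i, 1 + 0i, 1)
  expect_true(attr(s2, "flagged")[1])
  expect_true(is.na(as.vector(s2)))

  # round trip against the Eq. 2 forward model with known R
  set.seed(5)
  rho <- 1060
  sc <- encoding_scheme(venc = c(1.5))
  sp <- c(4L, 4L, 4L)
  r6 <- array(0, c(sp, 6L))
  r6[, , , 1:3] <- rho * 0.03
  r6[, , , 4] <- rho * 0.01
  u <- array(rnorm(prod(sp) * 3, sd = 0.1), c(sp, 3L))
  sig <- encode_signal(u, r6, sc, rho = rho)
  Hu <- turbmri:::rst_system_matrix(sc)
  for (d in 1:6) {
    k <- pi / 1.5
    s2 <- ivsd_single_point(sig$ref, sig$signals[, , , d, 1], k)
    truth <- sum(Hu[d, ] * r6[1, 1, 1, ]) / rho
    expect_lt(max(abs(s2 - truth)), 1e-10)
  }
})

test_that("multipoint unfolding recovers (nu, sigma) exactly when noise-free", {
  f <- tiny_field()
  spec <- mtf_spec(1, 1)
  ds <- downsample_field(f, spec)
  sc <- encoding_scheme()
  u1 <- turbmri:::frame_u(ds, 1); r1 <- turbmri:::frame_rst(ds, 1)
  sig <- encode_signal(u1, r1, sc, rho = ds$rho, grid = ds$grid,
                       mask = ds$mask)
  est <- multipoint_combine(sig)
  nv <- prod(ds$grid$shape)
  interior <- interior_mask(ds, r1, sc)
  dir_vel <- matrix(u1, nv, 3L) %*% t(sc$directions)
  dir_var <- (matrix(r1, nv, 6L) %*% t(turbmri:::rst_system_matrix(sc))) /
    ds$rho
  idx <- as.vector(interior)
  expect_lt(max(abs(matrix(est$nu, nv, 6L)[idx, ] - dir_vel[idx, ])), 1e-6)
  expect_lt(max(abs(matrix(est$sigma2, nv, 6L)[idx, ] - dir_var[idx, ])),
            1e-6)
})

test_that("multipoint unfolding resolves aliasing beyond the smallest VENC", {
  # true velocity beyond the two smaller VENCs but inside the largest
  sc <- encoding_scheme(venc = c(2, 0.6, 0.2))
  sp <- c(4L, 4L, 4L)
  nu_true <- 1.17
  u <- array(0, c(sp, 3L)); u[, , , 1] <- nu_true
  r6 <- array(0, c(sp, 6L)); r6[, , , 1:3] <- 1060 * 0.01
  sig <- encode_signal(u, r6, sc, rho = 1060)
  for (init in c("modes", "grid")) {
    est <- multipoint_combine(sig, init = init)
    expect_lt(max(abs(est$nu[, , , 1] - nu_true)), 1e-6)
  }
  # zero-signal voxel flagged and excluded
  sigz <- sig
  sigz$ref[1, 1, 1] <- 0 + 0i
  est <- multipoint_combine(sigz)
  expect_true(est$flagged[1, 1, 1])
  expect_equal(est$nu[1, 1, 1, 1], 0)
})

test_that("RST and velocity assembly match brute-force normal equations", {
  set.seed(9)
  sc <- encoding_scheme()
  rho <- 1060
  Hu <- turbmri:::rst_system_matrix(sc)
  K <- sc$directions

  # 100 random voxels against explicit per-voxel normal-equation oracles
  n <- 100L
  s2 <- matrix(abs(rnorm(n * 6)), n, 6L)
  nu <- matrix(rnorm(n * 6), n, 6L)
  # reshape inputs as c(n,1,1,6) fields for the vectorized path
  s2f <- array(s2, c(n, 1L, 1L, 6L))
  nuf <- array(nu, c(n, 1L, 1L, 6L))
  r_pkg <- matrix(rst_from_ivsd(s2f, sc, rho = rho), n, 6L)
  u_pkg <- matrix(velocity_from_phases(nuf, sc), n, 3L)
  for (i in seq_len(n)) {
    r_or <- rho * solve(t(Hu) %*% Hu) %*% t(Hu) %*% s2[i, ]
    u_or <- solve(t(K) %*% K) %*% t(K) %*% nu[i, ]
    expect_lt(max(abs(r_pkg[i, ] - r_or)), 1e-10 * max(1, max(abs(r_or))))
    expect_lt(max(abs(u_pkg[i, ] - u_or)), 1e-12 * max(1, max(abs(u_or))))
  }

  # linear-algebra round trips
  r_true <- c(2, 3, 4, 0.5, -0.3, 0.8) * rho * 0.01
  s2_fwd <- as.vector(Hu %*% r_true) / rho
  r_back <- matrix(rst_from_ivsd(array(s2_fwd, c(1, 1, 1, 6)), sc,
                                 rho = rho), 1, 6)
  expect_lt(max(abs(r_back - r_true)), 1e-10)

  u_true <- c(0.3, -0.2, 1.1)
  nu_fwd <- as.vector(K %*% u_true)
  u_back <- matrix(velocity_from_phases(array(nu_fwd, c(1, 1, 1, 6)), sc),
                   1, 3)
  expect_lt(max(abs(u_back - u_true)), 1e-12)

  # isotropic directional variances give rho*c*I
  cval <- 0.02
  r_iso <- matrix(rst_from_ivsd(array(cval, c(1, 1, 1, 6)), sc, rho = rho),
                  1, 6)
  expect_equal(as.vector(r_iso), c(rep(rho * cval, 3), rep(0, 3)),
               tolerance = 1e-10)
  # zero in, zero out
  expect_true(all(rst_from_ivsd(array(0, c(1, 1, 1, 6)), sc) == 0))
  expect_true(all(velocity_from_phases(array(0, c(1, 1, 1, 6)), sc) == 0))
})

test_that("six-direction least squares beats any 3-direction subset", {
  set.seed(21)
  sc <- encoding_scheme()
  K <- sc$directions
  u_true <- c(0.4, -0.1, 0.7)
  sig_nu <- 0.05
  n_tr <- 10000L
  pinv6 <- solve(crossprod(K), t(K))
  est6 <- est3 <- matrix(0, n_tr, 3L)
  K3 <- K[1:3, ]
  for (i in seq_len(n_tr)) {
    nu <- as.vector(K %*% u_true) + rnorm(6, sd = sig_nu)
    est6[i, ] <- pinv6 %*% nu
    est3[i, ] <- solve(K3, nu[1:3])
  }
  v6 <- apply(est6, 2, var)
  v3 <- apply(est3, 2, var)
  expect_true(all(v6 < v3))
})

test_that("TKE and KE maps satisfy their identities", {
  # R = diag(2, 2, 2) Pa -> TKE = 3 J/m^3
  r <- array(c(2, 2, 2, 0, 0, 0), c(1, 1, 1, 6))
  expect_equal(as.vector(tke_map(r)), 3)
  # u = (1, 0, 0), rho = 1060 -> KE = 530
  u <- array(c(1, 0, 0), c(1, 1, 1, 3))
  expect_equal(as.vector(ke_map(u, 1060)), 530)
  # TKE invariant under rotation of R
  set.seed(2)
  A <- matrix(rnorm(9), 3)
  R0 <- crossprod(A)
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
  R1 <- qr_ %*% R0 %*% t(qr_)
  to6 <- function(m) array(c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3],
                             m[2, 3]), c(1, 1, 1, 6))
  expect_equal(as.vector(tke_map(to6(R0))), as.vector(tke_map(to6(R1))),
               tolerance = 1e-12)
  # reconstruct() keeps the pointwise identities
  f <- tiny_field()
  ds <- downsample_field(f, mtf_spec(1, 1))
  sig <- encode_signal(turbmri:::frame_u(ds, 1), turbmri:::frame_rst(ds, 1),
                       encoding_scheme(), rho = ds$rho, grid = ds$grid,
                       mask = ds$mask)
  rec <- reconstruct(sig)
  expect_equal(rec$tke, tke_map(rec$rst_star), tolerance = 1e-12)
  expect_equal(rec$ke, ke_map(rec$u_star, 1060), tolerance = 1e-12)
})

test_that("noise inflates reconstructed TKE on average", {
  # Voxel-wise TKE bias is positive at SNR = 30 and grows as SNR drops:
  # the noise floor folds into apparent IVSD at low-dispersion voxels
  # (clamping at sigma^2 = 0 makes the error one-sided).  Needs a field
  # with a laminar noise floor, so use the phantom.
  f <- tiny_field()
  ds <- downsample_field(f, mtf_spec(1, 1))
  sc <- encoding_scheme()
  clean <- encode_signal(turbmri:::frame_u(ds, 1),
                         turbmri:::frame_rst(ds, 1), sc, rho = ds$rho,
                         grid = ds$grid, mask = ds$mask)
  tke0 <- mean(reconstruct(clean)$tke[ds$mask])
  bias <- sapply(c(30, 10), function(snr) {
    set.seed(123)
    mean(replicate(15, {
      noisy <- add_noise(clean, noise_spec(8, 5, snr = snr))
      mean(reconstruct(noisy)$tke[ds$mask]) - tke0
    }))
  })
  expect_gt(bias[1], 0)
  expect_gt(bias[2], bias[1])
})
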