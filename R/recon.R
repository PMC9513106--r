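#' Single-point intra-voxel standard deviation (magnitude ratio)
#'
#' `sigma^2 = (2 / |k_v|^2) * ln(|S_ref| / |S_enc|)`.  Negative results
#' (noise making `|S_enc| > |S_ref|`) are clamped to zero and counted;
#' voxels with `|S_ref| = 0` are flagged `NA`.
#'
#' @param s_ref,s_enc complex reference / encoded signals (any shape).
#' @param kv encoding strength `|k_v|` in s/m.
#' @return array of `sigma^2` (m^2/s^2) with attributes `"n_clamped"` and
#'   `"flagged"` (logical, excluded voxels).
#' @export
ivsd_single_point <- function(s_ref, s_enc, kv) {
  aref <- Mod(s_ref)
  aenc <- Mod(s_enc)
  flagged <- aref == 0
  s2 <- array(NA_real_, dim(aref) %||% length(aref))
  ok <- !flagged & aenc > 0
  s2[ok] <- (2 / kv^2) * log(aref[ok] / aenc[ok])
  ncl <- sum(s2[ok] < 0)
  s2[ok][s2[ok] < 0] <- 0
  attr(s2, "n_clamped") <- ncl
  attr(s2, "flagged") <- flagged
  s2
}

# MAP cost of the multipoint likelihood for one encoding direction,
# vectorized over voxels.  amp: |S_ref|; a, phi: nvox x L magnitudes and
# reference-subtracted phases; k: strengths; nu, s: parameter vectors.
mp_cost <- function(nu, s, amp, a, phi, k, inv2se, prior) {
  J <- 0
  for (l in seq_along(k)) {
    m <- amp * exp(-s * k[l]^2 / 2)
    J <- J + (m^2 - 2 * m * a[, l] * cos(phi[, l] + k[l] * nu)) * inv2se
  }
  if (prior) J <- J + 0.5 * log(pmax(s, 1e-300))
  J
}

# Damped Newton refinement of (nu, s = sigma^2), vectorized over voxels.
mp_newton <- function(nu, s, amp, a, phi, k, inv2se, prior, s_range,
                      iters = 30L, tol = 1e-12) {
  nv <- length(nu)
  J0 <- mp_cost(nu, s, amp, a, phi, k, inv2se, prior)
  for (it in seq_len(iters)) {
    gn <- gs <- hnn <- hns <- hss <- numeric(nv)
    for (l in seq_along(k)) {
      kl <- k[l]
      m <- amp * exp(-s * kl^2 / 2)
      ps <- phi[, l] + kl * nu
      cp <- cos(ps); sn <- sin(ps)
      al <- a[, l]
      gn <- gn + 2 * m * al * kl * sn * inv2se
      gs <- gs - kl^2 * m * (m - al * cp) * inv2se
      hnn <- hnn + 2 * m * al * kl^2 * cp * inv2se
      hns <- hns - kl^3 * m * al * sn * inv2se
      hss <- hss + (kl^2 / 2)^2 * m * (4 * m - 2 * al * cp) * inv2se
    }
    if (prior) {
      gs <- gs + 0.5 / pmax(s, 1e-300)
      hss <- hss - 0.5 / pmax(s, 1e-300)^2
    }
    # Regularize indefinite Hessians toward gradient descent.
    det <- hnn * hss - hns^2
    bad <- det <= 0 | hnn <= 0
    hnn[bad] <- abs(hnn[bad]) + 1
    hss[bad] <- abs(hss[bad]) + 1
    hns[bad] <- 0
    det <- hnn * hss - hns^2
    dn <- -(hss * gn - hns * gs) / det
    ds <- -(hnn * gs - hns * gn) / det
    step <- rep(1, nv)
    for (bt in 1:8) {
      nu1 <- nu + step * dn
      s1 <- pmin(pmax(s + step * ds, s_range[1]), s_range[2])
      J1 <- mp_cost(nu1, s1, amp, a, phi, k, inv2se, prior)
      worse <- J1 > J0 + 1e-15
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    move <- abs(nu1 - nu) + abs(s1 - s)
    nu <- nu1; s <- s1; J0 <- J1
    if (max(move) < tol) break
  }
  list(nu = nu, s = s, J = J0)
}

#' Bayesian multipoint unfolding of directional velocities and IVSDs
#'
#' Per voxel and encoding direction, maximum-a-posteriori estimation of
#' the directional velocity `nu` and IVSD variance `sigma^2` under the
#' Gaussian-IVSD signal model with complex-Gaussian noise of known
#' `sigma_eta`: flat prior on `nu` over the widest unambiguous range
#' (+/- max(VENC)), log-uniform prior on `sigma` over `sigma_range`.
#' The posterior's discrete phase-wrap modes are enumerated (seeded by
#' the lowest-strength point and sequentially unfolded to the higher
#' strengths; `init = "grid"` adds a dense search), then the best mode is
#' refined by damped Newton iterations.  With a single encoding strength
#' the estimate degenerates to the phase of that point plus the
#' magnitude-ratio IVSD of [ivsd_single_point()].
#'
#' @param sigset a [signal_set][encode_signal()], possibly noisy.
#' @param sigma_range IVSD prior support in m/s, `c(min, max)`.
#' @param init `"modes"` (wrap-branch enumeration) or `"grid"` (adds a
#'   dense `nu` x `sigma` grid before refinement).
#' @return list with `nu` and `sigma2` arrays `c(shape, 6)`, per-voxel
#'   `flagged` (zero reference signal or boundary solution) and the
#'   negative-variance clamp count `n_clamped`.
#' @export
multipoint_combine <- function(sigset, sigma_range = c(1e-4, 10),
                               init = c("modes", "grid")) {
  init <- match.arg(init)
  sp <- dim(sigset$ref)
  nv <- prod(sp)
  mask <- sigset$mask %||% array(TRUE, sp)
  k <- sort(sigset$scheme$kv)              # ascending strength
  ord <- order(sigset$scheme$kv)
  L <- length(k)
  vmax <- pi / k[1]                        # widest unambiguous range
  s_range <- sigma_range^2
  se <- sigset$sigma_eta
  prior <- se > 0
  inv2se <- if (prior) 1 / (2 * se^2) else 0.5
  ref <- as.vector(sigset$ref)
  amp_all <- Mod(ref)
  act <- which(as.vector(mask) & amp_all > 0)
  flagged <- array(as.vector(mask) & amp_all == 0, sp)
  nu_out <- array(0, c(sp, 6L))
  s2_out <- array(0, c(sp, 6L))
  n_clamped <- 0L
  if (length(act)) {
    amp <- amp_all[act]
    rph <- Arg(ref[act])
    for (d in 1:6) {
      a <- phi <- matrix(0, length(act), L)
      for (l in seq_len(L)) {
        sl <- as.vector(array(sigset$signals[, , , d, ord[l]], sp))[act]
        a[, l] <- Mod(sl)
        phi[, l] <- wrap_pi(Arg(sl) - rph)  # reference phase subtracted
      }
      # Init: coarse velocity from the lowest strength, then unfold each
      # higher strength to the branch nearest the running estimate.
      nu0 <- -phi[, 1] / k[1]
      wcum <- (k[1] * a[, 1])^2
      for (l in seq_len(L)[-1]) {
        r <- -phi[, l] / k[l]
        per <- 2 * pi / k[l]
        cand <- r + per * round((nu0 - r) / per)
        w <- (k[l] * a[, l])^2
        nu0 <- (wcum * nu0 + w * cand) / (wcum + w)
        wcum <- wcum + w
      }
      # IVSD init: weighted LS of log magnitude ratios against k^2/2.
      num <- den <- 0
      for (l in seq_len(L)) {
        y <- log(pmax(amp, 1e-300) / pmax(a[, l], 1e-300))
        wl <- a[, l]^2 * (k[l]^2 / 2)
        num <- num + wl * y
        den <- den + wl * (k[l]^2 / 2)
      }
      s0 <- pmin(pmax(num / pmax(den, 1e-300), s_range[1]), s_range[2])
      nu0 <- pmin(pmax(nu0, -vmax), vmax)
      if (init == "grid") {
        nug <- seq(-vmax, vmax, length.out = 41L)
        sg <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = 15L))
        bestJ <- mp_cost(nu0, s0, amp, a, phi, k, inv2se, prior)
        for (nu_g in nug) for (s_g in sg) {
          Jg <- mp_cost(rep(nu_g, length(act)), rep(s_g, length(act)),
                        amp, a, phi, k, inv2se, prior)
          better <- Jg < bestJ
          if (any(better)) {
            nu0[better] <- nu_g
            s0[better] <- s_g
            bestJ[better] <- Jg[better]
          }
        }
      }
      fit <- mp_newton(nu0, s0, amp, a, phi, k, inv2se, prior, s_range)
      n_clamped <- n_clamped + sum(fit$s <= s_range[1] * (1 + 1e-6))
      on_edge <- abs(fit$nu) >= vmax * (1 - 1e-9)
      nu_d <- array(0, sp); s2_d <- array(0, sp)
      nu_d[act] <- fit$nu
      s2_d[act] <- pmax(fit$s, 0)
      nu_out[, , , d] <- nu_d
      s2_out[, , , d] <- s2_d
      fb <- array(FALSE, sp); fb[act[on_edge]] <- TRUE
      flagged <- flagged | fb
    }
  }
  list(nu = nu_out, sigma2 = s2_out, flagged = flagged,
       n_clamped = n_clamped)
}

#' Reynolds stress tensor from directional IVSD variances
#'
#' Solves the voxel-wise 6 x 6 linear system
#' `sigma^2 = H r / rho` by the pseudoinverse `r* = rho (H^T H)^{-1} H^T
#' sigma^2`.  No PSD projection is applied by default: negative
#' eigenvalues are a genuine artifact signal.
#'
#' @param sigma2 directional variance array `c(shape, 6)` (m^2/s^2).
#' @param scheme an [encoding_scheme()].
#' @param rho fluid density kg/m^3.
#' @param psd_project clip negative eigenvalues to zero.
#' @return RST array `c(shape, 6)` in Pa.
#' @export
rst_from_ivsd <- function(sigma2, scheme, rho = 1060, psd_project = FALSE) {
  sp <- dim(sigma2)[1:3]
  Hu <- rst_system_matrix(scheme)
  pinv <- solve(crossprod(Hu), t(Hu))
  s2 <- matrix(sigma2, prod(sp), 6L)
  s2[is.na(s2)] <- 0
  r6 <- rho * s2 %*% t(pinv)
  if (psd_project) r6 <- sym3_psd_project(r6)
  array(r6, c(sp, 6L))
}

#' Cartesian velocity from directional velocities
#'
#' Least-squares solution of the overdetermined 6 x 3 system
#' `nu = K u` with `K` the matrix of unit encoding directions:
#' `u* = (K^T K)^{-1} K^T nu`.
#'
#' @param nu directional velocity array `c(shape, 6)` (m/s).
#' @param scheme an [encoding_scheme()].
#' @return velocity array `c(shape, 3)` in m/s.
#' @export
velocity_from_phases <- function(nu, scheme) {
  K <- scheme$directions
  if (qr(K)$rank < 3L)
    stop_domain("velocity_from_phases: encoding directions do not span R^3")
  pinv <- solve(crossprod(K), t(K))
  sp <- dim(nu)[1:3]
  nm <- matrix(nu, prod(sp), 6L)
  nm[is.na(nm)] <- 0
  array(nm %*% t(pinv), c(sp, 3L))
}

#' Turbulent kinetic energy map
#'
#' `TKE = Tr(R) / 2` in J/m^3.
#'
#' @param rst RST array `c(shape, 6)` in Pa.
#' @return 3-D array in J/m^3.
#' @export
tke_map <- function(rst) {
  sp <- dim(rst)[1:3]
  array(rowSums(matrix(rst, prod(sp), 6L)[, 1:3, drop = FALSE]) / 2, sp)
}

#' Kinetic energy map
#'
#' `KE = rho |u|^2 / 2` in J/m^3.
#'
#' @param u velocity array `c(shape, 3)` in m/s.
#' @param rho fluid density kg/m^3.
#' @return 3-D array in J/m^3.
#' @export
ke_map <- function(u, rho = 1060) {
  sp <- dim(u)[1:3]
  array(rho * rowSums(matrix(u, prod(sp), 3L)^2) / 2, sp)
}

#' Full multipoint reconstruction
#'
#' [multipoint_combine()] followed by [rst_from_ivsd()],
#' [velocity_from_phases()], [tke_map()] and [ke_map()].
#'
#' @param sigset a [signal_set][encode_signal()].
#' @param psd_project see [rst_from_ivsd()].
#' @param ... passed to [multipoint_combine()].
#' @return object of class `"recon_result"`: `u_star` `c(shape, 3)`,
#'   `rst_star` `c(shape, 6)`, `tke`, `ke`, `grid`, `mask`, and a `qc`
#'   list with clamp and flag counts.
#' @export
reconstruct <- function(sigset, psd_project = FALSE, ...) {
  est <- multipoint_combine(sigset, ...)
  rst_star <- rst_from_ivsd(est$sigma2, sigset$scheme, rho = sigset$rho,
                            psd_project = psd_project)
  u_star <- velocity_from_phases(est$nu, sigset$scheme)
  mask <- sigset$mask %||% array(TRUE, dim(sigset$ref))
  for (c3 in 1:3) u_star[, , , c3][!mask] <- 0
  for (c6 in 1:6) rst_star[, , , c6][!mask] <- 0
  structure(list(u_star = u_star, rst_star = rst_star,
                 tke = tke_map(rst_star), ke = ke_map(u_star, sigset$rho),
                 grid = sigset$grid, mask = mask, scheme = sigset$scheme,
                 qc = list(n_clamped = est$n_clamped,
                           n_flagged = sum(est$flagged)),
                 flagged = est$flagged),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("recon_result: %s voxels, peak TKE %.3g J/m^3, peak |u| %.3g m/s\n",
              paste(dim(x$tke), collapse = " x "), max(x$tke),
              sqrt(max(x$ke) * 2 / 1060)))
  cat(sprintf("  QC: %d IVSD clamps, %d flagged voxels\n",
              x$qc$n_clamped, x$qc$n_flagged))
  invisible(x)
}
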