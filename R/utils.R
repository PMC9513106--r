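# Internal helpers shared across modules.

# Component order of the 6-vector RST representation, fixed package-wide.
RST_COMP <- c("xx", "yy", "zz", "xy", "xz", "yz")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Eigenvalues of symmetric 3x3 tensors, vectorized
#'
#' Closed-form (trigonometric) eigenvalues for a set of symmetric 3x3
#' tensors in 6-component form (xx, yy, zz, xy, xz, yz).  Used for PSD
#' validation and for the optional PSD projection of reconstructed RSTs.
#'
#' @param r6 numeric matrix, n x 6.
#' @return n x 3 matrix of eigenvalues in decreasing order.
#' @keywords internal
sym3_eigenvalues <- function(r6) {
  r6 <- matrix(r6, ncol = 6L)
  a <- r6[, 1L]; b <- r6[, 2L]; c <- r6[, 3L]
  d <- r6[, 4L]; e <- r6[, 5L]; f <- r6[, 6L]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2, 0) / 6)
  out <- matrix(q, nrow = length(q), ncol = 3L)
  nz <- p > 0
  if (any(nz)) {
    ps <- p[nz]
    aa <- (a[nz] - q[nz]) / ps; bb <- (b[nz] - q[nz]) / ps
    cc <- (c[nz] - q[nz]) / ps
    dd <- d[nz] / ps; ee <- e[nz] / ps; ff <- f[nz] / ps
    detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
      ee * (dd * ff - bb * ee)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * ps * cos(phi)
    e3 <- q[nz] + 2 * ps * cos(phi + 2 * pi / 3)
    out[nz, 1L] <- e1
    out[nz, 3L] <- e3
    out[nz, 2L] <- 3 * q[nz] - e1 - e3
  }
  out
}

# Project each tensor of an n x 6 matrix onto the PSD cone (eigenvalue clip).
sym3_psd_project <- function(r6) {
  r6 <- matrix(r6, ncol = 6L)
  ev <- sym3_eigenvalues(r6)
  bad <- which(ev[, 3L] < 0)
  for (i in bad) {
    m <- matrix(c(r6[i, 1], r6[i, 4], r6[i, 5],
                  r6[i, 4], r6[i, 2], r6[i, 6],
                  r6[i, 5], r6[i, 6], r6[i, 3]), 3, 3)
    es <- eigen(m, symmetric = TRUE)
    lam <- pmax(es$values, 0)
    mp <- es$vectors %*% (lam * t(es$vectors))
    r6[i, ] <- c(mp[1, 1], mp[2, 2], mp[3, 3], mp[1, 2], mp[1, 3], mp[2, 3])
  }
  r6
}

# Quadratic outer-product terms (u u^T) in 6-component order for velocity
# arrays of dimension c(dims, 3).
vel_outer6 <- function(u) {
  dims <- dim(u)
  sp <- dims[-length(dims)]
  u <- array(u, c(prod(sp), 3L))
  out <- cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
               u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3])
  array(out, c(sp, 6L))
}

# Derive a bounded child seed from a parent seed and a stage label, so that
# pipeline stages are independently reproducible without a hashing package.
derive_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647L)
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

# Wrap angles to (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Trilinear interpolation of a 3-D array at fractional 1-based indices.
# Coordinates are clamped to the array extent.
interp3 <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  xi <- cl(xi, d[1]); yi <- cl(yi, d[2]); zi <- cl(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); x0[d[1] == 1L] <- 1L
  y0 <- pmin(floor(yi), d[2] - 1L); y0[d[2] == 1L] <- 1L
  z0 <- pmin(floor(zi), d[3] - 1L); z0[d[3] == 1L] <- 1L
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  at <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}
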