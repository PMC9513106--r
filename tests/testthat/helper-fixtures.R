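# Shared in-code fixtures: everything is generated at test time.

tiny_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- turbmri:::fixture_field("tiny")
    cache
  }
})

small_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- turbmri:::fixture_field("small")
    cache
  }
})

# A small stenosis spec / grid pair that fits a 16^3..20^3 grid.
tiny_stenosis <- function(severity = 0.75, eccentricity = 0.05) {
  stenosis_spec(severity = severity, eccentricity = eccentricity,
                diameter = 10, throat_position = 0.5,
                downstream_length = 0.9)
}

tiny_grid <- function(n = 16L, spacing = 1, ...) {
  grid3d(c(n, n, n), spacing = spacing, ...)
}

# Interior voxels for round-trip comparisons: away from the wall and with
# an invertible acquisition model (all directional variances >= 0).
interior_mask <- function(field, rst_ref, scheme) {
  m <- turbmri:::erode6(turbmri:::erode6(field$mask))
  Hu <- turbmri:::rst_system_matrix(scheme)
  dv <- (matrix(rst_ref, prod(dim(field$mask)), 6L) %*% t(Hu)) / field$rho
  m & array(apply(dv, 1, min) >= 0, dim(field$mask))
}

# Direct-space separable circular-convolution oracle for the MTF: builds
# the explicit 1-D PSF of each axis (inverse DFT of the truncated Gaussian
# weights) and applies it with dense circulant matrices -- no use of the
# implementation's FFT filtering path.
mtf_psf_1d <- function(spec, n) {
  w <- turbmri:::mtf_weights_1d(spec, n)
  Re(fft(w, inverse = TRUE)) / n
}

circulant <- function(v) {
  n <- length(v)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, ] <- v[((i - seq_len(n)) %% n) + 1L]
  m
}

oracle_filter3 <- function(x, spec) {
  d <- dim(x)
  m1 <- circulant(mtf_psf_1d(spec, d[1]))
  m2 <- circulant(mtf_psf_1d(spec, d[2]))
  m3 <- circulant(mtf_psf_1d(spec, d[3]))
  y <- array(0, d)
  for (k in seq_len(d[3])) y[, , k] <- m1 %*% x[, , k] %*% t(m2)
  y <- aperm(apply(y, c(1, 2), function(v) m3 %*% v), c(2, 3, 1))
  array(y, d)
}
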