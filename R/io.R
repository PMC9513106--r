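#' Write a ground-truth field to an HDF5 container
#'
#' Layout: datasets `/u_mean` (`shape x 3 x frames`), `/rst`
#' (`shape x 6 x frames`, component order xx, yy, zz, xy, xz, yz), `/mask`
#' (0/1 integers), `/time_ms`, and root attributes `spacing_mm`,
#' `origin_mm`, `period_ms`, `rho`, `mu`.  Arrays are stored in R (column
#' -major) dimension order; HDF5 tools therefore see the dimensions
#' reversed (frames x components x n_z x n_y x n_x).
#'
#' @param field a [gt_field()].
#' @param path output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_gridded_fields <- function(field, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(field$u, path, "u_mean")
  rhdf5::h5write(field$rst, path, "rst")
  rhdf5::h5write(array(as.integer(field$mask), dim(field$mask)), path, "mask")
  rhdf5::h5write(field$grid$time_ms, path, "time_ms")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(field$grid$spacing, fid, "spacing_mm")
  rhdf5::h5writeAttribute(field$grid$origin, fid, "origin_mm")
  rhdf5::h5writeAttribute(field$grid$period_ms, fid, "period_ms")
  rhdf5::h5writeAttribute(field$rho, fid, "rho")
  rhdf5::h5writeAttribute(field$mu, fid, "mu")
  invisible(path)
}

#' Load gridded velocity / Reynolds-stress fields
#'
#' Reads the container written by [write_gridded_fields()] (or an
#' equivalent CFD export projected onto a regular grid).  The RST may be
#' stored with 6 components (symmetric vector form) or 9 (full tensor,
#' checked for symmetry and folded); 3 components (variances only) are
#' rejected naming the missing covariances.  Small negative eigenvalues
#' are clipped to zero and the adjustment reported via `message()`.
#'
#' @param path HDF5 file path.
#' @param sym_tol absolute symmetry tolerance for 9-component input.
#' @param psd_tol relative eigenvalue tolerance below which negative
#'   eigenvalues are clipped rather than rejected.
#' @return a validated [gt_field()].
#' @export
load_gridded_fields <- function(path, sym_tol = 1e-9, psd_tol = 1e-6) {
  if (!file.exists(path)) stop_domain("load_gridded_fields: no such file: %s", path)
  ls <- rhdf5::h5ls(path)$name
  for (need in c("u_mean", "rst", "mask"))
    if (!need %in% ls)
      stop_domain("load_gridded_fields: missing dataset '/%s'", need)
  u <- rhdf5::h5read(path, "u_mean")
  rst <- rhdf5::h5read(path, "rst")
  mask <- rhdf5::h5read(path, "mask")
  time_ms <- if ("time_ms" %in% ls) as.numeric(rhdf5::h5read(path, "time_ms")) else 0
  att <- rhdf5::h5readAttributes(path, "/")
  for (need in c("spacing_mm", "rho"))
    if (is.null(att[[need]]))
      stop_domain("load_gridded_fields: missing root attribute '%s'", need)
  sp <- dim(mask)
  if (length(sp) != 3L)
    stop_domain("load_gridded_fields: 'mask' must be 3-D")
  du <- dim(u); dr <- dim(rst)
  if (length(du) == 4L) dim(u) <- du <- c(du, 1L)
  if (length(dr) == 4L) dim(rst) <- dr <- c(dr, 1L)
  if (!identical(du[1:3], sp) || du[4L] != 3L)
    stop_domain("load_gridded_fields: 'u_mean' shape inconsistent with 'mask'")
  ncomp <- dr[4L]
  if (ncomp == 3L)
    stop_domain(paste("load_gridded_fields: 'rst' has variances only (3",
                      "components); covariances Rxy, Rxz, Ryz are missing"))
  if (ncomp == 9L) {
    nv <- prod(sp); nt <- dr[5L]
    r9 <- array(rst, c(nv, 9L, nt))
    asym <- max(abs(r9[, 2, ] - r9[, 4, ]), abs(r9[, 3, ] - r9[, 7, ]),
                abs(r9[, 6, ] - r9[, 8, ]))
    if (asym > sym_tol)
      stop_domain("load_gridded_fields: asymmetric RST (max |R_ij - R_ji| = %.3g)",
                  asym)
    # column-major 3x3: components 1,5,9 diagonal; symmetrize off-diagonals
    r6 <- array(0, c(nv, 6L, nt))
    r6[, 1, ] <- r9[, 1, ]; r6[, 2, ] <- r9[, 5, ]; r6[, 3, ] <- r9[, 9, ]
    r6[, 4, ] <- (r9[, 2, ] + r9[, 4, ]) / 2
    r6[, 5, ] <- (r9[, 3, ] + r9[, 7, ]) / 2
    r6[, 6, ] <- (r9[, 6, ] + r9[, 8, ]) / 2
    rst <- array(r6, c(sp, 6L, nt))
  } else if (ncomp != 6L) {
    stop_domain("load_gridded_fields: 'rst' must have 6 or 9 components, got %d",
                ncomp)
  }
  # Clip slightly negative eigenvalues (numerical noise in CFD exports).
  nt <- dim(rst)[5L]
  nv <- prod(sp)
  nclip <- 0L
  for (t in seq_len(nt)) {
    r6 <- matrix(array(rst, c(nv, 6L, nt))[, , t], nv, 6L)
    ev <- sym3_eigenvalues(r6)
    tr <- pmax(rowSums(r6[, 1:3, drop = FALSE]), .Machine$double.eps)
    bad <- which(ev[, 3L] < 0 & ev[, 3L] >= -psd_tol * tr)
    if (length(bad)) {
      r6[bad, ] <- sym3_psd_project(r6[bad, , drop = FALSE])
      rst[, , , , t] <- array(r6, c(sp, 6L))
      nclip <- nclip + length(bad)
    }
  }
  if (nclip > 0L)
    message(sprintf("load_gridded_fields: clipped negative eigenvalues at %d voxel(s)",
                    nclip))
  grid <- grid3d(sp, spacing = att$spacing_mm,
                 origin = att$origin_mm %||% c(0, 0, 0),
                 time_ms = time_ms,
                 period_ms = if (is.null(att$period_ms)) NULL else
                   as.numeric(att$period_ms))
  gt_field(grid, u, rst, array(mask != 0, sp),
           rho = as.numeric(att$rho), mu = as.numeric(att$mu %||% 3.5e-3))
}

#' Export a scalar map as legacy ASCII VTK structured points
#'
#' Minimal writer for visualization of TKE/KE maps in ParaView.
#'
#' @param field 3-D numeric array.
#' @param grid a [grid3d()].
#' @param path output `.vtk` file.
#' @param name dataset name.
#' @return `path`, invisibly.
#' @export
write_vtk_scalar <- function(field, grid, path, name = "scalar") {
  sp <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", sp[1], sp[2], sp[3]),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("SPACING %g %g %g", grid$spacing[1], grid$spacing[2],
                       grid$spacing[3]),
               sprintf("POINT_DATA %d", prod(sp)),
               sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"),
             con)
  writeLines(sprintf("%.9g", as.vector(field)), con)
  invisible(path)
}
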