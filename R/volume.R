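#' Construct a volume grid
#'
#' A `volume_grid` bundles voxel dimensions, voxel size, the voxel-to-mm
#' affine and a boolean gray-matter mask — the spatial frame every other
#' stage works in. Coordinates are RAS; voxel indices are 1-based in R and
#' mapped through the affine as 0-based indices (NIfTI convention).
#'
#' @param mask logical 3D array.
#' @param voxel_size mm per voxel along each axis.
#' @param affine optional 4x4 voxel-to-mm map; default centres the grid so
#'   the midsagittal plane sits at x = 0 mm.
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(mask, voxel_size = c(2, 2, 2), affine = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop_hv("mask is empty")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    # centre: voxel index (dims-1)/2 maps to 0 mm
    affine[1:3, 4] <- -voxel_size * (dim(mask) - 1) / 2
  }
  if (abs(det(affine)) < 1e-12) stop_hv("affine is singular")
  structure(list(dims = dim(mask), voxel_size = as.numeric(voxel_size),
                 affine = affine, mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels (%s mm), %d in mask\n",
              paste(x$dims, collapse = "x"),
              paste(x$voxel_size, collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Voxel indices of masked voxels
#'
#' @param grid a `volume_grid`.
#' @return integer matrix, one row per masked voxel, columns i/j/k (1-based).
#' @export
mask_voxels <- function(grid) {
  which(grid$mask, arr.ind = TRUE)
}

#' Map voxel indices to mm coordinates
#'
#' @param grid a `volume_grid`.
#' @param vox integer matrix of 1-based voxel indices (rows = voxels).
#' @return numeric matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, vox) {
  vox <- rbind(vox)  # tolerate single voxel as vector
  h <- cbind(vox - 1, 1)
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' Generate a synthetic gray-matter mask
#'
#' Stands in for a standard-space gray-matter template. Both kinds are
#' bilaterally symmetric about the midsagittal (x) plane by construction:
#' `ellipsoid` is a single filled ellipsoid, `two_lobes` a mirrored pair of
#' off-centre ellipsoids emulating two hemispheres.
#'
#' @param shape voxel dims, each >= 8.
#' @param kind `"ellipsoid"` or `"two_lobes"`.
#' @param voxel_size mm per voxel.
#' @param seed unused for the deterministic shapes, kept so every generator
#'   entry point shares one signature; recorded for provenance.
#' @return a `volume_grid`.
#' @export
make_mask <- function(shape = c(20, 20, 20), kind = c("ellipsoid", "two_lobes"),
                      voxel_size = c(2, 2, 2), seed = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop_hv("mask shape must have 3 axes, each >= 8 voxels (got %s)",
            paste(shape, collapse = "x"))
  }
  cx <- (shape - 1) / 2
  ii <- slice.index(array(0, shape), 1) - 1
  jj <- slice.index(array(0, shape), 2) - 1
  kk <- slice.index(array(0, shape), 3) - 1
  ell <- function(c0, r) {
    ((ii - c0[1]) / r[1])^2 + ((jj - c0[2]) / r[2])^2 + ((kk - c0[3]) / r[3])^2 <= 1
  }
  mask <- switch(kind,
    ellipsoid = ell(cx, 0.45 * shape),
    two_lobes = {
      off <- 0.22 * shape[1]
      r <- c(0.24 * shape[1], 0.42 * shape[2], 0.42 * shape[3])
      ell(cx + c(-off, 0, 0), r) | ell(cx + c(off, 0, 0), r)
    })
  # enforce exact mirror symmetry (guards against odd/even rounding)
  mask <- mask | mask[shape[1]:1, , , drop = FALSE]
  volume_grid(mask, voxel_size = voxel_size)
}
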