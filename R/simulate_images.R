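#' Fluorescence z-stack container
#'
#' @param voxels 3D intensity array indexed (z, row, col), non-negative.
#' @param pixel_size lateral pixel size, um/pixel.
#' @param z_step axial slice spacing, um.
#' @return object of class `zstack`.
#' @export
zstack <- function(voxels, pixel_size, z_step) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array (z, row, col)")
  if (any(dim(voxels) < 1L)) stop("all stack dimensions must be >= 1")
  if (pixel_size <= 0 || z_step <= 0) stop("pixel_size and z_step must be > 0")
  structure(list(voxels = voxels, pixel_size = pixel_size, z_step = z_step),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Z-stack: %d slices of %d x %d px (%.3g um/px, dz %.3g um)\n",
              d[1L], d[2L], d[3L], x$pixel_size, x$z_step))
  invisible(x)
}

#' Render a synthetic territory z-stack
#'
#' Renders each backbone point of `curve` as a 3D Gaussian spot centred on
#' the mid z-plane, using the error-function integral of the PSF over each
#' voxel so a spot deposits `photons_per_spot` expected counts in total.
#' Spots are summed, a uniform expected `background` is added, and Poisson
#' shot noise is applied. The curve (translated into the image frame) is
#' retained as ground truth in attribute `truth_curve`.
#'
#' Default optics emulate a widefield z-series: 10 slices at 0.25 um and a
#' diffraction-limited PSF (sigma 0.12 um lateral, 0.3 um axial) sampled at
#' 0.1 um/pixel.
#'
#' @param curve a [territory_curve()] (um coordinates).
#' @param pixel_size um/pixel. Default 0.1.
#' @param n_z number of z slices. Default 10.
#' @param z_step slice spacing, um. Default 0.25.
#' @param psf_sigma_xy,psf_sigma_z PSF Gaussian sigmas, um.
#' @param photons_per_spot expected photon count per backbone point.
#' @param background expected background counts per voxel.
#' @param fov_px optional `c(n_row, n_col)` field of view; the default is
#'   sized to fit the curve with a 4-sigma margin. A curve that does not
#'   fit the requested field of view is a geometry error.
#' @param seed integer RNG seed (Poisson noise).
#' @return a [zstack()] with attribute `truth_curve` (the input curve in
#'   image-frame coordinates).
#' @export
generate_image_stack <- function(curve, pixel_size = 0.1, n_z = 10L,
                                 z_step = 0.25, psf_sigma_xy = 0.12,
                                 psf_sigma_z = 0.3, photons_per_spot = 500,
                                 background = 10, fov_px = NULL,
                                 seed = NULL) {
  p <- as_curve_matrix(curve)
  if (n_z < 1L) stop("n_z must be >= 1")
  if (pixel_size <= 0 || z_step <= 0 || psf_sigma_xy <= 0 || psf_sigma_z <= 0)
    stop("pixel_size, z_step and PSF sigmas must be > 0")
  if (photons_per_spot < 0 || background < 0)
    stop("photons_per_spot and background must be >= 0")
  margin <- 4 * psf_sigma_xy + 2 * pixel_size
  # translate the curve into the image frame with a margin
  off <- margin - unname(apply(p, 2L, min))
  pimg <- sweep(p, 2L, off, `+`)
  span <- unname(apply(pimg, 2L, max)) + margin
  if (is.null(fov_px)) {
    fov_px <- c(ceiling(span[2L] / pixel_size), ceiling(span[1L] / pixel_size))
  } else {
    if (any(pimg[, 1L] > fov_px[2L] * pixel_size - margin + 4 * psf_sigma_xy) ||
        any(pimg[, 2L] > fov_px[1L] * pixel_size - margin + 4 * psf_sigma_xy))
      stop("geometry error: curve does not fit the requested field of view")
  }
  nr <- fov_px[1L]; nc <- fov_px[2L]
  # pixel edges in um; pixel (row, col) covers x in [(col-1), col]*pixel_size
  xe <- (0:nc) * pixel_size
  ye <- (0:nr) * pixel_size
  zc <- (seq_len(n_z) - (n_z + 1) / 2) * z_step  # slice centres, curve at z=0
  ze <- c(zc - z_step / 2, zc[n_z] + z_step / 2)
  pz <- diff(stats::pnorm(ze, 0, psf_sigma_z))
  expected <- array(0, dim = c(n_z, nr, nc))
  plane <- matrix(0, nr, nc)
  for (i in seq_len(nrow(pimg))) {
    px <- diff(stats::pnorm(xe, pimg[i, 1L], psf_sigma_xy))
    py <- diff(stats::pnorm(ye, pimg[i, 2L], psf_sigma_xy))
    plane <- plane + tcrossprod(py, px)
  }
  for (iz in seq_len(n_z))
    expected[iz, , ] <- photons_per_spot * pz[iz] * plane + background
  if (!is.null(seed)) set.seed(as.integer(seed))
  noisy <- array(stats::rpois(length(expected), expected), dim = dim(expected))
  st <- zstack(noisy, pixel_size = pixel_size, z_step = z_step)
  attr(st, "truth_curve") <- territory_curve(pimg, source = "synthetic")
  st
}

#' Write / read a z-stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored normalised to \[0, 1\]; the scale factor, voxel
#' geometry and (if present) the ground-truth curve go to `<path>.json`.
#'
#' @param stack a [zstack()].
#' @param path TIFF file path.
#' @return `read_zstack_tiff` returns a `zstack` (with `truth_curve`
#'   attribute when the sidecar holds one); `write_zstack_tiff` returns
#'   `path` invisibly.
#' @export
write_zstack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  mx <- max(stack$voxels, 1)
  pages <- lapply(seq_len(dim(stack$voxels)[1L]),
                  function(iz) stack$voxels[iz, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(max_intensity = mx, pixel_size = stack$pixel_size,
               z_step = stack$z_step)
  tc <- attr(stack, "truth_curve")
  if (!is.null(tc)) side$truth_curve <- unname(tc$points)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zstack_tiff
#' @export
read_zstack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vox <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (iz in seq_along(pages)) vox[iz, , ] <- pages[[iz]] * side$max_intensity
  st <- zstack(vox, pixel_size = side$pixel_size, z_step = side$z_step)
  if (!is.null(side$truth_curve))
    attr(st, "truth_curve") <- territory_curve(side$truth_curve,
                                               source = "synthetic")
  st
}
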