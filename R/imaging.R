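#' 2D intensity image
#'
#' @param pixels 2D non-negative intensity matrix (row, col).
#' @param pixel_size um/pixel.
#' @return object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size), class = "image2d")
}

#' Maximum-intensity projection of a z-stack
#'
#' Each output pixel is the maximum over z of the corresponding voxel
#' column; the lateral pixel size is preserved. This is the standard
#' reduction of a territory z-series to the 2D image on which shape is
#' quantified.
#'
#' @param stack a [zstack()].
#' @return an [image2d()].
#' @export
max_intensity_project <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$voxels)
  proj <- if (d[1L] == 1L) {
    matrix(stack$voxels[1L, , ], d[2L], d[3L])
  } else {
    apply(stack$voxels, c(2L, 3L), max)
  }
  img <- image2d(proj, stack$pixel_size)
  attr(img, "truth_curve") <- attr(stack, "truth_curve")
  img
}

#' Territory mask
#'
#' @param mask logical matrix.
#' @param pixel_size um/pixel.
#' @return object of class `territory_mask` with `area_um2 = sum(mask) *
#'   pixel_size^2`.
#' @export
territory_mask <- function(mask, pixel_size) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(mask = mask, pixel_size = pixel_size,
                 area_um2 = sum(mask) * pixel_size^2),
            class = "territory_mask")
}

#' @export
print.territory_mask <- function(x, ...) {
  cat(sprintf("Territory mask: %d px (%.3f um^2) in %d x %d image\n",
              sum(x$mask), x$area_um2, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Segment the chromosome territory in a projected image
#'
#' Otsu threshold, then a radius-1 morphological opening applied by
#' reconstruction: connected components of the thresholded mask that
#' survive the opening are kept in full, components erased by it (salt
#' noise, 1-px specks) are dropped. Plain opening would also erode
#' genuinely thin diagonal territory backbones to nothing, which the
#' reconstruction step avoids. Connected-component labelling then keeps
#' the largest component with at least `min_area_px` pixels. A constant
#' (featureless) image yields an empty mask, flagged via attribute `empty`
#' rather than an error, so batch runs can skip blank fields.
#'
#' @param img an [image2d()].
#' @param min_area_px minimum component area in pixels; the default 20 px is about the PSF footprint at 0.1 um/pixel sampling, so sub-diffraction specks are rejected.
#' @param contrast_min minimum ratio of mean above-threshold to mean
#'   below-threshold intensity for the threshold to count as real signal;
#'   Otsu always splits a distribution, so without this guard a
#'   signal-free noise image would segment its own shot noise. Default 2.
#' @return a [territory_mask()]; attribute `empty` is `TRUE` when no
#'   component passed.
#' @export
segment_territory <- function(img, min_area_px = 20L, contrast_min = 2) {
  stopifnot(inherits(img, "image2d"))
  px <- img$pixels
  rng <- range(px)
  if (rng[2L] <= rng[1L]) {
    m <- territory_mask(matrix(FALSE, nrow(px), ncol(px)), img$pixel_size)
    attr(m, "empty") <- TRUE
    return(m)
  }
  norm <- (px - rng[1L]) / (rng[2L] - rng[1L])
  # EBImage images are (x, y) = (col-major transpose of our (row, col))
  eb <- EBImage::Image(t(norm))
  th <- EBImage::otsu(eb)
  fg <- mean(px[norm > th]); bg <- mean(px[norm <= th])
  if (is.finite(fg) && bg > 0 && fg / bg < contrast_min) {
    m <- territory_mask(matrix(FALSE, nrow(px), ncol(px)), img$pixel_size)
    attr(m, "empty") <- TRUE
    return(m)
  }
  bw <- eb > th
  opened <- EBImage::opening(bw, EBImage::makeBrush(3L, shape = "diamond"))
  lab <- EBImage::bwlabel(bw)
  labm <- t(EBImage::imageData(lab))
  openm <- t(EBImage::imageData(opened)) > 0
  surviving <- unique(labm[openm & labm > 0])
  labm[!(labm %in% surviving)] <- 0L
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) {
    m <- territory_mask(matrix(FALSE, nrow(px), ncol(px)), img$pixel_size)
    attr(m, "empty") <- TRUE
    return(m)
  }
  best <- keep[which.max(sizes[keep])]
  territory_mask(labm == best, img$pixel_size)
}

#' Territory area
#'
#' @param mask a [territory_mask()].
#' @return area in um^2 (true-pixel count times pixel_size^2).
#' @export
territory_area <- function(mask) {
  stopifnot(inherits(mask, "territory_mask"))
  sum(mask$mask) * mask$pixel_size^2
}

#' Extract an ordered backbone curve from a territory mask
#'
#' For tube-like masks (a territory much longer than it is wide) the
#' backbone is the skeleton midline: the mask is skeletonized (Zhang-Suen
#' thinning), the 8-connected skeleton pixel graph is built, the longest
#' geodesic path is taken (double-sweep breadth-first search from an
#' arbitrary pixel: exact on tree-shaped skeletons, a standard
#' approximation when the skeleton has loops), the pixel path is converted
#' to physical um coordinates (x = col * pixel_size, y = row * pixel_size,
#' 0-based) and smoothed with a centred moving average of `smooth_window`
#' points to suppress pixel-lattice zigzag.
#'
#' When the territory is a compact blob — the geodesic midline is shorter
#' than `blob_aspect` times the local tube width — no 1D backbone is
#' resolvable (the medial axis of a disc is a point, and its K would be
#' spuriously huge). The curve returned is then an ordered serpentine
#' sweep through all mask pixel centres (strips along the principal axis,
#' alternating direction), whose gyration tensor equals that of the mask
#' region, so a round blob correctly yields K near 1 rather than a
#' spurious elongation.
#'
#' @param mask a non-empty [territory_mask()].
#' @param smooth_window moving-average window (odd, >= 1) for the midline
#'   branch. Default 5.
#' @param blob_aspect midline-length to tube-width ratio below which the
#'   mask is treated as a blob. Default 12 (calibrated on simulated territories: the midline only represents shape faithfully when the object is roughly an order of magnitude longer than wide).
#' @return a [territory_curve()] with source `"image"`; attribute
#'   `backbone` is `"midline"` or `"region_sweep"`.
#' @export
extract_curve <- function(mask, smooth_window = 5L, blob_aspect = 12) {
  stopifnot(inherits(mask, "territory_mask"))
  if (sum(mask$mask) < 3L)
    stop("degenerate curve: mask has fewer than 3 pixels")
  skel <- skeletonize(mask$mask)
  idx <- which(skel, arr.ind = TRUE)
  path <- if (nrow(idx) >= 3L) longest_skeleton_path(idx) else idx
  # local tube width: twice the mean distance-to-background along the path
  dm <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask$mask * 1)))))
  width_px <- 2 * mean(dm[path])
  path_len <- if (nrow(path) >= 2L) sum(sqrt(rowSums(diff(path)^2))) else 0
  if (nrow(path) < 3L || path_len < blob_aspect * width_px) {
    pix <- which(mask$mask, arr.ind = TRUE)
    pts <- serpentine_sweep(cbind((pix[, 2L] - 1) * mask$pixel_size,
                                  (pix[, 1L] - 1) * mask$pixel_size),
                            strip = mask$pixel_size)
    crv <- territory_curve(pts, source = "image")
    attr(crv, "backbone") <- "region_sweep"
    return(crv)
  }
  pts <- cbind((path[, 2L] - 1) * mask$pixel_size,
               (path[, 1L] - 1) * mask$pixel_size)
  crv <- territory_curve(smooth_polyline(pts, smooth_window), source = "image")
  attr(crv, "backbone") <- "midline"
  crv
}

# Order a point cloud as a serpentine path: strips along the first
# principal axis, alternating direction along the second. The ordered path
# visits every point once, so its gyration tensor equals the cloud's.
serpentine_sweep <- function(p, strip) {
  ctr <- colMeans(p)
  d <- sweep(p, 2L, ctr)
  ev <- eigen(crossprod(d) / nrow(d), symmetric = TRUE)$vectors
  uv <- d %*% ev[, c(1L, 2L)]  # u along major axis
  band <- floor((uv[, 1L] - min(uv[, 1L])) / strip + 1e-9)
  ord <- order(band, ifelse(band %% 2 == 0, 1, -1) * uv[, 2L])
  p[ord, , drop = FALSE]
}

# Zhang-Suen binary thinning; logical matrix in, logical skeleton out.
skeletonize <- function(m) {
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  img <- pad
  nr <- nrow(img); nc <- ncol(img)
  sh <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # clockwise neighbours p2..p9 starting from north
      p2 <- sh(img, -1, 0);  p3 <- sh(img, -1, 1); p4 <- sh(img, 0, 1)
      p5 <- sh(img, 1, 1);   p6 <- sh(img, 1, 0);  p7 <- sh(img, 1, -1)
      p8 <- sh(img, 0, -1);  p9 <- sh(img, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- img & B >= 2 & B <= 6 & A == 1
      if (pass == 1L) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nr - 1L), 2:(nc - 1L)]
}

# Longest geodesic path through the 8-connected pixel graph, via two
# breadth-first sweeps (diameter endpoints) and a weighted shortest path.
longest_skeleton_path <- function(idx) {
  n <- nrow(idx)
  if (n == 1L) return(idx)
  key <- idx[, 1L] + 1i * idx[, 2L]
  edges <- NULL
  w <- NULL
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  lookup <- seq_len(n)
  names(lookup) <- as.character(key)
  for (k in seq_len(nrow(offs))) {
    nb <- as.character(key + offs[k, 1L] + 1i * offs[k, 2L])
    hit <- which(nb %in% names(lookup))
    if (length(hit)) {
      edges <- rbind(edges, cbind(hit, lookup[nb[hit]]))
      w <- c(w, rep(sqrt(sum(offs[k, ]^2)), length(hit)))
    }
  }
  if (is.null(edges)) return(idx[1L, , drop = FALSE])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  d1 <- igraph::distances(g, v = main[1L])[1L, main]
  a <- main[which.max(d1)]
  d2 <- igraph::distances(g, v = a)[1L, main]
  b <- main[which.max(d2)]
  vp <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1L]]
  idx[as.integer(vp), , drop = FALSE]
}

# Centred moving average with shrinking windows at the ends (the curve is
# smoothed, not shortened).
smooth_polyline <- function(p, window = 5L) {
  window <- as.integer(window)
  if (window <= 1L || nrow(p) < 3L) return(p)
  h <- window %/% 2L
  n <- nrow(p)
  out <- p
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  out
}
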