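#' Gyration tensor of a 2D point set
#'
#' The gyration tensor is the second central moment matrix of the backbone
#' points,
#' \deqn{Q_{\alpha\beta} = \frac{1}{N}\sum_{i=1}^{N}
#'   (r_{i,\alpha} - r_{c,\alpha})(r_{i,\beta} - r_{c,\beta}),}
#' where \eqn{r_c} is the centroid of the \eqn{N} positions. Its eigenvalues
#' \eqn{\lambda_1 \le \lambda_2} are the squared principal extents of the
#' territory; their ratio is the aspect ratio \eqn{K} (see
#' [aspect_ratio()]).
#'
#' Collinear point sets have \eqn{\lambda_1 = 0}; these are not an error but
#' carry an infinite-K flag so downstream mixture fits can exclude them.
#'
#' @param curve a [territory_curve()] or an n x 2 coordinate matrix (um).
#' @return an object of class `gyration`: list with `Q` (2 x 2 matrix, um^2),
#'   `centroid` (length-2, um), `lambda` (eigenvalues ascending, um^2), `K`
#'   (aspect ratio, `Inf` when degenerate), `infinite_K` (flag), `n`.
#' @examples
#' gyration_tensor(rbind(c(1, 0), c(-1, 0), c(0, 0.5), c(0, -0.5)))
#' @export
gyration_tensor <- function(curve) {
  p <- as_curve_matrix(curve)
  if (nrow(unique(p)) < 2L)
    stop("gyration tensor needs at least 2 distinct points")
  n <- nrow(p)
  ctr <- colMeans(p)
  d <- sweep(p, 2L, ctr)
  Q <- crossprod(d) / n  # 1/N sum (r - r_c)(r - r_c)^T
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  lambda <- sort(ev)
  lambda[lambda < 0 & lambda > -1e-14 * max(lambda, 1)] <- 0
  inf_K <- lambda[1L] <= .Machine$double.eps * lambda[2L]
  K <- if (inf_K) Inf else lambda[2L] / lambda[1L]
  structure(
    list(Q = Q, centroid = ctr, lambda = lambda, K = K,
         infinite_K = inf_K, n = n),
    class = "gyration"
  )
}

#' @export
print.gyration <- function(x, ...) {
  cat(sprintf("Gyration tensor of %d points\n", x$n))
  cat(sprintf("  eigenvalues: %.4g, %.4g um^2\n", x$lambda[1L], x$lambda[2L]))
  if (x$infinite_K) {
    cat("  aspect ratio K: infinite (collinear points)\n")
  } else {
    cat(sprintf("  aspect ratio K: %.3f\n", x$K))
  }
  invisible(x)
}

#' Principal-axis aspect ratio K
#'
#' \eqn{K = \lambda_{max}/\lambda_{min}} of the gyration tensor. \eqn{K = 1}
#' corresponds to a perfectly round shape; larger K means a more extended
#' conformation. Collinear inputs (zero minor axis) return `Inf` with a
#' warning rather than raising an error, so callers can exclude them from
#' mixture fits while keeping count.
#'
#' @param gr a `gyration` object from [gyration_tensor()].
#' @return scalar K >= 1, or `Inf` for degenerate (collinear) input.
#' @export
aspect_ratio <- function(gr) {
  stopifnot(inherits(gr, "gyration"))
  if (gr$infinite_K) {
    warning("collinear points: aspect ratio K is infinite; ",
            "exclude from mixture fits")
    return(Inf)
  }
  gr$K
}

#' Shape statistics of a territory curve
#'
#' Convenience composition of [gyration_tensor()] and [aspect_ratio()].
#' K is invariant under rotation, translation, reflection and uniform
#' scaling of the curve.
#'
#' @inheritParams gyration_tensor
#' @param resample_arclength if `TRUE`, resample the curve to equally spaced
#'   arc-length positions (same point count) before computing the tensor;
#'   off by default since the reference procedure uses spline points as
#'   given, but uneven point density can bias Q.
#' @return a `gyration` object (contains `K`).
#' @export
shape_from_curve <- function(curve, resample_arclength = FALSE) {
  p <- as_curve_matrix(curve)
  if (isTRUE(resample_arclength)) p <- resample_curve(p, nrow(p))
  gyration_tensor(p)
}

# Resample a polyline to n points equally spaced in arc length.
resample_curve <- function(p, n) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(p)
  si <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, p[, 1L], xout = si)$y,
        stats::approx(s, p[, 2L], xout = si)$y)
}
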