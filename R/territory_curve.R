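#' Territory backbone curve
#'
#' An ordered sequence of 2D points (micrometres) tracing the backbone of a
#' chromosome territory, as produced by spline/skeleton extraction from an
#' image or by the synthetic worm-like-chain generator.
#'
#' @param points numeric matrix with >= 3 rows and 2 columns (x, y in um),
#'   all coordinates finite.
#' @param source provenance label, one of `"image"`, `"synthetic"`,
#'   `"external"`.
#' @return an object of class `territory_curve`: a list with elements
#'   `points` (n x 2 matrix, columns `x_um`, `y_um`) and `source`.
#' @examples
#' crv <- territory_curve(cbind(seq(0, 5, by = 0.05), 0.2 * sin(seq(0, 5, by = 0.05))))
#' crv
#' @export
territory_curve <- function(points, source = c("external", "image", "synthetic")) {
  source <- match.arg(source)
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  if (nrow(points) < 3L)
    stop("a territory curve needs at least 3 points")
  if (!all(is.finite(points)))
    stop("curve coordinates must be finite")
  colnames(points) <- c("x_um", "y_um")
  structure(list(points = points, source = source), class = "territory_curve")
}

#' @export
print.territory_curve <- function(x, ...) {
  rng <- apply(x$points, 2L, range)
  cat(sprintf(
    "Territory curve: %d points (%s), span %.2f x %.2f um\n",
    nrow(x$points), x$source, diff(rng[, 1L]), diff(rng[, 2L])
  ))
  invisible(x)
}

#' Arc length of a territory curve
#'
#' @param curve a [territory_curve()].
#' @return total polyline length in um.
#' @export
curve_length <- function(curve) {
  p <- as_curve_matrix(curve)
  sum(sqrt(rowSums(diff(p)^2)))
}

# Accept a territory_curve or a bare n x 2 matrix.
as_curve_matrix <- function(curve) {
  if (inherits(curve, "territory_curve")) return(curve$points)
  p <- as.matrix(curve)
  if (ncol(p) != 2L) stop("expected a territory_curve or an n x 2 matrix")
  storage.mode(p) <- "double"
  p
}

#' Read / write territory curves as CSV
#'
#' The on-disk format has columns `idx,x_um,y_um` with `idx` starting at 1.
#'
#' @param curve a [territory_curve()].
#' @param path file path.
#' @param source provenance label attached on read.
#' @return `read_curve_csv` returns a `territory_curve`;
#'   `write_curve_csv` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  p <- as_curve_matrix(curve)
  df <- data.frame(idx = seq_len(nrow(p)), x_um = p[, 1L], y_um = p[, 2L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path, source = "external") {
  df <- utils::read.csv(path)
  need <- c("idx", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns idx,x_um,y_um: ", path)
  df <- df[order(df$idx), , drop = FALSE]
  territory_curve(cbind(df$x_um, df$y_um), source = source)
}
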