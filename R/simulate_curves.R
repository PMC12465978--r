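#' Simulate a territory backbone curve (discrete worm-like chain)
#'
#' Generates an ordered 2D chain of `n_points` with fixed inter-point
#' spacing `step_len` and turning angles drawn from
#' \eqn{N(0, 1/(1 + persistence))}: persistence 0 gives a strongly turning,
#' compact chain and large persistence a nearly straight, extended one, so a
#' single stiffness knob spans the collapsed-to-extended regime of observed
#' territory conformations. `persistence = Inf` yields a perfectly straight
#' (collinear) chain, for which the shape stage reports an infinite aspect
#' ratio.
#'
#' @param n_points number of backbone points (>= 3). Default 200.
#' @param step_len inter-point distance in um (> 0). Default 0.05.
#' @param persistence dimensionless stiffness >= 0 (may be `Inf`). If `NULL`,
#'   set from `mode`: 50 for `"extended"`, 0 for `"collapsed"`.
#' @param mode conformation label, `"extended"` or `"collapsed"`; used only
#'   to default `persistence` and recorded as an attribute.
#' @param seed integer RNG seed; same seed and parameters give an identical
#'   curve.
#' @return a [territory_curve()] (source `"synthetic"`) with attributes
#'   `mode` and `persistence`.
#' @examples
#' crv <- generate_territory_curve(mode = "extended", seed = 1)
#' shape_from_curve(crv)$K
#' @export
generate_territory_curve <- function(n_points = 200L, step_len = 0.05,
                                     persistence = NULL,
                                     mode = c("extended", "collapsed"),
                                     seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(persistence))
    persistence <- if (mode == "extended") 50 else 0
  if (n_points < 3L) stop("n_points must be >= 3")
  if (step_len <= 0) stop("step_len must be > 0")
  if (is.na(persistence) || persistence < 0)
    stop("persistence must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  turn_sd <- if (is.infinite(persistence)) 0 else sqrt(1 / (1 + persistence))
  # heading of the first step is uniform; subsequent headings accumulate
  # Gaussian turning angles
  theta0 <- stats::runif(1L, -pi, pi)
  turns <- if (n_points > 2L) stats::rnorm(n_points - 2L, 0, turn_sd) else numeric()
  theta <- cumsum(c(theta0, turns))
  pts <- cbind(cumsum(c(0, step_len * cos(theta))),
               cumsum(c(0, step_len * sin(theta))))
  crv <- territory_curve(pts, source = "synthetic")
  attr(crv, "mode") <- mode
  attr(crv, "persistence") <- persistence
  crv
}

#' Simulate aspect-ratio samples from a two-component Gaussian mixture
#'
#' Draws `n` values from
#' \eqn{w_e N(\mu_e, \sigma_e^2) + (1 - w_e) N(\mu_c, \sigma_c^2)},
#' truncated below at 1 by redrawing within the same component (K >= 1 by
#' definition; clipping would pile mass at 1 and distort the collapsed
#' mode). The defaults are the osteoblast (OB) condition: collapsed and
#' extended mode means 1.82 and 3.58 with extended weight 0.81; the
#' osteosarcoma (OS) condition corresponds to means 1.65 / 2.93 with
#' `w_extended = 0.31`. Component SDs are free parameters (defaults 0.3
#' collapsed / 0.6 extended are a modelling choice, not measured values).
#'
#' @param n sample count (> 0).
#' @param mu_collapsed,mu_extended component means, `mu_extended >
#'   mu_collapsed >= 1`.
#' @param sigma_collapsed,sigma_extended component SDs (> 0).
#' @param w_extended extended-mode weight in \[0, 1\].
#' @param seed integer RNG seed.
#' @return numeric vector of `n` aspect ratios (all >= 1), with attribute
#'   `component` (`"extended"`/`"collapsed"` true label per draw).
#' @examples
#' k <- generate_k_sample(500, seed = 7)
#' mean(k)
#' @export
generate_k_sample <- function(n,
                              mu_collapsed = 1.82, mu_extended = 3.58,
                              sigma_collapsed = 0.3, sigma_extended = 0.6,
                              w_extended = 0.81, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("n must be a positive count")
  n <- as.integer(n)
  if (!(mu_extended > mu_collapsed) || mu_collapsed < 1)
    stop("need mu_extended > mu_collapsed >= 1")
  if (sigma_collapsed <= 0 || sigma_extended <= 0) stop("sigmas must be > 0")
  if (w_extended < 0 || w_extended > 1) stop("w_extended must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  comp <- stats::runif(n) < w_extended
  mu <- ifelse(comp, mu_extended, mu_collapsed)
  sd <- ifelse(comp, sigma_extended, sigma_collapsed)
  x <- stats::rnorm(n, mu, sd)
  # truncate below 1 by redraw, keeping each draw's component
  bad <- which(x < 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
    bad <- bad[x[bad] < 1]
  }
  attr(x, "component") <- ifelse(comp, "extended", "collapsed")
  x
}
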