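#' Drift-correct a trajectory against its nuclear-centroid series
#'
#' Whole-cell motion is removed by referencing locus positions to the
#' nuclear centroid: \eqn{p'(t_k) = p(t_k) - c(t_k) + c(t_0)}. The first
#' frame is unchanged and the output's centroid series is constant, so a
#' second correction is a no-op.
#'
#' @param traj a [locus_trajectory()] with a `centroid` series.
#' @return a drift-corrected `locus_trajectory`.
#' @export
drift_correct <- function(traj) {
  stopifnot(inherits(traj, "locus_trajectory"))
  if (is.null(traj$centroid))
    stop("drift correction needs a nuclear-centroid series")
  c0 <- traj$centroid[1L, ]
  pos <- traj$pos - traj$centroid + matrix(c0, nrow(traj$pos), 2L, byrow = TRUE)
  locus_trajectory(traj$t, pos,
                   centroid = matrix(c0, nrow(traj$pos), 2L, byrow = TRUE))
}

#' Mean squared displacement (overlapping time-average)
#'
#' The time-averaged MSD at lag \eqn{k\Delta t} over a trajectory with
#' frames \eqn{0..n} uses all \eqn{n - k + 1} overlapping displacement
#' pairs:
#' \deqn{MSD(k\Delta t) = \frac{1}{n-k+1} \sum_{m=0}^{n-k}
#'   |p(m\Delta t + k\Delta t) - p(m\Delta t)|^2 .}
#'
#' @param traj a [locus_trajectory()].
#' @param k_max largest lag index, `1 <= k_max <= n` (default `n`).
#' @return object of class `msd_curve`: data frame with columns `lag_s`,
#'   `msd` (um^2), `n_pairs`; attributes `dt` and `n`.
#' @export
compute_msd <- function(traj, k_max = NULL) {
  stopifnot(inherits(traj, "locus_trajectory"))
  n <- traj$n
  if (is.null(k_max)) k_max <- n
  if (k_max < 1L || k_max > n)
    stop("k_max must be between 1 and n = ", n)
  msd <- numeric(k_max)
  npair <- integer(k_max)
  for (k in seq_len(k_max)) {
    d <- traj$pos[(1L + k):(n + 1L), , drop = FALSE] -
      traj$pos[1L:(n + 1L - k), , drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    npair[k] <- n - k + 1L
  }
  structure(
    data.frame(lag_s = seq_len(k_max) * traj$dt, msd = msd, n_pairs = npair),
    dt = traj$dt, n = n, class = c("msd_curve", "data.frame")
  )
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Fits \eqn{MSD(\Delta t) = 4 D_{app} \Delta t^{\alpha}} by ordinary
#' least squares of \eqn{\log MSD} on \eqn{\log} lag over the first
#' `fit_fraction` of available lags (default the first 25%, where the
#' time-averaged MSD is least noisy). \eqn{\alpha} is the slope;
#' \eqn{D_{app} = e^{intercept}/4}. \eqn{\alpha = 1} is Brownian motion,
#' \eqn{\alpha < 1} subdiffusion.
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param fit_fraction fraction of the trajectory's lags to fit over
#'   (default 0.25); at least 3 lags are required and all fitted MSD values
#'   must be positive.
#' @return object of class `msd_powerlaw`: list with `D_app`
#'   (um^2/s^alpha), `alpha`, `fit_range` (lag indices), `r_squared`.
#'   Methods: `print`, `coef`, `predict`, `plot`.
#' @export
fit_power_law <- function(msd, fit_fraction = 0.25) {
  stopifnot(inherits(msd, "msd_curve"))
  n <- attr(msd, "n")
  k_hi <- min(max(floor(fit_fraction * n), 3L), nrow(msd))
  if (k_hi < 3L) stop("power-law fit needs at least 3 lags in range")
  sel <- seq_len(k_hi)
  if (any(msd$msd[sel] <= 0))
    stop("fit error: non-positive MSD in fit range (constant trajectory?)")
  lx <- log(msd$lag_s[sel])
  ly <- log(msd$msd[sel])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2L])
  D_app <- exp(unname(fit$coefficients[1L])) / 4
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(D_app = D_app, alpha = alpha, fit_range = sel,
                 r_squared = r2, msd = msd),
            class = "msd_powerlaw")
}

#' @export
print.msd_powerlaw <- function(x, ...) {
  cat(sprintf(
    "Power-law MSD fit over lags %d-%d: D_app = %.4g um^2/s^alpha, alpha = %.3f (R^2 = %.3f)\n",
    min(x$fit_range), max(x$fit_range), x$D_app, x$alpha, x$r_squared))
  invisible(x)
}

#' @export
coef.msd_powerlaw <- function(object, ...) {
  c(D_app = object$D_app, alpha = object$alpha)
}

#' @export
predict.msd_powerlaw <- function(object, lag_s = NULL, ...) {
  if (is.null(lag_s)) lag_s <- object$msd$lag_s
  4 * object$D_app * lag_s^object$alpha
}

#' @export
plot.msd_powerlaw <- function(x, ...) {
  graphics::plot(x$msd$lag_s, x$msd$msd, log = "xy",
                 xlab = "lag time (s)", ylab = expression(MSD ~ (mu * m^2)),
                 main = "MSD with power-law fit", pch = 16, col = "grey30", ...)
  graphics::lines(x$msd$lag_s, predict(x), col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "D_app = %.3g, alpha = %.2f", x$D_app, x$alpha))
  invisible(x)
}

#' Trajectory gyration radius
#'
#' \eqn{R_g = \sqrt{\frac{1}{n+1}\sum_{k=0}^{n} |p(t_k) - p_c|^2}} with
#' \eqn{p_c} the trajectory centroid: the root-mean-square distance of
#' positions from their centroid, i.e. the radius of the area explored by
#' the locus during the acquisition.
#'
#' @param traj a [locus_trajectory()] (a single position gives 0).
#' @return R_g in um.
#' @export
trajectory_radius <- function(traj) {
  pos <- if (inherits(traj, "locus_trajectory")) traj$pos else as.matrix(traj)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2L, ctr)^2)))
}

#' Effective diffusion constant from short-lag MSD
#'
#' Fits \eqn{MSD^{(s)} = 4 D_{eff} \Delta t} through the origin over the
#' first three lags (\eqn{\Delta t, 2\Delta t, 3\Delta t}); the zero
#' intercept reflects MSD(0) = 0.
#'
#' @param msd an `msd_curve` with at least 3 lags.
#' @return D_eff in um^2/s.
#' @export
effective_diffusion <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  if (nrow(msd) < 3L) stop("D_eff needs MSD at lags 1-3")
  lag <- msd$lag_s[1:3]
  val <- msd$msd[1:3]
  sum(val * lag) / sum(lag^2) / 4
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom, used for
#' group comparisons of trajectory statistics (R_g, D_eff). When both
#' groups are constant with equal values the comparison is vacuous and
#' p = 1 by convention; a single degenerate (zero-variance) group is an
#' error.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return list with `t`, `dof`, `p_two_sided`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, dof = length(a) + length(b) - 2L, p_two_sided = 1))
    stop("degenerate variance: both groups constant with different means")
  }
  if (va == 0 || vb == 0)
    stop("degenerate variance: one group is constant")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p_two_sided = tt$p.value)
}

#' Per-trajectory summary statistics
#'
#' Applies the full dynamics chain to one trajectory: optional drift
#' correction (when a centroid series is present), MSD, power-law fit,
#' R_g and D_eff.
#'
#' @param traj a [locus_trajectory()].
#' @param fit_fraction passed to [fit_power_law()].
#' @return one-row data frame with `n_frames`, `R_g`, `D_eff`, `D_app`,
#'   `alpha`, `r_squared`.
#' @export
trajectory_stats <- function(traj, fit_fraction = 0.25) {
  stopifnot(inherits(traj, "locus_trajectory"))
  if (!is.null(traj$centroid)) traj <- drift_correct(traj)
  msd <- compute_msd(traj)
  pl <- fit_power_law(msd, fit_fraction)
  data.frame(
    n_frames = traj$n + 1L,
    R_g = trajectory_radius(traj),
    D_eff = effective_diffusion(msd),
    D_app = pl$D_app, alpha = pl$alpha, r_squared = pl$r_squared
  )
}
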