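#' Locus trajectory
#'
#' Time-stamped 2D positions of a tracked genomic locus at a fixed frame
#' interval, optionally with a matched nuclear-centroid reference series
#' used for drift correction.
#'
#' @param t times in seconds, uniformly spaced.
#' @param pos n x 2 matrix of positions (um).
#' @param centroid optional n x 2 matrix of nuclear-centroid positions (um).
#' @return object of class `locus_trajectory`: list with `t`, `pos`,
#'   `centroid` (or `NULL`), `dt`, and `n` (index of the last frame; there
#'   are `n + 1` positions).
#' @export
locus_trajectory <- function(t, pos, centroid = NULL) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  if (ncol(pos) != 2L) stop("`pos` must be n x 2")
  if (length(t) != nrow(pos)) stop("length(t) must match nrow(pos)")
  if (length(t) < 2L) stop("a trajectory needs at least 2 positions")
  dt <- diff(t)
  if (any(abs(dt - dt[1L]) > 1e-9))
    stop("frame times must be uniformly spaced")
  if (!is.null(centroid)) {
    centroid <- as.matrix(centroid)
    storage.mode(centroid) <- "double"
    if (!all(dim(centroid) == dim(pos)))
      stop("`centroid` must have the same dimensions as `pos`")
  }
  structure(
    list(t = as.numeric(t), pos = pos, centroid = centroid,
         dt = dt[1L], n = nrow(pos) - 1L),
    class = "locus_trajectory"
  )
}

#' @export
print.locus_trajectory <- function(x, ...) {
  cat(sprintf("Locus trajectory: %d frames, dt = %g s%s\n",
              x$n + 1L, x$dt,
              if (is.null(x$centroid)) "" else ", with nuclear-centroid series"))
  invisible(x)
}

#' Simulate fractional-Brownian locus trajectories
#'
#' Generates 2D fractional Brownian motion with Hurst exponent
#' \eqn{H = \alpha/2}, scaled so the ensemble MSD obeys
#' \eqn{MSD(k\Delta t) = 4 D (k\Delta t)^{\alpha}} exactly, by Cholesky
#' factorisation of the exact fBM position covariance
#' \eqn{C_{ij} = D(t_i^{\alpha} + t_j^{\alpha} - |t_i - t_j|^{\alpha})} per
#' coordinate. Exact synthesis is preferred over spectral approximations at
#' the typical tracking length of ~100 frames. A constant per-frame drift
#' can be superimposed; the emitted nuclear-centroid series equals exactly
#' the injected cumulative drift, so drift correction inverts it exactly.
#' An optional reflecting circular confinement of radius
#' `confinement_radius` (about the starting position) is applied to the
#' diffusive part frame by frame; reflection breaks exact fBM increment
#' covariance and is intended for qualitative confined-motion scenarios.
#'
#' @param n_traj number of trajectories to generate.
#' @param D_true generalized diffusion coefficient, um^2/s^alpha.
#' @param alpha_true anomalous exponent, in (0, 2).
#' @param n_frames frames per trajectory (>= 2). Default 100.
#' @param dt frame interval in seconds. Default 0.2.
#' @param drift_per_frame length-2 drift vector added cumulatively per
#'   frame (um).
#' @param confinement_radius reflecting radius in um, or `NULL` for free
#'   motion.
#' @param seed integer RNG seed.
#' @return `generate_trajectories` returns a list of `n_traj`
#'   [locus_trajectory()] objects; `generate_trajectory` returns a single
#'   one.
#' @examples
#' tr <- generate_trajectory(D_true = 0.01, alpha_true = 1, seed = 3)
#' compute_msd(tr, k_max = 10)
#' @export
generate_trajectories <- function(n_traj, D_true, alpha_true,
                                  n_frames = 100L, dt = 0.2,
                                  drift_per_frame = c(0, 0),
                                  confinement_radius = NULL, seed = NULL) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (dt <= 0) stop("dt must be > 0")
  if (!(alpha_true > 0 && alpha_true < 2))
    stop("alpha_true must be in (0, 2)")
  if (D_true <= 0) stop("D_true must be > 0")
  if (length(drift_per_frame) != 2L) stop("drift_per_frame must be length 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_frames - 1L
  tk <- (1:n) * dt
  # exact per-coordinate position covariance: Var(X(t)) = 2 D t^alpha,
  # so the 2D ensemble MSD is 4 D t^alpha
  C <- D_true * (outer(tk^alpha_true, tk^alpha_true, `+`) -
                   abs(outer(tk, tk, `-`))^alpha_true)
  L <- t(chol(C + diag(1e-12 * max(diag(C)), n)))
  drift_path <- outer(0:n, drift_per_frame)
  times <- (0:n) * dt
  lapply(seq_len(n_traj), function(i) {
    z <- matrix(stats::rnorm(2L * n), n, 2L)
    pos <- rbind(c(0, 0), L %*% z)
    if (!is.null(confinement_radius)) {
      pos <- reflect_in_disc(pos, confinement_radius)
    }
    locus_trajectory(times, pos + drift_path, centroid = drift_path)
  })
}

#' @rdname generate_trajectories
#' @export
generate_trajectory <- function(D_true, alpha_true, n_frames = 100L,
                                dt = 0.2, drift_per_frame = c(0, 0),
                                confinement_radius = NULL, seed = NULL) {
  generate_trajectories(1L, D_true, alpha_true, n_frames, dt,
                        drift_per_frame, confinement_radius, seed)[[1L]]
}

# Reflect a path into a disc of radius R about the first position,
# applying the reflection increment by increment.
reflect_in_disc <- function(pos, R) {
  if (R <= 0) stop("confinement_radius must be > 0")
  out <- pos
  shift <- c(0, 0)
  for (i in 2:nrow(pos)) {
    p <- pos[i, ] + shift
    r <- sqrt(sum(p^2))
    while (r > R) {
      p <- p * (2 * R - r) / r
      r <- abs(2 * R - r)
    }
    shift <- p - pos[i, ]
    out[i, ] <- p
  }
  out
}

#' Read / write locus trajectories as CSV
#'
#' Columns: `frame,t_s,x_um,y_um` and, when a nuclear-centroid series is
#' present, `nucx_um,nucy_um`. `frame` starts at 0.
#'
#' @param traj a [locus_trajectory()].
#' @param path file path.
#' @return `read_trajectory_csv` returns a `locus_trajectory`;
#'   `write_trajectory_csv` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "locus_trajectory"))
  df <- data.frame(frame = 0:traj$n, t_s = traj$t,
                   x_um = traj$pos[, 1L], y_um = traj$pos[, 2L])
  if (!is.null(traj$centroid)) {
    df$nucx_um <- traj$centroid[, 1L]
    df$nucy_um <- traj$centroid[, 2L]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns frame,t_s,x_um,y_um: ", path)
  df <- df[order(df$frame), , drop = FALSE]
  ctr <- NULL
  if (all(c("nucx_um", "nucy_um") %in% names(df)))
    ctr <- cbind(df$nucx_um, df$nucy_um)
  locus_trajectory(df$t_s, cbind(df$x_um, df$y_um), centroid = ctr)
}
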