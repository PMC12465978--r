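#' Fit the bimodal Gaussian model to an aspect-ratio distribution
#'
#' Territory aspect ratios K form a bimodal distribution whose low mode is
#' the collapsed and whose high mode the extended conformation. This fits a
#' two-component Gaussian mixture
#' \eqn{w_e N(\mu_e, \sigma_e^2) + (1 - w_e) N(\mu_c, \sigma_c^2)} and
#' relabels components so \eqn{\mu_c < \mu_e}.
#'
#' Two fitting routes are provided. `method = "em"` (default) runs
#' expectation-maximization on the raw values with 10 restarts from
#' quantile-spread initializations, keeping the best log-likelihood;
#' it is free of binning choices. `method = "histogram_ls"` reproduces the
#' common histogram-based workflow: a two-Gaussian sum is least-squares
#' fitted to the histogram density (Freedman-Diaconis bin width), with the
#' extended weight taken from the component areas.
#'
#' Fits whose components are closer than half the summed SDs
#' (\eqn{|\mu_e - \mu_c| < (\sigma_c + \sigma_e)/2}) are overlap-flagged:
#' the two modes are not separable and mode percentages are refused.
#'
#' @param k numeric vector of finite aspect ratios (all >= 1). Infinite-K
#'   territories must be excluded upstream (see [aspect_ratio()]).
#' @param method `"em"` or `"histogram_ls"`.
#' @param condition optional free-text condition label stored in the fit.
#' @param seed integer seed for the EM restart jitter.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return an object of class `k_mixfit` with components `mu_c`, `mu_e`,
#'   `sigma_c`, `sigma_e`, `w_e`, `assignment_threshold` (K where the
#'   posterior probability of the extended component crosses 0.5),
#'   `loglik`, `converged`, `method`, `overlap_flag`, `n`, `condition`, and
#'   the data in `k`. Methods: `print`, `summary`, `coef`, `predict` (per-K
#'   labels or posteriors), `plot`, `simulate`, `logLik`.
#' @examples
#' k <- generate_k_sample(500, seed = 11)
#' fit <- fit_bimodal(k, seed = 1)
#' fit
#' conformation_percentages(fit)
#' @export
fit_bimodal <- function(k, method = c("em", "histogram_ls"),
                        condition = NULL, seed = NULL,
                        max_iter = 500L, tol = 1e-8) {
  method <- match.arg(method)
  k <- as.numeric(k)
  if (any(!is.finite(k)))
    stop("non-finite K values: exclude infinite-K territories upstream")
  if (any(k < 1)) stop("aspect ratios must be >= 1")
  if (length(k) < 20L)
    stop("insufficient data: bimodal fitting needs n >= 20 (got ",
         length(k), ")")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- if (method == "em") {
    em_mixture(k, n_restarts = 10L, max_iter = max_iter, tol = tol)
  } else {
    histogram_ls_mixture(k)
  }
  # relabel so the low-mean component is "collapsed"
  if (fit$mu[1L] > fit$mu[2L]) {
    fit$mu <- rev(fit$mu); fit$sigma <- rev(fit$sigma); fit$w <- rev(fit$w)
  }
  overlap <- abs(fit$mu[2L] - fit$mu[1L]) < (fit$sigma[1L] + fit$sigma[2L]) / 2
  thr <- if (overlap) NA_real_ else {
    posterior_threshold(fit$mu, fit$sigma, fit$w)
  }
  structure(
    list(mu_c = fit$mu[1L], mu_e = fit$mu[2L],
         sigma_c = fit$sigma[1L], sigma_e = fit$sigma[2L],
         w_e = fit$w[2L], assignment_threshold = thr,
         loglik = fit$loglik, converged = fit$converged,
         method = method, overlap_flag = overlap,
         n = length(k), condition = condition, k = k,
         loglik_trace = fit$loglik_trace),
    class = "k_mixfit"
  )
}

# Two-component univariate Gaussian EM with quantile-spread restarts.
em_mixture <- function(x, n_restarts = 10L, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  sd_floor <- max(1e-4 * stats::sd(x), 1e-8)
  lo_q <- seq(0.1, 0.35, length.out = n_restarts)
  hi_q <- seq(0.9, 0.65, length.out = n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- stats::quantile(x, c(lo_q[r], hi_q[r]), names = FALSE)
    sigma <- rep(max(stats::sd(x) / 2, sd_floor), 2L)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    trace <- numeric()
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w[1L] * stats::dnorm(x, mu[1L], sigma[1L])
      d2 <- w[2L] * stats::dnorm(x, mu[2L], sigma[2L])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll < ll_old - 1e-9)
        stop("EM log-likelihood decreased; numerical failure")
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      g2 <- d2 / tot
      g1 <- 1 - g2
      n1 <- sum(g1); n2 <- sum(g2)
      if (n1 < 1e-10 || n2 < 1e-10) break  # component died; restart
      w <- c(n1, n2) / n
      mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
      sigma <- pmax(c(sqrt(sum(g1 * (x - mu[1L])^2) / n1),
                      sqrt(sum(g2 * (x - mu[2L])^2) / n2)), sd_floor)
    }
    cand <- list(mu = mu, sigma = sigma, w = w, loglik = ll_old,
                 converged = converged, loglik_trace = trace)
    if (is.null(best) || (is.finite(cand$loglik) && cand$loglik > best$loglik))
      best <- cand
  }
  best
}

# Least-squares fit of a two-Gaussian sum to the histogram density.
histogram_ls_mixture <- function(x) {
  n <- length(x)
  bw <- 2 * stats::IQR(x) / n^(1 / 3)  # Freedman-Diaconis
  if (bw <= 0) bw <- diff(range(x)) / ceiling(sqrt(n))
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, dens = h$density)
  start <- list(
    w = 0.5,
    mu1 = stats::quantile(x, 0.2, names = FALSE),
    mu2 = stats::quantile(x, 0.8, names = FALSE),
    s1 = stats::sd(x) / 2, s2 = stats::sd(x) / 2
  )
  fit <- minpack.lm::nlsLM(
    dens ~ (1 - w) * stats::dnorm(mid, mu1, s1) + w * stats::dnorm(mid, mu2, s2),
    data = df, start = start,
    lower = c(0, min(x), min(x), 1e-4, 1e-4),
    upper = c(1, max(x), max(x), diff(range(x)), diff(range(x))),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  mu <- c(cf[["mu1"]], cf[["mu2"]])
  sigma <- c(cf[["s1"]], cf[["s2"]])
  w <- c(1 - cf[["w"]], cf[["w"]])
  # weights are the component areas of the fitted density sum
  d1 <- w[1L] * stats::dnorm(x, mu[1L], sigma[1L])
  d2 <- w[2L] * stats::dnorm(x, mu[2L], sigma[2L])
  ll <- sum(log(pmax(d1 + d2, .Machine$double.xmin)))
  list(mu = mu, sigma = sigma, w = w, loglik = ll,
       converged = fit$convInfo$isConv %||% TRUE, loglik_trace = numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# K at which the posterior probability of the extended component is 0.5,
# i.e. w_e dnorm(K, mu_e, s_e) = (1 - w_e) dnorm(K, mu_c, s_c); solved on
# [mu_c, mu_e].
posterior_threshold <- function(mu, sigma, w) {
  f <- function(k) {
    log(w[2L]) + stats::dnorm(k, mu[2L], sigma[2L], log = TRUE) -
      log(w[1L]) - stats::dnorm(k, mu[1L], sigma[1L], log = TRUE)
  }
  if (w[2L] >= 1) return(mu[1L])
  if (w[2L] <= 0) return(mu[2L])
  if (f(mu[1L]) >= 0) return(mu[1L])
  if (f(mu[2L]) <= 0) return(mu[2L])
  stats::uniroot(f, c(mu[1L], mu[2L]), tol = 1e-10)$root
}

#' @export
print.k_mixfit <- function(x, ...) {
  cat(sprintf("Bimodal Gaussian fit of K (%s, n = %d%s)\n", x$method, x$n,
              if (is.null(x$condition)) "" else paste0(", ", x$condition)))
  cat(sprintf("  collapsed: mean %.3f, sd %.3f (weight %.1f%%)\n",
              x$mu_c, x$sigma_c, 100 * (1 - x$w_e)))
  cat(sprintf("  extended:  mean %.3f, sd %.3f (weight %.1f%%)\n",
              x$mu_e, x$sigma_e, 100 * x$w_e))
  if (x$overlap_flag)
    cat("  WARNING: components overlap; modes not separable\n")
  else
    cat(sprintf("  assignment threshold: K = %.3f\n", x$assignment_threshold))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.k_mixfit <- function(object, ...) {
  print(object)
  cat(sprintf("  log-likelihood: %.3f\n", object$loglik))
  lab <- predict(object)
  cat(sprintf("  hard labels: %d extended, %d collapsed\n",
              sum(lab == "extended"), sum(lab == "collapsed")))
  invisible(object)
}

#' @export
coef.k_mixfit <- function(object, ...) {
  c(mu_c = object$mu_c, mu_e = object$mu_e,
    sigma_c = object$sigma_c, sigma_e = object$sigma_e,
    w_e = object$w_e)
}

#' @export
logLik.k_mixfit <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n, class = "logLik")
}

#' Classify aspect ratios against a fitted mixture
#'
#' @param object a `k_mixfit`.
#' @param newdata aspect ratios to classify; defaults to the fitted data.
#'   Infinite values are labelled `"extended"` by convention.
#' @param type `"label"` for hard labels (posterior of the extended
#'   component >= 0.5, ties to extended) or `"posterior"` for the extended
#'   posterior probability.
#' @param ... unused.
#' @return character vector of labels, or numeric posteriors.
#' @export
predict.k_mixfit <- function(object, newdata = NULL,
                             type = c("label", "posterior"), ...) {
  type <- match.arg(type)
  k <- if (is.null(newdata)) object$k else as.numeric(newdata)
  if (!object$converged) stop("cannot classify with a non-converged fit")
  de <- object$w_e * stats::dnorm(k, object$mu_e, object$sigma_e)
  dc <- (1 - object$w_e) * stats::dnorm(k, object$mu_c, object$sigma_c)
  post <- de / (de + dc)
  post[is.infinite(k)] <- 1  # infinite K: maximally extended
  post[is.nan(post)] <- as.numeric(k[is.nan(post)] >= object$assignment_threshold)
  if (type == "posterior") return(post)
  ifelse(post >= 0.5, "extended", "collapsed")
}

#' Classify a single territory
#'
#' Thin wrapper over [predict.k_mixfit()] matching the per-territory call
#' signature.
#'
#' @param K aspect ratio value(s); `Inf` allowed.
#' @param fit a converged `k_mixfit`.
#' @return `"extended"` or `"collapsed"` per value.
#' @export
classify_territory <- function(K, fit) {
  stopifnot(inherits(fit, "k_mixfit"))
  predict(fit, newdata = K, type = "label")
}

#' @export
simulate.k_mixfit <- function(object, nsim = 1L, seed = NULL, ...) {
  generate_k_sample(nsim,
                    mu_collapsed = object$mu_c, mu_extended = object$mu_e,
                    sigma_collapsed = object$sigma_c,
                    sigma_extended = object$sigma_e,
                    w_extended = object$w_e, seed = seed)
}

#' @export
plot.k_mixfit <- function(x, breaks = "FD", main = NULL, ...) {
  h <- graphics::hist(x$k, breaks = breaks, freq = FALSE,
                      xlab = "aspect ratio K",
                      main = main %||% "K distribution with bimodal fit",
                      col = "grey90", border = "grey60", ...)
  kk <- seq(min(x$k), max(x$k), length.out = 400L)
  dc <- (1 - x$w_e) * stats::dnorm(kk, x$mu_c, x$sigma_c)
  de <- x$w_e * stats::dnorm(kk, x$mu_e, x$sigma_e)
  graphics::lines(kk, dc, col = "firebrick", lwd = 2)
  graphics::lines(kk, de, col = "purple3", lwd = 2)
  graphics::lines(kk, dc + de, col = "black", lwd = 2)
  if (!x$overlap_flag)
    graphics::abline(v = x$assignment_threshold, lty = 2, col = "grey40")
  invisible(h)
}

#' Extended/collapsed percentages from a mixture fit
#'
#' The mode percentages are the mixture weights (the area under each
#' fitted component), not hard-label counts; hard labels are available via
#' [classify_territory()] for per-cell displays.
#'
#' @param fit a converged, non-overlap-flagged `k_mixfit`.
#' @return named vector `c(pct_extended, pct_collapsed)` in percent.
#' @export
conformation_percentages <- function(fit) {
  stopifnot(inherits(fit, "k_mixfit"))
  if (fit$overlap_flag)
    stop("mixture components overlap (|mu_e - mu_c| < (sigma_c + sigma_e)/2): ",
         "mode percentages are not meaningful for this sample")
  if (!fit$converged) stop("fit did not converge")
  c(pct_extended = 100 * fit$w_e, pct_collapsed = 100 * (1 - fit$w_e))
}

#' Count classified conformations
#'
#' @param labels character vector of `"extended"`/`"collapsed"` labels.
#' @return named integer vector `c(n_extended, n_collapsed)`.
#' @export
conformation_counts <- function(labels) {
  stopifnot(all(labels %in% c("extended", "collapsed")))
  c(n_extended = sum(labels == "extended"),
    n_collapsed = sum(labels == "collapsed"))
}

#' Compare conformation counts between two conditions (Fisher's exact test)
#'
#' Builds the 2 x 2 table of extended/collapsed counts for the two
#' conditions and applies the two-sided Fisher's exact test (summing
#' hypergeometric probabilities no larger than that of the observed table),
#' with the conditional maximum-likelihood odds ratio.
#'
#' @param a,b named count vectors `c(n_extended, n_collapsed)` (see
#'   [conformation_counts()]).
#' @return list with `table`, `odds_ratio`, `p_two_sided`.
#' @export
compare_conditions <- function(a, b) {
  tab <- rbind(a = as.integer(a[c("n_extended", "n_collapsed")]),
               b = as.integer(b[c("n_extended", "n_collapsed")]))
  colnames(tab) <- c("extended", "collapsed")
  if (any(tab < 0) || any(is.na(tab))) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined test: a margin of the 2x2 table is zero")
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_two_sided = ft$p.value)
}
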