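# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition with plain loops so they share
# no code path with the implementation they check.

# gyration tensor by explicit double loop over components
brute_gyration <- function(p) {
  n <- nrow(p)
  ctr <- c(sum(p[, 1]) / n, sum(p[, 2]) / n)
  Q <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    s <- 0
    for (i in 1:n) s <- s + (p[i, a] - ctr[a]) * (p[i, b] - ctr[b])
    Q[a, b] <- s / n
  }
  Q
}

# MSD by explicit double loop over (m, k)
brute_msd <- function(pos, dt, k_max) {
  n <- nrow(pos) - 1
  sapply(seq_len(k_max), function(k) {
    s <- 0
    for (m in 0:(n - k)) {
      d <- pos[m + k + 1, ] - pos[m + 1, ]
      s <- s + sum(d^2)
    }
    s / (n - k + 1)
  })
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins
brute_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  amin <- max(0, r1 + c1 - n); amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, c1, n - c1, r1)
  p_obs <- stats::dhyper(a_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Welch statistic, Satterthwaite dof and p from the textbook formulas
brute_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2a <- va / length(a); se2b <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  dof <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  list(t = t, dof = dof, p = 2 * stats::pt(-abs(t), dof))
}

# random rigid/similarity transform of a point set
random_similarity <- function(p, scale = 1) {
  th <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (stats::runif(1) < 0.5) R[, 2] <- -R[, 2]  # reflection
  shift <- stats::rnorm(2, 0, 10)
  sweep(scale * p %*% R, 2, shift, `+`)
}
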