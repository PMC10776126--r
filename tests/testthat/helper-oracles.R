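# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the tau2 oracle solves the Paule-Mandel equation
# by bisection, the MANOVA oracle permutes labels, and the biased-urn oracle
# samples genes weighted by probe count.

# Bisection root of the Paule-Mandel estimating equation
# sum_i w_i (y_i - mu_hat)^2 = k - 1, w_i = 1/(v_i + tau2), on [0, hi].
oracle_tau2_pm <- function(y, v, hi = 10, tol = 1e-10) {
  f <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2) - (length(y) - 1)
  }
  if (f(0) <= 0) return(0)
  while (f(hi) > 0) hi <- hi * 10
  stats::uniroot(f, c(0, hi), tol = tol)$root
}

# Closed-form random-effects pooling given tau2 (kept separate from the
# package's pool_random_effects).
oracle_pool <- function(y, v, tau2) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  list(mu = mu, se = se, p = 2 * stats::pnorm(-abs(mu / se)))
}

# Permutation p-value for the two-group MANOVA of rank columns on set
# membership. For two groups and fixed column totals, Pillai's trace is a
# fixed monotone function of the quadratic form d' T^{-1} d, d = in-set mean
# minus grand mean, with T the (permutation-invariant) total scatter; so
# permuting that quadratic form permutes Pillai exactly.
oracle_manova_perm_p <- function(R, member, n_perm = 20000, seed = 1) {
  set.seed(seed)
  N <- nrow(R); m <- sum(member)
  xbar <- colMeans(R)
  Tinv <- solve(crossprod(sweep(R, 2, xbar)))
  qform <- function(idx) {
    d <- colMeans(R[idx, , drop = FALSE]) - xbar
    drop(t(d) %*% Tinv %*% d)
  }
  obs <- qform(which(member))
  perm <- vapply(seq_len(n_perm), function(i) {
    qform(sample.int(N, m))
  }, 0)
  (1 + sum(perm >= obs)) / (1 + n_perm)
}

# Monte-Carlo biased-urn oracle: upper-tail probability that >= x of n genes
# drawn sequentially without replacement, with weights w, fall in `in_set`.
oracle_biased_urn_tail <- function(x, in_set, weights, n_draw, n_mc = 1e5,
                                   seed = 1) {
  set.seed(seed)
  N <- length(weights)
  hits <- vapply(seq_len(n_mc), function(i) {
    idx <- sample.int(N, n_draw, prob = weights)
    sum(in_set[idx])
  }, 0L)
  list(p = mean(hits >= x), se = stats::sd(hits >= x) / sqrt(n_mc))
}

# Manual Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}
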