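test_that("tau2 is zero when effects show no excess dispersion", {
  expect_equal(as.numeric(estimate_tau2_eb(c(0.3, 0.3, 0.3), c(0.02, 0.05, 0.1))), 0)
  # two cohorts, spread well inside sampling noise: root truncates at 0
  y <- c(0.1, 0.2); v <- c(5, 5)
  expect_equal(as.numeric(estimate_tau2_eb(y, v)), 0)
  expect_equal(oracle_tau2_pm(y, v), 0)
  # fewer than two cohorts: defined as 0 and flagged
  t1 <- estimate_tau2_eb(0.4, 0.01)
  expect_equal(as.numeric(t1), 0)
  expect_false(attr(t1, "converged"))
})

test_that("the EB fixed point matches the Paule-Mandel bisection root", {
  y <- c(0.1, 0.3, 0.5); v <- c(0.01, 0.01, 0.01)
  expect_equal(as.numeric(estimate_tau2_eb(y, v)), oracle_tau2_pm(y, v),
               tolerance = 1e-6)
  set.seed(77)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0, runif(1, 0.1, 2))
    v <- runif(k, 0.001, 0.5)
    est <- as.numeric(estimate_tau2_eb(y, v))
    expect_equal(est, oracle_tau2_pm(y, v), tolerance = 1e-5)
  }
})

test_that("the estimator agrees with metafor's EB implementation", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    y <- rnorm(k, 0.2, 0.4)
    v <- runif(k, 0.005, 0.2)
    fit <- suppressWarnings(metafor::rma(yi = y, vi = v, method = "EB",
                                         control = list(stepadj = 0.5,
                                                        maxiter = 10000,
                                                        threshold = 1e-8)))
    expect_equal(as.numeric(estimate_tau2_eb(y, v)), fit$tau2, tolerance = 1e-4)
  }
})

test_that("random-effects pooling follows the inverse-variance contract", {
  # single cohort: pass-through, flagged
  one <- pool_random_effects(0.2, 0.04)
  expect_equal(one$effect, 0.2)
  expect_equal(one$se, 0.2)
  expect_true(one$flag)
  # four identical cohorts: SE halves twice
  four <- pool_random_effects(rep(1, 4), rep(1, 4), tau2 = 0)
  expect_equal(four$effect, 1)
  expect_equal(four$se, 0.5)
  expect_equal(four$I2, 0)
  # toy triple matches the independent bisection-then-pool oracle
  y <- c(0.1, 0.3, 0.5); v <- c(0.01, 0.01, 0.01)
  t2 <- as.numeric(estimate_tau2_eb(y, v))
  got <- pool_random_effects(y, v, t2)
  want <- oracle_pool(y, v, oracle_tau2_pm(y, v))
  expect_equal(got$effect, want$mu, tolerance = 1e-6)
  expect_equal(got$p, want$p, tolerance = 1e-6)
})

test_that("presence filtering applies the inclusive 'at least' rule", {
  feats <- sprintf("f%02d", 1:100)
  set.seed(5)
  present_in <- sample(0:16, 100, replace = TRUE)
  tabs <- lapply(1:16, function(i) {
    has <- present_in >= i  # feature j appears in cohorts 1..present_in[j]
    tibble::tibble(feature = feats[has], effect = 0, se = 1, p = 0.5,
                   n = 30L, df = 27L, flag = FALSE)
  })
  kept <- presence_filter(tabs, k_min = 10)
  expect_setequal(kept, feats[present_in >= 10])
  expect_true(feats[which(present_in == 10)[1]] %in% kept)   # boundary kept
  expect_false(feats[which(present_in == 9)[1]] %in% kept)   # below dropped
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  suppressMessages(q <- bh_fdr(c(0.01, NA, 0.5)))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.01, 0.5)))
  expect_true(all(q >= c(0.01, NA, 0.5), na.rm = TRUE))  # q >= p
})

test_that("a thresholded null gives essentially no discoveries", {
  set.seed(10)
  n_hit <- vapply(1:200, function(i) sum(bh_fdr(runif(1000)) < 0.005), 0L)
  expect_gte(mean(n_hit == 0), 0.95)
})

test_that("the vectorised meta-analysis matches the per-feature estimator", {
  set.seed(33)
  tabs <- synthetic_assoc_tables(50, k = 6, mu = rnorm(50, 0, 0.1),
                                 tau2 = 0.005, seed = 3)
  m <- meta_analyze(tabs, k_min = 6)
  for (f in sample(m$feature, 10)) {
    y <- vapply(tabs, function(tb) tb$effect[tb$feature == f], 0)
    v <- vapply(tabs, function(tb) tb$se[tb$feature == f]^2, 0)
    t2 <- as.numeric(estimate_tau2_eb(y, v))
    row <- m[m$feature == f, ]
    expect_equal(row$tau2, t2, tolerance = 1e-6)
    expect_equal(row$effect, oracle_pool(y, v, t2)$mu, tolerance = 1e-8)
  }
  expect_true(all(m$I2 >= 0 & m$I2 <= 100))
  expect_true(all(m$q >= m$p))
})

test_that("meta-analysis is invariant to cohort order", {
  tabs <- synthetic_assoc_tables(40, k = 5, mu = 0.05, tau2 = 0.002, seed = 4)
  m1 <- meta_analyze(tabs, k_min = 5)
  m2 <- meta_analyze(rev(tabs), k_min = 5)
  expect_equal(m1, m2)
})

test_that("pooling approaches the fixed-effect answer as heterogeneity vanishes", {
  deltas <- c(0.05, 0.005, 5e-4)
  max_diff <- vapply(deltas, function(t2p) {
    tabs <- synthetic_assoc_tables(80, k = 16, mu = 0.1, tau2 = t2p, seed = 6)
    m <- meta_analyze(tabs, k_min = 16)
    fe <- vapply(m$feature, function(f) {
      y <- vapply(tabs, function(tb) tb$effect[tb$feature == f], 0)
      v <- vapply(tabs, function(tb) tb$se[tb$feature == f]^2, 0)
      sum(y / v) / sum(1 / v)
    }, 0)
    max(abs(m$effect - fe))
  }, 0)
  expect_true(all(diff(max_diff) < 0))
  expect_lt(max_diff[3], 0.01)
})

test_that("selection respects the FDR threshold, direction, and convergence flags", {
  empty <- meta_analyze(synthetic_assoc_tables(5, 3, mu = 0, tau2 = 0, seed = 1),
                        k_min = 4)
  expect_equal(nrow(select_age_features(empty)), 0)
  tabs <- synthetic_assoc_tables(200, k = 8,
                                 mu = c(rep(0.3, 20), rep(-0.3, 20), rep(0, 160)),
                                 tau2 = 0.001, seed = 9)
  m <- meta_analyze(tabs, k_min = 8)
  sel <- select_age_features(m, q_threshold = 0.005)
  expect_true(all(sel$q < 0.005))
  expect_setequal(unique(sel$direction), c("up", "down"))
  expect_true(all(sel$direction[sel$effect > 0] == "up"))
})

test_that("forest export carries per-cohort rows plus the pooled row", {
  tabs <- synthetic_assoc_tables(10, k = 4, mu = 0.2, tau2 = 0, seed = 2)
  m <- meta_analyze(tabs, k_min = 4)
  fd <- forest_data(tabs, m, m$feature[1])
  expect_equal(nrow(fd), 5)
  expect_equal(fd$cohort[5], "pooled")
  expect_true(all(fd$lo < fd$effect & fd$effect < fd$hi))
})
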