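test_that("restriction-then-FDR equals FDR on the subset, with no leakage", {
  tabs <- synthetic_assoc_tables(100, k = 5, mu = rnorm(100, 0, 0.15),
                                 tau2 = 0.001, seed = 14)
  full <- meta_analyze(tabs, k_min = 5)
  sub <- sample(full$feature, 30)
  restricted <- restrict_and_meta(tabs, sub, k_min = 5)
  expect_setequal(restricted$feature, sub)
  idx <- match(restricted$feature, full$feature)
  expect_equal(restricted$p, full$p[idx])
  expect_equal(restricted$q, bh_fdr(full$p[idx]))
  # single-feature restriction: q equals p
  single <- restrict_and_meta(tabs, sub[1], k_min = 5)
  expect_equal(single$q, single$p)
  expect_error(restrict_and_meta(tabs, character()), "nonempty")
  expect_error(restrict_and_meta(tabs, "not_a_feature"), "cohort")
})

test_that("secondary effects at age features separate from null features", {
  sim <- small_sim(seed = 16, n_cohorts = 6, n_features = 800)
  vo2 <- suppressMessages(fit_contrast_cohorts(
    sim$cohorts, contrast_spec("vo2max", covariates = c("age", "sex"))))
  sig <- sim$truth$features$feature[sim$truth$features$is_signal]
  nul <- sim$truth$features$feature[!sim$truth$features$is_signal]
  m <- restrict_and_meta(vo2, c(sig, nul), k_min = 4)
  med_sig <- median(m$p[m$feature %in% sig])
  med_nul <- median(m$p[m$feature %in% nul])
  expect_lt(med_sig, med_nul)
  # permuted fitness: essentially nothing selected
  perm_cohorts <- purrr::map(sim$cohorts, function(ch) {
    set.seed(1); ch$samples$vo2max <- sample(ch$samples$vo2max); ch
  })
  vo2p <- suppressMessages(fit_contrast_cohorts(
    perm_cohorts, contrast_spec("vo2max", covariates = c("age", "sex"))))
  mp <- restrict_and_meta(vo2p, c(sig, nul), k_min = 4)
  expect_lte(sum(mp$q < 0.005, na.rm = TRUE), 2)
})

test_that("external summary ingestion joins, reports match rate, and rejects bad input", {
  uni <- sprintf("g%03d", 1:40)
  full <- tibble::tibble(feature = uni, effect = rnorm(40), p = runif(40))
  got <- ingest_external_summary(full, uni)
  expect_equal(attr(got, "match_rate"), 1)
  expect_equal(got$effect, full$effect)
  half <- full[1:20, ]
  suppressMessages(got2 <- ingest_external_summary(half, uni))
  expect_equal(attr(got2, "match_rate"), 0.5)
  expect_setequal(attr(got2, "unmatched"), uni[21:40])
  expect_equal(sum(!got2$matched), 20)
  expect_error(ingest_external_summary(full[0, ], uni), "empty")
  expect_error(ingest_external_summary(dplyr::bind_rows(full, full[3, ]), uni),
               "row")
  # log2FC column is accepted as the effect
  lfc <- dplyr::rename(full, log2FC = "effect")
  expect_equal(ingest_external_summary(lfc, uni)$effect, full$effect)
  # round-trips through TSV on disk
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(full, path)
  expect_equal(ingest_external_summary(path, uni)$effect, full$effect)
})

test_that("effect correlation behaves like a Spearman correlation should", {
  x <- rnorm(50)
  panel <- build_contrast_panel(
    sprintf("f%02d", 1:50),
    a = tibble::tibble(feature = sprintf("f%02d", 1:50), effect = x, p = 0.5),
    b = tibble::tibble(feature = sprintf("f%02d", 1:50), effect = x, p = 0.5),
    c = tibble::tibble(feature = sprintf("f%02d", 1:50), effect = -x, p = 0.5),
    d = tibble::tibble(feature = sprintf("f%02d", 1:50), effect = exp(2 * x), p = 0.5)
  )
  expect_equal(effect_correlation(panel, "a", "b")$rho, 1)
  expect_equal(effect_correlation(panel, "a", "c")$rho, -1)
  # symmetry and invariance to strictly monotone transforms
  expect_equal(effect_correlation(panel, "a", "d")$rho,
               effect_correlation(panel, "d", "a")$rho)
  expect_equal(effect_correlation(panel, "a", "d")$rho, 1)
  const <- build_contrast_panel(
    sprintf("f%02d", 1:50),
    a = tibble::tibble(feature = sprintf("f%02d", 1:50), effect = x, p = 0.5),
    k = tibble::tibble(feature = sprintf("f%02d", 1:50), effect = 1, p = 0.5)
  )
  expect_error(effect_correlation(const, "a", "k"), "constant")
  expect_error(effect_correlation(panel, "a", "nope"), "unknown")
})

test_that("scaling effects to unit SD preserves ranks and errors on zero SD", {
  feats <- sprintf("f%02d", 1:30)
  set.seed(2)
  panel <- build_contrast_panel(
    feats,
    age = tibble::tibble(feature = feats, effect = rnorm(30, sd = 2), p = 0.5),
    fit = tibble::tibble(feature = feats, effect = rnorm(30, sd = 1), p = 0.5)
  )
  scaled <- scale_effects(panel)
  expect_equal(sd(scaled$effect_age), 1)
  expect_equal(scaled$effect_age, panel$effect_age / sd(panel$effect_age))
  expect_equal(effect_correlation(scaled, "age", "fit")$rho,
               effect_correlation(panel, "age", "fit")$rho)
  # already unit SD: unchanged
  rescaled <- scale_effects(scaled)
  expect_equal(rescaled$effect_fit, scaled$effect_fit)
  # ordering for heatmap export: most decreased first
  ordered <- scale_effects(panel, order_by = "age")
  expect_true(!is.unsorted(ordered$effect_age))
  panel$effect_fit <- 0
  expect_error(scale_effects(panel), "zero-SD")
})

test_that("inflation factor is calibrated on a uniform grid and monotone", {
  n <- 10000
  grid <- seq_len(n) / (n + 1)
  qq <- qq_inflation(grid)
  expect_equal(qq$lambda, 1, tolerance = 0.02)
  expect_true(all(diff(qq$expected) > 0))
  qq_half <- qq_inflation(grid / 2)
  expect_gt(qq_half$lambda, 1)
  expect_gt(qq_half$lambda, qq$lambda)
  expect_error(qq_inflation(numeric(0)), "empty")
  expect_error(qq_inflation(c(0.5, 0)), "\\(0, 1\\]")
  g <- glance(qq)
  expect_equal(g$n, n)
  td <- tidy(qq)
  expect_equal(nrow(td), n)
})

test_that("fitness-linked variation surfaces on the leading principal component", {
  set.seed(55)
  n <- 60; nf <- 200
  vo2 <- runif(n, 25, 60)
  loadings <- rnorm(nf)
  mat <- outer(loadings, scale(vo2)[, 1] * 4) + matrix(rnorm(nf * n), nf, n)
  dimnames(mat) <- list(sprintf("f%03d", 1:nf), sprintf("s%02d", 1:n))
  pf <- pca_fitness_association(mat, vo2)
  expect_gt(abs(pf$assoc$r[1]), 0.9)
  expect_lt(pf$assoc$p[1], 1e-6)
  # duplicating every sample leaves the correlations unchanged
  pf2 <- pca_fitness_association(mat[, rep(1:n, 2)], rep(vo2, 2))
  expect_equal(abs(pf2$assoc$r[1]), abs(pf$assoc$r[1]), tolerance = 1e-6)
  expect_equal(nrow(tidy(pf)), 3)
})

test_that("PC associations are null when fitness is permuted", {
  set.seed(66)
  n <- 40; nf <- 120
  mat <- matrix(rnorm(nf * n), nf, n,
                dimnames = list(sprintf("f%03d", 1:nf), sprintf("s%02d", 1:n)))
  pvals <- replicate(40, {
    pca_fitness_association(mat, rnorm(n))$assoc$p
  })
  expect_gt(mean(pvals < 0.05), 0.0)  # sanity: some rejections can occur
  expect_lt(mean(pvals < 0.05), 0.12)
  ks <- suppressWarnings(stats::ks.test(as.vector(pvals), "punif"))
  expect_gt(ks$p.value, 0.01)
})
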