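#' Empirical-Bayes (Paule-Mandel) between-cohort variance estimator
#'
#' Solves the Paule-Mandel estimating equation
#' `sum_i w_i(tau2) * (y_i - mu_hat(tau2))^2 = k - 1`, with
#' `w_i = 1/(v_i + tau2)` and `mu_hat` the weighted mean, by a damped
#' fixed-point iteration (the empirical-Bayes scheme, whose fixed point is the
#' Paule-Mandel root): at each step the candidate update is
#' `sum_i w_i * ((k/(k-1)) * (y_i - mu_hat)^2 - v_i) / sum_i w_i`, moved
#' toward by a fraction `step`, truncated at zero. Iteration stops when
#' successive iterates differ by less than `tol` or after `max_iter` steps
#' (non-convergence is flagged in the `converged` attribute).
#'
#' @param effects Per-cohort effect estimates `y_i`.
#' @param variances Per-cohort sampling variances `v_i` (all > 0).
#' @param step Damping factor in (0, 1], default 0.5.
#' @param max_iter Iteration cap, default 10000.
#' @param tol Convergence tolerance on successive iterates, default 1e-8.
#' @return `tau2_hat >= 0`, with attribute `converged`. With fewer than two
#'   cohorts the estimate is defined as 0 and flagged unconverged.
#' @export
#' @examples
#' estimate_tau2_eb(c(0.1, 0.3, 0.5), c(0.01, 0.01, 0.01))
#' estimate_tau2_eb(c(0.3, 0.3, 0.3), c(0.02, 0.05, 0.1)) # zero dispersion
estimate_tau2_eb <- function(effects, variances, step = 0.5,
                             max_iter = 10000L, tol = 1e-8) {
  k <- length(effects)
  stopifnot(length(variances) == k)
  if (k < 2) {
    return(structure(0, converged = FALSE))
  }
  if (any(variances <= 0)) abort("all sampling variances must be > 0")
  tau2 <- max(0, var(effects) - mean(variances))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / (variances + tau2)
    mu <- sum(w * effects) / sum(w)
    target <- sum(w * ((k / (k - 1)) * (effects - mu)^2 - variances)) / sum(w)
    new_tau2 <- max(0, tau2 + step * (target - tau2))
    if (abs(new_tau2 - tau2) < tol) {
      tau2 <- new_tau2
      converged <- TRUE
      break
    }
    tau2 <- new_tau2
  }
  structure(tau2, converged = converged)
}

# Vectorised EB/PM iteration over a features-by-cohorts effect matrix with
# missingness; same update, all features advanced simultaneously.
tau2_eb_matrix <- function(E, V, step = 0.5, max_iter = 10000L, tol = 1e-8) {
  obs <- !is.na(E) & !is.na(V) & V > 0
  k <- rowSums(obs)
  E0 <- ifelse(obs, E, 0)
  V0 <- ifelse(obs, V, 1)  # placeholder variance; masked by obs everywhere
  # same moment-based start as the scalar estimator: var(y) - mean(v)
  ybar <- rowSums(E0) / pmax(k, 1)
  vary <- rowSums(obs * (E0 - ybar)^2) / pmax(k - 1, 1)
  tau2 <- pmax(0, vary - rowSums(V0 * obs) / pmax(k, 1))
  tau2[k < 2] <- 0
  converged <- k < 2  # flagged separately; nothing to iterate
  active <- k >= 2
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    a <- which(active)
    w <- obs[a, , drop = FALSE] / (V0[a, , drop = FALSE] + tau2[a])
    sw <- rowSums(w)
    mu <- rowSums(w * E0[a, , drop = FALSE]) / sw
    kk <- k[a]
    target <- rowSums(w * ((kk / (kk - 1)) * (E0[a, , drop = FALSE] - mu)^2 -
                             V0[a, , drop = FALSE])) / sw
    new_tau2 <- pmax(0, tau2[a] + step * (target - tau2[a]))
    done <- abs(new_tau2 - tau2[a]) < tol
    tau2[a] <- new_tau2
    converged[a[done]] <- TRUE
    active[a[done]] <- FALSE
  }
  list(tau2 = tau2, converged = converged & k >= 2, k = k)
}

#' Random-effects pooling of per-cohort effects
#'
#' Inverse-variance pooling with weights `w_i = 1/(v_i + tau2)`:
#' `mu_hat = sum(w y)/sum(w)`, `SE = sum(w)^(-1/2)`, `z = mu_hat/SE`,
#' `p = 2 * pnorm(-|z|)`. Also reports Cochran's Q (computed with
#' fixed-effect weights `1/v_i`) and `I2 = max(0, (Q - (k-1))/Q) * 100`.
#' With a single cohort the estimate passes through (`mu_hat = y_1`,
#' `SE = sqrt(v_1)`) and is flagged.
#'
#' @param effects,variances Per-cohort effects and sampling variances.
#' @param tau2 Between-cohort variance (>= 0), e.g. from
#'   [estimate_tau2_eb()].
#' @return One-row tibble: `k`, `effect`, `se`, `z`, `p`, `tau2`, `Q`, `I2`,
#'   `flag`.
#' @export
#' @examples
#' pool_random_effects(c(1, 1, 1, 1), c(1, 1, 1, 1), tau2 = 0) # SE = 0.5
pool_random_effects <- function(effects, variances, tau2 = 0) {
  k <- length(effects)
  stopifnot(length(variances) == k, tau2 >= 0)
  if (k == 1) {
    return(tibble::tibble(k = 1L, effect = effects, se = sqrt(variances),
                          z = effects / sqrt(variances),
                          p = 2 * pnorm(-abs(effects / sqrt(variances))),
                          tau2 = tau2, Q = NA_real_, I2 = NA_real_,
                          flag = TRUE))
  }
  w <- 1 / (variances + tau2)
  mu <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- mu / se
  w_fe <- 1 / variances
  mu_fe <- sum(w_fe * effects) / sum(w_fe)
  Q <- sum(w_fe * (effects - mu_fe)^2)
  I2 <- max(0, (Q - (k - 1)) / Q) * 100
  tibble::tibble(k = as.integer(k), effect = mu, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), tau2 = tau2, Q = Q, I2 = I2,
                 flag = FALSE)
}

#' Presence filter across cohorts
#'
#' Features are only meta-analysed when estimably present in at least `k_min`
#' cohorts (the "at least" is inclusive: a feature in exactly `k_min` cohorts
#' is retained).
#'
#' @param assoc_tables Named list of per-cohort association tibbles
#'   ([fit_contrast()] output).
#' @param k_min Minimum number of contributing cohorts (default 10, the rule
#'   used for methylation; 15 is the usual expression rule).
#' @return Character vector of retained feature IDs.
#' @export
presence_filter <- function(assoc_tables, k_min = 10L) {
  stopifnot(k_min >= 1)
  counts <- purrr::map_dfr(assoc_tables, ~ dplyr::filter(.x, !.data$flag)) |>
    dplyr::count(.data$feature)
  counts$feature[counts$n >= k_min]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values: `q_(i) = min_{j >= i}(p_(j) * n / j)`, capped at 1.
#' Missing or NaN p-values propagate as NA (with a message reporting how
#' many) and do not count toward `n`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  ok <- !is.na(p)
  if (any(!ok)) message(sprintf("%d missing p-value(s) propagated as NA", sum(!ok)))
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Random-effects meta-analysis across cohorts, per feature
#'
#' Pools per-cohort association results feature by feature: presence
#' filtering, empirical-Bayes (Paule-Mandel) tau-squared estimation, and
#' inverse-variance random-effects pooling, followed by BH-FDR across the
#' tested features. Features whose tau-squared iteration did not converge are
#' reported with `converged = FALSE`; [select_age_features()] excludes them.
#'
#' @param assoc_tables Named list of per-cohort association tibbles.
#' @param k_min Presence threshold, see [presence_filter()].
#' @param features Optional feature subset to restrict the analysis (and the
#'   FDR correction) to, e.g. a previously selected age-related list.
#' @param step,max_iter,tol Passed to the tau-squared iteration.
#' @return Tibble of class `meta_tbl`: `feature`, `k`, `effect`, `se`, `z`,
#'   `p`, `tau2`, `Q`, `I2`, `q`, `converged`.
#' @export
meta_analyze <- function(assoc_tables, k_min = 10L, features = NULL,
                         step = 0.5, max_iter = 10000L, tol = 1e-8) {
  stopifnot(length(assoc_tables) >= 1)
  if (is.null(names(assoc_tables))) {
    names(assoc_tables) <- sprintf("cohort%02d", seq_along(assoc_tables))
  }
  long <- purrr::imap_dfr(assoc_tables, function(tb, id) {
    tb <- dplyr::filter(tb, !.data$flag)
    dplyr::transmute(tb, cohort = id, feature = .data$feature,
                     effect = .data$effect, v = .data$se^2)
  })
  if (!is.null(features)) {
    missing_everywhere <- setdiff(features, long$feature)
    if (length(missing_everywhere) == length(features)) {
      abort("none of the requested features are present in any cohort")
    }
    long <- dplyr::filter(long, .data$feature %in% features)
  }
  keep <- presence_filter(assoc_tables, k_min = k_min)
  if (!is.null(features)) keep <- intersect(keep, features)
  long <- dplyr::filter(long, .data$feature %in% keep)
  if (nrow(long) == 0) {
    return(structure(tibble::tibble(
      feature = character(), k = integer(), effect = double(), se = double(),
      z = double(), p = double(), tau2 = double(), Q = double(), I2 = double(),
      q = double(), converged = logical()), class = c("meta_tbl", class(tibble::tibble()))))
  }

  cohort_ids <- names(assoc_tables)
  wide <- long |>
    tidyr::pivot_wider(names_from = "cohort",
                       values_from = c("effect", "v")) |>
    dplyr::arrange(.data$feature)
  feat <- wide$feature
  have <- cohort_ids[paste0("effect_", cohort_ids) %in% names(wide)]
  Em <- as.matrix(wide[paste0("effect_", have)])
  Vm <- as.matrix(wide[paste0("v_", have)])

  t2 <- tau2_eb_matrix(Em, Vm, step = step, max_iter = max_iter, tol = tol)
  obs <- !is.na(Em) & !is.na(Vm)
  E0 <- ifelse(obs, Em, 0); V0 <- ifelse(obs, Vm, 1)
  W <- obs / (V0 + t2$tau2)
  sw <- rowSums(W)
  mu <- rowSums(W * E0) / sw
  se <- sqrt(1 / sw)
  z <- mu / se
  Wfe <- obs / V0
  mu_fe <- rowSums(Wfe * E0) / rowSums(Wfe)
  Q <- rowSums(Wfe * (E0 - mu_fe)^2)
  I2 <- pmax(0, (Q - (t2$k - 1)) / Q) * 100
  p <- 2 * pnorm(-abs(z))

  out <- tibble::tibble(
    feature = feat, k = as.integer(t2$k), effect = mu, se = se, z = z, p = p,
    tau2 = t2$tau2, Q = Q, I2 = I2,
    q = bh_fdr(p), converged = t2$converged
  )
  structure(dplyr::arrange(out, .data$p), class = c("meta_tbl", class(out)))
}

#' Select age-related features from a meta-analysis
#'
#' Thresholds the BH-FDR q-value (default q < 0.005) and annotates the
#' direction of change: `"up"` (hypermethylated / upregulated with age) or
#' `"down"` (hypomethylated / downregulated). Features whose tau-squared
#' estimate did not converge are excluded.
#'
#' @param meta A `meta_tbl` from [meta_analyze()].
#' @param q_threshold FDR threshold, default 0.005.
#' @return Tibble with `feature`, `effect`, `q`, `direction`.
#' @export
select_age_features <- function(meta, q_threshold = 0.005) {
  meta |>
    dplyr::filter(.data$converged, !is.na(.data$q), .data$q < q_threshold) |>
    dplyr::transmute(.data$feature, .data$effect, .data$q,
                     direction = ifelse(.data$effect > 0, "up", "down"))
}

#' Per-feature forest-plot data
#'
#' Exports the per-cohort effects and confidence bounds for one feature along
#' with its pooled row, ready for forest plotting or TSV export.
#'
#' @param assoc_tables Named list of per-cohort association tibbles.
#' @param meta A `meta_tbl` from [meta_analyze()].
#' @param feature Feature ID.
#' @return Tibble with `cohort` (`"pooled"` last), `effect`, `lo`, `hi`.
#' @export
forest_data <- function(assoc_tables, meta, feature) {
  per <- purrr::imap_dfr(assoc_tables, function(tb, id) {
    tb <- dplyr::filter(tb, .data$feature == !!feature, !.data$flag)
    if (nrow(tb) == 0) return(NULL)
    tibble::tibble(cohort = id, effect = tb$effect,
                   lo = tb$effect - 1.96 * tb$se, hi = tb$effect + 1.96 * tb$se)
  })
  mrow <- dplyr::filter(meta, .data$feature == !!feature)
  if (nrow(mrow) == 1) {
    per <- dplyr::bind_rows(per, tibble::tibble(
      cohort = "pooled", effect = mrow$effect,
      lo = mrow$effect - 1.96 * mrow$se, hi = mrow$effect + 1.96 * mrow$se))
  }
  per
}

#' @export
glance.meta_tbl <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    k_min = if (nrow(x)) min(x$k) else NA_integer_,
    k_max = if (nrow(x)) max(x$k) else NA_integer_,
    n_significant = sum(x$q < 0.005 & x$converged, na.rm = TRUE),
    median_I2 = median(x$I2, na.rm = TRUE)
  )
}
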