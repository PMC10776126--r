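#' Meta-analyse a secondary contrast at age-related features
#'
#' Reuses the meta-analysis machinery on a restricted feature list (typically
#' the age-related DMPs or DEGs), so that the FDR correction is computed over
#' the restricted set only — the multiplicity burden matches the question
#' actually asked ("which *age-related* features respond to fitness or
#' training?").
#'
#' @param assoc_tables Named list of per-cohort association tibbles for the
#'   secondary contrast (VO2max or PRE/POST training).
#' @param age_features Nonempty character vector of age-related feature IDs.
#' @param k_min Presence threshold among the contributing cohorts (secondary
#'   contrasts usually involve fewer cohorts; default 2).
#' @param ... Passed on to [meta_analyze()].
#' @return A `meta_tbl` restricted to `age_features`.
#' @export
restrict_and_meta <- function(assoc_tables, age_features, k_min = 2L, ...) {
  if (length(age_features) == 0) abort("`age_features` must be nonempty")
  present <- purrr::map_lgl(assoc_tables,
                            ~ any(.x$feature %in% age_features))
  if (!any(present)) {
    abort(paste0("no age-related features found in any cohort: ",
                 paste(names(assoc_tables), collapse = ", ")))
  }
  meta_analyze(assoc_tables, k_min = k_min, features = age_features, ...)
}

#' Ingest an external summary-statistic table
#'
#' Reads (or accepts) a published meta-analysis summary table — columns
#' `feature`, `log2FC` (or `effect`), `p` — and aligns it to a feature
#' universe by ID. The external statistics are taken as-is; nothing is
#' refitted. The match rate and the unmatched features are reported in
#' attributes.
#'
#' @param table A data frame, or path to a TSV with the columns above.
#' @param feature_universe Character vector of features to align to.
#' @return Tibble with one row per universe feature: `feature`, `effect`,
#'   `p`, `matched`; attributes `match_rate` and `unmatched`.
#' @export
ingest_external_summary <- function(table, feature_universe) {
  if (is.character(table)) {
    table <- readr::read_tsv(table, show_col_types = FALSE)
  }
  tb <- tibble::as_tibble(table)
  if (nrow(tb) == 0) abort("external summary table is empty")
  if (!"effect" %in% names(tb) && "log2FC" %in% names(tb)) {
    tb <- dplyr::rename(tb, effect = "log2FC")
  }
  need <- c("feature", "effect", "p")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) {
    abort(paste0("external table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- which(duplicated(tb$feature))
  if (length(dup) > 0) {
    abort(paste0("duplicate feature IDs in external table at row(s): ",
                 paste(head(dup, 10), collapse = ", ")))
  }
  out <- tibble::tibble(feature = feature_universe) |>
    dplyr::left_join(dplyr::select(tb, "feature", "effect", "p"),
                     by = "feature") |>
    dplyr::mutate(matched = !is.na(.data$effect))
  attr(out, "match_rate") <- mean(out$matched)
  attr(out, "unmatched") <- out$feature[!out$matched]
  if (any(!out$matched)) {
    message(sprintf("external table matched %.1f%% of the universe (%d unmatched)",
                    100 * mean(out$matched), sum(!out$matched)))
  }
  out
}

#' Assemble a cross-contrast effect panel
#'
#' Aligns per-contrast effect and p-value vectors on a common feature list
#' (typically age-related features), from internal `meta_tbl`s and/or external
#' summaries already aligned by [ingest_external_summary()].
#'
#' @param features Character vector fixing the row order.
#' @param ... Named tibbles, each with `feature`, `effect`, `p` columns.
#' @return A `contrast_panel` tibble: `feature`, then `effect_<name>` and
#'   `p_<name>` per contrast.
#' @export
#' @examples
#' a <- tibble::tibble(feature = c("f1", "f2"), effect = c(1, -1), p = c(.01, .2))
#' b <- tibble::tibble(feature = c("f1", "f2"), effect = c(-2, 1), p = c(.05, .5))
#' build_contrast_panel(c("f1", "f2"), age = a, vo2max = b)
build_contrast_panel <- function(features, ...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == "")) {
    abort("every contrast table must be named")
  }
  out <- tibble::tibble(feature = features)
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    j <- dplyr::left_join(out["feature"],
                          dplyr::select(tb, "feature", "effect", "p"),
                          by = "feature")
    out[[paste0("effect_", nm)]] <- j$effect
    out[[paste0("p_", nm)]] <- j$p
  }
  structure(out, class = c("contrast_panel", class(out)),
            contrasts = names(tabs))
}

#' Spearman correlation between two contrasts' effect sizes
#'
#' Rank correlation (average ranks for ties) between the aligned effect
#' vectors of two contrasts, over complete cases. The p-value uses the exact
#' permutation distribution for fewer than 20 untied pairs and the
#' t-approximation otherwise.
#'
#' @param panel A [build_contrast_panel()] result.
#' @param contrast_a,contrast_b Contrast names as used in the panel.
#' @return One-row tibble: `contrast_a`, `contrast_b`, `rho`, `p`, `n`.
#' @export
effect_correlation <- function(panel, contrast_a, contrast_b) {
  a <- panel[[paste0("effect_", contrast_a)]]
  b <- panel[[paste0("effect_", contrast_b)]]
  if (is.null(a) || is.null(b)) abort("unknown contrast name")
  cc <- stats::complete.cases(a, b)
  a <- a[cc]; b <- b[cc]
  if (length(a) < 10) abort("need at least 10 paired non-missing values")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Spearman correlation is undefined for a constant effect vector")
  }
  exact <- length(a) < 20 && !anyDuplicated(a) && !anyDuplicated(b)
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = exact))
  tibble::tibble(contrast_a = contrast_a, contrast_b = contrast_b,
                 rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Standardise a panel's effect columns to unit SD
#'
#' Divides each contrast's effect vector by its SD so magnitudes are
#' comparable across contrasts (the scaling used before joint heatmap
#' display). Feature order is preserved; rank-based statistics are unchanged.
#'
#' @param panel A `contrast_panel`.
#' @param order_by Optional contrast name; if given, rows are ordered by that
#'   contrast's scaled effect, most decreased first (the heatmap convention:
#'   most hypomethylated / downregulated with age at the top).
#' @return The scaled panel.
#' @export
scale_effects <- function(panel, order_by = NULL) {
  for (nm in attr(panel, "contrasts")) {
    col <- paste0("effect_", nm)
    s <- sd(panel[[col]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("contrast `%s` has zero-SD effects; cannot scale", nm))
    }
    panel[[col]] <- panel[[col]] / s
  }
  if (!is.null(order_by)) {
    panel <- dplyr::arrange(panel, .data[[paste0("effect_", order_by)]])
  }
  panel
}

#' Q-Q inflation diagnostic for a p-value vector
#'
#' Compares observed p-value quantiles with the uniform expectation
#' `i/(n+1)` and reports the genomic inflation factor
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549` (the null median of a
#' 1-df chi-square). Bulk inflation (`lambda > 1`) indicates an excess of
#' true associations (or confounding) among the tested features.
#'
#' @param p P-values in (0, 1].
#' @return A `qq_inflation` object; see [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
#' @examples
#' qq <- qq_inflation(runif(1000))
#' glance(qq)$lambda
qq_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) abort("empty p-value vector")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  n <- length(p)
  obs <- sort(p)
  expd <- seq_len(n) / (n + 1)
  lambda <- median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
  structure(list(observed = obs, expected = expd, lambda = lambda, n = n),
            class = "qq_inflation")
}

#' @export
print.qq_inflation <- function(x, ...) {
  cat(sprintf("<qq_inflation> n = %d, lambda = %.3f\n", x$n, x$lambda))
  invisible(x)
}

#' @export
tidy.qq_inflation <- function(x, ...) {
  tibble::tibble(expected = -log10(x$expected), observed = -log10(x$observed))
}

#' @export
glance.qq_inflation <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n = x$n)
}

#' Principal-component association with fitness
#'
#' Decomposes the (feature-restricted) matrix by SVD after centring and
#' unit-scaling features, and correlates each sample's coordinates on the
#' first three principal components with VO2max (Pearson). The sign of each
#' component is fixed so its largest-magnitude feature loading is positive.
#'
#' @param mat Feature-by-sample matrix, typically restricted to age-related
#'   features (M-values or log2 expression).
#' @param vo2max Per-sample VO2max, aligned with the matrix columns.
#' @param n_pc Number of leading components to test (default 3).
#' @return A `pca_fitness` object with per-PC Pearson `r` and `p`; see
#'   [tidy()] and [autoplot()].
#' @export
pca_fitness_association <- function(mat, vo2max, n_pc = 3L) {
  stopifnot(ncol(mat) == length(vo2max))
  if (ncol(mat) < 10) abort("need at least 10 samples")
  keep <- apply(mat, 1, sd) > 0
  pc <- prcomp(t(mat[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
  n_pc <- min(n_pc, ncol(pc$x))
  for (j in seq_len(n_pc)) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  assoc <- purrr::map_dfr(seq_len(n_pc), function(j) {
    ct <- cor.test(pc$x[, j], vo2max, method = "pearson")
    tibble::tibble(pc = paste0("PC", j), r = unname(ct$estimate), p = ct$p.value)
  })
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(assoc = assoc, scores = pc$x[, seq_len(n_pc), drop = FALSE],
                 vo2max = vo2max, var_explained = var_explained[seq_len(n_pc)],
                 n = ncol(mat)),
            class = "pca_fitness")
}

#' @export
print.pca_fitness <- function(x, ...) {
  cat(sprintf("<pca_fitness> %d samples\n", x$n))
  print(x$assoc)
  invisible(x)
}

#' @export
tidy.pca_fitness <- function(x, ...) {
  dplyr::mutate(x$assoc, var_explained = x$var_explained)
}

#' @export
glance.pca_fitness <- function(x, ...) {
  tibble::tibble(n = x$n, min_p = min(x$assoc$p), best_pc = x$assoc$pc[which.min(x$assoc$p)])
}
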