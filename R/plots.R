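#' @describeIn qq_inflation Q-Q plot of observed vs expected -log10(p) with
#'   the identity line and the inflation factor in the subtitle.
#' @param object A `qq_inflation` object.
#' @param ... Unused.
#' @export
autoplot.qq_inflation <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda = %.2f (n = %d)", object$lambda, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn pca_fitness_association Scatter plots of sample coordinates on
#'   each tested principal component against VO2max, with the Pearson r in
#'   the panel strip.
#' @param object A `pca_fitness` object.
#' @param ... Unused.
#' @export
autoplot.pca_fitness <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(ncol(object$scores)), function(j) {
    tibble::tibble(
      panel = sprintf("%s (r = %.2f)", object$assoc$pc[j], object$assoc$r[j]),
      coordinate = object$scores[, j],
      vo2max = object$vo2max
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vo2max, y = .data$coordinate)) +
    ggplot2::geom_point(size = 0.9, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "VO2max (mL/min/kg)", y = "PC coordinate") +
    ggplot2::theme_minimal()
}

#' Heatmap-style view of scaled cross-contrast effects
#'
#' Tile display of a (scaled) contrast panel: features ordered by the age
#' effect, one column per contrast — the data view behind joint effect-size
#' heatmaps. Expects the panel to have been through [scale_effects()] so the
#' colour scale is comparable across contrasts.
#'
#' @param object A `contrast_panel`.
#' @param order_by Contrast used to order features (default `"age"` if
#'   present, else the first contrast).
#' @param ... Unused.
#' @export
autoplot.contrast_panel <- function(object, order_by = NULL, ...) {
  contrasts <- attr(object, "contrasts")
  order_by <- order_by %||% if ("age" %in% contrasts) "age" else contrasts[1]
  ord <- order(object[[paste0("effect_", order_by)]])
  df <- object |>
    dplyr::mutate(.row = match(dplyr::row_number(), ord)) |>
    dplyr::select(".row", dplyr::starts_with("effect_")) |>
    tidyr::pivot_longer(-".row", names_to = "contrast", values_to = "effect",
                        names_prefix = "effect_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$.row,
                                   fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = sprintf("features (ordered by %s effect)",
                                        order_by),
                  fill = "scaled\neffect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Forest plot for one feature's meta-analysis
#'
#' Per-cohort effect estimates with 95% intervals and the pooled
#' random-effects row.
#'
#' @param assoc_tables Named list of per-cohort association tibbles.
#' @param meta A `meta_tbl`.
#' @param feature Feature ID.
#' @return A ggplot.
#' @export
plot_forest <- function(assoc_tables, meta, feature) {
  df <- forest_data(assoc_tables, meta, feature) |>
    dplyr::mutate(cohort = factor(.data$cohort,
                                  levels = rev(unique(.data$cohort))),
                  pooled = .data$cohort == "pooled")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$cohort,
                                   colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled), size = 2) +
    ggplot2::scale_colour_manual(values = c("black", "firebrick"),
                                 guide = "none") +
    ggplot2::scale_shape_manual(values = c(15, 18), guide = "none") +
    ggplot2::labs(x = "effect size", y = NULL, title = feature) +
    ggplot2::theme_minimal()
}

#' @describeIn multi_contrast_enrichment Dot plot of the leading sets'
#'   per-contrast enrichment scores, sized by -log10(q).
#' @param object A `multi_enrich` tibble.
#' @param top Number of leading sets to display (default 20).
#' @param ... Unused.
#' @export
autoplot.multi_enrich <- function(object, top = 20, ...) {
  df <- head(object, top) |>
    tidyr::pivot_longer(dplyr::starts_with("s_"), names_to = "contrast",
                        values_to = "s", names_prefix = "s_") |>
    dplyr::mutate(set = factor(.data$set, levels = rev(unique(.data$set))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$set,
                                   fill = .data$s,
                                   size = -log10(pmax(.data$q, 1e-20)))) +
    ggplot2::geom_point(shape = 21) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "s", size = "-log10(q)") +
    ggplot2::theme_minimal()
}
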