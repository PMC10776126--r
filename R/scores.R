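#' Signed importance score
#'
#' `Score = sign(log2FC) * (-log10 p)`: direction from the effect sign,
#' magnitude from the evidence. A transcript falling in expression with age
#' at log2FC = -0.12 per year and p = 1.24e-10 scores
#' `-1 * -log10(1.24e-10) = -9.9`. P-values are floored at 1e-300 to keep
#' scores finite; non-positive p-values are floored with a warning;
#' `sign(0) = 0` so a zero effect scores 0 regardless of p.
#'
#' @param log2FC Effect size (vectorised).
#' @param p P-value in (0, 1] (vectorised).
#' @return Signed score vector.
#' @export
#' @examples
#' compute_score(-0.12, 1.24e-10) # -9.9066...
#' compute_score(0.5, 0.01)       # 2
compute_score <- function(log2FC, p) {
  if (any(p > 1, na.rm = TRUE)) abort("p-values above 1 are not valid")
  n_floor <- sum(p <= 0, na.rm = TRUE)
  if (n_floor > 0) {
    warn(sprintf("%d non-positive p-value(s) floored at 1e-300", n_floor))
  }
  p <- pmax(p, 1e-300)
  sign(log2FC) * (-log10(p))
}

#' Build a cross-contrast score matrix
#'
#' Merges per-contrast summary tables on feature ID (complete cases only),
#' computes each contrast's signed score via [compute_score()], and ranks the
#' scores ascending with average ties — so high ranks mean "up-regulated /
#' higher with the contrast", and a positive set-level enrichment score later
#' means a shift toward the top of that contrast's ranking.
#'
#' @param ... Named tibbles, each with `feature`, `effect` (or `log2FC`) and
#'   `p` columns; at least two.
#' @return A `score_matrix` tibble: `feature`, `score_<name>` and
#'   `rank_<name>` per contrast.
#' @export
score_matrix <- function(...) {
  tabs <- list(...)
  if (length(tabs) < 2) abort("need at least two contrasts")
  if (is.null(names(tabs)) || any(names(tabs) == "")) {
    abort("every contrast table must be named")
  }
  norm <- purrr::map(tabs, function(tb) {
    if (!"effect" %in% names(tb) && "log2FC" %in% names(tb)) {
      tb <- dplyr::rename(tb, effect = "log2FC")
    }
    stopifnot(all(c("feature", "effect", "p") %in% names(tb)))
    dplyr::select(tb, "feature", "effect", "p")
  })
  merged <- purrr::reduce(purrr::imap(norm, function(tb, nm) {
    setNames(tb, c("feature", paste0(c("effect_", "p_"), nm)))
  }), dplyr::inner_join, by = "feature")
  merged <- merged[stats::complete.cases(merged), ]
  out <- tibble::tibble(feature = merged$feature)
  for (nm in names(tabs)) {
    s <- compute_score(merged[[paste0("effect_", nm)]], merged[[paste0("p_", nm)]])
    out[[paste0("score_", nm)]] <- s
    out[[paste0("rank_", nm)]] <- rank(s, ties.method = "average")
  }
  structure(out, class = c("score_matrix", class(out)),
            contrasts = names(tabs))
}

# Pillai's trace for a two-group MANOVA of the d rank columns on set
# membership, with its exact-F equivalent (one nonzero eigenvalue when
# g = 2): F = V/(1-V) * (N-d-1)/d on (d, N-d-1) df.
pillai_two_group <- function(R, member) {
  N <- nrow(R); d <- ncol(R); m <- sum(member)
  xbar <- colMeans(R)
  m1 <- colMeans(R[member, , drop = FALSE])
  m2 <- colMeans(R[!member, , drop = FALSE])
  B <- m * tcrossprod(m1 - xbar) + (N - m) * tcrossprod(m2 - xbar)
  Tm <- crossprod(sweep(R, 2, xbar))
  V <- tryCatch(sum(diag(B %*% solve(Tm))), error = function(e) {
    abort("rank columns are collinear; joint MANOVA test is undefined")
  })
  V <- min(max(V, 0), 1 - 1e-12)
  Fstat <- V / (1 - V) * (N - d - 1) / d
  p <- pf(Fstat, d, N - d - 1, lower.tail = FALSE)
  list(pillai = V, statistic = Fstat, p = p)
}

#' Multi-contrast rank-MANOVA gene-set enrichment
#'
#' Tests whether each gene set occupies extreme, coordinated positions across
#' several contrasts' signed-score rankings simultaneously. Per contrast the
#' set-level enrichment score is the scaled mean-rank shift
#' `s = 2 * (mean in-set rank - (N + 1)/2) / N`, bounded in (-1, 1), and the
#' joint p-value is a one-way MANOVA (Pillai's trace with its F
#' approximation) of the rank columns on in-set/out-of-set membership.
#' Sets with fewer than `set_size[1]` or more than `set_size[2]` members in
#' the score universe are skipped with a note; BH-FDR is computed across the
#' tested sets. Ties in q are broken by set name for a deterministic order.
#'
#' @param scores A [score_matrix()].
#' @param collection Named list of gene sets.
#' @param set_size Inclusive size bounds in the score universe, default
#'   `c(10, 500)`.
#' @return A `multi_enrich` tibble: `set`, `set_size`, one `s_<contrast>`
#'   column per contrast, `pillai`, `p`, `q`.
#' @export
multi_contrast_enrichment <- function(scores, collection,
                                      set_size = c(10, 500)) {
  stopifnot(inherits(scores, "score_matrix"))
  contrasts <- attr(scores, "contrasts")
  if (length(contrasts) < 2) abort("need at least two contrasts")
  N <- nrow(scores)
  R <- as.matrix(scores[paste0("rank_", contrasts)])
  feats <- scores$feature
  sz_in <- vapply(collection, function(g) length(intersect(g, feats)), 0L)
  skip <- sz_in < set_size[1] | sz_in > set_size[2]
  if (any(skip)) {
    message(sprintf("%d set(s) outside the %d-%d size range skipped",
                    sum(skip), set_size[1], set_size[2]))
  }
  sets <- collection[!skip]
  out <- purrr::imap_dfr(sets, function(members, nm) {
    member <- feats %in% members
    m <- sum(member)
    s <- unname(2 * (colMeans(R[member, , drop = FALSE]) - (N + 1) / 2) / N)
    pil <- pillai_two_group(R, member)
    row <- tibble::tibble(set = nm, set_size = m)
    for (i in seq_along(contrasts)) row[[paste0("s_", contrasts[i])]] <- s[i]
    row$pillai <- pil$pillai
    row$p <- pil$p
    row
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(set = character(), set_size = integer())
    for (cn in contrasts) out[[paste0("s_", cn)]] <- double()
    out$pillai <- double(); out$p <- double(); out$q <- double()
    return(structure(out, class = c("multi_enrich", class(out))))
  }
  out$q <- bh_fdr(out$p)
  structure(dplyr::arrange(out, .data$q, .data$set),
            class = c("multi_enrich", class(out)))
}

#' Ordered concordance table for multi-contrast enrichment
#'
#' Pure formatting: orders the enrichment table by q (ties broken by set
#' name) and annotates each set's sign pattern across contrasts, e.g.
#' `age-, vo2max+, training+, disuse-` for a set behaving like the
#' mitochondrial programme (down with age and disuse, up with fitness and
#' training).
#'
#' @param result A `multi_enrich` tibble.
#' @return Tibble with `set`, `set_size`, `sign_pattern`, the `s_` columns,
#'   `p`, `q`.
#' @export
contrast_concordance_export <- function(result) {
  s_cols <- grep("^s_", names(result), value = TRUE)
  if (nrow(result) == 0) {
    return(tibble::tibble(set = character(), set_size = integer(),
                          sign_pattern = character()))
  }
  pattern <- apply(result[s_cols], 1, function(s) {
    paste0(sub("^s_", "", s_cols), ifelse(s >= 0, "+", "-"), collapse = ", ")
  })
  result |>
    dplyr::mutate(sign_pattern = pattern) |>
    dplyr::arrange(.data$q, .data$set) |>
    dplyr::select("set", "set_size", "sign_pattern",
                  dplyr::all_of(s_cols), "p", "q")
}

#' @export
glance.multi_enrich <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x),
                 n_significant = sum(x$q < 0.005, na.rm = TRUE),
                 min_q = if (nrow(x)) min(x$q) else NA_real_)
}
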