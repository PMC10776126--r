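#' Specify a per-cohort association contrast
#'
#' A contrast names the predictor regressed against every feature, the
#' covariates adjusted for, and whether the design is subject-paired. The
#' three predictors of interest are chronological `age` (years), `vo2max`
#' (mL/min/kg, cardiorespiratory fitness), and `timepoint` (PRE/POST an
#' exercise-training intervention). The paired flag is only valid with the
#' `timepoint` predictor, where subject indicator terms turn the timepoint
#' coefficient into the within-subject PRE-to-POST change.
#'
#' @param name Label for the contrast (defaults to the predictor).
#' @param predictor One of `"age"`, `"vo2max"`, `"timepoint"`.
#' @param covariates Character vector of sample-sheet columns to adjust for
#'   (e.g. `c("sex", "batch")`).
#' @param paired Include subject fixed effects (timepoint contrasts only).
#' @return A `contrast_spec` list.
#' @export
#' @examples
#' contrast_spec("age", covariates = c("sex", "batch"))
#' contrast_spec("timepoint", paired = TRUE)
contrast_spec <- function(predictor = c("age", "vo2max", "timepoint"),
                          covariates = character(), paired = FALSE,
                          name = NULL) {
  predictor <- match.arg(predictor)
  if (paired && predictor != "timepoint") {
    abort("`paired` is only valid with the timepoint (PRE/POST) predictor")
  }
  structure(list(name = name %||% predictor, predictor = predictor,
                 covariates = covariates, paired = paired),
            class = "contrast_spec")
}

#' Fit one contrast across every feature of a cohort
#'
#' Runs an ordinary-least-squares regression of each feature on the contrast's
#' predictor plus covariates (the per-cohort EWAS/TWAS building block), with
#' two-sided t-test p-values. Methylation matrices are converted to M-values
#' before fitting. For paired timepoint contrasts, subject indicator terms are
#' included so the timepoint coefficient is the within-subject PRE-to-POST
#' change. For `age` and `vo2max` contrasts in cohorts with repeated samples
#' per subject, only each subject's baseline (PRE, or first) sample is used,
#' since a between-subject predictor cannot be separated from subject effects.
#' Samples with missing predictor or covariate values are dropped with a
#' message. Features with zero residual variance are flagged, not dropped.
#'
#' If the predictor is constant in the cohort the whole contrast is skipped
#' with a message (age-associated change cannot be estimated when age does not
#' vary) and a zero-row table is returned.
#'
#' @param dataset A [cohort_dataset()].
#' @param spec A [contrast_spec()].
#' @return Tibble with columns `feature`, `effect`, `se`, `p`, `n`, `df`,
#'   `flag`; effects are per year, per mL/min/kg, or the PRE-to-POST delta,
#'   on the M-value (methylation) or log2 (expression) scale.
#' @export
fit_contrast <- function(dataset, spec) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(spec, "contrast_spec"))
  smp <- dataset$samples
  y <- dataset$matrix
  if (dataset$modality == "methylation") {
    y <- suppressWarnings(beta_to_mvalue(y))
    dim(y) <- dim(dataset$matrix)
    dimnames(y) <- dimnames(dataset$matrix)
  }

  pred_col <- switch(spec$predictor, age = "age", vo2max = "vo2max",
                     timepoint = "timepoint")
  if (spec$predictor != "timepoint" && anyDuplicated(smp$subject_id) > 0) {
    first <- smp |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::arrange(.data$subject_id, .data$timepoint != "PRE") |>
      dplyr::distinct(.data$subject_id, .keep_all = TRUE)
    keep <- sort(first$.row)
    message(sprintf("[%s] %d repeated samples reduced to one baseline per subject",
                    dataset$id, nrow(smp) - length(keep)))
    smp <- smp[keep, ]
    y <- y[, keep, drop = FALSE]
  }

  used_cols <- c(pred_col, spec$covariates,
                 if (spec$paired) "subject_id")
  miss <- setdiff(used_cols, names(smp))
  if (length(miss) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(miss, collapse = ", ")))
  }
  cc <- stats::complete.cases(smp[used_cols])
  if (any(!cc)) {
    message(sprintf("[%s] dropping %d sample(s) with missing predictor/covariate values",
                    dataset$id, sum(!cc)))
    smp <- smp[cc, ]
    y <- y[, cc, drop = FALSE]
  }

  x_pred <- if (spec$predictor == "timepoint") {
    as.numeric(smp$timepoint == "POST")
  } else {
    smp[[pred_col]]
  }
  if (length(unique(x_pred)) < 2) {
    message(sprintf("[%s] predictor `%s` is constant: contrast skipped",
                    dataset$id, spec$predictor))
    return(tibble::tibble(feature = character(), effect = double(),
                          se = double(), p = double(), n = integer(),
                          df = integer(), flag = logical()))
  }

  xdf <- data.frame(.pred = x_pred)
  for (cv in spec$covariates) {
    v <- smp[[cv]]
    if (length(unique(v)) < 2) {
      message(sprintf("[%s] covariate `%s` is constant in this cohort: dropped",
                      dataset$id, cv))
      next
    }
    xdf[[cv]] <- if (is.character(v) || is.logical(v)) factor(v) else v
  }
  if (spec$paired) xdf$.subject <- factor(smp$subject_id)
  X <- stats::model.matrix(~ ., data = xdf)

  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    kept <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), kept)]
    if (".pred" %in% dropped) {
      abort(sprintf("[%s] predictor is aliased with the covariates", dataset$id))
    }
    message(sprintf("[%s] dropping aliased design column(s): %s",
                    dataset$id, paste(dropped, collapse = ", ")))
    X <- X[, kept, drop = FALSE]
    qrX <- qr(X)
  }
  p_terms <- ncol(X)
  if (n < p_terms + 3) {
    abort(sprintf("[%s] too few samples (%d) for %d model terms",
                  dataset$id, n, p_terms))
  }

  yt <- t(y)                                   # samples x features
  cf <- qr.coef(qrX, yt)                       # terms x features
  res <- yt - X %*% cf
  df <- n - p_terms
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- match(".pred", colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  eff <- cf[j, ]
  tstat <- eff / se
  pv <- 2 * pt(-abs(tstat), df)
  y_var <- colSums(sweep(yt, 2, colMeans(yt))^2)
  flag <- !is.finite(se) | se <= 0 | !is.finite(pv) | y_var <= 0

  tibble::tibble(feature = rownames(y), effect = unname(eff),
                 se = unname(se), p = unname(pv),
                 n = n, df = df, flag = unname(flag))
}

#' Drop features whose association is inestimable
#'
#' Removes flagged rows (zero residual variance or undefined statistics) from
#' an association table, reporting how many were dropped.
#'
#' @param results Tibble from [fit_contrast()].
#' @return The filtered tibble.
#' @export
drop_inestimable <- function(results) {
  n_bad <- sum(results$flag)
  if (n_bad > 0) {
    message(sprintf("dropping %d inestimable feature(s)", n_bad))
  }
  dplyr::filter(results, !.data$flag)
}

#' Fit one contrast in every cohort
#'
#' Maps [fit_contrast()] over a list of cohorts, returning a named list of
#' association tables (cohorts whose predictor is constant yield zero-row
#' tables and are retained so that presence counting stays explicit).
#'
#' @param cohorts List of [cohort_dataset()] objects.
#' @param spec A [contrast_spec()].
#' @return Named list of association tibbles.
#' @export
fit_contrast_cohorts <- function(cohorts, spec) {
  purrr::map(cohorts, fit_contrast, spec = spec)
}
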