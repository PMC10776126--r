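#' Beta-value from methylated/unmethylated signal intensities
#'
#' Computes the array methylation proportion estimate
#' `beta = M / (U + M + 100)`; the +100 offset regularises low-intensity
#' probes and keeps beta strictly below 1.
#'
#' @param methylated,unmethylated Non-negative signal intensities (vectorised).
#' @return Beta-values in `[0, 1)`.
#' @export
#' @examples
#' beta_from_signals(900, 0)   # 0.9
#' beta_from_signals(500, 400) # 0.5
beta_from_signals <- function(methylated, unmethylated) {
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE)) {
    abort("signal intensities must be non-negative")
  }
  methylated / (unmethylated + methylated + 100)
}

#' Convert beta-values to M-values (and back)
#'
#' `beta_to_mvalue()` applies the logit2 transform `M = log2(beta/(1-beta))`,
#' the regression-friendly methylation scale; values outside
#' `[eps, 1 - eps]` are clipped first (with a warning reporting how many).
#' `mvalue_to_beta()` is the exact inverse.
#'
#' @param beta Beta-values in `[0, 1]`.
#' @param m M-values.
#' @param eps Clipping bound, default `1e-6`.
#' @return Numeric vector on the other scale.
#' @export
#' @examples
#' beta_to_mvalue(0.5) # 0
#' beta_to_mvalue(0.8) # 2
beta_to_mvalue <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta-values must lie in [0, 1]")
  }
  n_clip <- sum(beta < eps | beta > 1 - eps, na.rm = TRUE)
  if (n_clip > 0) {
    warn(sprintf("%d beta-value(s) clipped to [%g, %g] before logit", n_clip,
                 eps, 1 - eps))
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_mvalue
#' @export
mvalue_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Probe annotation constructor
#'
#' @param feature Probe IDs.
#' @param is_cg Logical, CG (cytosine-guanine) probe.
#' @param is_snp Logical, SNP-related probe.
#' @param is_multimap Logical, aligns to multiple genomic locations.
#' @param chromosome Chromosome label (`"chrX"`/`"chrY"` are the sex
#'   chromosomes).
#' @return Tibble annotation usable by [qc_filter()].
#' @export
probe_annotation <- function(feature, is_cg = TRUE, is_snp = FALSE,
                             is_multimap = FALSE, chromosome = "chr1") {
  tibble::tibble(feature = feature, is_cg = is_cg, is_snp = is_snp,
                 is_multimap = is_multimap, chromosome = chromosome)
}

#' Sample and probe quality-control filtering
#'
#' Applies the standard array QC rules, in two passes. Samples are filtered
#' first: any sample with 10% or more of probes failing detection
#' (detection p-value > 0.01) is removed ("<10%" is strict). Probe rules are
#' then evaluated on the remaining samples only: probes are removed when they
#' have any missing beta-value, a detection p-value > 0.01 in more than 5% of
#' samples, a bead count < 3 in more than 5% of samples, or when the
#' annotation flags them as non-CG, SNP-related, or multi-mapping. Sex
#' chromosome probes are removed only for mixed-sex cohorts. When the
#' detection p-value or bead-count matrix is unavailable the corresponding
#' rules are skipped and the report notes it.
#'
#' @param dataset A [cohort_dataset()].
#' @param detection_p Optional matrix of detection p-values, conformable with
#'   the beta matrix.
#' @param bead_count Optional matrix of bead counts, conformable likewise.
#' @param annotation [probe_annotation()] tibble covering every probe.
#' @param mixed_sex Remove X/Y probes? Default: inferred from the sample
#'   sheet's `sex` column.
#' @param sample_fail_frac Threshold fraction of failing probes at which a
#'   sample is removed (default 0.10).
#' @param probe_fail_frac Strict threshold fraction of samples at which a
#'   failing probe is removed (default 0.05).
#' @return List with `dataset` (filtered `cohort_dataset`) and `report`
#'   (a `qc_report`: tibbles of removals with reasons, plus notes).
#' @export
qc_filter <- function(dataset, detection_p = NULL, bead_count = NULL,
                      annotation, mixed_sex = NULL,
                      sample_fail_frac = 0.10, probe_fail_frac = 0.05) {
  mat <- dataset$matrix
  probes <- rownames(mat)
  miss_ann <- setdiff(probes, annotation$feature)
  if (length(miss_ann) > 0) {
    abort(sprintf("%d probes lack an annotation row (e.g. %s)",
                  length(miss_ann), miss_ann[1]))
  }
  ann <- annotation[match(probes, annotation$feature), ]
  if (is.null(mixed_sex)) mixed_sex <- dplyr::n_distinct(dataset$samples$sex) > 1
  notes <- character()
  conformable <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!identical(dim(x), dim(mat))) {
      abort(sprintf("`%s` matrix is not conformable with the data matrix", what))
    }
    x
  }
  detection_p <- conformable(detection_p, "detection_p")
  bead_count <- conformable(bead_count, "bead_count")

  # pass 1: samples
  if (!is.null(detection_p)) {
    fail_frac <- colMeans(detection_p > 0.01, na.rm = TRUE)
    bad_smp <- fail_frac >= sample_fail_frac
  } else {
    bad_smp <- rep(FALSE, ncol(mat))
    notes <- c(notes, "no detection p-value matrix: sample filter skipped")
  }
  samples_removed <- tibble::tibble(
    sample_id = colnames(mat)[bad_smp],
    reason = rep("detection failure in >=10% of probes", sum(bad_smp))
  )
  keep_smp <- !bad_smp
  mat2 <- mat[, keep_smp, drop = FALSE]
  det2 <- if (!is.null(detection_p)) detection_p[, keep_smp, drop = FALSE]
  bead2 <- if (!is.null(bead_count)) bead_count[, keep_smp, drop = FALSE]

  # pass 2: probes, evaluated on retained samples only
  rules <- list(missing_beta = rowSums(is.na(mat2)) > 0)
  if (!is.null(det2)) {
    rules$detection_p <- rowMeans(det2 > 0.01, na.rm = TRUE) > probe_fail_frac
  } else {
    notes <- c(notes, "no detection p-value matrix: probe detection rule skipped")
  }
  if (!is.null(bead2)) {
    rules$bead_count <- rowMeans(bead2 < 3, na.rm = TRUE) > probe_fail_frac
  } else {
    notes <- c(notes, "no bead-count matrix: bead-count rule skipped")
  }
  rules$non_cg <- !ann$is_cg
  rules$snp_related <- ann$is_snp
  rules$multi_mapping <- ann$is_multimap
  if (mixed_sex) {
    rules$sex_chromosome <- ann$chromosome %in% c("chrX", "chrY", "X", "Y")
  }
  rule_mat <- do.call(cbind, rules)
  bad_probe <- rowSums(rule_mat) > 0
  probes_removed <- purrr::map_dfr(names(rules), function(r) {
    tibble::tibble(feature = probes[rules[[r]]], reason = r)
  })

  out <- dataset
  out$matrix <- mat2[!bad_probe, , drop = FALSE]
  out$samples <- dataset$samples[match(colnames(out$matrix),
                                       dataset$samples$sample_id), ]
  out$features <- rownames(out$matrix)

  report <- structure(list(
    samples_removed = samples_removed,
    probes_removed = probes_removed,
    probe_reason_counts = dplyr::count(probes_removed, .data$reason),
    n_samples_in = ncol(mat), n_samples_retained = ncol(out$matrix),
    n_probes_in = nrow(mat), n_probes_retained = nrow(out$matrix),
    notes = notes
  ), class = "qc_report")
  stopifnot(report$n_samples_retained + nrow(samples_removed) == report$n_samples_in,
            report$n_probes_retained + sum(bad_probe) == report$n_probes_in)
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> samples: %d -> %d; probes: %d -> %d\n",
              x$n_samples_in, x$n_samples_retained,
              x$n_probes_in, x$n_probes_retained))
  if (nrow(x$probe_reason_counts) > 0) {
    for (i in seq_len(nrow(x$probe_reason_counts))) {
      cat(sprintf("  probe rule %-16s removed %d\n",
                  x$probe_reason_counts$reason[i], x$probe_reason_counts$n[i]))
    }
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$samples_removed, axis = "sample",
                  .before = 1) |> dplyr::rename(id = "sample_id"),
    dplyr::mutate(x$probes_removed, axis = "probe",
                  .before = 1) |> dplyr::rename(id = "feature")
  )
}
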