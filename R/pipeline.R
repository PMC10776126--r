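#' Configure an end-to-end pipeline run
#'
#' Bundles the generator configuration (or pre-built cohorts) with the
#' analysis thresholds of the two-step design: step 1 finds age-related
#' features by multi-cohort meta-analysis; step 2 quantifies fitness,
#' training, and disuse effects at those features only.
#'
#' @param sim A [sim_config()] describing the cohorts to simulate (ignored
#'   when `cohorts`/`truth` are supplied directly to [run_pipeline()]).
#' @param out_dir Output directory for stage TSVs, the provenance log, and
#'   the config echo; `NULL` keeps everything in memory.
#' @param q_threshold FDR threshold for selection at every stage (default
#'   0.005).
#' @param k_min Presence threshold for the age meta-analysis; default 10 for
#'   methylation and 15 for expression.
#' @param k_min_secondary Presence threshold for the restricted secondary
#'   contrasts (default 2: secondary contrasts involve fewer cohorts).
#' @param set_size Gene-set size bounds, default `c(10, 500)`.
#' @param include_disuse Ingest a disuse summary table (default: expression
#'   runs only, matching the availability of disuse data).
#' @param external_se Typical SE of the simulated external training/disuse
#'   summary statistics.
#' @param n_gene_sets Number of simulated gene sets for the enrichment
#'   stages.
#' @param seed Seed for the externally ingested summaries and gene-set
#'   simulation (the cohorts carry their own seed inside `sim`).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), out_dir = NULL,
                       q_threshold = 0.005, k_min = NULL,
                       k_min_secondary = 2L, set_size = c(10, 500),
                       include_disuse = NULL, external_se = 0.03,
                       n_gene_sets = 50L, seed = 1L) {
  stopifnot(q_threshold > 0, set_size[1] > 0, set_size[1] <= set_size[2])
  if (is.null(k_min)) k_min <- if (sim$modality == "methylation") 10L else 15L
  if (is.null(include_disuse)) include_disuse <- sim$modality == "expression"
  structure(list(sim = sim, out_dir = out_dir, q_threshold = q_threshold,
                 k_min = as.integer(k_min),
                 k_min_secondary = as.integer(k_min_secondary),
                 set_size = set_size, include_disuse = include_disuse,
                 external_se = external_se, n_gene_sets = as.integer(n_gene_sets),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full two-step analysis pipeline
#'
#' Orchestrates, deterministically for a given configuration: cohort
#' simulation (unless cohorts are supplied), per-cohort age association fits,
#' random-effects meta-analysis with presence filtering and FDR, selection of
#' age-related features, the restricted VO2max and PRE/POST training
#' contrasts, ingestion of an external disuse summary, cross-contrast
#' correlation and Q-Q inflation diagnostics, gene-set over-representation of
#' the age-related features, and multi-contrast rank-MANOVA enrichment. Each
#' stage's table is written to `out_dir` (when set) together with a
#' provenance log of counts and a YAML echo of the configuration.
#'
#' @param config A [run_config()].
#' @param cohorts Optional list of [cohort_dataset()]s to analyse instead of
#'   simulating.
#' @param truth Optional `ground_truth` matching `cohorts` (enables the
#'   external summary simulation and recovery scoring).
#' @return A `pipeline_result` list: `age_meta`, `age_features`,
#'   `secondary` (named list of `meta_tbl`s / external tables), `panel`,
#'   `correlations`, `qq`, `enrichment`, `multi_enrichment`, `log`,
#'   `truth`, `config`.
#' @export
run_pipeline <- function(config, cohorts = NULL, truth = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_rows <- list()
  note <- function(stage, key, value) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, key = key, value = as.character(value))
  }

  if (is.null(cohorts)) {
    sim <- simulate_multicohort(config$sim)
    cohorts <- sim$cohorts
    truth <- sim$truth
  }
  modality <- cohorts[[1]]$modality
  note("simulate", "n_cohorts", length(cohorts))
  note("simulate", "n_samples",
       sum(purrr::map_int(cohorts, ~ ncol(.x$matrix))))

  covs <- c("sex", "batch")
  # Step 1: age EWAS/TWAS and meta-analysis
  age_assoc <- fit_contrast_cohorts(cohorts, contrast_spec("age", covariates = covs))
  age_meta <- meta_analyze(age_assoc, k_min = config$k_min)
  age_feats <- select_age_features(age_meta, config$q_threshold)
  note("meta_age", "features_tested", nrow(age_meta))
  note("meta_age", "selected", nrow(age_feats))

  secondary <- list()
  # Step 2a: VO2max at age-related features
  if (nrow(age_feats) > 0) {
    # age is a covariate here: VO2max and age are correlated within cohorts,
    # so the unadjusted fitness effect would re-absorb the age effect
    vo2_assoc <- fit_contrast_cohorts(cohorts,
                                      contrast_spec("vo2max", covariates = c("age", covs)))
    secondary$vo2max <- restrict_and_meta(vo2_assoc, age_feats$feature,
                                          k_min = config$k_min_secondary)
    note("contrast_vo2max", "selected",
         nrow(select_age_features(secondary$vo2max, config$q_threshold)))

    # Step 2b: PRE/POST training in the paired cohorts
    paired <- purrr::keep(cohorts, ~ any(.x$samples$timepoint == "POST"))
    note("contrast_training", "paired_cohorts", length(paired))
    if (length(paired) >= config$k_min_secondary) {
      tr_assoc <- fit_contrast_cohorts(
        paired, contrast_spec("timepoint", covariates = character(), paired = TRUE))
      secondary$training <- restrict_and_meta(tr_assoc, age_feats$feature,
                                              k_min = config$k_min_secondary)
      note("contrast_training", "selected",
           nrow(select_age_features(secondary$training, config$q_threshold)))
    }

    # Step 2c: external disuse summary
    if (config$include_disuse && !is.null(truth)) {
      dis_tab <- simulate_summary_stats(truth, "disuse",
                                        se_scale = config$external_se,
                                        seed = config$seed + 1L)
      secondary$disuse <- ingest_external_summary(dis_tab, age_feats$feature)
    }
  }

  # cross-contrast panel, correlations, inflation
  panel <- correlations <- qq <- NULL
  if (nrow(age_feats) >= 10) {
    tabs <- list(age = dplyr::select(age_meta, "feature", "effect", "p"))
    for (nm in names(secondary)) {
      tabs[[nm]] <- dplyr::select(secondary[[nm]], "feature", "effect", "p")
    }
    panel <- do.call(build_contrast_panel, c(list(age_feats$feature), tabs))
    pairs <- utils::combn(names(tabs), 2, simplify = FALSE)
    correlations <- purrr::map_dfr(pairs, function(pr) {
      tryCatch(effect_correlation(panel, pr[1], pr[2]),
               error = function(e) NULL)
    })
    if (!is.null(secondary$vo2max)) {
      qq <- qq_inflation(pmax(secondary$vo2max$p, 1e-300))
      note("contrast_vo2max", "lambda", sprintf("%.3f", qq$lambda))
    }
  }

  # enrichment of age-related features
  enrichment <- multi_enr <- NULL
  ann <- simulate_probe_annotation(
    purrr::reduce(purrr::map(cohorts, "features"), union),
    n_genes = config$sim$n_genes, seed = config$seed + 2L)
  sets <- simulate_gene_sets(unique(ann$gene), n_sets = config$n_gene_sets,
                             seed = config$seed + 3L)
  if (nrow(age_feats) > 0) {
    if (modality == "methylation") {
      enrichment <- ora_methylation(age_feats$feature, age_meta$feature, ann,
                                    sets, config$set_size)
    } else {
      bg_genes <- unique(ann$gene[ann$feature %in% age_meta$feature])
      hit_genes <- unique(ann$gene[ann$feature %in% age_feats$feature])
      enrichment <- ora_hypergeometric(hit_genes, bg_genes, sets,
                                       config$set_size)
    }
    note("enrich", "sets_tested", nrow(enrichment))
    note("enrich", "sets_selected",
         sum(enrichment$q < config$q_threshold, na.rm = TRUE))
  }

  # multi-contrast integration
  if (!is.null(panel) && length(secondary) >= 1) {
    tabs <- list(age = dplyr::select(age_meta, "feature", "effect", "p"))
    for (nm in names(secondary)) {
      tb <- secondary[[nm]]
      tb <- dplyr::filter(tb, !is.na(.data$effect) & !is.na(.data$p))
      tabs[[nm]] <- dplyr::select(tb, "feature", "effect", "p")
    }
    sm <- do.call(score_matrix, tabs)
    feat_sets <- purrr::map(sets, function(g) {
      ann$feature[ann$gene %in% g]
    })
    multi_enr <- suppressMessages(
      multi_contrast_enrichment(sm, feat_sets, config$set_size))
    note("integrate", "sets_tested", nrow(multi_enr))
    note("integrate", "sets_selected",
         sum(multi_enr$q < config$q_threshold, na.rm = TRUE))
  }

  log_tbl <- dplyr::bind_rows(log_rows)
  res <- structure(list(
    age_meta = age_meta, age_features = age_feats, secondary = secondary,
    panel = panel, correlations = correlations, qq = qq,
    enrichment = enrichment, multi_enrichment = multi_enr,
    log = log_tbl, truth = truth, config = config
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")))
    }
  }
  wr(res$age_meta, "age_meta")
  wr(res$age_features, "age_features")
  for (nm in names(res$secondary)) wr(res$secondary[[nm]], paste0(nm, "_meta"))
  wr(res$panel, "panel")
  wr(res$correlations, "correlations")
  wr(res$enrichment, "enrichment_age")
  wr(res$multi_enrichment, "multi_enrichment")
  wr(res$log, "run_log")
  cfg <- res$config
  cfg$sim <- unclass(cfg$sim)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$log, n = Inf)
  invisible(x)
}

#' Read cohorts previously written by [write_cohorts()]
#'
#' @param dir Directory holding `<cohort>.matrix.tsv` / `<cohort>.samples.tsv`
#'   pairs.
#' @param modality `"methylation"` or `"expression"`.
#' @return Named list of [cohort_dataset()]s.
#' @export
read_cohort_dir <- function(dir, modality = c("methylation", "expression")) {
  modality <- match.arg(modality)
  mats <- list.files(dir, pattern = "\\.matrix\\.tsv$")
  ids <- sub("\\.matrix\\.tsv$", "", mats)
  if (length(ids) == 0) abort(sprintf("no cohort matrices found in %s", dir))
  out <- purrr::map(ids, function(id) {
    m <- readr::read_tsv(file.path(dir, paste0(id, ".matrix.tsv")),
                         show_col_types = FALSE)
    mat <- as.matrix(m[-1])
    rownames(mat) <- m$feature
    smp <- readr::read_tsv(file.path(dir, paste0(id, ".samples.tsv")),
                           show_col_types = FALSE)
    cohort_dataset(id = id, modality = modality, matrix = mat, samples = smp)
  })
  setNames(out, ids)
}
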