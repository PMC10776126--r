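#' Configuration for the multi-cohort simulator
#'
#' Builds and validates the parameter set used by [simulate_multicohort()].
#' Defaults emulate the study conditions the pipeline is designed for: many
#' modest-sized skeletal-muscle cohorts profiled on heterogeneous platforms,
#' sparse age effects of roughly 1% methylation change per decade, fitness and
#' training effects anti-correlated with the age effects, and disuse effects
#' positively correlated with them. Every emitted cohort satisfies the
#' inclusion rules applied to real cohorts: more than 20 samples, age SD above
#' 5 years, and baseline VO2max SD above 5 mL/min/kg.
#'
#' @param modality `"methylation"` (CpG beta-values) or `"expression"`
#'   (log2 expression).
#' @param n_cohorts Number of cohorts (default 16 for methylation, 21 for
#'   expression, mirroring the scale of published muscle meta-analyses).
#' @param samples_per_cohort Length-2 integer range; each cohort's sample size
#'   is drawn uniformly from it. Must keep every cohort above 20 samples.
#' @param n_features Number of features (CpGs or transcripts).
#' @param n_genes Number of genes behind the probe-to-gene annotation.
#' @param frac_age_features Proportion of features carrying a true age effect.
#' @param age_slope_sd SD of true age slopes at signal features, in beta-units
#'   per year (methylation) or log2FC per year (expression). The methylation
#'   default 0.00125 makes the mean absolute noiseless beta change per decade
#'   equal to 0.01 (1% per decade), since E|N(0, sd^2)| = sd * sqrt(2/pi).
#' @param tau2 Between-cohort variance of realized age slopes on the analysis
#'   scale (logit for methylation, log2 for expression).
#' @param rho_fitness,rho_training Target correlation (in \[-1, 0\]) between
#'   age effects and VO2max / training effects at signal features.
#' @param rho_disuse Target correlation (in \[0, 1\]) between age and disuse
#'   effects at signal features.
#' @param missing_platform_frac Proportion of features absent from each
#'   cohort's platform, dropped uniformly at random per cohort.
#' @param paired_frac Proportion of cohorts given a paired PRE/POST training
#'   design.
#' @param seed Master seed; all per-cohort seeds are derived from it.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_cohorts = 3, n_features = 100, seed = 7)
#' cfg$n_cohorts
sim_config <- function(modality = c("methylation", "expression"),
                       n_cohorts = NULL,
                       samples_per_cohort = c(25L, 60L),
                       n_features = 5000L,
                       n_genes = 2000L,
                       frac_age_features = 0.1,
                       age_slope_sd = NULL,
                       tau2 = NULL,
                       rho_fitness = -0.4,
                       rho_training = -0.4,
                       rho_disuse = 0.4,
                       missing_platform_frac = 0.2,
                       paired_frac = 0.375,
                       seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(n_cohorts)) n_cohorts <- if (modality == "methylation") 16L else 21L
  if (is.null(age_slope_sd)) age_slope_sd <- if (modality == "methylation") 0.00125 else 0.01
  if (is.null(tau2)) tau2 <- if (modality == "methylation") 1e-6 else 4e-6

  cfg <- list(
    modality = modality,
    n_cohorts = as.integer(n_cohorts),
    samples_per_cohort = as.integer(samples_per_cohort),
    n_features = as.integer(n_features),
    n_genes = as.integer(n_genes),
    frac_age_features = frac_age_features,
    age_slope_sd = age_slope_sd,
    tau2 = tau2,
    rho_fitness = rho_fitness,
    rho_training = rho_training,
    rho_disuse = rho_disuse,
    missing_platform_frac = missing_platform_frac,
    paired_frac = paired_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid `%s`: %s", field, msg))
  }
  chk(cfg$n_cohorts >= 1, "n_cohorts", "must be >= 1")
  chk(length(cfg$samples_per_cohort) == 2 && all(cfg$samples_per_cohort > 20),
      "samples_per_cohort", "every cohort must have more than 20 samples")
  chk(cfg$samples_per_cohort[1] <= cfg$samples_per_cohort[2],
      "samples_per_cohort", "must be an increasing range")
  chk(cfg$n_features >= 1, "n_features", "must be >= 1")
  chk(cfg$n_genes >= 1, "n_genes", "must be >= 1")
  for (f in c("frac_age_features", "missing_platform_frac", "paired_frac")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a proportion in [0, 1]")
  }
  chk(cfg$age_slope_sd >= 0, "age_slope_sd", "must be >= 0")
  chk(cfg$tau2 >= 0, "tau2", "must be a variance >= 0")
  chk(cfg$rho_fitness >= -1 && cfg$rho_fitness <= 0,
      "rho_fitness", "must lie in [-1, 0]")
  chk(cfg$rho_training >= -1 && cfg$rho_training <= 0,
      "rho_training", "must lie in [-1, 0]")
  chk(cfg$rho_disuse >= 0 && cfg$rho_disuse <= 1,
      "rho_disuse", "must lie in [0, 1]")
  chk(cfg$missing_platform_frac < 1, "missing_platform_frac",
      "must leave some features on every platform")
  invisible(cfg)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# One factor model: each secondary contrast's standardized effect is
# rho * z_age + sqrt(1 - rho^2) * independent noise, so its correlation with
# the age effect equals rho exactly (in expectation) and the joint
# correlation matrix is positive semi-definite by construction.
draw_correlated_effects <- function(n_sig, cfg, sds) {
  z_age <- rnorm(n_sig)
  mix <- function(rho) rho * z_age + sqrt(1 - rho^2) * rnorm(n_sig)
  tibble::tibble(
    slope_age = z_age * cfg$age_slope_sd,
    slope_fitness = mix(cfg$rho_fitness) * sds$fitness,
    delta_training = mix(cfg$rho_training) * sds$training,
    delta_disuse = mix(cfg$rho_disuse) * sds$disuse
  )
}

#' Simulate a multi-cohort methylation or expression study
#'
#' Generates `n_cohorts` cohort datasets with planted, mutually correlated age,
#' fitness, training, and disuse effects, plus the ground truth needed to score
#' recovery. Methylation data are generated on the logit scale (baseline +
#' age slope + cohort deviation + covariate effects + Gaussian noise) and
#' mapped back through the inverse logit, so beta-values stay strictly inside
#' (0, 1); expression data are generated directly on the log2 scale. Each
#' cohort loses a random `missing_platform_frac` of features, emulating
#' platform differences, and a `paired_frac` share of cohorts receives a
#' paired PRE/POST design with planted training deltas and subject-level
#' baselines.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohorts` (list of `cohort_dataset`), `truth`
#'   (a `ground_truth` list: `features` tibble of per-feature true effects,
#'   `cohort_slopes` tibble of per-cohort realized analysis-scale age slopes),
#'   and `config`.
#' @export
#' @examples
#' sim <- simulate_multicohort(sim_config(n_cohorts = 2, n_features = 50,
#'                                        n_genes = 20, seed = 3))
#' names(sim$cohorts)
#' dplyr::count(sim$truth$features, is_signal)
simulate_multicohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  meth <- cfg$modality == "methylation"

  feat_ids <- if (meth) sprintf("cg%06d", seq_len(cfg$n_features))
              else sprintf("gene%05d", seq_len(cfg$n_features))

  n_sig <- round(cfg$frac_age_features * cfg$n_features)
  is_signal <- c(rep(TRUE, n_sig), rep(FALSE, cfg$n_features - n_sig))
  is_signal <- sample(is_signal)

  sds <- if (meth) {
    list(fitness = 8e-4, training = 0.01, disuse = 0.015)
  } else {
    list(fitness = 8e-3, training = 0.10, disuse = 0.15)
  }

  eff <- tibble::tibble(
    feature = feat_ids, is_signal = is_signal,
    slope_age = 0, slope_fitness = 0, delta_training = 0, delta_disuse = 0
  )
  if (n_sig > 0) {
    eff[eff$is_signal, c("slope_age", "slope_fitness",
                         "delta_training", "delta_disuse")] <-
      draw_correlated_effects(n_sig, cfg, sds)
  }

  # analysis-scale quantities
  if (meth) {
    base_beta <- pmin(pmax(stats::rbeta(cfg$n_features, 0.4, 0.4), 0.03), 0.97)
    base <- logit(base_beta)
    to_analysis <- 1 / (base_beta * (1 - base_beta))  # d logit / d beta
  } else {
    base <- rnorm(cfg$n_features, mean = 6, sd = 2)
    to_analysis <- rep(1, cfg$n_features)
  }
  slope_a <- eff$slope_age * to_analysis
  slope_f <- eff$slope_fitness * to_analysis
  delta_t <- eff$delta_training * to_analysis
  noise_sd <- if (meth) runif(cfg$n_features, 0.10, 0.25)
              else runif(cfg$n_features, 0.30, 0.70)

  # covariate (nuisance) effects on a random 10% of features each
  sex_eff <- batch_eff <- numeric(cfg$n_features)
  idx <- sample.int(cfg$n_features, round(0.1 * cfg$n_features))
  sex_eff[idx] <- rnorm(length(idx), 0, if (meth) 0.15 else 0.30)
  idx <- sample.int(cfg$n_features, round(0.1 * cfg$n_features))
  batch_eff[idx] <- rnorm(length(idx), 0, if (meth) 0.10 else 0.20)

  n_paired <- round(cfg$paired_frac * cfg$n_cohorts)
  paired <- seq_len(cfg$n_cohorts) <= n_paired

  cohort_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_cohorts)
  cohort_ids <- sprintf("cohort%02d", seq_len(cfg$n_cohorts))

  cohorts <- vector("list", cfg$n_cohorts)
  slopes_realized <- matrix(0, cfg$n_features, cfg$n_cohorts,
                            dimnames = list(feat_ids, cohort_ids))

  for (i in seq_len(cfg$n_cohorts)) {
    set.seed(cohort_seeds[i])
    dev <- numeric(cfg$n_features)
    if (cfg$tau2 > 0 && n_sig > 0) {
      dev[eff$is_signal] <- rnorm(n_sig, 0, sqrt(cfg$tau2))
    }
    sl_i <- slope_a + dev
    slopes_realized[, i] <- sl_i
    cohorts[[i]] <- simulate_one_cohort(
      id = cohort_ids[i], cfg = cfg, feat_ids = feat_ids, base = base,
      slope_age = sl_i, slope_fit = slope_f, delta_train = delta_t,
      sex_eff = sex_eff, batch_eff = batch_eff, noise_sd = noise_sd,
      paired = paired[i], meth = meth
    )
  }
  names(cohorts) <- cohort_ids

  truth <- structure(
    list(
      features = eff,
      cohort_slopes = tibble::as_tibble(slopes_realized) |>
        dplyr::mutate(feature = feat_ids, .before = 1) |>
        tidyr::pivot_longer(-"feature", names_to = "cohort",
                            values_to = "realized_slope")
    ),
    class = "ground_truth"
  )
  list(cohorts = cohorts, truth = truth, config = cfg)
}

simulate_one_cohort <- function(id, cfg, feat_ids, base, slope_age, slope_fit,
                                delta_train, sex_eff, batch_eff, noise_sd,
                                paired, meth) {
  n_nominal <- sample(seq(cfg$samples_per_cohort[1], cfg$samples_per_cohort[2]), 1)
  n_sub <- if (paired) max(12L, as.integer(round(n_nominal / 2))) else n_nominal
  n_smp <- if (paired) 2L * n_sub else n_sub

  centre <- runif(1, 35, 60)
  halfw <- runif(1, 12, 28)
  age_sub <- runif(n_sub, centre - halfw, centre + halfw)
  # VO2max coupled to age with within-cohort correlation about -0.3
  vo2_sd <- 8
  vo2_sub <- runif(1, 38, 50) - 0.3 * vo2_sd / sd(age_sub) * (age_sub - mean(age_sub)) +
    rnorm(n_sub, 0, vo2_sd * sqrt(1 - 0.3^2))
  vo2_sub <- pmax(vo2_sub, 12)
  sex_sub <- sample(c("F", "M"), n_sub, replace = TRUE)
  batch_sub <- sample(c("b1", "b2"), n_sub, replace = TRUE)

  if (paired) {
    subject <- rep(sprintf("%s_s%03d", id, seq_len(n_sub)), each = 2)
    timepoint <- rep(c("PRE", "POST"), n_sub)
    rep2 <- rep(seq_len(n_sub), each = 2)
  } else {
    subject <- sprintf("%s_s%03d", id, seq_len(n_sub))
    timepoint <- rep("PRE", n_sub)
    rep2 <- seq_len(n_sub)
  }
  samples <- tibble::tibble(
    sample_id = sprintf("%s_smp%03d", id, seq_len(n_smp)),
    subject_id = subject,
    age = age_sub[rep2],
    sex = sex_sub[rep2],
    vo2max = vo2_sub[rep2],
    timepoint = timepoint,
    batch = batch_sub[rep2]
  )

  nf <- length(feat_ids)
  mu <- base +
    outer(slope_age, samples$age) +
    outer(slope_fit, samples$vo2max - mean(samples$vo2max)) +
    outer(sex_eff, as.numeric(samples$sex == "M")) +
    outer(batch_eff, as.numeric(samples$batch == "b2"))
  if (paired) {
    mu <- mu + outer(delta_train, as.numeric(samples$timepoint == "POST"))
    subj_base <- matrix(rnorm(nf * n_sub, 0, if (meth) 0.15 else 0.40),
                        nf, n_sub)
    mu <- mu + subj_base[, rep2]
  }
  y <- mu + matrix(rnorm(nf * n_smp), nf, n_smp) * noise_sd
  if (meth) y <- inv_logit(y)
  dimnames(y) <- list(feat_ids, samples$sample_id)

  keep <- sort(sample.int(nf, nf - floor(cfg$missing_platform_frac * nf)))
  cohort_dataset(id = id, modality = cfg$modality,
                 matrix = y[keep, , drop = FALSE], samples = samples)
}

#' Construct a cohort dataset
#'
#' Bundles one cohort's feature matrix (features x samples) with its sample
#' sheet and platform feature list, validating that every sample-sheet row
#' matches exactly one matrix column, that PRE/POST samples share subject IDs,
#' and that methylation values lie strictly inside (0, 1).
#'
#' @param id Cohort identifier.
#' @param modality `"methylation"` or `"expression"`.
#' @param matrix Numeric matrix, features in rows (rownames required), samples
#'   in columns (colnames required).
#' @param samples Sample sheet with columns `sample_id`, `subject_id`, `age`,
#'   `sex`, `vo2max`, `timepoint`, `batch`.
#' @return A `cohort_dataset` list with elements `id`, `modality`, `matrix`,
#'   `samples`, `features`.
#' @export
cohort_dataset <- function(id, modality, matrix, samples) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  need <- c("sample_id", "subject_id", "age", "sex", "vo2max", "timepoint", "batch")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!identical(sort(samples$sample_id), sort(colnames(matrix))) ||
      anyDuplicated(samples$sample_id) > 0) {
    abort("every sample sheet row must match exactly one matrix column")
  }
  samples <- samples[match(colnames(matrix), samples$sample_id), ]
  if (modality == "methylation" &&
      (any(matrix <= 0, na.rm = TRUE) || any(matrix >= 1, na.rm = TRUE))) {
    abort("methylation beta-values must lie strictly inside (0, 1)")
  }
  post <- samples$timepoint == "POST"
  if (any(post) && !all(samples$subject_id[post] %in% samples$subject_id[!post])) {
    abort("every POST sample must share its subject ID with a PRE sample")
  }
  structure(list(id = id, modality = modality, matrix = matrix,
                 samples = tibble::as_tibble(samples),
                 features = rownames(matrix)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s (%s): %d features x %d samples\n",
              x$id, x$modality, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Simulate an external summary-statistic table
#'
#' Emulates ingesting a published meta-analysis: per feature, the reported
#' log2FC is the true contrast effect plus Gaussian sampling noise with the
#' feature's standard error, and the p-value is the matching two-sided z-test.
#'
#' @param truth A `ground_truth` object from [simulate_multicohort()].
#' @param contrast `"training"` or `"disuse"`.
#' @param se_scale Typical standard error of the reported effects; per-feature
#'   SEs are jittered around it. `se_scale = 0` returns the noiseless truth.
#' @param seed Integer seed.
#' @return Tibble with `feature`, `log2FC`, `SE`, `p`.
#' @export
simulate_summary_stats <- function(truth, contrast = c("training", "disuse"),
                                   se_scale = 0.03, seed = 1L) {
  contrast <- match.arg(contrast)
  stopifnot(se_scale >= 0)
  set.seed(as.integer(seed))
  delta <- switch(contrast,
                  training = truth$features$delta_training,
                  disuse = truth$features$delta_disuse)
  n <- length(delta)
  se <- se_scale * runif(n, 0.8, 1.2)
  lfc <- delta + rnorm(n, 0, 1) * se
  p <- ifelse(se > 0, 2 * pnorm(-abs(lfc / se)),
              ifelse(delta == 0, 1, 0))
  tibble::tibble(feature = truth$features$feature, log2FC = lfc, SE = se, p = p)
}

#' Simulate a probe-to-gene annotation with long-tailed probe counts
#'
#' Assigns every feature to a gene, with the number of probes per gene drawn
#' from a long-tailed (negative-binomial) distribution so that gene-set tests
#' on methylation data face the probe-number bias they must correct for.
#' A small fraction of probes is additionally annotated to a second gene
#' (multi-gene probes).
#'
#' @param feature_ids Character vector of probe IDs.
#' @param n_genes Number of genes.
#' @param multi_frac Fraction of probes annotated to two genes.
#' @param seed Integer seed.
#' @return Tibble with columns `feature`, `gene` (one row per mapping).
#' @export
simulate_probe_annotation <- function(feature_ids, n_genes,
                                      multi_frac = 0.02, seed = 1L) {
  set.seed(as.integer(seed))
  genes <- sprintf("G%05d", seq_len(n_genes))
  w <- stats::rnbinom(n_genes, size = 1.2, mu = 8) + 1
  gene_of <- sample(genes, length(feature_ids), replace = TRUE, prob = w)
  map <- tibble::tibble(feature = feature_ids, gene = gene_of)
  n_multi <- round(multi_frac * length(feature_ids))
  if (n_multi > 0) {
    idx <- sample.int(length(feature_ids), n_multi)
    extra <- tibble::tibble(feature = feature_ids[idx],
                            gene = sample(genes, n_multi, replace = TRUE, prob = w))
    map <- dplyr::bind_rows(map, extra) |> dplyr::distinct()
  }
  dplyr::arrange(map, .data$feature, .data$gene)
}

#' Simulate a gene-set collection
#'
#' Draws named gene sets with sizes spanning a wide range (default 5 to 600)
#' so that downstream size filtering (10 to 500 members in the background) is
#' exercised at both ends.
#'
#' @param genes Character vector of gene IDs to draw from.
#' @param n_sets Number of sets.
#' @param size_range Length-2 range of set sizes.
#' @param seed Integer seed.
#' @return A named list of character vectors (a gene-set collection).
#' @export
simulate_gene_sets <- function(genes, n_sets = 50, size_range = c(5, 600),
                               seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- round(exp(runif(n_sets, log(size_range[1]), log(size_range[2]))))
  sizes <- pmin(sizes, length(genes))
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  sets
}

#' Write simulated cohorts to disk
#'
#' Emits one `<cohort>.matrix.tsv` and `<cohort>.samples.tsv` per cohort, the
#' ground-truth table as `truth.tsv`, and a structured `config.yaml` echo of
#' the generating configuration.
#'
#' @param sim Result of [simulate_multicohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in sim$cohorts) {
    mat <- tibble::as_tibble(ch$matrix, rownames = "feature")
    readr::write_tsv(mat, file.path(dir, paste0(ch$id, ".matrix.tsv")))
    readr::write_tsv(ch$samples, file.path(dir, paste0(ch$id, ".samples.tsv")))
  }
  readr::write_tsv(sim$truth$features, file.path(dir, "truth.tsv"))
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
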