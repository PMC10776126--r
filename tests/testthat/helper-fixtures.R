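# Small shared fixtures, built in code at load time.

small_sim <- function(seed = 11, modality = "methylation", n_cohorts = 4,
                      n_features = 600, frac = 0.1, ...) {
  simulate_multicohort(sim_config(
    modality = modality, n_cohorts = n_cohorts, n_features = n_features,
    n_genes = 200, frac_age_features = frac, seed = seed, ...
  ))
}

# A deterministic expression-style cohort with known structure.
toy_cohort <- function(n = 30, n_feat = 5, seed = 42, paired = FALSE,
                       fill = function(nf, n) matrix(rnorm(nf * n), nf, n)) {
  set.seed(seed)
  if (paired) {
    n_sub <- n %/% 2
    subject <- rep(sprintf("s%02d", seq_len(n_sub)), each = 2)
    timepoint <- rep(c("PRE", "POST"), n_sub)
    idx <- rep(seq_len(n_sub), each = 2)
  } else {
    n_sub <- n
    subject <- sprintf("s%02d", seq_len(n))
    timepoint <- rep("PRE", n)
    idx <- seq_len(n)
  }
  age <- runif(n_sub, 20, 75)[idx]
  smp <- tibble::tibble(
    sample_id = sprintf("smp%02d", seq_len(n)),
    subject_id = subject, age = age,
    sex = sample(c("F", "M"), n, replace = TRUE),
    vo2max = runif(n_sub, 25, 60)[idx],
    timepoint = timepoint,
    batch = sample(c("b1", "b2"), n, replace = TRUE)
  )
  mat <- fill(n_feat, n)
  dimnames(mat) <- list(sprintf("f%03d", seq_len(n_feat)), smp$sample_id)
  cohort_dataset("toy", "expression", mat, smp)
}

# Per-cohort association tables drawn from a known random-effects model:
# effect_i ~ N(mu + u_i, v_i), u_i ~ N(0, tau2) for signal features.
synthetic_assoc_tables <- function(n_features, k, mu, tau2, v_range = c(0.001, 0.01),
                                   seed = 1) {
  set.seed(seed)
  feats <- sprintf("f%04d", seq_len(n_features))
  lapply(setNames(seq_len(k), sprintf("c%02d", seq_len(k))), function(i) {
    v <- runif(n_features, v_range[1], v_range[2])
    y <- rnorm(n_features, mu + rnorm(n_features, 0, sqrt(tau2)), sqrt(v))
    tibble::tibble(feature = feats, effect = y, se = sqrt(v),
                   p = 2 * pnorm(-abs(y / sqrt(v))), n = 30L, df = 27L,
                   flag = FALSE)
  })
}

# a 50-probe x 25-sample fixture with known violations of each printed rule
qc_fixture <- function() {
  set.seed(99)
  n_probe <- 50; n_smp <- 25
  beta <- matrix(runif(n_probe * n_smp, 0.2, 0.8), n_probe, n_smp,
                 dimnames = list(sprintf("cg%03d", 1:n_probe),
                                 sprintf("s%02d", 1:n_smp)))
  det <- matrix(0.001, n_probe, n_smp, dimnames = dimnames(beta))
  bead <- matrix(10, n_probe, n_smp, dimnames = dimnames(beta))
  # sample s01 fails 6/50 probes (12% >= 10% -> removed);
  # s02 fails 4/50 (8% -> retained)
  det[1:6, 1] <- 0.5
  det[1:4, 2] <- 0.5
  # after removing s01, 24 samples remain: cg010 fails detection in 2/24
  # (8.3% > 5% -> removed), cg011 in 1/24 (4.2% -> retained)
  det[10, 3:4] <- 0.5
  det[11, 3] <- 0.5
  # cg012: bead count < 3 in 2/24 samples -> removed
  bead[12, 5:6] <- 2
  # cg013: missing beta -> removed
  beta[13, 7] <- NA
  smp <- tibble::tibble(
    sample_id = colnames(beta),
    subject_id = paste0("sub", 1:n_smp),
    age = seq(20, 68, length.out = n_smp),
    sex = rep(c("F", "M"), length.out = n_smp),
    vo2max = seq(30, 55, length.out = n_smp),
    timepoint = "PRE", batch = "b1"
  )
  ds <- cohort_dataset("qcfix", "methylation",
                       ifelse(is.na(beta), NA, pmin(pmax(beta, 0.01), 0.99)), smp)
  ann <- probe_annotation(rownames(beta))
  ann$is_cg[20:21] <- FALSE       # 2 non-CG
  ann$is_snp[22] <- TRUE          # 1 SNP probe
  ann$is_multimap[23] <- TRUE     # 1 multi-mapper
  ann$chromosome[24] <- "chrX"    # sex chromosome probe
  list(ds = ds, det = det, bead = bead, ann = ann)
}
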