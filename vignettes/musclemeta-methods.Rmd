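---
title: "Methods: multi-cohort meta-analysis of the aging muscle methylome and transcriptome"
author: "musclemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort meta-analysis of the aging muscle methylome and transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclemeta)
```

## The question and the design

Skeletal muscle ages in a measurable way: DNA methylation drifts at
thousands of CpGs (typically on the order of 1% methylation per decade) and
hundreds of transcripts change expression. The question this package
operationalises is whether cardiorespiratory fitness (VO~2max~), exercise
training, and muscle disuse move those same molecular features — and in
which direction relative to aging.

The analysis is a two-step design over many independent cohorts:

1. **Step 1 — find age-related features.** In every cohort, each feature
   (CpG M-value or log2 expression) is regressed on age with
   dataset-specific covariates. The per-cohort slopes are pooled by
   random-effects meta-analysis, and features passing a strict FDR threshold
   (q < 0.005) become the age-related set (DMPs / DEGs).
2. **Step 2 — interrogate those features only.** The same machinery is
   re-run with VO~2max~ or PRE/POST training as the predictor, restricted to
   the age-related set; published summary statistics (for training and
   disuse meta-analyses) are ingested rather than refitted. Cross-contrast
   effect-size correlations, Q-Q inflation, signed importance scores, and a
   rank-MANOVA multi-contrast enrichment summarise how fitness and training
   oppose — and disuse mimics — the age direction.

Because the real cohorts are not redistributable, the package ships a
synthetic multi-cohort generator with planted ground truth; every statistical
claim the package makes is validated against that ground truth or against an
independent oracle (bisection roots, exact enumeration, label permutation,
weighted-sampling Monte Carlo).

## Per-cohort association model

`fit_contrast()` fits ordinary least squares per feature:
response ~ predictor + covariates, with two-sided t-tests. Choices worth
stating:

- **M-values.** Beta-values are logit2-transformed (`beta_to_mvalue()`,
  with clipping at 1e-6 and a warning count) before regression; the logit
  scale stabilises variance near the (0, 1) boundaries.
- **Paired designs.** For PRE/POST training contrasts with `paired = TRUE`,
  subject indicator columns are included, so the timepoint coefficient is the
  within-subject change. Subject baselines then cancel, which is where the
  paired design's precision advantage comes from (asserted in the tests).
- **Repeated measures in cross-sectional contrasts.** A between-subject
  predictor (age, VO~2max~) cannot be separated from subject fixed effects,
  so cohorts with repeated samples per subject are reduced to one baseline
  sample per subject for those contrasts, with a message.
- **Degenerate designs.** Covariates that are constant within a cohort are
  dropped; covariate columns aliased with each other are dropped (with a
  message); a predictor aliased with covariates, or constant, skips the
  cohort — age effects cannot be estimated where age does not vary.
- **No moderated variances.** Plain OLS t-tests are used, not
  empirical-Bayes-shrunken variances: the meta-analysis downstream expects
  honest per-cohort standard errors, and shrinkage would couple features.
- **VO~2max~ adjusted for age.** Fitness declines with age, so within any
  cohort the two predictors are correlated. The pipeline includes age as a
  covariate in the VO~2max~ contrast; without it the fitness effect simply
  re-absorbs the age effect and the cross-contrast correlation is
  mechanically inflated (we observed about −0.8 against a planted −0.4).

## Random-effects meta-analysis

For a feature with effects $y_i$ and sampling variances $v_i$ in $k$
cohorts, the model is $y_i \sim N(\mu, v_i + \tau^2)$. The between-cohort
variance $\tau^2$ is estimated by the empirical-Bayes iteration (step
length 0.5, at most 10,000 iterations, tolerance 1e-8), whose fixed point is
the Paule–Mandel estimating equation

$$\sum_i w_i(\tau^2)\,(y_i - \hat\mu(\tau^2))^2 = k - 1,
\qquad w_i = \frac{1}{v_i + \tau^2},$$

truncated at zero. The estimate is verified in the tests against an
independent bisection root-finder on 1000 random instances (and
spot-checked against `metafor::rma(method = "EB")`); bit-equivalence with
any particular damping scheme is not claimed, agreement to 1e-5 is.
Pooling is inverse-variance with $w_i = 1/(v_i + \hat\tau^2)$, Wald z
p-values, Cochran's Q with fixed-effect weights, and
$I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$.

Features must be estimably present in at least `k_min` cohorts (defaults 10
of 16 for methylation, 15 of 21 for expression — the inclusion rules the
thresholds were designed around). FDR is Benjamini–Hochberg; the selection
rule everywhere is q < 0.005. Features whose $\tau^2$ iteration fails to
converge are flagged and excluded from selection, a conservative default.

**Known limitation — Wald intervals.** The z-based confidence intervals
undercover as heterogeneity grows: in our own calibration experiments,
95% CIs at $k = 16$ cover the true pooled slope about 95% of the time at
$I^2 \approx 8$–15% but only about 92% at $I^2 \approx 40$%. The coverage
test therefore runs at a representative low-moderate heterogeneity
($\tau^2 = 0.001$ against per-cohort variances of 0.001–0.01,
$I^2 \approx 15$%); a Knapp–Hartung adjustment would widen intervals but is
deliberately not applied, since the method description names none.

## Restricted secondary contrasts

Step-2 contrasts are meta-analysed only at the age-related features, and the
BH correction runs over that restricted set — the multiplicity burden
matches the question asked. The tests assert there is no leakage:
restriction-then-FDR equals FDR-on-subset exactly. External summary tables
(training, disuse) are joined by feature ID; unmatched features are dropped
from correlations, never imputed, and the match rate is reported.

Diagnostics mirror the published figures: Spearman correlations between
aligned effect vectors (average ranks for ties; exact permutation p below
20 untied pairs, t-approximation otherwise), effect scaling to unit SD for
joint heatmap export (rank statistics unchanged), the genomic inflation
factor $\lambda = \mathrm{median}(\chi^2_{obs})/0.4549$ from the Q-Q plot of
secondary-contrast p-values, and PCA of the age-related feature matrix with
Pearson correlations of sample coordinates on the first three components
against VO~2max~ (component signs fixed by the largest-magnitude loading).

## Gene-set over-representation and the probe-count bias

Expression-side ORA is the one-sided hypergeometric upper tail against the
tested-gene universe. Methylation-side ORA collapses probes to genes (a gene
is a hit iff at least one of its probes is a hit; multi-gene probes count
for every annotated gene) — which biases naive tests, because genes carrying
many probes are more likely to contain a significant probe by chance. The
package models hit-gene selection as a biased urn (Wallenius noncentral
hypergeometric) with a single odds parameter, the ratio of mean probe counts
in-set versus out-of-set.

The Wallenius distribution is computed exactly by dynamic programming over
the draw sequence (no numerical integration), and reduces to the central
hypergeometric at odds 1 to machine precision. Two caveats are documented
rather than hidden:

- The single-odds summary is exact when probe counts are constant within the
  in-set and out-of-set groups, and an approximation otherwise. The test
  suite pins the exact case against a 100,000-draw weighted-sampling Monte
  Carlo oracle, and demonstrates on a long-tailed probe-count background
  that the adjustment restores nominal type-I error (rejection at
  $\alpha = 0.05$ within 0.05 ± 0.02) where the unadjusted test rejects more
  than half the time.
- The calibration experiment uses hit fractions of 1–2% of probes,
  matching the sparse regime of genome-scale studies (thousands of hits
  against half a million probes); at much denser hit fractions the gene-hit
  probability saturates in probe count and a single odds is no longer
  adequate.

Sets are restricted to 10–500 members within the background (inclusive
bounds) before testing, and BH-FDR runs across the tested sets. The same
machinery doubles as the cell-type-marker confound check
(`celltype_confound_check()`): enrichment of age-related features in
cell-type marker sets would point at composition shifts rather than
cell-intrinsic aging. The DMG-by-DEG overlap test is the hypergeometric
upper tail on the intersection within a shared gene universe, symmetric in
its two lists.

## Signed scores and multi-contrast enrichment

Each feature-contrast pair gets the signed importance score
$S = \mathrm{sign}(\log_2 FC) \times (-\log_{10} p)$, with p floored at
1e-300 and $\mathrm{sign}(0) = 0$. Scores are ranked ascending per contrast
(average ties), so positive set-level shifts mean "toward the top of the
up-regulated end".

For a set of $m$ of $N$ features, the per-contrast enrichment score is the
scaled mean-rank shift $s = 2(\bar r_{set} - (N+1)/2)/N \in (-1, 1)$, which
attains $\pm(N-m)/N$ exactly when the set packs the extreme ranks (asserted
in closed form in the tests). The joint p-value is a one-way MANOVA of the
rank columns on set membership using Pillai's trace; with two groups the
statistic has a single nonzero eigenvalue, so the F mapping
$F = \frac{V}{1-V}\cdot\frac{N-d-1}{d}$ on $(d, N-d-1)$ degrees of freedom
is exact for the trace, and the implementation is checked both against
`stats::manova()` and against a 20,000-label-permutation oracle (agreement
within 3 Monte-Carlo SEs across 20 instances at $N = 500$, $d = 3$).
Pillai's trace was chosen as the standard robust default among MANOVA
statistics; its accuracy here is established by the permutation oracle, not
assumed. Ties in q are broken by set name so output order is deterministic.

## The synthetic study generator

`simulate_multicohort()` emulates the study conditions the thresholds were
designed for. What it plants, and why:

- **Cohort structure.** Default 16 methylation / 21 expression cohorts of
  25–60 samples; per-cohort age ranges drawn wide enough that every cohort
  passes the real inclusion rules (n > 20, age SD > 5 years, VO~2max~
  SD > 5 mL/min/kg). VO~2max~ is drawn jointly with age at a within-cohort
  correlation of about −0.3 (fitness declines a few mL/min/kg per decade);
  this coupling is simulated, not asserted.
- **Age effects.** A `frac_age_features = 0.1` share of features carries a
  true age slope drawn N(0, sd²) with sd = 0.00125 beta-units/year, so the
  mean absolute noiseless change is 1% methylation per decade
  ($E|N(0,\sigma^2)| = \sigma\sqrt{2/\pi}$). Methylation is generated on the
  logit scale — baseline + slope·age + cohort deviation + covariate effects
  + Gaussian noise, then inverse-logit — which keeps beta in (0, 1) and
  matches the M-value analysis downstream. Expression is generated directly
  in log2 units (slope SD 0.01/year).
- **Cross-contrast structure.** Fitness, training, and disuse effects at
  signal features follow a one-factor model
  $b_c = \rho_c z_{age} + \sqrt{1-\rho_c^2}\,\varepsilon$, giving exact
  target correlations with the age effect (defaults −0.4, −0.4, +0.4) and a
  positive-semidefinite joint structure by construction. Null features have
  all effects exactly zero — including the cohort deviations — so false
  discovery proportions are measurable.
- **Heterogeneity and platforms.** Realized per-cohort age slopes add
  N(0, τ²) deviations on the analysis scale (defaults 1e-6 methylation,
  4e-6 expression — modest heterogeneity). Each cohort drops a
  `missing_platform_frac = 0.2` share of features uniformly at random as a
  proxy for 27K/450K/EPIC-style platform differences, which exercises the
  presence filter.
- **Designs and seeds.** A `paired_frac = 0.375` share of cohorts gets a
  paired PRE/POST design with planted training deltas and subject baselines.
  One master seed drives everything; per-cohort seeds are drawn from the
  master stream, so runs are reproducible end to end and byte-identical on
  repeat.

What the generator does **not** emulate: raw array intensities, probe-design
(type I/II) normalisation artifacts, batch structure needing empirical-Bayes
correction (batch enters only as a planted covariate), and cell-type
composition shifts. Passing recovery tests on this generator therefore shows
the statistical pipeline is correct and calibrated under its assumed model —
not that those upstream preprocessing problems are solved.

## Validation scales and observed behaviour

The suite sizes were chosen to keep the whole run in a few minutes on one
core while leaving Monte-Carlo error well below the tolerances: 1000
random instances for the heterogeneity-estimator oracle; 2000 features for
OLS type-I and CI coverage; 20 generator seeds for the false-discovery
proportion; 500 resamples for ORA type-I restoration; 20 instances × 20,000
permutations for the rank-MANOVA oracle plus 100 runs × 200 sets for its
size; the full default configurations (16 + 21 cohorts, 5000 features) for
fixed-seed selection precision; and 100 reduced-size generator seeds
(8 cohorts, 1500 features) for the directional sign experiment.

On the default configurations the pipeline recovers the planted structure:
selection precision at q < 0.005 is above 0.99 for both modalities, the
estimated age-by-fitness and age-by-training Spearman correlations land
within ±0.15 of the planted −0.4 (selection on significant features inflates
the magnitude slightly — the selected features have above-average signal),
the age-by-disuse correlation is positive near +0.4, and the training /
disuse correlation signs are recovered in 100 of 100 seeds. These are the
package's own measurements, produced by the test suite.
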