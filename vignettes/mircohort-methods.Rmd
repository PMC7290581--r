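---
title: "Statistical methods behind miRcohort"
author: "miRcohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind miRcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcohort)
```

miRcohort implements the statistical chain used to evaluate circulating
microRNAs as coronary-artery-disease (CAD) biomarkers in two epidemiological
designs — a matched case-control contrast of myocardial-infarction patients
against healthy controls, and a case-cohort sample of a population cohort
followed ten years for incident CAD — plus the in-vitro screening and
annotation steps that select and interpret the candidate miRNAs. This
vignette explains each model, its assumptions, the tunable parameters, and
the choices we made where the methodology was genuinely open.

## 1. qPCR measurements, non-detects, and why censoring is the right model

A qPCR panel reports, per sample and miRNA, a cycle threshold Ct: the
amplification cycle at which fluorescence crosses a fixed threshold. Lower
Ct means more template. Two kinds of observations are unusable: reactions
whose amplification curve fails quality control (no exponential phase, poor
amplification score), and reactions that never cross the threshold within
the run — *non-detects*. A non-detect is not a missing-at-random value: it
says the miRNA's abundance was *below* the detection limit, i.e. its Ct lay
*above* the largest observable value. That is interval information, and the
pipeline preserves it as right censoring.

Processing order is fixed and recorded in each object's provenance log:

1. **Validity filter** (`apply_validity_filter`): QC-failed observations
   become missing, exactly like non-detects.
2. **Feature filter** (`filter_features`): miRNAs with strictly more than
   90% missing values are dropped, as are miRNAs with fewer than two
   observed values on some plate — the minimal condition for estimating
   that plate's location and scale, so such miRNAs cannot be
   plate-corrected. Both thresholds are strict inequalities; a miRNA
   observed in exactly 10% of samples is retained.
3. **Sample filter** (`filter_samples`): individuals with strictly more
   than 95% missing values are dropped.
4. **Plate correction** (`correct_plate_effects`): see below.
5. **Global normalization** (`global_normalize`): each observed Ct has the
   mean Ct of all *expressed* (observed) miRNAs of its sample subtracted,
   giving ΔCt. "Expressed" means observed after all filters — only those
   entries carry values. Lower ΔCt = higher relative expression. The
   transformation is invariant to per-sample additive shifts (so any
   sample-wide efficiency offset cancels) and a sample with a single
   observed miRNA gets ΔCt = 0.

### Plate-effect correction

Plates are batches: each contributes an additive Ct offset and a
multiplicative noise inflation. We adjust them with the standard parametric
empirical-Bayes location/scale batch model. Per miRNA, values are
standardized against a design-weighted grand mean and pooled variance; per
plate, location (γ) and scale (δ²) estimates are shrunk toward across-plate
priors — normal for γ, inverse-gamma for δ², hyperparameters fitted by
method of moments, posteriors found by the usual fixed-point iteration
(tolerance `1e-4`) — and the values are rescaled back. All sums run over
observed entries only, so the missing-by-design structure of qPCR data is
handled naturally; missing entries stay missing. A single plate makes the
step the identity; a miRNA/plate cell with zero within-plate variance
degrades to a location-only adjustment with a warning. On complete
matrices the unit tests verify agreement to `1e-6` with the reference
empirical-Bayes batch implementation in `sva`.

Correction uses no covariates by default (case status is not protected);
plates are expected to be randomized with respect to case status, as the
generator enforces. A `mean_only` switch restricts to location adjustment.

## 2. Censored differential expression

For each miRNA the case-control contrast treats ΔCt as the ordering axis of
a survival problem: non-detects are imputed at the per-miRNA maximum
observed ΔCt with a censoring flag (`censor_nondetects`) — right censoring,
because a non-detect means *less* expression, i.e. *larger* ΔCt than
anything observed. Group location is the Kaplan–Meier **restricted mean**:
the area under the product-limit survivor curve from the smallest
observation to the largest observation, censored or not
(`km_restricted_mean`). Without censoring this equals the arithmetic mean
exactly. The effect measure is the conventional ΔΔCt fold change

$$\mathrm{FC} = 2^{-(\overline{\Delta Ct}_{case} - \overline{\Delta Ct}_{control})},$$

which exceeds 1 for miRNAs upregulated in cases. Group comparison uses the
two-group log-rank test with the hypergeometric-variance tie handling
(`logrank_test`), and p-values are Benjamini–Hochberg-adjusted across the
miRNAs surviving the filters in the same run (`bh_adjust`,
`run_case_control`).

Choices worth stating:

* The reference quantity is the restricted **mean**, not the median; with
  heavy censoring the restricted mean is biased toward the censoring limit,
  which is the standard, conservative behaviour of the estimator.
* The upper limit of the restricted mean is the largest observation
  (censored or not) — the conventional default.
* Censored values tied with an uncensored value rank after it (deaths
  before censorings), the standard product-limit convention.
* The matched design is analysed unpaired (no pair strata), matching how
  such panels are conventionally analysed; the generator accordingly draws
  case and control covariates from one distribution instead of explicit
  pairing.
* A parametric censored-Gaussian (Tobit) model would use the interval
  information more efficiently but is deliberately out of scope; the
  KM/log-rank route makes no distributional assumption on ΔCt.

## 3. Case-cohort weighted Cox regression

The cohort arm observes all incident CAD events plus a random subcohort
drawn at four non-cases per case. Analysing that sample as if it were a
cohort would overweight events; instead, non-case subcohort person-time is
reweighted by the inverse sampling fraction α (subcohort size / cohort
size) while every failure contributes weight 1 at its failure time — the
Barlow scheme, realized by record splitting: subcohort non-cases cover
(0, t]; subcohort cases cover (0, t−ε] at weight 1/α plus (t−ε, t] at
weight 1; cases outside the subcohort enter just before failure
(ε = 10⁻⁵ years). Prentice weighting (subcohort person-time unweighted) is
available behind a flag. The weighted partial likelihood is maximized with
Breslow tie handling and the variance is the robust sandwich clustered on
subject id, giving normal-approximation 95% CIs on the log-hazard scale
(`fit_weighted_cox`). With α = 1 the estimator reduces exactly to ordinary
Cox partial likelihood, and the tests verify the maximizer against a
grid search of the weighted partial likelihood on small instances.

`run_mirna_scan` fits, per miRNA, complete-case records (non-detects
removed, matching the primary analysis convention for this design) under
two adjustment sets — age + sex, and the full classical set (age, sex,
smoking, total cholesterol, systolic blood pressure, diabetes) — with BH
adjustment per set. miRNAs with fewer than 10 complete cases or zero
variance are flagged, not fitted. The sampling fraction is estimated from
the data when not supplied.

## 4. Risk reclassification metrics

Absolute 10-year risk from a Cox fit is
$1 - S_0(10)^{\exp(\mathrm{lp} - \overline{\mathrm{lp}})}$ with the
baseline survival taken at the covariate means (`predicted_risk`,
`risk_from_fit`). Incremental value of an extended model over the baseline
risk-factor model is quantified by:

* **Continuous NRI** — net proportion of events whose predicted risk rises
  plus non-events whose risk falls; ties count neither way; reported in
  percent (range ±200%).
* **Categorical NRI** — the same net movement across the conventional 10%
  ten-year-risk boundary.
* **IDI** — the gain in mean risk separation between events and
  non-events.
* **Δ C-index** — the change in Harrell concordance over usable pairs
  (an event and a subject known to survive longer), ties counting ½.

All four honour case-cohort weights (events 1, non-event subcohort members
1/α) as weighted means / weighted pair counts, so the subcohort represents
the cohort. Confidence intervals are percentile bootstrap over subjects
(default B = 1000) with a two-sided p-value from the bootstrap
distribution's position relative to zero; all resampling is seeded and
deterministic. Continuous NRI and the C-index are invariant to strictly
monotone common transforms of both models' risks; IDI and categorical NRI
are scale-dependent by construction, which the tests assert as documented
behaviour rather than "fixing". The published risk-function coefficients
for this population are not public, so the baseline model is refit on the
data at hand (or supplied by the user); that choice affects absolute risks
but leaves the comparison between baseline and extended model internally
consistent.

## 5. In-vitro screening

The candidate-generation arm measures miRNA expression in endothelial and
vascular smooth muscle cells exposed to three ordered lipoprotein
conditions (native, moderately oxidized, highly oxidized LDL). Per cell
type:

* **Moderated t** (`moderated_t`): two-group contrasts of each oxidized
  condition against native, with per-feature pooled variances shrunk
  toward a common prior, posterior variance
  $(d_0 s_0^2 + d s^2)/(d_0 + d)$ and $d_0 + d$ degrees of freedom. The
  prior $(d_0, s_0^2)$ is fitted by method of moments on the log sample
  variances (the scaled-F model), with a Newton inversion of the trigamma
  function. Forcing $d_0 = 0$ recovers the ordinary pooled t exactly;
  $d_0 = \infty$ gives every feature the common variance. The tests verify
  agreement with `limma::eBayes` to `1e-8` on the same input.
* **Trend tests** (`trend_test`): per-feature Gaussian linear model on
  orthogonal polynomial contrasts of the ordered conditions, so linear
  (−1, 0, +1) and quadratic (+1, −2, +1) departures are tested separately
  and orthogonally.
* **Selection rule** (`select_candidates`): |fold change| ≥ 1.5 with
  p < 0.05 in at least one oxidized-vs-native contrast, AND a linear or
  quadratic trend with p < 0.05, in at least one cell type. p-values are
  deliberately unadjusted at this screening stage (the downstream
  epidemiological analyses carry the multiplicity control); trend models
  are fit per cell type, the literal reading of the "at least one cell
  type" rule.

Cross-platform validation (`cross_platform_correlation`) is the Spearman
correlation between per-feature array summaries and qPCR ΔCt; agreement
appears as a *negative* coefficient since lower ΔCt means higher
expression.

## 6. Target filtering, enrichment, overlap

Predicted-target records carry a cumulative weighted context score (more
negative = stronger predicted repression) and an aggregate score. Targets
are kept when context < −0.3 (strict) and aggregate ≥ 0.3 (inclusive)
(`filter_targets`). Pathway over-representation is the upper-tail
hypergeometric probability $P(X \ge k)$ for an overlap of $k$ with a set of
size $K$, $n$ targets drawn from a universe of $N$, BH-adjusted across sets
(`hypergeom_enrichment`); the universe defaults to all genes in the
supplied annotation, overridable. Expressed-target overlap counts
(`expressed_overlap`) use exact, case-normalized identifier matching
against per-cell-type expressed lists and optional curated
athero-protective/athero-prone lists, which ship as editable inputs since
they are literature curation, not computation.

## 7. The synthetic-data generator

Every analysis stage is exercised on data from `simulate_case_control`,
`simulate_cohort`, `simulate_array` and `simulate_annotation`, which
emulate the study design rather than any particular dataset:

* **Case-control qPCR**: latent Ct = per-miRNA baseline − status ×
  log2-fold-change + plate shift + plate scale × N(0, sd²); a latent Ct
  above the limit of detection is emitted as a non-detect. This makes the
  censoring assumption of the analysis *mechanistically true*: non-detects
  really are the upper tail of the Ct distribution. Defaults: 476 cases /
  487 controls, a 48-assay panel with baselines spanning 24–33 cycles
  (so the panel covers abundant through near-limit species), 8 balanced
  plates with shift SD 0.5 Ct and log-scale SD 0.1, Ct noise SD 1.5,
  detection limit 35 cycles, 1% QC-failure rate. The truth table reports
  the realized per-miRNA fold change and non-detect fraction.
* **Cohort**: exponential (optionally Weibull) proportional-hazards event
  times on the classical risk factors plus miRNA values (standard-normal
  on the normalized ΔCt scale), linear predictor centered, administrative
  censoring at 10 years; all events plus a seeded random subcohort of four
  per event form the case-cohort table. Default baseline hazard 0.002/yr
  at the covariate mean yields ≈100 events per 5000 participants over
  10 years — the scale of the cohort arm it emulates. Covariate
  distributions and log-hazard ratios (age 0.06/yr, male 0.45, smoking
  0.55, cholesterol 0.20/mmol/L, SBP 0.015/mmHg, diabetes 0.65) are
  typical of Mediterranean-population coronary risk functions; the source
  study does not publish its per-stratum event rates, so these are chosen
  once for statistical testability, not demographic realism.
* **Array**: per-feature flat/linear/quadratic mean profiles across the
  three ordered conditions (quadratic peaking at the middle condition)
  with declared log2 amplitudes and replicate noise.
* **Annotation**: a gene universe with target scores drawn on both sides
  of the filtering thresholds, random pathway sets (optionally with a
  planted enriched set), and per-cell-type expressed lists.

One base seed drives everything through named substreams
(`derive_seed`), so regenerating one stage never perturbs another and
identical configurations are bit-identical.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: amplification-curve artefacts and the
quality score itself (validity is a Bernoulli flag), miRNA–miRNA
correlation within a sample, informative missingness beyond the detection
limit mechanism, pair-matched covariate structure, competing risks and
loss to follow-up (censoring is purely administrative), and probe-level
microarray noise.

## 8. Numerical choices and degenerate inputs

* Empirical-Bayes iteration: convergence `1e-4` on the relative change,
  100-iteration cap; denominators floored at `1e-8`.
* Cox: Breslow ties, convergence `1e-9`, 100 iterations, robust variance
  clustered on subject; ε = `1e-5` years for pre-failure entry.
* Restricted mean of an all-censored group, concordance with no usable
  pair, rank correlation of a constant vector: explicit `NA`/error with a
  message, never a silent number. Per-miRNA failures inside table-level
  drivers become flagged rows, not aborts.
* Noiseless trend fits (zero residual variance) report p = 0 for nonzero
  contrasts and p = 1 for zero contrasts rather than NaN.
* Bootstrap resamples where a metric is undefined are tolerated up to 10%
  and excluded; beyond that the computation fails loudly.

## 9. Problem sizes used in the shipped checks

The test suite and the acceptance script run at sizes chosen to make the
statistical properties visible while keeping a laptop run comfortable:
fold-change recovery at the design's full 476/487 with a 48-assay panel
over 50 (tests) or 10 (script) seeds; hazard-ratio recovery on cohorts of
5000 with ~100 events over 100 (tests) or 10 (script) replicates;
log-rank type-I error over 1000 (tests) or 500 (script) replicates at
n = 100/group; reclassification bootstraps at B = 200–500 in checks versus
the B = 1000 default. Enumeration oracles (hypergeometric, product-limit,
reclassification metrics, partial-likelihood grid) run exhaustively at
N ≤ 12 or n ≤ 20, where enumeration is exact.

## 10. Known limitations

* The restricted-mean fold change is attenuated when the planted effect is
  large relative to the panel (the global-normalization reference moves
  with the effect) and when censoring is heavily differential between
  groups; at the shipped design (one active miRNA in a 48-assay panel)
  the attenuation is ≈3%.
* The case-cohort C-statistic estimator in the literature this design
  follows is not uniquely specified; we implement weighted Harrell
  concordance with pluggable weights and document it as an
  interpretation.
* The baseline risk model is refit per dataset rather than using published
  coefficients (not public), so absolute risks are internally calibrated
  only.
* Bootstrap p-values are position-based percentile p-values; for very
  small event counts they are granular at 2/B.
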