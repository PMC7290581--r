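# miRcohort

Statistical analysis of circulating microRNA qPCR panels in cardiovascular
epidemiology: case-control differential expression with censored
non-detects, case-cohort survival association, and risk-reclassification
metrics — plus the in-vitro screening and target-annotation steps that feed
such studies, and a synthetic-data generator that emulates the whole design
so everything is testable offline.

## The problem

Coronary risk functions miss most people who go on to have an event, so
circulating biomarkers — here serum microRNAs measured by qPCR — are
evaluated for what they add on top of classical risk factors. The data
are statistically awkward in three specific ways this package addresses:

1. **Non-detects are censored, not missing.** A qPCR reaction that never
   crosses the fluorescence threshold says the miRNA's Ct lies *above*
   every observable value (expression below the detection limit). After
   QC filtering, plate-effect correction (parametric empirical-Bayes
   location/scale batch adjustment that tolerates missing entries) and
   global mean normalization to ΔCt, non-detects are right-censored at the
   per-miRNA maximum observed ΔCt. Group means are Kaplan–Meier restricted
   means, groups are compared by the log-rank test, and the effect measure
   is the fold change

   FC = 2^−(ΔCt̄_case − ΔCt̄_control),

   with Benjamini–Hochberg correction across the panel.

2. **A case-cohort sample is not a cohort.** The survival arm holds all
   incident CAD events plus a random subcohort (1 : 4). Association of each
   miRNA with time-to-event uses a weighted Cox partial likelihood with
   Barlow weights (subcohort person-time at the inverse sampling fraction,
   failures at weight 1, outside-subcohort cases entering just before
   failure) and robust variance clustered on subject.

3. **"Does it reclassify?" is the clinical question.** Incremental value
   over the classical risk-factor model is measured on absolute 10-year
   risks by continuous and categorical (10% cutoff) net reclassification
   improvement, integrated discrimination improvement, and the change in
   weighted Harrell concordance, all honouring the case-cohort weights,
   with seeded percentile-bootstrap confidence intervals.

The in-vitro arm (empirical-Bayes moderated t plus orthogonal linear /
quadratic trend tests across three ordered oxidized-LDL conditions, and the
|FC| ≥ 1.5 ∧ p < 0.05 ∧ trend selection rule) and the annotation arm
(target-score filtering, upper-tail hypergeometric pathway enrichment,
expressed-target overlap counts) complete the chain. See
`vignettes/mircohort-methods.Rmd` for the models, assumptions and design
choices.

## Worked example

```r
library(miRcohort)

## case-control arm: 476 cases / 487 controls, 48-assay panel, one miRNA
## planted at fold change 4.85
sim <- simulate_case_control(cc_config(true_log2_fc = c(mir24 = log2(4.85)),
                                       seed = 42))
res <- process_ct(sim$ct)                      # QC -> plates -> deltaCt
de  <- run_case_control(res$delta, sim$meta$group)
head(de[, c("mirna", "mean_case", "mean_control", "fold_change",
            "p", "p_adj", "n_censored")], 3)
#>    mirna mean_case mean_control fold_change        p    p_adj n_censored
#> 24 mir24    -2.116      -0.0376       4.223 2.33e-52 1.12e-50         12
#> 25 mir25     0.378       0.1371       0.846 1.04e-02 2.49e-01          9
#> 48 mir48     4.676       4.5456       0.913 2.65e-02 3.28e-01        118
```

The planted miRNA tops the table: its restricted-mean ΔCt is ~2.1 cycles
lower in cases (higher expression), an estimated fold change of 4.2 on one
realization (the estimate is mildly attenuated because the normalization
reference moves with the effect), BH-significant at 1e-50; the other rows
are null miRNAs at their nominal noise level, with `n_censored` counting
non-detects.

```r
## case-cohort arm: cohort of 5000, ~100 events, planted HR 0.56 per unit
sco  <- simulate_cohort(cohort_config(mirna_log_hr = c(mir01 = log(0.56)),
                                      seed = 42))
scan <- run_mirna_scan(sco$casecohort, "mir01", cohort_size = 5000)
scan[, c("mirna", "adjustment", "hr", "ci_low", "ci_high", "p")]
#>   mirna adjustment    hr ci_low ci_high        p
#> 1 mir01    age_sex 0.591  0.493   0.710 1.77e-08
#> 2 mir01       full 0.519  0.417   0.646 4.38e-09

iv <- incremental_value(sco$casecohort, "mir01", cohort_size = 5000,
                        B = 500, seed = 1)
iv$metrics
#>   metric estimate  ci_low ci_high     p n_boot
#> 1   cNRI  41.1111 23.2862 57.6423 0.000    500
#> 2 catNRI  10.0597  3.8111 16.9631 0.004    500
#> 3    IDI   0.0309  0.0190  0.0456 0.000    500
#> 4 deltaC   0.0541  0.0197  0.0899 0.000    500
```

The weighted Cox fit recovers the planted protective hazard ratio (0.59 and
0.52 against a truth of 0.56, within one realization's noise) under both
adjustment sets, and adding the marker to the classical risk factors gives
a continuous NRI of ~41% with a bootstrap interval excluding zero.

## Command line

The same chain is scriptable via `inst/exec/mircohort` (or
`mircohort_cli()` from R):

```sh
mircohort simulate  --seed 7 --out-dir sim
mircohort normalize --ct sim/ct.tsv --meta sim/meta.tsv --out delta.tsv
mircohort de        --delta delta.tsv --meta sim/meta.tsv --out de.tsv
mircohort cox       --survival sim/survival.tsv --delta sim/cohort_delta.tsv \
                    --cohort-size $(cat sim/cohort_size.txt) --out cox.tsv
mircohort reclassify --survival sim/survival.tsv --delta sim/cohort_delta.tsv \
                     --add-mirnas mir01 --cohort-size $(cat sim/cohort_size.txt)
mircohort screen    --expr sim/expression.tsv --samples sim/expression_samples.tsv
mircohort enrich    --targets sim/target_scores.tsv --gmt sim/gene_sets.gmt
```

All tables are tab-separated text; an empty cell in a wide Ct table is a
non-detect.

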