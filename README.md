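# hubreserve

Does a highly connected left frontal cortex protect cognition against
Alzheimer's disease pathology? `hubreserve` is an R package for testing
that *cognitive reserve* hypothesis end to end: it computes a global
hub-connectivity score from resting-state fMRI, fits
severity-by-connectivity moderation models of cognition, models cognitive
and biomarker trajectories over disease time, and ships seedable
synthetic-data generators emulating an autosomal-dominant Alzheimer's
cohort (DIAN-like; mutation carriers vs non-carrier siblings, disease time
= estimated years to symptom onset, EYO) and a sporadic multicentre cohort
(DELCODE-like; amyloid status from the CSF A&beta;42/40 ratio, severity =
CSF tau) — so the whole pipeline is testable without access-controlled
patient data.

It is written for imaging/biostatistics researchers who want a tested,
scriptable reference implementation of this analysis class.

## The measures and models

**Global connectivity (weighted degree centrality).** For an 8 mm seed
sphere (left frontal cortex, MNI −42, 6, 28; plus right-homotope and two
null-region controls), after denoising (linear detrend, zero-phase
0.01–0.08 Hz band-pass, regression of 6 motion parameters + WM/CSF means)
and motion scrubbing (censor FD > 0.5 mm with 1 preceding / 2 following
volumes; exclude subjects >30% censored):

    gConn = mean over grey-matter voxels v with r_v > 0 of atanh(r_v)

where `r_v` is the Pearson correlation between the mean seed series and
voxel `v`.

**Reserve moderation model.** Per cohort and stratum, a linear mixed
model on z-scored variables (connectivity and CSF tau log-transformed
first),

    z(cognition) ~ z(severity) * z(conn) + covariates + (1 | site)

fitted by ML and compared by AIC against the model without the
interaction. A positive interaction coefficient means the severity slope
is attenuated at higher connectivity — the reserve signature.

**Trajectories.** Polynomial (order 1–3, AICc-selected) mixed models over
EYO or CSF tau per group, summarized as standardized between-group
difference curves on EYO ∈ [−20, +10] years, optionally stratified by a
connectivity median split.

## Worked example

```r
library(hubreserve)

## 1. connectivity from a (simulated) BOLD run
sim <- simulate_bold_run(grid_shape = c(10, 10, 10), n_volumes = 120,
                         coupled_fraction = 0.3, coupling_rho = 0.4,
                         rng_seed = 7)
compute_global_connectivity(sim$run, sim$motion, sim$gm_mask,
                            sim$wm_mask, sim$csf_mask, seeds = "LFC")
#>   subject_id seed     score n_positive_voxels n_gm_voxels censored_fraction excluded
#> 1    subject  LFC 0.7164825               893         903             0.125    FALSE

## 2. reserve moderation on a simulated carrier stratum (planted
##    standardized interaction 0.269, the published value)
tab <- simulate_cohort("DIAN", rng_seed = 11)
fit <- fit_reserve_interaction(tab, outcome = "mmse", severity = "eyo",
                               connectivity_seed = "LFC", stratum = "MC",
                               cohort = "DIAN")
print(fit)
#> Reserve moderation model (DIAN, stratum MC)
#>   outcome: mmse ~ eyo * conn_lfc + covariates, site random intercept
#>                  beta    se      t     p
#> eyo            -0.661 0.205 -3.227 0.005
#> conn_lfc       -0.053 0.191 -0.277 0.785
#> eyo x conn_lfc  0.223 0.172  1.298 0.213
#>   n = 74, overall R^2 = 0.906
#>   AIC full 176.5 vs reduced 181.9 -> interaction improves fit
```

The interaction row is the reserve effect: here one simulated stratum
recovers 0.223 (SE 0.172) for a planted 0.269 — unbiased across
replicates (the acceptance suite shows the 500-replicate mean within 0.03
and 95% CI coverage ≈ 95%). The full-vs-reduced AIC drop mirrors the
published model comparison. Note the honest SEs: family-affiliation
dummies consume half the degrees of freedom at n = 74, so single-stratum
estimates are noisy.

```r
## 3. trajectory difference curves with a connectivity median split
tab <- simulate_cohort("DIAN", n_per_group = c(MC = 287, NC = 213),
                       cognition_trajectory = "sigmoid", rng_seed = 42)
f_mc <- select_polynomial_model(tab, "mmse", "eyo", "MC", "DIAN",
                                with_connectivity_interaction = TRUE)
f_nc <- select_polynomial_model(tab, "mmse", "eyo", "NC", "DIAN")
curve <- predict_difference_curve(f_mc, f_nc, pooled_sd = sd(tab$mmse))
plot(curve)
```

The curve shows the standardized carrier deficit growing from ~0 at
EYO −20 to about −2 SD after onset; with the planted moderation, the
high-connectivity half of carriers crosses any decline threshold several
years later than the low half (the "right shift" of reserve).

```r
## 4. or everything at once
cfg <- default_config(); cfg$simulate <- TRUE; cfg$out_dir <- "out"
run_pipeline(cfg)   # writes models.tsv, interactions.tsv, curves.tsv,
                    # descriptives.tsv, config.yaml, manifest.json
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline quantities from scratch: it simulates a
BOLD run and scores it, then runs the complete statistical pipeline
(moderation models with Bonferroni gating, education and scanner models,
trajectory difference curves) on freshly simulated DIAN-like and
DELCODE-like cohorts, writing the pipeline outputs next to the JSON
report.

## Layout

* `R/` — implementation: NIfTI-1 I/O, scrubbing, denoising, connectivity,
  transforms/effect sizes, moderation and trajectory mixed models,
  generators, pipeline.
* `vignettes/hub-connectivity-reserve.Rmd` — the models, every tunable
  parameter with its default and rationale, numerical choices, and what
  the synthetic world does and does not establish.
* `tests/testthat/` — unit, property and acceptance tests.
* `inst/cli/hubreserve.R` — thin command-line wrapper
  (`simulate`, `compute-gc`, `run-all`).
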