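---
title: "Global left-frontal hub connectivity and cognitive reserve: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global left-frontal hub connectivity and cognitive reserve: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

People differ in how well they maintain cognition at a given load of
Alzheimer's disease pathology. One candidate substrate of this *reserve* is
the hubness of the left frontal cortex (LFC, Brodmann area 6/44) in the
fronto-parietal control network: its **global connectivity** — a weighted
degree-centrality measure — may buffer the effect of disease severity on
cognition. `hubreserve` implements the full analysis chain needed to test
this on resting-state fMRI plus phenotype data from two cohort designs: an
autosomal-dominant Alzheimer's cohort (DIAN-like: mutation carriers, MC,
vs non-carrier siblings, NC; disease time indexed by estimated years to
symptom onset, EYO) and a sporadic multicentre cohort (DELCODE-like: four
diagnostic groups dichotomized by CSF A$\beta_{42/40}$ ratio $< 0.1$;
disease severity indexed by CSF total tau).

Because both source datasets are access-controlled, the package ships a
first-class synthetic-data module that emulates both input classes, and
every claim the test-suite makes is made against data generated by it.

# The connectivity score

For each subject the pipeline computes, per seed region,

$$\mathrm{gConn} = \frac{1}{|P|}\sum_{v \in P} \operatorname{atanh}(r_v),
  \qquad P = \{v \in \mathrm{GM} \setminus \mathrm{seed}: r_v > 0\},$$

where $r_v$ is the Pearson correlation between the mean seed time series
and grey-matter voxel $v$ after denoising. Negative correlations are
excluded from numerator and denominator (averaging signed values would
cancel them); an empty $P$ yields a score of 0 with a warning flag.
Correlations are clipped to $\pm(1-10^{-7})$ before the Fisher transform,
so the score is bounded by $\operatorname{atanh}(1-10^{-7}) \approx 8.4$.

Seeds are 8 mm-radius spheres in MNI space: LFC $(-42, 6, 28)$, its right
homotope RFC $(42, 6, 28)$, and two null regions, occipital pole
$(-19, -102, -3)$ and M1 $(-38, -22, 56)$. Sphere membership is decided in
world millimetres through the image affine; no voxel-index arithmetic is
ever done across grids.

## Denoising and scrubbing

Per voxel, in order: linear detrend; zero-phase band-pass 0.01–0.08 Hz;
regression of the six motion parameters and the mean white-matter and CSF
signals. Confounds are detrended and filtered identically before the
regression, so regression cannot reintroduce removed frequencies.

*Numerical choice — the filter.* No DSP library is available in the target
environment, so the band-pass applies the squared magnitude of an order-2
Butterworth band-pass prototype in the frequency domain after full mirror
padding. This is the frequency response a forward–backward (`filtfilt`)
implementation would have, with exactly zero phase. The contract is tested
numerically: at TR = 2.23 s a 0.04 Hz sinusoid passes with gain within 5%
of unity and a 0.2 Hz sinusoid is attenuated by more than 98%.

*Framewise displacement.* The verbal definition ("average spatial
displacement between adjacent volumes") is implemented as the
sum-of-absolute-differences convention: $\mathrm{FD}_t = \sum |\Delta
\mathrm{trans}| + 50\,\mathrm{mm} \cdot \sum |\Delta \mathrm{rot}|$, the
convention under which the 0.5 mm censoring cutoff is standard. Volumes
with $\mathrm{FD} > 0.5$ mm (strict) are censored with 1 preceding and 2
subsequent volumes (windows unioned, clipped at run edges); subjects with
more than 30% (strict) censored volumes are excluded. Censoring is applied
*after* filtering, by dropping volumes before correlation, because the
filter needs a contiguous series.

All cutoffs in the package (`fd > 0.5`, `fraction > 0.30`, grey-matter
probability `> 0.3`) are strict inequalities.

# The reserve (moderation) models

The central model, fitted separately per cohort and stratum (MC/NC, or
amyloid-positive/negative), is a linear mixed model

$$z(\mathrm{cognition}) \sim z(\mathrm{severity}) \cdot z(\mathrm{conn})
  + \mathrm{covariates} + (1 \mid \mathrm{site}),$$

with severity = EYO (DIAN) or log CSF tau (DELCODE), connectivity log-z
transformed (it is right-skewed), covariates gender + family affiliation
(DIAN; age is excluded there because it is collinear with EYO) or age +
gender (DELCODE). A *positive* interaction coefficient is the reserve
signature: the negative severity slope is attenuated at higher
connectivity. The four primary analyses (severity × connectivity on MMSE
and delayed recall, one per cohort) are gated at the Bonferroni-corrected
$\alpha < 0.0125$; everything else at 0.05.

Models are fitted by maximum likelihood (not REML) because the full model
is compared by AIC against the reduced model without the interaction term,
and AIC comparisons across fixed-effect structures require ML.

*"Standardized beta".* The outcome and all continuous predictors are
z-scored before the fit; the interaction column is the product of the
z-scored mains and is not re-standardized (the conventional reading).
Reported betas are therefore invariant to affine rescaling of any raw
input, which the test-suite asserts to $10^{-8}$.

*Numerical choice — honest standard errors.* Family affiliation enters as
a fixed factor, and with sibships of size 1–3 the dummy count is of the
same order as the stratum size. `lme4`'s ML standard errors use a residual
variance that ignores the fixed-effect count and were anti-conservative by
a factor of about two in this design (measured 67% coverage of a nominal
95% CI). The engine therefore rescales fixed-effect standard errors by
$\sqrt{n/(n-p)}$ — the standard finite-sample correction — and computes
p-values from $t$ with $n-p$ degrees of freedom. Simulated coverage after
the correction is 95.5%. (`lmerTest`/Satterthwaite is not available in the
target environment.)

*Overall $R^2$* is reported as the squared correlation between fitted and
observed values (no particular $R^2$ definition is standard for these
models; with
many family dummies this quantity is optimistic, which is why it plays no
role in any test).

# Trajectory models and difference curves

Disease-time trajectories are modelled per stratum by polynomial mixed
models of order 1–3 in the centred axis (EYO, or z-scored log CSF tau),
with the same cohort covariates and site random intercept, fitted by ML.
When cognition is the outcome a first-order axis × connectivity term is
added to every candidate. The axis is centred *and scaled by its SD*
before powering — this only reparameterizes the polynomial (predictions
are invariant) but keeps the cubic term numerically tame.

*Numerical choice — AICc, not AIC, for order selection.* With the
family-saturated designs above, plain ML AIC over-selects aggressively:
in simulation it chose a cubic for *flat* control data in 60% of
replicates, because the ML log-likelihood gain of a noise parameter is
inflated by roughly $n/(n-p)$. Order selection therefore defaults to the
small-sample corrected AICc; plain AIC remains available
(`criterion = "aic"`), and the classical property that AIC penalizes each
added order by exactly 2 is tested against that option. The full-vs-reduced
comparison in the reserve models keeps plain AIC, the quantity the
published model summaries report.

**Difference curves.** Group trajectories are compared as
$(\hat{y}_{g1}(x) - \hat{y}_{g2}(x)) / \mathrm{SD}_{\mathrm{pooled}}$ on a
0.5-step grid, restricted to EYO $\in [-20, +10]$ years (outside that
range the cohorts are too sparse) or to the central 95% of the observed
tau axis. Predictions are population-level: factor dummies at sample
proportions (equivalent to averaging level-wise predictions), continuous
covariates at their means, random effects at zero, connectivity at its
mean (z = 0). Subject-level prediction averaging gives nearly identical
curves in this design and is not separately exposed.

For plots stratified by connectivity, carriers are median-split (strictly
above the median = "high"; ties go "low", a documented rule); the split is
*only* used for curves and plots — inference always uses the continuous
score.

# The synthetic-data generators

`simulate_bold_run()` builds a stated world for the image pipeline: seed
voxels share a band-limited (0.01–0.08 Hz) latent signal $s$; a chosen
fraction of grey-matter voxels equals $\rho s + \sqrt{1-\rho^2}\,
\varepsilon$ with band-limited $\varepsilon$, so the *population*
correlation with the seed is exactly $\rho$ and survives the pipeline's
own band-pass; white-matter and CSF blocks carry shared nuisance signals
that leak into grey matter; a linear drift is added everywhere; and the
motion trace is a slow random walk with Bernoulli displacement spikes
(default 1 mm, i.e. above the scrubbing cutoff). The default spike
probability is 0.02 per volume: each spike censors about five volumes
under the 1-back/2-forward rule, so 0.02 yields a typical usable run with
roughly 10% censoring. Identical `rng_seed` gives bitwise-identical
output.

`simulate_cohort()` generates phenotype tables with planted structure:

* **Cognition** follows the standardized linear moderation model
  $y = \beta_{\mathrm{sev}} z_{\mathrm{sev}} + \beta_{\mathrm{conn}}
  z_{\mathrm{conn}} + \beta_{\times} z_{\mathrm{sev}} z_{\mathrm{conn}} +
  \mathrm{gender} + u_{\mathrm{site}} + \varepsilon$ with unit total
  variance, in the affected stratum only; main effects default to the
  published coefficients and $\beta_\times$ defaults to the published
  0.269 (DIAN) / 0.285 (DELCODE).
* **Raw scale maps.** The latent is mapped affinely to the raw scale with
  group gaps placed to hit the published Cohen's d targets (RMS-of-SDs
  convention). The published raw MMSE SDs themselves (e.g. 5.1 for
  carriers) describe a heavily skewed, ceiling-compressed distribution; a
  Gaussian with that SD would put ~28% of carriers above the 30-point
  ceiling. The generator instead uses bounded-safe SDs with the same d
  targets; a [0, 30] clamp remains as a safety net that binds for under
  1% of subjects (asserted in the tests), so the linear generative
  contract stays essentially exact.
* **Biomarkers** (CSF tau, p-tau181, PiB) are moment-matched lognormals at
  the published group means/SDs — strictly positive, right-skewed, and
  exactly normalized by the pipeline's log-z transform — whose
  within-carrier deviate mixes a standardized sigmoid of EYO (inflection
  near onset) with noise, emulating the cascading-biomarker shape.
* **Amyloid status** is derived, not assigned: the CSF ratio is drawn per
  diagnostic group truncated on the correct side of the 0.1 cutoff, so
  the status/ratio invariant holds by construction.
* **Education** correlates with the connectivity latent at 0.25 by
  default.
* An optional **sigmoid cognition mode** (DIAN) replaces the linear MMSE
  model with a logistic decline over EYO whose midpoint shifts right by 3
  years per SD of connectivity — reserve expressed as a trajectory delay.
  Defaults (4 MMSE points lost, slope scale 5 years) put the standardized
  carrier deficit near $-2$ SD at EYO $+10$, the scale of the published
  trajectory figures. `sigmoid_generating_curve()` returns the implied
  ground-truth curve for recovery checks.

## What a green test does and does not establish

The generators plant linear (or logistic) signal with Gaussian noise,
independent subjects, exact lognormal biomarkers, and exchangeable sites.
Real cohort data have measurement floors/ceilings with mass *at* the
bounds, informative missingness, site-by-scanner confounding, familial
correlation of outcomes (families here only consume degrees of freedom;
no family effects are planted), and spatially structured, non-stationary
fMRI noise. A green suite therefore establishes that the estimators
recover what they claim *under the stated model*, with calibrated
uncertainty — not that the published effect sizes are correct.

Trajectory recovery in particular is asserted on curves averaged over
replicate cohorts: a single 500-subject cohort leaves 0.3–0.5 SD of
pointwise sampling noise at the sparse right edge of the EYO grid (family
dummies halve the effective sample), so the 0.25 SD recovery band is a
statement about systematic bias, not per-cohort noise.

# Degenerate inputs and tie-breaks

* Correlations of zero-variance voxels are treated as 0 (excluded from the
  positive mean); a zero-variance *seed* is an error.
* A subject over the censoring cut is refused by the scoring function with
  a QC message; the batch pipeline emits `NA` rows instead.
* Aliased family-affiliation dummies are dropped with a warning; any other
  rank deficiency is an error naming the aliased terms. A single-site
  table falls back to a fixed-intercept model with a warning.
* Median-split ties go to "low"; `fd[1] = 0` by definition; grey-matter
  probability exactly 0.3 is excluded (strict inequality).
* Log-z transforms refuse non-positive values and zero variance; whether
  they are computed per stratum (the default: each model standardizes
  within its analysis sample) or per cohort is a documented choice — the
  education association is also reported one-sided because the published
  trend-level p is consistent with a directional test whose sidedness the
  source does not state.

# Known limitations

* Cross-sectional only: trajectories are between-subject curves over
  disease time, not within-subject change.
* Upstream spatial preprocessing (segmentation, normalization,
  realignment, slice-time correction) is out of scope; images are assumed
  to be in a common space and motion parameters are consumed as given.
* The NIfTI-1 reader/writer is deliberately minimal (single-file, sform
  affine, common datatypes) — enough for the pipeline's own formats, not a
  general neuroimaging I/O layer.
* p-values use the $t$ approximation with $n-p$ degrees of freedom; no
  Satterthwaite/Kenward–Roger machinery is available in the target
  environment.
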