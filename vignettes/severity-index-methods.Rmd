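---
title: "Methods: an OPLS-DA severity index for brain atrophy patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an OPLS-DA severity index for brain atrophy patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevindex)
```

## The problem

Subjective cognitive decline (SCD) — cognitive complaints without objective
deficit — carries an elevated risk of progression to mild cognitive
impairment (MCI) and dementia. Structural MRI morphometry offers a cheap,
non-invasive neurodegeneration marker, and the *pattern* of regional
atrophy is more informative than any single structure. A standard design
trains a discriminant model separating cognitively normal (CN) elderly
from patients with manifest Alzheimer-type dementia and projects at-risk
subjects onto it, reading the predicted class value as a continuous
"disease severity index". The question this package operationalizes is
whether a model trained on an *earlier* disease stage — amyloid-positive
amnestic MCI (aMCI), whose atrophy pattern is similar but milder — ranks
SCD subjects' progression risk better than the dementia-trained model.
`sevindex` implements the full workflow — preprocessing, OPLS-DA model
fitting, cutoff derivation, minimal-atrophy pruning, classification and
longitudinal evaluation — together with a synthetic cohort generator so
that every stage is testable without access to clinical data.

## The model

### Input panel and preprocessing

The feature panel is 51 bilaterally averaged FreeSurfer-style measures: 34
cortical thicknesses (mm, Desikan–Killiany parcels) and 17 subcortical
volumes (mm³). Preprocessing runs in a fixed order, each step fit on a
designated reference set and then frozen:

1. **Hemisphere averaging** — `(left + right) / 2` per region.
2. **Head-size adjustment** — per volumetric feature, the OLS slope on
   estimated total intracranial volume (eTIV) is fitted over the matched
   amyloid-negative CN training subjects and subtracted:
   `v' = v − b (eTIV − mean eTIV)`. Thickness features are exempt, since
   thickness does not scale with head size. The reference choice mirrors
   the role of the CN group as the normative anchor; it is configurable.
3. **Normative age detrending** — per feature, an OLS slope on age fitted
   within the full CN pool, subtracted from *every* subject regardless of
   group. The assumption is that feature change within CN reflects aging,
   so removing it leaves disease-related deficits (which are
   age-independent in the model) untouched in expectation.
4. **Unit-variance scaling and mean centering** — fitted on the matched
   training set; projected subjects are scaled with the stored training
   statistics. Scaling is last because it must see the nuisance-adjusted
   data.

A within-group PCA screen (`pca_outlier_screen`) flags subjects beyond 4
SD on either of the first two components; flags are reported rather than
silently removed. Whether PCA runs on standardized or raw features is
exposed as a flag (default: standardized, the scale-free choice for a
panel mixing mm and mm³).

### Control matching

Each disease training group receives one-to-one age- and sex-matched CN
controls: exact on sex, and within sex the assignment minimizing total
absolute age difference. Because ages live on a line, the optimum pairs
age-sorted cases with an age-sorted control subset without crossings; we
compute it exactly by dynamic programming with deterministic id
tie-breaks. (A greedy nearest-age pass was considered and rejected: it can
be strictly suboptimal — cases {1, 2} against pool {0, 1.4} is a
two-line counterexample — while the DP is just as reproducible.)

### OPLS-DA

With the class coding CN = 0 / disease = 1 and `y_c` the centered coding,
the single-response OPLS of Trygg & Wold splits X-variation into a
predictive part and parts orthogonal to the response:

* predictive weights `w ∝ X'y_c`, normalized;
* for each orthogonal component: `p = X't/(t't)` with `t = Xw`;
  `w_o ∝ p − (w'p)w`, normalized; `t_o = X w_o`; `p_o = X't_o/(t_o't_o)`;
  deflate `X ← X − t_o p_o'`;
* finally `t1 = Xw` on the deflated matrix and the scalar regression
  `b = t1'y_c / (t1't1)`.

The severity index of any subject is `ȳ + b·t`, after the stored
orthogonal components are removed from the subject's (scaled) profile. By
construction `t_o ⊥ t1` and `t_o ⊥ y_c` exactly, and the X sum of squares
decomposes conservatively into predictive + orthogonal + residual parts;
the test suite asserts all three to 1e-8 and the `n_ortho = 0` limit
against an independently coded one-component PLS1 oracle to 1e-10. The
default is **one** orthogonal component; there is no automatic component
selection, both deliberate fidelity choices — the reference workflow this
reimplements used a single orthogonal component throughout.

### Cross-validation, permutation

Model quality is summarized by `R²` (goodness of fit of the full model)
and `Q² = 1 − PRESS/SS` under stratified 10-fold cross-validation, with
the total sum of squares about the full-sample class-coding mean
(SIMCA-style convention). By the usual rule of thumb `Q² > 0.05` is
significant and `Q² > 0.5` a good model. Because preprocessing is part of
the model, the bundle-level cross-validation refits the eTIV slopes, the
age detrend and the scaler inside every training fold — the honest `Q²`;
`k = n` is special-cased to deterministic leave-one-out. The permutation
comparison refits the full pipeline under label shuffles and reports
`p = (1 + #{perm ≥ observed}) / (1 + n_perm)`.

### Cutoff and classification

The decision cutoff is the point of maximum separation between the
Gaussian-kernel-smoothed cumulative distribution functions of the CN and
disease training severity scores. The smoothed CDFs are evaluated on a
2001-point grid spanning the pooled scores ± 3 bandwidths, augmented with
the midpoints between adjacent pooled scores so that maximizing plateaus
narrower than one grid step are never missed; the default bandwidth is
Silverman's rule on the pooled scores. A plateau of maximizers is resolved
at the midpoint of the contiguous run containing the argmax. As the
bandwidth shrinks, the cutoff converges to the location of the two-sample
Kolmogorov–Smirnov statistic (tested against a brute-force ECDF sweep).
Classification is `severity ≥ cutoff → disease-like`, with boundary
equality going to disease-like — an arbitrary but documented rule needed
for bit-exact reproducibility. Whether the cutoff derives from fitted or
cross-validated training scores is configurable; the default uses fitted
scores, matching a workflow in which all training patients are projected
through the final model.

### Minimal-atrophy pruning

A known phenotype of clinically manifest disease shows little measurable
atrophy; such cases add label noise to an atrophy-pattern classifier.
After the first fit, disease-group training subjects whose severity falls
below the cutoff (projected CN-like) are removed and the whole bundle —
matching, preprocessing, OPLS, cutoff — is refitted. One pass is the
default; the pass count is configurable with the removal log retained.

## Longitudinal evaluation

Progression is defined from yearly Global Deterioration Scale (GDS)
scores: the event is the first visit with GDS ≥ 3, censoring at the last
observed visit. Evaluation of a baseline classification against these
events comprises:

* **Confusion metrics** — positive = disease-like at baseline;
  condition-positive = progression at any observed time within the 8-year
  horizon (no inverse-probability weighting — this replicates the plain
  count arithmetic of the reference workflow).
* **ROC/AUC** — threshold sweep over the severity index (through `pROC`);
  the trapezoid AUC equals the normalized Mann–Whitney statistic,
  asserted exactly in tests.
* **Paired DeLong comparison** of the two flavors' AUCs (structural
  components, two-sided normal p, no continuity correction); identical
  rankings degenerate to p = 1 with a warning.
* **Kaplan–Meier / log-rank / Cox** — through the `survival` package,
  with Efron tie handling in the Cox model because the yearly visit grid
  produces heavily tied event times (Breslow would be slightly biased
  here). The Cox model reports classification, amyloid status and sex
  jointly; the oracle test pins the partial-likelihood maximizer to a
  grid search at 1e-4.

## The synthetic cohort generator

The generator emulates an amyloid-stratified memory-clinic cohort with
groups CN (n = 220, amyloid-negative), aMCI (n = 106, amyloid-positive),
AD-dementia (n = 39) and SCD (n = 139), ages ~60–90 with group means near
70–72, eTIV ~ N(1.565·10⁶, 1.45·10⁵) mm³.

**Latent severity.** Each subject carries a hidden severity `s ∈ [0, 1]`:
CN ~ Beta(1.2, 10) (mean 0.11 — normal elderly carry some
neurodegeneration, which also keeps within-CN severity ranks meaningful),
aMCI ~ Beta(11, 9) (mean 0.55), dementia ~ Beta(16, 4) (mean 0.8). The
SCD group is a 50/50 mixture of CN-like subjects and a milder "prodromal"
component ~ Beta(4, 8.5) (mean 0.32, i.e. about two-thirds of the way
from CN to aMCI in hippocampal terms, matching the intermediate
hippocampal volumes reported for SCD progressors). A configurable 14% of
aMCI subjects are the minimal-atrophy phenotype: they keep the aMCI label
but draw severity from the CN distribution.

**Staged regional trajectories.** Region `r` loses
`effect_r · g_r(s)` of its healthy reference mean, with
`g_r(s) = min(1, max(0, (s − onset_r)/span_r))`. Medial-temporal regions
(hippocampus, entorhinal, amygdala, inferior temporal, parahippocampal,
fusiform, middle temporal, temporal pole, accumbens) start at onset 0 and
saturate at s = 0.55 (atrophy floors early); temporo-parietal association
regions onset at 0.45; frontal, sensorimotor, occipital, striatal and
callosal regions at 0.60. This is the canonical medial-temporal-outward
spread of Alzheimer-type atrophy, and it is load-bearing: it is what makes
the dementia-trained and aMCI-trained models learn genuinely different
loading patterns (the dementia contrast recruits late neocortical regions
that carry no signal at SCD-level severities). With a single unstaged
severity axis the two flavors would learn the same weight vector up to
noise and no flavor could dominate in AUC.

**Calibration.** The hippocampal and entorhinal effect sizes and reference
means are solved in closed form so that simulated CN and amyloid-positive
aMCI group means land at 3852.8 mm³ / 3068.3 mm³ and 2.95 mm / 2.37 mm —
representative published values for such cohorts — given the severity
distributions above (tested to within two standard errors at group size
91). Remaining effect sizes are fixed so per-region discriminabilities at
full expression are a realistic 0.3–2 pooled SD, maximal in the medial
temporal lobe. Measurement noise is 0.7 of each region's reference SD,
which keeps the simulated CN hippocampal SD near 446 mm³ (reference
431 mm³) once age, head-size and severity variance are added. Ventricular
effect sizes are 0: disease-driven ventricular *expansion* does not fit a
fraction-of-mean-lost model, and the invariant that effects are
non-negative and medial-temporal-maximal is kept instead.

**Progression.** Time to progression follows a Weibull-baseline
proportional-hazards model,
`S(t) = exp(−h₀ t^k exp(β_s s + β_a amyloid))` with h₀ = 0.038, k = 0.45,
β_s = 4.5, β_a = log(3.4), discretized to the first yearly visit with
GDS ≥ 3; GDS trajectories are non-decreasing (progression is absorbing).
Non-progressors are censored via a 4%/year dropout over the 8-year visit
grid — the censoring mechanism is a modeling choice (real attrition
structure is rarely published) and is exposed in the spec. These values
put ~34% of SCD subjects past GDS 3 within 8 years, two-thirds of events
in the first two years, and an aMCI-flavor progression AUC near 0.71.

**What passing tests do and do not show.** The generator is a
one-dimensional severity model with stage-dependent topography, Gaussian
noise, independent regions given (s, age, eTIV), and no missing data, no
scanner/site effects, no comorbid pathologies, and no mortality process.
Tests passing on it demonstrate the *pipeline's* correctness and the
qualitative stage-matching mechanism; they say nothing about effect sizes
achievable on real cohorts.

## Numerical choices and degenerate inputs

* OPLS requires both classes, n ≥ 4, and errors when the requested
  orthogonal component count exceeds the orthogonal rank of X (weight
  residual below 1e-12 of norm).
* Zero-SD features, zero eTIV/age variance in a reference set, missing
  hemisphere columns, empty score sets and identical constant score sets
  are all hard errors naming the offending feature/region.
* Cox fitting uses `survival::coxph` (Efron ties, tolerance 1e-8, max 50
  iterations); suspected monotone likelihood (|coef| > 15 or non-finite
  SE) is surfaced as an explicit warning.
* The cross-validation fold assignment, the simulator and the pipeline
  all derive their seeds deterministically from a single global seed
  (`seed × 101 + stage offset`), so a manifest's configuration reproduces
  every output bit for bit.

## Problem sizes used in the shipped checks

The packaged tests run the full double-flavor workflow over 20 seeds at
the default cohort sizes (504 subjects), 100 pure-noise cross-validation
replicates at 60 × 51, 200 Cox-recovery replicates at n = 600, 1000
DeLong null simulations at n = 100, and 50-instance oracle sweeps for the
cutoff; the whole suite completes in well under a minute on one core.
These sizes were chosen so that Monte-Carlo error is small relative to
each asserted margin.

## Known limitations

* Single-response, single-predictive-component OPLS only; no multi-class
  variant, no kernel OPLS, no automatic component selection.
* One cutoff strategy (maximum CDF separation); no Youden index or
  fixed-specificity alternatives.
* The generator's SCD mixture and censoring distribution are stylized;
  hazards are proportional by construction, so the Cox model is
  well-specified in simulation — real data offer no such guarantee.
* No competing risks: mortality is absent from the generator and the
  evaluation.

## A minimal end-to-end run

```{r, eval = FALSE}
library(sevindex)
cfg <- run_config(cohort = cohort_spec(), seed = 1)
man <- run_pipeline(cfg)
man
summary(man$models[["aMCI-based"]])
plot(man$models[["aMCI-based"]])      # smoothed training CDFs + cutoff
plot(man$evaluation[["aMCI-based"]]$km)
```
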