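---
title: "Methods: within- and between-lesion MTR treatment-effect analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within- and between-lesion MTR treatment-effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Magnetisation transfer ratio (MTR) is a semi-quantitative MRI index that
tracks myelin density; in chronic multiple-sclerosis lesions an increase
in MTR between two timepoints is conventionally read as remyelination.
MTR is computed voxelwise from a saturated/unsaturated acquisition pair,

\[ \mathrm{MTR} = 100 \cdot \frac{\mathrm{MT_{off}} - \mathrm{MT_{on}}}{\mathrm{MT_{off}}} \]

in percentage units (pu). Remyelination is heterogeneous: it differs
between grey-matter (GM) and white-matter (WM) lesions, across a
lesion's spatial components, with proximity to CSF surfaces, and with
the degree of baseline damage. This package implements a three-level
analysis of treatment effects on 6-month MTR change in a two-arm trial
— whole lesions, lesion components/segments, and individual lesional
voxels — plus the sample-size machinery needed to design follow-up
trials around the most sensitive metrics.

## The estimator

Every analysis level uses the same baseline-adjusted linear mixed model.
For unit $i$ (a lesion, component, segment or voxel) in patient $p$:

\[
y^{\mathrm{m6}}_{i} = \beta_0 + \tau\,\mathrm{arm}_p + \gamma\, y^{\mathrm{m0}}_{i}
 + \mathbf{x}_p'\boldsymbol\delta + b_p + (b_{\ell(i)}) + \varepsilon_i
\]

where $\mathbf{x}_p$ are the four binary minimisation covariates (age
band, gender, centre, EDSS band), $b_p$ is a patient random intercept,
and $b_{\ell(i)}$ a lesion random intercept included whenever units are
nested within lesions (components, segments, voxels). $\tau$ is the
adjusted active-minus-placebo difference in pu. Interaction analyses add
subgroup main effects and arm-by-subgroup terms; per-subgroup
differences are linear contrasts and the interaction p-value is the
joint test that all arm-by-subgroup terms vanish. Because patients can
contribute units to several subgroups, interaction contrasts have a
strong within-patient component and are considerably better powered
than the purely between-patient main treatment contrast.

Estimation is REML via `lme4`. Inference uses Satterthwaite
denominator-degree-of-freedom t and F statistics (`lmerTest`) rather
than a plain normal approximation: the arm contrast is estimated
between patients, so in a cohort of a few dozen patients its effective
df is small and normal-based Wald tests are anticonservative — with 12
patients they inflate the type-I error of the arm test to roughly twice
the nominal level, which the simulation studies in
`tests/testthat/test-acceptance.R` would flag. At voxel-level unit
counts the Satterthwaite df are large and the inference coincides with
the normal approximation.

Degenerate fits degrade explicitly, with each step logged in the
returned object's `notes`: a boundary (zero) variance component
triggers a refit of the reduced model; a failed REML fit is retried
with ML; when no grouping structure remains the model collapses to OLS.
Covariates that are constant in a subset are dropped rather than left
to break the design matrix.

## Geometric decomposition

* **Components.** Each lesion is split into a *core* (one-voxel-layer
  morphological erosion) and a *rim* (the remainder); three concentric
  perilesional *cuffs* of normal-appearing tissue are built by
  successive one-voxel-layer dilations. Cuffs exclude lesional and CSF
  voxels, and any voxel reached by the cuffs of two or more lesions is
  excluded from all of them (the exclusion is applied per voxel across
  all three rings jointly, after all dilations). Thin lesions may have
  an empty core; they simply contribute no core-level unit.
* **Connectivity.** "One voxel layer" is read conservatively as the
  6-connected (face-adjacent) structuring element, configurable to 26;
  component labelling uses the same connectivity as the morphology.
  Voxels outside the grid count as background.
* **Outer-layer stripping.** Pure-WM voxel- and segment-level analyses
  drop each lesion's outermost layer (equal to the core operator) to
  mitigate partial volume effects; CGM/DGM lesions are too small to
  survive stripping, so it is not applied there.
* **Bands.** WM and deep GM are banded together by exact Euclidean
  distance from the ventricular CSF surface: the per-subject distance
  range is split into 10 equal-width bins, bins 1 and 10 are excluded
  (partial volume at both surfaces), and the survivors are renumbered
  1–8 with band 1 nearest the ventricles. Equal-width binning is the
  reproducible, monotone choice where no rule is otherwise fixed; an
  equal-count scheme is available in the configuration. The cortical
  ribbon is split at the per-subject median depth from the outer CSF
  into an outer band 2 and inner band 1. Lesions get the band holding
  the plurality of their banded voxels, ties breaking toward the
  nearer-CSF band. DGM bands are computed but band-stratified DGM
  analyses are not run (DGM lesion counts cannot support them).
* **Strata.** Baseline-MTR and baseline-T1 cutpoints are cohort-level
  and tissue-specific, computed from baseline values only: quartiles
  for WM lesions, a median split for CGM/DGM lesions at the whole-lesion
  level, and quartiles for all voxel- and segment-level analyses.
  Quantiles interpolate linearly between order statistics (type 7); a
  value equal to a cutpoint goes to the lower stratum; all-tied inputs
  collapse into stratum 1 with a warning. T1 "intensity" is the raw
  non-quantitative T1-weighted value pooled across the cohort; a
  per-subject normalisation hook exists but is off by default, since
  within a single-scanner-model cohort raw pooling is defensible and
  any rescaling choice would be arbitrary.

## The synthetic trial generator

Real trial imaging is not redistributable, so validation runs on a
generator that reproduces the statistical structure the analysis
assumes, on a schematic atlas:

* **Atlas.** Nested ellipsoidal shells — ventricular CSF, deep GM,
  WM bulk, a cortical ribbon thick enough for two depth bands, an
  outer-CSF rind, and a small cerebellar GM blob. This is deliberately
  not anatomical: the analysis consumes only tissue labels, two CSF
  surfaces and distances.
* **Voxel model.** Baseline = tissue mean − deficit profile + patient
  intercept + lesion intercept + voxel noise; follow-up = the same
  systematic part + arm × planted effect + new independent voxel noise.
  The deficit is maximal (default 8 pu) at the lesion's deepest layer
  and shades outward by a per-layer gradient, giving lesional voxels
  lower MTR than surrounding tissue and a within-lesion depth gradient.
  The T1-weighted volume is a linear transform of baseline MTR plus
  independent noise, so T1-hypointensity tracks damage.
* **Planted effects.** A tissue-level effect (pu) times optional
  multipliers by baseline-MTR quartile, distance band and core/rim
  component. The labels used for planting are computed with the same
  operators the analysis uses (the cohort quartiles pool all lesional
  voxels per tissue, which differs slightly from the pure-lesion
  stripped pool the analysis stratifies on — a small, deliberate
  attenuation rather than a circular reuse of the analysis pipeline).
  Placebo subjects carry an identically-zero truth volume.
* **Randomisation.** The four binary covariates are Bernoulli(1/2);
  arms are assigned by stratified alternation along a single randomly
  started alternating sequence ordered by minimisation stratum, giving
  ±1 balance within every stratum and overall — the balance property
  that the covariate adjustment consumes, without simulating a full
  minimisation algorithm.
* **Correlation calibration.** Because the two timepoints share their
  systematic-plus-intercept signal $S$ and differ only by independent
  voxel noise, the pooled placebo baseline/follow-up lesional-voxel
  Pearson correlation is exactly $r = \mathrm{var}(S) /
  (\mathrm{var}(S) + \sigma_v^2)$. `calibrate_sigma_voxel()` inverts
  this to hit a target (default 0.85, the mid-range of published
  longitudinal lesional-voxel correlations, 0.74–0.96);
  `predicted_voxel_correlation()` provides the closed-form check.
* **Defaults.** 49 patients on a 48³ grid (unit 1 mm spacing recorded
  in headers); per-patient Poisson lesion counts with a WM-dominated
  mix (8 WM, 5 mixed, 2 cortical, 1 deep GM; cerebellar lesions off by
  default, as real analyses exclude their small numbers); ellipsoid
  semi-axes 1.5–3.5 voxels; tissue MTR means around 32–38 pu; patient /
  lesion / voxel SDs 0.5 / 0.75 / 1.1 pu. The per-patient lesion load
  is far below a real cohort's (a schematic 48³ atlas cannot hold ~65
  non-overlapping lesions); the variance decomposition across
  patient/lesion/voxel levels is a free choice, not an estimate, since
  no published decomposition exists to copy.

What the generator does **not** emulate: MRI physics (bias fields,
motion, registration error), anisotropic acquisitions, longitudinal
atrophy, lesion contouring error, spatially correlated noise, and
anatomical geometry. Passing tests therefore demonstrate that the
pipeline recovers what it assumes — planted effects under the stated
noise model — not that it is robust to real-world artefacts.

## Validation study sizes

Simulation studies use a reduced 12-patient 32³ profile
(`scaled_trial_config()`): type-I error and CI coverage of the
lesion-level model over 200 replicate trials, and recovery of a planted
GM 1.4 pu / WM 0.2 pu contrast. The voxel-level interaction study uses
a voxel-rich variant (9 WM lesions per patient, semi-axes 2–4,
~2,300 stripped WM voxels per cohort): a 3-df joint-test power
calculation (noncentrality $\lambda \approx m \sum_q c_q^2 / 4s^2$ for
per-cell count $m$, centred quartile effects $c_q$, residual SD $s$)
shows that ~1,000 voxels cannot support majority detection of a
0.7→0.05 pu quartile gradient, while ~2,500 voxels give ~80% power;
the study is sized accordingly. Voxel tables can be deterministically
subsampled (`cap`, default 20,000) because the estimates, not
exhaustive enumeration, are the contract.

## Sample-size planning

For future trials the package sizes an ANCOVA comparison of
patient-averaged lesional MTR (patients, not lesions, are randomised):

\[ n_{\text{per arm}} = \left\lceil \frac{2 (z_{1-\alpha/2} + z_{\text{power}})^2 \sigma^2 (1-\rho^2)}{\Delta^2} \right\rceil \]

with $\sigma$ the placebo follow-up SD and $\rho$ the placebo
baseline/follow-up correlation of the metric; totals are twice the
per-arm ceiling (per-arm rounding reproduces even published totals),
and an optional +1-per-arm t-correction is recorded in the output. The
biological ceiling on $\Delta$ is the lesion-to-NAWM MTR gap times an
ex-vivo recoverable fraction — `ceiling_effect(5.92, 0.5)` gives the
canonical 2.96 pu maximum. Patients with no qualifying lesion are
excluded and counted, a practical caveat for GM-lesion-based outcomes.

## Known limitations

* The atlas and lesion geometry are schematic; distance-band geometry
  in particular is cleaner than cortical anatomy ever is.
* Whether real cuffs should cross tissue boundaries is unknowable from
  published descriptions; the default excludes only CSF, with
  `restrict_to_tissue` to confine cuffs to the lesion's own tissue.
* Cohort-level banding/stratification choices (per-subject equal-width
  bands, cohort-pooled raw T1) are reproducible defaults for decisions
  that real pipelines make in scanner-specific ways.
* Voxel-level models use two nested random intercepts
  (patient/lesion); no richer within-lesion covariance is attempted.
* No multiplicity correction is applied by default (matching the
  exploratory framing); `p.adjust` on the report's p columns is the
  one-liner for users who want Benjamini–Hochberg.
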