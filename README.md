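# lesionmtr

Within- and between-lesion treatment-effect analysis of magnetisation
transfer ratio (MTR) for two-arm remyelination trials in multiple
sclerosis, plus sample-size planning for future trials.

Remyelination is heterogeneous: grey-matter (GM) lesions respond
differently from white-matter (WM) lesions, lesion rims differ from
cores, and effects vary with distance from CSF and with baseline
damage. This package implements the full analysis chain needed to see
that heterogeneity, for imaging statisticians and trial methodologists:

* **MTR maps** — `MTR = 100 * (MToff − MTon) / MToff` (percentage
  units, pu) and follow-up minus baseline change maps.
* **Lesion geometry** — connected-component labelling, tissue
  classification (pure WM / cortical GM / deep GM / cerebellar /
  mixed), core/rim split by one-voxel-layer 3D erosion, three
  perilesional cuffs by successive dilations with the
  "no voxel in two lesions' cuffs" exclusion rule, outer-layer
  stripping for partial-volume control.
* **CSF-distance bands** — exact Euclidean distance transforms; 10
  per-subject WM/deep-GM bands from the ventricular surface (bands 1
  and 10 excluded, survivors renumbered 1–8) and 2 cortical depth
  bands from the outer CSF surface.
* **Stratification** — cohort-level, tissue-specific baseline-MTR and
  baseline-T1 quartiles (or median splits), applied at lesion, segment
  and voxel level.
* **Treatment effects** — baseline-adjusted linear mixed models with
  patient and lesion random intercepts:
  `m6 ~ arm + m0 + age_band + gender + centre + edss_band +
  (1|patient) [+ (1|lesion)]`, REML with Satterthwaite t/F inference,
  per-subgroup contrasts and joint treatment-by-subgroup interaction
  tests, assembled into a full report grid by `run_analysis_suite()`.
* **Trial design** — remyelination ceiling (`gap × fraction`) and
  ANCOVA sample sizes
  `n/arm = ⌈2 (z₁₋α/₂ + z_power)² σ² (1 − ρ²) / Δ²⌉` from
  patient-averaged lesional metrics.
* **Synthetic trials** — a generator with plantable ground-truth
  effects (by tissue, baseline quartile, band and component), shared
  patient/lesion intercepts and calibratable voxel noise, used by the
  validation suite because trial imaging is not public.

## Worked example

Simulate a reduced 12-patient trial (default planted effects: 1.4 pu
in pure GM lesions, 0.2 pu in pure WM lesions), then estimate the
adjusted whole-lesion treatment differences:

```r
library(lesionmtr)
trial <- simulate_trial(scaled_trial_config(seed = 7))
trial
#> mtr_trial: 12 patients (6 active / 6 placebo), 123 lesions, grid 32x32x32

lt <- lesion_unit_table(trial)
fit_adjusted_difference(lt[lt$tissue %in% c("cgm", "dgm"), ])
#> Adjusted active-placebo difference: 1.157 pu (95% CI 0.751 to 1.563), p = 0.00028
#>   units: 13 active / 20 placebo; model: lmer-reml with (1 | patient_id)

fit_adjusted_difference(lt[lt$tissue == "wm", ])
#> Adjusted active-placebo difference: 0.138 pu (95% CI 0.014 to 0.262), p = 0.0303
#>   units: 32 active / 33 placebo; model: ols
```

The GM estimate recovers the planted 1.4 pu effect (within one CI
half-width); the WM estimate is an order of magnitude smaller — the
GM-positive / WM-near-null pattern the three-level analysis is built
to expose. `run_analysis_suite(trial)` produces the full grid (levels
× tissues × stratifying factors, each with subgroup estimates and
interaction p-values) as a data frame plus a rendered text report.

Sample-size planning for a future trial using a GM-lesion metric with
placebo follow-up SD 2.2 pu and baseline/follow-up correlation 0.7:

```r
ceiling_effect(5.92, 0.5)   # biological ceiling on the effect, pu
#> [1] 2.96
power_table(sd_followup = 2.2, rho = 0.7)
#>   delta total_n_power_80 total_n_power_90
#> 1   1.3               46               62
#> 2   1.4               40               54
#> 3   1.5               36               48
#> 4   1.6               32               42
#> 5   1.7               28               36
#> 6   1.8               24               34
```

Totals fall from 46 to 24 participants as the detectable effect grows
from 44% to 61% of the 2.96 pu ceiling — whole-GM-lesion metrics keep
remyelination trials small.

A thin CLI covers the same stages
(`Rscript inst/cli/lesionmtr.R simulate|mtr|decompose|bands|power|power-table|run-all ...`),
and `run_pipeline()` chains them with YAML configuration and
provenance-stamped CSV outputs.

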