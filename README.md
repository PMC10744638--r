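# cannmrm

Targeted LC-MS/MS (multiple-reaction-monitoring) data analysis for
cannabinoid metabolites in whole blood, with a synthetic-data generator for
end-to-end validation.

## The problem

Hexahydrocannabinol metabolites complicate forensic cannabinoid analysis in
two ways. First, 11-nor-9-carboxy-HHC (HHC-COOH) and 11-hydroxy-HHC
(11-OH-HHC) appear in blood both after HHC intake and as reductive
metabolites of ordinary Δ⁹-THC, so their presence alone cannot prove HHC
use. Second, HHC-COOH is isobaric with the M+2 isotopologue of THC-COOH:
blood rich in THC-COOH shows a ¹³C₂ peak on the HHC-COOH channels
(m/z 347.22 → 193.12 / 123.04) eluting *between* the two HHC-COOH epimers,
which a method with insufficient chromatographic resolution will misread as
HHC-COOH.

`cannmrm` implements the data-analysis layer such an assay needs, for
toxicologists and method developers who want the logic tested and
inspectable rather than buried in vendor software:

* **Identification** — retention time ±0.02 min and quantifier/qualifier
  ion ratio ±20% relative to a processed standard, per-analyte area
  cutoffs, internal-standard recovery (< 50% excludes) and a Δ⁸-THC screen.
* **Quantification** — response factors `RF = A_analyte / A_IS`, weighted
  (1/x) six-point calibration (0.53–53 ng/mL) with back-calculation
  acceptance, and semi-quantification of analytes lacking reference
  material through a surrogate's curve and a correction factor
  `CF = mean_d(RF_surrogate,d / RF_target,d)` from replicate-day standards,
  so that `conc = curve⁻¹(RF_target × CF)`.
* **Isotopologue interference** — exact multinomial convolution of
  heavy-isotope distributions over a molecular formula, and a
  hypergeometric fragment-retention model
  `P = C(n_total − n_frag, k) / C(n_total, k)` for the probability that a
  ¹³C_k precursor still yields the unlabelled product ion.
* **Peak integration** — windowed, baseline-subtracted trapezoidal
  integration with valley splitting for epimer pairs on shared channels.
* **Reporting** — cohort grouping by THC/HHC status, prevalence and
  median/maximum summaries, the relative-median statistic, and qualitative
  (+ / (+) / −) call matrices for liver-microsome incubation time series
  with impurity masking.
* **Synthetic data** — cohorts, calibration/correction/reference standards
  and incubation series with full ground truth, so every statistic above is
  validated by parameter recovery.

## Worked example

```r
library(cannmrm)
library(dplyr)

panel <- default_panel()

# standards: identification reference, calibration curves, correction factors
ref <- reference_from_standards(
  simulate_reference_standards(panel, seed = 3)$chromatograms, panel)
cal <- fit_panel_calibrations(simulate_calibration_runs(panel, seed = 4), panel)
cfs <- panel_correction_factors(simulate_correction_runs(panel, seed = 5), panel)

cal[["THC-COOH"]]
#> <calibration_model> THC-COOH: response = 0.04029 * conc + -0.00356 (1/x weighting, LLOQ 1.06 ng/mL)
cfs[["9R-HHC-COOH"]]
#> <correction_factor> 9R-HHC-COOH -> THC-COOH: 1.314 (CV 11.7%, 6 days)
```

The correction factor sits at the ratio of the generator's response slopes
(2000/1500 ≈ 1.33): 9R-HHC-COOH responses can be read off THC-COOH's curve
after scaling. Now a small cohort, end to end:

```r
sim <- simulate_cohort(cohort_sim_config(n_cases = 60, seed = 6), panel)
res <- process_cohort(sim$chromatograms, panel, ref, cal, cfs)
res
#> <cohort_result> 60 cases (1 excluded); groups: A:27 B:1 C:31

included <- semi_join(res$records, filter(res$validity, !excluded), "case_id")
est <- included |> inner_join(res$groups, "case_id") |> filter(group == "A")
s <- concentration_summary(est)
filter(s, analyte %in% c("D9-THC", "THC-COOH", "9R-HHC-COOH"))
#> # A tibble: 3 × 5
#>   group analyte         n median   max
#>   <chr> <chr>       <int>  <dbl> <dbl>
#> 1 A     9R-HHC-COOH    27   1.11  17.6
#> 2 A     D9-THC         27   3.07  28.4
#> 3 A     THC-COOH       27  29.5  109.
relative_median(s, "9R-HHC-COOH", "THC-COOH")
#> [1] 4
```

One case was excluded (internal-standard recovery below 50%). Group A
(THC-positive, HHC-negative) medians land near the generator's targets
(2.8 and 21 ng/mL) within the sampling noise of 27 cases; the 9R-HHC-COOH
median is an estimate through THC-COOH's borrowed curve. Note the grouping
uses *confirmed* detections: truth-positive cases whose THC concentration
sits below the identification thresholds land in group C, which is why
group A is smaller than the configured 72%.

The interference logic in isolation:

```r
# probability that THC-COOH (C21H28O4) carries a +2 Da isotopologue ...
isotopologue_distribution("C21H28O4", max_shift = 2)[["2"]]
#> [1] 0.02667661
# ... and that both labels miss the 14-carbon m/z 193 fragment
fragment_label_avoidance(21, 14, 2)
#> [1] 0.1
```

## Package layout

| Area | Functions |
|---|---|
| Panel | `default_panel()`, `read_panel()` / `write_panel()` |
| Isotopes | `parse_formula()`, `isotopologue_distribution()`, `fragment_label_avoidance()`, `interference_area()` |
| Simulation | `cohort_sim_config()`, `simulate_cohort()`, `simulate_calibration_runs()`, `simulate_correction_runs()`, `simulate_reference_standards()`, `simulate_incubation_series()` |
| Peaks | `find_peak()`, `ion_ratio()`, `epimer_pair_resolve()`, `process_injection()` |
| Identification | `reference_from_standards()`, `apply_identification()`, `sample_exclusions()`, `detect_case()` |
| Quantification | `response_factor()`, `fit_calibration()`, `correction_factor()`, `estimate_concentration()` |
| Pipeline | `fit_panel_calibrations()`, `panel_correction_factors()`, `process_cohort()`, `incubation_detections()` |
| Reporting | `group_cases()`, `prevalence()`, `cohort_prevalence()`, `concentration_summary()`, `relative_median()`, `incubation_calls()` |

Fitted calibration models support `tidy()`, `glance()` and `autoplot()`;
chromatograms plot with `plot_chromatograms()`. The methods vignette
(`vignettes/cannmrm-methods.Rmd`) documents the models, parameter choices
and known limitations.
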