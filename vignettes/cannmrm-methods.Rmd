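---
title: "Methods: targeted MRM quantification of cannabinoid metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted MRM quantification of cannabinoid metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannmrm)
```

## Scope

`cannmrm` re-implements, as tested and reusable code, the data-analysis
layer of a targeted LC-MS/MS (multiple-reaction-monitoring) assay for
Delta-9-THC, HHC and their 11-hydroxy and 11-nor-9-carboxy metabolites in
whole blood: peak identification rules, internal-standard quantification,
correction-factor semi-quantification for analytes lacking reference
material, isotopologue-interference handling, cohort grouping and
summaries, and qualitative detection calls for human-liver-microsome
incubation series. Everything upstream of the chromatogram — extraction
chemistry, instrument control, vendor file formats — is out of scope. The
pipeline is exercised end to end on synthetic MRM chromatograms with
recorded ground truth, so every downstream statistic can be checked by
parameter recovery.

## The analyte panel

The panel (`default_panel()`) monitors two transitions per analyte
(quantifier and qualifier) and one per deuterated internal standard.
Epimer pairs — 9R/9S-HHC, 9R/9S-11-OH-HHC, 9R/9S-HHC-COOH — share their
precursor/product channels and are distinguished chromatographically:
the HHC-COOH epimers elute at 1.80 and 1.97 min on either side of
THC-COOH (1.90 min), and the 11-OH-HHC pair (1.86/1.91 min) is only
marginally separated. The low-mass product ion of each pair is the
quantifier; `swap_quantifier = TRUE` flips the assignment if a method
revision reassigns it.

Identification follows forensic practice: retention time within
±0.02 min of a processed standard, quantifier/qualifier ion ratio within
±20% of the standard's, and a quantifier area cutoff of 1000 counts
(2000 for HHC and 11-OH-HHC, whose channels are noisier in practice).
A detection is *confirmed* when all criteria pass, *partial* when a
quantifier peak exists but a criterion fails, *absent* otherwise.
Criteria are inclusive at their edges, with one deliberate exception:
the internal-standard recovery rule excludes a sample only when recovery
is *strictly below* 50% of the calibrator mean, matching the rule's
wording. A confirmed Delta-8-THC screen (a channel pair sharing the
Delta-9-THC transitions at a distinct retention time) also excludes the
sample, since Delta-8 interferences compromise the whole cannabinoid
profile.

## The M+2 isotopologue interference

HHC-COOH has the same nominal mass as THC-COOH carrying two heavy
isotopes, so at high THC-COOH concentrations a peak appears on the
HHC-COOH channels *between* the two epimers. The `isotopes` functions
model this from first principles:

* `isotopologue_distribution()` computes the exact probability of each
  integer mass shift by convolving per-element multinomial single-atom
  distributions — no Poisson or Gaussian approximation. Natural
  abundances (13C 0.0107, 2H 0.000115, 15N 0.00364, 17O 0.00038,
  18O 0.00205) are configurable so closed-form oracle values can be
  reproduced exactly; a `carbon_only` mode isolates the carbon backbone
  for binomial cross-checks.
* `fragment_label_avoidance()` gives the hypergeometric probability that
  all heavy labels fall outside the product-ion fragment (only then does
  the labelled precursor contribute signal at the unlabelled product
  m/z), under uniform-random label placement.
* `interference_area()` multiplies parent area, shift probability and
  fragment-retention probability.

Two parameters are assumptions, not measurements: the carbon counts of
the m/z 193.12 and 123.04 product ions (defaults 14 and 8) are not
derivable from published data, so they are configurable per transition.
With those defaults the interference's effective quantifier/qualifier
ratio is `fragment_label_avoidance(21, 14, 2) /
fragment_label_avoidance(21, 8, 2)` ≈ 0.27. The generator deliberately
sets the true HHC-COOH ion ratio to 0.30 — isobars of the same scaffold
fragment similarly — so the ion-ratio criterion *cannot* reject the
interference and the ±0.02 min retention-time criterion has to do the
work, which is exactly the identification hazard the assay faces. The
interference's parent area is scaled from the THC-COOH
quantifier-equivalent response, assuming the 193/123 fragments form with
efficiency comparable to the monitored THC-COOH channels; this is an
approximation the package documents rather than hides.

```{r isotopes}
isotopologue_distribution("C21H28O4", max_shift = 3)
fragment_label_avoidance(21, 14, 2)
```

## Peak picking and integration

Published integrator settings are not available, so windowed trapezoidal
integration is declared as this package's reference behavior:

* The search window is three times the retention-time tolerance
  (±0.06 min), wide enough that jittered peaks are found *before* the
  identification RT test is applied.
* Baseline is the median — and noise the MAD — of the samples outside
  the window: robust and deterministic.
* A peak is found only at a *local maximum* rising more than three noise
  SDs above baseline with both neighbouring samples elevated; this
  rejects both isolated noise spikes and the tail of a peak centered
  outside the window.
* The area is the baseline-subtracted trapezoidal integral over the
  contiguous region above baseline around the apex, trimmed back to the
  valley minima on each side, rescaled by the sampling step so areas are
  in counts and invariant to grid refinement.
* For epimer pairs on a shared channel, local maxima are assigned to the
  epimer whose expected retention time they are nearer; overlapping
  windows are split at the valley minimum between the two apexes, and a
  valley that does not return to baseline flags both results as
  partially resolved. A peak equidistant from both expected times (true
  coelution) is split at the midpoint and flagged. The 13C2-THC-COOH
  peak at 1.90 min therefore contributes to neither epimer window — and
  even if a jittered interference apex slips into the 9S window, the
  ±0.02 min RT criterion still rejects it.

## Quantification

Response factors (analyte area / internal-standard area) make all
downstream math invariant to extraction recovery and injection-level
scaling. Calibration is a weighted least-squares line (1/x weighting,
the bioanalytical default; intercept retained) over the six-point curve
at 0.53–53 ng/mL, accepted only when every back-calculated calibrator is
within ±20% of nominal (±25% at the lowest level). LLOQs are 0.53 ng/mL
for Delta-9-THC and 11-OH-THC and 1.06 ng/mL for THC-COOH; analytes
without reference material inherit their surrogate's LLOQ.

For those analytes — HHC (surrogate Delta-9-THC), 11-OH-HHC (surrogate
11-OH-THC), HHC-COOH (surrogate THC-COOH) — a correction factor is the
mean over replicate days of the surrogate/target response-factor ratio,
measured from the all-analyte 2.5 ng/mL mixture analyzed on six
different days (same-day pairing preserved; a median aggregate is
selectable). The orientation is fixed by a chain-consistency property:
multiplying the target's response factor by the correction factor
places it on the surrogate's response scale, so quantifying the
surrogate through a self-correction factor of 1 reproduces its direct
result exactly. Non-confirmed detections are censored to 0 for summary
purposes; inverted values below the LLOQ keep their numeric value but
carry a `below-LLOQ` flag. Whether reported medians should instead
censor below-LLOQ values to LLOQ/2 is a reporting convention the
package leaves to the caller — summaries operate on whatever `value`
column they are given.

## The identification reference

Reference retention times and ion ratios are always taken from processed
standard injections, never hard-coded. The reference protocol matters
more than it looks: with detector noise calibrated so a cutoff-sized
peak has signal-to-noise about 10, a *single* 2.5 ng/mL standard
injection estimates a qualifier/quantifier ratio with ~15% CV, which
alone consumes most of the ±20% ion-ratio budget and turns
confirmed/partial calls into coin flips. `simulate_reference_standards()`
therefore injects the standard mixture in triplicate at a
mid-calibration concentration (25 ng/mL), bringing the reference-ratio
error to about one percent; the 2.5 ng/mL six-day runs remain the source
of correction factors. This replaces a single-most-recent-standard
convention with a replicate protocol, a deliberate design choice of this
package.

## The synthetic-data generator

The generator emulates the study's inputs with full ground truth:

* **Cohort structure.** 308 cases split A/B/C (THC-only / THC+HHC /
  negative) at 222/10/76; group D (HHC only) is defined and reported
  although the study period contained none. Per-analyte prevalences in
  group A follow the reported positives; concentrations are zero-inflated
  log-normals. Where a whole-group median (zeros included) is targeted —
  Delta-9-THC 2.8, 11-OH-THC 1.1, THC-COOH 21, 9R-HHC-COOH 1.4 ng/mL —
  the log-mean is solved from the prevalence so the group median of the
  mixture hits the target; analytes detected in at most half the cases
  (9S-HHC-COOH) get a positive-case median instead, consistent with
  their reported group median of 0. `sdlog = 1` puts the expected cohort
  maxima near the reported ones (e.g. THC-COOH max 269 at n ≈ 222).
  Cross-analyte correlations within a case are not modelled; the true
  biological correlation structure is unknown and per-analyte summaries
  do not depend on it.
* **Chromatograms.** Gaussian peaks (sigma 0.008 min) on a uniform
  100 points/min grid over the 6.8 min run; at this width the HHC-COOH
  epimers (0.17 min apart) are baseline-resolved and the 11-OH-HHC pair
  (0.05 min) nearly so. Additive Gaussian noise (SD 50 counts on a
  100-count baseline, clipped at zero) gives signal-to-noise ≈ 10 for a
  peak at the 1000-count cutoff. Retention-time jitter is uniform within
  half the identification tolerance. Internal-standard recovery is
  uniform on 0.6–1.1 with a configurable fraction of low-recovery
  (< 0.5) cases to exercise the exclusion rule.
* **Interference.** Every THC-COOH-positive case receives the M+2 peak
  on both HHC-COOH channels at the THC-COOH retention time, with area
  from `interference_area()` — linear in the THC-COOH response by
  construction.
* **Incubations.** A first-order cascade solved with `deSolve`:
  THC → 11-OH-THC → 11-oxo-THC, the oxo intermediate branching to
  THC-COOH or, via double-bond reduction, to 11-oxo-HHC, which branches
  to HHC-COOH or 11-OH-HHC (terminal in this network — its onward
  oxidation is folded into the oxo branch, which also keeps the
  11-OH-HHC *impurity* in the 11-OH-THC substrate material constant
  across timepoints and negative controls, as observed). Routing the
  reduction through the 11-oxo stage is not only mechanistically the
  favoured hypothesis (alkene reduction typically requires a conjugated
  carbonyl); it is what produces the sigmoidal onset that makes
  metabolites invisible at 20 min yet strong at 120 min under the area
  cutoffs. Rate constants are hand-set to reproduce the qualitative
  call pattern, and stereoselectivity is substrate-specific: the
  enantiopure THC-derived route yields almost exclusively 9R products,
  while the racemic 11-OH-THC reference material yields both epimers —
  the generator's account of why 9S-HHC-COOH appears only in that
  incubation. Two quantitative observations are knowingly *not*
  reproduced: with rates slow enough to keep products undetected at
  20 min, the 11-OH-THC substrate is barely consumed by 180 min
  (reported: ~15% remaining), a tension between the reported call
  pattern and first-order kinetics that the package resolves in favour
  of the call pattern. Substrate depletion in the Delta-9-THC
  incubation *is* reproduced.

What passing tests on these data do and do not show: the generator's
peaks are Gaussian, its noise white and homoscedastic, its responses
perfectly linear, and its matrix effects absent. Recovery results
therefore demonstrate the correctness of the *data-analysis* logic, not
the performance of any real assay.

## Numerical choices and degenerate inputs

* Area unit: trapezoidal integral divided by the sampling step, so a
  rendered peak of area A integrates back to A within 1% in noiseless
  mode and areas are comparable across grids.
* Percent rounding is half-up to the nearest integer, consistent with
  all reported group percentages (83.78 → 84, 50.45 → 50, 14.86 → 15,
  91.89 → 92, 80.18 → 80) and the headline 6.67 → 7% relative-median
  statistic, which is computed as the ratio of group medians, not the
  median of per-case ratios.
* Identification tolerance edges carry a 1e-9 relative epsilon so
  inclusive boundaries survive floating-point arithmetic.
* Degenerate inputs: identical epimer retention times are an error; a
  window holding only a monotone tail yields `found = FALSE`; a zero
  internal-standard area yields an undefined response factor (`NA`),
  never a division error; negative inverted concentrations clamp to 0
  with a `below-LLOQ` flag.
* Text round-trips are bit-exact: writers emit 17 significant digits and
  readers use correctly rounded `strtod` parsing.

## Detection efficiency near the LLOQ

One pipeline property deserves emphasis because it shapes cohort
summaries. For analytes whose cohort median sits near the LLOQ with a
small ion ratio — 9R-HHC-COOH at 1.4 ng/mL with ratio 0.30 is the
extreme — the qualifier area at the median is a few hundred counts,
where integration noise gives it a ~30% CV. A substantial fraction of
genuinely positive cases therefore fails the ±20% ion-ratio criterion
and is censored to 0, so the *pipeline* group median is biased below
the *truth* median even though every confirmed case is quantified
accurately (median absolute relative error of quantified estimates is a
few percent). This mirrors the real assay, where qualitative "(+)"
observations near the limit are reported instead of concentrations. The
test suite asserts the directional fact (pipeline median ≤ truth
median; confirmed cases quantified within 10%) rather than pretending
the bias away.

## Problem sizes

The shipped tests and the acceptance script use a 500-case cohort for
the interference-rejection experiment (with THC-COOH capped at the
reported cohort maximum of 269 ng/mL and zero HHC-COOH truth), a
300-case cohort for parameter recovery, a 250-case cohort for summary
fidelity, exhaustive isotopologue enumeration up to 12 heavy-capable
atoms, Monte-Carlo checks at 10^6 draws, and the three-substrate
incubation study in duplicate (with and without NADPH). These sizes keep
estimator noise small relative to the margins being asserted.

## Limitations

* Fragment carbon counts for the product ions are assumptions; the
  interference magnitude scales with them.
* The generator's prevalence parameters are *truth* prevalences; the
  detected prevalence is necessarily lower near the LLOQ (see above),
  whereas reported study prevalences are detected ones.
* No carryover, batch drift, matrix effects, quadratic calibration or
  measurement-uncertainty budgets; these are out of scope.
* Incubation kinetics are a qualitative device, not an enzymological
  model; rate constants have no mechanistic interpretation beyond
  reproducing the call pattern.
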