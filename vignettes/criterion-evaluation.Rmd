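---
title: "Evaluating glaucoma diagnostic criteria: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating glaucoma diagnostic criteria: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaucodx)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, and the design decisions
taken where the underlying methodology left choices open.

## The data model

Everything operates on report-level categories, never on raw thickness
or sensitivity values. An `eye_visit` record carries:

* **OCT sector color codes** for six measures — BMO–MRW, circumpapillary
  RNFL at the 3.5 mm (`RNFL_SMALL`) and 4.7 mm (`RNFL_LARGE`) circles,
  and macular GCL, IPL and total retina — each with a global (G) value
  and six sectors. Peripapillary sectors follow the Garway-Heath
  labels (T, TS, TI, N, NS, NI); macular measures use S, TS, TI, I,
  NS, NI. Codes are an ordered scale green < yellow < red: within
  normal limits, borderline (*P* < 5%), outside normal limits
  (*P* < 1%) against a normative database.
* **VF indices**: the p-category of MD and PSD for the 24-2 and 10-2
  tests on the ladder ns < p10 < p5 < p2 < p1 < p05, the categorical
  GHT for the 24-2, and reliability indices (false-positive response
  rate, fixation-loss rate, both fractions of 1). One ordinal
  p-category type expresses all three thresholds the package needs:
  5% (VF abnormality), 10% (structural regions), 1% (strict mode).
* **Pointwise maps** (optional; required for the reference standard):
  pattern-deviation p-categories for the 52 non-blind-spot 24-2
  locations and 68 10-2 locations, and p-categories of RNFL and GCL+
  probability-map regions, linked by a correspondence map
  (location → region set, region → layer).

A deliberate asymmetry: a criterion that references a **missing** metric
errors instead of treating it as green. Silently imputing "normal" would
inflate specificity of combinations exactly where data are thinnest.

Visits are excluded when either VF test has a false-positive rate
> 15% or fixation losses > 1/3; values exactly at the limit are kept
(the rules are strict inequalities). The whole visit is dropped rather
than the single test, because most combination criteria consult both
tests; keeping half a visit would make criterion evaluation depend on
which criterion is asked.

## The criterion engine

A criterion is a finite boolean tree: leaves select one metric, `AND` /
`OR` nodes combine subtrees, and two special forms capture rules that
are awkward as plain trees (`crit_any_paired` for same-sector agreement
across two measures; `crit_quadrant_ght` for quadrant-plus-GHT).
Evaluation is pure and order-independent; there is no negation anywhere
in the grammar, so every criterion is monotone in abnormality. Two
consequences are load-bearing and are asserted as properties in the
test suite:

* **Threshold monotonicity.** Under the strict mode (abnormal = red /
  p ≤ 1% / GHT outside normal limits / GSS2 stage ≥ 1) every flag set
  is a subset of the borderline mode's (abnormal = yellow-or-worse /
  p ≤ 5% / GHT borderline-or-worse / GSS2 borderline-or-worse). Strict
  mode can therefore only trade sensitivity for specificity.
* **Combination monotonicity.** flags(A AND B) ⊆ flags(A) ⊆
  flags(A OR B) on any cohort, hence AND-combinations never lose
  specificity relative to a component and never gain sensitivity.

The GHT outcome "other" (e.g. general reduction of sensitivity) does
not count as abnormal by default; `ght_other_abnormal = TRUE` flips
this. The default is the conservative reading: those messages are not a
glaucoma-specific defect signal.

### GSS2 staging

The Brusini GSS2 places a 24-2 field on a nonlinear MD–PSD chart and
returns normal (stage 0), a borderline band, or stages 1–5. The chart
is published as a graphic, not as formulas; this package encodes its
own piecewise-constant approximation (version 1, constants in
`R/gss2.R`): a field's stage is the worse of an MD-derived and a
PSD-derived stage, with cut-points at MD ≤ −2, −4, −8, −14, −20 dB and
PSD ≥ 2, 4, 7, 10, 13 dB, and a borderline band at MD ≤ −1 dB or
PSD ≥ 1.7 dB. The encoding is validated for the property that actually
matters downstream — the stage is monotone in defect depth along both
axes — rather than against chart coordinates, and no headline result
depends on where exactly the boundaries sit: worked examples drive the
GSS2 leaf with clearly normal or clearly end-stage values.

## The reference standard

A VF location shows aS–aF agreement when its pattern-deviation
p-category is ≥ p5 **and** at least one corresponding structural region
is ≥ p10. An eye is likely glaucoma when both baseline OCT–VF pairs
show at least `min_locations = 3` aS–aF locations. Design choices where
the methodology is underdetermined:

* **Pooling, not deduplicating.** 24-2 and 10-2 locations both
  contribute, per test location, even though central 24-2 points
  spatially coincide with 10-2 points. Pooled counting is consistent
  with a per-eye maximum of 64 (> 52), and the alternative is a
  configuration away (`count_asaf` operates on whatever maps it is
  given).
* **Either layer suffices.** A location's corresponding regions may
  belong to RNFL or GCL+; abnormality in either counts
  (`layer_rule = "either"`, with `"both"` and single-layer variants
  available). Requiring both layers would conflate the reference
  standard with the S–S metric it is meant to adjudicate.
* **Single-region rule.** One abnormal corresponding region is enough;
  no contiguity requirement is imposed, since the package's regions are
  already aggregates.
* **The correspondence map is an input.** Instrument-specific
  widefield-report mappings are not published as tables;
  `default_correspondence()` ships a hemifield-respecting synthetic
  mapping (superior VF ↔ inferior retina) that the generator also uses,
  so labelling results in the test suite never depend on the anatomical
  fidelity of a guessed atlas.

Monotonicity properties (relaxing either significance cutoff never
decreases the count; raising `min_locations` never grows the LG set)
are asserted in the tests.

## Performance statistics

Specificity is measured on HC eyes, sensitivity on LG eyes; patient
eyes failing the reference standard (`NEITHER`) are excluded from every
denominator. Reported percentages are rounded half up — the convention
under which integer-percent tables and their confusion counts agree
(82.5 → 83, 37.5 → 38; banker's rounding would not reproduce them).
Exact values are kept alongside the reported integers.

Bootstrap CIs are percentile intervals over resampled eyes
(default 1000 iterations). Resampling is **stratified by class** by
default: plain pooled resampling can produce replicates with an empty
class whose statistics are undefined. The unstratified variant is
available (`stratified = FALSE`); replicates with an empty class are
then dropped from that statistic's percentile pool. For pooled
two-baseline CIs the pipeline treats eye-visits as independent resample
units; a per-eye cluster bootstrap would be the natural refinement but
is not implemented.

## The synthetic cohort generator

The generator emulates the *statistical structure* the analysis
assumes, not clinical realism:

* **Cohort design** (defaults): 56 HC eyes, 61 patient eyes of which
  round(61 × 40/61) = 40 are designed-LG; two baseline visits per eye.
* **Defect geometry**: each patient eye draws a defect hemifield
  (inferior 0.5, superior 0.3, both 0.2). Within it, each OCT measure
  "detects" the defect via a Gaussian copula with cross-measure
  correlation ρ = 0.7 on a shared hemifield latent, thresholded by a
  per-eye Beta(5, 2) severity (Beta(1.5, 4) for suspects). Detection
  marks the temporal sector of the hemifield (TI or TS) abnormal and
  the remaining hemifield sectors with probability 0.2 + 0.5·severity.
  This is the simplest mechanism that produces the hemifield-level
  RNFL–GCL agreement structure the S–S metric looks for.
* **Exact aS–aF counts**: per designed-LG eye-visit, a count is drawn
  from a truncated negative binomial on [3, 64] whose *truncated*
  moments are fitted to mean 19, SD 16 (`fit_trunc_nbinom`; matching
  after truncation makes the configured moments the moments of what is
  sampled). That many VF locations in the defect hemifield are set
  ≥ p5 with a corresponding region ≥ p10; every unselected location
  stays ≤ p10, so `count_asaf` recovers the drawn count exactly and
  designed-LG eyes satisfy the reference standard by construction. A
  single hemifield only spans 60 locations, so counts above that spill
  into the other hemifield, as severe defects cross the horizontal
  meridian. Suspect eyes stay below 3 locations on at least one visit.
* **Healthy noise**: each HC sector is independently abnormal at
  `oct_fp_rate = 0.04` (yellow 70% / red 30%); VF indices at rates
  0.07–0.11; pointwise maps carry sub-significant noise at
  `map_noise_rate = 0.04`. These defaults echo single metrics
  miscategorising on the order of 1–6 of 56 healthy eyes, with VF
  indices noisier than OCT.
* **Test–retest**: eye-level latents are shared between visits with
  weight `test_retest_agreement = 0.9`; measurement noise is
  independent per visit.
* **Null model**: with all false-positive and noise rates 0 and
  severity forced to 0 the generator emits all-green/all-NS records —
  the VF severity response is constructed to vanish exactly at
  severity 0.

What the generator does **not** emulate: real spatial point-to-point
correlation within maps, instrument segmentation errors, fixation
artefacts, eccentricity-dependent variability, or any joint
distribution calibrated to real patients. Passing tests therefore
demonstrate the *machinery* (counting, labelling, evaluation,
monotonicity) is correct under the designed structure, not that the
criteria would achieve any particular sensitivity on clinical data.

## Problem sizes and numerical choices

The test suite runs in about a minute: property tests sweep 20 cohorts
of 8 HC + 10 patient eyes; truth-table oracle checks are exhaustive up
to 6 leaf slots (3^6 assignments per criterion) and sample 300
assignments beyond that; reference-standard recovery uses ten
default-size cohorts plus one 200-LG-eye cohort for count moments
(sample moments are compared within two standard errors); bootstrap
checks use 1000 iterations against Clopper–Pearson intervals from the
same counts. The moment fit uses Nelder–Mead on (log μ, log size) with
a squared-moment objective; color/p-category parsing is
case-insensitive with report synonyms (wnl/borderline/onl) and rejects
everything else at read time, naming the offending row.

## Known limitations

* The GSS2 boundary table is an approximation (above); stage values
  near boundaries should not be over-interpreted.
* The GHT is modelled as a single categorical outcome, so the
  quadrant-plus-GHT rule implements "matching" as co-occurrence rather
  than hemifield-matched agreement.
* Only the named sector pairs appear for the paired small-circle/MRW
  style combinations (G and TI); the catalog does not span every
  possible sector pairing.
* ROC analysis over continuous thicknesses is out of scope by design —
  only the categorical codes clinicians see on reports are modelled.
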