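# glaucodx

Diagnostic performance of OCT and visual-field summary metrics for early
glaucoma.

Clinicians judge glaucomatous damage largely from the summary statistics
("metrics") printed on commercial optical coherence tomography (OCT) and
Humphrey visual-field (VF) reports: color-coded sector thicknesses
(green = within normal limits, yellow = borderline, *P* < 5%, red =
outside normal limits, *P* < 1%) for the Bruch's-membrane-opening
minimum rim width (BMO–MRW), the circumpapillary retinal nerve fiber
layer (cpRNFL, 3.5 mm and 4.7 mm circles), and the macular ganglion cell
layer (GCL), IPL and total-retina maps, plus the 24-2 and 10-2 indices
MD, PSD and the glaucoma hemifield test (GHT). `glaucodx` is an engine
for evaluating how well such metrics — singly or in boolean
combinations — detect early glaucomatous damage, built for biostatistics
and reading-center work rather than for image processing (it consumes
report-level categories only).

Three things make up the package:

1. **A composable criterion engine.** Any diagnostic rule is a boolean
   predicate tree over a per-eye record: leaves test one metric against
   an abnormality threshold (borderline *P* < 5%, or a strict *P* < 1%
   mode), internal nodes are AND/OR. Named builders provide the
   literature criteria, including the structure–structure (S–S)
   hemifield agreement metric

   `[TI_cpRNFL AND (TI_GCL OR I_GCL)] OR [TS_cpRNFL AND (TS_GCL OR S_GCL)]`,

   the paired-sector cpRNFL×BMO–MRW agreement rule (any of the six
   matched sectors abnormal in both), the quadrant-plus-GHT
   structure–function rule, and Brusini GSS2 staging of the MD–PSD
   plane. `criteria_catalog()` enumerates the full grid (42 single OCT
   metrics, 5 VF indices, all pairwise function–function combinations,
   and the structure–structure / structure–function combinations).

2. **A topographic structure–function reference standard.** A VF
   location shows aS–aF (abnormal structure – abnormal function)
   agreement when its pattern-deviation category is abnormal at the 5%
   level and a corresponding RNFL or GCL+ probability-map region is
   abnormal at the 10% level. An eye is *likely glaucoma* (LG) when both
   baseline OCT–VF pairs show ≥ 3 aS–aF locations. Sensitivity is then
   measured on LG eyes, specificity on healthy controls (HC):

   sens = TP/(TP+FN), spec = TN/(TN+FP), acc = (TP+TN)/N, with
   percentile bootstrap 95% CIs (1000 iterations, stratified by class).

3. **A synthetic cohort generator.** Because per-eye clinical data of
   this kind are not public, the package generates cohorts with the
   right statistical structure: hemifield-localised defects, sector
   abnormalities correlated across measures through a shared latent
   severity, pointwise maps constructed so each designed-LG eye's aS–aF
   count is an exact draw from a truncated negative-binomial model
   (mean 19, SD 16, support 3–64), and two baseline visits with
   configurable test–retest agreement.

## Worked example

```r
library(glaucodx)

sim <- generate_cohort(generator_config(seed = 1))   # 56 HC + 61 patients
labels <- label_cohort(sim$records, sim$corr)        # topographic reference standard
table(labels)
#>      HC      LG NEITHER
#>      56      40      21

v1 <- sim$records[vapply(sim$records, `[[`, 1L, "visit") == 1L]
cat <- criteria_catalog()
sel <- cat[cat$name %in% c("RNFL_SMALL_G", "RNFL_SMALL_TI", "SS_METRIC",
                           "YANG_PAIRED", "VF_GHT", "GSS2"), ]
evaluate_criteria(v1, labels, sel)[, c("name", "tp", "fn", "fp", "tn",
                                       "sens_pct", "spec_pct", "acc_pct")]
#>           name tp fn fp tn sens_pct spec_pct acc_pct
#>   RNFL_SMALL_G 16 24  3 53       40       95      72
#>  RNFL_SMALL_TI 25 15  2 54       63       96      82
#>      SS_METRIC 31  9  0 56       78      100      91
#>    YANG_PAIRED 31  9  1 55       78       98      90
#>         VF_GHT 37  3  4 52       93       93      93
#>           GSS2 40  0 27 29      100       52      72
```

The 21 `NEITHER` eyes are patients who failed the reference standard;
they are excluded from every denominator. On this cohort the S–S
hemifield metric flags 31 of 40 LG eyes with no healthy false positives
— the same high-specificity/moderate-sensitivity pattern the global
cpRNFL metric (`RNFL_SMALL_G`, 3 FPs but only 16 TPs) and the GHT
(more sensitive, more FPs) trade off in opposite directions. Bootstrap
CIs for any criterion:

```r
pred <- predict_criterion(build_ss_metric(), v1)
bootstrap_ci(pred, labels, n_iter = 1000, seed = 1)
#> <performance> sens 77.5%, spec 100.0%, acc 90.6% (TP=31 FN=9 FP=0 TN=56)
#>   sensitivity 95% CI [65.0, 90.0]
#>   specificity 95% CI [100.0, 100.0]
#>   accuracy 95% CI [85.4, 95.8]
```

`performance()` reports integer percentages with round-half-up, the
convention under which published confusion counts and percentages agree
(e.g. `performance(list(tp = 32, fn = 8, fp = 1, tn = 55))` gives
sensitivity 80%, specificity 98%, accuracy 91%).

`run_pipeline(out_dir, config = generator_config(seed = 1))` chains
simulate → reliability filter → label → evaluate → repeatability →
bootstrap and writes CSV tables plus a YAML run manifest.

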