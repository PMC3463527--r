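# mesopanel

Reproducible serum-proteomic panel discovery and blinded evaluation for
malignant pleural mesothelioma (MM) surveillance.

## The problem

MM is a rare, aggressive asbestos-induced cancer. Surveillance of the
large asbestos-exposed population needs a noninvasive, highly specific
blood test: imaging screens produce far more benign findings than true
malignancies. Multiplexed affinity proteomics (aptamer/SOMAmer-style
assays reporting ~1000 protein analytes per serum sample in relative
fluorescence units, RFU) makes panel discovery possible, but archived
multi-center case-control sets carry serious preanalytic hazards —
collection-site batch effects, blood-draw procedure differences
(intra-operative case draws vs clinic control draws), plate effects,
and outright sample degradation — that can masquerade as disease
signal.

`mesopanel` implements the complete analysis as a tested R pipeline:

1. **IO / data model** — strict TSV readers/writers for RFU matrices
   (samples × analytes, strictly positive, no missing cells) and sample
   annotations with controlled vocabularies.
2. **Preprocessing** — per-plate multiplicative calibration from the
   eight reference calibrator wells on each plate
   (`g_pa = reference_a / median(calibrator RFU on plate p)`), then
   median normalization of each sample to a common per-analyte
   reference (`f_s = median_a(reference_a / x_sa)`).
3. **Preanalytic QC** — three screens on log2(RFU), all blind to the
   case/control contrast: exclusion of analytes whose distribution
   differs between control collection sites by a two-sample
   Kolmogorov–Smirnov distance D > 0.45; exclusion of analytes shifted
   between matched intra-op/pre-op draws of the same control subjects
   (Wilcoxon signed-rank p < 0.05 **and** |median log2 ratio| ≥ 0.5);
   and a PCA screen, derived from the control sets, that flags
   artifact components, outlying samples, and high-loading analytes.
4. **Marker discovery** — Welch t and KS univariate screens with
   Benjamini–Hochberg control (q < 0.01), then a single random forest
   over all candidates ranked by Gini importance (mean decrease in
   node impurity), and a nested panel-size scan by out-of-bag AUC to a
   13-analyte panel.
5. **Classifier** — a fixed-panel random forest whose decision
   threshold is set once from out-of-bag scores by the Youden rule
   (maximal sensitivity + specificity, ties to the balanced point) and
   is immutable thereafter; blinded scoring reads only the RFU matrix.
   Assay-version bridging retrains the same panel and verifies score
   rank agreement (Spearman) on shared samples.
6. **Evaluation** — sensitivity/specificity/accuracy with Wald
   intervals `p ± 1.96·√(p(1−p)/n)` clipped to [0, 100]; empirical ROC
   with AUC (Mann–Whitney, half-credit ties) and DeLong or bootstrap
   intervals; stage-stratified detection; alternative operating
   points; and prevalence-adjusted screening estimates
   `PPV = se·π / (se·π + (1−sp)(1−π))`.
7. **Synthetic cohorts** — a generator that emulates the study's data
   structure (log-normal analytes, signed marker effects scaling with
   pathologic stage, site/plate batch effects, a degraded control
   sub-cohort, draw-procedure artifact analytes, paired control
   draws), with ground truth for parameter-recovery testing.

## Worked example

```r
library(mesopanel)

run <- run_pipeline(pipeline_config(seed = 1))
print(run)
#> mm surveillance pipeline run (seed 1 )
#>   analytes after QC: 716
#>   candidates: 76 | panel size: 13
#>   training     sens 94.9  spec 98.3  acc 96.6
#>   verification sens 100.0  spec 100.0  acc 100.0
#>   validation   sens 84.2  spec 100.0  acc 94.0
#>   combined     sens 92.3  spec 99.3  acc 96.1
#>   blinding audit: clean
```

The run simulates a discovery cohort (79 MM cases, 110 asbestos-exposed
controls across three collection sites, one 30-sample site carrying a
protein-degradation artifact), applies calibration, normalization and
the three QC screens (the degraded site is detected and removed), makes
a 75/25 training/verification split, discovers candidates and a
13-analyte panel on training samples only, freezes the Youden
threshold, and scores the blinded verification and validation cohorts.
The training row reports out-of-bag performance; the blinded cohorts
confirm that accuracy holds up on samples the discovery stages provably
never saw (`run$provenance$id_audit`).

The published evaluation arithmetic is available directly:

```r
pm <- confusion_metrics(pool_cohorts(reference_confusion_counts()))
round(pm$estimate, 1)
#> [1] 93.2 90.8 91.9   # pooled sensitivity, specificity, accuracy (%)

est <- screening_estimates(0.932, 0.908, prevalence = 0.014)
round(100 * c(est$ppv, est$npv), 1)
#> [1] 12.6 99.9        # PPV / NPV in a 1.4%-prevalence screening setting
```

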