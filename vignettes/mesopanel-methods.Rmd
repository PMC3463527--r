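---
title: "Methods: serum proteomic panel discovery with preanalytic QC and blinded evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum proteomic panel discovery with preanalytic QC and blinded evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesopanel)
```

## Scope and model

`mesopanel` implements a case–control biomarker-panel workflow for
multiplexed affinity proteomics of serum, aimed at surveillance of
malignant pleural mesothelioma (MM) in asbestos-exposed populations.
The quantity measured per (sample, analyte) is a relative fluorescence
unit (RFU): a positive intensity, approximately log-normal. All
distributional computations therefore run on log2(RFU); missing or
non-positive cells are treated as data corruption and rejected at load
time rather than imputed.

The workflow is: plate calibration → median normalization →
preanalytic QC → stratified split → univariate candidate selection →
random-forest Gini ranking → panel-size scan → fixed-threshold
random-forest classifier → blinded scoring → evaluation statistics.
The discovery stages may only ever see training-split samples; the
pipeline records the sample ids each stage received and aborts if a
held-out id reaches discovery. This audit is the software counterpart
of running a blinded study.

## Preprocessing

Both corrections are multiplicative on the raw scale.

*Calibration.* Every plate carries reference calibrator wells (eight
by default). For plate $p$ and analyte $a$ the factor is
$g_{pa} = r_a / \mathrm{median}(\text{calibrator RFU of } a \text{ on } p)$,
applied to all wells of the plate. When no external reference $r_a$ is
given it is the median across plates of the per-plate calibrator
medians; with that construction re-calibrating a calibrated matrix
yields factors identically 1 (exact idempotence), which the tests
assert to 1e-9.

*Median normalization.* Each sample is scaled by
$f_s = \mathrm{median}_a (r_a / x_{sa})$ — the median of ratios, not
the ratio of medians, making $f_s$ invariant under per-analyte
reweighting. After scaling, the per-sample median ratio to the
reference is exactly 1.

*Order.* The pipeline calibrates first and normalizes second, so plate
bias cannot contaminate the study-internal common reference. Each
transform is also exposed standalone, with an optional explicit
reference, because whether the original assays used an external
standard or a study-internal reference is not recoverable; both modes
are supported.

Dilution-group-specific scaling, hybridization controls, and
limit-of-detection flooring are deliberately out of scope.

## Preanalytic quality control

Archived multi-center sets confound collection covariates with case
status: in this design most case sera are drawn at surgery
(intra-operative) while controls are clinic draws, and some sites
contribute only cases or only controls. QC must therefore remove
technical signal without ever consulting the case/control contrast.
Three screens run in sequence (KS → paired → PCA by default; the order
is configurable):

1. **Control-set KS screen.** For each analyte, the two-sample
   Kolmogorov–Smirnov distance $D$ between every pair of control
   collection sites (log2 scale); the analyte is excluded iff the
   maximum pairwise $D$ strictly exceeds 0.45. The max-over-pairs
   aggregation is the conservative choice among unspecified
   alternatives and is configurable. The 0.45 threshold is calibrated
   for control sets of roughly 30+ samples, where the null exclusion
   rate is negligible ($P(D > 0.45) \approx 2 e^{-2 \cdot 0.45^2 n/2}$);
   the synthetic defaults size control sites accordingly.

2. **Paired-draw screen.** Using control subjects sampled both
   pre-operatively and intra-operatively, per-analyte paired log2
   ratios are tested by Wilcoxon signed rank. Exclusion requires both
   p < 0.05 *and* |median ratio| ≥ 0.5 log2 units: the conjunction
   prevents discarding analytes for consistent but trivially small
   shifts, and keeps the false-exclusion rate at or below the nominal
   level under the null (asserted by simulation).

3. **PCA screen.** Log2 values are standardized per analyte and
   decomposed by PCA **computed from the control samples only**; all
   clinical samples are then projected onto those components. This is
   the one genuinely open design point in the screen, and the package
   resolves it deliberately: with draw procedure and site confounded
   with disease, a PCA over all samples mixes the disease axis into
   every batch component, and screening against such components
   discards genuine markers (we observed exactly this failure mode).
   Deriving the subspace from controls is the in-study analogue of
   identifying preanalytic components from dedicated control
   experiments. Components explaining ≥ 1% variance whose control
   scores associate with a technical covariate (correlation ratio
   η > 0.5 with site, draw type, or plate) are flagged; samples more
   than 3 robust MADs from the median score on a flagged component and
   analytes that are simultaneously in the top decile of |loading| and
   more than 3 MADs above the median |loading| are flagged. Flags
   become exclusions only in the explicit `qc_report()` assembly step,
   mirroring the judgment-driven removal the original analysis
   describes.

Limitations worth knowing: the sample-flag rule assumes the artifact
sub-cohort is a minority (≲ 20% of samples); a contaminated fraction
much larger than that inflates the robust scale and weakens detection.
With ~16% degraded samples at full panel width — the regime the study
describes — detection is reliable across seeds.

## Candidate selection, ranking, and the panel

Welch's unequal-variance t-test on log2 values is used as the
two-sample location test (the original "modified t-test" is not
defined in enough detail to reproduce; Welch is the conservative
default), alongside a two-sample KS test. Multiplicity is controlled
by Benjamini–Hochberg at q < 0.01 per test; the original analysis used
a local-fdr package, but BH is deterministic, dependency-free, and the
candidate-set cardinality on synthetic data (~64–85) brackets the
study's 64 rather than claiming to equal it.

Candidates are ranked **once** by Gini importance from a single random
forest over all candidates (1000 trees, bootstrap per tree, Gini split
criterion, √p features per split — standard forest defaults, all
configurable), explicitly avoiding stepwise reselection. Panels are
nested: the size-$k$ panel is the top $k$ of that fixed ranking. The
panel-size scan records out-of-bag AUC with its DeLong standard error
per size; the chosen size defaults to the hard override 13 (the
study's design), with a one-standard-error rule (smallest $k$ within
one SE of the maximum) available when no override is given.

## Classifier and threshold

The final model is a random forest on log2 values of the panel, with
scores defined as the fraction of trees voting for disease (classical
vote fractions rather than leaf-probability averaging). The decision
threshold is fixed at training time from **out-of-bag** scores — never
resubstitution — as the cutoff maximizing sensitivity + specificity;
ties break first toward the balanced point (minimal |sens − spec|,
operationalizing "equal importance"), then toward the lower cutoff.
After training, the threshold is immutable; prediction takes only an
RFU matrix, so there is no access path from scoring to labels, and a
missing panel analyte is a hard error.

Assay-version bridging retrains the identical panel on the new
version's measurements of the shared training samples and compares the
two models' out-of-bag scores on those samples by Spearman rank
correlation (average-rank ties), flagging below 0.9. Out-of-bag scores
are used on both sides to avoid resubstitution optimism.

## Evaluation statistics

Sensitivity, specificity, and accuracy are percentages with Wald
intervals $100\,(p \pm 1.96\,\sqrt{p(1-p)/n})$, clipped to [0, 100];
cross-checking this formula against the reference study's printed
intervals (e.g. specificity 55/60 → 91.7, 84.7–98.7) is what
identified Wald-with-clipping as the interval in use. Full precision
is retained internally; rounding to one decimal happens only at
display. Cohorts pool by summing confusion counts — never by averaging
percentages — and stage-stratified detection pools the same way.

The ROC curve is the empirical curve over all distinct cutoffs
(positive iff score ≥ cutoff); the AUC is the Mann–Whitney concordance
probability with half credit for ties, identical to the trapezoidal
area of the stored points. The default confidence interval is DeLong's
(deterministic); a stratified bootstrap is available. Both the AUC and
the KS distance are verified in the tests against brute-force oracles
(exhaustive pair counting; exhaustive ECDF evaluation) on random
instances, and DeLong bounds against an independent implementation.

Screening estimates apply Bayes' rule at a stated prevalence
(default 0.014, a screen-detected malignancy rate reported for
asbestos-exposed surveillance cohorts). Perfect sensitivity or
specificity is accepted (the formulas remain well-defined); prevalence
0 and 1 return documented limit values.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised and tested. For analyte $a$ in sample $s$:

$$\log_2 x_{sa} = b_a + \text{site}_{a,\mathrm{site}(s)}
  + \delta_a m_{\mathrm{stage}(s)} [s \in \text{cases}, a \in \text{markers}]
  + \text{draw}_a [s \in \text{intra-op}]
  + \text{degr}_a [s \in \text{degraded}]
  + \text{plate}_{p(s)} + \varepsilon_{sa}$$

with baselines $b_a \sim N(10, 1.5^2)$, residual noise
$\varepsilon \sim N(0, 0.5^2)$, 13 strong markers at ±1.0 log2 units
(9 up, 4 down) and 51 weaker markers at ±0.5 (64 differential
candidates in total), stage multipliers 0.5/0.75/1.0/1.25 for stages
I–IV (a monotone disease-burden gradient; the exact magnitudes are
free parameters), per-site offsets of ±1.0 log2 on a random 3% of
non-marker analytes, plate biases $N(0, 0.2^2)$ with eight calibrator
wells per plate, 30 draw-artifact analytes shifted +1.5 log2 in
intra-operative draws (60% of case draws are intra-operative,
reproducing the draw/disease confounding), a degradation artifact of
−1.5 log2 on a random 20% of analytes in the degraded sub-cohort, and
twelve paired pre-op/intra-op control subjects with a shared
subject-level effect (SD 0.3). One master seed fans out into named
substreams so adding a component never perturbs earlier draws, and a
separate structure seed lets a validation cohort share the discovery
cohort's biology while drawing new samples.

Three structural choices are idealizations to keep ground truth
identifiable, and they bound what passing tests can show: marker,
draw-artifact, and degradation analyte sets are mutually disjoint
(and site offsets avoid markers), whereas real panels can overlap;
batch effects are additive on the log scale with homoscedastic noise,
whereas real assays show intensity-dependent variance; and degradation
is modeled as a uniform negative shift on a fixed analyte subset
rather than protein-specific decay kinetics. Tests passing on this
generator demonstrate that the pipeline recovers the structure it is
designed for — they do not certify performance on real sera, which is
exactly why the original study's blinded-verification design exists.

## Problem sizes and numerical choices

The default pipeline run uses the study design: a discovery cohort of
79 cases / 110 controls (40 + 40 clean controls plus a fully degraded
30-sample site that QC is expected to remove), a 75/25 split, a
blinded validation cohort of 38 cases / 62 controls, 1045 analytes,
and 1000-tree forests; a run takes a few seconds. Module tests use
reduced cohorts (30/30, 200–700 analytes, 200–500 trees) where the
property under test does not depend on panel width; the
parameter-recovery acceptance checks run 20 full-scale pipeline seeds.
Ties in the Gini ranking break alphabetically by analyte id for
determinism; the stratified split uses proportional allocation with
largest-remainder rounding; Youden ties resolve toward balance, then
the lower cutoff; degenerate inputs (constant analytes in PCA,
identical paired values, single-class labels, missing panel analytes)
are either handled with documented semantics or rejected with named
errors.

## Known limitations

* The proprietary ADAT container is not parsed; TSV is the interchange
  format.
* Reproducing the original exclusion memberships (e.g. which 214
  analytes fell to QC) or the exact published AUCs requires the
  original full-panel cohort, which was never deposited; the package
  instead proves the properties of each operation and recovers known
  structure from synthetic cohorts.
* The pre-specified numeric threshold of the original classifier was
  never published; only its selection principle is implemented.
* Scores are vote fractions, not calibrated probabilities.
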