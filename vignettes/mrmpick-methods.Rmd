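---
title: "Automatic MRM preprocessing: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic MRM preprocessing: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrmpick` automates the three decisions of targeted LC-QQQ-MS peak review:
which candidate peak is the analyte, where to integrate it, and whether the
result is good enough to report. This vignette explains the underlying
models, the tunable parameters, the synthetic data the tests rely on, and
the design decisions taken where more than one reasonable choice existed.

## The processing model

Processing a batch is a fixed sequence of stages:

1. **Initial picking.** Per metabolite and sample, candidate peaks are
   strict local maxima of a moving-average-smoothed quantifier trace,
   ranked by smoothed height, at most `n_candidates` (default 5). Borders
   are found by walking out from the apex until the first local minimum or
   the first point below `border_frac` of the apex.
2. **Quality scores.** Each candidate gets 20 scores in $[0,1]$ (1 ideal)
   in three families: peak shape, quantifier/qualifier agreement, and
   deviation from the expected retention time. Unbounded ratios $r$ are
   squashed by $s = \max(0, 1 - 1/r)$ so all scores are commensurable —
   necessary because the model-free fallback simply averages them.
3. **Classification.** A trained peak-picking classifier maps the 20 scores
   to a probability-like score; the fallback is their mean.
4. **Reference selection.** The sample with the highest mean best-candidate
   score across metabolites anchors the RT alignment (missing metabolites
   count as 0; ties go to the earlier sample).
5. **Two-pass RT alignment.** Per-metabolite shifts against the reference
   are measured by cross-correlating quantifier and qualifier traces
   simultaneously over a lag grid (one common sampling interval per step)
   within ±`initial_shift_window`. Shifts are regularised per sample by
   least squares of shift on $(rt^2, rt, 1)$ — run-to-run drift in HILIC is
   well described as quadratic in RT, while individual metabolites deviate
   from the trend on the scale of tens of seconds. The measurement is then
   repeated with the lag search centred on the fitted shift within the
   narrower ±`refined_shift_window`, and the quadratic is refitted.
6. **Prototype picking.** All samples' traces are moved onto the reference
   time axis (subtracting each sample's fitted shift), resampled onto a
   uniform grid at the reference's median sampling interval and summed per
   role. Candidate search, scoring and best-peak selection run on this
   summed prototype — summation stabilises picking for noisy and
   low-abundance signals.
7. **Border propagation and integration.** The prototype borders, moved by
   each sample's fitted shift, delimit integration on that sample's raw
   trace: trapezoidal area above the straight baseline between the border
   intensities, clamped at zero, and the baseline-subtracted height.
   ¹³C-internal-standard normalisation divides by the ISTD trace integrated
   over the same borders.
8. **Reporting gate.** Per cell, the 20 scores of the final peak are
   extended by the cell's picking score and the 0/25/50/75/100th
   percentiles (linear interpolation between order statistics) of picking
   scores of that metabolite across samples — 26 features that let the
   reporting classifier judge a peak relative to its peers. Cells whose
   reporting score reaches `report_threshold` are reported; the rest stay
   empty. Raising the threshold can only shrink the reported set.

Failures are contained per metabolite: a bad trace empties its cells and is
logged, it never aborts the batch.

## The twenty quality scores

Eight scores follow their field-established definitions: the quantifier
apex over the highest point outside the peak (`qs_t_o`), the same for the
qualifier (`qs_to2`), the qualifier apex over its higher and lower border
intensity (`qs_t_h`, `qs_t_l`), deviation from the expected RT without and
with the predicted shift (`qs_drt`, `qs_drts` — linear decay over
`drt_window`), mean pairwise correlation among the traces (`qs_cor123`) and
correlation of the quantifier peak with a least-squares Gaussian
(`qs_gauss`). The remaining twelve are defined by this package within the
same three families and frozen in code and documentation: quantifier border
ratios (`qs_quant_h`, `qs_quant_l`), qualifier-trace Gaussian correlation
and symmetry (`qs_qual_gauss`, `qs_qual_sym`), quantifier symmetry
(`qs_sym`), height- and area-ratio agreement with the expected
quantifier/qualifier ratio (`qs_ratio_h`, `qs_ratio_a`, as
$\min(r/e, e/r)$), width plausibility (`qs_width`, flat over
`peak_width_range`), apex over three times the noise floor (`qs_noise`,
noise as the median absolute successive difference outside the peak),
fraction of positive points inside the peak (`qs_missing`), qualifier
presence (`qs_qual_present`) and raw-versus-smoothed correlation
(`qs_smooth`). Every score is invariant under scaling all intensities by a
positive constant, and scores that need a qualifier are 0 when none exists.

## Classifier training

Labels for peak picking follow the solution-table rule: a candidate is
correct iff the solution marks the cell as present (area > 0) and the apex
lies between the solution's start and end. Reporting labels use the
three-valued convention 2 = report, 0 = do not, 1 = exclude from training.
Training splits examples 80/20 stratified by label; a small fixed grid per
algorithm (forest: 200/500 trees × mtry fraction 0.3/0.6; boosted trees:
100/200 rounds × depth 3/6; SVM: RBF with C ∈ {0.1, 1, 10}; neural net: one
hidden layer of 8/32 with two decay values) is searched by 3-fold
cross-validated F1 on the training split, and the winner's F1 is estimated
once on the held-out 20%. Random forest is the default backend for its
combination of accuracy and training speed; SVM decision values are mapped
to probabilities by the backend's internal calibration so every model
yields scores in $[0,1]$. Seeds are recorded in the model artifact;
tree-backend training is deterministic given the seed.

## The synthetic-data generator

The generator emulates the statistical structure the method assumes:
metabolites with uniform expected RTs, Gaussian peaks (per-metabolite width
0.03–0.06 min, log-uniform amplitudes over 10⁴–10⁶ counts, per-sample
log-normal variation), qualifier traces proportional to the quantifier
(factor 0.5, defining the expected ratio 2), an always-present
internal-standard trace with constant per-metabolite amplitude, constant
baseline (100 counts) with additive Gaussian noise (SD 50, clipped at 0),
and a 0.01-min sampling interval — values on the scale of routine
triple-quadrupole metabolomics acquisitions. RT structure: the drift
coefficient ramps linearly with run order from 0 to `drift_a` (a batch
drifts progressively, and relative drift between samples is what alignment
can observe), plus per-cell Gaussian jitter truncated at ±0.5 min. Peaks go
missing with probability 0.1; with probability 0.2 a decoy peak of 0.5–1.5
times the analyte amplitude appears 0.3–0.8 min away on the quantifier
only. Traces cover ±1.2 min around the expected RT, mimicking
per-transition acquisition segments. An optional exponential tail constant
produces exponentially modified Gaussian peaks.

Ground truth stores the analytic area $A\sigma\sqrt{2\pi}$ and borders at
apex ± 3σ — the visible extent an expert marks as peak start/end (the
signal there is ≈1% of the apex, matching the default border-detection
fraction). All randomness flows from one seed through deterministically
derived sub-seeds per sample and metabolite.

What the generator does **not** emulate: correlated (pink) detector noise,
baseline drift within a trace, saturation, tailing that varies within a
batch, co-eluting interferences on the qualifier, and real inter-batch
variation of peak shape. Passing tests on synthetic batches therefore
demonstrate the mechanics of the chain — candidate ranking, alignment,
prototype integration, gating — not instrument-grade performance on real
chromatography.

## Numerical choices and degenerate inputs

* `border_frac` defaults to 0.01: with borders at 1% of the apex and the
  baseline drawn between border intensities, a noiseless Gaussian retains
  ≈97% of its analytic area; at 5% it would lose ≈11%, which is too lossy
  for area-accuracy targets. The walk-out rule still stops at shared
  valleys between merged peaks first.
* Lag searches use the reference's median sampling interval; equal
  correlation scores prefer the lag closest to the search centre, equal
  candidate heights prefer the earlier RT — all ties deterministic.
* Quadratic fits need ≥3 finite shifts; 1–2 degrade to the median shift as
  a constant, none to the zero model with a warning. A robust variant (one
  reweighting pass dropping residuals beyond 3×MAD) is available behind
  `robust = TRUE` and off by default.
* Correlation-type scores are 0 for windows with fewer than 3–4 points or
  zero variance; flat cross-correlation windows return the search centre
  with a warning.
* Integration clamps area and height at 0 and interpolates the trace at
  the exact border times, so results are insensitive to the grid phase.
* Processing contains no random number draws: identical inputs yield
  bit-identical outputs, independent of any seed.

## Problem sizes

The test suite and the acceptance script run batches between 6 × 5 and
24 × 20 (samples × metabolites) at the 0.01-min sampling interval — large
enough that reference selection, drift fitting and percentile features are
meaningful, and representative of a small routine batch. Training uses the
24 × 20 batch (2400 labelled candidates, decoy probability 0.3, generator
seed 7) for the held-out F1 benchmark.

## Known limitations

* The reporting gate applies a configurable score threshold (default 0.5)
  rather than a hard classifier decision; the two coincide for calibrated
  forests but not necessarily for SVMs.
* Per-metabolite fitted shifts are evaluated at the expected RT, so the
  drift model is locally constant across one peak; peaks wider than the
  drift curvature scale would need within-peak warping, which is out of
  scope.
* Only quantifier decoys are simulated; qualifier interferences, which
  depress the agreement scores, are not.
* xlsx input is supported opportunistically (via readxl when installed);
  CSV/TSV is the canonical, bit-exactly round-tripped dialect.
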