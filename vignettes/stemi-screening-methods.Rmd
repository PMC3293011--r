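---
title: "Methods: screening prehospital ECGs with a bagged neural-network ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening prehospital ECGs with a bagged neural-network ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemiscreen)
```

## The screening problem

When ambulance personnel suspect an acute coronary syndrome, a 12-lead ECG
is transmitted to the coronary care unit (CCU), where the on-call physician
decides whether the patient goes straight to the catheterization laboratory
for acute percutaneous coronary intervention (PCI). Because ST-elevation
myocardial infarction (STEMI) must not be missed, ECGs are transmitted
liberally, and most of them turn out negative. A screening classifier with
a very high, fixed sensitivity can withhold the clearly negative ECGs and
spare the physician the bulk of the traffic: only screen-positive ECGs are
transmitted, and the physician remains the confirmatory reader in series.

`stemiscreen` implements that pipeline end to end: synthetic cohort
generation, waveform measurement, dimensionality reduction, a bagged
neural-network ensemble, and diagnostic-test evaluation with
sensitivity-anchored triage.

## Synthetic cohorts

No ambulance ECG waveforms are publicly deposited for this problem, so the
package ships a seeded generator (`generate_cohort()`) that emulates a
screening cohort: by default 560 records at a STEMI prevalence of 38/560
(about 7%), with the need of acute PCI drawn conditionally
(P(PCI | STEMI) = 0.9, P(PCI | no STEMI) = 0.01, mirroring the
near-complete overlap of the two outcomes in such cohorts).

Each beat is a sum of five Gaussian components (P, Q, R, S, T) per lead.
Eight leads (I, II, V1–V6) are synthesized independently; III, aVR, aVL,
aVF are derived exactly through the Einthoven/Goldberger relations, so the
linear lead identities hold to machine precision in every record — a
property the test suite checks. Defaults are typical clinical values:
500 Hz sampling, 10 s records, 60 bpm, additive white noise of 0.02 mV and
a 0.05 mV / 0.3 Hz sinusoidal baseline wander per lead.

STEMI cases receive an ST-segment offset in one of three territories
(anterior V1–V4, inferior II/III/aVF, lateral I/aVL/V5/V6). The offset is a
plateau of the drawn magnitude spanning the J point through the end of the
T wave, entered and left through 20 ms raised-cosine ramps so no step
discontinuity is introduced. The injection is applied to the synthesized
basis leads and the limb leads are re-derived, which both preserves the
lead identities and produces the physiological reciprocal depression (an
inferior injection depresses aVL by half the magnitude). Magnitudes are
drawn uniformly from 0.15–0.5 mV and clamped to clear the territory's
diagnostic threshold (0.2 mV in V1–V3, 0.1 mV elsewhere; 1 mm = 0.1 mV)
with a 0.05 mV margin, so generated labels satisfy the rule-based criterion
on noise-free ground truth.

What the generator does **not** emulate: realistic P/T morphology
variation, arrhythmias, bundle branch block (left bundle branch block
belongs to the clinical STEMI definition but has no waveform description
to build from, so it is excluded rather than guessed), pectoral muscle
noise bursts, electrode motion artifacts, or the slight waveform changes of
proximal ("Lund") limb-lead placement. Passing tests on this generator
therefore demonstrate that the pipeline's machinery is correct and can
recover a clean ST signal — not that it reaches any particular performance
on real ambulance ECGs.

## Waveform measurement

`detect_fiducials()` computes one global set of beat landmarks per record
on the root-mean-square (RMS) signal across the 12 leads — more robust than
per-lead detection when single leads are noisy. The RMS maximum of each
beat is the R peak; QRS onset and offset are found by scanning outward
until the absolute RMS slope stays below 10% of its beat maximum for at
least 8 ms; T end is the return of the RMS to within 0.05 mV of its
baseline level after the T peak. A record whose RMS never reaches 0.2 mV
contains no usable beat and is rejected.

`measure_lead()` extracts 13 measures per lead, relative to a per-lead
isoelectric baseline (mean over a 40 ms PR window ending 10 ms before QRS
onset) and averaged over beats: Q, R, S amplitudes (unsigned, zero when the
deflection is absent), QRS area (mV·ms), QRS duration (ms), positive and
negative T amplitudes, and six signed ST amplitudes. The six ST positions
are J + 0, 16, 32, 48, 64, 80 ms — equally spaced J-anchored samples
covering the clinically read ST segment; the exact positions are a design
choice (configurable in source) since only their number is canonical.
Concatenated over the 12 leads this yields the 156-variable feature vector
(`extract_features()`), in the fixed order I, II, III, aVR, aVL, aVF,
V1–V6 × the 13 measures.

`stemi_criteria()` encodes the rule-based ECG criterion: at least two
adjacent leads with J-point ST elevation ≥ 0.2 mV in V1–V3 or ≥ 0.1 mV in
other leads. "Adjacent" is defined explicitly (the rule itself never is):
consecutive precordial pairs, plus any pair within {II, III, aVF},
{I, aVL}, and {V5, V6, I, aVL}.

## Reduction to network inputs

`fit_reducer()` standardizes the 156 features (they mix mV, ms and mV·ms;
unscaled PCA would be dominated by area and duration), fits PCA, keeps 20
components, and Z-scores the component scores with training-set means and
standard deviations. All parameters are frozen at fit time;
`apply_reducer()` is pure, so no test-set information can leak into the
transform. Component signs are fixed (largest-magnitude loading entry
positive) for bit-reproducibility. An alternative reading — Z-scoring raw
features instead of component scores — is noted as possible; the package
Z-scores the scores, which is the natural input scaling for the network
either way.

## The ensemble classifier

Each member is a fully connected feed-forward perceptron: 20 inputs, one
hidden layer of 15 tanh units, one logistic output. The training loss is
the summed cross-entropy plus a weight-elimination penalty

$$E = \sum_i -[t_i \ln y_i + (1-t_i)\ln(1-y_i)]
      + \lambda \sum_w \frac{w^2/w_0^2}{1 + w^2/w_0^2},$$

over the connection weights only (biases unpenalized). Each penalty term
saturates at 1, so the penalty prunes small weights without forbidding
large ones; $w_0 = 1$ is the natural scale for Z-scored inputs. This is the
canonical weight-elimination form; $\lambda$ (default 0.01) and the hidden
layer size are selectable by stratified cross-validation
(`cross_validate()`, 5 folds, selection on mean held-out AUROC, ties broken
toward larger $\lambda$ then fewer hidden nodes).

Training choices are made for determinism and testability: weights
initialized uniformly in [−0.1, 0.1] from a per-member seed, full-batch
gradient descent with a fixed learning rate for a fixed epoch count
(defaults 0.5 and 300). The loss is defined as a sum over cases, but the
descent step uses the mean gradient (`learning_rate * gradient / n`), so
the same learning rate works across training-set sizes. The analytic
backpropagation gradient is verified against central finite differences to
1e−5 relative error — the central correctness oracle of this module.

The ensemble (`train_ensemble()`) bags 25 members, each trained on its own
full-size bootstrap resample with its own derived seed; a resample that
happens to contain one class is redrawn from a disjoint seed stream.
Prediction is the arithmetic mean of member outputs, hence always inside
(0, 1). `cross_validate()` trains a single network (not a full ensemble)
per fold and grid point — the selection signal is the same and the cost is
25-fold lower.

## Evaluation and triage

A case is called positive iff its score ≥ the threshold (closed lower
bound; this fixes tie behavior). `auroc()` uses the rank (Mann–Whitney)
form with ties counted ½, which is identical to the trapezoidal area and
is checked against an all-pairs oracle and against pROC in the tests. The
AUROC interval is a stratified bootstrap percentile interval (2000
replicates, seeded; positives and negatives resampled separately so no
replicate is degenerate), widened if necessary to contain the point
estimate.

`threshold_at_sensitivity()` returns the largest threshold whose
sensitivity meets the target (default 0.95) — equivalently, the maximal
specificity subject to the sensitivity constraint. By default the anchor is
placed on the training cohort's own predictions and then applied to the
test cohort; calibrating on the test cohort itself (the apparent-
performance mode, as when an operating point is set on the study cohort) is
available via `calibration = "test"`.

Sensitivity, specificity, PPV and NPV all carry exact Clopper–Pearson
intervals (beta-quantile inversion; `binom.test` is the independent oracle
in the tests). `serial_combine()` models the two-stage workflow — combined
positive iff screen and confirmatory reader agree — and
`transmission_reduction()` reports the fraction of ECGs withheld.

## Numerical choices and degenerate inputs

* Clipping of network outputs to [1e−12, 1−1e−12] before logarithms.
* Constant feature columns get sd 1 with a warning (they carry no variance
  and are annihilated by centering).
* ST sampling positions beyond the record end are clipped to the last
  sample with a warning.
* Fiducial scans that never meet the quiescence criterion fall back to a
  ±120 ms QRS search window edge; T end falls back to just before the next
  beat.
* All seeds are derived from one integer by a fixed mixing function and
  stay inside the signed 32-bit range.

## Problem sizes

The study-design defaults are a 3000-record training cohort (prevalence
0.2, so roughly 600 positive examples reach the trainer) and a 560-record
test cohort at prevalence 38/560. A full `run_experiment()` at these sizes
takes on the order of one to two minutes on a single CPU; the test suite
exercises the same code paths mostly on smaller cohorts (tens to hundreds
of records) plus one full-sized signal-recovery run. The prevalence-
recovery property is checked on 10,000 short (2 s, 100 Hz) records, which
share the label-drawing code with the full-length ones.

## Known limitations

* The generator's STEMI signal is far cleaner than real ischemic ECG
  change; test AUROC near 1.0 on synthetic cohorts says nothing about
  clinical performance.
* Fiducial detection assumes a regular rhythm at the configured heart
  rate; it is not a general-purpose QRS detector.
* The per-record ST measurement uses global (cross-lead) fiducials;
  leads with genuinely divergent timing (e.g. bundle branch block) are out
  of scope.
* `cross_validate()` selects hyperparameters with single networks per
  fold; the selected point is then used for the full bagged ensemble.
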