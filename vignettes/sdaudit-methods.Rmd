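---
title: "Auditing neonatal seizure detection algorithms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing neonatal seizure detection algorithms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdaudit)
```

## What this package audits, and how

Automated seizure detection algorithms (SDAs) for continuous multichannel
neonatal EEG output a per-epoch probability of seizure which is compared to
an adjustable sensitivity threshold; runs above the threshold become
detector events. Standard engineering metrics — the seizure detection rate
(SDR), false detections per hour (FD/hr), and epoch-based
sensitivity/specificity — summarize performance but say nothing about
*which* seizures a detector misses or *why* it false-alarms. `sdaudit`
implements the deeper, electrophysiology-oriented audit: score every
expert-annotated seizure on a ten-criterion schema, model which features
predict automated detection with random-intercept logistic regression, and
categorize every false detection into an artefact taxonomy with per-patient
and per-threshold structure.

The package operates on exported annotation lists (expert gold standard) and
detector event lists (onset, duration, channel of peak detection, one list
per threshold), plus a per-seizure feature table. Because clinical EEG
cannot be bundled, a synthetic-data module generates every input with known
ground truth, and a small transparent reference detector lets the whole
chain run end to end on raw (synthetic) EEG.

## Event matching

Intervals are half-open `[start, end)` in seconds from record start; clock
times in exported lists are converted with an explicit record start time. A
gold seizure counts as **detected** if at least one detector event overlaps
it by any nonzero amount, on any channel — the detection-anywhere
(spatio-temporal manifold) rule used clinically: a long generalized seizure
flagged for 30 s on one channel is a detected seizure. A detector event
overlapping no gold seizure is a **false detection**; an event straddling
two seizures marks both detected and is not a false detection; every event
is classified exactly once. "Coincident" is not quantified further, so the
default demands any nonzero overlap; a symmetric `tolerance` (seconds,
default 0) is exposed for sensitivity analyses. Detector events are counted
as exported — no merging of adjacent events — and the FD/hr denominator is
the full record duration including seizure time, since false-detection
rates are reported for whole recordings.

Epoch metrics tile each record into non-overlapping epochs (default 1 s,
configurable; the natural resolution of per-second probability outputs) and
label an epoch positive if it overlaps any gold (resp. detector) interval;
sensitivity and specificity follow from the pooled confusion counts.

## The seizure assessment schema

Ten criteria per seizure, in three groups:

* **Signal signature** — peak-to-trough amplitude (µV) measured on the
  highest-amplitude discharge at mid seizure; rhythmicity (1 = significant
  dysrhythmia … 3 = highly rhythmic); background EEG score (1 = normal …
  3 = severe abnormality); discharge morphology at onset and at peak
  (RDD/RDT/RDA rhythmic delta/theta/alpha discharges, SH spikes/sharp
  waves, SH+W/SP+W sharp-/spike-and-slow-wave complexes).
* **Temporal context** — duration (s); frequency variability, the sample
  standard deviation (n − 1; the convention of standard statistical
  packages) of the discharge frequency read over the first 5 s, at mid
  seizure, and over the last 5 s (Hz); morphology change onset→peak
  (boolean).
* **Spatial context** — number of channels involved at onset and at peak.

Visual scores are manual-entry inputs; `validate_feature_table()` enforces
the closed vocabularies and ranges, flagging (not throwing) issues. The
onset vocabulary has five morphology levels; at seizure peak RDA is rarely
observed and a four-level variant is the default, switchable via
`peak_variant`. Amplitude is in microvolts peak-to-trough throughout.

Automated helpers exist for synthetic data only and never substitute expert
scores: `peak_amplitude()` is the mid-window excursion (max − min), which
is DC- and sign-invariant but positively biased by additive noise extremes
— on clean discharges it recovers the planted envelope to within 5%;
`dominant_frequency()` takes the periodogram peak over 0.3–8 Hz (the
neonatal discharge range implied by the delta/theta/alpha morphology
categories) after whitening by frequency (neonatal background is
approximately 1/f) and 5-bin smoothing, so that broadband segments do not
fake a narrow peak by chance; a peak-to-mean prominence below 4 flags the
estimate as low confidence. An autocorrelation method is available as an
alternative.

## Modelling detectability

For each threshold independently (separate analyses per threshold), the
detected/non-detected indicator is modelled by mixed-effects logistic
regression with seizure features as fixed effects and baby identity as a
random intercept, acknowledging that seizures cluster within babies. Fits
use `lme4::glmer` with adaptive Gauss–Hermite quadrature (15 nodes by
default; estimates move by less than 1e-4 when refined to 31) and fall back
to the Laplace approximation on failure. Results are reported as odds
ratios with 95% Wald intervals, `exp(est ± 1.959964·se)`.

The model-building procedure is: univariate screen of every feature
(significance at p < 0.05; one p per feature — Wald z for single-coefficient
terms, block likelihood-ratio for multi-level categorical terms);
collinearity filter on the candidates (absolute pairwise Spearman
correlation above 0.8, configurable, with ordinal/categorical features
entering by their numeric codes; within a collinear cluster the feature
with the highest univariate AUC is kept, and each decision is logged);
backward stepwise deletion, repeatedly removing the largest non-significant
term until all remaining terms have p < 0.05 (an empty model returns the
intercept-only fit with a warning). Reference levels are fixed at RDD for
morphology, significant dysrhythmia for rhythmicity, and normal background.
No multiple-testing correction is applied, matching common practice for
this kind of exploratory audit.

Model discrimination is the AUC of the fixed-effects (population-level)
linear predictor with a DeLong 95% CI — the honest choice for predicting
detection in a *new* baby, since random intercepts are unknown out of
sample; a conditional AUC is available behind a flag. Competing models on
the same seizures are compared with the paired DeLong test. Per-patient
FD/hr distributions between seizure and seizure-free babies are compared
with the Mann–Whitney U test, exact for small untied samples (both n ≤ 10,
the typical 10-vs-10 design) and normal-approximated with tie correction
otherwise.

Two numerical safeguards: (quasi-)complete separation is screened with a
plain logistic fit before quadrature (error naming the offending term when
the linear predictor is pinned beyond ±12 and a unit-scaled coefficient
exceeds 8); and a constant linear predictor makes the AUC undefined,
signalled rather than defaulted.

On the boundary between the mixed and the ordinary model: when data are
generated with zero random-intercept variance, the variance MLE lands
exactly on the boundary in most replicates — and there the GLMM must
reproduce `glm` coefficients to numerical accuracy (1e-3), which is how the
quadrature machinery is validated. In the remaining replicates the variance
estimate is a small positive sampling artefact (this happens with any
maximum-likelihood mixed-model software); those fits are checked against
the weaker but universal property that the mixed log-likelihood can never
fall below the nested ordinary fit's.

## False-detection analysis

Every false detection carries one of nine artefact categories
(`fd_categories()`): respiration, ECG/pulse, chewing/sucking, bad/loose
electrode, patient movement/handling, electronic equipment, sweat,
unclassified artefact, or no obvious artefact — the last requiring a
background description (normal, highly rhythmic, sharp waves, low
amplitude). Labels are closed-vocabulary strings; unknown labels are
rejected, never coerced, and categorization itself is an expert-supplied
input (no automated artefact classifier is claimed).

`aggregate_fd()` tabulates counts and percentages of all false detections
per category, with the no-artefact breakdown expressed as percentages of
the no-artefact count; rendered tables round to one decimal, machine output
keeps full precision. `patient_concentration()` reports the single patient
dominating a category — in practice one recording often contributes the
majority of, say, respiration-artefact false detections.
`threshold_dropoff()` expresses each category's count at every threshold as
a fraction of its count at the most sensitive threshold: sustained rhythmic
artefacts that mimic seizure morphology (respiration, pulse) hold high
detector probabilities and survive threshold raises, while intermittent
semi-rhythmic artefacts (sweat) collapse.

## The synthetic cohort generator

`generate_cohort()` draws a cohort emulating a neonatal monitoring study:
10 babies with seizures plus 10 seizure-free babies, one record each with
lognormal duration centred on 63.1 h (so ~1260 h of EEG in total), and a
zero-truncated Poisson number of seizures per seizure baby with mean 40
(~420 seizures per cohort). Feature distributions are chosen to look like
scored clinical seizures: lognormal duration (median 60 s) and amplitude
(median 70 µV), 25/35/40% rhythmicity levels, onset morphology
predominantly rhythmic delta, evolution to sharp-and-slow-wave complexes
with probability 0.45, channel counts at peak 1 + Binomial(7, 0.45) with
the onset count derived from (hence strongly correlated with) the peak
count, and frequency variability as the sample SD of three lognormal
frequency readings.

Detectability is planted as a latent-variable logistic model: with
`eta = intercept + b_baby + beta' (x - mean)` and `u` standard-logistic
noise, the latent probability `p = plogis(eta + u)` is drawn **once** per
seizure and compared to every threshold, so `detected_at(t) = (p >= t)`.
This single-draw construction guarantees the threshold nesting observed in
real sweeps (raising the threshold can only lose detections), and makes the
indicator at threshold `t` follow exactly a random-intercept logistic model
with intercept shifted by `-qlogis(t)` — so fitted feature effects are
directly comparable to the planted ones. Default planted effects put the
signal in duration (log 1.02 per second, i.e. OR 1.02/s — the scale on
which duration effects are conventionally reported), amplitude (log 1.02
per µV), rhythmicity (log 2.5 and log 8 against significant dysrhythmia)
and channels at peak (log 1.5 per channel), with the remaining features
null; the per-baby intercept SD defaults to 1.

`generate_fd_stream()` plants a clustered false-detection process: Poisson
per-category counts over the cohort's total hours, spread over patients by
a Dirichlet-multinomial draw (concentration 0.3, so single patients
dominate categories, as observed clinically), each event carrying a latent
uniform level compared against a per-category survival profile so that
higher-threshold event lists are exact subsets of lower-threshold lists.
Default rates and survival profiles are stylized from an audited cohort's
per-category totals over ~1263 h: respiration the most common and most
persistent (retention 0.8 at the least sensitive threshold), sweat common
but fragile (retention ~0.09), no-artefact in between.

## Synthetic EEG and the reference detector

`synthesize_eeg()` builds toy multichannel EEG on an eight-channel neonatal
bipolar montage at 256 Hz: pink-noise (1/f) background at 25 µV RMS, plus a
planted waveform on the first `channels_involved` channels. Seizures are
amplitude-enveloped oscillations (cosine-tapered so mid-seizure reaches the
full peak-to-trough amplitude) whose instantaneous frequency is resampled
every second with relative jitter 0.35/0.15/0.04 for rhythmicity 1/2/3, and
whose waveform morphs linearly from a near-sinusoid to a harmonic-rich
spike-and-slow-wave shape when `evolution` is set. Respiration artefact is
a sustained ~0.9 Hz sinusoid; sweat an intermittent ~0.35 Hz semi-rhythmic
drift; pulse an impulse train at cardiac rate convolved with a decaying
delta-band kernel; movement high-amplitude broadband bursts. None of this
claims physiological realism: it reproduces the *amplitude, rhythmicity,
spectral-concentration and persistence contrasts* the audit methodology
keys on, which is what passing tests certify — not performance on clinical
EEG.

The reference detector mirrors the canonical SDA architecture in a
transparent form: per channel, 8-s epochs with 50% overlap; per epoch a
three-feature vector (log RMS amplitude relative to 25 µV, spectral
concentration within ±0.4 Hz of the in-band peak, normalized spectral
entropy over 0.3–12 Hz); a fixed linear score (intercept −4.2, weights 1.9,
5.2, 3.0 on log-RMS, concentration, and one-minus-entropy) through a
sigmoid; moving-average smoothing over 3 epochs; cross-channel combination
by per-epoch maximum; events as maximal runs above threshold with onset,
duration, and channel of peak probability. Epochs with RMS above 300 µV are
pre-masked to zero probability (gross-artefact energy gate). The weights
are fixed, documented constants — the detector audits the *pipeline*, it is
not trained and claims no clinical performance; they were chosen so that
pink-noise background sits near probability 0.1, high-amplitude rhythmic
discharges and sustained respiration artefact near 0.95, and low-amplitude
dysrhythmic single-channel discharges below the usual 0.4–0.6 operating
band — reproducing the characteristic detected/missed contrast and the
artefact-driven false detections the audit is designed to expose.

`adaptive_baseline()` implements local-baseline correction of a probability
trace: subtract the trailing-window median (default 30 min — long relative
to seizures, short relative to artefact runs; the window is configurable
because no canonical value exists) and rescale the remaining headroom by
`1 / max(1 - median, 0.5)`. The floor stops a near-saturated baseline from
amplifying its own fluctuations; a constant elevated trace corrects to ~0
after warm-up, isolated transients on a quiet baseline pass through
unchanged, and a transient superimposed on a step of sustained elevation
survives while the step itself is suppressed. Traces shorter than the
window use available history, with a warning. The subtract-rescale form is
one admissible reading of "comparison to the local preceding baseline" and
is isolated in a single function so alternatives can be swapped in.

## Numerical and testing choices

* Quadrature: 15 nodes default, Laplace fallback; derivative-based
  convergence checks are disabled in favour of optimizer status (the
  gradient check is noisy for binary GLMMs near boundaries).
* Ties in AUC count one half, matching the rank-sum definition; AUC is
  validated against brute-force concordance counting for n ≤ 200.
* The exact Mann–Whitney p for {1,2,3} vs {4,5,6} is 0.1 (2 of the 20
  equally likely orderings are at least as extreme, doubled).
* Test problem sizes are chosen to make sampling bands sharp but cheap:
  1,000 random matching instances against the brute-force oracle, 200
  cohort replicates of 20 babies × 20 seizures for CI coverage, and
  one-hour synthetic records for detector scenarios.

## Known limitations

* Expert visual scores (rhythmicity, morphology, background, channel
  counts) cannot be computed from EEG by this package; automated helpers
  serve the synthetic pipeline only.
* The synthetic EEG has no sleep–wake architecture, no inter-seizure
  background evolution, and no real artefact morphology; conclusions about
  clinical detectors require clinical EEG.
* Mixed-model Wald intervals are first-order; with very few babies or rare
  categorical levels, profile or bootstrap intervals would be preferable.
* The reference detector's fixed weights are a design point, not an
  optimum; its purpose is to exercise the audit, not to compete with
  trained SVM-based detectors.
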