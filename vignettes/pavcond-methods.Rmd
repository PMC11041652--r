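---
title: "Methods: quantifying cue-punishment conditioning across recording modalities"
author: "pavcond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cue-punishment conditioning across recording modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavcond)
```

## The experimental design the package models

`pavcond` analyzes recordings from an aversive Pavlovian conditioning task
in head-fixed mice. One auditory cue (CS+) predicts an airpuff to the eye
(US), a second cue (CS-) does not. A habituation session presents 30 CS+,
30 CS- and 5 unpredicted airpuffs in random order; a conditioning session
presents 30 CS+ each followed, 0.5 s after cue offset, by a 0.5-s airpuff,
interleaved with 30 CS-. Cues last 1 s and inter-trial intervals are drawn
uniformly from 30-45 s. Four data modalities are analyzed around this
task: extracellular spike trains with foot-shock stimulation (anesthetized
preparation), two-photon calcium traces of individual habenular neurons,
eye-area videography of the anticipatory blink, and fiber-photometry
photon counts from neurotransmitter sensors.

All trial-aligned analyses share one time convention: trial time zero at
cue (or event) onset, windows half-open `[start, end)`, sample indices
mapped as `floor((t - t_start) * rate)`. Behavioral and imaging trials
span 15 s starting 5 s before the event.

## Spike trains: featurization and foot-shock classification

Spontaneous activity is characterized by the firing rate, the coefficient
of variation of the inter-spike intervals (ISI SD / mean), the burst index
(fraction of ISIs below 25 ms), a 100-bin ISI histogram (10-ms bins over
one second) and autocorrelograms at 1-ms resolution over 1-500 ms and
1-100 ms. The 1-s window after each foot shock is excised from all
spontaneous statistics, and ISIs are never taken across an excised window
(the source recordings leave open whether stimulation windows were
excluded; excising them keeps "spontaneous" honest). The cohort embedding
uses 15 features per neuron: the first four principal components of each
of the three histogram families - PCA fitted on the whole cohort, each
family separately, which is the only reading that sums to 15 with the
three scalar features - plus rate, CV and burst index, z-scored across the
cohort and embedded in two dimensions with exact t-SNE (perplexity 30,
seeded; the exact O(n^2) gradient is adequate for cohorts of a few
hundred neurons and is implemented in the package because the R stack
used here ships no t-SNE).

Foot-shock responses compare per-trial spike counts in the 1-s pre-onset
baseline against the 1-s post-onset window with a Wilcoxon rank-sum test
at `alpha = 0.05`; only neurons with more than 20 stimulation trials are
accepted. The test is applied unpaired, as named, although the design is
paired; a signed-rank variant sits behind `paired = TRUE`. Response
strength is the modulation index
`(FR_stimulus - FR_baseline) / (FR_stimulus + FR_baseline)`, defined as 0
with a degeneracy flag when both rates are zero so cohort tables stay
total. The population statistic is the Pearson correlation between
spontaneous rate and modulation index, which is negative when excitation
concentrates in low-firing neurons.

## Calcium imaging: dF/F0, AUC classification, plasticity

Fluorescence is converted trial by trial to
`dF/F0 = 100 * (F - F0) / F0`, `F0` being the mean over the 3 s before
cue onset. The response statistic is the trapezoidal AUC of dF/F0 over
the anticipatory window (cue onset to airpuff onset, 0-1.5 s) compared
against the AUC over the 1.5-s baseline ending at cue onset (the baseline
placement immediately before the cue is the package's choice), again with
a rank-sum test at 0.05 and a 5-trial minimum per cue. For airpuff-epoch
classification the response window is the 0.5-s airpuff; because an AUC
scales with window length, the airpuff comparison uses a duration-matched
0.5-s baseline rather than the 1.5-s one. Numerically, window AUCs treat
the window as half-open: the sample falling exactly on the window end
belongs to the next epoch (so the airpuff transient never leaks into the
anticipatory AUC), and the final subinterval is extended at the last
included value so a constant trace `c` integrates to exactly
`c * length`.

Plasticity across learning is a Pearson chi-squared test (no continuity
correction) on the 2 x 3 contingency of inhibited / nonresponsive /
excited counts in habituation versus conditioning, restricted to neurons
tracked in both phases; a class empty in both phases is dropped with a
degrees-of-freedom adjustment. Histological expression is quantified by
the relative arbitrary fluorescence
`(signal - background) / (signal + background)`.

## Behavior: conditioned response and discrimination score

Eye-area traces (10 Hz) are normalized per trial to percent of the mean
area over the 5 s before the cue. The conditioned-response amplitude is
the mean normalized area between cue onset and airpuff onset (0-1.5 s);
lower values mean a stronger anticipatory blink. The discrimination score
is the CS- mean minus the CS+ mean, positive when blinking is selective
for the punishment-predictive cue; this sign convention makes successful
learning positive. Trials with non-positive baselines (tracking dropouts)
are dropped rather than interpolated. Group-level learning is a paired
t-test of per-mouse discrimination scores, habituation versus
conditioning.

## Decoding: per-neuron eyeblink prediction

For each neuron, trials are labeled by the session-wise percentiles of
the conditioned response (linear-interpolation quantiles): below the 40th
percentile one class, above the 60th the other, the overlapping middle
band excluded - the printed labeling rule overlaps on the middle band, and
the dead-band reading is the only one yielding disjoint classes. The
scalar feature is the cue-window AUC (0-1.5 s), standardized on the
training split only. One hundred repeated stratified random splits (20 %
held out) replace a literal 100-fold scheme, which is impossible with ~60
trials; k-fold is available in spirit by setting the test fraction. Per
split, the penalty (`0.1, 1, 10, 100`) and RBF kernel width (scaled
default, `0.01, 0.1, 1`) of a support-vector classifier are selected on
an inner stratified holdout of 25 % of the training split (leakage-free
and several-fold cheaper than inner k-fold, with identical selections on
these one-dimensional features), the winner refit and scored on the test
split; accuracy is the mean over splits. The shuffle null permutes the
blink labels once (seeded; permuting labels rather than cue identity is
the reading consistent with the decoder's target) and reruns the
identical procedure on the same split stream, so the
accuracy-versus-shuffle comparison is paired and an identity permutation
reproduces the unshuffled accuracy exactly. The population test is an
unpaired t-test of accuracies against shuffle accuracies. On planted-null
data single-neuron accuracies scatter around 0.5 with SD near 0.07 (an
inherent property of repeated small splits), which is why calibration
claims are made at the cohort level.

## Photometry: transients, validity, binned cue effect

Photon counts (10-ms bins) are smoothed with a centered 10-sample running
average with edge truncation (a trailing window is available); dF/F0 uses
the same formula as imaging with `F0` anchored at the event onset -
including unpredicted airpuffs, whose baseline is the 3 s before the
airpuff itself. The per-trial statistic is the peak dF/F0 over 0-1.5 s;
centered smoothing bleeds a few post-onset samples into the F0 span, a
sub-percent edge effect the tests account for. Signal validity follows
the habituation-average rule: the response span is cut into consecutive
50-ms epochs and the signal is valid when at least 3 epoch means (not
necessarily consecutive) lie beyond the baseline mean +/- 2 SD; an animal
is kept when any habituation stimulus (CS+, CS-, airpuff) passes. Peaks
are averaged over consecutive 5-trial bins per cue and phase (a trailing
partial bin is kept and flagged), and the sensor-level statistic is the
cue main effect of a cue-by-bin analysis of variance on the conditioning
bins pooled across animals; when a single animal saturates the
interaction the additive model is used.

## The synthetic cohorts: what they plant and what they omit

Every analysis is validated against generated cohorts whose ground truth
is emitted alongside the data; all generators are pure functions of their
parameters and a master seed (per-entity seeds derive from it by a fixed
counter scheme).

**Spike cohorts.** Baseline rates are log-normal (median 5 Hz, log-SD
0.8, a realistic habenular range). Foot-shock modulation couples to rate
through a Gaussian copula: the modulation coordinate correlates with
log-rate at `coupling_rho` (default -0.5), classes are assigned by its
order statistics at the planted proportions (0.68 excited / 0.19
inhibited / 0.13 non-modulated, the proportions reported for this
preparation), and within each class the planted modulation index spreads
monotonically by +/- 50 % around `(R - 1) / (R + 1)` for effect ratio `R`
(default 3). The realized rate-modulation correlation is mildly
attenuated relative to `coupling_rho` because class assignment is a step
function; at the defaults it stays within 0.15 of -0.5. Spiking is a
gamma-renewal process simulated by time rescaling through the
piecewise-constant rate (stepped by the per-neuron effect ratio in each
1-s post-shock window), with burst riders (probability 0.15 of 2-4 extra
spikes at 5-15 ms lags) and a 1-ms refractory pass. Rate steps, not
kinetic subtypes, are modeled: the classification window statistic is
insensitive to within-window kinetics.

**Calcium cohorts.** Transients are unit-peak double-exponentials (50 ms
rise, 500 ms decay, GCaMP6f-like) sampled at 5 Hz, signed by class
(0.36 excited / 0.14 inhibited / 0.50 nonresponsive), with amplitude
10 % dF/F0 in habituation and 20 % in conditioning and additive Gaussian
noise (SD 5 %). Each responsive neuron expresses its habituation response
with probability 0.5 and always responds during conditioning - modeling
both enhancement of existing responses and recruitment of new responders,
which is what shifts the class distribution across learning. Paired
airpuffs add a same-signed transient at 1.5 s. A shared per-trial latent
(SD 0.3) scales all responsive neurons together; it is the hook through
which behavior couples to neural activity.

**Behavior.** On CS+ trials the eye area drops by a fractional depth
during the 0-1.5 s window (mean 0.05 in habituation, 0.3 in conditioning
for learners; zero for non-learners; trial noise SD 0.05), airpuffs force
a near-total closure, and CS- trials blink only by noise. With
`neuron_coupling` the depth is modulated by the calcium cohort's shared
latent; at coupling 1 with zero blink noise the depth is strictly
increasing in that latent, so blink rank order equals neural-activity
rank order. The decoder validation cohort uses coupling 1 with the
idiosyncratic calcium noise turned off, which is what "full coupling"
means operationally.

**Photometry.** Counts are Poisson around a 50 photons-per-bin baseline
modulated by unit-peak transients at each cue and airpuff. A stable
sensor (glutamate / GABA / serotonin-like) keeps amplitudes 0.4 (cues)
and 1.0 (airpuff) in both phases; a potentiating (acetylcholine-like)
sensor doubles its CS+ amplitude to 0.8 during conditioning. Sessions are
concatenated with a 60-s gap and events carry phase labels.

The generators plant exactly the statistical structure the analyses test
and nothing else: no slow drift or bleaching, no motion artifacts, no
correlated noise across neurons beyond the shared amplitude latent, no
foot-shock kinetic diversity, no video-level nuisances. Passing tests
therefore certify the statistical machinery - calibration of the rank
tests, recovery of planted classes, detection of planted couplings - not
robustness to instrumental nuisances that upstream preprocessing is
assumed to have removed.

## Numerical and design choices

- Significance is `p <= 0.05` two-sided throughout and configurable; the
  rank tests use the normal approximation with mid-rank tie correction.
- The rank tests are unpaired by design fidelity even where trials pair
  naturally; signed-rank variants are exposed behind flags.
- Events whose trial window leaves the recording are dropped with a
  warning by default (mirroring trial exclusion practice); a strict mode
  fails instead.
- Sessions without a behavioral learning phenotype can be screened by
  requiring a positive conditioning discrimination score before imaging
  sessions enter the plasticity contingency; the threshold is the
  caller's choice since no numeric criterion is fixed by the protocol.
- On-disk formats are plain text: CSV matrices/series with JSON sidecars
  and YAML configs, written at 9 significant digits; the package's
  round-trip tests cover them. These dialects are artifact choices.
- ISI and autocorrelogram binning guards exact bin boundaries with a
  1e-9 epsilon so features are invariant under time translation of the
  recording despite floating-point drift.
- Cohort sizes used by the validation suite and the acceptance script -
  2000 neurons for null calibrations, 400 for foot-shock recovery, 300
  for the plasticity contingency, 50 neurons at 100 repeats for
  decoding - were chosen so binomial bands around the nominal rates are
  tight enough to be diagnostic.

## Known limitations

- The embedding is a visualization aid; no claims are made about cluster
  counts, and t-SNE coordinates are only comparable within one seeded
  run.
- The decoder feature is the scalar cue-window AUC per trial, as in the
  source analysis; population decoding and richer per-trial features are
  out of scope.
- The photometry model treats photon counts as intensity; lifetime
  (TCSPC) information, isosbestic correction and bleaching detrending are
  not modeled.
- The validity criterion's false-positive rate depends on the baseline
  span's autocorrelation after smoothing; it is calibrated here against
  the package's own stationary-Poisson null, not against hardware noise.
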