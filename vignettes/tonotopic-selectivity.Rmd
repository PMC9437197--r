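---
title: "Measuring tonotopic selectivity with cortical onset responses and masked psychophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tonotopic selectivity with cortical onset responses and masked psychophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortone)
```

## The problem

Tonotopy — the orderly mapping of sound frequency along the cochlea and up
the auditory pathway — degrades with sensory hearing loss and, severely,
with cochlear-implant stimulation. Quantifying how *selective* a listener's
frequency analysis is, without hours of behavioural training, calls for an
objective scalp-recorded measure that can be compared directly with
psychophysics, in humans and in laboratory animals.

`cortone` implements one such paradigm end to end. A tone probe is
presented once per second against a continuous noise masker whose bandwidth
is either narrow (1/8 octave) or wide (1 octave), geometrically centred on
4 kHz (human) or 8 kHz (cat). The scalp-recorded *cortical onset response*
(COR) to the probe shrinks when the masker excites the same auditory
filters as the probe; sweeping the probe across frequencies traces out a
masked excitation pattern. The same stimuli support behavioural masked
detection thresholds, and notched-noise maskers yield auditory-filter
bandwidths, so the electrophysiological and psychophysical selectivity
measures can be compared on one stimulus axis.

The package provides: stimulus synthesis (`band_spec()`,
`make_band_noise()`, `make_pink_noise()`, `make_notched_noise()`,
`make_tone_probe()`, `equalize_masker_level()`); COR extraction
(`cor_pipeline()` and its parts); hold-release behavioural scoring and
signal-detection statistics (`score_trials()`, `detection_stats()`,
`fit_threshold_pcmax()`, `permutation_chance()`); staircase simulation
(`run_staircase()`); roex auditory-filter fitting (`fit_roex()`,
`bootstrap_erb()`); the COR-to-threshold-shift conversion (`fit_growth()`,
`masking_to_threshold_shift()`); an excitation-pattern surrogate
(`channel_array()`, `excitation()`); and synthetic-data generators with
machine-readable ground truth (`sim_eeg_session()`,
`sim_holdrelease_session()`, `sim_notch_thresholds()`).

## Stimulus model

Maskers are built in the frequency domain with flat amplitude spectra and
uniformly random phases between brick-wall cutoffs (DC and Nyquist bins
zero), then scaled so the waveform RMS equals the requested dB SPL re
20 µPa; the digital calibration maps 1 unit to 1 pascal. Band edges are
geometric: `centre * 2^(±width/2)`. Pink noise (equal energy per octave,
amplitude ∝ 1/√f) masks quadratic distortion products; its level is
specified per 1/6th octave, 25.3 dB below the narrowband masker's overall
level in the reference paradigm. Notched-noise maskers keep each flanking
band's width constant in Hz as the notch widens, so the spectrum level is
independent of the notch width Δf (0–30% of the centre frequency); Δf = 0
reproduces the 1-octave band exactly.

`equalize_masker_level()` returns the level offset that makes a
rectangular filter of one equivalent rectangular bandwidth (ERB) pass
equal power from two co-centred maskers: +7.9 dB for 1-oct vs 1/8-oct at
4 kHz with the 456-Hz ERB, +8.0 dB at 8 kHz with the 888-Hz ERB. A
rectangular window is an idealization: integrating the same maskers
through a roex filter of equal ERB changes the narrow/wide balance by
about 1 dB (the narrow band loses more under the roex skirts than the
rectangle predicts). This is why the historically used cat 1-oct pilot
level of 73.2 dB SPL does not follow exactly from rectangular-ERB
arithmetic on the printed band edges (which gives 73.0 dB); the package
reports the rectangular-ERB value and treats the residual as model
mismatch, not as an error to be absorbed.

Default sampling rates are 48 kHz for stimulus work (97.7 kHz was used in
the original cat hardware); tests synthesize at 32 kHz, which comfortably
covers all band edges.

## COR extraction

One code path serves both species; only the configuration differs
(`recording_config()`):

* **human** — contralateral-mastoid-minus-vertex montage (P7−Cz for
  right-ear stimulation), epochs −200 to 600 ms around each probe onset,
  zero-phase FIR bandpass 1–20 Hz (1-Hz transition bandwidth, 2-s
  reflection padding so transients fall outside the epoch), ocular
  rejection of epochs whose below-minus-above-eye z-score exceeds 4
  (z over the whole recording), baseline subtraction over −200 to 0 ms,
  N1 = minimum in 50–150 ms, P2 = maximum in 100–200 ms, amplitude =
  P2 − N1.
* **cat** — single derived channel, 3–20 Hz, analysis window 0–120 ms,
  rejection of epochs exceeding 4× the pooled RMS background in that
  window, peaks by the earliest slope reversal of the correct polarity
  (P1 in 15–55 ms, N1 in 55–120 ms), amplitude = P1 − N1.

The first probe of each 13-probe sweep coincides with the masker onset and
is dropped, so 20 sweeps yield 240 analysable epochs per condition.
Masked amplitudes are expressed as `20 log10(masked/unmasked)` dB re the
no-masker condition.

Numerical choices: the FIR is a Hamming-window design with order
`3.3 * rate / transition` (≥ 40 dB attenuation one transition width beyond
the band edges; the group delay of the linear-phase filter is removed
exactly). Slope reversals are detected on a first difference after a 2-ms
boxcar smoothing, earliest reversal winning, because "reversal of the
slope" is not otherwise discretized. The cat preset applies no baseline
correction (only 0–120 ms is analysed and the choice is not documented in
the source paradigm); the human preset does. Artifact flagging never
modifies samples, so the pipeline is invariant to epoch order, and
rejected fractions are reported alongside the result.

## Behavioural scoring and detection statistics

In the hold-release task the animal presses a pedal, holds through a delay
of 2–5 s ("Hold 2" … "Hold 5"), and releases when it detects the probe.
Releases earlier than 1000 ms before probe onset are unscored ("early");
releases in [−1000, 0) ms are false alarms; [0, 1000] ms are hits; later
or absent releases are misses. The half-open boundaries make the
categories an exact partition (the verbal windows leave boundary
membership open; this convention is declared once and tested).

Because the false-alarm window of Hold N+1 coincides with the hit window
of Hold N, later holds serve as catch trials for earlier ones: per-hold
false-alarm rates (Holds 3–5) are averaged with weights given by the
distribution of tested Holds 2–4, and Hold-5 hits are excluded from hit
counts. The published description does not state the rate denominators; we
use hits/(hits+misses) for probe-bearing trials and FA/(all scored trials
of that hold) for the catch rates, since every scored trial survived to
its catch window.

Sensitivity is the equal-variance Gaussian index `d' = z(P_hit) −
z(P_fa)`, and performance the bias-free maximum proportion correct
`P(c)max = Φ(d'/2)`; `d' = 1` corresponds to `P(c)max = 0.69`, the
threshold criterion. (The source's printed equation omits the z on the
second term typographically; both terms are z-transformed, which is also
required for `Φ(d'/2)` to be the unbiased maximum.) Proportions of 0 or 1
are clipped to `1/(2N)` before the z-transform — the standard correction;
the source is silent on this point. Thresholds come from a least-squares
logistic fit of P(c)max versus level with the lower asymptote fixed at
chance (0.5) and the upper at 1, interpolated at the 0.69 crossing;
non-bracketing or non-monotone data are flagged rather than silently
extrapolated.

The chance ceiling for P(c)max is estimated by permutation: release times
are re-expressed on the masker-onset timebase, shuffled across trials
(hold labels fixed — equivalent to shuffling hold labels, and cheaper),
rescored, and the 95th percentile of the permuted pooled P(c)max is
reported. The published ceiling (0.61) depends on that study's trial
counts and is not a reproducible constant; the package instead verifies
*calibration*: on null synthetic sessions the observed statistic exceeds
its own 95% ceiling about 5% of the time.

## Staircases

The human task is 2AFC with a 2-down 1-up rule: level up after every
incorrect, down after two consecutive corrects (the correct counter resets
on every level change), 6-dB steps until the second turnpoint then 2 dB,
stop at 8 turnpoints, run threshold = mean of the last 6; sessions average
2 runs, adding a third when the first two differ by more than 5 dB. The
rule nominally targets the 70.7%-correct point. With finite steps this is
an approximation: the stationary distribution of the induced random walk
centres slightly below the `p² = 1/2` balance point, while an 8-turnpoint
run started above threshold retains a small upward transient. For the
convergence study we fix a logistic 2AFC observer with midpoint 40 dB and
slope 2 dB (a typical steepness for tone-in-noise detection) and start
runs 15 dB above the midpoint, as an experimenter would; simulated at
10,000 runs the mean converged level sits within about 0.2 dB of the
70.7% level, i.e. about one percentage point on the psychometric function.

## roex filter fitting

The auditory filter is the single-parameter symmetric rounded exponential,
`W(g) = (1 + pg) e^{−pg}` with `g = |f − fc|/fc` and `ERB = 4 fc / p`. The
band integral has the closed form
`[(2 + pg₁)e^{−pg₁} − (2 + pg₂)e^{−pg₂}]/p`, verified against adaptive
quadrature to 1e−8. Under the power-spectrum model of masking, the
detection threshold for a tone at `fc` is
`K + 10 log10(fc · Σ_bands ∫W dg · density)`: a fixed efficiency `K` at
the output of one filter centred on the signal (no off-frequency
listening, symmetric notches only — both deliberate scope limits).

`fit_roex()` minimizes squared dB error over `(p, K)`; `K` is linear given
`p` and is solved in closed form, while `p` is profiled on a log grid and
refined by golden-section search, ties broken toward the smaller
(broader-filter) `p`. The loss is unweighted dB-space least squares — the
convention for this model; the source does not state its loss. By default
the model is fit to mean thresholds per notch width, with uncertainty from
resampling *subjects* with replacement and refitting
(`bootstrap_erb()`, 10,000 samples in the reference analyses) — matching
the "fit to the mean data" description while propagating between-subject
variability; a per-subject-fit mode is available by fitting each subject's
rows separately. An optional absolute-threshold floor clips predictions
for conditions limited by thresholds in quiet.

## Level growth and the COR-to-threshold-shift conversion

COR amplitude (in dB re 1 µV) grows roughly linearly with probe level in
dB — about 0.16 dB/dB for human N1–P2 and 0.34 dB/dB for cat P1–N1.
`fit_growth()` fits a shared-slope model (`COR = x·level` + per-subject
intercept + per-subject log10-frequency term when several frequencies are
present) by ordinary least squares with subject-resampling bootstrap CIs.
This replaces the original mixed-model machinery with an equivalent
fixed-slope structure; whether the source model carried subject intercepts
besides its frequency terms is ambiguous, so intercepts are included and
the choice is flagged here. Masked COR reductions divide by the slope to
become equivalent probe-level reductions (`masking_to_threshold_shift()`),
placing electrophysiology and psychophysics on the same dB SPL axis;
`compare_shift_estimates()` sweeps the slope over its confidence limits
(0.13/0.16/0.19 dB/dB), under which all shifts scale exactly inversely.

## The excitation-pattern surrogate

`channel_array()` builds a tonotopic array of roex filters (2 per ERB,
500–16,000 Hz) with an explicit, non-physiological level dependence: a
channel's lower-side steepness is scaled by
`max(0.1, 1 − c(L − 51)/50)` where `L` is its linear output level, so
intense input broadens excitation toward higher channel frequencies. The
default `c = 0.3` is the module's reference operating point. This is a
deliberate stand-in for a compressive nonlinear filterbank and is
validated only qualitatively: at the +10 dB probe-to-masker ratio of the
COR paradigm, a probe on the upper edge of the 1-octave masker excites
more above-masker channels than a centred probe. A symmetric-base
surrogate cannot additionally reproduce the *lower*-edge asymmetry (a real
cochlea spreads little downward because upper filter skirts are steeper
than lower ones); modelling that asymmetry is out of scope, and no
quantitative match to any nonlinear-filterbank output is claimed.
`predicted_masking()` turns filtered masker power at the probe's best
channel (plus a 30-dB detection offset, chosen so a centred probe at
+10 dB SNR suffers masking of the order of tens of dB of equivalent level
reduction) into the generative masking law used by the EEG simulator — a
labelled device for producing ground truth, not a physiological claim.

## What the synthetic data emulate — and what they do not

`sim_eeg_session()` lays out sweeps exactly like the human recordings
(13 probes per sweep at 1-s onset asynchrony, 20 sweep repeats per
condition, ~1.2-s gaps, the first probe coinciding with masker onset), so
240 analysable epochs per condition fall out of the defaults. The response
template is a sum of Gaussians (human: N1 −4 µV at 100 ms, P2 +3 µV at
180 ms; cat: P1 +2 µV at 30 ms, N1 −3 µV at 80 ms), scaled per condition
by `10^((x·(level − ref) + masking)/20)` — a growth law times a masking
law. Background noise is 1/f (amplitude ∝ 1/√f down to 0.5 Hz) at 8 µV
RMS per channel; 80% of each scalp channel's noise power comes from a
shared source, reflecting the volume-conducted origin of low-frequency
scalp background, so the montage difference retains about 5 µV. Ocular
artifacts are slow ±150 µV deflections on the eye channels with scaled
scalp projections, injected at a configurable rate.

These simulations validate bookkeeping, filtering, rejection and the
recovery of injected amplitudes and masking. They do *not* contain real
EEG features — no alpha rhythm, no non-stationarity, no evoked-latency
jitter, no electrode drift — so passing recovery tests demonstrates
correctness of the analysis chain, not robustness to every property of
real recordings. Equally, `sim_holdrelease_session()` draws spontaneous
releases from a per-second hazard that grows with time into the hold
(emulating impatience and yielding false-alarm rates that rise with hold
time) and detection latencies uniform in 200–800 ms; real response-time
distributions are richer. `sim_notch_thresholds()` adds iid Gaussian noise
to power-spectrum-model thresholds — adequate for recovery and bootstrap
calibration, silent about systematic subject differences in filter shape.

One measurement property worth knowing: extremum-based peak picking on an
averaged waveform is biased upward by residual noise (the expected maximum
of noise over a window is positive). At the default noise and 240 epochs
this inflates small masked responses by a few tenths of a µV, so
single-session masking estimates scatter by up to ~1 dB; group means over
a handful of sessions recover injected masking well within 1.5 dB, which
is how the recovery checks are framed.

## Problem sizes used by the test-suite

Unit tests run stimuli at 32 kHz and EEG at 250 Hz (ample for a 20-Hz
analysis band). The heavier simulation checks use: 200 noisy cohorts for
roex ERB recovery (median error < 10%), 100 replicates per slope for
growth-fit bias (< 5%), four 3-condition sessions of 240 epochs for
end-to-end masking recovery (group mean within 1.5 dB), 200 null sessions
× 1000 permutations for chance-ceiling calibration (exceedance ≈ 5%), and
10,000 staircase runs for the convergence study. These sizes give stable
statistics while keeping the default test run fast; all are package
choices, set here once.
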