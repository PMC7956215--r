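---
title: "Fear recognition from ECG, GSR and skin temperature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fear recognition from ECG, GSR and skin temperature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearsense)
```

## The problem

Fear-related emotional states leave an autonomic signature in peripheral
physiology: sympathetic activation raises heart rate and electrodermal
activity and constricts peripheral circulation. `fearsense` implements a
binary fear-recognition pipeline over the three signals a wrist- or
chest-worn device can realistically provide — ECG, galvanic skin response
and skin temperature — together with the evaluation protocols needed to
ask the two questions that matter for a deployed system: how well does a
model personalized to one wearer perform (subject-dependent), and how well
does a model generalize to a wearer it has never seen
(leave-one-subject-out)?

Ground truth comes from dimensional self-reports: each stimulus is rated
on the 1–9 SAM scales for valence, arousal and dominance, and fear is
defined as the low-valence / high-arousal / low-dominance octant of that
PAD space. Windows inherit their trial's binary label.

## Data model and segmentation

A `trial` is a tri-channel block at a common sampling rate (256 Hz in the
emulated protocol) with its self-report and the lengths of the neutral
recovery slots recorded before and after the stimulus. Recovery carries no
stimulus-related physiology and is removed (`trim_recovery`) before
windowing; a 120 s slot with 30 s padding on each side keeps the central
60 s.

`segment_trial` computes all window timing in integer samples: with `N`
samples, window length `L` and step `S`, the count is
`floor((N − L)/S) + 1` and trailing samples that cannot fill a window are
discarded — every feature operator relies on fixed-length input. The
default 20 s window with 10 s overlap balances three constraints: the
full-window periodogram resolves 0.05 Hz/bin (enough to separate the
sub-0.5 Hz autonomic bands), a tri-channel 32-bit window fits in 60 KB of
buffer memory on an embedded target, and skin-conductance responses (1 to
roughly 30 s long) are rarely cut by a window boundary given the 50 %
overlap. A 60 s stimulus therefore yields exactly 5 windows per trial and
100 windows per 20-trial subject.

## Denoising

All filters are odd-length Hamming-windowed linear-phase FIRs applied
zero-phase: the window is reflect-padded by half the filter length,
convolved with the centered taps and cropped, so the output has the
input's length, no group delay, and no start-up transient inside a 20 s
window. Low-pass taps are renormalized to exact unit DC gain, and the
high-pass is the spectral inversion of a unit-DC low-pass, which makes its
DC null exact; at the very low normalized cutoffs used here (0.5 Hz at
256 Hz) a directly designed FIR of practical length would otherwise leak a
substantial fraction of any baseline offset.

Defaults, exposed through `fear_config()`: ECG band 0.5–40 Hz (255 taps) —
a standard QRS-preserving band; GSR low-pass 2 Hz and SKT low-pass 1 Hz
(129 taps) — both signals are sub-Hz phenomena and the 2 Hz edge keeps the
whole 0.05–1.5 Hz phasic band intact.

The ECG additionally passes through automatic gain control before peak
detection: each sample is divided by a smoothed running amplitude envelope
(moving maximum of |x| over 1.5 s, smoothed by a 0.5 s moving average,
floored at 5 % of the global maximum). The envelope span is deliberately
longer than the longest plausible beat interval (1.33 s at 45 bpm), so it
never collapses between beats and amplify T waves, yet shorter than two
intervals, so neighboring beats of different height are normalized
independently. AGC makes the fixed detection threshold scale-invariant;
the floor keeps quiet stretches from amplifying noise.

## Linear features

R peaks are local maxima of the gain-controlled ECG above half its 99th
percentile, with a 0.25 s refractory period resolved in favor of the
larger candidate; inter-beat intervals outside (0.25 s, 3 s) are discarded
as ectopic. The two time-domain ECG features are the mean interval and
SDNN (the sample standard deviation of the intervals). For the spectral
block, the interval series is resampled to a uniform 4 Hz grid by natural
cubic splines — the standard route to a spectrum of an unevenly sampled
beat series — and band powers are read off a single full-window
periodogram (mean removed, rectangular window): LF below 0.08 Hz, MF
0.08–0.15 Hz, HF 0.15–0.5 Hz, with the MF ratio normalized by LF+MF+HF
and the LF/HF ratio flagged to 0 when HF is at machine tolerance. The four
additional 0–0.4 Hz band powers are computed on the preprocessed ECG
waveform itself; a configuration switch (`ecg.band_source = "ibi"`)
computes them on the resampled interval series instead, since the source
signal for these bands is genuinely ambiguous in the protocol the package
follows.

Electrodermal activity splits into a tonic level (centered moving median,
default 4 s, shrinking to the valid range at edges) and the phasic
residual, so tonic + phasic reconstructs the input exactly.
Skin-conductance responses are detected trough-to-peak: each local maximum
of the phasic signal pairs with the preceding local minimum and is kept
when the amplitude reaches 0.01 µS (a common electrodermal convention;
configurable). The GSR time-domain block is the SCR count, mean amplitude
and mean rise time plus raw mean, SD and a dispersion value; the frequency
block is tonic power below 0.05 Hz, phasic power in 0.05–1.5 Hz, and the
low-band ratio.

SKT contributes its mean, SD, skewness and Pearson kurtosis (fourth
standardized moment, not excess — so a Gaussian window scores 3), plus two
band powers (0–0.1, 0.1–0.2 Hz).

### The 48-column contract

The feature registry (`feature_names()`) fixes 48 ordered names: 25 ECG,
17 GSR, 6 SKT. The GSR time-domain block nominally lists first and third
quartiles separately, which would give 49 columns; the default `"iqr"`
profile merges them into a single interquartile range to honor the
48-feature total, and `fear_config(gsr.quartiles = "separate")` emits both
quartiles for anyone who prefers the 49-column layout. Degenerate windows
(too few beats, zero variance, collapsed phase-space geometry) produce
flagged zeros rather than missing values, keeping the 5-windows-per-trial
geometry intact; the flags ride along as an attribute of
`extract_features()`.

## Non-linear features

ECG and GSR windows are decimated to 32 Hz (anti-aliased) before the
non-linear block: their discriminative content for these descriptors lives
well below 16 Hz and the recurrence computations are quadratic in series
length, so a 20 s window becomes 640 points instead of 5120.

The embedding delay is the first local minimum of the auto mutual
information (16 equal-width bins) after light 5-point smoothing of the MI
curve — the raw histogram estimate ripples at the 1e-3 level, and an
unsmoothed first-minimum rule latches onto those ripples well before the
true minimum. The embedding dimension comes from false nearest neighbors
(Rtol = 15, Atol = 2, threshold 1 %), with the neighbor distance floored
at 1e-8 of the signal SD so numerically identical points on a periodic
orbit do not explode the ratio criterion.

The recurrence matrix thresholds pairwise Euclidean distances at 10 % of
the phase-space diameter, read as the mean pairwise distance (the maximum
is noise-dominated; both conventions are available). Recurrence
quantification excludes a Theiler band of one diagonal and uses minimum
line lengths of 2 for determinism, laminarity, diagonal entropy (nats) and
trapping time; the recurrence-rate denominator also excludes the band, so
the line of identity never inflates the rate. Correlation dimension is the
Grassberger–Procaccia slope of log C(r) over log r fitted between the 2nd
and 20th percentiles of the pairwise distances — above that range boundary
saturation flattens C(r) and biases the slope low (a uniform square reads
~1.67 with a 50th-percentile upper end versus ~1.85 here). Multiscale
entropy is the sample entropy (m = 2, Chebyshev tolerance 0.2 × SD of the
scale-1 series) of non-overlapping coarse-grainings at scales 1–5.
Detrended fluctuation analysis integrates the mean-removed series,
removes a per-box linear trend over log-spaced box sizes from 4 to N/4 and
reports the log–log slope: 0.5 for white noise, 1.5 for a random walk.

One deliberate substitution: the "DFA of the inter-beat series" feature is
computed on the 4 Hz-resampled interval series (80 samples per 20 s
window) rather than the raw beat sequence — a 20 s window holds only
20–30 beats, far below any regime where a fluctuation slope is
meaningful.

## Labeling and evaluation

`binarize_pad` is total and deterministic: label 1 iff valence ≤ 5,
arousal > 5 and dominance ≤ 5. Assigning the boundary rating 5 to "low"
(and to "not high" for arousal) is a genuine convention choice — the 1–9
scale has a true midpoint at 5 and the octant definition does not say
which side it belongs to; the midpoint is configurable. With this rule
100 of the 729 possible rating triples map to fear.

Features are standardized per subject (each subject's own mean and SD),
which removes between-subject physiological offsets and, because the
statistics never cross subjects, cannot leak the training pool into a
held-out subject. The converse concern — that a subject's own test folds
contribute to that subject's scaling statistics — is real in the
subject-dependent protocol; an alternative mode
(`evaluate_loso(..., scale_mode = "train")`) freezes statistics on the
training pool for readers who want strict train-only scaling.

Hyperparameters are tuned by sequential model-based optimization: a
Latin-hypercube design over the encoded search space, a Gaussian-process
surrogate (squared-exponential kernel on the unit cube) and the
expected-improvement acquisition over a seeded candidate pool, each
configuration scored by mean stratified 5-fold misclassification. The
default budget is 30 evaluations; the end-to-end tests use 8, which is
already enough to separate the synthetic conditions. The "ensemble"
algorithm is boosted decision trees (exact greedy splits — the histogram
variant places split points at class edges on small samples, which
misclassifies boundary points these data sets genuinely contain). KNN is
implemented directly because the search space includes cityblock distance
and distance weighting. All stochastic components derive from one run
seed; identical seeds give identical models.

The subject-dependent protocol reports fold-averaged validation metrics of
a per-subject stratified 5-fold cross-validation; if a fold lacks one
class (possible for extremely imbalanced subjects), the subject's metrics
are computed on the pooled validation predictions instead. The
leave-one-subject-out protocol tunes and fits on the remaining subjects
and tests on the held-out one; metrics aggregate as mean ± mean absolute
deviation. AUC is the pairwise probability that a positive window
outscores a negative one, with ties credited one half, so a constant
scorer earns exactly 0.5 — the honest value for a degenerate model.

## The synthetic cohort

The generator emulates the structure of the reference recordings: 12
subjects, 20 trials each, every trial 30 s neutral + 60 s stimulus + 30 s
neutral at 256 Hz, self-reports coupled to the imposed condition, and 20 %
of trials in the fear condition by default. Per-subject profiles are drawn
from physiologically typical adult ranges (heart rate 55–85 bpm,
beat-to-beat SD 0.02–0.08 s, tonic conductance 2–12 µS, 1–4 SCR/min, skin
temperature 31–35 °C).

ECG is a train of PQRST-shaped templates (sums of Gaussian bumps) at
intervals from a positive-truncated AR(1) process; GSR is tonic + drift +
Poisson-timed double-exponential responses (rise 0.75 s, decay 2–10 s);
SKT is baseline + drift + a sum of random sub-0.15 Hz sinusoids, which
keeps its spectrum clean above the band by construction. Fear trials apply
a sympathetic-activation pattern to the stimulus span only — heart rate
up, variability down, SCR rate and amplitude up, temperature down — with
smooth 5 s shoulders; the effect signs are generator conventions chosen as
the standard sympathetic pattern, and the default magnitudes (+10 bpm,
×0.6 variability, ×2 SCR rate, −0.3 °C) sit between the "strong" setting
used in the recovery tests (+15 bpm, ×3, −0.5 °C) and the null generator
(`null_effect()`), which imposes no physiological or report contrast at
all. Self-report targets are (2, 8, 2) for fear and (7, 3, 7) for neutral
with 0.7 rating-points of noise — clearly inside the respective octants,
so label noise is negligible at the default setting.

What the generator does *not* emulate: real QRS morphology and ectopy,
motion artifacts, electrode drift, respiration coupling, and the
subject-specific idiosyncrasies of how people rate stimuli. Passing tests
therefore demonstrate that the pipeline recovers effects it was pointed
at, under clean if noisy signals — not field performance on real
recordings.

## Validation strategy and problem sizes

Every non-trivial operator is checked against an independent oracle:
recurrence measures against exhaustive line enumeration, sample entropy
against direct template counting (and a second implementation), AUC
against O(n²) pair counting, band powers against Parseval's identity,
quantiles against sort-and-interpolate, detectors against generator ground
truth. Known-exponent checks run over 10 seeds (DFA on white noise and
random walks; correlation dimension on a segment and a square). The
end-to-end checks use scaled-down cohorts chosen to keep the full suite in
a few CPU-minutes — 2 subjects × 20 trials for the strong-effect
subject-dependent check and 3 subjects × 20 trials for the null-effect
leave-one-subject-out check — with the per-trial geometry (5 windows of
20 s) always at protocol scale. The SCR amplitude-recovery oracle runs on
5-minute records with an 80 s tonic median and scores only isolated events
(no neighbor within 20 s): responses riding on another response's decay
have genuinely smaller trough-to-peak amplitude than their kernel
amplitude, and a 20 s analysis window could not host an 80 s median in the
first place.

## Known limitations

- The R-peak detector is tuned for template-like beats; heavily diseased
  or inverted-lead ECG would need a more elaborate front end.
- The moving-median tonic split attenuates slow-decay SCRs inside 20 s
  windows; features remain discriminative because the attenuation is
  condition-independent, but absolute amplitudes are biased low there.
- Per-subject z-scoring assumes each subject contributes enough windows
  (≥ 2, realistically dozens) to estimate stable statistics.
- The Gaussian-process tuner assumes a modest budget (tens of
  evaluations) and a low-dimensional space; it is not a general-purpose
  optimizer.
- With 3 LOSO models on small null cohorts the chance-level AUC band is
  wide; the tests assert the model-averaged AUC, not each model's.
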