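---
title: "Methods: sleep and circadian EEG analysis under shortened light-dark cycles"
author: "circsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep and circadian EEG analysis under shortened light-dark cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`circsleep` implements an end-to-end analysis chain for mouse EEG/EMG
recordings collected under shortened light-dark (LD) schedules — LD12/12,
LD11/11, LD10.5/10.5, LD10/10 and constant darkness (DD):

1. rule-based vigilance-state scoring on 4-s epochs,
2. state-specific power spectra with cluster-permutation comparisons,
3. theta-gamma phase-amplitude coupling (PAC) with surrogate
   z-normalization and cluster-based permutation statistics,
4. chi-square periodogram and cosinor rhythmometry (individual and
   population-mean),
5. two-process-model sleep-homeostasis fits (exponential slow-wave-activity
   decay, logistic buildup) with extra-sum-of-squares F tests.

Because no public dataset accompanies this design, the package ships a
first-class synthetic-data generator whose ground-truth parameters embody
every statistical structure the analyses assume. All validation is
property-based: each analysis is required to recover what the generator
put in, and to stay calibrated when the generator puts nothing in.

# The synthetic generator

## Vigilance states

Hypnograms are drawn from a first-order Markov chain on 4-s epochs over
(WAKE, NREM, REM), with separate transition matrices for photophase and
scotophase. REM is reachable only from NREM (enforced at construction) —
the biological constraint that REM arises out of consolidated sleep. The
default matrices give stationary state fractions of roughly 42/45/13%
(WAKE/NREM/REM) in the photophase and 79/17/4% in the scotophase, the
nocturnal pattern the downstream analyses assume. These are configuration
choices of the generator, not claims about any particular animal.

## EEG synthesis

The EEG is a sum of three frequency-modulated narrowband oscillations plus
broadband Gaussian noise (default SD 0.3 in signal units), sampled at
200 Hz:

* **SWA** (carrier 2.5 Hz, FM +/- 0.3 Hz): dominant in NREM. Its NREM
  amplitude is `a_swa * sqrt(D(t_s) * r(t))`, where
  `D(t_s) = SWA0 * exp(-t_s / tau) + SWAinf` is the Process-S discharge
  over NREM time `t_s` accumulated within the current zeitgeber cycle
  (defaults SWA0 = 1.5, tau = 1 h, SWAinf = 1), and
  `r(t) = min + (max - min) / (1 + 10^((log_t50 - log10 t) * slope))`
  is the logistic rise after each wake-to-NREM transition (defaults
  min = 0.3, max = 1, t50 = 20 s, slope = 3.5, i.e. ~96% of the span is
  reached by 50 s). Because binned 1-3 Hz power is proportional to squared
  amplitude, the binned SWA series traces the two-process envelope exactly
  when the noise is off. The accumulated-sleep clock advances only during
  NREM and resets at each cycle start, so that every cycle exhibits a
  fresh discharge — the regime the decay fit is applied to.
* **Theta** (carrier 8 Hz, FM +/- 0.5 Hz): dominant in REM, present in
  WAKE. The FM is deliberate: a pure sinusoid would make the
  cut-and-swap surrogate test for PAC degenerate, since every cyclic
  shift of a perfectly periodic signal is indistinguishable from a phase
  offset.
* **Gamma** (carrier 38 Hz, FM +/- 2 Hz, inside the 30-45 Hz gamma
  convention): its WAKE amplitude is `base * (1 + kappa * cos(phi_theta))`
  — the ground-truth phase-amplitude coupling, with depth `kappa`
  (default 0.4). `kappa = 0` produces statistically uncoupled theta phase
  and gamma amplitude. The magnitude of `kappa` is a free generator
  parameter: published PACz magnitudes do not constrain it.

Theta and gamma base **power** is modulated sinusoidally at the zeitgeber
period (amplitude scaled by `sqrt(1 + m cos)`, default relative depth 0.4,
peak 5 h after lights-off), so cosinor fits on band power recover a known
amplitude and acrophase; setting the depth to 0 produces the arrhythmic
regime.

EMG is 20-90 Hz band-limited noise with state-dependent RMS in the ratio
WAKE : NREM : REM = 5 : 1 : 0.5; only the ordering matters for scoring.

Locomotor activity is the rectified sum of a cosine at the entrained
period (peak mid-scotophase), a mesor and Gaussian noise, in 1-min bins.

What the generator does **not** emulate: 1/f background, spindles and
K-complexes, state-transition dynamics beyond first order, movement or
electrode artifacts, inter-animal variability in spectra. Passing tests
therefore certify the estimators' correctness and calibration on signals
with the assumed structure, not performance on raw laboratory data.

# Preprocessing and epochs

EEG conditioning follows the usual acquisition chain: mean removal, 0.5-Hz
high-pass (4th-order Butterworth) and 49-51 Hz band-stop (2nd-order
Butterworth), both applied forward-backward (zero-phase), because PAC
depends on undistorted instantaneous phase. The acquisition-side 0.3-Hz
high-pass is dominated by the 0.5-Hz software filter and is not applied
separately. Epochs are 4 s (800 samples), 0-based, half-open, trailing
partial epochs dropped; each epoch carries the phase-of-day label of its
first sample, which disambiguates epochs straddling light transitions.

# Spectra

A 4-s epoch holds 800 samples but the FFT size is 512; the two settings
are reconciled Welch-style: each epoch is split into 512-sample Hann
windows with 50% overlap (two per epoch) whose one-sided periodograms are
averaged. Resolution is 200/512 ~ 0.39 Hz over 0-50 Hz. State spectra are
the mean over a state's epochs of these periodograms, each divided by the
median total (0-50 Hz) power of all epochs in its zeitgeber cycle
(cycle-aligned, not astronomic-day-aligned, because every other analysis
is cycle-aligned), averaged over the last two complete cycles of a stage.

Band conventions (configurable): SWA/delta 1-4 Hz (1-3 Hz for the
homeostasis fits), theta 7-9.5 Hz, alpha 9.5-15, beta 15-30, gamma
30-45 Hz.

For the 2-s bins of the buildup analysis, 400-sample segments are
Hann-windowed and zero-padded to 512.

# Filter bank and PAC

The analytic decomposition uses linear-phase Hamming-windowed-sinc FIR
band-pass filters of the nominal 1500-point length at 1-Hz steps, applied
by FFT convolution with group-delay compensation; 1501 taps are used so
the group delay (750 samples) is an integer. The first and last 750
samples are edge-invalid and excluded from every statistic. The Hilbert
transform yields instantaneous phase and squared-magnitude power.

The coupling statistic is the mean-vector-length modulation index
`mi = |sum_t a_t e^(i phi_t)| / n`, computed in 1-min bins restricted to
in-state, edge-valid samples (bins under 50% in-state are dropped — never
filled from out-of-state samples). Each bin's `mi` is z-scored against
surrogates built by cutting the power series at a random point and
swapping the halves, which preserves both autocorrelation structures
while destroying the alignment. A cut at point `c` is exactly a cyclic
shift by `c`, so the package computes the modulation index of **all**
shifts at once through an FFT cross-correlation and samples 200 of them;
this is algebraically identical to the looped procedure. Comodulograms
are matrices of the median PACz over bins, separately for photophase and
scotophase.

**Amplitude bandwidth.** A 1-Hz-wide amplitude filter cannot pass envelope
modulation faster than ~0.5 Hz: the sidebands of theta-modulated gamma sit
8 Hz from the carrier, deep in such a filter's stopband, so no theta-gamma
coupling is detectable through a uniformly narrow bank — whatever the
nominal analysis settings. `pac_comodulogram()` therefore keeps the 1-Hz
bank for the **phase** axis and extracts each row's **amplitude** series
with half-width `phase frequency + 1 Hz`, the standard bandwidth rule for
this estimator. The low-level `comodulogram()` accepts any combination of
banks for users who want the literal narrow-band behaviour. The phase
axis is capped at 20 Hz (a phase band above the amplitude band is
meaningless); the amplitude axis spans 2-50 Hz.

**Cluster statistics.** Condition comparisons use cell-wise paired t
tests thresholded at two-sided p = 0.01; suprathreshold cells form
4-connected clusters (contiguous runs for 1-D spectra) whose summed t
(sign retained) is referred to the distribution of the maximum absolute
cluster mass over sign-flip permutations of the subject difference maps;
clusters with permutation p < 0.05 are significant. Positive and negative
clusters are tested against the same max-|mass| null, so the direction of
a PAC change is a finding, not an assumption. Surrogate and permutation
counts (defaults 200 and 500) are calibration choices reported in the
output metadata.

# Rhythm analysis

The **chi-square periodogram** (Sokolove-Bushell) folds the series at
every candidate period of a whole number of bins (default grid 16-32 h,
bracketing all schedules of interest) and computes
`Qp = N * Var(column means) / Var(data)` (population variances), which is
chi-square with P-1 degrees of freedom under the null; the p = 0.01
quantile gives the per-period significance threshold.

The **cosinor** fits `y = M + A cos(omega t + theta)` by its exact
linearization `y = M + beta x + gamma z` (`x = cos omega t`,
`z = sin omega t`, `beta = A cos theta`, `gamma = -A sin theta`) with
`omega` fixed by the zeitgeber period — the linearized model requires a
known frequency, and entrainment analysis asks about the zeitgeber
frequency specifically. Zero amplitude is tested by the F statistic on
(2, n-3) df. Acrophase is reported both as the fitted phase `theta` and
as the peak lag after lights-off in [0, 360) degrees; all comparisons use
circular distance. Missing bins (state-masked series are inherently
gappy) are dropped, not imputed.

The **population-mean cosinor** averages per-subject `(beta, gamma)`
pairs; the between-subject bivariate covariance gives a Hotelling-type F
test of zero population amplitude, an elliptical confidence region, and
two-sample Hotelling comparisons between conditions (Bonferroni over
pairs — the original correction is unstated, so the most conservative
standard choice is used).

# Homeostasis

SWA (1-3 Hz) in NREM epochs is binned into 10 min of **accumulated NREM
time** from the first NREM incidence — cumulative sleep time, not clock
time, is the two-process convention — and normalized per median photophase
NREM SWA. The first 60 s of NREM after each wake-to-NREM transition are
excluded from the decay series (while still advancing the clock): that
window belongs to the logistic buildup model and would otherwise bias the
decay constant. `SWA0 e^(-t/tau) + SWAinf` is fitted by
Levenberg-Marquardt with deterministic starts (SWAinf = last bin,
SWA0 = first - last, tau = span/3) and bounds tau > 0, SWAinf >= 0; flat
series are flagged degenerate rather than silently fitted.

The buildup model is the 4-parameter logistic in log10 time,
`y = min + (max-min) / (1 + 10^((log_t50 - log10 t) * slope))` — the
printed form of this model in the source literature omits the time
variable in the exponent, an evident typo; the standard log-time logistic
is implemented and the interpretation is flagged in the output metadata.
Transitions qualify when NREM onset follows at least 60 s of WAKE and is
itself followed by at least 60 s of NREM; SWA is taken in 2-s bins over
the first 60 s and averaged across transitions before fitting.

Conditions are compared by the extra-sum-of-squares F test between a fit
with the chosen parameters shared and a fit with them separate; degrees
of freedom are emitted for transparency. Pooled-bins fitting is used; the
df conventions of other software may differ.

# Pipeline, determinism, problem sizes

`run_pipeline()` executes simulate -> preprocess -> score -> spectra ->
rhythms -> homeostasis (-> PAC, off by default) per LD stage under one
config, writing tidy CSV/JSON per stage and a manifest with an MD5 for
every file; identical config and seed reproduce the manifest
byte-identically. Every random operation receives an explicit seed
derived from the master seed; no global RNG state leaks. A stage failure
aborts with a stage-attributed error and the manifest records the partial
run.

Default problem sizes are desk-scale choices: 3 days per LD stage (7 for
the end-to-end reproduction runs, where the activity periodogram needs
the longer span) with EEG synthesized for the trailing 2 cycles
(analyses use the last 2 cycles of a stage throughout), 12-h recordings
for scoring-agreement checks, 10-day hypnograms for architecture
statistics, 14-day activity series for periodogram detection, and
200-500 replicates for the calibration studies. The full experimental
scale (14/7/14/14 days) is available by configuration.

# Known limitations

* The scorer is a transparent three-rule threshold classifier (EMG RMS,
  SWA ratio, theta/delta ratio with REM-context enforcement), a testable
  stand-in for the semi-automatic scorer used in the original workflow;
  it is calibrated on the generator's clean state signatures and is not a
  validated clinical scorer.
* Narrow-band FM carriers make several spectral checks sharper than real
  EEG would allow; tolerances in the tests reflect that.
* The decay/buildup F tests assume approximately normal residuals of the
  binned series; with very few bins the stated type-I level is nominal.
* EDF support is a minimal 16-bit implementation (two channels, 1-s
  records) sufficient for interchange, not a full EDF+ reader.
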