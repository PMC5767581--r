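---
title: "Estimating and comparing corticomuscular coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing corticomuscular coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcoh)
```

## The measurement problem

Corticomuscular coherence (CMC) quantifies the frequency-domain coupling
between scalp EEG over the motor cortex and the surface EMG of a contracting
muscle. During steady submaximal contraction the coupling concentrates in
the beta band (15–30 Hz) and is read as a proxy for the integrity of the
corticospinal drive; clinically, one wants to know whether the coupling for
a given muscle *changed* between two recording sessions — for instance
before and after motor recovery. That comparison is statistically awkward
for two reasons this package addresses head-on:

1. coherence estimates are biased, and the bias depends on the number of
   data segments, which may differ between sessions;
2. the comparison is made across many frequencies at once, so naive
   per-frequency tests inflate the false-positive rate.

`cmcoh` implements the full chain: EDF input, zero-phase band-pass
filtering, ICA-based artifact rejection, segmentation of the contraction
period, a spherical-spline surface Laplacian (current source density, CSD),
multitaper coherence with explicit degrees-of-freedom bookkeeping, beta-band
topographies with peak-electrode selection, and a nonparametric
cluster-based permutation test of the coherence difference.

## Trial structure and segmentation

The analysis assumes an isometric force-tracking task: 11-s trials separated
by 2-s gaps, 20 trials per run and two runs per side in a session, with the
3-N target force reached within the first 2 s of each trial. Only the stable
contraction period enters the analysis: `segment_epochs()` skips the first
2 s of every trial and tiles the remainder with non-overlapping 1-s windows
(the partial trailing window is discarded), so an 11-s trial contributes
exactly 9 epochs, a run 180 and a session 360 per side. One-second epochs
give a 1-Hz frequency grid, which is what makes "clusters of adjacent
frequencies" a meaningful unit later.

## Filtering and artifact removal

Signals are band-pass filtered from 3 to 45 Hz with a Hamming-windowed sinc
FIR applied forward and backward (`design_bandpass()`, `filter_twopass()`).
The two-pass scheme squares the magnitude response and cancels the phase, so
filtering cannot displace EEG–EMG phase relations; the kernel order
(`ceiling(3.3 * fs)`, rounded to an odd tap count) yields a ~1-Hz transition
at the low edge and >40 dB attenuation at 1.5 Hz and 50 Hz. EMG is filtered
with the same band and deliberately **not** rectified. Force channels pass
through untouched.

Artifact rejection uses a deterministic symmetric fixed-point ICA
(`fit_ica()`) with a seeded initial rotation, so results are reproducible
bit-for-bit. Because band-limited Gaussian background EEG has no unique ICA
rotation, the decomposition is judged by its contracts — exact
reconstruction and determinism — rather than convergence of the Gaussian
subspace. Components are scored (`score_artifacts()`) on three 0–1 scales:
correlation with a low-passed frontal average (blinks), regularity of a
0.8–2 Hz peak train (ECG), and the fraction of power within 50 ± 1 Hz
(mains). The automatic threshold of 0.7 on any score
(`clean_artifacts()`) is a configurable stand-in for the manual component
selection common in practice. Removing a component necessarily removes the
background activity projected onto it; on simulated data the 50-Hz
component removal attenuates mains power by >99.9% while moving total
beta-band power by well under 10%.

## Current source density

Scalp potentials are reference-dependent; the surface Laplacian is not.
`csd_operator()` builds the spherical-spline Laplacian on a unit-sphere head
model with the canonical constants of that literature: spline order `m = 4`,
ridge regulariser `lambda = 1e-5`, 50 Legendre terms. The operator
annihilates spatially constant maps (so adding any offset to all channels
changes nothing), is exactly linear, and markedly sharpens focal source
patterns. It is applied sample-wise in the time domain before spectral
estimation (`apply_csd()`), matching the analysis order CSD-then-coherence;
because it is a fixed linear channel mix, `band_topography()` can apply it
to the tapered spectra instead, which is algebraically identical and cheaper
on long sessions.

## Multitaper coherence and its degrees of freedom

`coherence_spectrum()` uses `K = 3` Slepian tapers at time–bandwidth
`NW = 2` (±2 Hz smoothing on 1-s epochs; both configurable), computed from
the standard tridiagonal eigenproblem. With `L` epochs the estimate averages
`K * L` tapered cross-spectra and carries `d = 2KL` degrees of freedom —
the quantity the z-transform needs. Coherence is reported as magnitude
`C(f) = |S_xy| / sqrt(S_xx S_yy)` (with `C^2` alongside), because the
bias-corrected z-transform below is defined for the magnitude. Since epochs
do not overlap, no overlap correction of `d` is needed.

Beta-band topographies average `C(f)` over 15–30 Hz (endpoints inclusive)
per electrode; the statistical comparison is made at each session's own
peak electrode (`select_peak_spectrum()`), tolerating the small shifts in
peak location that cap repositioning produces between sessions.

## The cluster-based permutation test

For two conditions with coherences `C1, C2` and degrees of freedom
`d1, d2`, the difference is transformed to

```
Z(f) = ((atanh C1(f) - n1) - (atanh C2(f) - n2)) / sqrt(n1 + n2),
n_i = 1 / (d_i - 2),
```

which removes the segment-count-dependent bias and standardises the
variance. Within the beta band, maximal runs of adjacent frequencies with
`Z > 1.645` (one-sided; `|Z|` with sign-split clusters in two-sided mode)
form clusters whose mass is the summed `Z`; the test statistic is the
maximum cluster mass, 0 if nothing crosses the threshold. The null
distribution pools the 1-s segments of both conditions, reassigns them at
random to two pseudo-conditions of the original sizes, and re-runs the whole
sub-pipeline (coherence → z → clusters → max mass) 5000 times; the Monte
Carlo p-value is `(1 + #(null >= observed)) / (1 + n_perm)`. The add-one
form avoids p = 0 and implements "at least as large" with `>=`.

Design choices worth stating. The statistic is the canonical maximum
cluster *mass* (not extent or peak height). The printed bias term is read as
`n_i = 1/(d_i - 2)` — the reciprocal form of the cited framework; the
alternative reading `1/d_i - 2` is a typesetting artifact that would make
the variance negative. Permutation exchanges 1-s segments by default;
`permute_unit = "trial"` keeps each trial's segments together for robustness
to within-trial autocorrelation. Electrode selection is fixed before
permuting (matching a fixed-electrode analysis); `selection_aware = TRUE`
re-selects the peak electrode inside every permutation for users worried
about selection bias. The directional test (condition 1 > condition 2 at
threshold 1.645) suits a recovery hypothesis; the two-sided mode suits a
no-change null.

## The synthetic-data generator

No public recordings accompany this kind of single-patient study, so the
package ships a generator (`simulate_session()`) whose ground truth is known
in closed form. One band-limited Gaussian source `s(t)` — spectral amplitude
a sum of Gaussian lobes centred at 18 and 24 Hz with 3-Hz half-width,
echoing the twin beta peaks typical of such data — is mixed linearly into
the scalp with gain `g_i = exp(-1.5 * greatcircle(i, target))` peaking at a
left-central electrode, and into the EMG with coupling gain `kappa` after a
10-ms conduction delay (a pure delay leaves coherence magnitude untouched,
so it exercises phase handling without biasing magnitude checks). White
noise of SD 1 µV is added per channel; the EMG is amplitude-modulated to
near-zero outside contraction windows; the force channel ramps to 3 N within
2 s and holds with small jitter. Optional blink (~0.3 Hz frontal lobes), ECG
(~1.2 Hz low-gain spike train) and 50-Hz artifacts draw from the same
seeded RNG stream, so a session is a pure function of its parameters.

For this linear model the coherence between the target electrode and the
EMG is available in closed form,

```
C(f) = g kappa A(f)^2 / sqrt((g^2 A(f)^2 + sd_eeg^2) (kappa^2 A(f)^2 + sd_emg^2)),
```

exposed as `expected_coherence()` and used as the oracle for estimator
consistency. Session asymmetry is represented purely by `kappa`: 0.6 and
1.2 for sessions 1 and 2 of the affected side (recovery as doubled
coupling), 1.0 for both unaffected sessions. The Gaussian spectral lobes
are deliberately smooth on the ±2-Hz multitaper bandwidth so the closed
form is comparable to the estimate without modelling taper smoothing; the
consistency check is run on the unfiltered target channel because coherence
is invariant to any common per-channel linear filter with nonzero in-band
gain.

What the generator does *not* emulate: volume conduction through a
realistic head, motor-unit pool EMG statistics, nonstationary coupling
within a trial, or the true geodesic net geometry (the montage is a
golden-angle spiral on the upper sphere). Passing tests therefore validate
the estimators and the test machinery, not the physiology of real
recordings.

## Numerical and scale choices

Validation problem sizes were chosen to exercise the estimators at the
study's native scale while staying desk-sized: estimator consistency uses
10 full 128-channel sessions (360 epochs each; RMS tolerance 0.05 over
15–30 Hz), topography recovery 20 such sessions, the type-I-error study 500
replicate null pairs with 45 epochs/condition and 200 partitions, and the
power study 100 replicate pairs with 180 epochs/condition. Inside the
permutation loop the per-epoch tapered spectra are computed once and
reaveraged per partition — numerically identical to re-running the
estimator, since the estimator is a mean over taper-epoch products.
Coherence is clipped at `1 - 1e-12` before `atanh`; ties at the cluster
threshold are excluded (strict inequality); the EDF writer sets physical
ranges from data extrema with 5% headroom so 16-bit quantisation stays far
below the noise floor; constant channels fall back to a ±1 range.

## Limitations

The montage is an idealised spiral, not a vendor net; the CSD assumes a
spherical head; ICA scoring thresholds are heuristics exposed as
configuration, not learned; the permutation test treats 1-s segments as
exchangeable under the null, which slightly underestimates dependence if
coupling is strongly autocorrelated across adjacent segments within a trial
(use trial-level permutation when that worries you); and the EDF writer
pads non-integer-second recordings with zeros to complete the last record.
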