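---
title: "Methods: band power and spreading depolarizations in ischemic ECoG"
author: "ecogsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power and spreading depolarizations in ischemic ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After an arterial occlusion, the electrocorticogram (ECoG) over and around
the developing infarct changes in two characteristic ways. First, the
spontaneous activity loses power, band by band, in spatial and temporal
patterns that track tissue fate: electrodes over the ischemic core show an
abrupt, non-spreading depression of all bands at occlusion; penumbral
electrodes lose fast activity quickly and slow (delta) activity only hours
later; remote territory declines late or not at all. Second, spreading
depolarizations (SDs) traverse the cortex: each one appears on an
AC-coupled recording as a negative near-DC shift (NDCS) lasting on the
order of a minute, accompanied by a broadband depression of spontaneous
activity, and repeats at adjacent electrodes with delays of minutes.

`ecogsd` implements the full measurement chain for both phenomena —
preprocessing views, band-power decomposition, NDCS detection and
segmentation, incidence binning, and exact small-sample statistics —
together with a ground-truthed generator of synthetic recordings, so that
every stage is testable without animal data.

## Signal model and preprocessing views

Recordings are multichannel, in microvolts, at a sampling rate of 200 Hz
(anything ≥ 2× the highest analysis band works), with time in seconds from
recording start and all intervals half-open `[start, end)`. Three derived
views are provided, all zero-phase (forward–backward filtering with
odd-reflection padding of about three time constants, run as second-order
sections for numerical accuracy):

* **cleaned raw** — a constrained biquad notch (default 50 Hz, Q = 30)
  removes line noise with > 30 dB rejection and < 1 dB passband loss;
* **near-DC view** — a 4th-order Butterworth low-pass, default 0.5 Hz.
  SD-related potential shifts are slower than ~0.05 Hz at the tissue, but
  an AC recorder's 0.1 Hz coupling turns them into transients whose energy
  sits between DC and a few tenths of a Hz; 0.5 Hz keeps the transient's
  shape while rejecting spontaneous activity;
* **powered signal** — band-pass, square, 60-s running mean: an
  instantaneous band-power trace on which depressions of activity are
  visible at a glance.

### DC restoration

A first-order 0.1 Hz high-pass has a time constant of ~1.6 s, so a 50-s
plateau-shaped DC shift is differentiated into a pair of short transients:
durations measured directly on the coupled signal would reflect the ramp
times, not the shift. `dc_restore()` therefore inverts the documented
coupling model — a first-order RC high-pass discretized by the bilinear
transform — by exact leaky-integrator deconvolution before the near-DC
view is taken. This model-based full-band reconstruction is standard
practice when SDs must be quantified from AC-coupled recordings. Content
truly absent from the recording (static DC offsets) is not recoverable;
transient shifts are, and for the simulator's recordings (which apply the
same discrete coupling model to the whole electrode signal) the inversion
is exact to rounding error. For real hardware whose coupling deviates from
first order, restored shift amplitudes are approximate, but half-depth
durations are robust to moderate model error because they are read off a
waveform that is locally scaled, not shifted.

## Band-power decomposition

Five-minute epochs are decomposed Welch-style: consecutive 512-sample
windows (no overlap by default — 117 windows per 5-min epoch at 200 Hz
already give a low-variance mean; overlap is configurable), each demeaned,
Hanning-weighted and transformed; one-sided power densities
`|X|²/(fs·Σw²)` are averaged across windows. A 512-point window was chosen
over a single long DFT because averaging many short windows is what makes
per-epoch means statistically stable. Band values are the *mean density*
over the bins whose center frequency falls in the half-open band
(delta 0.1–4, theta 4–7, alpha 8–12, beta 13–31, gamma 32–45 Hz); bins in
the inter-band gaps belong to no band, and the DC bin lies below every
band. Mean density (rather than integrated power) keeps bands of unequal
width comparable; all downstream statistics are rank-based and therefore
insensitive to this choice. Whether one reports density or totals, the
unit is µV²-based; microvolts are the native amplitude scale of cortical
surface recordings.

Timepoint epochs are anchored at the occlusion marker `m`: baseline
`[m−300, m)`, then `[m, m+300)` and the same window 4, 8 and 12 h later.
Epochs not covered by a (shorter) recording are reported missing, never
fabricated; epochs overlapping annotated artifact intervals are flagged.

## SD detection and segmentation

Detection operates per channel on the restored near-DC view, decimated to
10 Hz (the view has no content above 0.5 Hz):

1. a rolling robust baseline scale — the Gaussian-scaled median absolute
   deviation over 10-min blocks — sets the threshold at 6× scale. The MAD
   is insensitive to the SDs themselves occupying a minority of each
   block; the factor 6 was fixed so that Gaussian background produces
   essentially no threshold excursions sustained for 15 s (the
   minimum-duration gate) over 24 h;
2. maximal below-threshold intervals are candidates; candidates separated
   by under 30 s merge (SD waveforms can be polyphasic);
3. onset and end are the outermost crossings of half the excursion depth,
   linearly interpolated; the half-depth convention is stable under both
   the low-pass rounding of the ramps and moderate restoration error,
   where full-threshold crossings are threshold-sensitive;
4. events with half-depth duration outside [15, 300] s are discarded.

Detection is deliberately NDCS-only: on isoelectric-core channels there is
no spontaneous activity left to depress, yet SDs still traverse them, so no
band-depression requirement is imposed. Events on adjacent electrodes of
one strip whose onset lag falls in [60, 420] s (10-mm spacing at roughly
1.5–10 mm/min) are chained into propagation groups; grouping annotates but
never deduplicates per-electrode counts, which is how incidence is
reported. Incidence uses *all* detected events, binned per electrode into
eight 3-h bins after the occlusion.

For spectral phase analysis an event must have artifact-free,
event-free 5-min flanks on both sides (and the flanks must lie inside the
recording). Included events are segmented into preSD `[onset−300, onset)`,
SD `[onset, end)` and postSD `[end, end+300)`; SD segments shorter than 512
samples fall back to the largest power-of-two window that fits. Per-event
phase band powers are averaged within each 3-h lapse, giving the paired
eight-lapse design.

## Statistics

Both designs are paired and small (n = 6 animals; n = 8 lapses), so the
package uses the Wilcoxon matched-pairs signed-rank test with the *exact*
conditional null distribution: all `2^n` sign assignments of the observed
`|difference|` multiset, evaluated by dynamic-programming convolution over
midranks — exact under ties, where the textbook tables and
`stats::wilcox.test` give up. Zero differences are dropped (Wilcoxon's
original treatment; the Pratt variant is available by flag). Above n = 15
a normal approximation with tie and continuity correction takes over. No
multiplicity correction is applied by default — results are reported
per-test at α = 0.05, with Holm available for reuse. A tie-corrected
Friedman test (chi-square or within-row permutation null) is provided as
an omnibus across the three SD phases; the package applies it as an
optional companion to the two pairwise contrasts. Normality screening is
deliberately absent: the pipeline is nonparametric unconditionally rather
than conditioning the test choice on a pretest.

Two numerical caveats are documented rather than hidden. The exact test's
attainable two-sided levels at n = 6 are {1/32, 2/32, ...}: the realized
type-I error at nominal 0.05 is 1/32 ≈ 0.031, i.e. the test is
conservative. And the chi-square approximation to the Friedman null is
accurate in the decision-relevant tail (p ≈ 0.01–0.05 already at n = 8)
but visibly off near the center of the discrete null (p ≳ 0.2), where only
the permutation option should be trusted.

## The synthetic generator

The generator emulates the study's phenomenology, not its biophysics.
Background is a sum of five band-limited Gaussian noise components per
channel, synthesized in the frequency domain (exact band confinement; no
marginally-stable filters at 0.1 Hz) and normalized to per-band RMS
amplitudes of 20/10/8/5/3 µV (delta through gamma) — amplitudes in the
range seen on cortical surface recordings, with the characteristic
red-shifted spectrum. Depression schedules multiply band *amplitudes*
piecewise-constantly in time (power scales with the square). The presets
mirror the three tissue zones: core electrodes (E4L/E5L) ×0.05 in all
bands at occlusion; penumbral electrodes (E2L/E3L) ×0.3 in theta–gamma at
occlusion and in delta 8 h later; the remote/ACA electrode (E1L) ×0.3 in
all but gamma at 8 h; the right strip unchanged.

Each SD injects a raised-cosine-edged trapezoidal DC shift of 1000 µV
(literature-scale shifts are millivolts at the tissue; 1000 µV keeps the
coupled transient comfortably above background while staying within a
16-bit EDF physical range) whose half-depth width equals the drawn
duration — Normal(51.3, 14.1²) s truncated to [20, 120] s, the truncation
keeping events inside the detector gates at a mean bias below 0.5 s — plus
a broadband amplitude suppression to 0.1× during the event. Recovery is
immediate in `full` mode; in `impaired` mode the background is held at
0.4× through the 5-min postSD window and ramps back afterwards, so
penumbra-like electrodes show a sustained postSD deficit while
unaffected-zone electrodes show none. Propagating events spawn copies on
adjacent electrodes delayed by 10 mm at 3 mm/min (200 s). Artifacts are
high-amplitude broadband bursts, annotated in the output. Finally the
*entire* electrode signal passes through the first-order AC-coupling
model, as a real AC front end would couple it.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: physiological non-stationarity and 1/f structure
beyond the five-band mixture, realistic artifact morphologies (movement,
electrode pops), clustered/re-entrant SD timing, SD waveform variability
beyond duration, hemispheric interactions, and hardware coupling that is
not first-order. Detection on real recordings will need threshold and
restoration parameters revisited against visual scoring.

## Problem sizes and numerical choices

The validation suite runs the scales the questions demand: duration
recovery uses 200 isolated events on one channel (~27 h of signal); count
recovery uses the full 24-h five-electrode left strip with 420 injected
SDs; the default end-to-end scenario is one 24-h ten-channel recording;
the recovery-mode contrast uses 25-h single-channel recordings with two
SDs per 3-h lapse. The orchestration demo in `analysis/` uses a six-animal
cohort (the smallest paired design in which the exact signed-rank test can
reach p ≤ 0.05) of 13.25-h recordings — the shortest duration that still
exposes the 12-h timepoint — sampled at 100 Hz, which keeps every analysis
band below Nyquist while exercising the same code path at a friendlier
size.

Scattered numerical decisions, collected: filters run as second-order
sections because a 4th-order 0.1 Hz recursion at 200 Hz loses ~7 digits in
direct form; edge effects are handled by odd reflection over three time
constants; crossing times are linearly interpolated on the 10 Hz detection
grid (0.1 s resolution, ~0.01 s effective); the EDF writer chooses
per-channel physical ranges from data min/max with a 5% margin to minimize
quantization, and a constant channel gets a unit range; ties in ranks use
midranks throughout; degenerate inputs (all-zero differences, fully tied
Friedman matrices, empty bands, epochs off the end of a recording) are
surfaced as explicit errors, untestable entries or flags, never silently
patched. Reproducibility is strict: a simulation config plus seed yields a
bit-identical recording, and the pipeline writes its echoed config, seed
and config hash beside every run.
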