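---
title: "Separating cardiac and respiratory signals in functional EIT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating cardiac and respiratory signals in functional EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional electrical impedance tomography (EIT) reconstructs a movie of
impedance changes over a transverse chest slice, typically a 32 x 32
pixel grid at tens of frames per second. Each lung pixel's time trace is
a mixture: a large breath-synchronous component (linearly related to
regional lung volume change) and a cardiac-synchronous component roughly
one order of magnitude smaller, usually attributed to pulsatile blood
volume in the lung. Pixels over the heart itself also pulse at the heart
rate, but roughly in antiphase (a phase shift of about 150-180 degrees)
with respect to the cardiac signal inside the lung. Comparing cardiac
amplitudes across body positions requires (i) separating the two
spectral components, (ii) excluding the heart region spatially, and
(iii) reducing each recording to per-cycle amplitudes that can enter a
repeated-measures analysis.

`feit` implements that pipeline end to end, together with a synthetic
thorax-movie generator whose ground truth (per-breath and per-beat
amplitudes, rates, masks, tidal volumes) every stage can be validated
against.

## The separation model

**Two-stage filtering.** The mean trace of a high-ventilation region is
first split with fixed "rough" band-pass filters: 2-40 bpm for
respiration and 40-400 bpm (capped at 95% of Nyquist) for cardiac
activity. Periodograms of the two rough traces (rectangular window,
linear detrend, 4x zero-padding for peak localisation) give the
respiratory rate `f_RR` and heart rate `f_HR` as the maximal in-band
peaks. The movie is then refined pixel-wise into three filtered movies
with adaptive bands: `[0.5, 2.5]*f_RR` (respiratory domain),
`[0.5, 2.5]*f_HR` (cardiac domain) and the strict `[0.8, 1.2]*f_HR`
(cardiac fundamental only). When the respiratory band would overlap the
cardiac one, its upper edge is capped at 90% of `0.5*f_HR`.

**Harmonics of breathing vs the heart rate.** When `f_HR` falls within
one frequency-resolution bin (`1/T`, with `T` the record duration) of an
integer multiple of `f_RR`, the cardiac peak cannot be attributed
automatically; the estimate moves to the strongest non-harmonic peak if
that peak holds at least 50% of the maximal power, and otherwise the
recording requires a manual rate override (`rate_override` in the
analysis configuration) — the automated counterpart of visually
inspecting the spectra. Note the harmonic positions `k * f_RR` inherit
`k` times the uncertainty of the respiratory-rate estimate, so short
records flag conflicts liberally; at the 44 Hz / 45 s study conditions
this affects only genuinely rate-locked subjects.

**Filters.** All filtering uses linear-phase FIR band-passes
(Hamming-windowed sinc, `signal::fir1`) applied forward-backward, so the
effective impulse response is the autocorrelation of the taps: exactly
symmetric, hence zero group delay at every frequency. Design choices:

* transition width 30% of the lower band edge; order
  `ceiling(3.3 * fs / tw)` rounded to even (Hamming rule);
* the -6 dB cutoffs sit half a transition width *outside* the nominal
  band, so the nominal band is flat pass-band (amplitude preserved
  within 2% after the forward-backward pass) and attenuation reaches
  40 dB by `0.5*low` and `1.5*high`;
* on finite records the order is capped at a third of the record length
  (the applicability limit of forward-backward filtering), trading
  low-edge roll-off for record length — at 44 Hz and 60 s this cap is
  active for respiratory bands;
* edges are handled by odd-reflection padding, and the convolution is
  evaluated by FFT, so filtering a whole 32 x 32 movie is a single
  matrix operation.

Because the filters are linear, filtering the mean trace of a region
equals averaging the filtered pixel traces: single-trace analyses are
exact, not approximations.

## Spatial separation of heart and lung

The pixel with the maximal temporal standard deviation of the
respiratory-domain movie lies in the lung with high probability; it and
its in-grid 4-connected neighbours form the *reference region*. The mean
cardiac-domain trace of that region is cross-correlated with every
pixel's cardiac-domain trace over integer lags spanning one centred
cardiac period (`T = fs / f_HR` frames; an unbounded search would alias
the phase). The lag of maximal normalised correlation, times `360/T`,
is the pixel's phase in `(-180, 180]`; positive phase means the pixel
lags the reference. Pixels whose cardiac-band standard deviation falls
below 10% of the reference trace's are marked invalid — this floor is
what keeps background pixels out of the phase image, and it presumes the
few-percent pixel noise of regularised reconstructions (see
*Limitations*).

Valid pixels with `|phase| > 30` degrees form the raw heart mask, which
is cleaned by a morphological closing (fills holes) then opening
(removes isolated pixels), both with a 3 x 3 cross structuring element;
if several 4-connected components survive, the largest is kept. The lung
mask is this package's own construction (the criterion has no canonical
definition): pixels whose respiratory-band standard deviation reaches
25% of the grid maximum, minus the heart mask, then an opening.

The lag quantisation bounds the phase accuracy at `360 * f_HR / fs`
degrees per lag step; the phase-recovery tests assert a mean absolute
error within that bound plus 2 degrees of noise allowance.

## Per-cycle amplitudes

Four amplitude series are extracted over the lung-mask mean trace:

* `dZ_RR` — breathing segment, respiratory-domain trace;
* `dZ_CR` — breathing segment, cardiac-domain trace, with beat
  boundaries detected on the strict trace (whose single surviving
  fundamental makes minima unambiguous);
* `dZ_CA` — apnea segment, *raw* (baseline-subtracted only) trace, beat
  boundaries again from the strict trace;
* `V_T` — per-breath tidal volumes from the cumulative trapezoidal
  integral of the spirometric flow.

Cycles run minimum to minimum; the amplitude of a cycle is the
peak-to-trough difference of the analysed trace within it. Extrema
closer than `0.3/f` seconds are merged (debouncing noise-induced double
peaks). Two robustness rules are this package's additions: cycles whose
median length is inconsistent with the detected rate, or strict-band
energy below 1% of the trace, raise an error instead of fabricating
beats from band leakage; and cycles within one nominal period (capped at
10% of the slice) of a slice edge are dropped, because the
forward-backward filter's edge transients inflate their amplitudes by up
to ~15% — with them removed, noise-free per-cycle amplitudes match the
generated truth to a few percent.

Amplitudes are averaged cycles → replicate → triplicate, giving one
value per subject, position and kind; `dZ_RR_per_VT` (replicate mean of
`dZ_RR` over mean `V_T`) normalises ventilation amplitudes between
subjects. Because every amplitude is a peak-to-trough difference of a
band-passed (or slice-centred) trace, the results are invariant to the
per-pixel constant removed by reference subtraction; the pipeline still
applies the subtraction (local mode: per-pixel mean over the most stable
5 s window of the first breathing segment, operationalising "stable
phase" as the minimum-variance window; global mode: a supplied baseline
from the subject's first upright recording).

## Posture statistics

The subject x position table of triplicate means enters Friedman's
repeated-measures rank test (blocks = subjects). The tie-corrected
chi-square statistic is standard; for small tie-free tables
(`k!^n <= 50000`) the p-value is computed exactly by enumerating all
within-block orderings, because at 5 blocks x 3 treatments the
chi-square approximation can be off by more than 0.1. After a
significant omnibus, Conover's all-pairs post-hoc compares rank sums,
`t = (R_i - R_j) / sqrt(2 (n A1 - sum R_j^2) / ((n-1)(k-1)))` on
`(n-1)(k-1)` degrees of freedom (`A1` = sum of squared within-block
ranks); pairwise p-values are Holm-corrected by default (uniformly more
powerful than Bonferroni with no independence assumption; Bonferroni
available). Simulated family-wise error on null 14 x 5 tables is ~0.03
at a nominal 0.05. The Anderson-Darling normality check is computed and
reported but gates nothing — the pipeline is nonparametric throughout.
The Wilcoxon signed rank test (exact for n <= 25 without ties) compares
`dZ_CR` with `dZ_CA`, i.e. whether extracting the cardiac amplitude by
filtering during breathing biases it relative to raw apnea amplitudes.

## The synthetic generator

`make_geometry()` places two dorsolateral elliptical lungs and one
ventral heart inside an elliptical body on a square grid (default 32,
minimum 16), with a small seed-driven jitter; regions are disjoint,
4-connected, at least 4 pixels. `simulate_recording()` builds, at 44 Hz:

* a raised-cosine volume curve per breath — smooth, differentiable, with
  an analytic flow derivative whose per-breath excursion is the tidal
  volume (default 0.5 L); lung-pixel respiratory peak-to-trough is
  `2 * resp_amplitude`;
* a cardiac waveform with harmonics (1, 0.5, 0.2) — a decaying series
  typical of pulsatile impedance signals — normalised to unit
  peak-to-trough, at `f_HR`; the 3rd harmonic lies outside
  `[0.5, 2.5]*f_HR`, so the strict/loose band comparison genuinely
  changes the waveform (truncation shifts peak-to-trough by ~6%, within
  the <=10% filter-effect contract);
* the heart-region trace as a pure time delay of the cardiac waveform
  (default 165 degrees at the fundamental; the heart amplitude is twice
  the lung cardiac amplitude — a simulation knob, not a physiological
  claim);
* per-breath/per-beat amplitude jitter and period jitter (both 3% CV —
  conventions, not literature values), white pixel noise, and an
  optional Gaussian point-spread blur emulating reconstruction
  smoothing;
* ~45 s of breathing followed by ~15 s of apnea (cardiac continues,
  respiration and flow stop at end-expiration after the last complete
  breath).

Default rates are 0.25 Hz (15 bpm) and 1.15 Hz (69 bpm). The heart rate
deliberately sits halfway between respiratory harmonics (4.6 x f_RR): a
default of exactly 4.8 x f_RR would trigger the harmonic-conflict flag
on short records through no fault of the detector. The default pixel
noise (sd 0.01, i.e. ~37 dB respiratory SNR per pixel) reflects the
strongly regularised character of reconstructed EIT movies, whose pixel
noise is a small fraction of the breath signal; `noise_sd_for_snr()`
converts a target SNR into the noise level (20 dB -> sd 0.0707).

What the generator does *not* emulate: electrode-level physics and
reconstruction artifacts, posture-dependent anatomy (posture enters only
as a label and an amplitude scale), cardiac-respiratory coupling
(amplitude modulation of the cardiac signal by lung volume),
within-region amplitude gradients, and correlated (reconstruction-
smeared) noise unless `psf_sigma > 0`. Passing tests therefore validate
the signal-processing chain under its stated assumptions, not the
behaviour of any particular reconstruction algorithm on real subjects.

## The cohort experiment

`demo_experiment()` generates a cohort with the target study's design —
14 subjects x 5 positions (upright, supine, prone, left/right lateral) x
3 replicates — in which the cardiac amplitude of two positions (default
upright and supine, scale 0.5) is reduced, runs the full pipeline on
every recording, and checks that Friedman plus Conover flag exactly the
scaled-vs-unscaled pairs. Desk-scale sizes keep a full cohort run at a
few seconds: 16-pixel grid, 25 s of breathing for each subject's first
recording (which supplies that subject's masks and rates — anatomy is
posture-invariant in this simulator by construction, so per-subject
segmentation is exact), 16 s for the other 14 recordings, 1 s apnea
tail. Between-subject variability: log-normal amplitude scale (15%),
rates drawn uniformly with a clearance margin from respiratory harmonics
(the generator analogue of recruiting subjects whose spectra are
unambiguous); if rate detection is still ambiguous for a subject, the
generator's known rates are used, mirroring manual verification. With
the amplitude halved the effect is large, so the experiment is a
structural end-to-end check (does the whole chain preserve a known
between-condition difference, and does the null hold its level?) rather
than a delicate power analysis.

## Numerical choices and degenerate inputs

* FFT sizes are the next `2^a`, `3*2^a` or `5*2^a`; forward-backward
  convolution uses the exact symmetric kernel, so matrix and column-wise
  filtering agree to machine precision.
* Cross-correlation uses full-trace norms (Cauchy-Schwarz keeps
  `|corr| <= 1`); lag ties take the first (most negative) lag;
  reference-pixel ties break in row-major order.
* Degenerate inputs error loudly: constant traces, empty regions or
  masks, all-zero movies, missing flow/segments, bands at or beyond
  Nyquist, cardiac periods under 4 frames, fewer than 2 complete cycles,
  unresolved harmonic conflicts, fewer than 3 breaths in a simulated
  breathing segment.
* Exact-test switches: Friedman exact for tie-free `k!^n <= 5e4`;
  Wilcoxon exact for `n <= 25` without ties.
* Problem sizes used by the validation suite (chosen for a desk-scale
  study): 200 recordings for rate recovery, 100 random delays for phase
  mapping, 20 seeds for heart-mask Dice, 50 recordings at 20 dB SNR for
  amplitude recovery, 1000 null tables for the Friedman level, 50
  cohort runs each for the posture experiment's power and null.

## Known limitations

* The validity floor (10% of the reference standard deviation) separates
  background only when pixel noise is well below the cardiac signal — at
  20 dB *respiratory* SNR with iid noise it no longer does, so heart
  segmentation is specified for the regularised-reconstruction noise
  regime; amplitude extraction (which only needs the lung mask) is
  robust far beyond it.
* Phase accuracy is lag-quantised at `360 * f_HR / fs` degrees; at 44 Hz
  and 69 bpm that is ~9 degrees, ample for a ±30 degree threshold but
  not for fine phase physiology.
* Min-to-min cycle anchoring plus edge trimming discards the first and
  last cycle of each slice; very short segments (< ~4 respiratory
  cycles) cannot be analysed.
* Rate-locked subjects (`f_HR` on a respiratory harmonic) require the
  manual override, as in the original analysis procedure.
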