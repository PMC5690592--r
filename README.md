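# feit — separation of cardiac and respiratory signals in functional EIT

Functional electrical impedance tomography (EIT) records a movie of
reconstructed impedance changes over a transverse slice of the thorax
(typically 32 × 32 pixels at 44 Hz). Every lung pixel mixes a large
breath-synchronous component ΔZ_RR with a cardiac-synchronous component
about one order of magnitude smaller, and pixels over the heart pulse
roughly in antiphase (150°–180°) to the cardiac signal inside the lung.
`feit` is for researchers who need to quantify those components per
recording and compare them across conditions (body positions, in the
motivating design): it separates them spectrally, segments the heart
spatially, extracts per-cycle amplitudes, and runs the nonparametric
repeated-measures statistics.

The pipeline:

1. **Rough split** of a region trace at 2–40 bpm (respiration) and
   40–400 bpm (cardiac, capped below Nyquist), then periodogram peak
   detection of f_RR and f_HR, with an explicit flag when f_HR collides
   with a respiratory harmonic.
2. **Refined zero-phase filtering** of every pixel trace with
   forward–backward Hamming-windowed FIR band-passes at
   [0.5, 2.5]·f_RR, [0.5, 2.5]·f_HR and the strict [0.8, 1.2]·f_HR.
3. **Heart/lung segmentation**: the cardiac-domain trace of a
   maximal-ventilation reference region is cross-correlated with every
   pixel over one centred cardiac period; pixels with |phase| > 30° form
   the heart mask after a morphological closing and opening (3 × 3
   cross).
4. **Per-cycle amplitudes** over the lung-mean trace: ΔZ_RR, ΔZ_CR
   (cardiac during breathing), ΔZ_CA (raw apnea trace), and per-breath
   tidal volumes V_T by cumulative trapezoidal integration of the
   spirometric flow; averaged cycles → replicate → triplicate.
5. **Posture statistics**: Friedman test across positions within
   subjects (exact permutation p for small tables), Conover all-pairs
   post-hoc with Holm correction, Wilcoxon signed rank for
   ΔZ_CR vs ΔZ_CA, Pearson correlation, Anderson–Darling normality
   report.

A synthetic thorax-movie generator (`make_geometry()`,
`simulate_recording()`) produces movies, spirometric flow and a
ground-truth sidecar (per-breath/per-beat amplitudes, rates, masks), so
the whole chain is testable without any real EIT data.

## Worked example

```r
library(feit)

geom   <- make_geometry(32, seed = 1)          # two lungs + heart on 32x32
params <- sim_params(seed = 42)                # 44 Hz, 45 s breathing + 15 s apnea
rec    <- simulate_recording(params, geom)

out <- analyze_recording(rec$movie, rec$flow,
                         list(segmentation_window = 20))
out$rates
#> <rate_estimate> f_RR = 0.2471 Hz (14.8 bpm), f_HR = 1.1494 Hz (69.0 bpm)
#>   harmonic conflict: FALSE (resolution: none); bin width 0.0222 Hz

dice(out$heart, geom$heart_mask)               # 0.988
dice(out$lung,  geom$lung_mask)                # 0.992

summarize_amplitudes(out$amplitudes)
#>   subject_id position         kind mean_amplitude n_replicates
#> 1        S01  upright        dZ_CA         0.2011            1
#> 2        S01  upright        dZ_CR         0.1887            1
#> 3        S01  upright        dZ_RR         1.9871            1
#> 4        S01  upright dZ_RR_per_VT         4.0548            1
#> 5        S01  upright          V_T         0.4901            1
```

The detected rates sit within one resolution bin of the generated truth
(0.2455 / 1.1483 Hz). The respiratory amplitude (1.99, truth 1.96) is an
order of magnitude above the cardiac one; the cardiac amplitude
extracted by filtering during breathing (ΔZ_CR = 0.189) agrees with the
raw apnea amplitude (ΔZ_CA = 0.201) to within the filter-truncation
effect on the pulse's third harmonic, and the per-breath tidal volume
recovers the simulated 0.5 L (amplitude-jittered to 0.49 L).

A cohort-level experiment with the motivating study's design
(14 subjects × 5 positions × 3 replicates, cardiac amplitude halved in
two positions) runs the full pipeline per recording and checks that
Friedman + Conover flag exactly the scaled positions:

```r
d <- demo_experiment(seed = 1)
d$stats$friedman$p_value        # ~5e-9
d$success                       # TRUE: all scaled-vs-unscaled pairs flagged
```

Disk-based cohorts go through `write_recording()` / `read_recording()`
and `run_pipeline(manifest, out_dir)`, which writes tidy amplitude,
summary and statistics CSVs plus a run log.

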