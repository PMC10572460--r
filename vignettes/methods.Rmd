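---
title: "Methods: signal models, measurement conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal models, measurement conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiphys)
```

This vignette documents the models and procedures the package
implements, the parameters that matter, and the design decisions taken
where the underlying measurement conventions are genuinely open. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. Astrocyte Ca²⁺ transients

### Signal model and ΔF/F₀

A soma's raw fluorescence `F[t]` (arbitrary units, uniform frame period,
nominally 1 Hz for 5 minutes) is normalised as

\[ \Delta F/F_0[t] = \frac{(F[t] - bg) - (F_0 - bg)}{F_0 - bg}, \]

with `bg` a scalar background and `F₀` the mean of a quiescent window of
at least 30 consecutive frames. The ratio is invariant under any
multiplicative gain applied to background-subtracted fluorescence, which
the tests assert.

### Baseline window selection

"Quiescent" is operationalised as follows (the underlying convention
only demands ≥ 30 event-free frames):

1. Candidate windows are all 30-frame spans whose mean lies no more than
   4 noise-SDs above the trace's lower quartile. Ca²⁺ transients only
   *raise* fluorescence, so a flat event plateau — which can have lower
   variance than the baseline — is excluded by its elevated mean.
2. Among candidates, the window with the smallest within-window SD gives
   `F₀`.
3. One refinement pass: events are detected against this provisional
   baseline, and if any overlap the window the best non-intersecting
   candidate is chosen instead. A failure to find one is an error that
   asks for a manual window, which `find_baseline(window = c(a, b))`
   accepts.

The baseline noise `sd₀` is *not* the SD of the selected window: the
minimum over ~270 overlapping windows understates the noise by a
selection bias of tens of percent, which would shift the effective
detection threshold. Instead `sd₀ = mad(diff(F))/√2`, the robust
first-difference estimator — unbiased for frame-to-frame noise and
insensitive to sparse, smooth transients. A constant trace yields
`sd₀ = 0` and detection then refuses to run rather than dividing by
zero.

### Detection, splitting, classification

- **Detection**: maximal runs with ΔF/F₀ ≥ `k_sd · sd₀` (default 2) for
  at least `min_frames` (default 5) consecutive frames. Both constants
  are behavioural invariants of the suite: the length boundary is
  exactly 5 frames and the amplitude boundary exactly 2 SD (the
  threshold comparison is `≥`).
- **Multi-peak splitting**: within a detected run, the event is cut at a
  trough that falls to ≤ 50 % of the smaller adjacent local maximum
  (`mode = "relative"`, the default). The alternative reading — cutting
  wherever ΔF/F₀ itself drops below 0.5, i.e. below 50 % of F₀ — is
  available as `mode = "absolute"`; the two printed formulations of the
  rule are ambiguous and neither is asserted as the original intent.
  Peaks and troughs are located on a lightly smoothed copy (3-frame
  running mean): at 1 Hz frame rates a genuine calcium trough spans
  several frames, so a single noisy frame cannot split an event.
  Fragments shorter than `min_frames` are discarded; fragments are
  contiguous and non-overlapping, with the trough frame opening the
  second fragment.
- **Duration**: first to last supra-threshold frame, inclusive, times
  the frame period — so `duration_s` always equals frame count ×
  `frame_period_s`. Because the event edges sit *at* the threshold, a
  recovered duration carries up to one frame of crossing jitter per
  flank under noise; the tests assert ±1 frame for onsets and ±2 frames
  for durations at SNR 10.
- **Cut-off**: `derive_cutoff()` is the type-7 empirical percentile
  (linear interpolation between order statistics, the most widespread
  convention, recorded in the result's attributes), applied at the 75th
  percentile of pooled durations. The default classification cut-off is
  23.1 s.
- **Classification tie rule**: FT strictly below the cut-off, ST at or
  above — the printed rule makes "fast" strictly less-than, so the
  boundary case is ST.
- **FT/ST index**: the per-cell ratio of FT to ST *counts* (for
  equal-length recordings, identical to a rate ratio; the alternative
  reading is noted here rather than implemented separately). A cell
  without STs reports the ratio as missing, never as a division error.

## 2. Synaptic currents

### Spontaneous PSC detection

The detection method is deliberately simple and parameter-transparent:
the polarity-rectified, median-baseline-subtracted trace is lightly
smoothed (0.75 ms running mean) and local maxima above a threshold
(default 3 × robust MAD noise SD) are events, subject to three
confirmations that a bare amplitude threshold lacks:

1. **Dwell**: the rectified signal must stay above half the threshold
   for ≥ 2 ms around the peak (rejects isolated noise excursions — at
   4 kHz a 60 s sweep has 240 000 samples, so 3-SD noise crossings are
   routine).
2. **Re-rise**: a peak must rise by at least the threshold above the
   minimum since the previous accepted peak (rejects noise wiggles
   riding a slow decay tail, where the local slope is smaller than the
   noise).
3. **Refractory merge**: peaks closer than `min_interval_ms` (10 ms)
   collapse to the larger one.

Amplitudes are read from the *raw* rectified trace near the smoothed
peak so smoothing does not bias them low. Frequency is event count over
sweep duration. Template matching is future work.

### Paired-pulse ratio

`PPR = A₂/A₁`, baseline-to-peak within a 2–50 ms post-stimulus window,
baseline from 10 ms pre-stimulus. With `decay_correction` (default, and
appropriate at the 100 ms inter-stimulus interval used throughout) a
single exponential is fitted to the inter-stimulus tail of response 1
and subtracted from window 2 before taking A₂. The ratio is exactly
invariant under positive gain rescaling. A first response within 5
robust SDs of the baseline noise is an error (undefined ratio) — the
maximum of ~200 noise samples routinely reaches 3.3 SD, so a 3-SD floor
would pass pure noise.

### Compound-PSC E/I balance

For a compound PSC at −40 mV, the excitatory component is the inward
lobe (peak = |minimum|, area = |trapezoidal integral of the negative
part|, pA·ms) and the inhibitory component the outward lobe, over the
post-stimulus window after a 2 ms artifact blank. Lobe boundaries are
the zero crossings of the baseline-subtracted trace, so
`exc_area + inh_area` equals the total rectified area (an oracle check
in the suite). Both the peak ratio and the area ratio are always
reported, since which one a given figure uses is not always stated.
Missing outward phase (below 3 robust SDs) reports zero magnitudes and
missing ratios, never infinities.

## 3. Field EPSPs

`measure_fepsp()` takes, per sweep: baseline (5 ms pre-stimulus), fiber
volley (most negative point in the 2–5 ms window after the 2 ms artifact
blank), fEPSP amplitude (baseline to negative peak in the 5–40 ms
window), slope (line fit between the 20 % and 80 % amplitude crossings
of the falling-voltage phase — the field's convention; the underlying
protocol does not define its slope window), and a population-spike flag:
an interior positive-going notch in the trough region whose prominence
exceeds 10 % of the fEPSP amplitude (configurable; an absolute-mV
criterion can be emulated by scaling). Sweeps whose post-stimulus
excursion stays within 5 robust noise SDs return a zeroed measure with
`ok = FALSE`.

`build_io()` orders measures by intensity; `ps_threshold()` is the
lowest intensity with a spike; `compare_io()` returns per-intensity
amplitude ratios and their mean, so a uniform 2× enhancement appears as
ratio 2 at every intensity. `fc_ppr_effect()` handles paired
before/after designs (e.g. bath fluorocitrate) via per-pair differences
and a paired gated comparison.

## 4. LFP analysis

### Multitaper PSD

DPSS tapers are computed in-package from the symmetric tridiagonal
Slepian eigenproblem (no R multitaper package is part of this stack);
for windows longer than 1024 samples they are computed at 1024,
spline-interpolated and re-orthonormalised — the standard large-n
construction. The suite asserts orthonormality, the white-noise flatness
of the estimate, Parseval's identity (total one-sided power ≈ signal
variance within 5 %) and the frequency spacing 1/segment-duration.
Defaults follow the reference analysis: 4000 ms segments, 500 ms
overlap, time-bandwidth 5, 9 tapers; requesting more than `2·nw − 1`
tapers warns (concentration degrades) but does not error. Note the
implied bandwidth: with nw = 5 over 4 s, a spectral line is smeared over
±1.25 Hz, which bounds how sharply power can concentrate in the 1–3 Hz
band.

`band_power()` integrates the density over a half-open band `[lo, hi)`
so adjacent bands add exactly.

### Event detection

The underlying protocol identified interictal spikes and seizures
manually; the automated detectors here are a repository decision with
all thresholds exposed, not a claim about the original procedure.

- **Interictal spikes**: |signal| above `amp_threshold_sd` (default 5)
  robust SDs; above-threshold runs separated by < 20 ms merge (a
  poly-spike complex is one event); accepted if the half-amplitude width
  lies in 20–70 ms.
- **After-discharges**: the 250 ms RMS envelope must exceed
  `envelope_threshold_sd` (default 2) robust SDs for at least
  `min_duration_s` (default 2 s — ictal episodes last several seconds,
  and the floor rejects the occasional sustained background excursion
  that 1/f noise produces); supra-threshold stretches separated by less
  than 1 s merge, since a momentary envelope dip inside one spike-wave
  episode does not end the seizure. Latency is the first AD start minus
  the injection marker and is reported missing without a marker;
  incidence is count per recording minute.
- Band-pass preprocessing (0.1–100 Hz) uses a zero-phase
  forward–backward Butterworth filter so event times acquire no latency
  bias.

## 5. Statistical gating

`normality_gate()` runs Shapiro–Wilk (deciding, at α = 0.05) and
Lilliefors KS (reported alongside; when they disagree Shapiro–Wilk
governs, and the result says so). `compare_two()` uses Student's
two-tailed t (equal variances) when both samples pass, otherwise
Mann–Whitney; paired variants are the paired t and Wilcoxon signed-rank,
with identical paired samples short-circuited to a "no difference"
result (p = 1) rather than an error. `compare_multi()` requires all
groups normal for the ANOVA branch — any non-normal group switches the
whole comparison to Kruskal–Wallis — and always reports pairwise tests
with the Bonferroni identity `adjusted_p = min(1, m·p)`. The decision
path taken is recorded in every result.

## 6. What the generators emulate — and what they do not

The generators reproduce the *geometry* of each recording type with
known ground truth:

- **Calcium** (`gen_calcium_traces`): baseline ≈ 2000 AU (somata in the
  reference protocol were selected above 2000 units), Gaussian noise
  (default 40 AU, 2 %), optional linear drift, and transients with a
  linear rise (~10 % of duration), plateau, and geometric fall scaled so
  the supra-threshold time at the 2-SD criterion equals the drawn
  duration, followed by a fast sub-threshold tail. Event peak
  amplitudes are drawn in multiples of the noise SD (default mean 10 —
  i.e. SNR 10 — truncated at 4). FT durations are log-normal
  (meanlog log 8, sdlog 0.35) and ST durations log-normal (meanlog
  log 45, sdlog 0.25): both tails clear the 23.1 s cut-off with ≥ 99 %
  margin, so ground-truth labels are meaningful. The default ST
  fraction is 0.25 — consistent with a cut-off *defined* as the 75th
  percentile. Events are placed with ≥ 2-frame gaps and the first 30
  frames are kept event-free so a baseline window always exists;
  `overlap_mode` instead writes merged two-peak events (trough at 40 %
  of the peak, three frames wide) to exercise the splitting rule. No
  published amplitude or SNR statistics exist for these signals, so the
  noise and amplitude defaults are realistic free choices, not
  calibrations.
- **PSCs** (`gen_psc_sweep`): Poisson event times, log-normal amplitudes
  (mean 20, SD 8 pA), unit-peak biexponential kernel (1 ms rise, 6 ms
  decay), Gaussian noise; inward polarity gives negative deflections.
  `gen_paired_pulse` superimposes the second response on the decay of
  the first so the true PPR is recoverable exactly by the
  decay-corrected convention. `gen_compound_psc` solves the kernel decay
  constants so the component peaks *and* areas equal the requested
  values, and delays the outward component by at least 8 excitatory
  decay constants so the lobes do not materially overlap.
- **fEPSP families** (`gen_fepsp_family`): fiber volley linear in
  intensity, fEPSP amplitude `amp_scale` × a sigmoid of intensity
  (midpoint 50 µA, slope 15 µA — standard input–output phenomenology),
  so a condition effect is a pure amplitude multiplier; the
  population-spike notch scales with the fEPSP so inter-family ratios
  are preserved exactly.
- **LFP** (`gen_lfp`): pink (1/f) background by default, resembling
  cortical LFP; ADs as amplitude-modulated sinusoids under a Tukey
  envelope (5 % taper — near-full amplitude over the scheduled span so
  detected durations track the schedule); interictal spikes as Gaussian
  deflections whose FWHM equals the scheduled width.

None of this is biophysical: there are no conductance-based cells, no
kindling progression dynamics, no receptor pharmacology. Passing tests
therefore demonstrate that the *measurement conventions* are implemented
correctly and are recoverable under realistic noise — not that the
pipeline would be robust to every artifact of real recordings
(photobleaching curves, movement, electrode drift, seizure-morphology
diversity).

## 7. Numerical choices and problem sizes

- All generators accept a seed and restore the caller's RNG state;
  identical configuration and seed give byte-identical output.
- Quantile type 7; trapezoidal areas; zero crossings as lobe bounds;
  0-based inclusive frame indexing; seconds always derived by
  multiplying frame counts by the frame period, never by resampling.
- Degenerate inputs have defined behaviour rather than NaNs: flat
  baselines error in detection, absent inhibitory lobes give missing
  ratios, empty duration samples error in `derive_cutoff`, a cell with
  no ST reports a missing FT/ST index.
- The test suite runs simulation-based checks at deliberately moderate
  sizes — e.g. 100 traces for calcium injection-recovery, 50 seeds for
  AD recovery, 200 sweeps for rate unbiasedness, 2000 simulations for
  the type-I calibration — chosen to keep the full suite around half a
  minute while leaving the binomial noise on each assertion small
  relative to its margin.

## 8. Known limitations

- The spontaneous-PSC detector is amplitude-based; heavily overlapping
  events within the 10 ms refractory window merge, biasing frequency
  slightly low at high rates.
- The AD detector's thresholds are not calibrated to any published
  manual criteria (none are quantified); they are defaults that separate
  cleanly on the synthetic conditions and are meant to be tuned on real
  data.
- Population-spike detection assumes a single notch; multi-spike bursts
  report only the most prominent one.
- The fEPSP slope is returned as a magnitude; sign conventions differ
  between laboratories.
- The statistics layer implements per-comparison gating exactly as
  described, including its quirks: gating inflates neither test's
  nominal level materially (the suite checks the two-sample type-I rate
  stays within 0.03–0.07), but no hierarchical modelling of
  cells-within-animal nesting is attempted.
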