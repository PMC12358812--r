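---
title: "Methods: mesoscale GABA imaging analysis in mesogaba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesoscale GABA imaging analysis in mesogaba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mesogaba` analyses wide-field movies of an extracellular GABA sensor
recorded with dual-wavelength strobed illumination: a blue-excited
fluorescence channel carrying the GABA signal and a green reflectance
channel carrying the hemodynamic (blood-volume) artifact, interleaved
frame-by-frame at 80 Hz (40 Hz per channel). This vignette documents the
models, the tunable parameters, the synthetic-data generator used to test
everything, and the numerical choices made where the design was open.

## The preprocessing model

Each blue pixel intensity is modelled as

$$F(t) = F_0\,\bigl(1 + \Delta F/F(t) + \alpha\,h(t)\bigr)\,b(t) + \varepsilon,$$

where $h(t)$ is the hemodynamic process shared with the reflectance channel
($R(t) = R_0 (1 + h(t)) + \varepsilon$), $\alpha$ a per-pixel gain, and
$b(t)$ a slow photobleaching trend. The chain is:

1. **De-interleave** the strobed stack by frame parity and verify channel
   identity by correlating first frames against reference images.
2. **Align** the green channel onto the blue frame clock by per-pixel
   linear interpolation (channels are offset by half the total frame
   period; endpoints held).
3. **Hemodynamic regression**: ordinary least squares of $F$ on aligned
   $R$ per pixel, with intercept, over the full recording;
   $F_{\mathrm{corr}}(t) = F(t) - \hat\alpha R(t)$.
4. **ΔF/F**: $(F_{\mathrm{corr}} - F_{\mathrm{corr},0}) / F_{0,\mathrm{raw}}$.
5. **Band-pass** 0.1–5 Hz, 4th-order Butterworth run forward–backward.

Two numerical decisions deserve emphasis.

*The ΔF/F denominator uses the raw-fluorescence baseline.* The corrected
signal subtracts the full scaled reflectance, so its own baseline shrinks to
roughly $(1-\alpha) F_0$; dividing the corrected fluctuation by that shrunk
baseline would inflate ΔF/F by $1/(1-\alpha)$ (a factor of two at the
typical $\alpha \approx 0.5$). `compute_dff()` therefore always zeroes the
numerator against the *corrected* baseline window (making the
baseline-window mean exactly zero) while normalizing by the *raw*
fluorescence baseline map, preserving the physical ΔF/F scale. Both maps
are recorded in the output provenance.

*Zero-phase filtering.* Response latencies (time-to-peak, decay time) are
scientific outputs, so the Butterworth band-pass is applied
forward–backward (`signal::filtfilt`); the filter's own pass/stop behaviour
is pinned by dedicated frequency-response tests. The trace mean is removed
before filtering because a DC offset excites large edge transients at the
very low normalized high-pass cutoff (0.1 Hz at 40 Hz sampling).

*Regression window.* $\hat\alpha$ is fitted on the entire recording. Evoked
windows are a small fraction of samples, the hemodynamic process dominates
the 0.05–0.3 Hz band, and a longer window tightens the estimate; the fit
window is written to provenance. The regression is run on raw intensities
(not baseline-normalized signals); with matched channel baselines the
fitted intensity gain is directly comparable to the generative gain.

## Evoked-response features

ROI traces are unweighted means over 3×3-pixel neighbourhoods. Trials are
epoched at [−1 s, +3 s] around each stimulus, baseline-subtracted over the
1-s pre-stimulus window, and averaged with SEM (sample sd / √n). Features
of the trial-mean trace:

* **peak amplitude** — maximum within the half-open 1-s post-stimulus
  interval (the stimulus frame itself never counts);
* **time-to-peak** — earliest argmax, in ms (ties break to the earliest
  sample, which matters on plateaus);
* **decay time** — first post-peak crossing of 50% of the peak, located by
  linear interpolation between frames; flagged invalid when the trace ends
  above half-peak.

Decay is measured on the trial-mean trace (not per-trial then averaged);
this choice is recorded in provenance. Trials overlapping detected
movement periods are excluded before averaging.

Feature recovery is validated on unfiltered trial averages so that
estimator bias and filter bias are assessed separately; the band-pass is
characterized by its own response tests. In the full pipeline the §-style
0.1–5 Hz ROI filter slightly attenuates sharp peaks (a few percent), which
is visible in the worked example.

## Motion exclusion and sleep scoring

The EMG is squared and median-filtered (0.1 s window) into a robust power
envelope — the running median rejects single-sample artifacts yet never
dips inside a sustained burst. Movement periods are maximal runs strictly
above the 95th percentile of the envelope. Because a percentile threshold
always marks ~5% of samples, brief noise excursions are inevitable whenever
movement occupies less time than that; runs shorter than 0.1 s are
therefore dropped *before* gaps under 0.5 s are closed (the reverse order
would merge noise excursions into spurious long intervals). Imaging frames
whose times fall inside a period are excluded downstream.

Sleep scoring works on 5-s epochs (long enough for stable 1–4 Hz power,
short enough to resolve brief REM bouts) with three features: mean EMG
envelope power, hippocampal theta/delta band-power ratio (5–10 Hz over
1–4 Hz, Welch periodogram, conventional rodent band edges), and the mean of
the z-scored composite motion-energy signal. Rules, in order: WAKE if EMG
power or motion exceeds threshold; else REM if theta/delta ≥ 1.5; else
NREM. Labels are smoothed by a 3-epoch majority vote that can never invent
a label absent from the raw pass. Epochs with undefined features are
UNSCORED and excluded.

Auto-thresholds default to the 60th percentile of epoch EMG power, ratio
1.5, and 1 z of motion, all overridable. **Limitation**: the percentile
rule presumes a sleep-majority session (the regime sleep-deprivation
protocols produce); in wake-heavy recordings it lands inside the wake
cluster and `emg_thr` should be set explicitly.

## Connectivity

Seed-pixel maps correlate every pixel's 0.1–5 Hz-filtered trace with a seed
trace (3×3 neighbourhood mean, mirroring the ROI convention; a single-pixel
mode is available, for which the seed's self-correlation is exactly 1).
ROI matrices are Pearson correlations among filtered 3×3-ROI traces; the
interhemispheric summary is the mean over the ten homotopic pairs of the
default bilateral ROI table (bregma-referenced nominal atlas coordinates —
full atlas image registration is out of scope). State-resolved analysis
assigns frames to states by epoch membership, drops motion-masked frames,
and filters each contiguous usable bout *separately* before concatenation,
so filter transients never bridge discontinuous time; states with fewer
than 100 usable frames are skipped. Every correlation path is tested
against a naive two-pass Pearson oracle at 1e-12.

## Spontaneous transients

ROI traces are detrended by a robust mono-exponential-plus-offset fit
(Levenberg–Marquardt; 60-s running-median fallback when the trend is
unidentifiable, flagged in the result). Pre- and post-drug sessions are
detrended independently, because a drug-elevated baseline would alias into
a joint trend fit.

The detector — the package's own design, with every parameter exposed and
written to provenance — thresholds a 0.1-s boxcar-smoothed copy of the
detrended trace at median + 3·MAD, extends supra-threshold runs to the
surrounding half-threshold crossings, merges events closer than 0.2 s, and
drops events shorter than 0.2 s. Peak amplitude and time are read from a
lighter 0.075-s smoothing: heavy smoothing stabilizes detection but
attenuates sharp peaks. The smoothing and duration floor were calibrated by
Monte-Carlo on pure noise to an operating point below 0.5 false events/min
at the default threshold, and frozen. At matched scale (event amplitude
five times the noise sd) the detector recovers 20 injected events per
5-minute trace within ±1 and mean amplitudes within 10% (a few percent low,
from the amplitude smoothing).

The paired pre/post comparison is the classical paired t statistic,
computed directly and cross-checked against `t.test` in the suite.

## The synthetic-data generator

The generator emulates the recordings the analysis assumes, with complete
ground truth, and its defaults are the study conditions used throughout the
tests:

| parameter | default | rationale |
|---|---|---|
| image | 64×64 px, 8.6-mm field | desk-scale geometry; no tested property needs the full sensor |
| acquisition | 80 Hz strobed (40 Hz/channel) or 150 Hz continuous | the two recording modes |
| blue noise | 0.01 ΔF/F | shot-noise scale of the fluorescence channel |
| reflectance noise | 0.005 | the reflectance channel is photon-rich |
| hemodynamics | 0.05–0.3 Hz band-limited, sd 4% of baseline, gain map mean 0.5 sd 0.1 (smooth) | slow blood-volume fluctuations with smooth spatial gain |
| bleach | exp(−t/10 000 s), blue only | ~9% loss over a 15-min session; reflectance is not a fluorophore |
| evoked kinetic | linear 0.1-s rise, exponential 0.4-s decay, peak 0.05 ΔF/F; contra:ipsi 2, +50 ms ipsi latency | linear-rise/exponential-decay makes the 50%-decay closed form (τ ln 2) exact |
| stimulation | 40 trials, 10-s ISI, frame-synchronous | stimulus TTLs locked to the blue frame clock |
| spontaneous synchrony | shared-variance (= homotopic r) 0.70 wake / 0.45 REM / 0.15 NREM | wake > REM > NREM bilateral synchrony |
| sleep session | 300 s: W60 N90 R30 W60 N60 (40/50/10%) | post-deprivation, sleep-majority composition |
| EMG | sd 1 wake / 0.25 NREM / 0.2 REM; 8× bursts in wake | ≥5× wake/sleep variance contrast |
| LFP | delta- vs theta-dominated mixtures by state | REM theta/delta > 2, NREM < 0.5 by periodogram |
| REM twitches | 0.1/s, 0.2–0.4 s | brief motor twitches visible to video, not EMG |

Spontaneous cortical signals are built from three independent band-limited
(0.2–3 Hz) unit processes — one global, one per hemisphere — mixed as
$\sqrt{c}\,g(t) + \sqrt{1-c}\,h_{\mathrm{side}}(t)$ so the interhemispheric
correlation equals $c$ by construction. Evoked transients use a flat-core
(radius 1.6 px) Gaussian-skirt footprint so a centred 3×3 ROI reads the
full amplitude.

What the generator does **not** emulate: vascular anatomy and spatially
structured hemodynamics, optics/PSF blur, frame-to-frame brain motion,
pixel-level spontaneous structure within a hemisphere (all pixels of a
hemisphere share one signal), sensor nonlinearity and photon (Poisson)
statistics, and pupil signals. Passing tests therefore demonstrate that the
implementation inverts its stated model at realistic SNR — not that the
model captures every failure mode of real recordings.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed; one global seed fans out
to per-stage seeds via `split_seed()` so stage outcomes are independent of
execution order, and `run_pipeline()` writes the fully resolved
configuration plus seeds next to its outputs — the provenance file alone
suffices to re-run identically, and repeated runs are byte-identical.

The suite exercises the full 64×64, 300-s recovery scene once and otherwise
uses 8–32-px scenes of 30–410 s, 10-seed batches for stochastic claims, and
trace-level simulation where the image dimension is irrelevant — sizes at
which every recovery criterion is already tight while the whole suite runs
in a few minutes.

## Known limitations

* The hemodynamic model is a single scaled regressor; nonlinear
  (Beer–Lambert) corrections are out of scope.
* The percentile-based EMG auto-threshold assumes sleep-majority sessions
  (see above).
* `detrend_baseline` falls back to a running median when the exponential
  is unidentifiable (e.g. trend-free traces) — flagged, not silent.
* Atlas handling is a rigid bregma-anchored coordinate table; no image
  registration.
* The transient detector's absolute event counts depend on its calibrated
  operating point; comparisons across conditions (its intended use) are
  insensitive to the exact point.
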