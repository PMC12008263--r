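---
title: "Methods: simulating and analysing pressure-stimulation cardiovascular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing pressure-stimulation cardiovascular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocuff)
```

## Overview

`cardiocuff` models a multi-site cardiovascular acquisition session in
which six cuffs (both wrists, arms and ankles) apply a seven-phase pressure
stimulus while 27 signal channels are recorded synchronously. The package
has two halves that are deliberately coupled: a *simulator* that encodes
known physiological quantities into the raw channels, and an *analysis
stack* that recovers them. Every analysis operation is therefore testable
end-to-end against configured ground truth, which is the package's central
design idea: the simulator is not a test fixture but a first-class model of
what the analysis assumes the data to look like.

## The pressure protocol

The schedule built by `build_protocol()` has seven analyzed segments
(RMPS1–RMPS7): a no-pressure baseline (40 s), a gradual deflation from the
maximum pressure MP = 180 mmHg to a 30 mmHg floor on the wrist+ankle cuffs
(120 s), a constant hold at the maximum-pulse-amplitude pressure MPAP
(30 s), an occlusive hold at MP (40 s), and the same deflation/hold/occlusion
triplet on the arm+ankle cuffs. A 15 s non-pressure rest separates
consecutive phases.

Two numerical choices deserve explanation:

* **Inflation inside the segment.** The nominal segment duration includes
  the inflation ramp (default 20 mmHg/s). For gradual-deflation segments
  the default vent rate is therefore *derived*: it is chosen per segment so
  that the deflation spans MP down to the floor in the time remaining after
  the ramp (about 1.35 mmHg/s under defaults). An explicit `vent_rate`
  overrides this, in which case the trace clamps at the floor. This keeps
  three properties simultaneously: segments contain their own transitions,
  rest gaps are truly pressure-free, and a deflation sweeps the entire
  MP-to-floor range that oscillometric estimation needs.
* **MPAP per cuff.** The MPAP used for a constant hold is the one located
  on that cuff's own preceding deflation, never pooled across cuffs, since
  per-site mean arterial pressures differ.

## The simulator

All channels derive from a single continuous-time beat sequence
(R-peak times), evaluated directly on each channel's own sampling grid
(400/1600/3200 Hz). Because every waveform is a closed-form function of
continuous time, channels share the protocol clock exactly and no
resampling or decimation step is needed.

* **ECG**: a sum of Gaussian bumps per beat (P, Q, R, S, T at fixed offsets
  relative to R, R dominant). R-R intervals are `60/HR` plus Gaussian
  jitter; premature beats (optional) shorten one interval by 25 % and
  lengthen the next by 25 %, with a halved S1 on the premature cycle.
* **Heart sound**: damped-oscillation bursts; S1 at 40 ms after R, S2 at a
  configurable fraction (default 0.36) of the R-R interval so it falls in
  the second third of the cycle at every calibrated heart rate, with a
  configurable S2/S1 amplitude ratio (default 0.6). **Lung sound**:
  100–500 Hz band-limited noise under a 0.25 Hz respiration envelope.
* **Pulse channels** (pressure pulse and PPG): each beat contributes an
  asymmetric waveform — a 30 ms half-cosine upstroke followed by an
  exponential decay — delayed from R by the site transit time. The sharp
  upstroke places the maximum-change-rate point within ~15 ms of the pulse
  onset, so RWMACR-time differences between sites track the configured
  transit-time differences closely.
* **Oscillometric coupling.** A pressure-pulse channel under its own cuff
  has beat amplitudes following an asymmetric Gaussian envelope in cuff
  pressure, centred at the site MAP (`DBP + PP/3`). The two half-widths are
  set so the envelope passes through the fixed-ratio definition of blood
  pressure: amplitude = 0.55 of peak at SBP (above MAP) and 0.75 of peak at
  DBP (below MAP), on top of a 10 % pressure-independent floor. This is the
  standard normalized-oscillogram model, and it is what makes the
  generator's SBP/DBP *definitionally* recoverable by the fixed-coefficient
  analysis — the generator encodes blood pressure by the same convention
  the estimator reads it with. Distal channels (finger/toe optics, finger
  PPG) are attenuated by an occlusion factor `max(0, 1 − P_up/SBP_up)` of
  the most occlusive upstream cuff; earlobe channels ignore all cuffs.
* **Dual-wavelength blood-oxygen channels**: DC level plus a pulsatile AC
  dip. The per-beat AC train is centred (its analytic per-beat mean is
  subtracted) so that the per-cycle `(max − min)/mean` ratio equals the
  configured AC/DC ratio exactly; the 660 nm ratio is the 940 nm ratio
  times `r_from_spo2(SpO2)`, making the analysis-side ratio-of-ratios
  recover the configured saturation through the calibration parabola.
  While flow is blocked the pulsation is suppressed and the DC level
  drifts linearly at the configured per-wavelength rate (negative at
  660 nm, positive at 940 nm by default, the deoxygenation direction).
* **Quantization**: an affine map to 14-bit integers (round half away from
  zero, clipped to 0–16383) with per-kind gains, plus the inverse map.

Randomness: the profile seed seeds one root RNG; the beat sequence is drawn
first, then one sub-seed per channel is drawn from the root, so adding or
removing channels does not change the beats and identical (profile,
schedule) pairs give bit-identical recordings.

**What the simulator does not model**: baseline wander, motion artifacts,
mains interference, waveform-morphology pathology (only premature-beat
timing), reflected waves, or hemodynamic feedback between sites. Passing
recovery tests therefore demonstrates the correctness of the analysis
pipeline's logic and its statistical behaviour under white noise and the
modelled couplings — not robustness to every artifact class of real
recordings.

## The analysis stack

* **Smoothing**: a centred 5-point moving average on every raw channel;
  edge windows shrink so length is preserved.
* **R peaks**: squared first differences thresholded at 0.4 times their
  98th percentile (computed per 10 s block), supra-threshold runs grouped,
  refined to the local ECG maximum within ±50 ms, with a 250 ms refractory
  period. The three constants are exposed as arguments.
* **Cycle selection**: all R-R intervals inside analyzed segments are
  sorted; the *base time* is the mean of the middle 50 % (trimming
  `ceiling(N/4)` from each end — the rounding convention is documented and
  the bounds are inclusive). An interval is a calculated cycle iff it lies
  in `[0.7, 1.6] ×` base time; it belongs to the segment containing its
  starting R peak. The brute-force restatement of this rule is frozen in
  the test suite as an oracle.
* **Per-cycle parameters**: ECG fiducials are searched in fixed windows
  (Q: 60 ms before R; S: 100 ms after; P: 250–80 ms before; T: 80–400 ms
  after S) — the windows are configuration, not discovery. Pulse cycles get
  `A_d`, `K = mean/(max − min)` (implemented literally; the conventional
  `(mean − min)/(max − min)` variant exists behind an argument), NMACR,
  NMARR and the R-referenced timings, with derivatives as central
  differences scaled by the sampling rate and argmax ties resolved to the
  earliest sample. Sounds are analyzed on a 20 ms rectified-smoothed
  envelope, with S1/S2 as the envelope maxima of the first/second thirds.
* **Oscillometric BP**: the envelope comes from per-cycle amplitudes of the
  band-passed (0.5–20 Hz, zero-phase) pulse versus mean cycle pressure,
  restricted to the deflation (after the window's pressure maximum),
  lightly smoothed (3-point) over pressure-sorted cycles, and normalized.
  Systolic/diastolic pressures are linearly interpolated where the
  normalized envelope crosses 0.55/0.75; per-site coefficient overrides are
  supported. MPAP ties break to the higher pressure. Degenerate envelopes
  flag the affected reading instead of guessing.
* **Occlusion trends**: `ACR = A/(DI × T)` is implemented exactly as the
  formula is printed, with `A` the mean per-cycle last-minus-first change
  and `DI` the window's last-minus-first difference. Note a consequence: if
  both wavelengths drift linearly, the drift magnitude cancels in ACR and
  `ROS = 1`; the simpler convention `ACR = DI/T`, in which ROS equals the
  drift ratio, is available via `convention = "simple"` and both are
  exercised in the tests with hand-computed values.
* **Harmonic bands**: the band rule is evaluated as
  `Round((n ± 0.2) × HR/FN)` — dividing by the bin width FN, which is what
  maps a frequency to a bin index; the printed multiplicative form is
  available via `literal = TRUE` for audit. HR enters in Hz (converted
  centrally from bpm), and the spectrum is mean-removed before the FFT so
  the DC bin cannot contaminate the first harmonic at low heart rates.
  `Round` is half away from zero throughout.

## Parameter defaults

| Parameter | Default | Why |
|---|---|---|
| MP | 180 mmHg | protocol default maximum pressure |
| deflation floor | 30 mmHg | below diastolic range, completes the envelope |
| inflation rate | 20 mmHg/s | fast ramp, small fraction of the segment |
| rest interval | 15 s | inter-phase recovery |
| cycle bounds | 0.7–1.6 × base | the base-time selection rule |
| oscillometric c_sys / c_dia | 0.55 / 0.75 | common literature ratios; per-site overrides |
| envelope floor | 0.10 | keeps uncuffed pulse channels pulsatile |
| R-peak threshold | 0.4 × P98 per 10 s | robust to amplitude drift |
| refractory | 250 ms | above the 150 bpm upper calibrated rate |
| band half-width | 0.2 × HR | the harmonic band rule |

## Problem sizes

The test suite and examples run the protocol with shortened phases
(e.g. 20/60/12/20/60/12/20 s with 8 s rests) and, for recovery studies, a
channel subset; the deflations still sweep the full MP-to-floor pressure
range, only faster, so the oscillometric envelope is sampled by fewer
cycles (~2.5 mmHg per cycle instead of ~1.2). Twenty seeded subjects at
this size characterize recovery error medians well. The acceptance script
runs one subject under the full-length schedule with all 27 channels.

## Known limitations

* The occlusion-trend `DI` is the literal first/last difference of the
  occlusion window; the first seconds of an occlusive hold still contain
  the inflation ramp and residual pulsation, which adds variance to ROS.
  This is inherent to the printed definition, not to the implementation.
* SpO2 estimation uses per-cycle `(max − min)/mean`, which is
  noise-biased upward when the AC amplitude is small; the simulator's
  optical noise default is correspondingly small (ambient-light subtraction
  and 4-sample summation justify a clean channel).
* R-peak detection is tuned for the simulator's single-lead morphology and
  the calibrated 40–150 bpm range; pathological morphologies (bundle
  branch block, large T waves) would need re-tuned windows.
* Blood pressure readings are only as meaningful as the fixed-ratio
  convention; no auscultatory or intra-arterial reference is modelled.
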