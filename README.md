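# cardiocuff

Simulation and analysis of multi-site cardiovascular recordings acquired
under cuff pressure stimulation.

## The problem

Screening-grade cardiovascular assessment benefits from recording many
physiological signals at once — ECG, heart and lung sounds, pressure pulses
at the limbs, photoplethysmography (PPG), and dual-wavelength blood-oxygen
optics — while *stimulating* the circulation with cuff pressure. Inflating
cuffs on the wrists, arms and ankles and then deflating them slowly, holding
them at the pressure of maximal pulsation, or occluding flow entirely, turns
a passive recording into a controlled experiment: each phase exposes
different quantities (oscillometric blood pressure, personalized-pressure
pulse morphology, occlusion metabolism at the fingers and toes).

`cardiocuff` is a software counterpart of such an acquisition system, for
people developing or validating analysis methods for this class of data:

* a **protocol** module that lays out the seven-phase schedule — a
  no-pressure baseline, two gradual deflations from the maximum pressure MP
  (180 mmHg by default) down to a 30 mmHg floor on the wrist/ankle and
  arm/ankle cuff groups, two constant holds at the maximum-pulse-amplitude
  pressure (MPAP), and two occlusive holds at MP — with 15 s rest gaps;
* a seeded **simulator** that emits the full 27-channel recording structure
  (4 PPG at 400 Hz, ECG at 1600 Hz, heart/lung sound at 3200 Hz, 6 pressure
  pulses, 6 cuff pressures, 8 dual-wavelength blood-oxygen channels) with
  the physiological couplings the analysis assumes, so every analysis
  result can be checked against configured ground truth;
* the complete **analysis stack**: 5-point smoothing, differential-threshold
  R-peak detection, the base-time cycle-selection rule, per-cycle
  time-domain parameters, oscillometric blood pressure, SpO2 from the
  ratio-of-ratios, pulse wave velocity, occlusion trend statistics, and FFT
  harmonic-band statistics.

## The core quantities

* **Calculated cycles.** R-R intervals are sorted; the mean of the middle
  50 % is the *base time* `t_base`; an interval is analyzed iff it lies in
  `[0.7, 1.6] × t_base`.
* **Calibration.** ECG voltage `V = -0.01042 + 4.30532e-4 × ADCV` (mV);
  SpO2 `= -160.01396 + 1370.04653 R + 41.14279 R²` (%) where
  `R = (AC/DC)₆₆₀ / (AC/DC)₉₄₀` per cycle; cuff pressure by per-channel
  linear fits.
* **Per-cycle parameters.** Amplitude difference `A_d = max − min`; the
  roundness index `K = mean/(max − min)`; NMACR (max |derivative| over the
  cycle maximum); NMARR (max rising derivative over `A_d`); timings from
  the R peak to the maximum, minimum and maximum-change-rate point
  (RWMACR); ECG fiducial amplitudes/timings; S1/S2 heart-sound amplitudes.
  Per segment: mean, SD and NSD = SD/mean.
* **Oscillometric BP.** The per-cycle pulse-amplitude envelope over a
  deflation peaks at MPAP; systolic/diastolic pressures are read where the
  normalized envelope crosses fixed coefficients (0.55 above, 0.75 below).
* **PWV** `= L_ab / t_ab` with `t_ab` the mean RWMACR-time difference
  between sites and `L` from height regressions
  (`L_heart→ankle = 0.8129 H + 12.328` cm, `L_heart→arm = 0.2195 H − 2.0734` cm).
* **Occlusion trends.** Per wavelength, `ACR = A/(DI × T)` over a
  blocking-flow hold; `ROS = ACR₆₆₀/ACR₉₄₀`; NROS normalizes by the
  baseline per-cycle amplitudes.
* **Harmonic bands.** For harmonic `n` of the heart rate, bins
  `Round((n ± 0.2) × HR/FN)`; per band the mean (AveF), max (MaxF),
  `RAMF = AveF/MaxF` and `RMMF = MaxF_n/MaxF_1`.

## Worked example

```r
library(cardiocuff)

profile  <- subject_profile(heart_rate = 72, seed = 42)   # ground truth
schedule <- build_protocol(protocol_config(
  durations = c(20, 60, 12, 20, 60, 12, 20), rest_interval = 8))
rec <- simulate_recording(profile, schedule)
rec
#> <cuff_recording> 27 channels, 252 s, units = calibrated, seed = 42

ana <- analyze_recording(rec, compute_bands = FALSE)
glance(ana)
#> # A tibble: 1 × 6
#>   base_time_s hr_bpm n_cycles t_qs_mean_s s1_s2_ratio mean_spo2
#> 1       0.833   72.1      245      0.0632        1.74      97.5

ana$bp[ana$bp$site == "wrist", c("site","side","rmps","sbp","dbp","mpap")]
#>   site  side  rmps    sbp   dbp  mpap
#> 1 wrist L     RMPS2  121.  79.4  94.1
#> 2 wrist R     RMPS2  121.  79.5  94.1

ana$pwv[, c("site_b","length_cm","t_ab_s","pwv_m_s")]
#>   site_b  length_cm t_ab_s pwv_m_s
#> 1 ankle_L     151.   0.314    4.79
#> 2 arm_L        35.2  0.174    2.02
#> ...
```

The heart rate (72.1 vs the configured 72 bpm), wrist pressures (121/79 vs
120/80 mmHg), MPAP (94.1 vs the wrist MAP of 93.3 mmHg) and SpO2 (98.0 vs
98 %) are all *recovered* from the simulated signals by the same code path
a real recording would take. `tidy(ana)` returns the long per-cycle
parameter table; `write_report(ana, "report/")` writes CSV tables plus a
JSON summary; `autoplot(schedule)` and `plot_recording(rec)` draw the
protocol and the signals.

A command-line interface is installed as `exec/cardiocuff` with
`protocol`, `simulate`, `analyze` and `calibrate` subcommands.

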