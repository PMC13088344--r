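# thermopulse

Signal processing for headband-style thermal-film biosensors that record,
at 100 Hz, a **hot-film** channel (arterial pulse pressure waveform +
perfusion baseline, via skin thermal conductance), a **cold-film** channel
(forehead skin temperature, linear in volts), and **3-axis head
acceleration**. The package is aimed at wearable-sensing researchers who
need the full computational stack between those raw channels and
physiological outputs:

1. **Motion-artifact model.** Skin deformation under head acceleration is a
   second-order spring–damper response to the gravity-subtracted
   acceleration magnitude `A = ‖(ax,ay,az)‖₂ − g`:

   `H(s) = K·ωₙ² / (s² + 2ζωₙ·s + ωₙ²)`

   discretized by the bilinear transform and run causally in real time.

2. **Per-wearer calibration by Bayesian optimization.** `(K, ζ, ωₙ)` are
   recognized on a 2-minute natural-running recording by minimizing the
   mean normalized Euclidean distance between time-normalized pulse beats,
   `f = Σᵢ∈S Σⱼ D_ij / (mN)` with `D_ij = ‖Pᵢ − Pⱼ‖₂ / n`, using a
   Gaussian-process surrogate (ARD Matérn 5/2) with Expected Improvement,
   8 space-filling initializations and up to 40 acquisitions.

3. **Vitals.** Artifact-subtracted, band-passed (0.5–5 Hz) pulse waveforms;
   heart rate from a 10 s sliding Hann/FFT window with quadratic peak
   interpolation; temperature from a linear cold-film calibration.

4. **Metabolic rate.** Log-magnitude STFT spectrograms (10 s window, 2 s
   STFT window, 1 s step → 101 bins × 9 frames per channel) feed a compact
   CNN (per-channel conv trunks → dense → softplus, trained with Adam,
   implemented in base R with analytic backprop) that outputs total
   metabolic rate in W/kg, evaluated by leave-one-out cross-validation with
   MAPE/AAE metrics.

5. **Simulator.** `synth_session()` generates multimodal streams with
   complete ground truth (clean pulse, artifact, baseline, heart rate,
   metabolic rate, temperature, beat onsets), so every stage above is
   testable end to end without recorded data.

## Worked example

```r
library(thermopulse)

truth <- artifact_params(K = 0.25, zeta = 0.7, omega_n = 2 * pi * 3)

# 2-minute natural-running calibration recording (simulated, with truth)
calib <- synth_session(calibration_protocol(), truth, seed = 2)
res <- calibrate_artifact(calib, cfg = list(seed = 2))
res
#> calibration_result: 48 evaluations, raw objective 0.033822 -> best 0.0046055
#> artifact_params: K = 0.2635, zeta = 0.7277, omega_n = 18.58 rad/s (2.96 Hz), fs = 100 Hz
```

The raw inter-beat distance 0.0338 drops to 0.0046 after filtering — the
recognized parameters (true values: K 0.25, ζ 0.7, ωₙ 18.85 rad/s) remove
the bulk of the motion artifact. Applying them to a monitoring session:

```r
session <- synth_session(default_protocol(300), truth, seed = 4)  # 30 min
vitals <- sliding_vitals(session, res$params)
tail(vitals[vitals$flags == "ok", ], 3)
#>         t   hr_bpm   temp_c pulse_amp flags
#> 1798 1798 69.90877 34.14778 0.4182495    ok
#> 1799 1799 69.95708 34.14323 0.4288331    ok
#> 1800 1800 69.98524 34.13934 0.4371288    ok
```

One record per second: heart rate in BPM (here the final-rest recovery
toward 70 BPM), smoothed forehead temperature in °C, and a robust pulse
amplitude. Records in the first 10 s are flagged `warmup`; flat spectra or
out-of-range values are flagged rather than silently reported.

Metabolic estimation on synthetic labelled sessions:

```r
ds <- synth_metabolic_dataset(n_sessions = 3, hop_s = 3, seed = 11)
loo_evaluate(ds, cfg = list(seed = 1))
#> eval_report: MAPE 8.95%, AAE 0.774 W/kg over 3 folds
```

## Command line

A thin CLI over the same functions ships in `inst/cli/thermopulse.R`:

```sh
Rscript inst/cli/thermopulse.R simulate  --seed 1 --out stream.csv
Rscript inst/cli/thermopulse.R calibrate --in stream.csv --seed 1 --out params.json
Rscript inst/cli/thermopulse.R vitals    --in stream.csv --params params.json --out vitals.csv
Rscript inst/cli/thermopulse.R pipeline  --config run.yaml
```

## Documentation

The methods vignette (`vignettes/thermopulse-methods.Rmd`) describes the
artifact model and its assumptions, the calibration objective and the
surrogate parameterization, what the simulator does and does not emulate,
the identifiability limits of the damping ratio, and every numerical
default.
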