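# imukam

Estimation of the external knee adduction moment (KAM) during walking from
**two inertial measurement units**: one on the lower back (L3) and one on the
lower lateral shank (LLS).

The KAM — the frontal-plane external moment about the knee during stance —
is the standard surrogate for medial tibiofemoral compartment load and is
central to gait analysis in knee osteoarthritis. Measuring it normally
requires an optical motion-capture laboratory with force plates. `imukam`
implements a minimal wearable alternative for movement scientists and
rehabilitation researchers who want a laboratory-free estimate of the KAM
waveform during the early phase of single-limb support, where a two-sensor
model is adequate.

## The model

With `BW = m·g` the body weight (N), `a_vert(t)` the globally vertical
specific force measured at L3 (g units, gravity-inclusive), `θ(t)` the
frontal-plane shank tilt angle (FP-STA, degrees) from the LLS sensor, and
`L` the shank length (m):

    GRF_VT(t) = BW · a_vert(t)            vertical ground reaction force
    lever(t)  = L · sin θ(t)              frontal-plane lever arm
    KAM(t)    = GRF_VT(t) · lever(t)      external knee adduction moment

Sensor orientation comes from quiet-standing calibration against gravity
followed by quaternion integration of the (12 Hz low-passed) gyroscope;
the vertical acceleration is low-passed at 10 Hz. Single-limb support (SLS)
is detected where the contralateral force-plate vertical GRF stays strictly
below 10 N, time-normalized to 101 points (0–100 %), and split into early
and late halves. Waveform agreement is scored with the coefficient of
multiple correlation (CMC), including its complex-radicand → `NaN` failure
mode and the conventional similarity bands (moderate/good/very good/
excellent). A seeded forward gait simulator provides ground-truth KAM, GRF
and shank-tilt trajectories plus the raw IMU and force-plate streams, so
the whole estimation chain can be validated without laboratory data.

## Worked example

```r
library(imukam)

cfg     <- gait_sim_config(cadence = 115, seed = 42)   # 115 steps/min, bimodal GRF
trial   <- simulate_trial(cfg)
subject <- subject_parameters(body_mass = 64, shank_length = 0.39, initial_sta = 3)

est <- run_kam_pipeline(trial$l3_imu, trial$lls_imu, subject, kam_config())
est
#> <kam_estimate> 1267 samples @ 200 Hz; KAM 9.53..26.73 N.m; peak GRF-VT 724.5 N

contra <- lowpass(trial$contra_grf, 10)
sls    <- split_early_late(detect_sls(contra, threshold = 10))
sls
#> <sls_interval> samples 258..300 (t = 2.570..2.990 s, 420 ms) below 10 N
#>   early: grid points 0..50, late: 50..100 (fraction 0.50)

imu_wave <- normalize_time(est$kam, sls, source = "imu")
ref_wave <- normalize_time(ground_truth_kam(trial), sls, source = "truth")
cmc_segment(imu_wave, ref_wave, "early")
#> <cmc_result> early = 0.9779 (excellent)
cmc_segment(imu_wave, ref_wave, "late")
#> <cmc_result> late = 0.9790 (excellent)
```

Reading the output: the estimated KAM peaks at ~27 N·m (≈ 0.42 N·m/kg for
this 64 kg subject, mid-range for healthy walking); the contralateral foot
is unloaded for 420 ms (≈ 40 % of the 1.04 s gait cycle at 115 steps/min);
and at the default sensor-noise levels (0.05 g, 1 deg/s) the estimated
waveform tracks the simulator's ground truth with CMC ≈ 0.98 ("excellent")
in both SLS halves. On real data the late half is the hard part — the shipped
reference table (`read_reference_cmc()`, summarized by
`summarize_cmc_table()`) records per-trial CMC values between IMU-estimated
and optically measured KAM from a three-participant pilot at the three
cadence conditions, where late-SLS trials are mostly `NaN` or below 0.65.

A command-line front end wrapping the same functions ships at
`system.file("cli/imukam.R", package = "imukam")` with subcommands
`simulate`, `estimate`, `events`, `cmc` and `validate`.

## Methods documentation

`vignettes/imu-kam-estimation.Rmd` documents the estimation model and its
assumptions, the orientation/filtering/event-detection design choices, the
CMC formulation, what the synthetic gait model does and does not emulate,
and the package's numerical conventions.
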