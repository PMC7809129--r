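# gaitipm

Stride-by-stride spatial gait parameters — stride length, stride
velocity and shank vertical displacement — from a single six-axis IMU
(accelerometer + gyroscope) mounted on each shank just above the
malleolus.

## Who this is for

Movement scientists and wearable-sensor engineers who want clinically
meaningful spatial gait parameters without an instrumented walkway or
motion-capture volume, and who need them *per stride* (stride-to-stride
variability is what matters for, e.g., Parkinsonian gait assessment),
not just as trial averages.

## The method

Double-integrating IMU acceleration diverges within seconds, so the
integral must be re-anchored every gait cycle. The classical anchor is
the zero-velocity update (ZUPT): declare the sensor stationary at
mid-stance. But a shank-mounted sensor is *not* stationary at
mid-stance — the shank pivots over the planted foot. This package
implements the refinement in which the mid-stance anchor is the
tangential velocity of an inverted pendulum rotating about the
stationary malleolus:

```
v̆ᴱ = ωᴱ × rᴱ,      ωᴱ = q ωˢ q*,      rᴱ = r · q (aˢ/‖aˢ‖) q*
```

with `r` the (known, fixed) sensor-to-malleolus distance. Per stride
segment `[ms(i), ms(i+1))`:

1. **Events**: mid-stance = maximum of the sagittal angular velocity
   between heel strike and toe off; heel strike / toe off located from
   peaks of ω_z inside windows set by the extrema of the integrated
   shank tilt (SMF / SMB).
2. **Orientation**: gravity alignment (shortest-arc quaternion) at each
   mid-stance, first-order gyro quaternion integration in between; no
   filtering.
3. **Velocity**: trapezoidal integration of the gravity-free lab-frame
   acceleration, started at v̆; residual drift modelled as a straight
   line fixed by the endpoint mismatches and subtracted, so the
   corrected velocity equals v̆ at both segment boundaries exactly.
4. **Trajectory & parameters**: integrate to position, rotate each
   stride into a frame with y = walking direction and x = vertical;
   stride length = forward displacement between mid-stances, vertical
   displacement = peak vertical excursion, velocity = length over the
   heel-strike interval.

A ZUPT baseline (`method = "zupt"`), a ground-truth walking simulator
and Bland–Altman agreement statistics are included so the method's
accuracy claims can be exercised end-to-end without human-subject data.

## Worked example

```r
library(gaitipm)

cfg   <- gait_sim_config(n_strides = 20, accel_sigma = 0.05,
                         gyro_sigma = 0.005, seed = 1)
trial <- simulate_walk(cfg)           # IMU streams + full ground truth
trial
#> <synthetic_trial> 20 strides of 1.20 m / 1.10 s, 2461 samples @ 100 Hz

recon <- reconstruct_gait(trial$rec, r = 0.05, method = "ipm")
recon
#> <gait_reconstruction> method=ipm, r=0.050 m, 20 strides
#>   stride length 1.203 +/- 0.002 m, velocity 1.094 m/s

head(recon$strides[, c("stride_index", "stride_length_m",
                       "vertical_disp_m", "duration_s", "velocity_mps")], 4)
#>   stride_index stride_length_m vertical_disp_m duration_s velocity_mps
#> 1            1        1.203271      0.07876328        1.1     1.093883
#> 2            2        1.201345      0.07877900        1.1     1.092132
#> 3            3        1.202388      0.07820120        1.1     1.093080
#> 4            4        1.200841      0.07802223        1.1     1.091673

# agreement with ground truth, stride-matched
pr <- pair_strides(recon$strides, trial$truth_params)
agreement(pr, "stride_length_m")
#> <agreement_stats> n=20 E=0.0035 (0.0019) |E|=0.0035 (0.0019) |E|%=0.29 (0.16)
#>   r=-0.271  bias=0.0035  LOA=[-0.0003, 0.0072]
```

The commanded stride length is 1.2 m: with realistic sensor noise the
pendulum-anchored pipeline recovers it with a +3.5 mm bias (~0.3%
relative error). The comparison harness shows why the pendulum anchor
matters — the ZUPT baseline, which wrongly assumes a still shank,
underestimates stride length by ~16 mm with wider limits of agreement,
while the vertical displacement (tiny mid-stance vertical velocity) is
indifferent to the anchor:

```r
compare_methods(trial)$summary[, c("label", "mean_error", "sd_error")]
#>                  label   mean_error     sd_error
#> 1  ipm stride_length_m  0.003488288 0.0019158091
#> 2     ipm velocity_mps  0.003171171 0.0017416447
#> 3  ipm vertical_disp_m -0.001005767 0.0004682091
#> 4 zupt stride_length_m -0.015975472 0.0020184057
#> 5    zupt velocity_mps -0.014523156 0.0018349143
#> 6 zupt vertical_disp_m -0.001006484 0.0004674837
```

Real recordings enter as plain CSV (`t,ax,ay,az,gx,gy,gz`, gyro in
deg/s by default) via `read_imu_csv()`; results leave via
`write_stride_csv()` / `write_trajectory_csv()`. Mind `flip_z`: the
sagittal-rate polarity depends on which shank (mounting side) the
sensor is on — see the methods vignette.

## Command line

```sh
Rscript inst/cli/gaitipm simulate    --n-strides 20 --seed 1 --out-prefix sim
Rscript inst/cli/gaitipm reconstruct --imu sim_imu.csv --r 0.05 --out strides.csv
Rscript inst/cli/gaitipm validate    --est strides.csv --ref sim_truth_strides.csv
Rscript inst/cli/gaitipm compare     --n-strides 50 --seed 7 --out compare.csv
```

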