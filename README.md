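# magstep

Step detection and counting from a **single wrist-worn magnetometer axis**.

Walking swings the arm like a pendulum, out of phase with the legs. A
magnetometer strapped to the wrist therefore sees the Earth's field component
along its Z axis rise and fall once per stride: the field peaks at the swing
turnarounds and dips when the arm hangs perpendicular to the ground. Every
local extremum of the low-pass filtered signal marks one step — no
accelerometer or gyroscope needed. `magstep` implements the complete
real-time detection pipeline for such traces, plus a seeded simulator so the
method can be studied and validated without hardware.

The package is for signal-processing and wearable/HAR researchers who want a
reference desk implementation of magnetometer-only step counting, and for
anyone who needs a testable, fully scripted version of the algorithm.

## The method

For walking speed $v$ (m/s) and stride length $L$ (m), the stride frequency
is

$$f = \frac{v}{L},$$

about 0.85–1.39 Hz over normal speeds (4–6.5 km/h) at $L = 1.3$ m. The
pipeline processes the 40 Hz Z-axis stream through five stages:

1. **Block buffering** — a circular buffer split into three subblocks
   (*historical* / *current* / *pending*); full pending blocks rotate in,
   keeping memory at exactly three blocks while preserving history for the
   filter warm-up.
2. **FIR low-pass** — an order-47 Hamming-windowed-sinc filter with 2 Hz
   cutoff and exactly unit DC gain, applied block-wise with historical
   warm-up so block filtering is *bit-identical* to filtering the whole
   stream in one pass (> 60 dB attenuation at 4 Hz).
3. **Extrema detection** — strict local peaks and valleys of the filtered
   signal, detected incrementally across block boundaries.
4. **Fake-step rejection** — each extremum complementary to the last
   accepted one must differ from it by at least 0.5 µT (twice the sensor
   noise level); a rejected extremum and the one following it are skipped
   and the test repeats with the next complementary extremum.
5. **Motionless rejection** — blocks whose mean absolute deviation falls
   below a calibrated threshold (default 0.6 µT = 3× the noise-only
   deviation) are labelled standing and contribute no steps.

Every surviving extremum is one step; detected step counts `d` are scored
against reference counts `t` as `100 · min(d,t) / max(d,t)` percent.

## Worked example

```r
library(magstep)

cfg <- gait_sim_config(walk_speed_kmh = 5, seed = 1)   # 60 s walk, 40 Hz
tr  <- simulate_walk(cfg)
tr
#> Field trace: 2400 samples @ 40 Hz (60.00 s), units uT
#>   ground truth: 128 steps, 100% of samples walking

report <- detect_steps(tr)
summary(report)
#> Steps detected: 128
#> Raw extrema: 128 (peak/valley alternation)
#> Rejected as fake steps (< 0.5 uT gap): 0
#> Rejected in motionless blocks: 0 (of 31 blocks, 31 moving)
#> Median step interval: 0.475 s (cadence 2.11 steps/s)
#> First block warm-up used replicated-sample history

accuracy(report$step_count, length(tr$truth$step_times))
#> [1] 100
```

At 5 km/h the stride frequency is 1.068 Hz, i.e. ~2.14 steps/s; the 128
detected steps over 60 s match the simulator's ground truth exactly, and the
measured cadence (2.11 steps/s) recovers it. `run_benchmark()` scales this
to lists of scenarios (speeds, noise, ambient disturbance pulses) and
reports worst-trial accuracies; `plot(report)` overlays detected steps on
the filtered trace.

A command-line front end is installed at `inst/cli/magstep`
(`magstep simulate | detect | evaluate`) for working with CSV traces.

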