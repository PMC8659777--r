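---
title: "Magnetometer-only step detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetometer-only step detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magstep)
```

## The physical model

During walking the arm swings like a pendulum, out of phase with the legs:
the left arm reaches its forward turnaround as the right leg plants. A
magnetometer on the wrist is carried through the Earth's magnetic field by
this swing, so the field component along the sensor's Z axis (perpendicular
to the direction of travel, parallel to the ground) is modulated
periodically. The field is extremal at the swing turnarounds, and because
arm and leg are phase-locked, each turnaround coincides with a step.

`magstep` models the Z-axis trace during walking as

$$B(t) = B_0 + \Delta B \,\sin(2\pi f t + \varphi) + \varepsilon(t),$$

with baseline $B_0$ (an Earth-field component), swing amplitude $\Delta B$,
stride frequency $f = v/L$ (speed $v$ in m/s over stride length $L$), and
white Gaussian sensor noise $\varepsilon$. One sinusoid period is one
stride; its peak and valley are the two steps of that stride, so the step
rate is $2f$ — about 2.1 steps/s at 5 km/h, which is normal cadence.
Standing intervals hold $B(t) = B_0 + \varepsilon(t)$.

A geometric argument can also be made that *both* swing endpoints raise the
field while the perpendicular position lowers it, which would put the
dominant component at $2f$ instead of $f$. The two pictures are not
mutually exclusive (real traces contain both components); the simulator
exposes an optional second-harmonic amplitude (`second_harmonic_uT`), but
all validation uses the stride-frequency model, which is the one consistent
with a one-extremum-per-step reading and normal cadence.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sampling_hz` | 40 | Hz | sensor configuration; 20 Hz Nyquist comfortably above the gait band |
| `noise_sigma_uT` | 0.25 | µT | sensor datasheet noise level |
| `sensitivity_uT_per_lsb` | 0.1 | µT | sensor resolution; ±1000 µT in 16 bits |
| filter `order` | 47 | – | lowest order giving stable stopband behaviour (orders ≥ 45 filter well); odd order keeps a half-sample-symmetric linear phase |
| filter `cutoff_hz` | 2 | Hz | above the 0.85–1.39 Hz walking band for all normal speeds, below the first interfering harmonics |
| `block_size` | 80 | samples | 2 s at 40 Hz: at least one full gait cycle per block and strictly more than the filter order, so one historical block suffices as warm-up |
| `fake_step_threshold_uT` | 0.5 | µT | twice the sensor noise; the average adjacent-extrema gap observed in disturbance-free recordings. (Equivalently 5 sensor counts at 0.1 µT/LSB; the threshold is exposed in µT, the physical unit.) |
| `motionless_threshold_uT` | 0.6 | µT | $3\sigma\sqrt{2/\pi}$ at the datasheet noise $\sigma = 0.25$ µT: three times the mean absolute deviation of noise-only blocks. `calibrate_motionless_threshold()` recomputes it from measured standing traces (mean MAD × safety factor, default 3) |
| `stride_length_m` | 1.3 | m | average adult stride |
| `swing_amplitude_uT` | 5 | µT | a typical wrist-swing modulation depth; an order of magnitude above the fake-step threshold, as any detectable walk must be |
| `field_mean_uT` | 40 | µT | mid-latitude Earth-field component; only the *variation* matters, since the filter has unit DC gain |

## What the simulator emulates — and what it does not

The generator reproduces the features the detector actually exploits: a
narrowband oscillation at the stride frequency during walking, a flat
baseline while standing, datasheet-level white noise, quantization to
0.1 µT counts on request, and ambient disturbances as additive
Gaussian-shaped pulses of configurable amplitude and width. Ground truth is
exact by construction (the analytic extrema times of the noiseless
sinusoid), so detected counts can be scored without hand labelling.

It does **not** emulate: cadence jitter or stride-to-stride amplitude
variation; gradual acceleration (walking↔standing transitions are
instantaneous, a deliberate simplification — a ramped transition is a
config extension left off by default); 1/f sensor noise; gesticulation or
involuntary hand movement; hard/soft-iron effects or heading changes; or
the broadband field environment of a real urban walk. Passing tests
therefore show that the pipeline recovers steps from the *idealized* signal
mechanism at realistic noise levels — they support the algorithm's internal
correctness and its noise margins, not a field-accuracy claim for human
subjects, which only wearable trials can establish.

Two artefacts of the idealization are worth knowing. First, an
instantaneous walk→stand transition introduces a field step whose filtered
image can contribute about one extra extremum per transition. Second, a
gait turnaround falling within half a sampling interval of the end of a
recording is genuinely ambiguous and is typically not recovered (a
systematic undercount of at most one step per trace; at 60 s this bounds
accuracy below by ~99%).

## Numerical and streaming design choices

**Filter design.** Coefficients are the closed-form Hamming-windowed sinc,
normalized so they sum to exactly 1 (unit DC gain): the Earth-field
baseline must pass through unchanged for the motionless detector's
block-mean deviations to be meaningful. Library design routines often
scale the response to 1 at mid-passband instead; the test suite uses one
(`signal::fir1`, renormalized) as an independent reference and checks
agreement of $|H(f)|$ to within 0.02 across the band, plus the properties
that matter: $|H(0)| = 1$ exactly, $>40$ dB attenuation at 4 Hz.

**Block filtering and warm-up.** Each current block is filtered by causal
convolution warmed up on the last `order` samples of the historical block,
making block-wise output bit-identical to one continuous pass (asserted to
$10^{-12}$). The very first block has no history; it is warmed up on a
replicate of its own first sample. A zero warm-up would inject a
~`field_mean`-sized step whose response ripple produces spurious extrema at
the start of every trace; replicating the first sample introduces no
discontinuity at all. The report flags the warm-up block.

**Group delay and end-of-trace flush.** The linear-phase filter delays
everything by `order/2` = 23.5 samples; reported step times subtract this
constant. At end of stream the partial pending block is processed and
`ceil(order/2)` held-last-value samples are fed through, so the delayed
images of the final ~0.6 s are not lost; extrema are kept only if their
delay-corrected time lies within the recorded duration $[0, n/f_s]$.

**Extrema and ties.** Detection is strict-neighbour comparison; a plateau
(run of equal values) flanked by lower (higher) values on both sides is one
peak (valley) at the run's first index. The streaming detector operates on
run-length state, so its output is identical to whole-trace detection no
matter where block boundaries fall — including plateaus spanning blocks.
Ties are measure-zero on filtered floating-point data but the rule is
total.

**Threshold test conventions.** The gap comparison accepts at
`gap >= threshold` (so threshold 0 is the identity), always compares the
candidate against the *last accepted* extremum, and on rejection skips
exactly the candidate and the one extremum following it. Input that fails
to alternate (impossible for strict extrema, possible for user-supplied
lists) is first normalized by keeping the most extreme member of each
same-kind run, with a warning. The first extremum of a trace is accepted
unconditionally — it has no predecessor to compare against.

**Stage order.** The motionless test runs *after* the amplitude threshold,
as the final classification: the amplitude test is local and cheap, while
the motionless test summarizes whole blocks and is the authority on
standing phases.

**Threshold monotonicity is an operating-regime property.** On gait
signals — where extrema gaps are bimodal (≈10 µT step swings vs. sub-0.3 µT
noise wiggles) — raising the fake-step threshold can only remove steps, and
the suite asserts this over thresholds spanning 0–12 µT. It is *not* a
theorem for the one-pass greedy rule on arbitrary sequences: when every gap
is comparable to the threshold, rejecting a candidate (which also skips the
following extremum) can expose a deeper complementary extremum and unblock
later acceptances, so the accepted count can locally *increase* with the
threshold. A five-extremum counterexample is frozen in the test suite as a
documented limitation of the greedy rule.

**Accuracy metric.** Reported accuracy is
$100\cdot\min(d,t)/\max(d,t)$ to one decimal — symmetric in over- and
under-counting and scale-invariant. This is the formula that reproduces the
reference wrist-trial scores for all internally consistent rows (e.g.
216 detected / 211 counted → 97.7; one reference row, 220/207 → 93.7,
is inconsistent with every symmetric ratio formula and is treated as a
typo, 94.1). Signed error (`detected − true`) is reported alongside, since
the ratio deliberately discards direction.

## Problem sizes

Validation runs use 30–60 s traces at 40 Hz (1 200–2 400 samples), nine
benchmark walks spanning 4–6.5 km/h with three seeds per speed, and
1 000-case randomized property checks for the extrema detector and
threshold rule; these sizes give stable statistics while the whole suite
runs in well under a minute.

## Known limitations

* A single 0.5 µT threshold cannot separate steps from ambient pulses of
  comparable amplitude and period; strong disturbances (≫ the threshold,
  several per minute) degrade accuracy, and the benchmark shows the
  degradation is monotone in disturbance amplitude.
* Gesticulation, hand tremor, and non-walking arm motion are out of scope;
  the motionless detector only distinguishes standing from walking.
* Calibration of the motionless threshold assumes standing noise comparable
  to the datasheet level; strongly heteroscedastic environments need
  per-session recalibration via `calibrate_motionless_threshold()`.
* The simulator's fixed cadence makes ground truth exact but optimistic;
  real stride-interval variability blurs the spectral peak and will lower
  accuracy before it breaks detection.
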