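---
title: "Assessing runners' motor coordination from multichannel EMG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing runners' motor coordination from multichannel EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runcoord)
```

## The problem

Well-trained runners repeat their movement pattern with remarkable
consistency, and they load their left and right legs nearly symmetrically.
Both properties are observable in surface electromyography (sEMG): the
electrical activity of a muscle, recorded with skin electrodes, has an
amplitude envelope that tracks muscular effort. `runcoord` quantifies two
aspects of coordination from synchronous multichannel sEMG and shank-mounted
gyroscope recordings during treadmill running:

* **K_EMG** — the integral amplitude and spatiotemporal stability
  coefficient of muscle EMG profiles: how repeatable, cycle after cycle,
  are the energy and timing of each muscle's effort in each phase of the
  running cycle. 100% means perfect repetition.
* **α (alpha)** — the symmetry coefficient of left/right muscular effort:
  the mean normalized cross-correlation, at the antiphase lag of half a
  cycle, between the EMG energy envelopes of the same muscle on opposite
  legs. 100% means mirror-identical effort profiles.

Seven muscles per leg are analyzed by default: rectus femoris, vastus
lateralis, vastus medialis, tibialis anterior, biceps femoris, and the
medial and lateral gastrocnemius heads.

## The processing pipeline

### 1. Cycle segmentation from the shank gyroscope

The angular velocity of the shank about the mediolateral axis has one
dominant positive peak per running cycle, at mid-swing. Segmentation
proceeds as:

1. a provisional movement period from the highest local maximum of the
   biased autocorrelation function within 0.4–1.6 s (cadences of roughly
   37–150 cycles/min per leg);
2. moving-average smoothing, `y[i] = mean(x[i..i+N-1])`, delay-compensated
   by `(N-1)/2` samples. The window is tied to the period:
   `N = round(period/20)`, clamped to `[3, period/4]` samples and forced
   odd. No formula for N was available, so the choice is ours: about 5% of
   the period suppresses intra-cycle noise without eroding the single swing
   peak. The period is then re-estimated once on the smoothed signal,
   resolving the circular dependency between the two steps;
3. swing peaks: local maxima with prominence ≥ 30% of the signal range,
   separated by at least 60% of the period (the higher of two close
   candidates wins);
4. heel strike = the global minimum in the half inter-peak interval after
   each swing peak; toe-off = the global minimum in the half interval
   before the next peak. Flat minima resolve to the earliest sample. This
   minima rule is a documented design choice — the flanking troughs of the
   shank angular velocity are the standard inertial-sensor correlates of
   ground contact — not something the underlying method prescribes.

Cycles are anchored at heel strikes: cycle *i* runs from heel strike *i* to
heel strike *i+1*, containing a stance phase `[heel strike, toe-off)` and a
swing phase `[toe-off, next heel strike)`. Two phases per cycle is the
default (`F = 2`). Because the last detected swing peak has no following
heel strike, the final cycle's swing is truncated at that peak (mid-swing);
*n* detected peaks therefore always yield *n − 1* usable cycles. The
partial segment before the first heel strike is dropped. Segmentation is
invariant under time shifts and positive amplitude scaling of the gyro
signal.

### 2. EMG preprocessing

Each EMG channel passes through a 4th-order Butterworth high-pass at 10 Hz
(motion artifacts) and a two-pole notch at the 50 Hz mains frequency
(Q = 30; configurable to 60 Hz). Orders and Q are unspecified upstream;
these are standard sEMG practice. Filters are applied zero-phase
(forward–backward over an odd-symmetric extension, with steady-state
initial conditions) so that burst timing stays aligned with the gyro-derived
events — a causal filter would delay EMG bursts relative to the cycle
boundaries. The padding length adapts to the slowest filter pole (decay to
1e-7), because the high-Q notch rings for hundreds of samples; a fixed
short pad would leak edge transients into short recordings. Filtering is
linear to machine precision and moves an isolated burst's energy centroid
by less than one sample.

### 3. Energy envelopes and the symmetry coefficient

The instantaneous energy is the pointwise square of the preprocessed EMG
(mV²). The envelope is a natural cubic spline through knots placed at the
maximum of each 25 ms block of the 50 ms moving-averaged energy, evaluated
on a time-normalized grid of 200 points per cycle and clamped at zero.
Three choices here deserve justification:

* **Block maxima instead of raw local maxima.** At 2000 Hz the squared EMG
  has a local maximum every few samples; a spline through all of them
  reproduces the stochastic interference pattern of the signal rather than
  the effort profile, and a spline through only the tallest, widely-spaced
  peaks oscillates wildly between them. Block maxima over ~25 ms give a
  dense, stable knot set — the classic low-passed "linear envelope" in
  spline form. For an already-smooth energy signal the knots simply follow
  the signal.
* **Common cycle grid for both legs.** Each leg's envelope is sampled on
  the left leg's cycle partition. The two signals are recorded
  synchronously and opposite limbs move in antiphase, so on this common
  grid the right leg's bursts genuinely appear half a cycle displaced —
  which is exactly what the half-cycle lag of the cross-correlation then
  compensates. (Sampling each leg on its own heel-strike-anchored
  partition would already phase-align the envelopes and the antiphase lag
  would wrongly anti-align them.) The right partition is still used to
  verify that the two legs' cadences agree within 5%.
* **Normalization and clamping.** A raw lagged product sum has the units of
  mV⁴ and cannot be a percentage; the implementation subtracts means and
  divides by both standard deviations, i.e. a Pearson correlation at the
  half-cycle lag, times 100. Negative correlations are clamped to zero:
  anti-symmetric effort is "0% symmetric". The half-cycle shift is a
  rotation within each cycle's 200-point block, which makes the ±half-cycle
  directions coincide, so swapping the legs changes nothing.

α is the unweighted mean of the per-muscle coefficients. It is invariant
under any positive rescaling of the EMG amplitudes — which is also why the
synthetic generator's asymmetry control must distort burst *shape*, not
just gain (below).

### 4. Localization windows and the stability coefficient

For each muscle, phase and cycle, the *effort localization window* is the
shortest contiguous interval inside the phase containing at least 90% of
the phase's EMG energy, earliest on ties. "Shortest with ≥ 90%, earliest"
is the unique minimal-support reading of "the interval of maximum energy
concentration", and it is verifiable against an exhaustive search — the
test suite does exactly that. The search is O(n log n): a binary search on
the window length (feasibility is monotone because energies are
non-negative) followed by a vectorized scan for the earliest start.

Across the `N = 20` analyzed cycles of each phase, two per-cycle quantities
are collected: the window energy `E` and the duration ratio
`dt = T_window / t_phase ∈ [0, 1]`. Their means and **population** standard
deviations (denominator N) give the stability coefficients

    k = (1 − sd / mean) × 100,  clamped below at 0,

and K_EMG is the flat average of `(k_E + k_dt)/2` over all muscle × phase
pairs. K_EMG = 100 exactly if and only if every spread is zero. A silent
muscle phase (zero energy) is treated as missing data, not instability: the
pair is excluded from the average and counted in the report. Left- and
right-leg analyses are pooled by averaging the two K_EMG values
(`pool_sides = "average"`; either single leg can be selected instead).

Two standard-deviation conventions coexist deliberately: within-athlete
cycle-to-cycle spreads use the population form, while across-athlete study
summaries (`summarise_values()`) use the sample form (n − 1), which is what
reproduces the published group tables bundled with the package
(`reference_kemg_table()`, `reference_alpha_table()`).

## The synthetic-data generator

No recordings are deposited with the source study, so the package ships a
simulator (`simulate_session()`) whose defaults state a plausible world for
low-intensity treadmill running at 10 km/h:

| parameter | default | meaning |
|---|---|---|
| `cadence_hz` | 1.25 | cycles/s per leg (period 0.8 s) |
| `stance_fraction` | 0.40 | fraction of the cycle on the ground |
| `duration_s` | 30 | session length (≥ 25 complete cycles per leg) |
| `emg_rate_hz` / `gyro_rate_hz` | 2000 / 148 | sampling rates |
| `baseline_mv` | 0.05 | EMG activation floor (muscle tone + noise) |
| `sigma_amp` | 0.10 | SD of per-cycle multiplicative amplitude jitter |
| `sigma_time` | 0.02 | SD of burst-centre jitter (fraction of phase) |
| `asymmetry_rho` | 0 | inter-limb asymmetry, see below |
| `hum_amplitude_mv` / `dc_offset_mv` | 0 / 0 | mains hum and DC artifacts |

The gyro waveform has a +300 deg/s Gaussian peak at mid-swing and troughs
at heel strike (−150) and toe-off (−100), plus white noise (SD 8 deg/s);
the right leg is delayed by half a cycle. EMG is band-limited (20–450 Hz)
Gaussian noise modulated by per-cycle Gaussian activation bursts placed in
normalized phase time (knee extensors in early-mid stance, tibialis
anterior at heel strike, gastrocnemii at push-off, biceps femoris in late
swing), on top of the baseline floor. The carrier's energy is normalized
within every stance and swing segment so that the *configured jitter is the
only source of cycle-to-cycle variability in the phase energies* the
stability pipeline measures.

Two honest caveats about what a green test establishes:

* Even at zero configured jitter, K_EMG is ~92–95, not ~100: the
  *duration* of the shortest-90%-energy window still varies because each
  cycle's energy profile is a fresh noise realization. Only bit-identical
  cycles give exactly 100 (and the tests verify that separately). A real
  athlete's "perfectly repeatable" running would face the same floor.
* A normalized correlation cannot see a pure gain difference between legs,
  so `asymmetry_rho` skews the right leg's burst timing (centres shifted
  by `0.2·rho` of the phase) and width (×(1+rho)) *in addition to* scaling
  its amplitude by (1−rho). Without the shape component, no
  correlation-based symmetry index could respond to rho at all.

The generator does not model crosstalk between channels, electrode lift or
motion artifacts beyond DC/hum, motor-unit physiology, or fatigue drift —
green tests say the algorithms recover what the generator put in, not that
the indices are clinically validated.

## Numerical choices and degenerate inputs

* Nearest-sample projection of event times onto other channels' grids, ties
  toward the earlier sample; error ≤ half a sample period.
* `align_timebases()` trims channels to their common interval and treats
  starts/ends within one sample of the coarsest channel as already aligned
  (sub-sample offsets are unobservable at that rate), which makes it
  idempotent.
* Constant gyro signals raise a periodicity error; aperiodic signals (no
  autocorrelation maximum in range) likewise.
* A zero-variance envelope makes the symmetry coefficient undefined
  (error), as does a silent phase for the stability coefficients
  (excluded, logged).
* Localization-window ties (several intervals with identical energy) go to
  the earliest start; feasibility comparisons carry a 1e-12 relative
  tolerance against accumulated floating-point error.
* Display rounding of study summaries is half-away-from-zero to 2 decimals,
  matching the published tables; unrounded values are retained.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(speed_kmh = 10, seed = 1)
ses <- simulate_session(cfg)
report <- analyze_recording(ses$recording, seed = 1L)
report
#> <coordination_report> 'synthetic-10kmh-seed1' @ 10 km/h
#>   K_EMG = 90.97 %
#>   alpha = 90.91 %
```

With the default jitter (`sigma_amp = 0.1`), K_EMG lands near 91% and α
near 91% — inside the 80–95% band reported for elite runners. Raising
`sigma_amp` to 0.2–0.3 drops K_EMG to the low 80s; raising `asymmetry_rho`
to 0.4–0.5 pulls α to the 70s. Both responses are strictly monotone, which
is what the acceptance tests check.

## Limitations

* Heel-strike/toe-off detection from a single gyro axis is approximate
  (±2–3 samples at 148 Hz against the generator's ground truth); kinematic
  or force-plate events would be better anchors where available.
* The method assumes steady-state treadmill running with a shared cadence
  across legs; overground, sprinting or walking gait would need different
  peak/trough heuristics.
* The half-cycle antiphase lag is fixed, not fitted; a runner with a
  genuinely shifted inter-limb phase would read as asymmetric.
* With two phases per cycle, K_EMG mixes burst-carrying and quiet phases;
  the per-phase table in the report allows finer inspection.
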