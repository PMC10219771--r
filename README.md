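# runcoord

Motor-coordination indices for runners from synchronous multichannel surface
EMG and shank-mounted gyroscope recordings.

Well-trained runners repeat their movement pattern consistently and load
both legs almost symmetrically. `runcoord` turns those two properties into
numbers, for sports scientists and biomechanists working with wearable
EMG+IMU systems:

* **K_EMG** — the integral amplitude and spatiotemporal stability
  coefficient of muscle EMG profiles. For each muscle *m*, phase *f* and
  cycle *i*, the effort localization window is the shortest interval with at
  least 90% of the phase energy, `E_{f,T} ≥ 0.9 E_f`. Over N = 20 cycles the
  window energy `E` and the duration ratio `Δt = T/t_phase` give stability
  coefficients `k = (1 − σ/mean)·100` (population σ, clamped at 0), and

      K_EMG = (1 / (F·M)) Σ_m Σ_f (k_E + k_Δt) / 2   ∈ [0, 100] %

* **α** — the left/right muscular-effort symmetry coefficient: per muscle,
  the normalized cross-correlation of the two legs' EMG energy envelopes at
  the antiphase lag of half a cycle (opposite limbs move in antiphase),
  clamped to [0, 1] and averaged over muscles, in percent.

The pipeline: running cycles segmented from the tibialis-anterior gyro
signal (moving-average smoothing, autocorrelation period, swing-peak and
heel-strike/toe-off detection) → EMG preprocessing (4th-order 10 Hz
Butterworth high-pass + 50 Hz notch, zero-phase) → spline energy envelopes →
the two indices. A synthetic-session generator with full ground truth makes
everything testable without recorded data. See the methods vignette
(`vignettes/coordination-indices.Rmd`) for every design decision.

## Worked example

```r
library(runcoord)

cfg <- simulation_config(speed_kmh = 10, seed = 1)   # 30 s, cadence 1.25 Hz
ses <- simulate_session(cfg)                          # 14 EMG + 2 gyro channels
report <- analyze_recording(ses$recording, seed = 1L)
report
#> <coordination_report> 'synthetic-10kmh-seed1' @ 10 km/h
#>   K_EMG = 90.97 %
#>   alpha = 90.91 %
```

K_EMG ≈ 91% says the per-cycle EMG energies and window timings vary by
under ~10% around their means — the generator's default 10% amplitude
jitter, recovered. α ≈ 91% says the two legs' effort envelopes are nearly
mirror images at the half-cycle lag (the generator was configured
symmetric). Published values for elite runners sit around 83–85% (K_EMG)
and 64–96% (α per athlete); the bundled per-athlete reference tables
reproduce those summaries:

```r
summarise_values(reference_kemg_table()$stage3_10kmh)[c("mean_display", "sd_display")]
#> $mean_display
#> [1] 84.63
#> $sd_display
#> [1] 1.76
```

Recordings round-trip through a wide CSV plus JSON descriptor
(`write_recording()` / `read_recording()`), and a CLI covers the whole
workflow:

```sh
Rscript inst/cli/runcoord simulate --duration 30 --seed 1 --out session
Rscript inst/cli/runcoord analyze --descriptor session.descriptor.json --out report.json
Rscript inst/cli/runcoord summarize --reports reports/ --out summary.csv
```

## Layout

- `R/` — signal containers and I/O, gait segmentation, EMG filters,
  symmetry, stability, simulator, reports, CLI
- `src/` — direct-form-II-transposed IIR filter kernel (Rcpp)
- `inst/extdata/` — published per-athlete reference tables (CSV), report
  JSON schema
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (naive sums, exhaustive window search, analytic filter responses)
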