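# Synthetic running sessions with known ground truth.
#
# The generator emulates steady treadmill running: antiphase left/right limbs,
# a shank angular-velocity waveform with one dominant positive peak at
# mid-swing and troughs at heel strike and toe-off, and EMG as band-limited
# (20-450 Hz) Gaussian noise amplitude-modulated by phase-locked activation
# bursts. Cycle-to-cycle variability enters only through the configured
# controls: multiplicative amplitude jitter (sigma_amp), burst-center timing
# jitter (sigma_time) and inter-limb asymmetry (asymmetry_rho). The noise
# carrier is energy-normalized per cycle so that, at zero jitter, per-cycle
# burst energies are deterministic and the stability pipeline sees
# near-perfect repetition.
#
# A normalized-correlation symmetry index is blind to a pure gain difference
# between legs, so asymmetry_rho additionally skews the right leg's burst
# timing (center shifted by 0.2 * rho of the phase) and width (scaled by
# 1 + rho) besides scaling its amplitude by 1 - rho.

#' Default per-muscle activation templates
#'
#' Bursts are Gaussian in normalized phase time: the knee extensors fire in
#' early-to-mid stance, tibialis anterior around heel strike, the
#' gastrocnemii in late stance (push-off) and biceps femoris in late swing.
#' `center_frac` and `width_frac` (the Gaussian SD) are fractions of the
#' phase duration; `center +/- 2 * width` must stay inside the phase.
#'
#' @return Named list of templates
#'   `list(phase, center_frac, width_frac, amplitude_mv)`.
#' @export
default_muscle_templates <- function() {
  list(
    rectus_femoris         = list(phase = "stance", center_frac = 0.35,
                                  width_frac = 0.12, amplitude_mv = 0.90),
    vastus_lateralis       = list(phase = "stance", center_frac = 0.30,
                                  width_frac = 0.12, amplitude_mv = 1.00),
    vastus_medialis        = list(phase = "stance", center_frac = 0.32,
                                  width_frac = 0.12, amplitude_mv = 0.95),
    tibialis_anterior      = list(phase = "stance", center_frac = 0.15,
                                  width_frac = 0.07, amplitude_mv = 0.70),
    biceps_femoris         = list(phase = "swing",  center_frac = 0.75,
                                  width_frac = 0.12, amplitude_mv = 0.80),
    gastrocnemius_medialis = list(phase = "stance", center_frac = 0.70,
                                  width_frac = 0.12, amplitude_mv = 1.10),
    gastrocnemius_lateralis = list(phase = "stance", center_frac = 0.72,
                                   width_frac = 0.12, amplitude_mv = 1.00))
}

#' Simulation configuration
#'
#' Defaults emulate low-intensity treadmill running at 10 km/h: cadence
#' 1.25 cycles/s per leg, 40% stance, 30 s duration, EMG at 2000 Hz and
#' gyro at 148 Hz.
#'
#' @param speed_kmh Nominal treadmill speed (label only).
#' @param cadence_hz Cycles per second per leg.
#' @param duration_s Session duration, seconds.
#' @param stance_fraction Fraction of the cycle spent in stance, in (0, 1).
#' @param emg_rate_hz,gyro_rate_hz Sampling rates, Hz.
#' @param muscles Activation templates, see [default_muscle_templates()].
#' @param baseline_mv Baseline activation floor (mV): low-level muscle tone
#'   plus instrumentation noise, present in every phase, as in real surface
#'   EMG. Without it, off-phase energy would be burst-tail leakage only.
#' @param sigma_amp SD of the multiplicative per-cycle amplitude jitter.
#' @param sigma_time SD of the per-cycle burst-center jitter, as a fraction
#'   of the phase duration.
#' @param asymmetry_rho Inter-limb asymmetry in `[0, 1]` (see file header).
#' @param hum_amplitude_mv Amplitude of an additive 50 Hz mains hum.
#' @param dc_offset_mv Additive DC offset on EMG channels.
#' @param gyro_noise_sd Additive Gaussian noise SD on gyro channels, deg/s.
#' @param seed Integer RNG seed; identical configs give identical sessions.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(speed_kmh = 10, cadence_hz = 1.25,
                              duration_s = 30, stance_fraction = 0.40,
                              emg_rate_hz = 2000, gyro_rate_hz = 148,
                              muscles = default_muscle_templates(),
                              baseline_mv = 0.05,
                              sigma_amp = 0.1, sigma_time = 0.02,
                              asymmetry_rho = 0, hum_amplitude_mv = 0,
                              dc_offset_mv = 0, gyro_noise_sd = 8,
                              seed = 1L) {
  stopifnot(cadence_hz > 0, duration_s > 0, emg_rate_hz > 0,
            gyro_rate_hz > 0, stance_fraction > 0, stance_fraction < 1,
            sigma_amp >= 0, sigma_time >= 0,
            asymmetry_rho >= 0, asymmetry_rho <= 1)
  for (m in names(muscles)) {
    tpl <- muscles[[m]]
    if (tpl$center_frac - 2 * tpl$width_frac < 0 ||
        tpl$center_frac + 2 * tpl$width_frac > 1)
      stop("template for ", m, " does not lie inside its phase",
           call. = FALSE)
  }
  structure(list(speed_kmh = speed_kmh, cadence_hz = cadence_hz,
                 duration_s = duration_s, stance_fraction = stance_fraction,
                 emg_rate_hz = emg_rate_hz, gyro_rate_hz = gyro_rate_hz,
                 muscles = muscles, baseline_mv = baseline_mv,
                 sigma_amp = sigma_amp,
                 sigma_time = sigma_time, asymmetry_rho = asymmetry_rho,
                 hum_amplitude_mv = hum_amplitude_mv,
                 dc_offset_mv = dc_offset_mv, gyro_noise_sd = gyro_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic sub-seed per (seed, tag) pair, kept below 2^31
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.numeric(seed) * 10007 + h) %% (2^31 - 1)
}

#' Ground-truth events and realized burst parameters for a session
#'
#' Draws everything stochastic about the session layout up front (event
#' times are deterministic; per-cycle amplitudes and burst centers are
#' drawn here), so that [simulate_gyro()] and [simulate_emg()] are pure
#' functions of (config, ground truth).
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `ground_truth` with per-side event times
#'   (`cycle_starts` = heel strikes, `toe_offs`, `swing_peaks`) and, per
#'   side and muscle, realized per-cycle `amplitude_mv`, `center_s` and
#'   `width_s`.
#' @export
draw_ground_truth <- function(cfg) {
  T <- 1 / cfg$cadence_hz
  sf <- cfg$stance_fraction
  sides <- list()
  bursts <- list()
  for (side in .sides) {
    off <- if (side == "left") 0 else T / 2
    starts <- seq(off, cfg$duration_s - T + 1e-9, by = T)
    to <- starts + sf * T
    peaks <- starts + sf * T + (1 - sf) * T / 2
    sides[[side]] <- list(cycle_starts = starts, heel_strikes = starts,
                          toe_offs = to, swing_peaks = peaks,
                          n_cycles = length(starts), period_s = T)
    K <- length(starts)
    mus <- list()
    for (m in names(cfg$muscles)) {
      tpl <- cfg$muscles[[m]]
      rho <- if (side == "right") cfg$asymmetry_rho else 0
      ph_start <- if (tpl$phase == "stance") starts else to
      ph_dur <- if (tpl$phase == "stance") sf * T else (1 - sf) * T
      cf <- tpl$center_frac + 0.2 * rho
      wf <- tpl$width_frac * (1 + rho)
      cf <- min(max(cf, 2 * wf), 1 - 2 * wf)
      amp <- with_seed(sub_seed(cfg$seed, paste("amp", side, m)),
                       tpl$amplitude_mv * (1 - rho) *
                         pmax(1 + rnorm(K, 0, cfg$sigma_amp), 0))
      jit <- with_seed(sub_seed(cfg$seed, paste("time", side, m)),
                       rnorm(K, 0, cfg$sigma_time))
      cf_i <- pmin(pmax(cf + jit, wf), 1 - wf)
      mus[[m]] <- list(amplitude_mv = amp,
                       center_s = ph_start + cf_i * ph_dur,
                       width_s = rep(wf * ph_dur, K))
    }
    bursts[[side]] <- mus
  }
  structure(list(sides = sides, bursts = bursts, period_s = T,
                 stance_fraction = sf, seed = cfg$seed),
            class = "ground_truth")
}

# add Gaussian bumps amp * exp(-(t - c)^2 / (2 sd^2)) to y (support +-5 sd)
add_bumps <- function(y, t, centers, sds, amps) {
  dt <- t[2] - t[1]
  for (k in seq_along(centers)) {
    lo <- max(1L, as.integer(floor((centers[k] - 5 * sds[k] - t[1]) / dt)))
    hi <- min(length(t),
              as.integer(ceiling((centers[k] + 5 * sds[k] - t[1]) / dt)) + 1L)
    if (hi < lo) next
    seg <- lo:hi
    y[seg] <- y[seg] + amps[k] * exp(-(t[seg] - centers[k])^2 / (2 * sds[k]^2))
  }
  y
}

#' Simulate a shank angular-velocity (gyro) channel
#'
#' One dominant positive Gaussian peak per cycle at mid-swing (+300 deg/s),
#' troughs at heel strike (-150) and toe-off (-100), plus additive Gaussian
#' noise. The right leg is the left leg's pattern delayed by half a cycle.
#'
#' @param cfg A [simulation_config()].
#' @param side `"left"` or `"right"`.
#' @param gt Ground truth from [draw_ground_truth()] (drawn from `cfg` when
#'   omitted).
#' @return A `sampled_signal` at `cfg$gyro_rate_hz`, units deg/s.
#' @export
simulate_gyro <- function(cfg, side, gt = draw_ground_truth(cfg)) {
  side <- match.arg(side, .sides)
  T <- gt$period_s
  sf <- gt$stance_fraction
  n <- as.integer(round(cfg$duration_s * cfg$gyro_rate_hz))
  t <- (0:(n - 1)) / cfg$gyro_rate_hz
  off <- if (side == "left") 0 else T / 2
  # event grids extended one cycle past both ends for a seamless waveform
  starts <- seq(off - T, cfg$duration_s + T, by = T)
  y <- numeric(n)
  y <- add_bumps(y, t, starts + sf * T + (1 - sf) * T / 2,
                 rep(0.06 * T, length(starts)), rep(300, length(starts)))
  y <- add_bumps(y, t, starts, rep(0.05 * T, length(starts)),
                 rep(-150, length(starts)))
  y <- add_bumps(y, t, starts + sf * T, rep(0.05 * T, length(starts)),
                 rep(-100, length(starts)))
  noise <- with_seed(sub_seed(cfg$seed, paste("gyro", side)),
                     rnorm(n, 0, cfg$gyro_noise_sd))
  sampled_signal(y + noise, cfg$gyro_rate_hz, 0, units = "deg/s")
}

# band-limited unit-RMS Gaussian carrier via FFT masking
bandlimited_noise <- function(n, rate_hz, f_lo = 20, f_hi = 450, seed) {
  z <- with_seed(seed, rnorm(n))
  X <- stats::fft(z)
  f <- (0:(n - 1)) * rate_hz / n
  f <- pmin(f, rate_hz - f)                  # two-sided frequency
  X[f < f_lo | f > min(f_hi, rate_hz / 2)] <- 0
  c0 <- Re(stats::fft(X, inverse = TRUE)) / n
  c0 / sqrt(mean(c0^2))
}

#' Simulate one EMG channel
#'
#' Band-limited (20-450 Hz) Gaussian carrier modulated by the ground truth's
#' per-cycle activation bursts, energy-normalized per cycle (so configured
#' jitter is the only source of cycle-to-cycle energy variability), with
#' optional 50 Hz hum and DC offset.
#'
#' @param cfg A [simulation_config()].
#' @param muscle Muscle name (must appear in `cfg$muscles`).
#' @param side `"left"` or `"right"`.
#' @param gt Ground truth from [draw_ground_truth()].
#' @return A `sampled_signal` at `cfg$emg_rate_hz`, units mV.
#' @export
simulate_emg <- function(cfg, muscle, side, gt = draw_ground_truth(cfg)) {
  side <- match.arg(side, .sides)
  if (!muscle %in% names(cfg$muscles))
    stop("unknown muscle: ", muscle, call. = FALSE)
  n <- as.integer(round(cfg$duration_s * cfg$emg_rate_hz))
  t <- (0:(n - 1)) / cfg$emg_rate_hz
  b <- gt$bursts[[side]][[muscle]]
  env <- add_bumps(rep(cfg$baseline_mv, n), t, b$center_s, b$width_s,
                   b$amplitude_mv)
  carrier <- bandlimited_noise(n, cfg$emg_rate_hz,
                               seed = sub_seed(cfg$seed,
                                               paste("emg", side, muscle)))
  x <- env * carrier
  # per-phase energy normalization: sum(x^2) == sum(env^2) within each
  # stance and swing segment, so configured jitter is the only source of
  # cycle-to-cycle variability in the phase energies the stability pipeline
  # measures
  gs <- gt$sides[[side]]
  bounds <- sort(c(gs$cycle_starts, gs$toe_offs, cfg$duration_s))
  for (k in seq_len(length(bounds) - 1L)) {
    seg <- which(t >= bounds[k] & t < bounds[k + 1])
    ex <- sum(x[seg]^2)
    if (ex > 0) x[seg] <- x[seg] * sqrt(sum(env[seg]^2) / ex)
  }
  if (cfg$hum_amplitude_mv != 0)
    x <- x + cfg$hum_amplitude_mv * sin(2 * pi * 50 * t)
  x <- x + cfg$dc_offset_mv
  sampled_signal(x, cfg$emg_rate_hz, 0, units = "mV")
}

#' Simulate a full recording session
#'
#' All muscles in `cfg$muscles` on both sides (EMG) plus one
#' tibialis-anterior gyro channel per side, with the ground truth used to
#' build them.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `recording` and `ground_truth`.
#' @export
simulate_session <- function(cfg = simulation_config()) {
  gt <- draw_ground_truth(cfg)
  channels <- list()
  for (side in .sides) {
    sfx <- if (side == "left") "l" else "r"
    channels[[length(channels) + 1L]] <- list(
      meta = channel_meta(paste0("gyro_ta_", sfx), "gyro_x",
                          "tibialis_anterior", side),
      signal = simulate_gyro(cfg, side, gt))
    for (m in names(cfg$muscles))
      channels[[length(channels) + 1L]] <- list(
        meta = channel_meta(paste0("emg_", m, "_", sfx), "emg", m, side),
        signal = simulate_emg(cfg, m, side, gt))
  }
  rec <- recording(channels,
                   label = sprintf("synthetic-%gkmh-seed%d", cfg$speed_kmh,
                                   cfg$seed),
                   speed_kmh = cfg$speed_kmh)
  list(recording = rec, ground_truth = gt)
}
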