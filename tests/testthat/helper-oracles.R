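# Independent oracles and fixture builders. Oracles are deliberately naive
# (double loops, O(n^2) searches) and share no code with the implementation.

# Eq.-style windowed mean, naive double loop
naive_moving_average <- function(x, n) {
  len <- length(x) - n + 1
  out <- numeric(len)
  for (i in seq_len(len)) {
    s <- 0
    for (j in 0:(n - 1)) s <- s + x[i + j]
    out[i] <- s / n
  }
  out
}

# normalized cross-correlation at the per-cycle half-cycle lag, from scratch
naive_cross_corr_symmetry <- function(v1, v2, P) {
  n_cyc <- length(v2) / P
  v2s <- numeric(length(v2))
  for (c0 in seq_len(n_cyc)) {
    for (g in seq_len(P)) {
      src <- (c0 - 1) * P + ((g - 1 + P / 2) %% P) + 1
      v2s[(c0 - 1) * P + g] <- v2[src]
    }
  }
  m1 <- mean(v1); m2 <- mean(v2s)
  num <- sum((v1 - m1) * (v2s - m2))
  den <- sqrt(sum((v1 - m1)^2) * sum((v2s - m2)^2))
  100 * min(max(num / den, 0), 1)
}

# exhaustive shortest-window search over all (start, end) pairs
brute_localization <- function(w, fraction = 0.9) {
  n <- length(w)
  target <- fraction * sum(w)
  tol <- target * 1e-12
  best <- NULL
  for (L in 1:n) {
    for (s in 1:(n - L + 1)) {
      if (sum(w[s:(s + L - 1)]) >= target - tol) {
        best <- c(s, L)
        break
      }
    }
    if (!is.null(best)) break
  }
  best   # c(start index, length)
}

# direct evaluation of the per-phase mean/SD formulas (population form)
naive_phase_formulas <- function(E, dt) {
  N <- length(E)
  mE <- sum(E) / N
  mdt <- sum(dt) / N
  list(mean_E = mE, sd_E = sqrt(sum((E - mE)^2) / N),
       mean_dt = mdt, sd_dt = sqrt(sum((dt - mdt)^2) / N))
}

# an energy_envelope object from raw values
make_envelope <- function(values, P) {
  structure(list(values = values, cycle_len_pts = as.integer(P),
                 n_cycles = length(values) %/% P),
            class = "energy_envelope")
}

# a cycle_partition with uniform cycles/phases on a given timebase
make_partition <- function(starts, cycle_s, stance_frac = 0.4,
                           side = "left") {
  n <- length(starts)
  cyc <- data.frame(i = seq_len(n), start_s = starts,
                    end_s = starts + cycle_s)
  ph <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- starts[i]
    data.frame(i = i, f = 1:2, name = c("stance", "swing"),
               start_s = c(s, s + stance_frac * cycle_s),
               end_s = c(s + stance_frac * cycle_s, s + cycle_s))
  }))
  structure(list(side = side, cycles = cyc, phases = ph, n_cycles = n),
            class = "cycle_partition")
}

# a minimal two-channel recording for I/O tests (equal rates so the channels
# share one CSV and a common duration)
toy_recording <- function(n = 4, label = "toy") {
  recording(list(
    list(meta = channel_meta("emg_rf_l", "emg", "rectus_femoris", "left"),
         signal = sampled_signal(seq_len(n) / 10, 2000)),
    list(meta = channel_meta("gyro_ta_l", "gyro_x", "tibialis_anterior",
                             "left"),
         signal = sampled_signal(sin(seq_len(n)), 2000))),
    label = label)
}

# random multi-rate recording for round-trip property tests
random_recording <- function(seed) {
  set.seed(seed)
  muscles <- sample(runcoord_muscles(), 3)
  chans <- list(
    list(meta = channel_meta("g_l", "gyro_x", "tibialis_anterior", "left"),
         signal = sampled_signal(rnorm(74), 148)),
    list(meta = channel_meta("g_r", "gyro_x", "tibialis_anterior", "right"),
         signal = sampled_signal(rnorm(74), 148)))
  for (m in muscles)
    chans[[length(chans) + 1]] <-
      list(meta = channel_meta(paste0("e_", m), "emg", m, "left"),
           signal = sampled_signal(rnorm(1000), 2000))
  recording(chans, label = paste0("rand", seed), speed_kmh = 9)
}

# small, fast simulation config for pipeline tests (>= 21 usable cycles)
fast_cfg <- function(...) {
  simulation_config(duration_s = 20, ...)
}

# smooth unimodal-per-cycle energy: one Gaussian bump per centre
add_bumps_test <- function(t, centers, sd = 0.08, amp = 1) {
  y <- numeric(length(t))
  for (c0 in centers) y <- y + amp * exp(-(t - c0)^2 / (2 * sd^2))
  y
}

periodogram_power <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * rate / n
  sum(sp[f >= f_lo & f <= f_hi & f <= rate / 2])
}
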