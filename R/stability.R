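# Amplitude and spatiotemporal stability of muscle EMG profiles.
#
# For every muscle, phase and cycle, the effort localization window is the
# shortest contiguous interval inside the phase holding at least 90% of the
# phase's EMG energy (earliest start on ties). Across the repeated cycles of
# one phase, the window energies E and the window/phase duration ratios dt
# give means, population standard deviations and stability coefficients
# k = (1 - sd/mean) * 100 clamped at 0. The integral coefficient K_EMG is
# the flat average of (k_E + k_dt)/2 over all muscle x phase pairs.

#' Shortest localization window holding a given energy fraction
#'
#' Two-phase search over the cumulative energy: a binary search on the window
#' length (feasibility is monotone because energies are non-negative), then
#' the earliest start achieving that length. Equivalent to the exhaustive
#' search over all (start, end) pairs.
#'
#' @param e Energy `sampled_signal` (mV^2).
#' @param phase_start_s,phase_end_s Phase boundaries, seconds (end exclusive).
#' @param fraction Minimum fraction of the phase energy inside the window
#'   (default 0.9).
#' @return An object of class `localization_window`: `start_s`, `end_s`,
#'   `T_s` (duration), `E_fT` (window energy), `E_f` (phase energy),
#'   `degenerate` (TRUE for a silent phase, where the full phase is returned
#'   and the caller excludes it from statistics).
#' @export
localization_window <- function(e, phase_start_s, phase_end_s,
                                fraction = 0.9) {
  stopifnot(inherits(e, "sampled_signal"), fraction > 0, fraction <= 1)
  if (phase_end_s <= phase_start_s)
    stop("empty phase interval", call. = FALSE)
  # nearest-sample projection of the boundaries, end exclusive; computed
  # unclamped so a phase ending exactly at the signal end keeps its last
  # sample
  k0 <- ceiling((phase_start_s - e$t0_s) * e$rate_hz - 0.5) + 1
  k1 <- ceiling((phase_end_s - e$t0_s) * e$rate_hz - 0.5)
  i0 <- max(1L, as.integer(k0))
  i1 <- min(length(e$samples), max(i0, as.integer(k1)))
  w <- e$samples[i0:i1]
  n <- length(w)
  E_f <- sum(w)
  t_of <- function(i_rel) e$t0_s + (i0 + i_rel - 2) / e$rate_hz
  if (E_f <= 0) {
    return(structure(list(start_s = t_of(1), end_s = t_of(n) + 1 / e$rate_hz,
                          T_s = n / e$rate_hz, E_fT = E_f, E_f = E_f,
                          degenerate = TRUE),
                     class = "localization_window"))
  }
  target <- fraction * E_f
  tol <- target * 1e-12
  cs <- c(0, cumsum(w))
  feasible <- function(L) max(cs[(L + 1):(n + 1)] - cs[1:(n + 1 - L)]) >=
    target - tol
  lo <- 1L; hi <- n
  while (lo < hi) {                     # smallest feasible length
    mid <- (lo + hi) %/% 2L
    if (feasible(mid)) hi <- mid else lo <- mid + 1L
  }
  L <- lo
  s <- which(cs[(L + 1):(n + 1)] - cs[1:(n + 1 - L)] >= target - tol)[1]
  structure(list(start_s = t_of(s), end_s = t_of(s + L - 1) + 1 / e$rate_hz,
                 T_s = L / e$rate_hz,
                 E_fT = cs[s + L] - cs[s], E_f = E_f, degenerate = FALSE),
            class = "localization_window")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-phase statistics over repeated cycles
#'
#' Collects the localization-window energies and the window/phase duration
#' ratios `dt_i = T_i / t_i` across cycles, and computes their means and
#' population standard deviations (denominator N).
#'
#' @param windows List of `localization_window`s, one per cycle.
#' @param durations Phase durations `t_f^i` in seconds, same order.
#' @param muscle,phase Optional labels carried into the result.
#' @return An object of class `phase_stability_stats` with per-cycle vectors
#'   `energies`, `dt`, their `mean_E`, `sd_E`, `mean_dt`, `sd_dt`, and (after
#'   [stability_coefficients()]) `k_E`, `k_dt`.
#' @export
phase_stats <- function(windows, durations, muscle = NA_character_,
                        phase = NA_integer_) {
  N <- length(windows)
  if (N < 2L || length(durations) != N)
    stop("need >= 2 cycles with matching durations", call. = FALSE)
  if (any(durations <= 0)) stop("phase durations must be > 0", call. = FALSE)
  E <- vapply(windows, function(w) w$E_fT, numeric(1))
  Tw <- vapply(windows, function(w) w$T_s, numeric(1))
  dt <- pmin(Tw / durations, 1)
  structure(list(muscle = muscle, phase = phase, n = N,
                 energies = E, dt = dt,
                 mean_E = mean(E), sd_E = pop_sd(E),
                 mean_dt = mean(dt), sd_dt = pop_sd(dt),
                 k_E = NA_real_, k_dt = NA_real_,
                 excluded = any(vapply(windows, function(w) w$degenerate,
                                       logical(1)))),
            class = "phase_stability_stats")
}

#' Cycle-to-cycle stability coefficients of one phase
#'
#' `k = (1 - sd/mean) * 100`, clamped below at 0 so the coefficient stays in
#' `[0, 100]` even when the spread exceeds the mean.
#'
#' @param stats A `phase_stability_stats` object.
#' @return The same object with `k_E` and `k_dt` filled in.
#' @export
stability_coefficients <- function(stats) {
  stopifnot(inherits(stats, "phase_stability_stats"))
  if (stats$excluded || stats$mean_E <= 0 || stats$mean_dt <= 0)
    stop("undefined coefficient: degenerate (silent) phase", call. = FALSE)
  stats$k_E <- max(0, 1 - stats$sd_E / stats$mean_E) * 100
  stats$k_dt <- max(0, 1 - stats$sd_dt / stats$mean_dt) * 100
  stats
}

#' Integral stability coefficient over all muscle x phase pairs
#'
#' `K_EMG` is the flat average of `(k_E + k_dt) / 2` over the included pairs.
#' Pairs flagged as degenerate (a silent muscle phase is missing data, not
#' instability) are excluded and listed in the report.
#'
#' @param all_stats List of `phase_stability_stats` (coefficients computed
#'   for non-excluded entries).
#' @param M Number of muscles.
#' @param F Number of phases per cycle.
#' @param n_cycles Cycles per phase (bookkeeping only).
#' @param side Leg label (bookkeeping only).
#' @return An object of class `stability_report`: `K_EMG_pct`, `M`, `F`,
#'   `n_cycles`, a `per_phase` data.frame and the excluded pairs.
#' @export
integral_stability <- function(all_stats, M, F, n_cycles = NA_integer_,
                               side = NA_character_) {
  included <- Filter(function(s) !s$excluded, all_stats)
  if (length(included) == 0L)
    stop("no data: all muscle/phase pairs excluded", call. = FALSE)
  pair_means <- vapply(included, function(s) (s$k_E + s$k_dt) / 2, numeric(1))
  per <- do.call(rbind, lapply(all_stats, function(s)
    data.frame(muscle = s$muscle, phase = s$phase,
               k_E = s$k_E, k_dt = s$k_dt,
               mean_E = s$mean_E, sd_E = s$sd_E,
               mean_dt = s$mean_dt, sd_dt = s$sd_dt,
               excluded = s$excluded)))
  structure(list(K_EMG_pct = mean(pair_means), M = M, F = F,
                 n_cycles = n_cycles, side = side, per_phase = per,
                 n_excluded = sum(per$excluded)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report>%s K_EMG = %.2f %% (%d muscles x %d phases, %s cycles%s)\n",
              if (is.na(x$side)) "" else paste0(" ", x$side, " leg:"),
              x$K_EMG_pct, x$M, x$F, x$n_cycles,
              if (x$n_excluded > 0)
                sprintf(", %d pairs excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Assess EMG profile stability for one leg
#'
#' Full amplitude/spatiotemporal stability pipeline: for each muscle and each
#' phase, localization windows over the first `n_cycles` cycles, per-phase
#' statistics, stability coefficients, and the integral coefficient K_EMG.
#'
#' @param rec A preprocessed `recording`.
#' @param part `cycle_partition` of the leg to assess (its `side` selects the
#'   EMG channels).
#' @param muscles Muscles to include (default all seven).
#' @param n_cycles Cycles to analyze (default 20).
#' @param fraction Energy fraction of the localization window (default 0.9).
#' @return A `stability_report`.
#' @export
assess_stability <- function(rec, part, muscles = runcoord_muscles(),
                             n_cycles = 20L, fraction = 0.9) {
  stopifnot(inherits(rec, "recording"), inherits(part, "cycle_partition"))
  if (part$n_cycles < n_cycles)
    stop(sprintf("partition has %d cycles, %d requested", part$n_cycles,
                 n_cycles), call. = FALSE)
  phases <- part$phases[part$phases$i <= n_cycles, ]
  F <- length(unique(phases$f))
  all_stats <- list()
  for (m in muscles) {
    ch <- get_channels(rec, kind = "emg", muscle = m, side = part$side)
    if (length(ch) == 0L)
      stop("muscle missing on side ", part$side, ": ", m, call. = FALSE)
    e <- energy_signal(ch[[1]]$signal)
    for (f in sort(unique(phases$f))) {
      rows <- phases[phases$f == f, ]
      wins <- lapply(seq_len(nrow(rows)), function(r)
        localization_window(e, rows$start_s[r], rows$end_s[r], fraction))
      st <- phase_stats(wins, rows$end_s - rows$start_s, muscle = m,
                        phase = f)
      if (!st$excluded) st <- stability_coefficients(st)
      all_stats[[length(all_stats) + 1L]] <- st
    }
  }
  integral_stability(all_stats, M = length(muscles), F = F,
                     n_cycles = n_cycles, side = part$side)
}
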