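# Left/right symmetry of muscular effort. The squared (energy) EMG of each
# muscle is enveloped by a cubic spline through its local maxima, resampled
# onto a time-normalized grid of points_per_cycle points per running cycle,
# and the two limbs are compared by a normalized cross-correlation at the
# antiphase lag of half a cycle. The symmetry coefficient alpha is the
# unweighted mean over muscles, in percent.

#' Instantaneous EMG energy
#'
#' Pointwise square of a (preprocessed) EMG signal; the sum over a window is
#' the window's digital energy.
#'
#' @param x A `sampled_signal` (mV).
#' @return A `sampled_signal` in mV^2 on the same timebase.
#' @export
energy_signal <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  sampled_signal(x$samples^2, x$rate_hz, x$t0_s, units = "mV^2")
}

#' Spline envelope of an energy signal on a per-cycle grid
#'
#' A natural cubic spline is drawn through the local maxima of the energy
#' signal over the partition's span (span endpoints included as knots;
#' plateaus count as maxima so a constant signal envelopes to itself), then
#' evaluated on a uniform grid of `points_per_cycle` points per cycle.
#' Negative spline excursions are clamped to zero. Time-normalizing each
#' cycle removes cadence differences between legs before correlation.
#'
#' At EMG sampling rates the raw squared signal has a local maximum every few
#' samples, so knots are the block maxima over consecutive `min_sep_s`
#' windows: the envelope then traces muscular effort rather than the
#' stochastic carrier (analogous to the conventional low-passed linear
#' envelope), and for an already-smooth signal the knots simply follow the
#' signal, avoiding cubic oscillation between sparse peaks.
#'
#' @param e Energy `sampled_signal` (see [energy_signal()]).
#' @param part A `cycle_partition` covered by `e`.
#' @param points_per_cycle Grid points per cycle (>= 16; rounded up to even
#'   so the antiphase half-cycle lag is exact). Default 200.
#' @param min_sep_s Knot-block length in seconds (default 0.025, i.e. an
#'   envelope bandwidth of a few tens of Hz).
#' @param smooth_s Moving-average window (s) applied to the energy before
#'   knot detection — the classic moving-RMS amplitude estimate (default
#'   0.05). Set to 0 to envelope the raw squared signal.
#' @return An object of class `energy_envelope` with `values`
#'   (`n_cycles * cycle_len_pts`, non-negative), `cycle_len_pts`, `n_cycles`.
#' @export
energy_envelope <- function(e, part, points_per_cycle = 200L,
                            min_sep_s = 0.025, smooth_s = 0.05) {
  stopifnot(inherits(e, "sampled_signal"), inherits(part, "cycle_partition"))
  P <- as.integer(points_per_cycle)
  if (P < 16L) stop("points_per_cycle must be >= 16", call. = FALSE)
  if (P %% 2L == 1L) P <- P + 1L
  w <- as.integer(round(smooth_s * e$rate_hz))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= 3L && w < length(e$samples)) e <- moving_average(e, w)
  span <- c(min(part$cycles$start_s), max(part$cycles$end_s))
  i0 <- time_to_index(e, span[1])
  i1 <- time_to_index(e, span[2])
  v <- e$samples[i0:i1]
  n <- length(v)
  if (n < 4L) stop("envelope error: too few samples in span", call. = FALSE)
  blk <- max(1L, as.integer(round(min_sep_s * e$rate_hz)))
  grp <- (seq_len(n) - 1L) %/% blk
  cand <- vapply(split(seq_len(n), grp),
                 function(ix) ix[which.max(v[ix])], integer(1))
  knots <- sort(unique(c(1L, cand, n)))
  if (length(knots) < 4L)
    stop("envelope error: fewer than 4 local maxima in span", call. = FALSE)
  tk <- e$t0_s + (i0 + knots - 2) / e$rate_hz
  fn <- stats::splinefun(tk, v[knots], method = "natural")
  vals <- unlist(lapply(seq_len(nrow(part$cycles)), function(r) {
    s <- part$cycles$start_s[r]; en <- part$cycles$end_s[r]
    fn(s + (0:(P - 1)) / P * (en - s))
  }), use.names = FALSE)
  structure(list(values = pmax(vals, 0), cycle_len_pts = P,
                 n_cycles = nrow(part$cycles)),
            class = "energy_envelope")
}

# rotate each cycle's block of the envelope by half a cycle (antiphase lag);
# a per-cycle rotation makes the +/- half-cycle shifts coincide, so the
# left/right comparison is symmetric by construction
shift_half_cycle <- function(env) {
  P <- env$cycle_len_pts
  h <- P %/% 2L
  idx <- unlist(lapply(seq_len(env$n_cycles), function(c0) {
    base <- (c0 - 1L) * P
    base + c((h + 1L):P, 1L:h)
  }), use.names = FALSE)
  env$values[idx]
}

#' Half-cycle-lagged normalized cross-correlation of two envelopes
#'
#' The right-leg envelope is rotated by half a cycle (opposite limbs move in
#' antiphase), then the normalized (zero-mean, unit-variance) correlation
#' coefficient with the left-leg envelope is computed over the full grid,
#' clamped to `[0, 1]` (anti-symmetric effort counts as 0% symmetric) and
#' returned in percent.
#'
#' @param env_l,env_r `energy_envelope` objects sharing `cycle_len_pts` and
#'   `n_cycles`.
#' @return Per-muscle symmetry in percent, in `[0, 100]`.
#' @export
cross_corr_symmetry <- function(env_l, env_r) {
  stopifnot(inherits(env_l, "energy_envelope"),
            inherits(env_r, "energy_envelope"))
  if (env_l$cycle_len_pts != env_r$cycle_len_pts ||
      env_l$n_cycles != env_r$n_cycles)
    stop("envelopes must share grid size and cycle count", call. = FALSE)
  x1 <- env_l$values
  x2 <- shift_half_cycle(env_r)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
    stop("symmetry undefined: zero-variance envelope", call. = FALSE)
  r <- stats::cor(x1, x2)
  100 * min(max(r, 0), 1)
}

#' Symmetry coefficient of left/right muscular efforts
#'
#' For each muscle present on both sides, the EMG energy envelopes of BOTH
#' legs are sampled on the left leg's cycle grid (the signals are recorded
#' synchronously, so the right leg's bursts appear displaced by half a cycle
#' on that grid — opposite limbs move in antiphase) and compared by
#' [cross_corr_symmetry()], which applies the compensating half-cycle lag.
#' alpha is the unweighted mean over muscles. The right partition is used to
#' truncate to a common cycle count and to check that the two legs' cadences
#' agree (a shared treadmill cadence is assumed; a > 5% mismatch errors).
#'
#' @param rec A preprocessed `recording` (see [preprocess_emg()]).
#' @param part_l,part_r `cycle_partition`s for the left and right leg. When
#'   their cycle counts differ, both are truncated to the common count.
#' @param muscles Muscles to analyze (default: all seven).
#' @param points_per_cycle Envelope grid points per cycle.
#' @return An object of class `symmetry_report` with `per_muscle` (named
#'   percent vector) and `alpha_pct`.
#' @export
symmetry_coefficient <- function(rec, part_l, part_r,
                                 muscles = runcoord_muscles(),
                                 points_per_cycle = 200L) {
  stopifnot(inherits(rec, "recording"))
  n_common <- min(part_l$n_cycles, part_r$n_cycles)
  truncate_part <- function(p) {
    p$cycles <- p$cycles[p$cycles$i <= n_common, ]
    p$phases <- p$phases[p$phases$i <= n_common, ]
    p$n_cycles <- n_common
    p
  }
  part_l <- truncate_part(part_l)
  part_r <- truncate_part(part_r)
  mdur <- function(p) mean(p$cycles$end_s - p$cycles$start_s)
  if (abs(mdur(part_l) - mdur(part_r)) > 0.05 * mdur(part_l))
    stop("left/right cadences differ by more than 5%", call. = FALSE)
  per <- vapply(muscles, function(m) {
    chl <- get_channels(rec, kind = "emg", muscle = m, side = "left")
    chr <- get_channels(rec, kind = "emg", muscle = m, side = "right")
    if (length(chl) == 0L || length(chr) == 0L)
      stop("muscle missing on one side: ", m, call. = FALSE)
    env_l <- energy_envelope(energy_signal(chl[[1]]$signal), part_l,
                             points_per_cycle)
    env_r <- energy_envelope(energy_signal(chr[[1]]$signal), part_l,
                             points_per_cycle)
    cross_corr_symmetry(env_l, env_r)
  }, numeric(1))
  names(per) <- muscles
  structure(list(per_muscle = per, alpha_pct = mean(per)),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry_report> alpha = %.2f %%\n", x$alpha_pct))
  for (m in names(x$per_muscle))
    cat(sprintf("  %-24s %6.2f %%\n", m, x$per_muscle[[m]]))
  invisible(x)
}
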