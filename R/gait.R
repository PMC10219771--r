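# Running-cycle segmentation from shank angular velocity.
#
# The tibialis-anterior gyroscope signal has one dominant positive peak per
# cycle at mid-swing. Cycles are found by (1) smoothing with a moving-average
# filter whose width follows the movement period, (2) estimating the period
# from the autocorrelation function, (3) picking swing peaks as prominent
# local maxima, and (4) locating heel strike / toe-off as the signal minima
# flanking each peak. Amplitude scaling and time shifts leave all outputs
# unchanged (up to the shift itself).

#' Moving-average (sliding window) filter
#'
#' `y[i] = mean(x[i], ..., x[i + N - 1])`; the output is delay-compensated by
#' shifting its start time forward by `(N - 1) / 2` samples so that peak
#' positions align with the input. Output length is `length(x) - N + 1`.
#'
#' @param x A `sampled_signal`.
#' @param n_samples Window width N (1 <= N <= length(x)).
#' @return A `sampled_signal`.
#' @export
moving_average <- function(x, n_samples) {
  stopifnot(inherits(x, "sampled_signal"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L || n_samples > length(x$samples))
    stop("window width must be in [1, length(x)]", call. = FALSE)
  cs <- c(0, cumsum(x$samples))
  len <- length(x$samples) - n_samples + 1L
  y <- (cs[(n_samples + 1):(n_samples + len)] - cs[1:len]) / n_samples
  sampled_signal(y, x$rate_hz,
                 x$t0_s + (n_samples - 1) / 2 / x$rate_hz, x$units)
}

#' Estimate the movement period from the autocorrelation function
#'
#' Returns the lag (s) of the highest local maximum of the biased sample
#' autocorrelation within `[min_s, max_s]`. The default search range
#' corresponds to running cadences of roughly 37-150 cycles/min per leg.
#'
#' @param x A `sampled_signal` (raw or smoothed gyro channel).
#' @param min_s,max_s Search range for the period, seconds.
#' @return Period in seconds.
#' @export
estimate_period <- function(x, min_s = 0.4, max_s = 1.6) {
  stopifnot(inherits(x, "sampled_signal"), min_s < max_s)
  if (signal_duration(x) < 3 * max_s)
    stop("signal too short: need at least 3 * max_s = ",
         3 * max_s, " s", call. = FALSE)
  if (stats::sd(x$samples) == 0)
    stop("periodicity error: constant signal has no period", call. = FALSE)
  lag_max <- min(length(x$samples) - 1L, as.integer(ceiling(max_s * x$rate_hz)) + 1L)
  r <- as.numeric(stats::acf(x$samples, lag.max = lag_max, plot = FALSE,
                             demean = TRUE)$acf)      # biased, denominator n
  k <- seq_along(r) - 1L                               # lag in samples
  in_range <- k / x$rate_hz >= min_s & k / x$rate_hz <= max_s
  # local maxima (ties flatten to the left-most sample of a plateau)
  is_max <- c(FALSE, r[2:(length(r) - 1)] > r[1:(length(r) - 2)] &
                      r[2:(length(r) - 1)] >= r[3:length(r)], FALSE)
  cand <- which(is_max & in_range)
  if (length(cand) == 0L)
    stop("periodicity error: no autocorrelation maximum in [",
         min_s, ", ", max_s, "] s", call. = FALSE)
  best <- cand[which.max(r[cand])]
  k[best] / x$rate_hz
}

# Peak prominence: height above the higher of the two valley floors between
# the peak and the nearest higher sample on each side (or the signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    li <- p - 1L
    lmin <- h
    while (li >= 1L && x[li] <= h) { lmin <- min(lmin, x[li]); li <- li - 1L }
    ri <- p + 1L
    rmin <- h
    n <- length(x)
    while (ri <= n && x[ri] <= h) { rmin <- min(rmin, x[ri]); ri <- ri + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect swing peaks in a smoothed gyro signal
#'
#' Local maxima separated by at least `0.6 * period` with prominence at least
#' `0.3 * (max - min)` of the signal. When two candidates are closer than the
#' minimum separation, the higher one wins.
#'
#' @param x_filtered Smoothed `sampled_signal` (see [moving_average()]).
#' @param period_s Movement period from [estimate_period()].
#' @return Sorted integer vector of 1-based peak sample indices.
#' @export
detect_swing_peaks <- function(x_filtered, period_s) {
  stopifnot(inherits(x_filtered, "sampled_signal"), period_s > 0)
  v <- x_filtered$samples
  n <- length(v)
  cand <- which(c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] &
                         v[2:(n - 1)] >= v[3:n], FALSE))
  rng <- max(v) - min(v)
  if (rng > 0) {
    prom <- peak_prominence(v, cand)
    cand <- cand[prom >= 0.3 * rng]
  }
  min_sep <- 0.6 * period_s * x_filtered$rate_hz
  keep <- logical(length(cand))
  ord <- order(v[cand], decreasing = TRUE)   # greedy by height
  taken <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - taken) >= min_sep)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 2L)
    stop("segmentation error: fewer than 2 swing peaks detected",
         call. = FALSE)
  peaks
}

#' Locate heel strike and toe-off around each swing peak
#'
#' Heel strike for stride k is the global minimum of the smoothed signal in
#' the half inter-peak interval following swing peak k; toe-off is the global
#' minimum in the half interval preceding swing peak k + 1. Flat minima break
#' ties to the earliest index.
#'
#' @param x_filtered Smoothed `sampled_signal`.
#' @param swing_peaks Peak indices from [detect_swing_peaks()].
#' @return An object of class `gait_events` with fields `swing_peaks`,
#'   `heel_strikes`, `toe_offs` (sample indices) and `rate_hz`, `t0_s`.
#' @export
detect_cycle_events <- function(x_filtered, swing_peaks) {
  stopifnot(inherits(x_filtered, "sampled_signal"), length(swing_peaks) >= 2L)
  v <- x_filtered$samples
  K <- length(swing_peaks)
  hs <- integer(K - 1L)
  to <- integer(K - 1L)
  for (k in seq_len(K - 1L)) {
    p0 <- swing_peaks[k]; p1 <- swing_peaks[k + 1L]
    half <- (p1 - p0) / 2
    a <- (p0 + 1L):min(p1, as.integer(floor(p0 + half)))
    hs[k] <- a[which.min(v[a])]               # which.min: earliest on ties
    b <- max(p0 + 1L, as.integer(ceiling(p1 - half))):(p1 - 1L)
    to[k] <- b[which.min(v[b])]
    if (to[k] <= hs[k])
      stop("segmentation error: toe-off not after heel strike in stride ", k,
           call. = FALSE)
  }
  structure(list(swing_peaks = as.integer(swing_peaks), heel_strikes = hs,
                 toe_offs = to, rate_hz = x_filtered$rate_hz,
                 t0_s = x_filtered$t0_s),
            class = "gait_events")
}

#' Partition gait events into running cycles with stance and swing phases
#'
#' Cycles are anchored at heel strikes: cycle i spans heel strike i to heel
#' strike i + 1, with stance = \[heel strike, toe-off) and swing = \[toe-off,
#' next heel strike). The final available cycle's swing ends at the last
#' detected swing peak (mid-swing) when no further heel strike exists, so that
#' n detected peaks always yield n - 1 usable cycles. The partial segment
#' before the first heel strike is dropped.
#'
#' @param events A `gait_events` object.
#' @param rate_hz Sampling rate of the gyro timebase (defaults to the one
#'   recorded in `events`).
#' @param n_cycles Number of cycles to keep (default 20, matching the
#'   repeated-movement analysis window).
#' @param side `"left"` or `"right"` label carried into the partition.
#' @return An object of class `cycle_partition`: `side` plus a data.frame
#'   `cycles` (i, start_s, end_s) and a data.frame `phases`
#'   (i, f, name, start_s, end_s).
#' @export
partition_cycles <- function(events, rate_hz = events$rate_hz, n_cycles = 20L,
                             side = "left") {
  stopifnot(inherits(events, "gait_events"))
  side <- match.arg(side, .sides)
  tt <- function(idx) events$t0_s + (idx - 1) / rate_hz
  hs <- events$heel_strikes
  to <- events$toe_offs
  n_avail <- length(hs)                 # strides with a complete HS/TO pair
  if (n_avail < n_cycles)
    stop(sprintf(paste0("insufficient data: %d complete cycles available, ",
                        "%d requested"), n_avail, n_cycles), call. = FALSE)
  ends <- c(hs[-1], events$swing_peaks[length(events$swing_peaks)])
  cyc <- data.frame(i = seq_len(n_cycles), start_s = tt(hs[1:n_cycles]),
                    end_s = tt(ends[1:n_cycles]))
  ph <- do.call(rbind, lapply(seq_len(n_cycles), function(i) {
    data.frame(i = i, f = 1:2, name = c("stance", "swing"),
               start_s = c(tt(hs[i]), tt(to[i])),
               end_s = c(tt(to[i]), tt(ends[i])))
  }))
  if (any(ph$end_s - ph$start_s <= 0))
    stop("segmentation error: non-positive phase duration", call. = FALSE)
  structure(list(side = side, cycles = cyc, phases = ph,
                 n_cycles = n_cycles),
            class = "cycle_partition")
}

#' @export
print.cycle_partition <- function(x, ...) {
  dur <- x$cycles$end_s - x$cycles$start_s
  cat(sprintf("<cycle_partition> %s leg: %d cycles, mean duration %.3f s\n",
              x$side, nrow(x$cycles), mean(dur)))
  invisible(x)
}

#' Serialize / deserialize a cycle partition as JSON
#' @param part A `cycle_partition`.
#' @param path Output file path.
#' @return `write_partition` invisibly returns `path`; `read_partition`
#'   returns the `cycle_partition`.
#' @export
write_partition <- function(part, path) {
  cycles <- lapply(seq_len(nrow(part$cycles)), function(r) {
    i <- part$cycles$i[r]
    phr <- part$phases[part$phases$i == i, ]
    list(i = i, start_s = part$cycles$start_s[r],
         end_s = part$cycles$end_s[r],
         phases = lapply(seq_len(nrow(phr)), function(q)
           list(f = phr$f[q], name = phr$name[q],
                start_s = phr$start_s[q], end_s = phr$end_s[q])))
  })
  jsonlite::write_json(list(side = part$side, cycles = cycles), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cyc <- do.call(rbind, lapply(obj$cycles, function(cy)
    data.frame(i = cy$i, start_s = cy$start_s, end_s = cy$end_s)))
  ph <- do.call(rbind, lapply(obj$cycles, function(cy)
    do.call(rbind, lapply(cy$phases, function(p)
      data.frame(i = cy$i, f = p$f, name = p$name,
                 start_s = p$start_s, end_s = p$end_s)))))
  structure(list(side = obj$side, cycles = cyc, phases = ph,
                 n_cycles = nrow(cyc)),
            class = "cycle_partition")
}

# Window width for the moving-average filter: ~1/20 of the movement period,
# clamped to [3, period/4] samples and forced odd so that the
# delay compensation lands on the sample grid.
filter_window_for_period <- function(period_s, rate_hz) {
  p <- period_s * rate_hz
  n <- round(p / 20)
  n <- max(3, min(n, floor(p / 4)))
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Segment running cycles from a shank gyro channel
#'
#' Full gait pipeline for one leg: a provisional period is estimated on the
#' raw signal, the moving-average window is derived from it, the period is
#' re-estimated on the smoothed signal, then swing peaks, heel strikes and
#' toe-offs are detected and the first `n_cycles` cycles partitioned.
#'
#' @param rec A `recording` (see [validate_recording()] requirements).
#' @param side `"left"` or `"right"`.
#' @param n_cycles Number of cycles to analyze (default 20).
#' @param min_period_s,max_period_s Autocorrelation search range, seconds.
#' @return A list with `partition` (`cycle_partition`), `events`
#'   (`gait_events`), `period_s`, `window_n` and the smoothed signal
#'   `filtered`.
#' @export
segment_gait <- function(rec, side, n_cycles = 20L,
                         min_period_s = 0.4, max_period_s = 1.6) {
  gyro <- get_channels(rec, kind = c("gyro_x", "gyro_y", "gyro_z"),
                       muscle = "tibialis_anterior", side = side)
  if (length(gyro) == 0L)
    stop("no tibialis-anterior gyro channel on side ", side, call. = FALSE)
  # if several axes are present, use the one with the largest variance
  vars <- vapply(gyro, function(ch) stats::var(ch$signal$samples), numeric(1))
  x <- gyro[[which.max(vars)]]$signal
  p0 <- estimate_period(x, min_period_s, max_period_s)
  w <- filter_window_for_period(p0, x$rate_hz)
  xf <- moving_average(x, w)
  period <- estimate_period(xf, min_period_s, max_period_s)
  peaks <- detect_swing_peaks(xf, period)
  events <- detect_cycle_events(xf, peaks)
  part <- partition_cycles(events, xf$rate_hz, n_cycles = n_cycles,
                           side = side)
  list(partition = part, events = events, period_s = period, window_n = w,
       filtered = xf)
}
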