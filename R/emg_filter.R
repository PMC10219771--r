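# EMG preprocessing: Butterworth high-pass (motion-artifact removal) and IIR
# notch (mains interference). No DSP package is assumed: the designs use the
# standard bilinear transform and the classic two-pole notch; the per-sample
# IIR recursion runs in compiled code. Zero-phase application (default)
# filters forward and backward over an odd-symmetric extension seeded with
# the filter's steady-state step response, so constants are rejected exactly
# and burst timing is not skewed relative to the gyro events.

poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (rt in r) coef <- c(coef, 0) - rt * c(0, coef)
  coef
}

#' Design a digital Butterworth high-pass filter
#'
#' Analog Butterworth prototype, low-pass to high-pass transform at the
#' prewarped cutoff, bilinear transform to the z-domain.
#'
#' @param order Filter order (poles).
#' @param cutoff_hz -3 dB cutoff frequency, Hz.
#' @param rate_hz Sampling rate, Hz (`cutoff_hz` must be below Nyquist).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_highpass <- function(order, cutoff_hz, rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2)
    stop("cutoff must lie in (0, Nyquist)", call. = FALSE)
  n <- as.integer(order)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # prototype poles, LHP
  fs2 <- 2 * rate_hz
  wc <- fs2 * tan(pi * cutoff_hz / rate_hz)       # prewarped cutoff, rad/s
  ph <- wc / p                                    # low-pass -> high-pass
  # n analog zeros at s = 0 map to z = 1
  pd <- (fs2 + ph) / (fs2 - ph)
  kd <- Re(fs2^n / prod(fs2 - ph))
  b <- Re(poly_from_roots(rep(1 + 0i, n))) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Design a two-pole IIR notch filter
#'
#' @param notch_hz Notch center frequency, Hz.
#' @param rate_hz Sampling rate, Hz.
#' @param q Quality factor; -3 dB bandwidth is `notch_hz / q`.
#' @return List with `b` and `a` coefficients.
#' @export
notch_design <- function(notch_hz, rate_hz, q = 30) {
  if (notch_hz <= 0 || notch_hz >= rate_hz / 2)
    stop("notch frequency must lie in (0, Nyquist)", call. = FALSE)
  w0 <- notch_hz / (rate_hz / 2)                  # normalized (1 = Nyquist)
  bw <- w0 / q
  beta <- tan(pi * bw / 2)
  gain <- 1 / (1 + beta)
  cw <- cos(pi * w0)
  list(b = gain * c(1, -2 * cw, 1),
       a = c(1, -2 * gain * cw, 2 * gain - 1))
}

#' Complex frequency response of a digital filter
#'
#' @param b,a Filter coefficients (descending powers of z).
#' @param f_hz Frequencies at which to evaluate, Hz.
#' @param rate_hz Sampling rate, Hz.
#' @return Complex vector `H(e^{i 2 pi f / rate})`.
#' @export
filter_response <- function(b, a, f_hz, rate_hz) {
  w <- 2 * pi * f_hz / rate_hz
  ev <- function(cf, w) {
    n <- length(cf)
    sapply(w, function(wi) sum(cf * exp(-1i * wi * (0:(n - 1)))))
  }
  ev(b, w) / ev(a, w)
}

# Steady-state state vector of the direct-form-II-transposed filter for a
# unit step input; seeds filtering so a constant passes through (or is
# rejected) without transient.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a))) / a[1]
  b <- c(b, rep(0, nf - length(b)))
  if (nf == 1L) return(numeric(0))
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[2:nf]
  if (nf > 2L) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  IminusA <- diag(nf - 1) - t(comp)
  B <- b[2:nf] - a[2:nf] * b[1]
  as.numeric(solve(IminusA, B))
}

# One-pass IIR filter (direct form II transposed) with optional initial state.
lfilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  if (is.null(zi)) zi <- rep(0, nf - 1)
  .lfilter_cpp(as.numeric(b) / a[1], as.numeric(a) / a[1], as.numeric(x),
               as.numeric(zi))
}

# Transient guard: samples needed for the slowest pole to decay to ~1e-7.
transient_guard <- function(a) {
  r <- suppressWarnings(max(Mod(polyroot(rev(a)))))
  if (!is.finite(r) || r >= 1) return(0L)
  as.integer(ceiling(log(1e-7) / log(r)))
}

#' Zero-phase forward-backward IIR filtering
#'
#' Odd-symmetric padding at both ends (length adapted to the slowest pole's
#' decay, capped at the signal length) with steady-state initial conditions,
#' then a forward and a backward pass. Squares the magnitude response and
#' cancels the phase.
#'
#' @param b,a Filter coefficients.
#' @param x Numeric vector.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  padlen <- min(n - 2L, max(3L * (nf - 1L), transient_guard(a)))
  if (padlen < 0L) padlen <- 0L
  ext <- if (padlen > 0L)
    c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  else x
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  if (padlen > 0L) y[(padlen + 1):(padlen + n)] else y
}

#' EMG preprocessing specification
#'
#' Defaults follow standard surface-EMG practice: a 4th-order 10 Hz
#' Butterworth high-pass against motion artifacts and a Q = 30 notch at the
#' 50 Hz mains frequency (set `notch_freq_hz = 60` for 60 Hz mains), both
#' applied zero-phase so that burst timing stays aligned with gyro events.
#'
#' @param highpass_cutoff_hz High-pass cutoff, Hz.
#' @param highpass_order Butterworth order.
#' @param notch_freq_hz Mains frequency, Hz.
#' @param notch_q Notch quality factor.
#' @param zero_phase Apply filters forward-backward (`TRUE`) or causally.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_cutoff_hz = 10, highpass_order = 4,
                        notch_freq_hz = 50, notch_q = 30, zero_phase = TRUE) {
  stopifnot(highpass_cutoff_hz > 0, highpass_order >= 1, notch_freq_hz > 0,
            notch_q > 0)
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 highpass_order = as.integer(highpass_order),
                 notch_freq_hz = notch_freq_hz, notch_q = notch_q,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

apply_design <- function(x, des, zero_phase) {
  y <- if (zero_phase) filtfilt(des$b, des$a, x$samples)
       else lfilter(des$b, des$a, x$samples)
  sampled_signal(y, x$rate_hz, x$t0_s, x$units)
}

#' High-pass filter an EMG channel
#'
#' @param x A `sampled_signal`.
#' @param spec A [filter_spec()].
#' @return Filtered `sampled_signal`, same length and timebase.
#' @export
emg_highpass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "sampled_signal"))
  if (spec$highpass_cutoff_hz >= x$rate_hz / 2)
    stop("high-pass cutoff at or above Nyquist", call. = FALSE)
  des <- butter_highpass(spec$highpass_order, spec$highpass_cutoff_hz,
                         x$rate_hz)
  apply_design(x, des, spec$zero_phase)
}

#' Notch-filter an EMG channel at the mains frequency
#'
#' @inheritParams emg_highpass
#' @return Filtered `sampled_signal`.
#' @export
emg_notch <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "sampled_signal"))
  if (spec$notch_freq_hz >= x$rate_hz / 2)
    stop("notch frequency at or above Nyquist", call. = FALSE)
  des <- notch_design(spec$notch_freq_hz, x$rate_hz, spec$notch_q)
  apply_design(x, des, spec$zero_phase)
}

#' Preprocess all EMG channels of a recording
#'
#' Every EMG channel is replaced by `notch(highpass(channel))`; gyro channels
#' pass through untouched.
#'
#' @param rec A `recording`.
#' @param spec A [filter_spec()].
#' @return The preprocessed `recording`.
#' @export
preprocess_emg <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "recording"))
  rec$channels <- lapply(rec$channels, function(ch) {
    if (ch$meta$kind == "emg")
      ch$signal <- emg_notch(emg_highpass(ch$signal, spec), spec)
    ch
  })
  rec
}
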