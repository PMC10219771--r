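# Containers and I/O for multichannel EMG + gyroscope recordings.
#
# Time is implicit: sample i (1-based) of a channel occurs at
# t0_s + (i - 1) / rate_hz seconds from session start. Recordings are stored
# as wide CSV (one column per channel) plus a JSON descriptor that maps every
# column to (kind, muscle, side) and carries the sampling rate; channels with
# different rates live in separate CSV files referenced by one descriptor.

#' Construct a uniformly sampled signal
#'
#' The basic substrate of every computation in the package: one channel of
#' real-valued samples at a fixed rate, with an offset from session start.
#'
#' @param samples Numeric vector (mV for EMG, deg/s for gyroscope channels).
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param t0_s Time of the first sample relative to session start, seconds.
#' @param units Optional unit string ("mV", "deg/s").
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(samples, rate_hz, t0_s = 0, units = NA_character_) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0)
    stop("rate_hz must be a positive finite number", call. = FALSE)
  if (length(samples) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  if (anyNA(samples))
    stop("samples must not contain NA", call. = FALSE)
  structure(list(samples = samples, rate_hz = as.numeric(rate_hz),
                 t0_s = as.numeric(t0_s), units = units),
            class = "sampled_signal")
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Sample times of a signal
#' @param x A `sampled_signal`.
#' @return Numeric vector of times (s) of each sample.
#' @export
signal_times <- function(x) {
  x$t0_s + (seq_along(x$samples) - 1) / x$rate_hz
}

#' Duration of a signal in seconds
#' @param x A `sampled_signal`.
#' @return Length of the sampled interval, `n / rate_hz`.
#' @export
signal_duration <- function(x) length(x$samples) / x$rate_hz

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz, t0 = %g s (%.3f s)%s\n",
              length(x$samples), x$rate_hz, x$t0_s, signal_duration(x),
              if (is.na(x$units)) "" else paste0(" [", x$units, "]")))
  invisible(x)
}

#' Map a session time to the nearest sample index
#'
#' Nearest-sample rounding with ties broken toward the earlier sample; the
#' result is clamped to the valid index range. Used to project gyro-derived
#' cycle boundaries onto EMG sample indices; the projection error is at most
#' half a sample period.
#'
#' @param x A `sampled_signal`.
#' @param t Time(s) in seconds from session start.
#' @return 1-based integer sample index (vectorized over `t`).
#' @export
time_to_index <- function(x, t) {
  k <- (t - x$t0_s) * x$rate_hz
  idx <- ceiling(k - 0.5)              # nearest, ties toward earlier sample
  as.integer(pmin(pmax(idx, 0), length(x$samples) - 1L) + 1L)
}

#' Channel metadata
#'
#' @param name Channel (CSV column) name.
#' @param kind One of `"emg"`, `"gyro_x"`, `"gyro_y"`, `"gyro_z"`.
#' @param muscle One of [runcoord_muscles()] or `"none"` (gyro channels on
#'   the shank are conventionally tagged `tibialis_anterior`). EMG channels
#'   must name a muscle.
#' @param side `"left"` or `"right"`.
#' @return An object of class `channel_meta`.
#' @export
channel_meta <- function(name, kind, muscle = "none", side) {
  kind <- match.arg(kind, .kinds)
  side <- match.arg(side, .sides)
  muscle <- match.arg(muscle, c("none", runcoord_muscles()))
  if (kind == "emg" && muscle == "none")
    stop("EMG channels must name a muscle", call. = FALSE)
  structure(list(name = as.character(name), kind = kind, muscle = muscle,
                 side = side),
            class = "channel_meta")
}

meta_key <- function(meta) paste(meta$muscle, meta$side, meta$kind, sep = "/")

#' Assemble a multichannel recording
#'
#' @param channels List of `list(meta = channel_meta, signal = sampled_signal)`
#'   entries. The `(muscle, side, kind)` triple must be unique.
#' @param label Free-text identifier (athlete / load-stage id).
#' @param speed_kmh Optional treadmill speed in km/h.
#' @return An object of class `recording`.
#' @export
recording <- function(channels, label = "", speed_kmh = NULL) {
  stopifnot(is.list(channels), length(channels) > 0L)
  for (ch in channels) {
    if (!inherits(ch$meta, "channel_meta") ||
        !inherits(ch$signal, "sampled_signal"))
      stop("each channel needs a channel_meta and a sampled_signal",
           call. = FALSE)
  }
  keys <- vapply(channels, function(ch) meta_key(ch$meta), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (muscle, side, kind) channel: ",
         keys[duplicated(keys)][1], call. = FALSE)
  names(channels) <- vapply(channels, function(ch) ch$meta$name, character(1))
  structure(list(channels = channels, label = as.character(label),
                 speed_kmh = if (is.null(speed_kmh)) NULL
                             else as.numeric(speed_kmh)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> '%s'%s, %d channels\n", x$label,
              if (is.null(x$speed_kmh)) ""
              else sprintf(" @ %g km/h", x$speed_kmh),
              length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  %-24s %-7s %-22s %-5s %d @ %g Hz\n", ch$meta$name,
                ch$meta$kind, ch$meta$muscle, ch$meta$side,
                length(ch$signal$samples), ch$signal$rate_hz))
  invisible(x)
}

#' Extract channels from a recording
#'
#' @param rec A `recording`.
#' @param kind,muscle,side Optional filters; `NULL` matches everything.
#' @return A list of matching channel entries (possibly empty).
#' @export
get_channels <- function(rec, kind = NULL, muscle = NULL, side = NULL) {
  Filter(function(ch) {
    (is.null(kind) || ch$meta$kind %in% kind) &&
      (is.null(muscle) || ch$meta$muscle %in% muscle) &&
      (is.null(side) || ch$meta$side %in% side)
  }, rec$channels)
}

#' @rdname get_channels
#' @return `get_channel` returns exactly one channel entry or errors.
#' @export
get_channel <- function(rec, kind = NULL, muscle = NULL, side = NULL) {
  hits <- get_channels(rec, kind, muscle, side)
  if (length(hits) != 1L)
    stop(sprintf("expected exactly one channel for (%s, %s, %s), found %d",
                 muscle %||% "*", side %||% "*", kind %||% "*", length(hits)),
         call. = FALSE)
  hits[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structural check used by analysis entry points (not by the constructor, so
# that toy recordings remain expressible): a shank gyro channel per side and
# at least one EMG channel; optionally every listed muscle on both sides.
validate_recording <- function(rec, muscles = NULL) {
  for (s in .sides) {
    g <- get_channels(rec, kind = c("gyro_x", "gyro_y", "gyro_z"),
                      muscle = "tibialis_anterior", side = s)
    if (length(g) == 0L)
      stop("recording lacks a tibialis-anterior gyro channel on side ", s,
           call. = FALSE)
  }
  if (length(get_channels(rec, kind = "emg")) == 0L)
    stop("recording has no EMG channels", call. = FALSE)
  for (m in muscles %||% character(0)) for (s in .sides) {
    if (length(get_channels(rec, kind = "emg", muscle = m, side = s)) == 0L)
      stop("muscle missing on side ", s, ": ", m, call. = FALSE)
  }
  invisible(rec)
}

# ---------------------------------------------------------------------------
# CSV + JSON descriptor round trip

group_key <- function(ch) sprintf("r%g_t%g", ch$signal$rate_hz, ch$signal$t0_s)

#' Write a recording to CSV file(s) plus a JSON descriptor
#'
#' Channels sharing a rate and start offset are written as columns of one wide
#' CSV (no timestamp column: time is implicit from the rate). Channels with
#' other rates go to sibling files whose names carry a rate suffix. The
#' descriptor lists every file with its rate, offset and column metadata.
#'
#' @param rec A `recording`.
#' @param csv_path Path of the (primary) CSV file.
#' @param descriptor_path Path of the JSON descriptor.
#' @return Invisibly, the vector of CSV paths written.
#' @export
write_recording <- function(rec, csv_path, descriptor_path) {
  keys <- vapply(rec$channels, group_key, character(1))
  groups <- split(rec$channels, factor(keys, levels = unique(keys)))
  stem <- sub("\\.csv$", "", csv_path)
  paths <- if (length(groups) == 1L) csv_path else
    vapply(seq_along(groups), function(g) {
      rate <- groups[[g]][[1]]$signal$rate_hz
      sprintf("%s_%ghz_%d.csv", stem, rate, g)
    }, character(1))
  files <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    chans <- groups[[g]]
    df <- as.data.frame(lapply(chans, function(ch) ch$signal$samples),
                        check.names = FALSE, optional = TRUE)
    names(df) <- vapply(chans, function(ch) ch$meta$name, character(1))
    ok <- tryCatch({
      write.csv(df, paths[g], row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("cannot write CSV '", paths[g], "': ", conditionMessage(ok),
           call. = FALSE)
    files[[g]] <- list(
      path = basename(paths[g]),
      rate_hz = chans[[1]]$signal$rate_hz,
      t0_s = chans[[1]]$signal$t0_s,
      columns = lapply(chans, function(ch)
        list(name = ch$meta$name, kind = ch$meta$kind,
             muscle = ch$meta$muscle, side = ch$meta$side)))
    names(files[[g]]$columns) <- NULL
  }
  desc <- list(label = rec$label, speed_kmh = rec$speed_kmh, files = files)
  jsonlite::write_json(desc, descriptor_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

#' Read a recording from CSV file(s) plus a JSON descriptor
#'
#' @param csv_path Path of the primary CSV file, or a directory holding the
#'   files named in the descriptor; `NULL` resolves file names relative to the
#'   descriptor's directory.
#' @param descriptor_path Path of the JSON descriptor.
#' @return A `recording`.
#' @export
read_recording <- function(csv_path = NULL, descriptor_path) {
  if (!file.exists(descriptor_path))
    stop("descriptor not found: ", descriptor_path, call. = FALSE)
  desc <- jsonlite::fromJSON(descriptor_path, simplifyVector = FALSE)
  if (is.null(desc$files) || length(desc$files) == 0L)
    stop("descriptor lists no files", call. = FALSE)
  base_dir <- if (!is.null(csv_path) && dir.exists(csv_path)) csv_path
              else dirname(descriptor_path)
  channels <- list()
  durations <- numeric(0)
  rates <- numeric(0)
  for (f in desc$files) {
    path <- if (length(desc$files) == 1L && !is.null(csv_path) &&
                !dir.exists(csv_path)) csv_path
            else file.path(base_dir, f$path)
    if (!file.exists(path))
      stop("CSV file not found: ", path, call. = FALSE)
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    for (col in f$columns) {
      if (!col$name %in% names(df))
        stop("descriptor/CSV mismatch: column '", col$name,
             "' absent from ", basename(path), call. = FALSE)
      raw <- df[[col$name]]
      vals <- suppressWarnings(as.numeric(raw))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1]
        stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                     col$name, bad, raw[bad]), call. = FALSE)
      }
      meta <- channel_meta(col$name, col$kind, col$muscle %||% "none",
                           col$side)
      sig <- sampled_signal(vals, f$rate_hz, f$t0_s %||% 0,
                            units = if (col$kind == "emg") "mV" else "deg/s")
      channels[[length(channels) + 1L]] <- list(meta = meta, signal = sig)
      durations <- c(durations, signal_duration(sig))
      rates <- c(rates, f$rate_hz)
    }
  }
  med <- stats::median(durations)
  off <- abs(durations - med)
  if (any(off > 1 / rates + 1e-9))
    stop(sprintf(paste0("channel durations inconsistent with a common session",
                        " duration (max deviation %.4f s > 1 sample)"),
                 max(off)), call. = FALSE)
  recording(channels, label = desc$label %||% "",
            speed_kmh = desc$speed_kmh)
}

#' Trim all channels to their common time interval
#'
#' Computes the maximal interval covered by every channel and drops samples
#' outside it. Channels already sharing a start and end (within one sample of
#' the coarsest channel — sub-sample offsets are unobservable at that rate)
#' are returned unchanged, which makes the operation idempotent.
#'
#' @param rec A `recording`.
#' @return The trimmed `recording`.
#' @export
align_timebases <- function(rec) {
  t0 <- vapply(rec$channels, function(ch) ch$signal$t0_s, numeric(1))
  ends <- vapply(rec$channels,
                 function(ch) ch$signal$t0_s + signal_duration(ch$signal),
                 numeric(1))
  rates <- vapply(rec$channels, function(ch) ch$signal$rate_hz, numeric(1))
  S <- max(t0); E <- min(ends)
  if (E <= S + 1e-12)
    stop("channels have no common time interval", call. = FALSE)
  coarse <- 1 / min(rates)
  if (max(t0) - min(t0) <= coarse + 1e-12 &&
      max(ends) - min(ends) <= coarse + 1e-12)
    return(rec)
  rec$channels <- lapply(rec$channels, function(ch) {
    sig <- ch$signal
    i0 <- max(0L, as.integer(ceiling((S - sig$t0_s) * sig$rate_hz - 1e-9)))
    n_keep <- as.integer(floor((E - sig$t0_s) * sig$rate_hz + 1e-9)) - i0
    if (n_keep < 1L)
      stop("channel '", ch$meta$name, "' empty after alignment",
           call. = FALSE)
    ch$signal <- sampled_signal(sig$samples[(i0 + 1):(i0 + n_keep)],
                                sig$rate_hz, sig$t0_s + i0 / sig$rate_hz,
                                sig$units)
    ch
  })
  rec
}
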