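# Study-style aggregation and the final per-recording coordination report.
#
# Two SD conventions deliberately coexist: within-athlete cycle-to-cycle
# spreads (stability module) use the population form (denominator N), while
# across-athlete summaries here use the sample form (denominator n - 1),
# which is what reproduces published "mean +/- SD" rows.

round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Mean and sample standard deviation of a set of values
#'
#' @param values Numeric vector, length >= 2.
#' @return List with unrounded `mean` and `sd` (denominator n - 1), their
#'   2-decimal display versions (`mean_display`, `sd_display`, rounded half
#'   away from zero) and `n`.
#' @export
summarise_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s, n = length(values),
       mean_display = round_half_away(m, 2), sd_display = round_half_away(s, 2))
}

#' Bundled reference tables from a published 13-runner treadmill study
#'
#' Per-athlete published index values shipped with the package:
#' `reference_kemg_table()` returns the integral stability coefficient
#' K_EMG (%) of 13 professional runners at five incremental load stages
#' (8-12 km/h); `reference_alpha_table()` returns their left/right symmetry
#' coefficient alpha (%, mean and SD over the load stages) with a training
#' experience bracket.
#'
#' @return A data.frame.
#' @export
reference_kemg_table <- function() {
  read.csv(system.file("extdata", "runner_kemg_stages.csv",
                       package = "runcoord"), check.names = FALSE)
}

#' @rdname reference_kemg_table
#' @export
reference_alpha_table <- function() {
  read.csv(system.file("extdata", "runner_alpha.csv", package = "runcoord"),
           check.names = FALSE)
}

#' Merge stability and symmetry results into one coordination report
#'
#' @param stab A `stability_report`, or a list of them (e.g. one per leg);
#'   `K_EMG_pct` is then the mean over legs (`pool_sides = "average"`).
#' @param sym A `symmetry_report`, or `NULL` for a partial report (the
#'   symmetry block is then flagged `null`).
#' @param meta List of metadata: `label`, `speed_kmh`, `n_cycles`, `seed`
#'   (for synthetic sessions), free-form `config` echo.
#' @return An object of class `coordination_report` (a list ready for JSON
#'   serialization).
#' @export
coordination_report <- function(stab, sym = NULL, meta = list()) {
  stabs <- if (inherits(stab, "stability_report")) list(stab) else stab
  for (s in stabs) stopifnot(inherits(s, "stability_report"))
  labels <- c(vapply(stabs, function(s) attr(s, "label") %||% NA_character_,
                     character(1)),
              if (!is.null(sym)) attr(sym, "label") %||% NA_character_)
  labels <- labels[!is.na(labels)]
  if (length(unique(labels)) > 1L)
    stop("consistency error: reports come from different recordings: ",
         paste(unique(labels), collapse = " vs "), call. = FALSE)
  k <- mean(vapply(stabs, function(s) s$K_EMG_pct, numeric(1)))
  per_side <- lapply(stabs, function(s)
    list(side = s$side, K_EMG_pct = s$K_EMG_pct, n_cycles = s$n_cycles,
         M = s$M, F = s$F, n_excluded = s$n_excluded,
         per_phase = s$per_phase))
  rep <- list(
    label = meta$label %||% (if (length(labels)) labels[1] else ""),
    speed_kmh = meta$speed_kmh,
    n_cycles = meta$n_cycles %||% stabs[[1]]$n_cycles,
    K_EMG_pct = k,
    alpha_pct = if (is.null(sym)) NULL else sym$alpha_pct,
    symmetry = if (is.null(sym)) NULL
               else list(per_muscle = as.list(sym$per_muscle),
                         alpha_pct = sym$alpha_pct),
    stability = per_side,
    config = meta$config,
    seed = meta$seed,
    software = paste0("runcoord ", as.character(packageVersion("runcoord"))))
  structure(rep, class = "coordination_report")
}

#' @export
print.coordination_report <- function(x, ...) {
  cat(sprintf("<coordination_report> '%s'%s\n", x$label,
              if (is.null(x$speed_kmh)) ""
              else sprintf(" @ %g km/h", x$speed_kmh)))
  cat(sprintf("  K_EMG = %.2f %%\n", x$K_EMG_pct))
  if (is.null(x$alpha_pct)) cat("  alpha = (no symmetry analysis)\n")
  else cat(sprintf("  alpha = %.2f %%\n", x$alpha_pct))
  invisible(x)
}

#' Validate, write and read coordination reports
#'
#' `validate_report()` checks the report against the schema shipped in
#' `inst/extdata/report-schema.json`: required fields, types, and that both
#' indices lie in `[0, 100]`. A missing symmetry block must be explicitly
#' `null`.
#'
#' @param x A `coordination_report` or a list parsed from report JSON.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_report <- function(x) {
  need <- c("label", "n_cycles", "K_EMG_pct", "stability", "software")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("report missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(x$K_EMG_pct) || x$K_EMG_pct < 0 || x$K_EMG_pct > 100)
    stop("K_EMG_pct out of [0, 100]", call. = FALSE)
  if (!is.null(x$alpha_pct) &&
      (!is.numeric(x$alpha_pct) || x$alpha_pct < 0 || x$alpha_pct > 100))
    stop("alpha_pct out of [0, 100]", call. = FALSE)
  if (!is.null(x$symmetry)) {
    if (!all(c("per_muscle", "alpha_pct") %in% names(x$symmetry)))
      stop("symmetry block malformed", call. = FALSE)
    vals <- unlist(x$symmetry$per_muscle)
    if (any(vals < 0 | vals > 100))
      stop("per-muscle symmetry out of [0, 100]", call. = FALSE)
  }
  if (length(x$stability) == 0L)
    stop("stability block empty", call. = FALSE)
  invisible(TRUE)
}

#' @rdname validate_report
#' @param path File path for the report JSON.
#' @export
write_report <- function(x, path) {
  validate_report(x)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname validate_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_report(x)
  structure(x, class = "coordination_report")
}

#' End-to-end coordination analysis of one recording
#'
#' Aligns the channels, segments each leg's running cycles from its shank
#' gyro channel, preprocesses the EMG channels, and computes the stability
#' report for each leg and the left/right symmetry report.
#'
#' @param rec A `recording` with a tibialis-anterior gyro channel per side
#'   and every analyzed muscle on both sides.
#' @param spec A [filter_spec()].
#' @param muscles Muscles to analyze.
#' @param n_cycles Cycles per leg (default 20).
#' @param points_per_cycle Envelope grid density for the symmetry analysis.
#' @param pool_sides How to combine the two legs' K_EMG: `"average"`
#'   (default), `"left"` or `"right"`.
#' @param seed Optional seed echoed into the report (synthetic sessions).
#' @return A validated `coordination_report`.
#' @export
analyze_recording <- function(rec, spec = filter_spec(),
                              muscles = runcoord_muscles(), n_cycles = 20L,
                              points_per_cycle = 200L,
                              pool_sides = c("average", "left", "right"),
                              seed = NULL) {
  pool_sides <- match.arg(pool_sides)
  validate_recording(rec, muscles)
  rec <- align_timebases(rec)
  seg_l <- segment_gait(rec, "left", n_cycles = n_cycles)
  seg_r <- segment_gait(rec, "right", n_cycles = n_cycles)
  pre <- preprocess_emg(rec, spec)
  stab_l <- assess_stability(pre, seg_l$partition, muscles, n_cycles)
  stab_r <- assess_stability(pre, seg_r$partition, muscles, n_cycles)
  attr(stab_l, "label") <- rec$label
  attr(stab_r, "label") <- rec$label
  sym <- symmetry_coefficient(pre, seg_l$partition, seg_r$partition, muscles,
                              points_per_cycle)
  attr(sym, "label") <- rec$label
  stabs <- switch(pool_sides, average = list(stab_l, stab_r),
                  left = list(stab_l), right = list(stab_r))
  rep <- coordination_report(stabs, sym,
                             meta = list(label = rec$label,
                                         speed_kmh = rec$speed_kmh,
                                         n_cycles = n_cycles,
                                         seed = seed,
                                         config = list(
                                           highpass_cutoff_hz = spec$highpass_cutoff_hz,
                                           highpass_order = spec$highpass_order,
                                           notch_freq_hz = spec$notch_freq_hz,
                                           notch_q = spec$notch_q,
                                           zero_phase = spec$zero_phase,
                                           points_per_cycle = points_per_cycle,
                                           pool_sides = pool_sides,
                                           muscles = muscles)))
  validate_report(rep)
  rep
}

#' Summarize a set of coordination reports per load stage
#'
#' @param paths Character vector of report JSON paths, or a directory
#'   containing `*.json` reports.
#' @param index Which index to summarize: `"K_EMG_pct"` or `"alpha_pct"`.
#' @return data.frame with columns `stage` (km/h), `n`, `mean`, `sd`
#'   (2-decimal display rounding).
#' @export
summarize_reports <- function(paths, index = c("K_EMG_pct", "alpha_pct")) {
  index <- match.arg(index)
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.json$", full.names = TRUE)
  reps <- lapply(paths, read_report)
  stage <- vapply(reps, function(r) as.numeric(r$speed_kmh %||% NA_real_),
                  numeric(1))
  val <- vapply(reps, function(r) as.numeric(r[[index]] %||% NA_real_),
                numeric(1))
  out <- do.call(rbind, lapply(split(val, stage), function(v) {
    s <- summarise_values(v)
    data.frame(n = s$n, mean = s$mean_display, sd = s$sd_display)
  }))
  data.frame(stage = as.numeric(rownames(out)), out, row.names = NULL)
}
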