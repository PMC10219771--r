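test_that("moving_average matches direct evaluation and the naive oracle", {
  expect_equal(moving_average(sampled_signal(c(5, 5, 5, 5), 100), 3)$samples,
               c(5, 5))
  expect_equal(moving_average(sampled_signal(1:5, 100), 2)$samples,
               c(1.5, 2.5, 3.5, 4.5))
  set.seed(11)
  x <- rnorm(500)
  expect_equal(moving_average(sampled_signal(x, 100), 7)$samples,
               naive_moving_average(x, 7))
  expect_error(moving_average(sampled_signal(1:3, 100), 5), "window")
})

test_that("moving_average is delay-compensated", {
  # centre of mass of a symmetric bump must not move
  t <- (0:999) / 100
  x <- sampled_signal(exp(-(t - 5)^2), 100)
  y <- moving_average(x, 9)
  peak_t <- signal_times(y)[which.max(y$samples)]
  expect_lt(abs(peak_t - 5), 1.5 / 100)
  expect_equal(y$t0_s, x$t0_s + 4 / 100)
})

test_that("estimate_period finds the autocorrelation peak", {
  t <- (0:(148 * 8 - 1)) / 148
  sine <- sampled_signal(sin(2 * pi * t / 1.0), 148)
  expect_lt(abs(estimate_period(sine, 0.5, 2.0) - 1.0), 1 / 148 + 1e-9)

  # bump train with known period and additive noise (SNR ~ 10 dB)
  cfg <- simulation_config(cadence_hz = 1 / 0.78, duration_s = 20, seed = 5,
                           gyro_noise_sd = 60)
  g <- simulate_gyro(cfg, "left")
  expect_lt(abs(estimate_period(g) - 0.78), 2 / 148 + 1e-9)

  expect_error(estimate_period(sampled_signal(rep(2, 1000), 148)),
               "period")
  expect_error(estimate_period(sine, 0.5, 3.0), "signal too short")
})

test_that("detect_swing_peaks finds bump centres and respects separation", {
  cfg <- simulation_config(duration_s = 17, seed = 3)
  gt <- draw_ground_truth(cfg)
  g <- simulate_gyro(cfg, "left", gt)
  p <- estimate_period(g)
  w <- runcoord:::filter_window_for_period(p, g$rate_hz)
  gf <- moving_average(g, w)
  peaks <- detect_swing_peaks(gf, p)
  truth <- gt$sides$left$swing_peaks
  detected_t <- signal_times(gf)[peaks]
  matched <- detected_t[detected_t > min(truth) - 0.1 &
                        detected_t < max(truth) + 0.1]
  expect_equal(length(matched), length(truth))
  err <- vapply(matched, function(tt) min(abs(tt - truth)), numeric(1))
  expect_true(all(err <= 2 / g$rate_hz + 1e-9))

  # sinusoid of 5 full periods -> 5 peaks at quarter-period offsets
  t <- (0:(100 * 5 - 1)) / 100
  s <- sampled_signal(sin(2 * pi * t), 100)
  pk <- detect_swing_peaks(s, 1.0)
  expect_length(pk, 5)
  expect_equal((pk - 1) / 100, 0.25 + 0:4, tolerance = 0.02)

  # two candidates 0.1 period apart: only the higher survives
  t2 <- (0:499) / 100
  v <- exp(-(t2 - 0.5)^2 / 5e-4) + 0.8 * exp(-(t2 - 0.55)^2 / 5e-4) +
       exp(-(t2 - 3.0)^2 / 5e-4)
  pk2 <- detect_swing_peaks(sampled_signal(v, 100), 0.5)
  expect_equal(pk2, c(51L, 301L))
})

test_that("detect_cycle_events locates flanking minima, earliest on ties", {
  # trapezoidal troughs with a 3-sample plateau spanning the midpoint
  n <- 400
  v <- rep(1, n)
  peaks <- c(51L, 151L, 251L, 351L)
  for (p in peaks) v[p] <- 2
  for (tr in c(100L, 200L, 300L)) v[(tr - 1):(tr + 1)] <- -1
  ev <- detect_cycle_events(sampled_signal(v, 100), peaks)
  # heel-strike search covers the plateau from its left edge (tie -> 99);
  # the toe-off search window starts at the interval midpoint (101)
  expect_equal(ev$heel_strikes, c(99L, 199L, 299L))
  expect_equal(ev$toe_offs, c(101L, 201L, 301L))
  # invariant: one heel strike then one toe-off between consecutive peaks
  expect_true(all(ev$heel_strikes > peaks[-length(peaks)] &
                  ev$toe_offs < peaks[-1] &
                  ev$heel_strikes < ev$toe_offs))
})

test_that("detected events match simulator ground truth within 3 samples", {
  cfg <- fast_cfg(seed = 21)
  ses <- simulate_session(cfg)
  for (side in c("left", "right")) {
    seg <- segment_gait(ses$recording, side)
    ev <- seg$events
    truth <- ses$ground_truth$sides[[side]]
    tt <- function(idx) ev$t0_s + (idx - 1) / ev$rate_hz
    err_hs <- vapply(tt(ev$heel_strikes),
                     function(x) min(abs(x - truth$heel_strikes)), numeric(1))
    err_to <- vapply(tt(ev$toe_offs),
                     function(x) min(abs(x - truth$toe_offs)), numeric(1))
    expect_lt(stats::quantile(err_hs, 0.95), 3 / 148)
    expect_lt(stats::quantile(err_to, 0.95), 3 / 148)
  }
})

test_that("cycle boundaries track ground truth across seeds", {
  # scaled-down version of the 50-seed invariant: >= 95% of matched
  # boundaries within 3 gyro samples, checked over 8 seeds
  errs <- unlist(lapply(1:8, function(s) {
    cfg <- simulation_config(duration_s = 15, seed = 200 + s)
    gt <- draw_ground_truth(cfg)
    g <- simulate_gyro(cfg, "left", gt)
    p <- estimate_period(g)
    gf <- moving_average(g, runcoord:::filter_window_for_period(p, g$rate_hz))
    ev <- detect_cycle_events(gf, detect_swing_peaks(gf, p))
    bt <- gf$t0_s + (c(ev$heel_strikes, ev$toe_offs) - 1) / gf$rate_hz
    truth <- c(gt$sides$left$heel_strikes, gt$sides$left$toe_offs)
    vapply(bt, function(x) min(abs(x - truth)), numeric(1)) * gf$rate_hz
  }))
  expect_gte(mean(errs <= 3), 0.95)
})

test_that("partition_cycles counts cycles and phases correctly", {
  # 21 evenly spaced swing peaks -> 20 cycles, 40 phases
  peaks <- as.integer(seq(10, 10 + 20 * 100, by = 100))
  hs <- peaks[-21] + 30L
  to <- peaks[-1] - 30L
  ev <- structure(list(swing_peaks = peaks, heel_strikes = hs, toe_offs = to,
                       rate_hz = 100, t0_s = 0),
                  class = "gait_events")
  part <- partition_cycles(ev, n_cycles = 20)
  expect_equal(nrow(part$cycles), 20)
  expect_equal(nrow(part$phases), 40)
  # phases tile each cycle
  for (i in part$cycles$i) {
    ph <- part$phases[part$phases$i == i, ]
    expect_equal(ph$start_s[2], ph$end_s[1])
    expect_equal(ph$start_s[1], part$cycles$start_s[i])
    expect_equal(ph$end_s[2], part$cycles$end_s[i])
  }
  expect_error(partition_cycles(ev, n_cycles = 25), "insufficient")

  ev5 <- structure(list(swing_peaks = peaks[1:5], heel_strikes = hs[1:4],
                        toe_offs = to[1:4], rate_hz = 100, t0_s = 0),
                   class = "gait_events")
  expect_error(partition_cycles(ev5, n_cycles = 20), "insufficient")
})

test_that("simulated stance fraction is recovered", {
  ses <- simulate_session(fast_cfg(seed = 9))
  part <- segment_gait(ses$recording, "left")$partition
  st <- part$phases[part$phases$name == "stance", ]
  frac <- (st$end_s - st$start_s) /
    (part$cycles$end_s - part$cycles$start_s)
  expect_equal(mean(frac), 0.40, tolerance = 0.03 / 0.40)
})

test_that("gait outputs are shift- and scale-invariant", {
  cfg <- fast_cfg(seed = 13)
  g <- simulate_gyro(cfg, "left")
  run <- function(x) {
    p <- estimate_period(x)
    xf <- moving_average(x, runcoord:::filter_window_for_period(p, x$rate_hz))
    ev <- detect_cycle_events(xf, detect_swing_peaks(xf, p))
    list(p = p, ev = ev)
  }
  base <- run(g)

  shifted <- sampled_signal(g$samples, g$rate_hz, g$t0_s + 2.5)
  sh <- run(shifted)
  expect_equal(sh$p, base$p)
  expect_equal(sh$ev$swing_peaks, base$ev$swing_peaks)  # same indices
  expect_equal(sh$ev$t0_s - base$ev$t0_s, 2.5)          # events shift in time

  scaled <- sampled_signal(7.3 * g$samples, g$rate_hz, g$t0_s)
  sc <- run(scaled)
  expect_equal(sc$p, base$p)
  expect_identical(sc$ev$swing_peaks, base$ev$swing_peaks)
  expect_identical(sc$ev$heel_strikes, base$ev$heel_strikes)
  expect_identical(sc$ev$toe_offs, base$ev$toe_offs)
})

test_that("cycle partitions serialize to JSON and back", {
  ses <- simulate_session(fast_cfg(seed = 2))
  part <- segment_gait(ses$recording, "right")$partition
  f <- withr::local_tempfile(fileext = ".json")
  write_partition(part, f)
  back <- read_partition(f)
  expect_equal(back$side, part$side)
  expect_equal(back$cycles, part$cycles)
  expect_equal(back$phases, part$phases)
})
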