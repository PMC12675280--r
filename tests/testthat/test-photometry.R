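test_that("demultiplexing recovers constant and stepped channel values", {
  sch <- pulse_schedule()

  # constant stream -> every channel constant at that value
  stream <- tibble::tibble(time_s = (0:(150 * 4 - 1)) / 1000, value = 7)
  traces <- demultiplex(stream, sch)
  expect_named(traces, c("465", "560", "405"))
  for (tr in traces) expect_true(all(tr$value == 7))

  # per-channel step functions are recovered exactly (noise-free)
  levels <- list(`465` = c(1, 2, 3, 4), `560` = c(5, 5, 6, 6),
                 `405` = c(0.5, 0.5, 0.5, 0.5))
  traces <- demultiplex(make_step_stream(levels, sch, n_frames = 4), sch)
  for (ch in names(levels)) {
    expect_equal(traces[[ch]]$value, levels[[ch]])
  }

  # per-channel sampling: one sample per pulse window, channels rotate,
  # so each channel is revisited every n_channels / cycle_rate seconds
  expect_equal(diff(traces$`465`$time_s),
               rep(sch$n_channels / sch$cycle_rate_hz, 3))
})

test_that("pulse averaging drops the first and last 2 samples", {
  # single-channel schedule, one 24-sample pulse carrying 0..23:
  # retained samples are 2..21 whose mean is 11.5
  sch <- pulse_schedule(channel_order = "465")
  stream <- tibble::tibble(time_s = (0:49) / 1000,
                           value = c(0:23, rep(0, 26)))
  tr <- demultiplex(stream, sch)$`465`
  expect_equal(tr$value, mean(2:21))
  expect_equal(tr$value, 11.5)
})

test_that("demultiplex rejects short streams and partial cycles", {
  sch <- pulse_schedule()
  expect_error(demultiplex(tibble::tibble(time_s = (0:9) / 1000,
                                          value = 0), sch),
               "shorter than one pulse cycle")
  expect_warning(
    demultiplex(tibble::tibble(time_s = (0:309) / 1000, value = 1), sch),
    "partial cycle"
  )
})

test_that("moving-average smoothing matches hand-computed references", {
  tr <- make_trace(c(0, 0, 3, 0, 0), provenance = "raw")
  expect_equal(smooth_trace(tr, 1)$value, tr$value)     # identity
  expect_equal(smooth_trace(tr, 3)$value, c(0, 1, 1, 1, 0))

  # interior-supported impulse: energy conserved by the shrinking-edge rule
  imp <- make_trace(c(0, 0, 0, 0, 5, 0, 0, 0, 0), provenance = "raw")
  expect_equal(sum(smooth_trace(imp, 3)$value), 5)
  expect_equal(sum(smooth_trace(imp, 5)$value), 5)

  expect_error(smooth_trace(tr, 2), "odd")
  expect_error(smooth_trace(tr, 0), "odd")
})

test_that("bleach correction flattens linear drift and preserves bumps", {
  t <- (0:999) / 20

  flat <- make_trace(rep(7, 1000), provenance = "smoothed")
  corr <- detrend_bleach(flat)
  expect_equal(corr$value, rep(1, 1000))
  expect_equal(attr(corr, "slope"), 0)
  expect_equal(attr(corr, "intercept"), 7)

  drift <- make_trace(10 - 0.01 * t, provenance = "smoothed")
  corr <- detrend_bleach(drift)
  expect_lt(max(abs(corr$value - 1)), 1e-9)
  expect_equal(attr(corr, "slope"), -0.01, tolerance = 1e-9)

  # multiplicative bump on a drifting baseline is recovered within 2 %
  # (the bump must be brief relative to the recording or the line fit
  # absorbs it)
  t <- (0:3999) / 20
  bump <- 0.2 * exp(-(t - 25)^2 / 8)
  tr <- make_trace((10 - 0.01 * t) * (1 + bump), provenance = "smoothed")
  corr <- detrend_bleach(tr)
  expect_lt(max(abs(corr$value - (1 + bump))), 0.02)

  # fitted line crossing zero flags an unusable recording
  dying <- make_trace(1 - 0.05 * t, provenance = "smoothed")
  expect_error(detrend_bleach(dying), "not strictly positive")
  expect_error(detrend_bleach(make_trace(c(1, 2), provenance = "smoothed")),
               "at least 3")
})

test_that("dF/F is the +1 ratio minus the baseline mean", {
  # identical channels: ratio 1 everywhere, dff 0
  s <- make_trace(rep(1.05, 100))
  d <- compute_dff(s, s, baseline_window_s = c(0, 2))
  expect_equal(d$dff, rep(0, 100))
  expect_equal(attr(d, "baseline_value"), 1)

  # hand example: signal 1.2, reference 1.0 against a unity baseline
  # gives 2.2/2.0 - 1.0 = 0.1
  sig <- make_trace(c(rep(1, 50), rep(1.2, 50)))
  ref <- make_trace(rep(1, 100), channel = "405")
  d <- compute_dff(sig, ref, baseline_window_s = c(0, 2))
  expect_equal(attr(d, "baseline_value"), 1)
  expect_equal(d$dff[100], 0.1)

  # contract checks
  expect_error(compute_dff(make_trace(1:10, provenance = "raw"), ref, c(0, 1)),
               "detrended")
  expect_error(compute_dff(sig, make_trace(rep(1, 50), channel = "405"),
                           c(0, 1)), "mismatched lengths")
  expect_error(compute_dff(sig, ref, c(90, 99)), "no samples")
  bad_ref <- make_trace(rep(-1, 100), channel = "405")
  expect_error(compute_dff(sig, bad_ref, c(0, 2)), "-1")
})

test_that("transient metrics match closed-form oracles", {
  fs <- 20

  zero <- make_dff(rep(0, 200), fs)
  m <- transient_metrics(zero, c(0, 9.9))
  expect_equal(m$peak_dff, 0)
  expect_equal(m$auc, 0)
  expect_true(is.na(m$half_decay_s))

  # unit-height rectangular pulse lasting 30 s: trapezoid AUC = 30 up to
  # the two half-sample edge triangles
  t <- seq(0, 100, by = 1 / fs)
  rect <- make_dff(as.numeric(t >= 10 & t < 40), fs)
  m <- transient_metrics(rect, c(0, 100))
  expect_equal(m$auc, 30, tolerance = 1 / fs)

  # mono-exponential decay: half-decay = tau * ln 2 within one sample
  tau <- 100
  y <- exp(-t / tau)
  m <- transient_metrics(make_dff(y, fs), c(0, 100))
  expect_equal(m$peak_dff, 1)
  expect_equal(m$half_decay_s, tau * log(2), tolerance = 1 / fs)

  # AUC is additive over adjacent windows and linear in amplitude
  y2 <- 0.3 * sin(t / 7) + 0.1
  d2 <- make_dff(y2, fs)
  a_full <- transient_metrics(d2, c(0, 100))$auc
  a_left <- transient_metrics(d2, c(0, 50))$auc
  a_right <- transient_metrics(d2, c(50, 100))$auc
  expect_equal(a_left + a_right, a_full, tolerance = 1e-12)
  d3 <- make_dff(3 * y2, fs)
  expect_equal(transient_metrics(d3, c(0, 100))$auc, 3 * a_full,
               tolerance = 1e-12)

  expect_error(transient_metrics(d2, c(200, 300)), "no samples")
})

test_that("band-pass filter rejects DC, passes 0.01 Hz, stops 9 Hz", {
  fs <- 20

  const <- make_dff(rep(3, 2000), fs)
  out <- bandpass_filter(const)
  expect_lt(max(abs(out$dff)), 3 * 1e-3)

  gain_at <- function(freq, dur) {
    t <- seq(0, dur, by = 1 / fs)
    x <- sin(2 * pi * freq * t)
    y <- bandpass_filter(make_dff(x, fs))$dff
    core <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
    sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  }
  expect_gte(gain_at(0.01, 1200), 0.9)
  expect_lte(gain_at(9, 120), 0.1)

  expect_error(bandpass_filter(const, low_hz = 0), "Band edges")
  expect_error(bandpass_filter(const, low_hz = 0.5, high_hz = 15),
               "Band edges")
})

test_that("event detection thresholds at baseline mean + k x SD", {
  fs <- 20
  # alternating +-1 baseline supplies SD = 1 (approximately), then a
  # square bump of amplitude 6 exceeds the 4 x SD threshold exactly once
  base <- rep(c(1, -1), 30 * fs / 2)           # 30 s of +-1
  bump <- c(rep(0, 5 * fs), rep(6, 2 * fs), rep(0, 3 * fs))
  y <- c(base, bump)
  d <- make_dff(y, fs)
  prm <- event_params(quiescent_windows_s = list(c(0, 30 - 1 / fs)))
  ev <- detect_events(d, prm)
  base_sd <- attr(ev, "baseline_sd")
  expect_equal(attr(ev, "baseline_mean"), 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 6)
  expect_gt(ev$amplitude, 4 * base_sd)

  # sub-threshold trace: no events (threshold ~4, bump of 2 stays below)
  y2 <- c(base, 0.5 * bump)
  ev2 <- detect_events(make_dff(y2, fs), prm)
  expect_equal(nrow(ev2), 0)
  expect_equal(event_stats(ev2)$frequency_per_min, 0)

  # nearby runs merge into one event; distant runs stay separate
  gap_short <- c(rep(6, 5), rep(0, 4), rep(6, 5))        # 0.2 s gap
  gap_long <- c(rep(6, 5), rep(0, 30), rep(6, 5))        # 1.5 s gap
  ev3 <- detect_events(make_dff(c(base, 0, gap_short), fs), prm)
  expect_equal(nrow(ev3), 1)
  ev4 <- detect_events(make_dff(c(base, 0, gap_long), fs), prm)
  expect_equal(nrow(ev4), 2)

  # contract: quiescent coverage must reach 20 s, SD must be nonzero
  expect_error(
    detect_events(d, event_params(quiescent_windows_s = list(c(0, 10)))),
    "20 s"
  )
  flat <- make_dff(c(rep(0, 30 * fs), bump), fs)
  expect_error(detect_events(flat, prm), "SD is zero")
})

test_that("event statistics are plain arithmetic on the train", {
  tr <- tibble::tibble(start_s = c(1, 50, 99), end_s = c(2, 51, 100),
                       peak_time_s = c(1.5, 50.5, 99.5),
                       amplitude = c(0.5, 0.9, 0.4))
  s <- event_stats(tr, duration_s = 120)
  expect_equal(s$mean_amplitude, 0.6)
  s6 <- event_stats(dplyr::bind_rows(tr, tr), duration_s = 120)
  expect_equal(s6$frequency_per_min, 3)   # 6 events in 120 s
  expect_error(event_stats(tr, duration_s = 0), "positive")
})

test_that("full chain cancels a shared multiplicative motion artefact", {
  # null recording: no transients, no noise, only motion + bleach shared
  # between 465 and 405 -> dF/F must stay within 0.01
  cfg <- photometry_config(duration_s = 120, motion_artifact_sd = 0.2,
                           bleach_slope_per_s = -5e-4, seed = 11)
  sim <- simulate_photometry(cfg)
  traces <- demultiplex(sim$stream, sim$schedule)
  prep <- function(ch) detrend_bleach(smooth_trace(traces[[ch]], 5))
  d <- compute_dff(prep("465"), prep("405"), baseline_window_s = c(0, 30))
  expect_lt(max(abs(d$dff)), 0.01)
})

test_that("the chain is deterministic: same stream, identical metrics", {
  cfg <- photometry_config(
    duration_s = 60,
    transients = list(`465` = tibble::tibble(onset_s = 20, amplitude = 0.3,
                                             tau_s = 10)),
    motion_artifact_sd = 0.05, noise_sd = 0.01, seed = 4
  )
  run <- function() {
    sim <- simulate_photometry(cfg)
    traces <- demultiplex(sim$stream, sim$schedule)
    prep <- function(ch) detrend_bleach(smooth_trace(traces[[ch]], 5))
    d <- compute_dff(prep("465"), prep("405"), c(0, 15))
    transient_metrics(d, c(0, 59))
  }
  expect_identical(run(), run())
})
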