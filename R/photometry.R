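#' Build a per-channel fluorescence trace
#'
#' Light-weight constructor for the tibble format used throughout the
#' photometry chain: one row per sample, columns `channel_id`, `time_s`
#' and `value`, plus a `provenance` attribute recording how far along the
#' processing chain the trace is (`"raw"`, `"smoothed"` or `"detrended"`).
#'
#' @param time_s Numeric vector of strictly increasing, uniformly spaced
#'   sample times in seconds.
#' @param value Numeric vector of fluorescence values (arbitrary units).
#' @param channel_id Channel identifier (single string).
#' @param provenance One of `"raw"`, `"smoothed"`, `"detrended"`.
#' @return A tibble of class `gliatrace_trace`.
#' @export
channel_trace <- function(time_s, value, channel_id = "465",
                          provenance = c("raw", "smoothed", "detrended")) {
  provenance <- match.arg(provenance)
  if (length(time_s) != length(value)) {
    abort("`time_s` and `value` must have the same length.")
  }
  if (length(time_s) >= 2) {
    dt <- diff(time_s)
    if (any(dt <= 0)) abort("`time_s` must be strictly increasing.")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      abort("`time_s` must be uniformly spaced.")
    }
  }
  out <- tibble::tibble(
    channel_id = as.character(channel_id),
    time_s = as.numeric(time_s),
    value = as.numeric(value)
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("gliatrace_trace", class(out))
  out
}

trace_provenance <- function(trace) {
  p <- attr(trace, "provenance")
  if (is.null(p)) "raw" else p
}

trace_dt <- function(trace) {
  t <- trace$time_s
  if (length(t) < 2) abort("Trace has fewer than 2 samples.")
  stats::median(diff(t))
}

#' Demultiplex a time-division multiplexed photometry stream
#'
#' Splits a raw acquisition stream into per-channel traces. The LEDs
#' alternate: pulse window `i` (50 ms by default) belongs to channel
#' `channel_order[(i mod k) + 1]`. Within each on-window the first and
#' last 2 raw samples are dropped (to avoid switching artefacts at the
#' LED transitions) and the remainder averaged into one output sample,
#' timestamped at the centre of the on-window.
#'
#' @param stream A data frame with columns `time_s` and `value`
#'   (1 row per raw sample), or a bare numeric vector of samples starting
#'   at `t0_s`.
#' @param schedule A [pulse_schedule()].
#' @param t0_s Start time of the stream (used when `stream` is a bare
#'   vector; otherwise taken from `stream$time_s[1]`).
#' @return A named list of [channel_trace()] tibbles, one per channel, all
#'   sharing the cycle indexing of the stream. Each channel's trace is
#'   sampled at `cycle_rate_hz / n_channels`.
#' @examples
#' sch <- pulse_schedule()
#' stream <- tibble::tibble(time_s = (0:149) / 1000, value = 7)
#' demultiplex(stream, sch)$`465`
#' @export
demultiplex <- function(stream, schedule = pulse_schedule(), t0_s = 0) {
  if (is.data.frame(stream)) {
    if (!all(c("time_s", "value") %in% names(stream))) {
      abort("`stream` data frame must have columns `time_s` and `value`.")
    }
    values <- stream$value
    t0_s <- stream$time_s[1]
  } else {
    values <- as.numeric(stream)
  }
  spc <- schedule$samples_per_cycle
  n <- length(values)
  if (n < spc) abort("Stream shorter than one pulse cycle.")
  n_cycles <- n %/% spc
  if (n %% spc != 0) {
    warn(sprintf("Dropping %d trailing raw samples (partial cycle).", n %% spc))
  }
  drop <- 2L
  keep <- (drop + 1L):(schedule$on_samples - drop)
  if (length(keep) < 1) abort("Pulse too short after dropping edge samples.")

  cyc <- seq_len(n_cycles) - 1L
  start <- cyc * spc
  means <- vapply(start, function(s) mean(values[s + keep]), numeric(1))
  centre <- t0_s + cyc / schedule$cycle_rate_hz + schedule$on_ms / 2000
  chan <- schedule$channel_order[(cyc %% schedule$n_channels) + 1L]

  out <- lapply(schedule$channel_order, function(ch) {
    idx <- chan == ch
    channel_trace(centre[idx], means[idx], channel_id = ch, provenance = "raw")
  })
  names(out) <- schedule$channel_order
  out
}

#' Smooth a trace with a centred moving average
#'
#' Edges use a shrinking window (the average of whatever part of the
#' window falls inside the trace), so the output length equals the input
#' length.
#'
#' @param trace A [channel_trace()] tibble.
#' @param window_samples Odd positive window width in samples.
#' @return The smoothed trace (provenance `"smoothed"`).
#' @export
smooth_trace <- function(trace, window_samples = 5) {
  if (window_samples < 1 || window_samples %% 2 == 0) {
    abort("`window_samples` must be a positive odd integer.")
  }
  v <- trace$value
  n <- length(v)
  half <- (window_samples - 1) / 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  channel_trace(trace$time_s, sm, channel_id = trace$channel_id[1],
                provenance = "smoothed")
}

#' Correct a trace for photobleaching by a least-squares line
#'
#' Fits an ordinary least-squares line to the whole trace and divides by
#' the fitted values, so a purely drifting trace becomes approximately 1
#' everywhere. The fit is rejected if the fitted line is not strictly
#' positive over the recording (such a recording is unusable for a
#' ratiometric analysis).
#'
#' @param trace A [channel_trace()] tibble with at least 3 samples.
#' @return The corrected, dimensionless trace (provenance `"detrended"`),
#'   with attributes `slope` (units/s) and `intercept` (units at t = 0).
#'   Retrieve them with `attr(x, "slope")` / `attr(x, "intercept")`.
#' @export
detrend_bleach <- function(trace) {
  if (nrow(trace) < 3) abort("Bleach correction needs at least 3 samples.")
  if (stats::var(trace$time_s) == 0) abort("Degenerate time axis.")
  fit <- stats::lm.fit(cbind(1, trace$time_s), trace$value)
  intercept <- unname(fit$coefficients[1])
  slope <- unname(fit$coefficients[2])
  fitted <- intercept + slope * trace$time_s
  if (any(fitted <= 0)) {
    abort("Fitted bleaching line is not strictly positive; recording unusable.")
  }
  out <- channel_trace(trace$time_s, trace$value / fitted,
                       channel_id = trace$channel_id[1],
                       provenance = "detrended")
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  out
}

#' Isosbestic-referenced fluorescence response (dF/F)
#'
#' Computes the ratiometric response
#' `ratio_t = (signal_t + 1) / (reference_t + 1)` from two
#' bleach-corrected traces, then subtracts the mean ratio over a baseline
#' window: `dff_t = ratio_t - baseline`. Because a multiplicative motion
#' artefact shared by the signal and isosbestic channels appears in both
#' numerator and denominator, it cancels in the ratio.
#'
#' @param signal,reference Bleach-corrected ([detrend_bleach()]) traces
#'   with identical cycle indexing (same length and sampling interval).
#' @param baseline_window_s Numeric length-2 `(start, end)` in seconds; a
#'   quiet pre-context segment (for example 1-2 min of home-cage
#'   recording before context exposure).
#' @return A tibble of class `gliatrace_dff` with columns `time_s`, `dff`
#'   and attributes `baseline_value` and `baseline_window_s`. Times are
#'   taken from the signal channel.
#' @export
compute_dff <- function(signal, reference, baseline_window_s) {
  for (tr in list(signal, reference)) {
    if (trace_provenance(tr) != "detrended") {
      abort("Both traces must be bleach-corrected (provenance \"detrended\").")
    }
  }
  if (nrow(signal) != nrow(reference)) {
    abort("Signal and reference traces have mismatched lengths.")
  }
  if (abs(trace_dt(signal) - trace_dt(reference)) > 1e-9) {
    abort("Signal and reference traces have mismatched sampling intervals.")
  }
  if (any(reference$value == -1)) {
    abort("Reference trace equals -1 somewhere; ratio undefined.")
  }
  ratio <- (signal$value + 1) / (reference$value + 1)
  t <- signal$time_s
  if (length(baseline_window_s) != 2 || baseline_window_s[2] <= baseline_window_s[1]) {
    abort("`baseline_window_s` must be (start, end) with end > start.")
  }
  in_base <- t >= baseline_window_s[1] & t <= baseline_window_s[2]
  if (!any(in_base)) abort("Baseline window contains no samples.")
  baseline <- mean(ratio[in_base])
  out <- tibble::tibble(time_s = t, dff = ratio - baseline)
  attr(out, "baseline_value") <- baseline
  attr(out, "baseline_window_s") <- baseline_window_s
  class(out) <- c("gliatrace_dff", class(out))
  out
}

#' Transient summary metrics: peak, AUC and half-decay
#'
#' Within the analysis window: the peak is the maximum dF/F; the AUC is
#' the trapezoidal integral of dF/F over the window (negative excursions
#' included, units dF/F x s); the half-decay is the time from the peak to
#' the first post-peak instant at which dF/F falls to half the peak,
#' linearly interpolated between the bracketing samples, and `NA` if the
#' trace never reaches half-peak inside the window (or if the peak is not
#' positive, where "half the response" is meaningless).
#'
#' @param dff A `gliatrace_dff` tibble (or any data frame with `time_s`
#'   and `dff`).
#' @param analysis_window_s Numeric length-2 `(start, end)` in seconds.
#' @return A one-row tibble: `peak_dff`, `peak_time_s`, `auc`,
#'   `half_decay_s` (`NA` when undefined).
#' @export
transient_metrics <- function(dff, analysis_window_s) {
  if (length(analysis_window_s) != 2 || analysis_window_s[2] <= analysis_window_s[1]) {
    abort("`analysis_window_s` must be (start, end) with end > start.")
  }
  idx <- dff$time_s >= analysis_window_s[1] & dff$time_s <= analysis_window_s[2]
  if (!any(idx)) abort("Analysis window contains no samples.")
  t <- dff$time_s[idx]
  y <- dff$dff[idx]
  ipk <- which.max(y)
  peak <- y[ipk]
  peak_time <- t[ipk]
  auc <- if (length(y) >= 2) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2) else 0

  half_decay <- NA_real_
  if (peak > 0 && ipk < length(y)) {
    post <- seq(ipk + 1, length(y))
    j <- post[which(y[post] <= peak / 2)[1]]
    if (!is.na(j)) {
      if (y[j] == peak / 2 || y[j - 1] == y[j]) {
        t_half <- t[j]
      } else {
        t_half <- t[j - 1] + (y[j - 1] - peak / 2) / (y[j - 1] - y[j]) * (t[j] - t[j - 1])
      }
      half_decay <- t_half - peak_time
    }
  }
  tibble::tibble(peak_dff = peak, peak_time_s = peak_time,
                 auc = auc, half_decay_s = half_decay)
}

#' Zero-phase band-pass filter
#'
#' Removes the trace mean, then applies a zero-phase (forward-backward)
#' second-order Butterworth high-pass at `low_hz` followed by a
#' zero-phase second-order Butterworth low-pass at `high_hz`. Length is
#' preserved and DC is rejected. The default band (0.0003-1 Hz) targets
#' slow astrocytic calcium dynamics while discarding drift and
#' high-frequency noise.
#'
#' @param trace A data frame with `time_s` and a `value` or `dff` column.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low < high < Nyquist`.
#' @return The filtered object, same shape and class as the input.
#' @export
bandpass_filter <- function(trace, low_hz = 0.0003, high_hz = 1) {
  col <- if ("dff" %in% names(trace)) "dff" else "value"
  fs <- 1 / trace_dt(trace)
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort("Band edges must satisfy 0 < low_hz < high_hz < Nyquist.")
  }
  y <- trace[[col]] - mean(trace[[col]])
  hp <- signal::butter(2, low_hz / nyq, type = "high")
  lp <- signal::butter(2, high_hz / nyq, type = "low")
  y <- signal::filtfilt(hp, y)
  y <- signal::filtfilt(lp, y)
  out <- trace
  out[[col]] <- as.numeric(y)
  out
}

#' Event-detection parameters
#'
#' @param k_sd Threshold multiplier: events must exceed
#'   `baseline mean + k_sd x baseline SD` (strictly). The default of 4
#'   follows the convention of defining calcium peaks as points exceeding
#'   4 standard deviations above the baseline mean.
#' @param quiescent_windows_s List of `(start, end)` numeric pairs marking
#'   intervals without spontaneous activity, used to estimate baseline
#'   noise; total coverage must be at least 20 s. These are
#'   caller-supplied (identified by inspection), not auto-detected.
#' @param merge_gap_s Supra-threshold runs separated by less than this gap
#'   are merged into one event.
#' @param min_duration_samples Runs shorter than this many samples (after
#'   merging) are dropped.
#' @param bandpass_hz Band `(low, high)` in Hz the trace is expected to be
#'   filtered with before detection.
#' @return A list of class `event_params`.
#' @export
event_params <- function(k_sd = 4,
                         quiescent_windows_s = list(),
                         merge_gap_s = 0.5,
                         min_duration_samples = 1,
                         bandpass_hz = c(0.0003, 1)) {
  if (k_sd <= 0) abort("`k_sd` must be positive.")
  if (length(quiescent_windows_s) && !is.list(quiescent_windows_s)) {
    quiescent_windows_s <- list(quiescent_windows_s)
  }
  w <- quiescent_windows_s
  if (length(w)) {
    m <- do.call(rbind, lapply(w, as.numeric))
    if (ncol(m) != 2 || any(m[, 2] <= m[, 1])) {
      abort("Each quiescent window must be (start, end) with end > start.")
    }
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) {
      abort("Quiescent windows must not overlap.")
    }
  }
  structure(list(k_sd = k_sd, quiescent_windows_s = w,
                 merge_gap_s = merge_gap_s,
                 min_duration_samples = min_duration_samples,
                 bandpass_hz = bandpass_hz),
            class = "event_params")
}

#' Detect calcium events by baseline-referenced thresholding
#'
#' Pools the samples inside the quiescent windows to estimate the
#' baseline mean and standard deviation, sets the threshold at
#' `mean + k_sd x SD`, and turns contiguous strictly-supra-threshold runs
#' into candidate events. Runs separated by less than `merge_gap_s` are
#' merged; merged runs shorter than `min_duration_samples` are dropped.
#' Each event records its start/end times, peak time, and amplitude
#' (peak dF/F minus baseline mean). A sample exactly at threshold is not
#' an event.
#'
#' @param dff A (band-pass filtered) `gliatrace_dff` tibble.
#' @param params An [event_params()] object; its quiescent windows must
#'   cover at least 20 s of the recording.
#' @return A tibble of class `gliatrace_events` with columns `start_s`,
#'   `end_s`, `peak_time_s`, `amplitude`, and attributes `baseline_mean`,
#'   `baseline_sd`, `duration_s`.
#' @export
detect_events <- function(dff, params = event_params()) {
  t <- dff$time_s
  y <- dff$dff
  dt <- trace_dt(dff)
  w <- params$quiescent_windows_s
  if (!length(w)) abort("No quiescent windows supplied.")
  in_quiet <- rep(FALSE, length(t))
  total <- 0
  for (win in w) {
    in_quiet <- in_quiet | (t >= win[1] & t <= win[2])
    total <- total + (min(win[2], max(t)) - max(win[1], min(t)))
  }
  if (sum(in_quiet) * dt < 20) {
    abort("Quiescent windows must cover at least 20 s of the recording.")
  }
  base_mean <- mean(y[in_quiet])
  base_sd <- stats::sd(y[in_quiet])
  if (!is.finite(base_sd) || base_sd == 0) abort("Baseline SD is zero.")
  threshold <- base_mean + params$k_sd * base_sd

  above <- y > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  events <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                           peak_time_s = numeric(), amplitude = numeric())
  if (nrow(runs)) {
    # merge runs separated by < merge_gap_s
    merged <- list()
    cur <- runs[1, ]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        gap <- t[runs$start[i]] - t[cur$end]
        if (gap < params$merge_gap_s) {
          cur$end <- runs$end[i]
        } else {
          merged[[length(merged) + 1]] <- cur
          cur <- runs[i, ]
        }
      }
    }
    merged[[length(merged) + 1]] <- cur
    merged <- do.call(rbind, merged)
    len <- merged$end - merged$start + 1
    merged <- merged[len >= params$min_duration_samples, , drop = FALSE]
    if (nrow(merged)) {
      events <- purrr::map_dfr(seq_len(nrow(merged)), function(i) {
        seg <- merged$start[i]:merged$end[i]
        ipk <- seg[which.max(y[seg])]
        tibble::tibble(start_s = t[merged$start[i]], end_s = t[merged$end[i]],
                       peak_time_s = t[ipk], amplitude = y[ipk] - base_mean)
      })
    }
  }
  attr(events, "baseline_mean") <- base_mean
  attr(events, "baseline_sd") <- base_sd
  attr(events, "duration_s") <- length(t) * dt
  class(events) <- c("gliatrace_events", class(events))
  events
}

#' Event-train summary: frequency and mean amplitude
#'
#' @param train A `gliatrace_events` tibble from [detect_events()].
#' @param duration_s Recording duration in seconds; defaults to the
#'   duration recorded on the train.
#' @return A one-row tibble: `n_events`, `frequency_per_min`
#'   (`60 x count / duration`), `mean_amplitude` (`NA` for an empty
#'   train).
#' @export
event_stats <- function(train, duration_s = attr(train, "duration_s")) {
  if (is.null(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.")
  }
  tibble::tibble(
    n_events = nrow(train),
    frequency_per_min = 60 * nrow(train) / duration_s,
    mean_amplitude = if (nrow(train)) mean(train$amplitude) else NA_real_
  )
}
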