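#' Time-division multiplexing pulse schedule
#'
#' Describes how excitation LEDs alternate in a time-division multiplexed
#' photometry rig. One pulse window lasts `on_ms + off_ms` milliseconds and
#' must tile the cycle rate exactly; the channels in `channel_order` take
#' turns, one active channel per pulse window, so each channel is revisited
#' every `length(channel_order)` windows.
#'
#' The default mirrors a common two-colour-plus-isosbestic configuration:
#' 465 nm and 560 nm signal LEDs plus a 405 nm isosbestic reference,
#' alternating at 20 Hz (24 ms on, 26 ms off) over a 1 kHz acquisition
#' stream.
#'
#' @param cycle_rate_hz Alternation rate of the pulse windows (Hz).
#' @param on_ms LED-on duration per pulse window (ms).
#' @param off_ms LED-off duration per pulse window (ms).
#' @param channel_order Character vector of channel identifiers in firing
#'   order, e.g. `c("465", "560", "405")`.
#' @param raw_rate_hz Acquisition sampling rate of the raw stream (Hz);
#'   must be divisible by `cycle_rate_hz`.
#'
#' @return An object of class `pulse_schedule`: a list with the validated
#'   fields plus derived counts (`samples_per_cycle`, `on_samples`,
#'   `n_channels`, `frame_s`, the seconds between two visits of the same
#'   channel).
#' @examples
#' pulse_schedule()
#' @export
pulse_schedule <- function(cycle_rate_hz = 20, on_ms = 24, off_ms = 26,
                           channel_order = c("465", "560", "405"),
                           raw_rate_hz = 1000) {
  if (cycle_rate_hz <= 0 || raw_rate_hz <= 0) {
    abort("`cycle_rate_hz` and `raw_rate_hz` must be positive.")
  }
  if (abs(on_ms + off_ms - 1000 / cycle_rate_hz) > 1e-9) {
    abort("`on_ms + off_ms` must equal 1000 / cycle_rate_hz (pulses must tile the cycle).")
  }
  if (abs(raw_rate_hz %% cycle_rate_hz) > 1e-9) {
    abort("`raw_rate_hz` must be divisible by `cycle_rate_hz`.")
  }
  if (length(channel_order) < 1 || anyDuplicated(channel_order)) {
    abort("`channel_order` must contain at least one unique channel id.")
  }
  samples_per_cycle <- as.integer(round(raw_rate_hz / cycle_rate_hz))
  on_samples <- as.integer(round(on_ms * raw_rate_hz / 1000))
  if (on_samples < 5) {
    abort("Pulse too short: fewer than 5 raw samples fall inside the on window.")
  }
  structure(
    list(
      cycle_rate_hz = cycle_rate_hz,
      on_ms = on_ms,
      off_ms = off_ms,
      channel_order = as.character(channel_order),
      raw_rate_hz = raw_rate_hz,
      samples_per_cycle = samples_per_cycle,
      on_samples = on_samples,
      n_channels = length(channel_order),
      frame_s = length(channel_order) / cycle_rate_hz
    ),
    class = "pulse_schedule"
  )
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat(sprintf(
    "<pulse_schedule> %g Hz alternation (%g ms on / %g ms off), raw %g Hz\n",
    x$cycle_rate_hz, x$on_ms, x$off_ms, x$raw_rate_hz
  ))
  cat(sprintf(
    "  channels: %s (per-channel rate %.3g Hz)\n",
    paste(x$channel_order, collapse = " -> "), 1 / x$frame_s
  ))
  invisible(x)
}
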