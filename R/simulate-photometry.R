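# Seeded RNG without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Configuration for a synthetic photometry recording
#'
#' Describes a two-or-three-wavelength time-division multiplexed
#' recording in which all channels share a multiplicative, slow
#' (< 0.5 Hz) motion artefact and a linear bleaching drift, each signal
#' channel may carry deterministic sensor transients (instantaneous rise,
#' mono-exponential decay), and one channel may carry Poisson-timed
#' calcium events.
#'
#' @param duration_s Recording length (s), > 0.
#' @param schedule A [pulse_schedule()].
#' @param transients Named list, one element per signal channel id, each a
#'   data frame with columns `onset_s`, `amplitude` (dF/F units) and
#'   `tau_s` (mono-exponential decay constant; half-decay is
#'   `tau_s * log(2)`).
#' @param event_channel Channel id carrying stochastic calcium events
#'   (`NULL` for none).
#' @param event_rate_hz Mean event rate (events/s) on `event_channel`.
#' @param event_amplitude Peak amplitude of each event (dF/F units).
#' @param event_tau_s Mono-exponential decay constant of each event (s).
#' @param bleach_slope_per_s Fractional drift per second (negative for
#'   bleaching), applied multiplicatively as `1 + slope * t`.
#' @param motion_artifact_sd Standard deviation of the shared
#'   multiplicative motion artefact (dimensionless).
#' @param noise_sd Standard deviation of additive per-sample detector
#'   noise.
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @return A list of class `photometry_config`.
#' @export
photometry_config <- function(duration_s = 600,
                              schedule = pulse_schedule(),
                              transients = list(),
                              event_channel = NULL,
                              event_rate_hz = 0,
                              event_amplitude = 0.5,
                              event_tau_s = 3,
                              bleach_slope_per_s = 0,
                              motion_artifact_sd = 0,
                              noise_sd = 0,
                              seed = 0) {
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  if (event_rate_hz < 0 || motion_artifact_sd < 0 || noise_sd < 0) {
    abort("Rates and standard deviations must be non-negative.")
  }
  for (ch in names(transients)) {
    tr <- transients[[ch]]
    if (!ch %in% schedule$channel_order) {
      abort(sprintf("Transient channel '%s' is not in the schedule.", ch))
    }
    if (!all(c("onset_s", "amplitude", "tau_s") %in% names(tr))) {
      abort("Each transient table needs onset_s, amplitude, tau_s.")
    }
    if (any(tr$onset_s < 0 | tr$onset_s >= duration_s)) {
      abort("Transient onsets must lie within [0, duration_s).")
    }
    if (any(tr$amplitude < 0) || any(tr$tau_s <= 0)) {
      abort("Transient amplitudes must be >= 0 and tau_s > 0.")
    }
  }
  if (!is.null(event_channel) && !event_channel %in% schedule$channel_order) {
    abort("`event_channel` is not in the schedule.")
  }
  structure(
    list(duration_s = duration_s, schedule = schedule,
         transients = transients, event_channel = event_channel,
         event_rate_hz = event_rate_hz, event_amplitude = event_amplitude,
         event_tau_s = event_tau_s, bleach_slope_per_s = bleach_slope_per_s,
         motion_artifact_sd = motion_artifact_sd, noise_sd = noise_sd,
         seed = seed),
    class = "photometry_config"
  )
}

#' Preset transient kinetics for conditioning-like and recall-like responses
#'
#' Two single-transient presets whose decay constants are derived from
#' measured noradrenaline responses in the amygdala: a relatively fast
#' foot-shock-evoked response (peak dF/F 0.206, half-decay 4.3 min) and a
#' larger, prolonged recall-evoked response (peak dF/F 0.211, half-decay
#' 13.5 min). Decay constants are `tau = half_decay / log(2)`. A third
#' preset models the smaller response to context exposure alone (peak
#' dF/F 0.142; same fast kinetics).
#'
#' @param which One of `"FC"`, `"FR"`, `"context"`.
#' @param onset_s Transient onset (s).
#' @return A one-row transient table usable in [photometry_config()].
#' @export
transient_preset <- function(which = c("FC", "FR", "context"), onset_s = 60) {
  which <- match.arg(which)
  p <- switch(which,
    FC = list(amplitude = 0.206, half_decay_s = 4.3 * 60),
    FR = list(amplitude = 0.211, half_decay_s = 13.5 * 60),
    context = list(amplitude = 0.142, half_decay_s = 4.3 * 60)
  )
  tibble::tibble(onset_s = onset_s, amplitude = p$amplitude,
                 tau_s = p$half_decay_s / log(2))
}

# Mono-exponential kernel sum at times t for a transient table.
transient_response <- function(t, table) {
  r <- numeric(length(t))
  for (i in seq_len(nrow(table))) {
    d <- t - table$onset_s[i]
    on <- d >= 0
    r[on] <- r[on] + table$amplitude[i] * exp(-d[on] / table$tau_s[i])
  }
  r
}

#' Generate a synthetic interleaved photometry stream
#'
#' Produces a raw 1 kHz-style stream in which, for each pulse window, the
#' active channel's value is
#' `(1 + bleach drift) * (1 + motion artefact) * (1 + sensor response)`
#' plus additive noise. The motion artefact is a smoothed, standardized
#' random walk held constant across the channels of one frame (one full
#' rotation of the channel order), which is exactly the property the
#' isosbestic ratio exploits to cancel it. Samples outside any on-window
#' carry only noise.
#'
#' @param config A [photometry_config()].
#' @return A list of class `photometry_sim`:
#'   * `stream` - tibble `time_s`, `value` at the raw rate;
#'   * `schedule` - the pulse schedule;
#'   * `truth` - injected transient tables, event times per channel, and
#'     the seed.
#' @examples
#' sim <- simulate_photometry(photometry_config(duration_s = 3))
#' demultiplex(sim$stream, sim$schedule)$`465`
#' @export
simulate_photometry <- function(config = photometry_config()) {
  sch <- config$schedule
  n_frames <- floor(config$duration_s / sch$frame_s)
  if (n_frames < 1) abort("Duration shorter than one frame.")
  n_cycles <- n_frames * sch$n_channels
  spc <- sch$samples_per_cycle
  n_samples <- n_cycles * spc

  with_seed(config$seed, {
    # shared multiplicative motion artefact: random walk at frame rate,
    # smoothed below 0.5 Hz, standardized to the configured SD
    if (config$motion_artifact_sd > 0 && n_frames > 2) {
      walk <- cumsum(rnorm(n_frames))
      w <- max(3, round((1 / sch$frame_s) / 0.5))
      if (w %% 2 == 0) w <- w + 1
      k <- rep(1 / w, w)
      sm <- as.numeric(stats::filter(walk, k, sides = 2))
      sm[is.na(sm)] <- walk[is.na(sm)]
      motion <- config$motion_artifact_sd * (sm - mean(sm)) / stats::sd(sm)
    } else {
      motion <- rep(0, n_frames)
    }

    # Poisson-timed events on the event channel
    responses <- config$transients
    event_times <- numeric(0)
    if (!is.null(config$event_channel) && config$event_rate_hz > 0) {
      n_ev <- rpois(1, config$event_rate_hz * config$duration_s)
      event_times <- sort(runif(n_ev, 0, config$duration_s))
      ev_table <- tibble::tibble(onset_s = event_times,
                                 amplitude = config$event_amplitude,
                                 tau_s = config$event_tau_s)
      ch <- config$event_channel
      responses[[ch]] <- if (is.null(responses[[ch]])) ev_table else
        dplyr::bind_rows(responses[[ch]], ev_table)
    }

    value <- if (config$noise_sd > 0) {
      rnorm(n_samples, 0, config$noise_sd)
    } else {
      numeric(n_samples)
    }

    cyc <- seq_len(n_cycles) - 1L
    frame_of_cycle <- cyc %/% sch$n_channels + 1L
    chan_of_cycle <- sch$channel_order[(cyc %% sch$n_channels) + 1L]
    on_idx <- seq_len(sch$on_samples)
    for (ch in sch$channel_order) {
      sel <- which(chan_of_cycle == ch)
      idx <- rep((sel - 1L) * spc, each = sch$on_samples) +
        rep(on_idx, times = length(sel))
      t_idx <- (idx - 1) / sch$raw_rate_hz
      resp <- if (!is.null(responses[[ch]]) && nrow(responses[[ch]])) {
        transient_response(t_idx, responses[[ch]])
      } else {
        numeric(length(t_idx))
      }
      m <- rep(motion[frame_of_cycle[sel]], each = sch$on_samples)
      b <- config$bleach_slope_per_s * t_idx
      value[idx] <- value[idx] + (1 + b) * (1 + m) * (1 + resp)
    }
  })

  truth <- list(transients = config$transients,
                event_channel = config$event_channel,
                event_times = event_times,
                seed = config$seed)
  structure(
    list(stream = tibble::tibble(time_s = (seq_len(n_samples) - 1) / sch$raw_rate_hz,
                                 value = value),
         schedule = sch, truth = truth, config = config),
    class = "photometry_sim"
  )
}
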