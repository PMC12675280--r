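# Shared fixture builders: everything is generated in code at test time.

# Uniformly sampled trace at `fs` Hz, already marked detrended so it can
# feed compute_dff directly.
make_trace <- function(values, fs = 20, channel = "465",
                       provenance = "detrended", t0 = 0) {
  channel_trace(t0 + (seq_along(values) - 1) / fs, values,
                channel_id = channel, provenance = provenance)
}

# dF/F tibble at `fs` Hz without going through the ratio step.
make_dff <- function(values, fs = 20, t0 = 0) {
  out <- tibble::tibble(time_s = t0 + (seq_along(values) - 1) / fs,
                        dff = values)
  class(out) <- c("gliatrace_dff", class(out))
  out
}

# Raw interleaved stream built from per-channel step values: channel k of
# cycle i carries constant `levels[[channel]][frame]`.
make_step_stream <- function(levels, schedule = pulse_schedule(),
                             n_frames = 4) {
  spc <- schedule$samples_per_cycle
  n_cycles <- n_frames * schedule$n_channels
  values <- numeric(n_cycles * spc)
  for (cyc in seq_len(n_cycles) - 1L) {
    ch <- schedule$channel_order[(cyc %% schedule$n_channels) + 1L]
    frame <- cyc %/% schedule$n_channels + 1L
    values[cyc * spc + seq_len(schedule$on_samples)] <- levels[[ch]][frame]
  }
  tibble::tibble(time_s = (seq_along(values) - 1) / schedule$raw_rate_hz,
                 value = values)
}

# Small wide cell table for the quantification tests.
make_cells <- function(df) {
  tibble::as_tibble(df)
}

# Brute-force Benjamini-Hochberg step-up definition, used as the oracle
# against the production adjustment.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    candidates <- vapply(seq(rank_i, m), function(j) {
      m * p[ord[j]] / j
    }, numeric(1))
    q[i] <- min(1, min(candidates))
  }
  q
}

# Exact two-sided Mann-Whitney p by full enumeration of group labellings.
mw_enumerate <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- u_stat(x, y)
  mid <- n1 * length(y) / 2
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  # two-sided: as extreme as observed in distance from the null centre
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}
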