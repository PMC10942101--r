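# Small session configurations and trace builders used across the suite.

tiny_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, session_length = 320, n_dendrites = 2L,
             spines_per_dendrite = 8L, ...)
}

# Binary event train from ground-truth onsets: each event lasts `dur` frames.
train_from_onsets <- function(onsets_s, frame_times, frame_rate, dur = 30L,
                              block = NULL) {
  active <- rep(FALSE, length(frame_times))
  for (o in onsets_s) {
    i0 <- findInterval(o - 1e-9, frame_times) + 1L
    i1 <- min(length(frame_times), i0 + dur - 1L)
    if (i0 <= length(frame_times)) active[i0:i1] <- TRUE
  }
  train_from_binary(active, frame_rate, block = block)
}

# dF/F0-like trace with injected instantaneous-rise exponential events.
injected_trace <- function(onsets, amp, tau_frames, n, sigma = 0.1) {
  dff <- stats::rnorm(n, 0, sigma)
  for (o in onsets) {
    idx <- o:min(n, o + round(6 * tau_frames))
    dff[idx] <- dff[idx] + amp * exp(-(idx - o) / tau_frames)
  }
  dff
}

detect_from_raw_dff <- function(dff, frame_rate, ...) {
  sm <- spinefate:::moving_average(dff, round(0.5 * frame_rate))
  detect_events(sm, estimate_noise(dff), frame_rate, dff_raw = dff, ...)
}
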