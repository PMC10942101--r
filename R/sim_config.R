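#' Configuration for a synthetic imaging session
#'
#' Bundles every parameter of the synthetic-session generator: session and
#' block structure, dendrite geometry, event statistics, the co-activity
#' coupling model, and the stable/eliminated phenotype contrasts. Defaults
#' describe a session of apical dendrites imaged at 58.3 Hz in 5-min-on /
#' 5-min-off blocks during a cued lever-press task.
#'
#' @param seed integer seed; identical configs give bit-identical sessions.
#' @param n_dendrites,spines_per_dendrite counts of simulated dendritic
#'   branches and spines per branch.
#' @param dendrite_length branch length in micrometers; spine positions are
#'   uniform along it.
#' @param frame_rate imaging frame rate in Hz.
#' @param lever_rate lever sampling rate in Hz (must exceed `frame_rate`).
#' @param session_length total session duration in seconds.
#' @param block_on,block_off imaging block structure in seconds; frames are
#'   acquired only during on-blocks.
#' @param base_event_rate target per-spine event rate, events per minute of
#'   imaged time.
#' @param cluster_rate rate of shared local (cluster) events per dendrite,
#'   events per minute of imaged time.
#' @param cluster_length_constant spatial decay constant (um) of the
#'   probability that a spine joins a cluster event.
#' @param cluster_coupling probability in `[0, 1]` that a spine at the cluster
#'   center joins the event.
#' @param dendrite_event_min_spines cluster events recruiting at least this
#'   many spines trigger a dendritic calcium event.
#' @param mrs_fraction fraction of spines given movement-locked drive
#'   (ground-truth movement-related spines).
#' @param movement_response_prob probability that a movement-related spine
#'   emits an event for a given lever press.
#' @param eliminated_fraction fraction of spines per dendrite labelled
#'   eliminated (at least one per dendrite).
#' @param eliminated_coupling_deficit multiplicative reduction in cluster
#'   coupling for eliminated spines, in `[0, 1]`.
#' @param eliminated_lag extra onset lag (seconds) of eliminated spines'
#'   cluster-driven events relative to the dendritic event.
#' @param onset_jitter_sd SD (seconds) of per-event onset jitter.
#' @param noise_sigma Gaussian noise SD on the dF/F0 scale.
#' @param event_amplitude_mean mean event amplitude in dF/F0 units.
#' @param event_tau exponential decay time constant of events, seconds.
#' @param area_lognormal_params `c(meanlog, sdlog)` of the spine-area
#'   lognormal (areas in um^2).
#' @param eliminated_area_scale multiplicative area deficit of eliminated
#'   spines (smaller spines are preferentially eliminated).
#' @param trial_period seconds between cue onsets.
#' @param press_prob probability a cue evokes a rewarded press.
#' @param reaction_mean mean reaction time (s) from cue to press onset.
#' @param uncued_press_rate rate (per second) of spontaneous unrewarded
#'   presses during intertrial intervals.
#' @param f0_level raw-fluorescence baseline level (arbitrary units).
#' @param f0_drift relative amplitude of the slow sinusoidal baseline drift.
#' @param sensor spine sensor, `"iGluSnFR2"` or `"iGluSnFR3"`; governs the
#'   0.2 dF/F0 event floor during detection.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_dendrites = 4L,
                       spines_per_dendrite = 14L,
                       dendrite_length = 70,
                       frame_rate = 58.3,
                       lever_rate = 1000,
                       session_length = 1500,
                       block_on = 300,
                       block_off = 300,
                       base_event_rate = 2,
                       cluster_rate = 1.5,
                       cluster_length_constant = 10,
                       cluster_coupling = 0.7,
                       dendrite_event_min_spines = 3L,
                       mrs_fraction = 0.4,
                       movement_response_prob = 0.3,
                       eliminated_fraction = 0.15,
                       eliminated_coupling_deficit = 0.5,
                       eliminated_lag = 0.05,
                       onset_jitter_sd = 0.015,
                       noise_sigma = 0.1,
                       event_amplitude_mean = 1,
                       event_tau = 0.5,
                       area_lognormal_params = c(meanlog = -0.7, sdlog = 0.5),
                       eliminated_area_scale = 0.7,
                       trial_period = 10,
                       press_prob = 0.75,
                       reaction_mean = 0.6,
                       uncued_press_rate = 2 / 60,
                       f0_level = 100,
                       f0_drift = 0.05,
                       sensor = c("iGluSnFR2", "iGluSnFR3")) {
  sensor <- match.arg(sensor)
  cfg <- list(
    seed = as.integer(seed), n_dendrites = as.integer(n_dendrites),
    spines_per_dendrite = as.integer(spines_per_dendrite),
    dendrite_length = dendrite_length, frame_rate = frame_rate,
    lever_rate = lever_rate, session_length = session_length,
    block_on = block_on, block_off = block_off,
    base_event_rate = base_event_rate, cluster_rate = cluster_rate,
    cluster_length_constant = cluster_length_constant,
    cluster_coupling = cluster_coupling,
    dendrite_event_min_spines = as.integer(dendrite_event_min_spines),
    mrs_fraction = mrs_fraction,
    movement_response_prob = movement_response_prob,
    eliminated_fraction = eliminated_fraction,
    eliminated_coupling_deficit = eliminated_coupling_deficit,
    eliminated_lag = eliminated_lag, onset_jitter_sd = onset_jitter_sd,
    noise_sigma = noise_sigma, event_amplitude_mean = event_amplitude_mean,
    event_tau = event_tau, area_lognormal_params = area_lognormal_params,
    eliminated_area_scale = eliminated_area_scale,
    trial_period = trial_period, press_prob = press_prob,
    reaction_mean = reaction_mean, uncued_press_rate = uncued_press_rate,
    f0_level = f0_level, f0_drift = f0_drift, sensor = sensor
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_dendrites >= 1L, cfg$spines_per_dendrite >= 2L,
    cfg$dendrite_length > 0, cfg$frame_rate > 0, cfg$lever_rate > 0,
    cfg$session_length > 0, cfg$block_on > 0, cfg$block_off >= 0,
    cfg$base_event_rate > 0, cfg$cluster_rate >= 0,
    cfg$cluster_length_constant > 0, cfg$event_tau > 0,
    cfg$noise_sigma >= 0, cfg$event_amplitude_mean > 0,
    cfg$eliminated_area_scale > 0, cfg$eliminated_area_scale <= 1,
    cfg$trial_period > 0
  )
  if (cfg$frame_rate >= cfg$lever_rate) {
    stop("frame_rate must be below lever_rate")
  }
  for (f in c("cluster_coupling", "mrs_fraction", "eliminated_fraction",
              "eliminated_coupling_deficit", "movement_response_prob",
              "press_prob")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop(sprintf("%s must be in [0, 1]", f))
  }
  if (cfg$session_length < cfg$trial_period) {
    stop("session_length too short for a single trial")
  }
  invisible(cfg)
}

# Frame clock for the 5-on/5-off acquisition: frame times (s) and the
# on-block index of each frame. Gaps carry no frames at all.
frame_clock <- function(cfg) {
  period <- cfg$block_on + cfg$block_off
  starts <- seq(0, cfg$session_length - 1e-9, by = period)
  times <- list()
  block <- list()
  for (i in seq_along(starts)) {
    t0 <- starts[i]
    t1 <- min(t0 + cfg$block_on, cfg$session_length)
    if (t1 <= t0) next
    tt <- seq(t0, t1 - 1e-9, by = 1 / cfg$frame_rate)
    times[[i]] <- tt
    block[[i]] <- rep(i, length(tt))
  }
  list(times = unlist(times), block = unlist(block),
       imaged_seconds = sum(vapply(times, function(t) length(t), 1L)) / cfg$frame_rate)
}
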