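#' Generate synthetic lever-press behavior
#'
#' Simulates a lever displacement trace at `cfg$lever_rate` with resting
#' baseline noise plus cue-triggered press waveforms, together with a trial
#' table (cue onset, reward time). Presses are smooth dips of 4--5 mm that
#' cross both task thresholds (1.5 and 3 mm below rest) within 200 ms and
#' whose velocity envelope far exceeds the 4.9 mm/s segmentation threshold.
#'
#' @param cfg a [sim_config()].
#' @param n_presses optional exact number of cued presses to inject (overrides
#'   `press_prob`); `0` yields a trace with cues but no movements.
#' @return A `lever_trace`: list with `samples` (displacement, mm; negative =
#'   pressed), `rate` (Hz), `trials` (data.frame `cue_s`, `reward_s`), and
#'   `press_onsets` (ground-truth press onset times, s).
#' @export
generate_behavior <- function(cfg, n_presses = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  lr <- cfg$lever_rate
  n <- round(cfg$session_length * lr)
  tt <- (seq_len(n) - 1) / lr

  # broadband resting sensor noise on the force-transducer voltage
  x <- stats::rnorm(n, 0, 0.03)

  cue_s <- seq(2, cfg$session_length - cfg$trial_period, by = cfg$trial_period)
  n_trials <- length(cue_s)
  if (is.null(n_presses)) {
    pressed <- stats::runif(n_trials) < cfg$press_prob
  } else {
    # deterministic spread: presses on evenly spaced trials
    n_presses <- min(n_presses, n_trials)
    sel <- if (n_presses > 0) {
      unique(round(seq(1, n_trials, length.out = n_presses)))
    } else integer(0)
    pressed <- seq_len(n_trials) %in% sel
  }

  press_onsets <- numeric(0)
  reward_s <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    if (!pressed[i]) next
    rt <- max(0.2, stats::rgamma(1, shape = 4, scale = cfg$reaction_mean / 4))
    onset <- cue_s[i] + rt
    amp <- stats::runif(1, 4, 5)
    dur <- stats::runif(1, 0.4, 0.7)
    if (onset + dur >= cfg$session_length) next
    idx <- which(tt >= onset & tt < onset + dur)
    x[idx] <- x[idx] - amp * sin(pi * (tt[idx] - onset) / dur)^2
    press_onsets <- c(press_onsets, onset)
    # reward at the 3-mm threshold crossing
    cross <- idx[which(x[idx] <= -3)[1]]
    if (!is.na(cross)) reward_s[i] <- tt[cross]
  }

  # spontaneous uncued presses in intertrial intervals, kept clear of trials
  if (is.null(n_presses) && cfg$uncued_press_rate > 0) {
    k <- stats::rpois(1, cfg$uncued_press_rate * cfg$session_length)
    cand <- stats::runif(k, 1, cfg$session_length - 2)
    for (onset in cand) {
      if (length(press_onsets) && min(abs(press_onsets - onset)) < 3) next
      amp <- stats::runif(1, 2, 4)
      dur <- stats::runif(1, 0.3, 0.6)
      idx <- which(tt >= onset & tt < onset + dur)
      x[idx] <- x[idx] - amp * sin(pi * (tt[idx] - onset) / dur)^2
      press_onsets <- c(press_onsets, onset)
    }
  }

  structure(
    list(samples = x, rate = lr,
         trials = data.frame(cue_s = cue_s, reward_s = reward_s),
         press_onsets = sort(press_onsets)),
    class = "lever_trace"
  )
}
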