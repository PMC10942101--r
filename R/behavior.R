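#' Segment lever movements from a displacement trace
#'
#' Implements the standard lever-press segmentation chain: down-sample to
#' 1 kHz (decimation after anti-alias filtering, when needed), zero-phase
#' four-pole 10-Hz low-pass Butterworth smoothing, velocity from first
#' differences smoothed with a 5-ms moving average, Hilbert-transform
#' envelope, tentative bouts where the envelope exceeds 4.9 mm/s, extension by
#' 75 ms on each side, merging of bouts separated by less than 500 ms, and
#' refinement of start/end times against a displacement threshold set at the
#' local resting position plus the 99th percentile of the smoothing-residual
#' noise.
#'
#' @param lever a `lever_trace` (see [generate_behavior()]) or a list with
#'   `samples` (mm), `rate` (Hz), and optionally `trials`.
#' @param envelope_threshold velocity-envelope threshold, mm/s.
#' @param extend_s extension applied to each side of a tentative bout, s.
#' @param merge_gap_s bouts closer than this are considered continuous, s.
#' @param rest_window_s extent of the rest period before/after each bout used
#'   for the local resting position, s.
#' @return A data.frame of disjoint, ordered bouts with columns `start_s`,
#'   `end_s`, `rewarded`, `cued`.
#' @export
segment_movements <- function(lever, envelope_threshold = 4.9,
                              extend_s = 0.075, merge_gap_s = 0.5,
                              rest_window_s = 0.5) {
  x <- lever$samples
  rate <- lever$rate
  if (rate < 1000) stop("lever trace must be sampled at >= 1 kHz")
  if (length(x) < rate) stop("lever trace shorter than 1 s")
  if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0 || anyNA(x)) {
    warning("flat or NaN lever trace; no movements")
    return(empty_bouts())
  }
  if (rate > 1000) {
    q <- round(rate / 1000)
    x <- signal::decimate(x, q)
    rate <- rate / q
  }

  # center on the session median so filter edge transients do not depend on
  # the absolute lever offset (segmentation is displacement-relative)
  x <- x - stats::median(x)
  bf <- signal::butter(4, 10 / (rate / 2), type = "low")
  xs <- signal::filtfilt(bf, x)
  vel <- c(0, diff(xs)) * rate
  vel <- moving_average(vel, round(0.005 * rate))
  env <- hilbert_envelope(vel)

  runs <- binary_runs(env > envelope_threshold)
  if (nrow(runs) == 0L) return(empty_bouts())

  ext <- round(extend_s * rate)
  starts <- pmax(runs[, "onset"] - ext, 1L)
  ends <- pmin(runs[, "offset"] - 1L + ext, length(x))

  # merge bouts separated by < merge_gap_s (applied after the extension)
  gap <- round(merge_gap_s * rate)
  merged_s <- starts[1]
  merged_e <- ends[1]
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      if (starts[i] - merged_e[length(merged_e)] < gap) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], ends[i])
      } else {
        merged_s <- c(merged_s, starts[i])
        merged_e <- c(merged_e, ends[i])
      }
    }
  }

  # refine against rest-period displacement threshold
  noise <- x - xs
  thr_q <- stats::quantile(abs(noise), 0.99, names = FALSE)
  rw <- round(rest_window_s * rate)
  out_s <- numeric(length(merged_s))
  out_e <- numeric(length(merged_s))
  for (i in seq_along(merged_s)) {
    # rest estimated just outside the scan range so the refined start can
    # move up to one rest window earlier than the tentative envelope start
    s0 <- max(1L, merged_s[i] - rw)
    e0 <- min(length(x), merged_e[i] + rw)
    pre <- xs[max(1, s0 - rw):max(1, s0 - 1)]
    post <- xs[min(length(x), e0 + 1):min(length(x), e0 + rw)]
    rest <- stats::median(c(pre, post))
    # crossings are read off the smoothed trace: the threshold is the 99th
    # percentile of the smoothing residual, which the smoothed trace only
    # clears during genuine movement
    dev <- abs(xs[s0:e0] - rest) > thr_q
    idx <- which(dev)
    if (length(idx) == 0L) {
      out_s[i] <- merged_s[i]
      out_e[i] <- merged_e[i]
    } else {
      out_s[i] <- s0 + idx[1] - 1L
      out_e[i] <- s0 + idx[length(idx)] - 1L
    }
  }

  start_s <- (out_s - 1) / rate
  end_s <- (out_e - 1) / rate
  rewarded <- rep(FALSE, length(start_s))
  cued <- rep(FALSE, length(start_s))
  if (!is.null(lever$trials) && nrow(lever$trials)) {
    tr <- lever$trials
    for (i in seq_along(start_s)) {
      rewarded[i] <- any(!is.na(tr$reward_s) &
                           tr$reward_s >= start_s[i] & tr$reward_s <= end_s[i])
      # cued: bout starts during its trial's cue period, which lasts at
      # most 10 s and closes at the reward
      j <- findInterval(start_s[i], tr$cue_s)
      if (j >= 1) {
        cue_end <- tr$cue_s[j] + 10
        if (!is.na(tr$reward_s[j])) cue_end <- min(cue_end, tr$reward_s[j])
        cued[i] <- start_s[i] >= tr$cue_s[j] && start_s[i] <= cue_end
      }
    }
  }
  data.frame(start_s = start_s, end_s = end_s,
             rewarded = rewarded, cued = cued)
}

empty_bouts <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             rewarded = logical(0), cued = logical(0))
}

# Fixed-length lever snippets aligned to movement onsets, at 1 kHz.
movement_windows <- function(lever, onsets, pre_s = 0.5, post_s = 1.5) {
  x <- lever$samples
  rate <- lever$rate
  if (rate > 1000) {
    q <- round(rate / 1000)
    x <- signal::decimate(x, q)
    rate <- rate / q
  }
  len <- round((pre_s + post_s) * rate)
  rows <- lapply(onsets, function(o) {
    i0 <- round((o - pre_s) * rate) + 1L
    i1 <- i0 + len - 1L
    if (i0 < 1L || i1 > length(x)) return(NULL)
    x[i0:i1]
  })
  ok <- !vapply(rows, is.null, TRUE)
  m <- do.call(rbind, rows[ok])
  attr(m, "onsets") <- onsets[ok]
  m
}

#' Session-by-session correlogram of rewarded movement trajectories
#'
#' For each pair of sessions, the median pairwise Pearson correlation between
#' 3-s onset-aligned rewarded-movement trajectories (within-session pairs on
#' the diagonal).
#'
#' @param sessions list of `lever_trace` objects.
#' @param bouts_list optional list of precomputed [segment_movements()]
#'   tables, one per session.
#' @param window_s trajectory window from movement onset, s.
#' @return A symmetric `length(sessions)` square matrix; cells with fewer
#'   than two rewarded movements available are `NA`.
#' @export
movement_correlogram <- function(sessions, bouts_list = NULL, window_s = 3) {
  if (is.null(bouts_list)) bouts_list <- lapply(sessions, segment_movements)
  wins <- mapply(function(lever, bouts) {
    on <- bouts$start_s[bouts$rewarded]
    movement_windows(lever, on, pre_s = 0, post_s = window_s)
  }, sessions, bouts_list, SIMPLIFY = FALSE)
  k <- length(sessions)
  m <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      wi <- wins[[i]]
      wj <- wins[[j]]
      if (is.null(wi) || is.null(wj)) next
      if (i == j) {
        if (nrow(wi) < 2L) next
        cm <- stats::cor(t(wi))
        m[i, i] <- stats::median(cm[upper.tri(cm)])
      } else {
        if (nrow(wi) < 1L || nrow(wj) < 1L) next
        cm <- stats::cor(t(wi), t(wj))
        m[i, j] <- m[j, i] <- stats::median(cm)
      }
    }
  }
  m
}

#' Extract movements coincident with a spine's activity
#'
#' Selects movement bouts that overlap at least one active period of the
#' spine, discards prolonged movements (> `max_duration_s`), excludes any
#' movement whose onset-aligned window (`pre_s` before to `post_s` after
#' onset) overlaps another movement's window, and returns the fixed-length
#' lever snippets of the survivors.
#'
#' @param bouts [segment_movements()] table.
#' @param train an `event_train` for the spine (see [detect_events()]).
#' @param lever the session's `lever_trace`.
#' @param frame_times frame clock times (s) matching `train`.
#' @param pre_s,post_s window around movement onset, s.
#' @param max_duration_s movements longer than this are excluded.
#' @return A matrix of lever snippets (one row per retained movement), with
#'   the matching onsets in `attr(, "onsets")`; `NULL` when none remain.
#' @export
extract_spine_movements <- function(bouts, train, lever, frame_times,
                                    pre_s = 0.5, post_s = 1.5,
                                    max_duration_s = 3) {
  if (nrow(bouts) == 0L) return(NULL)
  # exclusion windows computed over all movements of the session
  w0 <- bouts$start_s - pre_s
  w1 <- bouts$start_s + post_s
  overlapped <- vapply(seq_len(nrow(bouts)), function(i) {
    any(w0[-i] < w1[i] & w1[-i] > w0[i])
  }, TRUE)
  keep <- !overlapped & (bouts$end_s - bouts$start_s) <= max_duration_s
  keep <- keep & bouts_coincident(bouts, train, frame_times)
  if (!any(keep)) return(NULL)
  m <- movement_windows(lever, bouts$start_s[keep], pre_s, post_s)
  if (!is.null(m)) attr(m, "rewarded") <- bouts$rewarded[keep][
    match(attr(m, "onsets"), bouts$start_s[keep])]
  m
}

# Which bouts overlap >= 1 active frame of the train.
bouts_coincident <- function(bouts, train, frame_times) {
  at <- frame_times[train$active]
  vapply(seq_len(nrow(bouts)), function(i) {
    any(at >= bouts$start_s[i] & at <= bouts$end_s[i])
  }, TRUE)
}

#' Stereotypy of movements encoded by a spine
#'
#' Mean pairwise Pearson correlation between all onset-aligned movement
#' snippets associated with a spine's activity.
#'
#' @param windows snippet matrix from [extract_spine_movements()].
#' @return Mean pairwise correlation, or `NA` with fewer than two snippets.
#' @export
stereotypy <- function(windows) {
  mean_pairwise_cor(windows)
}

#' Learned movement pattern and per-spine LMP correlation
#'
#' The learned movement pattern (LMP) is the average lever trajectory of
#' rewarded movements that started after cue onset in the late training
#' sessions. Each spine's LMP correlation is the mean Pearson correlation
#' between the LMP and the movements coincident with its activity.
#'
#' @param late_sessions list of late-session `lever_trace` objects.
#' @param windows snippet matrix for one spine ([extract_spine_movements()]).
#' @param bouts_list optional precomputed bout tables for the late sessions.
#' @param pre_s,post_s window around movement onset, s (must match the
#'   window used for `windows`).
#' @return list with `lmp` (numeric trajectory) and `correlation` (mean r of
#'   `windows` with the LMP; `NA` when `windows` is empty).
#' @export
lmp_and_correlation <- function(late_sessions, windows, bouts_list = NULL,
                                pre_s = 0.5, post_s = 1.5) {
  if (is.null(bouts_list)) bouts_list <- lapply(late_sessions, segment_movements)
  snips <- mapply(function(lever, bouts) {
    on <- bouts$start_s[bouts$rewarded & bouts$cued]
    movement_windows(lever, on, pre_s, post_s)
  }, late_sessions, bouts_list, SIMPLIFY = FALSE)
  snips <- do.call(rbind, snips[!vapply(snips, is.null, TRUE)])
  if (is.null(snips) || nrow(snips) == 0L) {
    stop("no rewarded cued movements in the late sessions")
  }
  lmp <- colMeans(snips)
  corr <- NA_real_
  if (!is.null(windows) && nrow(windows) >= 1L) {
    corr <- mean(apply(windows, 1L, function(w) stats::cor(w, lmp)))
  }
  list(lmp = lmp, correlation = corr, n_movements = nrow(snips))
}
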