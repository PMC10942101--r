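#' Estimate the time-varying fluorescence baseline F0
#'
#' Iterative baseline estimation on a raw ROI trace: (1) smooth the currently
#' inactive frames with a long window to obtain a provisional F0, (2) compute
#' provisional dF/F0 and its mirrored-negative noise SD, (3) mask frames
#' provisionally active (0.5-s-smoothed dF/F0 above twice the noise), and
#' (4) repeat until the active mask is stable or `max_iter` is reached.
#' Blocks (acquisition gaps) are processed independently. If nearly every
#' frame is masked as active the routine falls back to a running
#' 10th-percentile baseline with a warning.
#'
#' @param raw raw fluorescence per frame.
#' @param frame_rate frames per second.
#' @param block optional per-frame block index (acquisition gaps).
#' @param window_s smoothing window for the baseline, s.
#' @param max_iter maximum mask iterations.
#' @return Numeric F0 series, same length as `raw`.
#' @export
estimate_baseline <- function(raw, frame_rate, block = NULL,
                              window_s = 30, max_iter = 10) {
  n <- length(raw)
  if (n < 60 * frame_rate) {
    warning("baseline estimated from less than 60 s of frames")
  }
  if (is.null(block)) block <- rep(1L, n)
  half <- max(1L, round(window_s * frame_rate / 2))
  sm_half <- max(1L, round(0.25 * frame_rate))
  out <- numeric(n)
  for (b in unique(block)) {
    idx <- which(block == b)
    x <- raw[idx]
    keep <- rep(TRUE, length(x))
    f0 <- masked_roll_mean(x, keep, half)
    for (it in seq_len(max_iter)) {
      dff <- (x - f0) / f0
      neg <- dff[dff < 0]
      if (length(neg) == 0L) break
      sigma <- sqrt(mean(neg^2))
      sm <- roll_sum_partial(dff, sm_half) /
        roll_count_partial(length(dff), sm_half)
      new_keep <- !(sm > 2 * sigma)
      if (mean(new_keep) < 0.05) {
        warning("nearly all frames active; using running-percentile baseline")
        f0 <- running_percentile(x, frame_rate, window_s, 0.10)
        keep <- new_keep
        break
      }
      if (identical(new_keep, keep)) break
      keep <- new_keep
      f0 <- masked_roll_mean(x, keep, half)
    }
    out[idx] <- f0
  }
  out
}

# Coarse running percentile: percentile per window-sized chunk, then linear
# interpolation between chunk centers.
running_percentile <- function(x, frame_rate, window_s, p) {
  n <- length(x)
  w <- max(2L, round(window_s * frame_rate))
  starts <- seq(1L, n, by = w)
  centers <- pmin(starts + w %/% 2L, n)
  q <- vapply(starts, function(s) {
    stats::quantile(x[s:min(s + w - 1L, n)], p, names = FALSE)
  }, 0)
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' Compute the normalized dF/F0 trace
#'
#' `dff = (raw - f0) / f0`, then denoised with a 0.5-s moving-average window
#' (applied per block so smoothing never crosses acquisition gaps).
#'
#' @param raw raw fluorescence per frame.
#' @param f0 baseline from [estimate_baseline()]; must be positive.
#' @param frame_rate frames per second.
#' @param block optional per-frame block index.
#' @param smooth_s denoising window, s; `0` disables smoothing.
#' @return list with `dff` (smoothed), `dff_raw` (unsmoothed), `f0`, and
#'   `sigma` (mirrored-negative noise SD of the unsmoothed dF/F0).
#' @export
compute_dff <- function(raw, f0, frame_rate, block = NULL, smooth_s = 0.5) {
  bad <- which(f0 <= 0)
  if (length(bad)) stop(sprintf("non-positive baseline at frame %d", bad[1]))
  dff_raw <- (raw - f0) / f0
  if (is.null(block)) block <- rep(1L, length(raw))
  dff <- dff_raw
  if (smooth_s > 0) {
    for (b in unique(block)) {
      idx <- which(block == b)
      dff[idx] <- moving_average(dff_raw[idx], round(smooth_s * frame_rate))
    }
  }
  sigma <- tryCatch(estimate_noise(dff_raw), error = function(e) NA_real_)
  list(dff = dff, dff_raw = dff_raw, f0 = f0, sigma = sigma)
}

#' Noise SD from mirrored negative dF/F0 values
#'
#' The noise of a dF/F0 trace is the population SD of its negative values
#' mirrored about the origin, i.e. of the multiset {negatives, -negatives}.
#' Since that multiset has zero mean by construction, this equals
#' `sqrt(mean(negatives^2))`.
#'
#' @param dff dF/F0 trace.
#' @return Noise SD (scalar, >= 0).
#' @export
estimate_noise <- function(dff) {
  neg <- dff[dff < 0]
  if (length(neg) == 0L) stop("no negative dF/F0 values; degenerate trace")
  sqrt(mean(neg^2))
}

#' Detect activity events in a dF/F0 trace
#'
#' Active portions are frames where the 1-s local-linear (LOESS-style)
#' smoothed dF/F0 exceeds `k` times the noise (`k = 2` for spines, `3` for
#' dendritic calcium). Each active portion is extended backward along the
#' unsmoothed trace to the most recent crossing of the 1x-noise baseline
#' threshold, and forward while the smoothed trace remains above the baseline
#' threshold. For the iGluSnFR2 sensor, events whose peak (unsmoothed) dF/F0
#' is below 0.2 are discarded. Events never span acquisition gaps.
#'
#' @param dff smoothed dF/F0 trace ([compute_dff()]`$dff`).
#' @param sigma noise SD ([estimate_noise()] on the unsmoothed trace).
#' @param frame_rate frames per second.
#' @param dff_raw unsmoothed dF/F0 used for backward extension and the peak
#'   floor; defaults to `dff`.
#' @param block optional per-frame block index.
#' @param roi_kind `"spine"`, `"dendrite"`, or `"soma"`.
#' @param sensor sensor name; `"iGluSnFR2"` enables the 0.2 peak floor.
#' @param active_k override of the active-threshold noise multiple.
#' @param min_peak override of the peak floor (`0` disables it).
#' @param smooth_s span of the event-detection smoother, s.
#' @return An `event_train`: list with `active` (logical per frame), `events`
#'   (data.frame `onset`, `offset` as half-open 1-based frame indices, plus
#'   `onset_s`, `offset_s`, `peak_dff`), `n_frames`, `frame_rate`.
#' @export
detect_events <- function(dff, sigma, frame_rate, dff_raw = dff,
                          block = NULL, roi_kind = c("spine", "dendrite", "soma"),
                          sensor = "iGluSnFR2", active_k = NULL,
                          min_peak = NULL, smooth_s = 1) {
  roi_kind <- match.arg(roi_kind)
  if (is.null(active_k)) active_k <- if (roi_kind == "spine") 2 else 3
  if (is.null(min_peak)) {
    min_peak <- if (roi_kind == "spine" && sensor == "iGluSnFR2") 0.2 else 0
  }
  n <- length(dff)
  if (is.null(block)) block <- rep(1L, n)
  half <- max(1L, round(smooth_s * frame_rate / 2))

  events <- list()
  for (b in unique(block)) {
    idx <- which(block == b)
    sm <- loess_kernel_smooth(dff[idx], half)
    base_runs <- binary_runs(sm > sigma)
    if (nrow(base_runs) == 0L) next
    act <- sm > active_k * sigma
    for (r in seq_len(nrow(base_runs))) {
      lo <- base_runs[r, 1L]
      hi <- base_runs[r, 2L]            # half-open
      if (!any(act[lo:(hi - 1L)])) next
      # backward extension: from the event's raw peak, walk back along the
      # unsmoothed trace to the most recent 1-sigma (baseline) crossing
      p <- lo + which.max(dff_raw[idx][lo:(hi - 1L)]) - 1L
      j <- p
      while (j > 1L && dff_raw[idx][j - 1L] > sigma) j <- j - 1L
      onset <- j
      peak <- max(dff_raw[idx][onset:(hi - 1L)])
      if (peak < min_peak) next
      events[[length(events) + 1L]] <-
        c(onset = idx[onset], offset = idx[hi - 1L] + 1L, peak = peak)
    }
  }
  if (length(events) == 0L) {
    return(empty_train(n, frame_rate))
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev[, "onset"]), , drop = FALSE]
  # merge overlapping events (backward extension can reach a previous event)
  merged <- list(ev[1, ])
  if (nrow(ev) > 1L) {
    for (i in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      if (ev[i, "onset"] < last["offset"]) {
        last["offset"] <- max(last["offset"], ev[i, "offset"])
        last["peak"] <- max(last["peak"], ev[i, "peak"])
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- ev[i, ]
      }
    }
  }
  ev <- do.call(rbind, merged)
  active <- rep(FALSE, n)
  for (i in seq_len(nrow(ev))) active[ev[i, "onset"]:(ev[i, "offset"] - 1L)] <- TRUE
  structure(list(
    active = active,
    events = data.frame(
      onset = as.integer(ev[, "onset"]), offset = as.integer(ev[, "offset"]),
      onset_s = (ev[, "onset"] - 1) / frame_rate,
      offset_s = (ev[, "offset"] - 1) / frame_rate,
      peak_dff = ev[, "peak"]
    ),
    n_frames = n, frame_rate = frame_rate
  ), class = "event_train")
}

empty_train <- function(n, frame_rate) {
  structure(list(
    active = rep(FALSE, n),
    events = data.frame(onset = integer(0), offset = integer(0),
                        onset_s = numeric(0), offset_s = numeric(0),
                        peak_dff = numeric(0)),
    n_frames = n, frame_rate = frame_rate
  ), class = "event_train")
}

#' Build an event train directly from a binary activity vector
#'
#' @param active logical per-frame activity.
#' @param frame_rate frames per second.
#' @param block optional per-frame block index; runs never span blocks.
#' @return An `event_train`.
#' @export
train_from_binary <- function(active, frame_rate, block = NULL) {
  runs <- binary_runs_blocked(active, block)
  structure(list(
    active = as.logical(active),
    events = data.frame(
      onset = as.integer(runs[, 1L]), offset = as.integer(runs[, 2L]),
      onset_s = (runs[, 1L] - 1) / frame_rate,
      offset_s = (runs[, 2L] - 1) / frame_rate,
      peak_dff = rep(NA_real_, nrow(runs))
    ),
    n_frames = length(active), frame_rate = frame_rate
  ), class = "event_train")
}

#' Event amplitudes and decay kinetics
#'
#' For each event: find the peak of the dF/F0 trace in a 3-s window starting
#' 1 s before and ending 2 s after event onset (minimum peak separation
#' 0.5 s; minimum peak height the median plus SD of the peri-event window),
#' then fit `A * exp(-t / tau)` from the maximum peak to the window end.
#' Events where no peak is found or the fit fails are flagged
#' `fit_ok = FALSE`.
#'
#' @param dff dF/F0 trace.
#' @param train [detect_events()] result.
#' @param frame_rate frames per second.
#' @return data.frame with one row per event: `onset`, `amplitude`, `tau_s`,
#'   `fit_ok`.
#' @export
event_shapes <- function(dff, train, frame_rate) {
  ev <- train$events
  if (nrow(ev) == 0L) stop("empty event train")
  pre <- round(1 * frame_rate)
  post <- round(2 * frame_rate)
  res <- lapply(seq_len(nrow(ev)), function(i) {
    i0 <- ev$onset[i] - pre
    i1 <- ev$onset[i] + post
    if (i0 < 1L || i1 > length(dff)) {
      warning("peri-event window truncated at trace bounds")
      i0 <- max(i0, 1L)
      i1 <- min(i1, length(dff))
    }
    w <- dff[i0:i1]
    minh <- stats::median(w) + stats::sd(w)
    pk <- pracma::findpeaks(w, minpeakheight = minh,
                            minpeakdistance = max(1L, round(0.5 * frame_rate)))
    if (is.null(pk)) {
      return(data.frame(onset = ev$onset[i], amplitude = NA_real_,
                        tau_s = NA_real_, fit_ok = FALSE))
    }
    j <- pk[which.max(pk[, 1L]), 2L]
    amp <- w[j]
    seg <- w[j:length(w)]
    t <- (seq_along(seg) - 1) / frame_rate
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                        data = data.frame(y = seg, t = t),
                        start = list(A = amp, tau = 0.5),
                        lower = c(0, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(data.frame(onset = ev$onset[i], amplitude = amp,
                        tau_s = NA_real_, fit_ok = FALSE))
    }
    cf <- stats::coef(fit)
    # a flat or rising post-peak segment gives a boundary/degenerate tau
    ok <- is.finite(cf["tau"]) && cf["tau"] > 2e-3 &&
      stats::sd(seg) > 1e-12 && cf["tau"] < 100
    data.frame(onset = ev$onset[i], amplitude = unname(cf["A"]),
               tau_s = unname(cf["tau"]), fit_ok = ok)
  })
  do.call(rbind, res)
}
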