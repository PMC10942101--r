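#' Movement-related spine classification by permutation
#'
#' The observed statistic is the dot product of the binarized movement mask
#' (1 during movement bouts, 0 otherwise, at frame resolution) with the
#' continuous dF/F0 trace. The null distribution is built by relocating the
#' movement intervals uniformly at random within the session (durations
#' preserved, non-overlap enforced) `n_shuffles` times; a spine is
#' movement-related when the observed value exceeds the 97.5th percentile of
#' the shuffled values. A circular-shift null is available as an alternative
#' shuffle scheme.
#'
#' @param dff continuous dF/F0 trace.
#' @param bouts [segment_movements()] table.
#' @param frame_times frame clock times, s.
#' @param n_shuffles number of relocations (10,000 in the full analysis).
#' @param seed RNG seed for the shuffles.
#' @param scheme `"relocate"` (default) or `"circular"` shift of the mask.
#' @param quantile_cut null quantile for the decision rule.
#' @return An `mrs_result`: list with `observed`, `null_q` (the decision
#'   quantile of the null), `p_exceed` (fraction of shuffles at or above the
#'   observed value), `is_mrs`, `n_shuffles`. `NA` when there are no bouts.
#' @export
classify_mrs <- function(dff, bouts, frame_times, n_shuffles = 10000,
                         seed = 1L, scheme = c("relocate", "circular"),
                         quantile_cut = 0.975) {
  scheme <- match.arg(scheme)
  if (is.null(bouts) || nrow(bouts) == 0L) {
    return(structure(list(observed = NA_real_, null_q = NA_real_,
                          p_exceed = NA_real_, is_mrs = NA,
                          n_shuffles = n_shuffles), class = "mrs_result"))
  }
  mask <- movement_mask(bouts, frame_times)
  durations <- binary_runs(mask)
  durations <- as.integer(durations[, 2L] - durations[, 1L])
  observed <- sum(dff * mask)
  set.seed(seed)
  if (scheme == "relocate") {
    null <- shuffled_interval_sums(dff, durations, n_shuffles)
  } else {
    n <- length(dff)
    shifts <- sample.int(n, n_shuffles, replace = TRUE)
    cs <- c(0, cumsum(dff))
    runs <- binary_runs(mask)
    null <- vapply(shifts, function(s) {
      on <- ((runs[, 1L] - 1L + s) %% n) + 1L
      off <- on + (runs[, 2L] - runs[, 1L]) - 1L
      sum(ifelse(off <= n, cs[off + 1L] - cs[on],
                 cs[n + 1L] - cs[on] + cs[off - n + 1L]))
    }, 0)
  }
  q <- stats::quantile(null, quantile_cut, names = FALSE)
  structure(list(observed = observed, null_q = q,
                 p_exceed = mean(null >= observed),
                 is_mrs = observed > q, n_shuffles = n_shuffles),
            class = "mrs_result")
}

# Frame-resolution movement mask from a bout table.
movement_mask <- function(bouts, frame_times) {
  mask <- rep(FALSE, length(frame_times))
  for (i in seq_len(nrow(bouts))) {
    mask <- mask | (frame_times >= bouts$start_s[i] &
                      frame_times <= bouts$end_s[i])
  }
  mask
}

#' Movement reliability and specificity of a spine
#'
#' Reliability is the fraction of movements coincident with the spine's
#' activity; specificity is the fraction of the spine's active frames that
#' fall inside movement bouts.
#'
#' @param train the spine's `event_train`.
#' @param bouts [segment_movements()] table (>= 1 movement).
#' @param frame_times frame clock times, s.
#' @return list with `reliability` and `specificity` (`NA` specificity for a
#'   silent spine, whose reliability is 0).
#' @export
reliability_specificity <- function(train, bouts, frame_times) {
  stopifnot(nrow(bouts) >= 1L)
  if (!any(train$active)) {
    return(list(reliability = 0, specificity = NA_real_))
  }
  coin <- bouts_coincident(bouts, train, frame_times)
  mask <- movement_mask(bouts, frame_times)
  list(reliability = mean(coin),
       specificity = sum(train$active & mask) / sum(train$active))
}

#' Peak timing of movement-aligned spine activity
#'
#' Averages the dF/F0 trace over onset-aligned windows of the movements
#' during which the spine was active, z-scores the average, and reports the
#' time of its peak relative to movement onset.
#'
#' @param dff dF/F0 trace.
#' @param bouts [segment_movements()] table.
#' @param train the spine's `event_train`.
#' @param frame_times frame clock times, s.
#' @param pre_s,post_s alignment window around movement onset, s.
#' @return list with `peak_time_s`, `profile` (z-scored mean trace), and
#'   `n_movements`; `NA`/`NULL` when no coincident movement yields a full
#'   window or the mean trace is flat.
#' @export
peak_timing <- function(dff, bouts, train, frame_times,
                        pre_s = 0.5, post_s = 1.5) {
  coin <- which(bouts_coincident(bouts, train, frame_times))
  if (length(coin) == 0L) {
    return(list(peak_time_s = NA_real_, profile = NULL, n_movements = 0L))
  }
  fr <- train$frame_rate
  npre <- round(pre_s * fr)
  npost <- round(post_s * fr)
  rows <- lapply(coin, function(i) {
    j <- findInterval(bouts$start_s[i], frame_times)
    if (j - npre < 1L || j + npost > length(dff)) return(NULL)
    dff[(j - npre):(j + npost)]
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(list(peak_time_s = NA_real_, profile = NULL, n_movements = 0L))
  }
  prof <- colMeans(do.call(rbind, rows))
  if (stats::sd(prof) == 0) {
    return(list(peak_time_s = NA_real_, profile = NULL,
                n_movements = length(rows)))
  }
  z <- (prof - mean(prof)) / stats::sd(prof)
  list(peak_time_s = (which.max(z) - 1L - npre) / fr,
       profile = z, n_movements = length(rows))
}

#' Fraction of a spine's coincident movements that were rewarded
#'
#' @param train the spine's `event_train`.
#' @param bouts [segment_movements()] table.
#' @param frame_times frame clock times, s.
#' @return Fraction in `[0, 1]`, or `NA` with no coincident movements.
#' @export
rewarded_fraction <- function(train, bouts, frame_times) {
  coin <- bouts_coincident(bouts, train, frame_times)
  if (!any(coin)) return(NA_real_)
  mean(bouts$rewarded[coin])
}
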