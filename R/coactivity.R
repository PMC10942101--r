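#' Pairwise co-activity between two spine event trains
#'
#' A single co-activity event is a maximal run of frames during which both
#' binary traces are simultaneously active (runs are clipped at acquisition
#' gaps). The raw co-activity rate is co-events per minute of imaged time;
#' the normalized rate divides by the geometric mean of the two spines'
#' event rates. A Pearson correlation of the binarized traces is also
#' reported (`use_dff` switches it to the continuous traces).
#'
#' @param train_a,train_b `event_train` objects on the same frame clock.
#' @param imaged_minutes minutes of imaged (on-block) time.
#' @param block optional per-frame block index.
#' @param dff_a,dff_b continuous traces, used only when `use_dff = TRUE`.
#' @param use_dff compute the correlation on continuous dF/F0 instead of the
#'   binarized traces.
#' @return list with `co_rate`, `norm_co_rate`, `r`, `n_co_events`,
#'   `rate_a`, `rate_b`; `NULL` when either spine has no events (the pair is
#'   excluded).
#' @export
pairwise_coactivity <- function(train_a, train_b, imaged_minutes,
                                block = NULL, dff_a = NULL, dff_b = NULL,
                                use_dff = FALSE) {
  stopifnot(train_a$n_frames == train_b$n_frames)
  na <- nrow(train_a$events)
  nb <- nrow(train_b$events)
  if (na == 0L || nb == 0L) return(NULL)
  co <- train_a$active & train_b$active
  runs <- binary_runs_blocked(co, block)
  co_rate <- nrow(runs) / imaged_minutes
  rate_a <- na / imaged_minutes
  rate_b <- nb / imaged_minutes
  r <- if (use_dff) {
    suppressWarnings(stats::cor(dff_a, dff_b))
  } else {
    suppressWarnings(stats::cor(as.numeric(train_a$active),
                                as.numeric(train_b$active)))
  }
  list(co_rate = co_rate,
       norm_co_rate = co_rate / sqrt(rate_a * rate_b),
       r = r, n_co_events = nrow(runs),
       rate_a = rate_a, rate_b = rate_b)
}

#' Assign an interspine distance to its 5-um bin center
#'
#' Bins are half-open on the left: the 2.5-um bin holds distances in
#' (0, 5], the 7.5-um bin (5, 10], and so on.
#'
#' @param d distances, um.
#' @param bin_width bin width, um.
#' @return Bin centers, um.
#' @export
distance_bin <- function(d, bin_width = 5) {
  (ceiling(d / bin_width) - 0.5) * bin_width
}

#' Distance-binned co-activity curve
#'
#' @param pairs data.frame with columns `distance_um` and `norm_co_rate`
#'   (one row per spine pair).
#' @param bin_width bin width, um.
#' @return data.frame `bin_center`, `mean_norm_co_rate`, `n_pairs`, ordered
#'   by bin center.
#' @export
coactivity_curve <- function(pairs, bin_width = 5) {
  stopifnot(nrow(pairs) >= 1L)
  bin <- distance_bin(pairs$distance_um, bin_width)
  agg <- stats::aggregate(pairs$norm_co_rate, list(bin_center = bin),
                          function(v) c(mean(v), length(v)))
  data.frame(bin_center = agg$bin_center,
             mean_norm_co_rate = agg$x[, 1L],
             n_pairs = agg$x[, 2L])
}

#' Co-activity environment scores around an eliminated spine
#'
#' Three groups per target eliminated spine: (i) the eliminated-spine score,
#' the mean normalized co-activity between the target and its neighbors
#' within `radius`; (ii) the nearby environment, the mean pairwise
#' co-activity among those neighbors themselves, excluding any eliminated
#' spines; (iii) the distant environment, the mean local (<= `radius`)
#' co-activity of spines farther than `radius` from the target, excluding
#' spines in the nearby group and spines within `radius` of any non-target
#' eliminated spine.
#'
#' @param coact symmetric matrix of normalized co-activity rates (NA where a
#'   pair is excluded), rows/cols named by spine id.
#' @param positions named numeric vector of positions along the dendrite, um.
#' @param labels named character vector, `"stable"` / `"eliminated"`.
#' @param target id of the target eliminated spine.
#' @param radius neighborhood radius, um.
#' @return list with `eliminated_score`, `nearby_env`, `distant_env` (each a
#'   mean over >= 1 pair or `NA`), and `values`, the underlying per-pair
#'   normalized co-activity values of each group.
#' @export
environment_scores <- function(coact, positions, labels, target, radius = 10) {
  stopifnot(labels[target] == "eliminated")
  ids <- names(positions)
  d_to <- function(a, b) abs(positions[a] - positions[b])
  nbrs <- ids[ids != target & d_to(ids, target) <= radius]

  pair_val <- function(a, b) coact[a, b]
  mean_or_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }

  elim_vals <- if (length(nbrs)) {
    vapply(nbrs, function(s) pair_val(target, s), 0)
  } else numeric(0)
  elim_score <- mean_or_na(elim_vals)

  env <- setdiff(nbrs, ids[labels[ids] == "eliminated"])
  nearby_vals <- numeric(0)
  nearby <- NA_real_
  if (length(env) >= 2L) {
    prs <- utils::combn(env, 2L)
    nearby_vals <- apply(prs, 2L, function(p) pair_val(p[1], p[2]))
    nearby <- mean_or_na(nearby_vals)
  }

  other_elim <- ids[labels == "eliminated" & ids != target]
  near_other <- unique(unlist(lapply(other_elim, function(e) {
    ids[d_to(ids, e) <= radius]
  })))
  distant_targets <- ids[d_to(ids, target) > radius]
  distant_targets <- setdiff(distant_targets, c(nbrs, near_other))
  dvals <- c()
  excluded_partners <- c(nbrs, near_other)
  for (s in distant_targets) {
    partners <- ids[ids != s & d_to(ids, s) <= radius]
    partners <- setdiff(partners, excluded_partners)
    if (length(partners)) {
      dvals <- c(dvals, vapply(partners, function(p) pair_val(s, p), 0))
    }
  }
  distant <- mean_or_na(dvals)

  list(eliminated_score = elim_score, nearby_env = nearby,
       distant_env = distant,
       values = list(eliminated = elim_vals[!is.na(elim_vals)],
                     nearby = nearby_vals[!is.na(nearby_vals)],
                     distant = if (is.null(dvals)) numeric(0)
                               else dvals[!is.na(dvals)]))
}

#' Spine-dendrite co-activity
#'
#' Same co-event counting and geometric-mean normalization as spine pairs,
#' applied to a spine train and its dendrite's calcium train, plus the
#' fraction of spine events that overlap at least one dendritic event.
#'
#' @param spine_train,dendrite_train `event_train` objects on the same clock.
#' @param imaged_minutes minutes of imaged time.
#' @param block optional per-frame block index.
#' @return list with `norm_co_rate`, `co_rate`, `coincident_fraction`;
#'   `NULL` when the dendrite (or the spine) is silent.
#' @export
spine_dendrite_coactivity <- function(spine_train, dendrite_train,
                                      imaged_minutes, block = NULL) {
  core <- pairwise_coactivity(spine_train, dendrite_train, imaged_minutes,
                              block = block)
  if (is.null(core)) return(NULL)
  sev <- spine_train$events
  dev <- dendrite_train$events
  hit <- vapply(seq_len(nrow(sev)), function(i) {
    any(dev$onset < sev$offset[i] & dev$offset > sev$onset[i])
  }, TRUE)
  list(norm_co_rate = core$norm_co_rate, co_rate = core$co_rate,
       coincident_fraction = mean(hit))
}
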