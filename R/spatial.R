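#' Local movement-related-spine density around a spine
#'
#' Counts movement-related spines within `radius` um of dendritic distance
#' from the target and normalizes by the dendritic length actually surveyed:
#' `nf = min(radius, distance to left branch end) + min(radius, distance to
#' right branch end)`, so 10 um <= nf <= 20 um for the default radius on
#' branches longer than the window.
#'
#' @param target_pos position of the target spine along the branch, um.
#' @param mrs_positions positions of movement-related spines on the same
#'   branch (excluding the target itself), um.
#' @param branch_range `c(lo, hi)` extent of the branch, um.
#' @param radius neighborhood radius, um (boundary ties included).
#' @return list with `density` (spines per um), `count`, and `nf` (um).
#' @export
local_mrs_density <- function(target_pos, mrs_positions,
                              branch_range, radius = 10) {
  lo <- branch_range[1]
  hi <- branch_range[2]
  stopifnot(hi > lo, target_pos >= lo, target_pos <= hi)
  if (hi - lo < radius) {
    warning("branch shorter than the density window; nf is the branch length")
  }
  nf <- min(radius, target_pos - lo) + min(radius, hi - target_pos)
  count <- sum(abs(mrs_positions - target_pos) <= radius)
  list(density = count / nf, count = count, nf = nf)
}

#' One-sided label-shuffle test
#'
#' Permutes the stable/eliminated labels across the pooled spine set (spine
#' positions and counts fixed, only labels move), recomputes the statistic
#' for each shuffle, and reports the one-sided p-value as the fraction of
#' shuffled statistics at or beyond the observed value in the direction of
#' the hypothesis.
#'
#' @param statistic_fn function of a label vector returning a scalar.
#' @param labels character/factor vector with >= 2 classes.
#' @param n_shuffles number of label permutations.
#' @param direction `"greater"` (observed expected above the null) or
#'   `"less"`.
#' @param seed RNG seed.
#' @return A `shuffle_test_result`: list with `observed`, `null` (numeric
#'   vector), `p`, `p_label` (reports `< 1/n_shuffles` instead of a literal
#'   zero), `direction`, `n_shuffles`.
#' @export
shuffle_label_test <- function(statistic_fn, labels, n_shuffles = 1000,
                               direction = c("greater", "less"), seed = 1L) {
  direction <- match.arg(direction)
  if (length(unique(labels)) < 2L) {
    stop("labels are degenerate (a single class)")
  }
  observed <- statistic_fn(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i) {
    statistic_fn(sample(labels))
  }, 0)
  p <- if (direction == "greater") mean(null >= observed) else mean(null <= observed)
  structure(list(
    observed = observed, null = null, p = p,
    p_label = if (p == 0) sprintf("< %g", 1 / n_shuffles) else format(p),
    direction = direction, n_shuffles = n_shuffles
  ), class = "shuffle_test_result")
}

#' Dendritic distance to the nearest plasticity event
#'
#' Minimum dendritic distance from a target spine to any spine on the same
#' dendrite carrying the queried plasticity event on the following session,
#' excluding the target itself.
#'
#' @param target_pos target spine position, um.
#' @param event_positions positions of spines displaying the event (the
#'   target, if it carries the event, must not be included).
#' @return Distance in um, or `NA` when no event of that kind exists on the
#'   dendrite (the dendrite is then excluded for that event kind).
#' @export
nearest_plasticity_distance <- function(target_pos, event_positions) {
  if (length(event_positions) == 0L) return(NA_real_)
  min(abs(event_positions - target_pos))
}
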