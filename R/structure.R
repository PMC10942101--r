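#' Spine area from ROI pixel intensities
#'
#' Area is the summed intensity of spine-ROI pixels above background, divided
#' by the mean intensity of the dendritic pixels within 20 um of the spine
#' base (a per-pixel normalizer that cancels expression level and optics),
#' times the physical pixel area given the zoom.
#'
#' @param spine_pixels intensities of the spine ROI pixels.
#' @param background scalar background intensity; pixels at or below it do
#'   not count.
#' @param dendrite_pixels intensities of dendritic pixels within 20 um of the
#'   spine base.
#' @param pixel_area physical area of one pixel, um^2.
#' @return Spine area in um^2.
#' @export
spine_area <- function(spine_pixels, background, dendrite_pixels, pixel_area) {
  stopifnot(length(dendrite_pixels) > 0L, background >= 0, pixel_area > 0)
  dend_mean <- mean(dendrite_pixels)
  if (dend_mean == 0) stop("mean dendrite intensity is zero")
  sum(spine_pixels[spine_pixels > background]) / dend_mean * pixel_area
}

#' Classify a spine's structural plasticity between two sessions
#'
#' The session-to-session area ratio classifies a spine as enlarged
#' (ratio >= `enlarge`), shrunken (ratio <= `shrink`), or unchanged.
#' Boundaries are inclusive.
#'
#' @param area_prev,area_next spine areas (um^2) on consecutive sessions.
#' @param enlarge,shrink classification thresholds on the ratio.
#' @return list with `kind` (`"enlargement"`, `"shrinkage"`, `"none"`, or
#'   `NA` when an area is missing) and `ratio`.
#' @export
classify_plasticity <- function(area_prev, area_next,
                                enlarge = 1.5, shrink = 0.75) {
  if (is.na(area_prev) || is.na(area_next)) {
    return(list(kind = NA_character_, ratio = NA_real_))
  }
  stopifnot(area_prev > 0, area_next > 0)
  ratio <- area_next / area_prev
  kind <- if (ratio >= enlarge) "enlargement"
          else if (ratio <= shrink) "shrinkage"
          else "none"
  list(kind = kind, ratio = ratio)
}

#' Classify spine stability from a 3-session presence vector
#'
#' Presence over (early, middle, late) maps to: stable (1,1,1); eliminated
#' early-to-middle (1,0,0); eliminated middle-to-late (1,1,0) -- such spines
#' also count as stable for early-to-middle analyses; new (0,1,1) or (0,0,1);
#' transient (0,1,0); excluded re-emergent (1,0,1).
#'
#' @param presence logical or 0/1 vector of length 3.
#' @return One of `"stable"`, `"eliminated_EtoM"`, `"eliminated_MtoL"`,
#'   `"new"`, `"transient"`, `"excluded_reemergent"`.
#' @export
classify_stability <- function(presence) {
  stopifnot(length(presence) == 3L)
  p <- as.integer(as.logical(presence))
  key <- paste(p, collapse = "")
  switch(key,
    "111" = "stable",
    "100" = "eliminated_EtoM",
    "110" = "eliminated_MtoL",
    "011" = "new",
    "001" = "new",
    "010" = "transient",
    "101" = "excluded_reemergent",
    "000" = stop("spine absent on every session; ROI should not exist")
  )
}

#' Size-matched small stable spine subset
#'
#' Scans lower-percentile cuts of the stable-spine area distribution (10th to
#' 90th) and, at each cut, compares the subset against the eliminated-spine
#' areas via the median ratio and a Wilcoxon rank-sum test. The selected cut
#' is the one whose median ratio is closest to 1 among cuts where the
#' rank-sum test is non-significant; if no cut is non-significant the
#' best-ratio cut is returned with a warning.
#'
#' @param stable_areas,eliminated_areas numeric area vectors (>= 10 each).
#' @param percentiles percentile grid to scan.
#' @param alpha rank-sum significance level.
#' @return list with `percentile` (selected), `subset` (stable areas at or
#'   below the cut), and `table` (data.frame `percentile`, `median_ratio`,
#'   `rank_sum_p`).
#' @export
match_small_stable <- function(stable_areas, eliminated_areas,
                               percentiles = seq(10, 90, by = 5),
                               alpha = 0.05) {
  stopifnot(length(stable_areas) >= 10L, length(eliminated_areas) >= 10L)
  med_e <- stats::median(eliminated_areas)
  tab <- do.call(rbind, lapply(percentiles, function(p) {
    cut <- stats::quantile(stable_areas, p / 100, names = FALSE)  # type 7
    sub <- stable_areas[stable_areas <= cut]
    pv <- suppressWarnings(
      stats::wilcox.test(sub, eliminated_areas)$p.value)
    data.frame(percentile = p,
               median_ratio = stats::median(sub) / med_e,
               rank_sum_p = pv)
  }))
  ok <- which(tab$rank_sum_p > alpha)
  if (length(ok) == 0L) {
    warning("no percentile yields a non-significant rank-sum test; ",
            "returning the best-ratio cut")
    sel <- which.min(abs(tab$median_ratio - 1))
  } else {
    sel <- ok[which.min(abs(tab$median_ratio[ok] - 1))]
  }
  cut <- stats::quantile(stable_areas, tab$percentile[sel] / 100, names = FALSE)
  list(percentile = tab$percentile[sel],
       subset = stable_areas[stable_areas <= cut],
       table = tab)
}
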