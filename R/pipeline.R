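#' Run fluorescence processing for every ROI of a session
#'
#' Baseline estimation, dF/F0 computation, noise estimation, and event
#' detection for each spine and dendrite trace of a session.
#'
#' @param session a `spine_session` ([generate_session()] or
#'   [read_session()]).
#' @param baseline_window_s baseline smoothing window, s.
#' @return list with `spines` and `dendrites`, each a named list of
#'   per-ROI results (`dff`, `dff_raw`, `sigma`, `train`).
#' @export
process_session <- function(session, baseline_window_s = 30) {
  fr <- session$config$frame_rate
  block <- session$frames$block
  sensor <- session$config$sensor
  one <- function(raw, kind, sens) {
    f0 <- estimate_baseline(raw, fr, block, window_s = baseline_window_s)
    d <- compute_dff(raw, f0, fr, block)
    train <- detect_events(d$dff, d$sigma, fr, dff_raw = d$dff_raw,
                           block = block, roi_kind = kind, sensor = sens)
    list(dff = d$dff, dff_raw = d$dff_raw, sigma = d$sigma, train = train)
  }
  spines <- lapply(seq_len(ncol(session$spine_raw)), function(j) {
    one(session$spine_raw[, j], "spine", sensor)
  })
  names(spines) <- colnames(session$spine_raw)
  dendrites <- lapply(seq_len(ncol(session$dendrite_raw)), function(j) {
    one(session$dendrite_raw[, j], "dendrite", "RCaMP2")
  })
  names(dendrites) <- colnames(session$dendrite_raw)
  list(spines = spines, dendrites = dendrites)
}

#' Pairwise co-activity table for a processed session
#'
#' All same-dendrite spine pairs where both spines displayed activity, with
#' dendritic distance, raw and normalized co-activity rates, and a pair
#' stability label (`"eliminated"` when either member is eliminated).
#'
#' @param session a `spine_session`.
#' @param proc [process_session()] output.
#' @return data.frame with one row per included pair.
#' @export
coactivity_table <- function(session, proc) {
  meta <- session$metadata
  block <- session$frames$block
  imaged_min <- length(session$frames$times) / session$config$frame_rate / 60
  rows <- list()
  for (d in unique(meta$dendrite_id)) {
    ids <- meta$spine_id[meta$dendrite_id == d]
    if (length(ids) < 2L) next
    prs <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]
      b <- prs[2, k]
      core <- pairwise_coactivity(proc$spines[[a]]$train,
                                  proc$spines[[b]]$train,
                                  imaged_min, block = block)
      if (is.null(core)) next
      la <- meta$label[meta$spine_id == a]
      lb <- meta$label[meta$spine_id == b]
      rows[[length(rows) + 1L]] <- data.frame(
        dendrite_id = d, spine_a = a, spine_b = b,
        distance_um = abs(meta$position_um[meta$spine_id == a] -
                            meta$position_um[meta$spine_id == b]),
        co_rate = core$co_rate, norm_co_rate = core$norm_co_rate,
        r = core$r,
        pair_label = if (la == "eliminated" || lb == "eliminated")
          "eliminated" else "stable"
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$bin_center <- distance_bin(out$distance_um)
  out
}

# Symmetric normalized co-activity matrix for one dendrite, from the table.
coactivity_matrix <- function(pairs, ids) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(pairs))) {
    m[pairs$spine_a[i], pairs$spine_b[i]] <- pairs$norm_co_rate[i]
    m[pairs$spine_b[i], pairs$spine_a[i]] <- pairs$norm_co_rate[i]
  }
  m
}

#' Run the full analysis pipeline on one session
#'
#' Stage order: behavior segmentation, per-ROI event detection, pairwise
#' co-activity and distance curves, co-activity environment scores per
#' eliminated spine, spine-dendrite onset timing, optional movement-related
#' classification, and a stable-versus-eliminated comparison table. Rerunning
#' with an identical session and arguments reproduces identical tables.
#'
#' @param session a `spine_session`.
#' @param radius neighborhood radius for environment scores, um.
#' @param lag_window onset-lag matching window, s.
#' @param run_tuning run the per-spine permutation classification (the
#'   expensive stage).
#' @param n_shuffles shuffles for the permutation classification.
#' @param run_models fit the mixed-effects co-activity model (grouping by
#'   dendrite within the single session).
#' @param seed seed for the stochastic stages.
#' @return A report: list with `bouts`, `events`, `pairs`, `curve`,
#'   `environment`, `lags`, `tuning` (or `NULL`), `models` (or `NULL`),
#'   `comparisons`, `provenance`.
#' @export
run_pipeline <- function(session, radius = 10, lag_window = 1,
                         run_tuning = FALSE, n_shuffles = 1000,
                         run_models = TRUE, seed = session$config$seed) {
  meta <- session$metadata
  fr <- session$config$frame_rate
  times <- session$frames$times
  bouts <- segment_movements(session$behavior)
  proc <- process_session(session)

  ev_rows <- lapply(names(proc$spines), function(id) {
    ev <- proc$spines[[id]]$train$events
    if (nrow(ev) == 0L) return(NULL)
    cbind(roi_id = id, ev)
  })
  events <- do.call(rbind, ev_rows)

  pairs <- coactivity_table(session, proc)
  curve <- if (!is.null(pairs)) coactivity_curve(pairs) else NULL

  # environment scores per eliminated spine, plus pooled per-pair values
  env_rows <- list()
  env_pools <- list(eliminated = numeric(0), nearby = numeric(0))
  for (d in unique(meta$dendrite_id)) {
    sub <- meta[meta$dendrite_id == d, ]
    dp <- pairs[pairs$dendrite_id == d, , drop = FALSE]
    if (is.null(pairs) || nrow(dp) == 0L) next
    cm <- coactivity_matrix(dp, sub$spine_id)
    pos <- stats::setNames(sub$position_um, sub$spine_id)
    lab <- stats::setNames(sub$label, sub$spine_id)
    for (t in sub$spine_id[sub$label == "eliminated"]) {
      sc <- environment_scores(cm, pos, lab, t, radius = radius)
      env_rows[[length(env_rows) + 1L]] <- data.frame(
        dendrite_id = d, spine_id = t,
        eliminated_score = sc$eliminated_score,
        nearby_env = sc$nearby_env, distant_env = sc$distant_env)
      env_pools$eliminated <- c(env_pools$eliminated, sc$values$eliminated)
      env_pools$nearby <- c(env_pools$nearby, sc$values$nearby)
    }
  }
  environment <- do.call(rbind, env_rows)

  # spine-dendrite onset lags and co-activity
  imaged_min <- length(times) / fr / 60
  block <- session$frames$block
  lag_pools <- list(stable = numeric(0), eliminated = numeric(0))
  lag_rows <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$spine_id[i]
    dt <- proc$dendrites[[meta$dendrite_id[i]]]$train
    st <- proc$spines[[id]]$train
    if (nrow(st$events) == 0L || nrow(dt$events) == 0L) return(NULL)
    lags <- event_onset_lags(st, dt, window = lag_window)
    lag_pools[[meta$label[i]]] <<- c(lag_pools[[meta$label[i]]],
                                     lags$delta_t)
    sd_co <- spine_dendrite_coactivity(st, dt, imaged_min, block = block)
    data.frame(spine_id = id, dendrite_id = meta$dendrite_id[i],
               label = meta$label[i], n_pairs = lags$n_pairs,
               median_dt_s = lags$summary_dt,
               sd_norm_co_rate = if (is.null(sd_co)) NA_real_ else sd_co$norm_co_rate,
               sd_coincident_fraction = if (is.null(sd_co)) NA_real_
               else sd_co$coincident_fraction)
  })
  lags <- do.call(rbind, lag_rows)

  tuning <- NULL
  if (run_tuning) {
    # within a single session the LMP is built from that session's own
    # rewarded cued movements
    lmp_ref <- tryCatch(
      lmp_and_correlation(list(session$behavior), NULL,
                          bouts_list = list(bouts)),
      error = function(e) NULL)
    tuning <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
      id <- meta$spine_id[i]
      mrs <- classify_mrs(proc$spines[[id]]$dff, bouts, times,
                          n_shuffles = n_shuffles, seed = seed + i)
      rs <- reliability_specificity(proc$spines[[id]]$train, bouts, times)
      pt <- peak_timing(proc$spines[[id]]$dff, bouts,
                        proc$spines[[id]]$train, times)
      w <- extract_spine_movements(bouts, proc$spines[[id]]$train,
                                   session$behavior, times)
      lmp_corr <- if (is.null(lmp_ref) || is.null(w)) NA_real_ else {
        mean(apply(w, 1L, function(x) stats::cor(x, lmp_ref$lmp)))
      }
      data.frame(spine_id = id, label = meta$label[i],
                 is_mrs = mrs$is_mrs, dot = mrs$observed,
                 reliability = rs$reliability, specificity = rs$specificity,
                 peak_time_s = pt$peak_time_s,
                 rewarded_frac = rewarded_fraction(proc$spines[[id]]$train,
                                                   bouts, times),
                 stereotypy = stereotypy(w), lmp_corr = lmp_corr)
    }))
  }

  models <- NULL
  if (run_models && !is.null(pairs) && nrow(pairs) > 4L) {
    pairs$pair_label <- stats::relevel(factor(pairs$pair_label), "stable")
    models <- suppressWarnings(fit_lme(
      "norm_co_rate ~ pair_label + distance_um + pair_label:distance_um + (1 | dendrite_id)",
      pairs))
  }

  comparisons <- summarize_comparisons(pairs, environment, lags,
                                       radius = radius,
                                       lag_pools = lag_pools,
                                       env_pools = env_pools)
  list(bouts = bouts, events = events, pairs = pairs, curve = curve,
       environment = environment, lags = lags, tuning = tuning,
       models = models, comparisons = comparisons,
       provenance = list(seed = seed,
                         config = unclass(session$config),
                         spinefate_version =
                           as.character(utils::packageVersion("spinefate"))))
}

# Stable-vs-eliminated comparison table: short-range co-activity, onset lag,
# and eliminated-vs-nearby environment scores. Group estimates pool the
# per-pair values (a handful of per-spine summaries is dominated by
# spurious-match noise at single-session scale); p-values come from the
# spine-level comparisons, whose units are closer to independent. Spines
# with fewer than `min_pairs` matched event pairs are excluded from the
# spine-level timing test.
summarize_comparisons <- function(pairs, environment, lags, radius = 10,
                                  min_pairs = 3L, lag_pools = NULL,
                                  env_pools = NULL) {
  rows <- list()
  if (!is.null(pairs)) {
    near <- pairs[pairs$distance_um <= radius, ]
    if (nrow(near) && length(unique(near$pair_label)) == 2L) {
      a <- near$norm_co_rate[near$pair_label == "eliminated"]
      b <- near$norm_co_rate[near$pair_label == "stable"]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "coactivity_le10um", eliminated = mean(a), stable = mean(b),
        diff = mean(a) - mean(b),
        p = suppressWarnings(stats::wilcox.test(a, b)$p.value),
        n_eliminated = length(a), n_stable = length(b))
    }
  }
  if (!is.null(lags)) {
    dl <- lags[!is.na(lags$median_dt_s) & lags$n_pairs >= min_pairs, ]
    if (nrow(dl) && length(unique(dl$label)) == 2L) {
      a <- dl$median_dt_s[dl$label == "eliminated"]
      b <- dl$median_dt_s[dl$label == "stable"]
      if (!is.null(lag_pools) && length(lag_pools$eliminated) &&
            length(lag_pools$stable)) {
        est_e <- stats::median(lag_pools$eliminated)
        est_s <- stats::median(lag_pools$stable)
      } else {
        est_e <- stats::median(a)
        est_s <- stats::median(b)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "delta_t", eliminated = est_e, stable = est_s,
        diff = est_e - est_s,
        p = suppressWarnings(stats::wilcox.test(a, b)$p.value),
        n_eliminated = length(a), n_stable = length(b))
    }
  }
  if (!is.null(environment)) {
    ok <- stats::complete.cases(environment[, c("eliminated_score",
                                                "nearby_env")])
    e <- environment[ok, ]
    if (nrow(e) >= 2L) {
      if (!is.null(env_pools) && length(env_pools$eliminated) &&
            length(env_pools$nearby)) {
        est_e <- mean(env_pools$eliminated)
        est_s <- mean(env_pools$nearby)
      } else {
        est_e <- mean(e$eliminated_score)
        est_s <- mean(e$nearby_env)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "environment", eliminated = est_e, stable = est_s,
        diff = est_e - est_s,
        p = suppressWarnings(stats::wilcox.test(e$eliminated_score,
                                                e$nearby_env,
                                                paired = TRUE)$p.value),
        n_eliminated = nrow(e), n_stable = nrow(e))
    }
  }
  do.call(rbind, rows)
}

#' Write a pipeline report as a CSV bundle
#'
#' @param report [run_pipeline()] output.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x)) utils::write.csv(x, file.path(dir, name),
                                      row.names = FALSE)
  }
  wr(report$bouts, "bouts.csv")
  wr(report$events, "events.csv")
  wr(report$pairs, "pairs.csv")
  wr(report$curve, "coactivity_curve.csv")
  wr(report$environment, "environment_scores.csv")
  wr(report$lags, "onset_lags.csv")
  wr(report$tuning, "tuning.csv")
  wr(report$comparisons, "comparisons.csv")
  if (!is.null(report$models)) {
    wr(report$models$coefficients, "lme_coefficients.csv")
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a synthetic session as a plain-text bundle
#'
#' One directory with CSV tables (`metadata.csv`, `trials.csv`, `lever.csv`,
#' `frames.csv`, `spine_traces.csv`, `dendrite_traces.csv`) and a
#' `ground_truth.json`.
#'
#' @param session a `spine_session`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(session$behavior$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(displacement_mm = session$behavior$samples),
    file.path(dir, "lever.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = session$frames$times, block = session$frames$block),
    file.path(dir, "frames.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$spine_raw),
                   file.path(dir, "spine_traces.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$dendrite_raw),
                   file.path(dir, "dendrite_traces.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(session$ground_truth,
      list(lever_rate = session$behavior$rate,
           press_onsets = session$behavior$press_onsets,
           config = unclass(session$config))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir bundle directory.
#' @return A `spine_session`.
#' @export
read_session <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  cfg <- do.call(sim_config, gt$config[names(gt$config) %in%
                                         names(formals(sim_config))])
  frames <- utils::read.csv(file.path(dir, "frames.csv"))
  structure(list(
    config = cfg,
    behavior = structure(list(
      samples = utils::read.csv(file.path(dir, "lever.csv"))$displacement_mm,
      rate = gt$lever_rate,
      trials = utils::read.csv(file.path(dir, "trials.csv")),
      press_onsets = gt$press_onsets), class = "lever_trace"),
    frames = list(times = frames$time_s, block = frames$block),
    spine_raw = as.matrix(utils::read.csv(file.path(dir, "spine_traces.csv"),
                                          check.names = FALSE)),
    dendrite_raw = as.matrix(utils::read.csv(
      file.path(dir, "dendrite_traces.csv"), check.names = FALSE)),
    metadata = utils::read.csv(file.path(dir, "metadata.csv")),
    ground_truth = gt[c("spine_onsets", "cluster_onsets", "dendrite_onsets",
                        "lag", "mrs", "label")]
  ), class = "spine_session")
}
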