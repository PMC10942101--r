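test_that("identical configs give bit-identical sessions", {
  cfg <- tiny_cfg(seed = 9)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$behavior$samples, s2$behavior$samples)
  expect_identical(s1$spine_raw, s2$spine_raw)
  expect_identical(s1$dendrite_raw, s2$dendrite_raw)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- generate_session(tiny_cfg(seed = 10))
  expect_false(identical(s1$spine_raw, s3$spine_raw))
})

test_that("a zero-press config yields cues but no suprathreshold movement", {
  cfg <- tiny_cfg(seed = 2)
  beh <- generate_behavior(cfg, n_presses = 0)
  expect_gt(nrow(beh$trials), 0)
  expect_true(all(is.na(beh$trials$reward_s)))
  expect_equal(nrow(segment_movements(beh)), 0)
})

test_that("well-separated injected presses are recovered one-for-one", {
  for (seed in c(3, 7)) {
    cfg <- tiny_cfg(seed = seed)
    beh <- generate_behavior(cfg)
    bouts <- segment_movements(beh)
    expect_equal(nrow(bouts), length(beh$press_onsets))
    err <- vapply(beh$press_onsets, function(o) min(abs(bouts$start_s - o)), 0)
    expect_lt(max(err), 0.1)
  }
})

test_that("per-spine event rates are calibrated to base_event_rate", {
  cfg <- sim_config(seed = 11, session_length = 3600, n_dendrites = 2L,
                    spines_per_dendrite = 10L)
  s <- generate_session(cfg)
  imaged_min <- length(s$frames$times) / cfg$frame_rate / 60
  rates <- vapply(s$ground_truth$spine_onsets, length, 1L) / imaged_min
  se <- sqrt(cfg$base_event_rate / imaged_min)
  expect_true(all(abs(rates - cfg$base_event_rate) < 3 * se))
})

test_that("ground-truth labels and fractions are consistent with the config", {
  cfg <- tiny_cfg(seed = 5)
  s <- generate_session(cfg)
  meta <- s$metadata
  expect_setequal(unique(meta$label), c("stable", "eliminated"))
  per_dend <- tapply(meta$label == "eliminated", meta$dendrite_id, sum)
  expect_true(all(per_dend == max(1, round(cfg$eliminated_fraction *
                                             cfg$spines_per_dendrite))))
  expect_true(all(meta$present_early))
  expect_true(all(meta$present_late[meta$label == "stable"]))
  expect_true(all(!meta$present_late[meta$label == "eliminated"]))
})

test_that("co-activity decays with distance when coupling is on, not when off", {
  co_by_dist <- function(cfg) {
    s <- generate_session(cfg)
    fc <- s$frames
    imaged_min <- length(fc$times) / cfg$frame_rate / 60
    meta <- s$metadata
    trains <- lapply(s$ground_truth$spine_onsets, train_from_onsets,
                     frame_times = fc$times, frame_rate = cfg$frame_rate,
                     block = fc$block)
    rows <- list()
    for (d in unique(meta$dendrite_id)) {
      ids <- meta$spine_id[meta$dendrite_id == d]
      prs <- utils::combn(ids, 2L)
      for (k in seq_len(ncol(prs))) {
        core <- pairwise_coactivity(trains[[prs[1, k]]], trains[[prs[2, k]]],
                                    imaged_min, block = fc$block)
        if (is.null(core)) next
        rows[[length(rows) + 1L]] <- c(
          d = abs(meta$position_um[meta$spine_id == prs[1, k]] -
                    meta$position_um[meta$spine_id == prs[2, k]]),
          co = core$norm_co_rate)
      }
    }
    as.data.frame(do.call(rbind, rows))
  }
  on <- co_by_dist(sim_config(seed = 21, session_length = 920,
                              n_dendrites = 3L, spines_per_dendrite = 10L,
                              mrs_fraction = 0))
  curve <- coactivity_curve(data.frame(distance_um = on$d,
                                       norm_co_rate = on$co))
  rho <- suppressWarnings(
    stats::cor(curve$bin_center, curve$mean_norm_co_rate,
               method = "spearman"))
  expect_lt(rho, 0)

  # coupling off: near and far pairs are statistically indistinguishable
  off <- co_by_dist(sim_config(seed = 22, session_length = 920,
                               n_dendrites = 3L, spines_per_dendrite = 10L,
                               cluster_coupling = 0, mrs_fraction = 0))
  p <- stats::wilcox.test(off$co[off$d <= 10], off$co[off$d > 10])$p.value
  expect_gt(p, 0.01)
})

test_that("a coupling deficit depresses short-range co-activity of eliminated spines", {
  per_rep <- lapply(1:8, function(seed) {
    cfg <- sim_config(seed = 30 + seed, eliminated_coupling_deficit = 0.5)
    s <- generate_session(cfg)
    fc <- s$frames
    imaged_min <- length(fc$times) / cfg$frame_rate / 60
    meta <- s$metadata
    trains <- lapply(s$ground_truth$spine_onsets, train_from_onsets,
                     frame_times = fc$times, frame_rate = cfg$frame_rate,
                     block = fc$block)
    vals <- list(stable = c(), eliminated = c())
    for (d in unique(meta$dendrite_id)) {
      ids <- meta$spine_id[meta$dendrite_id == d]
      prs <- utils::combn(ids, 2L)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b <- prs[2, k]
        dd <- abs(meta$position_um[meta$spine_id == a] -
                    meta$position_um[meta$spine_id == b])
        if (dd > 10) next
        core <- pairwise_coactivity(trains[[a]], trains[[b]],
                                    imaged_min, block = fc$block)
        if (is.null(core)) next
        lab <- if (any(meta$label[meta$spine_id %in% c(a, b)] == "eliminated"))
          "eliminated" else "stable"
        vals[[lab]] <- c(vals[[lab]], core$norm_co_rate)
      }
    }
    vals
  })
  # pooled across replicates the deficit must depress eliminated co-activity
  pooled_e <- unlist(lapply(per_rep, `[[`, "eliminated"))
  pooled_s <- unlist(lapply(per_rep, `[[`, "stable"))
  expect_lt(mean(pooled_e), mean(pooled_s))
  diffs <- vapply(per_rep, function(v) {
    mean(v$eliminated) - mean(v$stable)
  }, 0)
  expect_gte(mean(diffs < 0), 0.5)
})
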