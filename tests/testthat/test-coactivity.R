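fr <- 58.3

rand_train <- function(n, p = 0.02, seed = NULL, block = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train_from_binary(runif(n) < p, fr, block = block)
}

test_that("identical trains have normalized co-activity exactly 1", {
  set.seed(1)
  a <- rand_train(5000, 0.03)
  res <- pairwise_coactivity(a, a, imaged_minutes = 5000 / fr / 60)
  expect_equal(res$norm_co_rate, 1)
  expect_equal(res$n_co_events, nrow(a$events))
})

test_that("disjoint trains have zero co-activity", {
  act <- rep(FALSE, 4000)
  act[100:200] <- TRUE
  b_act <- rep(FALSE, 4000)
  b_act[300:400] <- TRUE
  res <- pairwise_coactivity(train_from_binary(act, fr),
                             train_from_binary(b_act, fr), 1)
  expect_equal(res$norm_co_rate, 0)
})

test_that("a silent spine excludes the pair", {
  a <- rand_train(2000, 0.05, seed = 2)
  b <- train_from_binary(rep(FALSE, 2000), fr)
  expect_null(pairwise_coactivity(a, b, 1))
})

test_that("run counting matches the brute-force AND-trace scan on random pairs", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(50:5000, 1)
    block <- if (runif(1) < 0.3) {
      sort(sample(1:3, n, replace = TRUE))
    } else NULL
    a <- rand_train(n, runif(1, 0.01, 0.3), block = block)
    b <- rand_train(n, runif(1, 0.01, 0.3), block = block)
    if (nrow(a$events) == 0L || nrow(b$events) == 0L) next
    res <- pairwise_coactivity(a, b, 1, block = block)
    expect_identical(res$n_co_events,
                     oracle_co_events(a$active, b$active, block))
  }
})

test_that("distance bins are half-open on the left", {
  expect_equal(distance_bin(5.0), 2.5)
  expect_equal(distance_bin(5.01), 7.5)
  expect_equal(distance_bin(0.1), 2.5)
  expect_equal(distance_bin(10), 7.5)
  expect_equal(distance_bin(10.5), 12.5)
})

test_that("uniform pairs give bin means equal to the overall mean", {
  pairs <- data.frame(distance_um = c(1, 3, 7, 12, 18),
                      norm_co_rate = rep(0.4, 5))
  curve <- coactivity_curve(pairs)
  expect_true(all(curve$mean_norm_co_rate == 0.4))
  expect_equal(sum(curve$n_pairs), 5)
})

test_that("environment scores reproduce the trivial configurations", {
  ids <- sprintf("s%d", 1:5)
  pos <- setNames(c(0, 4, 8, 30, 34), ids)
  lab <- setNames(c("stable", "eliminated", "stable", "stable", "stable"), ids)
  # all spines share one identical train -> all pairwise co-activity 1
  cm <- matrix(1, 5, 5, dimnames = list(ids, ids))
  diag(cm) <- NA
  sc <- environment_scores(cm, pos, lab, "s2")
  expect_equal(sc$eliminated_score, 1)
  expect_equal(sc$nearby_env, 1)
  expect_equal(sc$distant_env, 1)
  # target disjoint from neighbors, neighbors identical to each other
  cm2 <- cm
  cm2["s2", ] <- 0
  cm2[, "s2"] <- 0
  sc2 <- environment_scores(cm2, pos, lab, "s2")
  expect_equal(sc2$eliminated_score, 0)
  expect_equal(sc2$nearby_env, 1)
})

test_that("environment scores equal the naive set construction on random dendrites", {
  set.seed(4)
  for (i in 1:60) {
    n <- sample(6:20, 1)
    ids <- sprintf("s%d", seq_len(n))
    pos <- setNames(sort(runif(n, 0, 60)), ids)
    lab <- setNames(sample(c("stable", "eliminated"), n, replace = TRUE,
                           prob = c(0.75, 0.25)), ids)
    if (!any(lab == "eliminated")) lab[sample(n, 1)] <- "eliminated"
    cm <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
    diag(cm) <- NA
    # random exclusions from the pair table (inactive spines)
    cm[sample(length(cm), round(0.05 * n * n))] <- NA
    cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
    target <- sample(ids[lab == "eliminated"], 1)
    got <- environment_scores(cm, pos, lab, target)
    want <- oracle_env_scores(cm, as.list(pos), as.list(lab), target)
    expect_equal(got$eliminated_score, want$eliminated_score)
    expect_equal(got$nearby_env, want$nearby_env)
    expect_equal(got$distant_env, want$distant_env)
  }
})

test_that("spine-dendrite coincident fraction matches an explicit overlap scan", {
  set.seed(5)
  # spine events strictly inside dendrite events -> fraction 1
  d_act <- rep(FALSE, 3000)
  d_act[c(100:220, 800:950, 2000:2200)] <- TRUE
  s_act <- rep(FALSE, 3000)
  s_act[c(120:150, 2050:2080)] <- TRUE
  res <- spine_dendrite_coactivity(train_from_binary(s_act, fr),
                                   train_from_binary(d_act, fr), 1)
  expect_equal(res$coincident_fraction, 1)
  # disjoint -> 0
  s2 <- rep(FALSE, 3000)
  s2[400:450] <- TRUE
  res2 <- spine_dendrite_coactivity(train_from_binary(s2, fr),
                                    train_from_binary(d_act, fr), 1)
  expect_equal(res2$coincident_fraction, 0)
  # random trains vs explicit scan
  for (i in 1:50) {
    a <- rand_train(2000, runif(1, 0.02, 0.2))
    b <- rand_train(2000, runif(1, 0.02, 0.2))
    if (nrow(a$events) == 0L || nrow(b$events) == 0L) next
    res3 <- spine_dendrite_coactivity(a, b, 1)
    hits <- 0L
    for (k in seq_len(nrow(a$events))) {
      ov <- FALSE
      for (m in seq_len(nrow(b$events))) {
        if (b$events$onset[m] < a$events$offset[k] &&
            b$events$offset[m] > a$events$onset[k]) ov <- TRUE
      }
      if (ov) hits <- hits + 1L
    }
    expect_equal(res3$coincident_fraction, hits / nrow(a$events))
  }
})

test_that("normalized co-activity is symmetric in the pair", {
  a <- rand_train(4000, 0.05, seed = 6)
  b <- rand_train(4000, 0.08, seed = 7)
  r1 <- pairwise_coactivity(a, b, 2)
  r2 <- pairwise_coactivity(b, a, 2)
  expect_equal(r1$norm_co_rate, r2$norm_co_rate)
  expect_equal(r1$co_rate, r2$co_rate)
})
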