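make_lever <- function(samples, rate = 1000, trials = NULL) {
  structure(list(samples = samples, rate = rate, trials = trials),
            class = "lever_trace")
}

test_that("a constant trace at rest yields no bouts", {
  set.seed(1)
  lever <- make_lever(rnorm(10000, 0, 0.02))
  expect_equal(nrow(segment_movements(lever)), 0)
})

test_that("bursts separated by less than 500 ms merge into one bout", {
  set.seed(2)
  x <- rnorm(20000, 0, 0.02)
  press <- function(x, onset, dur = 0.3, amp = 4, rate = 1000) {
    idx <- which(seq_along(x) / rate >= onset &
                   seq_along(x) / rate < onset + dur)
    x[idx] <- x[idx] - amp * sin(pi * (idx / rate - onset) / dur)^2
    x
  }
  x <- press(press(x, 5), 5.6)  # gap of 0.3 s between bursts
  bouts <- segment_movements(make_lever(x))
  expect_equal(nrow(bouts), 1)
  x2 <- press(press(rnorm(20000, 0, 0.02), 5), 7)
  expect_equal(nrow(segment_movements(make_lever(x2))), 2)
})

test_that("segmentation is invariant to a constant offset and its bouts disjoint", {
  cfg <- tiny_cfg(seed = 4)
  beh <- generate_behavior(cfg)
  b1 <- segment_movements(beh)
  beh2 <- beh
  beh2$samples <- beh$samples + 2.7
  b2 <- segment_movements(beh2)
  expect_equal(b1$start_s, b2$start_s, tolerance = 1e-8)
  expect_true(all(diff(b1$start_s) > 0))
  expect_true(all(b1$end_s > b1$start_s))
  expect_true(all(b1$start_s[-1] > b1$end_s[-nrow(b1)]))
})

test_that("rewarded and cued flags follow the trial table", {
  cfg <- tiny_cfg(seed = 6)
  beh <- generate_behavior(cfg)
  bouts <- segment_movements(beh)
  rewarded_times <- beh$trials$reward_s[!is.na(beh$trials$reward_s)]
  for (rt in rewarded_times) {
    expect_true(any(bouts$start_s <= rt & bouts$end_s >= rt))
  }
  expect_true(all(bouts$cued[bouts$rewarded]))
})

test_that("stereotypy matches the brute-force pairwise mean", {
  set.seed(3)
  w <- matrix(rnorm(8 * 50), nrow = 8)
  expect_equal(stereotypy(w), oracle_mean_pairwise_r(w))
  ident <- matrix(rep(sin(1:50), 4), nrow = 4, byrow = TRUE)
  expect_equal(stereotypy(ident), 1)
  pairneg <- rbind(sin(1:50), -sin(1:50))
  expect_equal(stereotypy(pairneg), -1)
  expect_true(is.na(stereotypy(w[1, , drop = FALSE])))
})

test_that("the correlogram is symmetric with unit diagonal for identical movements", {
  cfg <- tiny_cfg(seed = 8)
  sessions <- list(generate_behavior(cfg),
                   generate_behavior(tiny_cfg(seed = 12)))
  m <- movement_correlogram(sessions)
  expect_equal(m, t(m))
  # a session whose rewarded movements are literally the same waveform
  x <- rnorm(40000, 0, 0.001)
  onsets <- c(5, 15, 25)
  for (o in onsets) {
    idx <- which(seq_along(x) / 1000 >= o & seq_along(x) / 1000 < o + 0.5)
    x[idx] <- x[idx] - 4 * sin(pi * (idx / 1000 - o) / 0.5)^2
  }
  trials <- data.frame(cue_s = onsets - 1, reward_s = onsets + 0.2)
  m1 <- movement_correlogram(list(make_lever(x, trials = trials)))
  expect_equal(m1[1, 1], 1, tolerance = 0.05)
})

test_that("movement extraction applies the duration and overlap exclusions", {
  cfg <- tiny_cfg(seed = 5)
  s <- generate_session(cfg)
  bouts <- segment_movements(s$behavior)
  fr <- cfg$frame_rate
  nf <- length(s$frames$times)
  # a spine active everywhere sees every retained movement
  all_on <- train_from_binary(rep(TRUE, nf), fr)
  w <- extract_spine_movements(bouts, all_on, s$behavior, s$frames$times)
  expect_true(nrow(w) <= nrow(bouts))
  expect_equal(ncol(w), 2000)
  # a silent spine sees none
  silent <- train_from_binary(rep(FALSE, nf), fr)
  expect_null(extract_spine_movements(bouts, silent, s$behavior,
                                      s$frames$times))
  # a >3 s movement is excluded
  long_bouts <- data.frame(start_s = 10, end_s = 14,
                           rewarded = TRUE, cued = TRUE)
  expect_null(extract_spine_movements(long_bouts, all_on, s$behavior,
                                      s$frames$times))
  # two movements with overlapping windows are both excluded
  near <- data.frame(start_s = c(10, 11), end_s = c(10.4, 11.4),
                     rewarded = c(TRUE, TRUE), cued = c(TRUE, TRUE))
  expect_null(extract_spine_movements(near, all_on, s$behavior,
                                      s$frames$times))
})

test_that("LMP correlation is 1 for identical movements and decays with noise", {
  cfg <- tiny_cfg(seed = 13)
  s <- generate_session(cfg)
  bouts <- segment_movements(s$behavior)
  nf <- length(s$frames$times)
  all_on <- train_from_binary(rep(TRUE, nf), cfg$frame_rate)
  w <- extract_spine_movements(bouts, all_on, s$behavior, s$frames$times)
  res <- lmp_and_correlation(list(s$behavior), w, bouts_list = list(bouts))
  expect_length(res$lmp, 2000)
  exact <- lmp_and_correlation(list(s$behavior),
                               matrix(res$lmp, nrow = 1),
                               bouts_list = list(bouts))
  expect_equal(exact$correlation, 1)
  set.seed(1)
  cors <- vapply(c(0.1, 1, 5), function(sd) {
    noisy <- t(replicate(20, res$lmp + rnorm(2000, 0, sd)))
    lmp_and_correlation(list(s$behavior), noisy,
                        bouts_list = list(bouts))$correlation
  }, 0)
  expect_true(all(diff(cors) < 0))
})

test_that("degenerate lever inputs are rejected or produce empty output", {
  expect_error(segment_movements(make_lever(rnorm(5000), rate = 500)),
               "1 kHz")
  expect_error(segment_movements(make_lever(rnorm(200))), "shorter")
  expect_warning(b <- segment_movements(make_lever(rep(0, 5000))), "flat")
  expect_equal(nrow(b), 0)
})
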