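fr <- 58.3

test_that("baseline of a constant trace is that constant", {
  f0 <- estimate_baseline(rep(5, 6000), fr)
  expect_equal(f0, rep(5, 6000))
})

test_that("baseline tracks a slow drift under sparse events", {
  set.seed(4)
  n <- round(600 * fr)
  drift <- 100 + 10 * sin(2 * pi * seq_len(n) / n)
  sigma_raw <- 0.05 * 100
  raw <- drift * (1 + injected_trace(round(seq(500, n - 500, length.out = 15)),
                                     1, 0.5 * fr, n, sigma = 0.05))
  f0 <- estimate_baseline(raw, fr)
  expect_lt(max(abs(f0 - drift)), sigma_raw)
})

test_that("the active mask reaches a fixed point", {
  set.seed(5)
  n <- round(300 * fr)
  raw <- 100 * (1 + injected_trace(round(seq(500, n - 500, length.out = 10)),
                                   1, 0.5 * fr, n, sigma = 0.05))
  f10 <- estimate_baseline(raw, fr, max_iter = 10)
  f11 <- estimate_baseline(raw, fr, max_iter = 11)
  expect_identical(f10, f11)
})

test_that("dF/F0 identities hold and smoothing preserves the mean", {
  n <- 4000
  f0 <- rep(100, n)
  d <- compute_dff(f0, f0, fr)
  expect_equal(d$dff, rep(0, n))
  raw <- f0
  raw[1000:1200] <- 200
  d2 <- compute_dff(raw, f0, fr, smooth_s = 0)
  expect_equal(d2$dff[1100], 1)
  set.seed(6)
  raw3 <- 100 + rnorm(n)
  d3 <- compute_dff(raw3, f0, fr)
  expect_equal(mean(d3$dff), mean(d3$dff_raw), tolerance = 1e-3)
  expect_error(compute_dff(raw3, rep(0, n), fr), "frame 1")
})

test_that("mirrored-negative noise matches the forced example and the generator SD", {
  expect_equal(estimate_noise(c(-1, -2, 5, 7)), sqrt(2.5))
  set.seed(7)
  x <- rnorm(10000, 0, 0.3)
  expect_equal(estimate_noise(x), 0.3, tolerance = 0.05 * 0.3)
  # positive-only additions leave sigma unchanged
  expect_identical(estimate_noise(c(x, runif(500, 0.1, 3))),
                   estimate_noise(x))
  expect_error(estimate_noise(c(0, 1, 2)), "negative")
})

test_that("detection handles silent and rectangular traces", {
  expect_equal(nrow(detect_events(rep(0, 3000), 0.1, fr)$events), 0)
  dff <- rep(0, 3000)
  dff[1000:1116] <- 1  # 2 s at 10x a 0.1 noise floor
  tr <- detect_events(dff, 0.1, fr, roi_kind = "spine", sensor = "iGluSnFR3")
  expect_equal(nrow(tr$events), 1)
  expect_true(tr$events$onset <= 1000 && tr$events$offset > 1116)
  expect_true(all(tr$active[1000:1116]))
})

test_that("binary trace and event list are mutually consistent", {
  set.seed(8)
  dff <- injected_trace(round(seq(300, 15000, length.out = 12)), 0.8,
                        0.5 * fr, 15500)
  tr <- detect_from_raw_dff(dff, fr, roi_kind = "spine", sensor = "iGluSnFR3")
  rebuilt <- rep(FALSE, tr$n_frames)
  for (i in seq_len(nrow(tr$events))) {
    rebuilt[tr$events$onset[i]:(tr$events$offset[i] - 1L)] <- TRUE
  }
  expect_identical(rebuilt, tr$active)
  expect_true(all(diff(tr$events$onset) > 0))
  expect_true(all(tr$events$offset > tr$events$onset))
  expect_true(all(tr$events$onset[-1] >= tr$events$offset[-nrow(tr$events)]))
})

test_that("detection is scale-invariant with the amplitude floor disabled", {
  set.seed(9)
  dff <- injected_trace(round(seq(300, 15000, length.out = 10)), 0.6,
                        0.5 * fr, 15500)
  sm <- spinefate:::moving_average(dff, round(0.5 * fr))
  sig <- estimate_noise(dff)
  t1 <- detect_events(sm, sig, fr, dff_raw = dff, min_peak = 0)
  t2 <- detect_events(37 * sm, 37 * sig, fr, dff_raw = 37 * dff, min_peak = 0)
  expect_identical(t1$events$onset, t2$events$onset)
  expect_identical(t1$events$offset, t2$events$offset)
})

test_that("the iGluSnFR2 floor removes small-amplitude events", {
  set.seed(19)
  n <- 15500
  dff <- injected_trace(round(seq(300, 15000, length.out = 10)), 0.15,
                        0.5 * fr, n, sigma = 0.02)
  sm <- spinefate:::moving_average(dff, round(0.5 * fr))
  sig <- estimate_noise(dff)
  with_floor <- detect_events(sm, sig, fr, dff_raw = dff, sensor = "iGluSnFR2")
  without <- detect_events(sm, sig, fr, dff_raw = dff, sensor = "iGluSnFR3")
  expect_equal(nrow(with_floor$events), 0)
  expect_gt(nrow(without$events), 5)
})

test_that("event count is non-increasing in the active-threshold multiple", {
  set.seed(10)
  dff <- injected_trace(round(seq(300, 15000, length.out = 15)),
                        0.45, 0.5 * fr, 15500)
  sm <- spinefate:::moving_average(dff, round(0.5 * fr))
  sig <- estimate_noise(dff)
  counts <- vapply(c(1.5, 2, 3, 4, 6), function(k) {
    nrow(detect_events(sm, sig, fr, dff_raw = dff, active_k = k,
                       min_peak = 0)$events)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("events never span acquisition gaps", {
  n <- 6000
  block <- rep(1:2, each = n / 2)
  dff <- rep(0, n)
  dff[2900:3100] <- 1  # excursion straddling the block boundary
  tr <- detect_events(dff, 0.05, fr, block = block, sensor = "iGluSnFR3")
  expect_equal(nrow(tr$events), 2)
  expect_true(all(tr$events$offset[1] <= n / 2 + 1))
  expect_true(tr$events$onset[2] >= n / 2 + 1)
})

test_that("injected events at SNR 5 are recovered with small onset error", {
  recall <- c()
  errs <- c()
  for (seed in 1:5) {
    set.seed(seed)
    n <- round(300 * fr)
    onsets <- round(seq(200, n - 200, length.out = 20) + runif(20, -30, 30))
    dff <- injected_trace(onsets, 0.5, 0.5 * fr, n, sigma = 0.1)
    tr <- detect_from_raw_dff(dff, fr, roi_kind = "spine",
                              sensor = "iGluSnFR3")
    m <- vapply(onsets, function(o) {
      d <- tr$events$onset - o
      d[which.min(abs(d))]
    }, 0)
    recall <- c(recall, mean(abs(m) <= 5))
    errs <- c(errs, abs(m[abs(m) <= 5]))
  }
  expect_gte(mean(recall), 0.9)
  expect_lte(median(errs), 2)
})

test_that("event shapes recover a pure exponential and flag flat segments", {
  n <- 2000
  tau_f <- 0.5 * fr
  dff <- rep(0, n)
  o <- 500
  idx <- o:(o + round(6 * tau_f))
  dff[idx] <- exp(-(idx - o) / tau_f)
  tr <- detect_events(dff, 0.01, fr, sensor = "iGluSnFR3")
  sh <- event_shapes(dff, tr, fr)
  expect_true(sh$fit_ok[1])
  expect_equal(sh$amplitude[1], 1, tolerance = 0.01)
  expect_equal(sh$tau_s[1], 0.5, tolerance = 0.05)
  # a flat post-peak plateau has no qualifying peak and is excluded
  flat <- rep(0, n)
  flat[500:1600] <- 1
  trf <- detect_events(flat, 0.01, fr, sensor = "iGluSnFR3")
  shf <- event_shapes(flat, trf, fr)
  expect_false(any(shf$fit_ok))
})

test_that("tau estimates are unbiased within 10% at SNR 10", {
  taus <- c()
  amps <- c()
  for (seed in 1:5) {
    set.seed(seed)
    n <- round(300 * fr)
    onsets <- round(seq(200, n - 200, length.out = 15))
    dff <- injected_trace(onsets, 1, 0.5 * fr, n, sigma = 0.1)
    tr <- detect_from_raw_dff(dff, fr, roi_kind = "spine",
                              sensor = "iGluSnFR3")
    sh <- event_shapes(dff, tr, fr)
    taus <- c(taus, sh$tau_s[sh$fit_ok])
    amps <- c(amps, sh$amplitude[sh$fit_ok])
  }
  expect_equal(mean(taus), 0.5, tolerance = 0.1 * 0.5)
  expect_equal(mean(amps), 1, tolerance = 0.1)
})
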