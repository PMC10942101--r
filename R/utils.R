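# Internal numeric helpers shared by the trace-processing modules.

# Rolling sum over a centered window of half-width `half`, with partial
# windows at the edges (window is clipped, never padded).
roll_sum_partial <- function(x, half) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi] - c(0, cs)[lo]
}

roll_count_partial <- function(n, half) {
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  hi - lo + 1
}

# Centered moving average with edge clipping.
moving_average <- function(x, width) {
  half <- max(1L, floor(width / 2))
  roll_sum_partial(x, half) / roll_count_partial(length(x), half)
}

# Rolling mean of x over kept samples only; frames where the window holds no
# kept sample are filled by linear interpolation from neighbours.
masked_roll_mean <- function(x, keep, half) {
  n <- length(x)
  s <- roll_sum_partial(x * keep, half)
  k <- roll_sum_partial(as.numeric(keep), half)
  out <- ifelse(k > 0, s / pmax(k, 1), NA_real_)
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    if (length(ok) == 0L) return(rep(mean(x), n))
    out <- stats::approx(ok, out[ok], xout = seq_len(n), rule = 2)$y
  }
  out
}

# LOESS-style smoother: local linear regression with tricube weights over a
# centered span of 2 * half + 1 frames. With symmetric weights the fitted
# value at the window center equals the tricube-weighted mean, so the whole
# series is one convolution; edges are handled by reflection.
loess_kernel_smooth <- function(x, half) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- min(half, n - 1L)
  if (half < 1L) return(x)
  u <- (-half:half) / (half + 1)
  k <- (1 - abs(u)^3)^3
  k <- k / sum(k)
  pad_l <- rev(x[seq_len(half)])
  pad_r <- rev(x[n - seq_len(half) + 1L])
  y <- stats::filter(c(pad_l, x, pad_r), k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

# Maximal runs of TRUE, as half-open [onset, offset) 1-based frame indices.
binary_runs <- function(active) {
  if (length(active) == 0L || !any(active)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("onset", "offset"))))
  }
  r <- rle(as.logical(active))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(onset = starts[keep], offset = ends[keep] + 1L)
}

# Runs of TRUE that never span a block boundary (acquisition gap).
binary_runs_blocked <- function(active, block) {
  if (is.null(block)) return(binary_runs(active))
  out <- lapply(unique(block), function(b) {
    idx <- which(block == b)
    r <- binary_runs(active[idx])
    r[, 1L] <- r[, 1L] + idx[1L] - 1L
    r[, 2L] <- r[, 2L] + idx[1L] - 1L
    r
  })
  do.call(rbind, out)
}

# Interval sums of `x` (via its cumulative sum) for n_shuffles uniform
# random relocations of k non-overlapping intervals with fixed durations
# (the standard spacings construction). O(n_shuffles * k) per call.
shuffled_interval_sums <- function(x, durations, n_shuffles) {
  n <- length(x)
  k <- length(durations)
  slack <- n - sum(durations)
  if (slack < 0) stop("intervals do not fit in the session")
  cs <- c(0, cumsum(x))
  offs <- cumsum(c(0L, durations[-k]))
  u <- matrix(sample.int(slack + 1L, n_shuffles * k, replace = TRUE) - 1L,
              nrow = n_shuffles)
  u <- t(apply(u, 1L, sort))
  if (k == 1L) u <- matrix(u, nrow = n_shuffles)
  starts <- sweep(u, 2L, offs, "+") + 1L
  ends <- sweep(starts, 2L, durations, "+") - 1L
  sums <- cs[ends + 1L] - cs[starts]
  dim(sums) <- dim(starts)
  rowSums(sums)
}

# Magnitude of the analytic signal (Hilbert-transform envelope) via FFT:
# zero the negative frequencies, double the positive ones.
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Mean of all pairwise Pearson correlations between the rows of `m`.
mean_pairwise_cor <- function(m) {
  if (is.null(dim(m)) || nrow(m) < 2L) return(NA_real_)
  cm <- suppressWarnings(stats::cor(t(m)))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}
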