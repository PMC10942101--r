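# Independent brute-force oracles: deliberately naive loop implementations
# kept free of the package's internal run/scan machinery.

# Count maximal co-active runs of two binary vectors by explicit scanning.
oracle_co_events <- function(a, b, block = NULL) {
  n <- length(a)
  if (is.null(block)) block <- rep(1L, n)
  co <- a & b
  count <- 0L
  for (i in seq_len(n)) {
    if (co[i] && (i == 1L || !co[i - 1L] || block[i] != block[i - 1L])) {
      count <- count + 1L
    }
  }
  count
}

# Naive environment-score construction straight from the group definitions.
oracle_env_scores <- function(coact, positions, labels, target, radius = 10) {
  ids <- names(positions)
  dist <- function(a, b) abs(positions[[a]] - positions[[b]])
  avg <- function(v) { v <- v[!is.na(v)]; if (length(v)) mean(v) else NA_real_ }

  nbr <- c()
  for (s in ids) if (s != target && dist(s, target) <= radius) nbr <- c(nbr, s)

  ev <- c()
  for (s in nbr) ev <- c(ev, coact[target, s])
  elim_score <- avg(ev)

  keep <- c()
  for (s in nbr) if (labels[[s]] != "eliminated") keep <- c(keep, s)
  nv <- c()
  if (length(keep) >= 2L) {
    for (i in 1:(length(keep) - 1L)) {
      for (j in (i + 1L):length(keep)) {
        nv <- c(nv, coact[keep[i], keep[j]])
      }
    }
  }
  nearby <- avg(nv)

  banned <- nbr
  for (e in ids) {
    if (labels[[e]] == "eliminated" && e != target) {
      for (s in ids) if (dist(s, e) <= radius) banned <- c(banned, s)
    }
  }
  dv <- c()
  for (s in ids) {
    if (dist(s, target) <= radius) next
    if (s %in% banned) next
    for (p in ids) {
      if (p == s || dist(p, s) > radius) next
      if (p %in% banned) next
      dv <- c(dv, coact[s, p])
    }
  }
  list(eliminated_score = elim_score, nearby_env = nearby,
       distant_env = avg(dv))
}

oracle_density <- function(target_pos, mrs_positions, branch_range, radius = 10) {
  count <- 0L
  for (p in mrs_positions) if (abs(p - target_pos) <= radius) count <- count + 1L
  left <- target_pos - branch_range[1]
  right <- branch_range[2] - target_pos
  nf <- min(radius, left) + min(radius, right)
  count / nf
}

oracle_nearest <- function(target_pos, event_positions) {
  best <- Inf
  for (p in event_positions) best <- min(best, abs(p - target_pos))
  if (is.finite(best)) best else NA_real_
}

# Mean pairwise correlation by explicit double loop.
oracle_mean_pairwise_r <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      vals <- c(vals, stats::cor(m[i, ], m[j, ]))
    }
  }
  mean(vals)
}
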