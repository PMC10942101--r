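#' Generate synthetic spine and dendrite fluorescence
#'
#' Builds per-spine raw fluorescence traces on the imaging frame clock as a
#' sum of (i) shared local "cluster" events whose recruitment probability
#' decays with dendritic distance from the event center as
#' `exp(-d / cluster_length_constant) * coupling`, (ii) movement-locked events
#' for ground-truth movement-related spines, and (iii) independent events that
#' top the per-spine rate up to `base_event_rate`; plus Gaussian noise on the
#' dF/F0 scale riding on a slowly drifting baseline. Eliminated spines receive
#' `coupling * (1 - eliminated_coupling_deficit)` and an onset lag of
#' `+eliminated_lag` seconds. A dendritic calcium event is emitted whenever a
#' cluster event recruits at least `dendrite_event_min_spines` spines, for a
#' fraction of lever presses, and at a low independent rate. Every event that
#' contributes fluorescence is recorded in the ground truth.
#'
#' @param cfg a [sim_config()].
#' @param behavior the matching [generate_behavior()] output.
#' @return A list with `frames` (frame clock), `spine_raw` and `dendrite_raw`
#'   (frames x ROI matrices of raw fluorescence), `metadata` (per-spine
#'   table), and `ground_truth`.
#' @export
generate_activity <- function(cfg, behavior) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1000003L)
  fc <- frame_clock(cfg)
  tt <- fc$times
  nf <- length(tt)
  imaged_min <- fc$imaged_seconds / 60
  blocks <- unique(fc$block)
  block_start <- vapply(blocks, function(b) min(tt[fc$block == b]), 0)
  block_end <- vapply(blocks, function(b) max(tt[fc$block == b]), 0)
  block_of_time <- function(s) {
    i <- which(s >= block_start - 1e-9 & s <= block_end + 1e-9)
    if (length(i)) blocks[i[1]] else NA_integer_
  }
  # uniform draw of a time within imaged (on-block) time
  sample_imaged_times <- function(k) {
    if (k == 0L) return(numeric(0))
    lens <- block_end - block_start
    b <- sample(seq_along(blocks), k, replace = TRUE, prob = lens)
    block_start[b] + stats::runif(k) * lens[b]
  }

  ns <- cfg$spines_per_dendrite
  nd <- cfg$n_dendrites
  L <- cfg$dendrite_length
  lam <- cfg$cluster_length_constant

  meta <- list()
  spine_events <- list()    # all onsets per spine
  cluster_events <- list()  # cluster/movement-driven onsets (carry the lag)
  dend_events <- vector("list", nd)
  spine_dff <- matrix(0, nf, ns * nd)
  dend_dff <- matrix(0, nf, nd)

  draw_amp <- function(k, scale = 1) {
    m <- cfg$event_amplitude_mean * scale
    stats::rlnorm(k, meanlog = log(m) - 0.045, sdlog = 0.3)
  }
  add_events <- function(col, onsets, amps, tau) {
    for (j in seq_along(onsets)) {
      o <- onsets[j]
      b <- block_of_time(o)
      if (is.na(b)) next
      hi <- min(o + 8 * tau, block_end[match(b, blocks)])
      i0 <- findInterval(o - 1e-9, tt) + 1L
      i1 <- findInterval(hi + 1e-9, tt)
      if (i1 < i0) next
      col[i0:i1] <- col[i0:i1] + amps[j] * exp(-(tt[i0:i1] - o) / tau)
    }
    col
  }

  # presses that fall inside imaged blocks drive movement-locked activity
  press <- behavior$press_onsets
  press <- press[!is.na(vapply(press, block_of_time, 0L))]

  for (d in seq_len(nd)) {
    pos <- sort(stats::runif(ns, 0, L))
    n_elim <- max(1L, round(cfg$eliminated_fraction * ns))
    elim <- rep(FALSE, ns)
    elim[sample.int(ns, n_elim)] <- TRUE
    mrs <- stats::runif(ns) < cfg$mrs_fraction
    lag <- pmax(stats::rnorm(ns, 0.01, 0.01), -0.01) +
      ifelse(elim, cfg$eliminated_lag, 0)
    coupling <- cfg$cluster_coupling *
      ifelse(elim, 1 - cfg$eliminated_coupling_deficit, 1)
    area1 <- stats::rlnorm(ns, cfg$area_lognormal_params[1],
                           cfg$area_lognormal_params[2]) *
      ifelse(elim, cfg$eliminated_area_scale, 1)

    sp_on <- replicate(ns, numeric(0), simplify = FALSE)
    cl_on <- replicate(ns, numeric(0), simplify = FALSE)
    d_on <- numeric(0)

    # shared local cluster events
    n_cl <- stats::rpois(1, cfg$cluster_rate * imaged_min)
    cl_t <- sample_imaged_times(n_cl)
    cl_c <- stats::runif(n_cl, 0, L)
    for (e in seq_len(n_cl)) {
      p <- coupling * exp(-abs(pos - cl_c[e]) / lam)
      joins <- which(stats::runif(ns) < p)
      for (s in joins) {
        o <- cl_t[e] + lag[s] + stats::rnorm(1, 0, cfg$onset_jitter_sd)
        sp_on[[s]] <- c(sp_on[[s]], o)
        cl_on[[s]] <- c(cl_on[[s]], o)
      }
      if (length(joins) >= cfg$dendrite_event_min_spines) {
        d_on <- c(d_on, cl_t[e])
      }
    }

    # movement-locked drive: dendritic output during a fraction of presses,
    # with MRS spines responding around the same times. The coupling deficit
    # applies to joining any shared event, movement-locked ones included.
    elim_scale <- ifelse(elim, 1 - cfg$eliminated_coupling_deficit, 1)
    d_press <- press[stats::runif(length(press)) < 0.5]
    d_on <- c(d_on, d_press + 0.15)
    for (s in which(mrs)) {
      resp <- press[stats::runif(length(press)) <
                      cfg$movement_response_prob * elim_scale[s]]
      if (length(resp)) {
        o <- resp + 0.15 + lag[s] +
          stats::rnorm(length(resp), 0, cfg$onset_jitter_sd)
        sp_on[[s]] <- c(sp_on[[s]], o)
        cl_on[[s]] <- c(cl_on[[s]], o)
      }
    }

    # independent global dendritic events
    d_on <- c(d_on, sample_imaged_times(stats::rpois(1, 0.5 * imaged_min)))

    # independent spine events top rates up to base_event_rate
    p_join <- coupling * (lam / L) *
      (2 - exp(-pos / lam) - exp(-(L - pos) / lam))
    r_clust <- cfg$cluster_rate * p_join
    r_mov <- ifelse(mrs,
                    length(press) * cfg$movement_response_prob * elim_scale /
                      imaged_min, 0)
    r_indep <- pmax(0, cfg$base_event_rate - r_clust - r_mov)
    for (s in seq_len(ns)) {
      k <- stats::rpois(1, r_indep[s] * imaged_min)
      sp_on[[s]] <- c(sp_on[[s]], sample_imaged_times(k))
    }

    # render traces; drop onsets that land outside imaged blocks
    for (s in seq_len(ns)) {
      keep <- !is.na(vapply(sp_on[[s]], block_of_time, 0L))
      sp_on[[s]] <- sort(sp_on[[s]][keep])
      cl_on[[s]] <- sort(cl_on[[s]][cl_on[[s]] %in% sp_on[[s]]])
      col <- (d - 1L) * ns + s
      spine_dff[, col] <- add_events(spine_dff[, col], sp_on[[s]],
                                     draw_amp(length(sp_on[[s]])),
                                     cfg$event_tau)
    }
    d_on <- sort(d_on[!is.na(vapply(d_on, block_of_time, 0L))])
    dend_dff[, d] <- add_events(dend_dff[, d], d_on,
                                draw_amp(length(d_on), 1.3),
                                cfg$event_tau * 1.5)
    dend_events[[d]] <- d_on

    spine_events <- c(spine_events, sp_on)
    cluster_events <- c(cluster_events, cl_on)
    pe <- rep(TRUE, ns)
    pm <- !elim | (stats::runif(ns) < 0.5)  # half of eliminations are late
    pl <- !elim
    area_noise <- function() stats::rlnorm(ns, 0, 0.05)
    meta[[d]] <- data.frame(
      spine_id = sprintf("d%02d_s%02d", d, seq_len(ns)),
      dendrite_id = sprintf("d%02d", d),
      position_um = pos,
      area = area1,
      label = ifelse(elim, "eliminated", "stable"),
      present_early = pe, present_middle = pm, present_late = pl,
      area_early = area1,
      area_middle = ifelse(pm, area1 * area_noise(), NA_real_),
      area_late = ifelse(pl, area1 * area_noise(), NA_real_),
      mrs_true = mrs, lag_true = lag, coupling_true = coupling,
      stringsAsFactors = FALSE
    )
  }

  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  names(spine_events) <- meta$spine_id
  names(cluster_events) <- meta$spine_id
  names(dend_events) <- sprintf("d%02d", seq_len(nd))

  # raw fluorescence: drifting baseline, per-ROI level, additive dF/F0 noise
  f0_of <- function(level) {
    level * (1 + cfg$f0_drift * sin(2 * pi * tt / max(600, cfg$session_length / 2)))
  }
  for (j in seq_len(ncol(spine_dff))) {
    f0 <- f0_of(cfg$f0_level * stats::runif(1, 0.8, 1.2))
    spine_dff[, j] <- f0 * (1 + spine_dff[, j] +
                              stats::rnorm(nf, 0, cfg$noise_sigma))
  }
  for (j in seq_len(nd)) {
    f0 <- f0_of(cfg$f0_level * stats::runif(1, 0.8, 1.2))
    dend_dff[, j] <- f0 * (1 + dend_dff[, j] +
                             stats::rnorm(nf, 0, cfg$noise_sigma))
  }
  colnames(spine_dff) <- meta$spine_id
  colnames(dend_dff) <- names(dend_events)

  list(
    frames = fc,
    spine_raw = spine_dff,
    dendrite_raw = dend_dff,
    metadata = meta,
    ground_truth = list(
      spine_onsets = spine_events,
      cluster_onsets = cluster_events,
      dendrite_onsets = dend_events,
      lag = stats::setNames(meta$lag_true, meta$spine_id),
      mrs = stats::setNames(meta$mrs_true, meta$spine_id),
      label = stats::setNames(meta$label, meta$spine_id)
    )
  )
}

#' Generate a complete synthetic session
#'
#' Couples [generate_behavior()] and [generate_activity()] under one config.
#'
#' @param cfg a [sim_config()].
#' @return A `spine_session`: list with `config`, `behavior`, `frames`,
#'   `spine_raw`, `dendrite_raw`, `metadata`, `ground_truth`.
#' @export
generate_session <- function(cfg) {
  behavior <- generate_behavior(cfg)
  act <- generate_activity(cfg, behavior)
  structure(c(list(config = cfg, behavior = behavior), act),
            class = "spine_session")
}
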