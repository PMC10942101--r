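#' Relative onset timing of spine events versus dendritic calcium events
#'
#' Matches spine event onsets to dendritic event onsets within a +/- `window`
#' and computes `delta_t = spine onset - dendrite onset` per matched pair.
#' Matching is greedy by `|delta_t|` and one-to-one: each spine event and
#' each dendritic event participates in at most one pair. The per-spine
#' summary is the median (or mean) of the matched lags.
#'
#' @param spine_train,dendrite_train `event_train` objects on a common clock,
#'   or numeric vectors of onset times (s).
#' @param window matching half-window, s.
#' @param summary `"median"` (default) or `"mean"`.
#' @return A `lag_result`: list with `delta_t` (per matched pair, s),
#'   `summary_dt` (per-spine summary, s), `n_pairs`. `summary_dt` is `NA`
#'   when no dendritic event has a spine event within the window.
#' @export
event_onset_lags <- function(spine_train, dendrite_train, window = 1,
                             summary = c("median", "mean")) {
  summary <- match.arg(summary)
  s_on <- if (is.numeric(spine_train)) spine_train else spine_train$events$onset_s
  d_on <- if (is.numeric(dendrite_train)) dendrite_train else dendrite_train$events$onset_s
  if (length(s_on) == 0L || length(d_on) == 0L) {
    stop("both event trains must be nonempty")
  }
  cand <- expand.grid(s = seq_along(s_on), d = seq_along(d_on))
  cand$dt <- s_on[cand$s] - d_on[cand$d]
  cand <- cand[abs(cand$dt) <= window, , drop = FALSE]
  cand <- cand[order(abs(cand$dt)), , drop = FALSE]
  used_s <- logical(length(s_on))
  used_d <- logical(length(d_on))
  dts <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$s[i]
    d <- cand$d[i]
    if (used_s[s] || used_d[d]) next
    used_s[s] <- TRUE
    used_d[d] <- TRUE
    dts <- c(dts, cand$dt[i])
  }
  sm <- if (length(dts) == 0L) NA_real_
        else if (summary == "median") stats::median(dts) else mean(dts)
  structure(list(delta_t = dts, summary_dt = sm, n_pairs = length(dts)),
            class = "lag_result")
}

#' Soma-dendrite calcium event coupling
#'
#' Matches dendritic calcium events to overlapping somatic events and
#' summarizes the coupling: the coincidence fraction (matched dendritic
#' events / total dendritic events), per-pair peak amplitudes normalized to
#' each compartment's own maximum, and the Pearson correlation of the
#' normalized amplitude pairs.
#'
#' @param dendrite_train,soma_train `event_train` objects on a common clock
#'   (with `peak_dff` populated by [detect_events()]).
#' @return list with `coincidence_fraction`, `amplitudes` (data.frame
#'   `dendrite`, `soma`, peak-normalized), and `r` (`NA` with < 3 pairs).
#' @export
soma_dendrite_coupling <- function(dendrite_train, soma_train) {
  dev <- dendrite_train$events
  sev <- soma_train$events
  if (nrow(dev) == 0L) {
    return(list(coincidence_fraction = NA_real_,
                amplitudes = NULL, r = NA_real_))
  }
  if (nrow(sev) == 0L) {
    return(list(coincidence_fraction = 0,
                amplitudes = NULL, r = NA_real_))
  }
  pairs <- list()
  for (i in seq_len(nrow(dev))) {
    j <- which(sev$onset < dev$offset[i] & sev$offset > dev$onset[i])
    if (length(j)) {
      pairs[[length(pairs) + 1L]] <-
        c(dend = dev$peak_dff[i], soma = max(sev$peak_dff[j]))
    }
  }
  frac <- length(pairs) / nrow(dev)
  if (length(pairs) == 0L) {
    return(list(coincidence_fraction = 0, amplitudes = NULL, r = NA_real_))
  }
  amp <- as.data.frame(do.call(rbind, pairs))
  names(amp) <- c("dendrite", "soma")
  amp$dendrite <- amp$dendrite / max(amp$dendrite)
  amp$soma <- amp$soma / max(amp$soma)
  r <- if (nrow(amp) >= 3L) stats::cor(amp$dendrite, amp$soma) else NA_real_
  list(coincidence_fraction = frac, amplitudes = amp, r = r)
}
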