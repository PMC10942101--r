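#' Fit a linear mixed-effects model for nested spine data
#'
#' Fits the group-comparison model families used throughout the analysis
#' (e.g. `Response ~ Stability + (1 | Animal) + (Stability - 1 | Animal)`,
#' or the distance-interaction family for co-activity curves) by maximum
#' likelihood and reports the fixed-effect table with large-sample Wald z
#' p-values, plus the log-likelihood for model comparison. When the formula
#' has no random terms, or the grouping factor has fewer than two levels, or
#' the mixed fit fails, the model collapses to ordinary least squares (with
#' the same fixed-effect table).
#'
#' @param formula model formula (string or formula) in lme4 syntax; the
#'   printed forms with `(X - 1 | Animal)` random slopes pass through
#'   unchanged.
#' @param data long-format data.frame; factors should use treatment coding
#'   with `"stable"` / `"early"` as reference levels.
#' @param reml fit by REML instead of ML (`FALSE` by default so
#'   log-likelihoods are comparable across fixed structures).
#' @return An `lme_result`: list with `coefficients` (data.frame `term`,
#'   `estimate`, `se`, `z`, `p`), `logLik`, `converged`, `singular`,
#'   `method` (`"lmer"` or `"ols"`), and `fit` (the underlying model).
#' @export
fit_lme <- function(formula, data, reml = FALSE) {
  f <- stats::as.formula(formula)
  bars <- lme4::findbars(f)
  groups_ok <- length(bars) > 0L
  if (groups_ok) {
    gvars <- unique(vapply(bars, function(b) deparse(b[[3]]), ""))
    gvars <- gvars[gvars %in% names(data)]
    groups_ok <- length(gvars) > 0L &&
      all(vapply(gvars, function(g) length(unique(data[[g]])) >= 2L, TRUE))
  }
  if (groups_ok) {
    fit <- tryCatch(
      suppressMessages(lme4::lmer(f, data = data, REML = reml)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      singular <- lme4::isSingular(fit)
      if (singular) {
        warning("singular random-effect structure; consider a reduced model")
      }
      msgs <- fit@optinfo$conv$lme4$messages
      # boundary (singular) fits are flagged via `singular`, not here
      conv <- is.null(msgs) || !any(grepl("failed to converge", msgs))
      sm <- summary(fit)$coefficients
      tab <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"],
                        z = sm[, "Estimate"] / sm[, "Std. Error"],
                        row.names = NULL)
      tab$p <- if (conv) 2 * stats::pnorm(-abs(tab$z)) else NA_real_
      return(structure(list(coefficients = tab,
                            logLik = as.numeric(stats::logLik(fit)),
                            converged = conv, singular = singular,
                            method = "lmer", fit = fit),
                       class = "lme_result"))
    }
    warning("mixed fit failed; collapsing to ordinary least squares")
  }
  fx <- lme4::nobars(f)
  fit <- stats::lm(fx, data = data)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    z = sm[, "Estimate"] / sm[, "Std. Error"],
                    row.names = NULL)
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  structure(list(coefficients = tab,
                 logLik = as.numeric(stats::logLik(fit)),
                 converged = TRUE, singular = FALSE,
                 method = "ols", fit = fit),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("Linear mixed-effects fit (%s, logLik = %.2f%s)\n",
              x$method, x$logLik,
              if (x$singular) ", singular" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}
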