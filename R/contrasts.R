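.endpoint_measure <- c(PFS = "logHR", OS = "logHR", ORR = "logOR",
                       CR = "logOR", SAFETY = "logRR")

.arm_effect_vs_baseline <- function(arm, base, endpoint, cc = 0.5) {
  measure <- .endpoint_measure[[endpoint]]
  s <- arm$endpoints[[endpoint]]
  if (measure == "logHR") {
    if (is.null(s)) return(NULL)
    switch(s$type,
      loghr_se = effect_estimate("logHR", s$loghr, s$se^2, "reported"),
      pvalue_events = loghr_from_logrank(s$p, s$events, arm$n / base$n,
                                         s$direction),
      hr_ci = loghr_from_ci(s$hr, s$lo, s$hi, s$level),
      NULL)
  } else {
    sb <- base$endpoints[[endpoint]]
    if (is.null(s) || is.null(sb) || s$type != "events_total" ||
        sb$type != "events_total") return(NULL)
    fn <- if (measure == "logOR") logor_from_counts else logrr_from_counts
    fn(s$events, s$total, sb$events, sb$total, cc)
  }
}

# variance contribution of the shared baseline arm, used as the
# off-diagonal covariance of a multi-arm trial's contrasts
.baseline_var_share <- function(base, endpoint, cc = 0.5) {
  measure <- .endpoint_measure[[endpoint]]
  sb <- base$endpoints[[endpoint]]
  eb <- sb$events; nb <- sb$total
  if (eb == 0 || eb == nb) { eb <- eb + cc; nb <- nb + 2 * cc }
  if (measure == "logOR") 1 / eb + 1 / (nb - eb) else 1 / eb - 1 / nb
}

#' Convert trial records to contrast-level data for one endpoint
#'
#' Each trial contributes the vector of log-scale effects of its
#' non-baseline arms against its first (baseline) arm, with the within-trial
#' covariance matrix: contrast variances on the diagonal and, for multi-arm
#' trials, the variance share of the common baseline arm off the diagonal
#' (for event counts, `1/e_b + 1/(n_b - e_b)` on the odds-ratio scale and
#' `1/e_b - 1/n_b` on the risk-ratio scale; for reported hazard ratios the
#' caller-supplied `hr_baseline_share`, default 0, since the baseline arm's
#' contribution is not recoverable from a reported HR + SE).
#'
#' Binary endpoints (ORR, CR) are converted to log odds ratios, safety to
#' log risk ratios, and time-to-event endpoints (PFS, OS) use reported or
#' reconstructed log hazard ratios. Trials with no usable summary for the
#' endpoint on some arm are dropped with a warning.
#'
#' @param trials An `nma_trials` object.
#' @param endpoint One of `"PFS"`, `"OS"`, `"ORR"`, `"CR"`, `"SAFETY"`.
#' @param hr_baseline_share Off-diagonal covariance for multi-arm trials
#'   whose survival effects are reported/reconstructed HRs.
#' @param cc Continuity constant for zero event cells.
#' @return An `nma_contrasts` object: list of per-trial elements
#'   `study_id`, `baseline`, `treatments`, `y`, `S`, with attributes
#'   `endpoint` and `measure`.
#' @export
to_contrasts <- function(trials, endpoint, hr_baseline_share = 0, cc = 0.5) {
  endpoint <- match.arg(endpoint, mm_endpoints)
  measure <- .endpoint_measure[[endpoint]]
  out <- list()
  dropped <- character()
  for (tr in trials) {
    base <- tr$arms[[1]]
    others <- tr$arms[-1]
    if (measure != "logHR") {
      sb <- base$endpoints[[endpoint]]
      if (is.null(sb) || sb$type != "events_total") {
        dropped <- c(dropped, tr$study_id); next
      }
    }
    effs <- lapply(others, .arm_effect_vs_baseline, base = base,
                   endpoint = endpoint, cc = cc)
    if (any(vapply(effs, is.null, logical(1)))) {
      dropped <- c(dropped, tr$study_id); next
    }
    m <- length(effs)
    y <- vapply(effs, `[[`, numeric(1), "value")
    S <- diag(vapply(effs, `[[`, numeric(1), "variance"), nrow = m)
    if (m > 1L) {
      share <- if (measure == "logHR") hr_baseline_share
               else .baseline_var_share(base, endpoint, cc)
      S[upper.tri(S)] <- share
      S[lower.tri(S)] <- share
    }
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("trial '", tr$study_id,
           "': within-trial covariance not positive-definite", call. = FALSE)
    out[[length(out) + 1L]] <- list(
      study_id = tr$study_id,
      baseline = base$treatment,
      treatments = vapply(others, `[[`, character(1), "treatment"),
      y = y, S = S)
  }
  if (length(dropped))
    warning("dropped trial(s) without usable ", endpoint, " data: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  structure(out, endpoint = endpoint, measure = measure,
            class = "nma_contrasts")
}

#' @export
print.nma_contrasts <- function(x, ...) {
  cat(sprintf("<nma_contrasts> %s (%s): %d trials, %d contrasts\n",
              attr(x, "endpoint"), attr(x, "measure"), length(x),
              sum(vapply(x, function(d) length(d$y), integer(1)))))
  invisible(x)
}
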