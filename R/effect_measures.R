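#' Construct a log-scale relative effect estimate
#'
#' @param measure One of `"logHR"`, `"logOR"`, `"logRR"`.
#' @param value Effect on the log scale.
#' @param variance Positive sampling variance.
#' @param derivation Provenance label: `"reported"`, `"counts"`,
#'   `"logrank_p"` or `"ci_backcalc"`.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(measure, value, variance, derivation = "reported") {
  measure <- match.arg(measure, c("logHR", "logOR", "logRR"))
  derivation <- match.arg(derivation,
                          c("reported", "counts", "logrank_p", "ci_backcalc"))
  if (!is.finite(value) || !is.finite(exp(value)))
    stop("effect value must be finite on the ratio scale", call. = FALSE)
  if (!is.finite(variance) || variance <= 0)
    stop("variance must be positive", call. = FALSE)
  structure(list(measure = measure, value = value, variance = variance,
                 derivation = derivation), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s = %.4f (SE %.4f, %s); ratio %.3f\n",
              x$measure, x$value, sqrt(x$variance), x$derivation,
              exp(x$value)))
  invisible(x)
}

.check_counts <- function(e1, n1, e0, n0) {
  if (n1 < 1 || n0 < 1) stop("totals must be >= 1", call. = FALSE)
  if (e1 < 0 || e1 > n1 || e0 < 0 || e0 > n0)
    stop("events must lie in [0, total]", call. = FALSE)
}

#' Log odds ratio from 2x2 event counts
#'
#' Used for the binary efficacy endpoints (ORR, CR). When any cell of the
#' 2x2 table is zero, the continuity constant `cc` is added to all four
#' cells first (Gart correction).
#'
#' @param e1,n1 Events and total in the comparator arm.
#' @param e0,n0 Events and total in the reference arm.
#' @param cc Continuity constant, default 0.5.
#' @return An `effect_estimate` with measure `"logOR"`.
#' @export
logor_from_counts <- function(e1, n1, e0, n0, cc = 0.5) {
  .check_counts(e1, n1, e0, n0)
  cells <- c(e1, n1 - e1, e0, n0 - e0)
  if (any(cells == 0)) cells <- cells + cc
  a <- cells[1]; b <- cells[2]; c0 <- cells[3]; d0 <- cells[4]
  if ((a == 0 && c0 == 0) || (b == 0 && d0 == 0))
    stop("both arms all-events or all-zero; odds ratio undefined",
         call. = FALSE)
  effect_estimate("logOR", log((a * d0) / (c0 * b)),
                  1 / a + 1 / b + 1 / c0 + 1 / d0, "counts")
}

#' Log risk ratio from 2x2 event counts
#'
#' Used for the safety endpoint (risk of the most frequent grade 3-4
#' adverse event). Zero cells are handled as in [logor_from_counts()].
#'
#' @inheritParams logor_from_counts
#' @return An `effect_estimate` with measure `"logRR"`.
#' @export
logrr_from_counts <- function(e1, n1, e0, n0, cc = 0.5) {
  .check_counts(e1, n1, e0, n0)
  cells <- c(e1, n1 - e1, e0, n0 - e0)
  if (any(cells == 0)) cells <- cells + cc
  a <- cells[1]; m1 <- cells[1] + cells[2]
  c0 <- cells[3]; m0 <- cells[3] + cells[4]
  if (a == 0 || c0 == 0)
    stop("no events in an arm after correction; risk ratio undefined",
         call. = FALSE)
  effect_estimate("logRR", log((a / m1) / (c0 / m0)),
                  1 / a - 1 / m1 + 1 / c0 - 1 / m0, "counts")
}

#' Log hazard ratio reconstructed from a log-rank p-value
#'
#' Tierney-style reconstruction for trials reporting survival curves with a
#' log-rank p-value but no hazard ratio. With total observed events `E` and
#' allocation ratio `R`, the log-rank variance is `V = E R / (1 + R)^2`;
#' the observed-minus-expected statistic is recovered from the two-sided
#' p-value and the caller-supplied direction, and `logHR = (O - E)/V`,
#' `var = 1/V`.
#'
#' @param p_two_sided Two-sided log-rank p-value, strictly in (0, 1).
#' @param total_events Total observed events across both arms.
#' @param alloc_ratio Allocation ratio `n1/n0`, default 1 (equal).
#' @param direction +1 when the effect favors the comparator arm
#'   (logHR > 0), -1 otherwise. A p-value carries no sign, so the caller
#'   must supply it.
#' @return An `effect_estimate` with measure `"logHR"`.
#' @export
loghr_from_logrank <- function(p_two_sided, total_events, alloc_ratio = 1,
                               direction = 1) {
  if (!is.finite(p_two_sided) || p_two_sided <= 0 || p_two_sided >= 1)
    stop("p-value must lie strictly in (0, 1)", call. = FALSE)
  if (total_events < 1) stop("total_events must be >= 1", call. = FALSE)
  if (alloc_ratio <= 0) stop("alloc_ratio must be positive", call. = FALSE)
  direction <- sign(direction)
  if (direction == 0) stop("direction must be +1 or -1", call. = FALSE)
  V <- total_events * alloc_ratio / (1 + alloc_ratio)^2
  z <- stats::qnorm(p_two_sided / 2, lower.tail = FALSE)
  o_minus_e <- direction * z * sqrt(V)
  effect_estimate("logHR", o_minus_e / V, 1 / V, "logrank_p")
}

#' Log hazard ratio back-calculated from a reported HR and CI
#'
#' Companion reconstruction for trials reporting a hazard ratio with a
#' confidence interval but no standard error: `logHR = log hr`,
#' `SE = (log hi - log lo) / (2 z)` with `z` the two-sided normal quantile
#' of the interval's coverage.
#'
#' @param hr Reported hazard ratio.
#' @param lo,hi Confidence-interval bounds, `0 < lo <= hr <= hi`.
#' @param level Interval coverage, default 0.95.
#' @return An `effect_estimate` with measure `"logHR"`.
#' @export
loghr_from_ci <- function(hr, lo, hi, level = 0.95) {
  if (any(!is.finite(c(hr, lo, hi))) || lo <= 0 || hi <= 0 || hr <= 0)
    stop("hr and CI bounds must be positive", call. = FALSE)
  if (lo > hr || hr > hi)
    stop("CI bounds must bracket the hazard ratio", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- (log(hi) - log(lo)) / (2 * z)
  if (se <= 0)
    stop("degenerate interval (zero width) gives zero variance", call. = FALSE)
  effect_estimate("logHR", log(hr), se^2, "ci_backcalc")
}
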