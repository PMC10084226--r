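#' Pooled direct estimate for one pairwise comparison
#'
#' Inverse-variance pooling with weights `1/(v_i + tau2)`, i.e. a
#' random-effects pooled estimate at a given (externally estimated)
#' heterogeneity.
#'
#' @param estimates List of [effect_estimate()] objects on a common
#'   measure and comparison.
#' @param tau2 Shared between-trial variance added to each study variance.
#' @return An `effect_estimate` holding the pooled value and its variance.
#' @export
direct_estimate <- function(estimates, tau2 = 0) {
  if (!length(estimates)) stop("no estimates to pool", call. = FALSE)
  if (tau2 < 0) stop("tau2 must be nonnegative", call. = FALSE)
  meas <- unique(vapply(estimates, `[[`, character(1), "measure"))
  if (length(meas) != 1L)
    stop("mixed measures: ", paste(meas, collapse = ", "), call. = FALSE)
  y <- vapply(estimates, `[[`, numeric(1), "value")
  w <- 1 / (vapply(estimates, `[[`, numeric(1), "variance") + tau2)
  effect_estimate(meas, sum(w * y) / sum(w), 1 / sum(w), "reported")
}

#' Bucher loop inconsistency for one triangular loop
#'
#' Confronts the direct estimate of one edge with the indirect estimate
#' implied by the other two: on the log scale
#' `ror = |ab - (ac - bc)|`, with standard error
#' `sqrt(v_ab + v_ac + v_bc)`. Values near 0 indicate that direct and
#' indirect evidence agree. The 95% CI (normal approximation around the
#' signed difference) is truncated at 0 below, matching the absolute-value
#' scale.
#'
#' @param ab,ac,bc Direct `effect_estimate`s for the loop's three edges
#'   (A vs B, A vs C, C vs B orientation: `ab` is compared with
#'   `ac - bc`), all on a common measure.
#' @param tau2_loop Loop heterogeneity to record alongside (default 0).
#' @param loop Optional character triple naming the loop.
#' @return A `loop_assessment`: list with `loop`, `ror`, `se`, `z`,
#'   `ci95`, `tau2_loop`.
#' @export
loop_inconsistency <- function(ab, ac, bc, tau2_loop = 0, loop = NULL) {
  meas <- unique(c(ab$measure, ac$measure, bc$measure))
  if (length(meas) != 1L)
    stop("loop edges use different measures: ",
         paste(meas, collapse = ", "), call. = FALSE)
  diff <- ab$value - (ac$value - bc$value)
  se <- sqrt(ab$variance + ac$variance + bc$variance)
  ror <- abs(diff)
  ci <- ror + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(loop = loop, ror = ror, se = se, z = ror / se,
                 ci95 = c(max(0, ci[1]), ci[2]), tau2_loop = tau2_loop),
            class = "loop_assessment")
}

#' @export
print.loop_assessment <- function(x, ...) {
  cat(sprintf(
    "<loop_assessment> %s: RoR %.3f (SE %.3f, z %.2f, 95%% CI %.3f-%.3f), tau2 %.4f\n",
    if (is.null(x$loop)) "?" else paste(x$loop, collapse = "-"),
    x$ror, x$se, x$z, x$ci95[1], x$ci95[2], x$tau2_loop))
  invisible(x)
}

# restricted log-likelihood of a random-effects meta-analysis, optionally
# with group-specific means (fixed group effects, common tau2)
.reml_ll <- function(tau2, y, v, groups) {
  w <- 1 / (v + tau2)
  ll <- 0
  for (g in unique(groups)) {
    i <- groups == g
    mu <- sum(w[i] * y[i]) / sum(w[i])
    ll <- ll - 0.5 * (log(sum(w[i])) + sum(w[i] * (y[i] - mu)^2))
  }
  ll - 0.5 * sum(log(v + tau2))
}

#' REML estimate of between-trial heterogeneity
#'
#' Maximizes the restricted log-likelihood
#' `-1/2 [sum log(v_i + tau2) + log sum w_i + sum w_i (y_i - mu_hat)^2]`
#' (`w_i = 1/(v_i + tau2)`, `mu_hat` the weighted mean) by bounded 1-D
#' optimization. With `groups` given, a common tau2 is estimated across
#' groups each with its own mean — used for loop-level heterogeneity on
#' the union of a loop's pairwise estimates.
#'
#' @param estimates List of at least two [effect_estimate()] objects.
#' @param groups Optional grouping vector (one entry per estimate).
#' @param tau2_max Upper bound of the search interval (default 100).
#' @return Nonnegative tau2 estimate.
#' @export
reml_tau2 <- function(estimates, groups = NULL, tau2_max = 100) {
  if (length(estimates) < 2L)
    stop("need at least 2 estimates", call. = FALSE)
  y <- vapply(estimates, `[[`, numeric(1), "value")
  v <- vapply(estimates, `[[`, numeric(1), "variance")
  if (is.null(groups)) groups <- rep(1L, length(y))
  if (length(groups) != length(y))
    stop("groups must match estimates", call. = FALSE)
  # every group needs a residual degree of freedom somewhere
  if (all(table(groups) < 2L))
    stop("no group with >= 2 estimates", call. = FALSE)
  opt <- stats::optimize(.reml_ll, c(0, tau2_max), y = y, v = v,
                         groups = groups, maximum = TRUE, tol = 1e-9)
  if (.reml_ll(0, y, v, groups) >= opt$objective) 0 else opt$maximum
}

#' Loop inconsistency report over all evaluable triangles
#'
#' For every triangular loop whose three edges all carry direct evidence
#' for the endpoint, pools each edge's trial estimates (weights include
#' the loop-level REML tau2, estimated on the union of the loop's pairwise
#' estimates under a common-tau2 assumption) and computes the Bucher
#' inconsistency. Loops missing direct evidence on an edge are skipped
#' with a message.
#'
#' @param network A `treatment_network`.
#' @param trials The `nma_trials` the network was built from.
#' @param endpoint Endpoint label.
#' @return List of `loop_assessment` objects (possibly empty), one per
#'   evaluable triangle, with a `skipped` attribute naming skipped loops.
#' @export
network_inconsistency_report <- function(network, trials, endpoint) {
  endpoint <- match.arg(endpoint, mm_endpoints)
  tri <- enumerate_triangles(network)
  out <- list()
  skipped <- character()
  for (r in seq_len(nrow(tri))) {
    trip <- unlist(tri[r, c("a", "b", "c")], use.names = FALSE)
    edges <- list(c(trip[1], trip[2]), c(trip[1], trip[3]),
                  c(trip[3], trip[2]))
    ests <- lapply(edges, function(e)
      .pairwise_estimates(trials, e[1], e[2], endpoint))
    if (any(lengths(ests) == 0L)) {
      skipped <- c(skipped, paste(trip, collapse = "-"))
      message("loop ", paste(trip, collapse = "-"),
              ": no direct ", endpoint, " evidence on an edge; skipped")
      next
    }
    all_ests <- do.call(c, ests)
    grp <- rep(seq_along(ests), lengths(ests))
    t2 <- if (any(table(grp) >= 2L)) reml_tau2(all_ests, groups = grp) else 0
    pooled <- lapply(ests, direct_estimate, tau2 = t2)
    out[[length(out) + 1L]] <-
      loop_inconsistency(pooled[[1]], pooled[[2]], pooled[[3]],
                         tau2_loop = t2, loop = trip)
  }
  attr(out, "skipped") <- skipped
  out
}

# per-trial direct estimates of treatment t1 vs t2 (t1 relative to t2)
.pairwise_estimates <- function(trials, t1, t2, endpoint, cc = 0.5) {
  out <- list()
  for (tr in trials) {
    labs <- vapply(tr$arms, `[[`, character(1), "treatment")
    if (!(t1 %in% labs && t2 %in% labs)) next
    a1 <- tr$arms[[match(t1, labs)]]
    a2 <- tr$arms[[match(t2, labs)]]
    est <- .two_arm_effect(a1, a2, tr$arms[[1]], endpoint, cc)
    if (!is.null(est)) out[[length(out) + 1L]] <- est
  }
  out
}

# relative effect of arm a1 vs arm a2 within one trial, using counts when
# binary and baseline-relative log HRs (differenced if needed) for survival
.two_arm_effect <- function(a1, a2, base, endpoint, cc = 0.5) {
  measure <- .endpoint_measure[[endpoint]]
  if (measure != "logHR") {
    s1 <- a1$endpoints[[endpoint]]; s2 <- a2$endpoints[[endpoint]]
    if (is.null(s1) || is.null(s2) || s1$type != "events_total" ||
        s2$type != "events_total") return(NULL)
    fn <- if (measure == "logOR") logor_from_counts else logrr_from_counts
    return(tryCatch(fn(s1$events, s1$total, s2$events, s2$total, cc),
                    error = function(e) NULL))
  }
  e1 <- .arm_effect_vs_baseline(a1, base, endpoint, cc)
  e2 <- .arm_effect_vs_baseline(a2, base, endpoint, cc)
  if (identical(a2$treatment, base$treatment)) {
    return(e1)
  }
  if (identical(a1$treatment, base$treatment)) {
    if (is.null(e2)) return(NULL)
    return(effect_estimate(measure, -e2$value, e2$variance, e2$derivation))
  }
  if (is.null(e1) || is.null(e2)) return(NULL)
  # both relative to the shared baseline: difference, variances add
  effect_estimate(measure, e1$value - e2$value, e1$variance + e2$variance,
                  "reported")
}
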