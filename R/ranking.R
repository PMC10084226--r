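#' Rank probabilities from posterior draws
#'
#' Ranks all treatments (the reference included at effect 0) within each
#' retained draw, orients ranks so that rank 1 is best for the endpoint's
#' direction, and tallies frequencies into the a x a rank-probability
#' matrix (rankogram). Exact ties within a draw are broken by the stable
#' treatment order.
#'
#' @param samples An `nma_posterior` with at least 1000 retained draws.
#' @param direction `"lower"` when a smaller log effect is better (PFS/OS
#'   hazard ratios, safety risk ratios) or `"higher"` (ORR/CR odds
#'   ratios).
#' @return A `rank_summary` with `rank_probability` filled; rows are
#'   treatments, columns ranks.
#' @export
rank_probabilities <- function(samples, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  dmat <- .d_draws(samples)
  if (nrow(dmat) < 1000L)
    warning("fewer than 1000 retained draws; rank probabilities will be noisy",
            call. = FALSE)
  a <- ncol(dmat)
  signed <- if (direction == "lower") dmat else -dmat
  counts <- matrix(0L, a, a, dimnames = list(colnames(dmat), NULL))
  rk <- apply(signed, 1, rank, ties.method = "first")  # a x draws
  for (i in seq_len(a))
    counts[i, ] <- tabulate(rk[i, ], nbins = a)
  structure(list(endpoint = samples$endpoint, direction = direction,
                 treatments = colnames(dmat),
                 rank_probability = counts / nrow(dmat),
                 cumulative = NULL, sucra = NULL),
            class = "rank_summary")
}

#' Cumulative ranking curves
#'
#' Row-wise partial sums of the rank-probability matrix: entry (i, j) is
#' the probability that treatment i ranks among the best j.
#'
#' @param summary A `rank_summary` with `rank_probability` filled.
#' @return The summary with `cumulative` filled.
#' @export
cumulative_ranking <- function(summary) {
  stopifnot(inherits(summary, "rank_summary"),
            !is.null(summary$rank_probability))
  summary$cumulative <- t(apply(summary$rank_probability, 1, cumsum))
  summary
}

#' Surface under the cumulative ranking curve
#'
#' `SUCRA_i = mean(cumulative_{i,1..a-1})`: 1 for a certainly-best
#' treatment, 0 for a certainly-worst one, 0.5 when all treatments are
#' exchangeable. With a single treatment SUCRA is 1 by convention.
#'
#' @param summary A `rank_summary` with `cumulative` filled (it is
#'   computed on the fly from `rank_probability` if absent).
#' @return The summary with `sucra` filled (named vector in `[0, 1]`).
#' @export
sucra <- function(summary) {
  stopifnot(inherits(summary, "rank_summary"))
  if (is.null(summary$cumulative)) summary <- cumulative_ranking(summary)
  a <- length(summary$treatments)
  summary$sucra <-
    if (a == 1L) stats::setNames(1, summary$treatments)
    else stats::setNames(
      rowMeans(summary$cumulative[, seq_len(a - 1L), drop = FALSE]),
      summary$treatments)
  summary
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("<rank_summary> %s (%s is better), %d treatments%s\n",
              x$endpoint, x$direction, length(x$treatments),
              if (is.null(x$sucra)) "" else "; SUCRA filled"))
  if (!is.null(x$sucra)) {
    top <- sort(x$sucra, decreasing = TRUE)
    show <- utils::head(top, 5)
    cat("  top SUCRA:", paste(sprintf("%s %.3f", names(show), show),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mean-SUCRA ranking chart across the five endpoints
#'
#' Assembles per-endpoint SUCRA values into the treatments x endpoints
#' chart and ranks treatments by their unweighted mean. The safety
#' summary must already be oriented so that a higher SUCRA means safer
#' (i.e. ranked with `direction = "lower"` on the adverse-event risk
#' ratio).
#'
#' @param summaries Named list of `rank_summary` objects with SUCRA
#'   filled, one per endpoint, all over the same treatment set.
#' @return A `sucra_chart`: data frame with one row per treatment, one
#'   column per endpoint, a `mean` column, sorted by decreasing mean (ties
#'   broken by label).
#' @export
mean_sucra_chart <- function(summaries) {
  stopifnot(length(summaries) >= 1L, !is.null(names(summaries)))
  trt <- sort(summaries[[1]]$treatments)
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    if (is.null(s$sucra)) stop("endpoint ", nm, ": SUCRA not filled",
                               call. = FALSE)
    if (!setequal(s$treatments, trt))
      stop("endpoint ", nm, " treatment set differs: missing {",
           paste(setdiff(trt, s$treatments), collapse = ", "),
           "}, extra {",
           paste(setdiff(s$treatments, trt), collapse = ", "), "}",
           call. = FALSE)
  }
  mat <- vapply(summaries, function(s) s$sucra[trt], numeric(length(trt)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1,
                                       dimnames = list(trt, names(summaries)))
  df <- data.frame(treatment = trt, mat, mean = rowMeans(mat),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$mean, df$treatment), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sucra_chart", "data.frame")
  df
}

#' @export
print.sucra_chart <- function(x, ...) {
  cat("<sucra_chart> treatments ranked by mean SUCRA\n")
  print.data.frame(cbind(x["treatment"],
                         round(x[setdiff(names(x), "treatment")], 3)))
  invisible(x)
}
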