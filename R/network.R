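#' Build the treatment evidence network
#'
#' One node per distinct treatment label, weighted by the total number of
#' randomized patients; one edge per label pair co-randomized in at least
#' one trial, with multiplicity the number of such trials.
#'
#' @param trials An `nma_trials` object with canonicalized labels.
#' @return A `treatment_network`: list with `nodes` (data frame
#'   `treatment`, `n_total`), `edges` (data frame `treatment1`,
#'   `treatment2`, `n_trials`, with `treatment1 < treatment2`), `connected`
#'   flag and `components` (membership list). A disconnected network emits
#'   a warning, not an error.
#' @export
build_network <- function(trials) {
  if (length(trials) == 0L) stop("no trials", call. = FALSE)
  labs <- treatment_labels(trials)
  wt <- stats::setNames(integer(length(labs)), labs)
  pair_counts <- new.env(parent = emptyenv())
  for (tr in trials) {
    alabs <- vapply(tr$arms, `[[`, character(1), "treatment")
    ns <- vapply(tr$arms, `[[`, integer(1), "n")
    wt[alabs] <- wt[alabs] + ns
    if (length(alabs) >= 2L) {
      prs <- utils::combn(sort(alabs), 2L)
      for (j in seq_len(ncol(prs))) {
        key <- paste(prs[1, j], prs[2, j], sep = "\r")
        pair_counts[[key]] <- (if (is.null(pair_counts[[key]])) 0L
                               else pair_counts[[key]]) + 1L
      }
    }
  }
  keys <- sort(ls(pair_counts))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    treatment1 = vapply(parts, `[[`, character(1), 1L),
    treatment2 = vapply(parts, `[[`, character(1), 2L),
    n_trials = vapply(keys, function(k) pair_counts[[k]], integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  nodes <- data.frame(treatment = labs, n_total = unname(wt[labs]),
                      stringsAsFactors = FALSE)
  comp <- .components(labs, edges)
  net <- structure(list(nodes = nodes, edges = edges,
                        connected = length(comp) == 1L, components = comp),
                   class = "treatment_network")
  if (!net$connected)
    warning("evidence network is disconnected (",
            length(comp), " components)", call. = FALSE)
  net
}

# connected components by repeated frontier expansion
.components <- function(labs, edges) {
  adj <- .adjacency(labs, edges)
  left <- labs
  comps <- list()
  while (length(left)) {
    frontier <- left[1]
    comp <- character()
    while (length(frontier)) {
      comp <- c(comp, frontier)
      frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), comp)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    left <- setdiff(left, comp)
  }
  comps
}

.adjacency <- function(labs, edges) {
  adj <- stats::setNames(rep(list(character()), length(labs)), labs)
  for (i in seq_len(nrow(edges))) {
    a <- edges$treatment1[i]; b <- edges$treatment2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' @export
print.treatment_network <- function(x, ...) {
  cat(sprintf("<treatment_network> %d nodes, %d edges, %s\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$connected) "connected"
              else sprintf("%d components", length(x$components))))
  invisible(x)
}

#' Enumerate triangular loops of an evidence network
#'
#' All unordered, mutually adjacent treatment triples, each listed once in
#' lexicographic order. Triangular loops are where direct and indirect
#' evidence can be confronted (Bucher method).
#'
#' @param network A `treatment_network`.
#' @return Data frame with columns `a`, `b`, `c` (`a < b < c`), zero rows
#'   when the network has no triangle.
#' @export
enumerate_triangles <- function(network) {
  adj <- .adjacency(network$nodes$treatment, network$edges)
  adj <- lapply(adj, sort)
  out <- list()
  ed <- network$edges
  for (i in seq_len(nrow(ed))) {
    a <- ed$treatment1[i]; b <- ed$treatment2[i]
    common <- intersect(adj[[a]], adj[[b]])
    for (w in common[common > b])     # a < b < w ensures each triangle once
      out[[length(out) + 1L]] <- c(a, b, w)
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(), c = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  df <- data.frame(a = m[, 1], b = m[, 2], c = m[, 3],
                   stringsAsFactors = FALSE)
  df[order(df$a, df$b, df$c), , drop = FALSE]
}

#' Funnel-plot coordinates for one pairwise comparison
#'
#' Centers each study effect on the fixed-effect (inverse-variance) pooled
#' value, the diagnostic used to inspect publication bias: with no bias the
#' centered effects scatter symmetrically around zero at every precision.
#'
#' @param estimates List of [effect_estimate()] objects for a single
#'   comparison and measure.
#' @return Data frame with columns `centered` and `se`, one row per study.
#' @export
funnel_points <- function(estimates) {
  if (!length(estimates)) stop("no estimates", call. = FALSE)
  y <- vapply(estimates, `[[`, numeric(1), "value")
  v <- vapply(estimates, `[[`, numeric(1), "variance")
  if (any(v <= 0)) stop("zero or negative variance", call. = FALSE)
  pooled <- sum(y / v) / sum(1 / v)
  data.frame(centered = y - pooled, se = sqrt(v))
}
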