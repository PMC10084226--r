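#' Assemble the treatments x endpoints SUCRA profile matrix
#'
#' Rows follow the chart's (mean-SUCRA) order; columns are the five
#' endpoints in the fixed order PFS, OS, ORR, CR, SAFETY (safety already
#' oriented so that higher = safer).
#'
#' @param chart A `sucra_chart` from [mean_sucra_chart()].
#' @return A `sucra_profile`: numeric matrix with treatment rownames and
#'   endpoint colnames.
#' @export
assemble_profile <- function(chart) {
  stopifnot(inherits(chart, "sucra_chart"))
  missing <- setdiff(mm_endpoints, names(chart))
  if (length(missing))
    stop("chart is missing endpoint(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  mat <- as.matrix(chart[, mm_endpoints, drop = FALSE])
  rownames(mat) <- chart$treatment
  if (any(mat < 0 | mat > 1))
    stop("SUCRA values must lie in [0, 1]", call. = FALSE)
  structure(mat, class = c("sucra_profile", class(mat)))
}

#' Principal component analysis of a SUCRA profile
#'
#' Eigendecomposition of the covariance (or, with `scale = TRUE`, the
#' correlation) structure of the profile matrix, computed via
#' [stats::prcomp()]. PCs are ordered by decreasing eigenvalue and signed
#' so that each PC's largest-magnitude loading is positive, making the
#' decomposition deterministic.
#'
#' @param profile A `sucra_profile` (or any numeric matrix, treatments in
#'   rows).
#' @param center,scale Center/scale columns before decomposition; both
#'   default `TRUE` (correlation PCA).
#' @return A `cluster_result` with `scores` (treatments x PCs),
#'   `loadings` (endpoints x PCs) and `explained_variance` (per-PC
#'   fraction summing to 1) filled.
#' @export
pca_scores <- function(profile, center = TRUE, scale = TRUE) {
  x <- unclass(profile)
  if (nrow(x) < 2L) stop("need at least 2 treatments", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (scale && any(sds == 0))
    stop("constant column(s) cannot be scaled: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  p <- stats::prcomp(x, center = center, scale. = scale)
  flip <- apply(p$rotation, 2, function(l) {
    j <- which.max(abs(l))
    if (l[j] < 0) -1 else 1
  })
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev, assignments = NULL,
                 medoids = NULL, silhouette = NULL, k = NULL),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>")
  if (!is.null(x$explained_variance))
    cat(sprintf(" %d PCs (PC1 %.1f%%, PC2 %.1f%%)",
                length(x$explained_variance),
                100 * x$explained_variance[1],
                100 * ifelse(length(x$explained_variance) > 1,
                             x$explained_variance[2], 0)))
  if (!is.null(x$assignments))
    cat(sprintf("; k = %d clusters, medoids: %s",
                length(x$medoids), paste(x$medoids, collapse = ", ")))
  cat("\n")
  invisible(x)
}

.dist_matrix <- function(points) as.matrix(stats::dist(points))

.pam_objective <- function(D, medoid_idx) {
  sum(apply(D[, medoid_idx, drop = FALSE], 1, min))
}

# BUILD phase: greedy seeding of k medoids
.pam_build <- function(D, k) {
  n <- nrow(D)
  medoids <- which.min(colSums(D))[1]
  while (length(medoids) < k) {
    nearest <- apply(D[, medoids, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(nearest - D[, j], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain)[1])
  }
  medoids
}

#' Partitioning around medoids on PC scores
#'
#' Classical PAM: the BUILD phase greedily seeds `k` medoids, then the
#' SWAP phase exhaustively tries every (medoid, non-medoid) exchange and
#' applies the best improving swap until none reduces the total Euclidean
#' dissimilarity. Deterministic given the input row order (ties are broken
#' by the first index).
#'
#' @param points Numeric matrix of coordinates (e.g. retained PC scores),
#'   one row per treatment.
#' @param k Number of clusters, `1 <= k <= nrow(points)`.
#' @param seed Unused by the deterministic algorithm; kept in the
#'   signature so callers can treat all clustering entry points uniformly.
#' @return A `cluster_result` with `assignments` (named integer vector),
#'   `medoids` (row labels) and the final `objective` filled.
#' @export
pam_cluster <- function(points, k, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1L || k > n) stop("k must lie in [1, n]", call. = FALSE)
  if (is.null(rownames(points)))
    rownames(points) <- paste0("p", seq_len(n))
  D <- .dist_matrix(points)
  medoids <- sort(.pam_build(D, k))
  obj <- .pam_objective(D, medoids)
  repeat {
    best <- list(obj = obj)
    for (m in medoids) for (h in setdiff(seq_len(n), medoids)) {
      cand <- sort(c(setdiff(medoids, m), h))
      o <- .pam_objective(D, cand)
      if (o < best$obj - 1e-12) best <- list(obj = o, medoids = cand)
    }
    if (is.null(best$medoids)) break
    medoids <- best$medoids
    obj <- best$obj
  }
  assign_idx <- apply(D[, medoids, drop = FALSE], 1, which.min)
  structure(list(scores = points, loadings = NULL,
                 explained_variance = NULL,
                 assignments = stats::setNames(as.integer(assign_idx),
                                               rownames(points)),
                 medoids = rownames(points)[medoids],
                 objective = obj, silhouette = NULL, k = as.integer(k)),
            class = "cluster_result")
}

#' Mean silhouette width of a partition
#'
#' Standard silhouette: for each point, `a` is the mean distance to its
#' own cluster's other members, `b` the smallest mean distance to another
#' cluster, and `s = (b - a) / max(a, b)`; members of singleton clusters
#' contribute 0.
#'
#' @param points Coordinate matrix.
#' @param assignments Integer cluster labels, one per row of `points`.
#' @return Mean silhouette width.
#' @export
mean_silhouette <- function(points, assignments) {
  D <- .dist_matrix(as.matrix(points))
  n <- nrow(D)
  ks <- unique(assignments)
  if (length(ks) < 2L) stop("need at least 2 clusters", call. = FALSE)
  s <- vapply(seq_len(n), function(i) {
    own <- assignments == assignments[i]
    if (sum(own) == 1L) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(ks, assignments[i]),
                    function(g) mean(D[i, assignments == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Runs [pam_cluster()] for every `k` in `k_range`, computes the mean
#' silhouette width, and keeps the partition maximizing it (ties broken by
#' the smaller k). The full silhouette table is retained for reporting.
#'
#' @param points Coordinate matrix.
#' @param k_range Candidate cluster counts within `[2, n - 1]`; default
#'   `2:6`.
#' @param seed Passed through to [pam_cluster()].
#' @return The winning `cluster_result` with `silhouette` (named vector
#'   over `k_range`) and `k` filled.
#' @export
choose_k <- function(points, k_range = 2:6, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range has no admissible value", call. = FALSE)
  fits <- lapply(k_range, function(k) pam_cluster(points, k, seed))
  sil <- vapply(fits, function(f) mean_silhouette(points, f$assignments),
                numeric(1))
  names(sil) <- k_range
  best <- fits[[which.max(sil)]]
  best$silhouette <- sil
  best$k <- k_range[which.max(sil)]
  best
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings of the same items: 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}

#' Retain the leading principal components for clustering
#'
#' Smallest PC set whose cumulative explained variance reaches
#' `threshold` (default 0.80).
#'
#' @param pca A `cluster_result` from [pca_scores()].
#' @param threshold Cumulative explained-variance target in (0, 1].
#' @return Score matrix restricted to the retained PCs.
#' @export
retained_scores <- function(pca, threshold = 0.8) {
  stopifnot(!is.null(pca$explained_variance))
  npc <- which(cumsum(pca$explained_variance) >= threshold - 1e-12)[1]
  pca$scores[, seq_len(npc), drop = FALSE]
}
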