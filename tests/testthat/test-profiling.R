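make_chart <- function(mat) {
  df <- data.frame(treatment = rownames(mat), mat, mean = rowMeans(mat),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$mean, df$treatment), ]
  rownames(df) <- NULL
  class(df) <- c("sucra_chart", "data.frame")
  df
}

rand_profile <- function(n, seed) {
  set.seed(seed)
  mat <- matrix(runif(n * 5), n, 5,
                dimnames = list(sprintf("T%02d", 1:n), mm_endpoints))
  mat
}

test_that("profiles assemble in chart order with fixed endpoint columns", {
  mat <- rand_profile(6, 1)
  chart <- make_chart(mat)
  prof <- assemble_profile(chart)
  expect_identical(dim(unclass(prof)), c(6L, 5L))
  expect_identical(colnames(prof), mm_endpoints)
  expect_identical(rownames(prof), chart$treatment)
  expect_true(all(prof >= 0 & prof <= 1))

  single <- make_chart(rand_profile(1, 2))
  expect_identical(dim(unclass(assemble_profile(single))), c(1L, 5L))

  expect_error(assemble_profile(chart[, setdiff(names(chart), "CR")]), "CR")
})

test_that("PCA matches an independent eigendecomposition", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(sprintf("T%02d", 1:n), mm_endpoints))
    res <- pca_scores(x, center = TRUE, scale = TRUE)
    eig <- eigen(cor(x), symmetric = TRUE)
    # compare the components carrying variance (rank <= min(n - 1, 5));
    # the trailing null space is numerically arbitrary
    r <- sum(eig$values > 1e-8)
    expect_equal(res$explained_variance[seq_len(r)],
                 (eig$values / sum(eig$values))[seq_len(r)],
                 tolerance = 1e-9)
    expect_equal(sum(res$explained_variance), 1, tolerance = 1e-9)
    sc_oracle <- scale(x) %*% eig$vectors
    expect_equal(abs(unname(res$scores[, seq_len(r)])),
                 abs(unname(sc_oracle[, seq_len(r)])), tolerance = 1e-8)
  }
})

test_that("PCA sign convention, reconstruction and rank-1 behaviour", {
  # rank-1 matrix: PC1 carries all the variance
  u <- c(1, 2, 3, 4); v <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  r1 <- pca_scores(outer(u, v), center = TRUE, scale = FALSE)
  expect_equal(r1$explained_variance[1], 1, tolerance = 1e-12)

  x <- rand_profile(8, 4)
  res <- pca_scores(x)
  # largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(res$loadings)))
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  # full reconstruction of the scaled input
  expect_equal(res$scores %*% t(res$loadings),
               scale(unclass(x)), tolerance = 1e-10, ignore_attr = TRUE)
  # row permutation leaves explained variance untouched
  perm <- sample(nrow(x))
  expect_equal(pca_scores(x[perm, ])$explained_variance,
               res$explained_variance, tolerance = 1e-12)

  const <- x; const[, 2] <- 0.5
  colnames(const) <- mm_endpoints
  expect_error(pca_scores(const, scale = TRUE), "OS")
})

test_that("PAM recovers exact solutions and planted partitions", {
  pts <- matrix(rnorm(12), 6, 2)
  all_own <- pam_cluster(pts, k = 6)
  expect_equal(all_own$objective, 0)
  expect_length(all_own$medoids, 6)
  expect_error(pam_cluster(pts, 7), "k must")

  # the solution is 2-swap stable (the algorithm's termination guarantee)
  # and never undercuts the exhaustive medoid-subset optimum
  set.seed(44)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    D <- as.matrix(dist(pts))
    for (k in 1:(n - 1)) {
      fit <- pam_cluster(pts, k)
      med <- match(fit$medoids, rownames(fit$scores))
      for (m in med) for (h in setdiff(seq_len(n), med)) {
        cand <- c(setdiff(med, m), h)
        expect_gte(sum(apply(D[, cand, drop = FALSE], 1, min)),
                   fit$objective - 1e-12)
      }
      best <- min(apply(utils::combn(n, k), 2, function(idx)
        sum(apply(D[, idx, drop = FALSE], 1, min))))
      expect_gte(fit$objective, best - 1e-12)
    }
  }

  # three tight, well-separated blobs are recovered exactly
  set.seed(45)
  centers <- rbind(c(0, 0), c(2, 0), c(0, 2))
  pts <- centers[rep(1:3, each = 10), ] + matrix(rnorm(60, 0, 0.01), 30)
  fit <- pam_cluster(pts, 3)
  expect_equal(adjusted_rand_index(fit$assignments, rep(1:3, each = 10)), 1)
  # medoids belong to their own cluster
  expect_true(all(fit$assignments[fit$medoids] ==
                    seq_along(fit$medoids)))
})

test_that("PAM agrees with the reference implementation's objective", {
  skip_if_not_installed("cluster")
  set.seed(46)
  for (rep in 1:10) {
    n <- sample(10:25, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    k <- sample(2:5, 1)
    mine <- pam_cluster(pts, k)
    ref <- cluster::pam(pts, k)
    ref_obj <- sum(apply(as.matrix(dist(pts))[, ref$id.med,
                                              drop = FALSE], 1, min))
    expect_equal(mine$objective, ref_obj, tolerance = 1e-8)
  }
})

test_that("silhouette-based selection finds the planted cluster count", {
  set.seed(47)
  blobs <- function(k, per = 8, sd = 0.05) {
    centers <- matrix(rnorm(k * 2, sd = 3), k, 2)
    centers[rep(seq_len(k), each = per), ] +
      matrix(rnorm(k * per * 2, 0, sd), k * per, 2)
  }
  p3 <- blobs(3)
  expect_identical(choose_k(p3, 2:6)$k, 3L)
  p2 <- blobs(2)
  expect_identical(choose_k(p2, 2:6)$k, 2L)
  sel <- choose_k(p3, 2:6)
  expect_named(sel$silhouette, as.character(2:6))

  # singleton clusters contribute silhouette 0
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10))
  s <- mean_silhouette(pts, c(1, 1, 2))
  manual <- local({
    d12 <- sqrt(sum((pts[1, ] - pts[2, ])^2))
    b1 <- sqrt(sum((pts[1, ] - pts[3, ])^2))
    b2 <- sqrt(sum((pts[2, ] - pts[3, ])^2))
    ((b1 - d12) / b1 + (b2 - d12) / b2 + 0) / 3
  })
  expect_equal(s, manual, tolerance = 1e-12)
})

test_that("adjusted Rand index matches the reference implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  skip_if_not_installed("mclust")
  set.seed(48)
  for (rep in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("retained PCs cover the requested variance", {
  x <- rand_profile(10, 49)
  res <- pca_scores(x)
  sc <- retained_scores(res, 0.8)
  npc <- ncol(sc)
  expect_gte(sum(res$explained_variance[1:npc]), 0.8 - 1e-9)
  if (npc > 1)
    expect_lt(sum(res$explained_variance[1:(npc - 1)]), 0.8)
  expect_identical(ncol(retained_scores(res, 1)), 5L)
})
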