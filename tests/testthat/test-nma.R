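test_that("contrast construction handles two- and multi-arm trials", {
  tr <- read_trials(fixture_path())
  ctr <- to_contrasts(tr, "PFS")
  expect_length(ctr, 27)
  first <- ctr[[which(vapply(ctr, `[[`, character(1), "study_id") ==
                        "Facon/IFM99-06")]]
  expect_identical(dim(first$S), c(1L, 1L))

  facon <- ctr[[which(vapply(ctr, `[[`, character(1), "study_id") ==
                        "Facon/FIRST")]]
  expect_length(facon$y, 2)
  expect_identical(dim(facon$S), c(2L, 2L))
  expect_identical(facon$baseline, "MPT")

  # multi-arm counts: off-diagonal = baseline-arm variance share
  t3 <- trial_record("T3", 2020, list(
    arm_record("A", 100, list(ORR = list(type = "events_total",
                                         events = 40, total = 100))),
    arm_record("B", 90, list(ORR = list(type = "events_total",
                                        events = 50, total = 90))),
    arm_record("C", 80, list(ORR = list(type = "events_total",
                                        events = 30, total = 80)))))
  ts <- structure(list(T3 = t3), class = "nma_trials")
  c3 <- to_contrasts(ts, "ORR")
  expect_equal(c3[[1]]$S[1, 2], 1 / 40 + 1 / 60, tolerance = 1e-12)
  expect_equal(c3[[1]]$S[2, 1], 1 / 40 + 1 / 60, tolerance = 1e-12)
  # safety uses the risk-ratio share 1/e_b - 1/n_b
  t3s <- trial_record("T3", 2020, lapply(t3$arms, function(a) {
    a$endpoints <- list(SAFETY = a$endpoints$ORR); a
  }))
  cs <- to_contrasts(structure(list(T3 = t3s), class = "nma_trials"),
                     "SAFETY")
  expect_equal(cs[[1]]$S[1, 2], 1 / 40 - 1 / 100, tolerance = 1e-12)

  # trials without usable data for the endpoint are dropped with a warning
  expect_warning(
    short <- to_contrasts(structure(list(
      T3 = t3, B = bare_trial("B", c("A", "B"))), class = "nma_trials"),
      "ORR"),
    "dropped")
  expect_length(short, 1)
})

test_that("symmetric data give a symmetric posterior", {
  ctr <- manual_contrasts(
    y = as.list(rep(0, 6)), v = as.list(rep(0.04, 6)),
    baselines = list("A", "A", "B", "A", "B", "C"),
    treatments = list("B", "C", "C", "B", "C", "A"))
  fit <- suppressWarnings(fit_nma(ctr, quick_config(seed = 2),
                                  reference = "A"))
  expect_lt(max(abs(colMeans(fit$draws[, 1:2]))), 0.06)
  expect_true(all(fit$draws[, "tau"] >= 0))
  expect_identical(ncol(fit$draws), 3L)  # (#treatments - 1) + tau
})

test_that("a single-edge network reduces to pairwise REML meta-analysis", {
  skip_if_not_installed("metafor")
  truth <- simulation_truth(c("A", "B"),
                            rbind(0, c(-0.5, -0.4, 0.45, 0.4, 0.1)),
                            tau_true = setNames(rep(0.15, 5), mm_endpoints))
  tr <- simulate_trialset(truth, trial_design(n_trials = 10), seed = 11)
  ctr <- to_contrasts(tr, "PFS")
  fit <- fit_nma(ctr, nma_config(iterations = 8000, burn_in = 2000,
                                 chains = 2, seed = 3), reference = "A")
  y <- vapply(ctr, function(d) if (d$baseline == "A") d$y else -d$y,
              numeric(1))
  v <- vapply(ctr, function(d) d$S[1, 1], numeric(1))
  reml <- metafor::rma(yi = y, vi = v, method = "REML")
  expect_lt(abs(mean(fit$draws[, 1]) - as.numeric(coef(reml))), 0.05)
})

test_that("disconnected networks are rejected with component names", {
  ctr <- manual_contrasts(y = list(0.1, 0.2), v = list(0.04, 0.04),
                          baselines = list("A", "C"),
                          treatments = list("B", "D"))
  expect_error(fit_nma(ctr, quick_config()), "disconnected")
})

test_that("relative effects are exact per-draw re-referencings", {
  set.seed(9)
  dmat <- cbind(rnorm(2000, -0.5, 0.2), rnorm(2000, 0.3, 0.2))
  post <- fake_posterior(dmat, c("A", "B", "C"), "A")

  self <- relative_effects(post, reference = "A")
  arow <- self[self$treatment == "A", ]
  expect_equal(unlist(arow[c("estimate", "lower", "upper")]),
               c(estimate = 1, lower = 1, upper = 1))

  # percentile oracle on the raw draw matrix, reference B
  relB <- relative_effects(post, reference = "B")
  man <- exp(quantile(dmat[, 2] - dmat[, 1], c(0.5, 0.025, 0.975),
                      names = FALSE))
  crow <- relB[relB$treatment == "C", ]
  expect_equal(unlist(crow[c("estimate", "lower", "upper")]),
               c(estimate = man[1], lower = man[2], upper = man[3]),
               tolerance = 1e-12)

  # consistency identity d_BC = d_AC - d_AB holds exactly per draw
  dd <- dmat[, 2] - dmat[, 1]
  expect_identical(dd, (dmat[, 2] - 0) - (dmat[, 1] - 0))

  expect_error(relative_effects(post, reference = "Z"), "unknown")
})

test_that("posterior heterogeneity collapses when the data carry none", {
  truth <- simulation_truth(c("A", "B"),
                            rbind(0, c(-0.4, -0.3, 0.3, 0.3, 0)),
                            tau_true = setNames(rep(0, 5), mm_endpoints))
  tr <- simulate_trialset(truth,
                          trial_design(n_trials = 12,
                                       n_per_arm = c(3000L, 4000L)),
                          seed = 21)
  fit <- suppressWarnings(fit_nma(to_contrasts(tr, "PFS"),
                                  quick_config(seed = 4, iterations = 6000,
                                               burn_in = 2000),
                                  reference = "A"))
  expect_gt(mean(fit$draws[, "tau"] < 0.1), 0.8)
})

test_that("simulated consistent networks are recovered without bias", {
  set.seed(600)
  K <- 6
  d <- rbind(0, matrix(rnorm(5 * 5, 0, 0.5), 5, 5))
  truth <- simulation_truth(LETTERS[1:K], d,
                            tau_true = setNames(rep(0.2, 5), mm_endpoints))
  post_means <- vapply(1:15, function(r) {
    tr <- simulate_trialset(truth, trial_design(n_trials = 40,
                                                n_per_arm = c(150L, 250L)),
                            seed = 600 + r)
    fit <- suppressWarnings(
      fit_nma(to_contrasts(tr, "PFS"),
              nma_config(iterations = 4000, burn_in = 1000, chains = 2,
                         seed = 6000 + r), reference = "A"))
    colMeans(fit$draws[, 1:(K - 1)])
  }, numeric(K - 1))
  bias <- rowMeans(post_means) - truth$d_true[-1, "PFS"]
  expect_lt(max(abs(bias)), 0.1)

  tr <- simulate_trialset(truth, trial_design(n_trials = 40,
                                              n_per_arm = c(150L, 250L)),
                          seed = 601)
  fit <- suppressWarnings(
    fit_nma(to_contrasts(tr, "PFS"),
            nma_config(iterations = 8000, burn_in = 2000, chains = 2,
                       seed = 602), reference = "A"))
  tau_ci <- quantile(fit$draws[, "tau"], c(0.025, 0.975))
  expect_true(tau_ci[1] <= 0.2 && 0.2 <= tau_ci[2])
})
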