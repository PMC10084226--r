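test_that("the packaged trial roster parses to the published structure", {
  tr <- read_trials(fixture_path())
  expect_length(tr, 27)
  expect_identical(total_patients(tr), 12935L)
  # arm order preserved: first listed arm is the baseline comparator
  expect_identical(
    vapply(tr[["Palumbo/MM-015"]]$arms, `[[`, character(1), "treatment"),
    c("MPR-R", "MPR", "MP"))
})

test_that("degenerate and malformed input files are handled", {
  hdr <- tempfile(fileext = ".csv")
  writeLines("study_id,year,treatment,n,endpoint,stat_type,value1,value2", hdr)
  expect_length(read_trials(hdr), 0)

  tiny <- tempfile(fileext = ".csv")
  writeLines(c("study_id,year,treatment,n,endpoint,stat_type,value1,value2",
               "S1,2020,A,10,ORR,events_total,5,10",
               "S1,2020,B,10,ORR,events_total,6,10"), tiny)
  tr <- read_trials(tiny)
  expect_length(tr, 1)
  expect_identical(total_patients(tr), 20L)

  nocol <- tempfile(fileext = ".csv")
  writeLines(c("study_id,year,treatment,endpoint,stat_type,value1,value2",
               "S1,2020,A,ORR,events_total,5,10"), nocol)
  expect_error(read_trials(nocol), "n")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("study_id,year,treatment,n,endpoint,stat_type,value1,value2",
               "S1,2020,A,10,ORR,events_total,5,10",
               "S1,2020,A,10,ORR,events_total,5,10",
               "S1,2020,B,10,ORR,events_total,6,10"), dup)
  expect_error(read_trials(dup), "duplicate")

  neg <- tempfile(fileext = ".csv")
  writeLines(c("study_id,year,treatment,n,endpoint,stat_type,value1,value2",
               "S1,2020,A,0,ORR,events_total,0,0",
               "S1,2020,B,10,ORR,events_total,6,10"), neg)
  expect_error(read_trials(neg), "positive")
})

test_that("trial records enforce their invariants", {
  expect_error(trial_record("S", 2020, list(arm_record("A", 10))), "2 arms")
  expect_error(bare_trial("S", c("A", "A")), "duplicate")
  expect_error(arm_record("A", 10, list(ORR = list(
    type = "events_total", events = 11, total = 10))), "events")
})

test_that("canonicalization merges typeset variants and the default map", {
  tr <- read_trials(fixture_path())
  expect_length(treatment_labels(tr), 24)
  merged <- canonicalize_treatments(tr)
  expect_length(treatment_labels(merged), 23)
  expect_false("VTP" %in% treatment_labels(merged))
  # empty map: identity up to spelling unification
  same <- canonicalize_treatments(tr, merge_map = character(0))
  expect_identical(treatment_labels(same), treatment_labels(tr))
  # case/punctuation-insensitive matching unifies Rd/RD and MPT-T/MPTT
  t2 <- list(
    bare_trial("X1", c("RD", "MP")),
    bare_trial("X2", c("Rd", "mpt-t")),
    bare_trial("X3", c("MPTT", "MP")))
  t2 <- structure(setNames(t2, c("X1", "X2", "X3")), class = "nma_trials")
  expect_identical(treatment_labels(canonicalize_treatments(t2, character(0))),
                   c("RD", "MP", "mpt-t"))
  # degenerate merge collapsing a trial's arms is rejected
  labs <- treatment_labels(tr)
  allx <- setNames(rep("X", length(labs)), labs)
  expect_error(canonicalize_treatments(tr, allx), "collapses")
})

test_that("network nodes, weights and edge multiplicities are correct", {
  tr <- canonicalize_treatments(read_trials(fixture_path()))
  net <- build_network(tr)
  expect_identical(nrow(net$nodes), 23L)
  expect_true(net$connected)
  expect_identical(sum(net$nodes$n_total), 12935L)

  one <- structure(list(S = bare_trial("S", c("A", "B", "C"))),
                   class = "nma_trials")
  n1 <- build_network(one)
  expect_identical(nrow(n1$nodes), 3L)
  expect_identical(nrow(n1$edges), 3L)
  expect_true(all(n1$edges$n_trials == 1L))
})

test_that("edge multiplicities match exhaustive pair counting", {
  set.seed(101)
  for (rep in 1:50) {
    n_tr <- sample(3:10, 1)
    trials <- lapply(seq_len(n_tr), function(i)
      bare_trial(sprintf("S%d", i),
                 sample(LETTERS[1:6], sample(2:4, 1))))
    ts <- structure(setNames(trials, vapply(trials, `[[`, character(1),
                                            "study_id")),
                    class = "nma_trials")
    net <- suppressWarnings(build_network(ts))
    # oracle: count pairs across trials by brute force
    tally <- table(unlist(lapply(trials, function(tr) {
      labs <- sort(vapply(tr$arms, `[[`, character(1), "treatment"))
      apply(utils::combn(labs, 2), 2, paste, collapse = "|")
    })))
    got <- setNames(net$edges$n_trials,
                    paste(net$edges$treatment1, net$edges$treatment2,
                          sep = "|"))
    expect_identical(sort(names(got)), sort(names(tally)))
    expect_identical(got[names(tally)] == as.vector(tally),
                     setNames(rep(TRUE, length(tally)), names(tally)))
  }
})

test_that("triangle enumeration matches a brute-force triple scan", {
  tr <- canonicalize_treatments(read_trials(fixture_path()))
  net <- build_network(tr)
  tri <- enumerate_triangles(net)
  expect_identical(nrow(tri), 9L)
  expect_identical(paste(tri$a, tri$b, tri$c, sep = "|"),
                   brute_triangles(net$nodes$treatment, net$edges))

  star <- net_from_edges(letters[1:5],
    data.frame(treatment1 = "a", treatment2 = letters[2:5],
               stringsAsFactors = FALSE))
  expect_identical(nrow(enumerate_triangles(star)), 0L)

  set.seed(77)
  for (rep in 1:100) {
    n <- sample(4:15, 1)
    labs <- sprintf("N%02d", seq_len(n))
    all_pairs <- t(utils::combn(labs, 2))
    keep <- runif(nrow(all_pairs)) < 0.3
    edges <- data.frame(treatment1 = all_pairs[keep, 1],
                        treatment2 = all_pairs[keep, 2],
                        stringsAsFactors = FALSE)
    got <- enumerate_triangles(net_from_edges(labs, edges))
    expect_identical(paste(got$a, got$b, got$c, sep = "|"),
                     brute_triangles(labs, edges))
  }
})

test_that("quality score counts true items over all combinations", {
  for (bits in 0:31) {
    items <- as.logical(bitwAnd(bits, 2^(0:4)) > 0)
    tr <- trial_record("S", 2020,
                       list(arm_record("A", 10), arm_record("B", 10)),
                       quality_items = items)
    expect_identical(quality_score(tr)$score, sum(items))
  }
  expect_error(quality_score(bare_trial("S", c("A", "B"))), "quality")
})

test_that("funnel points center on the fixed-effect pooled estimate", {
  single <- funnel_points(list(ee(0.4, 0.02)))
  expect_equal(single$centered, 0)

  two <- funnel_points(list(ee(0.2, 0.05), ee(0.6, 0.05)))
  expect_equal(two$centered, c(-0.2, 0.2))

  expect_error(funnel_points(list(structure(
    list(value = 0, variance = 0), class = "effect_estimate"))), "variance")

  # unbiased studies: regression of centered effect on SE has slope ~ 0
  set.seed(5)
  v <- runif(200, 0.005, 0.2)
  est <- lapply(seq_along(v), function(i) ee(rnorm(1, 0.3, sqrt(v[i])), v[i]))
  fp <- funnel_points(est)
  fit <- summary(lm(centered ~ se, data = fp))$coefficients
  expect_lt(abs(fit["se", "Estimate"]), 2 * fit["se", "Std. Error"])
})
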