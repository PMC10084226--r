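#' Simulation truth for a synthetic trial network
#'
#' @param treatments Treatment labels; the first is the reference and must
#'   have zero effect on every endpoint.
#' @param d_true Treatments x endpoints matrix of true log-scale effects
#'   versus the reference (log HR for PFS/OS, log OR for ORR/CR, log RR
#'   for SAFETY).
#' @param tau_true Named per-endpoint between-trial SD.
#' @param endpoint_corr 5x5 positive semi-definite correlation of
#'   treatment effects across endpoints.
#' @param group_plan Optional planted group id per treatment.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(treatments, d_true,
                             tau_true = stats::setNames(rep(0.1, 5),
                                                        mm_endpoints),
                             endpoint_corr = diag(5),
                             group_plan = NULL) {
  d_true <- as.matrix(d_true)
  stopifnot(nrow(d_true) == length(treatments),
            ncol(d_true) == length(mm_endpoints))
  colnames(d_true) <- mm_endpoints
  rownames(d_true) <- treatments
  if (any(abs(d_true[1, ]) > 1e-12))
    stop("reference treatment (first) must have zero effect", call. = FALSE)
  ev <- eigen(endpoint_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("endpoint_corr must be positive semi-definite", call. = FALSE)
  if (!is.null(group_plan)) stopifnot(length(group_plan) == length(treatments))
  structure(list(treatments = treatments, d_true = d_true,
                 tau_true = tau_true[mm_endpoints],
                 endpoint_corr = endpoint_corr, group_plan = group_plan),
            class = "simulation_truth")
}

#' Design of a synthetic trial set
#'
#' @param n_trials Number of trials to generate.
#' @param arm_probs Probabilities of a trial having 2, 3, ... arms.
#' @param n_per_arm Range (min, max) of randomized patients per arm.
#' @param baseline_risks Named baseline event risks for the binary
#'   endpoints (ORR, CR, SAFETY).
#' @param event_fracs Named fraction of patients with an observed event
#'   for the survival endpoints (PFS, OS); the log-rank noise variance is
#'   `4 / events` (equal-allocation approximation).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_trials = 30L,
                         arm_probs = c(`2` = 0.8, `3` = 0.2),
                         n_per_arm = c(100L, 400L),
                         baseline_risks = c(ORR = 0.5, CR = 0.15,
                                            SAFETY = 0.3),
                         event_fracs = c(PFS = 0.7, OS = 0.5)) {
  stopifnot(n_trials >= 1, all(n_per_arm >= 1), all(arm_probs >= 0),
            sum(arm_probs) > 0)
  structure(list(n_trials = as.integer(n_trials), arm_probs = arm_probs,
                 n_per_arm = as.integer(n_per_arm),
                 baseline_risks = baseline_risks,
                 event_fracs = event_fracs), class = "trial_design")
}

# fill endpoint summaries for fixed trial structures (consumes the RNG)
.simulate_endpoints <- function(structures, truth, baseline_risks,
                                event_fracs) {
  Rc <- chol(truth$endpoint_corr + diag(1e-10, 5))
  trials <- lapply(structures, function(st) {
    k <- length(st$treatments)
    m <- k - 1L
    idx <- match(st$treatments, truth$treatments)
    mu <- truth$d_true[idx[-1], , drop = FALSE] -
      matrix(truth$d_true[idx[1], ], m, 5, byrow = TRUE)
    # trial random effects: corr 1/2 across contrasts, endpoint_corr
    # across endpoints, per-endpoint scale tau
    Cm <- (diag(m) + matrix(1, m, m)) / 2
    E <- matrix(stats::rnorm(m * 5), m, 5)
    pert <- t(chol(Cm)) %*% E %*% Rc
    delta <- mu + sweep(pert, 2, truth$tau_true, `*`)
    total_n <- sum(st$n)
    arms <- vector("list", k)
    base_ep <- list()
    for (ep in c("ORR", "CR", "SAFETY"))
      base_ep[[ep]] <- list(
        type = "events_total",
        events = stats::rbinom(1, st$n[1], baseline_risks[[ep]]),
        total = st$n[1])
    arms[[1]] <- arm_record(st$treatments[1], st$n[1], base_ep)
    for (j in seq_len(m)) {
      eps <- list()
      for (ep in c("PFS", "OS")) {
        events <- max(2L, as.integer(round(event_fracs[[ep]] * total_n)))
        se <- sqrt(4 / events)
        eps[[ep]] <- list(type = "loghr_se",
                          loghr = delta[j, ep] + stats::rnorm(1, 0, se),
                          se = se)
      }
      for (ep in c("ORR", "CR")) {
        p <- stats::plogis(stats::qlogis(baseline_risks[[ep]]) +
                           delta[j, ep])
        eps[[ep]] <- list(type = "events_total",
                          events = stats::rbinom(1, st$n[j + 1], p),
                          total = st$n[j + 1])
      }
      p <- min(0.99, baseline_risks[["SAFETY"]] * exp(delta[j, "SAFETY"]))
      eps[["SAFETY"]] <- list(type = "events_total",
                              events = stats::rbinom(1, st$n[j + 1], p),
                              total = st$n[j + 1])
      arms[[j + 1]] <- arm_record(st$treatments[j + 1], st$n[j + 1], eps)
    }
    trial_record(st$study_id, st$year, arms,
                 quality_items = stats::rbinom(5, 1, 0.8) == 1,
                 ae_label = st$ae_label)
  })
  new_trialset(trials)
}

#' Simulate a randomized-trial network with known truth
#'
#' Draws trial treatment sets so that the evidence network is connected (a
#' random spanning tree over the treatments is laid down first), then
#' generates per-trial random effects around the true contrasts with
#' between-trial SD `tau_true`, correlation 1/2 between contrasts sharing
#' a baseline arm and `endpoint_corr` across endpoints. Binary endpoints
#' produce binomial event counts from the baseline risks and true log
#' odds/risk ratios; survival endpoints produce observed log HRs with
#' noise variance `4 / events`. Identical seeds give identical records.
#'
#' @param truth A [simulation_truth()].
#' @param design A [trial_design()].
#' @param seed Integer seed.
#' @return An `nma_trials` object.
#' @export
simulate_trialset <- function(truth, design, seed = 1L) {
  set.seed(seed)
  K <- length(truth$treatments)
  if (design$n_trials < K - 1L)
    stop("cannot connect ", K, " treatments with ", design$n_trials,
         " trials", call. = FALSE)
  order_k <- sample.int(K)
  sets <- vector("list", design$n_trials)
  for (i in seq_len(K - 1L)) {
    anchor <- order_k[sample.int(i, 1)]
    sets[[i]] <- c(anchor, order_k[i + 1L])
  }
  n_extra <- design$n_trials - (K - 1L)
  narms_extra <- as.integer(names(design$arm_probs))[
    sample.int(length(design$arm_probs), n_extra, replace = TRUE,
               prob = design$arm_probs)]
  for (i in seq_len(n_extra))
    sets[[K - 1L + i]] <- sample.int(K, min(narms_extra[i], K))
  structures <- lapply(seq_along(sets), function(i) {
    idx <- sets[[i]]
    list(study_id = sprintf("SIM%03d", i), year = 2020L,
         treatments = truth$treatments[idx],
         n = sample(seq(design$n_per_arm[1], design$n_per_arm[2]),
                    length(idx), replace = TRUE),
         ae_label = "Neutropenia")
  })
  .simulate_endpoints(structures, truth, design$baseline_risks,
                      design$event_fracs)
}

#' Simulation truth with planted regimen groups
#'
#' Treatments in the same group share their endpoint-effect vector up to a
#' small jitter; group centers are spaced by `separation` on the log scale
#' in the efficacy endpoints (group 1 best), with a non-monotone toxicity
#' pattern so that profiles differ in more than one direction. The jitter
#' is drawn with `endpoint_corr` across endpoints, inducing correlated
#' SUCRA profiles. All effects are expressed relative to the first
#' treatment (reference effect 0).
#'
#' @param groups Integer group id per treatment (at least 2 distinct
#'   groups); names, when present, become the treatment labels.
#' @param separation Gap between adjacent group centers on the log scale,
#'   positive.
#' @param jitter SD of the within-group effect jitter (default 0.05).
#' @param tau_true Per-endpoint between-trial SD passed through.
#' @param endpoint_corr Endpoint correlation of the jitter (default
#'   exchangeable 0.5).
#' @param seed Integer seed.
#' @return A [simulation_truth()] with `group_plan` set.
#' @export
simulate_profiled_network <- function(groups, separation, jitter = 0.05,
                                      tau_true = stats::setNames(
                                        rep(0.1, 5), mm_endpoints),
                                      endpoint_corr =
                                        0.5 + 0.5 * diag(5),
                                      seed = 1L) {
  if (length(unique(groups)) < 2L)
    stop("need at least 2 planted groups", call. = FALSE)
  if (separation < 0) stop("separation must be nonnegative", call. = FALSE)
  set.seed(seed)
  K <- length(groups)
  labels <- if (!is.null(names(groups))) names(groups)
            else sprintf("T%02d", seq_len(K))
  g <- as.integer(factor(groups))
  G <- max(g)
  benefit <- (G - g) * separation
  tox <- separation * rep_len(c(0.5, 0, 0.25), G)[g]
  centers <- cbind(PFS = -benefit, OS = -0.8 * benefit,
                   ORR = 0.9 * benefit, CR = 0.8 * benefit, SAFETY = tox)
  Rc <- chol(endpoint_corr + diag(1e-10, 5))
  d <- centers + jitter * (matrix(stats::rnorm(K * 5), K, 5) %*% Rc)
  d <- sweep(d, 2, d[1, ])              # reference effect = 0
  simulation_truth(labels, d, tau_true = tau_true,
                   endpoint_corr = endpoint_corr, group_plan = g)
}

# Trial roster of the 27 first-line NEMM randomized trials: study label,
# year, arm labels (first = baseline comparator as listed), per-trial
# total n and the most frequent grade 3-4 adverse event.
.table1_structure <- function() {
  raw <- list(
    list("Facon/IFM99-06",       2007, c("MPT", "MP"),            321, "Neutropenia"),
    list("Palumbo2008",          2008, c("MPT-T", "MP"),          331, "Cytopenia"),
    list("Hulin/IFM01-01",       2009, c("MPT", "MP"),            229, "Neutropenia"),
    list("Waage",                2009, c("MPT-T", "MP"),          357, "Neutropenia"),
    list("Ludwig",               2009, c("TD", "MP"),             288, "Infections/Leukopenia"),
    list("Beksac",               2010, c("MPT-T", "MP"),          115, "Cytopenia"),
    list("Wijermans/HOVON49",    2010, c("MPT-T", "MP"),          344, "Infections"),
    list("Mateos/VISTA",         2010, c("VMP", "MP"),            682, "Neutropenia"),
    list("Palumbo2010",          2010, c("VMPT", "VMP"),          511, "Neutropenia"),
    list("Morgan/MRC-IX",        2011, c("CTD", "MP"),            849, "Cytopenia/Infections"),
    list("Sacchi",               2011, c("MPT", "MP"),            118, "Neutropenia"),
    list("Palumbo/MM-015",       2012, c("MPR-R", "MPR", "MP"),   459, "Neutropenia"),
    list("SanMiguel",            2013, c("VMPS", "VMP"),          106, "Neutropenia"),
    list("Mateos/GEM2005",       2014, c("VMP", "VTP"),           260, "Neutropenia"),
    list("Hungria",              2015, c("MPT-T", "TD", "CTD"),    82, "Neutropenia/Neuropathy"),
    list("Stewart/E1A06",        2015, c("MPR-R", "MPT-T"),       298, "Neutropenia"),
    list("Niesvizky/UPFRONT",    2015, c("VD", "VTD", "VMP"),     502, "Neuropathy"),
    list("Magarotto",            2016, c("MPR", "CPR", "Rd9"),    662, "Neutropenia"),
    list("Zweegman",             2016, c("MPR-R", "MPT-T"),       637, "Neutropenia"),
    list("Durie/SWOG-S0777",     2016, c("VRD", "Rd"),            471, "Neutropenia"),
    list("Facon/FIRST",          2018, c("MPT", "Rd", "Rd18"),   1623, "Neutropenia/Infections"),
    list("Mateos/ALCYONE",       2018, c("DrVMP", "VMP"),         706, "Neutropenia"),
    list("Facon/MAIA",           2018, c("DrRd", "Rd"),           737, "Neutropenia"),
    list("Usmani/KEYNOTE-185",   2018, c("PRd", "Rd"),            301, "Neutropenia"),
    list("Facon/CLARION",        2019, c("KMP", "VMP"),           955, "Neutropenia"),
    list("Facon/TOURMALINE-MM2", 2021, c("IRD", "Rd"),            705, "Neutropenia"),
    list("Puig/CLARIDEX",        2021, c("ClRd", "Rd"),           286, "Infections"))
  lapply(raw, function(r) {
    k <- length(r[[3]])
    base <- r[[4]] %/% k
    n <- rep(base, k)
    n[1] <- n[1] + r[[4]] - base * k   # remainder to the first arm
    list(study_id = r[[1]], year = r[[2]], treatments = r[[3]], n = n,
         ae_label = r[[5]])
  })
}

# planted groups used to fill the fixture's synthetic endpoint data:
# group 1 = preferred, 2 = alternative, 3 = least beneficial; VTP shares
# the VTD profile (same bortezomib-thalidomide + steroid backbone)
.table1_groups <- c(
  MP = 3, MPT = 2, `MPT-T` = 3, TD = 3, VMP = 2, VMPT = 1, CTD = 3,
  MPR = 3, `MPR-R` = 2, VMPS = 2, VTP = 2, VD = 2, VTD = 2, CPR = 3,
  Rd9 = 3, VRD = 1, Rd = 1, Rd18 = 2, DrVMP = 1, DrRd = 1, PRd = 2,
  KMP = 2, IRD = 1, ClRd = 2)

#' Structural fixture of the 27-trial first-line myeloma network
#'
#' Rebuilds the published trial roster (27 randomized trials, 12,935
#' patients, 24 arm labels collapsing to 23 regimens once VTP is
#' aggregated with VTD) with per-trial totals split equally across arms
#' (remainder to the first arm). The roster prints no per-arm endpoint
#' data, so endpoint summaries are synthetic: seeded draws from a planted
#' three-group truth, for use in structural checks and end-to-end
#' demonstrations. Two trials additionally carry their survival summaries
#' as a log-rank p-value + events and as an HR confidence interval, the
#' reconstruction routes used when trials do not report an HR directly.
#'
#' @param seed Integer seed for the synthetic endpoint values.
#' @return An `nma_trials` object with 27 trials.
#' @export
table1_fixture <- function(seed = 20220711L) {
  set.seed(seed)
  structures <- .table1_structure()
  labels <- names(.table1_groups)
  labels <- c("MP", setdiff(labels, "MP"))   # reference first
  truth <- simulate_profiled_network(
    stats::setNames(.table1_groups[labels], labels),
    separation = 0.4, jitter = 0.05, seed = seed)
  set.seed(seed + 1L)
  trials <- .simulate_endpoints(structures, truth,
                                baseline_risks = c(ORR = 0.5, CR = 0.15,
                                                   SAFETY = 0.3),
                                event_fracs = c(PFS = 0.7, OS = 0.5))
  # exercise the HR-reconstruction input routes on two equal-arm trials
  trials <- .convert_to_hr_ci(trials, "Sacchi", "PFS")
  trials <- .convert_to_logrank_p(trials, "Ludwig", "OS")
  trials
}

.convert_to_hr_ci <- function(trials, study, endpoint) {
  tr <- trials[[study]]
  for (i in seq_along(tr$arms)[-1]) {
    s <- tr$arms[[i]]$endpoints[[endpoint]]
    if (is.null(s) || s$type != "loghr_se") next
    z <- stats::qnorm(0.975)
    tr$arms[[i]]$endpoints[[endpoint]] <-
      list(type = "hr_ci", hr = exp(s$loghr), lo = exp(s$loghr - z * s$se),
           hi = exp(s$loghr + z * s$se), level = 0.95)
  }
  trials[[study]] <- tr
  trials
}

.convert_to_logrank_p <- function(trials, study, endpoint) {
  tr <- trials[[study]]
  for (i in seq_along(tr$arms)[-1]) {
    s <- tr$arms[[i]]$endpoints[[endpoint]]
    if (is.null(s) || s$type != "loghr_se") next
    events <- as.integer(round(4 / s$se^2))
    z <- abs(s$loghr) / s$se
    tr$arms[[i]]$endpoints[[endpoint]] <-
      list(type = "pvalue_events", p = 2 * stats::pnorm(-z),
           events = events, direction = if (s$loghr < 0) -1 else 1)
  }
  trials[[study]] <- tr
  trials
}
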