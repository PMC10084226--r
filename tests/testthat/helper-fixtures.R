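# shared builders for the test suite; all randomness is locally seeded

fixture_path <- function()
  system.file("extdata", "table1_synthetic.csv", package = "mmnma")

# two-arm trial carrying event counts for one binary endpoint
count_trial <- function(id, t1, t0, e1, n1, e0, n0, endpoint = "ORR") {
  trial_record(id, 2020, list(
    arm_record(t0, n0, setNames(list(
      list(type = "events_total", events = e0, total = n0)), endpoint)),
    arm_record(t1, n1, setNames(list(
      list(type = "events_total", events = e1, total = n1)), endpoint))))
}

# trial with arbitrary arms and no endpoint data (network-structure tests)
bare_trial <- function(id, treatments, n = rep(100L, length(treatments))) {
  trial_record(id, 2020, Map(arm_record, treatments, n))
}

ee <- function(value, variance, measure = "logOR")
  effect_estimate(measure, value, variance)

# minimal treatment_network wrapper around an explicit edge list
net_from_edges <- function(labels, edges) {
  structure(list(
    nodes = data.frame(treatment = labels, n_total = 1L,
                       stringsAsFactors = FALSE),
    edges = edges, connected = TRUE, components = list(labels)),
    class = "treatment_network")
}

# independent cubic brute force over all triples (oracle for triangles)
brute_triangles <- function(labels, edges) {
  has_edge <- function(x, y) {
    a <- pmin(x, y); b <- pmax(x, y)
    any(edges$treatment1 == a & edges$treatment2 == b)
  }
  if (length(labels) < 3) return(character(0))
  combos <- utils::combn(sort(labels), 3)
  keep <- apply(combos, 2, function(tr)
    has_edge(tr[1], tr[2]) && has_edge(tr[1], tr[3]) && has_edge(tr[2], tr[3]))
  apply(combos[, keep, drop = FALSE], 2, paste, collapse = "|")
}

# hand-rolled nma_posterior around an explicit draw matrix (ranking tests)
fake_posterior <- function(dmat_basic, treatments, reference,
                           endpoint = "PFS") {
  basic <- setdiff(treatments, reference)
  colnames(dmat_basic) <- paste0("d[", basic, "]")
  draws <- cbind(dmat_basic, tau = 0.1)
  structure(list(draws = draws, treatments = treatments,
                 reference = reference, endpoint = endpoint,
                 measure = "logHR",
                 rhat = setNames(rep(1, ncol(draws)), colnames(draws)),
                 converged = TRUE), class = "nma_posterior")
}

# small consistent two-treatment contrast set built by hand
manual_contrasts <- function(y, v, baselines, treatments,
                             endpoint = "PFS") {
  out <- Map(function(yi, vi, b, t, i) {
    list(study_id = sprintf("M%02d", i), baseline = b, treatments = t,
         y = yi, S = matrix(vi, 1, 1))
  }, y, v, baselines, treatments, seq_along(y))
  structure(out, endpoint = endpoint, measure = "logHR",
            class = "nma_contrasts")
}

quick_config <- function(seed = 1L, iterations = 4000L, burn_in = 1000L)
  nma_config(iterations = iterations, burn_in = burn_in, chains = 2L,
             seed = seed)
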