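#' Endpoint labels used throughout the package
#'
#' The five endpoints analysed for every regimen: progression-free survival
#' (PFS) and overall survival (OS) on the log hazard-ratio scale, overall
#' response rate (ORR) and complete response (CR) on the log odds-ratio
#' scale, and safety (the most frequent grade 3-4 adverse event) on the log
#' risk-ratio scale.
#'
#' @format Character vector of length 5.
#' @export
mm_endpoints <- c("PFS", "OS", "ORR", "CR", "SAFETY")

.stat_types <- c("loghr_se", "events_total", "pvalue_events", "hr_ci")

#' Construct a single trial arm
#'
#' @param treatment Treatment label.
#' @param n Number of randomized patients in the arm (positive integer).
#' @param endpoints Named list of endpoint summaries, one entry per endpoint.
#'   Each summary is a list with a `type` field: `"loghr_se"` (`loghr`, `se`,
#'   relative to the trial's baseline arm), `"events_total"` (`events`,
#'   `total`), `"pvalue_events"` (`p`, `events`, `direction`) or `"hr_ci"`
#'   (`hr`, `lo`, `hi`, `level`).
#' @return An object of class `arm_record`.
#' @export
arm_record <- function(treatment, n, endpoints = list()) {
  stopifnot(is.character(treatment), length(treatment) == 1L, nzchar(treatment))
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("arm '", treatment, "': n must be a positive integer", call. = FALSE)
  if (length(endpoints)) {
    bad <- setdiff(names(endpoints), mm_endpoints)
    if (length(bad))
      stop("unknown endpoint(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(names(endpoints)))
      stop("arm '", treatment, "': more than one summary for an endpoint",
           call. = FALSE)
    for (ep in names(endpoints)) {
      s <- endpoints[[ep]]
      if (!is.list(s) || is.null(s$type) || !s$type %in% .stat_types)
        stop("arm '", treatment, "', endpoint ", ep, ": invalid summary",
             call. = FALSE)
      if (s$type == "events_total" && (s$events < 0 || s$events > s$total))
        stop("arm '", treatment, "', endpoint ", ep,
             ": events must lie in [0, total]", call. = FALSE)
    }
  }
  structure(list(treatment = treatment, n = n, endpoints = endpoints),
            class = "arm_record")
}

#' Construct a randomized-trial record
#'
#' The first arm is the trial's baseline: survival summaries of the other
#' arms are interpreted relative to it.
#'
#' @param study_id Study label, unique within a trial set.
#' @param year Publication year.
#' @param arms List of [arm_record()] objects, at least two; first = baseline.
#' @param quality_items Named logical vector of the five Cochrane-style
#'   quality items (randomization method, allocation concealment, blinding,
#'   withdrawal/dropout, adequacy of follow-up), or `NULL` when unknown.
#' @param ae_label Label of the trial's most frequent grade 3-4 adverse
#'   event, or `NA`.
#' @return An object of class `nma_trial`.
#' @export
trial_record <- function(study_id, year, arms, quality_items = NULL,
                         ae_label = NA_character_) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  if (length(arms) < 2L)
    stop("trial '", study_id, "' must have at least 2 arms", call. = FALSE)
  if (!all(vapply(arms, inherits, logical(1), "arm_record")))
    stop("arms must be arm_record objects", call. = FALSE)
  labs <- vapply(arms, `[[`, character(1), "treatment")
  if (anyDuplicated(labs))
    stop("trial '", study_id, "': duplicate treatment '",
         labs[duplicated(labs)][1], "'", call. = FALSE)
  if (!is.null(quality_items)) {
    quality_items <- as.logical(quality_items)
    if (length(quality_items) != 5L || anyNA(quality_items))
      stop("quality_items must be 5 non-missing logicals", call. = FALSE)
  }
  structure(list(study_id = study_id, year = as.integer(year), arms = arms,
                 quality_items = quality_items,
                 ae_label = as.character(ae_label)),
            class = "nma_trial")
}

new_trialset <- function(trials) {
  ids <- vapply(trials, `[[`, character(1), "study_id")
  if (anyDuplicated(ids))
    stop("duplicate study_id '", ids[duplicated(ids)][1], "'", call. = FALSE)
  names(trials) <- ids
  structure(trials, class = "nma_trials")
}

#' @export
print.nma_trial <- function(x, ...) {
  labs <- vapply(x$arms, `[[`, character(1), "treatment")
  ns <- vapply(x$arms, `[[`, integer(1), "n")
  cat(sprintf("<nma_trial> %s (%d): %s; n = %s (total %d)\n",
              x$study_id, x$year, paste(labs, collapse = "/"),
              paste(ns, collapse = "/"), sum(ns)))
  invisible(x)
}

#' @export
print.nma_trials <- function(x, ...) {
  ntot <- sum(vapply(x, function(tr) sum(vapply(tr$arms, `[[`, integer(1), "n")),
                     integer(1)))
  cat(sprintf("<nma_trials> %d trials, %d arms, %d patients, %d regimens\n",
              length(x), sum(lengths(lapply(x, `[[`, "arms"))), ntot,
              length(treatment_labels(x))))
  invisible(x)
}

#' Distinct treatment labels of a trial set
#'
#' @param trials An `nma_trials` object.
#' @return Character vector in order of first appearance.
#' @export
treatment_labels <- function(trials) {
  labs <- unlist(lapply(trials, function(tr)
    vapply(tr$arms, `[[`, character(1), "treatment")), use.names = FALSE)
  unique(labs)
}

#' Total number of randomized patients in a trial set
#'
#' @param trials An `nma_trials` object.
#' @return Integer patient count summed over all arms.
#' @export
total_patients <- function(trials) {
  sum(vapply(trials, function(tr)
    sum(vapply(tr$arms, `[[`, integer(1), "n")), integer(1)))
}

.required_cols <- c("study_id", "year", "treatment", "n", "endpoint",
                    "stat_type", "value1", "value2")
.quality_cols <- c("q_randomization", "q_concealment", "q_blinding",
                   "q_withdrawal", "q_followup")

.parse_summary <- function(stat_type, value1, value2) {
  switch(stat_type,
    loghr_se = list(type = "loghr_se", loghr = value1, se = value2),
    events_total = list(type = "events_total", events = as.integer(value1),
                        total = as.integer(value2)),
    pvalue_events = list(type = "pvalue_events", p = abs(value1),
                         events = as.integer(value2),
                         direction = if (value1 < 0) -1 else 1),
    hr_ci = list(type = "hr_ci", hr = sqrt(value1 * value2), lo = value1,
                 hi = value2, level = 0.95),
    stop("unknown stat_type '", stat_type, "'", call. = FALSE))
}

.format_summary <- function(s) {
  switch(s$type,
    loghr_se = c(s$loghr, s$se),
    events_total = c(s$events, s$total),
    pvalue_events = c(s$direction * s$p, s$events),
    hr_ci = c(s$lo, s$hi))
}

#' Read trial records from a long-format CSV file
#'
#' One row per (arm, endpoint) with columns
#' `study_id, year, treatment, n, endpoint, stat_type, value1, value2`.
#' `stat_type` is one of `loghr_se` (value1 = log HR vs the trial baseline,
#' value2 = SE), `events_total` (value1 = events, value2 = total),
#' `pvalue_events` (|value1| = two-sided log-rank p, its sign the direction
#' of the effect, value2 = total events) or `hr_ci` (value1/value2 = 95% CI
#' bounds of the HR; the point HR is taken as their geometric mean, the
#' standard log-symmetric reporting convention). Optional columns: five
#' `q_*` quality items (0/1, constant within a trial) and `ae_label`.
#' Arm order within a trial follows row order; the first arm is the
#' baseline.
#'
#' @param path CSV file path.
#' @return An `nma_trials` object.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.required_cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(new_trialset(list()))
  if (any(df$n <= 0))
    stop("non-positive arm size for study '",
         df$study_id[df$n <= 0][1], "'", call. = FALSE)
  key3 <- paste(df$study_id, df$treatment, df$endpoint, sep = "\r")
  if (anyDuplicated(key3))
    stop("duplicate (study_id, treatment, endpoint) row: ",
         gsub("\r", "/", key3[duplicated(key3)][1]), call. = FALSE)
  has_q <- all(.quality_cols %in% names(df))
  trials <- list()
  for (sid in unique(df$study_id)) {
    rows <- df[df$study_id == sid, , drop = FALSE]
    arms <- list()
    for (tr in unique(rows$treatment)) {
      arows <- rows[rows$treatment == tr, , drop = FALSE]
      if (length(unique(arows$n)) != 1L)
        stop("study '", sid, "', arm '", tr, "': inconsistent n", call. = FALSE)
      eps <- list()
      for (i in seq_len(nrow(arows))) {
        ep <- arows$endpoint[i]
        if (!ep %in% mm_endpoints)
          stop("study '", sid, "': unknown endpoint '", ep, "'", call. = FALSE)
        eps[[ep]] <- .parse_summary(arows$stat_type[i], arows$value1[i],
                                    arows$value2[i])
      }
      arms[[length(arms) + 1L]] <- arm_record(tr, arows$n[1], eps)
    }
    q <- if (has_q) as.logical(unlist(rows[1, .quality_cols])) else NULL
    ae <- if ("ae_label" %in% names(rows)) rows$ae_label[1] else NA_character_
    trials[[length(trials) + 1L]] <-
      trial_record(sid, rows$year[1], arms, quality_items = q, ae_label = ae)
  }
  new_trialset(trials)
}

#' Write trial records to the long-format CSV dialect
#'
#' Inverse of [read_trials()].
#'
#' @param trials An `nma_trials` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  rows <- list()
  for (tr in trials) {
    for (arm in tr$arms) {
      for (ep in names(arm$endpoints)) {
        v <- .format_summary(arm$endpoints[[ep]])
        row <- data.frame(study_id = tr$study_id, year = tr$year,
                          treatment = arm$treatment, n = arm$n,
                          endpoint = ep,
                          stat_type = arm$endpoints[[ep]]$type,
                          value1 = v[1], value2 = v[2],
                          stringsAsFactors = FALSE)
        if (!is.null(tr$quality_items)) {
          q <- as.integer(tr$quality_items)
          names(q) <- .quality_cols
          row <- cbind(row, as.data.frame(as.list(q)))
        }
        row$ae_label <- tr$ae_label
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Canonical form of a treatment label
#'
#' Uppercased with punctuation and whitespace stripped, so that typeset
#' variants such as `"Rd"`/`"RD"` or `"MPT-T"`/`"MPTT"` compare equal.
#'
#' @param x Character vector of labels.
#' @return Character vector of canonical keys.
#' @export
canonical_label <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

#' Canonicalize and merge treatment labels across a trial set
#'
#' Labels are matched case-insensitively ignoring punctuation, unified to
#' their first-seen spelling, then rewritten through `merge_map`. The
#' default map aggregates VTP with VTD (bortezomib-thalidomide + steroid
#' backbone); maintenance-containing schedules (MPT-T, MPR-R, Rd18, Rd9)
#' stay distinct nodes.
#'
#' @param trials An `nma_trials` object.
#' @param merge_map Named character vector, `old label -> new label`
#'   (matched on canonical form).
#' @return An `nma_trials` object with rewritten labels.
#' @export
canonicalize_treatments <- function(trials, merge_map = c(VTP = "VTD")) {
  if (length(merge_map) && is.null(names(merge_map)))
    stop("merge_map must be named (old -> new)", call. = FALSE)
  seen <- character()            # canonical key -> display label
  display <- character()
  map_keys <- canonical_label(names(merge_map))
  out <- lapply(trials, function(tr) {
    labs <- vapply(tr$arms, `[[`, character(1), "treatment")
    for (i in seq_along(labs)) {
      key <- canonical_label(labs[i])
      j <- match(key, map_keys)
      if (!is.na(j)) {
        labs[i] <- unname(merge_map[j])
        key <- canonical_label(labs[i])
      }
      k <- match(key, seen)
      if (is.na(k)) {
        seen <<- c(seen, key)
        display <<- c(display, labs[i])
      } else {
        labs[i] <- display[k]
      }
    }
    if (anyDuplicated(labs))
      stop("trial '", tr$study_id, "': merge map collapses two arms to '",
           labs[duplicated(labs)][1], "'", call. = FALSE)
    for (i in seq_along(tr$arms)) tr$arms[[i]]$treatment <- labs[i]
    tr
  })
  new_trialset(out)
}

#' Cochrane-style study quality score
#'
#' One point for each of: method of randomization, allocation concealment,
#' blinding, withdrawal or dropout, adequacy of follow-up.
#'
#' @param trial An `nma_trial` with `quality_items` present.
#' @return Data frame with columns `study_id` and `score` (integer 0-5).
#' @export
quality_score <- function(trial) {
  if (is.null(trial$quality_items))
    stop("trial '", trial$study_id, "' has no quality items", call. = FALSE)
  data.frame(study_id = trial$study_id,
             score = sum(trial$quality_items), stringsAsFactors = FALSE)
}
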