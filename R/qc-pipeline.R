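## Data-cleaning and inclusion rules: one subject per family, session
## completeness, go-trial accuracy filter, fast-guess trial removal, and the
## at-least-one-timepoint inclusion rule, with conservation accounting.

session_key <- function(trials) paste(trials$subject_id, trials$timepoint)

#' Per-session summary (trial count and go-trial accuracy)
#'
#' A response is correct when it matches the stimulus side (rightward
#' response coded 1).
#'
#' @param trials trial table with `subject_id`, `timepoint`, `side`,
#'   `response`, `rt`.
#' @return data.frame with one row per session: `subject_id`, `timepoint`,
#'   `n_trials`, `accuracy`.
#' @export
session_summary <- function(trials) {
  correct <- trials$response == as.integer(trials$side == "right")
  agg <- aggregate(correct,
                   by = list(subject_id = trials$subject_id,
                             timepoint = trials$timepoint),
                   FUN = function(z) c(length(z), mean(z)))
  data.frame(subject_id = agg$subject_id, timepoint = agg$timepoint,
             n_trials = agg$x[, 1], accuracy = agg$x[, 2],
             stringsAsFactors = FALSE)
}

#' Keep one randomly selected subject per family
#'
#' @param panel subject panel with `family_id`.
#' @param seed optional seed for the uniform random choice.
#' @return panel with exactly one row per family ID.
#' @export
select_one_per_family <- function(panel, seed = NULL) {
  stopifnot(!is.null(panel$family_id))
  if (!is.null(seed)) set.seed(seed)
  ord <- sample(nrow(panel))               # uniform random priority
  keep <- ord[!duplicated(panel$family_id[ord])]
  panel[sort(keep), , drop = FALSE]
}

#' Remove sessions with incomplete trial data
#'
#' A session is incomplete when any of its trials is missing the side,
#' response or RT field, or when it has zero trials.
#'
#' @param trials trial table.
#' @return list with `trials` (complete sessions only) and `n_removed`
#'   (number of sessions removed).
#' @export
filter_incomplete_sessions <- function(trials) {
  if (nrow(trials) == 0L) return(list(trials = trials, n_removed = 0L))
  need <- c("subject_id", "timepoint", "side", "response", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  bad_row <- is.na(trials$side) | is.na(trials$response) | is.na(trials$rt)
  key <- session_key(trials)
  bad_sessions <- unique(key[bad_row])
  list(trials = trials[!(key %in% bad_sessions), , drop = FALSE],
       n_removed = length(bad_sessions))
}

#' Exclude sessions with go-trial accuracy below threshold
#'
#' Strict inequality: a session exactly at the threshold is retained.
#'
#' @param trials trial table.
#' @param threshold accuracy threshold (default 0.60).
#' @return list with `trials` and `n_removed` (sessions).
#' @export
filter_low_accuracy <- function(trials, threshold = 0.60) {
  if (nrow(trials) == 0L) return(list(trials = trials, n_removed = 0L))
  ss <- session_summary(trials)
  bad <- paste(ss$subject_id, ss$timepoint)[ss$accuracy < threshold]
  key <- session_key(trials)
  list(trials = trials[!(key %in% bad), , drop = FALSE],
       n_removed = length(bad))
}

#' Remove fast-guess trials
#'
#' Trials with RT strictly below the cutoff are removed; a trial exactly at
#' the cutoff is retained.
#'
#' @param trials trial table with `rt` in seconds.
#' @param cutoff in seconds (default 0.200).
#' @return list with `trials` and `n_removed` (trials).
#' @export
drop_fast_trials <- function(trials, cutoff = 0.200) {
  fast <- trials$rt < cutoff
  list(trials = trials[!fast, , drop = FALSE], n_removed = sum(fast))
}

#' Build the analysis panel under the at-least-one-timepoint rule
#'
#' Merges per-session decision-parameter estimates and attention sum scores
#' into a wide subject panel and drops every subject who lacks both
#' timepoints for ANY main variable (each decision parameter and the
#' attention score).
#'
#' @param ddm_estimates data.frame `subject_id`, `timepoint`, `v`, `a`, `t`.
#' @param attention_scores data.frame `subject_id`, `timepoint`, `att`.
#' @param demographics optional data.frame keyed by `subject_id` with
#'   subject-constant columns (sex, covariates) to carry along.
#' @return list with `panel` (columns `v0, v2, a0, a2, t0, t2, att0, att2`
#'   plus demographics) and `report` (a `qc_report` step count list).
#' @export
build_analysis_panel <- function(ddm_estimates, attention_scores,
                                 demographics = NULL) {
  for (d in list(ddm_estimates, attention_scores)) {
    key <- paste(d$subject_id, d$timepoint)
    if (anyDuplicated(key)) stop("duplicate subject-timepoint keys in input")
  }
  widen <- function(d, vars) {
    out <- NULL
    for (tp in c(0, 2)) {
      sub <- d[d$timepoint == tp, c("subject_id", vars), drop = FALSE]
      names(sub) <- c("subject_id", paste0(vars, tp))
      out <- if (is.null(out)) sub else
        merge(out, sub, by = "subject_id", all = TRUE)
    }
    out
  }
  panel <- merge(widen(ddm_estimates, c("v", "a", "t")),
                 widen(attention_scores, "att"),
                 by = "subject_id", all = TRUE)
  if (!is.null(demographics))
    panel <- merge(panel, demographics, by = "subject_id", all.x = TRUE)
  n_in <- nrow(panel)
  has_one <- rep(TRUE, n_in)
  for (v in c("v", "a", "t", "att")) {
    c0 <- panel[[paste0(v, "0")]]; c2 <- panel[[paste0(v, "2")]]
    has_one <- has_one & (!is.na(c0) | !is.na(c2))
  }
  report <- qc_report(steps = list(
    list(step = "at_least_one_timepoint", input = n_in,
         removed = sum(!has_one), retained = sum(has_one))))
  list(panel = panel[has_one, , drop = FALSE], report = report)
}

#' Quality-control step report
#'
#' @param steps list of step records, each with `step`, `input`, `removed`,
#'   `retained`.
#' @return object of class `qc_report`; construction fails unless every step
#'   conserves counts (`input = retained + removed`, all non-negative).
#' @export
qc_report <- function(steps) {
  for (s in steps) {
    if (any(unlist(s[c("input", "removed", "retained")]) < 0))
      stop("negative count in QC step '", s$step, "'")
    if (s$input != s$retained + s$removed)
      stop("count conservation violated in QC step '", s$step, "'")
  }
  structure(list(steps = steps), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  for (s in x$steps)
    cat(sprintf("  %-28s in %6d  removed %5d  retained %6d\n",
                s$step, s$input, s$removed, s$retained))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  do.call(rbind, lapply(x$steps, function(s)
    data.frame(step = s$step, input = s$input, removed = s$removed,
               retained = s$retained, stringsAsFactors = FALSE)))
}

#' Flow-chart arithmetic over pre-processing step counts
#'
#' Applies the exclusion ledger of the standard pre-processing flow to
#' supplied step counts: per wave, input minus incomplete minus low-accuracy
#' gives the retained session count; the merged participant count minus the
#' at-least-one-timepoint removals gives the final analysis sample.
#'
#' @param baseline_input,followup_input session counts entering each wave.
#' @param baseline_incomplete,followup_incomplete incomplete-data exclusions.
#' @param baseline_low_acc,followup_low_acc accuracy-filter exclusions.
#' @param merged participants present after merging the two waves.
#' @param missing_rule_removed subjects failing the at-least-one-timepoint
#'   rule.
#' @return list with `baseline_retained`, `followup_retained`, `final_n` and
#'   the full `qc_report`.
#' @export
qc_flow_counts <- function(baseline_input, baseline_incomplete,
                           baseline_low_acc, followup_input,
                           followup_incomplete, followup_low_acc,
                           merged, missing_rule_removed) {
  b1 <- baseline_input - baseline_incomplete
  b2 <- b1 - baseline_low_acc
  f1 <- followup_input - followup_incomplete
  f2 <- f1 - followup_low_acc
  final_n <- merged - missing_rule_removed
  report <- qc_report(list(
    list(step = "baseline_incomplete", input = baseline_input,
         removed = baseline_incomplete, retained = b1),
    list(step = "baseline_low_accuracy", input = b1,
         removed = baseline_low_acc, retained = b2),
    list(step = "followup_incomplete", input = followup_input,
         removed = followup_incomplete, retained = f1),
    list(step = "followup_low_accuracy", input = f1,
         removed = followup_low_acc, retained = f2),
    list(step = "at_least_one_timepoint", input = merged,
         removed = missing_rule_removed, retained = final_n)))
  list(baseline_retained = b2, followup_retained = f2, final_n = final_n,
       report = report)
}
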