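## End-to-end orchestration: simulate -> QC -> decision-parameter estimation
## (EZ or hierarchical Bayesian) -> analysis panel -> univariate and
## bivariate latent change score models -> sex-equality constraint tests ->
## report; plus descriptive sex-difference t-tests.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()].
#' @param estimator `"ez"` (closed-form, fast) or `"hierarchical"` (batched
#'   Bayesian estimation).
#' @param covariates covariate column names entered at the baseline level.
#' @param mcmc list of [run_mcmc()] settings used when
#'   `estimator = "hierarchical"`.
#' @param constraints run the one-by-one cross-group equality tests.
#' @param trial_dt Euler step used when simulating the cohort's sessions.
#' @param seed master seed for QC selection, estimation and item draws.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort, estimator = c("ez", "hierarchical"),
                       covariates = c("age0", "gaf", "income"),
                       mcmc = list(n_chains = 3L, n_samples = 1500L,
                                   burn_in = 1000L),
                       constraints = TRUE, trial_dt = 5e-4, seed = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, estimator = estimator,
                 covariates = covariates, mcmc = mcmc,
                 constraints = constraints, trial_dt = trial_dt,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, x$cohort)
  run_config(cohort, estimator = x$estimator,
             covariates = unlist(x$covariates), mcmc = x$mcmc,
             constraints = x$constraints, trial_dt = x$trial_dt,
             seed = x$seed)
}

#' EZ-diffusion estimates for every session
#'
#' @param trials QC'ed trial table.
#' @return data.frame `subject_id`, `timepoint`, `v`, `a`, `t`; sessions
#'   where the closed form is undefined (below-chance accuracy,
#'   zero RT variance) yield `NA` estimates.
#' @export
estimate_ez <- function(trials) {
  key <- paste(trials$subject_id, trials$timepoint, sep = "\r")
  parts <- split(seq_len(nrow(trials)), key)
  out <- lapply(parts, function(idx) {
    tr <- trials[idx, , drop = FALSE]
    est <- tryCatch(ez_fit(summary_stats(tr)),
                    error = function(e) list(v = NA, a = NA, t = NA))
    data.frame(subject_id = tr$subject_id[1L], timepoint = tr$timepoint[1L],
               v = est$v, a = est$a, t = est$t, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

attention_scores <- function(panel) {
  out <- list()
  for (tp in c(0, 2)) {
    lat <- panel[[paste0("att", tp)]]
    ok <- !is.na(lat)
    if (!any(ok)) next
    s <- simulate_attention_items(lat[ok])
    out[[length(out) + 1L]] <- data.frame(
      subject_id = panel$subject_id[ok], timepoint = tp, att = s$sum,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Welch t-tests of sex differences per variable and timepoint
#'
#' @param panel analysis panel with `sex` and the variable columns.
#' @param variables columns to test (default: every decision parameter and
#'   the attention score at both timepoints).
#' @return data.frame with Welch statistic, df, p and group means/SDs;
#'   variables with an empty group are skipped with a note column.
#' @export
sex_difference_ttests <- function(panel,
                                  variables = c("v0", "v2", "a0", "a2",
                                                "t0", "t2", "att0", "att2")) {
  if (sum(panel$sex == "F", na.rm = TRUE) < 2 ||
      sum(panel$sex == "M", na.rm = TRUE) < 2)
    stop("need at least 2 subjects per sex")
  rows <- list()
  for (v in variables) {
    if (is.null(panel[[v]])) next
    xf <- panel[[v]][panel$sex == "F"]; xm <- panel[[v]][panel$sex == "M"]
    xf <- xf[!is.na(xf)]; xm <- xm[!is.na(xm)]
    if (length(xf) < 2 || length(xm) < 2) {
      rows[[v]] <- data.frame(variable = v, t = NA, df = NA, p = NA,
                              mean_F = NA, sd_F = NA, mean_M = NA, sd_M = NA,
                              note = "group empty or too small",
                              stringsAsFactors = FALSE)
      next
    }
    tt <- t.test(xf, xm)   # Welch by default
    rows[[v]] <- data.frame(variable = v, t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value,
                            mean_F = mean(xf), sd_F = sd(xf),
                            mean_M = mean(xm), sd_M = sd(xm), note = "",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Result table for a univariate latent change score fit
#'
#' Rows mirror the standard reporting layout: baseline mean, mean change,
#' variances of baseline and change, and the baseline-change association
#' reported as a standardized correlation.
#'
#' @param fit a `sem_fit` from [build_ulcs()] + [fit_sem()].
#' @return data.frame with Est., SE, z, p per group.
#' @export
ulcs_table <- function(fit) {
  std <- standardized_solution(fit)
  lab_map <- c(base_mean = "Baseline mean", change_mean = "Mean change",
               base_var = "Variance of baseline score",
               change_var = "Variance of change score",
               base_change_cov = "Correlation baseline-change")
  keep <- std[std$label %in% names(lab_map), ]
  keep$parameter <- lab_map[keep$label]
  keep$est <- ifelse(keep$label == "base_change_cov", keep$std, keep$est)
  keep[order(match(keep$label, names(lab_map)), keep$group),
       c("parameter", "group", "est", "se", "z", "p")]
}

#' Result table for a bivariate latent change score fit
#'
#' The four cross-domain effects (baseline correlation, the two coupling
#' regressions, correlated change), standardized.
#'
#' @param fit a `sem_fit` from [build_blcs()] + [fit_sem()].
#' @return data.frame with standardized Est., SE (of the unstandardized
#'   estimate), z, p per group.
#' @export
blcs_table <- function(fit) {
  std <- standardized_solution(fit)
  lab_map <- c(phi = "Correlation at baseline",
               gamma1 = "Attention baseline -> change in decision parameter",
               gamma2 = "Decision parameter baseline -> change in attention",
               rho = "Correlation of change score")
  keep <- std[std$label %in% names(lab_map), ]
  keep$parameter <- lab_map[keep$label]
  keep$est <- keep$std
  keep[order(match(keep$label, names(lab_map)), keep$group),
       c("parameter", "group", "est", "se", "z", "p")]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: cohort generation; one-subject-per-family selection; follow-up
#' attrition; trial simulation; session QC (completeness, accuracy >= 60%,
#' fast-guess removal); decision-parameter estimation (EZ closed form or
#' batched hierarchical Bayes); attention item scoring; analysis panel under
#' the at-least-one-timepoint rule; four univariate and three bivariate
#' latent change score models with optional one-by-one sex-equality
#' chi-square difference tests; Welch descriptives.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: `qc` (step report), `panel`,
#'   `ulcs`/`blcs` (fits and tables), `delta` (constraint-test tables),
#'   `ttests`, `convergence` (hierarchical only), `truth` (generating
#'   panel), and provenance (`config`, seeds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- stage("simulate", generate_cohort(config$cohort))
  set.seed(config$seed)
  panel <- stage("family_dedup", select_one_per_family(cohort))
  n_fam_removed <- nrow(cohort) - nrow(panel)
  panel <- stage("attrition",
                 apply_attrition(panel, config$cohort$attrition_rate))
  trials <- stage("trials",
                  simulate_trials(panel, config$cohort, dt = config$trial_dt))
  n_sessions <- nrow(unique(trials[, c("subject_id", "timepoint")]))

  fc <- stage("qc_complete", filter_incomplete_sessions(trials))
  fa <- stage("qc_accuracy", filter_low_accuracy(fc$trials))
  n_after_acc <- nrow(unique(fa$trials[, c("subject_id", "timepoint")]))
  ft <- stage("qc_fast_trials", drop_fast_trials(fa$trials))
  qc <- qc_report(list(
    list(step = "one_per_family", input = nrow(cohort),
         removed = n_fam_removed, retained = nrow(panel)),
    list(step = "incomplete_sessions", input = n_sessions,
         removed = fc$n_removed, retained = n_sessions - fc$n_removed),
    list(step = "low_accuracy_sessions", input = n_sessions - fc$n_removed,
         removed = fa$n_removed,
         retained = n_sessions - fc$n_removed - fa$n_removed),
    list(step = "fast_trials", input = nrow(fa$trials),
         removed = ft$n_removed, retained = nrow(ft$trials))))

  convergence <- NULL
  if (config$estimator == "ez") {
    est <- stage("estimate_ez", estimate_ez(ft$trials))
  } else {
    h <- stage("estimate_hierarchical",
               do.call(fit_hddm, c(list(trials = ft$trials,
                                        seed = config$seed), config$mcmc)))
    est <- h$estimates
    convergence <- h$convergence
  }
  att <- stage("attention_items", attention_scores(panel))
  demo <- panel[, c("subject_id", "sex", config$covariates), drop = FALSE]
  bp <- stage("analysis_panel", build_analysis_panel(est, att, demo))
  qc$steps <- c(qc$steps, bp$report$steps)
  apanel <- bp$panel

  ulcs <- list(); blcs <- list(); delta <- list()
  for (v in c("v", "a", "t", "att")) {
    spec <- build_ulcs(v, config$covariates)
    fit <- stage(paste0("ulcs_", v), fit_sem(spec, apanel))
    ulcs[[v]] <- list(fit = fit, table = ulcs_table(fit))
    if (config$constraints) {
      dd <- lapply(c("base_mean", "base_var", "change_mean", "change_var"),
                   function(pp) constrain_compare(spec, apanel, pp,
                                                  free_fit = fit))
      delta[[paste0("ulcs_", v)]] <- do.call(rbind, lapply(dd, function(d)
        data.frame(parameter = d$parameter, delta_chi2 = d$delta_chi2,
                   df = d$df, p = d$p, stringsAsFactors = FALSE)))
    }
  }
  for (v in c("v", "a", "t")) {
    spec <- build_blcs(v, "att", config$covariates)
    fit <- stage(paste0("blcs_", v), fit_sem(spec, apanel))
    blcs[[v]] <- list(fit = fit, table = blcs_table(fit))
    if (config$constraints) {
      dd <- lapply(c("phi", "gamma1", "gamma2", "rho"),
                   function(pp) constrain_compare(spec, apanel, pp,
                                                  free_fit = fit))
      delta[[paste0("blcs_", v)]] <- do.call(rbind, lapply(dd, function(d)
        data.frame(parameter = d$parameter, delta_chi2 = d$delta_chi2,
                   df = d$df, p = d$p, stringsAsFactors = FALSE)))
    }
  }
  tt <- stage("descriptives", sex_difference_ttests(apanel))
  structure(list(qc = qc, panel = apanel, truth = panel, ulcs = ulcs,
                 blcs = blcs, delta = delta, ttests = tt,
                 convergence = convergence, config = config,
                 seed = config$seed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  print(x$qc)
  cat(sprintf("analysis panel: %d subjects (%d F / %d M)\n",
              nrow(x$panel), sum(x$panel$sex == "F"),
              sum(x$panel$sex == "M")))
  for (v in names(x$ulcs))
    cat(sprintf("  ULCS %-4s chi2(%d) = %.3f  CFI %.3f RMSEA %.3f SRMR %.3f\n",
                v, x$ulcs[[v]]$fit$df, x$ulcs[[v]]$fit$T,
                x$ulcs[[v]]$fit$indices["cfi"],
                x$ulcs[[v]]$fit$indices["rmsea"],
                x$ulcs[[v]]$fit$indices["srmr"]))
  for (v in names(x$blcs))
    cat(sprintf("  BLCS %-4s chi2(%d) = %.3f  CFI %.3f RMSEA %.3f SRMR %.3f\n",
                v, x$blcs[[v]]$fit$df, x$blcs[[v]]$fit$T,
                x$blcs[[v]]$fit$indices["cfi"],
                x$blcs[[v]]$fit$indices["rmsea"],
                x$blcs[[v]]$fit$indices["srmr"]))
  invisible(x)
}

#' Save the result tables of a pipeline run
#'
#' Writes the QC report (JSON), each model table and the constraint-test
#' and descriptive tables (CSV) into a directory.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(qc = as.data.frame(report$qc), seed = report$seed),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  for (v in names(report$ulcs))
    write.csv(report$ulcs[[v]]$table,
              file.path(dir, paste0("ulcs_", v, ".csv")), row.names = FALSE)
  for (v in names(report$blcs))
    write.csv(report$blcs[[v]]$table,
              file.path(dir, paste0("blcs_", v, ".csv")), row.names = FALSE)
  for (nm in names(report$delta))
    write.csv(report$delta[[nm]],
              file.path(dir, paste0("delta_", nm, ".csv")), row.names = FALSE)
  write.csv(report$ttests, file.path(dir, "sex_ttests.csv"),
            row.names = FALSE)
  write.csv(report$panel, file.path(dir, "analysis_panel.csv"),
            row.names = FALSE)
  if (!is.null(report$convergence))
    write.csv(report$convergence, file.path(dir, "convergence.csv"),
              row.names = FALSE)
  invisible(dir)
}
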