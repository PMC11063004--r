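# Orchestration: descriptive tests, configuration round trips and the
# end-to-end pipeline on a small EZ-estimated cohort.

test_that("Welch t-tests match a textbook computation and handle edge cases", {
  panel <- data.frame(sex = c("F", "F", "F", "M", "M", "M"),
                      v0 = c(2.1, 2.5, 2.9, 1.8, 2.2, 2.0))
  res <- sex_difference_ttests(panel, "v0")
  xf <- panel$v0[1:3]; xm <- panel$v0[4:6]
  se2 <- var(xf) / 3 + var(xm) / 3
  t_hand <- (mean(xf) - mean(xm)) / sqrt(se2)
  df_hand <- se2^2 / ((var(xf) / 3)^2 / 2 + (var(xm) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  same <- data.frame(sex = rep(c("F", "M"), each = 3), v0 = rep(1:3, 2))
  r0 <- sex_difference_ttests(same, "v0")
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  # a shifted difference of one SD at n = 500/group is detected
  set.seed(41)
  big <- data.frame(sex = rep(c("F", "M"), each = 500),
                    v0 = c(rnorm(500, 1), rnorm(500, 0)))
  expect_lt(sex_difference_ttests(big, "v0")$p, 0.001)

  expect_error(sex_difference_ttests(data.frame(sex = "F", v0 = 1)),
               "at least 2")
  skipped <- sex_difference_ttests(
    data.frame(sex = rep(c("F", "M"), each = 3),
               v0 = c(1, 2, 3, NA, NA, NA)), "v0")
  expect_match(skipped$note, "empty")
})

test_that("run configuration round-trips through YAML", {
  cfg <- run_config(cohort_config(50, seed = 2), estimator = "ez",
                    constraints = FALSE, seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$cohort$n_subjects, 50L)
  expect_equal(back$estimator, "ez")
  expect_equal(back$seed, 9L)
  expect_false(back$constraints)
})

test_that("EZ pipeline completes with all model tables and is reproducible", {
  cfg <- run_config(cohort_config(150, seed = 21, attrition_rate = 0.2,
                                  low_accuracy_rate = 0.05),
                    estimator = "ez", constraints = FALSE, trial_dt = 1e-3,
                    seed = 21)
  rep1 <- run_pipeline(cfg)
  expect_named(rep1$ulcs, c("v", "a", "t", "att"))
  expect_named(rep1$blcs, c("v", "a", "t"))
  for (v in names(rep1$ulcs))
    expect_equal(rep1$ulcs[[v]]$fit$df, 12)
  expect_s3_class(rep1$qc, "qc_report")
  # count conservation at every step
  for (s in rep1$qc$steps) expect_equal(s$input, s$retained + s$removed)
  # low-accuracy subjects were actually caught
  expect_gt(rep1$qc$steps[[3]]$removed, 0)
  # determinism: identical tables on a re-run
  rep2 <- run_pipeline(cfg)
  expect_identical(rep1$ulcs$v$table, rep2$ulcs$v$table)
  expect_identical(rep1$blcs$v$table, rep2$blcs$v$table)
  expect_identical(rep1$ttests, rep2$ttests)

  dir <- tempfile()
  save_run_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "ulcs_v.csv")))
  expect_true(file.exists(file.path(dir, "qc_report.json")))
})

test_that("end-to-end pipeline reproduces the qualitative coupling pattern", {
  cfg <- run_config(cohort_config(2000, seed = 31), estimator = "ez",
                    constraints = FALSE, trial_dt = 1e-3, seed = 31)
  rep <- run_pipeline(cfg)
  # sample means of the decision parameters track the generative truth
  tt <- rep$ttests
  expect_gt(tt$mean_F[tt$variable == "v0"], tt$mean_M[tt$variable == "v0"])
  expect_gt(tt$mean_F[tt$variable == "a0"], tt$mean_M[tt$variable == "a0"])
  expect_lt(tt$mean_F[tt$variable == "att0"], tt$mean_M[tt$variable == "att0"])
  # drift-attention: negative baseline correlation (significant in both
  # sexes) and negative correlated change
  bv <- rep$blcs$v$table
  phi <- bv[bv$parameter == "Correlation at baseline", ]
  expect_true(all(phi$est < 0))
  expect_true(all(phi$z < -2))
  rho <- bv[bv$parameter == "Correlation of change score", ]
  expect_true(all(rho$est < 0))
  # threshold and non-decision time generated null: no spurious couplings
  for (vv in c("a", "t")) {
    bn <- rep$blcs[[vv]]$table
    expect_true(all(abs(bn$z) < 3.5, na.rm = TRUE))
  }
  # positive mean drift change, negative mean attention change in all groups
  uv <- rep$ulcs$v$table
  expect_true(all(uv$est[uv$parameter == "Mean change"] > 0))
  ua <- rep$ulcs$att$table
  expect_true(all(ua$est[ua$parameter == "Mean change"] < 0))
})

test_that("hierarchical pipeline completes with a convergence summary", {
  cfg <- run_config(cohort_config(40, n_trials = 80, seed = 5,
                                  attrition_rate = 0.25,
                                  low_accuracy_rate = 0,
                                  contaminant_rate = 0.01),
                    estimator = "hierarchical", constraints = FALSE,
                    trial_dt = 1e-3,
                    mcmc = list(n_chains = 2L, n_samples = 250L,
                                burn_in = 150L),
                    seed = 5)
  rep <- run_pipeline(cfg)
  expect_false(is.null(rep$convergence))
  expect_true(all(c("parameter", "rhat") %in% names(rep$convergence)))
  expect_named(rep$ulcs, c("v", "a", "t", "att"))
})
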