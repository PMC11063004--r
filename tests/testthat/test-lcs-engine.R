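# Latent change score engine: identification arithmetic, FIML likelihood,
# fitting, indices, constraint tests, standardization.

make_lcs_data <- function(n_per_group, truth = default_lcs_truth("drift"),
                          seed = 1, covariates = TRUE) {
  set.seed(seed)
  panel <- data.frame(sex = rep(c("F", "M"), each = n_per_group))
  panel <- simulate_lcs_panel(panel, truth, c("v", "att"))
  if (covariates) panel <- covariate_panel(panel)
  panel
}

test_that("ULCS parameter enumeration and degrees of freedom are exact", {
  spec <- build_ulcs("v", c("age0", "gaf", "income"))
  per_group <- sort(unique(spec$free$label))
  expect_setequal(per_group, c(
    "base_mean", "base_var", "change_mean", "change_var", "base_change_cov",
    "v0_on_age0", "v0_on_gaf", "v0_on_income",
    "var_age0", "var_gaf", "var_income",
    "cov_age0_gaf", "cov_age0_income", "cov_gaf_income"))
  expect_equal(length(unique(spec$free$theta)), 28)
  p <- length(spec$observed)
  expect_equal(2 * p * (p + 3) / 2 - 28, 12)   # two-group moment count

  d <- make_lcs_data(60, seed = 4)
  fit <- fit_sem(spec, d, se = FALSE)
  expect_equal(fit$df, 12)

  # no covariates: just-identified
  spec0 <- build_ulcs("v")
  fit0 <- fit_sem(spec0, make_lcs_data(60, seed = 5, covariates = FALSE),
                  se = FALSE)
  expect_equal(fit0$df, 0)
  expect_lt(fit0$T, 1e-4)
  expect_equal(fit0$indices[["cfi"]], 1)
  expect_equal(fit0$indices[["rmsea"]], 0)
})

test_that("BLCS construction has the cross-domain parameters and guards", {
  spec <- build_blcs("v", "att", c("age0", "gaf", "income"))
  expect_true(all(c("phi", "gamma1", "gamma2", "rho") %in% spec$free$label))
  expect_equal(length(spec$observed), 7)
  expect_error(build_blcs("v", "v"), "differ")
})

test_that("decoupled BLCS matches independent univariate fits", {
  truth0 <- default_lcs_truth("threshold")  # null couplings
  set.seed(8)
  d <- data.frame(sex = rep(c("F", "M"), each = 400))
  d <- simulate_lcs_panel(d, truth0, c("a", "att"))
  spec <- build_blcs("a", "att")
  # fix the cross-domain parameters at zero by removing them from the free set
  spec$free <- spec$free[!spec$free$label %in%
                           c("phi", "gamma1", "gamma2", "rho"), ]
  fitb <- fit_sem(spec, d, se = FALSE)
  fitu <- fit_sem(build_ulcs("a"), d, se = FALSE)
  # the univariate model parameterizes baseline-change dependence as a
  # covariance; the bivariate one as a regression: compare implied moments
  thb <- fitb$theta; thu <- fitu$theta
  for (g in c("F", "M")) {
    expect_equal(thb[paste0("a_base_mean|", g)],
                 thu[paste0("base_mean|", g)], tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(thb[paste0("a_base_var|", g)],
                 thu[paste0("base_var|", g)], tolerance = 1e-4,
                 ignore_attr = TRUE)
    # implied cov(baseline, change) = beta * var(baseline)
    expect_equal(thb[paste0("a_beta|", g)] * thb[paste0("a_base_var|", g)],
                 thu[paste0("base_change_cov|", g)], tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("pattern-wise FIML equals a naive per-row oracle", {
  set.seed(7)
  d <- make_lcs_data(25, seed = 7)
  for (cn in c("v0", "v2", "att0", "att2", "age0", "gaf"))
    d[[cn]][runif(nrow(d)) < 0.2] <- NA
  spec <- build_blcs("v", "att", c("age0", "gaf", "income"))
  th <- ddmlcs:::sem_start(spec, d)
  ll_pat <- fiml_loglik(spec, d, th)
  comp <- ddmlcs:::compile_spec(spec)
  mom <- ddmlcs:::implied_moments(comp, th)
  ll_naive <- 0
  for (i in seq_len(nrow(d))) {
    y <- as.numeric(d[i, spec$observed]); o <- which(!is.na(y))
    if (!length(o)) next
    S <- mom[[d$sex[i]]]$sigma[o, o, drop = FALSE]
    mu <- mom[[d$sex[i]]]$mu[o]
    ll_naive <- ll_naive - 0.5 *
      (length(o) * log(2 * pi) + as.numeric(determinant(S)$modulus) +
         as.numeric(t(y[o] - mu) %*% solve(S) %*% (y[o] - mu)))
  }
  expect_equal(ll_pat, ll_naive, tolerance = 1e-10)
  # single-observed-variable row contributes a univariate normal density
  d1 <- d[1, ]; d1[, setdiff(spec$observed, "v0")] <- NA; d1$v0 <- 2.5
  prep1 <- ddmlcs:::fiml_prepare(d1, spec)
  ll1 <- ddmlcs:::fiml_loglik_prepared(comp, prep1, th)
  g <- d1$sex
  i0 <- match("v0", spec$observed)
  expect_equal(ll1, dnorm(2.5, mom[[g]]$mu[i0],
                          sqrt(mom[[g]]$sigma[i0, i0]), log = TRUE),
               tolerance = 1e-12)
})

test_that("invalid inputs are rejected at the right boundary", {
  # generative truth with a non-PD implied covariance
  g <- list(mean_x0 = 0, var_x0 = 1, mean_y0 = 0, var_y0 = 1,
            nu_x = 0, nu_y = 0, beta_x = 0, beta_y = 0, gamma1 = 0,
            gamma2 = 0, phi = 1.5, zeta_x = 1, zeta_y = 1, rho = 0)
  expect_error(lcs_truth(g, g), "positive")
  # non-PD implied covariance during estimation is a penalty, not a crash
  d <- make_lcs_data(30, seed = 20, covariates = FALSE)
  spec <- build_ulcs("v")
  th <- ddmlcs:::sem_start(spec, d)
  th["base_var|F"] <- -1
  expect_identical(fiml_loglik(spec, d, th), -Inf)
  # unknown columns and undersized groups
  expect_error(fit_sem(build_ulcs("zzz"), d), "lacks modeled columns")
  expect_error(fit_sem(spec, d[d$sex == "F", ][1:3, ]), "fewer than 2")
})

test_that("saturated EM reduces to sample moments for complete data", {
  d <- make_lcs_data(100, seed = 10, covariates = FALSE)
  spec <- build_ulcs("v")
  prep <- ddmlcs:::fiml_prepare(d, spec)
  sat <- ddmlcs:::saturated_fit(prep, length(spec$observed))
  dF <- as.matrix(d[d$sex == "F", spec$observed])
  expect_equal(sat$F$mu, colMeans(dF), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sat$F$sigma, cov(dF) * (nrow(dF) - 1) / nrow(dF),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fit indices match an independent re-implementation", {
  d <- make_lcs_data(300, seed = 12)
  fit <- fit_sem(build_ulcs("v", c("age0", "gaf", "income")), d, se = FALSE)
  Td <- max(fit$T - fit$df, 0); T0d <- max(fit$T0 - fit$df0, 0)
  cfi_o <- 1 - Td / max(T0d, Td)
  rmsea_o <- sqrt(2) * sqrt(Td / (fit$df * fit$N))
  # SRMR: standardized residual moments against the saturated estimates
  srmr2 <- 0
  for (g in c("F", "M")) {
    Ss <- fit$saturated[[g]]$sigma; ms <- fit$saturated[[g]]$mu
    Sm <- fit$implied[[g]]$sigma; mm <- fit$implied[[g]]$mu
    sdv <- sqrt(diag(Ss)); e <- c()
    for (i in seq_along(ms)) for (j in i:length(ms))
      e <- c(e, (Ss[i, j] - Sm[i, j]) / (sdv[i] * sdv[j]))
    e <- c(e, (ms - mm) / sdv)
    srmr2 <- srmr2 + fit$prep[[g]]$n / fit$N * mean(e^2)
  }
  expect_equal(fit$indices[["cfi"]], cfi_o, tolerance = 1e-8)
  expect_equal(fit$indices[["rmsea"]], rmsea_o, tolerance = 1e-8)
  expect_equal(fit$indices[["srmr"]], sqrt(srmr2), tolerance = 1e-8)
})

test_that("constraint tests behave at the null and under large differences", {
  # identical data in both groups: estimates equal, delta chi-square ~ 0
  set.seed(14)
  half <- data.frame(sex = "F")
  half <- simulate_lcs_panel(data.frame(sex = rep("F", 300)),
                             default_lcs_truth("drift"), c("v", "att"))
  dup <- rbind(half, transform(half, sex = "M"))
  spec <- build_ulcs("v")
  cmp <- constrain_compare(spec, dup, "base_mean")
  expect_lt(cmp$delta_chi2, 0.02)
  expect_gt(cmp$p, 0.85)
  expect_equal(cmp$df, 1)
  expect_error(constrain_compare(spec, dup, "no_such_par"), "no free")

  # true group difference in the baseline mean is detected
  d <- make_lcs_data(2000, seed = 15, covariates = FALSE)
  cmp2 <- constrain_compare(build_ulcs("v"), d, "base_mean")
  expect_lt(cmp2$p, 0.001)
  expect_gte(cmp2$delta_chi2, 0)
  expect_equal(nrow(cmp2$group_estimates), 2)
})

test_that("standardized solution turns covariances into bounded correlations", {
  d <- make_lcs_data(500, seed = 16)
  fit <- fit_sem(build_ulcs("v", c("age0", "gaf", "income")), d)
  std <- standardized_solution(fit)
  covs <- std[std$label %in% c("base_change_cov", "cov_age0_gaf",
                               "cov_age0_income", "cov_gaf_income"), ]
  expect_true(all(abs(covs$std) <= 1))
  # hand check: cov / sqrt(var_baseline * var_change) from implied moments
  mom <- ddmlcs:::implied_moments(fit$comp, fit$theta, observed_only = FALSE)
  i_x0 <- match("v0", fit$spec$vars); i_d <- match("d", fit$spec$vars)
  hand <- fit$theta["base_change_cov|F"] /
    sqrt(mom$F$sigma[i_x0, i_x0] * mom$F$sigma[i_d, i_d])
  expect_equal(std$std[std$label == "base_change_cov" & std$group == "F"],
               unname(hand), tolerance = 1e-10)
})

test_that("FIML under MCAR matches complete-data fits in expectation", {
  # complete data: FIML likelihood equals the closed-form complete ML
  d <- make_lcs_data(400, seed = 17, covariates = FALSE)
  spec <- build_ulcs("v")
  fit_c <- fit_sem(spec, d, se = FALSE)
  # drop 15% of follow-ups; estimates stay close (same generative truth)
  d2 <- d; d2$v2[runif(nrow(d2)) < 0.15] <- NA
  fit_m <- fit_sem(spec, d2, se = FALSE)
  expect_lt(max(abs(fit_m$theta - fit_c$theta) /
                  pmax(abs(fit_c$theta), 0.05)), 0.35)
  expect_true(fit_m$converged)
})
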