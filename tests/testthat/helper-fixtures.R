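# Shared fixtures, built in code.  The hierarchical fixture is expensive and
# lazily cached so the recovery and posterior-predictive tests share one run.

simulate_cohort_sessions <- function(n_subjects, n_trials, seed,
                                     sz_true = 0.1, dt = 1e-4) {
  set.seed(seed)
  truth <- data.frame(
    id = sprintf("U%03d", seq_len(n_subjects)),
    v = pmax(rnorm(n_subjects, 2.7, 0.7), 0.3),
    a = exp(rnorm(n_subjects, log(1.7), 0.25)),
    t = pmax(rnorm(n_subjects, 0.26, 0.04), 0.12),
    z = plogis(rnorm(n_subjects, 0, 0.15)),
    stringsAsFactors = FALSE)
  tl <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- ddm_params(truth$v[i], truth$a[i], truth$t[i], truth$z[i],
                    sz = sz_true)
    side <- ifelse(runif(n_trials) < 0.5, "left", "right")
    tr <- sample_trial(p, side, dt = dt)
    tl[[i]] <- data.frame(session_id = truth$id[i], side = tr$side,
                          response = tr$response, rt = tr$rt,
                          stringsAsFactors = FALSE)
  }
  list(truth = truth, trials = do.call(rbind, tl))
}

covariate_panel <- function(panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel)
  panel$age0 <- rnorm(n); panel$age0 <- panel$age0 - mean(panel$age0)
  panel$gaf <- rnorm(n); panel$gaf <- panel$gaf - mean(panel$gaf)
  panel$income <- rnorm(n); panel$income <- panel$income - mean(panel$income)
  panel
}

# expected values of the univariate reporting parameterization implied by a
# structural truth group (used to compare ULCS estimates against truth)
ulcs_truth_values <- function(g) {
  chv <- g$beta_x^2 * g$var_x0 + g$gamma1^2 * g$var_y0 +
    2 * g$beta_x * g$gamma1 * g$phi + g$zeta_x
  c(base_mean = g$mean_x0, change_mean = g$nu_x, base_var = g$var_x0,
    change_var = chv,
    base_change_cov = g$beta_x * g$var_x0 + g$gamma1 * g$phi)
}

blcs_truth_values <- function(g, x = "v", y = "att") {
  out <- c(g$mean_x0, g$mean_y0,
           g$nu_x - g$beta_x * g$mean_x0 - g$gamma1 * g$mean_y0,
           g$nu_y - g$beta_y * g$mean_y0 - g$gamma2 * g$mean_x0,
           g$var_x0, g$var_y0, g$zeta_x, g$zeta_y,
           g$phi, g$rho, g$beta_x, g$beta_y, g$gamma1, g$gamma2)
  names(out) <- c(paste0(x, "_base_mean"), paste0(y, "_base_mean"),
                  paste0(x, "_change_mean"), paste0(y, "_change_mean"),
                  paste0(x, "_base_var"), paste0(y, "_base_var"),
                  paste0(x, "_change_var"), paste0(y, "_change_var"),
                  "phi", "rho", paste0(x, "_beta"), paste0(y, "_beta"),
                  "gamma1", "gamma2")
  out
}

.fixture_env <- new.env(parent = emptyenv())

# 40 subjects x 300 trials from known group distributions, fitted with
# 3 chains x 1500 samples (1000 burn-in); shared by the subject-level
# recovery and posterior-predictive-coverage tests
hddm_fixture <- function() {
  if (!is.null(.fixture_env$hddm)) return(.fixture_env$hddm)
  sim <- simulate_cohort_sessions(40, 300, seed = 2024)
  fit <- run_mcmc(sim$trials, n_chains = 3, n_samples = 1500,
                  burn_in = 1000, seed = 1)
  report <- gelman_rubin(fit)
  .fixture_env$hddm <- list(sim = sim, fit = fit, report = report)
  .fixture_env$hddm
}
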