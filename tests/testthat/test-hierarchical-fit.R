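# Hierarchical estimation machinery: batching, convergence diagnostics,
# posterior summaries, sampler calibration at desk scale.

test_that("batch assignment is balanced, complete and seed-deterministic", {
  ids <- sprintf("S%03d", 1:160)
  b <- assign_batches(ids, 80, seed = 1)
  expect_length(b, 80)
  expect_true(all(lengths(b) == 2))
  expect_setequal(unlist(b), ids)
  expect_identical(b, assign_batches(ids, 80, seed = 1))
  expect_setequal(assign_batches(ids, 1, seed = 2)[[1]], ids)
  b3 <- assign_batches(ids[1:10], 3, seed = 3)
  expect_true(max(lengths(b3)) - min(lengths(b3)) <= 1)
  expect_error(assign_batches(ids, 0), "n_batches")
  expect_error(assign_batches(ids[1:5], 6), "more batches")
})

test_that("Gelman-Rubin statistic matches a hand computation and flags correctly", {
  # converged case: three long chains from the same normal
  set.seed(21)
  same <- lapply(1:3, function(i)
    matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(gelman_rubin(same)$rhat, 1.05)
  # separated chains
  apart <- lapply(c(0, 10, 20), function(m)
    matrix(rnorm(500, m), ncol = 1, dimnames = list(NULL, "x")))
  gr <- gelman_rubin(apart)
  expect_gt(gr$rhat, 1.1)
  expect_true(gr$flagged)
  # brute-force oracle on a 2-chain x 4-sample toy array
  c1 <- c(1, 2, 3, 4); c2 <- c(2, 4, 4, 6)
  toy <- list(matrix(c1, ncol = 1, dimnames = list(NULL, "p")),
              matrix(c2, ncol = 1, dimnames = list(NULL, "p")))
  W <- (var(c1) + var(c2)) / 2
  B <- 4 * var(c(mean(c1), mean(c2)))
  oracle <- sqrt((3 / 4 * W + B / 4) / W)
  expect_equal(gelman_rubin(toy)$rhat, oracle, tolerance = 1e-12)
  expect_error(gelman_rubin(toy[1]), "2 chains")
  const <- lapply(1:2, function(i)
    matrix(1, 5, 1, dimnames = list(NULL, "p")))
  expect_error(gelman_rubin(const), "degenerate")
})

test_that("posterior summaries average draws and honor screening flags", {
  fake <- structure(list(
    draws = list(
      matrix(c(rep(2, 5), rep(1.5, 5), rep(0.3, 5), rep(0.5, 5)), 5, 4,
             dimnames = list(NULL, c("v[A]", "a[A]", "t[A]", "z[A]"))),
      matrix(c(rep(2, 5), rep(1.5, 5), rep(0.3, 5), rep(0.5, 5)), 5, 4,
             dimnames = list(NULL, c("v[A]", "a[A]", "t[A]", "z[A]")))),
    sessions = "A"), class = "ddm_mcmc")
  rep_ok <- data.frame(parameter = c("v[A]", "a[A]", "t[A]", "z[A]"),
                       rhat = c(1.0, 1.0, 1.0, 1.0), flagged = FALSE)
  s <- summarize_posterior(fake, rep_ok)
  expect_equal(s$v, 2); expect_equal(s$a, 1.5)   # constant draws -> mean
  rep_bad <- transform(rep_ok, rhat = c(1.2, 1.0, 1.0, 1.0))
  s2 <- summarize_posterior(fake, rep_bad)
  expect_true(is.na(s2$v))
  expect_equal(s2$a, 1.5)                        # others intact
})

test_that("sampler runs are shaped by the chain settings and deterministic", {
  expect_equal(formals(run_mcmc)$n_samples, 3000L)
  expect_equal(formals(run_mcmc)$burn_in, 2000L)
  expect_equal(formals(run_mcmc)$n_chains, 3L)
  sim <- simulate_cohort_sessions(4, 80, seed = 30)
  f1 <- run_mcmc(sim$trials, n_chains = 2, n_samples = 120, burn_in = 60,
                 seed = 3)
  expect_length(f1$draws, 2)
  expect_equal(nrow(f1$draws[[1]]), 60)          # retained = total - burn-in
  expect_equal(ncol(f1$draws[[1]]), 4 * 4 + 9)
  f2 <- run_mcmc(sim$trials, n_chains = 2, n_samples = 120, burn_in = 60,
                 seed = 3)
  expect_identical(f1$draws, f2$draws)
})

test_that("group-mean posterior covers the truth across replicate runs", {
  # simulation-based calibration at reduced scale: the 95% credible
  # interval for the drift group mean should cover the generating value in
  # nearly all replicates
  mu_v_true <- 2.7
  hits <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    n <- 10
    truth <- data.frame(v = rnorm(n, mu_v_true, 0.5),
                        a = exp(rnorm(n, log(1.6), 0.2)),
                        t = pmax(rnorm(n, 0.26, 0.03), 0.12))
    tl <- lapply(1:n, function(i) {
      p <- ddm_params(truth$v[i], truth$a[i], truth$t[i])
      side <- ifelse(runif(120) < 0.5, "left", "right")
      tr <- sample_trial(p, side, dt = 2e-4)
      data.frame(session_id = sprintf("R%02d", i), side = tr$side,
                 response = tr$response, rt = tr$rt)
    })
    fit <- run_mcmc(do.call(rbind, tl), n_chains = 2, n_samples = 500,
                    burn_in = 300, seed = r, estimate_sz = FALSE)
    mu_draws <- do.call(rbind, fit$draws)[, "mu_v"]
    ci <- quantile(mu_draws, c(0.025, 0.975))
    if (mu_v_true >= ci[1] && mu_v_true <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("posterior predictive checks validate inputs and are reproducible", {
  sim <- simulate_cohort_sessions(3, 60, seed = 33)
  fit <- run_mcmc(sim$trials, n_chains = 2, n_samples = 150, burn_in = 100,
                  seed = 2)
  expect_error(posterior_predictive_check(fit, sim$trials, n_rep = 0),
               "n_rep")
  p1 <- posterior_predictive_check(fit, sim$trials, n_rep = 20, seed = 5,
                                   dt = 2e-3)
  p2 <- posterior_predictive_check(fit, sim$trials, n_rep = 20, seed = 5,
                                   dt = 2e-3)
  expect_identical(p1, p2)
  expect_true(all(p1$acc_lo <= p1$acc_hi))
  expect_setequal(p1$session_id, unique(sim$trials$session_id))
})

test_that("two random batches of one population give compatible group means", {
  sim <- simulate_cohort_sessions(40, 100, seed = 55)
  batches <- assign_batches(unique(sim$trials$session_id), 2, seed = 56)
  mu <- list()
  for (b in 1:2) {
    tb <- sim$trials[sim$trials$session_id %in% batches[[b]], ]
    fit <- run_mcmc(tb, n_chains = 2, n_samples = 500, burn_in = 300,
                    seed = 57)
    mu[[b]] <- do.call(rbind, fit$draws)[, "mu_v"]
  }
  diff <- abs(mean(mu[[1]]) - mean(mu[[2]]))
  comb <- sqrt(var(mu[[1]]) + var(mu[[2]]))
  expect_lt(diff, 3 * comb)
})

test_that("rhat screening is monotone in the threshold", {
  sim <- simulate_cohort_sessions(4, 60, seed = 35)
  fit <- run_mcmc(sim$trials, n_chains = 2, n_samples = 150, burn_in = 100,
                  seed = 4)
  r_strict <- gelman_rubin(fit, threshold = 1.01)
  r_loose <- gelman_rubin(fit, threshold = 1.5)
  expect_gte(sum(r_strict$flagged), sum(r_loose$flagged))
  est_strict <- summarize_posterior(fit, r_strict, 1.01)
  est_loose <- summarize_posterior(fit, r_loose, 1.5)
  expect_gte(sum(is.na(est_strict[, c("v", "a", "t", "z")])),
             sum(is.na(est_loose[, c("v", "a", "t", "z")])))
})
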