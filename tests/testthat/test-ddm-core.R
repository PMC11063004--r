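# Decision-model core: first-passage density, moments, EZ inversion,
# simulator agreement.

test_that("parameter container enforces its constraints", {
  expect_error(ddm_params(v = 1, a = -1, t = 0.2), "threshold")
  expect_error(ddm_params(v = 1, a = 1, t = -0.1), "non-decision")
  expect_error(ddm_params(v = 1, a = 1, t = 0.2, z = 1.2), "starting point")
  expect_error(ddm_params(v = 1, a = 1, t = 0.2, z = 0.9, sz = 0.3), "sz")
  expect_s3_class(ddm_params(1, 1.5, 0.25, 0.45, 0.1), "ddm_params")
})

test_that("upper and lower first-passage densities integrate to one", {
  sets <- list(ddm_params(1.2, 1.6, 0.25, 0.45, 0.15),
               ddm_params(-0.8, 0.9, 0.1, 0.6, 0),
               ddm_params(3.0, 2.2, 0.3, 0.5, 0.2),
               ddm_params(0, 1.2, 0.2, 0.35, 0.1))
  for (p in sets) {
    tot <- sum(vapply(c("upper", "lower"), function(b)
      integrate(Vectorize(function(x) exp(wfpt_log_density(x, b, p))),
                p$t, Inf, rel.tol = 1e-9)$value, 0))
    expect_equal(tot, 1, tolerance = 1e-4)
  }
})

test_that("density obeys the reflection symmetry and the rt <= t edge", {
  p1 <- ddm_params(0.8, 1.4, 0.2, 0.4)
  p2 <- ddm_params(-0.8, 1.4, 0.2, 0.6)
  rt <- c(0.3, 0.5, 0.8, 1.5)
  expect_equal(wfpt_log_density(rt, "upper", p1),
               wfpt_log_density(rt, "lower", p2), tolerance = 1e-12)
  expect_identical(wfpt_log_density(c(0.1, 0.2), "upper", p1),
                   c(-Inf, -Inf))
})

test_that("starting-point quadrature is converged at the default node count", {
  p <- ddm_params(1.5, 1.6, 0.25, 0.45, 0.2)
  rt <- seq(0.3, 2, by = 0.1)
  d5 <- wfpt_log_density(rt, "upper", p, nodes = 5)
  d11 <- wfpt_log_density(rt, "upper", p, nodes = 11)
  d21 <- wfpt_log_density(rt, "upper", p, nodes = 21)
  expect_lt(max(abs(d11 - d21)), 1e-8)
  expect_lt(max(abs(d5 - d21)), 1e-6)   # sampler uses 5 nodes internally
})

test_that("density matches the brute-force simulator", {
  p <- ddm_params(1.8, 1.5, 0.25, 0.45, 0.15)
  set.seed(61)
  n <- 60000
  tr <- sample_trial(p, rep("right", n), dt = 1e-4)
  # empirical choice probability vs integrated density
  p_up <- integrate(Vectorize(function(x)
    exp(wfpt_log_density(x, "upper", p))), p$t, Inf, rel.tol = 1e-8)$value
  expect_lt(abs(mean(tr$response) - p_up), 3 * sqrt(p_up * (1 - p_up) / n) + 0.01)
  # empirical upper-boundary RT distribution vs integrated density at a grid
  up <- tr$rt[tr$response == 1]
  for (q in c(0.45, 0.6, 0.9, 1.4)) {
    theo <- integrate(Vectorize(function(x)
      exp(wfpt_log_density(x, "upper", p))), p$t, q, rel.tol = 1e-8)$value / p_up
    emp <- mean(up <= q)
    expect_lt(abs(emp - theo), 4 / sqrt(length(up)) + 0.01)
  }
})

test_that("closed-form moments agree with the simulator and their limits", {
  expect_equal(ddm_moments(50, 1.5, 0.3)$Pc, 1, tolerance = 1e-10)
  m0 <- ddm_moments(0, 1.5, 0.3)
  expect_equal(m0$Pc, 0.5)
  expect_equal(m0$MRT - 0.3, 1.5^2 / 4)
  # continuity across the small-drift series switch
  mlo <- ddm_moments(1.9e-3 / 1.5, 1.5, 0.3)
  mhi <- ddm_moments(2.1e-3 / 1.5, 1.5, 0.3)
  expect_equal(mlo$VRT, mhi$VRT, tolerance = 1e-6)
  # simulator check at v = 0 (mean decision time) and at a moderate drift
  set.seed(7)
  tr <- sample_trial(ddm_params(0, 1.5, 0.3), rep("right", 20000), dt = 1e-4)
  expect_lt(abs(mean(tr$rt) - m0$MRT),
            3 * sd(tr$rt) / sqrt(20000) + 0.01)
  m1 <- ddm_moments(1, 1.5, 0.3)
  tr1 <- sample_trial(ddm_params(1, 1.5, 0.3), rep("right", 20000), dt = 1e-4)
  crt <- tr1$rt[tr1$correct]
  expect_lt(abs(mean(tr1$correct) - m1$Pc), 3 * sqrt(m1$Pc * (1 - m1$Pc) / 20000) + 0.01)
  expect_lt(abs(mean(crt) - m1$MRT), 3 * sd(crt) / sqrt(length(crt)) + 0.01)
})

test_that("EZ inversion is an exact round trip of the forward moments", {
  grid <- expand.grid(v = seq(0.4, 3.5, length.out = 5),
                      a = seq(0.8, 2.4, length.out = 4),
                      t = seq(0.15, 0.4, length.out = 3))
  for (i in seq_len(nrow(grid))) {
    m <- ddm_moments(grid$v[i], grid$a[i], grid$t[i])
    est <- ez_fit(c(m, n = 300))
    expect_equal(unlist(est), unlist(grid[i, c("v", "a", "t")]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("EZ edge corrections and error conditions follow the documented rules", {
  m <- ddm_moments(2, 1.5, 0.3)
  perfect <- ez_fit(list(Pc = 1, MRT = m$MRT, VRT = m$VRT, n = 300))
  corrected <- ez_fit(list(Pc = 1 - 1 / 600, MRT = m$MRT, VRT = m$VRT, n = 300))
  expect_equal(perfect, corrected)
  chance <- ez_fit(list(Pc = 0.5, MRT = m$MRT, VRT = m$VRT, n = 300))
  expect_true(all(is.finite(unlist(chance))))
  expect_equal(chance, ez_fit(list(Pc = 0.5 + 1 / 600, MRT = m$MRT,
                                   VRT = m$VRT, n = 300)))
  expect_error(ez_fit(list(Pc = 0.4, MRT = 0.5, VRT = 0.05, n = 300)),
               "below-chance")
  expect_error(ez_fit(list(Pc = 0.8, MRT = 0.5, VRT = 0, n = 300)),
               "variance")
})

test_that("session log likelihood is additive and recovers generating parameters", {
  p <- ddm_params(2.2, 1.6, 0.25)
  set.seed(31)
  tr <- sample_trial(p, ifelse(runif(5000) < 0.5, "left", "right"), dt = 1e-4)
  ses <- data.frame(side = tr$side, response = tr$response, rt = tr$rt)
  expect_identical(session_loglik(ses[0, ], p), 0)
  llA <- session_loglik(ses[1:2000, ], p)
  llB <- session_loglik(ses[2001:5000, ], p)
  expect_equal(session_loglik(ses, p), llA + llB, tolerance = 1e-10)
  # rt at or below non-decision time kills the likelihood
  expect_identical(session_loglik(data.frame(side = "right", response = 1L,
                                             rt = 0.2), p), -Inf)
  # ML point estimate close to the generating parameters
  nll <- function(th) -session_loglik(ses, ddm_params(th[1], th[2], th[3]))
  opt <- optim(c(1.5, 1.2, 0.2), nll, hessian = TRUE,
               control = list(reltol = 1e-12))
  se <- sqrt(diag(solve(opt$hessian)))
  expect_true(all(abs(opt$par - c(2.2, 1.6, 0.25)) < 3 * se + 0.01))
})
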