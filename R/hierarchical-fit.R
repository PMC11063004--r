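## Hierarchical Bayesian estimation of session-level diffusion parameters in
## randomized batches: Metropolis-within-Gibbs sampler (C++ inner loop),
## Gelman-Rubin convergence screening, posterior predictive checks.

hddm_prior <- function() {
  # group-mean priors (m, s) and half-normal spread scales (hs) for
  # v, log a, t, logit z -- weakly informative on the scales of go-trial data
  c(v_m = 2, v_s = 3, v_hs = 2,
    la_m = log(1.5), la_s = 1, la_hs = 1,
    t_m = 0.3, t_s = 0.5, t_hs = 0.3,
    lz_m = 0, lz_s = 1, lz_hs = 1)
}

#' Randomly partition sessions into estimation batches
#'
#' @param subject_ids vector of session/subject identifiers.
#' @param n_batches number of batches (>= 1, <= number of ids).
#' @param seed optional seed.
#' @return list of id vectors; batch sizes differ by at most one.
#' @export
assign_batches <- function(subject_ids, n_batches, seed = NULL) {
  n <- length(subject_ids)
  if (n_batches < 1) stop("n_batches must be >= 1")
  if (n_batches > n) stop("more batches than subjects")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(subject_ids)
  split(perm, rep_len(seq_len(n_batches), n))
}

ez_init <- function(trials) {
  st <- summary_stats(trials)
  est <- tryCatch(ez_fit(st), error = function(e) NULL)
  if (is.null(est) || !all(is.finite(unlist(est))))
    est <- list(v = 1.5, a = 1.5, t = 0.25)
  list(v = min(max(est$v, 0.2), 6),
       a = min(max(est$a, 0.4), 4),
       t = max(min(est$t, 0.9 * min(trials$rt)), 0.03))
}

#' Run the hierarchical MCMC on one batch of sessions
#'
#' Session-level parameters (drift magnitude `v`, threshold `a`,
#' non-decision time `t`, bias `z`) are drawn from group-level normal
#' distributions on transformed scales (log for `a`, logit for `z`), with a
#' single group-level starting-point range `sz` shared by all sessions.
#' Sampling is Metropolis-within-Gibbs: blocked random-walk updates per
#' session, conjugate Gibbs draws for group means, random-walk updates for
#' group spreads and `sz`, with step-size adaptation during burn-in only.
#' Initial values come from per-session EZ estimates; non-finite starting
#' likelihoods are re-drawn a bounded number of times.
#'
#' @param trials trial table with columns `session_id` (or `subject_id` +
#'   `timepoint`), `side`, `response`, `rt`; fast guesses already removed.
#' @param n_chains,n_samples,burn_in chain settings (defaults 3 chains of
#'   3000 with 2000 burn-in).
#' @param seed integer seed; chains use seeds derived from it.
#' @param estimate_sz estimate the group starting-point range (else fixed 0).
#' @param tol series tolerance used inside the sampler.
#' @param nodes quadrature nodes for the `sz` average inside the sampler.
#' @param sz_every update `sz` every this many sweeps.
#' @return object of class `ddm_mcmc`: per-chain draw matrices (retained
#'   samples x parameters, named `v[id]`, ..., `mu_v`, `sigma_v`, ...,
#'   `sz`), session ids, and the run settings.
#' @export
run_mcmc <- function(trials, n_chains = 3L, n_samples = 3000L,
                     burn_in = 2000L, seed = 1L, estimate_sz = TRUE,
                     tol = 1e-7, nodes = 5L, sz_every = 2L) {
  stopifnot(burn_in < n_samples, n_chains >= 1L)
  if (is.null(trials$session_id))
    trials$session_id <- paste(trials$subject_id, trials$timepoint, sep = "@")
  parts <- split(seq_len(nrow(trials)), trials$session_id)
  ids <- names(parts)
  n <- length(ids)
  rt_l <- up_l <- sg_l <- vector("list", n)
  init_s <- matrix(0, n, 4)
  for (j in seq_len(n)) {
    tr <- trials[parts[[j]], , drop = FALSE]
    rt_l[[j]] <- as.numeric(tr$rt)
    up_l[[j]] <- as.integer(tr$response)
    sg_l[[j]] <- ifelse(tr$side == "right", 1, -1)
    e <- ez_init(tr)
    init_s[j, ] <- c(e$v, e$a, e$t, 0.5)
  }
  prior <- hddm_prior()
  mu0 <- c(mean(init_s[, 1]), mean(log(init_s[, 2])), mean(init_s[, 3]), 0)
  sg0 <- pmax(c(sd(init_s[, 1]), sd(log(init_s[, 2])), sd(init_s[, 3]), 0.1),
              c(0.2, 0.1, 0.02, 0.05))
  sz0 <- if (estimate_sz) 0.05 else 0
  init <- c(init_s[, 1], init_s[, 2], init_s[, 3], init_s[, 4],
            rbind(mu0, sg0), sz0)

  # bounded retries on a non-finite starting likelihood
  ll0 <- sum(vapply(seq_len(n), function(j)
    wfpt_loglik_cpp(rt_l[[j]], up_l[[j]], sg_l[[j]], init_s[j, 1],
                    init_s[j, 2], init_s[j, 3], 0.5, sz0, tol, nodes), 0))
  tries <- 0
  while (!is.finite(ll0) && tries < 20L) {
    tries <- tries + 1L
    bad <- which(!vapply(seq_len(n), function(j)
      is.finite(wfpt_loglik_cpp(rt_l[[j]], up_l[[j]], sg_l[[j]],
                                init_s[j, 1], init_s[j, 2], init_s[j, 3],
                                0.5, sz0, tol, nodes)), TRUE))
    init_s[bad, 3] <- init_s[bad, 3] * 0.7   # most failures: t >= min rt
    init_s[bad, 1] <- pmin(init_s[bad, 1], 4)
    init[seq_len(3 * n)] <- c(init_s[, 1], init_s[, 2], init_s[, 3])
    ll0 <- sum(vapply(seq_len(n), function(j)
      wfpt_loglik_cpp(rt_l[[j]], up_l[[j]], sg_l[[j]], init_s[j, 1],
                      init_s[j, 2], init_s[j, 3], 0.5, sz0, tol, nodes), 0))
  }
  if (!is.finite(ll0))
    stop("could not find a finite starting likelihood for the batch")

  pn <- c(paste0("v[", ids, "]"), paste0("a[", ids, "]"),
          paste0("t[", ids, "]"), paste0("z[", ids, "]"),
          "mu_v", "sigma_v", "mu_loga", "sigma_loga", "mu_t", "sigma_t",
          "mu_logitz", "sigma_logitz", "sz")
  set.seed(seed)
  chain_seeds <- sample.int(1000000L, n_chains)
  draws <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    res <- hddm_chain_cpp(rt_l, up_l, sg_l, as.integer(n_samples),
                          as.integer(burn_in), init, unname(prior),
                          estimate_sz, tol, as.integer(nodes),
                          as.integer(sz_every))
    m <- res$draws
    colnames(m) <- pn
    if (!estimate_sz) m <- m[, colnames(m) != "sz", drop = FALSE]
    draws[[ch]] <- m
  }
  structure(list(draws = draws, sessions = ids, n_chains = n_chains,
                 n_samples = n_samples, burn_in = burn_in, seed = seed,
                 chain_seeds = chain_seeds, estimate_sz = estimate_sz,
                 settings = list(tol = tol, nodes = nodes,
                                 sz_every = sz_every), prior = prior),
            class = "ddm_mcmc")
}

#' @export
print.ddm_mcmc <- function(x, ...) {
  cat(sprintf("ddm_mcmc: %d sessions, %d chains x %d retained draws (burn-in %d)\n",
              length(x$sessions), x$n_chains, x$n_samples - x$burn_in,
              x$burn_in))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Classic (non-split) potential scale reduction factor across chains:
#' with within-chain variance W and between-chain variance B,
#' `Rhat = sqrt(((n-1)/n W + B/n) / W)`.
#'
#' @param fit a `ddm_mcmc` object (or a list of draw matrices with common
#'   column names).
#' @param threshold flagging threshold (default 1.1).
#' @return data.frame of class `convergence_report` with `parameter`,
#'   `rhat`, `flagged`.
#' @export
gelman_rubin <- function(fit, threshold = 1.1) {
  draws <- if (inherits(fit, "ddm_mcmc")) fit$draws else fit
  m <- length(draws)
  if (m < 2L) stop("at least 2 chains are required")
  nit <- nrow(draws[[1L]])
  if (nit < 2L) stop("at least 2 retained samples per chain are required")
  pars <- colnames(draws[[1L]])
  rhat <- vapply(pars, function(p) {
    x <- vapply(draws, function(d) d[, p], numeric(nit)) # nit x m
    if (var(as.numeric(x)) == 0)
      stop("degenerate draws (zero variance) for parameter ", p)
    W <- mean(apply(x, 2L, var))
    B <- nit * var(colMeans(x))
    sqrt(((nit - 1) / nit * W + B / nit) / W)
  }, 0)
  structure(data.frame(parameter = pars, rhat = unname(rhat),
                       flagged = unname(rhat) > threshold,
                       stringsAsFactors = FALSE),
            class = c("convergence_report", "data.frame"),
            threshold = threshold)
}

#' Posterior point estimates with convergence screening
#'
#' Posterior means per session parameter, pooling chains; parameters whose
#' Gelman-Rubin statistic exceeds the threshold are set to missing.
#'
#' @param fit a `ddm_mcmc`.
#' @param report a `convergence_report` from [gelman_rubin()]; computed if
#'   `NULL`.
#' @param threshold flagging threshold.
#' @return data.frame with one row per session: `session_id`, `v`, `a`,
#'   `t`, `z`; group-level posterior means in attribute `"group"`.
#' @export
summarize_posterior <- function(fit, report = NULL, threshold = 1.1) {
  if (is.null(report)) report <- gelman_rubin(fit, threshold)
  pooled <- do.call(rbind, fit$draws)
  pm <- colMeans(pooled)
  flagged <- report$parameter[report$rhat > threshold]
  pm[names(pm) %in% flagged] <- NA_real_
  out <- data.frame(session_id = fit$sessions, stringsAsFactors = FALSE)
  for (p in c("v", "a", "t", "z"))
    out[[p]] <- unname(pm[paste0(p, "[", fit$sessions, "]")])
  attr(out, "group") <- pm[setdiff(names(pm), paste0(
    rep(c("v", "a", "t", "z"), each = length(fit$sessions)),
    "[", fit$sessions, "]"))]
  out
}

#' Posterior predictive check
#'
#' For each session, simulates `n_rep` replicate datasets from randomly
#' drawn posterior parameter values (same trial count and stimulus sides as
#' observed) and compares observed accuracy and RT quantiles
#' (10/30/50/70/90%) with their posterior predictive intervals.
#'
#' @param fit a `ddm_mcmc`.
#' @param trials the trial table the model was fitted to.
#' @param n_rep replicate datasets per session (> 0).
#' @param seed seed for draw selection and simulation.
#' @param dt Euler step for the replicate simulator.
#' @param level predictive interval coverage (default 0.95).
#' @return data.frame of class `ddm_ppc`: per session, observed accuracy
#'   with predictive bounds and inside-flag, and observed vs predictive
#'   median RT quantiles.
#' @export
posterior_predictive_check <- function(fit, trials, n_rep = 200L, seed = 1L,
                                       dt = 1e-3, level = 0.95) {
  if (n_rep <= 0) stop("n_rep must be positive")
  if (is.null(trials$session_id))
    trials$session_id <- paste(trials$subject_id, trials$timepoint, sep = "@")
  set.seed(seed)
  pooled <- do.call(rbind, fit$draws)
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  al <- (1 - level) / 2
  rows <- vector("list", length(fit$sessions))
  for (j in seq_along(fit$sessions)) {
    id <- fit$sessions[j]
    tr <- trials[trials$session_id == id, , drop = FALSE]
    obs_acc <- mean(tr$response == as.integer(tr$side == "right"))
    obs_q <- quantile(tr$rt, qs, names = FALSE)
    take <- sample.int(nrow(pooled), n_rep, replace = TRUE)
    acc <- numeric(n_rep)
    qmat <- matrix(0, n_rep, length(qs))
    sz_col <- if ("sz" %in% colnames(pooled)) pooled[, "sz"] else
      rep(0, nrow(pooled))
    for (r in seq_len(n_rep)) {
      i <- take[r]
      p <- ddm_params(v = pooled[i, paste0("v[", id, "]")],
                      a = pooled[i, paste0("a[", id, "]")],
                      t = pooled[i, paste0("t[", id, "]")],
                      z = pooled[i, paste0("z[", id, "]")],
                      sz = sz_col[i])
      sim <- sample_trial(p, tr$side, dt = dt)
      acc[r] <- mean(sim$correct)
      qmat[r, ] <- quantile(sim$rt, qs, names = FALSE)
    }
    acc_b <- quantile(acc, c(al, 1 - al), names = FALSE)
    qlo <- apply(qmat, 2L, quantile, al)
    qhi <- apply(qmat, 2L, quantile, 1 - al)
    rows[[j]] <- data.frame(
      session_id = id, observed_acc = obs_acc,
      acc_lo = acc_b[1L], acc_hi = acc_b[2L],
      acc_inside = obs_acc >= acc_b[1L] & obs_acc <= acc_b[2L],
      t(setNames(obs_q, paste0("obs_q", qs * 100))),
      t(setNames(qlo, paste0("pred_q", qs * 100, "_lo"))),
      t(setNames(qhi, paste0("pred_q", qs * 100, "_hi"))),
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("ddm_ppc", "data.frame"))
}

#' @export
plot.ddm_ppc <- function(x, ...) {
  ord <- order(x$observed_acc)
  n <- nrow(x)
  graphics::plot(seq_len(n), x$observed_acc[ord], pch = 16, cex = 0.6,
                 ylim = range(c(x$acc_lo, x$acc_hi, x$observed_acc)),
                 xlab = "session (sorted)", ylab = "go-trial accuracy",
                 main = "posterior predictive check", ...)
  graphics::segments(seq_len(n), x$acc_lo[ord], seq_len(n), x$acc_hi[ord],
                     col = "grey60")
  graphics::points(seq_len(n), x$observed_acc[ord], pch = 16, cex = 0.6,
                   col = ifelse(x$acc_inside[ord], "black", "red"))
  invisible(x)
}

#' Batched hierarchical estimation over a full cohort
#'
#' Partitions sessions into random batches (default batch size about 110
#' sessions), runs [run_mcmc()] per batch, screens convergence and returns
#' screened posterior-mean estimates per subject and timepoint.
#'
#' @param trials QC'ed trial table with `subject_id`, `timepoint`, `side`,
#'   `response`, `rt`.
#' @param n_batches number of batches; default `ceiling(n_sessions / 110)`.
#' @param seed integer seed.
#' @param rhat_threshold screening threshold.
#' @param ... passed to [run_mcmc()].
#' @return list with `estimates` (data.frame `subject_id`, `timepoint`,
#'   `v`, `a`, `t`, `z`), `convergence` (combined report) and `fits`.
#' @export
fit_hddm <- function(trials, n_batches = NULL, seed = 1L,
                     rhat_threshold = 1.1, ...) {
  trials$session_id <- paste(trials$subject_id, trials$timepoint, sep = "@")
  ids <- unique(trials$session_id)
  if (is.null(n_batches)) n_batches <- ceiling(length(ids) / 110)
  batches <- assign_batches(ids, n_batches, seed = seed)
  fits <- vector("list", length(batches))
  reports <- vector("list", length(batches))
  ests <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    tb <- trials[trials$session_id %in% batches[[b]], , drop = FALSE]
    fits[[b]] <- run_mcmc(tb, seed = seed + b, ...)
    reports[[b]] <- gelman_rubin(fits[[b]], rhat_threshold)
    ests[[b]] <- summarize_posterior(fits[[b]], reports[[b]], rhat_threshold)
  }
  est <- do.call(rbind, ests)
  parts <- strsplit(est$session_id, "@", fixed = TRUE)
  est$subject_id <- vapply(parts, `[`, "", 1L)
  est$timepoint <- as.numeric(vapply(parts, `[`, "", 2L))
  list(estimates = est[, c("subject_id", "timepoint", "v", "a", "t", "z")],
       convergence = do.call(rbind, reports), fits = fits)
}
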