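## Multigroup univariate / bivariate latent change score SEM with
## full-information maximum likelihood, fit indices and equality-constraint
## difference tests.  Models are held in RAM form (path matrix A, covariance
## matrix S, mean vector M over observed + latent variables); the latent
## change is defined by fixed unit loadings (follow-up = baseline + change)
## and a zero follow-up residual.

## ---------------------------------------------------------------------------
## Model specification
## ---------------------------------------------------------------------------

new_sem_spec <- function(observed, latents, groups, fixA, fixS, fixM, free,
                         meta) {
  vars <- c(observed, latents)
  structure(list(observed = observed, latents = latents, groups = groups,
                 vars = vars, A0 = fixA, S0 = fixS, M0 = fixM,
                 free = free, meta = meta),
            class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("sem_spec (%s): %d observed, %d latent, groups %s, %d free parameters\n",
              x$meta$type, length(x$observed), length(x$latents),
              paste(x$groups, collapse = "/"),
              length(unique(x$free$theta))))
  invisible(x)
}

free_row <- function(label, groups, mat, row, col) {
  data.frame(label = label, group = groups,
             theta = paste0(label, "|", groups),
             mat = mat, row = row, col = col, stringsAsFactors = FALSE)
}

covariate_free <- function(covariates, groups, vars, into) {
  # regressions of each baseline variable on each covariate, plus free
  # covariate variances/covariances (means stay fixed at 0: centred inputs)
  fr <- list()
  for (y in into) for (cv in covariates)
    fr[[length(fr) + 1L]] <- free_row(paste0(y, "_on_", cv), groups, "A",
                                      match(y, vars), match(cv, vars))
  nc <- length(covariates)
  for (i in seq_len(nc)) for (j in i:nc) {
    lab <- if (i == j) paste0("var_", covariates[i]) else
      paste0("cov_", covariates[i], "_", covariates[j])
    fr[[length(fr) + 1L]] <- free_row(lab, groups, "S",
                                      match(covariates[i], vars),
                                      match(covariates[j], vars))
  }
  do.call(rbind, fr)
}

#' Build a multigroup univariate latent change score model
#'
#' Observed variables are `<variable>0`, `<variable>2` and the centred
#' covariates.  The latent change `d` satisfies follow-up = baseline + d
#' (unit loadings, zero follow-up residual).  Free per group: baseline
#' intercept and (residual) variance, change mean and variance, the
#' baseline-change covariance, regressions of the baseline on each
#' covariate, and the covariate variances/covariances (covariate means are
#' fixed at 0 because inputs are centred).
#'
#' @param variable variable name prefix (e.g. `"v"`).
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param groups group labels (default `c("F", "M")`).
#' @return A `sem_spec` object.
#' @export
build_ulcs <- function(variable, covariates = character(),
                       groups = c("F", "M")) {
  x0 <- paste0(variable, "0"); x2 <- paste0(variable, "2")
  observed <- c(x0, x2, covariates)
  vars <- c(observed, "d")
  nv <- length(vars)
  A <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  M <- setNames(numeric(nv), vars)
  A[x2, x0] <- 1; A[x2, "d"] <- 1
  fr <- rbind(
    free_row("base_mean", groups, "M", match(x0, vars), 1L),
    free_row("change_mean", groups, "M", match("d", vars), 1L),
    free_row("base_var", groups, "S", match(x0, vars), match(x0, vars)),
    free_row("change_var", groups, "S", match("d", vars), match("d", vars)),
    free_row("base_change_cov", groups, "S", match(x0, vars), match("d", vars)))
  if (length(covariates))
    fr <- rbind(fr, covariate_free(covariates, groups, vars, x0))
  new_sem_spec(observed, "d", groups, A, S, M, fr,
               meta = list(type = "ulcs", variable = variable,
                           covariates = covariates))
}

#' Build a multigroup bivariate latent change score model
#'
#' Extends [build_ulcs()] to two variables with latent changes `dx`, `dy`.
#' Free per group, beyond the univariate pieces: the baseline covariance
#' `phi`, cross-couplings `gamma1` (attention baseline to change in the
#' decision parameter) and `gamma2` (decision parameter baseline to change
#' in attention), the change residual covariance `rho`, and self-feedback
#' regressions `<var>_beta` of each change on its own baseline (so
#' `<var>_change_var` is a residual variance and `<var>_change_mean` an
#' intercept).
#'
#' @param ddm_variable,attention_variable the two variable name prefixes.
#' @param covariates covariate column names.
#' @param groups group labels.
#' @return A `sem_spec` object.
#' @export
build_blcs <- function(ddm_variable, attention_variable,
                       covariates = character(), groups = c("F", "M")) {
  if (identical(ddm_variable, attention_variable))
    stop("the two variables must differ")
  x0 <- paste0(ddm_variable, "0"); x2 <- paste0(ddm_variable, "2")
  y0 <- paste0(attention_variable, "0"); y2 <- paste0(attention_variable, "2")
  observed <- c(x0, x2, y0, y2, covariates)
  vars <- c(observed, "dx", "dy")
  nv <- length(vars)
  A <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  M <- setNames(numeric(nv), vars)
  A[x2, x0] <- 1; A[x2, "dx"] <- 1
  A[y2, y0] <- 1; A[y2, "dy"] <- 1
  pre <- function(v, lab) paste0(v, "_", lab)
  fr <- rbind(
    free_row(pre(ddm_variable, "base_mean"), groups, "M", match(x0, vars), 1L),
    free_row(pre(attention_variable, "base_mean"), groups, "M", match(y0, vars), 1L),
    free_row(pre(ddm_variable, "change_mean"), groups, "M", match("dx", vars), 1L),
    free_row(pre(attention_variable, "change_mean"), groups, "M", match("dy", vars), 1L),
    free_row(pre(ddm_variable, "base_var"), groups, "S", match(x0, vars), match(x0, vars)),
    free_row(pre(attention_variable, "base_var"), groups, "S", match(y0, vars), match(y0, vars)),
    free_row(pre(ddm_variable, "change_var"), groups, "S", match("dx", vars), match("dx", vars)),
    free_row(pre(attention_variable, "change_var"), groups, "S", match("dy", vars), match("dy", vars)),
    free_row("phi", groups, "S", match(x0, vars), match(y0, vars)),
    free_row("rho", groups, "S", match("dx", vars), match("dy", vars)),
    free_row(pre(ddm_variable, "beta"), groups, "A", match("dx", vars), match(x0, vars)),
    free_row(pre(attention_variable, "beta"), groups, "A", match("dy", vars), match(y0, vars)),
    free_row("gamma1", groups, "A", match("dx", vars), match(y0, vars)),
    free_row("gamma2", groups, "A", match("dy", vars), match(x0, vars)))
  if (length(covariates))
    fr <- rbind(fr, covariate_free(covariates, groups, vars, c(x0, y0)))
  new_sem_spec(observed, c("dx", "dy"), groups, A, S, M, fr,
               meta = list(type = "blcs", ddm_variable = ddm_variable,
                           attention_variable = attention_variable,
                           covariates = covariates))
}

#' Impose a cross-group equality constraint on one parameter
#'
#' @param spec a `sem_spec`.
#' @param parameter a free-parameter label present in every group.
#' @return the constrained `sem_spec`.
#' @export
constrain_equal <- function(spec, parameter) {
  hit <- spec$free$label == parameter
  if (!any(hit)) stop("no free parameter named '", parameter, "'")
  if (length(unique(spec$free$group[hit])) != length(spec$groups))
    stop("parameter '", parameter, "' is not free in every group")
  spec$free$theta[hit] <- parameter
  spec
}

## ---------------------------------------------------------------------------
## Model-implied moments
## ---------------------------------------------------------------------------

compile_spec <- function(spec) {
  th_names <- unique(spec$free$theta)
  nv <- length(spec$vars)
  per_group <- lapply(spec$groups, function(g) {
    fr <- spec$free[spec$free$group == g, , drop = FALSE]
    lin <- function(r, c) (c - 1L) * nv + r
    list(
      A_idx = lin(fr$row[fr$mat == "A"], fr$col[fr$mat == "A"]),
      A_th = match(fr$theta[fr$mat == "A"], th_names),
      S_idx1 = lin(fr$row[fr$mat == "S"], fr$col[fr$mat == "S"]),
      S_idx2 = lin(fr$col[fr$mat == "S"], fr$row[fr$mat == "S"]),
      S_th = match(fr$theta[fr$mat == "S"], th_names),
      M_idx = fr$row[fr$mat == "M"],
      M_th = match(fr$theta[fr$mat == "M"], th_names))
  })
  names(per_group) <- spec$groups
  obs_idx <- match(spec$observed, spec$vars)
  list(spec = spec, theta_names = th_names, per_group = per_group,
       obs_idx = obs_idx, nv = nv)
}

implied_moments <- function(comp, theta, observed_only = TRUE) {
  spec <- comp$spec
  out <- list()
  for (g in spec$groups) {
    pg <- comp$per_group[[g]]
    A <- spec$A0; S <- spec$S0; M <- spec$M0
    A[pg$A_idx] <- theta[pg$A_th]
    S[pg$S_idx1] <- theta[pg$S_th]
    S[pg$S_idx2] <- theta[pg$S_th]
    M[pg$M_idx] <- theta[pg$M_th]
    IA <- solve(diag(comp$nv) - A)
    Sig <- IA %*% S %*% t(IA)
    mu <- as.numeric(IA %*% M)
    if (observed_only) {
      Sig <- Sig[comp$obs_idx, comp$obs_idx, drop = FALSE]
      mu <- mu[comp$obs_idx]
    }
    out[[g]] <- list(mu = mu, sigma = Sig)
  }
  out
}

## ---------------------------------------------------------------------------
## FIML likelihood over missingness patterns
## ---------------------------------------------------------------------------

fiml_prepare <- function(data, spec, group_col = "sex") {
  if (!all(spec$observed %in% names(data)))
    stop("data lacks modeled columns: ",
         paste(setdiff(spec$observed, names(data)), collapse = ", "))
  if (!group_col %in% names(data)) stop("missing group column '", group_col, "'")
  out <- list()
  for (g in spec$groups) {
    Y <- as.matrix(data[data[[group_col]] == g, spec$observed, drop = FALSE])
    Y <- Y[rowSums(!is.na(Y)) > 0L, , drop = FALSE]  # rows with nothing observed dropped
    pat <- apply(!is.na(Y), 1L, function(r) paste(as.integer(r), collapse = ""))
    pats <- lapply(split(seq_len(nrow(Y)), pat), function(rows) {
      obs <- which(!is.na(Y[rows[1L], ]))
      Yo <- Y[rows, obs, drop = FALSE]
      n <- nrow(Yo)
      ybar <- colMeans(Yo)
      Yc <- sweep(Yo, 2L, ybar)
      list(obs = obs, n = n, ybar = ybar, S = crossprod(Yc) / n)
    })
    out[[g]] <- list(patterns = unname(pats), n = nrow(Y))
  }
  out
}

mvn_pattern_loglik <- function(patterns, mu, Sigma) {
  ll <- 0
  for (p in patterns) {
    Sp <- Sigma[p$obs, p$obs, drop = FALSE]
    R <- tryCatch(chol(Sp), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    Sinv <- chol2inv(R)
    d <- p$ybar - mu[p$obs]
    k <- length(p$obs)
    ll <- ll - 0.5 * p$n * (k * log(2 * pi) + 2 * sum(log(diag(R))) +
                            sum(Sinv * p$S) + sum(d * (Sinv %*% d)))
  }
  ll
}

#' Full-information ML log likelihood
#'
#' Sums, over rows, the multivariate-normal log density restricted to each
#' row's observed subset of variables at the model-implied moments; rows are
#' grouped by missingness pattern purely as an optimization (the result is
#' identical to a naive per-row evaluation).
#'
#' @param spec a `sem_spec` from [build_ulcs()] or [build_blcs()].
#' @param data data.frame containing the modeled columns and the group
#'   column `sex`.
#' @param theta named parameter vector (order of
#'   `unique(spec$free$theta)`).
#' @return scalar log likelihood; `-Inf` when an implied covariance is not
#'   positive definite.
#' @export
fiml_loglik <- function(spec, data, theta) {
  comp <- compile_spec(spec)
  prep <- fiml_prepare(data, spec)
  fiml_loglik_prepared(comp, prep, theta)
}

fiml_loglik_prepared <- function(comp, prep, theta) {
  mom <- implied_moments(comp, theta)
  ll <- 0
  for (g in comp$spec$groups) {
    ll <- ll + mvn_pattern_loglik(prep[[g]]$patterns, mom[[g]]$mu,
                                  mom[[g]]$sigma)
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

## ---------------------------------------------------------------------------
## Saturated and null models
## ---------------------------------------------------------------------------

safe_chol_inv <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  ridge <- 1e-8 * mean(diag(S))
  while (is.null(R) && ridge < mean(diag(S))) {
    R <- tryCatch(chol(S + ridge * diag(nrow(S))), error = function(e) NULL)
    ridge <- ridge * 100
  }
  if (is.null(R)) stop("covariance irrecoverably singular")
  chol2inv(R)
}

# EM algorithm for the MVN saturated model under ignorable missingness
mvn_em <- function(patterns, p, max_iter = 1000L, tol = 1e-8) {
  # initialize from available-case moments
  sw <- numeric(p); sn <- numeric(p); sv <- numeric(p)
  for (pt in patterns) {
    sw[pt$obs] <- sw[pt$obs] + pt$n * pt$ybar
    sn[pt$obs] <- sn[pt$obs] + pt$n
    sv[pt$obs] <- sv[pt$obs] + pt$n * (diag(pt$S) + pt$ybar^2)
  }
  mu <- sw / pmax(sn, 1)
  Sigma <- diag(pmax(sv / pmax(sn, 1) - mu^2, 1e-6), p)
  n_tot <- sum(vapply(patterns, function(x) x$n, 0))
  complete <- length(patterns) == 1L && length(patterns[[1L]]$obs) == p
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    if (complete) {
      mu <- patterns[[1L]]$ybar
      Sigma <- patterns[[1L]]$S
      ll <- mvn_pattern_loglik(patterns, mu, Sigma)
      return(list(mu = mu, sigma = Sigma, loglik = ll, iter = iter))
    }
    sum_y <- numeric(p)
    sum_yy <- matrix(0, p, p)
    for (pt in patterns) {
      o <- pt$obs; m <- setdiff(seq_len(p), o)
      Soo_inv <- safe_chol_inv(Sigma[o, o, drop = FALSE])
      Ey <- matrix(0, p, 1)
      Ey[o] <- pt$ybar
      # expected moments of the completed data within this pattern
      Eyy <- matrix(0, p, p)
      Eyy[o, o] <- pt$S + tcrossprod(pt$ybar)
      if (length(m)) {
        B <- Sigma[m, o, drop = FALSE] %*% Soo_inv       # regression coefs
        mm <- Sigma[m, m] - B %*% Sigma[o, m, drop = FALSE]
        d <- pt$ybar - mu[o]
        Em <- mu[m] + as.numeric(B %*% d)
        Ey[m] <- Em
        # E[y_m y_o'] = B E[y_o y_o'] + (mu_m - B mu_o) E[y_o]'
        cross <- B %*% Eyy[o, o, drop = FALSE] +
          tcrossprod(mu[m] - as.numeric(B %*% mu[o]), pt$ybar)
        Eyy[m, o] <- cross
        Eyy[o, m] <- t(cross)
        Eyy[m, m] <- mm + B %*% Eyy[o, o] %*% t(B) +
          tcrossprod(mu[m] - as.numeric(B %*% mu[o]), Em) +
          tcrossprod(Em, mu[m] - as.numeric(B %*% mu[o])) -
          tcrossprod(mu[m] - as.numeric(B %*% mu[o]))
      }
      sum_y <- sum_y + pt$n * as.numeric(Ey)
      sum_yy <- sum_yy + pt$n * Eyy
    }
    mu <- sum_y / n_tot
    Sigma <- sum_yy / n_tot - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev))   # keep the M-step inside the PD cone
      Sigma <- Sigma + (1e-10 * max(ev) - min(ev)) * diag(p)
    ll <- mvn_pattern_loglik(patterns, mu, Sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = Sigma, loglik = ll, iter = iter)
}

saturated_fit <- function(prep, p) {
  lapply(prep, function(gr) mvn_em(gr$patterns, p))
}

null_loglik <- function(prep, p) {
  # independence model: free means and variances, zero covariances; under a
  # diagonal covariance the FIML likelihood separates per variable
  ll <- 0
  for (gr in prep) {
    for (j in seq_len(p)) {
      sw <- 0; sn <- 0; sv <- 0
      for (pt in gr$patterns) {
        k <- match(j, pt$obs)
        if (is.na(k)) next
        sw <- sw + pt$n * pt$ybar[k]
        sv <- sv + pt$n * (pt$S[k, k] + pt$ybar[k]^2)
        sn <- sn + pt$n
      }
      if (sn == 0) next
      m <- sw / sn; v <- sv / sn - m^2
      ll <- ll - 0.5 * sn * (log(2 * pi) + log(v) + 1)
    }
  }
  ll
}

## ---------------------------------------------------------------------------
## Fitting
## ---------------------------------------------------------------------------

sem_start <- function(spec, data, group_col = "sex") {
  th <- setNames(numeric(length(unique(spec$free$theta))),
                 unique(spec$free$theta))
  for (i in seq_len(nrow(spec$free))) {
    fr <- spec$free[i, ]
    d <- data[data[[group_col]] == fr$group, , drop = FALSE]
    lab <- fr$label
    val <- local({
      base_of <- function(v) d[[paste0(v, "0")]]
      diff_of <- function(v) d[[paste0(v, "2")]] - d[[paste0(v, "0")]]
      mvar <- function(x) max(var(x, na.rm = TRUE), 1e-4)
      # label grammar: [<var>_]<what>[_<cov>]
      if (grepl("base_mean$", lab)) {
        v <- sub("_?base_mean$", "", lab)
        if (v == "") v <- spec$meta$variable
        mean(base_of(v), na.rm = TRUE)
      } else if (grepl("change_mean$", lab)) {
        v <- sub("_?change_mean$", "", lab)
        if (v == "") v <- spec$meta$variable
        mean(diff_of(v), na.rm = TRUE)
      } else if (grepl("base_var$", lab)) {
        v <- sub("_?base_var$", "", lab)
        if (v == "") v <- spec$meta$variable
        mvar(base_of(v))
      } else if (grepl("change_var$", lab)) {
        v <- sub("_?change_var$", "", lab)
        if (v == "") v <- spec$meta$variable
        mvar(diff_of(v))
      } else if (lab == "base_change_cov") {
        v <- spec$meta$variable
        cov(base_of(v), diff_of(v), use = "pairwise.complete.obs")
      } else if (grepl("^var_", lab)) {
        mvar(d[[sub("^var_", "", lab)]])
      } else if (grepl("^cov_", lab)) {
        nm <- strsplit(sub("^cov_", "", lab), "_")[[1L]]
        cov(d[[nm[1L]]], d[[nm[2L]]], use = "pairwise.complete.obs")
      } else 0
    })
    if (!is.finite(val)) val <- 0
    th[fr$theta] <- val
  }
  th
}

#' Fit a latent change score model by FIML
#'
#' Maximizes the [fiml_loglik()] over the free parameters with `nlminb`
#' (random multistarts on convergence failure), computes standard errors
#' from the inverse observed information, the likelihood-ratio statistic
#' against the saturated model (estimated by an EM algorithm when data are
#' missing), and CFI / RMSEA / SRMR against the free-variance null model.
#'
#' @param spec a `sem_spec`.
#' @param data data.frame with the modeled columns and a `sex` group column.
#' @param se compute standard errors (observed information); disable for
#'   speed in simulations.
#' @param multistart number of jittered restarts tried on failure.
#' @param group_col grouping column name.
#' @return object of class `sem_fit` with elements `estimates` (label,
#'   group, est, se, z, p), `theta`, `vcov`, `loglik`, `loglik_sat`,
#'   `loglik_null`, `T` (LR chi-square), `df`, `indices`, `implied`,
#'   `saturated`, `converged`, `N`.
#' @export
fit_sem <- function(spec, data, se = TRUE, multistart = 5L,
                    group_col = "sex") {
  comp <- compile_spec(spec)
  prep <- fiml_prepare(data, spec, group_col)
  for (g in spec$groups)
    if (prep[[g]]$n < 2L) stop("fewer than 2 rows in group ", g)
  start <- sem_start(spec, data, group_col)
  negll <- function(th) {
    ll <- fiml_loglik_prepared(comp, prep, th)
    if (!is.finite(ll)) 1e12 else -ll
  }
  best <- NULL
  for (try in 0:multistart) {
    st <- if (try == 0) start else
      start * (1 + 0.2 * rnorm(length(start))) + 0.05 * rnorm(length(start))
    opt <- tryCatch(
      nlminb(st, negll, control = list(iter.max = 1000L, eval.max = 5000L,
                                       rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || opt$objective >= 1e11) next
    if (is.null(best) || opt$objective < best$objective - 1e-6) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best))
    stop("FIML optimization failed: no finite optimum after multistart ",
         "(groups of ", paste(vapply(prep, function(x) x$n, 0),
                              collapse = "/"), " rows)")
  if (best$convergence != 0) {
    # one polishing pass; "singular convergence" is common for weakly
    # identified small samples and still marks a usable optimum
    ref <- tryCatch(nlminb(best$par, negll,
                           control = list(iter.max = 1000L,
                                          eval.max = 5000L,
                                          rel.tol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(ref) && ref$objective <= best$objective + 1e-8) best <- ref
    if (best$convergence != 0)
      warning("optimizer stopped with '", best$message,
              "'; estimates may be weakly identified")
  }
  theta <- setNames(best$par, comp$theta_names)
  ll <- -best$objective

  p <- length(spec$observed)
  sat <- saturated_fit(prep, p)
  ll_sat <- sum(vapply(sat, function(x) x$loglik, 0))
  ll_null <- null_loglik(prep, p)
  G <- length(spec$groups)
  N <- sum(vapply(prep, function(x) x$n, 0))
  moments <- G * p * (p + 3) / 2
  df <- moments - length(theta)
  if (df < 0) stop("model not identified: negative degrees of freedom")
  Tstat <- max(2 * (ll_sat - ll), 0)
  df0 <- moments - G * 2 * p
  T0 <- max(2 * (ll_sat - ll_null), 0)

  vc <- NULL; ses <- rep(NA_real_, length(theta))
  if (se) {
    H <- pracma::hessian(negll, theta)
    vc <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(vc)) {
      dg <- diag(vc)
      ses <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    } else warning("observed information is singular; SEs unavailable")
  }
  est <- data.frame(label = spec$free$label, group = spec$free$group,
                    theta = spec$free$theta, stringsAsFactors = FALSE)
  est <- unique(est)
  est$est <- theta[est$theta]
  est$se <- ses[match(est$theta, names(theta))]
  est$z <- est$est / est$se
  est$p <- 2 * pnorm(-abs(est$z))

  mom <- implied_moments(comp, theta)
  fit <- structure(list(spec = spec, comp = comp, theta = theta, vcov = vc,
                        estimates = est, loglik = ll, loglik_sat = ll_sat,
                        loglik_null = ll_null, T = Tstat, df = df, T0 = T0,
                        df0 = df0, N = N, G = G, implied = mom,
                        saturated = sat, prep = prep,
                        converged = best$convergence == 0),
                   class = "sem_fit")
  fit$indices <- fit_indices(fit)
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("sem_fit (%s): chi-square(%d) = %.3f, N = %d\n",
              x$spec$meta$type, x$df, x$T, x$N))
  cat(sprintf("  CFI = %.3f, RMSEA = %.3f, SRMR = %.3f, loglik = %.2f\n",
              x$indices["cfi"], x$indices["rmsea"], x$indices["srmr"],
              x$loglik))
  invisible(x)
}

srmr_value <- function(fit) {
  tot <- 0
  for (g in fit$spec$groups) {
    Ss <- fit$saturated[[g]]$sigma; ms <- fit$saturated[[g]]$mu
    Sm <- fit$implied[[g]]$sigma; mm <- fit$implied[[g]]$mu
    sdv <- sqrt(diag(Ss))
    p <- length(ms)
    e <- c()
    for (i in seq_len(p)) for (j in i:p)
      e <- c(e, (Ss[i, j] - Sm[i, j]) / (sdv[i] * sdv[j]))
    e <- c(e, (ms - mm) / sdv)
    ng <- fit$prep[[g]]$n
    tot <- tot + ng / fit$N * mean(e^2)
  }
  sqrt(tot)
}

#' Fit indices (CFI, RMSEA, SRMR)
#'
#' CFI uses the noncentrality convention
#' `1 - max(T - df, 0) / max(T0 - df0, T - df, 0)`; RMSEA is
#' `sqrt(G) * sqrt(max(T - df, 0) / (df N))` (multigroup convention); SRMR
#' averages squared standardized residuals of the covariances and means
#' against the saturated estimates, group-weighted by sample size.  For a
#' just-identified model (`df = 0`) RMSEA is defined as 0 and CFI as 1.
#'
#' @param fit a `sem_fit`.
#' @return named numeric vector `c(cfi, rmsea, srmr)`.
#' @export
fit_indices <- function(fit) {
  Td <- max(fit$T - fit$df, 0)
  T0d <- max(fit$T0 - fit$df0, 0)
  cfi <- if (max(T0d, Td) == 0) 1 else 1 - Td / max(T0d, Td)
  rmsea <- if (fit$df == 0) 0 else sqrt(fit$G) * sqrt(Td / (fit$df * fit$N))
  c(cfi = cfi, rmsea = rmsea, srmr = srmr_value(fit))
}

#' Chi-square difference test of one cross-group equality constraint
#'
#' Refits the model with the named parameter constrained equal across
#' groups and compares likelihood-ratio statistics; `df` equals the number
#' of groups minus one.
#'
#' @param spec a `sem_spec`.
#' @param data the data.
#' @param parameter free-parameter label to constrain.
#' @param free_fit optionally a prefitted unconstrained `sem_fit` (avoids
#'   refitting across repeated calls).
#' @param se passed to [fit_sem()] for the refits.
#' @return list of class `delta_chi2` with `parameter`, `delta_chi2`, `df`,
#'   `p`, and the per-group unconstrained estimates.
#' @export
constrain_compare <- function(spec, data, parameter, free_fit = NULL,
                              se = FALSE) {
  if (is.null(free_fit)) free_fit <- fit_sem(spec, data, se = se)
  cspec <- constrain_equal(spec, parameter)
  cfit <- fit_sem(cspec, data, se = se)
  d <- max(2 * (free_fit$loglik - cfit$loglik), 0)
  df <- length(spec$groups) - 1L
  grp_est <- free_fit$estimates[free_fit$estimates$label == parameter,
                                c("group", "est")]
  structure(list(parameter = parameter, delta_chi2 = d, df = df,
                 p = pchisq(d, df, lower.tail = FALSE),
                 group_estimates = grp_est,
                 constrained_fit = cfit),
            class = "delta_chi2")
}

#' @export
print.delta_chi2 <- function(x, ...) {
  cat(sprintf("delta chi-square (%s): %.3f on %d df, p = %.4g\n",
              x$parameter, x$delta_chi2, x$df, x$p))
  invisible(x)
}

#' Standardized solution
#'
#' Covariance parameters become correlations via the model-implied total
#' variances of the connected variables; regression coefficients are scaled
#' by the SD ratio of predictor to outcome.  Mean parameters are returned
#' unstandardized.
#'
#' @param fit a `sem_fit`.
#' @return the estimates table with a `std` column.
#' @export
standardized_solution <- function(fit) {
  spec <- fit$spec
  mom_all <- implied_moments(fit$comp, fit$theta, observed_only = FALSE)
  est <- fit$estimates
  est$std <- NA_real_
  for (i in seq_len(nrow(est))) {
    fr <- spec$free[spec$free$theta == est$theta[i] &
                    spec$free$group == est$group[i], ][1L, ]
    Sg <- mom_all[[est$group[i]]]$sigma
    sdv <- sqrt(pmax(diag(Sg), 0))
    if (fr$mat == "S") {
      if (fr$row == fr$col) est$std[i] <- 1
      else {
        den <- sdv[fr$row] * sdv[fr$col]
        est$std[i] <- if (den > 0) est$est[i] / den else NA_real_
      }
    } else if (fr$mat == "A") {
      den <- sdv[fr$row]
      est$std[i] <- if (den > 0) est$est[i] * sdv[fr$col] / den else NA_real_
    } else est$std[i] <- est$est[i]
  }
  est
}

#' Model-implied mean of a latent change factor
#'
#' For bivariate models the change mean parameter is an intercept; this
#' returns the implied population mean of the latent change per group.
#'
#' @param fit a `sem_fit`.
#' @param latent latent variable name (`"d"`, `"dx"` or `"dy"`).
#' @return named numeric vector over groups.
#' @export
implied_change_mean <- function(fit, latent = "d") {
  mom <- implied_moments(fit$comp, fit$theta, observed_only = FALSE)
  idx <- match(latent, fit$spec$vars)
  vapply(mom, function(m) m$mu[idx], 0)
}
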