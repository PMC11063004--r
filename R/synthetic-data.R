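## Synthetic cohort generator: demographics, families, covariates, latent
## change score panels with known ground truth, ordinal attention items,
## follow-up attrition and trial-level diffusion data.

#' Cohort configuration
#'
#' Study-condition defaults emulate a large two-timepoint developmental
#' cohort performing a stop-signal task: ~300 go trials per session, a small
#' fraction of uniform fast-guess contaminant trials, a fraction of
#' non-compliant (near-zero-drift) subjects, sibling pairs within families,
#' and substantial follow-up attrition.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param female_fraction expected proportion of females.
#' @param sibling_rate proportion of subjects who share a family ID with one
#'   other subject (formed as pairs).
#' @param n_trials go trials per session.
#' @param contaminant_rate per-trial probability of a uniform fast-guess
#'   contaminant.
#' @param low_accuracy_rate proportion of subjects responding near chance
#'   (near-zero drift), to be caught by the accuracy filter.
#' @param attrition_rate proportion missing the follow-up assessment.
#' @param sz_true generative trial-to-trial starting-point range.
#' @param seed integer seed controlling every draw downstream.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          female_fraction = 0.477,
                          sibling_rate = 0.15,
                          n_trials = 300L,
                          contaminant_rate = 0.012,
                          low_accuracy_rate = 0.08,
                          attrition_rate = 0.29,
                          sz_true = 0.10,
                          seed = 1L) {
  props <- c(female_fraction = female_fraction, sibling_rate = sibling_rate,
             contaminant_rate = contaminant_rate,
             low_accuracy_rate = low_accuracy_rate,
             attrition_rate = attrition_rate)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 female_fraction = female_fraction,
                 sibling_rate = sibling_rate, n_trials = as.integer(n_trials),
                 contaminant_rate = contaminant_rate,
                 low_accuracy_rate = low_accuracy_rate,
                 attrition_rate = attrition_rate, sz_true = sz_true,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## ---------------------------------------------------------------------------
## Latent change score ground truth
## ---------------------------------------------------------------------------

lcs_group_implied <- function(g) {
  # implied 4x4 covariance of (x0, y0, dx, dy) from structural parameters
  S0 <- matrix(c(g$var_x0, g$phi, g$phi, g$var_y0), 2)
  B <- matrix(c(g$beta_x, g$gamma2, g$gamma1, g$beta_y), 2) # rows: dx, dy
  Sz <- matrix(c(g$zeta_x, g$rho, g$rho, g$zeta_y), 2)
  Sd <- B %*% S0 %*% t(B) + Sz
  rbind(cbind(S0, S0 %*% t(B)), cbind(B %*% S0, Sd))
}

#' Construct latent change score generative truth (structural form)
#'
#' Per sex group and per variable pair (a decision parameter `x` and the
#' attention score `y`): baseline means and variances, change intercepts
#' `nu`, self-feedback coefficients `beta` (centred baseline to own change),
#' cross-couplings `gamma1` (y0 to change in x) and `gamma2` (x0 to change
#' in y), baseline covariance `phi`, change residual variances `zeta` and
#' residual covariance `rho`.  The change equations are
#' `dx = nu_x + beta_x (x0 - mu_x0) + gamma1 (y0 - mu_y0) + e_x`, jointly
#' normal residuals.
#'
#' @param female,male named lists with fields `mean_x0`, `var_x0`,
#'   `mean_y0`, `var_y0`, `nu_x`, `nu_y`, `beta_x`, `beta_y`, `gamma1`,
#'   `gamma2`, `phi`, `zeta_x`, `zeta_y`, `rho`.
#' @return object of class `lcs_truth` with elements `F` and `M`.
#' @export
lcs_truth <- function(female, male) {
  tr <- list(F = female, M = male)
  need <- c("mean_x0", "var_x0", "mean_y0", "var_y0", "nu_x", "nu_y",
            "beta_x", "beta_y", "gamma1", "gamma2", "phi", "zeta_x",
            "zeta_y", "rho")
  for (s in names(tr)) {
    miss <- setdiff(need, names(tr[[s]]))
    if (length(miss)) stop("missing truth fields: ", paste(miss, collapse = ", "))
    g <- tr[[s]]
    if (any(c(g$var_x0, g$var_y0) <= 0)) stop("variances must be > 0")
    if (any(c(g$zeta_x, g$zeta_y) < 0)) stop("residual variances must be >= 0")
    imp <- lcs_group_implied(g)
    ev <- eigen(imp, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("implied covariance of (x0, y0, dx, dy) is not positive semi-definite")
  }
  structure(tr, class = "lcs_truth")
}

#' Convert table-style summaries to structural truth
#'
#' Accepts the reporting parameterization of latent change score results
#' (total change variances, baseline-change correlations, standardized
#' baseline correlation, couplings and correlated change) and solves for the
#' structural coefficients used by the generator.
#'
#' @param mean_x0,var_x0 baseline mean and variance of the decision variable.
#' @param change_mean_x,change_var_x mean and total variance of its change.
#' @param r_base_change_x correlation between baseline and change.
#' @param mean_y0,var_y0,change_mean_y,change_var_y,r_base_change_y same for
#'   the attention score.
#' @param r_phi standardized baseline covariance (correlation).
#' @param g1_std,g2_std standardized cross-couplings (y0 to dx, x0 to dy).
#' @param r_rho standardized correlated change (residual correlation).
#' @return named list of structural fields for one group.
#' @export
lcs_group_from_summary <- function(mean_x0, var_x0, change_mean_x,
                                   change_var_x, r_base_change_x,
                                   mean_y0, var_y0, change_mean_y,
                                   change_var_y, r_base_change_y,
                                   r_phi = 0, g1_std = 0, g2_std = 0,
                                   r_rho = 0) {
  sdx0 <- sqrt(var_x0); sdy0 <- sqrt(var_y0)
  sddx <- sqrt(change_var_x); sddy <- sqrt(change_var_y)
  phi <- r_phi * sdx0 * sdy0
  gamma1 <- g1_std * sddx / sdy0
  gamma2 <- g2_std * sddy / sdx0
  cov_xdx <- r_base_change_x * sdx0 * sddx
  cov_ydy <- r_base_change_y * sdy0 * sddy
  beta_x <- (cov_xdx - gamma1 * phi) / var_x0
  beta_y <- (cov_ydy - gamma2 * phi) / var_y0
  zeta_x <- change_var_x -
    (beta_x^2 * var_x0 + gamma1^2 * var_y0 + 2 * beta_x * gamma1 * phi)
  zeta_y <- change_var_y -
    (beta_y^2 * var_y0 + gamma2^2 * var_x0 + 2 * beta_y * gamma2 * phi)
  if (zeta_x <= 0 || zeta_y <= 0)
    stop("summary values imply non-positive change residual variance")
  rho <- r_rho * sqrt(zeta_x * zeta_y)
  list(mean_x0 = mean_x0, var_x0 = var_x0, mean_y0 = mean_y0,
       var_y0 = var_y0, nu_x = change_mean_x, nu_y = change_mean_y,
       beta_x = beta_x, beta_y = beta_y, gamma1 = gamma1, gamma2 = gamma2,
       phi = phi, zeta_x = zeta_x, zeta_y = zeta_y, rho = rho)
}

att_summary <- list(
  F = list(mean = 2.370, var = 9.150, change = -0.191, change_var = 5.439,
           r_bc = -0.444),
  M = list(mean = 3.501, var = 13.743, change = -0.243, change_var = 7.059,
           r_bc = -0.418))

#' Default generative truth for a decision-variable / attention pair
#'
#' Defaults are on the scale of published large-cohort estimates for early
#' adolescence: drift rate couples negatively with attention problems at
#' baseline and in change, while decision threshold and non-decision time
#' are generated with null cross-couplings.
#'
#' @param pair `"drift"`, `"threshold"` or `"ndt"`.
#' @return An [lcs_truth()] object.
#' @export
default_lcs_truth <- function(pair = c("drift", "threshold", "ndt")) {
  pair <- match.arg(pair)
  x <- switch(pair,
    drift = list(
      F = list(m = 2.742, v = 0.625, ch = 0.434, chv = 0.638, r = -0.414,
               r_phi = -0.244, g1 = -0.062, g2 = -0.084, r_rho = -0.127),
      M = list(m = 2.630, v = 0.674, ch = 0.373, chv = 0.683, r = -0.421,
               r_phi = -0.350, g1 = -0.052, g2 = -0.033, r_rho = -0.108)),
    threshold = list(
      F = list(m = 1.799, v = 0.303, ch = -0.117, chv = 0.332, r = -0.576,
               r_phi = 0, g1 = 0, g2 = 0, r_rho = 0),
      M = list(m = 1.620, v = 0.252, ch = -0.086, chv = 0.312, r = -0.530,
               r_phi = 0, g1 = 0, g2 = 0, r_rho = 0)),
    ndt = list(
      F = list(m = 0.264, v = 0.002, ch = -0.019, chv = 0.002, r = -0.592,
               r_phi = 0, g1 = 0, g2 = 0, r_rho = 0),
      M = list(m = 0.255, v = 0.002, ch = -0.021, chv = 0.002, r = -0.645,
               r_phi = 0, g1 = 0, g2 = 0, r_rho = 0)))
  grp <- function(s) {
    a <- att_summary[[s]]; d <- x[[s]]
    lcs_group_from_summary(d$m, d$v, d$ch, d$chv, d$r,
                           a$mean, a$var, a$change, a$change_var, a$r_bc,
                           r_phi = d$r_phi, g1_std = d$g1, g2_std = d$g2,
                           r_rho = d$r_rho)
  }
  lcs_truth(grp("F"), grp("M"))
}

## ---------------------------------------------------------------------------
## Cohort generation
## ---------------------------------------------------------------------------

#' Generate a synthetic cohort with known ground truth
#'
#' Builds the subject-level panel: demographics (sex, sibling-pair family
#' structure), centred covariates (baseline age from a truncated normal with
#' mean 9.9 and SD 0.6, one genetic-ancestry factor score and household
#' income as standard normals), and true decision-model and attention values
#' at both timepoints drawn from [default_lcs_truth()] (drift coupled with
#' attention; threshold and non-decision time with null couplings).
#'
#' @param config a [cohort_config()] object.
#' @return data.frame of class `true_panel`, one row per subject, with
#'   columns `subject_id`, `family_id`, `sex`, centred covariates `age0`,
#'   `gaf`, `income`, a `low_acc` compliance flag, the true diffusion
#'   parameters `v0, v2, a0, a2, t0, t2` and latent attention `att0, att2`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  id <- sprintf("S%05d", seq_len(n))

  # sibling pairs: sibling_rate of subjects share a family with one other
  n_pairs <- floor(round(n * config$sibling_rate) / 2)
  fam <- seq_len(n)
  if (n_pairs > 0) {
    paired <- sample(n, 2 * n_pairs)
    fam[paired[seq_len(n_pairs) * 2]] <- fam[paired[seq_len(n_pairs) * 2 - 1]]
  }
  family_id <- sprintf("F%05d", match(fam, unique(fam)))

  sex <- ifelse(runif(n) < config$female_fraction, "F", "M")

  # covariates, centred exactly to zero sample mean
  age <- qnorm(runif(n, pnorm(8.9, 9.9, 0.6), pnorm(11.0, 9.9, 0.6)), 9.9, 0.6)
  age0 <- age - mean(age)
  gaf <- rnorm(n); gaf <- gaf - mean(gaf)
  income <- rnorm(n); income <- income - mean(income)

  panel <- data.frame(subject_id = id, family_id = family_id, sex = sex,
                      age0 = age0, gaf = gaf, income = income,
                      low_acc = runif(n) < config$low_accuracy_rate,
                      stringsAsFactors = FALSE)
  panel <- simulate_lcs_panel(panel, default_lcs_truth("drift"),
                              vars = c("v", "att"))
  panel <- simulate_ulcs_values(panel, default_lcs_truth("threshold"), "a")
  panel <- simulate_ulcs_values(panel, default_lcs_truth("ndt"), "t")
  class(panel) <- c("true_panel", "data.frame")
  panel
}

#' Simulate a bivariate latent change score panel
#'
#' Draws baseline values and changes from the latent change score equations
#' per sex group and writes `<x>0, <x>2, <y>0, <y>2` columns (follow-up =
#' baseline + change).
#'
#' @param panel data.frame with a `sex` column (`"F"`/`"M"`).
#' @param truth an [lcs_truth()] object.
#' @param vars names of the two variables, e.g. `c("v", "att")`.
#' @param seed optional seed; by default draws from the current RNG stream.
#' @return `panel` with the four value columns added/overwritten.
#' @export
simulate_lcs_panel <- function(panel, truth, vars = c("v", "att"),
                               seed = NULL) {
  stopifnot(inherits(truth, "lcs_truth"), length(vars) == 2,
            all(panel$sex %in% c("F", "M")))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel)
  x0 <- y0 <- dx <- dy <- numeric(n)
  for (s in c("F", "M")) {
    idx <- which(panel$sex == s)
    if (!length(idx)) next
    g <- truth[[s]]
    S0 <- matrix(c(g$var_x0, g$phi, g$phi, g$var_y0), 2)
    base <- matrix(rnorm(2 * length(idx)), ncol = 2) %*% chol(S0)
    Sz <- matrix(c(g$zeta_x, g$rho, g$rho, g$zeta_y), 2)
    zt <- if (all(Sz == 0)) matrix(0, length(idx), 2) else
      matrix(rnorm(2 * length(idx)), ncol = 2) %*% chol(Sz)
    x0[idx] <- g$mean_x0 + base[, 1]
    y0[idx] <- g$mean_y0 + base[, 2]
    dx[idx] <- g$nu_x + g$beta_x * base[, 1] + g$gamma1 * base[, 2] + zt[, 1]
    dy[idx] <- g$nu_y + g$beta_y * base[, 2] + g$gamma2 * base[, 1] + zt[, 2]
  }
  panel[[paste0(vars[1], "0")]] <- x0
  panel[[paste0(vars[1], "2")]] <- x0 + dx
  panel[[paste0(vars[2], "0")]] <- y0
  panel[[paste0(vars[2], "2")]] <- y0 + dy
  panel
}

#' Simulate a univariate latent change panel column pair
#'
#' Uses only the decision-variable margin of `truth` (no cross-couplings):
#' `dx = nu + beta (x0 - mean) + e`.
#'
#' @inheritParams simulate_lcs_panel
#' @param var output variable name prefix.
#' @return `panel` with `<var>0`, `<var>2` added.
#' @export
simulate_ulcs_values <- function(panel, truth, var, seed = NULL) {
  stopifnot(inherits(truth, "lcs_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel)
  x0 <- dx <- numeric(n)
  for (s in c("F", "M")) {
    idx <- which(panel$sex == s)
    if (!length(idx)) next
    g <- truth[[s]]
    dev <- rnorm(length(idx), 0, sqrt(g$var_x0))
    x0[idx] <- g$mean_x0 + dev
    dx[idx] <- g$nu_x + g$beta_x * dev + rnorm(length(idx), 0, sqrt(g$zeta_x))
  }
  panel[[paste0(var, "0")]] <- x0
  panel[[paste0(var, "2")]] <- x0 + dx
  panel
}

#' Simulate 10 ordinal attention items from a latent score
#'
#' Cumulative-threshold model: 20 thresholds equally spaced at
#' 0.5, 1.5, ..., 19.5 are split across 10 three-category items (item j cuts
#' at j - 0.5 and 9.5 + j); an item scores the number of its thresholds
#' exceeded by `latent` plus small item-specific normal noise.  With zero
#' noise the sum is `round(latent)` truncated to [0, 20], so the expected
#' sum is monotone in the latent score.
#'
#' @param latent numeric vector of latent attention scores (sum-score scale).
#' @param item_sd SD of item-specific noise.
#' @param seed optional seed.
#' @return list with `items` (n x 10 integer matrix, values 0/1/2) and
#'   `sum` (integer vector in [0, 20]).
#' @export
simulate_attention_items <- function(latent, item_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(latent)
  tau1 <- seq_len(10) - 0.5
  tau2 <- 9.5 + seq_len(10)
  e <- matrix(rnorm(n * 10, 0, item_sd), n, 10)
  lat <- matrix(latent, n, 10) + e
  items <- (lat > rep(tau1, each = n)) + (lat > rep(tau2, each = n))
  storage.mode(items) <- "integer"
  list(items = items, sum = as.integer(rowSums(items)))
}

#' Mask follow-up data completely at random
#'
#' @param panel subject panel with follow-up columns (names ending in "2").
#' @param rate attrition probability in [0, 1].
#' @param seed optional seed.
#' @return `panel` with all follow-up fields of the masked subjects set to
#'   `NA`; attribute `"masked"` holds the masked subject IDs.
#' @export
apply_attrition <- function(panel, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  mask <- runif(nrow(panel)) < rate
  fu_cols <- grep("2$", names(panel), value = TRUE)
  panel[mask, fu_cols] <- NA
  attr(panel, "masked") <- panel$subject_id[mask]
  panel
}

#' Simulate trial-level go-trial sessions for a cohort
#'
#' For every subject and non-missing timepoint, simulates `n_trials` go
#' trials from the subject's true diffusion parameters (drift near zero for
#' flagged low-accuracy subjects), with random stimulus sides and a fraction
#' of uniform fast-guess contaminant trials (RT uniform on 0.05-0.5 s,
#' random response).  Values are clamped to a > 0.3, t > 0.05, v > 0.05 so
#' sessions remain simulable even for extreme latent draws.
#'
#' @param panel a panel from [generate_cohort()] (possibly after
#'   [apply_attrition()]).
#' @param config the [cohort_config()] used to build it.
#' @param dt Euler step for the trial simulator.
#' @param seed optional seed.
#' @return data.frame with columns `subject_id`, `timepoint` (0/2), `side`,
#'   `response`, `rt` (seconds).
#' @export
simulate_trials <- function(panel, config, dt = 5e-4, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", 2 * nrow(panel))
  k <- 0
  zs <- pmin(pmax(rnorm(nrow(panel), 0.5, 0.02), 0.40), 0.60)
  for (i in seq_len(nrow(panel))) {
    for (tp in c(0, 2)) {
      v <- panel[[paste0("v", tp)]][i]
      a <- panel[[paste0("a", tp)]][i]
      t0 <- panel[[paste0("t", tp)]][i]
      if (is.na(v) || is.na(a) || is.na(t0)) next
      if (isTRUE(panel$low_acc[i])) v <- 0.05
      p <- ddm_params(v = max(v, 0.05), a = max(a, 0.3), t = max(t0, 0.05),
                      z = zs[i], sz = config$sz_true)
      side <- ifelse(runif(config$n_trials) < 0.5, "left", "right")
      tr <- sample_trial(p, side, dt = dt)
      cont <- runif(config$n_trials) < config$contaminant_rate
      if (any(cont)) {
        tr$rt[cont] <- runif(sum(cont), 0.05, 0.5)
        tr$response[cont] <- as.integer(runif(sum(cont)) < 0.5)
      }
      k <- k + 1
      out[[k]] <- data.frame(subject_id = panel$subject_id[i], timepoint = tp,
                             side = tr$side, response = tr$response,
                             rt = tr$rt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}
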