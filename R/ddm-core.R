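## Drift-diffusion core: parameter container, Wiener first-passage density,
## trial simulator, closed-form moments and the EZ estimator.

#' Drift-diffusion model parameters
#'
#' Container for the parameters of a two-boundary diffusion process with the
#' diffusion scale fixed at 1 (identifiability convention).
#'
#' @param v drift rate (evidence per second). Under stimulus coding the sign
#'   of the effective per-trial drift is `+v` for rightward stimuli and `-v`
#'   for leftward ones; `v` itself is the drift magnitude toward the correct
#'   boundary.
#' @param a decision threshold (boundary separation), > 0.
#' @param t non-decision time in seconds, >= 0.
#' @param z relative starting point in (0, 1); 0.5 is unbiased.
#' @param sz total range of uniform trial-to-trial variability in `z`
#'   (group-level parameter); `z +- sz/2` must stay inside (0, 1).
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 2.7, a = 1.7, t = 0.26)
#' @export
ddm_params <- function(v, a, t, z = 0.5, sz = 0) {
  stopifnot(is.numeric(v), length(v) == 1L)
  if (a <= 0) stop("decision threshold 'a' must be > 0")
  if (t < 0) stop("non-decision time 't' must be >= 0")
  if (z <= 0 || z >= 1) stop("starting point 'z' must be in (0, 1)")
  if (sz < 0) stop("'sz' must be >= 0")
  if (sz > 0 && (z - sz / 2 <= 0 || z + sz / 2 >= 1))
    stop("'z +- sz/2' must lie inside (0, 1)")
  structure(list(v = v, a = a, t = t, z = z, sz = sz, s = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("ddm_params: v = %.4g, a = %.4g, t = %.4g, z = %.4g, sz = %.4g\n",
              x$v, x$a, x$t, x$z, x$sz))
  invisible(x)
}

#' Wiener first-passage-time log density
#'
#' Log density of the response time at the upper or lower boundary for a
#' diffusion with parameters `params`.  Series evaluation switches between
#' the small-time and large-time expansions by the standard truncation-count
#' criterion; when `sz > 0` the density is averaged over the uniform
#' starting-point range by fixed-node Gauss-Legendre quadrature.
#'
#' @param rt response time(s) in seconds (including non-decision time).
#' @param boundary `"upper"` or `"lower"`.
#' @param params a [ddm_params()] object.
#' @param tol series truncation tolerance.
#' @param nodes quadrature nodes for the `sz` average.
#' @return Log density, vectorized over `rt`; `-Inf` where `rt <= t`.
#' @export
wfpt_log_density <- function(rt, boundary = c("upper", "lower"), params,
                             tol = 1e-10, nodes = 11L) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"), tol > 0)
  wfpt_logdensity_cpp(as.numeric(rt),
                      rep.int(as.integer(boundary == "upper"), length(rt)),
                      params$v, params$a, params$t, params$z, params$sz,
                      tol, as.integer(nodes))
}

#' Simulate diffusion trials
#'
#' Euler-Maruyama simulation of go trials under stimulus coding: the
#' effective drift is `+v` for rightward stimuli and `-v` for leftward ones;
#' absorption at the upper boundary is a rightward response (coded 1),
#' absorption at the lower boundary a leftward response (coded 0).  Used as
#' the brute-force oracle for the analytic density and for posterior
#' predictive checks.
#'
#' @param params a [ddm_params()] object.
#' @param side character vector of stimulus sides (`"left"`/`"right"`); its
#'   length is the number of trials.
#' @param dt Euler step in seconds.
#' @param tmax cap on decision time (safety only).
#' @return data.frame with columns `side`, `response` (0/1), `rt` (s), and
#'   `correct` (response matches side).
#' @export
sample_trial <- function(params, side, dt = 1e-4, tmax = 30) {
  stopifnot(inherits(params, "ddm_params"), all(side %in% c("left", "right")))
  drift <- ifelse(side == "right", params$v, -params$v)
  m <- ddm_simulate_cpp(drift, params$a, params$t, params$z, params$sz, dt, tmax)
  data.frame(side = side, response = as.integer(m[, 1]), rt = m[, 2],
             correct = as.integer(m[, 1]) == as.integer(side == "right"),
             stringsAsFactors = FALSE)
}

#' Closed-form summary-statistic expectations of the unbiased diffusion
#'
#' Expected proportion correct, mean correct RT and RT variance for a
#' diffusion with `z = 0.5` and `sz = 0` (the forward map inverted by
#' [ez_fit()]).  Continuous limits are used at `v = 0`.
#'
#' @param v,a,t drift, threshold, non-decision time.
#' @param s diffusion scale (default 1).
#' @return list with `Pc`, `MRT`, `VRT`.
#' @export
ddm_moments <- function(v, a, t, s = 1) {
  stopifnot(a > 0, s > 0)
  c1 <- a * v / s^2
  y <- exp(-c1)
  Pc <- 1 / (1 + y)
  if (abs(c1) < 2e-3) {
    # series around v = 0: the closed forms suffer catastrophic
    # cancellation (numerators are O(c^3) differences of O(1) terms)
    MDT <- a^2 / (4 * s^2) * (1 - c1^2 / 12)
    VRT <- (a^4 / (2 * s^4)) * (1 - c1 + 0.55 * c1^2) / (3 * (1 + y)^2)
  } else {
    MDT <- (a / (2 * v)) * (1 - y) / (1 + y)
    VRT <- (a * s^2 / (2 * v^3)) * (1 - 2 * c1 * y - y^2) / (1 + y)^2
  }
  list(Pc = Pc, MRT = t + MDT, VRT = VRT)
}

#' Per-session summary statistics for EZ estimation
#'
#' @param trials data.frame of one session with columns `rt` and `correct`
#'   (or `response` and `side` from which correctness is derived).
#' @return list with `Pc`, `MRT`, `VRT` (moments of correct-response RTs)
#'   and `n`.
#' @export
summary_stats <- function(trials) {
  if (is.null(trials$correct))
    trials$correct <- trials$response == as.integer(trials$side == "right")
  n <- nrow(trials)
  stopifnot(n >= 1)
  crt <- trials$rt[as.logical(trials$correct)]
  list(Pc = mean(trials$correct), MRT = mean(crt),
       VRT = if (length(crt) > 1) var(crt) else 0, n = n)
}

#' EZ-diffusion closed-form estimator
#'
#' Inverts [ddm_moments()]: maps accuracy, mean correct RT and RT variance to
#' `(v, a, t)` under an unbiased diffusion.  Edge corrections: `Pc = 1` is
#' replaced by `1 - 1/(2n)` and `Pc = 0.5` by `0.5 + 1/(2n)` before
#' inversion.
#'
#' @param stats list with `Pc`, `MRT`, `VRT`, `n` (e.g. from
#'   [summary_stats()]).
#' @param s diffusion scale (default 1).
#' @return list with elements `v`, `a`, `t`.
#' @export
ez_fit <- function(stats, s = 1) {
  Pc <- stats$Pc; MRT <- stats$MRT; VRT <- stats$VRT; n <- stats$n
  if (is.null(n)) n <- 300L
  if (!is.finite(VRT) || VRT <= 0) stop("RT variance must be positive")
  if (Pc < 0.5) stop("below-chance session: Pc < 0.5 is not invertible")
  if (Pc == 1) Pc <- 1 - 1 / (2 * n)
  if (Pc == 0.5) Pc <- 0.5 + 1 / (2 * n)
  L <- qlogis(Pc)
  x <- L * (L * Pc^2 - L * Pc + Pc - 0.5) / VRT
  v <- sign(Pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  MDT <- (a / (2 * v)) * (1 - y) / (1 + y)
  list(v = v, a = a, t = MRT - MDT)
}

#' Session log likelihood under the stimulus-coded diffusion
#'
#' Sum of per-trial Wiener first-passage log densities: trial drift is
#' `+v`/`-v` by stimulus side, upper boundary is the rightward response.
#'
#' @param trials data.frame with columns `side`, `response`, `rt` (seconds,
#'   fast guesses already removed).
#' @param params a [ddm_params()] object.
#' @param tol series tolerance.
#' @param nodes quadrature nodes for `sz`.
#' @return Scalar log likelihood (0 for an empty session; `-Inf` if any
#'   `rt <= t`).
#' @export
session_loglik <- function(trials, params, tol = 1e-10, nodes = 11L) {
  stopifnot(inherits(params, "ddm_params"))
  if (nrow(trials) == 0L) return(0)
  wfpt_loglik_cpp(as.numeric(trials$rt), as.integer(trials$response),
                  ifelse(trials$side == "right", 1, -1),
                  params$v, params$a, params$t, params$z, params$sz,
                  tol, as.integer(nodes))
}
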