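#' Diffusion model parameters for one participant
#'
#' Constructs and validates the parameter set of the two-boundary Wiener
#' diffusion process used throughout the package: boundary separation `a`,
#' starting point `z` (evidence units, `0 < z < a`), non-decision time `ter`
#' (seconds), one drift-rate per difficulty level (`v1` = easy, `v2` =
#' difficult, evidence/s), and the within-trial noise `s`, fixed at 0.1 by
#' convention to resolve the scaling degeneracy of the model.
#'
#' @param a boundary separation, `> 0`.
#' @param z starting point in evidence units, `0 < z < a`.
#' @param ter non-decision time in seconds, `>= 0`.
#' @param v1,v2 drift-rates for the easy and difficult levels.
#' @param s within-trial noise standard deviation, `> 0`.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(a = 0.1, z = 0.05, ter = 0.3, v1 = 0.35, v2 = 0.25)
#' @export
ddm_params <- function(a, z, ter, v1, v2, s = 0.1) {
  stopifnot(is.numeric(a), is.numeric(z), is.numeric(ter),
            is.numeric(v1), is.numeric(v2), is.numeric(s))
  if (!(a > 0)) stop("boundary separation 'a' must be positive", call. = FALSE)
  if (!(z > 0 && z < a)) stop("starting point 'z' must lie in (0, a)", call. = FALSE)
  if (ter < 0) stop("non-decision time 'ter' must be non-negative", call. = FALSE)
  if (!(s > 0)) stop("noise 's' must be positive", call. = FALSE)
  structure(list(a = a, z = z, ter = ter, v1 = v1, v2 = v2, s = s),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Wiener diffusion parameters\n")
  cat(sprintf("  a = %.4g, z = %.4g (z/a = %.3f), ter = %.4g s\n",
              x$a, x$z, x$z / x$a, x$ter))
  cat(sprintf("  v1 (easy) = %.4g, v2 (difficult) = %.4g, s = %.3g\n",
              x$v1, x$v2, x$s))
  invisible(x)
}

drift_of <- function(p, v) if (is.null(v)) p$v1 else v

#' Wiener first-passage-time density
#'
#' Density (in 1/s) of a response at the given bound at total time `t`
#' (decision time plus non-decision time). Evaluated by the standard
#' small-time / large-time series with automatic switching; the truncation
#' error is below `err`. Returns 0 for `t <= ter`.
#'
#' @param t vector of total response times in seconds.
#' @param p a [ddm_params] object.
#' @param bound `"upper"` or `"lower"`.
#' @param v drift-rate to use; defaults to `p$v1`.
#' @param err absolute truncation tolerance of the series.
#' @return Vector of densities.
#' @export
wfpt_density <- function(t, p, bound = c("upper", "lower"), v = NULL,
                         err = 1e-7) {
  bound <- match.arg(bound)
  stopifnot(inherits(p, "ddm_params"))
  .wfpt_pdf_cpp(as.numeric(t), p$a, p$z / p$a, p$ter, drift_of(p, v), p$s,
                bound == "upper", err)
}

#' Defective cumulative distribution function
#'
#' Probability of a response at the given bound at or before total time `t`.
#' The limit as `t` grows is the absorption probability of that bound, so the
#' two bounds' limits sum to one.
#'
#' @inheritParams wfpt_density
#' @return Vector of probabilities.
#' @export
defective_cdf <- function(t, p, bound = c("upper", "lower"), v = NULL,
                          err = 1e-7) {
  bound <- match.arg(bound)
  stopifnot(inherits(p, "ddm_params"))
  .wfpt_cdf_cpp(as.numeric(t), p$a, p$z / p$a, p$ter, drift_of(p, v), p$s,
                bound == "upper", err)
}

#' Survivor function at a response deadline
#'
#' Probability that neither bound has been reached by `deadline`; this is the
#' likelihood contribution of a timeout (no-response) trial, modelled as a
#' non-terminating accumulation trajectory.
#'
#' @param deadline total time in seconds.
#' @inheritParams wfpt_density
#' @return A probability.
#' @export
survivor <- function(deadline, p, v = NULL, err = 1e-7) {
  stopifnot(inherits(p, "ddm_params"), length(deadline) == 1L)
  if (deadline <= p$ter) return(1)
  .wfpt_survivor_cpp(deadline, p$a, p$z / p$a, p$ter, drift_of(p, v), p$s, err)
}

#' Absorption probability at a bound
#'
#' Closed-form probability of ever reaching the given bound. At zero drift
#' the upper-bound probability is exactly `z/a`.
#'
#' @inheritParams wfpt_density
#' @return A probability.
#' @export
absorption_prob <- function(p, bound = c("upper", "lower"), v = NULL) {
  bound <- match.arg(bound)
  stopifnot(inherits(p, "ddm_params"))
  v <- drift_of(p, v)
  zr <- p$z / p$a
  vs <- v / p$s
  as <- p$a / p$s
  pu <- if (abs(vs) < 1e-10) zr else expm1(-2 * vs * as * zr) / expm1(-2 * vs * as)
  if (bound == "upper") pu else 1 - pu
}

#' Simulate diffusion trials
#'
#' Draws `(response, rt)` pairs from the diffusion process. The default
#' method inverts the defective CDFs (exact up to series truncation). The
#' `"euler"` method integrates the stochastic differential equation with a
#' Brownian-bridge correction for within-step boundary crossings and serves
#' as an independent route for validation. Decision times exceeding the
#' deadline are returned as censored (`response = NA`, `rt = NA`).
#'
#' Randomness comes from R's RNG, so `set.seed()` gives bit-exact
#' reproducibility.
#'
#' @param n number of trials.
#' @param p a [ddm_params] object.
#' @param v drift-rate; defaults to `p$v1`.
#' @param deadline response deadline in seconds.
#' @param method `"inverse"` (default) or `"euler"`.
#' @param dt Euler step size in seconds (only for `method = "euler"`).
#' @param err series truncation tolerance (only for `method = "inverse"`).
#' @return A data.frame with columns `rt` and `response`
#'   (`"upper"`/`"lower"`/`NA`).
#' @export
simulate_trials <- function(n, p, v = NULL, deadline = 2.5,
                            method = c("inverse", "euler"), dt = 1e-3,
                            err = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(p, "ddm_params"), n >= 0)
  v <- drift_of(p, v)
  out <- if (method == "inverse") {
    .wfpt_sim_inverse_cpp(as.integer(n), p$a, p$z / p$a, p$ter, v, p$s,
                          deadline, err)
  } else {
    .wfpt_sim_euler_cpp(as.integer(n), p$a, p$z / p$a, p$ter, v, p$s,
                        deadline, dt)
  }
  data.frame(rt = out$rt,
             response = c("lower", "upper")[out$response + 1L],
             stringsAsFactors = FALSE)
}

# Encode a participant's filtered trials for the C++ likelihood.
# Stimulus coding (default): upper bound = rightward response, drift sign
# set by the true stimulus direction. Accuracy coding: upper = correct.
encode_trials <- function(trials, coding = c("stimulus", "accuracy")) {
  coding <- match.arg(coding)
  keep <- !trials$excluded & trials$difficulty != "catch"
  tr <- trials[keep, , drop = FALSE]
  level <- ifelse(tr$difficulty == "easy", 1L, 2L)
  cens <- as.integer(tr$censored)
  if (coding == "stimulus") {
    vsign <- ifelse(tr$direction == "right", 1L, -1L)
    bound <- ifelse(tr$response == "right", 1L, 0L)
  } else {
    vsign <- rep(1L, nrow(tr))
    bound <- as.integer(tr$response == tr$direction)
  }
  bound[cens == 1L] <- 0L
  rt <- tr$rt
  rt[cens == 1L] <- 0
  if (any(rt < 0, na.rm = TRUE)) stop("negative RT in trial table", call. = FALSE)
  list(rt = as.numeric(rt), bound = bound, vsign = vsign,
       level = level, cens = cens)
}

#' Log-likelihood of one participant's trials
#'
#' Sum of log first-passage densities for responded trials plus the log
#' survivor function at the deadline for censored (no-response) trials.
#' Trials flagged `excluded` and catch trials contribute nothing. Any
#' responded RT at or below `ter` yields `-Inf` (the sampler then rejects)
#' rather than an error.
#'
#' @param trials rows of a trial table for one participant (see
#'   [filter_trials()] for the expected columns).
#' @param p a [ddm_params] object.
#' @param deadline response deadline in seconds.
#' @param coding `"stimulus"` (upper bound = rightward response, drift sign
#'   from the true stimulus direction; the starting point is a left/right
#'   response bias) or `"accuracy"` (upper bound = correct response).
#' @param err series truncation tolerance.
#' @return A single log-likelihood value.
#' @export
loglik_participant <- function(trials, p, deadline = 2.5,
                               coding = c("stimulus", "accuracy"),
                               err = 1e-7) {
  stopifnot(inherits(p, "ddm_params"))
  enc <- encode_trials(trials, coding)
  if (length(enc$rt) == 0L) return(0)
  .wfpt_loglik_cpp(enc$rt, enc$bound, enc$vsign, enc$level, enc$cens,
                   p$a, p$z / p$a, p$ter, p$v1, p$v2, p$s, deadline, err)
}
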