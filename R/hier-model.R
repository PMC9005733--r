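#' Convert between drift moments and per-level drifts
#'
#' The hierarchy places normal laws on the across-level drift average
#' `(v1 + v2)/2` and difference `v1 - v2` rather than on the drifts
#' themselves. Level 1 is the easy level, so a positive difference means
#' faster accumulation when the stimulus is easier. The two maps are exact
#' inverses.
#'
#' @param v.mean,v.diff drift average and difference.
#' @param v1,v2 per-level drifts (1 = easy, 2 = difficult).
#' @return A list with components `v1`,`v2` (or `v.mean`,`v.diff`).
#' @examples
#' drifts_from_moments(0.3, 0.1)  # v1 = 0.35, v2 = 0.25
#' @export
drifts_from_moments <- function(v.mean, v.diff) {
  list(v1 = v.mean + v.diff / 2, v2 = v.mean - v.diff / 2)
}

#' @rdname drifts_from_moments
#' @export
moments_from_drifts <- function(v1, v2) {
  list(v.mean = (v1 + v2) / 2, v.diff = v1 - v2)
}

# parameter bookkeeping ------------------------------------------------------

PARAMS <- c("a", "z", "ter", "v.diff", "v.mean")

#' Names of the group-level (hyper) parameters
#'
#' Location `mu`, spread `sigma` and half group difference `delta` for each
#' of the five model parameters, plus one regression weight `beta` per
#' (covariate x parameter) when covariates are partialled out.
#'
#' @param covariates optional character vector of covariate names.
#' @return Character vector of hyper-parameter names.
#' @export
hyper_names <- function(covariates = NULL) {
  nm <- c(paste0("mu.", PARAMS), paste0("sigma.", PARAMS),
          paste0("delta.", PARAMS))
  for (cv in covariates) nm <- c(nm, paste0("beta.", cv, ".", PARAMS))
  nm
}

# log density of a normal truncated to (lo, hi), normalising constant included
dtnorm_log <- function(x, mean, sd, lo = -Inf, hi = Inf) {
  out <- dnorm(x, mean, sd, log = TRUE) -
    log(pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
  out[x <= lo | x >= hi] <- -Inf
  out
}

#' Log density of the hyperpriors
#'
#' `mu_a ~ N+(0.2, 0.2)`, `mu_z ~ TN(0,1)(0.5, 0.2)`,
#' `mu_ter ~ N+(0.3, 0.3)`, `mu_v.diff ~ N(0, 0.1)`,
#' `mu_v.mean ~ N(0.3, 0.3)`, every `sigma ~ Gamma(1, 1)` (shape-rate),
#' every `delta ~ N(0, 0.01)`, and every covariate weight
#' `beta ~ N(0, 0.5)`. Second arguments of normals are standard deviations.
#'
#' @param hyper named numeric vector (see [hyper_names()]).
#' @return Scalar log density, `-Inf` off-support.
#' @export
hyper_prior_lp <- function(hyper) {
  mu <- hyper[paste0("mu.", PARAMS)]
  sg <- hyper[paste0("sigma.", PARAMS)]
  de <- hyper[paste0("delta.", PARAMS)]
  if (any(sg <= 0)) return(-Inf)
  lp <- dtnorm_log(mu[["mu.a"]], 0.2, 0.2, lo = 0) +
    dtnorm_log(mu[["mu.z"]], 0.5, 0.2, lo = 0, hi = 1) +
    dtnorm_log(mu[["mu.ter"]], 0.3, 0.3, lo = 0) +
    dnorm(mu[["mu.v.diff"]], 0, 0.1, log = TRUE) +
    dnorm(mu[["mu.v.mean"]], 0.3, 0.3, log = TRUE) +
    sum(dgamma(sg, shape = 1, rate = 1, log = TRUE)) +
    sum(dnorm(de, 0, 0.01, log = TRUE))
  betas <- grep("^beta\\.", names(hyper))
  if (length(betas)) lp <- lp + sum(dnorm(hyper[betas], 0, 0.5, log = TRUE))
  if (!is.finite(lp)) return(-Inf)
  lp
}

# group-level means for each participant: mu +/- delta + beta . x
participant_means <- function(hyper, sgn, covariates = NULL) {
  P <- length(sgn)
  m <- matrix(NA_real_, P, 5, dimnames = list(NULL, PARAMS))
  for (j in PARAMS)
    m[, j] <- hyper[[paste0("mu.", j)]] + sgn * hyper[[paste0("delta.", j)]]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    for (cv in colnames(covariates))
      for (j in PARAMS)
        m[, j] <- m[, j] + hyper[[paste0("beta.", cv, ".", j)]] * covariates[, cv]
  }
  m
}

#' Per-participant log prior under the group distributions
#'
#' `a ~ N+`, `z/a ~ TN(0,1)`, `ter ~ N+` (all with their truncation
#' normalising constants), and normal laws for the drift difference and
#' average, with group means `mu + delta` (autistic) or `mu - delta`
#' (comparison), optionally shifted by covariate terms.
#'
#' @param hyper named hyper-parameter vector.
#' @param pmat matrix `P x 5` with columns `a`, `z` (relative start),
#'   `ter`, `v.diff`, `v.mean`.
#' @param sgn `+1` per autistic-labelled participant, `-1` per comparison
#'   participant.
#' @param covariates optional `P x ncov` matrix of standardised covariates
#'   (mean 0, sd 1), with column names matching the `beta` entries of
#'   `hyper`.
#' @return Vector of `P` log densities (`-Inf` off-support).
#' @export
participant_prior_lp <- function(hyper, pmat, sgn, covariates = NULL) {
  sg <- hyper[paste0("sigma.", PARAMS)]
  if (any(sg <= 0)) return(rep(-Inf, nrow(pmat)))
  m <- participant_means(hyper, sgn, covariates)
  dtnorm_log(pmat[, 1], m[, "a"], sg[["sigma.a"]], lo = 0) +
    dtnorm_log(pmat[, 2], m[, "z"], sg[["sigma.z"]], lo = 0, hi = 1) +
    dtnorm_log(pmat[, 3], m[, "ter"], sg[["sigma.ter"]], lo = 0) +
    dnorm(pmat[, 4], m[, "v.diff"], sg[["sigma.v.diff"]], log = TRUE) +
    dnorm(pmat[, 5], m[, "v.mean"], sg[["sigma.v.mean"]], log = TRUE)
}

#' Joint log prior of the hierarchical model
#'
#' Hyperprior terms plus the sum of participant-level terms.
#'
#' @inheritParams participant_prior_lp
#' @return Scalar log density.
#' @export
log_prior <- function(hyper, pmat, sgn, covariates = NULL) {
  h <- hyper_prior_lp(hyper)
  if (!is.finite(h)) return(-Inf)
  pp <- participant_prior_lp(hyper, pmat, sgn, covariates)
  out <- h + sum(pp)
  if (!is.finite(out)) return(-Inf)
  out
}

# pack a filtered trial table into concatenated C++ likelihood inputs
pack_trials <- function(trials, participants, coding = "stimulus") {
  encs <- lapply(participants, function(pid) {
    encode_trials(trials[trials$participant == pid, , drop = FALSE], coding)
  })
  list(rt = unlist(lapply(encs, `[[`, "rt"), use.names = FALSE),
       bound = unlist(lapply(encs, `[[`, "bound"), use.names = FALSE),
       vsign = unlist(lapply(encs, `[[`, "vsign"), use.names = FALSE),
       level = unlist(lapply(encs, `[[`, "level"), use.names = FALSE),
       cens = unlist(lapply(encs, `[[`, "cens"), use.names = FALSE),
       offset = c(0L, cumsum(vapply(encs, function(e) length(e$rt), 1L))))
}

# likelihood vector for all participants given pmat (a, zr, ter, vdiff, vmean)
packed_loglik <- function(packed, pmat, s = 0.1, deadline = 2.5, err = 1e-7) {
  vv <- drifts_from_moments(pmat[, 5], pmat[, 4])
  par5 <- cbind(pmat[, 1], pmat[, 2], pmat[, 3], vv$v1, vv$v2)
  .wfpt_loglik_many_cpp(packed$rt, packed$bound, packed$vsign, packed$level,
                        packed$cens, packed$offset, par5, s, deadline, err)
}

#' Log posterior of the hierarchical model
#'
#' `log_prior` plus the summed per-participant diffusion log-likelihood.
#' With zero trials this reduces to the log prior; with all covariate
#' weights zero it coincides with the covariate-free model.
#'
#' @inheritParams log_prior
#' @param trials a filtered trial table (see [filter_trials()]); rows are
#'   matched to participants via the `participant` column, ordered as
#'   `participants`.
#' @param participants character vector of participant ids corresponding to
#'   the rows of `pmat`.
#' @param s within-trial noise.
#' @param deadline response deadline, seconds.
#' @param coding response coding, `"stimulus"` or `"accuracy"`.
#' @return Scalar log density.
#' @export
log_posterior <- function(hyper, pmat, sgn, trials, participants,
                          covariates = NULL, s = 0.1, deadline = 2.5,
                          coding = "stimulus") {
  lp <- log_prior(hyper, pmat, sgn, covariates)
  if (!is.finite(lp)) return(-Inf)
  if (is.null(trials) || nrow(trials) == 0L) return(lp)
  packed <- pack_trials(trials, participants, coding)
  ll <- sum(packed_loglik(packed, pmat, s = s, deadline = deadline))
  out <- lp + ll
  if (!is.finite(out)) return(-Inf)
  out
}

#' Standardise covariates for partialling
#'
#' Centres and scales each covariate to mean 0, SD 1 (the scale on which
#' the regression weights' `N(0, 0.5)` prior is placed).
#'
#' @param x data.frame or matrix of per-participant covariate values.
#' @return Numeric matrix of standardised covariates.
#' @export
standardise_covariates <- function(x) {
  x <- as.matrix(x)
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out[, , drop = FALSE]
}

# draw initial values from the priors (used for sampler initialisation)
draw_hyper_init <- function(covariates = NULL) {
  h <- c(rtnorm(1, 0.2, 0.2, lo = 0), rtnorm(1, 0.5, 0.2, lo = 0, hi = 1),
         rtnorm(1, 0.3, 0.3, lo = 0), rnorm(1, 0, 0.1), rnorm(1, 0.3, 0.3),
         rgamma(5, 1, 1), rnorm(5, 0, 0.01))
  nm <- hyper_names(covariates)
  if (!is.null(covariates))
    h <- c(h, rnorm(5 * length(covariates), 0, 0.5))
  names(h) <- nm
  h
}

draw_participant_init <- function(hyper, sgn, covariates = NULL) {
  P <- length(sgn)
  m <- participant_means(hyper, sgn, covariates)
  sg <- hyper[paste0("sigma.", PARAMS)]
  cbind(a = rtnorm(P, m[, "a"], sg[["sigma.a"]], lo = 0),
        z = rtnorm(P, m[, "z"], sg[["sigma.z"]], lo = 0, hi = 1),
        ter = rtnorm(P, m[, "ter"], sg[["sigma.ter"]], lo = 0),
        v.diff = rnorm(P, m[, "v.diff"], sg[["sigma.v.diff"]]),
        v.mean = rnorm(P, m[, "v.mean"], sg[["sigma.v.mean"]]))
}
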