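# bivariate normal log density; |rho| >= 1 (non-positive-definite) -> -Inf
lbvn <- function(x, y, mx, my, sx, sy, rho) {
  if (any(sx <= 0) || any(sy <= 0) || any(abs(rho) >= 1))
    return(rep(-Inf, length(x)))
  zx <- (x - mx) / sx
  zy <- (y - my) / sy
  q <- (zx^2 - 2 * rho * zx * zy + zy^2) / (1 - rho^2)
  -log(2 * pi * sx * sy * sqrt(1 - rho^2)) - q / 2
}

#' Collapse per-difficulty EEG slopes to mean and difference
#'
#' @param slopes data.frame `participant`, `difficulty`
#'   (`easy`/`difficult`), `slope`.
#' @return Data.frame `participant`, `eeg.mean` (average across levels),
#'   `eeg.diff` (easy minus difficult, matching the drift convention).
#' @export
slope_moments <- function(slopes) {
  ids <- unique(slopes$participant)
  e1 <- slopes$slope[match(paste(ids, "easy"),
                           paste(slopes$participant, slopes$difficulty))]
  e2 <- slopes$slope[match(paste(ids, "difficult"),
                           paste(slopes$participant, slopes$difficulty))]
  data.frame(participant = ids, eeg.mean = (e1 + e2) / 2,
             eeg.diff = e1 - e2, stringsAsFactors = FALSE)
}

eeg_hyper_names <- function(rho_by_group, covariates = NULL) {
  rho <- if (rho_by_group)
    c("rho.mean.comparison", "rho.mean.autistic",
      "rho.diff.comparison", "rho.diff.autistic")
  else c("rho.mean", "rho.diff")
  c(hyper_names(covariates),
    "mu.EEG.diff", "mu.EEG.mean", "sigma.EEG.diff", "sigma.EEG.mean",
    "delta.EEG.diff", "delta.EEG.mean", rho)
}

eeg_hyper_prior_lp <- function(hyper) {
  base <- hyper_prior_lp(hyper)
  if (!is.finite(base)) return(-Inf)
  sgE <- hyper[c("sigma.EEG.diff", "sigma.EEG.mean")]
  if (any(sgE <= 0)) return(-Inf)
  rho <- hyper[grep("^rho\\.", names(hyper))]
  if (any(abs(rho) >= 1)) return(-Inf)
  out <- base +
    dnorm(hyper[["mu.EEG.diff"]], 0, 0.5, log = TRUE) +
    dnorm(hyper[["mu.EEG.mean"]], 0, 1, log = TRUE) +
    sum(dgamma(sgE, 1, 1, log = TRUE)) +
    sum(dnorm(hyper[c("delta.EEG.diff", "delta.EEG.mean")], 0, 0.01,
              log = TRUE)) +
    length(rho) * dunif(0, -1, 1, log = TRUE)
  if (!is.finite(out)) return(-Inf)
  out
}

# participant-level prior for the EEG joint model: drift terms become
# bivariate with the slope measure; participants without EEG keep the
# univariate (marginal) drift terms
eeg_participant_prior_lp <- function(hyper, pmat, sgn, eeg, covariates = NULL) {
  sg <- hyper[paste0("sigma.", PARAMS)]
  if (any(sg <= 0)) return(rep(-Inf, nrow(pmat)))
  m <- participant_means(hyper, sgn, covariates)
  base <- dtnorm_log(pmat[, 1], m[, "a"], sg[["sigma.a"]], lo = 0) +
    dtnorm_log(pmat[, 2], m[, "z"], sg[["sigma.z"]], lo = 0, hi = 1) +
    dtnorm_log(pmat[, 3], m[, "ter"], sg[["sigma.ter"]], lo = 0)
  mEd <- hyper[["mu.EEG.diff"]] + sgn * hyper[["delta.EEG.diff"]]
  mEm <- hyper[["mu.EEG.mean"]] + sgn * hyper[["delta.EEG.mean"]]
  if ("rho.mean" %in% names(hyper)) {
    rho_m <- rep(hyper[["rho.mean"]], nrow(pmat))
    rho_d <- rep(hyper[["rho.diff"]], nrow(pmat))
  } else {
    rho_m <- ifelse(sgn > 0, hyper[["rho.mean.autistic"]],
                    hyper[["rho.mean.comparison"]])
    rho_d <- ifelse(sgn > 0, hyper[["rho.diff.autistic"]],
                    hyper[["rho.diff.comparison"]])
  }
  has <- !is.na(eeg[, "eeg.mean"]) & !is.na(eeg[, "eeg.diff"])
  drift <- numeric(nrow(pmat))
  if (any(has)) {
    drift[has] <-
      lbvn_safe(pmat[has, 4], eeg[has, "eeg.diff"], m[has, "v.diff"],
                mEd[has], sg[["sigma.v.diff"]], hyper[["sigma.EEG.diff"]],
                rho_d[has]) +
      lbvn_safe(pmat[has, 5], eeg[has, "eeg.mean"], m[has, "v.mean"],
                mEm[has], sg[["sigma.v.mean"]], hyper[["sigma.EEG.mean"]],
                rho_m[has])
  }
  if (any(!has)) {
    drift[!has] <-
      dnorm(pmat[!has, 4], m[!has, "v.diff"], sg[["sigma.v.diff"]],
            log = TRUE) +
      dnorm(pmat[!has, 5], m[!has, "v.mean"], sg[["sigma.v.mean"]],
            log = TRUE)
  }
  base + drift
}

# elementwise-rho variant of lbvn
lbvn_safe <- function(x, y, mx, my, sx, sy, rho) {
  out <- rep(-Inf, length(x))
  ok <- abs(rho) < 1 & sx > 0 & sy > 0
  if (any(ok)) {
    zx <- (x[ok] - mx[ok]) / sx
    zy <- (y[ok] - my[ok]) / sy
    r <- rho[ok]
    q <- (zx^2 - 2 * r * zx * zy + zy^2) / (1 - r^2)
    out[ok] <- -log(2 * pi * sx * sy * sqrt(1 - r^2)) - q / 2
  }
  out
}

#' Log posterior of the EEG joint model
#'
#' The hierarchical posterior with the two drift terms replaced by
#' bivariate normals linking the drift difference to the slope difference
#' and the drift average to the slope average, with a uniform prior on each
#' correlation. Participants lacking EEG contribute the marginal univariate
#' drift terms. With all correlations zero the joint density factorises
#' into the base posterior plus independent normal EEG terms.
#'
#' @param hyper extended hyper vector (see `eeg_hyper_names`).
#' @param pmat,sgn,trials,participants,covariates as in [log_posterior()].
#' @param eeg matrix with columns `eeg.mean`, `eeg.diff`, one row per
#'   participant (NA = no EEG).
#' @inheritParams log_posterior
#' @return Scalar log density.
#' @export
joint_log_posterior_eeg <- function(hyper, pmat, sgn, trials, participants,
                                    eeg, covariates = NULL, s = 0.1,
                                    deadline = 2.5, coding = "stimulus") {
  h <- eeg_hyper_prior_lp(hyper)
  if (!is.finite(h)) return(-Inf)
  pp <- eeg_participant_prior_lp(hyper, pmat, sgn, eeg, covariates)
  lp <- h + sum(pp)
  if (!is.finite(lp)) return(-Inf)
  if (!is.null(trials) && nrow(trials) > 0) {
    packed <- pack_trials(trials, participants, coding)
    lp <- lp + sum(packed_loglik(packed, pmat, s = s, deadline = deadline))
  }
  if (!is.finite(lp)) return(-Inf)
  lp
}

adhd_hyper_names <- function(subscale, rho_by_group, covariates = NULL) {
  rho <- if (rho_by_group) c("rho.comparison", "rho.autistic") else "rho"
  c(hyper_names(covariates),
    paste0(c("mu.", "sigma.", "delta."), subscale), rho)
}

adhd_hyper_prior_lp <- function(hyper, subscale) {
  base <- hyper_prior_lp(hyper)
  if (!is.finite(base)) return(-Inf)
  sgS <- hyper[[paste0("sigma.", subscale)]]
  if (sgS <= 0) return(-Inf)
  rho <- hyper[grep("^rho", names(hyper))]
  if (any(abs(rho) >= 1)) return(-Inf)
  out <- base +
    dnorm(hyper[[paste0("mu.", subscale)]], 0.5, 0.2, log = TRUE) +
    dgamma(sgS, 1, 1, log = TRUE) +
    dnorm(hyper[[paste0("delta.", subscale)]], 0, 0.01, log = TRUE) +
    length(rho) * dunif(0, -1, 1, log = TRUE)
  if (!is.finite(out)) return(-Inf)
  out
}

# participant prior for the ADHD joint model: the linked parameter's term
# becomes a bivariate normal with the subscale score. The bivariate term is
# the untruncated normal exactly as specified even for positive-support
# parameters; `truncate_support = TRUE` renormalises by the marginal mass
# of the linked parameter's support.
adhd_participant_prior_lp <- function(hyper, pmat, sgn, scores, subscale,
                                      link, covariates = NULL,
                                      truncate_support = FALSE) {
  sg <- hyper[paste0("sigma.", PARAMS)]
  if (any(sg <= 0)) return(rep(-Inf, nrow(pmat)))
  m <- participant_means(hyper, sgn, covariates)
  col <- match(link, PARAMS)
  terms <- list(
    a = function() dtnorm_log(pmat[, 1], m[, "a"], sg[["sigma.a"]], lo = 0),
    z = function() dtnorm_log(pmat[, 2], m[, "z"], sg[["sigma.z"]],
                              lo = 0, hi = 1),
    ter = function() dtnorm_log(pmat[, 3], m[, "ter"], sg[["sigma.ter"]],
                                lo = 0),
    v.diff = function() dnorm(pmat[, 4], m[, "v.diff"],
                              sg[["sigma.v.diff"]], log = TRUE),
    v.mean = function() dnorm(pmat[, 5], m[, "v.mean"],
                              sg[["sigma.v.mean"]], log = TRUE))
  lp <- numeric(nrow(pmat))
  for (j in PARAMS) if (j != link) lp <- lp + terms[[j]]()
  mS <- hyper[[paste0("mu.", subscale)]] +
    sgn * hyper[[paste0("delta.", subscale)]]
  sS <- hyper[[paste0("sigma.", subscale)]]
  rho <- if ("rho" %in% names(hyper)) rep(hyper[["rho"]], nrow(pmat))
         else ifelse(sgn > 0, hyper[["rho.autistic"]],
                     hyper[["rho.comparison"]])
  link_lp <- lbvn_safe(pmat[, col], scores, m[, link], mS,
                       sg[[paste0("sigma.", link)]], sS, rho)
  if (truncate_support && link %in% c("a", "ter")) {
    link_lp <- link_lp -
      pnorm(0, m[, link], sg[[paste0("sigma.", link)]],
            lower.tail = FALSE, log.p = TRUE)
    link_lp[pmat[, col] <= 0] <- -Inf
  }
  lp + link_lp
}

#' Log posterior of an ADHD joint model
#'
#' One diffusion parameter (`a`, `ter` or `v.mean`) is linked to one
#' questionnaire subscale through a bivariate normal whose correlation is
#' estimated (by default separately per group). The bivariate term is the
#' untruncated normal as specified; set `truncate_support = TRUE` for a
#' support-respecting variant.
#'
#' @param hyper extended hyper vector (see `adhd_hyper_names`).
#' @param scores numeric vector of subscale scores on the unit interval, one per
#'   participant.
#' @param subscale `"inatt"` or `"hyper"`.
#' @param link `"a"`, `"ter"` or `"v.mean"`.
#' @param truncate_support renormalise the linked positive-support
#'   parameter's term.
#' @inheritParams joint_log_posterior_eeg
#' @return Scalar log density.
#' @export
joint_log_posterior_adhd <- function(hyper, pmat, sgn, trials, participants,
                                     scores, subscale = "inatt",
                                     link = c("v.mean", "a", "ter"),
                                     covariates = NULL,
                                     truncate_support = FALSE, s = 0.1,
                                     deadline = 2.5, coding = "stimulus") {
  link <- match.arg(link)
  h <- adhd_hyper_prior_lp(hyper, subscale)
  if (!is.finite(h)) return(-Inf)
  pp <- adhd_participant_prior_lp(hyper, pmat, sgn, scores, subscale, link,
                                  covariates, truncate_support)
  lp <- h + sum(pp)
  if (!is.finite(lp)) return(-Inf)
  if (!is.null(trials) && nrow(trials) > 0) {
    packed <- pack_trials(trials, participants, coding)
    lp <- lp + sum(packed_loglik(packed, pmat, s = s, deadline = deadline))
  }
  if (!is.finite(lp)) return(-Inf)
  lp
}

joint_fit_engine <- function(trials, covariates, hyper_nm, prior_h_fn,
                             prior_p_fn_maker, extra_init_fn, chains,
                             iterations, burnin, migrate_every,
                             migrate_window, s, deadline, coding, seed,
                             err = 1e-7) {
  ids <- unique(trials$participant)
  P <- length(ids)
  grp <- trials$group[match(ids, trials$participant)]
  sgn <- ifelse(grp == "autistic", 1, -1)
  packed <- pack_trials(trials, ids, coding)
  xmat <- NULL
  cov_names <- NULL
  if (!is.null(covariates)) {
    xmat <- standardise_covariates(covariates)
    if (is.null(colnames(xmat)))
      colnames(xmat) <- paste0("x", seq_len(ncol(xmat)))
    cov_names <- colnames(xmat)
  }
  prior_p_fn <- prior_p_fn_maker(sgn, xmat)
  res <- run_hier_demcmc(
    prior_hyper_fn = prior_h_fn,
    prior_part_fn = prior_p_fn,
    lik_fn = function(th) packed_loglik(packed, th, s = s,
                                        deadline = deadline, err = err),
    hyper_init_fn = function() {
      h <- c(draw_hyper_init(cov_names), extra_init_fn())
      names(h) <- hyper_nm
      h
    },
    part_init_fn = function(h) draw_participant_init(h, sgn, xmat),
    P = P, ids = ids, chains = chains, iterations = iterations,
    burnin = burnin, migrate_every = migrate_every,
    migrate_window = migrate_window, seed = seed)
  res$groups <- grp
  res$sgn <- sgn
  res$deadline <- deadline
  res$s <- s
  res$coding <- coding
  class(res) <- c("joint_fit", "hddm_fit")
  res
}

#' Fit the EEG joint model
#'
#' DE-MCMC over the joint posterior of [joint_log_posterior_eeg()].
#' Defaults follow the study schedule for joint models: 15 chains, 3000
#' iterations, burn-in 1000, no migration.
#'
#' @param trials filtered trial table.
#' @param slopes data.frame `participant`, `difficulty`, `slope` (the EEG
#'   slope measure); participants absent from `slopes` are treated as
#'   having no EEG and enter through the behavioural marginals.
#' @param rho_by_group estimate the correlations separately per group
#'   (`TRUE`) or shared (`FALSE`, default: more precise posteriors).
#' @param covariates optional covariate data.frame (e.g. age) partialled
#'   out of every group-level mean.
#' @inheritParams fit_hddm
#' @return A `joint_fit` object.
#' @export
fit_joint_eeg <- function(trials, slopes, rho_by_group = FALSE,
                          covariates = NULL, chains = 15, iterations = 3000,
                          burnin = 1000, migrate_every = 0,
                          migrate_window = NULL, s = 0.1, deadline = 2.5,
                          coding = "stimulus", seed = 1L) {
  ids <- unique(trials$participant)
  sm <- slope_moments(slopes)
  eeg <- cbind(eeg.mean = sm$eeg.mean[match(ids, sm$participant)],
               eeg.diff = sm$eeg.diff[match(ids, sm$participant)])
  cov_names <- if (!is.null(covariates)) {
    cn <- colnames(as.matrix(covariates))
    if (is.null(cn)) paste0("x", seq_len(ncol(as.matrix(covariates)))) else cn
  } else NULL
  hyper_nm <- eeg_hyper_names(rho_by_group, cov_names)
  n_rho <- if (rho_by_group) 4L else 2L
  joint_fit_engine(
    trials, covariates, hyper_nm,
    prior_h_fn = eeg_hyper_prior_lp,
    prior_p_fn_maker = function(sgn, xmat)
      function(h, th) eeg_participant_prior_lp(h, th, sgn, eeg, xmat),
    extra_init_fn = function()
      c(rnorm(1, 0, 0.5), rnorm(1, 0, 1), rgamma(2, 1, 1),
        rnorm(2, 0, 0.01), runif(n_rho, -0.9, 0.9)),
    chains = chains, iterations = iterations, burnin = burnin,
    migrate_every = migrate_every, migrate_window = migrate_window,
    s = s, deadline = deadline, coding = coding, seed = seed)
}

#' Fit an ADHD joint model
#'
#' DE-MCMC over the joint posterior of [joint_log_posterior_adhd()], with
#' one model per (link parameter x subscale) and the correlation estimated
#' separately for each group by default.
#'
#' @param scores data.frame `participant`, plus a column named as
#'   `subscale`.
#' @param subscale `"inatt"` or `"hyper"`.
#' @param link `"v.mean"`, `"a"` or `"ter"`.
#' @param rho_by_group per-group correlations (default TRUE).
#' @param truncate_support support-respecting variant of the bivariate
#'   term.
#' @inheritParams fit_joint_eeg
#' @return A `joint_fit` object.
#' @export
fit_joint_adhd <- function(trials, scores, subscale = c("inatt", "hyper"),
                           link = c("v.mean", "a", "ter"),
                           rho_by_group = TRUE, truncate_support = FALSE,
                           covariates = NULL, chains = 15,
                           iterations = 3000, burnin = 1000,
                           migrate_every = 0, migrate_window = NULL,
                           s = 0.1, deadline = 2.5, coding = "stimulus",
                           seed = 1L) {
  subscale <- match.arg(subscale)
  link <- match.arg(link)
  ids <- unique(trials$participant)
  sc <- scores[[subscale]][match(ids, scores$participant)]
  if (anyNA(sc))
    stop("missing ", subscale, " score for some participants", call. = FALSE)
  cov_names <- if (!is.null(covariates)) {
    cn <- colnames(as.matrix(covariates))
    if (is.null(cn)) paste0("x", seq_len(ncol(as.matrix(covariates)))) else cn
  } else NULL
  hyper_nm <- adhd_hyper_names(subscale, rho_by_group, cov_names)
  n_rho <- if (rho_by_group) 2L else 1L
  joint_fit_engine(
    trials, covariates, hyper_nm,
    prior_h_fn = function(h) adhd_hyper_prior_lp(h, subscale),
    prior_p_fn_maker = function(sgn, xmat)
      function(h, th) adhd_participant_prior_lp(h, th, sgn, sc, subscale,
                                                link, xmat,
                                                truncate_support),
    extra_init_fn = function()
      c(rnorm(1, 0.5, 0.2), rgamma(1, 1, 1), rnorm(1, 0, 0.01),
        runif(n_rho, -0.9, 0.9)),
    chains = chains, iterations = iterations, burnin = burnin,
    migrate_every = migrate_every, migrate_window = migrate_window,
    s = s, deadline = deadline, coding = coding, seed = seed)
}
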