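#' Savage-Dickey Bayes factor for a point null
#'
#' For a parameter whose prior is continuous at the null value, the Bayes
#' factor in favour of the alternative is the ratio of prior to posterior
#' density at that value: `BF10 = p(0 | prior) / p(0 | posterior)`. The
#' posterior density is estimated from the draws with a Gaussian kernel
#' density estimate (Silverman bandwidth) by default; a normal
#' approximation (matching the posterior mean and SD) is available for
#' sensitivity analysis. Bayes factors above 3 are read as moderate
#' evidence for the alternative (a group difference), below 1/3 as moderate
#' evidence for the null, and anything between as anecdotal.
#'
#' @param draws numeric vector of post-burn-in posterior draws (>= 1000
#'   recommended).
#' @param prior_sd standard deviation of the zero-centred normal prior
#'   (0.01 for the group-difference parameters).
#' @param at null value (default 0).
#' @param method `"kde"` or `"normal"`.
#' @return A `bf_result` list: `bf10`, `prior_density`,
#'   `posterior_density`, `band`, `low_confidence` (TRUE when almost no
#'   draws fall near the null, making the density estimate unstable).
#' @export
savage_dickey <- function(draws, prior_sd, at = 0,
                          method = c("kde", "normal")) {
  method <- match.arg(method)
  stopifnot(is.numeric(draws), length(draws) >= 10, prior_sd > 0)
  prior0 <- dnorm(at, 0, prior_sd)
  if (method == "kde") {
    bw <- stats::bw.nrd0(draws)
    post0 <- mean(dnorm(at, draws, bw))
    near <- sum(abs(draws - at) < 2 * bw)
  } else {
    post0 <- dnorm(at, mean(draws), sd(draws))
    near <- sum(abs(draws - at) < 2 * sd(draws))
  }
  low_conf <- near < 10
  bf10 <- prior0 / post0
  structure(list(bf10 = bf10, prior_density = prior0,
                 posterior_density = post0, band = bf_band(bf10),
                 low_confidence = low_conf, method = method, at = at),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("Savage-Dickey BF10 = %.3g (%s)%s\n", x$bf10, x$band,
              if (x$low_confidence) " [low confidence: few draws near null]"
              else ""))
  invisible(x)
}

#' Interpretation band of a Bayes factor
#'
#' Pure function of BF10 with boundaries exactly 1/3 and 3:
#' `"moderate-null"` below 1/3, `"moderate-alt"` above 3, `"anecdotal"`
#' between.
#'
#' @param bf10 Bayes factor(s) in favour of the alternative.
#' @return Character vector of bands.
#' @export
bf_band <- function(bf10) {
  ifelse(bf10 < 1 / 3, "moderate-null",
         ifelse(bf10 > 3, "moderate-alt", "anecdotal"))
}

#' Posterior summary table
#'
#' Posterior mean, SD, central 95% credible interval (percentile method)
#' and Gelman-Rubin PSRF for every sampled parameter.
#'
#' @param fit an `hddm_fit` (or joint fit) object, or a 3-d array
#'   `chains x iterations x parameters` of post-burn-in samples.
#' @param pars optional subset of parameter names.
#' @return Data.frame with one row per parameter.
#' @export
summarise_fit <- function(fit, pars = NULL) {
  if (is.array(fit) && length(dim(fit)) == 3) {
    post <- fit
  } else {
    post <- fit$samples[, (fit$burnin + 1):dim(fit$samples)[2], ,
                        drop = FALSE]
  }
  nm <- dimnames(post)[[3]]
  if (is.null(nm)) nm <- paste0("par", seq_len(dim(post)[3]))
  if (!is.null(pars)) {
    keep <- match(pars, nm)
    if (anyNA(keep)) stop("unknown parameter(s)", call. = FALSE)
    post <- post[, , keep, drop = FALSE]
    nm <- nm[keep]
  }
  psrf <- gelman_rubin(post)
  flat <- apply(post, 3, as.vector)
  data.frame(parameter = nm,
             mean = colMeans(flat),
             sd = apply(flat, 2, sd),
             ci_lower = apply(flat, 2, quantile, 0.025),
             ci_upper = apply(flat, 2, quantile, 0.975),
             psrf = as.numeric(psrf),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior-predictive defective CDFs
#'
#' Model-fit check: for each group and difficulty level, trial sets of the
#' same size and composition as the data are simulated from posterior
#' draws, and the resulting defective cumulative distributions of correct
#' and error responses are evaluated on a time grid; the matching
#' empirical defective CDF of the data is overlaid. For each grid point
#' the band spans the 2.5-97.5 percentiles across draws, so it reflects
#' both posterior and trial-sampling uncertainty. The expected censored
#' mass under a draw is the average survivor function at the deadline.
#'
#' @param fit an `hddm_fit` object.
#' @param trials the filtered trial table the model was fit to.
#' @param n_draws number of posterior draws to evaluate.
#' @param t_grid evaluation grid in seconds; defaults to 50 points from 0
#'   to the deadline.
#' @param seed seed for draw selection.
#' @return A data.frame with columns `group`, `difficulty`, `outcome`
#'   (`correct`/`error`), `t`, `pred_lower`, `pred_median`, `pred_upper`,
#'   `data_cdf`.
#' @export
posterior_predictive_cdf <- function(fit, trials, n_draws = 100,
                                     t_grid = NULL, seed = 1L) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (n_draws < 1) stop("need at least one posterior draw", call. = FALSE)
  if (is.null(t_grid)) t_grid <- seq(0, fit$deadline, length.out = 50)
  post <- fit$samples[, (fit$burnin + 1):dim(fit$samples)[2], , drop = FALSE]
  nit <- dim(post)[2]
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  pick <- cbind(sample(dim(post)[1], n_draws, replace = TRUE),
                sample(nit, n_draws, replace = TRUE))
  ids <- fit$participant_ids
  out <- NULL
  for (g in unique(fit$groups)) {
    gi <- which(fit$groups == g)
    for (dif in c("easy", "difficult")) {
      # per-participant trial counts per stimulus direction, as in the data
      sub <- trials[trials$group == g & trials$difficulty == dif &
                      !trials$excluded, , drop = FALSE]
      n_tot <- nrow(sub)
      pred_c <- matrix(0, n_draws, length(t_grid))
      pred_e <- matrix(0, n_draws, length(t_grid))
      for (d in seq_len(n_draws)) {
        rt_c <- numeric(0); rt_e <- numeric(0)
        for (p in gi) {
          a <- post[pick[d, 1], pick[d, 2], paste0("a[", ids[p], "]")]
          zr <- post[pick[d, 1], pick[d, 2], paste0("z[", ids[p], "]")]
          ter <- post[pick[d, 1], pick[d, 2], paste0("ter[", ids[p], "]")]
          vm <- post[pick[d, 1], pick[d, 2], paste0("v.mean[", ids[p], "]")]
          vd <- post[pick[d, 1], pick[d, 2], paste0("v.diff[", ids[p], "]")]
          vv <- drifts_from_moments(vm, vd)
          v <- if (dif == "easy") vv$v1 else vv$v2
          pp <- try(ddm_params(a, zr * a, ter, vv$v1, vv$v2, fit$s),
                    silent = TRUE)
          if (inherits(pp, "try-error")) next
          for (dir in c("left", "right")) {
            n_d <- sum(sub$participant == ids[p] & sub$direction == dir)
            if (n_d == 0) next
            vs <- if (dir == "right") v else -v
            sim <- simulate_trials(n_d, pp, v = vs,
                                   deadline = fit$deadline)
            resp <- ifelse(sim$response == "upper", "right", "left")
            corr <- !is.na(sim$rt) & resp == dir
            rt_c <- c(rt_c, sim$rt[which(corr)])
            rt_e <- c(rt_e, sim$rt[which(!is.na(sim$rt) & !corr)])
          }
        }
        pred_c[d, ] <- vapply(t_grid, function(tt) sum(rt_c <= tt), 0) /
          max(n_tot, 1)
        pred_e[d, ] <- vapply(t_grid, function(tt) sum(rt_e <= tt), 0) /
          max(n_tot, 1)
      }
      for (outc in c("correct", "error")) {
        pred <- if (outc == "correct") pred_c else pred_e
        dat <- vapply(t_grid, function(tt) {
          ok <- !sub$censored & sub$rt <= tt &
            (if (outc == "correct") sub$response == sub$direction
             else sub$response != sub$direction)
          sum(ok) / max(n_tot, 1)
        }, 0)
        out <- rbind(out, data.frame(
          group = g, difficulty = dif, outcome = outc, t = t_grid,
          pred_lower = apply(pred, 2, quantile, 0.025),
          pred_median = apply(pred, 2, quantile, 0.5),
          pred_upper = apply(pred, 2, quantile, 0.975),
          data_cdf = dat, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
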