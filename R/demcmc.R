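#' Differential-evolution MCMC for a generic target
#'
#' Samples from an arbitrary continuous target with a population of
#' interacting chains. Each chain proposes
#' `current + gamma * (chain_r1 - chain_r2) + jitter` where `r1 != r2` are
#' two other chains and the jitter is uniform on `+/- jitter_width`;
#' proposals are Metropolis-accepted. Within the migration window, every
#' `migrate_every` iterations a random subset of chains exchanges states
#' cyclically through Metropolis-accepted swaps, which helps chains escape
#' local modes early in the run.
#'
#' @param log_post function taking a parameter vector, returning the log
#'   target density.
#' @param init matrix `chains x d` of starting values; every row must have
#'   finite log density.
#' @param iterations number of iterations recorded (including burn-in).
#' @param gamma scale of the difference proposal; default `2.38 / sqrt(2 d)`.
#' @param jitter_width half-width of the uniform jitter.
#' @param migrate_every migration interval in iterations (0 disables).
#' @param migrate_window integer pair: first and last iteration of the
#'   migration window.
#' @param seed optional integer seed.
#' @return A `demcmc_fit` list: `samples` (array chains x iterations x d),
#'   `lp` (chains x iterations), `accept_rate`, `migration_rate`.
#' @examples
#' set.seed(1)
#' init <- matrix(rnorm(15), 15, 1)
#' fit <- demcmc(function(x) dnorm(x, log = TRUE), init, 200)
#' @export
demcmc <- function(log_post, init, iterations, gamma = NULL,
                   jitter_width = 0.001, migrate_every = 0,
                   migrate_window = NULL, seed = NULL) {
  stopifnot(is.matrix(init), nrow(init) >= 3, iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  nc <- nrow(init); d <- ncol(init)
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  x <- init
  lp <- apply(x, 1, log_post)
  if (any(!is.finite(lp)))
    stop("initialization error: non-finite log posterior for chains ",
         paste(which(!is.finite(lp)), collapse = ", "), call. = FALSE)
  samples <- array(NA_real_, c(nc, iterations, d),
                   dimnames = list(NULL, NULL, colnames(init)))
  lps <- matrix(NA_real_, nc, iterations)
  n_acc <- 0; n_prop <- 0; n_mig_acc <- 0; n_mig <- 0
  for (it in seq_len(iterations)) {
    do_migrate <- migrate_every > 0 && !is.null(migrate_window) &&
      it >= migrate_window[1] && it <= migrate_window[2] &&
      (it - migrate_window[1]) %% migrate_every == 0
    if (do_migrate) {
      kmax <- max(2L, floor(nc / 2))
      k <- if (kmax == 2L) 2L else sample(2:kmax, 1)
      sel <- sample.int(nc, k)
      old_x <- x[sel, , drop = FALSE]
      old_lp <- lp[sel]
      for (j in seq_len(k)) {
        src <- if (j == 1L) k else j - 1L
        n_mig <- n_mig + 1
        if (log(runif(1)) < old_lp[src] - lp[sel[j]]) {
          x[sel[j], ] <- old_x[src, ]
          lp[sel[j]] <- old_lp[src]
          n_mig_acc <- n_mig_acc + 1
        }
      }
    }
    for (ci in seq_len(nc)) {
      rr <- sample(seq_len(nc)[-ci], 2)
      prop <- x[ci, ] + gamma * (x[rr[1], ] - x[rr[2], ]) +
        runif(d, -jitter_width, jitter_width)
      lpp <- log_post(prop)
      n_prop <- n_prop + 1
      if (is.finite(lpp) && log(runif(1)) < lpp - lp[ci]) {
        x[ci, ] <- prop
        lp[ci] <- lpp
        n_acc <- n_acc + 1
      }
    }
    samples[, it, ] <- x
    lps[, it] <- lp
  }
  structure(list(samples = samples, lp = lps,
                 accept_rate = n_acc / n_prop,
                 migration_rate = if (n_mig) n_mig_acc / n_mig else NA_real_,
                 gamma = gamma, chains = nc),
            class = "demcmc_fit")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF `sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean
#' within-chain variance and `B` the between-chain variance of chain means
#' (times `n`). Values near 1 indicate convergence; identical chains give
#' exactly `sqrt((n-1)/n)`.
#'
#' @param x matrix `chains x iterations` for one parameter, or a 3-d array
#'   `chains x iterations x parameters`.
#' @return A PSRF per parameter.
#' @export
gelman_rubin <- function(x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1))
  stopifnot(length(dim(x)) == 3, dim(x)[1] >= 2, dim(x)[2] >= 10)
  n <- dim(x)[2]
  out <- apply(x, 3, function(m) {
    W <- mean(apply(m, 1, var))
    B <- n * var(rowMeans(m))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  nms <- dimnames(x)[[3]]
  if (!is.null(nms)) names(out) <- nms
  out
}

# ---------------------------------------------------------------------------
# Hierarchical DE-MCMC engine: one hyper block plus one block per
# participant, with blockwise Metropolis acceptance. The posterior
# decomposes as hyperprior(h) + sum_p prior(theta_p | h) + sum_p lik(theta_p),
# so hyper updates never re-evaluate the likelihood, and all participant
# blocks of a chain are proposed together and accepted independently.
run_hier_demcmc <- function(prior_hyper_fn, prior_part_fn, lik_fn,
                            hyper_init_fn, part_init_fn, P, ids,
                            chains = 15, iterations = 4000, burnin = 1500,
                            migrate_every = 14, migrate_window = c(500, 1100),
                            jitter_width = 0.001, seed = NULL,
                            hyper_blocks = NULL, max_init = 100) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(chains >= 3, burnin < iterations)
  # initialise each chain from the priors until the posterior is finite
  H <- vector("list", chains)   # hyper vectors
  Th <- vector("list", chains)  # participant matrices P x 5
  lp_h <- numeric(chains)
  lp_pp <- vector("list", chains)
  lp_L <- vector("list", chains)
  for (ci in seq_len(chains)) {
    ok <- FALSE
    for (try in seq_len(max_init)) {
      h <- hyper_init_fn()
      if (!is.finite(prior_hyper_fn(h))) next
      # draw participant blocks from the group distributions, redrawing
      # each block until its prior and likelihood are finite
      th <- part_init_fn(h)
      b <- prior_part_fn(h, th)
      l <- lik_fn(th)
      for (inner in seq_len(50)) {
        bad <- !is.finite(b) | !is.finite(l)
        if (!any(bad)) break
        th2 <- part_init_fn(h)
        th[bad, ] <- th2[bad, , drop = FALSE]
        b <- prior_part_fn(h, th)
        l <- lik_fn(th)
      }
      if (all(is.finite(b)) && all(is.finite(l))) {
        H[[ci]] <- h; Th[[ci]] <- th
        lp_h[ci] <- prior_hyper_fn(h); lp_pp[[ci]] <- b; lp_L[[ci]] <- l
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("initialization error: could not find a finite posterior in ",
           max_init, " prior draws (chain ", ci, ")", call. = FALSE)
  }
  nh <- length(H[[1]])
  # hyper parameters are updated in sub-blocks: by default the
  # (mu, sigma, delta [, beta...]) triplet of each model parameter plus one
  # block for anything else (joint-model hyper parameters)
  if (is.null(hyper_blocks)) {
    hn <- names(H[[1]])
    hyper_blocks <- lapply(PARAMS, function(j)
      which(hn %in% c(paste0(c("mu.", "sigma.", "delta."), j),
                      grep(paste0("^beta\\..*\\.", j, "$"), hn, value = TRUE))))
    rest <- setdiff(seq_len(nh), unlist(hyper_blocks))
    if (length(rest)) hyper_blocks <- c(hyper_blocks, list(rest))
  }
  gam_hb <- vapply(hyper_blocks, function(b) 2.38 / sqrt(2 * length(b)), 0)
  gam_p <- 2.38 / sqrt(2 * 5)
  # spread parameters are proposed multiplicatively (DE step on the log
  # scale, with the Jacobian term in the acceptance ratio)
  log_scale <- grepl("^sigma\\.", names(H[[1]]))
  npar <- nh + 5L * P
  pn <- c(names(H[[1]]),
          as.vector(outer(c("a", "z", "ter", "v.diff", "v.mean"), ids,
                          function(a, b) paste0(a, "[", b, "]"))))
  samples <- array(NA_real_, c(chains, iterations, npar),
                   dimnames = list(NULL, NULL, pn))
  lps <- matrix(NA_real_, chains, iterations)
  acc_h <- 0; acc_p <- 0; prop_h <- 0; prop_p <- 0
  total_lp <- function(ci) lp_h[ci] + sum(lp_pp[[ci]]) + sum(lp_L[[ci]])
  for (it in seq_len(iterations)) {
    do_migrate <- migrate_every > 0 && !is.null(migrate_window) &&
      it >= migrate_window[1] && it <= migrate_window[2] &&
      (it - migrate_window[1]) %% migrate_every == 0
    if (do_migrate) {
      # migrate blockwise: a random subset of chains cyclically exchanges
      # each block, Metropolis-accepted under the receiving chain's target
      kmax <- max(2L, floor(chains / 2))
      k <- if (kmax == 2L) 2L else sample(2:kmax, 1)
      sel <- sample.int(chains, k)
      # hyper block
      oldH <- H[sel]; old_lp_h <- lp_h[sel]
      for (j in seq_len(k)) {
        src <- if (j == 1L) k else j - 1L
        dst <- sel[j]
        b_new <- prior_part_fn(oldH[[src]], Th[[dst]])
        delta <- (old_lp_h[src] + sum(b_new)) - (lp_h[dst] + sum(lp_pp[[dst]]))
        if (is.finite(delta) && log(runif(1)) < delta) {
          H[[dst]] <- oldH[[src]]
          lp_h[dst] <- old_lp_h[src]
          lp_pp[[dst]] <- b_new
        }
      }
      # participant blocks, each with its own random cycle
      oldTh <- Th[sel]; old_L <- lp_L[sel]
      for (p in seq_len(P)) {
        rot <- sample.int(k) # independent cycle per block
        for (j in seq_len(k)) {
          src <- rot[j]
          dst <- sel[rot[if (j == 1L) k else j - 1L]]
          th_in <- oldTh[[src]][p, , drop = FALSE]
          th_try <- Th[[dst]]
          th_try[p, ] <- th_in
          b_new <- prior_part_fn(H[[dst]], th_try)[p]
          delta <- (b_new + old_L[[src]][p]) -
            (lp_pp[[dst]][p] + lp_L[[dst]][p])
          if (is.finite(delta) && log(runif(1)) < delta) {
            Th[[dst]][p, ] <- th_in
            lp_pp[[dst]][p] <- b_new
            lp_L[[dst]][p] <- old_L[[src]][p]
          }
        }
      }
    }
    for (ci in seq_len(chains)) {
      # hyper sub-blocks
      for (bi in seq_along(hyper_blocks)) {
        blk <- hyper_blocks[[bi]]
        rr <- sample(seq_len(chains)[-ci], 2)
        hp <- H[[ci]]
        ls <- log_scale[blk]
        gstep <- gam_hb[bi] * runif(1, 0.5, 1)
        jit <- runif(length(blk), -jitter_width, jitter_width)
        lin <- blk[!ls]
        hp[lin] <- hp[lin] + gstep * (H[[rr[1]]][lin] - H[[rr[2]]][lin]) +
          jit[!ls]
        lgs <- blk[ls]
        jac <- 0
        if (length(lgs) && all(H[[rr[1]]][lgs] > 0) &&
            all(H[[rr[2]]][lgs] > 0) && all(hp[lgs] > 0)) {
          hp[lgs] <- exp(log(hp[lgs]) +
                           gstep * (log(H[[rr[1]]][lgs]) -
                                      log(H[[rr[2]]][lgs])) + jit[ls])
          jac <- sum(log(hp[lgs]) - log(H[[ci]][lgs]))
        }
        a_new <- prior_hyper_fn(hp)
        prop_h <- prop_h + 1
        if (is.finite(a_new)) {
          b_new <- prior_part_fn(hp, Th[[ci]])
          delta <- (a_new + sum(b_new)) - (lp_h[ci] + sum(lp_pp[[ci]])) + jac
          if (is.finite(delta) && log(runif(1)) < delta) {
            H[[ci]] <- hp; lp_h[ci] <- a_new; lp_pp[[ci]] <- b_new
            acc_h <- acc_h + 1
          }
        }
      }
      # participant blocks (proposed together, accepted independently)
      r1 <- numeric(P); r2 <- numeric(P)
      for (p in seq_len(P)) {
        rr <- sample(seq_len(chains)[-ci], 2)
        r1[p] <- rr[1]; r2[p] <- rr[2]
      }
      cur <- Th[[ci]]
      d1 <- do.call(rbind, lapply(seq_len(P),
                                  function(p) Th[[r1[p]]][p, ] - Th[[r2[p]]][p, ]))
      prop <- cur + gam_p * runif(P, 0.5, 1) * d1 +
        matrix(runif(5L * P, -jitter_width, jitter_width), P, 5)
      b_new <- prior_part_fn(H[[ci]], prop)
      finite_b <- is.finite(b_new)
      l_new <- rep(-Inf, P)
      if (any(finite_b)) {
        l_try <- lik_fn(prop)
        l_new[finite_b] <- l_try[finite_b]
      }
      delta <- (b_new + l_new) - (lp_pp[[ci]] + lp_L[[ci]])
      acc <- is.finite(delta) & log(runif(P)) < delta
      prop_p <- prop_p + P
      acc_p <- acc_p + sum(acc)
      if (any(acc)) {
        cur[acc, ] <- prop[acc, ]
        Th[[ci]] <- cur
        lp_pp[[ci]][acc] <- b_new[acc]
        lp_L[[ci]][acc] <- l_new[acc]
      }
      samples[ci, it, ] <- c(H[[ci]], as.vector(t(Th[[ci]])))
      lps[ci, it] <- total_lp(ci)
    }
  }
  list(samples = samples, lp = lps, burnin = burnin,
       hyper_names = names(H[[1]]), participant_ids = ids,
       accept_hyper = acc_h / prop_h, accept_participant = acc_p / prop_p)
}

#' Fit the hierarchical diffusion model with DE-MCMC
#'
#' Samples the full hierarchical posterior (group-level means, spreads and
#' group-difference parameters, plus five diffusion parameters per
#' participant) with interacting chains, blocked into one hyper block and
#' one block per participant. Defaults follow the study's sampling
#' schedule: 15 chains of 4000 iterations with the first 1500 discarded as
#' burn-in and chain migration every 14 iterations between iterations 500
#' and 1100. Chains are initialised from the priors, re-drawn until the
#' posterior is finite.
#'
#' @param trials a filtered trial table ([filter_trials()]).
#' @param covariates optional data.frame of per-participant covariates
#'   (rows matched to participants by the `participant` attribute or order
#'   of `unique(trials$participant)`); standardised internally, each enters
#'   every group-level mean linearly with a `N(0, 0.5)` weight.
#' @param chains,iterations,burnin sampler schedule.
#' @param migrate_every,migrate_window migration schedule (interval and
#'   iteration window); `migrate_every = 0` disables migration.
#' @param s within-trial noise.
#' @param deadline response deadline, seconds.
#' @param coding response coding (see [loglik_participant()]).
#' @param seed integer seed; the run is bit-reproducible given the seed and
#'   schedule.
#' @param err WFPT series tolerance.
#' @return An `hddm_fit` object: `samples` (chains x iterations x
#'   parameters), `lp`, acceptance rates, schedule, participant ids and
#'   group signs.
#' @export
fit_hddm <- function(trials, covariates = NULL, chains = 15,
                     iterations = 4000, burnin = 1500, migrate_every = 14,
                     migrate_window = c(500, 1100), s = 0.1, deadline = 2.5,
                     coding = "stimulus", seed = 1L, err = 1e-7) {
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
  res <- run_hier_demcmc(
    prior_hyper_fn = hyper_prior_lp,
    prior_part_fn = function(h, th) participant_prior_lp(h, th, sgn, xmat),
    lik_fn = function(th) packed_loglik(packed, th, s = s,
                                        deadline = deadline, err = err),
    hyper_init_fn = function() draw_hyper_init(cov_names),
    part_init_fn = function(h) draw_participant_init(h, sgn, xmat),
    P = P, ids = ids, chains = chains, iterations = iterations,
    burnin = burnin, migrate_every = migrate_every,
    migrate_window = migrate_window, seed = seed)
  res$groups <- grp
  res$sgn <- sgn
  res$deadline <- deadline
  res$s <- s
  res$coding <- coding
  class(res) <- "hddm_fit"
  res
}

#' @export
print.hddm_fit <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("Hierarchical diffusion fit: %d chains x %d iterations (burn-in %d), %d parameters\n",
              d[1], d[2], x$burnin, d[3]))
  cat(sprintf("  acceptance: hyper %.2f, participant %.2f\n",
              x$accept_hyper, x$accept_participant))
  invisible(x)
}

#' Post-burn-in draws of one parameter
#'
#' @param fit an `hddm_fit` (or joint fit) object.
#' @param par parameter name (see `dimnames(fit$samples)[[3]]`).
#' @return Numeric vector pooling all chains after burn-in.
#' @export
posterior_draws <- function(fit, par) {
  nm <- dimnames(fit$samples)[[3]]
  if (!par %in% nm) stop("unknown parameter: ", par, call. = FALSE)
  as.vector(fit$samples[, (fit$burnin + 1):dim(fit$samples)[2], par])
}
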