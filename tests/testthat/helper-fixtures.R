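# Shared fixtures and independent reference implementations used as oracles.

# ground truth with realistic spreads used throughout the recovery tests
truth_small <- function(seed = 1L, ...) {
  ground_truth(seed = seed, ...)
}

# a small filtered trial table: n participants per group, light trial load
make_behaviour <- function(n_per_group = 4, blocks = 1, repetitions = 5,
                           seed = 1L, truth = truth_small(seed), ...) {
  pp <- generate_participants(n_per_group, truth)
  des <- build_design("motion_coherence", blocks = blocks,
                      repetitions = repetitions, seed = seed)
  beh <- generate_behaviour(pp, des, seed = seed + 1L, ...)
  list(params = pp, design = des, trials = filter_trials(beh))
}

# naive per-trial log-likelihood: independent R loop over wfpt_density /
# survivor, no caching, no C++ batching
naive_loglik <- function(trials, p, deadline = 2.5) {
  keep <- !trials$excluded & trials$difficulty != "catch"
  tr <- trials[keep, , drop = FALSE]
  ll <- 0
  for (i in seq_len(nrow(tr))) {
    v <- if (tr$difficulty[i] == "easy") p$v1 else p$v2
    if (tr$direction[i] == "left") v <- -v
    if (tr$censored[i]) {
      ll <- ll + log(survivor(deadline, p, v = v))
    } else {
      bound <- if (tr$response[i] == "right") "upper" else "lower"
      d <- wfpt_density(tr$rt[i], p, bound, v = v)
      ll <- ll + log(d)
    }
  }
  ll
}

# independent PSRF via the classic ANOVA decomposition written directly
reference_psrf <- function(m) {
  nc <- nrow(m); n <- ncol(m)
  means <- rowMeans(m)
  W <- sum((m - means)^2) / (nc * (n - 1))
  B <- n * sum((means - mean(means))^2) / (nc - 1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# two-sided KS distance between a sample and a cdf given as function
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
}

# truncated-normal draws (inverse CDF), used to draw truths from the
# model's hyperpriors in recovery suites
rtnorm_h <- function(mean, sd) qnorm(runif(1, pnorm(0, mean, sd), 1),
                                     mean, sd)
rtnorm_01 <- function(mean, sd) qnorm(runif(1, pnorm(0, mean, sd),
                                            pnorm(1, mean, sd)), mean, sd)

# a deterministic toy 3-participant parameter setup for oracle tests
toy_hier <- function() {
  hyper <- c(mu.a = 0.2, mu.z = 0.5, mu.ter = 0.3, mu.v.diff = 0.05,
             mu.v.mean = 0.3, sigma.a = 0.05, sigma.z = 0.1,
             sigma.ter = 0.08, sigma.v.diff = 0.1, sigma.v.mean = 0.15,
             delta.a = 0.01, delta.z = -0.005, delta.ter = 0.02,
             delta.v.diff = 0, delta.v.mean = -0.01)
  pmat <- rbind(c(0.21, 0.52, 0.28, 0.1, 0.35),
                c(0.18, 0.47, 0.33, -0.02, 0.22),
                c(0.25, 0.55, 0.30, 0.07, 0.41))
  colnames(pmat) <- c("a", "z", "ter", "v.diff", "v.mean")
  list(hyper = hyper, pmat = pmat, sgn = c(1, -1, 1))
}
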