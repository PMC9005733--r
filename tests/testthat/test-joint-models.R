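# extended toy setup with EEG slope data for the joint models
toy_joint <- function(rho_by_group = FALSE) {
  toy <- toy_hier()
  extra <- c(mu.EEG.diff = 0.2, mu.EEG.mean = 1.1, sigma.EEG.diff = 0.8,
             sigma.EEG.mean = 1.5, delta.EEG.diff = 0.005,
             delta.EEG.mean = -0.003)
  rho <- if (rho_by_group)
    c(rho.mean.comparison = 0.2, rho.mean.autistic = 0.5,
      rho.diff.comparison = -0.1, rho.diff.autistic = 0.3)
  else c(rho.mean = 0.4, rho.diff = 0.1)
  eeg <- cbind(eeg.mean = c(1.4, 0.8, NA), eeg.diff = c(0.3, -0.2, NA))
  c(toy, list(hyper_j = c(toy$hyper, extra, rho), eeg = eeg))
}

test_that("zero correlation factorises the EEG joint posterior exactly", {
  tj <- toy_joint()
  h <- tj$hyper_j
  h[c("rho.mean", "rho.diff")] <- 0
  ids <- c("P1", "P2", "P3")
  joint <- joint_log_posterior_eeg(h, tj$pmat, tj$sgn, NULL, ids, tj$eeg)
  # base posterior + independent normal EEG terms + EEG hyperpriors
  base <- log_prior(tj$hyper, tj$pmat, tj$sgn)
  mEd <- h[["mu.EEG.diff"]] + tj$sgn * h[["delta.EEG.diff"]]
  mEm <- h[["mu.EEG.mean"]] + tj$sgn * h[["delta.EEG.mean"]]
  has <- !is.na(tj$eeg[, 1])
  eeg_terms <- sum(dnorm(tj$eeg[has, "eeg.diff"], mEd[has],
                         h[["sigma.EEG.diff"]], log = TRUE)) +
    sum(dnorm(tj$eeg[has, "eeg.mean"], mEm[has], h[["sigma.EEG.mean"]],
              log = TRUE))
  hyper_extra <- dnorm(h[["mu.EEG.diff"]], 0, 0.5, log = TRUE) +
    dnorm(h[["mu.EEG.mean"]], 0, 1, log = TRUE) +
    sum(dgamma(h[c("sigma.EEG.diff", "sigma.EEG.mean")], 1, 1, log = TRUE)) +
    sum(dnorm(h[c("delta.EEG.diff", "delta.EEG.mean")], 0, 0.01,
              log = TRUE)) + 2 * dunif(0, -1, 1, log = TRUE)
  expect_equal(joint, base + eeg_terms + hyper_extra, tolerance = 1e-10)
})

test_that("EEG joint posterior matches a brute-force bivariate summation", {
  tj <- toy_joint()
  h <- tj$hyper_j
  ids <- c("P1", "P2", "P3")
  joint <- joint_log_posterior_eeg(h, tj$pmat, tj$sgn, NULL, ids, tj$eeg)
  # oracle: write out every term with a dense 2x2 covariance
  dbvn <- function(x, mu, S)
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(t(x - mu) %*% solve(S) %*% (x - mu))
  dtn <- function(x, m, s, lo, hi)
    dnorm(x, m, s, log = TRUE) - log(pnorm(hi, m, s) - pnorm(lo, m, s))
  acc <- dtn(h[["mu.a"]], 0.2, 0.2, 0, Inf) +
    dtn(h[["mu.z"]], 0.5, 0.2, 0, 1) +
    dtn(h[["mu.ter"]], 0.3, 0.3, 0, Inf) +
    dnorm(h[["mu.v.diff"]], 0, 0.1, log = TRUE) +
    dnorm(h[["mu.v.mean"]], 0.3, 0.3, log = TRUE) +
    sum(dgamma(h[paste0("sigma.", c("a","z","ter","v.diff","v.mean"))],
               1, 1, log = TRUE)) +
    sum(dnorm(h[paste0("delta.", c("a","z","ter","v.diff","v.mean"))],
              0, 0.01, log = TRUE)) +
    dnorm(h[["mu.EEG.diff"]], 0, 0.5, log = TRUE) +
    dnorm(h[["mu.EEG.mean"]], 0, 1, log = TRUE) +
    sum(dgamma(h[c("sigma.EEG.diff", "sigma.EEG.mean")], 1, 1, log = TRUE)) +
    sum(dnorm(h[c("delta.EEG.diff", "delta.EEG.mean")], 0, 0.01,
              log = TRUE)) + 2 * dunif(0, -1, 1, log = TRUE)
  for (i in 1:3) {
    sg <- tj$sgn[i]
    acc <- acc +
      dtn(tj$pmat[i, 1], h[["mu.a"]] + sg * h[["delta.a"]],
          h[["sigma.a"]], 0, Inf) +
      dtn(tj$pmat[i, 2], h[["mu.z"]] + sg * h[["delta.z"]],
          h[["sigma.z"]], 0, 1) +
      dtn(tj$pmat[i, 3], h[["mu.ter"]] + sg * h[["delta.ter"]],
          h[["sigma.ter"]], 0, Inf)
    if (!is.na(tj$eeg[i, 1])) {
      sd1 <- h[["sigma.v.diff"]]; sd2 <- h[["sigma.EEG.diff"]]
      S_d <- matrix(c(sd1^2, sd1 * sd2 * h[["rho.diff"]],
                      sd1 * sd2 * h[["rho.diff"]], sd2^2), 2)
      sm1 <- h[["sigma.v.mean"]]; sm2 <- h[["sigma.EEG.mean"]]
      S_m <- matrix(c(sm1^2, sm1 * sm2 * h[["rho.mean"]],
                      sm1 * sm2 * h[["rho.mean"]], sm2^2), 2)
      acc <- acc +
        dbvn(c(tj$pmat[i, 4], tj$eeg[i, "eeg.diff"]),
             c(h[["mu.v.diff"]] + sg * h[["delta.v.diff"]],
               h[["mu.EEG.diff"]] + sg * h[["delta.EEG.diff"]]), S_d) +
        dbvn(c(tj$pmat[i, 5], tj$eeg[i, "eeg.mean"]),
             c(h[["mu.v.mean"]] + sg * h[["delta.v.mean"]],
               h[["mu.EEG.mean"]] + sg * h[["delta.EEG.mean"]]), S_m)
    } else {
      acc <- acc +
        dnorm(tj$pmat[i, 4], h[["mu.v.diff"]] + sg * h[["delta.v.diff"]],
              h[["sigma.v.diff"]], log = TRUE) +
        dnorm(tj$pmat[i, 5], h[["mu.v.mean"]] + sg * h[["delta.v.mean"]],
              h[["sigma.v.mean"]], log = TRUE)
    }
  }
  expect_equal(unname(joint), unname(acc), tolerance = 1e-10)
})

test_that("non-positive-definite correlation proposals reject, never error", {
  tj <- toy_joint()
  h <- tj$hyper_j
  h[["rho.mean"]] <- 1.2
  expect_identical(
    joint_log_posterior_eeg(h, tj$pmat, tj$sgn, NULL, c("P1","P2","P3"),
                            tj$eeg), -Inf)
})

test_that("ADHD joint posterior factorises at rho = 0 and matches an oracle", {
  toy <- toy_hier()
  scores <- c(0.2, 0.6, 0.4)
  extra <- c(mu.inatt = 0.5, sigma.inatt = 0.25, delta.inatt = 0.002,
             rho.comparison = 0, rho.autistic = 0)
  h <- c(toy$hyper, extra)
  ids <- c("P1", "P2", "P3")
  joint <- joint_log_posterior_adhd(h, toy$pmat, toy$sgn, NULL, ids,
                                    scores, subscale = "inatt", link = "a")
  base <- log_prior(toy$hyper, toy$pmat, toy$sgn)
  mS <- h[["mu.inatt"]] + toy$sgn * h[["delta.inatt"]]
  dtn <- function(x, m, s, lo, hi)
    dnorm(x, m, s, log = TRUE) - log(pnorm(hi, m, s) - pnorm(lo, m, s))
  # at rho = 0 the linked 'a' term becomes the UNTRUNCATED normal, so
  # correct the base (truncated) term and add independent score terms
  m_a <- toy$hyper[["mu.a"]] + toy$sgn * toy$hyper[["delta.a"]]
  corr_a <- sum(dnorm(toy$pmat[, 1], m_a, toy$hyper[["sigma.a"]],
                      log = TRUE)) -
    sum(dtn(toy$pmat[, 1], m_a, toy$hyper[["sigma.a"]], 0, Inf))
  score_terms <- sum(dnorm(scores, mS, h[["sigma.inatt"]], log = TRUE))
  hyper_extra <- dnorm(h[["mu.inatt"]], 0.5, 0.2, log = TRUE) +
    dgamma(h[["sigma.inatt"]], 1, 1, log = TRUE) +
    dnorm(h[["delta.inatt"]], 0, 0.01, log = TRUE) +
    2 * dunif(0, -1, 1, log = TRUE)
  expect_equal(joint, base + corr_a + score_terms + hyper_extra,
               tolerance = 1e-10)
  # support-respecting variant renormalises and rejects a <= 0
  jt <- joint_log_posterior_adhd(h, toy$pmat, toy$sgn, NULL, ids, scores,
                                 subscale = "inatt", link = "a",
                                 truncate_support = TRUE)
  norm_corr <- sum(pnorm(0, m_a, toy$hyper[["sigma.a"]], lower.tail = FALSE,
                         log.p = TRUE))
  expect_equal(jt, joint - norm_corr, tolerance = 1e-10)
})

test_that("ADHD joint model recovers a negative questionnaire link", {
  truth <- truth_small(seed = 71)
  pp <- generate_participants(20, truth)
  des <- build_design("motion_coherence", blocks = 1, repetitions = 12,
                      seed = 71)
  beh <- filter_trials(generate_behaviour(pp, des, seed = 72))
  sc <- generate_questionnaires(pp, link = "v.mean",
                                rho_target = c(comparison = 0,
                                               autistic = -0.31),
                                seed = 73)
  fit <- fit_joint_adhd(beh, sc, subscale = "hyper", link = "v.mean",
                        rho_by_group = TRUE, chains = 12,
                        iterations = 500, burnin = 250, seed = 74)
  s <- summarise_fit(fit, pars = c("rho.autistic", "rho.comparison"))
  au <- s[s$parameter == "rho.autistic", ]
  # the generating correlation lies inside the 95% credible interval and
  # the posterior mean carries its sign
  expect_gte(-0.31, au$ci_lower)
  expect_lte(-0.31, au$ci_upper)
  expect_lt(au$mean, 0)
})

test_that("shared-rho chains have one parameter fewer per correlation pair", {
  fx <- make_behaviour(n_per_group = 2, repetitions = 4, seed = 55)
  sl <- data.frame(participant = rep(unique(fx$trials$participant), each = 2),
                   difficulty = rep(c("easy", "difficult"), 4),
                   slope = rnorm(8, 5, 2))
  f_sh <- fit_joint_eeg(fx$trials, sl, rho_by_group = FALSE, chains = 5,
                        iterations = 25, burnin = 10, seed = 56)
  f_bg <- fit_joint_eeg(fx$trials, sl, rho_by_group = TRUE, chains = 5,
                        iterations = 25, burnin = 10, seed = 56)
  expect_equal(dim(f_bg$samples)[3] - dim(f_sh$samples)[3], 2L)
  # seeded reproducibility of the joint fit
  f_sh2 <- fit_joint_eeg(fx$trials, sl, rho_by_group = FALSE, chains = 5,
                         iterations = 25, burnin = 10, seed = 56)
  expect_identical(f_sh$samples, f_sh2$samples)
})
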