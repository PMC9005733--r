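test_that("ground truth validates its configuration", {
  expect_error(ground_truth(sigma = c(a = -1, z = 1, ter = 1, v.diff = 1,
                                      v.mean = 1)), "positive")
  expect_error(generate_questionnaires(
    generate_participants(2, truth_small()), rho_target = c(
      comparison = 1.5, autistic = 0)), "correlation")
  tr <- ground_truth()
  expect_s3_class(tr, "ground_truth")
})

test_that("participant generation is seeded and respects the group offsets", {
  tr <- truth_small(seed = 11)
  a <- generate_participants(5, tr)
  b <- generate_participants(5, tr)
  expect_identical(a, b) # same seed, bit-identical
  expect_true(all(a$a > 0 & a$ter > 0))
  expect_true(all(a$zr > 0 & a$zr < 1))
  expect_true(all(a$s == 0.1))
  expect_equal(nrow(a), 10)

  # zero group effect: group means differ by < 3 standard errors
  big <- generate_participants(1000, truth_small(seed = 12))
  for (par in c("a", "zr", "ter", "v.mean", "v.diff")) {
    x1 <- big[[par]][big$group == "autistic"]
    x2 <- big[[par]][big$group == "comparison"]
    se <- sqrt(var(x1) / length(x1) + var(x2) / length(x2))
    expect_lt(abs(mean(x1) - mean(x2)), 3 * se)
  }

  # delta_a = 0.02 (half difference): expected mean difference from the
  # truncated-normal closed form, ~ 0.04 when truncation is negligible
  tr2 <- ground_truth(delta = c(a = 0.02, z = 0, ter = 0, v.diff = 0,
                                v.mean = 0), seed = 13)
  many <- generate_participants(2000, tr2)
  d_hat <- mean(many$a[many$group == "autistic"]) -
    mean(many$a[many$group == "comparison"])
  tmean <- function(m, s) { # closed-form mean of N+(m, s)
    al <- -m / s
    m + s * dnorm(al) / (1 - pnorm(al))
  }
  d_true <- tmean(0.22, 0.05) - tmean(0.18, 0.05)
  se <- sqrt(2 * 0.05^2 / 2000)
  expect_lt(abs(d_hat - d_true), 4 * se)
  expect_lt(abs(d_true - 0.04), 1e-3) # negligible truncation at this scale
})

test_that("generated behaviour respects the deadline, floor and schedule", {
  tr <- truth_small(seed = 21)
  pp <- generate_participants(2, tr)
  des <- build_design("motion_coherence", blocks = 1, repetitions = 4,
                      seed = 21)
  beh <- generate_behaviour(pp, des, seed = 22)
  expect_equal(nrow(beh), nrow(des$schedule) * nrow(pp))
  # RT >= ter by construction when uncontaminated
  for (id in pp$participant) {
    rts <- beh$rt[beh$participant == id & beh$response != "none"]
    expect_true(all(rts >= pp$ter[pp$participant == id]))
  }
  expect_true(all(is.na(beh$rt[beh$response == "none"])))
  expect_true(all(beh$rt <= 2.5, na.rm = TRUE))
  # deadline below min(ter): everything is censored
  des0 <- build_design("motion_coherence", blocks = 1, repetitions = 2,
                       deadline = 0.05, rt_floor = 0.01, seed = 21)
  beh0 <- generate_behaviour(pp, des0, seed = 23)
  expect_true(all(beh0$response == "none"))
  # unknown participant requested
  expect_error(generate_behaviour(pp, des, participants = "nope", seed = 1),
               "missing participant")
  # seeded determinism
  expect_identical(generate_behaviour(pp, des, seed = 9),
                   generate_behaviour(pp, des, seed = 9))
})

test_that("strong drift gives near-ceiling accuracy (closed-form check)", {
  tr <- ground_truth(mu = c(a = 0.1, z = 0.5, ter = 0.3, v.diff = 0,
                            v.mean = 0.4),
                     sigma = c(a = 1e-4, z = 1e-4, ter = 1e-4,
                               v.diff = 1e-4, v.mean = 1e-4), seed = 31)
  pp <- generate_participants(1, tr)
  des <- build_design("motion_coherence", blocks = 4, repetitions = 9,
                      seed = 31)
  beh <- generate_behaviour(pp, des, seed = 32)
  easy <- beh[beh$difficulty == "easy" & beh$response != "none", ]
  # closed form: P(correct) = 1 / (1 + exp(-2 v z / s^2)) at z = a/2
  p_closed <- 1 / (1 + exp(-2 * 0.4 * 0.05 / 0.01))
  expect_gt(p_closed, 0.9)
  expect_gt(mean(easy$response == easy$direction), 0.9)
})

test_that("behavioural marginals match the analytic CDF and censoring rate", {
  tr <- truth_small(seed = 41)
  pp <- generate_participants(1, tr)
  row <- pp[1, ]
  p <- ddm_params(row$a, row$z, row$ter, row$v1, row$v2)
  set.seed(42)
  sim <- simulate_trials(1e5, p, v = row$v1, deadline = 2.5)
  up <- sim$rt[sim$response == "upper" & !is.na(sim$rt)]
  Fd <- defective_cdf(2.5, p, "upper", v = row$v1)
  expect_lt(ks_distance(up, function(t)
    defective_cdf(t, p, "upper", v = row$v1) / Fd), 0.02)
  s_true <- survivor(2.5, p, v = row$v1)
  expect_lt(abs(mean(is.na(sim$rt)) - s_true),
            4 * sqrt(max(s_true, 1e-6) / 1e5) + 1e-4)
})

test_that("contaminant trials exercise the RT floor filter", {
  tr <- truth_small(seed = 51)
  pp <- generate_participants(3, tr)
  des <- build_design("motion_coherence", blocks = 2, repetitions = 9,
                      seed = 51)
  beh <- generate_behaviour(pp, des, contamination_rate = 0.04, seed = 52)
  filt <- filter_trials(beh)
  cont <- filt$rt < 0.2 & !filt$censored
  expect_gt(sum(cont, na.rm = TRUE), 0)
  expect_true(all(filt$excluded[which(cont)]))
  expect_error(generate_behaviour(pp, des, contamination_rate = 0.2),
               "contamination")
})

test_that("questionnaire scores hit the configured group means and correlations", {
  tr <- truth_small(seed = 61)
  pp <- generate_participants(1000, tr)
  # zero correlation target
  q0 <- generate_questionnaires(pp, link = "v.mean",
                                rho_target = c(comparison = 0, autistic = 0),
                                seed = 62)
  expect_true(all(q0$inatt >= 0 & q0$inatt <= 1))
  for (g in c("comparison", "autistic")) {
    r <- cor(q0$inatt[q0$group == g], pp$v.mean[pp$group == g])
    expect_lt(abs(r), 3 / sqrt(1000))
  }
  # group means near the configured sample values (defaults 0.17 / 0.58)
  se_td <- 0.23 / sqrt(1000); se_au <- 0.29 / sqrt(1000)
  expect_lt(abs(mean(q0$inatt[q0$group == "comparison"]) - 0.17), 2 * se_td)
  expect_lt(abs(mean(q0$inatt[q0$group == "autistic"]) - 0.58), 2 * se_au)
  # a negative target correlation is recovered
  pp5 <- generate_participants(5000, truth_small(seed = 63))
  qn <- generate_questionnaires(pp5, link = "v.mean",
                                rho_target = c(comparison = 0,
                                               autistic = -0.31),
                                seed = 64)
  r_au <- cor(qn$inatt[qn$group == "autistic"],
              pp5$v.mean[pp5$group == "autistic"])
  expect_lt(abs(r_au - (-0.31)), 0.03)
})

test_that("synthetic EEG stores true slopes that track drift at the target correlation", {
  tr <- ground_truth(rho_eeg = 0.6, seed = 71)
  pp <- generate_participants(50, tr)
  des <- build_design("motion_coherence", blocks = 1, repetitions = 2,
                      seed = 71)
  beh <- generate_behaviour(pp, des, seed = 72)
  recs <- generate_eeg(pp, beh, tr)
  ts <- attr(recs, "true_slopes")
  sm <- slope_moments(ts)
  r <- cor(sm$eeg.mean, pp$v.mean[match(sm$participant, pp$participant)])
  expect_gt(r, 0.45)  # sampling band of r at n = 100
  expect_lt(r, 0.72)
  # null link: gain dropped entirely
  tr0 <- ground_truth(rho_eeg = 0, seed = 73)
  recs0 <- generate_eeg(pp, beh, tr0)
  ts0 <- attr(recs0, "true_slopes")
  sm0 <- slope_moments(ts0)
  r0 <- cor(sm0$eeg.mean, pp$v.mean[match(sm0$participant, pp$participant)])
  expect_lt(abs(r0), 3 / sqrt(100))
})

test_that("noiseless EEG reproduces the ramp around isolated responses", {
  tr <- ground_truth(eeg_noise_sd = 0, rho_eeg = 0.6, seed = 81)
  pp <- generate_participants(1, tr)
  des <- build_design("motion_coherence", blocks = 1, repetitions = 3,
                      seed = 81)
  beh <- generate_behaviour(pp, des, seed = 82)
  # no stimulus-evoked kernel, so the pre-response window is pure ramp
  cfg <- eeg_config(stim_kernel_amp = 0)
  recs <- generate_eeg(pp, beh, tr, cfg = cfg)
  rec <- recs[[1]]
  ts <- attr(recs, "true_slopes")
  ep <- epoch_responses(rec, window = c(-0.2, 0))
  tv <- attr(ep, "time")
  dif <- attr(ep, "difficulty")
  ch <- which.max(cfg$topo_response) # channel where the ramp projects at ~1
  sl_true <- ts$slope[ts$difficulty == "easy"][1]
  i <- which(dif == "easy")[1]
  fitl <- lm(ep[i, ch, ] ~ tv)
  expect_equal(unname(coef(fitl)[2]),
               sl_true * max(cfg$topo_response), tolerance = 0.05)
  # true slopes are reproducible without synthesising signals
  expect_equal(true_slopes(pp, tr), ts)
  # events must lie inside the recording
  expect_error(eeg_recording(matrix(0, 2, 10), 250,
                             data.frame(type = "stimulus", sample = 11,
                                        trial = 1, difficulty = "easy",
                                        rt = NA)),
               "scheduling")
})
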