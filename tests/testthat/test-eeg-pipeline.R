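# minimal synthetic epochs: trials x channels x time from one topography
# and one waveform plus optional noise
rank1_epochs <- function(n_trials = 20, n_ch = 6, n_t = 50, noise = 0,
                         topo = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(topo)) topo <- seq(-1, 1, length.out = n_ch)
  wave <- sin(seq(0, 2 * pi, length.out = n_t))
  ep <- array(0, c(n_trials, n_ch, n_t))
  for (i in seq_len(n_trials))
    ep[i, , ] <- outer(topo, wave) + noise * matrix(rnorm(n_ch * n_t), n_ch)
  attr(ep, "time") <- seq(0, 1, length.out = n_t)
  ep
}

test_that("RCA identifies a rank-1 topography up to sign", {
  topo <- c(0.2, 0.9, 0.4, -0.3, 0.1, 0.6)
  ep <- rank1_epochs(topo = topo, noise = 0.01)
  comp <- rca(ep, n_components = 1)[[1]]
  r <- cor(comp$projection, topo)
  expect_gt(abs(r), 0.999)
  expect_gt(comp$reliability, 0.9) # nearly fully reliable
  expect_gt(comp$explained, 0.9)
})

test_that("RCA eigenvalues agree with an independent dense generalized solver", {
  ep <- rank1_epochs(n_trials = 15, n_ch = 3, noise = 0.5, seed = 3)
  comps <- rca(ep, n_components = 3)
  # oracle: build the same covariances directly and solve
  # solve(Rw) %*% Rb with base eigen (non-symmetric route)
  nt <- dim(ep)[1]
  Rw <- matrix(0, 3, 3); S <- matrix(0, 3, dim(ep)[3])
  for (i in seq_len(nt)) {
    X <- matrix(ep[i, , ], 3)
    X <- X - rowMeans(X)
    Rw <- Rw + tcrossprod(X); S <- S + X
  }
  Sb <- (tcrossprod(S) - Rw) / (nt * (nt - 1))
  Rw <- Rw / nt
  Rw_s <- Rw + diag(0.01 * mean(diag(Rw)), 3)
  ev <- eigen(solve(Rw_s) %*% Sb, only.values = TRUE)$values
  expect_equal(sort(Re(ev), decreasing = TRUE),
               sort(vapply(comps, `[[`, 0, "reliability"),
                    decreasing = TRUE),
               tolerance = 1e-8)
})

test_that("RCA is invariant to trial order and needs at least 2 trials", {
  ep <- rank1_epochs(noise = 0.3, seed = 4)
  set.seed(5)
  perm <- sample(dim(ep)[1])
  c1 <- rca(ep)[[1]]
  c2 <- rca(ep[perm, , ], )[[1]]
  expect_equal(c1$weights, c2$weights, tolerance = 1e-10)
  expect_equal(c1$reliability, c2$reliability, tolerance = 1e-10)
  expect_error(rca(ep[1, , , drop = FALSE]), "2 trials")
})

test_that("projection is the weighted channel combination (linear, unit-vector)", {
  sig <- matrix(rnorm(5 * 100), 5, 100)
  rec <- eeg_recording(sig, 250, data.frame(type = character(),
                                            sample = integer(),
                                            trial = integer(),
                                            difficulty = character(),
                                            rt = numeric()))
  w_unit <- c(0, 0, 1, 0, 0)
  expect_equal(rca_project(rec, w_unit), sig[3, ])
  w1 <- rnorm(5); w2 <- rnorm(5)
  expect_equal(rca_project(rec, 2 * w1 + w2),
               2 * rca_project(rec, w1) + rca_project(rec, w2),
               tolerance = 1e-12)
})

# events spaced far apart: deconvolution must equal simple epoch averages
test_that("deconvolution equals epoch averages on an orthogonal design", {
  rate <- 250
  n <- 20000
  set.seed(6)
  series <- rnorm(n, 0, 0.1)
  ev_samp <- seq(600, n - 600, by = 550) # > window, no overlap
  kern <- 3 * exp(-((seq_len(125) / rate - 0.2)^2) / 0.005)
  for (s0 in ev_samp) series[s0:(s0 + 124)] <- series[s0:(s0 + 124)] + kern
  events <- data.frame(type = "stimulus", sample = ev_samp, trial = 1,
                       difficulty = rep(c("easy", "difficult"),
                                        length.out = length(ev_samp)),
                       rt = NA)
  bet <- deconvolve(series, events, rate = rate, lambda = 0)
  lags <- bet$time
  for (dif in c("easy", "difficult")) {
    sel <- events$sample[events$difficulty == dif]
    avg <- rowMeans(vapply(sel, function(s0)
      series[s0 + round(lags * rate)], numeric(length(lags))))
    expect_lt(max(abs(bet$beta[, paste0("stimulus.", dif)] - avg)), 1e-8)
  }
})

test_that("lambda = 0 equals a dense least-squares oracle on a tiny system", {
  rate <- 10
  set.seed(7)
  series <- rnorm(300)
  events <- data.frame(type = rep(c("stimulus", "response"), 8),
                       sample = sort(sample(30:270, 16)), trial = 1,
                       difficulty = "easy", rt = NA)
  bet <- deconvolve(series, events, rate = rate, window = c(-0.5, 0.5),
                    lambda = 0)
  # oracle: dense model matrix + lm
  lags <- round(-0.5 * rate):(round(0.5 * rate) - 1)
  blocks <- expand.grid(difficulty = c("difficult", "easy"),
                        type = c("stimulus", "response"),
                        stringsAsFactors = FALSE)
  Xd <- matrix(0, length(series), nrow(blocks) * length(lags))
  for (b in seq_len(nrow(blocks))) {
    evb <- events[events$type == blocks$type[b] &
                    events$difficulty == blocks$difficulty[b], ]
    for (s0 in evb$sample) for (li in seq_along(lags)) {
      r <- s0 + lags[li]
      if (r >= 1 && r <= length(series))
        Xd[r, (b - 1) * length(lags) + li] <- 1
    }
  }
  keep <- colSums(Xd) > 0
  fit <- lm.fit(Xd[, keep, drop = FALSE], series)
  est <- as.vector(bet$beta[, paste(blocks$type, blocks$difficulty,
                                    sep = ".")])
  expect_equal(est[keep], unname(fit$coefficients), tolerance = 1e-6)
})

test_that("ridge shrinks monotonically and high-amplitude samples are excluded", {
  rate <- 50
  set.seed(8)
  series <- rnorm(4000)
  events <- data.frame(type = "response",
                       sample = sort(sample(200:3800, 30)), trial = 1,
                       difficulty = "easy", rt = NA)
  norms <- vapply(c(0, 1, 10, 100, 1e4), function(l)
    sum(deconvolve(series, events, rate = rate, window = c(-0.5, 0.5),
                   lambda = l)$beta^2), 0)
  expect_true(all(diff(norms) <= 1e-10))
  expect_lt(norms[5], 1e-3 * norms[1])
  # artifact exclusion: a huge-amplitude segment must not leak into betas
  series2 <- series
  series2[events$sample[3] + (0:10)] <- 1e4
  b_ex <- deconvolve(series2, events, rate = rate, window = c(-0.5, 0.5),
                     lambda = 1, amp_threshold = 250)
  expect_lt(max(abs(b_ex$beta)), 50)
})

test_that("cross-validated penalty selection and the study-level mode", {
  expect_equal(modal_lambda(c(4.5, 4.5, 6)), 4.5)
  expect_equal(modal_lambda(c(1, 2, 2, 1)), 1) # smallest on ties
  # noise-free data prefer the smallest penalty on the grid
  rate <- 50
  series <- numeric(3000)
  ev <- seq(100, 2900, by = 120)
  kern <- sin(seq(0, pi, length.out = 25))
  for (s0 in ev) series[s0:(s0 + 24)] <- series[s0:(s0 + 24)] + kern
  events <- data.frame(type = "response", sample = ev, trial = 1,
                       difficulty = "easy", rt = NA)
  cl <- choose_lambda(series, events, rate = rate, window = c(-0.4, 0.4),
                      lambdas = c(0.01, 1, 100), folds = 4)
  expect_equal(cl$lambda, 0.01)
  expect_true(all(is.finite(cl$cv_error)))
})

test_that("slope extraction is exact for linear and constant waveforms", {
  tv <- seq(-1, 1 - 1 / 250, by = 1 / 250)
  bm <- cbind("response.easy" = 3 + 2 * tv, "response.difficult" = 1.5)
  bet <- structure(list(beta = bm, time = tv, lambda = 0, rate = 250),
                   class = "deconv_betas")
  expect_equal(extract_slope(bet, "easy"), 2, tolerance = 1e-10)
  expect_equal(extract_slope(bet, "difficult"), 0, tolerance = 1e-10)
  # the window is 51 samples at 250 Hz, endpoints inclusive
  sel <- tv >= -0.2 - 1e-9 & tv <= 0 + 1e-9
  expect_equal(sum(sel), 51)
})

test_that("EEG recordings round-trip through the binary + JSON format", {
  set.seed(9)
  sig <- matrix(rnorm(4 * 200, sd = 20), 4, 200)
  ev <- data.frame(type = c("random_onset", "stimulus", "response"),
                   sample = c(10L, 60L, 120L), trial = 1L,
                   difficulty = "easy", rt = c(NA, NA, 0.24))
  rec <- eeg_recording(sig, 250, ev, cp_channels = c(2L, 3L))
  prefix <- tempfile()
  write_eeg(rec, prefix)
  back <- read_eeg(prefix)
  expect_equal(back$signal, rec$signal, tolerance = 1e-6) # float32
  expect_equal(back$rate, rec$rate)
  expect_equal(back$cp_channels, rec$cp_channels)
  expect_equal(back$events$sample, rec$events$sample)
  expect_equal(back$events$type, rec$events$type)
  unlink(paste0(prefix, c(".dat", ".json")))
})

test_that("full pipeline recovers known slopes from clean recordings", {
  tr <- ground_truth(eeg_noise_sd = 1, rho_eeg = 0.6, seed = 91)
  pp <- generate_participants(4, tr)
  des <- build_design("motion_coherence", blocks = 1, repetitions = 6,
                      seed = 91)
  beh <- filter_trials(generate_behaviour(pp, des, seed = 92))
  recs <- generate_eeg(pp, beh, tr)
  out <- eeg_slopes(recs, lambda = 1)
  m <- merge(out$slopes, attr(recs, "true_slopes"),
             by = c("participant", "difficulty"))
  expect_gt(cor(m$slope.x, m$slope.y), 0.95)
})
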