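#' Ground truth for synthetic datasets
#'
#' Collects the population-level settings from which a synthetic study is
#' generated: group-level means, spreads and half group differences for each
#' diffusion parameter, the EEG slope link, and the questionnaire link. The
#' default means are the prior means of the hierarchical model (the
#' analysis makes no other population commitment), and the default spreads
#' are set to the population scale typical of hierarchical diffusion
#' studies of children, chosen so that a generated study reproduces the
#' observed data conditions (roughly 1% of trials censored at the deadline
#' and well under 2% excluded below the RT floor). Group values are
#' `mu + delta` for the autistic-labelled group and `mu - delta` for the
#' comparison group, so the generated group difference is `2 * delta`.
#'
#' @param mu named numeric: `a`, `z` (relative start), `ter`, `v.diff`,
#'   `v.mean`.
#' @param sigma named numeric of positive spreads, same names.
#' @param delta named numeric of half group differences, same names.
#' @param eeg_slope_gain EEG slope units (uV/s) per drift unit.
#' @param eeg_noise_sd measurement noise SD of the synthetic EEG (uV).
#' @param rho_eeg target correlation between the true slope average and
#'   `v.mean` across participants.
#' @param rho_adhd target latent correlations for the questionnaire link,
#'   one per group `c(comparison = , autistic = )`.
#' @param seed integer; reproduces every generated dataset bit-exactly.
#' @return A `ground_truth` object (list).
#' @export
ground_truth <- function(mu = c(a = 0.2, z = 0.5, ter = 0.3,
                                v.diff = 0, v.mean = 0.3),
                         sigma = c(a = 0.05, z = 0.1, ter = 0.1,
                                   v.diff = 0.1, v.mean = 0.15),
                         delta = c(a = 0, z = 0, ter = 0,
                                   v.diff = 0, v.mean = 0),
                         eeg_slope_gain = 40, eeg_noise_sd = 10,
                         rho_eeg = 0.6,
                         rho_adhd = c(comparison = 0, autistic = -0.31),
                         seed = 1L) {
  nms <- c("a", "z", "ter", "v.diff", "v.mean")
  mu <- mu[nms]; sigma <- sigma[nms]; delta <- delta[nms]
  if (anyNA(mu) || anyNA(sigma) || anyNA(delta))
    stop("mu, sigma and delta must name all of: ", paste(nms, collapse = ", "),
         call. = FALSE)
  if (any(sigma <= 0))
    stop("invalid configuration: all sigma must be positive", call. = FALSE)
  if (!(mu[["a"]] > 0) || !(mu[["ter"]] >= 0) ||
      !(mu[["z"]] > 0 && mu[["z"]] < 1))
    stop("invalid configuration: mu out of support", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, delta = delta,
                 eeg_slope_gain = eeg_slope_gain,
                 eeg_noise_sd = eeg_noise_sd,
                 rho_eeg = rho_eeg, rho_adhd = rho_adhd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# truncated-normal draws by inverse-CDF
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# mean of a truncated normal (closed form)
tnorm_mean <- function(mean, sd, lo = -Inf, hi = Inf) {
  al <- (lo - mean) / sd
  be <- (hi - mean) / sd
  Z <- pnorm(be) - pnorm(al)
  mean + sd * (dnorm(al) - dnorm(be)) / Z
}

#' Draw participant-level diffusion parameters
#'
#' Samples `2 * n_per_group` participants from the group distributions of
#' the hierarchical model: `a ~ N+(mu_a +/- delta_a, sigma_a)`,
#' `z/a ~ TN(0,1)(mu_z +/- delta_z, sigma_z)`,
#' `ter ~ N+(mu_ter +/- delta_ter, sigma_ter)`, and normal laws for the
#' drift average and difficulty difference (`+delta` for the
#' autistic-labelled group, `-delta` for the comparison group). Within-trial
#' noise is fixed at `s = 0.1` for everyone.
#'
#' @param n_per_group participants per group, `>= 1`.
#' @param truth a [ground_truth] object.
#' @param seed seed; defaults to `truth$seed`.
#' @return Data.frame with columns `participant`, `group`, `a`, `zr`
#'   (relative start), `z`, `ter`, `v.diff`, `v.mean`, `v1`, `v2`, `s`.
#' @export
generate_participants <- function(n_per_group, truth, seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), n_per_group >= 1)
  if (any(truth$sigma <= 0))
    stop("invalid configuration: non-positive sigma", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  groups <- rep(c("autistic", "comparison"), each = n_per_group)
  sgn <- ifelse(groups == "autistic", 1, -1)
  n <- 2L * n_per_group
  mu <- truth$mu; sg <- truth$sigma; de <- truth$delta
  a   <- rtnorm(n, mu[["a"]]   + sgn * de[["a"]],   sg[["a"]],   lo = 0)
  zr  <- rtnorm(n, mu[["z"]]   + sgn * de[["z"]],   sg[["z"]],   lo = 0, hi = 1)
  ter <- rtnorm(n, mu[["ter"]] + sgn * de[["ter"]], sg[["ter"]], lo = 0)
  vd  <- rnorm(n, mu[["v.diff"]] + sgn * de[["v.diff"]], sg[["v.diff"]])
  vm  <- rnorm(n, mu[["v.mean"]] + sgn * de[["v.mean"]], sg[["v.mean"]])
  vv <- drifts_from_moments(vm, vd)
  data.frame(participant = sprintf("P%03d", seq_len(n)),
             group = groups, a = a, zr = zr, z = zr * a, ter = ter,
             v.diff = vd, v.mean = vm, v1 = vv$v1, v2 = vv$v2, s = 0.1,
             stringsAsFactors = FALSE)
}

#' Simulate behaviour for a participant table
#'
#' Runs every scheduled trial of the design through the diffusion process of
#' the corresponding participant (exact inverse-CDF sampling). Decision
#' trajectories still running at the deadline become no-response trials
#' (`response = "none"`, `rt = NA`). Optionally, a small fraction of
#' responded trials is replaced by fast contaminant RTs uniform on
#' [0, 200 ms) with a random response, purely to exercise the RT-floor
#' filter; the model itself has no contaminant component.
#'
#' @param params a participant table from [generate_participants()].
#' @param design a [build_design()] object.
#' @param contamination_rate fraction in `[0, 0.05)`.
#' @param catch_drift drift magnitude used for catch trials (unambiguous
#'   motion).
#' @param participants optional subset of participant ids to schedule; all
#'   by default. Ids absent from `params` are an error.
#' @param seed seed for trial noise.
#' @return A trial table (one row per scheduled trial per participant) with
#'   columns `participant`, `group`, `task`, `block`, `trial`, `difficulty`,
#'   `direction`, `response`, `rt`.
#' @export
generate_behaviour <- function(params, design, contamination_rate = 0,
                               catch_drift = 0.4,
                               participants = params$participant,
                               seed = 1L) {
  stopifnot(inherits(design, "trial_design"),
            contamination_rate >= 0, contamination_rate < 0.05)
  missing_p <- setdiff(participants, params$participant)
  if (length(missing_p))
    stop("missing participant(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  sched <- design$schedule
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  out <- vector("list", length(participants))
  for (k in seq_along(participants)) {
    pid <- participants[k]
    row <- params[params$participant == pid, ]
    p <- ddm_params(row$a, row$zr * row$a, row$ter, row$v1, row$v2, row$s)
    tab <- sched
    tab$participant <- pid
    tab$group <- row$group
    tab$task <- design$task
    tab$response <- NA_character_
    tab$rt <- NA_real_
    for (dif in c("easy", "difficult", "catch")) {
      for (dir in c("left", "right")) {
        idx <- which(tab$difficulty == dif & tab$direction == dir)
        if (!length(idx)) next
        vmag <- switch(dif, easy = row$v1, difficult = row$v2,
                       catch = catch_drift)
        v <- if (dir == "right") vmag else -vmag
        sim <- simulate_trials(length(idx), p, v = v,
                               deadline = design$deadline)
        resp <- ifelse(is.na(sim$response), "none",
                       ifelse(sim$response == "upper", "right", "left"))
        tab$response[idx] <- resp
        tab$rt[idx] <- sim$rt
      }
    }
    out[[k]] <- tab
  }
  out <- do.call(rbind, out)
  if (contamination_rate > 0) {
    responded <- which(out$response != "none")
    n_cont <- rbinom(1, length(responded), contamination_rate)
    if (n_cont > 0) {
      sel <- sample(responded, n_cont)
      out$rt[sel] <- runif(n_cont, 0, 0.2)
      out$response[sel] <- sample(c("left", "right"), n_cont, replace = TRUE)
    }
  }
  rownames(out) <- NULL
  out[, c("participant", "group", "task", "block", "trial", "difficulty",
          "direction", "response", "rt")]
}

# linear correlation between a standard normal latent and its squashed
# transform pnorm(mu + sd * z); used to correct copula attenuation
squash_attenuation <- function(mu, sd) {
  m1 <- integrate(function(z) pnorm(mu + sd * z) * dnorm(z), -8, 8)$value
  m2 <- integrate(function(z) pnorm(mu + sd * z)^2 * dnorm(z), -8, 8)$value
  mz <- integrate(function(z) z * pnorm(mu + sd * z) * dnorm(z), -8, 8)$value
  v <- m2 - m1^2
  if (v <= 0) return(1)
  mz / sqrt(v)
}

# latent normal (mu, sd) such that pnorm(mu + sd Z) has the target mean/sd
calibrate_squash <- function(target_mean, target_sd) {
  obj <- function(par) {
    mu <- par[1]; sd <- exp(par[2])
    m1 <- integrate(function(z) pnorm(mu + sd * z) * dnorm(z), -8, 8)$value
    m2 <- integrate(function(z) pnorm(mu + sd * z)^2 * dnorm(z), -8, 8)$value
    (m1 - target_mean)^2 + (sqrt(max(m2 - m1^2, 0)) - target_sd)^2
  }
  fit <- optim(c(qnorm(pmin(pmax(target_mean, 0.01), 0.99)), 0), obj,
               method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  c(mu = fit$par[1], sd = exp(fit$par[2]))
}

#' Generate ADHD questionnaire scores linked to a model parameter
#'
#' Draws average item scores on two subscales (`inatt`, `hyper`) on the unit interval
#' from a Gaussian copula with the chosen diffusion parameter: within each
#' group, the participant's standardised parameter value and an independent
#' normal are mixed at the target correlation, and the latent value is
#' squashed through the normal CDF calibrated so that each group attains its
#' configured mean and SD. The latent correlation is inflated to compensate
#' for the (mild) attenuation of the Pearson correlation induced by the
#' squashing, so the sampled linear correlation matches the target.
#'
#' @param params a participant table from [generate_participants()].
#' @param link linked parameter: `"v.mean"`, `"a"` or `"ter"`.
#' @param rho_target named correlations `c(comparison = , autistic = )`,
#'   each between -1 and 1.
#' @param group_means,group_sds lists with elements `inatt` and `hyper`,
#'   each a named vector per group. Defaults follow the observed sample:
#'   inattentiveness 0.17 (SD 0.23) in the comparison group and 0.58 (SD
#'   0.29) in the autistic group; hyperactivity 0.08 (0.19) and 0.55 (0.34).
#' @param seed seed.
#' @return Data.frame `participant`, `group`, `inatt`, `hyper`.
#' @export
generate_questionnaires <- function(params, link = c("v.mean", "a", "ter"),
                                    rho_target = c(comparison = 0,
                                                   autistic = -0.31),
                                    group_means = list(
                                      inatt = c(comparison = 0.17, autistic = 0.58),
                                      hyper = c(comparison = 0.08, autistic = 0.55)),
                                    group_sds = list(
                                      inatt = c(comparison = 0.23, autistic = 0.29),
                                      hyper = c(comparison = 0.19, autistic = 0.34)),
                                    seed = 1L) {
  link <- match.arg(link)
  if (any(abs(rho_target) > 1))
    stop("invalid correlation: |rho| must be <= 1", call. = FALSE)
  x <- params[[link]]
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  out <- data.frame(participant = params$participant, group = params$group,
                    inatt = NA_real_, hyper = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in unique(params$group)) {
    idx <- which(params$group == g)
    zx <- as.numeric(scale(x[idx]))
    if (any(!is.finite(zx))) zx <- rep(0, length(idx))
    rho <- rho_target[[g]]
    for (sub in c("inatt", "hyper")) {
      cal <- calibrate_squash(group_means[[sub]][[g]], group_sds[[sub]][[g]])
      lam <- squash_attenuation(cal[["mu"]], cal[["sd"]])
      rho_lat <- max(-1, min(1, rho / lam))
      zl <- rho_lat * zx + sqrt(max(0, 1 - rho_lat^2)) * rnorm(length(idx))
      out[[sub]][idx] <- pnorm(cal[["mu"]] + cal[["sd"]] * zl)
    }
  }
  out
}

# 1/f ("pink") noise, band-limited to the cleaned-data passband (the
# pipeline starts from preprocessed EEG, band-pass filtered 0.3-40 Hz).
# Spectral shaping of white noise at a highly composite FFT length.
pink_noise <- function(n, sd, rate = 250, band = c(0.3, 40)) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  f <- fft(w)
  k <- c(1, seq_len(m - 1))
  k <- pmin(k, m - k + 1) # two-sided bin index
  hz <- (k - 1) * rate / m
  shape <- 1 / sqrt(pmax(k - 1, 1))
  shape[hz < band[1] | hz > band[2]] <- 0
  x <- Re(fft(f * shape, inverse = TRUE))[seq_len(n)] / m
  sd * x / stats::sd(x)
}

#' Continuous EEG recording container
#'
#' @param signal channels x samples numeric matrix (uV).
#' @param rate sampling rate in Hz.
#' @param events data.frame with columns `type` (`random_onset`,
#'   `stimulus`, `response`), `sample` (1-based index), `trial`,
#'   `difficulty`, `rt`.
#' @param cp_channels indices of centro-parietal-like channels (used to fix
#'   component sign).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(signal, rate, events, cp_channels = NULL) {
  stopifnot(is.matrix(signal), rate > 0)
  if (nrow(events) &&
      (min(events$sample) < 1 || max(events$sample) > ncol(signal)))
    stop("scheduling error: events outside recording span", call. = FALSE)
  if (is.null(cp_channels))
    cp_channels <- seq_len(nrow(signal))
  structure(list(signal = signal, rate = rate, events = events,
                 cp_channels = cp_channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s), %d events\n",
              nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate, nrow(x$events)))
  invisible(x)
}

# smooth topography over an abstract channel array: Gaussian bump
topo_bump <- function(n_channels, centre_frac, width_frac = 0.15) {
  i <- seq_len(n_channels)
  exp(-((i / n_channels - centre_frac)^2) / (2 * width_frac^2))
}

# Draw the per-participant, per-difficulty true pre-response slopes:
# slope = sign(rho) * |gain| * v + eta, with the participant-level
# disturbance eta scaled so that cor(slope average, v.mean) = rho in
# expectation. Consumes nrow(params) normal draws from the current RNG.
draw_true_slopes <- function(params, truth) {
  gain <- truth$eeg_slope_gain
  rho <- truth$rho_eeg
  sd_v <- stats::sd(params$v.mean)
  if (!is.finite(sd_v) || sd_v == 0) sd_v <- 1
  if (rho == 0) {
    slope_gain <- 0
    sd_eta <- abs(gain) * sd_v
  } else {
    slope_gain <- sign(rho) * abs(gain) # sign of the link follows the target
    sd_eta <- abs(gain) * sd_v * sqrt(1 / rho^2 - 1)
  }
  eta <- rnorm(nrow(params), 0, sd_eta)
  per <- lapply(seq_len(nrow(params)), function(k)
    c(easy = slope_gain * params$v1[k] + eta[k],
      difficult = slope_gain * params$v2[k] + eta[k],
      catch = slope_gain * params$v1[k] + eta[k]))
  tab <- data.frame(
    participant = rep(params$participant, each = 2),
    difficulty = rep(c("easy", "difficult"), nrow(params)),
    slope = as.numeric(vapply(per, function(s) s[c("easy", "difficult")],
                              numeric(2))),
    stringsAsFactors = FALSE)
  list(table = tab, per_participant = per)
}

#' Ground-truth slope table without signal synthesis
#'
#' Draws the same per-participant true slopes that [generate_eeg()] embeds
#' in its recordings (identical values for the same seed), without
#' synthesising any continuous signal. Useful for joint-model recovery
#' studies where the slope measure itself is the quantity of interest.
#'
#' @inheritParams generate_eeg
#' @return Data.frame `participant`, `difficulty`, `slope`.
#' @export
true_slopes <- function(params, truth, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  draw_true_slopes(params, truth)$table
}

#' Default synthetic-EEG configuration
#'
#' @param n_channels number of channels (32 for desk-scale work; 128
#'   available).
#' @param rate sampling rate, Hz.
#' @param ramp_duration seconds of pre-response build-up.
#' @param stim_kernel_peak,stim_kernel_width seconds: latency and width of
#'   the Gaussian stimulus-evoked kernel.
#' @param stim_kernel_amp amplitude of the stimulus kernel (uV).
#' @return A list of settings.
#' @export
eeg_config <- function(n_channels = 32, rate = 250, ramp_duration = 0.6,
                       stim_kernel_peak = 0.3, stim_kernel_width = 0.08,
                       stim_kernel_amp = 5) {
  list(n_channels = n_channels, rate = rate, ramp_duration = ramp_duration,
       stim_kernel_peak = stim_kernel_peak,
       stim_kernel_width = stim_kernel_width,
       stim_kernel_amp = stim_kernel_amp,
       # response-locked (centro-parietal-like) and stimulus-locked
       # (posterior) topographies over the abstract channel array
       topo_response = topo_bump(n_channels, 0.55),
       topo_stimulus = topo_bump(n_channels, 0.85),
       cp_channels = which(topo_bump(n_channels, 0.55) > 0.6))
}

#' Generate synthetic continuous EEG for each participant
#'
#' Emulates the signal structure the analysis assumes: a stimulus-locked
#' evoked kernel and a response-locked linear ramp whose pre-response slope
#' is tied to the participant's drift-rate, both projected through fixed
#' topographies, plus 1/f measurement noise. Trials follow the behavioural
#' schedule (jittered fixation and random-motion periods, stimulus until
#' response or deadline, brief offset period), so stimulus- and
#' response-locked activity genuinely overlap at short RTs.
#'
#' The per-participant, per-difficulty true slope is
#' `gain * v + eta_p`, with the participant-level disturbance `eta_p` scaled
#' so that the correlation between the true slope average and `v.mean`
#' matches `truth$rho_eeg` in expectation (when `rho_eeg = 0` the gain is
#' dropped entirely). True slopes are stored in the `"true_slopes"`
#' attribute.
#'
#' @param params participant table.
#' @param behaviour trial table from [generate_behaviour()].
#' @param truth a [ground_truth] object.
#' @param cfg an [eeg_config()] list.
#' @param seed seed.
#' @return Named list of [eeg_recording] objects (one per participant), with
#'   attribute `"true_slopes"`: data.frame `participant`, `difficulty`,
#'   `slope`.
#' @export
generate_eeg <- function(params, behaviour, truth, cfg = eeg_config(),
                         seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  rate <- cfg$rate
  slopes_all <- draw_true_slopes(params, truth)
  true_slopes <- slopes_all$table
  recs <- vector("list", nrow(params))
  names(recs) <- params$participant
  for (k in seq_len(nrow(params))) {
    pid <- params$participant[k]
    tr <- behaviour[behaviour$participant == pid, , drop = FALSE]
    tr <- tr[order(tr$block, tr$trial), , drop = FALSE]
    n_tr <- nrow(tr)
    if (n_tr == 0) stop("no behaviour for participant ", pid, call. = FALSE)
    slopes <- slopes_all$per_participant[[k]]
    fix_dur <- runif(n_tr, 0.8, 1.0)
    rnd_dur <- runif(n_tr, 0.8, 1.0)
    stim_dur <- ifelse(tr$response == "none", 2.5, tr$rt)
    off_dur <- runif(n_tr, 0.2, 0.4)
    trial_dur <- fix_dur + rnd_dur + stim_dur + off_dur
    t0 <- c(0, cumsum(trial_dur))[seq_len(n_tr)]
    total <- sum(trial_dur) + 1
    n_samp <- ceiling(total * rate)
    comp_resp <- numeric(n_samp)  # response-locked component time course
    comp_stim <- numeric(n_samp)  # stimulus-locked component time course
    ev <- NULL
    ramp_n <- round(cfg$ramp_duration * rate)
    decay_n <- round(0.2 * rate)
    kern_len <- round(0.8 * rate)
    kern_t <- seq_len(kern_len) / rate
    kern <- cfg$stim_kernel_amp *
      exp(-((kern_t - cfg$stim_kernel_peak)^2) /
            (2 * cfg$stim_kernel_width^2))
    for (i in seq_len(n_tr)) {
      s_rand <- floor((t0[i] + fix_dur[i]) * rate) + 1L
      s_stim <- floor((t0[i] + fix_dur[i] + rnd_dur[i]) * rate) + 1L
      ev <- rbind(ev, data.frame(
        type = c("random_onset", "stimulus"),
        sample = c(s_rand, s_stim), trial = tr$trial[i],
        difficulty = tr$difficulty[i], rt = tr$rt[i],
        stringsAsFactors = FALSE))
      ki <- s_stim:(min(s_stim + kern_len - 1L, n_samp))
      comp_stim[ki] <- comp_stim[ki] + kern[seq_along(ki)]
      if (tr$response[i] != "none") {
        s_resp <- floor((t0[i] + fix_dur[i] + rnd_dur[i] + tr$rt[i]) * rate) + 1L
        ev <- rbind(ev, data.frame(
          type = "response", sample = s_resp, trial = tr$trial[i],
          difficulty = tr$difficulty[i], rt = tr$rt[i],
          stringsAsFactors = FALSE))
        # ramp rises linearly from 0 to sl * ramp_duration at the response,
        # then decays linearly back to 0 over 200 ms
        sl <- slopes[[tr$difficulty[i]]]
        peak <- sl * cfg$ramp_duration
        wave <- c(seq(0, peak, length.out = ramp_n + 1L),
                  seq(peak, 0, length.out = decay_n + 1L)[-1])
        pos <- (s_resp - ramp_n):(s_resp + decay_n)
        ok <- pos >= 1L & pos <= n_samp
        comp_resp[pos[ok]] <- comp_resp[pos[ok]] + wave[ok]
      }
    }
    sig <- outer(cfg$topo_response, comp_resp) +
           outer(cfg$topo_stimulus, comp_stim)
    if (truth$eeg_noise_sd > 0) {
      for (ch in seq_len(cfg$n_channels))
        sig[ch, ] <- sig[ch, ] +
          pink_noise(n_samp, truth$eeg_noise_sd, rate = rate)
    }
    recs[[k]] <- eeg_recording(sig, rate, ev, cp_channels = cfg$cp_channels)
  }
  attr(recs, "true_slopes") <- true_slopes
  recs
}
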