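#' Response-locked epochs from a continuous recording
#'
#' Extracts one epoch per response made between `rt_range[1]` and
#' `rt_range[2]` seconds after stimulus onset, spanning `window` around the
#' response sample, baselined per channel to the mean over the last 100 ms
#' of the random-motion period (the interval just before stimulus onset).
#'
#' @param recording an [eeg_recording] object.
#' @param window seconds around the response, default `c(-0.6, 0.2)`.
#' @param rt_range admissible RT range in seconds.
#' @param baseline_dur baseline duration in seconds before stimulus onset.
#' @return A 3-d array `trials x channels x time` with a `"time"`
#'   attribute (seconds relative to the response) and a `"difficulty"`
#'   attribute per trial.
#' @export
epoch_responses <- function(recording, window = c(-0.6, 0.2),
                            rt_range = c(0.2, 2.5), baseline_dur = 0.1) {
  stopifnot(inherits(recording, "eeg_recording"))
  ev <- recording$events
  rate <- recording$rate
  resp <- ev[ev$type == "response" & !is.na(ev$rt) &
               ev$rt >= rt_range[1] & ev$rt <= rt_range[2], , drop = FALSE]
  stim <- ev[ev$type == "stimulus", , drop = FALSE]
  i0 <- round(window[1] * rate)
  i1 <- round(window[2] * rate)
  nb <- round(baseline_dur * rate)
  n_samp <- ncol(recording$signal)
  keep <- resp$sample + i0 >= 1 & resp$sample + i1 <= n_samp
  resp <- resp[keep, , drop = FALSE]
  if (nrow(resp) == 0) stop("no usable response epochs", call. = FALSE)
  nt <- nrow(resp); nc <- nrow(recording$signal); nti <- i1 - i0 + 1
  out <- array(NA_real_, c(nt, nc, nti))
  for (i in seq_len(nt)) {
    s <- resp$sample[i]
    ep <- recording$signal[, (s + i0):(s + i1), drop = FALSE]
    st <- stim$sample[match(resp$trial[i], stim$trial)]
    if (!is.na(st) && st - nb >= 1) {
      bl <- rowMeans(recording$signal[, (st - nb):(st - 1), drop = FALSE])
      ep <- ep - bl
    }
    out[i, , ] <- ep
  }
  attr(out, "time") <- (i0:i1) / rate
  attr(out, "difficulty") <- resp$difficulty
  out
}

#' Reliable Components Analysis
#'
#' Finds spatial filters maximising trial-to-trial reliability: the
#' generalized eigenvalue problem `R_between w = lambda R_within w`, where
#' `R_within` pools each epoch's spatial covariance and `R_between` pools
#' the covariance across distinct epochs (reliable, phase-locked activity
#' contributes to both; trial-varying noise only to `R_within`). The
#' within covariance is shrunk by diagonal loading at 1% of its average
#' eigenvalue before inversion, which regularises rank-deficient data.
#' Components are ordered by reliability (eigenvalue); each component's
#' sign is fixed so its mean forward projection over the centro-parietal
#' channels is positive.
#'
#' @param epochs array `trials x channels x time` (see
#'   [epoch_responses()]), or a list of such arrays which is pooled.
#' @param n_components number of components to return.
#' @param cp_channels channel indices used for sign fixing; defaults to
#'   all.
#' @return A list of `reliable_component` objects: `weights` (spatial
#'   filter), `projection` (forward model, `R_within w` normalised),
#'   `reliability` (eigenvalue), `explained` (fraction of across-trial
#'   covariance among positive eigenvalues).
#' @export
rca <- function(epochs, n_components = 1, cp_channels = NULL) {
  if (is.list(epochs)) {
    nc <- dim(epochs[[1]])[2]
    Rw <- matrix(0, nc, nc); Sb <- matrix(0, nc, nc)
    n_tr_tot <- 0
    for (e in epochs) {
      acc <- pool_trial_cov(e)
      Rw <- Rw + acc$Rw; Sb <- Sb + acc$Sb
      n_tr_tot <- n_tr_tot + dim(e)[1]
    }
  } else {
    acc <- pool_trial_cov(epochs)
    Rw <- acc$Rw; Sb <- acc$Sb
    n_tr_tot <- dim(epochs)[1]
  }
  if (n_tr_tot < 2) stop("need at least 2 trials", call. = FALSE)
  nc <- nrow(Rw)
  if (is.null(cp_channels)) cp_channels <- seq_len(nc)
  load <- 0.01 * mean(diag(Rw)) # = 1% of the average eigenvalue
  Rw_s <- Rw + diag(load, nc)
  ch <- tryCatch(chol(Rw_s), error = function(e) NULL)
  if (is.null(ch)) {
    warning("within-trial covariance not positive definite; increasing shrinkage")
    Rw_s <- Rw + diag(10 * load + 1e-10, nc)
    ch <- chol(Rw_s)
  }
  iC <- backsolve(ch, diag(nc))
  M <- t(iC) %*% Sb %*% iC
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  lambda <- eg$values
  pos <- sum(pmax(lambda, 0))
  out <- vector("list", n_components)
  for (i in seq_len(n_components)) {
    w <- iC %*% eg$vectors[, i]
    proj <- Rw_s %*% w
    proj <- proj / sqrt(sum(proj^2))
    # biorthogonal scaling: w' proj = 1, so projecting data that contain
    # the component topography recovers the source up to its channel norm
    w <- w / sum(w * proj)
    if (mean(proj[cp_channels]) < 0) {
      w <- -w; proj <- -proj
    }
    out[[i]] <- structure(list(weights = as.numeric(w),
                               projection = as.numeric(proj),
                               reliability = lambda[i],
                               explained = if (pos > 0)
                                 max(lambda[i], 0) / pos else NA_real_),
                          class = "reliable_component")
  }
  out
}

# within-trial and across-trial covariance accumulators for one epoch array
pool_trial_cov <- function(epochs) {
  stopifnot(length(dim(epochs)) == 3)
  nt <- dim(epochs)[1]; nc <- dim(epochs)[2]
  Rw <- matrix(0, nc, nc)
  S <- matrix(0, nc, dim(epochs)[3])
  for (i in seq_len(nt)) {
    X <- matrix(epochs[i, , ], nc)
    X <- X - rowMeans(X)
    Rw <- Rw + tcrossprod(X)
    S <- S + X
  }
  # sum over t != t' of X_t X_t'^T = S S^T - sum_t X_t X_t^T
  Sb <- tcrossprod(S) - Rw
  Sb <- (Sb + t(Sb)) / 2
  list(Rw = Rw / nt, Sb = Sb / max(nt * (nt - 1), 1))
}

#' @export
print.reliable_component <- function(x, ...) {
  cat(sprintf("Reliable component: reliability %.3g, explained covariance %.1f%%\n",
              x$reliability, 100 * x$explained))
  invisible(x)
}

#' Project a recording through a spatial filter
#'
#' Multiplies the continuous multichannel signal by the component's spatial
#' weights, yielding a single-channel component time series. Linear in the
#' weights; a unit weight on channel k returns channel k.
#'
#' @param recording an [eeg_recording] object.
#' @param component a `reliable_component` (or a bare numeric weight
#'   vector).
#' @return Numeric vector, one value per sample.
#' @export
rca_project <- function(recording, component) {
  w <- if (inherits(component, "reliable_component")) component$weights
       else as.numeric(component)
  stopifnot(length(w) == nrow(recording$signal))
  as.numeric(crossprod(w, recording$signal))
}

# triplets of the time-expanded design matrix: one predictor per
# (event type x difficulty x lag). Returns also the column dictionary.
build_design_triplets <- function(events, n_samp, rate, window,
                                  event_types = c("stimulus", "response"),
                                  difficulties = c("difficult", "easy")) {
  lag0 <- round(window[1] * rate)
  lag1 <- round(window[2] * rate) - 1L
  lags <- lag0:lag1
  nlag <- length(lags)
  cols <- expand.grid(lag_idx = seq_len(nlag), difficulty = difficulties,
                      type = event_types, stringsAsFactors = FALSE)
  blocks <- expand.grid(difficulty = difficulties, type = event_types,
                        stringsAsFactors = FALSE)
  ri <- integer(0); ci <- integer(0)
  for (b in seq_len(nrow(blocks))) {
    ev <- events[events$type == blocks$type[b] &
                   events$difficulty == blocks$difficulty[b], , drop = FALSE]
    if (!nrow(ev)) next
    rows <- rep(ev$sample, each = nlag) + rep(lags, nrow(ev))
    colv <- rep((b - 1L) * nlag + seq_len(nlag), nrow(ev))
    ok <- rows >= 1L & rows <= n_samp
    ri <- c(ri, rows[ok]); ci <- c(ci, colv[ok])
  }
  list(i = ri, j = ci, ncol = nrow(blocks) * nlag,
       cols = cols, lags = lags, nlag = nlag, blocks = blocks)
}

#' Deconvolve overlapping event-locked responses
#'
#' Estimates regression-ERP waveforms by time expansion: the design matrix
#' has one predictor per (event type x difficulty x timepoint) over the
#' `window` around each event, and the least-squares (or ridge) solution
#' unmixes temporally overlapping stimulus- and response-locked activity.
#' Samples whose absolute amplitude exceeds `amp_threshold` are excluded
#' from the design matrix. At the default 250 Hz and a -1 to +1 s window
#' each condition has 500 timepoints.
#'
#' @param series numeric vector: the projected single-channel continuous
#'   signal.
#' @param events event data.frame (`type`, `sample`, `difficulty`); only
#'   `stimulus` and `response` events are modelled.
#' @param rate sampling rate, Hz.
#' @param window seconds around each event, default `c(-1, 1)`.
#' @param lambda ridge penalty (0 = ordinary least squares; a singular
#'   system then falls back to the minimum-norm solution with a warning).
#' @param amp_threshold artifact amplitude threshold (uV).
#' @return A `deconv_betas` object: `beta` matrix `timepoints x condition`
#'   (columns named `type.difficulty`), `time` in seconds, `lambda`.
#' @export
deconvolve <- function(series, events, rate = 250, window = c(-1, 1),
                       lambda = 0, amp_threshold = 250) {
  stopifnot(lambda >= 0)
  n_samp <- length(series)
  if (nrow(events) && max(events$sample) > n_samp)
    stop("events outside recording span", call. = FALSE)
  trip <- build_design_triplets(events, n_samp, rate, window)
  bad <- which(abs(series) > amp_threshold)
  if (length(bad)) {
    keep <- !(trip$i %in% bad)
    trip$i <- trip$i[keep]; trip$j <- trip$j[keep]
  }
  X <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = 1,
                            dims = c(n_samp, trip$ncol))
  # predictors with no events (e.g. a condition absent from this
  # recording) are dropped and reported as zero
  used <- which(Matrix::colSums(X) > 0)
  Xu <- X[, used, drop = FALSE]
  XtX <- Matrix::crossprod(Xu)
  Xty <- as.numeric(Matrix::crossprod(Xu, series))
  bu <- tryCatch(
    as.numeric(Matrix::solve(XtX + Matrix::Diagonal(length(used), lambda),
                             Xty)),
    error = function(e) NULL)
  if (is.null(bu)) {
    warning("singular design; returning minimum-norm solution")
    A <- as.matrix(XtX) + diag(lambda, length(used))
    sv <- svd(A)
    tol <- max(sv$d) * 1e-10
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    bu <- sv$v %*% (dinv * crossprod(sv$u, Xty))
  }
  beta <- numeric(trip$ncol)
  beta[used] <- bu
  bm <- matrix(beta, nrow = trip$nlag)
  colnames(bm) <- paste(trip$blocks$type, trip$blocks$difficulty, sep = ".")
  structure(list(beta = bm, time = trip$lags / rate, lambda = lambda,
                 rate = rate),
            class = "deconv_betas")
}

#' Choose the ridge penalty by cross-validation
#'
#' Splits the recording into contiguous temporal folds, fits the
#' deconvolution model on the training folds for every candidate penalty
#' and scores predictive squared error on the held-out fold (over samples
#' covered by at least one predictor). Returns the per-participant error
#' curve and the arg-min; use [modal_lambda()] to constrain a study to one
#' shared value.
#'
#' @inheritParams deconvolve
#' @param lambdas candidate penalties; default a log grid from 1e-2 to 1e3
#'   augmented with the 4-6 region.
#' @param folds number of contiguous folds.
#' @return List: `lambda` (arg-min), `cv_error` (named per candidate).
#' @export
choose_lambda <- function(series, events, rate = 250, window = c(-1, 1),
                          lambdas = sort(c(10^seq(-2, 3, length.out = 11),
                                           4.5, 5.5, 6)),
                          folds = 5, amp_threshold = 250) {
  n_samp <- length(series)
  trip <- build_design_triplets(events, n_samp, rate, window)
  bad <- which(abs(series) > amp_threshold)
  if (length(bad)) {
    keep <- !(trip$i %in% bad)
    trip$i <- trip$i[keep]; trip$j <- trip$j[keep]
  }
  X <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = 1,
                            dims = c(n_samp, trip$ncol))
  fold_id <- cut(seq_len(n_samp), folds, labels = FALSE)
  covered <- Matrix::rowSums(X) > 0
  err <- setNames(numeric(length(lambdas)), signif(lambdas, 4))
  for (f in seq_len(folds)) {
    test <- fold_id == f & covered
    train <- fold_id != f
    Xtr <- X[train, , drop = FALSE]
    XtX <- Matrix::crossprod(Xtr)
    Xty <- as.numeric(Matrix::crossprod(Xtr, series[train]))
    Xte <- X[test, , drop = FALSE]
    yte <- series[test]
    for (k in seq_along(lambdas)) {
      beta <- Matrix::solve(XtX + Matrix::Diagonal(trip$ncol,
                                                   lambdas[k] + 1e-10),
                            Xty)
      pred <- as.numeric(Xte %*% beta)
      err[k] <- err[k] + sum((yte - pred)^2)
    }
  }
  err <- err / sum(covered)
  list(lambda = lambdas[which.min(err)], cv_error = err)
}

#' Modal penalty across participants
#'
#' The most frequent per-participant penalty (smallest value on ties),
#' used to constrain the study to a single regularisation parameter so
#' that regularisation differences cannot masquerade as group differences.
#'
#' @param lambdas numeric vector of per-participant arg-min penalties.
#' @return A single penalty value.
#' @examples
#' modal_lambda(c(4.5, 4.5, 6))  # 4.5
#' @export
modal_lambda <- function(lambdas) {
  tab <- table(lambdas)
  as.numeric(names(tab)[which.max(tab)])
}

#' Pre-response slope of a deconvolved waveform
#'
#' Ordinary least-squares slope (uV/s) of the response-locked regression
#' ERP over the window from 200 ms before the response to the response
#' itself (51 samples at 250 Hz, endpoints inclusive).
#'
#' @param betas a `deconv_betas` object.
#' @param difficulty `"easy"` or `"difficult"`.
#' @param window slope window in seconds relative to the response.
#' @return Slope in uV/s.
#' @export
extract_slope <- function(betas, difficulty = c("easy", "difficult"),
                          window = c(-0.2, 0)) {
  difficulty <- match.arg(difficulty)
  col <- paste0("response.", difficulty)
  if (!col %in% colnames(betas$beta))
    stop("no response waveform for difficulty ", difficulty, call. = FALSE)
  sel <- betas$time >= window[1] - 1e-9 & betas$time <= window[2] + 1e-9
  y <- betas$beta[sel, col]
  t <- betas$time[sel]
  as.numeric(coef(lm(y ~ t))[2])
}

#' Read / write an EEG recording on disk
#'
#' A recording is stored as two files: `<prefix>.dat`, the signal as
#' little-endian float32 values in channel-major order (all samples of
#' channel 1, then channel 2, ...), and `<prefix>.json`, a header with the
#' channel count, sampling rate, centro-parietal channel indices and the
#' event list. Values round-trip at float32 precision.
#'
#' @param recording an [eeg_recording] object.
#' @param prefix file path without extension.
#' @return `write_eeg` returns `prefix` invisibly; `read_eeg` returns an
#'   [eeg_recording].
#' @export
write_eeg <- function(recording, prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  header <- list(n_channels = nrow(recording$signal),
                 n_samples = ncol(recording$signal),
                 rate = recording$rate,
                 cp_channels = recording$cp_channels,
                 events = recording$events)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$signal)), con, size = 4,
           endian = "little")
  invisible(prefix)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(prefix) {
  header <- jsonlite::fromJSON(paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = header$n_channels * header$n_samples,
               size = 4, endian = "little")
  sig <- matrix(x, nrow = header$n_channels, byrow = TRUE)
  ev <- as.data.frame(header$events, stringsAsFactors = FALSE)
  eeg_recording(sig, header$rate, ev, cp_channels = header$cp_channels)
}

#' Full pipeline: recordings to per-participant slope measures
#'
#' Pools all participants' baselined response-locked epochs, runs Reliable
#' Components Analysis, projects each participant's continuous data through
#' the most reliable component's weights, deconvolves overlapping stimulus-
#' and response-locked activity with the given ridge penalty (chosen by
#' cross-validation and constrained to the modal value across participants
#' when `lambda = NULL`), and extracts the pre-response slope per
#' difficulty level.
#'
#' @param recordings named list of [eeg_recording] objects.
#' @param lambda ridge penalty; `NULL` selects it by per-participant
#'   cross-validation followed by the study-level mode.
#' @param window deconvolution window, seconds.
#' @param epoch_window response-locked epoch window for RCA, seconds.
#' @param amp_threshold artifact threshold (uV).
#' @return A list: `slopes` (data.frame `participant`, `difficulty`,
#'   `slope`), `component` (the reliable component), `lambda`.
#' @export
eeg_slopes <- function(recordings, lambda = NULL, window = c(-1, 1),
                       epoch_window = c(-0.6, 0.2), amp_threshold = 250) {
  epochs <- lapply(recordings, epoch_responses, window = epoch_window)
  comp <- rca(epochs, n_components = 1,
              cp_channels = recordings[[1]]$cp_channels)[[1]]
  series <- lapply(recordings, rca_project, component = comp)
  rate <- recordings[[1]]$rate
  if (is.null(lambda)) {
    per <- vapply(seq_along(recordings), function(k)
      choose_lambda(series[[k]], recordings[[k]]$events, rate = rate,
                    window = window, amp_threshold = amp_threshold)$lambda,
      0)
    lambda <- modal_lambda(per)
  }
  slopes <- NULL
  for (k in seq_along(recordings)) {
    bet <- deconvolve(series[[k]], recordings[[k]]$events, rate = rate,
                      window = window, lambda = lambda,
                      amp_threshold = amp_threshold)
    for (dif in c("easy", "difficult")) {
      slopes <- rbind(slopes, data.frame(
        participant = names(recordings)[k], difficulty = dif,
        slope = extract_slope(bet, dif), stringsAsFactors = FALSE))
    }
  }
  list(slopes = slopes, component = comp, lambda = lambda)
}
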