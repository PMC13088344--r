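#' STFT spectrogram features of a 10 s sensor window
#'
#' Per channel (hot film HF, cold film CF, and the scalar reference
#' acceleration ACC), computes a Hann-windowed short-time Fourier transform
#' with 2 s (200-sample) windows hopped by 1 s (100 samples), one-sided
#' spectrum, and `log(1 + magnitude)` scaling. At 100 Hz this yields exactly
#' `(1000 - 200) / 100 + 1 = 9` time frames and `200 / 2 + 1 = 101`
#' frequency bins per channel (0.5 Hz resolution).
#'
#' @param stream_window `sensor_stream` slice of exactly `window_s` seconds,
#'   or a list with numeric fields `hf`, `cf`, `aref` of equal length.
#' @param fs sampling rate in Hz (default 100).
#' @param window_s spectrogram window in seconds (default 10).
#' @param stft_window_s STFT window in seconds (default 2).
#' @param step_s STFT hop in seconds (default 1).
#' @return Numeric array of dimension `(3, bins, frames)` — `(3, 101, 9)` at
#'   the defaults — with channel dimnames `HF`, `CF`, `ACC`.
#' @export
stft_features <- function(stream_window, fs = 100, window_s = 10,
                          stft_window_s = 2, step_s = 1) {
  if (inherits(stream_window, "sensor_stream")) {
    chans <- list(HF = stream_window$hf, CF = stream_window$cf,
                  ACC = reference_acceleration(stream_window$acc))
    fs <- stream_window$fs
  } else {
    chans <- list(HF = stream_window$hf, CF = stream_window$cf,
                  ACC = stream_window$aref)
  }
  n_expect <- round(window_s * fs)
  if (any(vapply(chans, length, 1L) != n_expect)) {
    stop(sprintf("window must contain exactly %d samples per channel", n_expect))
  }
  nw <- round(stft_window_s * fs)
  hop <- round(step_s * fs)
  n_frames <- (n_expect - nw) %/% hop + 1L
  n_bins <- nw %/% 2L + 1L
  w <- as.numeric(signal::hanning(nw))
  out <- array(0, dim = c(3L, n_bins, n_frames),
               dimnames = list(c("HF", "CF", "ACC"), NULL, NULL))
  for (c_i in 1:3) {
    x <- chans[[c_i]]
    for (f_i in seq_len(n_frames)) {
      seg <- x[((f_i - 1L) * hop + 1L):((f_i - 1L) * hop + nw)]
      out[c_i, , f_i] <- log1p(Mod(stats::fft(seg * w))[seq_len(n_bins)])
    }
  }
  out
}

# Window features on the raw channel scale used to construct synthetic
# metabolic targets: band power of the reference acceleration (1-5 Hz),
# mean cold-film level, and low-frequency (<= 0.4 Hz, incl. DC) hot-film
# power.
window_target_features <- function(hf, cf, aref, fs) {
  n <- length(hf)
  freq <- (seq_len(n %/% 2L + 1L) - 1L) * fs / n
  pow <- function(x, f_lo, f_hi, keep_dc = FALSE) {
    X <- Mod(stats::fft(x))[seq_len(n %/% 2L + 1L)]
    wgt <- rep(2, length(X)) # one-sided spectrum doubles non-DC bins
    wgt[1L] <- 1
    sel <- freq >= f_lo & freq <= f_hi
    if (!keep_dc) sel[1L] <- FALSE
    sum(wgt[sel] * X[sel]^2) / n^2
  }
  c(acc = pow(aref, 1, 5),
    cf = mean(cf),
    hf = pow(hf, 0, 0.4, keep_dc = TRUE))
}

#' Synthetic labelled metabolic sessions
#'
#' Generates simulated sensor sessions with a known, recoverable mapping from
#' the channels to a metabolic-rate target: for every 10 s window,
#' `target = intercept + a*f_acc + b*f_cf + c*f_hf` where `f_acc` is the 1-5
#' Hz band power of the reference acceleration, `f_cf` the mean cold-film
#' level, and `f_hf` the low-frequency (<= 0.4 Hz) hot-film power. The
#' hot-film baseline carries a strong independent slow modulation
#' (`baseline_wander_sd`), so the `f_hf` component cannot be predicted from
#' the other channels — ablating the HF input must therefore cost accuracy
#' whenever `coupling["hf"] > 0`.
#'
#' Each session uses its own random segment intensities, so sessions differ
#' in activity content (the leave-one-out setting).
#'
#' @param n_sessions number of sessions (>= 3 for LOO).
#' @param n_segments activity segments per session.
#' @param segment_duration seconds per segment.
#' @param coupling named vector `c(acc=, cf=, hf=)` of target weights in
#'   W/kg per feature unit.
#' @param intercept target intercept in W/kg.
#' @param hop_s window hop in seconds.
#' @param seed integer seed.
#' @param true_params artifact model driving the simulated streams.
#' @param baseline_wander_sd sd of the independent hot-film baseline
#'   modulation.
#' @return List of sessions; each session is a list with `features`
#'   (`n_windows x 3 x 101 x 9` array), `target` (W/kg), `label` (activity
#'   label at each window end) and `stream`.
#' @export
synth_metabolic_dataset <- function(n_sessions = 3L, n_segments = 6L,
                                    segment_duration = 30,
                                    coupling = c(acc = 0.6, cf = 4, hf = 1.2),
                                    intercept = 0.8,
                                    hop_s = 2,
                                    seed = 1L,
                                    true_params = artifact_params(0.4, 0.5, 2 * pi * 4),
                                    baseline_wander_sd = 0.6) {
  sessions <- vector("list", n_sessions)
  for (s_i in seq_len(n_sessions)) {
    s_seed <- seed_child(seed, 1000L + s_i)
    intens <- with_seed(s_seed, stats::runif(n_segments, 0, 1))
    proto <- exercise_protocol(data.frame(
      label = paste0("seg", seq_len(n_segments), "_",
                     round(intens * 10)),
      duration = rep(segment_duration, n_segments),
      intensity = intens))
    stream <- synth_session(proto, true_params,
                            noise_cfg = list(baseline_wander_sd = baseline_wander_sd),
                            seed = seed_child(s_seed, 2L))
    ds <- windows_with_targets(stream, coupling, intercept, hop_s = hop_s)
    sessions[[s_i]] <- c(ds, list(stream = stream))
  }
  sessions
}

# Slice a stream into 10 s windows and attach synthetic targets.
windows_with_targets <- function(stream, coupling, intercept, hop_s = 2,
                                 window_s = 10) {
  fs <- stream$fs
  win <- window_s * fs
  hop <- hop_s * fs
  aref <- reference_acceleration(stream$acc)
  ends <- seq(win, length(stream$hf), by = hop)
  n_w <- length(ends)
  n_bins <- round(2 * fs) %/% 2L + 1L # 2 s STFT windows -> fs + 1 bins
  n_frames <- (window_s - 2L) %/% 1L + 1L
  features <- array(0, dim = c(n_w, 3L, n_bins, n_frames))
  target <- numeric(n_w)
  label <- character(n_w)
  for (k in seq_len(n_w)) {
    idx <- (ends[k] - win + 1L):ends[k]
    sw <- list(hf = stream$hf[idx], cf = stream$cf[idx], aref = aref[idx])
    features[k, , , ] <- stft_features(sw, fs = fs, window_s = window_s)
    fvec <- window_target_features(sw$hf, sw$cf, sw$aref, fs)
    target[k] <- intercept + sum(coupling * fvec[names(coupling)])
    label[k] <- if (!is.null(stream$truth)) stream$truth$label[ends[k]] else NA_character_
  }
  list(features = features, target = target, label = label,
       t_end = ends / fs)
}

#' Train the metabolic CNN
#'
#' Trains the compact convolutional regressor (per-channel conv trunks, 3x3
#' kernels with 16 then 32 filters and 2x2 average pooling, merged into a
#' dense 64 layer and a softplus scalar output in W/kg) with Adam on mean
#' squared error. Spectrograms are z-normalized per channel using training-set
#' statistics only.
#'
#' @param dataset list with `features` (`N x 3 x 101 x 9` array) and `target`
#'   (numeric, W/kg, finite).
#' @param cfg list: `lr` (default 1e-3), `epochs` (default 60), `batch_size`
#'   (default 32), `seed` (default 1), `channels` (default
#'   `c("HF","CF","ACC")`; drop names to ablate inputs), `filters`, `dense`.
#' @return An object of class `metabolic_model` with the trained weights,
#'   normalization statistics, channel set and training curve.
#' @export
train_metabolic <- function(dataset, cfg = list()) {
  cfg <- utils::modifyList(
    list(lr = 1e-3, epochs = 60L, batch_size = 32L, seed = 1L,
         channels = c("HF", "CF", "ACC"), filters = c(16L, 32L),
         dense = 64L, min_windows = 100L), cfg)
  features <- dataset$features
  y <- dataset$target
  stopifnot(length(dim(features)) == 4L, dim(features)[1L] == length(y),
            all(is.finite(y)))
  N <- length(y)
  if (N < cfg$min_windows) {
    stop(sprintf("need at least %d labelled windows, got %d",
                 cfg$min_windows, N))
  }
  if (stats::sd(y) < 1e-10) {
    warning("degenerate targets (zero variance); model will predict the constant")
  }
  all_channels <- c("HF", "CF", "ACC")
  channel_idx <- match(cfg$channels, all_channels)
  stopifnot(!anyNA(channel_idx))
  norm <- list(
    mean = vapply(channel_idx, function(ch) mean(features[, ch, , ]), 1),
    sd = vapply(channel_idx, function(ch) {
      s <- stats::sd(features[, ch, , ]); if (s < 1e-12) 1 else s
    }, 1))
  net <- cnn_init(input_dim = dim(features)[3:4],
                  n_channels = length(channel_idx),
                  filters = cfg$filters, dense = cfg$dense,
                  seed = seed_child(cfg$seed, 1L), y_mean = mean(y))
  xcols <- features_to_columns(features, channel_idx, norm)
  xmats <- lapply(xcols, function(xc) matrix(xc, nrow = N))
  opt <- adam_init(net$params)
  caches <- list()
  curve <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(seed_child(cfg$seed, 10L + epoch), sample.int(N))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      nb <- length(b)
      key <- as.character(nb)
      if (is.null(caches[[key]])) caches[[key]] <- make_rowcache(net$geom, nb)
      rc <- caches[[key]]
      # subset the column layout: rows of sample n are n, n+N, n+2N, ...
      xb <- lapply(xmats, function(m) {
        matrix(as.numeric(m[b, , drop = FALSE]), ncol = 1L)
      })
      fwd <- cnn_forward(net, xb, rc, keep = TRUE)
      ep_loss <- ep_loss + sum((fwd$yhat - y[b])^2)
      grads <- cnn_backward(net, xb, y[b], fwd, rc)
      upd <- adam_step(net$params, grads, opt, lr = cfg$lr)
      net$params <- upd$params
      opt <- upd$state
    }
    curve[epoch] <- ep_loss / N
  }
  structure(list(net = net, norm = norm, channels = cfg$channels,
                 channel_idx = channel_idx, cfg = cfg,
                 training_curve = curve),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "metabolic_model: channels [%s], final training MSE %.4g (W/kg)^2\n",
    paste(x$channels, collapse = ", "),
    x$training_curve[length(x$training_curve)]))
  invisible(x)
}

# Predict on a features array (N x 3 x 101 x 9), chunked to bound memory.
predict_features <- function(model, features, chunk = 128L) {
  N <- dim(features)[1L]
  out <- numeric(N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    sub <- features[idx, , , , drop = FALSE]
    rc <- make_rowcache(model$net$geom, length(idx))
    xcols <- features_to_columns(sub, model$channel_idx, model$norm)
    out[idx] <- cnn_forward(model$net, xcols, rc)$yhat
  }
  out
}

#' Predict metabolic rate along a sensor stream
#'
#' Emits one estimate per second from the trailing 10 s spectrogram window;
#' the first valid output is at t = 10 s.
#'
#' @param model a trained [train_metabolic()] model.
#' @param stream a `sensor_stream` of at least 10 s.
#' @return Data frame with columns `t` (seconds, window end) and `met_wkg`.
#' @export
predict_metabolic <- function(model, stream) {
  stopifnot(inherits(model, "metabolic_model"))
  fs <- stream$fs
  win <- round(10 * fs)
  if (length(stream$hf) < win) stop("stream shorter than one 10 s window")
  aref <- reference_acceleration(stream$acc)
  ends <- seq(win, length(stream$hf), by = round(fs))
  features <- array(0, dim = c(length(ends), 3L, 101L, 9L))
  for (k in seq_along(ends)) {
    idx <- (ends[k] - win + 1L):ends[k]
    features[k, , , ] <- stft_features(
      list(hf = stream$hf[idx], cf = stream$cf[idx], aref = aref[idx]),
      fs = fs)
  }
  data.frame(t = ends / fs, met_wkg = predict_features(model, features))
}

#' Mean absolute percentage error
#' @param predicted,actual numeric vectors; `actual` must be non-zero.
#' @return MAPE in percent.
#' @export
mape <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), all(actual != 0))
  100 * mean(abs(predicted - actual) / abs(actual))
}

#' Average absolute error
#' @param predicted,actual numeric vectors.
#' @return Mean absolute error (W/kg for metabolic targets).
#' @export
aae <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  mean(abs(predicted - actual))
}

#' Leave-one-out evaluation over labelled sessions
#'
#' For each session in turn, trains on all remaining sessions and tests on
#' the held-out one; reports the mean MAPE and AAE across folds and the AAE
#' per activity label.
#'
#' @param trials list of >= 3 sessions, each with `features`, `target` and
#'   optionally `label` (as produced by [synth_metabolic_dataset()]).
#' @param cfg training configuration passed to [train_metabolic()].
#' @return An object of class `eval_report`: list with `mape` (%), `aae`
#'   (W/kg), `per_fold` data frame and `per_segment` AAE by label.
#' @export
loo_evaluate <- function(trials, cfg = list()) {
  if (length(trials) < 3L) stop("leave-one-out evaluation needs >= 3 sessions")
  folds <- length(trials)
  per_fold <- data.frame(fold = seq_len(folds), mape = NA_real_,
                         aae = NA_real_)
  seg_err <- list()
  for (f in seq_len(folds)) {
    train_idx <- setdiff(seq_len(folds), f)
    feats <- do.call(abind1, lapply(trials[train_idx], `[[`, "features"))
    targs <- unlist(lapply(trials[train_idx], `[[`, "target"))
    fold_cfg <- utils::modifyList(cfg, list())
    fold_cfg$seed <- seed_child(cfg$seed %||% 1L, f)
    model <- train_metabolic(list(features = feats, target = targs),
                             cfg = fold_cfg)
    test <- trials[[f]]
    pred <- predict_features(model, test$features)
    per_fold$mape[f] <- mape(pred, test$target)
    per_fold$aae[f] <- aae(pred, test$target)
    if (!is.null(test$label)) {
      seg_err[[f]] <- data.frame(label = test$label,
                                 err = abs(pred - test$target))
    }
  }
  per_segment <- if (length(seg_err)) {
    all_seg <- do.call(rbind, seg_err)
    stats::aggregate(err ~ label, all_seg, mean)
  } else NULL
  structure(list(mape = mean(per_fold$mape), aae = mean(per_fold$aae),
                 per_fold = per_fold, per_segment = per_segment),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: MAPE %.2f%%, AAE %.3f W/kg over %d folds\n",
              x$mape, x$aae, nrow(x$per_fold)))
  invisible(x)
}

# rbind for 4-d feature arrays along the first dimension.
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n_tot <- sum(vapply(arrs, function(a) dim(a)[1L], 1L))
  out <- array(0, dim = c(n_tot, d[-1L]))
  at <- 0L
  for (a in arrs) {
    n_a <- dim(a)[1L]
    out[(at + 1L):(at + n_a), , , ] <- a
    at <- at + n_a
  }
  out
}

#' Save / load a metabolic model
#'
#' The model (architecture settings, trained weights, normalization
#' statistics) is serialized to a single RDS file.
#'
#' @param model a `metabolic_model`.
#' @param path file path.
#' @return `path` invisibly; `read_metabolic_model()` returns the model.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_metabolic_model
#' @export
read_metabolic_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "metabolic_model"))
  model
}
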