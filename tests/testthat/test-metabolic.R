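test_that("spectrogram features have the stated geometry and frequency mapping", {
  st <- steady_stream(duration = 10, seed = 3)
  feats <- stft_features(st)
  expect_equal(dim(feats), c(3L, 101L, 9L))
  expect_equal(dimnames(feats)[[1]], c("HF", "CF", "ACC"))
  expect_true(all(is.finite(feats)))
  # constant channel: energy confined to the DC lobe (the symmetric Hann
  # window leaks into the immediately adjacent bins only)
  const_win <- list(hf = rep(2, 1000), cf = rep(0.5, 1000), aref = rep(1, 1000))
  fc <- stft_features(const_win, fs = 100)
  expect_gt(fc["HF", 1, 1], 1)
  dc_mag <- expm1(fc["HF", 1, 1])
  expect_lt(max(expm1(fc["HF", 4:101, ])), 1e-3 * dc_mag)
  # 5 Hz sinusoid in HF: maximal bin at 5 / 0.5 Hz resolution (index 11, 1-based)
  t <- (0:999) / 100
  fs5 <- stft_features(list(hf = sin(2 * pi * 5 * t), cf = rep(0, 1000),
                            aref = rep(0, 1000)), fs = 100)
  expect_equal(unname(which.max(fs5["HF", , 4])), 11L)
  expect_error(stft_features(list(hf = t[1:999], cf = t[1:999],
                                  aref = t[1:999])), "1000 samples")
})

test_that("error metrics match hand computations", {
  expect_equal(mape(11, 10), 10)
  expect_equal(aae(c(2.0, 4.0), c(2.5, 3.0)), 0.75)
  expect_equal(mape(c(9, 11), c(10, 10)), 10)
  expect_error(mape(1, 0))
})

test_that("the network learns a constant target and is seed-reproducible", {
  n <- 110
  feats <- with_seed(5, array(rnorm(n * 3 * 101 * 9, sd = 0.3),
                              dim = c(n, 3, 101, 9)))
  y <- rep(4.2, n)
  expect_warning(
    m <- train_metabolic(list(features = feats, target = y),
                         cfg = list(epochs = 15L, seed = 1L)),
    "degenerate")
  pred <- thermopulse:::predict_features(m, feats)
  expect_true(all(abs(pred - 4.2) / 4.2 < 0.05))
  m2 <- suppressWarnings(
    train_metabolic(list(features = feats, target = y),
                    cfg = list(epochs = 15L, seed = 1L)))
  expect_identical(m$training_curve, m2$training_curve)
  expect_error(train_metabolic(list(features = feats[1:50, , , ],
                                    target = y[1:50])), "at least")
})

test_that("network gradients agree with finite differences", {
  tp <- asNamespace("thermopulse")
  feats <- with_seed(42, array(rnorm(3 * 3 * 101 * 9), dim = c(3, 3, 101, 9)))
  y <- c(2, 3, 4)
  net <- tp$cnn_init(seed = 7, y_mean = mean(y))
  rc <- tp$make_rowcache(net$geom, 3L)
  xc <- tp$features_to_columns(feats, 1:3, list(mean = rep(0, 3), sd = rep(1, 3)))
  fwd <- tp$cnn_forward(net, xc, rc, keep = TRUE)
  gr <- tp$cnn_backward(net, xc, y, fwd, rc)
  loss <- function(params) {
    net2 <- net; net2$params <- params
    mean((tp$cnn_forward(net2, xc, rc)$yhat - y)^2)
  }
  idx <- list(Wd2 = 10L, Wd1 = 777L, W2_2 = 55L, W1_1 = 3L, bd1 = 8L)
  for (nm in names(idx)) {
    i <- idx[[nm]]
    eps <- 1e-5
    p1 <- net$params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- net$params; p2[[nm]][i] <- p2[[nm]][i] - eps
    fd <- (loss(p1) - loss(p2)) / (2 * eps)
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-5)
  }
})

test_that("per-second prediction respects the window latency contract", {
  n <- 110
  feats <- with_seed(6, array(rnorm(n * 3 * 101 * 9, sd = 0.3),
                              dim = c(n, 3, 101, 9)))
  m <- suppressWarnings(
    train_metabolic(list(features = feats, target = rep(3, n)),
                    cfg = list(epochs = 5L, seed = 2L)))
  st <- steady_stream(duration = 14, seed = 4)
  pred <- predict_metabolic(m, st)
  expect_equal(pred$t, 10:14) # first output at t = 10 s, 1 Hz cadence
  expect_true(all(pred$met_wkg >= 0))
  short <- steady_stream(duration = 8, seed = 4)
  expect_error(predict_metabolic(m, short), "10 s")
})

test_that("ablating the only informative channel raises held-out error", {
  # target depends only on hot-film structure; ACC and CF are distractors
  ds <- synth_metabolic_dataset(n_sessions = 3,
                                coupling = c(acc = 0, cf = 0, hf = 1.2),
                                intercept = 2, hop_s = 3, seed = 31)
  feats <- do.call(thermopulse:::abind1, lapply(ds[1:2], `[[`, "features"))
  targs <- unlist(lapply(ds[1:2], `[[`, "target"))
  cfg_fast <- list(epochs = 30L, seed = 1L)
  m_full <- train_metabolic(list(features = feats, target = targs), cfg_fast)
  m_abl <- train_metabolic(list(features = feats, target = targs),
                           utils::modifyList(cfg_fast,
                                             list(channels = c("CF", "ACC"))))
  p_full <- thermopulse:::predict_features(m_full, ds[[3]]$features)
  p_abl <- thermopulse:::predict_features(m_abl, ds[[3]]$features)
  expect_lt(mape(p_full, ds[[3]]$target), mape(p_abl, ds[[3]]$target))
})

test_that("leave-one-out evaluation validates its inputs", {
  ds <- list(list(features = array(0, c(2, 3, 101, 9)), target = c(1, 2)))
  expect_error(loo_evaluate(ds), ">= 3")
})

test_that("models round-trip through serialization", {
  n <- 104
  feats <- with_seed(8, array(rnorm(n * 3 * 101 * 9, sd = 0.2),
                              dim = c(n, 3, 101, 9)))
  m <- suppressWarnings(train_metabolic(list(features = feats, target = rep(2, n)),
                                        cfg = list(epochs = 3L, seed = 1L)))
  path <- tempfile(fileext = ".rds")
  write_metabolic_model(m, path)
  m2 <- read_metabolic_model(path)
  expect_equal(thermopulse:::predict_features(m2, feats[1:5, , , , drop = FALSE]),
               thermopulse:::predict_features(m, feats[1:5, , , , drop = FALSE]))
})
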