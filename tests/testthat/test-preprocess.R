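test_that("channel QC drops spiking and flat channels only", {
  set.seed(1)
  x <- matrix(rnorm(6 * 1000, sd = 10), 6, 1000)
  rec <- eeg_recording(x, 120, paste0("ch", 1:6))
  expect_length(attr(qc_channels(rec), "rejected"), 0L)
  x2 <- x
  x2[3, 500] <- 1000               # amplitude spike beyond the 500 uV gate
  x2[5, ] <- 2.5                   # flat channel
  out <- qc_channels(eeg_recording(x2, 120, paste0("ch", 1:6)))
  expect_setequal(attr(out, "rejected"), c("ch3", "ch5"))
  flat_all <- eeg_recording(matrix(1, 3, 100), 120)
  expect_error(qc_channels(flat_all), "all channels rejected")
})

test_that("common average reference subtracts the instantaneous channel mean", {
  rec <- eeg_recording(matrix(c(3, 1), 2, 1), 120)
  expect_equal(unname(car_filter(rec)$signals[, 1]), c(1, -1))
  set.seed(2)
  x <- matrix(rnorm(400), 4, 100)
  rec <- eeg_recording(x, 120)
  out <- car_filter(rec)$signals
  expect_equal(out, sweep(x, 2, colMeans(x)), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(out))), 1e-12)
  # common-mode rejection and idempotence
  shifted <- car_filter(eeg_recording(x + 7, 120))$signals
  expect_equal(shifted, out, ignore_attr = TRUE)
  expect_equal(car_filter(car_filter(rec))$signals, out, ignore_attr = TRUE)
  expect_error(car_filter(eeg_recording(x[1, , drop = FALSE], 120)),
               "at least 2")
})

test_that("filter bank passes in-band tones and attenuates out-of-band by 60 dB", {
  t <- (0:5999) / 120
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 30 * t)), 120)
  out <- bandpass_filterbank(rec, list(mu = c(8, 12)))$mu$signals
  mid <- 1500:4500  # steady state away from edges
  expect_lt(abs(sd(out[1, mid]) / sd(rec$signals[1, mid]) - 1), 0.01)
  expect_lt(sqrt(mean(out[2, mid]^2)) / sqrt(mean(rec$signals[2, mid]^2)),
            1e-3)
  zero <- bandpass_filterbank(eeg_recording(matrix(0, 2, 600), 120),
                              list(mu = c(8, 12)))$mu$signals
  expect_equal(max(abs(zero)), 0)
  expect_error(bandpass_filterbank(rec, list(bad = c(50, 70))), "invalid band")
})

test_that("band power is the windowed mean square and counts windows correctly", {
  t <- (0:1199) / 120
  rec <- eeg_recording(rbind(2 * sin(2 * pi * 8 * t)), 120)
  bp <- band_power(rec, window_width = 0.25, window_step = 1 / 120)
  expect_equal(dim(bp$power)[3], floor((1200 - 30) / 1) + 1)
  # 0.25 s holds two full cycles of 8 Hz: mean square = A^2/2
  expect_lt(max(abs(bp$power[1, 1, ] - 2)), 0.02 * 2)
  expect_equal(max(band_power(eeg_recording(matrix(0, 1, 600), 120))$power), 0)
  # sign-flip invariance
  bp_neg <- band_power(eeg_recording(-rec$signals, 120))
  expect_equal(bp_neg$power, bp$power, ignore_attr = TRUE)
  expect_error(band_power(eeg_recording(matrix(1., 1, 10), 120),
                          window_width = 1), "longer than")
})

test_that("four-band power of white noise captures the 8-40 Hz spectral mass", {
  devs <- vapply(1:10, function(s) {
    set.seed(s)
    rec <- eeg_recording(matrix(rnorm(24000), 2, 12000), 120)
    bp <- band_power(bandpass_filterbank(rec, analysis_bands()),
                     window_step = 0.25)
    total <- mean(apply(bp$power, c(2, 3), sum))
    total / ((40 - 8) / 60)  # expected fraction of unit variance
  }, numeric(1))
  expect_true(all(abs(devs - 1) < 0.10))
})

test_that("standardization scales by training sigma only", {
  t <- (0:599) / 120
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 15 * t)), 120)
  bp <- band_power(bandpass_filterbank(rec, analysis_bands()[1:2]))
  ft <- standardize(bp)
  expect_equal(unname(apply(ft$S, 2, sd)), rep(1, ncol(ft$S)))
  # halving check on a hand-built series with sigma 2
  bp2 <- bp
  bp2$power[] <- bp2$power / rep(apply(bp2$power, c(1, 2), sd),
                                 dim(bp2$power)[3]) * 2
  ft2 <- standardize(bp2)
  m <- mtpbci:::bp_matrix(bp2)$m
  expect_equal(ft2$S, m / 2, ignore_attr = TRUE)
  # test-fold standardization reuses the training sigma verbatim
  sigma <- ft$sigma * 3
  ft3 <- standardize(bp, sigma = sigma)
  expect_equal(ft3$S, mtpbci:::bp_matrix(bp)$m / rep(sigma,
                                                     each = nrow(ft3$S)),
               ignore_attr = TRUE)
  # degenerate features are refused
  bp0 <- bp; bp0$power[1, 1, ] <- 5
  expect_error(standardize(bp0), "degenerate feature")
})

test_that("optional first-difference mode differences before scaling", {
  t <- (0:599) / 120
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t) * (1 + t / 5)), 120)
  bp <- band_power(bandpass_filterbank(rec, analysis_bands()[1]))
  fd <- standardize(bp, difference = TRUE)
  m <- mtpbci:::bp_matrix(bp)$m
  expect_equal(nrow(fd$S), nrow(m) - 1)
  expect_equal(fd$S[, 1] * fd$sigma[1], diff(m[, 1]), ignore_attr = TRUE)
})

test_that("lag embedding concatenates backward lags and drops short history", {
  S <- matrix(rnorm(200 * 4), 200, 4)
  ft <- structure(list(S = S, time = (1:200) * 0.025,
                       info = data.frame(band = "mu", channel = paste0("c", 1:4),
                                         lag = 0L),
                       sigma = rep(1, 4), step_s = 0.025, lag_spacing = NA,
                       n_lags = 0L, difference = FALSE),
                  class = "feature_tensor")
  emb <- lag_embed(ft, lag_spacing = 0.05, n_lags = 2L)
  expect_equal(dim(emb$S), c(196, 12))
  expect_equal(emb$S[1, 1:4], S[5, ])
  expect_equal(emb$S[1, 5:8], S[3, ])
  expect_equal(emb$S[1, 9:12], S[1, ])
  # n_lags = 0 keeps the current sample only (embedding dimension 1)
  expect_equal(dim(lag_embed(ft, 0.05, 0L)$S), c(200, 4))
  # 16 channels x 4 bands x embedding dimension 2 = 128 features
  S16 <- matrix(rnorm(100 * 64), 100, 64)
  ft16 <- ft
  ft16$S <- S16
  ft16$info <- data.frame(band = rep(paste0("b", 1:4), each = 16),
                          channel = rep(paste0("c", 1:16), 4), lag = 0L)
  ft16$sigma <- rep(1, 64)
  expect_equal(ncol(lag_embed(ft16, 0.05, 1L)$S), 128)
  # constant features embed to identical copies
  ftc <- ft; ftc$S <- matrix(3, 200, 4)
  embc <- lag_embed(ftc, 0.05, 1L)
  expect_equal(embc$S[, 1:4], embc$S[, 5:8], ignore_attr = TRUE)
  expect_error(lag_embed(ft, 0.05, 200L), "history longer")
})
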