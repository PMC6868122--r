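# Preprocessing: channel QC, common average reference, zero-phase FIR
# filter bank, windowed band power, standardization and lag embedding.

#' Default 16-channel sensorimotor montage
#'
#' 10/20-system labels covering pre-motor, motor and parietal areas, the
#' region carrying movement-related mu/beta/gamma modulation.
#' @export
sensorimotor_montage <- function() {
  c("FC3", "FCz", "FC4", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CPz", "CP4", "P3", "Pz", "P4")
}

#' Analysis band edges (Hz)
#'
#' The four bands driving the velocity decoder (mu 8-12, low beta 12-18,
#' high beta 18-28, low gamma 28-40 Hz) or, with `filterbank = TRUE`, the
#' six-band set used by the filter-bank classifier (adding delta 0.5-4 and
#' theta 4-8 Hz).
#' @param filterbank return the six-band classifier set.
#' @return named list of `c(low, high)` pairs.
#' @export
analysis_bands <- function(filterbank = FALSE) {
  b <- list(mu = c(8, 12), low_beta = c(12, 18), high_beta = c(18, 28),
            low_gamma = c(28, 40))
  if (filterbank) b <- c(list(delta = c(0.5, 4), theta = c(4, 8)), b)
  b
}

#' Multichannel EEG recording container
#'
#' @param signals channels x samples numeric matrix, microvolts.
#' @param sample_rate sampling rate, Hz.
#' @param labels channel labels (10/20 names).
#' @param reference reference description.
#' @export
eeg_recording <- function(signals, sample_rate = 120,
                          labels = rownames(signals), reference = "ear") {
  signals <- as.matrix(signals)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(signals)))
  if (length(labels) != nrow(signals))
    stop("`labels` length must match the number of signal rows")
  if (any(!is.finite(signals))) stop("non-finite samples in `signals`")
  rownames(signals) <- labels
  structure(list(signals = signals, sample_rate = sample_rate,
                 labels = labels, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (ref: %s)\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate, x$reference))
  invisible(x)
}

#' Automated channel quality control
#'
#' Surrogate for manual channel inspection: drops channels whose peak
#' absolute amplitude exceeds `abs_amp_threshold` (high-level noise or
#' artifact) or whose standard deviation falls below `flat_threshold`
#' (flat / disconnected channels).
#'
#' @param rec an [eeg_recording()].
#' @param abs_amp_threshold peak |amplitude| limit, microvolts.
#' @param flat_threshold minimum channel standard deviation, microvolts.
#' @return the recording with offending channels removed; rejected labels in
#'   attribute `"rejected"`.
#' @export
qc_channels <- function(rec, abs_amp_threshold = 500, flat_threshold = 1e-6) {
  if (abs_amp_threshold <= 0 || flat_threshold <= 0)
    stop("QC thresholds must be positive")
  peak <- apply(abs(rec$signals), 1, max)
  sds <- apply(rec$signals, 1, sd)
  bad <- peak > abs_amp_threshold | sds < flat_threshold
  if (all(bad)) stop("qc_channels: all channels rejected")
  out <- eeg_recording(rec$signals[!bad, , drop = FALSE], rec$sample_rate,
                       rec$labels[!bad], rec$reference)
  attr(out, "rejected") <- rec$labels[bad]
  out
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean over all channels:
#' `V_i - mean_j(V_j)`. Rejects common-mode artifacts; the channel mean of
#' the output is zero at every sample and the operation is idempotent.
#'
#' @param rec an [eeg_recording()] with at least two channels.
#' @export
car_filter <- function(rec) {
  if (nrow(rec$signals) < 2L)
    stop("car_filter requires at least 2 channels")
  out <- sweep(rec$signals, 2, colMeans(rec$signals), "-")
  eeg_recording(out, rec$sample_rate, rec$labels, reference = "CAR")
}

blackman_window <- function(n) {
  k <- seq(0, n - 1)
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

# Linear-phase FIR band-pass taps (Blackman window, >60 dB single-pass
# stop-band). Transition width defaults to 2 Hz, narrowed near a low edge.
fir_bandpass_taps <- function(low, high, sample_rate, transition = NULL) {
  nyq <- sample_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("invalid band edges (%g, %g) Hz at %g Hz sampling",
                 low, high, sample_rate))
  if (is.null(transition)) transition <- max(min(1, low), 0.25)
  n <- ceiling(5.5 * sample_rate / transition)
  if (n %% 2 == 1) n <- n + 1  # even order -> odd symmetric tap count
  signal::fir1(n, c(low, high) / nyq, type = "pass",
               window = blackman_window(n + 1))
}

# Zero-phase application: forward-backward filtering collapsed into one
# centred convolution with the tap autocorrelation (taps are symmetric), via
# FFT. Magnitude response is |H|^2, phase exactly zero.
apply_zero_phase <- function(signals, taps) {
  g <- convolve(taps, rev(taps), type = "open")
  ns <- ncol(signals); ng <- length(g); nf <- length(taps)
  nfft <- stats::nextn(ns + ng - 1L, 2)
  G <- fft(c(g, rep(0, nfft - ng)))
  out <- t(apply(signals, 1, function(x) {
    z <- Re(fft(fft(c(x, rep(0, nfft - ns))) * G, inverse = TRUE)) / nfft
    z[nf - 1L + seq_len(ns)]
  }))
  dimnames(out) <- dimnames(signals)
  out
}

#' Zero-phase FIR band-pass filter bank
#'
#' Filters a recording into each requested band with linear-phase FIR
#' filters applied forward and backward (zero net phase). Single-pass
#' designs exceed 60 dB stop-band attenuation, so the applied two-pass
#' response exceeds 120 dB with negligible pass-band ripple.
#'
#' @param rec an [eeg_recording()].
#' @param bands named list of `c(low, high)` Hz pairs, see
#'   [analysis_bands()].
#' @return named list of band-filtered `eeg_recording`s.
#' @export
bandpass_filterbank <- function(rec, bands = analysis_bands()) {
  out <- lapply(bands, function(b) {
    taps <- fir_bandpass_taps(b[1], b[2], rec$sample_rate)
    eeg_recording(apply_zero_phase(rec$signals, taps), rec$sample_rate,
                  rec$labels, rec$reference)
  })
  names(out) <- names(bands)
  out
}

#' Sliding-window band power
#'
#' Mean of the squared band-pass-filtered potentials in each half-open
#' window `[t, t + width)`; the number of windows is
#' `floor((T - width)/step) + 1`. The default step is one sample (8.33 ms at
#' 120 Hz); prediction-rate features use a 25 ms (3-sample) step.
#'
#' @param filtered a named list of band-filtered recordings (from
#'   [bandpass_filterbank()]) or a single `eeg_recording`.
#' @param window_width window width, seconds (0.25 in the standard
#'   pipeline).
#' @param window_step step between adjacent windows, seconds.
#' @return A `band_power_series`: array `power[band, channel, window]`
#'   (microvolts squared), window start times `time`, feature-availability
#'   times `time_end = time + width`.
#' @export
band_power <- function(filtered, window_width = 0.25,
                       window_step = 1 / 120) {
  if (inherits(filtered, "eeg_recording")) filtered <- list(band = filtered)
  fs <- filtered[[1]]$sample_rate
  M <- round(window_width * fs)
  if (M < 2) stop("window must span at least 2 samples")
  step <- max(1L, round(window_step * fs))
  ns <- ncol(filtered[[1]]$signals)
  if (M > ns) stop("window longer than recording")
  starts <- seq(1L, ns - M + 1L, by = step)
  pow <- array(NA_real_, c(length(filtered), nrow(filtered[[1]]$signals),
                           length(starts)),
               dimnames = list(names(filtered), filtered[[1]]$labels, NULL))
  for (f in seq_along(filtered)) {
    x2 <- filtered[[f]]$signals^2
    cs <- cbind(0, t(apply(x2, 1, cumsum)))
    pow[f, , ] <- (cs[, starts + M] - cs[, starts]) / M
  }
  structure(list(power = pow, time = (starts - 1L) / fs,
                 time_end = (starts - 1L) / fs + window_width,
                 window_width = window_width, step_s = step / fs,
                 bands = names(filtered), labels = filtered[[1]]$labels,
                 sample_rate = fs),
            class = "band_power_series")
}

bp_matrix <- function(bp) {
  nb <- dim(bp$power)[1]; nc <- dim(bp$power)[2]; nw <- dim(bp$power)[3]
  m <- matrix(aperm(bp$power, c(3, 2, 1)), nw, nb * nc)
  info <- data.frame(band = rep(bp$bands, each = nc),
                     channel = rep(bp$labels, times = nb),
                     stringsAsFactors = FALSE)
  list(m = m, info = info)
}

#' Standardize band-power features
#'
#' Divides each band-by-channel power series by its standard deviation
#' (scale-only standardization). When decoding with cross-validation the
#' `sigma` estimated on training folds must be supplied for test folds so
#' that test data never informs the scaling. An optional first-difference
#' transform (applied before scaling) is available but off by default.
#'
#' @param bp a `band_power_series`.
#' @param sigma `NULL` (estimate from `bp` and return for reuse) or a sigma
#'   vector previously returned in a `feature_tensor`.
#' @param difference apply a first difference over windows before scaling.
#' @return A `feature_tensor`: matrix `S` (time x features), feature
#'   metadata, `sigma`, and timing fields.
#' @export
standardize <- function(bp, sigma = NULL, difference = FALSE) {
  fm <- bp_matrix(bp)
  m <- fm$m
  time <- bp$time_end
  if (difference) {
    m <- diff(m)
    time <- time[-1]
  }
  if (is.null(sigma)) {
    sigma <- apply(m, 2, sd)
  } else if (length(sigma) != ncol(m)) {
    stop("`sigma` length does not match the feature count")
  }
  if (any(sigma <= 0))
    stop("degenerate feature: sigma = 0 for ",
         paste(unique(fm$info$channel[sigma <= 0]), collapse = ", "),
         " (channel should have been removed by QC)")
  S <- sweep(m, 2, sigma, "/")
  structure(list(S = S, time = time, info = cbind(fm$info, lag = 0L),
                 sigma = sigma, step_s = bp$step_s, lag_spacing = NA_real_,
                 n_lags = 0L, difference = difference),
            class = "feature_tensor")
}

#' Lag-embed a feature tensor
#'
#' Concatenates, at each time point, the standardized features at lags
#' `0, spacing, ..., n_lags * spacing` (embedding dimension `n_lags + 1`).
#' Leading samples without a full history are dropped. The decoder's lag
#' grid investigates spacings of 50, 100 and 200 ms and 1, 2, 4 or 8 lags.
#'
#' @param ft a `feature_tensor` from [standardize()].
#' @param lag_spacing lag spacing in seconds.
#' @param n_lags number of additional backward lags L (0 keeps only the
#'   current sample).
#' @export
lag_embed <- function(ft, lag_spacing = 0.1, n_lags = 1L) {
  if (n_lags < 0) stop("`n_lags` must be >= 0")
  if (n_lags == 0L) {
    ft$lag_spacing <- lag_spacing
    return(ft)
  }
  ls <- round(lag_spacing / ft$step_s)
  if (ls < 1) stop("`lag_spacing` is below the feature sampling step")
  drop <- n_lags * ls
  n <- nrow(ft$S)
  if (drop >= n) stop("lag history longer than the recording")
  keep <- (drop + 1L):n
  cols <- lapply(0:n_lags, function(k) ft$S[keep - k * ls, , drop = FALSE])
  S <- do.call(cbind, cols)
  info <- do.call(rbind, lapply(0:n_lags, function(k)
    cbind(ft$info[, c("band", "channel")], lag = k)))
  structure(list(S = S, time = ft$time[keep], info = info, sigma = ft$sigma,
                 step_s = ft$step_s, lag_spacing = lag_spacing,
                 n_lags = as.integer(n_lags), difference = ft$difference),
            class = "feature_tensor")
}
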