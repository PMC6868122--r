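# Synthetic EEG + kinematics sessions with known ground truth. Stands in
# for real recordings: every decoding stage can be validated against the
# encoding that generated the data.

# Carrier frequencies sit at band centres rounded so that every carrier,
# every pairwise sum/difference frequency and every second harmonic spans an
# integer number of cycles in the 250 ms power window at 120 Hz (all are
# multiples of 4 Hz): windowed power is then *exactly* affine in the lagged
# velocity, with no ripple from carrier interference.
BAND_CARRIERS <- c(mu = 10, low_beta = 14, high_beta = 22, low_gamma = 34,
                   delta = 2, theta = 6)

#' Velocity-encoding specification for synthetic sessions
#'
#' Describes which channel/band pairs carry which lagged velocity component.
#' On an encoding channel the band-limited carrier amplitude is
#' `sqrt(c0 + g * v_axis(t - lag)) * cos(2 pi f_c t + phi)` with `f_c` the
#' band's carrier frequency, so that the 250 ms windowed band power is
#' affine in the lagged velocity -- exactly the relationship the linear
#' decoder assumes. Defaults place the encodings on channels over the
#' contralateral sensorimotor cortex (around C3/C4).
#'
#' @param table data.frame with columns `arm`, `axis` (1:3), `channel`,
#'   `band`, `gain`; `NULL` for the default contralateral assignment.
#' @param gain per-(units/s) band-power gain applied in the default table.
#' @param baseline_power carrier baseline power c0, microvolts squared.
#' @param lag encoding lag between velocity and band power, seconds.
#' @export
encoding_spec <- function(table = NULL, gain = 2, baseline_power = 1,
                          lag = 0.1) {
  if (baseline_power <= 0) stop("`baseline_power` must be positive")
  if (is.null(table)) {
    table <- data.frame(
      arm = rep(c("left", "right"), each = 3L),
      axis = rep(1:3, 2L),
      channel = c("C4", "FC4", "CP4", "C3", "FC3", "CP3"),
      band = rep(c("mu", "low_beta", "high_beta"), 2L),
      gain = gain,
      stringsAsFactors = FALSE)
  }
  need <- c("arm", "axis", "channel", "band", "gain")
  if (!all(need %in% names(table)))
    stop("encoding table needs columns: ", paste(need, collapse = ", "))
  if (is.null(table$phase)) {
    # quarter-turn phase offsets between carriers sharing a band: their
    # cross terms after common-average referencing then average to zero
    # over the power window, keeping band power affine in velocity
    table$phase <- (stats::ave(seq_len(nrow(table)), table$band,
                               FUN = seq_along) - 1) * pi / 2
  }
  structure(list(table = table, baseline_power = baseline_power, lag = lag),
            class = "encoding_spec")
}

#' Background-noise specification for synthetic sessions
#'
#' @param one_over_f_exponent spectral exponent alpha of the 1/f^alpha
#'   per-channel background.
#' @param channel_scale per-channel background standard deviation,
#'   microvolts.
#' @param common_mode_scale standard deviation of the component added to all
#'   channels (rejected by the common average reference), microvolts.
#' @param line_amplitude 50 Hz line-noise amplitude, microvolts.
#' @export
noise_spec <- function(one_over_f_exponent = 1, channel_scale = 1,
                       common_mode_scale = 1, line_amplitude = 0.5) {
  if (channel_scale < 0 || common_mode_scale < 0 || line_amplitude < 0)
    stop("noise scales must be >= 0")
  structure(list(alpha = one_over_f_exponent, channel_scale = channel_scale,
                 common_mode_scale = common_mode_scale,
                 line_amplitude = line_amplitude, line_freq = 50),
            class = "noise_spec")
}

# Unit-variance 1/f^alpha noise via spectral shaping of white noise.
one_over_f_noise <- function(n, sample_rate, alpha) {
  w <- rnorm(n)
  if (alpha == 0) return(w)
  W <- fft(w)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * sample_rate / n
  shape <- c(0, freq[-1]^(-alpha / 2))
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sd(x)
}

# Unit-variance band-limited Gaussian noise.
band_noise <- function(n, sample_rate, band) {
  taps <- fir_bandpass_taps(band[1], band[2], sample_rate)
  x <- apply_zero_phase(matrix(rnorm(n), 1), taps)[1, ]
  x / sd(x)
}

background_noise <- function(n_channels, n, sample_rate, noise) {
  sig <- matrix(0, n_channels, n)
  if (noise$channel_scale > 0)
    for (ch in seq_len(n_channels))
      sig[ch, ] <- noise$channel_scale *
        one_over_f_noise(n, sample_rate, noise$alpha)
  if (noise$common_mode_scale > 0) {
    cm <- noise$common_mode_scale * one_over_f_noise(n, sample_rate, noise$alpha)
    sig <- sweep(sig, 2, cm, "+")
  }
  if (noise$line_amplitude > 0) {
    t <- (seq_len(n) - 1) / sample_rate
    line <- noise$line_amplitude * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    sig <- sweep(sig, 2, line, "+")
  }
  sig
}

#' Synthesize a velocity-encoded EEG session
#'
#' Generates a 120 Hz EEG recording whose designated channel/band carriers
#' have windowed band power affine in a lagged component of the target arm
#' velocity, plus 1/f background, a common-mode component and 50 Hz line
#' noise. Kinematics follow the schedule's ideal velocity templates.
#'
#' @param schedule a `paradigm_schedule` (offline protocol).
#' @param layout the `target_layout`; defaults to the schedule's.
#' @param enc an [encoding_spec()].
#' @param noise a [noise_spec()].
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @param sample_rate EEG sampling rate, Hz.
#' @param montage channel label set.
#' @return list with `recording` ([eeg_recording()]), `kinematics`
#'   (`kinematics_series`) and the `schedule`.
#' @export
synthesize_mtp_session <- function(schedule, layout = attr(schedule, "layout"),
                                   enc = encoding_spec(),
                                   noise = noise_spec(), seed = 1,
                                   sample_rate = 120,
                                   montage = sensorimotor_montage()) {
  kin <- schedule_kinematics(schedule, layout, sample_rate)
  n <- length(kin$time)
  unknown <- setdiff(enc$table$channel, montage)
  if (length(unknown))
    stop("encoding channels not in montage: ", paste(unknown, collapse = ", "))
  sig <- with_seed(seed, {
    s <- background_noise(length(montage), n, sample_rate, noise)
    lag_n <- round(enc$lag * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    for (i in seq_len(nrow(enc$table))) {
      row <- enc$table[i, ]
      v <- kin[[row$arm]]$velocity[, row$axis]
      v_lag <- c(rep(0, lag_n), head(v, n - lag_n))
      radicand <- enc$baseline_power + row$gain * v_lag
      if (any(radicand < 0))
        stop("encoding spec error: c0 + g*v is negative (carrier amplitude ",
             "would be imaginary); reduce `gain` or raise `baseline_power`")
      fc <- BAND_CARRIERS[[row$band]]
      phi <- row$phase
      ch <- match(row$channel, montage)
      s[ch, ] <- s[ch, ] + sqrt(2 * radicand) * cos(2 * pi * fc * t + phi)
    }
    s
  })
  rec <- eeg_recording(sig, sample_rate, montage, reference = "ear")
  list(recording = rec, kinematics = kin, schedule = schedule)
}

#' Class-conditional variance pattern map
#'
#' One row per (class, channel, band): during task epochs of that class the
#' band-limited rhythm on `channel` has its variance multiplied by `factor`
#' (a factor below one emulates event-related desynchronization). The
#' default emulates contralateral mu suppression: left-arm imagery halves mu
#' variance on C4, right-arm imagery halves it on C3.
#'
#' @param table data.frame with columns `class`, `channel`, `band`,
#'   `factor`, optionally `amplitude` (baseline rhythm standard deviation,
#'   microvolts; default 3).
#' @export
class_pattern_map <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(class = c("left", "right"), channel = c("C4", "C3"),
                        band = "mu", factor = 0.5, stringsAsFactors = FALSE)
  }
  if (is.null(table$amplitude)) table$amplitude <- 3
  if (any(table$factor <= 0)) stop("variance factors must be positive")
  table
}

#' Synthesize a class-conditional EEG session
#'
#' Generates EEG in which designated channels carry band-limited rhythms
#' whose variance is scaled by a class-specific factor during task epochs
#' (the 12 s imagery sub-blocks) of blocks belonging to that class, on top
#' of the same background-noise model as [synthesize_mtp_session()]. Trial
#' class is the cued arm. This is the fixture for the filter-bank spatial
#' pattern classifier.
#'
#' @inheritParams synthesize_mtp_session
#' @param class_map a [class_pattern_map()].
#' @return list with `recording`, `labels` (one row per block: `run`,
#'   `block`, `arm`, `target`, class and sub-block onsets) and `schedule`.
#' @export
synthesize_class_session <- function(schedule, class_map = class_pattern_map(),
                                     noise = noise_spec(), seed = 1,
                                     sample_rate = 120,
                                     montage = sensorimotor_montage()) {
  class_map <- class_pattern_map(class_map)
  total <- schedule_duration(schedule)
  n <- round(total * sample_rate)
  task <- schedule[!is.na(schedule$sub_block), , drop = FALSE]
  sig <- with_seed(seed, {
    s <- background_noise(length(montage), n, sample_rate, noise)
    for (i in seq_len(nrow(class_map))) {
      row <- class_map[i, ]
      ch <- match(row$channel, montage)
      if (is.na(ch)) stop("pattern channel not in montage: ", row$channel)
      rhythm <- band_noise(n, sample_rate, analysis_bands(TRUE)[[row$band]])
      env <- rep(1, n)
      eps <- task[task$arm == row$class, , drop = FALSE]
      for (k in seq_len(nrow(eps))) {
        i0 <- round(eps$onset[k] * sample_rate) + 1L
        i1 <- min(round((eps$onset[k] + eps$duration[k]) * sample_rate), n)
        if (i0 <= i1) env[i0:i1] <- sqrt(row$factor)
      }
      s[ch, ] <- s[ch, ] + row$amplitude * env * rhythm
    }
    s
  })
  blocks <- schedule[schedule$kind == "block_voice", , drop = FALSE]
  sb <- task[task$kind == "home_to_target" & task$sub_block %in% 1:2, ]
  labels <- data.frame(run = blocks$run, block = blocks$block,
                       arm = blocks$arm, target = blocks$target,
                       stringsAsFactors = FALSE)
  for (s_ix in 1:2) {
    on <- sb[sb$sub_block == s_ix, ]
    labels[[paste0("sub_block", s_ix, "_onset")]] <-
      on$onset[match(paste(labels$run, labels$block),
                     paste(on$run, on$block))]
  }
  rec <- eeg_recording(sig, sample_rate, montage, reference = "ear")
  list(recording = rec, labels = labels, schedule = schedule)
}
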