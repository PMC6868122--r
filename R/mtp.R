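# Motion trajectory prediction: lag-embedded multiple linear regression of
# 3D arm velocity on standardized band-power features, trajectory metrics,
# channel scoring and the recursive architecture search.

velocity_at <- function(kin, arm, times) {
  idx <- pmin(pmax(round(times * kin$sample_rate) + 1L, 1L),
              length(kin$time))
  kin[[arm]]$velocity[idx, , drop = FALSE]
}

#' Train the multiple linear regression velocity decoder
#'
#' Fits, by ordinary least squares, one regression per spatial axis of one
#' arm joint: `v_i[t] = a_i + sum_{n,f,k} b_{infk} S_{nf}[t - k]`. The three
#' axis regressions share the design matrix; left and right arms are trained
#' as independent models. A small ridge term (1e-8 on the normal matrix) is
#' the fallback for near-singular designs.
#'
#' @param features a `feature_tensor` (standardized, lag-embedded).
#' @param velocity n x 3 velocity target aligned to `features$time`, or a
#'   `kinematics_series` (then `arm` selects the joint and alignment is by
#'   nearest sample).
#' @param arm `"left"` or `"right"` when `velocity` is a series.
#' @return An `mtp_model`: intercepts `a` (3), weights `b` (features x 3),
#'   feature metadata, training sigma, lag parameters and residual record.
#' @export
train_mlr <- function(features, velocity, arm = "left") {
  X <- features$S
  if (inherits(velocity, "kinematics_series"))
    velocity <- velocity_at(velocity, arm, features$time)
  velocity <- as.matrix(velocity)
  if (nrow(velocity) != nrow(X))
    stop("feature and kinematic time bases differ in length")
  n <- nrow(X); p <- ncol(X) + 1L
  if (n < p) stop("fewer time points than regression coefficients")
  D <- cbind(`(intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < p) {
    drop_cols <- colnames(D)[qrD$pivot[(qrD$rank + 1L):p]]
    warning("near-singular design (", paste(head(drop_cols, 5), collapse = ", "),
            if (length(drop_cols) > 5) ", ..." else "",
            "); using ridge-regularized normal equations")
    G <- crossprod(D) + diag(1e-8, p)
    coef <- solve(G, crossprod(D, velocity))
  } else {
    coef <- qr.coef(qrD, velocity)
  }
  fitted <- D %*% coef
  res <- velocity - fitted
  structure(list(a = coef[1, ], b = coef[-1, , drop = FALSE],
                 info = features$info, sigma = features$sigma,
                 lag_spacing = features$lag_spacing,
                 n_lags = features$n_lags, step_s = features$step_s,
                 arm = arm,
                 residual_sd = apply(res, 2, sd),
                 rss = colSums(res^2)),
            class = "mtp_model")
}

#' @export
print.mtp_model <- function(x, ...) {
  cat(sprintf("<mtp_model> arm=%s, %d features (L=%d, spacing=%g s)\n",
              x$arm, nrow(x$b), x$n_lags, x$lag_spacing))
  invisible(x)
}

#' Predict velocity from features
#'
#' Applies the trained regression forward. Features must have been
#' standardized with the model's training sigma. Output is subsampled to
#' the requested prediction step (25 ms, i.e. the 40 Hz display rate, by
#' default) when the feature step is finer.
#'
#' @param model an `mtp_model`.
#' @param features a `feature_tensor` standardized with `model$sigma`.
#' @param output_step spacing of prediction samples, seconds; `NULL` keeps
#'   the feature step.
#' @return list with `time` and `velocity` (n x 3).
#' @export
predict_velocity <- function(model, features, output_step = 0.025) {
  if (length(features$sigma) != length(model$sigma) ||
      max(abs(features$sigma - model$sigma)) > 1e-12)
    stop("features were not standardized with the model's training sigma")
  if (ncol(features$S) != nrow(model$b))
    stop("feature dimensionality does not match the model")
  v <- sweep(features$S %*% model$b, 2, model$a, "+")
  time <- features$time
  if (!is.null(output_step) && output_step > features$step_s + 1e-12) {
    k <- round(output_step / features$step_s)
    keep <- seq(1L, length(time), by = k)
    v <- v[keep, , drop = FALSE]; time <- time[keep]
  }
  list(time = time, velocity = v)
}

#' Moving-average smoothing of predicted kinematics
#'
#' Centered moving average (default nine samples, 200 ms at 40 Hz) applied
#' per axis; windows shrink symmetrically at the series edges.
#'
#' @param v n x 3 matrix (or a `list(time, velocity)` as returned by
#'   [predict_velocity()]).
#' @param width odd window width in samples.
#' @export
smooth_prediction <- function(v, width = 9L) {
  if (width %% 2 != 1L || width < 1L) stop("`width` must be odd and >= 1")
  if (is.list(v) && !is.null(v$velocity)) {
    v$velocity <- smooth_prediction(v$velocity, width)
    return(v)
  }
  v <- as.matrix(v)
  if (width == 1L) return(v)
  h <- (width - 1L) %/% 2L
  n <- nrow(v)
  out <- v
  for (j in seq_len(ncol(v))) {
    cs <- cumsum(c(0, v[, j]))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    # shrink symmetrically so the window stays centered at the edges
    half <- pmin(seq_len(n) - lo, hi - seq_len(n))
    lo <- seq_len(n) - half; hi <- seq_len(n) + half
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Normalize velocity vectors to unit length
#'
#' Rows with norm below `tol` times the largest norm are returned as zero
#' vectors and flagged in attribute `"degenerate"` rather than raising.
#'
#' @param v length-3 vector or n x 3 matrix.
#' @param tol relative degeneracy tolerance.
#' @export
normalize_velocity <- function(v, tol = 1e-9) {
  single <- is.null(dim(v))
  v <- rbind(v)
  nrm <- sqrt(rowSums(v^2))
  scale_ref <- max(nrm, 1)
  deg <- nrm <= tol * scale_ref
  out <- v / ifelse(deg, 1, nrm)
  out[deg, ] <- 0
  if (single) {
    out <- out[1, ]
    attr(out, "degenerate") <- deg[1]
  } else {
    attr(out, "degenerate") <- deg
  }
  out
}

#' Relative trial coordinates from normalized velocities
#'
#' Converts a trial's normalized velocity samples into relative coordinates
#' with the trial start as the zero reference: the coordinate at sample m is
#' the running mean of the first m normalized velocity vectors (the form
#' used for model selection and accuracy metrics). A conventional
#' cumulative-sum integration (`mode = "integrate"`, coordinates in units of
#' `dt`) is provided for trajectory display only.
#'
#' @param v n x 3 matrix of (normalized) velocities for one trial.
#' @param mode `"running_mean"` or `"integrate"`.
#' @param dt sample spacing, used by the integrate mode.
#' @export
relative_coordinates <- function(v, mode = c("running_mean", "integrate"),
                                 dt = 0.025) {
  mode <- match.arg(mode)
  v <- as.matrix(v)
  if (nrow(v) == 0L) stop("empty trial")
  cs <- apply(v, 2, cumsum)
  cs <- rbind(cs)
  dimnames(cs) <- NULL
  if (mode == "running_mean") cs / seq_len(nrow(v)) else cs * dt
}

#' Trajectory reconstruction error
#'
#' Mean over samples of the Euclidean 3D distance between target and
#' reconstructed relative coordinates of a trial.
#'
#' @param target,reconstructed m x 3 coordinate matrices of equal length.
#' @export
reconstruction_error <- function(target, reconstructed) {
  target <- as.matrix(target); reconstructed <- as.matrix(reconstructed)
  if (nrow(target) != nrow(reconstructed))
    stop("coordinate series have different lengths")
  mean(sqrt(rowSums((target - reconstructed)^2)))
}

#' Channel scores from regression weights
#'
#' Per channel and band, the lag- and axis-summed squared weight
#' `R_nf = sum_k sum_i b_{infk}^2 / (L + 1)`; the per-channel score averages
#' this over the supplied models (one per test fold) and over bands, and the
#' channels are ranked by it (descending; ties rank the channel with the
#' lower montage index higher, so the higher index is eliminated first).
#'
#' @param models list of `mtp_model`s sharing one architecture.
#' @return A `channel_scores` list: `per_band` (channel x band matrix),
#'   `score` (named vector), `ranking` (labels, best first).
#' @export
score_channels <- function(models) {
  if (inherits(models, "mtp_model")) models <- list(models)
  info <- models[[1]]$info
  chans <- unique(info$channel)
  bands <- unique(info$band)
  L1 <- models[[1]]$n_lags + 1
  per_band <- matrix(0, length(chans), length(bands),
                     dimnames = list(chans, bands))
  for (m in models) {
    if (!identical(dim(m$b), dim(models[[1]]$b)))
      stop("models do not share one architecture")
    contrib <- rowSums(m$b^2) / L1
    agg <- tapply(contrib, list(info$channel, info$band), sum)
    per_band <- per_band + agg[chans, bands, drop = FALSE] / length(models)
  }
  score <- rowMeans(per_band)
  ord <- order(-score, match(chans, chans))
  structure(list(per_band = per_band, score = score,
                 ranking = chans[ord]),
            class = "channel_scores")
}

# ---------------------------------------------------------------------------
# Dataset plumbing: band power for a session, fold-wise standardization.

#' Band-power features for a decoding session
#'
#' Quality-controls, common-average-references and band-filters the
#' recording, then computes sliding-window band power for all channels at
#' the requested step. Channel subsets and lag embeddings are applied later,
#' per cross-validation fold, so this expensive step runs once per session.
#'
#' @param recording an [eeg_recording()].
#' @param bands band list, see [analysis_bands()].
#' @param feature_step band-power window step, seconds (0.025 gives the
#'   40 Hz prediction-rate feature series used for decoding).
#' @param qc apply [qc_channels()] first.
#' @return a `band_power_series`.
#' @export
session_band_power <- function(recording, bands = analysis_bands(),
                               feature_step = 0.025, qc = TRUE) {
  if (qc) recording <- qc_channels(recording)
  rec <- car_filter(recording)
  band_power(bandpass_filterbank(rec, bands), window_width = 0.25,
             window_step = feature_step)
}

bp_subset_channels <- function(bp, channels) {
  idx <- match(channels, bp$labels)
  if (anyNA(idx)) stop("unknown channels: ",
                       paste(channels[is.na(idx)], collapse = ", "))
  bp$power <- bp$power[, idx, , drop = FALSE]
  bp$labels <- channels
  bp
}

# sigma over a subset of window indices (training folds only)
bp_sigma <- function(bp, window_idx) {
  fm <- bp_matrix(bp)
  apply(fm$m[window_idx, , drop = FALSE], 2, sd)
}

times_in_epochs <- function(times, epochs) {
  inside <- rep(FALSE, length(times))
  for (i in seq_len(nrow(epochs))) {
    inside <- inside | (times >= epochs$onset[i] - 1e-9 &
                          times < epochs$onset[i] + epochs$duration[i] - 1e-9)
  }
  inside
}

#' Leave-one-run-out cross-validation of the velocity decoder
#'
#' For each fold (one offline run) the decoder is trained on the sub-block-2
#' task data of the remaining runs -- with the feature standard deviation
#' estimated on those training windows only -- and evaluated on the held-out
#' run's twelve movement trials (six forward, six backward). Predictions are
#' smoothed, both prediction and target are normalized per sample, converted
#' to relative coordinates and compared by the mean 3D distance.
#'
#' @param bp session band power from [session_band_power()].
#' @param kinematics the session `kinematics_series`.
#' @param schedule the offline `paradigm_schedule`.
#' @param channels channel subset used as decoder input.
#' @param lag_spacing,n_lags lag-embedding architecture.
#' @param arms arms to decode (each is an independent model).
#' @param sub_blocks sub-block(s) providing training/evaluation data.
#' @param smooth_width smoothing window, samples.
#' @param allow_nonstandard_runs permit run counts other than six.
#' @return An `mtp_cv` object: per-trial error table, per-fold models and
#'   the per-trial relative-coordinate series (predicted and target).
#' @export
crossvalidate <- function(bp, kinematics, schedule,
                          channels = bp$labels, lag_spacing = 0.1,
                          n_lags = 2L, arms = ARMS, sub_blocks = 2L,
                          smooth_width = 9L,
                          allow_nonstandard_runs = FALSE) {
  runs <- sort(unique(schedule$run[!is.na(schedule$run)]))
  if (length(runs) != 6L && !allow_nonstandard_runs)
    stop("expected 6 runs; set `allow_nonstandard_runs = TRUE` to override")
  bp <- bp_subset_channels(bp, channels)
  task <- schedule[!is.na(schedule$sub_block) &
                     schedule$sub_block %in% sub_blocks, , drop = FALSE]
  trials_all <- movement_trials(schedule, sub_blocks = sub_blocks)
  err_rows <- list(); models <- list(); trial_recs <- list()
  for (fold in seq_along(runs)) {
    test_run <- runs[fold]
    train_eps <- task[task$run != test_run, , drop = FALSE]
    sigma_idx <- which(times_in_epochs(bp$time_end, train_eps))
    sigma <- bp_sigma(bp, sigma_idx)
    ft <- standardize(bp, sigma = sigma)
    ft <- lag_embed(ft, lag_spacing, n_lags)
    train_idx <- times_in_epochs(ft$time, train_eps)
    fit_ft <- ft; fit_ft$S <- ft$S[train_idx, , drop = FALSE]
    fit_ft$time <- ft$time[train_idx]
    fold_models <- list()
    for (arm in arms) {
      model <- train_mlr(fit_ft, kinematics, arm = arm)
      fold_models[[arm]] <- model
      pred_all <- sweep(ft$S %*% model$b, 2, model$a, "+")
      pred_all <- smooth_prediction(pred_all, smooth_width)
      tr <- trials_all[trials_all$run == test_run &
                         trials_all$arm == arm, , drop = FALSE]
      for (i in seq_len(nrow(tr))) {
        rows <- which(ft$time >= tr$onset[i] - 1e-9 &
                        ft$time < tr$onset[i] + tr$duration[i] - 1e-9)
        if (!length(rows)) next
        pred <- normalize_velocity(pred_all[rows, , drop = FALSE])
        targ <- normalize_velocity(
          velocity_at(kinematics, arm, ft$time[rows]))
        pc <- relative_coordinates(pred)
        tc <- relative_coordinates(targ)
        eps <- reconstruction_error(tc, pc)
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          fold = fold, run = test_run, arm = arm, block = tr$block[i],
          target = tr$target[i], direction = tr$direction[i],
          sub_block = tr$sub_block[i], epsilon = eps,
          stringsAsFactors = FALSE)
        trial_recs[[length(trial_recs) + 1L]] <- list(
          fold = fold, arm = arm, target = tr$target[i],
          direction = tr$direction[i], predicted = pc, expected = tc)
      }
    }
    models[[fold]] <- fold_models
  }
  errs <- do.call(rbind, err_rows)
  structure(list(trial_errors = errs, models = models, trials = trial_recs,
                 mean_error = tapply(errs$epsilon, errs$arm, mean),
                 channels = channels, lag_spacing = lag_spacing,
                 n_lags = n_lags),
            class = "mtp_cv")
}

#' @export
print.mtp_cv <- function(x, ...) {
  cat(sprintf("<mtp_cv> %d folds, %d trials, mean eps: %s\n",
              length(x$models), nrow(x$trial_errors),
              paste(sprintf("%s=%.3f", names(x$mean_error), x$mean_error),
                    collapse = ", ")))
  invisible(x)
}

default_lag_grid <- function() {
  expand.grid(lag_spacing = c(0.05, 0.1, 0.2), n_lags = c(1L, 2L, 4L, 8L))
}

#' Recursive channel elimination and lag-grid architecture search
#'
#' Starting from all channels, repeatedly (i) cross-validates every cell of
#' the lag grid, (ii) ranks the current channels by their weight scores
#' ([score_channels()]) under the best grid cell, and (iii) drops the
#' lowest-scoring channel (ties drop the higher montage index), until
#' `min_channels` remain. Each arm is searched independently. The selected
#' architecture is the (channel set, lag spacing, lag count) with minimal
#' mean cross-validated reconstruction error among channel-set sizes within
#' `[min_channels, max_channels]`.
#'
#' @inheritParams crossvalidate
#' @param lag_grid data.frame with columns `lag_spacing`, `n_lags`; default
#'   spans 50/100/200 ms and 1/2/4/8 lags.
#' @param min_channels,max_channels channel-count constraint for selection.
#' @param verbose log each elimination step.
#' @return An `mtp_selection` per arm: elimination `trace` (one row per grid
#'   cell per step), full channel `ranking` (best first), and the `selected`
#'   architecture.
#' @export
recursive_selection <- function(bp, kinematics, schedule,
                                channels = bp$labels,
                                lag_grid = default_lag_grid(),
                                arms = ARMS, min_channels = 6L,
                                max_channels = 12L, sub_blocks = 2L,
                                verbose = FALSE, ...) {
  if (length(channels) < min_channels)
    stop("fewer than ", min_channels, " usable channels")
  out <- list()
  for (arm in arms) {
    chans <- channels
    eliminated <- character()
    trace <- list()
    step <- 0L
    final_ranking <- chans
    while (length(chans) >= min_channels) {
      step <- step + 1L
      cell_err <- numeric(nrow(lag_grid))
      cell_cv <- vector("list", nrow(lag_grid))
      for (g in seq_len(nrow(lag_grid))) {
        cv <- crossvalidate(bp, kinematics, schedule, channels = chans,
                            lag_spacing = lag_grid$lag_spacing[g],
                            n_lags = lag_grid$n_lags[g], arms = arm,
                            sub_blocks = sub_blocks, ...)
        cell_err[g] <- cv$mean_error[[arm]]
        cell_cv[[g]] <- cv
        trace[[length(trace) + 1L]] <- data.frame(
          arm = arm, step = step, n_channels = length(chans),
          lag_spacing = lag_grid$lag_spacing[g],
          n_lags = lag_grid$n_lags[g], mean_epsilon = cell_err[g],
          channels = paste(chans, collapse = ","),
          stringsAsFactors = FALSE)
      }
      best <- which.min(cell_err)
      best_models <- lapply(cell_cv[[best]]$models, `[[`, arm)
      sc <- score_channels(best_models)
      # tie-break: among equal scores eliminate the higher montage index
      ord <- order(sc$score, -match(names(sc$score), channels))
      worst <- names(sc$score)[ord[1]]
      final_ranking <- sc$ranking
      if (verbose)
        message(sprintf("[%s] step %d: %d channels, best eps %.4f (%g s x %d), drop %s",
                        arm, step, length(chans), cell_err[best],
                        lag_grid$lag_spacing[best], lag_grid$n_lags[best],
                        if (length(chans) > min_channels) worst else "none"))
      if (length(chans) == min_channels) break
      eliminated <- c(worst, eliminated)
      chans <- setdiff(chans, worst)
    }
    trace <- do.call(rbind, trace)
    eligible <- trace[trace$n_channels >= min_channels &
                        trace$n_channels <= max_channels, , drop = FALSE]
    sel <- eligible[which.min(eligible$mean_epsilon), , drop = FALSE]
    out[[arm]] <- structure(list(
      trace = trace,
      ranking = c(final_ranking, eliminated),
      selected = list(channels = strsplit(sel$channels, ",")[[1]],
                      lag_spacing = sel$lag_spacing, n_lags = sel$n_lags,
                      mean_epsilon = sel$mean_epsilon)),
      class = "mtp_selection")
  }
  out
}

#' @export
print.mtp_selection <- function(x, ...) {
  s <- x$selected
  cat(sprintf("<mtp_selection> %d channels, spacing %g s, L=%d, eps=%.4f\n",
              length(s$channels), s$lag_spacing, s$n_lags, s$mean_epsilon))
  invisible(x)
}

#' Serialize / restore a trained decoder as JSON
#' @param model an `mtp_model`.
#' @param path output file.
#' @export
write_mtp_model <- function(model, path) {
  doc <- list(arm = model$arm, a = model$a, b = model$b,
              info = model$info, sigma = model$sigma,
              lag_spacing = model$lag_spacing, n_lags = model$n_lags,
              step_s = model$step_s)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mtp_model
#' @export
read_mtp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a = as.numeric(doc$a), b = as.matrix(doc$b),
                 info = as.data.frame(doc$info), sigma = as.numeric(doc$sigma),
                 lag_spacing = doc$lag_spacing, n_lags = as.integer(doc$n_lags),
                 step_s = doc$step_s, arm = doc$arm),
            class = "mtp_model")
}
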