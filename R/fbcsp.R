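# Filter-bank common spatial patterns comparator: per-band CSP filters,
# time-varying log-variance features, quantized mutual-information feature
# selection, regularized LDA, one-vs-rest multi-class decisions and nested
# (inner-outer) cross-validation.

trial_cov <- function(x) {
  C <- tcrossprod(x)
  C / sum(diag(C))  # trace normalization conditions the class averages
}

csp_fit_cov <- function(Ca, Cb, n_pairs) {
  Cc <- Ca + Cb
  e <- eigen(Cc, symmetric = TRUE)
  shrunk <- FALSE
  if (min(e$values) < 1e-10 * max(e$values)) {
    # rank deficiency is expected after common-average referencing (the
    # channel-mean direction is null); a small shrinkage ridge restores
    # invertibility and the affected direction lands mid-spectrum
    shrunk <- TRUE
    Cc <- Cc + diag(1e-6 * sum(diag(Cc)) / nrow(Cc), nrow(Cc))
    e <- eigen(Cc, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  S <- P %*% Ca %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- t(es$vectors) %*% P            # rows = filters, eigenvalues descending
  n <- nrow(W)
  if (2 * n_pairs > n) stop("`n_pairs` too large for the channel count")
  sel <- c(seq_len(n_pairs), (n - n_pairs + 1L):n)
  # forward-model patterns (columns of W^-1): the channel distribution each
  # extracted component projects to, used for topographic maps
  A <- solve(W)
  structure(list(filters = W[sel, , drop = FALSE], filters_full = W,
                 patterns = t(A[, sel, drop = FALSE]),
                 eigenvalues = es$values, n_pairs = n_pairs,
                 shrinkage_applied = shrunk),
            class = "csp_model")
}

#' Common spatial patterns
#'
#' Fits spatial filters maximizing the ratio of class-conditional variances
#' by the generalized eigendecomposition of the (trace-normalized,
#' class-averaged) covariance `C_a` against the composite `C_a + C_b`. The
#' generalized eigenvalues lie in `[0, 1]`; the `n_pairs` filters from each
#' end of the spectrum are retained.
#'
#' @param trials_a,trials_b lists of channels x samples matrices, one per
#'   trial.
#' @param n_pairs filter pairs to retain.
#' @return A `csp_model`: `filters` (2*n_pairs x channels), the full filter
#'   matrix and the eigenvalue spectrum.
#' @export
csp_fit <- function(trials_a, trials_b, n_pairs = 3L) {
  if (length(trials_a) < 2L || length(trials_b) < 2L)
    stop("at least 2 trials per class are required")
  Ca <- Reduce(`+`, lapply(trials_a, trial_cov)) / length(trials_a)
  Cb <- Reduce(`+`, lapply(trials_b, trial_cov)) / length(trials_b)
  csp_fit_cov(Ca, Cb, n_pairs)
}

# Log-variance of sliding windows. x: components x samples matrix; starts:
# first sample index of each window; M: window length in samples.
logvar_windows <- function(x, starts, M) {
  cs1 <- cbind(0, t(apply(x, 1, cumsum)))
  cs2 <- cbind(0, t(apply(x^2, 1, cumsum)))
  mu <- (cs1[, starts + M, drop = FALSE] - cs1[, starts, drop = FALSE]) / M
  v <- (cs2[, starts + M, drop = FALSE] - cs2[, starts, drop = FALSE]) / M - mu^2
  v <- v * M / (M - 1)
  floor_v <- 1e-12 * max(v, 1e-300)
  if (any(v < floor_v)) v <- pmax(v, floor_v)
  t(log(v))  # windows x components
}

#' Time-varying log-variance features
#'
#' Log of the within-window variance of each (CSP-projected) component in a
#' sliding window (1 s width, 200 ms step) whose offsets cover -4 s before
#' to 12 s after the imagined-movement onset.
#'
#' @param trial components x samples matrix of one trial epoch.
#' @param sample_rate sampling rate, Hz.
#' @param epoch_start time of the first sample relative to the movement
#'   onset, seconds.
#' @param offsets window start offsets relative to onset, seconds.
#' @param window window width, seconds.
#' @return offsets x components matrix of log-variance features.
#' @export
logvar_features <- function(trial, sample_rate = 120, epoch_start = -4,
                            offsets = fbcsp_offsets(), window = 1) {
  M <- round(window * sample_rate)
  starts <- round((offsets - epoch_start) * sample_rate) + 1L
  if (any(starts < 1L) || any(starts + M - 1L > ncol(trial)))
    stop("trial too short for the requested window offsets")
  out <- logvar_windows(rbind(trial), starts, M)
  rownames(out) <- sprintf("%+.1fs", offsets)
  out
}

#' Default sliding-window offsets (-4 s to +11 s, 0.2 s step)
#' @export
fbcsp_offsets <- function() seq(-4, 11, by = 0.2)

# Equal-frequency quantization by rank: bin b holds the b-th n/n_levels
# share of the sorted values. Tied values share their average rank (and
# hence a bin), so ties never leak ordering information; constant features
# collapse to one bin.
quantize_ef <- function(x, n_levels) {
  if (max(x) - min(x) <= 0) return(rep(1L, length(x)))
  as.integer(ceiling(n_levels * rank(x, ties.method = "average") /
                       length(x)))
}

mi_bits <- function(bins, y_int, nb, ny) {
  n <- length(bins)
  tab <- tabulate(bins + nb * (y_int - 1L), nbins = nb * ny)
  p <- matrix(tab / n, nb, ny)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (px[row(p)][nz] * py[col(p)][nz])))
}

#' Mutual-information feature selection on a quantized feature space
#'
#' Each feature is quantized into `n_levels` equal-frequency bins and the
#' mutual information with the class label is estimated from the empirical
#' joint table (bits). The `k` features with the highest MI are selected;
#' the MI values serve as feature weights. Constant features carry zero MI.
#'
#' @param features trials x features matrix.
#' @param labels class label per trial.
#' @param n_levels quantization levels (>= 2).
#' @param k number of features to select.
#' @return list with `selected` (column indices, best first) and `mi`
#'   (weights for all features).
#' @export
mi_select <- function(features, labels, n_levels = 8L, k = 8L) {
  if (n_levels < 2L) stop("`n_levels` must be >= 2")
  features <- as.matrix(features)
  if (k > ncol(features)) stop("`k` exceeds the feature count")
  y <- as.integer(factor(labels))
  ny <- max(y)
  mi <- vapply(seq_len(ncol(features)), function(j) {
    bins <- quantize_ef(features[, j], n_levels)
    mi_bits(bins, y, max(bins), ny)
  }, numeric(1))
  list(selected = order(-mi)[seq_len(k)], mi = mi)
}

rlda_suffstats <- function(X0, X1) {
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) /
    (nrow(X0) + nrow(X1) - 2)
  list(mu0 = mu0, mu1 = mu1, S = S)
}

rlda_from_suff <- function(suff, gamma) {
  d <- length(suff$mu0)
  Sg <- (1 - gamma) * suff$S + gamma * (sum(diag(suff$S)) / d) * diag(d)
  w <- tryCatch(solve(Sg, suff$mu1 - suff$mu0),
                error = function(e) stop("singular covariance with gamma = ",
                                         gamma, "; increase shrinkage"))
  b <- -sum(w * (suff$mu0 + suff$mu1)) / 2
  list(w = w, b = b)
}

#' Regularized linear discriminant analysis
#'
#' Shrinks the pooled within-class covariance toward its scaled identity,
#' `S_gamma = (1 - gamma) S + gamma (tr(S)/d) I`, and places the decision
#' hyperplane `w = S_gamma^{-1} (mu_1 - mu_0)` through the midpoint of the
#' projected class means. Signed distances are positive for class
#' `levels[2]`.
#'
#' @param features trials x features matrix.
#' @param labels two-class label per trial.
#' @param gamma shrinkage in `[0, 1]`.
#' @return An `rlda_model` with `w`, `b`, `classes`, `gamma`.
#' @export
rlda_fit <- function(features, labels, gamma = 0.1) {
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("exactly two classes are required")
  X <- as.matrix(features)
  suff <- rlda_suffstats(X[f == levels(f)[1], , drop = FALSE],
                         X[f == levels(f)[2], , drop = FALSE])
  fit <- rlda_from_suff(suff, gamma)
  structure(list(w = fit$w, b = fit$b, classes = levels(f), gamma = gamma),
            class = "rlda_model")
}

#' Signed distance to an RLDA hyperplane
#' @param model an `rlda_model`.
#' @param features trials x features matrix.
#' @export
rlda_distance <- function(model, features) {
  drop(as.matrix(features) %*% model$w + model$b)
}

#' One-vs-rest multi-class decision
#'
#' Chooses the class whose target-vs-rest classifier reports the largest
#' signed distance; exact ties resolve to the lowest class index.
#'
#' @param distances trials x classes matrix (or a vector for one trial) of
#'   signed distances, columns named by class.
#' @export
multiclass_decide <- function(distances) {
  m <- rbind(distances)
  idx <- unname(apply(m, 1, which.max))  # first maximum wins ties
  if (!is.null(colnames(m))) colnames(m)[idx] else idx
}

# ---------------------------------------------------------------------------
# Dataset container and nested cross-validation

#' Build an FBCSP trial dataset from a recording
#'
#' Common-average-references the recording, filters it through the six-band
#' filter bank, and cuts one epoch per trial (-4 s to +12 s around the
#' imagined-movement onset). Per-band, per-trial covariances over the task
#' interval are precomputed for CSP fitting.
#'
#' @param recording an [eeg_recording()].
#' @param onsets trial onset times, seconds.
#' @param labels class label per trial.
#' @param fold_id cross-validation fold membership per trial (run or
#'   session index).
#' @param bands band list (defaults to the six-band filter bank).
#' @param epoch epoch window around onset, seconds.
#' @param csp_window interval (relative to onset) on which CSP filters are
#'   fitted.
#' @return An `fbcsp_dataset`.
#' @export
fbcsp_dataset <- function(recording, onsets, labels, fold_id,
                          bands = analysis_bands(filterbank = TRUE),
                          epoch = c(-4, 12), csp_window = c(0, 12)) {
  stopifnot(length(onsets) == length(labels),
            length(onsets) == length(fold_id))
  fs <- recording$sample_rate
  filt <- bandpass_filterbank(car_filter(recording), bands)
  n <- ncol(recording$signals)
  i0 <- round((onsets + epoch[1]) * fs) + 1L
  i1 <- round((onsets + epoch[2]) * fs)
  if (any(i0 < 1L) || any(i1 > n))
    stop("trial epochs extend beyond the recording")
  len <- min(i1 - i0 + 1L)
  c0 <- round((csp_window[1] - epoch[1]) * fs) + 1L
  c1 <- round((csp_window[2] - epoch[1]) * fs)
  trials <- vector("list", length(onsets))
  covs <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    per_band <- lapply(filt, function(fr)
      fr$signals[, i0[i]:(i0[i] + len - 1L), drop = FALSE])
    trials[[i]] <- per_band
    covs[[i]] <- lapply(per_band, function(x)
      trial_cov(x[, c0:min(c1, len), drop = FALSE]))
  }
  structure(list(trials = trials, covs = covs, labels = labels,
                 fold_id = fold_id, bands = names(bands),
                 sample_rate = fs, epoch = epoch, csp_window = csp_window,
                 channel_labels = recording$labels),
            class = "fbcsp_dataset")
}

#' Concatenate FBCSP datasets (e.g. sessions)
#' @param ... `fbcsp_dataset` objects with identical band/epoch structure.
#' @export
combine_fbcsp_datasets <- function(...) {
  ds <- list(...)
  out <- ds[[1]]
  for (d in ds[-1]) {
    stopifnot(identical(d$bands, out$bands), d$sample_rate == out$sample_rate)
    out$trials <- c(out$trials, d$trials)
    out$covs <- c(out$covs, d$covs)
    out$labels <- c(out$labels, d$labels)
    out$fold_id <- c(out$fold_id, d$fold_id)
  }
  out
}

#' @export
print.fbcsp_dataset <- function(x, ...) {
  cat(sprintf("<fbcsp_dataset> %d trials, %d bands, folds: %s\n",
              length(x$trials), length(x$bands),
              paste(sort(unique(x$fold_id)), collapse = ",")))
  invisible(x)
}

#' Default parameter grid for the nested cross-validation
#'
#' CSP pairs 1-3, MI quantization levels 4/8/16, selected features 4/8/16,
#' RLDA shrinkage over 0, 0.1, 0.3, 0.5, 0.9.
#' @export
fbcsp_param_grid <- function() {
  expand.grid(n_pairs = 1:3, n_levels = c(4L, 8L, 16L), k = c(4L, 8L, 16L),
              gamma = c(0, 0.1, 0.3, 0.5, 0.9))
}

# CSP models per band for a binary split, from precomputed covariances.
csp_per_band <- function(dataset, idx, y, n_pairs) {
  lapply(seq_along(dataset$bands), function(b) {
    Ca <- Reduce(`+`, lapply(dataset$covs[idx][y[idx]],
                             `[[`, b)) / sum(y[idx])
    Cb <- Reduce(`+`, lapply(dataset$covs[idx][!y[idx]],
                             `[[`, b)) / sum(!y[idx])
    csp_fit_cov(Ca, Cb, n_pairs)
  })
}

# Log-variance features of CSP-projected trials.
# Returns array [trials, offsets, bands * 2*n_pairs].
csp_logvar <- function(dataset, idx, csp_models, offsets, window = 1) {
  fs <- dataset$sample_rate
  M <- round(window * fs)
  starts <- round((offsets - dataset$epoch[1]) * fs) + 1L
  nb <- length(dataset$bands)
  nc <- nrow(csp_models[[1]]$filters)
  out <- array(NA_real_, c(length(idx), length(starts), nb * nc))
  for (ti in seq_along(idx)) {
    tr <- dataset$trials[[idx[ti]]]
    for (b in seq_len(nb)) {
      proj <- csp_models[[b]]$filters %*% tr[[b]]
      out[ti, , (b - 1L) * nc + seq_len(nc)] <- logvar_windows(proj, starts, M)
    }
  }
  out
}

# Vectorized one-vs-rest decision: argmax over the class dimension of a
# trials x offsets x classes distance array (ties take the lowest index).
argmax_classes <- function(d) {
  dm <- matrix(d, dim(d)[1] * dim(d)[2], dim(d)[3])
  matrix(max.col(dm, ties.method = "first"), dim(d)[1], dim(d)[2])
}

# Column indices keeping n_pairs of the n_max CSP pairs in every band block.
comp_subset <- function(n_bands, n_max, n_pairs) {
  block <- c(seq_len(n_pairs), (2 * n_max - n_pairs + 1L):(2 * n_max))
  as.vector(outer(block, (seq_len(n_bands) - 1L) * 2L * n_max, "+"))
}

# Signed distances of validation trials for every (config, offset).
# ftr/fva: feature arrays from csp_logvar at n_max pairs; y: logical target.
binary_config_distances <- function(ftr, y, fva, grid, n_bands, n_max) {
  n_off <- dim(ftr)[2]
  levels_set <- sort(unique(grid$n_levels))
  sel_grid <- unique(grid[, c("n_pairs", "n_levels", "k")])
  gammas <- sort(unique(grid$gamma))
  dist <- array(NA_real_, c(dim(fva)[1], nrow(grid), n_off))
  # map (selection config, gamma) -> grid rows, hoisted out of the hot loop
  sel_key <- paste(grid$n_pairs, grid$n_levels, grid$k)
  row_map <- lapply(seq_len(nrow(sel_grid)), function(si) {
    sk <- paste(sel_grid$n_pairs[si], sel_grid$n_levels[si], sel_grid$k[si])
    lapply(gammas, function(g) which(sel_key == sk & grid$gamma == g))
  })
  for (off in seq_len(n_off)) {
    Xtr <- ftr[, off, , drop = TRUE]; Xva <- fva[, off, , drop = TRUE]
    Xtr <- rbind(Xtr); Xva <- rbind(Xva)
    suff_cache <- new.env(parent = emptyenv())
    mi_tab <- lapply(levels_set, function(nl)
      vapply(seq_len(ncol(Xtr)), function(j) {
        bins <- quantize_ef(Xtr[, j], nl)
        mi_bits(bins, as.integer(y) + 1L, max(bins), 2L)
      }, numeric(1)))
    names(mi_tab) <- as.character(levels_set)
    for (si in seq_len(nrow(sel_grid))) {
      np <- sel_grid$n_pairs[si]; nl <- sel_grid$n_levels[si]
      k <- sel_grid$k[si]
      cols <- comp_subset(n_bands, n_max, np)
      miv <- mi_tab[[as.character(nl)]][cols]
      sel <- cols[order(-miv)[seq_len(min(k, length(cols)))]]
      skey <- paste(sel, collapse = ",")
      suff <- suff_cache[[skey]]
      if (is.null(suff)) {
        s0 <- rlda_suffstats(Xtr[!y, sel, drop = FALSE],
                             Xtr[y, sel, drop = FALSE])
        es <- eigen(s0$S, symmetric = TRUE)
        suff <- list(U = es$vectors, d = es$values,
                     trd = sum(es$values) / length(sel),
                     dmu_r = crossprod(es$vectors, s0$mu1 - s0$mu0),
                     smu = s0$mu0 + s0$mu1,
                     Xv_r = Xva[, sel, drop = FALSE] %*% es$vectors)
        suff_cache[[skey]] <- suff
      }
      for (gi in seq_along(gammas)) {
        g <- gammas[gi]
        dg <- (1 - g) * suff$d + g * suff$trd
        rows <- row_map[[si]][[gi]]
        if (min(dg) <= 1e-12 * max(dg)) { dist[, rows, off] <- -Inf; next }
        w_r <- suff$dmu_r / dg                       # rotated RLDA weights
        w <- suff$U %*% w_r
        dist[, rows, off] <- suff$Xv_r %*% w_r - sum(w * suff$smu) / 2
      }
    }
  }
  dist
}

#' Nested (inner-outer) cross-validation of the FBCSP pipeline
#'
#' Outer folds follow `fold_id` (runs for single-session, sessions for
#' multi-session analysis); the inner folds are the leave-one-out splits of
#' the remaining folds (six outer / five inner for a single session, seven
#' outer / six inner across sessions). The inner level selects the CSP pair
#' count, MI quantization level, selected-feature count and RLDA shrinkage
#' maximizing the peak inner decoding accuracy; the outer test fold is then
#' scored per window offset with classifiers trained on all outer-training
#' trials. Multi-class decisions take the argmax of the one-vs-rest signed
#' distances.
#'
#' @param dataset an [fbcsp_dataset()].
#' @param grid parameter grid, see [fbcsp_param_grid()].
#' @param offsets sliding-window offsets, seconds relative to onset.
#' @return An `fbcsp_cv`: `da` (outer folds x offsets, %), `mean_da`,
#'   `peak_da`, `peak_offset`, chosen `params` per fold and per-fold
#'   `models` (CSP filters and MI weights) for contribution maps.
#' @export
nested_cv <- function(dataset, grid = fbcsp_param_grid(),
                      offsets = fbcsp_offsets()) {
  classes <- sort(unique(dataset$labels))
  folds <- sort(unique(dataset$fold_id))
  if (length(folds) < 3L) stop("at least 3 folds are required")
  n_max <- max(grid$n_pairs)
  nb <- length(dataset$bands)
  da <- matrix(NA_real_, length(folds), length(offsets),
               dimnames = list(paste0("fold", folds), NULL))
  params <- vector("list", length(folds))
  models <- vector("list", length(folds))
  for (oi in seq_along(folds)) {
    test_idx <- which(dataset$fold_id == folds[oi])
    train_folds <- setdiff(folds, folds[oi])
    acc <- matrix(0, nrow(grid), length(offsets))
    n_dec <- 0L
    for (fi in seq_along(train_folds)) {
      val_idx <- which(dataset$fold_id == train_folds[fi])
      fit_idx <- which(dataset$fold_id %in% setdiff(train_folds,
                                                    train_folds[fi]))
      if (length(unique(dataset$labels[fit_idx])) < length(classes))
        stop("a class is absent from an inner training fold")
      dist_c <- lapply(classes, function(cl) {
        y <- dataset$labels == cl
        csp <- csp_per_band(dataset, fit_idx, y, n_max)
        ftr <- csp_logvar(dataset, fit_idx, csp, offsets)
        fva <- csp_logvar(dataset, val_idx, csp, offsets)
        binary_config_distances(ftr, y[fit_idx], fva, grid, nb, n_max)
      })
      truth <- match(dataset$labels[val_idx], classes)
      n_val <- length(val_idx)
      for (ci in seq_len(nrow(grid))) {
        d <- array(NA_real_, c(n_val, length(offsets), length(classes)))
        for (cl in seq_along(classes)) d[, , cl] <- dist_c[[cl]][, ci, ]
        pred <- argmax_classes(d)
        acc[ci, ] <- acc[ci, ] + colSums(pred == truth)
      }
      n_dec <- n_dec + length(val_idx)
    }
    inner_da <- acc / n_dec
    best <- which.max(apply(inner_da, 1, max))
    params[[oi]] <- grid[best, , drop = FALSE]
    # refit on all outer-training trials with the chosen parameters
    fit_idx <- which(dataset$fold_id %in% train_folds)
    np <- grid$n_pairs[best]
    per_class <- lapply(classes, function(cl) {
      y <- dataset$labels == cl
      csp <- csp_per_band(dataset, fit_idx, y, np)
      ftr <- csp_logvar(dataset, fit_idx, csp, offsets)
      fte <- csp_logvar(dataset, test_idx, csp, offsets)
      mi_w <- matrix(NA_real_, length(offsets), dim(ftr)[3])
      dist <- matrix(NA_real_, length(test_idx), length(offsets))
      for (off in seq_along(offsets)) {
        Xtr <- rbind(ftr[, off, , drop = TRUE])
        ms <- mi_select(Xtr, y[fit_idx], n_levels = grid$n_levels[best],
                        k = min(grid$k[best], ncol(Xtr)))
        mi_w[off, ] <- ms$mi
        suff <- rlda_suffstats(Xtr[!y[fit_idx], ms$selected, drop = FALSE],
                               Xtr[y[fit_idx], ms$selected, drop = FALSE])
        fit <- rlda_from_suff(suff, grid$gamma[best])
        dist[, off] <- rbind(fte[, off, , drop = TRUE])[, ms$selected,
                                                        drop = FALSE] %*%
          fit$w + fit$b
      }
      list(class = cl, csp = csp, mi = mi_w, distances = dist)
    })
    truth <- match(dataset$labels[test_idx], classes)
    d <- array(NA_real_, c(length(test_idx), length(offsets),
                           length(classes)))
    for (cl in seq_along(classes)) d[, , cl] <- per_class[[cl]]$distances
    pred <- argmax_classes(d)
    da[oi, ] <- 100 * colMeans(pred == truth)
    models[[oi]] <- per_class
  }
  mean_da <- colMeans(da)
  peak <- which.max(mean_da)
  structure(list(da = da, mean_da = mean_da, offsets = offsets,
                 peak_da = mean_da[peak], peak_offset = offsets[peak],
                 peak_index = peak, params = do.call(rbind, params),
                 models = models, classes = classes,
                 bands = dataset$bands,
                 channel_labels = dataset$channel_labels),
            class = "fbcsp_cv")
}

#' @export
print.fbcsp_cv <- function(x, ...) {
  cat(sprintf("<fbcsp_cv> %d classes, %d outer folds, peak DA %.1f%% at %+.1f s\n",
              length(x$classes), nrow(x$da), x$peak_da, x$peak_offset))
  invisible(x)
}

#' Band-by-time MI heat map and per-band channel topographies
#'
#' Averages the stored MI feature weights over folds and classes, per band
#' and window offset (the heat map of time-varying band contributions), and
#' forms, at the peak-accuracy offset, the MI-weighted average of the
#' absolute CSP filter coefficients per channel and band (the topography of
#' spatial contributions). Magnitudes are aggregated, so the maps are
#' invariant to CSP filter sign flips.
#'
#' @param cv an `fbcsp_cv` from [nested_cv()].
#' @param peak_index window-offset index at which topographies are taken;
#'   defaults to the peak-DA offset.
#' @return list with `heat` (bands x offsets MI matrix) and `topography`
#'   (bands x channels matrix).
#' @export
contribution_maps <- function(cv, peak_index = cv$peak_index) {
  nb <- length(cv$bands)
  n_off <- length(cv$offsets)
  n_feat <- ncol(cv$models[[1]][[1]]$mi)
  nc <- n_feat / nb
  heat <- matrix(0, nb, n_off, dimnames = list(cv$bands, NULL))
  topo <- matrix(0, nb, length(cv$channel_labels),
                 dimnames = list(cv$bands, cv$channel_labels))
  n_models <- 0L
  for (fold in cv$models) for (pc in fold) {
    n_models <- n_models + 1L
    for (b in seq_len(nb)) {
      cols <- (b - 1L) * nc + seq_len(nc)
      heat[b, ] <- heat[b, ] + rowMeans(pc$mi[, cols, drop = FALSE])
      w <- pc$mi[peak_index, cols]
      pat <- abs(pc$csp[[b]]$patterns)
      topo[b, ] <- topo[b, ] + colSums(pat * w)
    }
  }
  list(heat = heat / n_models, topography = topo / n_models,
       offsets = cv$offsets, peak_offset = cv$offsets[peak_index])
}
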