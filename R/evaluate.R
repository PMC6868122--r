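# Trajectory-level evaluation: time-varying decoding accuracy against the
# three target landmarks, permutation nulls, landmark distance curves and
# nonparametric comparisons.

#' Landmark directions for one arm
#'
#' Unit direction vectors of the three targets as seen from the arm's home
#' position, expressed in the relative-coordinate frame in which a perfectly
#' decoded straight trial sits at its target's unit vector.
#'
#' @param layout a [target_layout()].
#' @param arm `"left"` or `"right"`.
#' @return named list of unit 3D vectors (X, Y, Z).
#' @export
landmark_directions <- function(layout, arm) {
  lapply(layout$targets[[arm]], function(tgt) {
    u <- tgt - layout$home[[arm]]
    u / sqrt(sum(u^2))
  })
}

trial_coord_array <- function(trials) {
  len <- min(vapply(trials, nrow, 1L))
  arr <- array(NA_real_, c(length(trials), len, 3L))
  for (i in seq_along(trials)) arr[i, , ] <- trials[[i]][seq_len(len), ]
  arr
}

#' Time-varying decoding accuracy
#'
#' At each within-trial sample the predicted relative coordinate is
#' classified to the nearest landmark; a sample is a success when it is
#' strictly closer to the actual target's landmark than to both non-target
#' landmarks (ties count as failure). DA is the percentage of successes over
#' the pooled trials; trials are truncated to their common length.
#'
#' @param trials list of m x 3 relative-coordinate matrices (predicted
#'   trajectories).
#' @param labels per-trial target label, matching `names(landmarks)`.
#' @param landmarks named list of 3D landmark positions (one per target).
#' @param dt sample spacing, seconds, for the curve's time axis.
#' @return A `da_curve`: per-sample `da` (%), `time`, `n_trials`, `peak_da`
#'   and `peak_index`/`peak_latency`.
#' @export
time_varying_da <- function(trials, labels, landmarks, dt = 0.025) {
  if (!length(trials)) stop("at least one trial is required")
  if (length(labels) != length(trials))
    stop("`labels` must match `trials` in length")
  if (!all(labels %in% names(landmarks)))
    stop("label not among landmarks: ",
         paste(setdiff(labels, names(landmarks)), collapse = ", "))
  arr <- trial_coord_array(trials)
  len <- dim(arr)[2]
  lm <- do.call(rbind, landmarks)
  success <- matrix(FALSE, length(trials), len)
  for (i in seq_along(trials)) {
    # distances to every landmark at every sample of trial i
    d <- vapply(seq_len(nrow(lm)), function(l)
      sqrt(rowSums(sweep(arr[i, , , drop = TRUE], 2, lm[l, ], "-")^2)),
      numeric(len))
    own <- match(labels[i], rownames(lm))
    others <- setdiff(seq_len(nrow(lm)), own)
    success[i, ] <- d[, own] < apply(d[, others, drop = FALSE], 1, min)
  }
  da <- 100 * colMeans(success)
  peak <- which.max(da)
  structure(list(da = da, time = (seq_len(len) - 1) * dt,
                 n_trials = length(trials), peak_da = da[peak],
                 peak_index = peak, peak_latency = (peak - 1) * dt),
            class = "da_curve")
}

#' @export
print.da_curve <- function(x, ...) {
  cat(sprintf("<da_curve> %d trials, %d samples, peak DA %.1f%% at %.2f s\n",
              x$n_trials, length(x$da), x$peak_da, x$peak_latency))
  invisible(x)
}

#' Permutation null for the time-varying decoding accuracy
#'
#' Re-assigns target labels to whole predicted trajectories (the three
#' coordinates of a trial stay together) and recomputes the DA curve for
#' each permutation, giving the label-independence null distribution and a
#' per-sample permutation p-value for the observed curve.
#'
#' @inheritParams time_varying_da
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @return list with the observed `da_curve`, the `null` DA matrix
#'   (`n_perm` x samples), per-sample `p`, and `null_mean`/`null_sd`.
#' @export
permutation_null <- function(trials, labels, landmarks, n_perm = 200,
                             seed = 1, dt = 0.025) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (length(unique(labels)) < 2L)
    stop("permutation test requires at least two classes")
  obs <- time_varying_da(trials, labels, landmarks, dt = dt)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) {
      time_varying_da(trials, sample(labels), landmarks, dt = dt)$da
    }, numeric(length(obs$da))))
  })
  p <- (1 + colSums(null >= rep(obs$da, each = n_perm))) / (n_perm + 1)
  list(observed = obs, null = null, p = p,
       null_mean = colMeans(null), null_sd = apply(null, 2, sd))
}

#' Distances from a trajectory to a landmark set
#'
#' Per-sample Euclidean 3D distance between a coordinate trajectory and each
#' landmark (targets and home).
#'
#' @param trajectory m x 3 coordinate matrix.
#' @param landmarks named list of 3D points.
#' @return m x landmarks matrix of distances.
#' @export
distance_to_landmarks <- function(trajectory, landmarks) {
  trajectory <- as.matrix(trajectory)
  out <- vapply(landmarks, function(l)
    sqrt(rowSums(sweep(trajectory, 2, vec3(l), "-")^2)),
    numeric(nrow(trajectory)))
  out <- rbind(out)
  colnames(out) <- names(landmarks)
  out
}

#' Wilcoxon rank test
#'
#' Two-sided Wilcoxon signed-rank (paired) or rank-sum (unpaired) test with
#' the exact null for n <= 25 (when free of ties/zeros) and the normal
#' approximation otherwise. All-zero paired differences give p = 1 (no
#' evidence either way) with a warning.
#'
#' @param sample_a,sample_b numeric samples (paired samples must have equal
#'   length).
#' @param paired paired test?
#' @return the two-sided p-value.
#' @export
rank_test <- function(sample_a, sample_b, paired = FALSE) {
  if (length(sample_a) < 5 || length(sample_b) < 5)
    stop("at least 5 observations per sample are required")
  if (paired) {
    if (length(sample_a) != length(sample_b))
      stop("paired samples must have equal length")
    d <- sample_a - sample_b
    if (all(d == 0)) {
      warning("all paired differences are zero; returning p = 1")
      return(1)
    }
    d <- d[d != 0]
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    wilcox.test(d, exact = exact, correct = !exact)$p.value
  } else {
    exact <- length(sample_a) <= 25 && length(sample_b) <= 25 &&
      !any(duplicated(c(sample_a, sample_b)))
    wilcox.test(sample_a, sample_b, exact = exact, correct = !exact)$p.value
  }
}

#' Forward trials of a decoder cross-validation for DA analysis
#'
#' Pools the predicted relative-coordinate series of all forward
#' (home-to-target) trials of one arm from an `mtp_cv` result, with their
#' target labels, ready for [time_varying_da()].
#'
#' @param cv an `mtp_cv` from [crossvalidate()].
#' @param arm arm whose trials to pool.
#' @return list with `trials` (coordinate matrices) and `labels`.
#' @export
forward_trials <- function(cv, arm = "left") {
  keep <- vapply(cv$trials, function(tr)
    tr$arm == arm && tr$direction == "forward", logical(1))
  list(trials = lapply(cv$trials[keep], `[[`, "predicted"),
       labels = vapply(cv$trials[keep], `[[`, "", "target"))
}

#' Export a DA curve (with optional permutation band) as a TSV table
#' @param da a `da_curve`.
#' @param path output file.
#' @param null optional result of [permutation_null()].
#' @export
write_da_curve <- function(da, path, null = NULL) {
  df <- data.frame(time = da$time, da = da$da)
  if (!is.null(null)) {
    df$null_mean <- null$null_mean
    df$null_sd <- null$null_sd
    df$p <- null$p
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
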