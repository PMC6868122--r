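gauss_trials <- function(n, sds, len = 500) {
  lapply(seq_len(n), function(i)
    diag(sds) %*% matrix(rnorm(2 * len), 2, len))
}

test_that("CSP reproduces the two-channel eigenstructure by hand", {
  set.seed(21)
  ta <- gauss_trials(20, c(sqrt(2), 1))
  tb <- gauss_trials(20, c(1, sqrt(2)))
  m <- csp_fit(ta, tb, n_pairs = 1)
  # class covariances diag(2,1) vs diag(1,2): extreme eigenvalue 2/3 and
  # axis-aligned filters
  expect_lt(abs(m$eigenvalues[1] - 2 / 3), 0.03)
  expect_lt(abs(m$eigenvalues[2] - 1 / 3), 0.03)
  f1 <- abs(m$filters[1, ]) / max(abs(m$filters[1, ]))
  expect_lt(f1[2], 0.15)  # first filter picks channel 1
  expect_true(all(m$eigenvalues >= -1e-9 & m$eigenvalues <= 1 + 1e-9))
  # whitening: W (Ca + Cb) W' = I
  Ca <- Reduce(`+`, lapply(ta, mtpbci:::trial_cov)) / 20
  Cb <- Reduce(`+`, lapply(tb, mtpbci:::trial_cov)) / 20
  W <- m$filters_full
  expect_lt(max(abs(W %*% (Ca + Cb) %*% t(W) - diag(2))), 1e-8)
  # identical class covariances: no discriminability, eigenvalues 1/2
  m2 <- csp_fit(ta, ta, 1)
  expect_lt(max(abs(m2$eigenvalues - 0.5)), 1e-9)
  expect_error(csp_fit(ta[1], tb, 1), "at least 2")
})

test_that("CSP filters match brute-force variance-ratio maximization", {
  set.seed(22)
  A <- matrix(c(1, 0.4, 0.2, 0.8), 2)
  ta <- lapply(1:25, function(i) A %*% diag(c(2, 0.7)) %*% matrix(rnorm(1200), 2))
  tb <- lapply(1:25, function(i) A %*% diag(c(0.7, 2)) %*% matrix(rnorm(1200), 2))
  m <- csp_fit(ta, tb, 1)
  Ca <- Reduce(`+`, lapply(ta, mtpbci:::trial_cov)) / 25
  Cb <- Reduce(`+`, lapply(tb, mtpbci:::trial_cov)) / 25
  ratio <- function(w) drop(crossprod(w, Ca %*% w) /
                              crossprod(w, (Ca + Cb) %*% w))
  theta <- runif(1e4, 0, pi)
  brute <- max(vapply(theta, function(th) ratio(c(cos(th), sin(th))),
                      numeric(1)))
  expect_lt(abs(ratio(m$filters[1, ]) - brute) / brute, 0.01)
})

test_that("log-variance features scale and count windows as specified", {
  set.seed(23)
  x <- matrix(rnorm(1921), 1, 1921)  # one component, -4..12 s at 120 Hz
  f <- logvar_features(x, sample_rate = 120, epoch_start = -4)
  expect_equal(nrow(f), 76)  # -4.0 .. +11.0 s at 0.2 s steps
  expect_lt(abs(f[1, 1]), 0.3)  # unit variance -> logvar near 0
  f2 <- logvar_features(3 * x, 120, -4)
  expect_equal(f2 - f, matrix(2 * log(3), 76, 1), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_error(logvar_features(x[, 1:100, drop = FALSE], 120, -4),
               "too short")
})

test_that("quantized mutual information ranks informative features first", {
  set.seed(24)
  y <- rep(c(0, 1), each = 200)
  f_perfect <- y + 0  # identical to a balanced binary label
  f_noise <- rnorm(400)
  f_perm <- sample(f_perfect)
  ms <- mi_select(cbind(f_perfect, f_noise, f_perm), y, n_levels = 4, k = 3)
  expect_equal(ms$mi[1], 1)        # exactly one bit
  expect_lt(ms$mi[3], 0.05)        # label-independent after permutation
  expect_equal(ms$selected[1], 1L)
  # constant feature has zero MI and never outranks informative ones
  ms2 <- mi_select(cbind(f_perfect, rep(2, 400)), y, 4, 2)
  expect_equal(ms2$mi[2], 0)
  expect_equal(ms2$selected, c(1L, 2L))
  expect_error(mi_select(cbind(f_noise), y, 4, 5), "exceeds")
})

test_that("regularized LDA separates Gaussians through the mean midpoint", {
  set.seed(25)
  n <- 200
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(6, 6), "+"))
  y <- rep(c("a", "b"), each = n)
  m <- rlda_fit(X, y, gamma = 0.1)
  d <- rlda_distance(m, X)
  expect_true(all((d > 0) == (y == "b")))  # 100% training accuracy
  mid <- (colMeans(X[y == "a", ]) + colMeans(X[y == "b", ])) / 2
  expect_lt(abs(sum(m$w * mid) + m$b), 1e-9)
  # gamma = 1: direction parallel to the mean difference
  m1 <- rlda_fit(X, y, gamma = 1)
  dmu <- colMeans(X[y == "b", ]) - colMeans(X[y == "a", ])
  cosang <- sum(m1$w * dmu) / sqrt(sum(m1$w^2) * sum(dmu^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
  # label swap negates every signed distance
  m_swap <- rlda_fit(X, factor(y, levels = c("b", "a")), gamma = 0.1)
  expect_equal(rlda_distance(m_swap, X), -d, tolerance = 1e-9)
  expect_error(rlda_fit(X, rep("a", 2 * n), 0.1), "two classes")
})

test_that("multi-class decisions take the largest signed distance", {
  expect_equal(multiclass_decide(c(2, -1, -3)), 1L)
  expect_equal(multiclass_decide(c(0, 0, 0)), 1L)  # ties -> lowest index
  d <- rbind(c(2, -1, -3), c(-5, 1, 0))
  colnames(d) <- c("u", "v", "w")
  expect_equal(multiclass_decide(d), c("u", "v"))
  expect_equal(multiclass_decide(d + 10), multiclass_decide(d))
})

test_that("nested cross-validation keeps outer test data out of selection", {
  set.seed(26)
  # small synthetic dataset: 2 channels, variance difference between classes
  fs <- 120
  n_tr <- 24
  labels <- rep(c("l", "r"), n_tr / 2)
  onsets <- 10 + (0:(n_tr - 1)) * 20
  total <- max(onsets) + 16
  base <- matrix(rnorm(4 * total * fs), 4)
  for (i in seq_len(n_tr)) {
    idx <- round((onsets[i]) * fs):round((onsets[i] + 12) * fs)
    ch <- if (labels[i] == "l") 2 else 1  # contralateral suppression
    base[ch, idx] <- base[ch, idx] * 0.4
  }
  rec <- eeg_recording(base, fs, c("C3", "C4", "Cz", "Pz"))
  ds <- fbcsp_dataset(rec, onsets, labels, fold_id = rep(1:4, each = 6),
                      bands = analysis_bands()[1:2])
  grid <- expand.grid(n_pairs = 1L, n_levels = c(4L, 8L), k = 2L,
                      gamma = c(0.1, 0.5))
  cv <- nested_cv(ds, grid = grid, offsets = seq(-2, 10, by = 1))
  expect_equal(dim(cv$da), c(4L, 13L))
  expect_true(all(cv$da >= 0 & cv$da <= 100))
  expect_equal(nrow(cv$params), 4L)
  # broadband variance effect: well above the 50% chance level at the peak
  expect_gt(cv$peak_da, 75)
  maps <- contribution_maps(cv)
  expect_equal(dim(maps$heat), c(2L, 13L))
  expect_equal(colnames(maps$topography), c("C3", "C4", "Cz", "Pz"))
})
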