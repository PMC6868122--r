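make_ft <- function(S, sigma = rep(1, ncol(S)), step = 0.025) {
  structure(list(S = S, time = (seq_len(nrow(S)) - 1) * step,
                 info = data.frame(band = "mu",
                                   channel = paste0("c", seq_len(ncol(S))),
                                   lag = 0L),
                 sigma = sigma, step_s = step, lag_spacing = 0.05,
                 n_lags = 0L, difference = FALSE),
            class = "feature_tensor")
}

test_that("ordinary least squares recovers exact linear generators", {
  set.seed(3)
  X <- matrix(rnorm(500 * 6), 500, 6)
  a <- c(0.3, -1, 2)
  B <- matrix(rnorm(18), 6, 3)
  v <- sweep(X %*% B, 2, a, "+")
  m <- train_mlr(make_ft(X), v)
  expect_lt(max(abs(m$a - a)), 1e-10)
  expect_lt(max(abs(m$b - B)) / max(abs(B)), 1e-10)
  # residuals orthogonal to every regressor
  res <- v - sweep(X %*% m$b, 2, m$a, "+")
  expect_lt(max(abs(crossprod(X, res))), 1e-8 * max(abs(X)) * max(abs(v)))
})

test_that("all-zero features give the intercept-only solution", {
  v <- cbind(rnorm(100, 2), rnorm(100, -1), rnorm(100))
  expect_warning(m <- train_mlr(make_ft(matrix(0, 100, 3)), v),
                 "near-singular")
  expect_equal(m$a, colMeans(v), tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(m$b)), 1e-6)
})

test_that("no dense coefficient grid beats the least-squares solution", {
  set.seed(9)
  X <- matrix(rnorm(50 * 2), 50, 2)
  v <- cbind(0.5 + X %*% c(1, -2) + rnorm(50, sd = 0.3))
  m <- train_mlr(make_ft(X), v)
  rss_ls <- sum((v - (m$a + X %*% m$b))^2)
  grid <- as.matrix(expand.grid(a = seq(-1, 2, length.out = 25),
                                b1 = seq(-1, 3, length.out = 25),
                                b2 = seq(-4, 0, length.out = 25)))
  rss_grid <- apply(grid, 1, function(g)
    sum((v - (g[1] + X %*% g[2:3]))^2))
  expect_true(all(rss_grid >= rss_ls - 1e-9))
})

test_that("prediction applies the model forward at the 25 ms output rate", {
  set.seed(4)
  X <- matrix(rnorm(1200 * 4), 1200, 4)
  v <- sweep(X %*% matrix(rnorm(12), 4, 3), 2, c(1, 2, 3), "+")
  ft <- make_ft(X, step = 1 / 120)
  m <- train_mlr(ft, v)
  out <- predict_velocity(m, ft, output_step = 0.025)
  expect_equal(unique(round(diff(out$time), 10)), 0.025)
  # zero features -> constant intercept prediction
  ft0 <- make_ft(matrix(0, 50, 4), sigma = m$sigma)
  pred0 <- predict_velocity(m, ft0, output_step = NULL)
  expect_true(all(abs(sweep(pred0$velocity, 2, m$a)) < 1e-10))
  # sigma mismatch is refused
  ft_bad <- make_ft(X, sigma = rep(2, 4), step = 1 / 120)
  expect_error(predict_velocity(m, ft_bad), "training sigma")
})

test_that("moving-average smoothing behaves like the 9-sample kernel", {
  const <- matrix(5, 40, 3)
  expect_equal(smooth_prediction(const, 9), const)
  imp <- matrix(0, 41, 1); imp[21, 1] <- 1
  sm <- smooth_prediction(imp, 9)
  expect_equal(sm[17:25, 1], rep(1 / 9, 9))
  expect_equal(sum(sm), 1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(smooth_prediction(x, 1), x)
  expect_error(smooth_prediction(x, 4), "odd")
})

test_that("velocity normalization returns unit vectors and flags zeros", {
  expect_equal(normalize_velocity(c(3, 0, 4)), c(0.6, 0, 0.8),
               ignore_attr = TRUE)
  z <- normalize_velocity(c(0, 0, 0))
  expect_equal(unname(z[1:3]), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(z, "degenerate"))
  set.seed(1)
  m <- normalize_velocity(matrix(rnorm(30), 10, 3))
  expect_lt(max(abs(sqrt(rowSums(m^2)) - 1)), 1e-12)
})

test_that("relative coordinates are the running mean of normalized velocities", {
  v <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(relative_coordinates(v), rbind(c(1, 0, 0), c(1, 0, 0),
                                              c(1, 0, 0)))
  v2 <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(relative_coordinates(v2)[2, ], c(0, 0, 0))
  expect_equal(relative_coordinates(rbind(c(0, 1, 0))), rbind(c(0, 1, 0)))
  expect_error(relative_coordinates(matrix(0, 0, 3)), "empty")
  # integrate mode scales by dt
  expect_equal(relative_coordinates(v, mode = "integrate", dt = 0.5)[3, 1],
               1.5)
})

test_that("reconstruction error is the mean 3D distance and is translation-invariant", {
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(reconstruction_error(a, a), 0)
  b <- a; b[, 2] <- b[, 2] + 0.7
  expect_equal(reconstruction_error(a, b), 0.7)
  expect_equal(reconstruction_error(a, b), reconstruction_error(b, a))
  shift <- c(1, -2, 3)
  expect_equal(reconstruction_error(sweep(a, 2, shift, "+"),
                                    sweep(b, 2, shift, "+")),
               reconstruction_error(a, b))
  expect_error(reconstruction_error(a, b[1:5, ]), "lengths")
})

test_that("channel scores follow the squared-weight formula", {
  info <- data.frame(band = rep(c("mu", "beta"), each = 2),
                     channel = rep(c("c1", "c2"), 2), lag = 0L)
  m <- structure(list(a = rep(0, 3), b = matrix(0, 4, 3), info = info,
                      n_lags = 1L, lag_spacing = 0.05, sigma = rep(1, 4),
                      step_s = 0.025, arm = "left"),
                 class = "mtp_model")
  sc0 <- score_channels(m)
  expect_true(all(sc0$score == 0))
  m$b[1, 1] <- 2  # single coefficient b = 2, L = 1
  sc <- score_channels(m)
  expect_equal(unname(sc$per_band["c1", "mu"]), 4 / 2)
  expect_equal(sc$ranking[1], "c1")
  m_neg <- m; m_neg$b <- -m$b
  expect_equal(score_channels(m_neg)$score, sc$score)
})

test_that("cross-validation keeps folds structural and sigma training-only", {
  cv <- fix_noisy_cv()
  expect_equal(length(cv$models), 6L)
  expect_equal(sort(unique(cv$trial_errors$fold)), 1:6)
  # each run is tested exactly once with its 6 left-arm sub-block-2 trials
  tab <- table(cv$trial_errors$run)
  # one decoded arm: 3 blocks x (forward + backward) = 6 of the 12
  # movement trials per fold
  expect_true(all(tab == 6))
  expect_true(all(cv$trial_errors$epsilon >= 0))
  # sigma differs across folds on heteroscedastic (noisy) input
  sig1 <- cv$models[[1]]$left$sigma
  sig2 <- cv$models[[2]]$left$sigma
  expect_false(isTRUE(all.equal(sig1, sig2)))
  expect_error(crossvalidate(fix_noisy_bp(), fix_noisy_session()$kinematics,
                             build_offline_schedule(fix_layout(), 2, seed = 1)),
               "expected 6 runs")
})

test_that("recursive elimination keeps informative channels and respects the grid", {
  sess <- fix_noisy_session()
  bp <- fix_noisy_bp()
  sched <- fix_offline_schedule()
  start <- c("C4", "FC4", "CP4", "C3", "Cz", "Pz", "FCz", "P3")
  grid <- data.frame(lag_spacing = 0.1, n_lags = 2L)
  sel <- recursive_selection(bp, sess$kinematics, sched, channels = start,
                             lag_grid = grid, arms = "left",
                             min_channels = 6L)$left
  # the three left-arm encoding channels survive into the selected set
  expect_true(all(c("C4", "FC4", "CP4") %in% sel$selected$channels))
  # full ranking is a permutation of the starting set
  expect_setequal(sel$ranking, start)
  # 8 starting channels, floor 6 -> elimination steps at sizes 8, 7, 6
  expect_equal(sort(unique(sel$trace$n_channels)), 6:8)
  expect_error(recursive_selection(bp, sess$kinematics, sched,
                                   channels = c("C3", "C4"), arms = "left"),
               "fewer than")
})
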