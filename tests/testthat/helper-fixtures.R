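# Shared fixtures, computed lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Standard six-run offline protocol and its noiseless velocity-encoded
# session (the cleanest ground-truth fixture for decoder recovery).
fix_layout <- function() fixture("layout", target_layout)

fix_offline_schedule <- function()
  fixture("sched6", function() build_offline_schedule(fix_layout(), 6, seed = 7))

fix_noiseless_session <- function() fixture("sess0", function()
  synthesize_mtp_session(fix_offline_schedule(), fix_layout(),
                         encoding_spec(), noise_spec(0, 0, 0, 0), seed = 11))

fix_noiseless_bp <- function() fixture("bp0", function()
  session_band_power(fix_noiseless_session()$recording, feature_step = 0.025))

# A moderately noisy session exercising the full pipeline.
fix_noisy_session <- function() fixture("sessN", function()
  synthesize_mtp_session(fix_offline_schedule(), fix_layout(),
                         encoding_spec(),
                         noise_spec(1, 0.3, 0.5, 0.2), seed = 12))

fix_noisy_bp <- function() fixture("bpN", function()
  session_band_power(fix_noisy_session()$recording, feature_step = 0.025))

fix_noisy_cv <- function() fixture("cvN", function()
  crossvalidate(fix_noisy_bp(), fix_noisy_session()$kinematics,
                fix_offline_schedule(), arms = "left"))

# Window-averaged lagged velocity: the exact regressor for the generative
# band-power relation (power window [t, t+0.25) sees v averaged over the
# same window shifted by the encoding lag).
window_avg_lagged_velocity <- function(kin, arm, axis, lag_s, width_s = 0.25) {
  fs <- kin$sample_rate
  v <- kin[[arm]]$velocity[, axis]
  lag_n <- round(lag_s * fs)
  vlag <- c(rep(0, lag_n), utils::head(v, -lag_n))
  M <- round(width_s * fs)
  cs <- cumsum(c(0, vlag))
  starts <- seq(1, length(v) - M + 1)
  (cs[starts + M] - cs[starts]) / M
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
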