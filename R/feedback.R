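# Closed-loop machinery: assistance blending, the per-run assistance
# schedule, workspace clamping, cue muting and a replayable online-session
# simulator.

#' Feedback configuration
#'
#' @param assistance assistance level a in percent (0-100); the blending
#'   fraction is `rho = a/100`.
#' @param mode `"assisted"` or `"direct"`; direct mode forces zero
#'   assistance.
#' @param per_run_schedule in assisted mode, take the level from
#'   [assistance_schedule()] per run (50% decreasing to 20%) instead of the
#'   constant `assistance`.
#' @param mute_threshold fraction of the origin-destination distance below
#'   which the auditory cue is muted and the movement epoch ends (0.20).
#' @param bounds workspace bounds (`list(lower, upper)`); defaults to the
#'   standard layout's.
#' @export
feedback_config <- function(assistance = 50, mode = c("assisted", "direct"),
                            per_run_schedule = FALSE,
                            mute_threshold = 0.20,
                            bounds = target_layout()$bounds) {
  mode <- match.arg(mode)
  if (mode == "direct") assistance <- 0
  if (assistance < 0 || assistance > 100)
    stop("`assistance` must lie in [0, 100]")
  structure(list(assistance = assistance, rho = assistance / 100,
                 mode = mode,
                 per_run_schedule = per_run_schedule && mode == "assisted",
                 mute_threshold = mute_threshold,
                 bounds = bounds),
            class = "feedback_config")
}

#' Assistance-blended velocity
#'
#' Convex combination of the normalized target and predicted velocity
#' directions: `rho * v_target + (1 - rho) * v_predicted`, `rho = a/100`.
#'
#' @param v_target,v_predicted normalized 3D direction vectors.
#' @param assistance assistance level in percent.
#' @export
assisted_velocity <- function(v_target, v_predicted, assistance) {
  if (assistance < 0 || assistance > 100)
    stop("`assistance` must lie in [0, 100]")
  rho <- assistance / 100
  rho * vec3(v_target, "v_target") + (1 - rho) * vec3(v_predicted, "v_predicted")
}

#' Per-run assistance schedule
#'
#' The assisted online part starts at 50% assistance and decreases by 6% per
#' run, reaching 20% at run six: `a = 50 - 6 * (run - 1)`.
#'
#' @param run_index run number, 1 to 6.
#' @export
assistance_schedule <- function(run_index) {
  if (any(run_index < 1 | run_index > 6))
    stop("`run_index` must lie in 1..6")
  50 - 6 * (run_index - 1)
}

#' Clamp a displayed position to the workspace
#'
#' Componentwise clamp to the axis-aligned workspace box. (The simulator
#' keeps unclamped predicted coordinates separately.)
#'
#' @param pos 3D position.
#' @param bounds `list(lower, upper)` length-3 bounds.
#' @export
clamp_to_workspace <- function(pos, bounds) {
  pmin(pmax(vec3(pos, "pos"), bounds$lower), bounds$upper)
}

#' Cue-muting test
#'
#' TRUE once the hand is closer to the destination than `threshold` times
#' the origin-destination distance; the auditory cue is muted and the
#' movement epoch terminates early.
#'
#' @param pos current 3D position.
#' @param origin,destination movement endpoints.
#' @param threshold distance fraction (0.20).
#' @export
cue_mute_check <- function(pos, origin, destination, threshold = 0.20) {
  origin <- vec3(origin, "origin"); destination <- vec3(destination, "destination")
  d <- sqrt(sum((destination - origin)^2))
  if (d == 0) stop("degenerate movement: origin equals destination")
  sqrt(sum((vec3(pos, "pos") - destination)^2)) < threshold * d
}

#' Simulate a closed-loop online session
#'
#' Replays the online paradigm at the 40 Hz display rate: during each
#' movement epoch the displayed velocity is the assistance blend of the
#' normalized target direction and the decoder's normalized prediction, the
#' displayed position integrates that velocity (scaled so a perfect decoder
#' traverses home-to-target in the 4 s offline-template time), is clamped to
#' the workspace, and the epoch terminates early once the 20% cue-muting
#' rule fires; a 2 s hold follows, the hand relocates to the epoch endpoint,
#' and a 4 s pause precedes the next movement.
#'
#' @param schedule an online `paradigm_schedule`.
#' @param decoder `function(t, target_dir)` returning a (not necessarily
#'   normalized) predicted 3D velocity at session time `t`; see
#'   [oracle_decoder()] and [noisy_decoder()].
#' @param config a [feedback_config()]; with `per_run_schedule = TRUE` the
#'   per-run [assistance_schedule()] replaces the constant level.
#' @param layout the `target_layout`.
#' @param rate control-loop rate, Hz.
#' @param seed seed forwarded to stochastic decoders via the RNG state.
#' @return An `online_log` data frame, one row per control step.
#' @export
simulate_online_session <- function(schedule, decoder,
                                    config = feedback_config(),
                                    layout = attr(schedule, "layout"),
                                    rate = 40, seed = 1) {
  dt <- 1 / rate
  moves <- movement_trials(schedule)
  rows <- vector("list", 0L)
  with_seed(seed, {
    for (i in seq_len(nrow(moves))) {
      mv <- moves[i, ]
      arm <- mv$arm
      home <- layout$home[[arm]]
      tgt <- layout$targets[[arm]][[mv$target]]
      forward <- mv$direction == "forward"
      origin <- if (forward) home else tgt
      dest <- if (forward) tgt else home
      dist <- sqrt(sum((dest - origin)^2))
      speed <- dist / 4  # unit-blend speed scaling: 4 s ideal traverse
      a <- if (config$mode == "direct") 0
      else if (config$per_run_schedule) assistance_schedule(mv$run)
      else config$assistance
      pos <- origin
      n_steps <- round(mv$duration / dt)
      for (s in seq_len(n_steps)) {
        t <- mv$onset + (s - 1) * dt
        v_t <- normalize_velocity(dest - pos)
        v_p <- normalize_velocity(decoder(t, v_t))
        v_a <- assisted_velocity(v_t, v_p, a)
        raw <- pos + v_a * speed * dt
        pos <- clamp_to_workspace(raw, config$bounds)
        muted <- cue_mute_check(pos, origin, dest, config$mute_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          time = t, run = mv$run, block = mv$block, arm = arm,
          target = mv$target, direction = mv$direction, assistance = a,
          vt_x = v_t[1], vt_y = v_t[2], vt_z = v_t[3],
          vp_x = v_p[1], vp_y = v_p[2], vp_z = v_p[3],
          va_x = v_a[1], va_y = v_a[2], va_z = v_a[3],
          x = pos[1], y = pos[2], z = pos[3],
          clamped = any(raw != pos), muted = muted,
          stringsAsFactors = FALSE)
        if (muted) break
      }
    }
  })
  log <- do.call(rbind, rows)
  class(log) <- c("online_log", "data.frame")
  log
}

#' Reference decoders for closed-loop simulation
#'
#' `oracle_decoder()` returns the true target direction (perfect control);
#' `noisy_decoder(sd)` perturbs it with isotropic Gaussian noise;
#' `random_decoder()` ignores the target entirely.
#' @param sd standard deviation of the directional noise.
#' @export
oracle_decoder <- function() function(t, target_dir) target_dir

#' @rdname oracle_decoder
#' @export
noisy_decoder <- function(sd = 1) function(t, target_dir)
  target_dir + rnorm(3, sd = sd)

#' @rdname oracle_decoder
#' @export
random_decoder <- function() function(t, target_dir) rnorm(3)

#' Write an online log as a TSV table
#' @param log an `online_log`.
#' @param path output file.
#' @export
write_online_log <- function(log, path) {
  write.table(as.data.frame(log), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
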