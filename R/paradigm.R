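# Experiment paradigm: target geometry, offline/online schedules and the
# ideal velocity templates used both as decoder training targets and as
# ground truth for the synthetic-data generator.

TARGET_AXES <- c("X", "Y", "Z")
ARMS <- c("left", "right")

# Canonical epoch durations (seconds).
OFFLINE_EPOCHS <- c(home_to_target = 4, pause_at_target = 2,
                    target_to_home = 4, pause_at_home = 2)
RUN_INIT_S <- 10
BLOCK_VOICE_S <- 4
INTER_RUN_REST_S <- 40
ONLINE_MOVE_MAX_S <- 7
ONLINE_HOLD_S <- 2
ONLINE_PAUSE_S <- 4

#' Six-target virtual-arm layout
#'
#' Builds the two-arm workspace geometry: a home position per arm and three
#' targets per arm placed at the same orthogonal distance from that arm's
#' home along the horizontal (X), vertical (Y) and depth (Z) axes. Left-arm
#' targets point outward along -x; right-arm targets along +x; both arms
#' share +y (up) and +z (depth).
#'
#' @param target_distance distance (arbitrary units) from each home to each
#'   of its three targets.
#' @param home_separation distance between the two home positions.
#' @param margin extra workspace padding beyond the extreme landmark
#'   coordinates on each axis.
#' @return An object of class `target_layout`: home positions, a
#'   `targets[[arm]][[axis]]` map and axis-aligned `bounds`.
#' @export
target_layout <- function(target_distance = 1, home_separation = 1.2,
                          margin = 0.25) {
  stopifnot_scalar(target_distance, "target_distance")
  if (target_distance <= 0) stop("`target_distance` must be positive")
  h <- home_separation / 2
  home <- list(left = c(-h, 0, 0), right = c(h, 0, 0))
  dirs <- list(
    left  = list(X = c(-1, 0, 0), Y = c(0, 1, 0), Z = c(0, 0, 1)),
    right = list(X = c(1, 0, 0),  Y = c(0, 1, 0), Z = c(0, 0, 1)))
  targets <- lapply(ARMS, function(arm)
    lapply(dirs[[arm]], function(u) home[[arm]] + target_distance * u))
  names(targets) <- ARMS
  pts <- do.call(rbind, c(home, unlist(targets, recursive = FALSE)))
  bounds <- list(lower = apply(pts, 2, min) - margin,
                 upper = apply(pts, 2, max) + margin)
  structure(list(home = home, targets = targets, bounds = bounds,
                 target_distance = target_distance),
            class = "target_layout")
}

#' @export
print.target_layout <- function(x, ...) {
  cat("<target_layout> 2 homes, 6 targets, target distance",
      x$target_distance, "\n")
  invisible(x)
}

arm_target_combos <- function() {
  data.frame(arm = rep(ARMS, each = 3L),
             target = rep(TARGET_AXES, times = 2L),
             stringsAsFactors = FALSE)
}

new_schedule <- function(rows, mode, layout) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, mode = mode, layout = layout,
            class = c("paradigm_schedule", "data.frame"))
}

epoch_row <- function(kind, onset, duration, arm = NA_character_,
                      target = NA_character_, sub_block = NA_integer_,
                      run = NA_integer_, block = NA_integer_) {
  data.frame(onset = onset, duration = duration, kind = kind, arm = arm,
             target = target, sub_block = sub_block, run = run,
             block = block, stringsAsFactors = FALSE)
}

#' Offline calibration schedule
#'
#' One offline run is a 10 s run-initialisation voice period followed by six
#' blocks, one per arm-by-target combination in an order randomised per run.
#' Each block is a 4 s voice cue plus two identical 12 s sub-blocks, each
#' composed of home-to-target (4 s), pause-at-target (2 s), target-to-home
#' (4 s) and pause-at-home (2 s) epochs; so a block lasts 28 s and a run
#' 178 s. A 40 s rest separates runs (and follows the last run).
#'
#' @param layout a [target_layout()].
#' @param n_runs number of runs (6 in the standard protocol).
#' @param seed integer seed driving the per-run target-order permutations.
#' @param rest_s inter-run rest duration in seconds.
#' @return A `paradigm_schedule` data frame with columns `onset`, `duration`,
#'   `kind`, `arm`, `target`, `sub_block`, `run`, `block` (seconds from
#'   session start; epochs are half-open `[onset, onset + duration)`).
#' @export
build_offline_schedule <- function(layout = target_layout(), n_runs = 6,
                                   seed = 1, rest_s = INTER_RUN_REST_S) {
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  combos <- arm_target_combos()
  orders <- with_seed(seed, lapply(seq_len(n_runs), function(r) sample.int(6L)))
  rows <- list()
  t <- 0
  for (r in seq_len(n_runs)) {
    rows[[length(rows) + 1L]] <- epoch_row("run_init", t, RUN_INIT_S, run = r)
    t <- t + RUN_INIT_S
    for (b in seq_len(6L)) {
      cmb <- combos[orders[[r]][b], ]
      rows[[length(rows) + 1L]] <- epoch_row("block_voice", t, BLOCK_VOICE_S,
        arm = cmb$arm, target = cmb$target, run = r, block = b)
      t <- t + BLOCK_VOICE_S
      for (sb in 1:2) {
        for (k in names(OFFLINE_EPOCHS)) {
          rows[[length(rows) + 1L]] <- epoch_row(k, t, OFFLINE_EPOCHS[[k]],
            arm = cmb$arm, target = cmb$target, sub_block = sb,
            run = r, block = b)
          t <- t + OFFLINE_EPOCHS[[k]]
        }
      }
    }
    if (rest_s > 0) {
      rows[[length(rows) + 1L]] <- epoch_row("inter_run_rest", t, rest_s, run = r)
    }
    t <- t + rest_s
  }
  new_schedule(rows, "offline", layout)
}

#' Online feedback schedule
#'
#' One online block is a 4 s voice cue followed by a movement cycle with
#' maximal epoch durations 7 s forward movement, 2 s hold at the movement
#' end-point, 4 s pause at the target, 7 s backward movement, 2 s hold and a
#' 4 s pause at home (26 s cycle, 30 s block, 190 s run maximum). During
#' simulation movement epochs may terminate early under the cue-muting rule;
#' this builder lays out the maximal-duration timeline.
#'
#' @inheritParams build_offline_schedule
#' @param mode `"online_assisted"` or `"online_direct"`.
#' @return A `paradigm_schedule`.
#' @export
build_online_schedule <- function(layout = target_layout(), n_runs = 6,
                                  seed = 1, rest_s = INTER_RUN_REST_S,
                                  mode = c("online_assisted", "online_direct")) {
  mode <- match.arg(mode)
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  combos <- arm_target_combos()
  orders <- with_seed(seed, lapply(seq_len(n_runs), function(r) sample.int(6L)))
  rows <- list()
  t <- 0
  for (r in seq_len(n_runs)) {
    rows[[length(rows) + 1L]] <- epoch_row("run_init", t, RUN_INIT_S, run = r)
    t <- t + RUN_INIT_S
    for (b in seq_len(6L)) {
      cmb <- combos[orders[[r]][b], ]
      add <- function(kind, dur) {
        rows[[length(rows) + 1L]] <<- epoch_row(kind, t, dur, arm = cmb$arm,
          target = cmb$target, run = r, block = b)
        t <<- t + dur
      }
      add("block_voice", BLOCK_VOICE_S)
      add("home_to_target", ONLINE_MOVE_MAX_S)
      add("hold_at_endpoint", ONLINE_HOLD_S)
      add("pause_at_target", ONLINE_PAUSE_S)
      add("target_to_home", ONLINE_MOVE_MAX_S)
      add("hold_at_endpoint", ONLINE_HOLD_S)
      add("pause_at_home", ONLINE_PAUSE_S)
    }
    if (rest_s > 0) {
      rows[[length(rows) + 1L]] <- epoch_row("inter_run_rest", t, rest_s, run = r)
    }
    t <- t + rest_s
  }
  new_schedule(rows, mode, layout)
}

#' Total schedule duration in seconds
#' @param schedule a `paradigm_schedule`.
#' @export
schedule_duration <- function(schedule) {
  max(schedule$onset + schedule$duration)
}

#' Ideal home-to-target velocity template
#'
#' Speed starts at zero, ramps linearly until half of the home-target
#' distance is covered, then stays constant until arrival. Solving the two
#' phase areas gives a ramp lasting 2/3 of the epoch and a peak speed of
#' 1.5 x distance / duration. Direction is constant along the home-target
#' vector; position is the trapezoidal integral of velocity.
#'
#' @param home,target 3D coordinates (units).
#' @param duration movement duration in seconds.
#' @param sample_rate output rate in Hz.
#' @return list with `time` (s, starting at 0), `velocity` and `position`
#'   (n x 3 matrices), `peak_speed`.
#' @export
velocity_template <- function(home, target, duration = 4, sample_rate = 120) {
  home <- vec3(home, "home"); target <- vec3(target, "target")
  if (duration <= 0) stop("`duration` must be positive")
  d <- sqrt(sum((target - home)^2))
  if (d == 0) stop("degenerate trajectory: `home` equals `target`")
  u <- (target - home) / d
  n <- round(duration * sample_rate) + 1L  # closed [0, duration] grid
  t <- (seq_len(n) - 1L) / sample_rate
  t_ramp <- 2 * duration / 3
  peak <- 1.5 * d / duration
  speed <- ifelse(t < t_ramp, peak * t / t_ramp, peak)
  v <- outer(speed, u)
  dt <- 1 / sample_rate
  pos_s <- cumsum(c(0, (speed[-1] + speed[-n]) / 2 * dt))
  p <- sweep(outer(pos_s, u), 2, home, "+")
  list(time = t, velocity = v, position = p, peak_speed = peak,
       direction = u, distance = d)
}

#' Session-wide target kinematics implied by a schedule
#'
#' Expands a paradigm schedule into per-arm velocity and position series on
#' a uniform time grid. Movement epochs follow [velocity_template()] (the
#' backward epoch is the mirrored template); velocity is exactly zero in all
#' other epochs and position rests at the epoch endpoint. In the offline
#' paradigm the sub-block-1 displayed trajectory is reused as the expected
#' (imagined) trajectory of sub-block 2.
#'
#' @param schedule a `paradigm_schedule`.
#' @param layout a `target_layout`; defaults to the layout the schedule was
#'   built with.
#' @param sample_rate kinematics sample rate, Hz.
#' @return An object of class `kinematics_series`: `time` vector plus, per
#'   arm, `velocity` and `position` n x 3 matrices.
#' @export
schedule_kinematics <- function(schedule, layout = attr(schedule, "layout"),
                                sample_rate = 120) {
  total <- schedule_duration(schedule)
  n <- round(total * sample_rate)
  time <- (seq_len(n) - 1L) / sample_rate
  out <- list(time = time, sample_rate = sample_rate)
  for (arm in ARMS) {
    v <- matrix(0, n, 3)
    p <- matrix(rep(layout$home[[arm]], each = n), n, 3)
    eps <- schedule[!is.na(schedule$arm) & schedule$arm == arm, , drop = FALSE]
    for (i in seq_len(nrow(eps))) {
      e <- eps[i, ]
      i0 <- round(e$onset * sample_rate) + 1L
      i1 <- min(round((e$onset + e$duration) * sample_rate), n)
      if (i0 > i1) next
      idx <- i0:i1
      tgt <- layout$targets[[arm]][[e$target]]
      hom <- layout$home[[arm]]
      if (e$kind == "home_to_target") {
        tpl <- velocity_template(hom, tgt, e$duration, sample_rate)
        m <- min(length(idx), nrow(tpl$velocity))
        v[idx[seq_len(m)], ] <- tpl$velocity[seq_len(m), ]
        p[idx[seq_len(m)], ] <- tpl$position[seq_len(m), ]
      } else if (e$kind == "target_to_home") {
        tpl <- velocity_template(tgt, hom, e$duration, sample_rate)
        m <- min(length(idx), nrow(tpl$velocity))
        v[idx[seq_len(m)], ] <- tpl$velocity[seq_len(m), ]
        p[idx[seq_len(m)], ] <- tpl$position[seq_len(m), ]
      } else if (e$kind %in% c("pause_at_target", "hold_at_endpoint")) {
        p[idx, ] <- matrix(rep(tgt, each = length(idx)), length(idx), 3)
      }
      # pause_at_home / block_voice keep the home-position default.
    }
    out[[arm]] <- list(velocity = v, position = p)
  }
  structure(out, class = "kinematics_series")
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf("<paradigm_schedule> mode=%s, %d epochs, %d run(s), %.1f s total\n",
              attr(x, "mode"), nrow(x), max(x$run, na.rm = TRUE),
              schedule_duration(x)))
  invisible(x)
}

#' Write / read a schedule as a BIDS-events-like TSV table
#'
#' Columns: `onset_s`, `duration_s`, `kind`, `arm`, `target`, `sub_block`,
#' `run`, `block`. Onsets are seconds from session start, intervals
#' half-open.
#' @param schedule a `paradigm_schedule`.
#' @param path output file.
#' @export
write_events <- function(schedule, path) {
  df <- as.data.frame(schedule)
  names(df)[names(df) == "onset"] <- "onset_s"
  names(df)[names(df) == "duration"] <- "duration_s"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @param mode schedule mode recorded on the object read back.
#' @export
read_events <- function(path, mode = "offline") {
  df <- read.delim(path, sep = "\t", na.strings = "n/a",
                   stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "kind", "arm", "target", "sub_block",
            "run", "block")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event table is missing columns: ",
                         paste(miss, collapse = ", "))
  names(df)[names(df) == "onset_s"] <- "onset"
  names(df)[names(df) == "duration_s"] <- "duration"
  validate_events(df)
  structure(df, mode = mode, layout = target_layout(),
            class = c("paradigm_schedule", "data.frame"))
}

# Reject overlapping epochs within a run, reporting offending rows.
validate_events <- function(df) {
  for (r in unique(df$run[!is.na(df$run)])) {
    rows <- which(df$run == r)
    o <- rows[order(df$onset[rows])]
    ends <- df$onset[o] + df$duration[o]
    bad <- which(df$onset[o][-1] < ends[-length(o)] - 1e-9)
    if (length(bad))
      stop(sprintf("overlapping epochs in run %s at table rows %s", r,
                   paste(o[bad + 1L], collapse = ", ")))
  }
  invisible(df)
}

# Movement-epoch table helper used by decoding and evaluation code:
# one row per movement interval ("trial"), 12 per offline run.
movement_trials <- function(schedule, sub_blocks = NULL, arms = ARMS) {
  m <- schedule[schedule$kind %in% c("home_to_target", "target_to_home") &
                  schedule$arm %in% arms, , drop = FALSE]
  if (!is.null(sub_blocks)) m <- m[m$sub_block %in% sub_blocks, , drop = FALSE]
  m$direction <- ifelse(m$kind == "home_to_target", "forward", "backward")
  m
}
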