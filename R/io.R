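# Session persistence (delimited tables) and the top-level pipeline.
# All tables are tab-separated UTF-8 with a header row; times in seconds,
# potentials in microvolts; intervals half-open.

#' Write a session bundle to a directory
#'
#' Writes `eeg.tsv` (time + one column per channel, microvolts),
#' `events.tsv` (the schedule) and `kinematics.tsv` (time, arm, velocity
#' and position components).
#'
#' @param session list with `recording`, `schedule` and optionally
#'   `kinematics` (as returned by [synthesize_mtp_session()]).
#' @param dir output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- session$recording
  eeg <- data.frame(time = (seq_len(ncol(rec$signals)) - 1) / rec$sample_rate,
                    t(rec$signals), check.names = FALSE)
  write.table(eeg, file.path(dir, "eeg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_events(session$schedule, file.path(dir, "events.tsv"))
  if (!is.null(session$kinematics)) {
    kin <- session$kinematics
    rows <- lapply(ARMS, function(arm)
      data.frame(time = kin$time, arm = arm,
                 vx = kin[[arm]]$velocity[, 1], vy = kin[[arm]]$velocity[, 2],
                 vz = kin[[arm]]$velocity[, 3],
                 px = kin[[arm]]$position[, 1], py = kin[[arm]]$position[, 2],
                 pz = kin[[arm]]$position[, 3]))
    write.table(do.call(rbind, rows), file.path(dir, "kinematics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session bundle
#'
#' @param dir directory written by [write_session()].
#' @param mode schedule mode label.
#' @param montage optional expected channel label set; unknown labels in the
#'   EEG table raise an error.
#' @param require_kinematics fail when `kinematics.tsv` is absent (offline
#'   decoding needs kinematic targets).
#' @return list with `recording`, `schedule`, `kinematics`.
#' @export
read_session <- function(dir, mode = "offline", montage = NULL,
                         require_kinematics = TRUE) {
  eeg_path <- file.path(dir, "eeg.tsv")
  ev_path <- file.path(dir, "events.tsv")
  kin_path <- file.path(dir, "kinematics.tsv")
  if (!file.exists(eeg_path) || !file.exists(ev_path))
    stop("session bundle incomplete: need eeg.tsv and events.tsv in ", dir)
  eeg <- read.delim(eeg_path, check.names = FALSE)
  dt <- diff(eeg$time)
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("eeg.tsv time column is not uniformly sampled")
  fs <- 1 / dt[1]
  labels <- setdiff(names(eeg), "time")
  if (!is.null(montage)) {
    unknown <- setdiff(labels, montage)
    if (length(unknown))
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  rec <- eeg_recording(t(as.matrix(eeg[labels])), round(fs, 6), labels)
  schedule <- read_events(ev_path, mode = mode)
  kinematics <- NULL
  if (file.exists(kin_path)) {
    kd <- read.delim(kin_path)
    kinematics <- list(time = unique(kd$time))
    kinematics$sample_rate <- round(1 / diff(kinematics$time)[1], 6)
    for (arm in ARMS) {
      sub <- kd[kd$arm == arm, , drop = FALSE]
      kinematics[[arm]] <- list(
        velocity = as.matrix(sub[c("vx", "vy", "vz")]),
        position = as.matrix(sub[c("px", "py", "pz")]))
    }
    class(kinematics) <- "kinematics_series"
  } else if (require_kinematics) {
    stop("kinematics.tsv missing in ", dir,
         "; generate the session with synthesize_mtp_session() first")
  }
  list(recording = rec, schedule = schedule, kinematics = kinematics)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: a full six-run offline protocol, 25 ms feature
#' step, recursive selection over the central channel subset with a reduced
#' lag grid, closed-loop replay with the assisted schedule, and a
#' permutation test of the offline decoding accuracy.
#'
#' @param seed master seed; every random draw in the pipeline derives from
#'   it.
#' @param ... overrides for any configuration field.
#' @export
pipeline_config <- function(seed, ...) {
  if (missing(seed)) stop("`seed` is required: the pipeline refuses to run ",
                          "with silent nondeterminism")
  cfg <- list(
    seed = as.integer(seed),
    n_runs = 6L,
    sample_rate = 120,
    feature_step = 0.025,
    noise = noise_spec(channel_scale = 0.3, common_mode_scale = 0.5,
                       line_amplitude = 0.2),
    encoding = encoding_spec(),
    selection_channels = c("FC3", "C3", "CP3", "Cz", "FC4", "C4", "CP4", "Pz"),
    lag_grid = expand.grid(lag_spacing = c(0.05, 0.1, 0.2), n_lags = c(1L, 2L)),
    min_channels = 6L, max_channels = 12L,
    arm = "left",
    n_perm = 200L,
    run_fbcsp = FALSE)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Run the full offline-to-online pipeline
#'
#' Orchestrates the stages of the decoding study on a synthetic session:
#' simulate a calibration session, preprocess it into band-power features,
#' search the decoder architecture (recursive channel elimination over the
#' lag grid), cross-validate, replay a closed-loop online session with the
#' assisted schedule, and evaluate time-varying decoding accuracy against a
#' permutation null; optionally run the filter-bank classifier comparator.
#' Artifacts and a manifest recording seeds and parameter choices are
#' written to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifacts directory.
#' @param verbose log one line per stage.
#' @return invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config, out_dir = tempfile("mtp_run_"),
                         verbose = TRUE) {
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    if (verbose) message(sprintf("[%s] done in %.1f s", name,
                                 proc.time()[3] - t0))
    res
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- target_layout()
  sched <- stage("simulate", {
    build_offline_schedule(layout, n_runs = config$n_runs,
                           seed = subseed(config$seed, 1))
  })
  session <- stage("synthesize", {
    s <- synthesize_mtp_session(sched, layout, config$encoding, config$noise,
                                seed = subseed(config$seed, 2),
                                sample_rate = config$sample_rate)
    write_session(s, file.path(out_dir, "session"))
    s
  })
  bp <- stage("preprocess", {
    session_band_power(session$recording, feature_step = config$feature_step)
  })
  selection <- stage("select-architecture", {
    chans <- intersect(config$selection_channels, bp$labels)
    recursive_selection(bp, session$kinematics, sched, channels = chans,
                        lag_grid = config$lag_grid, arms = config$arm,
                        min_channels = config$min_channels,
                        max_channels = config$max_channels)
  })
  sel <- selection[[config$arm]]$selected
  cv <- stage("train", {
    crossvalidate(bp, session$kinematics, sched, channels = sel$channels,
                  lag_spacing = sel$lag_spacing, n_lags = sel$n_lags,
                  arms = config$arm)
  })
  online <- stage("simulate-online", {
    osched <- build_online_schedule(layout, n_runs = 1L,
                                    seed = subseed(config$seed, 3))
    log <- simulate_online_session(osched, noisy_decoder(sd = 0.5),
                                   feedback_config(mode = "assisted",
                                                   per_run_schedule = TRUE),
                                   layout, seed = subseed(config$seed, 4))
    write_online_log(log, file.path(out_dir, "online_log.tsv"))
    log
  })
  evaluation <- stage("evaluate", {
    ft <- forward_trials(cv, arm = config$arm)
    lms <- landmark_directions(layout, config$arm)
    pn <- permutation_null(ft$trials, ft$labels, lms,
                           n_perm = config$n_perm,
                           seed = subseed(config$seed, 5))
    write_da_curve(pn$observed, file.path(out_dir, "da_curve.tsv"), pn)
    pn
  })
  fb <- NULL
  if (isTRUE(config$run_fbcsp)) {
    fb <- stage("fbcsp", {
      cls <- synthesize_class_session(sched, noise = config$noise,
                                      seed = subseed(config$seed, 6),
                                      sample_rate = config$sample_rate)
      ds <- fbcsp_dataset(cls$recording, cls$labels$sub_block2_onset,
                          cls$labels$arm, cls$labels$run)
      nested_cv(ds)
    })
  }
  manifest <- list(
    seed = config$seed,
    stage_seeds = vapply(1:6, function(i) subseed(config$seed, i), 1L),
    n_runs = config$n_runs,
    selected = sel,
    mean_cv_error = unname(cv$mean_error[[config$arm]]),
    observed_peak_da = evaluation$observed$peak_da,
    null_mean_da_at_peak = evaluation$null_mean[evaluation$observed$peak_index],
    fbcsp_peak_da = if (!is.null(fb)) fb$peak_da else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(schedule = sched, session = session, selection = selection,
                 cv = cv, online = online, evaluation = evaluation,
                 fbcsp = fb, manifest = manifest, out_dir = out_dir))
}
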