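test_that("offline schedule reproduces the protocol arithmetic exactly", {
  sched <- fix_offline_schedule()
  blocks <- sched[!is.na(sched$block) & sched$run == 1, ]
  b1 <- blocks[blocks$block == 1, ]
  expect_equal(sum(b1$duration), 28)
  sb <- b1[!is.na(b1$sub_block) & b1$sub_block == 1, ]
  expect_equal(sum(sb$duration), 12)
  run1 <- sched[sched$run == 1 & sched$kind != "inter_run_rest", ]
  expect_equal(sum(run1$duration), 178)
  expect_equal(round(schedule_duration(sched) / 60), 22)
})

test_that("offline epochs are contiguous, non-overlapping and cover all six targets per run", {
  sched <- fix_offline_schedule()
  for (r in 1:6) {
    eps <- sched[sched$run == r, ]
    eps <- eps[order(eps$onset), ]
    expect_equal(eps$onset[-1], head(eps$onset + eps$duration, -1))
    combos <- unique(paste(eps$arm[!is.na(eps$arm)],
                           eps$target[!is.na(eps$arm)]))
    expect_length(combos, 6L)
  }
})

test_that("online schedule maxima match the protocol", {
  sched <- build_online_schedule(fix_layout(), n_runs = 6, seed = 2)
  b1 <- sched[!is.na(sched$block) & sched$run == 1 & sched$block == 1, ]
  expect_equal(sum(b1$duration), 30)
  expect_equal(sum(b1$duration[b1$kind != "block_voice"]), 26)
  run1 <- sched[sched$run == 1 & sched$kind != "inter_run_rest", ]
  expect_equal(sum(run1$duration), 190)
  expect_equal(schedule_duration(sched) / 60, 23)
  # zero-length rests: runs abut exactly
  nr <- build_online_schedule(fix_layout(), n_runs = 2, seed = 2, rest_s = 0)
  r1_end <- max(nr$onset[nr$run == 1] + nr$duration[nr$run == 1])
  expect_equal(min(nr$onset[nr$run == 2]), r1_end)
})

test_that("target order randomization is seed-deterministic and uniform", {
  a <- build_offline_schedule(fix_layout(), 3, seed = 42)
  b <- build_offline_schedule(fix_layout(), 3, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- build_offline_schedule(fix_layout(), 3, seed = 43)
  expect_false(identical(a$target, c$target))
  # uniformity of the first-block assignment over many seeded runs
  first <- vapply(1:1200, function(s) {
    sc <- build_offline_schedule(fix_layout(), 1, seed = s)
    bv <- sc[sc$kind == "block_voice", ][1, ]
    paste(bv$arm, bv$target)
  }, "")
  p <- chisq.test(table(first))$p.value
  expect_gt(p, 0.01)
})

test_that("velocity template ramps to 1.5 d/T and integrates to the displacement", {
  tpl <- velocity_template(c(0, 0, 0), c(1, 0, 0), duration = 4,
                           sample_rate = 120)
  expect_equal(sqrt(sum(tpl$velocity[1, ]^2)), 0)
  expect_equal(tpl$peak_speed, 0.375)
  # independent trapezoidal integration of the speed profile
  speed <- sqrt(rowSums(tpl$velocity^2))
  dt <- diff(tpl$time[1:2])
  integral <- sum((head(speed, -1) + tail(speed, -1)) / 2 * dt)
  expect_lt(abs(integral - 1), 1e-3)
  # ramp ends at 2/3 of the duration having covered half the distance
  i_ramp <- round(2 * 4 / 3 * 120) + 1
  expect_equal(speed[i_ramp], 0.375)
  covered <- sum((speed[1:(i_ramp - 1)] + speed[2:i_ramp]) / 2 * dt)
  expect_lt(abs(covered - 0.5), 1e-3)
  # 40 Hz grid still integrates within 0.1%
  tpl40 <- velocity_template(c(0, 0, 0), c(0, 2, 0), 4, 40)
  sp40 <- sqrt(rowSums(tpl40$velocity^2))
  int40 <- sum((head(sp40, -1) + tail(sp40, -1)) / 2 * (1 / 40))
  expect_lt(abs(int40 - 2) / 2, 1e-3)
  expect_error(velocity_template(c(1, 1, 1), c(1, 1, 1), 4), "degenerate")
})

test_that("schedule kinematics honor the epoch structure", {
  sched <- build_offline_schedule(fix_layout(), 1, seed = 3)
  kin <- schedule_kinematics(sched, sample_rate = 120)
  moves <- mtpbci:::movement_trials(sched)
  for (arm in c("left", "right")) {
    inside <- mtpbci:::times_in_epochs(kin$time, moves[moves$arm == arm, ])
    speed <- sqrt(rowSums(kin[[arm]]$velocity^2))
    expect_true(all(speed[!inside] == 0))
    expect_true(any(speed[inside] > 0))
  }
  # position follows the integral of velocity within a movement epoch
  mv <- moves[moves$arm == "left" & moves$direction == "forward", ][1, ]
  idx <- which(kin$time >= mv$onset & kin$time < mv$onset + mv$duration)
  v <- kin$left$velocity[idx, 1:3]
  p <- kin$left$position[idx, 1:3]
  dt <- 1 / 120
  integ <- apply(v, 2, function(col)
    cumsum(c(0, (head(col, -1) + tail(col, -1)) / 2 * dt)))
  expect_lt(max(abs(sweep(p, 2, p[1, ]) - integ)), 1e-6)
})

test_that("event tables round-trip and overlapping epochs are rejected", {
  sched <- build_offline_schedule(fix_layout(), 1, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_events(sched, path)
  back <- read_events(path)
  expect_equal(back$onset, sched$onset)
  expect_equal(back$kind, sched$kind)
  expect_equal(back$target, sched$target)
  bad <- as.data.frame(sched)
  bad$onset[5] <- bad$onset[4]  # collide with the previous epoch
  path2 <- tempfile(fileext = ".tsv")
  df <- bad; names(df)[1:2] <- c("onset_s", "duration_s")
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  expect_error(read_events(path2), "overlapping")
})
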