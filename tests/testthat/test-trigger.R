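make_trace <- function(time, erd) erd_trace(time, erd, foi = 10,
                                            algorithm = "fft")

test_that("a trial fires at the first threshold crossing, or not at all", {
  tt <- seq(0, 10, by = 0.01)

  # never below -35: unsuccessful
  tr <- make_trace(tt, rep(-20, length(tt)))
  expect_null(run_trial(tr, 35, task_onset = 5))

  # crossing -70 first at 2.30 s into the task
  erd <- ifelse(tt >= 7.30, -75, -10)
  tr2 <- make_trace(tt, erd)
  ev <- run_trial(tr2, 70, task_onset = 5)
  expect_equal(ev$time, 7.30)
  expect_lte(ev$erd_at_trigger, -70)

  # dip to -40 fires threshold 35 with erd_at_trigger <= -35
  erd3 <- -40 * exp(-((tt - 7) / 0.5)^2)
  tr3 <- make_trace(tt, erd3)
  ev3 <- run_trial(tr3, 35, task_onset = 5)
  expect_lte(ev3$erd_at_trigger, -35)
  expect_gte(ev3$time, 5)

  # the stream must cover the task phase
  expect_error(run_trial(make_trace(tt, erd), 70, task_onset = 8),
               "cover")
})

test_that("sessions stop at the target and honour the phase structure", {
  gen <- synth_eeg_config(block_schedule(1), foi = 10, erd_depth = 90,
                          noise = "white", snr = 20)
  res <- run_session(gen, "LIA35", target_successes = 5, max_trials = 20,
                     seed = 3)
  expect_equal(res$n_successful, 5)
  expect_equal(res$n_unsuccessful, 0)
  expect_true(res$complete)
  expect_equal(nrow(res$events), 5)

  # every trigger lies inside its task phase, none in rest or blank
  tasks <- schedule_phases(res$schedule, "task")
  on <- tasks$onset[res$events$trial_index]
  expect_true(all(res$events$time >= on &
                    res$events$time <= on + 5))
  expect_true(all(res$events$erd_at_trigger <= -35))
})

test_that("zero suppression never triggers and flags incompleteness", {
  gen <- synth_eeg_config(block_schedule(1), foi = 10, erd_depth = 0,
                          noise = "none")
  res <- run_session(gen, "FFT35", target_successes = 5, max_trials = 8,
                     seed = 1)
  expect_equal(res$n_successful, 0)
  expect_equal(res$n_unsuccessful, 8)
  expect_false(res$complete)
})

test_that("sessions are deterministic under a seed", {
  gen <- synth_eeg_config(block_schedule(1), foi = 10, erd_depth = 80,
                          noise = "pink", snr = 10)
  a <- run_session(gen, "FFT70", target_successes = 4, max_trials = 10,
                   seed = 7)
  b <- run_session(gen, "FFT70", target_successes = 4, max_trials = 10,
                   seed = 7)
  expect_identical(a$events, b$events)
})

test_that("depth 50 noiseless: threshold 35 always fires, 70 never", {
  gen <- synth_eeg_config(block_schedule(1), foi = 10, erd_depth = 50,
                          noise = "none")
  r35 <- run_session(gen, "FFT35", target_successes = 4, max_trials = 6,
                     seed = 2)
  expect_equal(r35$n_successful, 4)
  expect_equal(r35$n_unsuccessful, 0)
  r70 <- run_session(gen, "FFT70", target_successes = 4, max_trials = 6,
                     seed = 2)
  expect_equal(r70$n_successful, 0)
  expect_equal(r70$n_unsuccessful, 6)
})

test_that("deeper thresholds are reached later on ramped suppression", {
  gen <- synth_eeg_config(block_schedule(1), foi = 10, erd_depth = 90,
                          onset_ramp = 3, noise = "none")
  r35 <- run_session(gen, "LIA35", target_successes = 4, max_trials = 6,
                     seed = 5)
  r70 <- run_session(gen, "LIA70", target_successes = 4, max_trials = 6,
                     seed = 5)
  expect_gte(summary(r70)$mean_latency, summary(r35)$mean_latency)
})

test_that("the relaxed condition stimulates once per task phase", {
  gen <- synth_eeg_config(block_schedule(1), foi = 10, erd_depth = 70,
                          noise = "none")
  res <- run_session(gen, "RELAXED", target_successes = 6, max_trials = 10,
                     seed = 4)
  expect_equal(res$n_successful, 6)
  tasks <- schedule_phases(res$schedule, "task")
  on <- tasks$onset[res$events$trial_index]
  expect_true(all(res$events$time >= on & res$events$time <= on + 5))
  expect_true(all(is.na(res$events$erd_at_trigger)))
})
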