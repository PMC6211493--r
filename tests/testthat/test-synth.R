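test_that("task/rest power ratio matches the configured depth", {
  sim <- noiseless_fixture(depth = 70, foi = 10)
  x <- sim$recording$samples[1, ]
  tt <- sim$truth$time
  rest_ms <- mean(x[tt >= 2 & tt < 7.9]^2)
  task_ms <- mean(x[tt >= 8.1 & tt < 15.9]^2)
  expect_lt(abs(task_ms / rest_ms - 0.30), 1e-3)
  # ground-truth ERD mirrors the envelope
  expect_equal(sort(unique(sim$truth$erd)), c(-70, 0))
})

test_that("generation is deterministic under a seed", {
  sch <- block_schedule(1, rest = 6, task = 5)
  cfg <- synth_eeg_config(sch, noise = "pink", snr = 10, seed = 9)
  a <- synth_eeg(cfg); b <- synth_eeg(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  cfg2 <- synth_eeg_config(sch, noise = "pink", snr = 10, seed = 10)
  expect_false(identical(synth_eeg(cfg2)$recording$samples,
                         a$recording$samples))
})

test_that("realized noise level honours the alpha-band SNR", {
  sch <- block_schedule(1, rest = 6, task = 5)
  cfg <- synth_eeg_config(sch, erd_depth = 0, noise = "pink", snr = 10,
                          seed = 4)
  sim <- synth_eeg(cfg)
  noise <- sim$recording$samples[1, ] -
    sim$envelope * sin(2 * pi * cfg$foi * sim$truth$time + cfg$phase)
  bp <- erdlia:::band_power(noise, cfg$rate, 8, 13)
  carrier <- cfg$baseline_amp^2 / 2
  expect_lt(abs(carrier / bp - 10) / 10, 0.05)
})

test_that("flat-envelope fixtures keep both estimators near zero ERD", {
  # the baseline pools three rest phases; single-rest baselines fluctuate
  # by ~10 percent-ERD at this SNR, so the check averages over seeds
  sch <- block_schedule(3, rest = 6, task = 5)
  cfg <- estimator_config(foi = 10)
  tasks <- schedule_phases(sch, "task")
  task_mean <- function(tr) {
    mean(unlist(lapply(seq_len(nrow(tasks)), function(i)
      tr$erd[tr$time >= tasks$onset[i] + 2 &
               tr$time <= tasks$onset[i] + 5])))
  }
  for (alg in c("fft", "lia")) {
    ms <- sapply(1:10, function(s) {
      sim <- synth_eeg(synth_eeg_config(sch, erd_depth = 0, noise = "pink",
                                        snr = 10, phase = NA, seed = s))
      x <- sim$recording$samples[1, ]
      tr <- if (alg == "fft") erd_fft_trace(x, 1000, cfg, schedule = sch)
            else erd_lia_trace(x, 1000, cfg, schedule = sch)
      task_mean(tr)
    })
    expect_lt(abs(mean(ms)), 5)
  }
})

test_that("multichannel projection is maximal at the montage center", {
  sch <- block_schedule(1, rest = 6, task = 5)
  m <- montage_1020()
  cfg <- synth_eeg_config(sch, noise = "none",
                          channels = c("C3", "Cz", "O2"), layout = m)
  sim <- synth_eeg(cfg)
  pw <- apply(sim$recording$samples, 1, function(v) mean(v^2))
  expect_true(pw["C3"] > pw["Cz"] && pw["Cz"] > pw["O2"])
})

test_that("synthetic MEP amplitudes follow the construction", {
  # gain 0, sigma 0: all epochs identical peak-to-peak
  cfg0 <- synth_mep_config(baseline_p2p = 300, gain = 0, trial_sigma = 0,
                           emg_noise = 0, seed = 1)
  ep0 <- synth_emg_mep(c(-35, -70, 0), cfg0)
  expect_equal(ep0$true_p2p, rep(300, 3))
  p2p_raw <- apply(ep0$samples, 1, function(v) max(v) - min(v))
  expect_equal(p2p_raw, rep(300, 3), tolerance = 1e-9)

  # deeper ERD yields strictly larger MEPs under positive gain
  cfgg <- synth_mep_config(gain = 0.03, trial_sigma = 0, emg_noise = 0,
                           seed = 1)
  epg <- synth_emg_mep(c(-70, -35), cfgg)
  expect_gt(epg$true_p2p[1], epg$true_p2p[2])

  # injected artifacts are flagged by the rejection rule, exactly
  cfga <- synth_mep_config(trial_sigma = 0, emg_noise = 1,
                           artifact_fraction = 0.2, seed = 2)
  epa <- synth_emg_mep(rep(-35, 100), cfga)
  rej <- apply(epa$samples, 1, reject_prestim, time = epa$time)
  expect_equal(sum(rej), 20)
  expect_equal(which(rej), which(epa$artifact))
})
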