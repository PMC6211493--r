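test_that("EMG preprocessing notches 50 Hz and passes mid-band", {
  rate <- 2000
  tt <- (0:(2 * rate - 1)) / rate
  post <- tt > 1   # after the filter transient

  y50 <- preprocess_emg(sin(2 * pi * 50 * tt), rate)
  expect_lt(max(abs(y50[post])), 0.10)

  ydc <- preprocess_emg(rep(5, length(tt)), rate)
  expect_lt(max(abs(ydc[post])), 0.05)

  y200 <- preprocess_emg(sin(2 * pi * 200 * tt), rate)
  expect_lt(abs(max(abs(y200[post])) - 1), 0.10)

  expect_error(preprocess_emg(tt, rate, band = c(5, 1200)), "Nyquist")
})

test_that("pre-stimulus rejection is strict at the 20 uV limit", {
  time <- seq(-0.05, 0.1495, by = 1 / 2000)
  base <- numeric(length(time))
  over <- base; over[time < 0][10] <- 25
  expect_true(reject_prestim(over, time))
  under <- base; under[time < 0][10] <- -10
  expect_false(reject_prestim(under, time))
  atlim <- base; atlim[time < 0][10] <- 20
  expect_false(reject_prestim(atlim, time))   # exactly 20 is kept
  neg <- base; neg[time < 0][10] <- -20.5     # sign-symmetric
  expect_true(reject_prestim(neg, time))
  # post-stimulus activity never triggers rejection
  post <- base; post[time > 0.02][1] <- 500
  expect_false(reject_prestim(post, time))
})

test_that("peak-to-peak measures max minus min in the search window", {
  time <- seq(-0.05, 0.1495, by = 1 / 2000)
  x <- numeric(length(time))
  x[which(time >= 0.02)[1]] <- 400
  x[which(time >= 0.03)[1]] <- -240
  expect_equal(peak_to_peak(x, time), 640)
  expect_equal(peak_to_peak(numeric(length(time)), time), 0)
  expect_error(peak_to_peak(x, time, search = c(0.2, 0.3)), "empty")

  # constructed noiseless MEP: the raw epoch carries the target exactly;
  # the causal band-pass + notch distort the transient by a couple of
  # percent, so the filtered pipeline is held to 3%
  ep <- synth_emg_mep(-35, synth_mep_config(baseline_p2p = 500, gain = 0,
                                            trial_sigma = 0, emg_noise = 0))
  expect_lt(abs(peak_to_peak(ep$samples[1, ], ep$time) - 500) / 500, 0.01)
  meas <- mep_measures(ep)
  expect_false(meas$rejected[1])
  expect_lt(abs(meas$p2p[1] - 500) / 500, 0.03)
})

test_that("rejection commutes with measurement", {
  ep <- synth_emg_mep(rep(-50, 40),
                      synth_mep_config(trial_sigma = 0.3, emg_noise = 2,
                                       artifact_fraction = 0.25, seed = 8))
  rej_first <- apply(ep$samples, 1, reject_prestim, time = ep$time)
  meas <- mep_measures(ep)          # measures all, flags rejection
  expect_equal(meas$rejected, as.logical(rej_first))
  # p2p of accepted trials is the same whether rejected trials were
  # dropped before or after measurement
  keep <- !meas$rejected
  meas_kept <- mep_measures(ep$samples[keep, , drop = FALSE],
                            time = ep$time, rate = ep$rate)
  expect_equal(meas$p2p[keep], meas_kept$p2p)
})

test_that("normalization divides by the rest mean and summarizes", {
  meas <- data.frame(
    condition = c("FFT35", "FFT35", "RELAXED", "RELAXED"),
    p2p = c(400, 600, 150, 250),
    rejected = FALSE)
  out <- normalize_and_summarize(meas)
  expect_equal(out$measures$normalized[1:2], c(2.0, 3.0))
  sm <- out$summary
  expect_equal(sm$mean[sm$condition == "FFT35"], 2.5)
  # the rest condition itself normalizes to mean exactly 1
  expect_equal(sm$mean[sm$condition == "RELAXED"], 1.0)
  # equal trials -> SD 0
  eq <- data.frame(condition = c("A", "A", "RELAXED"), p2p = c(3, 3, 2),
                   rejected = FALSE)
  expect_equal(normalize_and_summarize(eq)$summary$sd[1], 0)
  # absent rest reference
  expect_error(normalize_and_summarize(meas, rest_condition = "NONE"),
               "normalization")
})

test_that("lower-dispersion construction yields lower reported SD", {
  set.seed(21)
  mk <- function(cond, sigma) {
    ep <- synth_emg_mep(rep(-35, 30),
                        synth_mep_config(trial_sigma = sigma, emg_noise = 1,
                                         seed = nchar(cond)))
    m <- mep_measures(ep)
    m$condition <- cond
    m
  }
  meas <- rbind(mk("LIA35", 0.05), mk("FFT35xx", 0.4),
                mk("RELAXED", 0.1))
  sm <- normalize_and_summarize(meas)$summary
  expect_lt(sm$sd[sm$condition == "LIA35"], sm$sd[sm$condition == "FFT35xx"])
})

test_that("stimulus intensity is 120% of rMT, rounded to integer %MSO", {
  expect_equal(stimulus_intensity(37), 44)
  expect_equal(stimulus_intensity(45), 54)
  expect_equal(stimulus_intensity(50), 60)
  expect_error(stimulus_intensity(90), "100%")
  expect_error(stimulus_intensity(0), "positive")

  # the full printed participant table reproduces, row by row
  tab <- participant_table()
  expect_equal(nrow(tab), 17)
  expect_equal(stimulus_intensity(tab$rmt), tab$si)
})
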