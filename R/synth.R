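#' Synthetic EEG configuration
#'
#' Parameters of the ground-truth generator: an alpha-band carrier at the
#' frequency of interest whose envelope is suppressed during task phases
#' by a known depth, embedded in seeded background noise. Depth is defined
#' on POWER: `erd_depth = 70` means the task-phase envelope is
#' `sqrt(1 - 0.70)` of the rest-phase envelope, so a perfect estimator
#' reads ERD = -70%.
#'
#' @param schedule a [task_schedule()] of rest/task/blank phases.
#' @param rate sampling rate, samples/s (default 1000).
#' @param foi carrier frequency in Hz (default 10).
#' @param baseline_amp rest-phase carrier amplitude in microvolts
#'   (default 10).
#' @param erd_depth task-phase power suppression in percent, 0-100
#'   (default 70).
#' @param onset_ramp envelope transition time in seconds (default 0: an
#'   instantaneous step at phase boundaries).
#' @param noise `"none"`, `"white"` or `"pink"` (1/f-amplitude) background.
#' @param snr rest-phase alpha-band power signal-to-noise ratio: carrier
#'   power (`baseline_amp^2/2`) divided by the realized noise power within
#'   the 8-13 Hz alpha band. Ignored when `noise = "none"`; mutually
#'   exclusive with `noise_amp`.
#' @param noise_amp alternatively, the noise standard deviation in
#'   microvolts (overrides `snr`).
#' @param phase carrier phase at t = 0 in radians (default 0; drawn
#'   uniformly when `NA`).
#' @param channels channel labels. With one label a single-channel
#'   recording is produced; with several plus a `layout`, the carrier is
#'   projected with a gain falling off with scalp distance from the
#'   layout's center and independent noise per channel.
#' @param layout optional [montage_layout()] for multichannel projection.
#' @param seed RNG seed for the noise (and phase when `phase = NA`).
#' @return An object of class `synth_eeg_config`.
#' @export
synth_eeg_config <- function(schedule, rate = 1000, foi = 10,
                             baseline_amp = 10, erd_depth = 70,
                             onset_ramp = 0,
                             noise = c("pink", "white", "none"),
                             snr = 10, noise_amp = NULL, phase = 0,
                             channels = "C3", layout = NULL, seed = NULL) {
  noise <- match.arg(noise)
  if (erd_depth < 0 || erd_depth > 100)
    stop_config("erd_depth must lie in [0, 100]")
  if (rate <= 2 * foi) stop_config("rate must exceed twice the FOI")
  structure(list(schedule = schedule, rate = rate, foi = foi,
                 baseline_amp = baseline_amp, erd_depth = erd_depth,
                 onset_ramp = onset_ramp, noise = noise, snr = snr,
                 noise_amp = noise_amp, phase = phase,
                 channels = channels, layout = layout, seed = seed),
            class = "synth_eeg_config")
}

# 1/f-amplitude noise via spectral shaping of seeded white noise, unit sd
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))            # protect DC
  f <- pmin(f, n - f + 1)              # symmetric |frequency| index
  X <- X / sqrt(f)
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# realized power of x within [lo, hi] Hz, from its periodogram
band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (0:(n - 1)) * rate / n
  sel <- freqs >= lo & freqs <= hi
  p <- (Re(X)^2 + Im(X)^2) / n^2
  2 * sum(p[sel])   # one-sided
}

#' Generate synthetic EEG with a known ERD ground truth
#'
#' Builds `a(t) sin(2 pi foi t + phase)` where the envelope `a(t)` equals
#' `baseline_amp` during rest/blank phases and
#' `baseline_amp * sqrt(1 - erd_depth/100)` during task phases (linear
#' transition over `onset_ramp` seconds), plus seeded background noise
#' scaled to the requested alpha-band SNR. The exact envelope and the
#' implied true ERD trace are returned alongside the recording.
#'
#' @param config a [synth_eeg_config()].
#' @return A list of class `synth_eeg`:
#'   \describe{
#'     \item{recording}{an [eeg_recording()].}
#'     \item{envelope}{the exact per-sample carrier envelope `a(t)`
#'       (microvolts).}
#'     \item{truth}{data.frame `time`, `envelope`, `erd` — the true ERD in
#'       percent implied by the envelope.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' sch <- block_schedule(1, rest = 6, task = 6)
#' s <- synth_eeg(synth_eeg_config(sch, noise = "none", erd_depth = 70))
#' range(s$truth$erd)  # 0 at rest, -70 during the task
#' @export
synth_eeg <- function(config) {
  stopifnot(inherits(config, "synth_eeg_config"))
  with_seed(config$seed, {
    sch <- config$schedule
    total <- max(sch$onset + sch$duration)
    n <- as.integer(round(total * config$rate))
    tt <- (seq_len(n) - 1) / config$rate
    scale_task <- sqrt(1 - config$erd_depth / 100)
    env <- rep(1, n)
    tasks <- schedule_phases(sch, "task")
    for (i in seq_len(nrow(tasks))) {
      on <- tasks$onset[i]; off <- on + tasks$duration[i]
      if (config$onset_ramp > 0) {
        ramp_in <- tt >= on & tt < on + config$onset_ramp
        env[ramp_in] <- 1 + (scale_task - 1) * (tt[ramp_in] - on) /
          config$onset_ramp
        core <- tt >= on + config$onset_ramp & tt < off
        env[core] <- scale_task
        ramp_out <- tt >= off & tt < off + config$onset_ramp
        env[ramp_out] <- scale_task + (1 - scale_task) * (tt[ramp_out] - off) /
          config$onset_ramp
      } else {
        env[tt >= on & tt < off] <- scale_task
      }
    }
    env <- env * config$baseline_amp
    phase <- if (is.na(config$phase)) stats::runif(1, 0, 2 * pi) else config$phase
    carrier <- env * sin(2 * pi * config$foi * tt + phase)

    make_noise <- function() {
      if (config$noise == "none") return(numeric(n))
      raw <- if (config$noise == "pink") pink_noise(n) else stats::rnorm(n)
      amp <- if (!is.null(config$noise_amp)) config$noise_amp else {
        carrier_p <- config$baseline_amp^2 / 2
        bp <- band_power(raw, config$rate, 8, 13)
        sqrt(carrier_p / (config$snr * bp))
      }
      raw * amp
    }

    chans <- config$channels
    if (length(chans) == 1L) {
      samples <- matrix(carrier + make_noise(), 1)
    } else {
      if (is.null(config$layout))
        stop_config("multichannel synthesis needs a montage layout")
      pos <- config$layout$positions
      ctr <- pos[pos$name == config$layout$center, ]
      samples <- matrix(0, length(chans), n)
      for (k in seq_along(chans)) {
        p <- pos[pos$name == chans[k], ]
        if (nrow(p) == 0)
          stop_config("channel '", chans[k], "' not in the layout")
        d <- sqrt((p$x - ctr$x)^2 + (p$y - ctr$y)^2)
        gain <- exp(-(d / 0.35)^2)   # focal source under the center
        samples[k, ] <- gain * carrier + make_noise()
      }
    }
    truth_erd <- ((env / config$baseline_amp)^2 - 1) * 100
    structure(list(
      recording = eeg_recording(samples, config$rate, chans),
      envelope = env,
      truth = data.frame(time = tt, envelope = env, erd = truth_erd),
      config = config), class = "synth_eeg")
  })
}

#' @export
print.synth_eeg <- function(x, ...) {
  cat(sprintf("<synth_eeg> FOI %g Hz, depth %g%%, noise %s, %d samples @ %g Hz\n",
              x$config$foi, x$config$erd_depth, x$config$noise,
              ncol(x$recording$samples), x$config$rate))
  invisible(x)
}

#' Synthetic MEP configuration
#'
#' Parameters of the EMG epoch generator that emulates the association
#' between pre-stimulus ERD magnitude and corticospinal excitability:
#' each simulated TMS pulse evokes a biphasic MEP whose peak-to-peak
#' amplitude grows with the true ERD magnitude at the trigger, with
#' multiplicative log-normal trial-to-trial variability.
#'
#' @param baseline_p2p MEP peak-to-peak amplitude at zero ERD, microvolts
#'   (default 200).
#' @param gain fractional peak-to-peak increase per percentage point of
#'   true ERD magnitude (default 0.03).
#' @param trial_sigma sigma of the multiplicative log-normal
#'   trial-to-trial factor (default 0.2; 0 disables it).
#' @param emg_noise background EMG noise sd in microvolts (default 5).
#' @param mep_latency MEP onset latency after the stimulus in seconds
#'   (default 0.02).
#' @param artifact_fraction fraction of epochs receiving injected
#'   pre-stimulus activity exceeding the rejection limit (default 0).
#' @param artifact_amp amplitude of the injected pre-stimulus activity in
#'   microvolts (default 30).
#' @param rate EMG sampling rate (default 2000).
#' @param seed RNG seed.
#' @return An object of class `synth_mep_config`.
#' @export
synth_mep_config <- function(baseline_p2p = 200, gain = 0.03,
                             trial_sigma = 0.2, emg_noise = 5,
                             mep_latency = 0.02, artifact_fraction = 0,
                             artifact_amp = 30, rate = 2000, seed = NULL) {
  if (baseline_p2p <= 0) stop_config("baseline_p2p must be positive")
  if (trial_sigma < 0) stop_config("trial_sigma must be non-negative")
  structure(list(baseline_p2p = baseline_p2p, gain = gain,
                 trial_sigma = trial_sigma, emg_noise = emg_noise,
                 mep_latency = mep_latency,
                 artifact_fraction = artifact_fraction,
                 artifact_amp = artifact_amp, rate = rate, seed = seed),
            class = "synth_mep_config")
}

# one cycle of a damped sine, scaled to unit peak-to-peak; 150 Hz carrier
# keeps it clear of the 50 Hz notch and inside the EMG passband
mep_waveform <- function(rate, f = 150, tau = 0.008) {
  tt <- seq(0, 1 / f, by = 1 / rate)
  w <- sin(2 * pi * f * tt) * exp(-tt / tau)
  w / (max(w) - min(w))
}

#' Generate synthetic EMG epochs with TMS-locked MEPs
#'
#' Produces one `-50..+150 ms` epoch around each simulated stimulus. The
#' MEP peak-to-peak amplitude of trial `i` is
#' `baseline_p2p * (1 + gain * |erd_i|) * lognormal(0, trial_sigma)`. A
#' configurable fraction of epochs receives injected pre-stimulus activity
#' above the +/-20 microvolt limit to exercise the rejection rule.
#'
#' @param true_erd numeric vector: true ERD (percent, sign ignored) at
#'   each trigger; one epoch is generated per element.
#' @param config a [synth_mep_config()].
#' @param condition condition label attached to the epochs.
#' @param window epoch window around the stimulus in seconds.
#' @return An object of class `emg_epochs`: list with `samples` (trials x
#'   time matrix, microvolts), `time` (s, 0 = stimulus), `rate`,
#'   `condition` (per-trial labels), `true_p2p` (the constructed
#'   peak-to-peak amplitudes) and `artifact` (logical, injected
#'   pre-stimulus activity).
#' @export
synth_emg_mep <- function(true_erd, config = synth_mep_config(),
                          condition = "TRIG", window = c(-0.05, 0.15)) {
  stopifnot(inherits(config, "synth_mep_config"))
  with_seed(config$seed, {
    n_tr <- length(true_erd)
    tt <- seq(window[1], window[2] - 1 / config$rate, by = 1 / config$rate)
    n <- length(tt)
    wave <- mep_waveform(config$rate)
    lat_i <- which.min(abs(tt - config$mep_latency))
    p2p <- config$baseline_p2p * (1 + config$gain * abs(true_erd))
    if (config$trial_sigma > 0)
      p2p <- p2p * stats::rlnorm(n_tr, 0, config$trial_sigma)
    artifact <- rep(FALSE, n_tr)
    n_art <- round(config$artifact_fraction * n_tr)
    if (n_art > 0) artifact[sample.int(n_tr, n_art)] <- TRUE
    samples <- matrix(0, n_tr, n)
    pre <- tt < 0
    for (i in seq_len(n_tr)) {
      ep <- if (config$emg_noise > 0) stats::rnorm(n, 0, config$emg_noise)
            else numeric(n)
      idx <- lat_i:min(n, lat_i + length(wave) - 1L)
      ep[idx] <- ep[idx] + p2p[i] * wave[seq_along(idx)]
      if (artifact[i])
        ep[pre] <- ep[pre] +
          config$artifact_amp * sin(2 * pi * 30 * tt[pre])
      samples[i, ] <- ep
    }
    structure(list(samples = samples, time = tt, rate = config$rate,
                   condition = rep_len(condition, n_tr),
                   true_p2p = p2p, artifact = artifact),
              class = "emg_epochs")
  })
}

#' @export
print.emg_epochs <- function(x, ...) {
  cat(sprintf("<emg_epochs> %d trials x %d samples @ %g Hz (%g..%g ms)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              1000 * min(x$time), 1000 * max(x$time)))
  invisible(x)
}
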