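#' Causal EMG preprocessing
#'
#' Second-order Butterworth band-pass (default 5-990 Hz) followed by a
#' 50 Hz band-stop notch against power-line contamination, both applied
#' forward-only. The nominal acquisition band reaches 1000 Hz, which is
#' exactly Nyquist at the 2 kHz trial rate; the digital default therefore
#' caps the upper edge just below Nyquist (the sampler's own anti-alias
#' limit).
#'
#' @param x raw EMG in microvolts (vector, or trials x time matrix
#'   filtered row-wise).
#' @param rate sampling rate in Hz.
#' @param band band-pass edges in Hz.
#' @param notch notch centre in Hz (`NA` disables); the stop band is
#'   `notch +/- 2` Hz.
#' @return Filtered EMG with the shape of `x`.
#' @export
preprocess_emg <- function(x, rate, band = c(5, min(990, rate / 2 * 0.99)),
                           notch = 50) {
  if (band[2] >= rate / 2)
    stop_config("band-pass upper edge at or above the Nyquist frequency")
  if (band[1] <= 0 || band[1] >= band[2])
    stop_config("invalid band-pass edges")
  bp <- signal::butter(2, band / (rate / 2), type = "pass")
  flt <- function(v) {
    y <- as.numeric(signal::filter(bp, v))
    if (!is.na(notch)) {
      bs <- signal::butter(2, c(notch - 2, notch + 2) / (rate / 2),
                           type = "stop")
      y <- as.numeric(signal::filter(bs, y))
    }
    y
  }
  if (is.matrix(x)) t(apply(x, 1, flt)) else flt(x)
}

#' Pre-stimulus activity rejection
#'
#' A trial is discarded when any pre-stimulus sample exceeds the limit in
#' absolute value — strictly: activity of exactly the limit is kept. This
#' guards the MEP measurement against background muscle activity.
#'
#' @param samples one epoch (numeric vector) in microvolts.
#' @param time per-sample times in seconds, 0 = stimulus.
#' @param limit rejection limit in microvolts (default 20).
#' @return `TRUE` when the trial must be rejected.
#' @export
reject_prestim <- function(samples, time, limit = 20) {
  pre <- time < 0
  if (!any(pre)) stop_config("epoch contains no pre-stimulus segment")
  any(abs(samples[pre]) > limit)
}

#' Peak-to-peak MEP amplitude
#'
#' Maximum minus minimum of the (filtered) EMG within the post-stimulus
#' search window. The default window starts 10 ms after the stimulus to
#' exclude the stimulus artifact and runs to the epoch end at 150 ms.
#'
#' @param samples one epoch (numeric vector) in microvolts.
#' @param time per-sample times in seconds, 0 = stimulus.
#' @param search search window in seconds (default c(0.010, 0.150)).
#' @return Peak-to-peak amplitude in microvolts (>= 0).
#' @export
peak_to_peak <- function(samples, time, search = c(0.010, 0.150)) {
  sel <- time >= search[1] & time <= search[2]
  if (!any(sel)) stop_config("empty MEP search window")
  max(samples[sel]) - min(samples[sel])
}

#' Measure MEPs in a set of EMG epochs
#'
#' Full per-trial pipeline: causal filtering ([preprocess_emg()]),
#' pre-stimulus rejection ([reject_prestim()]) and peak-to-peak
#' measurement ([peak_to_peak()]).
#'
#' @param epochs an `emg_epochs` object (see [synth_emg_mep()]), or a
#'   trials x time matrix plus `time` and `rate`.
#' @param time,rate required when `epochs` is a bare matrix.
#' @param condition per-trial condition labels (recycled).
#' @param filter apply [preprocess_emg()] first (default TRUE).
#' @param limit rejection limit in microvolts.
#' @param search peak-to-peak search window in seconds.
#' @return data.frame with one row per trial: `condition`, `p2p`
#'   (microvolts), `rejected`.
#' @export
mep_measures <- function(epochs, time = NULL, rate = NULL,
                         condition = NULL, filter = TRUE, limit = 20,
                         search = c(0.010, 0.150)) {
  if (inherits(epochs, "emg_epochs")) {
    samples <- epochs$samples; time <- epochs$time; rate <- epochs$rate
    condition <- condition %||% epochs$condition
  } else {
    samples <- as.matrix(epochs)
    if (is.null(time) || is.null(rate))
      stop_config("time and rate are required for matrix input")
    condition <- condition %||% "TRIG"
  }
  rejected <- apply(samples, 1, reject_prestim, time = time, limit = limit)
  if (filter) samples <- preprocess_emg(samples, rate)
  p2p <- apply(samples, 1, peak_to_peak, time = time, search = search)
  data.frame(condition = rep_len(condition, nrow(samples)),
             p2p = as.numeric(p2p), rejected = as.logical(rejected))
}

#' Normalize MEP amplitudes by the rest condition and summarize
#'
#' Rejected trials are excluded, every accepted amplitude is divided by
#' the mean accepted amplitude of the rest (control) condition, and the
#' mean and sample SD of the normalized amplitudes are reported per
#' condition.
#'
#' @param measures data.frame with columns `condition`, `p2p`, `rejected`
#'   (see [mep_measures()]).
#' @param rest_condition label of the rest/control condition
#'   (default "RELAXED").
#' @return A list of class `mep_summary`: `measures` (accepted trials
#'   with a `normalized` column) and `summary` (data.frame `condition`,
#'   `n`, `mean`, `sd` of normalized amplitudes).
#' @export
normalize_and_summarize <- function(measures, rest_condition = "RELAXED") {
  acc <- measures[!measures$rejected, , drop = FALSE]
  rest <- acc$p2p[acc$condition == rest_condition]
  if (!length(rest) || mean(rest) <= 0)
    stop("normalization error: rest condition '", rest_condition,
         "' has no accepted trials with positive mean amplitude")
  acc$normalized <- acc$p2p / mean(rest)
  conds <- unique(acc$condition)
  sm <- data.frame(
    condition = conds,
    n = vapply(conds, function(cn) sum(acc$condition == cn), 0L),
    mean = vapply(conds, function(cn) mean(acc$normalized[acc$condition == cn]), 0),
    sd = vapply(conds, function(cn) stats::sd(acc$normalized[acc$condition == cn]), 0),
    row.names = NULL)
  structure(list(measures = acc, summary = sm,
                 rest_condition = rest_condition),
            class = "mep_summary")
}

#' @export
print.mep_summary <- function(x, ...) {
  cat(sprintf("<mep_summary> normalized to '%s'\n", x$rest_condition))
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}

#' TMS stimulus intensity from the resting motor threshold
#'
#' Test pulses are delivered at 120% of the individual resting motor
#' threshold (rMT); stimulator outputs are integer percent of maximum
#' stimulator output (%MSO), so the product is rounded to the nearest
#' integer (halves away from zero).
#'
#' @param rmt resting motor threshold in %MSO; vectorized.
#' @return Stimulus intensity in %MSO (integer-valued).
#' @examples
#' stimulus_intensity(c(37, 45, 50))  # 44, 54, 60
#' @export
stimulus_intensity <- function(rmt) {
  if (any(rmt <= 0)) stop_config("rMT must be positive")
  si <- round_half_away(1.2 * rmt)
  if (any(si > 100))
    stop("stimulus intensity exceeds 100% of maximum stimulator output")
  si
}

#' Screening-session participant table
#'
#' The printed per-participant screening results used as package input
#' data: age, most reactive (FOI) frequency, resting motor threshold and
#' stimulus intensity, for 17 participants.
#'
#' @return data.frame with columns `participant`, `age`, `foi_hz`, `rmt`,
#'   `si` (%MSO).
#' @export
participant_table <- function() {
  utils::read.delim(system.file("extdata", "participants.tsv",
                                package = "erdlia"))
}
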