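#' ERD transform
#'
#' Converts instantaneous band power into event-related desynchronization,
#' expressed as a percent change relative to a resting baseline:
#' `ERD(f, t) = (A(f, t) - R(f)) / R(f) * 100`. Negative values indicate
#' desynchronization (power suppression); the theoretical floor is -100
#' (power cannot be negative).
#'
#' @param A instantaneous power (same units as `R`); vectorized.
#' @param R baseline (reference) power, a single positive number or a
#'   [baseline_model()].
#' @return ERD in percent, same length as `A`.
#' @examples
#' erd_transform(c(4, 2.6, 1.2), 4)  # 0, -35, -70
#' @export
erd_transform <- function(A, R) {
  if (inherits(R, "baseline_model")) R <- R$R
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop_config("invalid baseline: R must be a single positive number")
  if (any(A < 0, na.rm = TRUE))
    stop_config("instantaneous power A must be non-negative")
  (A - R) / R * 100
}

#' Estimator configuration
#'
#' Bundles the tunable parameters of both online ERD estimators. The FFT
#' pipeline segments the signal into `fft_window`-second windows with
#' `fft_overlap` fractional overlap and computes a single tapered
#' periodogram per window. The lock-in pipeline band-pass filters the
#' signal to `foi +/- lia_halfwidth` Hz with a causal Butterworth filter of
#' order `lia_filter_order`, then demodulates against quadrature
#' references at the FOI over `lia_integration`-second windows (default one
#' carrier period, 1/FOI s) with `lia_overlap` fractional overlap.
#'
#' @param foi frequency of interest in Hz.
#' @param alpha_band admissible FOI band in Hz (default 8-13).
#' @param fft_window FFT window length in seconds (default 1).
#' @param fft_overlap fractional window overlap in `[0, 1)` (default 0.99).
#' @param fft_taper `"hanning"` or `"rectangular"`.
#' @param lia_halfwidth band-pass half width in Hz (default 1).
#' @param lia_filter_order Butterworth order (default 2).
#' @param lia_integration integration window in seconds (default `1/foi`).
#' @param lia_overlap fractional overlap of integration windows
#'   (default 0.99).
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(foi, alpha_band = c(8, 13),
                             fft_window = 1.0, fft_overlap = 0.99,
                             fft_taper = c("hanning", "rectangular"),
                             lia_halfwidth = 1.0, lia_filter_order = 2,
                             lia_integration = 1 / foi,
                             lia_overlap = 0.99) {
  fft_taper <- match.arg(fft_taper)
  if (fft_overlap < 0 || fft_overlap >= 1 || lia_overlap < 0 || lia_overlap >= 1)
    stop_config("overlaps must lie in [0, 1)")
  if (fft_window <= 0 || lia_integration <= 0)
    stop_config("window and integration lengths must be positive")
  if (lia_halfwidth <= 0) stop_config("lia_halfwidth must be positive")
  structure(list(foi = foi, alpha_band = alpha_band,
                 fft_window = fft_window, fft_overlap = fft_overlap,
                 fft_taper = fft_taper,
                 lia_halfwidth = lia_halfwidth,
                 lia_filter_order = lia_filter_order,
                 lia_integration = lia_integration,
                 lia_overlap = lia_overlap),
            class = "estimator_config")
}

#' @export
print.estimator_config <- function(x, ...) {
  cat(sprintf("<estimator_config> FOI %g Hz (band %g-%g Hz)\n", x$foi,
              x$alpha_band[1], x$alpha_band[2]))
  cat(sprintf("  FFT: %g s %s window, %g%% overlap\n", x$fft_window,
              x$fft_taper, 100 * x$fft_overlap))
  cat(sprintf("  LIA: order-%d Butterworth FOI+/-%g Hz, %g s integration, %g%% overlap\n",
              x$lia_filter_order, x$lia_halfwidth, x$lia_integration,
              100 * x$lia_overlap))
  invisible(x)
}

#' Baseline (reference) power model
#'
#' Reference power `R` at the frequency of interest, pooled over the
#' 3-5 s sub-window of every rest phase, computed by the same estimator
#' that produces the instantaneous power it is later compared against.
#'
#' @param R reference power (> 0), in the producing estimator's units.
#' @param foi frequency of interest in Hz.
#' @param window offsets (s) of the sub-window within each rest phase.
#' @param n_windows number of rest phases pooled.
#' @param algorithm which estimator produced the pooled power.
#' @return An object of class `baseline_model`.
#' @export
baseline_model <- function(R, foi, window = c(3, 5), n_windows = NA_integer_,
                           algorithm = NA_character_) {
  if (!is.finite(R) || R <= 0)
    stop_config("invalid baseline: reference power must be positive")
  structure(list(R = R, foi = foi, window = window, n_windows = n_windows,
                 algorithm = algorithm),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> R = %.4g at %g Hz (%s), %s rest phase(s), window %g-%g s\n",
              x$R, x$foi, x$algorithm, x$n_windows, x$window[1], x$window[2]))
  invisible(x)
}

#' Baseline power from the rest phases of a schedule
#'
#' Pools instantaneous power over the `window` (default 3-5 s) sub-window
#' of every rest phase and averages, yielding the reference `R` of the ERD
#' transform. The power trace must come from the same estimator later used
#' for the instantaneous power (see [power_trace()]).
#'
#' @param trace a `power_trace` (time-stamped instantaneous power) from
#'   [power_trace()].
#' @param schedule a [task_schedule()] whose rest phases are each at least
#'   `window[2]` seconds long.
#' @param window two offsets in seconds within each rest phase.
#' @return A [baseline_model()].
#' @export
compute_baseline <- function(trace, schedule, window = c(3, 5)) {
  stopifnot(inherits(trace, "power_trace"))
  rests <- schedule_phases(schedule, "rest")
  if (nrow(rests) == 0L) stop_schedule("schedule contains no rest phase")
  if (any(rests$duration < window[2] - 1e-9))
    stop_schedule("rest phase shorter than the ", window[2],
                  " s baseline window")
  sel <- logical(length(trace$time))
  for (i in seq_len(nrow(rests))) {
    sel <- sel | (trace$time >= rests$onset[i] + window[1] &
                    trace$time <= rests$onset[i] + window[2])
  }
  if (!any(sel))
    stop_schedule("power trace does not cover the rest-phase baseline windows")
  baseline_model(mean(trace$power[sel]), foi = attr(trace, "foi"),
                 window = window, n_windows = nrow(rests),
                 algorithm = attr(trace, "algorithm"))
}

#' Causal ERD trace
#'
#' Time-stamped ERD values in percent at the frequency of interest. Stamps
#' are trailing-edge (causal): the value at time `t` uses only samples at
#' or before `t`, so the stamp is the moment the estimate becomes available
#' online.
#'
#' @param time strictly increasing timestamps in seconds.
#' @param erd ERD values in percent (>= -100).
#' @param foi frequency of interest in Hz.
#' @param algorithm `"fft"`, `"lia"` or `"oracle"`.
#' @return An object of class `erd_trace`.
#' @export
erd_trace <- function(time, erd, foi, algorithm) {
  stopifnot(length(time) == length(erd))
  if (length(time) > 1 && any(diff(time) <= 0))
    stop_config("erd_trace timestamps must be strictly increasing")
  if (any(erd < -100 - 1e-9, na.rm = TRUE))
    stop_config("ERD below -100% implies negative power")
  structure(list(time = time, erd = erd, foi = foi, algorithm = algorithm),
            class = "erd_trace")
}

#' @export
print.erd_trace <- function(x, ...) {
  cat(sprintf("<erd_trace> %s estimator, FOI %g Hz, %d samples (%.2f-%.2f s)\n",
              x$algorithm, x$foi, length(x$time),
              min(x$time), max(x$time)))
  cat(sprintf("  ERD range [%.1f, %.1f]%%\n", min(x$erd), max(x$erd)))
  invisible(x)
}

#' @export
plot.erd_trace <- function(x, ..., xlab = "time (s)", ylab = "ERD (%)") {
  graphics::plot(x$time, x$erd, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.erd_trace <- function(x, ...) {
  data.frame(time = x$time, erd = x$erd)
}

#' Select the frequency of interest from screening trials
#'
#' Given per-trial ERD spectra over the alpha band (one row per screening
#' trial, one column per candidate frequency, each entry the trial's mean
#' task-phase ERD at that frequency), returns the frequency with the most
#' negative trial-averaged ERD — the participant's most reactive
#' frequency. This deterministic rule replaces visual inspection. Ties are
#' broken toward the lowest frequency.
#'
#' @param spectra numeric matrix, trials x frequencies; column names (or
#'   `freqs`) give the frequencies in Hz.
#' @param freqs candidate frequencies in Hz; defaults to the numeric
#'   column names of `spectra`.
#' @return The selected FOI in Hz.
#' @export
select_foi <- function(spectra, freqs = NULL) {
  spectra <- as.matrix(spectra)
  if (is.null(freqs)) freqs <- as.numeric(colnames(spectra))
  if (length(freqs) != ncol(spectra) || any(is.na(freqs)))
    stop_config("spectra must carry numeric frequency column names or freqs")
  avg <- colMeans(spectra)
  if (all(avg >= 0))
    stop("no reactive frequency: mean ERD is non-negative at every candidate frequency")
  # most negative mean ERD; ties go to the lowest frequency
  ord <- order(freqs)
  freqs <- freqs[ord]; avg <- avg[ord]
  freqs[which.min(avg)]
}

#' Per-trial screening ERD spectra
#'
#' Runs the sliding-FFT pipeline at each candidate frequency and returns,
#' for every task phase (screening trial), the mean task-phase ERD — the
#' input expected by [select_foi()].
#'
#' @param x single-channel signal in microvolts (e.g. the output of
#'   [large_laplacian()]).
#' @param rate sampling rate in Hz.
#' @param schedule the screening [task_schedule()].
#' @param freqs candidate frequencies in Hz (default 8:13).
#' @param window,overlap FFT window length (s) and fractional overlap.
#' @return Matrix trials x frequencies with frequency column names.
#' @export
screening_spectra <- function(x, rate, schedule, freqs = 8:13,
                              window = 1.0, overlap = 0.99) {
  tasks <- schedule_phases(schedule, "task")
  if (nrow(tasks) == 0L) stop_schedule("schedule contains no task phase")
  out <- matrix(NA_real_, nrow(tasks), length(freqs),
                dimnames = list(NULL, freqs))
  psd <- sliding_psd(x, rate, window = window, overlap = overlap)
  for (j in seq_along(freqs)) {
    pw <- psd_power_at(psd, freqs[j])
    tr <- structure(list(time = psd$times, power = pw),
                    foi = freqs[j], algorithm = "fft", class = "power_trace")
    bl <- compute_baseline(tr, schedule)
    erd <- erd_transform(pw, bl)
    for (i in seq_len(nrow(tasks))) {
      sel <- psd$times >= tasks$onset[i] &
        psd$times <= tasks$onset[i] + tasks$duration[i]
      out[i, j] <- mean(erd[sel])
    }
  }
  out
}

# assemble a power_trace object (internal; produced by both estimators)
new_power_trace <- function(time, power, foi, algorithm) {
  structure(list(time = time, power = power), foi = foi,
            algorithm = algorithm, class = "power_trace")
}

#' Instantaneous power trace at the FOI
#'
#' Dispatches to the FFT or lock-in pipeline and returns the causal,
#' trailing-edge-stamped instantaneous power series at the configured
#' frequency of interest. [compute_baseline()] consumes this, ensuring the
#' baseline and the instantaneous power come from the same estimator.
#'
#' @param x single-channel signal in microvolts.
#' @param rate sampling rate in Hz.
#' @param config an [estimator_config()].
#' @param algorithm `"fft"` or `"lia"`.
#' @param start_time time of the first sample in seconds.
#' @return A `power_trace`: list with `time` and `power`, with `foi` and
#'   `algorithm` attributes.
#' @export
power_trace <- function(x, rate, config, algorithm = c("fft", "lia"),
                        start_time = 0) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "fft") fft_power_trace(x, rate, config, start_time)
  else lia_power_trace(x, rate, config, start_time)
}

#' @export
print.power_trace <- function(x, ...) {
  cat(sprintf("<power_trace> %s, FOI %g Hz, %d samples\n",
              attr(x, "algorithm"), attr(x, "foi"), length(x$time)))
  invisible(x)
}
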