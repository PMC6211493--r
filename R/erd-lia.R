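#' Causal narrow band-pass around the frequency of interest
#'
#' Forward-only (causal) Butterworth band-pass with passband
#' `foi +/- halfwidth` Hz. Causality is essential: the lock-in estimator
#' is an online method and its delay comparison against the FFT pipeline
#' would be meaningless with zero-phase (forward-backward) filtering.
#'
#' @param x numeric signal in microvolts.
#' @param rate sampling rate in Hz.
#' @param foi centre frequency in Hz.
#' @param halfwidth half bandwidth in Hz (default 1).
#' @param order Butterworth prototype order (default 2; the band-pass has
#'   `2 * order` poles).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_foi <- function(x, rate, foi, halfwidth = 1, order = 2) {
  lo <- foi - halfwidth; hi <- foi + halfwidth
  if (lo <= 0) stop_config("band edge at or below 0 Hz (foi - halfwidth)")
  if (hi >= rate / 2)
    stop_config("band edge at or above the Nyquist frequency")
  bf <- signal::butter(order, c(lo, hi) / (rate / 2), type = "pass")
  as.numeric(signal::filter(bf, x))
}

#' Lock-in (quadrature) demodulation at the FOI
#'
#' The lock-in-amplifier core: the narrowband signal is multiplied point
#' by point with quadrature reference sinusoids at the frequency of
#' interest and integrated (averaged) over short sliding windows,
#' `I = mean(x(t) sin(2 pi foi t))`, `Q = mean(x(t) cos(2 pi foi t))`.
#' The recovered instantaneous amplitude is `2 sqrt(I^2 + Q^2)` — for a
#' sinusoid `a sin(2 pi foi t + phi)` this equals the peak amplitude `a`
#' regardless of `phi` (the dual-phase magnitude is phase-insensitive) —
#' and the instantaneous power is its square. Each output is stamped at
#' the trailing edge of its integration window.
#'
#' @param x narrowband signal in microvolts (see [bandpass_foi()]).
#' @param rate sampling rate in Hz.
#' @param foi reference frequency in Hz.
#' @param integration integration window in seconds (default one carrier
#'   period, `1/foi`).
#' @param overlap fractional overlap of successive windows (default 0.99;
#'   hop at least one sample).
#' @param start_time time of the first sample in seconds; references use
#'   absolute recording time.
#' @return An object of class `lia_output`: list with `times` (s),
#'   `amplitude` (microvolts, >= 0), `power` (`amplitude^2`) and `foi`.
#' @export
lia_demodulate <- function(x, rate, foi, integration = 1 / foi,
                           overlap = 0.99, start_time = 0) {
  n <- as.integer(round(integration * rate))
  if (n < 2L) stop_config("integration window must span at least 2 samples")
  if (length(x) < n)
    stop("insufficient data: signal shorter than one integration window")
  if (overlap < 0 || overlap >= 1) stop_config("overlap must lie in [0, 1)")
  hop <- max(1L, as.integer(round(n * (1 - overlap))))
  tt <- start_time + (seq_along(x) - 1) / rate
  ph <- 2 * pi * foi * tt
  cs <- cumsum(x * sin(ph)); cc <- cumsum(x * cos(ph))
  ends <- seq.int(n, length(x), by = hop)
  I <- (cs[ends] - c(0, cs)[ends - n + 1L]) / n
  Q <- (cc[ends] - c(0, cc)[ends - n + 1L]) / n
  amp <- 2 * sqrt(I^2 + Q^2)
  structure(list(times = tt[ends], amplitude = amp, power = amp^2,
                 foi = foi, integration = integration, overlap = overlap),
            class = "lia_output")
}

#' @export
print.lia_output <- function(x, ...) {
  cat(sprintf("<lia_output> FOI %g Hz, %d samples, integration %g s\n",
              x$foi, length(x$times), x$integration))
  invisible(x)
}

lia_power_trace <- function(x, rate, config, start_time = 0) {
  nb <- bandpass_foi(x, rate, config$foi,
                     halfwidth = config$lia_halfwidth,
                     order = config$lia_filter_order)
  out <- lia_demodulate(nb, rate, config$foi,
                        integration = config$lia_integration,
                        overlap = config$lia_overlap,
                        start_time = start_time)
  new_power_trace(out$times, out$power, foi = config$foi, algorithm = "lia")
}

#' Online ERD trace by lock-in demodulation
#'
#' The low-latency estimator: (1) frequency of interest; (2) causal
#' second-order Butterworth band-pass at `foi +/- lia_halfwidth` Hz;
#' (3) lock-in demodulation — point-by-point multiplication with
#' quadrature trigonometric references and integration over
#' `lia_integration`-second windows (default 1/FOI s) with
#' `lia_overlap` overlap; (4) ERD transform of the squared amplitude
#' against a baseline computed with the identical pipeline. Squaring puts
#' the lock-in output on the same power scale the ERD definition assumes,
#' so its steady state matches the FFT pipeline's analytically.
#'
#' @inheritParams erd_fft_trace
#' @param baseline a [baseline_model()] from the LIA pipeline at the same
#'   FOI, or `NULL` to compute one from `schedule`.
#' @return An [erd_trace()].
#' @export
erd_lia_trace <- function(x, rate, config, baseline = NULL, schedule = NULL,
                          start_time = 0) {
  tr <- lia_power_trace(x, rate, config, start_time)
  if (is.null(baseline)) {
    if (is.null(schedule))
      stop_config("either a baseline or a schedule must be supplied")
    baseline <- compute_baseline(tr, schedule)
  }
  erd_trace(tr$time, erd_transform(tr$power, baseline),
            foi = config$foi, algorithm = "lia")
}
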