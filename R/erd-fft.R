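#' Sliding-window power spectral density
#'
#' Segments the signal into overlapping windows and computes one tapered
#' periodogram per window — the conventional online spectral front end for
#' ERD estimation. Each window's PSD row is stamped at the window's
#' trailing edge, i.e. the time its last sample was acquired, which is
#' when the estimate first becomes available to a causal (online)
#' consumer; the estimator's intrinsic delay is therefore visible in the
#' stamps.
#'
#' Bins are normalized by the taper's coherent gain
#' (`psd = 2 |X_k|^2 / (sum w)^2`, DC and Nyquist undoubled), so a
#' bin-centred sinusoid of amplitude `a` reads its mean-square power
#' `a^2/2` under any taper. With the rectangular taper this coincides with
#' the Parseval normalization: the bins sum to the mean square of the
#' signal in the window.
#'
#' @param x numeric signal in microvolts.
#' @param rate sampling rate in Hz.
#' @param window window length in seconds (default 1; frequency resolution
#'   is `1/window`).
#' @param overlap fractional overlap in `[0, 1)` (default 0.99; the hop is
#'   `window * (1 - overlap)`, at least one sample).
#' @param taper `"hanning"` (default) or `"rectangular"`.
#' @param start_time time of the first sample in seconds.
#' @return An object of class `sliding_psd`: list with `times`
#'   (trailing-edge stamps, s), `freqs` (Hz) and `psd` (windows x
#'   frequencies matrix, non-negative).
#' @export
sliding_psd <- function(x, rate, window = 1.0, overlap = 0.99,
                        taper = c("hanning", "rectangular"),
                        start_time = 0) {
  taper <- match.arg(taper)
  if (overlap < 0 || overlap >= 1) stop_config("overlap must lie in [0, 1)")
  n <- round(window * rate)
  if (n < 2) stop_config("window too short for the sampling rate")
  if (length(x) < n)
    stop("insufficient data: signal shorter than one analysis window")
  hop <- max(1L, as.integer(round(n * (1 - overlap))))
  starts <- seq.int(1L, length(x) - n + 1L, by = hop)
  w <- if (taper == "hanning") hanning_taper(n) else rep(1, n)
  sw <- sum(w)
  nf <- n %/% 2 + 1L
  freqs <- (seq_len(nf) - 1L) * rate / n
  scale <- rep(2 / sw^2, nf)
  scale[1] <- 1 / sw^2                       # DC
  if (n %% 2 == 0) scale[nf] <- 1 / sw^2     # Nyquist
  psd <- matrix(0, length(starts), nf)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + n - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    psd[i, ] <- (Re(X)^2 + Im(X)^2) * scale
  }
  structure(list(times = start_time + (starts + n - 2L) / rate,
                 freqs = freqs, psd = psd,
                 window = window, overlap = overlap, taper = taper),
            class = "sliding_psd")
}

# periodic Hann taper (denominator n, not n-1): integer-bin sinusoids
# then read their mean-square power exactly under the coherent-gain scaling
hanning_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' @export
print.sliding_psd <- function(x, ...) {
  cat(sprintf("<sliding_psd> %d windows x %d bins, df = %g Hz, %s taper\n",
              nrow(x$psd), ncol(x$psd), x$freqs[2] - x$freqs[1], x$taper))
  invisible(x)
}

# power series at the bin nearest freq; errors if freq falls between bins
psd_power_at <- function(psd, freq) {
  df <- psd$freqs[2] - psd$freqs[1]
  k <- which.min(abs(psd$freqs - freq))
  if (abs(psd$freqs[k] - freq) > df / 4 + 1e-9)
    stop_config("FOI ", freq, " Hz is not representable at the window's ",
                "frequency resolution of ", df, " Hz")
  psd$psd[, k]
}

fft_power_trace <- function(x, rate, config, start_time = 0) {
  psd <- sliding_psd(x, rate, window = config$fft_window,
                     overlap = config$fft_overlap, taper = config$fft_taper,
                     start_time = start_time)
  new_power_trace(psd$times, psd_power_at(psd, config$foi),
                  foi = config$foi, algorithm = "fft")
}

#' Online ERD trace by sliding-FFT PSD
#'
#' The conventional estimator: (1) segmentation into `fft_window`-second
#' windows with `fft_overlap` overlap; (2) Hanning-tapered periodogram per
#' window; (3) power at the frequency-of-interest bin; (4) ERD transform
#' against the rest-phase baseline. All stamps are trailing-edge, so the
#' trace is causal.
#'
#' @param x single-channel signal in microvolts (e.g. from
#'   [large_laplacian()]).
#' @param rate sampling rate in Hz.
#' @param config an [estimator_config()].
#' @param baseline a [baseline_model()] computed with the same FFT
#'   settings, or `NULL` to compute it from `schedule`.
#' @param schedule a [task_schedule()]; required when `baseline` is `NULL`.
#' @param start_time time of the first sample in seconds.
#' @return An [erd_trace()].
#' @export
erd_fft_trace <- function(x, rate, config, baseline = NULL, schedule = NULL,
                          start_time = 0) {
  tr <- fft_power_trace(x, rate, config, start_time)
  if (is.null(baseline)) {
    if (is.null(schedule))
      stop_config("either a baseline or a schedule must be supplied")
    baseline <- compute_baseline(tr, schedule)
  }
  erd_trace(tr$time, erd_transform(tr$power, baseline),
            foi = config$foi, algorithm = "fft")
}
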