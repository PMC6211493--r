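# Benchmark harness: delay, accuracy and stability of the causal ERD
# estimators on step-modulated synthetic signals with known ground truth.

# standard step fixture: one rest phase, one task phase with an
# instantaneous envelope-suppression step at the task onset
step_fixture <- function(seed, depth = 70, foi = 10, snr = 10,
                         noise = "pink", rate = 1000, rest = 6, task = 6) {
  sch <- block_schedule(1, rest = rest, task = task)
  synth_eeg(synth_eeg_config(sch, rate = rate, foi = foi,
                             erd_depth = depth, onset_ramp = 0,
                             noise = noise, snr = snr, phase = NA,
                             seed = seed))
}

# zero-latency reference estimator: ERD straight from the true envelope
oracle_trace <- function(sim) {
  truth <- sim$truth
  erd_trace(truth$time[-1], truth$erd[-1], foi = sim$config$foi,
            algorithm = "oracle")
}

estimator_trace <- function(sim, algorithm, config) {
  x <- sim$recording$samples[1, ]
  rate <- sim$config$rate
  if (algorithm == "oracle") return(oracle_trace(sim))
  if (algorithm == "fft")
    erd_fft_trace(x, rate, config, schedule = sim$config$schedule)
  else erd_lia_trace(x, rate, config, schedule = sim$config$schedule)
}

# effective analysis-window length in seconds, for steady-state margins
estimator_window <- function(algorithm, config) {
  switch(algorithm,
         fft = config$fft_window,
         lia = config$lia_integration + 1 / (2 * config$lia_halfwidth),
         oracle = 0)
}

#' Step-response detection delay of an ERD estimator
#'
#' For each seed, a synthetic recording with an instantaneous
#' envelope-suppression step at the task onset is generated, the causal
#' ERD trace is computed, and the delay is the time from the true step to
#' the FIRST trace sample reaching `criterion` (default 50%) of the
#' trace's own steady-state change. Referencing the crossing to the
#' trace's own steady state makes the criterion scale-free and applicable
#' to both estimators at any depth or SNR.
#'
#' @param algorithm `"fft"`, `"lia"` or `"oracle"` (ground-truth envelope
#'   passthrough, for harness validation).
#' @param config an [estimator_config()] (default: standard settings at
#'   `foi`).
#' @param depth step depth in percent power suppression (default 70).
#' @param n_seeds number of noise realizations (default 50).
#' @param seeds explicit seed vector (overrides `n_seeds`).
#' @param noise,snr background noise model and alpha-band SNR of the
#'   fixture (defaults "pink", 10).
#' @param foi carrier frequency in Hz (default 10).
#' @param criterion fraction of the steady-state change that must be
#'   reached (0.25, 0.5 or 0.9; default 0.5).
#' @param rate,rest,task fixture geometry (s).
#' @return A list of class `delay_result`: `mean_ms`, `sd_ms`,
#'   `delays_ms` (per seed), `n_failed` (seeds whose trace never reached
#'   the criterion, excluded with a warning).
#' @export
measure_delay <- function(algorithm = c("fft", "lia", "oracle"),
                          config = NULL, depth = 70, n_seeds = 50,
                          seeds = NULL, noise = "pink", snr = 10,
                          foi = 10, criterion = 0.5, rate = 1000,
                          rest = 6, task = 6) {
  algorithm <- match.arg(algorithm)
  if (depth <= 0 || depth > 100) stop_config("depth must lie in (0, 100]")
  if (is.null(config)) config <- estimator_config(foi = foi)
  seeds <- seeds %||% seq_len(n_seeds)
  step_t <- rest
  margin <- 2 * estimator_window(algorithm, config)
  delays <- rep(NA_real_, length(seeds))
  for (i in seq_along(seeds)) {
    sim <- step_fixture(seeds[i], depth = depth, foi = foi, snr = snr,
                        noise = noise, rate = rate, rest = rest,
                        task = task)
    tr <- estimator_trace(sim, algorithm, config)
    # settled rest segment just before the step (excludes filter start-up)
    pre <- mean(tr$erd[tr$time >= step_t - 2 & tr$time < step_t])
    steady <- mean(tr$erd[tr$time >= step_t + max(margin, 2) &
                            tr$time <= rest + task])
    change <- steady - pre
    if (!is.finite(change) || change >= 0) next
    hit <- which(tr$time > step_t & tr$erd <= pre + criterion * change)
    if (length(hit)) delays[i] <- tr$time[hit[1]] - step_t
  }
  failed <- sum(is.na(delays))
  if (failed)
    warning(failed, " seed(s) never reached the delay criterion; excluded")
  d <- delays[!is.na(delays)] * 1000
  structure(list(algorithm = algorithm, mean_ms = mean(d),
                 sd_ms = stats::sd(d), delays_ms = d, n_failed = failed,
                 criterion = criterion, depth = depth, snr = snr,
                 n_seeds = length(seeds)),
            class = "delay_result")
}

#' @export
print.delay_result <- function(x, ...) {
  cat(sprintf("<delay_result> %s: %.0f +/- %.1f ms (criterion %g%%, depth %g%%, %d seeds%s)\n",
              x$algorithm, x$mean_ms, x$sd_ms, 100 * x$criterion, x$depth,
              x$n_seeds,
              if (x$n_failed) paste0(", ", x$n_failed, " failed") else ""))
  invisible(x)
}

#' Steady-state accuracy and stability of an ERD estimator
#'
#' On the same step fixtures as [measure_delay()], restricted to the
#' steady-state segment (from two analysis windows after the step to the
#' task end, from ground truth): accuracy is the RMS error between the
#' estimated and the true ERD pooled over seeds; stability is the
#' within-segment SD of the estimate averaged over seeds (the smoothness
#' of the trace a threshold trigger would consume).
#'
#' @inheritParams measure_delay
#' @return A list of class `accuracy_result`: `accuracy` (RMS error,
#'   percent ERD), `stability` (mean within-segment SD, percent ERD),
#'   plus per-seed values.
#' @export
measure_accuracy_stability <- function(algorithm = c("fft", "lia", "oracle"),
                                       config = NULL, depth = 70,
                                       n_seeds = 20, seeds = NULL,
                                       noise = "pink", snr = 10, foi = 10,
                                       rate = 1000, rest = 6, task = 6) {
  algorithm <- match.arg(algorithm)
  if (is.null(config)) config <- estimator_config(foi = foi)
  seeds <- seeds %||% seq_len(n_seeds)
  margin <- max(2 * estimator_window(algorithm, config), 2)
  sq_err <- c(); sds <- rep(NA_real_, length(seeds))
  for (i in seq_along(seeds)) {
    sim <- step_fixture(seeds[i], depth = depth, foi = foi, snr = snr,
                        noise = noise, rate = rate, rest = rest,
                        task = task)
    tr <- estimator_trace(sim, algorithm, config)
    sel <- tr$time >= rest + margin & tr$time <= rest + task
    est <- tr$erd[sel]
    sq_err <- c(sq_err, (est - (-depth))^2)
    sds[i] <- stats::sd(est)
  }
  structure(list(algorithm = algorithm,
                 accuracy = sqrt(mean(sq_err)), stability = mean(sds),
                 stability_by_seed = sds, depth = depth, snr = snr,
                 n_seeds = length(seeds)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %s: RMS error %.2f%%, stability (SD) %.2f%% (depth %g%%, %d seeds)\n",
              x$algorithm, x$accuracy, x$stability, x$depth, x$n_seeds))
  invisible(x)
}

#' Compare ERD estimators across step depths
#'
#' Runs [measure_delay()] and [measure_accuracy_stability()] for every
#' algorithm x depth combination on identical seeded fixtures and
#' tabulates the results.
#'
#' @param algorithms estimators to compare (default FFT and LIA).
#' @param depths step depths in percent (default c(35, 70)).
#' @param n_seeds seeds per cell (default 20).
#' @param configs optional named list of [estimator_config()]s per
#'   algorithm.
#' @inheritParams measure_delay
#' @return A data.frame of class `benchmark_result`, one row per
#'   (algorithm, depth): `delay_ms`, `delay_sd_ms`, `accuracy`,
#'   `stability`, `n_seeds`.
#' @export
compare_algorithms <- function(algorithms = c("fft", "lia"),
                               depths = c(35, 70), n_seeds = 20,
                               configs = NULL, noise = "pink", snr = 10,
                               foi = 10, criterion = 0.5) {
  if (length(algorithms) < 2) stop_config("need at least two algorithms")
  rows <- NULL
  for (alg in algorithms) for (d in depths) {
    cfg <- if (!is.null(configs)) configs[[alg]] else NULL
    dl <- measure_delay(alg, config = cfg, depth = d, n_seeds = n_seeds,
                        noise = noise, snr = snr, foi = foi,
                        criterion = criterion)
    ac <- measure_accuracy_stability(alg, config = cfg, depth = d,
                                     n_seeds = n_seeds, noise = noise,
                                     snr = snr, foi = foi)
    rows <- rbind(rows, data.frame(
      algorithm = alg, depth = d, delay_ms = dl$mean_ms,
      delay_sd_ms = dl$sd_ms, accuracy = ac$accuracy,
      stability = ac$stability, n_seeds = n_seeds))
  }
  class(rows) <- c("benchmark_result", "data.frame")
  rows
}

#' Write a benchmark table as TSV and JSON
#' @param result a `benchmark_result` from [compare_algorithms()].
#' @param path_tsv,path_json output paths (`NULL` skips either).
#' @return `result`, invisibly.
#' @export
write_benchmark <- function(result, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(result, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(result, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
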