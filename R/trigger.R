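#' Threshold-triggered stimulation for one trial
#'
#' Scans a causal ERD trace over one task phase and fires at the FIRST
#' stamped sample whose ERD reaches the threshold, i.e. `erd <= -threshold`
#' (ERD magnitudes are suppressions, so "ERD reached 35%" means the signed
#' trace crossed -35%). At most one stimulus per trial; if no crossing
#' occurs before the phase ends the trial is unsuccessful and no stimulus
#' is delivered.
#'
#' @param trace an [erd_trace()] covering the task phase.
#' @param threshold trigger threshold in percent ERD magnitude (35 or 70
#'   in the emulated protocol).
#' @param task_onset task-phase onset in seconds.
#' @param task_duration task-phase duration in seconds (default 5).
#' @return A one-row data.frame (`time`, `erd_at_trigger`, `threshold`)
#'   for a successful trial, or `NULL` when the threshold is never
#'   reached.
#' @export
run_trial <- function(trace, threshold, task_onset, task_duration = 5) {
  stopifnot(inherits(trace, "erd_trace"))
  t_end <- task_onset + task_duration
  # one output hop of slack at the trailing end (stamps are discrete)
  hop <- if (length(trace$time) > 1) stats::median(diff(trace$time)) else 0
  if (min(trace$time) > task_onset + 1e-9 ||
      max(trace$time) < t_end - 1.5 * hop - 1e-9)
    stop("ERD trace does not cover the task phase [",
         task_onset, ", ", t_end, "] s")
  sel <- which(trace$time >= task_onset & trace$time <= t_end &
                 trace$erd <= -threshold)
  if (!length(sel)) return(NULL)
  i <- sel[1]
  data.frame(time = trace$time[i], erd_at_trigger = trace$erd[i],
             threshold = threshold)
}

#' Simulate an ERD-triggered TMS session
#'
#' Emulates the closed-loop protocol: rest periods randomized uniformly
#' in `rest_range` seconds (so task onsets are unpredictable) alternate
#' with `task_duration`-second task phases; the online estimator named by
#' the condition runs causally over the synthesized EEG, and each task
#' phase is monitored for the first threshold crossing. Conditions
#' `FFT35`/`FFT70`/`LIA35`/`LIA70` trigger at ERD magnitude 35% or 70%
#' with the corresponding estimator; `RELAXED` draws one stimulus time
#' uniformly within each task phase (the control condition, where every
#' trial counts as successful). The session stops once `target_successes`
#' successful trials have accumulated, or at `max_trials` with the result
#' flagged incomplete.
#'
#' The baseline reference power is computed from a dedicated 8-s
#' calibration rest phase prepended to the session (the randomized 4-6 s
#' rests are shorter than the 5 s the 3-5 s baseline window requires).
#'
#' @param generator a [synth_eeg_config()]; its schedule is replaced by
#'   the randomized session schedule built here, and its seed by `seed`.
#' @param condition `"FFT35"`, `"FFT70"`, `"LIA35"`, `"LIA70"` or
#'   `"RELAXED"`.
#' @param config an [estimator_config()]; defaults to the generator's FOI
#'   with standard settings.
#' @param target_successes successful trials required to end the session
#'   (default 25).
#' @param rest_range uniform range of the randomized rest duration in
#'   seconds (default c(4, 6)).
#' @param task_duration task-phase length in seconds (default 5).
#' @param max_trials hard cap on attempted trials (default 100).
#' @param seed RNG seed driving the rest randomization, the generator
#'   noise and the RELAXED stimulus times.
#' @return An object of class `session_result`: `events` (data.frame with
#'   `trial_index`, `time`, `erd_at_trigger`, `threshold`, `condition`),
#'   `n_successful`, `n_unsuccessful`, `schedule`, `condition`,
#'   `complete`.
#' @export
run_session <- function(generator, condition = c("FFT35", "FFT70", "LIA35",
                                                 "LIA70", "RELAXED"),
                        config = NULL, target_successes = 25,
                        rest_range = c(4, 6), task_duration = 5,
                        max_trials = 100, seed = 1) {
  stopifnot(inherits(generator, "synth_eeg_config"))
  condition <- match.arg(condition)
  threshold <- switch(condition, FFT35 = 35, LIA35 = 35,
                      FFT70 = 70, LIA70 = 70, RELAXED = NA_real_)
  algorithm <- if (startsWith(condition, "LIA")) "lia" else "fft"
  if (is.null(config)) config <- estimator_config(foi = generator$foi)

  with_seed(seed, {
    rests <- stats::runif(max_trials, rest_range[1], rest_range[2])
    relaxed_u <- stats::runif(max_trials)
    calib <- 8
    kinds <- c("rest"); onsets <- c(0); durs <- c(calib)
    t0 <- calib
    for (i in seq_len(max_trials)) {
      kinds <- c(kinds, "rest", "task")
      onsets <- c(onsets, t0, t0 + rests[i])
      durs <- c(durs, rests[i], task_duration)
      t0 <- t0 + rests[i] + task_duration
    }
    schedule <- task_schedule(data.frame(kind = kinds, onset = onsets,
                                         duration = durs))
    gen <- generator
    gen$schedule <- schedule
    gen$seed <- NULL                       # session RNG already seeded
    if (condition == "RELAXED") gen$erd_depth <- 0
    sim <- synth_eeg(gen)
    x <- sim$recording$samples[1, ]

    events <- NULL
    n_succ <- 0L; n_fail <- 0L; trials_run <- 0L
    tasks <- schedule_phases(schedule, "task")

    if (condition == "RELAXED") {
      for (i in seq_len(max_trials)) {
        trials_run <- i
        ev <- data.frame(trial_index = i,
                         time = tasks$onset[i] + relaxed_u[i] * task_duration,
                         erd_at_trigger = NA_real_, threshold = NA_real_,
                         condition = condition)
        events <- rbind(events, ev)
        n_succ <- n_succ + 1L
        if (n_succ >= target_successes) break
      }
    } else {
      # baseline from the calibration rest only; the randomized 4-6 s
      # rests are too short for the 3-5 s baseline window
      calib_sched <- task_schedule(data.frame(kind = "rest", onset = 0,
                                              duration = calib))
      pw <- power_trace(x, gen$rate, config, algorithm)
      baseline <- compute_baseline(pw, calib_sched)
      trace <- erd_trace(pw$time, erd_transform(pw$power, baseline),
                         foi = config$foi, algorithm = algorithm)
      for (i in seq_len(max_trials)) {
        trials_run <- i
        ev <- run_trial(trace, threshold, tasks$onset[i], task_duration)
        if (is.null(ev)) {
          n_fail <- n_fail + 1L
        } else {
          n_succ <- n_succ + 1L
          events <- rbind(events,
                          cbind(data.frame(trial_index = i), ev,
                                data.frame(condition = condition)))
        }
        if (n_succ >= target_successes) break
      }
    }
    used <- schedule[schedule$onset < if (trials_run < max_trials)
      tasks$onset[trials_run] + task_duration + 1e-9 else Inf, ,
      drop = FALSE]
    structure(list(events = events %||%
                     data.frame(trial_index = integer(), time = numeric(),
                                erd_at_trigger = numeric(),
                                threshold = numeric(),
                                condition = character()),
                   n_successful = n_succ, n_unsuccessful = n_fail,
                   schedule = task_schedule(used), condition = condition,
                   threshold = threshold,
                   complete = n_succ >= target_successes,
                   target_successes = target_successes),
              class = "session_result")
  })
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s: %d successful / %d unsuccessful trial(s)%s\n",
              x$condition, x$n_successful, x$n_unsuccessful,
              if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

#' @export
summary.session_result <- function(object, ...) {
  ev <- object$events
  tasks <- schedule_phases(object$schedule, "task")
  lat <- if (nrow(ev)) ev$time - tasks$onset[ev$trial_index] else numeric(0)
  out <- list(condition = object$condition,
              n_successful = object$n_successful,
              n_unsuccessful = object$n_unsuccessful,
              complete = object$complete,
              mean_latency = mean(lat),
              sd_latency = stats::sd(lat))
  class(out) <- "summary.session_result"
  out
}

#' @export
print.summary.session_result <- function(x, ...) {
  cat(sprintf("Session %s: %d ok, %d failed; trigger latency %.3f +/- %.3f s\n",
              x$condition, x$n_successful, x$n_unsuccessful,
              x$mean_latency, x$sd_latency))
  invisible(x)
}
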