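#' Multichannel EEG/EMG recording
#'
#' Container for a continuous multichannel recording: a channels-by-time
#' matrix in microvolts, a sampling rate and ordered channel labels. Sample
#' `i` of every channel is stamped at `start_time + (i - 1) / rate` seconds.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate in samples per second (> 0).
#' @param channel_names character vector of unique labels, one per row of
#'   `samples`.
#' @param start_time time of the first sample in seconds (default 0).
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(300), 3), 100, c("C3", "Cz", "C4"))
#' rec
#' @export
eeg_recording <- function(samples, rate, channel_names,
                          start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_config("rate must be a single positive number")
  if (length(channel_names) != nrow(samples))
    stop_config("channel_names length (", length(channel_names),
                ") must equal the number of sample rows (", nrow(samples), ")")
  if (anyDuplicated(channel_names))
    stop_config("channel names must be unique")
  rownames(samples) <- channel_names
  structure(list(samples = samples, rate = rate,
                 channel_names = as.character(channel_names),
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat("  channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Time stamps of a recording's samples
#' @param rec an [eeg_recording()].
#' @return numeric vector of per-sample times in seconds.
#' @export
recording_times <- function(rec) {
  rec$start_time + (seq_len(ncol(rec$samples)) - 1) / rec$rate
}

#' Read a recording from disk
#'
#' Two dialects are supported. `"csv"` is a plain matrix: one header row of
#' channel names preceded by a `time` column in seconds, sample values in
#' microvolts. `"edf"` is the 16-bit European Data Format subset written by
#' [write_recording()] (continuous recording, common rate across channels).
#'
#' @param path file to read.
#' @param format `"csv"` or `"edf"`; the default guesses from the extension.
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path))
    stop_io("cannot read recording: no such file: ", path)
  if (format == "edf") return(read_edf(path))
  tab <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop_io("malformed CSV recording ", path, ": ",
                                conditionMessage(e)))
  if (ncol(tab) < 2L || names(tab)[1] != "time")
    stop_io("CSV recording ", path,
            " must have a 'time' column followed by channel columns")
  if (any(!vapply(tab, is.numeric, logical(1))) || anyNA(tab))
    stop_io("format error: CSV recording ", path,
            " has missing or non-numeric values")
  tt <- tab[[1]]
  rate <- if (length(tt) > 1) 1 / stats::median(diff(tt)) else 1
  eeg_recording(t(as.matrix(tab[-1])), rate = rate,
                channel_names = names(tab)[-1], start_time = tt[1])
}

#' Write a recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @param format `"csv"` or `"edf"` (see [read_recording()]). EDF stores
#'   samples as 16-bit integers scaled to the per-channel physical range, so
#'   values round-trip only to within that quantization.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(write_edf(rec, path))
  tab <- data.frame(time = recording_times(rec), t(rec$samples),
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Electrode montage layout
#'
#' Geometry needed by the surface-Laplacian spatial filter: 2-D scalp
#' positions plus, for each filterable electrode, the ordered set of
#' neighbors whose mean is subtracted.
#'
#' @param positions data.frame with columns `name`, `x`, `y`.
#' @param neighbors named list mapping an electrode name to a character
#'   vector of neighbor names; every referenced name must exist in
#'   `positions`.
#' @param center default center electrode label (must exist; default "C3").
#' @return An object of class `montage_layout`.
#' @export
montage_layout <- function(positions, neighbors, center = "C3") {
  stopifnot(is.data.frame(positions),
            all(c("name", "x", "y") %in% names(positions)))
  positions$name <- as.character(positions$name)
  if (anyDuplicated(positions$name))
    stop_config("duplicate electrode names in montage")
  all_named <- unique(c(names(neighbors), unlist(neighbors)))
  missing <- setdiff(all_named, positions$name)
  if (length(missing))
    stop_config("montage neighbors reference unknown electrode(s): ",
                paste(missing, collapse = ", "))
  if (!center %in% positions$name)
    stop_config("montage center '", center, "' is not in the layout")
  structure(list(positions = positions, neighbors = neighbors,
                 center = center),
            class = "montage_layout")
}

#' @export
print.montage_layout <- function(x, ...) {
  cat(sprintf("<montage_layout> %d electrodes, center %s\n",
              nrow(x$positions), x$center))
  nb <- x$neighbors[[x$center]]
  if (!is.null(nb)) cat("  ", x$center, " ring: ",
                        paste(nb, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default 10-20 montage with a large-Laplacian ring around C3
#'
#' A 19-electrode 10-20 layout (schematic head coordinates, unit radius).
#' The C3 large-Laplacian ring is the four next-nearest neighbors
#' F3, Cz, P3 and T7; C4 gets the mirror-image ring.
#'
#' @return A [montage_layout()].
#' @export
montage_1020 <- function() {
  read_montage(system.file("extdata", "montage_1020.json",
                           package = "erdlia"))
}

#' Read / write a montage as JSON
#' @param path JSON file with fields `positions` (records of name, x, y),
#'   `neighbors` (name -> array of names) and `center`.
#' @return [read_montage()] returns a [montage_layout()];
#'   [write_montage()] returns `path` invisibly.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop_io("no such montage file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nb <- lapply(j$neighbors, as.character)
  montage_layout(as.data.frame(j$positions), nb, center = j$center %||% "C3")
}

#' @rdname read_montage
#' @param layout a [montage_layout()].
#' @export
write_montage <- function(layout, path) {
  stopifnot(inherits(layout, "montage_layout"))
  jsonlite::write_json(list(positions = layout$positions,
                            neighbors = layout$neighbors,
                            center = layout$center),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Task schedule of rest / task / blank phases
#'
#' @param phases data.frame with columns `kind` (one of `"rest"`, `"task"`,
#'   `"blank"`), `onset` (s) and `duration` (s). Phases must have positive
#'   durations, strictly increasing onsets and must not overlap.
#' @return An object of class `task_schedule` (a validated data.frame).
#' @export
task_schedule <- function(phases) {
  phases <- as.data.frame(phases)
  stopifnot(all(c("kind", "onset", "duration") %in% names(phases)))
  phases$kind <- as.character(phases$kind)
  if (!all(phases$kind %in% c("rest", "task", "blank")))
    stop_schedule("phase kind must be rest, task or blank")
  if (any(phases$duration <= 0))
    stop_schedule("phase durations must be positive")
  if (is.unsorted(phases$onset, strictly = TRUE))
    stop_schedule("phase onsets must be strictly increasing")
  ends <- phases$onset + phases$duration
  if (any(utils::head(ends, -1) > phases$onset[-1] + 1e-9))
    stop_schedule("phases overlap")
  class(phases) <- c("task_schedule", "data.frame")
  phases
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule> %d phases, %.1f s total\n", nrow(x),
              max(x$onset + x$duration)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Phases of a given kind
#' @param schedule a [task_schedule()].
#' @param kind phase kind to extract.
#' @return data.frame of the matching phases.
#' @export
schedule_phases <- function(schedule, kind = c("rest", "task", "blank")) {
  kind <- match.arg(kind)
  schedule[schedule$kind == kind, , drop = FALSE]
}

#' Read / write a task schedule as JSON
#' @param path JSON file holding an array of `{kind, onset, duration}`
#'   records.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop_io("no such schedule file: ", path)
  task_schedule(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_schedule
#' @param schedule a [task_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(unclass(schedule)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Alternating rest/task schedule
#'
#' Convenience constructor for the block design used throughout: rest then
#' task, repeated, with optional blank inter-trial gaps.
#'
#' @param n_trials number of rest+task repetitions.
#' @param rest,task,blank phase durations in seconds (`blank = 0` omits
#'   blanks). `rest` may be a vector of per-trial durations.
#' @return A [task_schedule()].
#' @export
block_schedule <- function(n_trials, rest = 5, task = 5, blank = 0) {
  rest <- rep_len(rest, n_trials)
  kinds <- character(0); onsets <- numeric(0); durs <- numeric(0)
  t0 <- 0
  for (i in seq_len(n_trials)) {
    kinds <- c(kinds, "rest", "task"); onsets <- c(onsets, t0, t0 + rest[i])
    durs <- c(durs, rest[i], task)
    t0 <- t0 + rest[i] + task
    if (blank > 0) {
      kinds <- c(kinds, "blank"); onsets <- c(onsets, t0); durs <- c(durs, blank)
      t0 <- t0 + blank
    }
  }
  task_schedule(data.frame(kind = kinds, onset = onsets, duration = durs))
}

#' Large-Laplacian spatial filter
#'
#' Subtracts, sample by sample, the arithmetic mean of the center
#' electrode's neighbor ring from the center channel. With a next-nearest
#' ("large") ring this acts as a spatial high-pass focusing the signal on
#' the cortical patch under the center electrode, and removes any
#' spatially uniform (common-mode) component exactly.
#'
#' @param rec an [eeg_recording()] containing the center and all its
#'   neighbors.
#' @param layout a [montage_layout()] supplying the neighbor ring.
#' @param center center electrode label; defaults to the layout's center.
#' @return Numeric vector (microvolts), one value per sample, with
#'   attributes `rate` and `start_time` carried over from `rec`.
#' @examples
#' m <- montage_1020()
#' rec <- eeg_recording(matrix(1, 5, 10), 100, c("C3", "F3", "Cz", "P3", "T7"))
#' all(large_laplacian(rec, m) == 0)  # uniform recording -> zero
#' @export
large_laplacian <- function(rec, layout, center = layout$center) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(layout, "montage_layout"))
  nb <- layout$neighbors[[center]]
  if (is.null(nb))
    stop_config("montage defines no neighbor ring for '", center, "'")
  need <- c(center, nb)
  missing <- setdiff(need, rec$channel_names)
  if (length(missing))
    stop_config("recording lacks channel(s) required by the Laplacian: ",
                paste(missing, collapse = ", "))
  out <- rec$samples[center, ] -
    colMeans(rec$samples[nb, , drop = FALSE])
  attr(out, "rate") <- rec$rate
  attr(out, "start_time") <- rec$start_time
  out
}
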