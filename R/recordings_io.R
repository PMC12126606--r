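#' Voltage-clamp recording container
#'
#' A single sweep of uniformly sampled membrane current with its acquisition
#' metadata. Unit conventions are fixed package-wide: current in pA, time in
#' ms (0-based from sweep start; sample i corresponds to time (i-1)/rate),
#' voltages in mV, sampling and filter rates in kHz. The holding potential is
#' stored already corrected for the liquid junction potential (downstream
#' maths uses corrected potentials only); the uncorrected command voltage may
#' be kept in `v_command`.
#'
#' @param samples Numeric vector of current samples in pA.
#' @param rate Sampling rate in kHz (e.g. 200 for evoked EPSCs, 50 for minis).
#' @param v_hold Junction-corrected holding potential in mV.
#' @param stim_times Stimulus onset times in ms (possibly empty), strictly
#'   increasing and within `[0, duration)`.
#' @param filter_khz Acquisition low-pass corner in kHz.
#' @param label Free-text label.
#' @param v_command Optional uncorrected command potential in mV.
#'
#' @return An object of class `recording` with fields `samples`, `rate`,
#'   `v_hold`, `stim_times`, `filter_khz`, `duration` (ms), `label`.
#' @export
recording <- function(samples, rate, v_hold, stim_times = numeric(0),
                      filter_khz = NA_real_, label = "", v_command = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1 || !(rate > 0))
    stop("rate must be a single positive number (kHz)")
  if (!is.finite(v_hold)) stop("v_hold must be finite (mV)")
  duration <- length(samples) / rate
  stim_times <- as.numeric(stim_times)
  if (length(stim_times)) {
    if (any(diff(stim_times) <= 0))
      stop("stim_times must be strictly increasing")
    if (any(stim_times < 0 | stim_times >= duration))
      stop("stim_times must lie within [0, duration)")
  }
  structure(list(samples = samples, rate = rate, v_hold = v_hold,
                 stim_times = stim_times, filter_khz = filter_khz,
                 duration = duration, label = label, v_command = v_command),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %.1f ms at %g kHz, V_hold %g mV, %d stimuli\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$duration, x$rate, x$v_hold, length(x$stim_times)))
  invisible(x)
}

#' Train-plus-recovery stimulation protocol
#'
#' High-frequency train of `n_train_pulses` at `train_freq` Hz followed by
#' single recovery pulses. `recovery_intervals` are the inter-stimulus
#' intervals between *consecutive* recovery pulses (the first measured from
#' the last train pulse), so the default 25, 50, 100, 300, 1000, 3000 ms
#' places the recovery stimuli 25, 75, 175, 475, 1475 and 4475 ms after the
#' train, covering ~4.5 s of recovery.
#'
#' @param n_train_pulses Number of train pulses (default 20).
#' @param train_freq Train frequency in Hz (100 or 300 in the standard
#'   protocol).
#' @param recovery_intervals Consecutive inter-stimulus intervals in ms.
#' @param n_repetitions Number of repetitions of the protocol (default 5).
#' @param inter_train_interval Interval between repetitions in s (default 30).
#'
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(n_train_pulses = 20, train_freq = 300,
                          recovery_intervals = c(25, 50, 100, 300, 1000, 3000),
                          n_repetitions = 5, inter_train_interval = 30) {
  stopifnot(n_train_pulses >= 1, train_freq > 0, n_repetitions >= 1)
  recovery_intervals <- as.numeric(recovery_intervals)
  if (length(recovery_intervals) && any(diff(recovery_intervals) <= 0))
    stop("recovery_intervals must be strictly increasing")
  structure(list(n_train_pulses = as.integer(n_train_pulses),
                 train_freq = train_freq,
                 recovery_intervals = recovery_intervals,
                 n_repetitions = as.integer(n_repetitions),
                 inter_train_interval = inter_train_interval),
            class = "stim_protocol")
}

#' Stimulus times of a protocol
#'
#' @param protocol A [stim_protocol].
#' @param t0 Time of the first pulse in ms (default 0).
#' @return Stimulus times in ms: the train pulses at the train ISI, then the
#'   recovery pulses at the cumulative recovery intervals.
#' @export
protocol_stim_times <- function(protocol, t0 = 0) {
  stopifnot(inherits(protocol, "stim_protocol"))
  isi <- 1000 / protocol$train_freq
  train <- t0 + (seq_len(protocol$n_train_pulses) - 1) * isi
  last <- train[length(train)]
  c(train, last + cumsum(protocol$recovery_intervals))
}

# ---- file formats -----------------------------------------------------------
# Single-sweep text format: leading "#key=value" metadata lines, then a
# header "current_pA" and one sample per line. RFC-4180 CSV with "." decimal.

#' Write a recording to a text file
#'
#' @param rec A [recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(
    sprintf("#rate_khz=%.17g", rec$rate),
    sprintf("#v_hold_mv=%.17g", rec$v_hold),
    sprintf("#filter_khz=%.17g", rec$filter_khz),
    sprintf("#stim_times_ms=%s", paste(sprintf("%.17g", rec$stim_times),
                                       collapse = ";")),
    sprintf("#label=%s", rec$label))
  if (!is.null(rec$v_command))
    meta <- c(meta, sprintf("#v_command_mv=%.17g", rec$v_command))
  writeLines(meta, con)
  writeLines("current_pA", con)
  writeLines(sprintf("%.17g", rec$samples), con)
  invisible(path)
}

#' Read a recording written by [write_recording]
#'
#' @param path File path.
#' @return A [recording]. Missing mandatory metadata (`rate_khz`,
#'   `v_hold_mv`) raises a format error naming the missing key;
#'   non-monotonic stimulus times raise a validation error.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  kv <- regmatches(meta_lines, regexpr("=", meta_lines), invert = TRUE)
  keys <- vapply(kv, function(x) sub("^#", "", x[1]), character(1))
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  meta <- stats::setNames(as.list(vals), keys)
  for (k in c("rate_khz", "v_hold_mv"))
    if (is.null(meta[[k]])) stop("recording format error: missing key '", k, "'")
  body <- lines[!is_meta]
  if (length(body) < 1 || body[1] != "current_pA")
    stop("recording format error: missing 'current_pA' column header")
  samples <- as.numeric(body[-1])
  st <- meta[["stim_times_ms"]]
  stim_times <- if (is.null(st) || !nzchar(st)) numeric(0) else
    as.numeric(strsplit(st, ";", fixed = TRUE)[[1]])
  recording(samples = samples,
            rate = as.numeric(meta[["rate_khz"]]),
            v_hold = as.numeric(meta[["v_hold_mv"]]),
            stim_times = stim_times,
            filter_khz = as.numeric(meta[["filter_khz"]] %||% NA),
            label = meta[["label"]] %||% "",
            v_command = if (!is.null(meta[["v_command_mv"]]))
              as.numeric(meta[["v_command_mv"]]) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write event tables
#'
#' An event table is a data.frame with columns `event_time` (ms, non-
#' decreasing), `amplitude` (pA, positive magnitudes), `charge` (pC),
#' `rise_10_90` (ms) and `decay_tau` (ms).
#'
#' @param events Event table data.frame.
#' @param path CSV file path.
#' @return `read_event_table` returns the validated data.frame;
#'   `write_event_table` returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  events <- validate_event_table(events)
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_event_table(utils::read.csv(path))
}

validate_event_table <- function(events) {
  req <- c("event_time", "amplitude", "charge", "rise_10_90", "decay_tau")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("event table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (is.unsorted(events$event_time))
    stop("event_time must be non-decreasing")
  if (any(events$amplitude < 0, na.rm = TRUE))
    stop("amplitudes must be positive magnitudes")
  events[, req]
}

#' Save result tables with a stable column order
#'
#' Writes one CSV per table; scalar fit results (named numeric lists) are
#' written to a JSON sidecar of the same stem.
#'
#' @param tables Named list of data.frames (written as CSV) and/or named
#'   lists of scalars (written as JSON).
#' @param dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
save_results <- function(tables, dir) {
  if (!length(tables)) stop("no tables to save")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a JSON scalar-result sidecar
#' @param path JSON path.
#' @return Named list.
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
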