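#' Read and write time series as CSV
#'
#' Plain-text interchange for LFP and similar series: two columns `t`
#' (seconds) and `value`. The sampling rate is recovered from the time
#' column on read.
#'
#' @param x an [lfp].
#' @param path file path.
#' @return `write_lfp_csv` invisibly returns `path`; `read_lfp_csv` returns
#'   an [lfp].
#' @export
write_lfp_csv <- function(x, path) {
  stopifnot(inherits(x, "lfp"))
  write.csv(data.frame(t = lfp_times(x), value = x$values), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @param units unit label to attach on read.
#' @export
read_lfp_csv <- function(path, units = "uV") {
  d <- read.csv(path)
  if (!all(c("t", "value") %in% names(d)))
    stop("expected columns `t` and `value`")
  dt <- median(diff(d$t))
  lfp(d$value, fs = 1 / dt, t0 = d$t[1], units = units)
}

#' Read and write event trains as JSON
#'
#' JSON layout: `{"times_s": [...], "mode": "...", "config": {...}}`.
#'
#' @param x an [event_train].
#' @param path file path.
#' @export
write_event_train <- function(x, path) {
  stopifnot(inherits(x, "event_train"))
  jsonlite::write_json(list(times_s = x$times, mode = x$mode,
                            config = x$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_train
#' @export
read_event_train <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  event_train(as.numeric(d$times_s),
              mode = if (is.null(d$mode)) "unspecified" else d$mode,
              config = as.list(d$config))
}

#' Write a motion trace as CSV (`t,motion`)
#'
#' @param x a `"motion_trace"`.
#' @param path file path.
#' @export
write_motion_csv <- function(x, path) {
  stopifnot(inherits(x, "motion_trace"))
  tf <- (seq_along(x$values) - 1) / x$fps
  write.csv(data.frame(t = tf, motion = x$values), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @param threshold stillness threshold to embed in the trace (motion files
#'   do not carry one).
#' @param design optional [epoch_design] to attach.
#' @export
read_motion_csv <- function(path, threshold = NULL, design = NULL) {
  d <- read.csv(path)
  if (!all(c("t", "motion") %in% names(d)))
    stop("expected columns `t` and `motion`")
  dt <- median(diff(d$t))
  structure(list(values = d$motion, fps = 1 / dt, threshold = threshold,
                 bouts = matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("start", "duration"))),
                 design = design),
            class = "motion_trace")
}

#' Write freezing-scoring output as JSON
#'
#' Stores the bout list, per-epoch freezing percentages (when an epoch
#' design is available), and the frame mask as run lengths.
#'
#' @param trace a `"freezing_trace"`.
#' @param path file path.
#' @export
write_freezing_json <- function(trace, path) {
  stopifnot(inherits(trace, "freezing_trace"))
  r <- rle(trace$freezing_mask)
  out <- list(fps = trace$fps,
              bouts = trace$bouts,
              mask_run_lengths = r$lengths,
              mask_run_values = r$values)
  if (!is.null(trace$design))
    out$percent_per_epoch <- percent_freezing_per_epoch(trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ground truth of a synthetic session as JSON
#'
#' @param truth a `"theta_truth"`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "theta_truth"))
  jsonlite::write_json(list(peak_times = truth$peak_times,
                            trough_times = truth$trough_times,
                            cycle_frequencies = truth$cycle_frequencies),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
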