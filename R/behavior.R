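#' Score freezing from a motion trace
#'
#' Frames whose motion value falls below the stillness threshold are grouped
#' into runs; a run is a freezing bout only if it lasts at least
#' `min_freeze_duration` seconds (boundary inclusive — "at least 6 s");
#' shorter stillness runs are discarded entirely.
#'
#' @param motion a `"motion_trace"` (see [generate_motion_trace()]), or any
#'   list with numeric `values` and `fps`.
#' @param motion_threshold stillness threshold on the motion scale; defaults
#'   to the threshold embedded in the trace.
#' @param min_freeze_duration minimum bout duration in seconds (default 6).
#' @return Object of class `"freezing_trace"`: `fps`, `freezing_mask`
#'   (per-frame logical), `bouts` (data frame with `start`, `duration` in
#'   seconds), `design` (if carried by the trace).
#' @export
score_freezing <- function(motion, motion_threshold = NULL,
                           min_freeze_duration = 6) {
  if (is.null(motion$values) || length(motion$values) == 0L)
    stop("empty motion trace")
  if (is.null(motion$fps) || motion$fps <= 0)
    stop("motion trace must carry a positive `fps`")
  if (is.null(motion_threshold)) motion_threshold <- motion$threshold
  if (is.null(motion_threshold) || motion_threshold <= 0)
    stop("`motion_threshold` must be > 0")
  fps <- motion$fps
  still <- motion$values < motion_threshold
  r <- rle(still)
  keep <- r$values & (r$lengths / fps >= min_freeze_duration - 1e-9)
  mask <- inverse.rle(list(lengths = r$lengths, values = keep))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bouts <- data.frame(start = (starts[keep] - 1) / fps,
                      duration = r$lengths[keep] / fps)
  structure(list(fps = fps, freezing_mask = mask, bouts = bouts,
                 design = motion$design,
                 min_freeze_duration = min_freeze_duration,
                 motion_threshold = motion_threshold),
            class = "freezing_trace")
}

#' @export
print.freezing_trace <- function(x, ...) {
  cat(sprintf("<freezing_trace> %d frames @ %g fps, %d bouts, %.1f%% freezing\n",
              length(x$freezing_mask), x$fps, nrow(x$bouts),
              100 * mean(x$freezing_mask)))
  invisible(x)
}

#' Percent time freezing per epoch
#'
#' @param trace a `"freezing_trace"`.
#' @param design an [epoch_design]; defaults to the design carried by the
#'   trace. The trace must cover all epochs.
#' @return Numeric vector of percentages (0-100), one per epoch.
#' @export
percent_freezing_per_epoch <- function(trace, design = trace$design) {
  stopifnot(inherits(trace, "freezing_trace"))
  if (is.null(design)) stop("no epoch design supplied")
  stopifnot(inherits(design, "epoch_design"))
  n <- length(trace$freezing_mask)
  tf <- (seq_len(n) - 1) / trace$fps
  if (n / trace$fps < design$total - 1e-9)
    stop("trace shorter than the epoch design")
  bounds <- c(design$onsets, design$total)
  idx <- findInterval(tf, bounds, rightmost.closed = FALSE)
  idx[idx > length(design$labels)] <- NA          # frames beyond the design
  out <- numeric(length(design$labels))
  for (e in seq_along(out))
    out[e] <- 100 * mean(trace$freezing_mask[which(idx == e)])
  out
}

#' Light-induced freezing
#'
#' The stimulation-locked increase in freezing for the standard four-epoch
#' trial (No Stim / Stim / No Stim / Stim): each Stim epoch is compared with
#' the No Stim epoch that precedes it and the two differences are averaged,
#' `((e2 - e1) + (e4 - e3)) / 2`. Positive values mean stimulation increased
#' freezing.
#'
#' @param percents numeric vector of four per-epoch freezing percentages.
#' @return Light-induced freezing in percentage points.
#' @examples
#' light_induced_freezing(c(10, 25, 12, 27))  # 15
#' @export
light_induced_freezing <- function(percents) {
  if (length(percents) != 4L)
    stop("`percents` must hold exactly four epoch values")
  ((percents[2] - percents[1]) + (percents[4] - percents[3])) / 2
}

#' Subject inclusion rule
#'
#' A subject is included when its light-induced freezing reached at least
#' `min_increase` percentage points on at least `min_days` of the four
#' experiment days.
#'
#' @param per_day_lif numeric vector of four daily light-induced-freezing
#'   values (percentage points).
#' @param min_increase threshold in percentage points (default 5).
#' @param min_days minimum number of qualifying days (default 2).
#' @return `TRUE` (include) or `FALSE` (exclude).
#' @examples
#' apply_inclusion_criteria(c(6, 3, 7, 2))   # TRUE
#' apply_inclusion_criteria(c(4, 4, 4, 4))   # FALSE
#' @export
apply_inclusion_criteria <- function(per_day_lif, min_increase = 5,
                                     min_days = 2) {
  if (length(per_day_lif) != 4L)
    stop("`per_day_lif` must hold exactly four daily values")
  sum(per_day_lif >= min_increase) >= min_days
}
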