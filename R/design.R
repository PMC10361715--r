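#' Epoch design of a stimulation trial
#'
#' The experimental sessions alternate no-stimulation and stimulation blocks;
#' the standard daily trial is four 3-minute epochs in the order
#' No Stim / Stim / No Stim / Stim. Other layouts (e.g. a single continuous
#' stimulation block for algorithm benchmarking) are allowed.
#'
#' @param labels character vector of epoch labels; entries equal to `"Stim"`
#'   mark stimulation epochs, anything else is treated as no-stimulation.
#' @param epoch_duration epoch length(s) in seconds: either a single value
#'   recycled over all epochs (default 180) or one value per epoch.
#' @return An object of class `"epoch_design"` with elements `labels`,
#'   `durations`, `onsets` (epoch start times) and `total` (trial length).
#' @examples
#' epoch_design()                                  # the standard 4 x 180 s trial
#' epoch_design("Stim", 180)                       # one continuous Stim block
#' @export
epoch_design <- function(labels = c("NoStim", "Stim", "NoStim", "Stim"),
                         epoch_duration = 180) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("`labels` must name at least one epoch")
  durations <- rep_len(as.numeric(epoch_duration), length(labels))
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("`epoch_duration` entries must be positive")
  onsets <- cumsum(c(0, durations[-length(durations)]))
  structure(list(labels = labels, durations = durations,
                 onsets = onsets, total = sum(durations)),
            class = "epoch_design")
}

#' @export
print.epoch_design <- function(x, ...) {
  cat(sprintf("<epoch_design> %d epochs, %.0f s total: %s\n",
              length(x$labels), x$total,
              paste(sprintf("%s(%.0fs)", x$labels, x$durations), collapse = " ")))
  invisible(x)
}

#' Stimulation intervals of an epoch design
#'
#' @param design an [epoch_design].
#' @return Two-column matrix of `[on, off)` interval bounds in seconds, one
#'   row per Stim epoch.
#' @export
stim_intervals <- function(design) {
  stopifnot(inherits(design, "epoch_design"))
  i <- design$labels == "Stim"
  cbind(on = design$onsets[i], off = design$onsets[i] + design$durations[i])
}

#' Is a time point inside a stimulation epoch?
#'
#' @param t numeric vector of times in seconds.
#' @param design an [epoch_design].
#' @return Logical vector.
#' @export
in_stim_epoch <- function(t, design) {
  iv <- stim_intervals(design)
  out <- rep(FALSE, length(t))
  for (r in seq_len(nrow(iv)))
    out <- out | (t >= iv[r, 1] & t < iv[r, 2])
  out
}
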