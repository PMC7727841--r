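# Firmware emulation: absolute-acceleration triggering and paired 3 s cuts.

acc_norm <- function(rec) {
  with(rec$channels, sqrt(acc_x^2 + acc_y^2 + acc_z^2))
}

new_trigger_event <- function(trigger_time, source_wearable, peak_norm) {
  structure(list(trigger_time = trigger_time, source_wearable = source_wearable,
                 peak_norm = peak_norm),
            class = "trigger_event")
}

#' @export
print.trigger_event <- function(x, ...) {
  cat(sprintf("<trigger_event> t=%.3f s  source=%s  norm=%.1f m/s^2 (%.1f g)\n",
              x$trigger_time, x$source_wearable, x$peak_norm, x$peak_norm / G0))
  invisible(x)
}

#' Detect the acquisition trigger on a wearable pair
#'
#' Scans the tri-axial accelerometers of both wearables on their shared time
#' base and returns the earliest sample whose absolute acceleration — the
#' Euclidean norm of the acceleration vector, gravity included — strictly
#' exceeds the threshold. Both wearables are governed by the single event:
#' if one is triggered, so is the other. Returns `NULL` if no sample crosses.
#'
#' @param left,right `raw_recording`s sharing `t0` and duration.
#' @param threshold trigger threshold in m/s^2; default 14 g = 137.34 m/s^2.
#' @return A `trigger_event` (time, source wearable, norm at the crossing) or
#'   `NULL`.
#' @export
detect_trigger <- function(left, right, threshold = 14 * G0) {
  stopifnot(inherits(left, "raw_recording"), inherits(right, "raw_recording"),
            threshold > 0)
  if (left$t0 != right$t0 || left$duration != right$duration)
    stop("recordings do not share a time base")
  fs <- 1000
  hits <- lapply(list(left = left, right = right), function(rec) {
    nrm <- acc_norm(rec)
    i <- which(nrm > threshold)
    if (!length(i)) NULL else
      list(t = rec$t0 + (i[1] - 1) / fs, norm = nrm[i[1]])
  })
  hits <- Filter(Negate(is.null), hits)
  if (!length(hits)) return(NULL)
  times <- vapply(hits, `[[`, numeric(1), "t")
  first <- names(hits)[order(times)][1]  # earliest; ties resolve to left
  new_trigger_event(hits[[first]]$t, first, hits[[first]]$norm)
}

cut_channel <- function(x, fs, t0, from, to) {
  # samples with t in [from, to): half-open, the trigger sample is post
  i0 <- ceiling(round((from - t0) * fs, 9))
  n_out <- round((to - from) * fs)
  if (i0 < 0 || i0 + n_out > length(x))
    stop("segment window [", from, ", ", to, ") s exceeds the recording; ",
         "the firmware needs 1 s of pre-trigger data and 2 s after")
  x[(i0 + 1):(i0 + n_out)]
}

#' Cut the synchronous 3 s attempt segment around a trigger
#'
#' Cuts every channel of both wearables to the half-open window
#' `[trigger - 1 s, trigger + 2 s)`, so a channel sampled at `fs` yields
#' exactly `3 * fs` samples (3000 at 1 kHz, 300 at 100 Hz, 24,000 at 8 kHz).
#' The label is copied from the recording.
#'
#' @param left,right `raw_recording`s covering the window.
#' @param event a `trigger_event` from [detect_trigger()].
#' @return An `attempt_segment`: per-wearable channel lists at native rates,
#'   the trigger, the window start time and the label.
#' @export
segment_attempt <- function(left, right, event) {
  stopifnot(inherits(event, "trigger_event"))
  spec <- sensor_channels()
  from <- event$trigger_time - 1
  to <- event$trigger_time + 2
  cut_all <- function(rec) {
    out <- lapply(setNames(nm = spec$name), function(ch)
      cut_channel(rec$channels[[ch]], spec$fs[spec$name == ch], rec$t0,
                  from, to))
    out
  }
  structure(list(left = cut_all(left), right = cut_all(right),
                 t_start = from, trigger = event, label = left$label,
                 scenario = left$scenario),
            class = "attempt_segment")
}

#' @export
print.attempt_segment <- function(x, ...) {
  cat(sprintf("<attempt_segment> label=%s  window=[%.3f, %.3f) s\n",
              x$label, x$t_start, x$t_start + 3))
  invisible(x)
}
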