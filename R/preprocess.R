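# Preparation of a 3 s two-wrist segment into the fixed 18,400 x 20 input.

#' Linear resampling onto a uniform output grid
#'
#' Upsamples `x` (sampled at `fs_in`, half-open convention: `n` samples cover
#' `n / fs_in` seconds) onto the uniform `fs_out` grid spanning the same
#' interval, by exact linear interpolation between neighbouring input
#' samples; output points beyond the last input sample hold its value.
#'
#' @param x numeric samples.
#' @param fs_in,fs_out input and output sampling frequencies in Hz,
#'   `fs_out >= fs_in > 0`.
#' @return Numeric vector of length `length(x) * fs_out / fs_in`.
#' @export
#' @examples
#' resample_linear(c(0, 1, 2), 1, 4)   # a ramp is reproduced exactly
resample_linear <- function(x, fs_in, fs_out) {
  if (!length(x)) stop("empty input")
  if (length(x) < 2) stop("need at least 2 samples to interpolate")
  stopifnot(fs_in > 0, fs_out >= fs_in)
  n_out <- round(length(x) * fs_out / fs_in)
  if (fs_out == fs_in) return(x)
  approx(x = (seq_along(x) - 1) / fs_in, y = x,
         xout = (seq_len(n_out) - 1) / fs_out, method = "linear", rule = 2)$y
}

#' Cut the first part of an 8 kHz signal
#'
#' Removes the first `cut` seconds (default 0.7 s, i.e. 5600 samples at
#' 8 kHz) to discard irrelevant data and artefacts at the segment head,
#' turning a 24,000-sample channel into 18,400 samples.
#'
#' @param x samples at `fs` Hz.
#' @param cut seconds to remove from the head.
#' @param fs sampling frequency (default 8000 Hz).
#' @return `x` without its first `cut * fs` samples.
#' @export
trim_head <- function(x, cut = 0.7, fs = 8000) {
  n_cut <- round(cut * fs)
  if (n_cut == 0) return(x)
  if (length(x) <= n_cut)
    stop("input of ", length(x), " samples is too short to cut ",
         cut, " s (", n_cut, " samples)")
  x[-seq_len(n_cut)]
}

#' Column order of the network input matrix
#'
#' Fixed, versioned channel order: the ten left-wrist channels (acceleration
#' x/y/z, spin rate x/y/z, flux density x/y/z, audio) followed by the same
#' ten for the right wrist. Pressure is excluded.
#'
#' @return Character vector of 20 column names; the order version is attached
#'   as attribute `version`.
#' @export
input_channel_names <- function() {
  chs <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
           "mag_x", "mag_y", "mag_z", "audio")
  structure(c(paste0("left_", chs), paste0("right_", chs)), version = "1")
}

# column indices of each sensor group across both wrists
channel_group_columns <- function() {
  nm <- input_channel_names()
  list(accelerometer = grep("_acc_", nm),
       audio = grep("_audio$", nm),
       gyroscope = grep("_gyro_", nm),
       magnetometer = grep("_mag_", nm))
}

#' Build the 18,400 x 20 network input from an attempt segment
#'
#' Every channel of both wearables is linearly upsampled to 8 kHz, the first
#' 0.7 s are cut from all signals, the pressure channel is dropped, and the
#' two wearables are merged into a single matrix of 18,400 time steps by 20
#' channels, columns ordered per [input_channel_names()]. Audio is already at
#' 8 kHz and bypasses interpolation. No amplitude normalization is applied.
#'
#' @param segment an `attempt_segment` from [segment_attempt()].
#' @param cut head cut in seconds (default 0.7).
#' @return An `input_matrix`: numeric matrix with attributes `label` and
#'   `channel_version`.
#' @export
build_input_matrix <- function(segment, cut = 0.7) {
  stopifnot(inherits(segment, "attempt_segment"))
  spec <- sensor_channels()
  fs_out <- 8000
  one <- function(w, ch) {
    x <- segment[[w]][[ch]]
    if (is.null(x)) stop("segment is missing channel ", ch, " on ", w)
    trim_head(resample_linear(x, spec$fs[spec$name == ch], fs_out), cut, fs_out)
  }
  nm <- input_channel_names()
  cols <- lapply(nm, function(full) {
    w <- sub("_.*$", "", full)
    ch <- sub("^(left|right)_", "", full)
    one(w, ch)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  structure(m, label = segment$label, channel_version = attr(nm, "version"),
            class = c("input_matrix", class(m)))
}

#' Materialize, acquire and preprocess a whole manifest
#'
#' Runs the full front end for every attempt of a manifest: materialize the
#' recordings, detect the trigger, cut the 3 s segment, and build the
#' 18,400 x 20 input matrix. Attempts that never cross the trigger threshold
#' are dropped with a warning (the firmware would never have recorded them).
#'
#' @param manifest an `attempt_manifest` from [generate_dataset()].
#' @param threshold_g trigger threshold in g (default 14).
#' @param verbose print progress every 50 attempts.
#' @return An `attempt_dataset`: list with `x` (3-D array, 18,400 x 20 x n),
#'   `y` (factor of labels, levels catch/drop), `ids`, `manifest`.
#' @export
build_dataset <- function(manifest, threshold_g = 14, verbose = FALSE) {
  stopifnot(inherits(manifest, "attempt_manifest"))
  n <- nrow(manifest)
  x <- array(NA_real_, c(18400L, 20L, n),
             dimnames = list(NULL, input_channel_names(), manifest$id))
  keep <- logical(n)
  for (i in seq_len(n)) {
    rec <- materialize_attempt(manifest, i)
    ev <- detect_trigger(rec$left, rec$right, threshold = threshold_g * G0)
    if (is.null(ev)) {
      warning("attempt ", manifest$id[i], " never crossed the trigger; dropped")
      next
    }
    seg <- segment_attempt(rec$left, rec$right, ev)
    x[, , i] <- build_input_matrix(seg)
    keep[i] <- TRUE
    if (verbose && i %% 50 == 0)
      message("  preprocessed ", i, "/", n, " attempts")
  }
  if (!all(keep)) x <- x[, , keep, drop = FALSE]
  structure(list(x = x,
                 y = factor(manifest$outcome[keep], levels = c("catch", "drop")),
                 ids = manifest$id[keep],
                 manifest = manifest[keep, , drop = FALSE]),
            class = "attempt_dataset")
}

#' @export
print.attempt_dataset <- function(x, ...) {
  cat("<attempt_dataset> ", length(x$ids), " attempts (",
      sum(x$y == "catch"), " catches, ", sum(x$y == "drop"), " drops), ",
      "input ", nrow(x$x), " x ", ncol(x$x), "\n", sep = "")
  invisible(x)
}
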