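#' @useDynLib catchsense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif rbinom median sd setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

# standard gravity used to convert thresholds given in g to m/s^2
G0 <- 9.81

#' Sensor channel specifications of the wrist wearable
#'
#' Per-channel native sampling rate, physical range and resolution of the
#' sensor platform: tri-axial acceleration (1 kHz, +-16 g i.e. +-156.96 m/s^2),
#' tri-axial spin rate (1 kHz, +-1000 deg/s), tri-axial magnetic flux density
#' (100 Hz, +-5 mT), audio (8 kHz, normalized 16-bit counts covering a
#' 0-122.5 dBSPL microphone) and absolute pressure (100 Hz, 260-1260 hPa).
#' All channels are quantized to 16 bit.
#'
#' @return A data.frame with one row per channel: `name`, `group`
#'   (accelerometer/gyroscope/magnetometer/audio/pressure), `fs` (Hz),
#'   `range_lo`, `range_hi` (channel units), `resolution_bits`.
#' @export
#' @examples
#' sensor_channels()
sensor_channels <- function() {
  acc_lim <- 16 * G0  # 156.96 m/s^2
  df <- rbind(
    data.frame(name = c("acc_x", "acc_y", "acc_z"), group = "accelerometer",
               fs = 1000, range_lo = -acc_lim, range_hi = acc_lim),
    data.frame(name = c("gyro_x", "gyro_y", "gyro_z"), group = "gyroscope",
               fs = 1000, range_lo = -1000, range_hi = 1000),
    data.frame(name = c("mag_x", "mag_y", "mag_z"), group = "magnetometer",
               fs = 100, range_lo = -5, range_hi = 5),
    data.frame(name = "audio", group = "audio",
               fs = 8000, range_lo = -1, range_hi = 1),
    data.frame(name = "pressure", group = "pressure",
               fs = 100, range_lo = 260, range_hi = 1260)
  )
  df$resolution_bits <- 16L
  stopifnot(all(df$fs > 0), all(df$range_lo < df$range_hi))
  df
}

channel_fs <- function(name) {
  spec <- sensor_channels()
  fs <- spec$fs[match(name, spec$name)]
  if (anyNA(fs)) stop("unknown channel: ", paste(name[is.na(fs)], collapse = ", "))
  fs
}

#' Clip and quantize samples to a channel's 16-bit grid
#'
#' Samples are clipped to `[range_lo, range_hi]` and rounded to the nearest
#' point of the uniform grid with `2^bits` levels spanning the range, the way
#' a 16-bit ADC stores them.
#'
#' @param x numeric samples in channel units.
#' @param range_lo,range_hi physical limits of the channel.
#' @param bits resolution (default 16).
#' @return Quantized numeric vector, elementwise within the range.
#' @export
quantize_channel <- function(x, range_lo, range_hi, bits = 16L) {
  stopifnot(range_lo < range_hi, bits >= 1)
  step <- (range_hi - range_lo) / (2^bits - 1)
  x <- pmin(pmax(x, range_lo), range_hi)
  range_lo + round((x - range_lo) / step) * step
}

quantize_to_spec <- function(x, name) {
  spec <- sensor_channels()
  i <- match(name, spec$name)
  if (is.na(i)) stop("unknown channel: ", name)
  quantize_channel(x, spec$range_lo[i], spec$range_hi[i], spec$resolution_bits[i])
}
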