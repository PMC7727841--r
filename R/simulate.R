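# Synthetic two-wrist attempt simulator.
#
# An attempt is modelled in four contiguous phases: starting pose (quiet,
# gravity only), positioning (band-limited movement noise, sharper for
# novices), catching (a short, large impulse in acceleration, spin rate and
# audio when the ball first contacts the hands) and post-impact. The
# post-impact phase carries the class signal: both outcomes share a damped
# oscillation that settles into the carry pose, while a drop additionally
# shows a secondary impact (ball leaving/striking again), sustained movement
# noise, an audio burst and a diverging orientation trajectory in the
# magnetometer. All drop-specific terms scale linearly with `class_effect`,
# so `class_effect = 0` makes the two classes statistically identical.

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

# band-limited Gaussian noise: white noise on a coarse grid at ~2*cutoff Hz,
# linearly interpolated to the target grid
smooth_noise <- function(n, fs, cutoff) {
  if (n == 1L) return(rnorm(1))
  if (cutoff >= fs / 2) return(rnorm(n))
  m <- max(4L, ceiling(n / fs * 2 * cutoff) + 2L)
  z <- rnorm(m)
  approx(seq(0, 1, length.out = m), z, xout = seq(0, 1, length.out = n))$y
}

rand_unit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Default simulator parameters
#'
#' Amplitude, timing and noise parameters of the four-phase attempt model.
#' Units: accelerations in m/s^2 (peaks in g, converted with g = 9.81 m/s^2),
#' spin rates in deg/s, flux density in mT, audio in normalized counts,
#' durations in seconds.
#'
#' @param class_effect scales every drop-specific signal component
#'   (secondary impact, sustained post-impact noise, orientation drift, audio
#'   burst). 1 is the default study-emulation strength; 0 removes all class
#'   differences (null simulator).
#' @param effect_accelerometer,effect_gyroscope,effect_magnetometer,effect_audio
#'   per-sensor-group multipliers on the drop-specific components, used to
#'   plant the class signal in selected channel groups only.
#' @param ... overrides for the remaining named defaults (see the returned
#'   list; e.g. `impact_peak_g`, `pos_sd_acc`, `sec_delay_s`).
#' @return Named list of simulator parameters.
#' @export
sim_params <- function(class_effect = 1,
                       effect_accelerometer = 1, effect_gyroscope = 1,
                       effect_magnetometer = 1, effect_audio = 1, ...) {
  p <- list(
    class_effect = class_effect,
    effect_accelerometer = effect_accelerometer,
    effect_gyroscope = effect_gyroscope,
    effect_magnetometer = effect_magnetometer,
    effect_audio = effect_audio,
    # phase layout
    impact_margin_s = c(1.1, 2.1),   # min time before / after the impact
    positioning_dur_s = 0.6,
    catching_dur_s = 0.15,
    # accelerometer (m/s^2 unless stated in g)
    start_sd_acc = 0.5, pos_sd_acc = 6, carry_sd_acc = 1.5,
    drop_extra_sd_acc = 5,
    noise_cutoff_hz = 30,
    impact_peak_g = c(18, 45), pulse_width_s = 0.004,
    offhand_frac = c(0.35, 0.75), twohand_frac = c(0.75, 1),
    ring_freq_hz = 60, ring_tau_s = 0.05, ring_frac = 0.4,
    catch_osc_freq_hz = 10, catch_osc_amp_acc = 25, catch_osc_tau_s = 0.3,
    sec_delay_s = c(0.25, 0.55), sec_peak_g = c(6, 14),
    sec_pulse_width_s = 0.006,
    # gyroscope (deg/s)
    start_sd_gyro = 15, pos_sd_gyro = 60, carry_sd_gyro = 20,
    drop_extra_sd_gyro = 120,
    impact_peak_gyro = c(300, 800), ring_amp_gyro = 200,
    catch_osc_amp_gyro = 100, sec_peak_gyro = c(100, 250),
    # magnetometer (mT, rad)
    mag_field_mT = 0.05, mag_noise_sd = 0.001, mag_walk_sd = 0.25,
    mag_impact_turn_sd = 0.6, drop_drift_rps = c(0.5, 1.5),
    # audio (normalized counts)
    audio_bg_sd_indoor = 0.004, audio_bg_sd_outdoor = 0.008,
    audio_impact_amp = 0.5, audio_burst_tau_s = 0.03, audio_sec_amp = 0.3,
    # pressure (hPa)
    pressure_base_hPa = 1013, pressure_noise_sd = 0.03,
    # athlete-level positioning sharpness
    athlete_factor = c(novice = 1.4, advanced = 1, expert = 0.8)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown simulator parameter(s): ", paste(unknown, collapse = ", "))
  modifyList(p, dots)
}

new_raw_recording <- function(wearable_id, channels, duration, scenario) {
  spec <- sensor_channels()
  for (ch in spec$name) {
    n_expect <- round(duration * spec$fs[spec$name == ch])
    if (abs(length(channels[[ch]]) - n_expect) > 1L)
      stop("channel ", ch, " has ", length(channels[[ch]]),
           " samples, expected ", n_expect)
  }
  structure(list(wearable_id = wearable_id, t0 = 0, duration = duration,
                 channels = channels, scenario = scenario,
                 label = scenario$outcome),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> wearable=", x$wearable_id, " label=", x$label,
      " duration=", x$duration, "s\n", sep = "")
  for (ch in names(x$channels))
    cat("  ", format(ch, width = 9), length(x$channels[[ch]]), "samples\n")
  invisible(x)
}

# one wrist's channel set, given the shared attempt latent state
sim_wrist <- function(shared, sc, p, duration) {
  t_imp <- shared$t_imp
  t_pos <- t_imp - p$positioning_dur_s
  t_end_catch <- t_imp + p$catching_dur_s
  ce <- p$class_effect * (sc$outcome == "drop")
  afac <- p$athlete_factor[[sc$athlete_level]]

  ## accelerometer, 1 kHz -------------------------------------------------
  fs <- 1000
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  tilt1 <- 0.15 * smooth_noise(n, fs, 0.8)
  tilt2 <- 0.15 * smooth_noise(n, fs, 0.8)
  grav <- G0 * cbind(sin(tilt1), sin(tilt2) * cos(tilt1), cos(tilt2) * cos(tilt1))
  sd_env <- rep(p$start_sd_acc, n)
  sd_env[t >= t_pos & t < t_imp] <- p$pos_sd_acc * afac
  sd_env[t >= t_imp] <- p$carry_sd_acc
  sd_env[t >= t_end_catch] <- p$carry_sd_acc +
    p$drop_extra_sd_acc * ce * p$effect_accelerometer
  acc <- grav + sapply(1:3, function(i)
    smooth_noise(n, fs, p$noise_cutoff_hz) * sd_env)
  pulse <- exp(-0.5 * ((t - t_imp) / p$pulse_width_s)^2)
  A <- shared$peak_g[[shared$this]] * G0
  acc <- acc + outer(pulse, shared$dir * A)
  ring <- ifelse(t >= t_imp,
                 exp(-(t - t_imp) / p$ring_tau_s) *
                   sin(2 * pi * p$ring_freq_hz * (t - t_imp)), 0)
  acc <- acc + outer(ring, rand_unit3() * p$ring_frac * min(A, 16 * G0))
  osc <- ifelse(t >= t_end_catch,
                exp(-(t - t_end_catch) / p$catch_osc_tau_s) *
                  sin(2 * pi * p$catch_osc_freq_hz * (t - t_end_catch)), 0)
  acc <- acc + outer(osc, rand_unit3() * p$catch_osc_amp_acc)
  pulse2 <- exp(-0.5 * ((t - shared$t_sec) / p$sec_pulse_width_s)^2)
  acc <- acc + outer(pulse2, shared$sec_dir *
                       shared$sec_peak_g * G0 * ce * p$effect_accelerometer)

  ## gyroscope, 1 kHz -----------------------------------------------------
  sd_g <- rep(p$start_sd_gyro, n)
  sd_g[t >= t_pos & t < t_imp] <- p$pos_sd_gyro * afac
  sd_g[t >= t_imp] <- p$carry_sd_gyro
  sd_g[t >= t_end_catch] <- p$carry_sd_gyro +
    p$drop_extra_sd_gyro * ce * p$effect_gyroscope
  gyr <- sapply(1:3, function(i) smooth_noise(n, fs, p$noise_cutoff_hz) * sd_g)
  gyr <- gyr + outer(pulse, rand_unit3() * shared$gyro_peak)
  gyr <- gyr + outer(ring, rand_unit3() * p$ring_amp_gyro)
  gyr <- gyr + outer(osc, rand_unit3() * p$catch_osc_amp_gyro)
  gyr <- gyr + outer(pulse2, rand_unit3() *
                       shared$sec_peak_gyro * ce * p$effect_gyroscope)

  ## magnetometer, 100 Hz ---------------------------------------------------
  fs_m <- 100
  n_m <- round(duration * fs_m)
  tm <- (seq_len(n_m) - 1) / fs_m
  s_imp <- pmin(1, pmax(0, (tm - t_imp) / 0.1))  # smoothed impact turn
  yaw <- p$mag_walk_sd * smooth_noise(n_m, fs_m, 0.5) + shared$yaw_jump * s_imp +
    ce * p$effect_magnetometer * shared$drift_rps *
      pmax(0, tm - t_end_catch)
  pitch <- 0.5 * p$mag_walk_sd * smooth_noise(n_m, fs_m, 0.5) +
    shared$pitch_jump * s_imp
  B <- p$mag_field_mT * cbind(cos(yaw) * cos(pitch), sin(yaw) * cos(pitch),
                              sin(pitch)) +
    matrix(rnorm(3 * n_m, sd = p$mag_noise_sd), n_m, 3)

  ## audio, 8 kHz -----------------------------------------------------------
  fs_a <- 8000
  n_a <- round(duration * fs_a)
  ta <- (seq_len(n_a) - 1) / fs_a
  bg_sd <- if (sc$environment == "outdoor") p$audio_bg_sd_outdoor else
    p$audio_bg_sd_indoor
  env_imp <- ifelse(ta >= t_imp, exp(-(ta - t_imp) / p$audio_burst_tau_s), 0)
  env_sec <- ifelse(ta >= shared$t_sec,
                    exp(-(ta - shared$t_sec) / p$audio_burst_tau_s), 0)
  audio <- rnorm(n_a, sd = bg_sd) +
    rnorm(n_a) * env_imp * p$audio_impact_amp +
    rnorm(n_a) * env_sec * p$audio_sec_amp * ce * p$effect_audio

  ## pressure, 100 Hz ---------------------------------------------------------
  pres <- p$pressure_base_hPa + shared$pressure_offset +
    0.2 * sin(2 * pi * 0.1 * tm) + rnorm(n_m, sd = p$pressure_noise_sd)

  channels <- list(
    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
    gyro_x = gyr[, 1], gyro_y = gyr[, 2], gyro_z = gyr[, 3],
    mag_x = B[, 1], mag_y = B[, 2], mag_z = B[, 3],
    audio = audio, pressure = pres
  )
  lapply(setNames(nm = names(channels)), function(ch)
    quantize_to_spec(channels[[ch]], ch))
}

#' Simulate one two-wrist attempt
#'
#' Generates the left and right wearable recordings of a single catch or drop
#' attempt. Both wrists share the impact timing and scenario (paired
#' triggering presumes a near-simultaneous event) but receive independent
#' noise and slightly different impact magnitudes; for one-handed and body
#' catches the off hand sees a reduced impact. All samples are clipped to the
#' sensor ranges and quantized to 16 bit, so hard impacts saturate the
#' accelerometer at +-156.96 m/s^2 exactly as a real +-16 g sensor would.
#'
#' @param scenario an [attempt_scenario()].
#' @param duration recording length in seconds, at least 4 so that a 1 s
#'   pre-trigger / 2 s post-trigger window fits around the impact.
#' @param seed integer seed; the same (scenario, duration, seed) always
#'   reproduces bit-identical recordings.
#' @param params simulator parameters from [sim_params()].
#' @return List with elements `left` and `right`, each a `raw_recording`.
#' @export
#' @examples
#' rec <- generate_attempt(attempt_scenario("catch"), seed = 1)
#' max(sqrt(rec$left$channels$acc_x^2 + rec$left$channels$acc_y^2 +
#'          rec$left$channels$acc_z^2)) / 9.81   # peak in g, > 14
generate_attempt <- function(scenario, duration = 4, seed,
                             params = sim_params()) {
  if (!inherits(scenario, "attempt_scenario"))
    scenario <- do.call(attempt_scenario, as.list(scenario))
  if (duration < 4)
    stop("duration must be >= 4 s so the 1 s pre / 2 s post trigger window ",
         "fits around the impact (got ", duration, " s)")
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required")
  p <- params
  with_preserved_rng({
    set.seed(as.integer(seed))
    lo <- p$impact_margin_s[1]; hi <- duration - p$impact_margin_s[2]
    catching_hand <- sample(c("left", "right"), 1)
    frac <- if (scenario$catch_style == "two_handed")
      runif(1, p$twohand_frac[1], p$twohand_frac[2]) else
      runif(1, p$offhand_frac[1], p$offhand_frac[2])
    peak <- runif(1, p$impact_peak_g[1], p$impact_peak_g[2])
    shared <- list(
      t_imp = runif(1, lo, hi),
      dir = rand_unit3(),
      peak_g = if (catching_hand == "left")
        list(left = peak, right = peak * frac) else
        list(left = peak * frac, right = peak),
      gyro_peak = runif(1, p$impact_peak_gyro[1], p$impact_peak_gyro[2]),
      sec_peak_g = runif(1, p$sec_peak_g[1], p$sec_peak_g[2]),
      sec_peak_gyro = runif(1, p$sec_peak_gyro[1], p$sec_peak_gyro[2]),
      sec_dir = rand_unit3(),
      yaw_jump = rnorm(1, sd = p$mag_impact_turn_sd),
      pitch_jump = rnorm(1, sd = 0.5 * p$mag_impact_turn_sd),
      drift_rps = sample(c(-1, 1), 1) *
        runif(1, p$drop_drift_rps[1], p$drop_drift_rps[2]),
      pressure_offset = runif(1, -5, 5)
    )
    shared$t_sec <- shared$t_imp + runif(1, p$sec_delay_s[1], p$sec_delay_s[2])
    out <- list()
    for (w in c("left", "right")) {
      shared$this <- w
      out[[w]] <- new_raw_recording(w, sim_wrist(shared, scenario, p, duration),
                                    duration, scenario)
    }
    out
  })
}

#' Quiet recording pair with a single calibrated impulse
#'
#' A gravity-only, noise-free recording pair whose left accelerometer carries
#' one short triangular impulse along the gravity axis so that the recorded
#' acceleration-norm peak equals `peak_g` (in g) exactly, up to 16-bit
#' quantization. Used to calibrate/verify the acquisition trigger threshold
#' by sweeping `peak_g`.
#'
#' @param peak_g impulse peak of the acceleration norm, in g.
#' @param t_impact impulse centre (s), snapped to the 1 kHz sample grid.
#' @param duration recording length (s).
#' @return List with `left` and `right` raw recordings (label "catch").
#' @export
impulse_recording <- function(peak_g, t_impact = 1.5, duration = 4) {
  fs <- 1000
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  t_impact <- round(t_impact * fs) / fs
  width <- 0.004
  tri <- pmax(0, 1 - abs(t - t_impact) / width)
  az <- G0 + (peak_g * G0 - G0) * tri
  zero1k <- numeric(n); zero100 <- numeric(round(duration * 100))
  zero8k <- numeric(round(duration * 8000))
  base <- list(acc_x = zero1k, acc_y = zero1k, acc_z = rep(G0, n),
               gyro_x = zero1k, gyro_y = zero1k, gyro_z = zero1k,
               mag_x = zero100, mag_y = zero100, mag_z = zero100,
               audio = zero8k, pressure = rep(1013, length(zero100)))
  q <- function(chs) lapply(setNames(nm = names(chs)), function(ch)
    quantize_to_spec(chs[[ch]], ch))
  sc <- attempt_scenario("catch")
  left <- base; left$acc_z <- az
  list(left = new_raw_recording("left", q(left), duration, sc),
       right = new_raw_recording("right", q(base), duration, sc))
}

#' Study-emulation dataset configuration
#'
#' Default composition mirrors the study: 759 attempts, 541 catches and
#' 218 drops, with scenario conditions drawn uniformly from the condition
#' grid of [scenario_levels()].
#'
#' @param n_catch,n_drop class counts (both must be positive).
#' @param duration per-attempt recording length (s).
#' @param params simulator parameters, see [sim_params()].
#' @return Object of class `dataset_config`.
#' @export
dataset_config <- function(n_catch = 541, n_drop = 218, duration = 4,
                           params = sim_params()) {
  if (n_catch < 1 || n_drop < 1)
    stop("class counts must be positive (got catch=", n_catch,
         ", drop=", n_drop, ")")
  structure(list(n_catch = as.integer(n_catch), n_drop = as.integer(n_drop),
                 duration = duration, params = params),
            class = "dataset_config")
}

#' Generate a dataset manifest of simulated attempts
#'
#' Draws a scenario and a per-attempt seed for every attempt, in shuffled
#' class order. The manifest is the dataset: recordings are materialized on
#' demand from the stored seeds with [materialize_attempt()], so identical
#' (config, seed) always reproduce identical samples.
#'
#' @param config a [dataset_config()].
#' @param seed master integer seed.
#' @return A data.frame of class `attempt_manifest` with columns `id`,
#'   `outcome`, the scenario condition fields, `duration` and `seed`; the
#'   simulator parameters are attached as attribute `params`.
#' @export
#' @examples
#' m <- generate_dataset(dataset_config(n_catch = 3, n_drop = 2), seed = 1)
#' table(m$outcome)
generate_dataset <- function(config = dataset_config(), seed) {
  stopifnot(inherits(config, "dataset_config"))
  if (missing(seed)) stop("an integer seed is required")
  with_preserved_rng({
    set.seed(as.integer(seed))
    n <- config$n_catch + config$n_drop
    outcome <- sample(rep(c("catch", "drop"), c(config$n_catch, config$n_drop)))
    rows <- lapply(seq_len(n), function(i) {
      sc <- random_scenario(outcome[i])
      as.data.frame(unclass(sc), stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    manifest <- cbind(id = sprintf("attempt_%04d", seq_len(n)), manifest)
    manifest$duration <- config$duration
    manifest$seed <- sample.int(.Machine$integer.max - 1L, n)
    attr(manifest, "params") <- config$params
    class(manifest) <- c("attempt_manifest", "data.frame")
    manifest
  })
}

#' Materialize one attempt of a manifest
#'
#' @param manifest an `attempt_manifest` from [generate_dataset()].
#' @param i row index.
#' @return The left/right recording pair for attempt `i`.
#' @export
materialize_attempt <- function(manifest, i) {
  row <- manifest[i, , drop = FALSE]
  sc <- attempt_scenario(row$outcome, row$pass_source, row$movement,
                         row$positioning, row$pass_style, row$catch_style,
                         row$athlete_level, row$environment)
  generate_attempt(sc, duration = row$duration, seed = row$seed,
                   params = attr(manifest, "params") %||% sim_params())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold baseline classifier on post-impact acceleration energy
#'
#' A deliberately simple, training-free sanity baseline used to verify that
#' the simulated classes are separable at all: it measures the RMS of the
#' dynamic acceleration norm (norm minus its median) 0.5-2 s after the
#' trigger, averaged over both wrists. A settled (caught) attempt decays
#' quickly; a drop keeps moving. Degenerate segments with no measurable
#' impact default to "drop".
#'
#' @param segment an `attempt_segment` (see [segment_attempt()]).
#' @param threshold RMS decision threshold in m/s^2.
#' @return "catch" or "drop".
#' @export
oracle_classify <- function(segment, threshold = 4) {
  stopifnot(inherits(segment, "attempt_segment"))
  fs <- 1000
  rms_in <- function(w, t0, t1) {
    a <- sqrt(w$acc_x^2 + w$acc_y^2 + w$acc_z^2)
    dyn <- a - median(a)
    i <- seq_len(length(a)) - 1
    t <- i / fs
    sqrt(mean(dyn[t >= t0 & t < t1]^2))
  }
  late <- mean(c(rms_in(segment$left, 1.5, 3), rms_in(segment$right, 1.5, 3)))
  impact <- max(rms_in(segment$left, 0.95, 1.2), rms_in(segment$right, 0.95, 1.2))
  if (impact < 1) return("drop")
  if (late > threshold) "drop" else "catch"
}
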