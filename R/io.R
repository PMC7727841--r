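# Columnar file I/O: long-format CSV per wearable per attempt
# (channel, t, value), CSV manifests with a YAML parameter sidecar, and JSON
# reports.

#' Write one wearable recording as long-format CSV
#'
#' Columns: `channel`, `t` (seconds on the shared time base), `value`
#' (channel units). Label and scenario travel in the attempt's metadata file,
#' see [write_attempt()].
#'
#' @param rec a `raw_recording`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  spec <- sensor_channels()
  parts <- lapply(spec$name, function(ch) {
    x <- rec$channels[[ch]]
    data.frame(channel = ch,
               t = rec$t0 + (seq_along(x) - 1) / spec$fs[spec$name == ch],
               value = x)
  })
  write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

read_recording_csv <- function(path, wearable_id, duration, scenario) {
  df <- read.csv(path)
  channels <- split(df$value, df$channel)
  channels <- lapply(channels, as.numeric)
  new_raw_recording(wearable_id, channels[sensor_channels()$name],
                    duration, scenario)
}

#' Write a two-wrist attempt (recordings + metadata)
#'
#' Writes `<id>_left.csv`, `<id>_right.csv` and `<id>_meta.json` (scenario,
#' label, duration) into `dir`.
#'
#' @param pair list with `left` and `right` raw recordings.
#' @param dir output directory (created if needed).
#' @param id attempt identifier used as the file stem.
#' @return `dir`, invisibly.
#' @export
write_attempt <- function(pair, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording(pair$left, file.path(dir, paste0(id, "_left.csv")))
  write_recording(pair$right, file.path(dir, paste0(id, "_right.csv")))
  meta <- c(unclass(pair$left$scenario), list(duration = pair$left$duration))
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a two-wrist attempt written by [write_attempt()]
#'
#' @param dir directory containing the attempt files.
#' @param id attempt identifier.
#' @return List with `left` and `right` raw recordings.
#' @export
read_attempt <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  sc <- do.call(attempt_scenario, meta[names(meta) != "duration"])
  list(left = read_recording_csv(file.path(dir, paste0(id, "_left.csv")),
                                 "left", meta$duration, sc),
       right = read_recording_csv(file.path(dir, paste0(id, "_right.csv")),
                                  "right", meta$duration, sc))
}

#' Write / read a dataset manifest
#'
#' The manifest CSV carries one row per attempt (id, scenario fields, label,
#' duration, seed); the simulator parameters go to a YAML sidecar
#' `<stem>_params.yaml` so the dataset is reproducible from the two files
#' alone.
#'
#' @param manifest an `attempt_manifest`.
#' @param path CSV file.
#' @return `path` (write) / the manifest (read), invisibly for write.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "_params.yaml", path)
  # named vectors go out as mappings so their names survive the round trip
  params <- lapply(attr(manifest, "params"), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(params, sidecar)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$duration <- as.numeric(df$duration)
  df$seed <- as.integer(df$seed)
  sidecar <- sub("\\.csv$", "_params.yaml", path)
  params <- if (file.exists(sidecar))
    modifyList(sim_params(), yaml::read_yaml(sidecar)) else sim_params()
  attr(df, "params") <- params
  class(df) <- c("attempt_manifest", "data.frame")
  df
}

#' Write an evaluation report as JSON (+ CSV accuracy table)
#'
#' @param report an `evaluation_report` from [run_iterations()].
#' @param path JSON file; the per-training accuracy table additionally goes
#'   to `<stem>_accuracies.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    mean_accuracy = report$mean_accuracy,
    optimizer = report$optimizer,
    k = report$k, trainings = report$trainings, seed = report$seed,
    accuracies = report$accuracies,
    confusion_test = as.data.frame(report$confusion_test),
    confusion_whole = as.data.frame(report$confusion_whole),
    confusion_last_val = as.data.frame(report$confusion_last_val),
    misprediction_counts = as.list(report$misprediction_counts),
    n_misprediction_events = report$n_misprediction_events,
    package_version = as.character(utils::packageVersion("catchsense"))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  write.csv(report$accuracies, sub("\\.json$", "_accuracies.csv", path),
            row.names = FALSE)
  invisible(path)
}

#' Plot a normalized confusion matrix
#'
#' @param m 2 x 2 matrix from [confusion_matrix()].
#' @param file optional PNG path; when given, the plot is written there.
#' @param main plot title.
#' @return `NULL`, invisibly.
#' @export
plot_confusion <- function(m, file = NULL, main = "Confusion matrix") {
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::image(1:2, 1:2, t(m[2:1, ]), axes = FALSE, xlab = "predicted",
                  ylab = "true", main = main,
                  col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE),
                  zlim = c(0, 1))
  graphics::axis(1, at = 1:2, labels = colnames(m))
  graphics::axis(2, at = 1:2, labels = rev(rownames(m)))
  for (i in 1:2) for (j in 1:2)
    graphics::text(j, 3 - i, sprintf("%.3f", m[i, j]))
  invisible(NULL)
}

#' Plot the misprediction recurrence histogram
#'
#' @param report an `evaluation_report`.
#' @param file optional PNG path.
#' @return `NULL`, invisibly.
#' @export
plot_misprediction_histogram <- function(report, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  h <- report$histogram
  graphics::barplot(as.numeric(h), names.arg = names(h),
                    xlab = "accumulated mispredictions per sequence",
                    ylab = "number of sequences",
                    main = "Misprediction recurrence")
  invisible(NULL)
}
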