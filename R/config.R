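# Single structured run configuration: every pipeline constant lives in one
# auditable tree (trigger threshold 14 g, target rate 8 kHz, head cut 0.7 s,
# stratified k = 5, early-stopping patience 20, ...) with YAML round-trip.

# recursively turn integers into doubles so YAML round trips compare equal
normalize_numeric <- function(x) {
  if (is.list(x)) return(lapply(x, normalize_numeric))
  if (is.integer(x)) return(as.numeric(x))
  x
}

#' Default run configuration
#'
#' All constants default to the pipeline's standard values: 541 catches and
#' 218 drops, trigger threshold 14 g, 8 kHz target rate with a 0.7 s head
#' cut, stratified k = 5 with 50 iterations, and the default
#' [model_config()] settings.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  mc <- unclass(model_config())
  structure(normalize_numeric(list(
    seed = 1,
    simulator = list(n_catch = 541, n_drop = 218, duration = 4,
                     class_effect = 1),
    acquisition = list(threshold_g = 14),
    preprocessing = list(target_fs = 8000, head_cut = 0.7),
    model = mc[setdiff(names(mc), "input_shape")],
    evaluation = list(k = 5, iterations = 50, trainings = "rotate",
                      ablation_iterations = 5),
    paths = list(out = "")
  )), class = "run_config")
}

merge_validate <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s)", if (nzchar(path)) paste0(" under ", path),
         ": ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", path, nm, " must be a mapping")
      defaults[[nm]] <- merge_validate(defaults[[nm]], user[[nm]],
                                       paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- normalize_numeric(user[[nm]])
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  check(cfg$acquisition$threshold_g > 0, "acquisition.threshold_g must be > 0")
  check(cfg$simulator$n_catch >= 1 && cfg$simulator$n_drop >= 1,
        "simulator class counts must be positive")
  check(cfg$simulator$duration >= 4, "simulator.duration must be >= 4 s")
  check(cfg$preprocessing$target_fs > 0, "preprocessing.target_fs must be > 0")
  check(cfg$preprocessing$head_cut >= 0, "preprocessing.head_cut must be >= 0")
  check(cfg$evaluation$k >= 2, "evaluation.k must be >= 2")
  check(cfg$evaluation$iterations >= 1, "evaluation.iterations must be >= 1")
  # model keys are validated by model_config()
  do.call(model_config, cfg$model)
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected with the offending path; missing keys are
#' filled from [default_run_config()]; the resolved values are validated.
#' An empty file resolves to all defaults.
#'
#' @param path YAML file.
#' @return A resolved, validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_validate(unclass(default_run_config()), user)
  cfg <- structure(cfg, class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Save a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
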