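# Shared in-memory fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 25-attempt study-proportioned dataset with default simulator parameters
tiny_dataset <- function() fixture("tiny_dataset", function() {
  man <- generate_dataset(dataset_config(16, 9), seed = 101)
  build_dataset(man)
})

# single catch and drop segments (default parameters)
example_segment <- function(outcome = "catch", seed = 1) {
  key <- paste0("segment_", outcome, "_", seed)
  fixture(key, function() {
    rec <- generate_attempt(attempt_scenario(outcome), seed = seed)
    ev <- detect_trigger(rec$left, rec$right)
    segment_attempt(rec$left, rec$right, ev)
  })
}

# very small network used where only the mechanics matter, not accuracy
tiny_train_config <- function(...) {
  scaled_model_config(filters = c(4, 6, 8), dense = 8, kernels = c(8, 5, 5),
                      pools = c(8, 4, 2), max_epochs = 10, patience = 10,
                      batch_size = 8, ...)
}

acc_norm_of <- function(rec) {
  with(rec$channels, sqrt(acc_x^2 + acc_y^2 + acc_z^2))
}

# ablation grid on a dataset whose class signal is planted only in the
# accelerometer; shared between the evaluation and acceptance suites
planted_ablation_grid <- function() fixture("planted_ablation", function() {
  par <- sim_params(class_effect = 3, effect_gyroscope = 0,
                    effect_magnetometer = 0, effect_audio = 0)
  man <- generate_dataset(dataset_config(30, 30, params = par), seed = 66)
  ds <- build_dataset(man)
  masks <- data.frame(
    accelerometer = c(TRUE, FALSE, TRUE),
    audio = c(TRUE, TRUE, TRUE),
    gyroscope = c(TRUE, TRUE, FALSE),
    magnetometer = c(TRUE, TRUE, TRUE))
  cfg <- scaled_model_config(seed = 3, max_epochs = 80, patience = 80,
                             batch_size = 8)
  ablate(ds, masks, config = cfg, n_iterations = 1, seed = 21)
})
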