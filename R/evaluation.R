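# Evaluation protocol: stratified 5-fold splits, repeated training
# iterations, normalized confusion matrices, misprediction recurrence, and
# the channel-group ablation grid.

#' Stratified k-fold assignment
#'
#' Partitions sequences into k nearly equally sized folds that each preserve
#' the global catch/drop proportion: within every class, members are dealt
#' evenly across folds, and the per-class remainders go to the currently
#' smallest folds. Fold sizes differ by at most one sequence, and per-fold
#' class counts differ from proportional allocation by at most one.
#'
#' @param labels vector of class labels, one per sequence.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffles.
#' @return Integer vector of fold indices in 1..k.
#' @export
#' @examples
#' table(stratified_kfold(rep(c("catch", "drop"), c(541, 218)), seed = 1))
stratified_kfold <- function(labels, k = 5, seed) {
  n <- length(labels)
  if (missing(seed)) stop("an integer seed is required")
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k = ", k, " members (got ",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  with_preserved_rng({
    set.seed(as.integer(seed))
    fold <- integer(n)
    fold_sizes <- integer(k)
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      q <- length(idx) %/% k
      r <- length(idx) %% k
      # r leftover sequences go to the currently smallest folds
      extra <- order(fold_sizes + stats::runif(k) * 1e-9)[seq_len(r)]
      sizes <- rep(q, k)
      sizes[extra] <- q + 1L
      fold[idx] <- rep(seq_len(k), times = sizes)
      fold_sizes <- fold_sizes + sizes
    }
    fold
  })
}

#' Two-class confusion matrix
#'
#' Rows are the true class (catch, drop), columns the predicted class; with
#' `normalize = TRUE` each row is divided by its total, so rows sum to 1.
#'
#' @param truth,predicted equal-length label vectors.
#' @param normalize divide rows by their totals (default TRUE).
#' @return 2 x 2 numeric matrix.
#' @export
confusion_matrix <- function(truth, predicted, normalize = TRUE) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  lev <- c("catch", "drop")
  m <- table(factor(as.character(truth), levels = lev),
             factor(as.character(predicted), levels = lev))
  m <- matrix(as.numeric(m), 2, 2, dimnames = list(true = lev, predicted = lev))
  if (normalize) {
    rs <- rowSums(m)
    m <- sweep(m, 1, ifelse(rs > 0, rs, 1), "/")
  }
  m
}

dataset_subset <- function(dataset, idx) {
  list(x = subset_cube(dataset$x, as.integer(idx)), y = dataset$y[idx],
       ids = dataset$ids[idx])
}

#' Repeated stratified training iterations
#'
#' One iteration draws a fresh stratified k-fold split, holds one fold out
#' as the test fold and performs `trainings_per_iteration` trainings: by
#' default the validation fold (used only for early stopping) rotates
#' through the remaining k-1 folds and the other k-2 folds train the network
#' ("rotate"); alternatively a fixed validation fold with reseeded repeats
#' ("reseed"). Test-fold accuracy and the mispredicted sequence ids are
#' logged per training.
#'
#' @param dataset an `attempt_dataset` (see [build_dataset()]).
#' @param n_iterations number of iterations.
#' @param config a [model_config()].
#' @param k number of folds.
#' @param trainings "rotate" (validation-fold rotation) or "reseed".
#' @param trainings_per_iteration trainings per iteration (default k - 1 for
#'   "rotate", i.e. 4 with 5 folds).
#' @param seed master integer seed; per-iteration and per-training seeds are
#'   derived from it.
#' @param verbose print progress.
#' @return An `evaluation_report`: `accuracies` (one row per training),
#'   `mean_accuracy`, `confusion_test` (pooled over all test-fold
#'   predictions, row-normalized), `confusion_whole` (the last model on the
#'   whole dataset, training folds included), `confusion_last_val` (the last
#'   model on its validation fold), `misprediction_counts` (per sequence) and
#'   `histogram` (recurrence distribution), plus the config.
#' @export
run_iterations <- function(dataset, n_iterations = 1, config = model_config(),
                           k = 5, trainings = c("rotate", "reseed"),
                           trainings_per_iteration = NULL, seed = 1,
                           verbose = FALSE) {
  trainings <- match.arg(trainings)
  stopifnot(n_iterations >= 1)
  n_train_per_it <- trainings_per_iteration %||%
    (if (trainings == "rotate") k - 1L else 4L)
  n <- length(dataset$y)
  acc_rows <- list()
  mispred <- setNames(numeric(n), dataset$ids)
  test_events <- character(0)
  last_model <- NULL; last_val_idx <- NULL
  pooled_truth <- character(0); pooled_pred <- character(0)
  for (it in seq_len(n_iterations)) {
    it_seed <- (seed * 1009L + it * 7919L) %% .Machine$integer.max
    fold <- stratified_kfold(dataset$y, k = k, seed = it_seed)
    test_idx <- which(fold == 1L)
    train_folds <- setdiff(seq_len(k), 1L)
    test <- dataset_subset(dataset, test_idx)
    for (tr in seq_len(n_train_per_it)) {
      if (trainings == "rotate") {
        val_fold <- train_folds[(tr - 1L) %% length(train_folds) + 1L]
      } else {
        val_fold <- train_folds[1L]
      }
      val_idx <- which(fold == val_fold)
      tr_idx <- which(!fold %in% c(1L, val_fold))
      cfg <- config
      cfg$seed <- as.integer((it_seed + 31L * tr) %% .Machine$integer.max)
      model <- build_model(cfg)
      model <- train_model(model, dataset_subset(dataset, tr_idx),
                           dataset_subset(dataset, val_idx))
      pred <- predict(model, test$x)
      acc <- mean(as.character(pred$label) == as.character(test$y))
      wrong <- test$ids[as.character(pred$label) != as.character(test$y)]
      mispred[wrong] <- mispred[wrong] + 1
      test_events <- c(test_events, wrong)
      pooled_truth <- c(pooled_truth, as.character(test$y))
      pooled_pred <- c(pooled_pred, as.character(pred$label))
      acc_rows[[length(acc_rows) + 1L]] <-
        data.frame(iteration = it, training = tr, val_fold = val_fold,
                   n_test = length(test_idx), accuracy = acc,
                   epochs = model$stopped_epoch)
      if (verbose)
        message(sprintf("iteration %d training %d: accuracy %.3f (%d epochs)",
                        it, tr, acc, model$stopped_epoch))
      last_model <- model; last_val_idx <- val_idx
    }
  }
  accuracies <- do.call(rbind, acc_rows)
  whole_pred <- predict(last_model, dataset$x)
  val_pred <- predict(last_model, dataset$x[, , last_val_idx, drop = FALSE])
  counts <- mispred[mispred > 0]
  structure(list(
    accuracies = accuracies,
    mean_accuracy = mean(accuracies$accuracy),
    confusion_test = confusion_matrix(pooled_truth, pooled_pred),
    confusion_whole = confusion_matrix(dataset$y, whole_pred$label),
    confusion_last_val = confusion_matrix(dataset$y[last_val_idx],
                                          val_pred$label),
    misprediction_counts = counts,
    n_misprediction_events = length(test_events),
    histogram = if (length(counts)) table(recurrence = counts) else table(numeric(0)),
    optimizer = config$optimizer,
    config = config, k = k, trainings = trainings, seed = seed),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d trainings, mean test accuracy %.2f%% (%s)\n",
              nrow(x$accuracies), 100 * x$mean_accuracy, x$optimizer))
  cat("pooled test confusion matrix (rows = truth, row-normalized):\n")
  print(round(x$confusion_test, 3))
  invisible(x)
}

#' Channel-group ablation masks
#'
#' The ten input settings of the ablation study, in grid order: every sensor
#' group on; each group zeroed alone; each group on alone; accelerometer and
#' magnetometer only.
#'
#' @return data.frame with logical columns `accelerometer`, `audio`,
#'   `gyroscope`, `magnetometer` (TRUE = on), one row per setting.
#' @export
default_ablation_masks <- function() {
  m <- rbind(
    c(TRUE,  TRUE,  TRUE,  TRUE),
    c(FALSE, TRUE,  TRUE,  TRUE),
    c(TRUE,  FALSE, TRUE,  TRUE),
    c(TRUE,  TRUE,  FALSE, TRUE),
    c(TRUE,  TRUE,  TRUE,  FALSE),
    c(TRUE,  FALSE, FALSE, FALSE),
    c(FALSE, TRUE,  FALSE, FALSE),
    c(FALSE, FALSE, TRUE,  FALSE),
    c(FALSE, FALSE, FALSE, TRUE),
    c(TRUE,  FALSE, FALSE, TRUE)
  )
  df <- as.data.frame(m)
  names(df) <- c("accelerometer", "audio", "gyroscope", "magnetometer")
  df
}

#' Zero the input columns of switched-off sensor groups
#'
#' @param x an 18,400 x 20 x n array (or matrix/list, see
#'   [predict.catch_cnn()]).
#' @param mask named logical vector or one-row data.frame over
#'   `accelerometer`, `audio`, `gyroscope`, `magnetometer`; FALSE groups are
#'   replaced by zeros (6 accelerometer, 2 audio, 6 gyroscope and 6
#'   magnetometer columns across both wrists).
#' @return The masked array.
#' @export
apply_ablation_mask <- function(x, mask) {
  x <- as_input_array(x)
  mask <- unlist(mask)
  groups <- channel_group_columns()
  unknown <- setdiff(names(mask), names(groups))
  if (length(unknown))
    stop("unknown sensor group(s): ", paste(unknown, collapse = ", "))
  for (g in names(mask))
    if (!isTRUE(mask[[g]])) x[, groups[[g]], ] <- 0
  x
}

#' Input-significance ablation grid
#'
#' Retrains and evaluates the network once per mask with the switched-off
#' sensor groups zeroed in both training and test inputs, reporting the mean
#' test accuracy over `n_iterations` iterations per setting.
#'
#' @param dataset an `attempt_dataset`.
#' @param masks data.frame of masks (default [default_ablation_masks()]).
#' @param config a [model_config()].
#' @param n_iterations iterations per mask (default 5).
#' @param trainings_per_iteration trainings per iteration (default 1 for the
#'   ablation grid).
#' @param k,seed,verbose as in [run_iterations()].
#' @return data.frame: the mask columns plus `accuracy` (mean, in 0..1).
#' @export
ablate <- function(dataset, masks = default_ablation_masks(),
                   config = model_config(), n_iterations = 5,
                   trainings_per_iteration = 1, k = 5, seed = 1,
                   verbose = FALSE) {
  masks <- as.data.frame(masks)
  unknown <- setdiff(names(masks), names(channel_group_columns()))
  if (length(unknown))
    stop("unknown sensor group(s): ", paste(unknown, collapse = ", "))
  acc <- numeric(nrow(masks))
  for (i in seq_len(nrow(masks))) {
    ds <- dataset
    ds$x <- apply_ablation_mask(ds$x, masks[i, , drop = FALSE])
    rep_i <- run_iterations(ds, n_iterations = n_iterations, config = config,
                            k = k, trainings_per_iteration =
                              trainings_per_iteration, seed = seed,
                            verbose = FALSE)
    acc[i] <- rep_i$mean_accuracy
    if (verbose)
      message(sprintf("mask %d (%s): accuracy %.3f", i,
                      paste(ifelse(unlist(masks[i, ]), "on", "zero"),
                            collapse = "/"), acc[i]))
  }
  cbind(masks, accuracy = acc)
}
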