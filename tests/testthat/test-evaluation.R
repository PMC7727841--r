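test_that("stratified folds partition the data and preserve class balance", {
  labels <- rep(c("catch", "drop"), c(541, 218))
  fold <- stratified_kfold(labels, k = 5, seed = 1)
  sizes <- as.numeric(table(fold))
  expect_equal(sort(sizes), c(151, 152, 152, 152, 152))
  # per-fold class counts within one of proportional allocation
  for (f in 1:5) {
    expect_lte(abs(sum(labels[fold == f] == "catch") - 541 / 5), 1)
    expect_lte(abs(sum(labels[fold == f] == "drop") - 218 / 5), 1)
  }
  # balanced 10-sequence case: exactly one of each class per fold
  lab10 <- rep(c("catch", "drop"), 5)
  f10 <- stratified_kfold(lab10, k = 5, seed = 2)
  for (f in 1:5) {
    expect_equal(sum(f10 == f), 2)
    expect_equal(sum(lab10[f10 == f] == "catch"), 1)
  }
  expect_error(stratified_kfold(rep(c("catch", "drop"), c(20, 3)), k = 5,
                                seed = 1), "at least k")
})

test_that("fold properties hold across random compositions", {
  set.seed(99)
  for (i in 1:20) {
    n_c <- sample(10:60, 1); n_d <- sample(10:60, 1)
    labels <- sample(rep(c("catch", "drop"), c(n_c, n_d)))
    k <- sample(3:6, 1)
    fold <- stratified_kfold(labels, k = k, seed = i)
    expect_setequal(unique(fold), seq_len(k))          # partition, no gaps
    expect_length(fold, n_c + n_d)
    expect_lte(diff(range(table(fold))), 1)            # near-equal sizes
    for (f in seq_len(k))
      expect_lte(abs(sum(labels[fold == f] == "catch") - n_c / k), 1)
  }
})

test_that("confusion matrices tally and normalize correctly", {
  truth <- c("catch", "catch", "drop", "drop")
  expect_equal(confusion_matrix(truth, truth),
               diag(2), ignore_attr = TRUE)
  m <- confusion_matrix(truth, rep("catch", 4))
  expect_equal(m[, "catch"], c(true.catch = 1, true.drop = 1),
               ignore_attr = TRUE)
  # random labels against a counting oracle
  set.seed(3)
  tr <- sample(c("catch", "drop"), 50, replace = TRUE)
  pr <- sample(c("catch", "drop"), 50, replace = TRUE)
  m_raw <- confusion_matrix(tr, pr, normalize = FALSE)
  for (a in c("catch", "drop")) for (b in c("catch", "drop"))
    expect_equal(m_raw[a, b], sum(tr == a & pr == b))
  m_norm <- confusion_matrix(tr, pr)
  expect_equal(rowSums(m_norm), c(catch = 1, drop = 1), ignore_attr = TRUE)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix(tr, pr[-1]), "equal length")
})

test_that("iteration bookkeeping conserves misprediction events", {
  ds <- tiny_dataset()
  cfg <- tiny_train_config(max_epochs = 6, seed = 1)
  rep <- run_iterations(ds, n_iterations = 2, config = cfg,
                        trainings_per_iteration = 2, seed = 5)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$accuracies), 4)
  expect_equal(rep$mean_accuracy, mean(rep$accuracies$accuracy))
  # conservation: histogram mass equals the number of logged events
  hist_mass <- sum(as.numeric(rep$histogram) *
                     as.numeric(names(rep$histogram)))
  expect_equal(hist_mass, rep$n_misprediction_events)
  # a sequence can only be mispredicted when it sat in a test fold
  expect_true(all(rep$misprediction_counts <= 2 * 2))
  expect_equal(rowSums(rep$confusion_test), c(catch = 1, drop = 1),
               ignore_attr = TRUE)
  expect_equal(rowSums(rep$confusion_whole), c(catch = 1, drop = 1),
               ignore_attr = TRUE)
})

test_that("reseeded repeats are available as the alternative protocol", {
  ds <- tiny_dataset()
  cfg <- tiny_train_config(max_epochs = 3, seed = 1)
  rep <- run_iterations(ds, n_iterations = 1, config = cfg,
                        trainings = "reseed", trainings_per_iteration = 2,
                        seed = 8)
  # both trainings validate on the same fixed fold but start differently
  expect_equal(unique(rep$accuracies$val_fold), rep$accuracies$val_fold[1])
  expect_equal(nrow(rep$accuracies), 2)
})

test_that("ablation masks map to the documented column groups", {
  groups <- catchsense:::channel_group_columns()
  expect_length(groups$accelerometer, 6)
  expect_length(groups$audio, 2)
  expect_length(groups$gyroscope, 6)
  expect_length(groups$magnetometer, 6)
  expect_setequal(unlist(groups), 1:20)
  masks <- default_ablation_masks()
  expect_equal(nrow(masks), 10)
  expect_true(all(as.logical(masks[1, ])))           # row 1: everything on
  x <- array(1, c(18400, 20, 2))
  xm <- apply_ablation_mask(x, c(accelerometer = FALSE, audio = TRUE,
                                 gyroscope = TRUE, magnetometer = TRUE))
  expect_true(all(xm[, groups$accelerometer, ] == 0))
  expect_true(all(xm[, -groups$accelerometer, ] == 1))
  expect_error(apply_ablation_mask(x, c(sonar = TRUE)), "unknown sensor group")
  expect_error(ablate(tiny_dataset(), data.frame(sonar = TRUE)),
               "unknown sensor group")
})

test_that("zeroing every sensor group collapses to the majority-class rate", {
  ds <- tiny_dataset()
  all_zero <- data.frame(accelerometer = FALSE, audio = FALSE,
                         gyroscope = FALSE, magnetometer = FALSE)
  cfg <- tiny_train_config(max_epochs = 6, seed = 2)
  grid <- ablate(ds, all_zero, config = cfg, n_iterations = 1, seed = 11)
  # constant input forces a constant prediction: accuracy equals the share
  # of the predicted class in the test fold
  fold <- stratified_kfold(ds$y, k = 5,
                           seed = (11 * 1009L + 7919L) %% .Machine$integer.max)
  test_y <- ds$y[fold == 1]
  majority <- max(mean(test_y == "catch"), mean(test_y == "drop"))
  expect_equal(grid$accuracy, majority)
})

test_that("ablating the informative group hurts, ablating others does not", {
  # class signal planted only in the accelerometer: zeroing it collapses
  # accuracy to roughly chance while zeroing the gyroscope does not
  grid <- planted_ablation_grid()
  expect_gt(grid$accuracy[1], 0.75)
  expect_lt(grid$accuracy[2], 0.7)
  expect_gt(grid$accuracy[3], 0.75)
  expect_gt(grid$accuracy[1] - grid$accuracy[2], 0.1)
})
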