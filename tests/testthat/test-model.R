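test_that("the default network has three conv/SE/max-pool blocks and a
           bounded sigmoid output", {
  m <- build_model(model_config())
  expect_length(m$dims$blocks, 3)
  expect_length(m$params$blocks, 3)
  x <- array(rnorm(18400 * 20 * 3), c(18400, 20, 3))
  p <- predict(m, x)
  expect_true(all(p$prob > 0 & p$prob < 1))
  expect_error(build_model(model_config(kernels = c(30000, 9, 9))), "kernel")
  expect_error(model_config(filters = c(8, 8)), "per block")
})

test_that("the reported parameter count matches layer-by-layer arithmetic", {
  cfg <- model_config(filters = c(8, 12, 16), kernels = c(8, 9, 9),
                      strides = c(8, 1, 1), pools = c(4, 4, 2),
                      se_reduction = 4, dense = 16)
  m <- build_model(cfg)
  # independent hand count: conv W + b, PReLU slopes, SE two dense layers
  # with their own PReLU, then dense head
  count_block <- function(c_in, f, k, r) {
    h <- ceiling(f / r)
    (k * c_in * f + f) + f + (h * f + h) + h + (f * h + f)
  }
  expected <- count_block(20, 8, 8, 4) + count_block(8, 12, 9, 4) +
    count_block(12, 16, 9, 4) +
    (16 * 16 + 16) + 16 + (16 + 1)
  expect_equal(m$n_params, expected)
})

test_that("backpropagation matches finite differences", {
  cfg <- model_config(filters = c(3, 4), kernels = c(5, 3), strides = c(2, 1),
                      pools = c(2, 2), dense = 5, input_shape = c(40, 3),
                      seed = 42)
  m <- build_model(cfg)
  set.seed(7)
  X <- array(rnorm(40 * 3 * 4), c(40, 3, 4))
  y <- c(1, 0, 1, 0)
  fw <- catchsense:::nn_forward(m$params, cfg, X)
  g <- catchsense:::flatten_params(catchsense:::nn_backward(m$params, cfg, fw, y))
  theta <- catchsense:::flatten_params(m$params)
  loss_at <- function(th) {
    p <- catchsense:::unflatten_params(th, m$params)
    catchsense:::bce_loss(catchsense:::nn_forward(p, cfg, X)$prob, y)
  }
  eps <- 1e-6
  idx <- seq(1, length(theta), by = 3)
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - g[idx]) / pmax(1e-6, abs(num) + abs(g[idx]))
  expect_lt(max(rel), 1e-5)
})

test_that("early stopping follows the patience arithmetic", {
  # frozen validation loss: best at epoch 1, patience exhausted at 21
  expect_equal(early_stop_epoch(rep(1, 100), patience = 20)$stop_epoch, 21)
  # strictly improving forever: runs the whole schedule
  es <- early_stop_epoch(seq(1, 0.01, length.out = 50), patience = 20)
  expect_equal(es$stop_epoch, 50)
  expect_equal(es$best_epoch, 50)
  # improvements below min_delta do not reset the counter
  es2 <- early_stop_epoch(1 - cumsum(rep(1e-4, 100)), patience = 10,
                          min_delta = 1e-3)
  expect_lt(es2$stop_epoch, 100)
  # a genuine improvement resets the counter
  losses <- c(1, rep(0.999, 15), 0.5, rep(0.6, 20), rep(0.7, 5))
  es3 <- early_stop_epoch(losses, patience = 20, min_delta = 1e-3)
  expect_equal(es3$best_epoch, 17)
  expect_equal(es3$stop_epoch, 37)
})

test_that("training rejects single-class sets and is seed-deterministic", {
  ds <- tiny_dataset()
  only_catch <- which(ds$y == "catch")[1:6]
  tr_bad <- catchsense:::dataset_subset(ds, only_catch)
  va <- catchsense:::dataset_subset(ds, 1:6)
  cfg <- tiny_train_config(max_epochs = 2, seed = 4)
  expect_error(train_model(build_model(cfg), tr_bad, va), "single class")

  tr <- catchsense:::dataset_subset(ds, 1:16)
  va <- catchsense:::dataset_subset(ds, 17:25)
  cfg <- tiny_train_config(max_epochs = 3, seed = 4)
  m1 <- train_model(build_model(cfg), tr, va)
  m2 <- train_model(build_model(cfg), tr, va)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("prediction applies the threshold with ties going to catch", {
  ds <- tiny_dataset()
  cfg <- tiny_train_config(max_epochs = 2, seed = 8)
  m <- train_model(build_model(cfg),
                   catchsense:::dataset_subset(ds, 1:16),
                   catchsense:::dataset_subset(ds, 17:25))
  p <- predict(m, catchsense:::subset_cube(ds$x, 1:6))
  # thresholding at an item's own probability labels it catch (tie -> catch)
  p_tie <- predict(m, catchsense:::subset_cube(ds$x, 1:6),
                   threshold = p$prob[3])
  expect_equal(as.character(p_tie$label[3]), "catch")
  expect_true(all(as.character(p$label[p$prob >= 0.5]) == "catch"))
  # permuting the batch permutes the outputs identically
  perm <- c(4, 2, 6, 1, 3, 5)
  p2 <- predict(m, catchsense:::subset_cube(ds$x, perm))
  expect_equal(p2$prob, p$prob[perm], tolerance = 1e-10)
  expect_error(predict(m, array(0, c(100, 20, 1))), "shape")
})

test_that("the network exceeds the fixed energy baseline when the class
           signal lives outside the accelerometer", {
  par <- sim_params(class_effect = 3, effect_accelerometer = 0)
  man <- generate_dataset(dataset_config(30, 30, params = par), seed = 404)
  ds <- build_dataset(man)
  fold <- stratified_kfold(ds$y, k = 5, seed = 2)
  te_idx <- which(fold == 1)
  oracle_pred <- vapply(te_idx, function(i) {
    r <- materialize_attempt(man, i)
    ev <- detect_trigger(r$left, r$right)
    oracle_classify(segment_attempt(r$left, r$right, ev))
  }, character(1))
  oracle_acc <- mean(oracle_pred == man$outcome[te_idx])
  cfg <- scaled_model_config(seed = 9, max_epochs = 80, batch_size = 8)
  m <- train_model(build_model(cfg),
                   catchsense:::dataset_subset(ds, which(!fold %in% c(1, 2))),
                   catchsense:::dataset_subset(ds, which(fold == 2)))
  p <- predict(m, catchsense:::subset_cube(ds$x, te_idx))
  cnn_acc <- mean(as.character(p$label) == as.character(ds$y[te_idx]))
  expect_gt(cnn_acc, oracle_acc)
  expect_gte(cnn_acc, 0.75)
})
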