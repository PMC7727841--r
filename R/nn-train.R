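# Training harness: Ranger-style optimizer (RAdam + Lookahead, Adam
# fallback), minibatch loop, and validation-loss early stopping with
# best-weight restoration.

make_optimizer <- function(name, n, lr, lookahead_k = 6, lookahead_alpha = 0.5) {
  list(name = name, lr = lr, t = 0L, m = numeric(n), v = numeric(n),
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
       slow = NULL, k = lookahead_k, alpha = lookahead_alpha)
}

optimizer_step <- function(opt, theta, grad) {
  opt$t <- opt$t + 1L
  t <- opt$t
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * grad^2
  m_hat <- opt$m / (1 - opt$beta1^t)
  if (opt$name == "adam") {
    v_hat <- opt$v / (1 - opt$beta2^t)
    theta <- theta - opt$lr * m_hat / (sqrt(v_hat) + opt$eps)
  } else {
    # RAdam: rectify the adaptive term only once its variance is tractable
    rho_inf <- 2 / (1 - opt$beta2) - 1
    rho_t <- rho_inf - 2 * t * opt$beta2^t / (1 - opt$beta2^t)
    if (rho_t > 4) {
      v_hat <- sqrt(opt$v / (1 - opt$beta2^t))
      r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      theta <- theta - opt$lr * r_t * m_hat / (v_hat + opt$eps)
    } else {
      theta <- theta - opt$lr * m_hat
    }
    # Lookahead: interpolate slow weights every k fast steps
    if (is.null(opt$slow)) opt$slow <- theta
    if (t %% opt$k == 0L) {
      opt$slow <- opt$slow + opt$alpha * (theta - opt$slow)
      theta <- opt$slow
    }
  }
  list(opt = opt, theta = theta)
}

#' Early-stopping epoch implied by a validation-loss sequence
#'
#' Pure bookkeeping shared with the training loop: the run stops after the
#' first epoch at which the validation loss has not improved on the running
#' best by at least `min_delta` for `patience` consecutive epochs, or at the
#' end of the sequence.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @param min_delta minimum improvement that resets the patience counter.
#' @return List with `stop_epoch` (last epoch run) and `best_epoch`.
#' @export
#' @examples
#' early_stop_epoch(rep(1, 100), patience = 20)$stop_epoch  # 21
early_stop_epoch <- function(val_losses, patience = 20, min_delta = 1e-3) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience)
        return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

labels_to_numeric <- function(y) {
  if (is.factor(y) || is.character(y)) as.numeric(as.character(y) == "catch")
  else as.numeric(y)
}

#' Train the catch/drop classifier
#'
#' Minibatch training with binary cross entropy, the configured optimizer,
#' and epoch-level early stopping on the validation loss (patience and
#' minimum improvement from the config). The parameters of the best
#' validation epoch are restored at the end.
#'
#' @param model an untrained `catch_cnn` from [build_model()].
#' @param train_set,val_set disjoint sets, each a list with `x` (18,400 x 20
#'   x n array, or list of input matrices) and `y` (labels, catch/drop).
#' @param seed integer seed for minibatch order and dropout; defaults to the
#'   config seed.
#' @param verbose print a line per epoch.
#' @return The trained `catch_cnn` with `history` (per-epoch train loss,
#'   validation loss and accuracy), `best_epoch` and `stopped_epoch`.
#' @export
train_model <- function(model, train_set, val_set,
                        seed = model$config$seed, verbose = FALSE) {
  stopifnot(inherits(model, "catch_cnn"))
  cfg <- model$config
  xt <- as_input_array(train_set$x)
  xv <- as_input_array(val_set$x)
  yt <- labels_to_numeric(train_set$y)
  yv <- labels_to_numeric(val_set$y)
  if (length(unique(yt)) < 2)
    stop("training set contains a single class; both catches and drops ",
         "are required to fit the classifier")
  if (cfg$standardize) {
    model$scaling <- column_scaling(xt)
    xt <- apply_scaling(xt, model$scaling)   # scale once, not per batch
    xv <- apply_scaling(xv, model$scaling)
  }
  n <- dim(xt)[3]
  skel <- model$params
  theta <- flatten_params(skel)
  opt <- make_optimizer(cfg$optimizer, length(theta), cfg$lr,
                        cfg$lookahead_k, cfg$lookahead_alpha)
  tl_hist <- vl_hist <- va_hist <- numeric(0)
  best_theta <- theta; best <- Inf; best_epoch <- 0L; wait <- 0L
  with_preserved_rng({
    set.seed(as.integer(seed))
    # fixed minibatch membership (one shuffle); the block-1 im2col workspace
    # of every batch is precomputed once and reused across epochs, and the
    # batch order is reshuffled each epoch
    perm <- sample(n)
    batches <- lapply(split(perm, ceiling(seq_along(perm) / cfg$batch_size)),
                      function(ix) list(
                        col = im2col_only(subset_cube(xt, ix),
                                          cfg$kernels[1], cfg$strides[1]),
                        y = yt[ix], n = length(ix)))
    rm(xt)
    nv <- dim(xv)[3]
    val_chunks <- lapply(split(seq_len(nv), ceiling(seq_len(nv) / 32)),
                         function(ix) list(
                           col = im2col_only(subset_cube(xv, ix),
                                             cfg$kernels[1], cfg$strides[1]),
                           ix = ix, n = length(ix)))
    rm(xv)
    val_forward <- function(params) {
      prob <- numeric(nv)
      for (ch in val_chunks)
        prob[ch$ix] <- nn_forward(params, cfg, NULL, col1 = ch$col,
                                  n1 = ch$n)$prob
      prob
    }
    for (epoch in seq_len(cfg$max_epochs)) {
      batch_losses <- numeric(0)
      for (bi in sample(length(batches))) {
        bt <- batches[[bi]]
        mask <- matrix(rbinom(cfg$dense * bt$n, 1, 1 - cfg$dropout),
                       cfg$dense, bt$n)
        params <- unflatten_params(theta, skel)
        fw <- nn_forward(params, cfg, NULL, dropmask = mask, col1 = bt$col,
                         n1 = bt$n)
        batch_losses <- c(batch_losses, bce_loss(fw$prob, bt$y))
        grads <- nn_backward(params, cfg, fw, bt$y)
        step <- optimizer_step(opt, theta, flatten_params(grads))
        opt <- step$opt; theta <- step$theta
      }
      vp <- val_forward(unflatten_params(theta, skel))
      vl <- bce_loss(vp, yv)
      va <- mean((vp >= cfg$threshold) == (yv == 1))
      tl_hist[epoch] <- mean(batch_losses); vl_hist[epoch] <- vl
      va_hist[epoch] <- va
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val acc %.3f",
                        epoch, mean(batch_losses), vl, va))
      # same bookkeeping as early_stop_epoch()
      if (vl < best - cfg$min_delta) {
        best <- vl; best_epoch <- epoch; wait <- 0L; best_theta <- theta
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- unflatten_params(best_theta, skel)
  model$history <- data.frame(epoch = seq_along(vl_hist), train_loss = tl_hist,
                              val_loss = vl_hist, val_acc = va_hist)
  model$best_epoch <- if (best_epoch > 0) best_epoch else length(vl_hist)
  model$stopped_epoch <- length(vl_hist)
  model
}
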