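# Binary catch/drop classifier: a sequential 1-D CNN over the 18,400 x 20
# input. Three blocks of (convolution -> PReLU -> squeeze-and-excitation ->
# max pooling), global average pooling over time, one dense hidden layer with
# PReLU and dropout, and a single sigmoid output giving P(catch). All
# activations except the output are PReLU with a learned per-channel slope.

#' Model configuration
#'
#' The published architecture fixes the block types (three convolution /
#' squeeze-and-excitation / max-pooling blocks, average pooling, dense and
#' dropout layers, PReLU activations, sigmoid output, binary cross entropy,
#' Ranger optimizer, max 1000 epochs, early stopping with patience 20 and
#' minimum validation-loss improvement 1e-3) but not the per-block
#' hyperparameters; the defaults here are deliberately modest and fully
#' recorded in the config.
#'
#' @param filters,kernels,strides,pools integer vectors, one entry per block.
#' @param se_reduction squeeze-and-excitation bottleneck reduction ratio.
#' @param dense width of the dense hidden layer.
#' @param dropout dropout rate on the dense hidden layer, in (0, 1).
#' @param lr learning rate.
#' @param optimizer "ranger" (RAdam + Lookahead) or "adam".
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs.
#' @param min_delta minimum validation-loss improvement that resets patience.
#' @param threshold classification threshold on P(catch); ties go to catch.
#' @param standardize if TRUE, standardize each input column with
#'   training-set statistics before the network (stored with the model).
#' @param lookahead_k,lookahead_alpha Lookahead synchronization period and
#'   interpolation step (Ranger only).
#' @param input_shape input dimensions (time steps, channels).
#' @param seed integer seed for weight initialization and minibatch order.
#' @return Object of class `model_config`.
#' @export
model_config <- function(filters = c(24, 32, 48),
                         kernels = c(16, 9, 9),
                         strides = c(8, 1, 1),
                         pools = c(4, 4, 2),
                         se_reduction = 4,
                         dense = 32,
                         dropout = 0.3,
                         lr = 2e-3,
                         optimizer = c("ranger", "adam"),
                         batch_size = 16,
                         max_epochs = 1000,
                         patience = 20,
                         min_delta = 1e-3,
                         threshold = 0.5,
                         standardize = FALSE,
                         lookahead_k = 6,
                         lookahead_alpha = 0.5,
                         input_shape = c(18400, 20),
                         seed = 1) {
  optimizer <- match.arg(optimizer)
  nb <- length(filters)
  if (!all(lengths(list(kernels, strides, pools)) == nb))
    stop("filters, kernels, strides and pools must have one entry per block")
  stopifnot(nb >= 1, all(filters >= 1), all(kernels >= 1), all(strides >= 1),
            all(pools >= 1), dense >= 1,
            dropout > 0, dropout < 1, patience >= 1, max_epochs >= 1,
            min_delta >= 0, lr > 0, batch_size >= 1)
  structure(list(filters = as.integer(filters), kernels = as.integer(kernels),
                 strides = as.integer(strides), pools = as.integer(pools),
                 se_reduction = se_reduction, dense = as.integer(dense),
                 dropout = dropout, lr = lr, optimizer = optimizer,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 threshold = threshold, standardize = standardize,
                 lookahead_k = lookahead_k, lookahead_alpha = lookahead_alpha,
                 input_shape = as.integer(input_shape), seed = as.integer(seed)),
            class = "model_config")
}

#' Scaled-down training configuration for desk-scale runs
#'
#' The reduced preset used for simulation studies on a single CPU: smaller
#' filter counts and dense width, a non-overlapping first convolution
#' (kernel = stride = 8, a learned 1 ms frame projection), at most 100
#' epochs, and per-channel input standardization from training-fold
#' statistics (the raw channel units span five orders of magnitude, mT to
#' deg/s, which a reduced-capacity network should not spend epochs
#' rescaling). Early-stopping patience (20) and
#' minimum improvement (1e-3) keep their defaults.
#'
#' @param ... overrides passed on to [model_config()].
#' @return A `model_config`.
#' @export
scaled_model_config <- function(...) {
  defaults <- list(filters = c(8, 12, 16), kernels = c(8, 9, 9),
                   strides = c(8, 1, 1), pools = c(4, 4, 2), dense = 16,
                   max_epochs = 100, standardize = TRUE)
  args <- modifyList(defaults, list(...))
  do.call(model_config, args)
}

# per-layer output sizes implied by a config; errors on incompatible shapes
model_dims <- function(cfg) {
  T <- cfg$input_shape[1]; C <- cfg$input_shape[2]
  blocks <- vector("list", length(cfg$filters))
  for (i in seq_along(cfg$filters)) {
    k <- cfg$kernels[i]; s <- cfg$strides[i]; p <- cfg$pools[i]
    if (T < k) stop("block ", i, ": kernel (", k,
                    ") longer than its input (", T, " time steps)")
    T_conv <- (T - k) %/% s + 1L
    if (T_conv < p) stop("block ", i, ": pool size ", p,
                         " larger than conv output (", T_conv, ")")
    h <- max(1L, as.integer(ceiling(cfg$filters[i] / cfg$se_reduction)))
    blocks[[i]] <- list(c_in = C, f = cfg$filters[i], k = k, stride = s,
                        pool = p, t_conv = T_conv, t_out = T_conv %/% p,
                        se_hidden = h)
    T <- T_conv %/% p
    C <- cfg$filters[i]
  }
  list(blocks = blocks, feat = C, t_final = T)
}

he_mat <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

init_params <- function(cfg) {
  dims <- model_dims(cfg)
  blocks <- lapply(dims$blocks, function(d) {
    list(W = he_mat(d$k * d$c_in, d$f, d$k * d$c_in),
         b = numeric(d$f),
         alpha = rep(0.25, d$f),
         se_W1 = he_mat(d$se_hidden, d$f, d$f),
         se_b1 = numeric(d$se_hidden),
         se_alpha = rep(0.25, d$se_hidden),
         se_W2 = he_mat(d$f, d$se_hidden, d$se_hidden),
         se_b2 = numeric(d$f))
  })
  dense <- list(W1 = he_mat(cfg$dense, dims$feat, dims$feat),
                b1 = numeric(cfg$dense),
                alpha = rep(0.25, cfg$dense),
                W2 = he_mat(1, cfg$dense, cfg$dense),
                b2 = numeric(1))
  list(blocks = blocks, dense = dense)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skel) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  walk(skel)
}

#' Build an untrained catch/drop classifier
#'
#' Instantiates the network for (18,400 x 20) inputs: the configured
#' convolution / squeeze-and-excitation / max-pooling blocks, global average
#' pooling, a dense hidden layer with PReLU and dropout, and one sigmoid
#' output unit. Weights use He initialization under the config seed.
#'
#' @param config a [model_config()].
#' @return Object of class `catch_cnn` with elements `params`, `config`,
#'   `dims` and `n_params` (trainable parameter count).
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  dims <- model_dims(config)
  params <- with_preserved_rng({
    set.seed(config$seed)
    init_params(config)
  })
  structure(list(params = params, config = config, dims = dims,
                 n_params = length(flatten_params(params)),
                 scaling = NULL, history = NULL),
            class = "catch_cnn")
}

#' @export
print.catch_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<catch_cnn> ", length(cfg$filters), " conv/SE/max-pool blocks, ",
      x$n_params, " trainable parameters\n", sep = "")
  for (i in seq_along(x$dims$blocks)) {
    d <- x$dims$blocks[[i]]
    cat(sprintf("  block %d: conv k=%d s=%d %d->%d ch, pool %d -> %d x %d\n",
                i, d$k, d$stride, d$c_in, d$f, d$pool, d$t_out, d$f))
  }
  cat(sprintf("  avg pool -> dense %d (dropout %.2f) -> sigmoid\n",
              cfg$dense, cfg$dropout))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs (best val loss %.4f at epoch %d), optimizer %s\n",
                nrow(x$history), min(x$history$val_loss),
                which.min(x$history$val_loss), cfg$optimizer))
  invisible(x)
}

## elementwise helpers ------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# broadcast a per-channel vector over a (T, C, N) array
bcast_channel <- function(v, d) array(rep(rep(v, each = d[1]), d[3]), d)
# broadcast a C x N matrix over time
bcast_time <- function(M, d) array(rep(M, each = d[1]), d)

prelu <- function(z, alpha_arr) pmax(z, 0) + alpha_arr * pmin(z, 0)

## forward / backward -------------------------------------------------------

# X: (T, C, N) array; returns probabilities and the cache for backprop.
# `col1` optionally carries a precomputed block-1 im2col workspace (then X may
# be NULL and `n1` gives the batch size), used to cache fixed minibatches
# across epochs.
nn_forward <- function(params, cfg, X, dropmask = NULL, col1 = NULL,
                       n1 = NULL) {
  caches <- vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    pb <- params$blocks[[i]]
    if (i == 1L && !is.null(col1)) {
      Z <- conv1d_forward_col(col1, pb$W, pb$b, n1 %||% dim(X)[3])
      cv <- list(col = col1)
    } else {
      cv <- conv1d_forward(X, pb$W, pb$b, cfg$kernels[i], cfg$strides[i])
      Z <- cv$out
    }
    d <- dim(Z)
    alpha_arr <- bcast_channel(pb$alpha, d)
    A <- prelu(Z, alpha_arr)
    M <- colMeans(A, dims = 1)                   # squeeze: F x N
    if (is.null(dim(M))) M <- matrix(M, ncol = 1)
    Hz <- pb$se_W1 %*% M + pb$se_b1
    H <- pmax(Hz, 0) + pb$se_alpha * pmin(Hz, 0)
    G <- sigmoid(pb$se_W2 %*% H + pb$se_b2)      # excitation gates: F x N
    A2 <- A * bcast_time(G, d)
    mp <- maxpool_forward(A2, cfg$pools[i])
    caches[[i]] <- list(col = cv$col, t_x = if (i > 1L) dim(X)[1] else NA,
                        Z = Z, A = A, M = M,
                        Hz = Hz, H = H, G = G, idx = mp$idx, t_in = d[1])
    X <- mp$out
  }
  feat <- colMeans(X, dims = 1)                  # global average pool: F x N
  if (is.null(dim(feat))) feat <- matrix(feat, ncol = 1)
  pd <- params$dense
  D1z <- pd$W1 %*% feat + pd$b1
  D1 <- pmax(D1z, 0) + pd$alpha * pmin(D1z, 0)
  D1d <- if (is.null(dropmask)) D1 else D1 * dropmask / (1 - cfg$dropout)
  logit <- as.numeric(pd$W2 %*% D1d + pd$b2)
  list(prob = sigmoid(logit),
       cache = list(blocks = caches, feat = feat, D1z = D1z, D1d = D1d,
                    t_last = dim(X)[1], dropmask = dropmask))
}

# y: numeric 0/1 (1 = catch). Mean binary cross entropy over the batch.
nn_backward <- function(params, cfg, fw, y) {
  N <- length(y)
  cache <- fw$cache
  dlogit <- matrix((fw$prob - y) / N, nrow = 1)
  pd <- params$dense
  gdense <- list(W1 = NULL, b1 = NULL, alpha = NULL,
                 W2 = dlogit %*% t(cache$D1d), b2 = sum(dlogit))
  dD1d <- t(pd$W2) %*% dlogit
  dD1 <- if (is.null(cache$dropmask)) dD1d else
    dD1d * cache$dropmask / (1 - cfg$dropout)
  neg <- cache$D1z <= 0
  dD1z <- dD1 * ifelse(neg, pd$alpha, 1)
  gdense$alpha <- rowSums(dD1 * cache$D1z * neg)
  gdense$W1 <- dD1z %*% t(cache$feat)
  gdense$b1 <- rowSums(dD1z)
  dfeat <- t(pd$W1) %*% dD1z
  dX <- bcast_time(dfeat / cache$t_last,
                   c(cache$t_last, nrow(dfeat), ncol(dfeat)))
  gblocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    cb <- cache$blocks[[i]]
    pb <- params$blocks[[i]]
    dA2 <- maxpool_backward(cb$idx, dX, cb$t_in)
    d <- dim(dA2)
    dA <- dA2 * bcast_time(cb$G, d)
    dG <- colSums(dA2 * cb$A, dims = 1)
    if (is.null(dim(dG))) dG <- matrix(dG, ncol = 1)
    dGz <- dG * cb$G * (1 - cb$G)
    g <- list()
    g$se_W2 <- dGz %*% t(cb$H)
    g$se_b2 <- rowSums(dGz)
    dH <- t(pb$se_W2) %*% dGz
    negH <- cb$Hz <= 0
    dHz <- dH * ifelse(negH, pb$se_alpha, 1)
    g$se_alpha <- rowSums(dH * cb$Hz * negH)
    g$se_W1 <- dHz %*% t(cb$M)
    g$se_b1 <- rowSums(dHz)
    dM <- t(pb$se_W1) %*% dHz
    dA <- dA + bcast_time(dM / d[1], d)
    negZ <- cb$Z <= 0
    alpha_arr <- bcast_channel(pb$alpha, d)
    dZ <- dA * (1 - negZ + alpha_arr * negZ)
    g$alpha <- rowSums(colSums(dA * cb$Z * negZ, dims = 1))
    cv <- conv1d_backward(cb$col, pb$W, dZ, cfg$kernels[i], cfg$strides[i],
                          if (i > 1L) cb$t_x else 0L,
                          need_dx = i > 1L)  # input grad unused at block 1
    g$W <- cv$dW
    g$b <- as.numeric(cv$db)
    dX <- cv$dx
    gblocks[[i]] <- g[c("W", "b", "alpha", "se_W1", "se_b1", "se_alpha",
                        "se_W2", "se_b2")]
  }
  list(blocks = gblocks, dense = gdense)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# standardization helpers (per input column, training-set statistics)
column_scaling <- function(x) {
  per_sample_mean <- colMeans(x, dims = 1)            # C x N
  if (is.null(dim(per_sample_mean)))
    per_sample_mean <- matrix(per_sample_mean, ncol = 1)
  mu <- rowMeans(per_sample_mean)
  ms <- rowMeans(matrix(colMeans(x^2, dims = 1), nrow = dim(x)[2]))
  sdv <- sqrt(pmax(ms - mu^2, 0))
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  standardize_cube(x, scaling$mean, scaling$sd)
}

as_input_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, c(dim(x), 1)))
  if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
    d <- dim(x[[1]])
    return(array(unlist(x, use.names = FALSE), c(d, length(x))))
  }
  stop("expected an input matrix, a list of input matrices, or a 3-D array")
}

#' Predict catch probabilities and labels
#'
#' @param object a trained `catch_cnn`.
#' @param newdata an `input_matrix`, a list of them, or an
#'   18,400 x 20 x n array.
#' @param threshold classification threshold on P(catch); defaults to the
#'   config value (0.5). The boundary case `prob == threshold` is a catch.
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return data.frame with columns `prob` (P(catch)) and `label`
#'   (factor catch/drop).
#' @export
predict.catch_cnn <- function(object, newdata,
                              threshold = object$config$threshold,
                              batch_size = 32, ...) {
  x <- as_input_array(newdata)
  if (!all(dim(x)[1:2] == object$config$input_shape))
    stop("input shape ", dim(x)[1], " x ", dim(x)[2],
         " does not match the model input ",
         paste(object$config$input_shape, collapse = " x "))
  n <- dim(x)[3]
  prob <- numeric(n)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- apply_scaling(subset_cube(x, ix), object$scaling)
    prob[ix] <- nn_forward(object$params, object$config, xb)$prob
  }
  data.frame(prob = prob,
             label = factor(ifelse(prob >= threshold, "catch", "drop"),
                            levels = c("catch", "drop")))
}
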