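#' Reshape a feature vector to a single-channel square grid
#'
#' 2x2 convolutions need two-dimensional input, but a gene subset is a flat
#' vector. The vector is laid out row-major on a `side x side` grid with
#' `side = ceiling(sqrt(d))`; the trailing `side^2 - d` cells are zero-padded.
#'
#' @param v Numeric feature vector.
#' @return A `side x side` numeric matrix.
#' @examples
#' reshape_to_grid(1:5)  # 3x3 grid, 4 zero cells
#' @export
reshape_to_grid <- function(v) {
  d <- length(v)
  if (d < 1L) stop("need at least one feature")
  side <- ceiling(sqrt(d))
  matrix(c(v, numeric(side * side - d)), side, side, byrow = TRUE)
}

#' Convolutional architecture description
#'
#' Six convolutional blocks with 8, 16, 32, 64, 128 and 256 filters of size
#' 2x2 at stride 1, each followed by batch normalization and ReLU, with 2x2
#' stride-2 max pooling after every block except the last (and skipped
#' whenever a spatial dimension is below 2). The classification head is
#' flatten -> dense(C) -> softmax.
#'
#' @param conv_channels Output channels per block.
#' @param kernel Kernel side (fixed 2 in this implementation).
#' @param stride Convolution stride (fixed 1).
#' @return An object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(conv_channels = c(8L, 16L, 32L, 64L, 128L,
                                               256L),
                             kernel = 2L, stride = 1L) {
  if (kernel != 2L || stride != 1L) {
    stop("this implementation supports kernel = 2, stride = 1")
  }
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = 2L, stride = 1L),
            class = "cnn_architecture")
}

bn_eps <- 1e-5

#' Build the convolutional classifier
#'
#' Constructs the block stack of [cnn_architecture()] for `d` input features
#' reshaped per [reshape_to_grid()] (an input grid smaller than 2x2 is
#' zero-padded up to 2x2, as is any intermediate map that shrinks below the
#' kernel). Weights use He initialization from the current RNG state. The
#' `shape_report` lists, per block, the input/output channels, the spatial
#' size after convolution, and whether pooling applies.
#'
#' @param d Number of input features (>= 1).
#' @param n_classes Number of output classes (>= 2).
#' @param arch A [cnn_architecture()].
#' @return A model object (class `cnn_model`) with a `shape_report`
#'   data frame.
#' @export
build_cnn <- function(d, n_classes, arch = cnn_architecture()) {
  if (d < 1L) stop("d must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  side <- max(2L, ceiling(sqrt(d)))
  nb <- length(arch$conv_channels)
  layers <- vector("list", nb)
  H <- side
  in_ch <- 1L
  report <- data.frame(block = integer(), in_channels = integer(),
                       out_channels = integer(), conv_side = integer(),
                       pooled = logical(), out_side = integer())
  for (b in seq_len(nb)) {
    out_ch <- arch$conv_channels[b]
    Hc <- max(2L, H)
    oh <- Hc - 1L
    pool <- (b < nb) && oh >= 2L
    fan_in <- 4L * in_ch
    layers[[b]] <- list(
      W = matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                 fan_in, out_ch),
      b = numeric(out_ch),
      gamma = rep(1, out_ch),
      beta = numeric(out_ch),
      run_mean = numeric(out_ch),
      run_var = rep(1, out_ch),
      pool = pool, in_ch = in_ch, out_ch = out_ch)
    H_after <- if (pool) oh %/% 2L else oh
    report <- rbind(report, data.frame(block = b, in_channels = in_ch,
                                       out_channels = out_ch,
                                       conv_side = oh, pooled = pool,
                                       out_side = H_after))
    H <- H_after
    in_ch <- out_ch
  }
  flat <- H * H * in_ch
  model <- list(side = side, d = as.integer(d),
                n_classes = as.integer(n_classes), arch = arch,
                layers = layers,
                Wd = matrix(stats::rnorm(flat * n_classes,
                                         sd = sqrt(2 / flat)),
                            flat, n_classes),
                bd = numeric(n_classes),
                flat_dim = flat, shape_report = report, step = 0L)
  class(model) <- "cnn_model"
  model
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("cnn_model: input ", x$side, "x", x$side, "x1 (", x$d,
      " features), ", x$n_classes, " classes\n", sep = "")
  print(x$shape_report, row.names = FALSE)
  invisible(x)
}

# ---- array plumbing ---------------------------------------------------------

# features (N x d) -> grids (N, side, side, 1), row-major per sample
features_to_grids <- function(X, side) {
  N <- nrow(X)
  pad <- side * side - ncol(X)
  if (pad > 0) X <- cbind(X, matrix(0, N, pad))
  arr <- aperm(array(X, c(N, side, side)), c(1L, 3L, 2L))
  dim(arr) <- c(N, side, side, 1L)
  arr
}

pad_min2 <- function(x) {
  d <- dim(x)
  if (d[2L] >= 2L && d[3L] >= 2L) return(x)
  out <- array(0, c(d[1L], max(2L, d[2L]), max(2L, d[3L]), d[4L]))
  out[, seq_len(d[2L]), seq_len(d[3L]), ] <- x
  out
}

# im2col for a 2x2 kernel: (N,H,W,C) -> (N*oh*ow, 4C)
build_cols <- function(x, oh, ow) {
  C <- dim(x)[4L]
  m <- dim(x)[1L] * oh * ow
  cbind(matrix(x[, 1:oh, 1:ow, , drop = FALSE], m, C),
        matrix(x[, 2:(oh + 1L), 1:ow, , drop = FALSE], m, C),
        matrix(x[, 1:oh, 2:(ow + 1L), , drop = FALSE], m, C),
        matrix(x[, 2:(oh + 1L), 2:(ow + 1L), , drop = FALSE], m, C))
}

# scatter dcols back onto the padded input
cols_backward <- function(dcols, xdim, oh, ow) {
  N <- xdim[1L]
  C <- xdim[4L]
  dx <- array(0, xdim)
  chunk <- function(k) {
    array(dcols[, (k - 1L) * C + seq_len(C), drop = FALSE], c(N, oh, ow, C))
  }
  dx[, 1:oh, 1:ow, ] <- dx[, 1:oh, 1:ow, , drop = FALSE] + chunk(1L)
  dx[, 2:(oh + 1L), 1:ow, ] <-
    dx[, 2:(oh + 1L), 1:ow, , drop = FALSE] + chunk(2L)
  dx[, 1:oh, 2:(ow + 1L), ] <-
    dx[, 1:oh, 2:(ow + 1L), , drop = FALSE] + chunk(3L)
  dx[, 2:(oh + 1L), 2:(ow + 1L), ] <-
    dx[, 2:(oh + 1L), 2:(ow + 1L), , drop = FALSE] + chunk(4L)
  dx
}

pool_forward <- function(a) {
  d <- dim(a)
  oh <- d[2L] %/% 2L
  ow <- d[3L] %/% 2L
  ri <- seq_len(oh) * 2L - 1L
  ci <- seq_len(ow) * 2L - 1L
  x1 <- a[, ri, ci, , drop = FALSE]
  x2 <- a[, ri + 1L, ci, , drop = FALSE]
  x3 <- a[, ri, ci + 1L, , drop = FALSE]
  x4 <- a[, ri + 1L, ci + 1L, , drop = FALSE]
  m <- pmax(x1, x2, x3, x4)
  w1 <- x1 == m
  w2 <- x2 == m & !w1
  w3 <- x3 == m & !(w1 | w2)
  w4 <- !(w1 | w2 | w3)
  list(out = m, picks = list(w1, w2, w3, w4), in_dim = d, oh = oh, ow = ow)
}

pool_backward <- function(dm, cache) {
  dx <- array(0, cache$in_dim)
  ri <- seq_len(cache$oh) * 2L - 1L
  ci <- seq_len(cache$ow) * 2L - 1L
  dx[, ri, ci, ] <- dm * cache$picks[[1L]]
  dx[, ri + 1L, ci, ] <- dm * cache$picks[[2L]]
  dx[, ri, ci + 1L, ] <- dm * cache$picks[[3L]]
  dx[, ri + 1L, ci + 1L, ] <- dm * cache$picks[[4L]]
  dx
}

# ---- forward / backward -----------------------------------------------------

block_forward <- function(layer, x, training) {
  orig_dim <- dim(x)
  x <- pad_min2(x)
  xdim <- dim(x)
  oh <- xdim[2L] - 1L
  ow <- xdim[3L] - 1L
  N <- xdim[1L]
  cols <- build_cols(x, oh, ow)
  z <- sweep(cols %*% layer$W, 2L, layer$b, "+")
  m <- nrow(z)
  if (training) {
    mu <- colMeans(z)
    vr <- pmax(colMeans(z^2) - mu^2, 0)
    layer$run_mean <- 0.9 * layer$run_mean + 0.1 * mu
    layer$run_var <- 0.9 * layer$run_var + 0.1 * vr
  } else {
    mu <- layer$run_mean
    vr <- layer$run_var
  }
  invstd <- 1 / sqrt(vr + bn_eps)
  xhat <- sweep(sweep(z, 2L, mu, "-"), 2L, invstd, "*")
  a <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  r <- pmax(a, 0)
  rarr <- array(r, c(N, oh, ow, layer$out_ch))
  pcache <- NULL
  out <- rarr
  if (layer$pool) {
    pcache <- pool_forward(rarr)
    out <- pcache$out
  }
  list(out = out, layer = layer,
       cache = list(orig_dim = orig_dim, xdim = xdim, oh = oh, ow = ow,
                    cols = cols, xhat = xhat, invstd = invstd,
                    relu_mask = a > 0, pool = pcache,
                    conv_dim = c(N, oh, ow, layer$out_ch)))
}

block_backward <- function(layer, cache, dout) {
  if (!is.null(cache$pool)) dout <- pool_backward(dout, cache$pool)
  m <- prod(cache$conv_dim[1:3])
  dr <- matrix(dout, m, layer$out_ch)
  da <- dr * cache$relu_mask
  dgamma <- colSums(da * cache$xhat)
  dbeta <- colSums(da)
  dxhat <- sweep(da, 2L, layer$gamma, "*")
  mdx <- colMeans(dxhat)
  mdxx <- colMeans(dxhat * cache$xhat)
  dz <- sweep(dxhat - matrix(mdx, m, layer$out_ch, byrow = TRUE) -
                cache$xhat * matrix(mdxx, m, layer$out_ch, byrow = TRUE),
              2L, cache$invstd, "*")
  dW <- crossprod(cache$cols, dz)
  db <- colSums(dz)
  dcols <- tcrossprod(dz, layer$W)
  dx <- cols_backward(dcols, cache$xdim, cache$oh, cache$ow)
  od <- cache$orig_dim
  dx <- dx[, seq_len(od[2L]), seq_len(od[3L]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db, dgamma = dgamma, dbeta = dbeta)
}

cnn_forward <- function(model, X, training = FALSE) {
  x <- features_to_grids(X, model$side)
  caches <- vector("list", length(model$layers))
  for (b in seq_along(model$layers)) {
    fw <- block_forward(model$layers[[b]], x, training)
    model$layers[[b]] <- fw$layer  # running BN stats
    caches[[b]] <- fw$cache
    x <- fw$out
  }
  N <- dim(x)[1L]
  flat <- matrix(x, N, model$flat_dim)
  logits <- sweep(flat %*% model$Wd, 2L, model$bd, "+")
  shift <- logits - apply(logits, 1L, max)
  eu <- exp(shift)
  probs <- eu / rowSums(eu)
  list(model = model, probs = probs, logits = logits, flat = flat,
       caches = caches, flat_out_dim = dim(x))
}

cnn_loss <- function(probs, y) {
  n <- nrow(probs)
  -mean(log(pmax(probs[cbind(seq_len(n), y + 1L)], 1e-12)))
}

cnn_backward <- function(model, fw, y) {
  n <- nrow(fw$probs)
  dlogits <- fw$probs
  dlogits[cbind(seq_len(n), y + 1L)] <- dlogits[cbind(seq_len(n), y + 1L)] - 1
  dlogits <- dlogits / n
  grads <- list(Wd = crossprod(fw$flat, dlogits), bd = colSums(dlogits),
                layers = vector("list", length(model$layers)))
  dflat <- tcrossprod(dlogits, model$Wd)
  dx <- array(dflat, fw$flat_out_dim)
  for (b in rev(seq_along(model$layers))) {
    bk <- block_backward(model$layers[[b]], fw$caches[[b]], dx)
    grads$layers[[b]] <- bk[c("dW", "db", "dgamma", "dbeta")]
    dx <- bk$dx
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init_like <- function(model) {
  zero_of <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  list(Wd = list(m = zero_of(model$Wd), v = zero_of(model$Wd)),
       bd = list(m = zero_of(model$bd), v = zero_of(model$bd)),
       layers = lapply(model$layers, function(l) {
         lapply(l[c("W", "b", "gamma", "beta")], function(p) {
           list(m = zero_of(p), v = zero_of(p))
         })
       }))
}

adam_step <- function(param, grad, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

adam_update <- function(model, opt, grads, lr) {
  model$step <- model$step + 1L
  t <- model$step
  s <- adam_step(model$Wd, grads$Wd, opt$Wd, lr, t)
  model$Wd <- s$param
  opt$Wd <- s$state
  s <- adam_step(model$bd, grads$bd, opt$bd, lr, t)
  model$bd <- s$param
  opt$bd <- s$state
  gnames <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  for (b in seq_along(model$layers)) {
    for (p in names(gnames)) {
      s <- adam_step(model$layers[[b]][[p]],
                     grads$layers[[b]][[gnames[[p]]]],
                     opt$layers[[b]][[p]], lr, t)
      model$layers[[b]][[p]] <- s$param
      opt$layers[[b]][[p]] <- s$state
    }
  }
  list(model = model, opt = opt)
}

# ---- training ---------------------------------------------------------------

#' Predict class codes with a trained model
#'
#' @param model A `cnn_model`.
#' @param X Feature matrix (samples x features, same `d` as at build time).
#' @return Integer class codes (argmax of the softmax; ties -> lowest code).
#' @export
cnn_predict <- function(model, X) {
  fw <- cnn_forward(model, X, training = FALSE)
  max.col(fw$probs, ties.method = "first") - 1L
}

eval_acc_loss <- function(model, X, y) {
  fw <- cnn_forward(model, X, training = FALSE)
  pred <- max.col(fw$probs, ties.method = "first") - 1L
  c(acc = 100 * sum(pred == y) / length(y), loss = cnn_loss(fw$probs, y))
}

stratified_holdout <- function(y, fraction) {
  test <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    n_test <- max(1L, round(fraction * length(idx)))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

#' Train and evaluate the convolutional classifier
#'
#' Stratified holdout split (default 80/20, seeded shuffle), cross-entropy
#' loss, Adam at the given learning rate, mini-batches of
#' `min(batch_size, n_train)`. Returns the held-out accuracy as a
#' [fitness_result()] together with per-epoch train/test accuracy and loss
#' curves. With `epochs = 0` the untrained network is evaluated (a chance
#'-level control) and the curves are empty.
#'
#' @param dataset An [expression_dataset()].
#' @param mask Logical gene mask (`NULL` selects every gene).
#' @param arch A [cnn_architecture()].
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size cap.
#' @param holdout Held-out fraction in `(0, 1)`.
#' @param seed Integer seed for the split, initialization and batching.
#' @return A list: `fitness` ([fitness_result()] on the held-out samples),
#'   `curves` (data frame `epoch`, `train_acc`, `test_acc`, `train_loss`,
#'   `test_loss`), `model`, `test_idx`.
#' @export
train_eval_cnn <- function(dataset, mask = NULL, arch = cnn_architecture(),
                           epochs = 50L, learning_rate = 1e-3,
                           batch_size = 16L, holdout = 0.2, seed = 1L) {
  if (is.null(mask)) mask <- rep(TRUE, n_genes(dataset))
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask must select at least one gene")
  X <- dataset$matrix[, mask, drop = FALSE]
  y <- dataset$labels
  C <- n_classes(dataset)
  set.seed(seed)
  test_idx <- stratified_holdout(y, holdout)
  train_idx <- setdiff(seq_len(nrow(X)), test_idx)
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  Xte <- X[test_idx, , drop = FALSE]
  yte <- y[test_idx]

  model <- build_cnn(ncol(X), C, arch)
  opt <- adam_init_like(model)
  bs <- min(batch_size, nrow(Xtr))
  curves <- data.frame(epoch = integer(), train_acc = numeric(),
                       test_acc = numeric(), train_loss = numeric(),
                       test_loss = numeric())
  for (e in seq_len(epochs)) {
    ord <- sample.int(nrow(Xtr))
    for (start in seq(1L, nrow(Xtr), by = bs)) {
      bi <- ord[start:min(start + bs - 1L, nrow(Xtr))]
      fw <- cnn_forward(model, Xtr[bi, , drop = FALSE], training = TRUE)
      model <- fw$model
      loss <- cnn_loss(fw$probs, ytr[bi])
      if (!is.finite(loss)) stop("training diverged (NaN loss) at epoch ", e)
      grads <- cnn_backward(model, fw, ytr[bi])
      upd <- adam_update(model, opt, grads, learning_rate)
      model <- upd$model
      opt <- upd$opt
    }
    tr <- eval_acc_loss(model, Xtr, ytr)
    te <- eval_acc_loss(model, Xte, yte)
    curves <- rbind(curves, data.frame(epoch = e, train_acc = tr[["acc"]],
                                       test_acc = te[["acc"]],
                                       train_loss = tr[["loss"]],
                                       test_loss = te[["loss"]]))
  }
  pred <- cnn_predict(model, Xte)
  list(fitness = fitness_result(pred, yte), curves = curves, model = model,
       test_idx = test_idx)
}

# LOOCV with the CNN: one training per fold; final-evaluation use only.
loocv_cnn <- function(X, y, C, arch = cnn_architecture(), epochs = 20L,
                      learning_rate = 1e-3, batch_size = 16L, seed = 1L) {
  n <- nrow(X)
  preds <- integer(n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    model <- build_cnn(ncol(X), C, arch)
    opt <- adam_init_like(model)
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    bs <- min(batch_size, nrow(Xtr))
    for (e in seq_len(epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (start in seq(1L, nrow(Xtr), by = bs)) {
        bi <- ord[start:min(start + bs - 1L, nrow(Xtr))]
        fw <- cnn_forward(model, Xtr[bi, , drop = FALSE], training = TRUE)
        model <- fw$model
        grads <- cnn_backward(model, fw, ytr[bi])
        upd <- adam_update(model, opt, grads, learning_rate)
        model <- upd$model
        opt <- upd$opt
      }
    }
    preds[i] <- cnn_predict(model, X[i, , drop = FALSE])
  }
  fitness_result(preds, y)
}
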