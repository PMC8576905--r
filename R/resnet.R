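#' Training protocol
#'
#' The declared, fully explicit training protocol: nothing about training is
#' implicit, so a protocol plus a seed reproduces a run bit-for-bit on the
#' same platform.
#'
#' @param epochs number of passes over the training split (default 10).
#' @param batch_size minibatch size (default 32).
#' @param input_resize `(height, width)` every image is resized to before
#'   entering the network (default 64 x 64).
#' @param seed integer seed controlling weight initialization and shuffling.
#' @param train_fraction fraction of the modeling pool assigned to the
#'   training split by the stratified random grouping (default 0.8).
#' @return An object of class `training_protocol`. The loss is always
#'   categorical cross-entropy.
#' @export
training_protocol <- function(epochs = 10L, batch_size = 32L,
                              input_resize = c(64L, 64L), seed = 1L,
                              train_fraction = 0.8) {
  stopifnot(epochs >= 1L, batch_size >= 1L, length(input_resize) == 2L,
            all(input_resize >= 4L), train_fraction > 0, train_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 input_resize = as.integer(input_resize),
                 seed = as.integer(seed),
                 train_fraction = train_fraction,
                 loss = "categorical_crossentropy"),
            class = "training_protocol")
}

#' Build a parametric residual network architecture
#'
#' The architecture is one stem convolution (`n_kernels` filters of size
#' `kernel_size`, stride 2, same padding) followed by a fixed 2 x 2 average
#' pooling, then `B = (n_layers - 2) / 2` identity residual blocks of two
#' same-shape convolutions each (skip connections add the block input
#' unchanged, so both endpoints always have identical shape), a single
#' average-pooling stage with window `pooling_size`, and one fully connected
#' softmax output layer. Weighted layers therefore count
#' `1 + 2B + 1 = n_layers`. All convolutions use the configured activation.
#'
#' A pooling window larger than the post-stem feature map is clipped to the
#' feature-map size with a warning rather than failing at small image sizes.
#'
#' @param config a [candidate_config()].
#' @param input_shape `(height, width, channels)`; channels must be 1.
#' @param n_classes number of output classes.
#' @return An object of class `resnet_architecture`.
#' @examples
#' cfg <- candidate_config(8, 3, 4, 14, "ReLU", "Adam")
#' build_resnet(cfg, c(64, 64, 1), 4)
#' @export
build_resnet <- function(config, input_shape = c(64L, 64L, 1L), n_classes) {
  stopifnot(inherits(config, "candidate_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || input_shape[3L] != 1L)
    stop("'input_shape' must be (height, width, 1)", call. = FALSE)
  if (n_classes < 1L) stop("'n_classes' must be positive", call. = FALSE)
  if ((config$n_layers - 2L) %% 2L != 0L)
    stop(sprintf(paste0(
      "n_layers = %d is invalid: (n_layers - 2) must be even to form ",
      "two-convolution residual blocks"), config$n_layers), call. = FALSE)
  B <- (config$n_layers - 2L) %/% 2L
  k <- config$kernel_size
  pad <- k %/% 2L
  H <- input_shape[1L]; W <- input_shape[2L]
  H1 <- (H + 2L * pad - k) %/% 2L + 1L
  W1 <- (W + 2L * pad - k) %/% 2L + 1L
  H2 <- (H1 + 1L) %/% 2L; W2 <- (W1 + 1L) %/% 2L
  win <- config$pooling_size
  if (win > min(H2, W2)) {
    warning(sprintf(
      "pooling window %d exceeds the %dx%d feature map; clipped to %d",
      win, H2, W2, min(H2, W2)), call. = FALSE)
    win <- min(H2, W2)
  }
  Hp <- (H2 + win - 1L) %/% win; Wp <- (W2 + win - 1L) %/% win
  C <- config$n_kernels
  layers <- list(list(
    type = "conv", name = "stem", kernels = C, kernel_size = k, stride = 2L,
    activation = config$activation, n_params = (k * k + 1L) * C,
    output_shape = c(H1, W1, C)))
  layers <- c(layers, list(list(
    type = "avgpool", name = "stem_pool", window = 2L,
    output_shape = c(H2, W2, C))))
  for (b in seq_len(B)) {
    layers <- c(layers, list(list(
      type = "residual_block", name = sprintf("block%d", b), kernels = C,
      kernel_size = k, stride = 1L, activation = config$activation,
      n_params = 2L * (C * k * k + 1L) * C,
      skip_from = c(H2, W2, C), skip_to = c(H2, W2, C),
      output_shape = c(H2, W2, C))))
  }
  layers <- c(layers, list(list(
    type = "avgpool", name = "pool", window = win,
    output_shape = c(Hp, Wp, C))))
  layers <- c(layers, list(list(
    type = "dense", name = "output", units = n_classes,
    activation = "softmax", n_params = (Hp * Wp * C + 1L) * n_classes,
    output_shape = c(n_classes))))
  structure(list(
    config = config, input_shape = input_shape, n_classes = as.integer(n_classes),
    layers = layers, weighted_layer_count = 2L + 2L * B,
    n_blocks = B,
    dims = list(k = k, pad = pad, C = C, H = H, W = W, H1 = H1, W1 = W1,
                H2 = H2, W2 = W2, win = win, Hp = Hp, Wp = Wp)),
    class = "resnet_architecture")
}

#' @export
print.resnet_architecture <- function(x, ...) {
  cat(sprintf(
    "resnet_architecture: %d weighted layers (%d residual blocks), %s/%s\n",
    x$weighted_layer_count, x$n_blocks, x$config$activation,
    x$config$optimizer))
  for (l in x$layers)
    cat(sprintf("  %-12s %-16s -> (%s)\n", l$type, l$name,
                paste(l$output_shape, collapse = "x")))
  invisible(x)
}

#' Write an architecture summary as JSON
#'
#' @param arch a `resnet_architecture`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_architecture_json <- function(arch, path) {
  obj <- list(weighted_layer_count = arch$weighted_layer_count,
              n_classes = arch$n_classes,
              input_shape = arch$input_shape,
              layers = arch$layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

## ---- activations -----------------------------------------------------

act_forward <- function(z, cfg) {
  switch(cfg$activation,
    ReLU = pmax(z, 0),
    LeakyReLU = ifelse(z > 0, z, cfg$leaky_slope * z),
    Tanh = tanh(z),
    SELU = cfg$selu_scale * ifelse(z > 0, z, cfg$selu_alpha * expm1(z)))
}

# derivative given pre-activation z and output a = act(z)
act_grad <- function(z, a, cfg) {
  switch(cfg$activation,
    ReLU = (z > 0) + 0,
    LeakyReLU = ifelse(z > 0, 1, cfg$leaky_slope),
    Tanh = 1 - a^2,
    SELU = ifelse(z > 0, cfg$selu_scale, a + cfg$selu_scale * cfg$selu_alpha))
}

## ---- parameters ------------------------------------------------------

# Activation-matched gaussian initialization (He for the rectifiers, LeCun
# for the self-normalizing/saturating ones), with each block's second
# convolution scaled down so residual blocks start near the identity —
# without normalization layers this keeps deep trunks numerically stable
# for every activation in the space. Call under an already-seeded RNG.
init_resnet_params <- function(arch) {
  d <- arch$dims
  gain <- if (arch$config$activation %in% c("ReLU", "LeakyReLU")) 2 else 1
  draw <- function(fan_in, n_out, scale = 1)
    matrix(stats::rnorm(fan_in * n_out, sd = scale * sqrt(gain / fan_in)),
           fan_in, n_out)
  list(stem = list(W = draw(d$k^2, d$C), b = numeric(d$C)),
       blocks = lapply(seq_len(arch$n_blocks), function(b)
         list(conv1 = list(W = draw(d$C * d$k^2, d$C), b = numeric(d$C)),
              conv2 = list(W = draw(d$C * d$k^2, d$C, scale = 0.1),
                           b = numeric(d$C)))),
       dense = list(W = draw(d$Hp * d$Wp * d$C, arch$n_classes),
                    b = numeric(arch$n_classes)))
}

## ---- forward / backward ---------------------------------------------

conv_apply <- function(A, layer_w, H, W, N, k, stride, pad) {
  P <- conv_im2col(A, H, W, N, k, stride, pad)
  Z <- P %*% layer_w$W
  Z <- sweep(Z, 2L, layer_w$b, `+`)
  list(Z = Z, P = P)
}

# X: (H*W*N) x 1 input batch. Returns logits and (optionally) caches.
forward_resnet <- function(params, arch, X, N, keep_cache = FALSE) {
  d <- arch$dims; cfg <- arch$config
  cache <- if (keep_cache) list(blocks = vector("list", arch$n_blocks))

  st <- conv_apply(X, params$stem, d$H, d$W, N, d$k, 2L, d$pad)
  A1 <- act_forward(st$Z, cfg)
  A <- pool_avg_fwd(A1, d$H1, d$W1, N, 2L)
  if (keep_cache) cache$stem <- list(P = st$P, Z = st$Z, A1 = A1)

  for (b in seq_len(arch$n_blocks)) {
    pb <- params$blocks[[b]]
    c1 <- conv_apply(A, pb$conv1, d$H2, d$W2, N, d$k, 1L, d$pad)
    Aa <- act_forward(c1$Z, cfg)
    c2 <- conv_apply(Aa, pb$conv2, d$H2, d$W2, N, d$k, 1L, d$pad)
    S <- c2$Z + A                       # identity skip connection
    Aout <- act_forward(S, cfg)
    if (keep_cache)
      cache$blocks[[b]] <- list(P1 = c1$P, Z1 = c1$Z, Aa = Aa, P2 = c2$P,
                                S = S, Aout = Aout, Ain = A)
    A <- Aout
  }

  Ap <- pool_avg_fwd(A, d$H2, d$W2, N, d$win)
  S2 <- d$Hp * d$Wp
  Fm <- t(matrix(aperm(array(Ap, c(S2, N, d$C)), c(1L, 3L, 2L)),
                 S2 * d$C, N))
  logits <- sweep(Fm %*% params$dense$W, 2L, params$dense$b, `+`)
  if (keep_cache) { cache$Fm <- Fm; cache$A_last <- A }
  list(logits = logits, cache = cache)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class indices 1..q. Returns loss and parameter gradients.
backward_resnet <- function(params, arch, fw, y, N) {
  d <- arch$dims; cfg <- arch$config
  cache <- fw$cache
  q <- arch$n_classes
  Pr <- softmax_rows(fw$logits)
  loss <- -mean(log(pmax(Pr[cbind(seq_len(N), y)], 1e-12)))
  dZ <- Pr
  dZ[cbind(seq_len(N), y)] <- dZ[cbind(seq_len(N), y)] - 1
  dZ <- dZ / N

  g_dense <- list(W = crossprod(cache$Fm, dZ), b = colSums(dZ))
  g_blocks <- vector("list", arch$n_blocks)
  dF <- dZ %*% t(params$dense$W)                        # N x (S2*C)
  S2 <- d$Hp * d$Wp
  dAp <- matrix(aperm(array(t(dF), c(S2, d$C, N)), c(1L, 3L, 2L)),
                S2 * N, d$C)
  dA <- pool_avg_bwd(dAp, d$H2, d$W2, N, d$win)

  for (b in rev(seq_len(arch$n_blocks))) {
    cb <- cache$blocks[[b]]; pb <- params$blocks[[b]]
    dS <- dA * act_grad(cb$S, cb$Aout, cfg)
    dW2 <- crossprod(cb$P2, dS); db2 <- colSums(dS)
    dAa <- conv_col2im(dS %*% t(pb$conv2$W), d$H2, d$W2, N, d$C, d$k, 1L,
                       d$pad)
    dZ1 <- dAa * act_grad(cb$Z1, cb$Aa, cfg)
    dW1 <- crossprod(cb$P1, dZ1); db1 <- colSums(dZ1)
    dA <- conv_col2im(dZ1 %*% t(pb$conv1$W), d$H2, d$W2, N, d$C, d$k, 1L,
                      d$pad) + dS                       # skip path
    g_blocks[[b]] <- list(conv1 = list(W = dW1, b = db1),
                          conv2 = list(W = dW2, b = db2))
  }

  dA1 <- pool_avg_bwd(dA, d$H1, d$W1, N, 2L)
  dZs <- dA1 * act_grad(cache$stem$Z, cache$stem$A1, cfg)
  # leaf order must mirror init_resnet_params for the optimizer walkers
  list(loss = loss,
       grads = list(stem = list(W = crossprod(cache$stem$P, dZs),
                                b = colSums(dZs)),
                    blocks = g_blocks, dense = g_dense))
}

## ---- optimizers ------------------------------------------------------

# Parameters are a nested list of (W, b) leaves; walk them generically,
# matching sub-lists by name where names exist.
map_leaves <- function(f, ...) {
  walk <- function(...) {
    xs <- list(...)
    if (is.numeric(xs[[1L]])) do.call(f, xs)
    else {
      keys <- if (is.null(names(xs[[1L]]))) seq_along(xs[[1L]])
              else names(xs[[1L]])
      out <- lapply(keys, function(i) do.call(walk, lapply(xs, `[[`, i)))
      names(out) <- names(xs[[1L]])
      out
    }
  }
  walk(...)
}

make_opt_state <- function(params, config) {
  if (config$optimizer == "SGD") return(list(t = 0L))
  list(t = 0L,
       m = map_leaves(function(p) p * 0, params),
       v = map_leaves(function(p) p * 0, params))
}

# Global L2 gradient-norm clipping: plain SGD on an unnormalized deep
# trunk can take destabilizing steps on rare batches; clipping at a large
# norm leaves ordinary steps untouched.
clip_grads <- function(grads, max_norm = 5) {
  total <- 0
  walk_sum <- function(x) {
    if (is.numeric(x)) total <<- total + sum(x^2)
    else for (el in x) walk_sum(el)
  }
  walk_sum(grads)
  nrm <- sqrt(total)
  if (is.finite(nrm) && nrm > max_norm)
    grads <- map_leaves(function(g) g * (max_norm / nrm), grads)
  grads
}

opt_step <- function(params, grads, state, config) {
  state$t <- state$t + 1L
  if (config$optimizer == "SGD") {
    params <- map_leaves(function(p, g) p - config$eta * g, params, grads)
  } else {
    b1 <- 0.9; b2 <- 0.999
    state$m <- map_leaves(function(m, g) b1 * m + (1 - b1) * g,
                          state$m, grads)
    state$v <- map_leaves(function(v, g) b2 * v + (1 - b2) * g^2,
                          state$v, grads)
    corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
    params <- map_leaves(function(p, m, v)
      p - config$eta * (m / corr1) / (sqrt(v / corr2) + config$adam_epsilon),
      params, state$m, state$v)
  }
  list(params = params, state = state)
}

## ---- data plumbing ---------------------------------------------------

# Stack a list of images into the (H*W*N) x 1 batch matrix, resizing when
# an image does not match the target height/width.
images_to_batch <- function(images, H, W) {
  n <- length(images)
  X <- matrix(0, H * W * n, 1L)
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (nrow(img) != H || ncol(img) != W)
      img <- t(EBImage::imageData(
        EBImage::resize(EBImage::Image(t(img)), w = W, h = H)))
    X[((i - 1L) * H * W + 1L):(i * H * W), 1L] <- as.numeric(img)
  }
  X
}

## ---- training --------------------------------------------------------

#' Train a residual network under a declared protocol
#'
#' Optimizes categorical cross-entropy with the configuration's optimizer
#' and constants. All randomness (weight initialization, epoch shuffling)
#' derives from `protocol$seed`, so the same seed, data and platform give
#' bit-identical results.
#'
#' @param arch a [build_resnet()] architecture; its class count must equal
#'   the number of classes of `train_set`.
#' @param train_set,val_set disjoint [labeled_image_set()]s over the same
#'   class alphabet; every class must be present in `train_set`.
#' @param protocol a [training_protocol()].
#' @return An object of class `trained_resnet` carrying the learned weights,
#'   `train_accuracy`, `validation_accuracy`, per-epoch `loss_history`, the
#'   class alphabet and the seed.
#' @export
train_model <- function(arch, train_set, val_set, protocol) {
  stopifnot(inherits(arch, "resnet_architecture"),
            inherits(train_set, "labeled_image_set"),
            inherits(protocol, "training_protocol"))
  if (length(train_set) == 0L) stop("empty training split", call. = FALSE)
  classes <- train_set$class_labels
  counts <- tabulate(factor(train_set$labels, classes), length(classes))
  if (any(counts == 0L))
    stop(sprintf("class absent from the training split: %s",
                 paste(classes[counts == 0L], collapse = ", ")),
         call. = FALSE)
  if (!is.null(val_set)) {
    stopifnot(inherits(val_set, "labeled_image_set"))
    if (!all(val_set$labels %in% classes))
      stop("validation split contains labels outside the training alphabet",
           call. = FALSE)
  }
  if (arch$n_classes != length(classes))
    stop(sprintf("architecture has %d classes but the data alphabet has %d",
                 arch$n_classes, length(classes)), call. = FALSE)

  d <- arch$dims
  y <- as.integer(factor(train_set$labels, classes))
  Xall <- images_to_batch(train_set$images, d$H, d$W)
  n <- length(train_set)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(protocol$seed)
  params <- init_resnet_params(arch)
  state <- make_opt_state(params, arch$config)
  loss_history <- numeric(protocol$epochs)

  px <- d$H * d$W
  for (ep in seq_len(protocol$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = protocol$batch_size)) {
      idx <- ord[start:min(start + protocol$batch_size - 1L, n)]
      N <- length(idx)
      rows <- as.integer(outer(seq_len(px), (idx - 1L) * px, `+`))
      Xb <- Xall[rows, , drop = FALSE]
      fw <- forward_resnet(params, arch, Xb, N, keep_cache = TRUE)
      bw <- backward_resnet(params, arch, fw, y[idx], N)
      losses <- c(losses, bw$loss)
      if (!is.finite(bw$loss)) next        # skip a degenerate batch
      upd <- opt_step(params, clip_grads(bw$grads), state, arch$config)
      params <- upd$params; state <- upd$state
    }
    loss_history[ep] <- mean(losses)
  }

  model <- structure(list(
    architecture = arch, params = params, class_labels = classes,
    seed = protocol$seed, protocol = protocol,
    loss_history = loss_history), class = "trained_resnet")
  model$train_accuracy <- mean(predict(model, train_set) == train_set$labels)
  model$validation_accuracy <- if (!is.null(val_set) && length(val_set))
    mean(predict(model, val_set) == val_set$labels) else NA_real_
  model
}

#' Predict class labels with a trained residual network
#'
#' Softmax argmax per image; ties are broken towards the lowest class index.
#'
#' @param object a `trained_resnet`.
#' @param newdata a [labeled_image_set()] or list of image matrices.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Character vector of predicted labels (empty input, empty output).
#' @export
predict.trained_resnet <- function(object, newdata, batch_size = 64L, ...) {
  images <- if (inherits(newdata, "labeled_image_set")) newdata$images
            else newdata
  if (!length(images)) return(character(0))
  d <- object$architecture$dims
  out <- character(length(images))
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    Xb <- images_to_batch(images[idx], d$H, d$W)
    fw <- forward_resnet(object$params, object$architecture, Xb,
                         length(idx))
    cls <- max.col(fw$logits, ties.method = "first")
    out[idx] <- object$class_labels[cls]
  }
  out
}

#' @export
print.trained_resnet <- function(x, ...) {
  cat(sprintf(
    "trained_resnet: seed %d, train accuracy %.4f, validation accuracy %s\n",
    x$seed, x$train_accuracy,
    ifelse(is.na(x$validation_accuracy), "NA",
           sprintf("%.4f", x$validation_accuracy))))
  invisible(x)
}

#' The default trainer: build and fit a residual network
#'
#' Trainers are the injection seam of the experiment runner: any function
#' with the signature `function(config, train_set, val_set, protocol, info)`
#' returning `list(train_accuracy, validation_accuracy, model)` can stand in
#' (see [accuracy_stub_trainer()]). This one builds the residual
#' architecture for `config` and trains it with [train_model()].
#'
#' @return A trainer function.
#' @export
resnet_trainer <- function() {
  function(config, train_set, val_set, protocol, info = NULL) {
    arch <- build_resnet(config,
                         input_shape = c(protocol$input_resize, 1L),
                         n_classes = length(train_set$class_labels))
    model <- train_model(arch, train_set, val_set, protocol)
    list(train_accuracy = model$train_accuracy,
         validation_accuracy = model$validation_accuracy,
         model = model)
  }
}

#' A stub trainer returning scripted accuracies
#'
#' Replays fixed train/validation accuracy tables instead of training, so
#' the replicate/SNR/selection pipeline can be exercised (and verified
#' against published tables) without any model fitting. `train_acc` and
#' `val_acc` are matrices indexed `[combination, replicate]`.
#'
#' @param train_acc,val_acc numeric matrices of scripted accuracies.
#' @return A trainer function compatible with [run_combination()].
#' @export
accuracy_stub_trainer <- function(train_acc, val_acc = train_acc) {
  train_acc <- as.matrix(train_acc); val_acc <- as.matrix(val_acc)
  function(config, train_set, val_set, protocol, info = NULL) {
    stopifnot(!is.null(info))
    list(train_accuracy = train_acc[info$combination, info$replicate],
         validation_accuracy = val_acc[info$combination, info$replicate],
         model = NULL)
  }
}
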