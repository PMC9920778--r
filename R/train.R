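# Binarization-aware training.
#
# Forward passes binarize latent weights (sign, with sign(0) -> +1) and
# activations; gradients pass through the sign non-linearity with the
# straight-through estimator, gated to |pre-activation| <= 1, and latent
# weights are clipped to [-1, 1] after every update.  Batch normalization is
# trained in float and folded into integer thresholds at export time.

#' Training configuration
#'
#' Defaults mirror the reference training recipe: Adam, cross-entropy,
#' 200 epochs, batch size 128, and a piecewise-constant learning rate of
#' 0.01 / 0.005 / 0.0005 / 0.00005 / 0.000005 switching at epochs 0, 40, 80,
#' 120 and 160, with an 80/20 stratified train/validation split.
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param lr_schedule named numeric vector: names are 0-based epoch indices
#'   at which each rate takes effect.
#' @param train_fraction fraction of the data used for training.
#' @param seed RNG seed for weight init and batch shuffling.
#' @param split_seed RNG seed for the train/validation split (kept separate
#'   from `seed` so the split is stable across initializations).
#' @param eps batch-normalization stabilizer.
#' @param bn_momentum running-statistics update rate.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 128,
                         lr_schedule = c(`0` = 0.01, `40` = 0.005,
                                         `80` = 0.0005, `120` = 0.00005,
                                         `160` = 0.000005),
                         train_fraction = 0.8,
                         seed = 1L, split_seed = seed + 1000L,
                         eps = 1e-5, bn_momentum = 0.1) {
  keys <- as.numeric(names(lr_schedule))
  if (anyNA(keys) || is.unsorted(keys, strictly = TRUE)) {
    stop_config("lr_schedule epochs must be strictly increasing")
  }
  if (any(lr_schedule <= 0)) stop_config("learning rates must be > 0")
  if (keys[1] != 0) stop_config("lr_schedule must define a rate for epoch 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_schedule = lr_schedule,
                 train_fraction = train_fraction,
                 seed = as.integer(seed),
                 split_seed = as.integer(split_seed),
                 eps = eps, bn_momentum = bn_momentum),
            class = "train_config")
}

#' Learning rate in effect at a given epoch
#'
#' @param config a [train_config()] (or a named schedule vector).
#' @param epoch 0-based epoch index.
#' @return the learning rate of the last schedule entry at or before `epoch`.
#' @export
lr_at_epoch <- function(config, epoch) {
  sched <- if (inherits(config, "train_config")) config$lr_schedule else config
  keys <- as.numeric(names(sched))
  unname(sched[max(which(keys <= epoch))])
}

init_float_network <- function(spec, seed, eps = 1e-5) {
  with_seed(seed, {
    layers <- list()
    for (l in seq_along(spec$conv)) {
      g <- spec$conv[[l]]
      layers[[l]] <- list(
        type = "conv",
        W = array(runif(g$weights, -1, 1),
                  dim = c(g$c_out, g$c_in, spec$kernel, spec$kernel)),
        bn = list(gamma = rep(1, g$c_out), beta = rep(0, g$c_out),
                  mu = rep(0, g$c_out), var = rep(1, g$c_out)))
    }
    off <- length(spec$conv)
    for (l in seq_along(spec$fc)) {
      g <- spec$fc[[l]]
      layers[[off + l]] <- list(
        type = "fc",
        W = matrix(runif(g$weights, -1, 1), nrow = g$n_out, ncol = g$n_in),
        bn = if (g$final) NULL else
          list(gamma = rep(1, g$n_out), beta = rep(0, g$n_out),
               mu = rep(0, g$n_out), var = rep(1, g$n_out)))
    }
    structure(list(spec = spec, layers = layers, eps = eps,
                   input_thresholds = NULL, history = NULL),
              class = "float_network")
  })
}

bn_forward <- function(acc, bn, eps, training, momentum, state = NULL) {
  if (training) {
    mu <- rowMeans(acc)
    v <- rowMeans(acc^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- bn$mu
    v <- bn$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (acc - mu) * istd
  y <- bn$gamma * xhat + bn$beta
  list(y = y, xhat = xhat, istd = istd, mu = mu, var = v)
}

pool_forward <- function(a) {
  d <- dim(a)  # (C,H,W,B)
  o1 <- seq(1, d[2], 2); o2 <- seq(1, d[3], 2)
  x11 <- a[, o1, o2, , drop = FALSE]; x21 <- a[, o1 + 1, o2, , drop = FALSE]
  x12 <- a[, o1, o2 + 1, , drop = FALSE]; x22 <- a[, o1 + 1, o2 + 1, , drop = FALSE]
  out <- pmax(x11, x21, x12, x22)
  list(out = out, x = list(x11, x21, x12, x22))
}

pool_backward <- function(dout, cache, dims) {
  out <- pmax(cache$x[[1]], cache$x[[2]], cache$x[[3]], cache$x[[4]])
  taken <- array(FALSE, dim = dim(out))
  dx <- array(0, dim = dims)
  o1 <- seq(1, dims[2], 2); o2 <- seq(1, dims[3], 2)
  slices <- list(list(o1, o2), list(o1 + 1, o2), list(o1, o2 + 1),
                 list(o1 + 1, o2 + 1))
  for (i in 1:4) {
    m <- (cache$x[[i]] == out) & !taken   # route to the first maximum
    dx[, slices[[i]][[1]], slices[[i]][[2]], ] <- dout * m
    taken <- taken | m
  }
  dx
}

# Full forward pass; X is (C, H, W, B).  Returns logits and, when
# keep_cache, everything the backward pass needs.
train_forward <- function(net, X, training = TRUE, keep_cache = training) {
  spec <- net$spec
  eps <- net$eps
  k <- spec$kernel; pad <- spec$padding
  B <- dim(X)[4]
  caches <- list()
  a <- X
  for (l in seq_along(spec$conv)) {
    g <- spec$conv[[l]]
    d <- dim(a)
    cols <- im2col_cpp(a, d[1], d[2], d[3], B, k, pad)
    Wb <- matrix(sign0(net$layers[[l]]$W), nrow = g$c_out)
    acc <- Wb %*% cols
    bnf <- bn_forward(acc, net$layers[[l]]$bn, eps, training)
    act <- sign0(bnf$y)
    a4 <- array(act, dim = c(g$c_out, d[2], d[3], B))
    pc <- NULL
    if (g$pool) {
      pc <- pool_forward(a4)
      a_next <- pc$out
    } else {
      a_next <- a4
    }
    caches[[l]] <- if (keep_cache) {
      list(cols = cols, Wb = Wb, bnf = bnf, y = bnf$y, pool = pc,
           in_dims = d, act_dims = dim(a4))
    } else NULL
    a <- a_next
  }
  nodes <- matrix(a, nrow = spec$flatten, ncol = B)
  off <- length(spec$conv)
  for (l in seq_along(spec$fc)) {
    g <- spec$fc[[l]]
    Wb <- matrix(sign0(net$layers[[off + l]]$W), nrow = g$n_out)
    acc <- Wb %*% nodes
    if (g$final) {
      caches[[off + l]] <- if (keep_cache) list(Wb = Wb, input = nodes) else NULL
      logits <- acc
    } else {
      bnf <- bn_forward(acc, net$layers[[off + l]]$bn, eps, training)
      act <- sign0(bnf$y)
      caches[[off + l]] <- if (keep_cache) {
        list(Wb = Wb, input = nodes, bnf = bnf, y = bnf$y)
      } else NULL
      nodes <- act
    }
  }
  list(logits = logits, caches = caches, flatten_dims = dim(a))
}

softmax_xent <- function(logits, labels) {
  B <- ncol(logits)
  m <- apply(logits, 2, max)
  z <- sweep(logits, 2, m)
  lse <- log(colSums(exp(z)))
  picked <- z[cbind(labels, seq_len(B))]
  loss <- mean(lse - picked)
  p <- sweep(exp(z), 2, exp(lse), "/")
  dlogits <- p
  dlogits[cbind(labels, seq_len(B))] <- dlogits[cbind(labels, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B)
}

bn_backward <- function(dY, bnf, gamma) {
  N <- ncol(dY)
  dgamma <- rowSums(dY * bnf$xhat)
  dbeta <- rowSums(dY)
  dXhat <- dY * gamma
  s1 <- rowSums(dXhat)
  s2 <- rowSums(dXhat * bnf$xhat)
  dAcc <- bnf$istd * (dXhat - s1 / N - bnf$xhat * (s2 / N))
  list(dAcc = dAcc, dgamma = dgamma, dbeta = dbeta)
}

train_backward <- function(net, fwd, dlogits) {
  spec <- net$spec
  k <- spec$kernel; pad <- spec$padding
  off <- length(spec$conv)
  grads <- vector("list", length(net$layers))
  d_nodes <- NULL
  for (l in rev(seq_along(spec$fc))) {
    g <- spec$fc[[l]]
    cache <- fwd$caches[[off + l]]
    if (g$final) {
      dAcc <- dlogits
    } else {
      dA <- d_nodes
      dY <- dA * (abs(cache$y) <= 1)          # STE gate
      bb <- bn_backward(dY, cache$bnf, net$layers[[off + l]]$bn$gamma)
      dAcc <- bb$dAcc
      grads[[off + l]]$dgamma <- bb$dgamma
      grads[[off + l]]$dbeta <- bb$dbeta
    }
    grads[[off + l]]$dW <- dAcc %*% t(cache$input)
    d_nodes <- t(cache$Wb) %*% dAcc
  }
  # reshape flatten gradient back to the last conv output
  d_a <- array(d_nodes, dim = fwd$flatten_dims)
  for (l in rev(seq_along(spec$conv))) {
    g <- spec$conv[[l]]
    cache <- fwd$caches[[l]]
    if (g$pool) {
      d_a <- pool_backward(d_a, cache$pool, cache$act_dims)
    }
    B <- cache$act_dims[4]
    dA <- matrix(d_a, nrow = g$c_out)
    dY <- dA * (abs(cache$y) <= 1)
    bb <- bn_backward(dY, cache$bnf, net$layers[[l]]$bn$gamma)
    grads[[l]]$dgamma <- bb$dgamma
    grads[[l]]$dbeta <- bb$dbeta
    dWmat <- bb$dAcc %*% t(cache$cols)
    grads[[l]]$dW <- array(dWmat, dim = dim(net$layers[[l]]$W))
    if (l > 1) {
      dCols <- crossprod(cache$Wb, bb$dAcc)
      d_a <- array(col2im_cpp(dCols, cache$in_dims[1], cache$in_dims[2],
                              cache$in_dims[3], B, k, pad),
                   dim = cache$in_dims)
    }
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(L) {
    st <- list(mW = array(0, dim = dim(L$W)), vW = array(0, dim = dim(L$W)))
    if (!is.null(L$bn)) {
      st$mg <- numeric(length(L$bn$gamma)); st$vg <- st$mg
      st$mb <- st$mg; st$vb <- st$mg
    }
    st
  })
}

adam_step <- function(val, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, ad_eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(val = val - lr * mhat / (sqrt(vhat) + ad_eps), m = m, v = v)
}

update_network <- function(net, grads, opt, lr, t, momentum) {
  for (l in seq_along(net$layers)) {
    L <- net$layers[[l]]
    st <- opt[[l]]
    up <- adam_step(L$W, grads[[l]]$dW, st$mW, st$vW, lr, t)
    L$W <- pmin(pmax(up$val, -1), 1)          # latent weight clipping
    st$mW <- up$m; st$vW <- up$v
    if (!is.null(L$bn)) {
      up <- adam_step(L$bn$gamma, grads[[l]]$dgamma, st$mg, st$vg, lr, t)
      L$bn$gamma <- up$val; st$mg <- up$m; st$vg <- up$v
      up <- adam_step(L$bn$beta, grads[[l]]$dbeta, st$mb, st$vb, lr, t)
      L$bn$beta <- up$val; st$mb <- up$m; st$vb <- up$v
    }
    net$layers[[l]] <- L
    opt[[l]] <- st
  }
  list(net = net, opt = opt)
}

update_running_stats <- function(net, fwd, momentum) {
  for (l in seq_along(net$layers)) {
    cache <- fwd$caches[[l]]
    if (is.null(net$layers[[l]]$bn) || is.null(cache$bnf)) next
    bn <- net$layers[[l]]$bn
    bn$mu <- (1 - momentum) * bn$mu + momentum * cache$bnf$mu
    bn$var <- (1 - momentum) * bn$var + momentum * cache$bnf$var
    net$layers[[l]]$bn <- bn
  }
  net
}

#' Per-bin input binarization thresholds
#'
#' The per-frequency-bin median of the training spectrograms; a pixel maps
#' to +1 iff its magnitude reaches its bin's median.  Computed once before
#' training and frozen, so training and inference binarize identically.
#'
#' @param x `32 x 32 x N` spectrogram array.
#' @return numeric vector, one threshold per frequency bin (row).
#' @export
input_bin_thresholds <- function(x) {
  apply(x, 1, median)
}

#' Stratified train/validation split
#'
#' @param labels integer class labels.
#' @param train_fraction fraction per class assigned to training.
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `val`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_tr <- max(1, round(length(idx) * train_fraction))
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, val = setdiff(seq_along(labels), train))
  })
}

#' Train the binarized network
#'
#' Binarization-aware training: the forward pass uses sign-binarized weights
#' and activations end to end (in `binary_input` mode the spectrogram itself
#' is binarized against frozen per-bin thresholds), gradients flow through
#' the straight-through estimator, and full-precision latent weights and
#' batch-norm parameters are updated with Adam under the configured
#' learning-rate schedule.  Deterministic for a fixed config up to
#' floating-point reduction order.
#'
#' @param data a `semg_trials` list (preprocessed internally) or a list with
#'   elements `x` (`32 x 32 x N` array) and `labels`.
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @param stft,filter preprocessing configuration used when `data` is a
#'   trial list.
#' @param verbose print a line per epoch.
#' @return a `float_network` with trained latent weights, batch-norm
#'   parameters (running statistics for export), frozen input thresholds,
#'   the split, and a per-epoch history data.frame (epoch, lr, loss,
#'   train_acc, val_acc).
#' @export
train_bnn <- function(data, spec = preset_network(1), config = train_config(),
                      stft = stft_config(), filter = harmonic_filter_spec(),
                      verbose = FALSE) {
  if (inherits(data, "semg_trials")) {
    data <- spectrogram_dataset(data, stft, filter)
  }
  x <- data$x
  labels <- as.integer(data$labels)
  if (any(table(labels) < 2)) stop_config("need >= 2 examples per class")
  split <- stratified_split(labels, config$train_fraction, config$split_seed)
  thr <- input_bin_thresholds(x[, , split$train, drop = FALSE])
  net <- init_float_network(spec, config$seed, config$eps)
  net$input_thresholds <- thr
  N <- length(labels)
  H <- dim(x)[1]; W <- dim(x)[2]
  X <- array(0, dim = c(1, H, W, N))
  if (spec$first_layer_mode == "binary_input") {
    for (i in seq_len(N)) X[1, , , i] <- 2 * (x[, , i] >= thr) - 1
  } else {
    for (i in seq_len(N)) X[1, , , i] <- x[, , i]
  }
  opt <- adam_init(net)
  t_step <- 0
  hist <- list()
  tr <- split$train
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at_epoch(config, epoch)
      order <- sample(tr)
      ep_loss <- 0; ep_correct <- 0
      n_batches <- 0
      for (start in seq(1, length(order), by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1, length(order))]
        Xb <- X[, , , idx, drop = FALSE]
        yb <- labels[idx]
        fwd <- train_forward(net, Xb, training = TRUE)
        sx <- softmax_xent(fwd$logits, yb)
        ep_loss <- ep_loss + sx$loss
        ep_correct <- ep_correct + sum(max.col(t(fwd$logits),
                                               ties.method = "first") == yb)
        n_batches <- n_batches + 1
        grads <- train_backward(net, fwd, sx$dlogits)
        net <- update_running_stats(net, fwd, config$bn_momentum)
        t_step <- t_step + 1
        res <- update_network(net, grads, opt, lr, t_step, config$bn_momentum)
        net <- res$net; opt <- res$opt
      }
      val_acc <- NA_real_
      if (length(split$val) > 0) {
        val_acc <- eval_accuracy(net, X[, , , split$val, drop = FALSE],
                                 labels[split$val])
      }
      hist[[epoch + 1]] <- data.frame(
        epoch = epoch, lr = lr, loss = ep_loss / n_batches,
        train_acc = ep_correct / length(order), val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d lr %.6f loss %.4f train %.3f val %.3f",
                        epoch, lr, ep_loss / n_batches,
                        ep_correct / length(order), val_acc))
      }
    }
  })
  net$history <- do.call(rbind, hist)
  net$split <- split
  net$config <- config
  net
}

# Accuracy of the float network (running BN statistics) on pre-binarized
# inputs; chunked to bound im2col memory.
eval_accuracy <- function(net, X, labels, chunk = 256) {
  N <- dim(X)[4]
  correct <- 0
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    fwd <- train_forward(net, X[, , , idx, drop = FALSE], training = FALSE,
                         keep_cache = FALSE)
    correct <- correct + sum(max.col(t(fwd$logits), ties.method = "first") ==
                               labels[idx])
  }
  correct / N
}

#' Fold batch normalization + sign activation into integer thresholds
#'
#' With `s = sqrt(var + eps)` the channel fires (+1) iff
#' `gamma * (x - mu) / s + beta >= 0`.  For `gamma > 0` this is
#' `x >= t` with `t = mu - beta * s / gamma`, i.e. an integer accumulator
#' fires iff `x >= ceiling(t)` (direction `ge`).  For `gamma < 0` it is
#' `x <= t`, i.e. `x < floor(t) + 1` (direction `lt`).  `gamma = 0` makes
#' the channel constant at `sign(beta)` (with sign(0) -> +1).  The
#' boundary handling makes the integer comparison agree with the float
#' sign for every integer accumulator, including `BN(x) = 0 -> +1`.
#'
#' @param bn list with per-channel `gamma`, `beta`, `mu`, `var`.
#' @param eps batch-normalization stabilizer.
#' @return a [threshold_params()].
#' @export
fold_bn_to_thresholds <- function(bn, eps = 1e-5) {
  if (!all(is.finite(bn$gamma)) || !all(is.finite(bn$beta)) ||
      !all(is.finite(bn$mu)) || !all(is.finite(bn$var))) {
    stop("non-finite batch-normalization parameters", call. = FALSE)
  }
  n <- length(bn$gamma)
  s <- sqrt(bn$var + eps)
  t_real <- bn$mu - bn$beta * s / bn$gamma
  # keep the integer conversion safe; anything this far out of the
  # achievable accumulator range becomes a constant channel downstream
  t_real <- pmin(pmax(t_real, -2^30), 2^30)
  theta <- integer(n)
  direction <- character(n)
  constant <- rep(NA_integer_, n)
  for (ch in seq_len(n)) {
    if (bn$gamma[ch] > 0) {
      theta[ch] <- as.integer(ceiling(t_real[ch]))
      direction[ch] <- "ge"
    } else if (bn$gamma[ch] < 0) {
      theta[ch] <- as.integer(floor(t_real[ch]) + 1)
      direction[ch] <- "lt"
    } else {
      theta[ch] <- 0L
      direction[ch] <- "ge"
      constant[ch] <- as.integer(sign0(bn$beta[ch]))
    }
  }
  threshold_params(theta, direction, constant)
}

#' Quantize thresholds to the 14-bit hardware range
#'
#' Clamps thresholds to `[-8192, 8191]` and converts channels whose
#' threshold lies outside the achievable accumulator range `[-fan_in,
#' fan_in]` into constant outputs (which is exact, the comparison can never
#' flip).  Channels that were genuinely clamped are reported in the
#' `"clamped"` attribute.
#'
#' @param params a [threshold_params()].
#' @param fan_in maximum accumulator magnitude of the layer.
#' @return a [threshold_params()] with 14-bit thresholds.
#' @export
quantize_thresholds <- function(params, fan_in) {
  lo <- -8192L; hi <- 8191L
  theta <- params$theta
  direction <- params$direction
  constant <- params$constant
  for (ch in seq_along(theta)) {
    if (!is.na(constant[ch])) next
    th <- theta[ch]
    if (direction[ch] == "ge") {
      # fires iff acc >= th
      if (th > fan_in) constant[ch] <- -1L
      else if (th <= -fan_in) constant[ch] <- 1L
    } else {
      # fires iff acc < th
      if (th > fan_in) constant[ch] <- 1L
      else if (th <= -fan_in) constant[ch] <- -1L
    }
  }
  clamped <- which(is.na(constant) & (theta < lo | theta > hi))
  theta <- pmin(pmax(theta, lo), hi)
  out <- threshold_params(theta, direction, constant)
  attr(out, "clamped") <- clamped
  out
}

#' Assemble an inference model from binarized components
#'
#' Packs +/-1 weights into the XNOR-popcount engine layout and attaches the
#' per-channel thresholds; the result is what [forward_bnn()] and the model
#' serialization consume.
#'
#' @param spec a [network_spec()].
#' @param weights list of +/-1 weight tensors, conv layers first (arrays
#'   dim `c(C_out, C_in, k, k)`) then FC matrices (`n_out x n_in`).
#' @param thresholds list of [threshold_params()], one per layer except the
#'   final FC layer (use `NULL` there).
#' @param input_thresholds per-bin input binarization thresholds
#'   (`binary_input` mode).
#' @return object of class `bnn_model`.
#' @export
bnn_model <- function(spec, weights, thresholds, input_thresholds = NULL) {
  n_conv <- length(spec$conv)
  n_layers <- n_conv + length(spec$fc)
  if (length(weights) != n_layers) stop_config("need %d weight tensors", n_layers)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_conv)) {
    g <- spec$conv[[l]]
    w <- weights[[l]]
    if (!identical(dim(w), as.integer(c(g$c_out, g$c_in, spec$kernel, spec$kernel)))) {
      stop_config("conv %d weight dims mismatch", l)
    }
    if (length(thresholds[[l]]$theta) != g$c_out) {
      stop_config("conv %d needs %d thresholds", l, g$c_out)
    }
    layers[[l]] <- list(w = w, wpack = pack_conv_weights(w),
                        thresholds = thresholds[[l]])
  }
  for (l in seq_along(spec$fc)) {
    g <- spec$fc[[l]]
    w <- weights[[n_conv + l]]
    if (!identical(dim(w), as.integer(c(g$n_out, g$n_in)))) {
      stop_config("fc %d weight dims mismatch", l)
    }
    th <- if (g$final) NULL else thresholds[[n_conv + l]]
    if (!g$final && length(th$theta) != g$n_out) {
      stop_config("fc %d needs %d thresholds", l, g$n_out)
    }
    layers[[n_conv + l]] <- list(w = w, wpack = pack_fc_weights(w),
                                 thresholds = th)
  }
  if (spec$first_layer_mode == "binary_input" && is.null(input_thresholds)) {
    stop_config("binary_input mode requires input_thresholds")
  }
  structure(list(spec = spec, layers = layers,
                 input_thresholds = input_thresholds),
            class = "bnn_model")
}

#' Fold a trained float network into a packed inference model
#'
#' Binarizes the latent weights (sign, with sign(0) -> +1), folds every
#' batch-normalization + sign pair into an integer threshold via
#' [fold_bn_to_thresholds()] using the running statistics, quantizes
#' thresholds to 14 bits with [quantize_thresholds()], and packs everything
#' for the XNOR-popcount engine.
#'
#' @param net a trained `float_network`.
#' @return a `bnn_model`.
#' @export
fold_network <- function(net) {
  spec <- net$spec
  n_conv <- length(spec$conv)
  weights <- list()
  thresholds <- list()
  for (l in seq_along(net$layers)) {
    L <- net$layers[[l]]
    wpm <- sign0(L$W)
    if (L$type == "conv") {
      weights[[l]] <- array(wpm, dim = dim(L$W))
      fan <- spec$conv[[l]]$fan_in
    } else {
      weights[[l]] <- matrix(wpm, nrow = nrow(L$W))
      fan <- spec$fc[[l - n_conv]]$fan_in
    }
    if (!is.null(L$bn)) {
      th <- fold_bn_to_thresholds(L$bn, net$eps)
      thresholds[[l]] <- quantize_thresholds(th, fan)
    } else {
      thresholds[l] <- list(NULL)
    }
  }
  bnn_model(spec, weights, thresholds, net$input_thresholds)
}

#' @export
print.bnn_model <- function(x, ...) {
  p <- count_parameters(x$spec)
  cat(sprintf("<bnn_model> %s | %s weight bits, %s thresholds, mode %s\n",
              paste(c(x$spec$conv_filters, x$spec$fc_nodes), collapse = "-"),
              format(p$weight_bits, big.mark = ","),
              format(p$thresholds, big.mark = ","),
              x$spec$first_layer_mode))
  invisible(x)
}
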