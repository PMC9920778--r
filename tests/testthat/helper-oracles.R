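# Independent oracles used to cross-check the package's optimized paths.
# These deliberately use naive formulations (O(N^2) DFT, dense +/-1
# arithmetic with explicit zero padding) and never call the code they check.

# O(N^2) discrete Fourier transform.
naive_dft <- function(x) {
  n <- length(x)
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  as.vector(W %*% x)
}

rand_pm <- function(n) sample(c(-1, 1), n, replace = TRUE)

rand_pm_array <- function(dims) array(rand_pm(prod(dims)), dim = dims)

# Dense +/-1 cross-correlation with literal zero padding (padded taps
# contribute 0 because the padded array holds zeros there).
ref_conv2d_pm <- function(x, w, pad = 1) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Cout <- dim(w)[1]; k <- dim(w)[3]
  xp <- array(0, dim = c(C, H + 2 * pad, W + 2 * pad))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  acc <- array(0, dim = c(Cout, H, W))
  for (j in seq_len(Cout)) {
    for (y in seq_len(H)) {
      for (xx in seq_len(W)) {
        win <- xp[, (y):(y + k - 1), (xx):(xx + k - 1), drop = FALSE]
        acc[j, y, xx] <- sum(win * array(w[j, , , ], dim = dim(win)))
      }
    }
  }
  storage.mode(acc) <- "integer"
  acc
}

# Per-channel threshold comparison on plain integers.
ref_threshold <- function(acc, th) {
  d <- dim(acc)
  out <- array(0, dim = d)
  for (ch in seq_len(d[1])) {
    out[ch, , ] <- if (!is.na(th$constant[ch])) {
      th$constant[ch]
    } else if (th$direction[ch] == "ge") {
      ifelse(acc[ch, , ] >= th$theta[ch], 1, -1)
    } else {
      ifelse(acc[ch, , ] < th$theta[ch], 1, -1)
    }
  }
  out
}

# 2x2 stride-2 max pooling on +/-1 values.
ref_pool2 <- function(a) {
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2] / 2, d[3] / 2))
  for (y in seq_len(d[2] / 2)) {
    for (x in seq_len(d[3] / 2)) {
      out[, y, x] <- apply(a[, (2 * y - 1):(2 * y), (2 * x - 1):(2 * x),
                             drop = FALSE], 1, max)
    }
  }
  out
}

# Dense +/-1 reference network: same layer semantics as the packed engine,
# computed with ordinary arithmetic on unpacked arrays.
ref_forward <- function(spec, weights, thresholds, spect, input_thresholds) {
  n_conv <- length(spec$conv)
  x <- array(2 * (spect >= input_thresholds) - 1,
             dim = c(1, nrow(spect), ncol(spect)))
  for (l in seq_len(n_conv)) {
    acc <- ref_conv2d_pm(x, weights[[l]], spec$padding)
    x <- ref_threshold(acc, thresholds[[l]])
    if (spec$conv[[l]]$pool) x <- ref_pool2(x)
  }
  nodes <- as.vector(x)
  for (l in seq_along(spec$fc)) {
    scores <- as.vector(weights[[n_conv + l]] %*% nodes)
    if (l < length(spec$fc)) {
      th <- thresholds[[n_conv + l]]
      nodes <- ifelse(is.na(th$constant), NA, th$constant)
      ge <- th$direction == "ge"
      open <- is.na(th$constant)
      nodes[open & ge] <- ifelse(scores[open & ge] >= th$theta[open & ge], 1, -1)
      nodes[open & !ge] <- ifelse(scores[open & !ge] < th$theta[open & !ge], 1, -1)
    }
  }
  list(label = which.max(scores), scores = scores)
}

# Random +/-1 weights and plausible thresholds for a spec; occasionally
# inserts lt-direction and constant channels so both code paths see them.
rand_model_params <- function(spec, seed) {
  set.seed(seed)
  n_conv <- length(spec$conv)
  weights <- c(
    lapply(spec$conv, function(g) {
      rand_pm_array(c(g$c_out, g$c_in, spec$kernel, spec$kernel))
    }),
    lapply(spec$fc, function(g) matrix(rand_pm(g$weights), nrow = g$n_out))
  )
  thresholds <- vector("list", n_conv + length(spec$fc))
  for (l in seq_len(n_conv)) {
    g <- spec$conv[[l]]
    thresholds[[l]] <- rand_thresholds(g$c_out, g$fan_in)
  }
  for (l in seq_along(spec$fc)) {
    g <- spec$fc[[l]]
    if (!g$final) thresholds[[n_conv + l]] <- rand_thresholds(g$n_out, g$fan_in)
  }
  list(weights = weights, thresholds = thresholds)
}

rand_thresholds <- function(n, fan_in) {
  theta <- sample(seq(-ceiling(fan_in / 3), ceiling(fan_in / 3)), n,
                  replace = TRUE)
  direction <- sample(c("ge", "lt"), n, replace = TRUE, prob = c(0.8, 0.2))
  constant <- rep(NA_integer_, n)
  if (n > 2) constant[sample(n, 1)] <- sample(c(-1L, 1L), 1)
  threshold_params(theta, direction, constant)
}

# Small dataset + short training used by several training/export tests;
# built once per test run.
tiny_trained_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- network_spec(conv_filters = c(8, 8), fc_nodes = c(16, 9),
                           input_shape = c(1, 32, 32))
      trials <- generate_dataset(8, master_seed = 3)
      ds <- spectrogram_dataset(trials)
      cfg <- train_config(epochs = 6, batch_size = 32, seed = 5)
      cache <<- list(net = train_bnn(ds, spec, cfg), ds = ds, spec = spec,
                     cfg = cfg)
    }
    cache
  }
})
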