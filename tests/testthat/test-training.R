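# Binarization-aware training, BN-to-threshold folding, quantization.

test_that("the learning-rate schedule is a left-continuous step function", {
  cfg <- train_config()
  expect_identical(vapply(c(0, 40, 80, 120, 160), function(e)
    lr_at_epoch(cfg, e), numeric(1)),
    c(0.01, 0.005, 0.0005, 0.00005, 0.000005))
  expect_identical(lr_at_epoch(cfg, 39), 0.01)
  expect_identical(lr_at_epoch(cfg, 199), 0.000005)
  expect_error(train_config(lr_schedule = c(`10` = 0.1)), "epoch 0")
  expect_error(train_config(lr_schedule = c(`0` = 0.1, `5` = -1)), "> 0")
})

test_that("BN folding reproduces sign(BN(x)) on integer accumulators", {
  # positive scale: t = mu - beta*s/gamma = 5 exactly
  eps <- 1e-5
  bn <- list(gamma = 1, beta = 0, mu = 5, var = 1 - eps)
  th <- fold_bn_to_thresholds(bn, eps)
  expect_identical(th$theta, 5L)
  expect_identical(th$direction, "ge")
  acc <- array(c(4L, 5L), dim = c(1, 2, 1))
  expect_identical(unpack_bitplane(threshold_activate(acc, th))[1, , 1],
                   c(-1, 1))
  # negative scale flips the direction and the outputs away from BN(x)=0
  bn_neg <- list(gamma = -2, beta = 0, mu = 5, var = 1 - eps)
  th_neg <- fold_bn_to_thresholds(bn_neg, eps)
  expect_identical(th_neg$direction, "lt")
  accs <- array(as.integer(-20:20), dim = c(1, 41, 1))
  pos <- unpack_bitplane(threshold_activate(accs, th))[1, , 1]
  neg <- unpack_bitplane(threshold_activate(accs, th_neg))[1, , 1]
  bnval <- bn$gamma * ((-20:20) - bn$mu) / sqrt(bn$var + eps) + bn$beta
  expect_identical(neg[bnval != 0], -pos[bnval != 0])
  # zero scale: constant at sign(beta)
  expect_identical(fold_bn_to_thresholds(
    list(gamma = 0, beta = -3, mu = 1, var = 1), eps)$constant, -1L)
  expect_identical(fold_bn_to_thresholds(
    list(gamma = 0, beta = 0, mu = 1, var = 1), eps)$constant, 1L)
  expect_error(fold_bn_to_thresholds(
    list(gamma = NaN, beta = 0, mu = 0, var = 1)), "non-finite")
})

test_that("folded thresholds agree with the float oracle over a full sweep", {
  set.seed(10)
  acc <- -1200:1200
  for (i in 1:200) {
    bn <- list(gamma = rnorm(1) * sample(c(1, 5), 1),
               beta = rnorm(1, sd = 3),
               mu = rnorm(1, sd = 50),
               var = runif(1, 0.01, 400))
    if (bn$gamma == 0) next
    th <- fold_bn_to_thresholds(bn, eps = 1e-5)
    want <- ifelse(bn$gamma * (acc - bn$mu) / sqrt(bn$var + 1e-5) +
                     bn$beta >= 0, 1, -1)
    got <- if (th$direction == "ge") ifelse(acc >= th$theta, 1, -1)
           else ifelse(acc < th$theta, 1, -1)
    expect_identical(got, want)
  }
})

test_that("threshold quantization clamps and detects unreachable channels", {
  th <- threshold_params(c(20000L, 100L, -20000L), "ge")
  q <- quantize_thresholds(th, fan_in = 1152)
  expect_identical(q$constant, c(-1L, NA_integer_, 1L))  # unreachable sides
  expect_identical(q$theta[2], 100L)
  expect_length(attr(q, "clamped"), 0)
  # in-reach but beyond 14 bits: genuinely clamped and reported
  th2 <- threshold_params(9000L, "ge")
  q2 <- quantize_thresholds(th2, fan_in = 10000)
  expect_identical(q2$theta, 8191L)
  expect_identical(attr(q2, "clamped"), 1L)
  # lt direction: fires iff acc < theta
  th3 <- threshold_params(c(20000L, -20000L), "lt")
  q3 <- quantize_thresholds(th3, fan_in = 1152)
  expect_identical(q3$constant, c(1L, -1L))
})

test_that("short training reduces the loss and is seed-reproducible", {
  tt <- tiny_trained_net()
  hist <- tt$net$history
  expect_lt(hist$loss[nrow(hist)], hist$loss[1])
  expect_gt(hist$train_acc[nrow(hist)], hist$train_acc[1])
  # bitwise reproducibility of the whole training run
  net2 <- train_bnn(tt$ds, tt$spec, tt$cfg)
  expect_identical(net2$layers[[1]]$W, tt$net$layers[[1]]$W)
  expect_identical(net2$history, tt$net$history)
})

test_that("quantization leaves inference unchanged when nothing is clamped", {
  tt <- tiny_trained_net()
  model <- fold_network(tt$net)
  # rebuild with unquantized thresholds and compare paired inference
  spec <- tt$net$spec
  weights <- lapply(tt$net$layers, function(L) {
    v <- ifelse(L$W >= 0, 1, -1)
    if (is.matrix(L$W)) matrix(v, nrow = nrow(L$W)) else array(v, dim(L$W))
  })
  thresholds <- lapply(tt$net$layers, function(L) {
    if (is.null(L$bn)) NULL else fold_bn_to_thresholds(L$bn, tt$net$eps)
  })
  clamped <- unlist(lapply(seq_along(thresholds), function(l) {
    if (is.null(thresholds[[l]])) return(integer(0))
    fan <- c(vapply(spec$conv, `[[`, numeric(1), "fan_in"),
             vapply(spec$fc, `[[`, numeric(1), "fan_in"))[l]
    attr(quantize_thresholds(thresholds[[l]], fan), "clamped")
  }))
  expect_length(clamped, 0)
  raw_model <- bnn_model(spec, weights, thresholds, tt$net$input_thresholds)
  val <- tt$net$split$val
  p1 <- predict_bnn(model, tt$ds$x[, , val, drop = FALSE])
  p2 <- predict_bnn(raw_model, tt$ds$x[, , val, drop = FALSE])
  expect_identical(p1, p2)
})

test_that("train -> fold -> serialize -> load -> forward is bit-exact", {
  tt <- tiny_trained_net()
  model <- fold_network(tt$net)
  dir <- tempfile("model_")
  write_model(model, dir)
  back <- read_model(dir)
  expect_identical(back$spec$conv_filters, model$spec$conv_filters)
  val <- tt$net$split$val
  for (i in val[1:5]) {
    a <- forward_bnn(model, tt$ds$x[, , i])
    b <- forward_bnn(back, tt$ds$x[, , i])
    expect_identical(a$scores, b$scores)
  }
  # the loaded model also matches the float network's evaluation path
  X <- array(0, dim = c(1, 32, 32, length(val)))
  for (j in seq_along(val)) {
    X[1, , , j] <- 2 * (tt$ds$x[, , val[j]] >= tt$net$input_thresholds) - 1
  }
  fwd <- emgbnn:::train_forward(tt$net, X, training = FALSE, keep_cache = FALSE)
  for (j in seq_along(val)) {
    expect_identical(forward_bnn(back, tt$ds$x[, , val[j]])$scores,
                     as.integer(fwd$logits[, j]))
  }
})

test_that("a trained model's labeling can be recovered by retraining", {
  tt <- tiny_trained_net()
  model <- fold_network(tt$net)
  # accuracy of model A on its own training split
  trn <- tt$net$split$train
  predsA <- predict_bnn(model, tt$ds$x[, , trn, drop = FALSE])
  accA <- mean(predsA == tt$ds$labels[trn])
  # relabel the same inputs with A and retrain a fresh network B
  relabeled <- list(x = tt$ds$x[, , trn, drop = FALSE], labels = predsA)
  if (min(table(factor(predsA, levels = 1:9))) >= 2) {
    cfgB <- train_config(epochs = 6, batch_size = 32, seed = 77,
                         train_fraction = 1)
    netB <- train_bnn(relabeled, tt$spec, cfgB)
    accB <- tail(netB$history$train_acc, 1)
    expect_gte(accB, accA - 0.05)
  } else {
    succeed("degenerate relabeling; surrogate not informative")
  }
})
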