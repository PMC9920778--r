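# Packed XNOR-popcount engine vs dense +/-1 arithmetic oracles.

test_that("bitplane packing round-trips arbitrary +/-1 tensors", {
  set.seed(1)
  for (dims in list(7, 64, 129, c(3, 4, 4), c(70, 6, 8))) {
    x <- if (length(dims) == 1) rand_pm(dims) else rand_pm_array(dims)
    expect_identical(unpack_bitplane(bitplane(x)), x)
  }
})

test_that("xnor-popcount dot equals the +/-1 arithmetic dot", {
  a <- rep(1, 8)
  expect_identical(xnor_popcount_dot(bitplane(a), bitplane(a)), 8L)
  expect_identical(xnor_popcount_dot(bitplane(a), bitplane(-a)), -8L)
  set.seed(2)
  for (i in 1:200) {
    n <- sample(1:256, 1)
    x <- rand_pm(n); y <- rand_pm(n)
    mask <- if (i %% 2 == 0) sample(c(TRUE, FALSE), n, replace = TRUE) else NULL
    got <- xnor_popcount_dot(bitplane(x), bitplane(y), mask)
    want <- if (is.null(mask)) sum(x * y) else sum(x[mask] * y[mask])
    expect_identical(got, as.integer(want))
  }
  expect_error(xnor_popcount_dot(bitplane(rep(1, 4)), bitplane(rep(1, 5))),
               "lengths differ")
})

test_that("binary convolution matches padding overlap counts and the oracle", {
  ones <- array(1, dim = c(1, 3, 3))
  k1 <- array(1, dim = c(1, 1, 3, 3))
  acc <- binary_conv2d(bitplane(ones), k1, padding = 1)
  expect_identical(acc[1, , ],
                   matrix(as.integer(c(4, 6, 4, 6, 9, 6, 4, 6, 4)), 3, 3))
  # negating the weights negates every accumulator
  expect_identical(binary_conv2d(bitplane(ones), -k1, padding = 1), -acc)
  set.seed(3)
  for (i in 1:10) {
    cin <- sample(c(2, 3, 70), 1)   # 70 crosses the 64-bit word boundary
    cout <- sample(2:4, 1)
    x <- rand_pm_array(c(cin, 8, 8))
    w <- rand_pm_array(c(cout, cin, 3, 3))
    expect_identical(binary_conv2d(bitplane(x), w, padding = 1),
                     ref_conv2d_pm(x, w, pad = 1))
  }
})

test_that("threshold activation implements the tie and direction rules", {
  acc <- array(c(4L, 5L, 6L), dim = c(1, 3, 1))
  ge <- threshold_params(5L, "ge")
  expect_identical(unpack_bitplane(threshold_activate(acc, ge))[1, , 1],
                   c(-1, 1, 1))                      # acc == theta fires
  lt <- threshold_params(5L, "lt")
  expect_identical(unpack_bitplane(threshold_activate(acc, lt))[1, , 1],
                   c(1, -1, -1))                     # complement off the tie
  const <- threshold_params(0L, "ge", constant = -1L)
  expect_identical(unpack_bitplane(threshold_activate(acc, const))[1, , 1],
                   c(-1, -1, -1))
  expect_error(threshold_activate(array(0L, c(2, 2, 2)), ge), "thresholds")
})

test_that("OR pooling equals max pooling, exhaustively and at random", {
  # all 16 possible 2x2 binary blocks
  for (bits in 0:15) {
    block <- 2 * as.integer(intToBits(bits)[1:4]) - 1
    x <- array(block, dim = c(1, 2, 2))
    pooled <- unpack_bitplane(or_maxpool2x2(bitplane(x)))
    expect_identical(pooled[1, 1, 1], max(block))
  }
  set.seed(4)
  for (i in 1:10) {
    x <- rand_pm_array(c(sample(c(3, 65), 1), 8, 8))
    expect_identical(unpack_bitplane(or_maxpool2x2(bitplane(x))),
                     ref_pool2(x))
  }
  expect_error(or_maxpool2x2(bitplane(rand_pm_array(c(2, 3, 4)))), "even")
})

test_that("fully connected scores match the +/-1 oracle and have fan-in parity", {
  w <- matrix(-1, 4, 4); diag(w) <- 1     # row i: +1 at i, -1 elsewhere
  scores <- binary_fc(bitplane(rep(1, 4)), w)
  expect_identical(scores, rep(-2L, 4))
  expect_identical(binary_fc(bitplane(rep(1, 1024)),
                             matrix(1, 2, 1024)), rep(1024L, 2))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(c(16, 130, 1024), 1)
    x <- rand_pm(n)
    w <- matrix(rand_pm(5 * n), 5, n)
    scores <- binary_fc(bitplane(x), w)
    expect_identical(scores, as.integer(w %*% x))
    expect_true(all(scores %% 2 == n %% 2))
    expect_true(all(abs(scores) <= n))
  }
})

test_that("the packed network is bit-exact with the dense reference network", {
  set.seed(6)
  for (i in 1:12) {
    spec <- network_spec(
      conv_filters = sample(3:6, sample(2:3, 1), replace = TRUE),
      fc_nodes = c(sample(c(8, 12), 1), 9),
      input_shape = c(1, 8, 8))
    pars <- rand_model_params(spec, seed = 100 + i)
    model <- bnn_model(spec, pars$weights, pars$thresholds,
                       input_thresholds = rep(0, 8))
    spect <- matrix(rnorm(64), 8, 8)
    got <- forward_bnn(model, spect)
    want <- ref_forward(spec, pars$weights, pars$thresholds, spect, rep(0, 8))
    expect_identical(got$scores, as.integer(want$scores))
    expect_identical(got$label, want$label)
    # deterministic across repeated calls
    expect_identical(forward_bnn(model, spect)$scores, got$scores)
  }
})

test_that("full-scale forward keeps score bounds, parity and the tie rule", {
  spec <- preset_network(1)
  pars <- rand_model_params(spec, seed = 7)
  model <- bnn_model(spec, pars$weights, pars$thresholds,
                     input_thresholds = rep(1, 32))
  set.seed(8)
  spect <- matrix(abs(rnorm(1024, 2)), 32, 32)
  res <- forward_bnn(model, spect)
  expect_true(res$class_index %in% 0:8)
  expect_true(all(abs(res$scores) <= 512))         # final fan-in
  expect_true(all(res$scores %% 2 == 0))           # 512 is even
  # identical rows in the output layer force a tie, broken to the lowest index
  w <- pars$weights
  w[[length(w)]][6, ] <- w[[length(w)]][3, ]
  tied <- bnn_model(spec, w, pars$thresholds, input_thresholds = rep(1, 32))
  rt <- forward_bnn(tied, spect)
  expect_identical(rt$scores[3], rt$scores[6])
  if (max(rt$scores) == rt$scores[3]) expect_identical(rt$label, 3L)
  # degenerate all-equal output rows always return class 1
  for (r in 1:9) w[[length(w)]][r, ] <- w[[length(w)]][1, ]
  alltied <- bnn_model(spec, w, pars$thresholds, input_thresholds = rep(1, 32))
  expect_identical(forward_bnn(alltied, spect)$label, 1L)
})
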