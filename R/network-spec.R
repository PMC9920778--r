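#' Binarized-network architecture specification
#'
#' Describes a CNN of `length(conv_filters)` convolution layers (square
#' kernels, stride 1, zero padding) followed by fully connected layers of
#' sizes `fc_nodes`, the last entry being the 9 gesture classes.  A 2x2
#' stride-2 pooling layer follows every convolution layer except the first
#' (indices in `pool_after`).  Every convolution channel and every fully
#' connected node except the final layer carries one integer threshold, the
#' folded form of batch normalization plus sign activation; the final layer
#' outputs raw integer scores for the argmax.
#'
#' For the selected architecture (16/32/64/128/256 filters, 256/512/9 nodes
#' on a 1x32x32 input) the kernel size and pooling placement are not free:
#' the published weight total 789,648 forces `k = 3` given the filter/node
#' counts, and the first fully connected fan-in of 1024 = 2*2*256 forces
#' four 2x2 pools; [network_spec()] recomputes and asserts the whole
#' geometry.
#'
#' @param conv_filters integer vector of output channels per conv layer.
#' @param fc_nodes integer vector of fully connected layer sizes, ending in
#'   the class count.
#' @param input_shape `c(channels, height, width)` of the classifier input.
#' @param kernel square kernel size (odd).
#' @param padding zero padding on every conv layer.
#' @param pool_after indices of conv layers followed by a 2x2 pool.
#' @param first_layer_mode `"binary_input"` (spectrogram binarized per
#'   frequency bin against stored thresholds; fully XNOR datapath) or
#'   `"integer_input"` (multi-bit pixels into the first convolution).
#' @return an object of class `network_spec` with per-layer geometry and
#'   weight/threshold counts.
#' @export
network_spec <- function(conv_filters = c(16, 32, 64, 128, 256),
                         fc_nodes = c(256, 512, 9),
                         input_shape = c(1, 32, 32),
                         kernel = 3, padding = 1,
                         pool_after = seq_along(conv_filters)[-1],
                         first_layer_mode = c("binary_input", "integer_input")) {
  first_layer_mode <- match.arg(first_layer_mode)
  if (kernel %% 2 != 1) stop_config("kernel size must be odd")
  if (length(fc_nodes) < 1) stop_config("need at least the output layer")
  h <- input_shape[2]; w <- input_shape[3]
  cin <- input_shape[1]
  conv <- vector("list", length(conv_filters))
  trace_h <- h
  for (l in seq_along(conv_filters)) {
    cout <- conv_filters[l]
    conv[[l]] <- list(c_in = cin, c_out = cout, h = h, w = w,
                      weights = cout * cin * kernel^2,
                      fan_in = cin * kernel^2,
                      pool = l %in% pool_after)
    if (conv[[l]]$pool) {
      if (h %% 2 || w %% 2) {
        stop_config("2x2 pooling after conv %d needs even spatial dims", l)
      }
      h <- h / 2; w <- w / 2
    }
    cin <- cout
    trace_h <- c(trace_h, h)
  }
  flat <- cin * h * w
  fc <- vector("list", length(fc_nodes))
  fan <- flat
  for (l in seq_along(fc_nodes)) {
    fc[[l]] <- list(n_in = fan, n_out = fc_nodes[l],
                    weights = fan * fc_nodes[l],
                    fan_in = fan,
                    final = l == length(fc_nodes))
    fan <- fc_nodes[l]
  }
  weight_bits <- sum(vapply(conv, `[[`, numeric(1), "weights")) +
    sum(vapply(fc, `[[`, numeric(1), "weights"))
  thresholds <- sum(conv_filters) + sum(head(fc_nodes, -1))
  structure(list(
    conv_filters = as.integer(conv_filters),
    fc_nodes = as.integer(fc_nodes),
    input_shape = as.integer(input_shape),
    kernel = as.integer(kernel),
    padding = as.integer(padding),
    pool_after = as.integer(pool_after),
    first_layer_mode = first_layer_mode,
    conv = conv, fc = fc,
    flatten = as.integer(flat),
    spatial_trace = as.integer(trace_h),
    weight_bits = weight_bits,
    n_thresholds = thresholds,
    n_classes = as.integer(fc_nodes[length(fc_nodes)])
  ), class = "network_spec")
}

#' Candidate architectures of the model-selection study
#'
#' The seven CNN candidates evaluated during model selection, identified by
#' their filter/node counts; network 1 (the default) is the architecture the
#' binarized system ships with.  All share 3x3 kernels, padding 1, and 2x2
#' pooling after every convolution layer except the first.
#'
#' @param id architecture number, 1..7.
#' @param ... passed on to [network_spec()] (e.g. `first_layer_mode`).
#' @return a [network_spec()].
#' @export
preset_network <- function(id = 1, ...) {
  tab <- list(
    `1` = list(conv = c(16, 32, 64, 128, 256), fc = c(256, 512, 9)),
    `2` = list(conv = c(16, 32, 64, 128),      fc = c(256, 512, 9)),
    `3` = list(conv = c(16, 32, 64, 128, 256), fc = c(512, 512, 9)),
    `4` = list(conv = c(16, 32, 64, 128, 256), fc = c(256, 512, 512, 9)),
    `5` = list(conv = c(16, 32, 64, 128, 256), fc = c(512, 1024, 9)),
    `6` = list(conv = c(16, 32, 64, 128, 256), fc = c(256, 256, 1024, 9)),
    `7` = list(conv = c(16, 32, 64, 128, 256), fc = c(256, 256, 512, 9))
  )
  key <- as.character(id)
  if (is.null(tab[[key]])) stop_config("preset id must be 1..7")
  spec <- network_spec(conv_filters = tab[[key]]$conv,
                       fc_nodes = tab[[key]]$fc, ...)
  if (id == 1) {
    # The published totals pin this geometry; fail loudly if it ever drifts.
    stopifnot(spec$weight_bits == 789648,
              spec$n_thresholds == 1264,
              spec$flatten == 1024,
              identical(spec$spatial_trace, c(32L, 32L, 16L, 8L, 4L, 2L)))
  }
  spec
}

#' Kernel size forced by a published weight total
#'
#' Solves `sum(conv C_out * C_in) * k^2 + FC weights = target` for integer
#' `k`; used to document that the selected architecture's kernel size is
#' derivable from its weight count rather than assumed.
#'
#' @param conv_filters,fc_nodes,input_channels layer sizes.
#' @param fc_fan_in fan-in of the first fully connected layer.
#' @param target_weight_bits published total weight count.
#' @return the unique integer `k`, or an error if none fits.
#' @export
derive_kernel_size <- function(conv_filters, fc_nodes, fc_fan_in,
                               input_channels = 1, target_weight_bits) {
  cin <- c(input_channels, head(conv_filters, -1))
  conv_pairs <- sum(conv_filters * cin)
  fans <- c(fc_fan_in, head(fc_nodes, -1))
  fc_weights <- sum(fans * fc_nodes)
  k2 <- (target_weight_bits - fc_weights) / conv_pairs
  k <- sqrt(k2)
  if (k != round(k) || k < 1) {
    stop_config("no integer kernel size matches %d weights", target_weight_bits)
  }
  as.integer(k)
}

#' Parameter accounting for an architecture
#'
#' @param spec a [network_spec()].
#' @return list with `weight_bits` (1-bit weights over all conv and FC
#'   layers), `thresholds` (one per conv channel and per non-final FC node)
#'   and `total = weight_bits + thresholds`.
#' @export
count_parameters <- function(spec) {
  list(weight_bits = spec$weight_bits,
       thresholds = spec$n_thresholds,
       total = spec$weight_bits + spec$n_thresholds)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> conv %s | fc %s | input %s | kernel %dx%d pad %d\n",
              paste(x$conv_filters, collapse = "-"),
              paste(x$fc_nodes, collapse = "-"),
              paste(x$input_shape, collapse = "x"),
              x$kernel, x$kernel, x$padding))
  p <- count_parameters(x)
  cat(sprintf("  weights %s bits, thresholds %s, total %s parameters; flatten %d\n",
              format(p$weight_bits, big.mark = ","),
              format(p$thresholds, big.mark = ","),
              format(p$total, big.mark = ","), x$flatten))
  invisible(x)
}
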