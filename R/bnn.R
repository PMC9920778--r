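# Bit-exact packed inference engine.
#
# A "bitplane" wraps a packed bit buffer: stored bit b in {0,1} encodes the
# value 2b - 1 in {-1,+1}.  Feature maps (dims c(C, H, W)) are packed per
# pixel with channels in the word bits; flat node/weight vectors are packed
# little-endian.  Zero padding contributes exactly 0 to every accumulation:
# padded taps are excluded from the popcount rather than materialized.

#' Pack a +/-1 tensor into a bitplane
#'
#' @param x numeric/integer array of +1/-1 values (0 is treated as +1, the
#'   datapath tie rule); a vector packs flat, a 3-d array dim `c(C, H, W)`
#'   packs per pixel.
#' @return an object of class `bitplane` holding the packed words and dims.
#' @export
bitplane <- function(x) {
  bits <- as.integer(c(x) >= 0)
  d <- dim(x)
  if (is.null(d) || length(d) == 1) {
    structure(list(packed = pack_bits_cpp(bits), n = length(bits),
                   dims = NULL), class = "bitplane")
  } else if (length(d) == 3) {
    structure(list(packed = pack_chw_cpp(bits, d[1], d[2], d[3]),
                   n = length(bits), dims = as.integer(d)),
              class = "bitplane")
  } else {
    stop_config("bitplane supports vectors and C x H x W arrays")
  }
}

#' Unpack a bitplane back to +/-1 values
#'
#' `unpack_bitplane(bitplane(x))` recovers `x` for any +/-1 tensor.
#'
#' @param bp a [bitplane()].
#' @return numeric vector or `C x H x W` array of +1/-1.
#' @export
unpack_bitplane <- function(bp) {
  stopifnot(inherits(bp, "bitplane"))
  if (is.null(bp$dims)) {
    2 * unpack_bits_cpp(bp$packed, bp$n) - 1
  } else {
    array(2 * unpack_chw_cpp(bp$packed, bp$dims[1], bp$dims[2], bp$dims[3]) - 1,
          dim = bp$dims)
  }
}

#' @export
print.bitplane <- function(x, ...) {
  shape <- if (is.null(x$dims)) sprintf("n=%d", x$n)
           else paste(x$dims, collapse = "x")
  cat(sprintf("<bitplane> %s, %d packed bytes\n", shape, length(x$packed)))
  invisible(x)
}

#' XNOR-popcount dot product of two packed bit vectors
#'
#' Computes the +/-1 dot product over valid positions as
#' `2 * popcount(XNOR(a, b) & mask) - popcount(mask)`.
#'
#' @param a,b flat [bitplane()]s of the same length.
#' @param mask optional logical/0-1 vector marking valid positions; invalid
#'   positions contribute 0 (how padding is represented).
#' @return integer dot product.
#' @export
xnor_popcount_dot <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "bitplane"), inherits(b, "bitplane"))
  if (a$n != b$n) stop_config("operand lengths differ (%d vs %d)", a$n, b$n)
  m <- if (is.null(mask)) NULL else {
    if (length(mask) != a$n) stop_config("mask length must match operands")
    pack_bits_cpp(as.integer(as.logical(mask)))
  }
  xnor_popcount_cpp(a$packed, b$packed, a$n, m)
}

# Pack conv weights (array dim c(Cout, Cin, k, k) of +/-1) into the engine
# tap layout.
pack_conv_weights <- function(w) {
  d <- dim(w)
  list(packed = pack_conv_weights_cpp(as.integer(c(w) >= 0),
                                      d[1], d[2], d[3]),
       c_out = d[1], c_in = d[2], k = d[3])
}

# Pack FC weights (matrix n_out x n_in of +/-1) into packed rows.
pack_fc_weights <- function(w) {
  n_out <- nrow(w); n_in <- ncol(w)
  wpr <- ceiling(n_in / 64)
  rows <- raw(0)
  buf <- vector("list", n_out)
  for (r in seq_len(n_out)) buf[[r]] <- pack_bits_cpp(as.integer(w[r, ] >= 0))
  # every row buffer already has wpr words
  list(packed = do.call(c, buf), n_in = n_in, n_out = n_out, wpr = wpr)
}

#' Binary convolution via the packed XNOR-popcount engine
#'
#' Stride-1 cross-correlation of a packed +/-1 feature map with packed +/-1
#' kernels; zero-padded positions are excluded from the accumulation (they
#' contribute 0, neither +1 nor -1).  Output spatial size equals input
#' spatial size.
#'
#' @param input a `C_in x H x W` [bitplane()].
#' @param weights +/-1 array dim `c(C_out, C_in, k, k)` or the result of an
#'   earlier internal packing.
#' @param padding zero padding (default `(k-1)/2`, size-preserving).
#' @return integer accumulator array dim `c(C_out, H, W)`.
#' @export
binary_conv2d <- function(input, weights, padding = NULL) {
  stopifnot(inherits(input, "bitplane"), !is.null(input$dims))
  pw <- if (is.list(weights)) weights else pack_conv_weights(weights)
  if (pw$c_in != input$dims[1]) {
    stop_config("weight C_in %d != input channels %d", pw$c_in, input$dims[1])
  }
  pad <- padding %||% ((pw$k - 1) / 2)
  acc <- bconv2d_cpp(input$packed, input$dims[1], input$dims[2], input$dims[3],
                     pw$packed, pw$c_out, pw$k, as.integer(pad))
  array(acc, dim = c(pw$c_out, input$dims[2], input$dims[3]))
}

#' Per-channel threshold parameters
#'
#' The folded form of batch normalization followed by a sign activation: the
#' channel fires (+1) iff `acc >= theta` (direction `"ge"`) or `acc < theta`
#' (direction `"lt"`, the negative-scale case); degenerate channels emit a
#' constant.  Thresholds are signed integers representable in 14 bits.
#'
#' @param theta integer thresholds, one per channel.
#' @param direction `"ge"` or `"lt"` per channel.
#' @param constant per-channel constant output (+1/-1) or `NA` for
#'   thresholded channels.
#' @return object of class `threshold_params`.
#' @export
threshold_params <- function(theta, direction = "ge",
                             constant = rep(NA_integer_, length(theta))) {
  n <- length(theta)
  direction <- rep_len(direction, n)
  if (!all(direction %in% c("ge", "lt"))) stop_config("direction must be ge/lt")
  if (!all(is.na(constant) | constant %in% c(-1L, 1L))) {
    stop_config("constant outputs must be +/-1 or NA")
  }
  structure(list(theta = as.integer(round(theta)), direction = direction,
                 constant = as.integer(constant)),
            class = "threshold_params")
}

#' Threshold activation: integer accumulators to a packed bitplane
#'
#' @param acc integer array dim `c(C, H, W)` (or a length-C-blocks vector for
#'   FC layers).
#' @param params a [threshold_params()] with one entry per channel.
#' @return a [bitplane()] of the same shape.
#' @export
threshold_activate <- function(acc, params) {
  d <- dim(acc) %||% c(length(acc), 1L, 1L)
  n_ch <- if (is.null(dim(acc))) length(acc) else d[1]
  if (length(params$theta) != n_ch) {
    stop_config("%d thresholds for %d channels", length(params$theta), n_ch)
  }
  fire_ge <- params$direction == "ge"
  bits <- array(0L, dim = d)
  accd <- array(acc, dim = d)
  for (ch in seq_len(n_ch)) {
    if (!is.na(params$constant[ch])) {
      bits[ch, , ] <- as.integer(params$constant[ch] > 0)
    } else if (fire_ge[ch]) {
      bits[ch, , ] <- as.integer(accd[ch, , ] >= params$theta[ch])
    } else {
      bits[ch, , ] <- as.integer(accd[ch, , ] < params$theta[ch])
    }
  }
  if (is.null(dim(acc))) {
    bitplane(2 * c(bits) - 1)
  } else {
    bitplane(array(2 * bits - 1, dim = d))
  }
}

#' OR pooling (2x2, stride 2) on a packed bitplane
#'
#' On binary feature maps the 2x2 block maximum over +/-1 values reduces to a
#' logical OR of the stored bits.
#'
#' @param input a `C x H x W` [bitplane()] with even `H`, `W`.
#' @return a `C x H/2 x W/2` [bitplane()].
#' @export
or_maxpool2x2 <- function(input) {
  stopifnot(inherits(input, "bitplane"), !is.null(input$dims))
  d <- input$dims
  if (d[2] %% 2 || d[3] %% 2) stop_config("OR pooling needs even spatial dims")
  structure(list(packed = orpool2_cpp(input$packed, d[1], d[2], d[3]),
                 n = d[1] * (d[2] / 2) * (d[3] / 2),
                 dims = c(d[1], d[2] %/% 2, d[3] %/% 2)),
            class = "bitplane")
}

#' Fully connected binary layer
#'
#' `m` XNOR-popcount dot products of a packed node vector against packed
#' weight rows; no padding, hence no mask.
#'
#' @param nodes a flat [bitplane()] of length `n`.
#' @param weights +/-1 matrix `m x n` (or pre-packed rows).
#' @return integer score vector of length `m`; each score has the parity of
#'   `n` and magnitude at most `n`.
#' @export
binary_fc <- function(nodes, weights) {
  stopifnot(inherits(nodes, "bitplane"), is.null(nodes$dims))
  pw <- if (is.list(weights)) weights else pack_fc_weights(weights)
  if (pw$n_in != nodes$n) {
    stop_config("weight fan-in %d != node count %d", pw$n_in, nodes$n)
  }
  bfc_cpp(nodes$packed, pw$n_in, pw$packed, pw$n_out)
}

# Flatten a C x H x W bitplane to a flat bitplane in R array order
# (channel fastest, then row, then column) -- the order the training-side
# flatten uses.
flatten_bitplane <- function(bp) {
  stopifnot(!is.null(bp$dims))
  bits <- unpack_chw_cpp(bp$packed, bp$dims[1], bp$dims[2], bp$dims[3])
  structure(list(packed = pack_bits_cpp(bits), n = bp$n, dims = NULL),
            class = "bitplane")
}

#' Binarize a spectrogram against per-bin input thresholds
#'
#' In `binary_input` mode the 32x32 spectrogram enters the network as +/-1:
#' pixel (bin, frame) maps to +1 iff its magnitude is at least the stored
#' threshold of its frequency bin.  Thresholds are computed once from the
#' training set (per-bin medians) and shipped with the model.
#'
#' @param spect 32x32 spectrogram matrix (frequency x time).
#' @param thresholds numeric vector, one threshold per frequency row.
#' @return a `1 x 32 x 32`... more precisely `c(1, nrow, ncol)` [bitplane()].
#' @export
binarize_input <- function(spect, thresholds) {
  if (length(thresholds) != nrow(spect)) {
    stop_config("need one threshold per frequency bin")
  }
  pm <- 2 * (spect >= thresholds) - 1   # thresholds recycle down columns
  bitplane(array(pm, dim = c(1, nrow(spect), ncol(spect))))
}

#' Run the packed binarized network on one spectrogram
#'
#' Applies the first-layer input handling, the convolution stack (each conv
#' layer's accumulators thresholded to bits; 2x2 OR pooling where the
#' architecture places it), the flatten, and the fully connected layers; the
#' final layer produces raw integer class scores and the predicted class is
#' the argmax with ties broken toward the lowest index.
#'
#' @param model a `bnn_model` (see [bnn_model()] / [read_model()]).
#' @param spect a 32x32 `spectrogram32` (or plain matrix).
#' @return list with `class_index` (0-based, 0..8), `label` (1-based),
#'   `scores` (integer vector of 9).
#' @export
forward_bnn <- function(model, spect) {
  spec <- model$spec
  layers <- model$layers
  n_conv <- length(spec$conv_filters)
  if (spec$first_layer_mode == "binary_input") {
    x <- binarize_input(unclass(spect), model$input_thresholds)
    acc <- binary_conv2d(x, layers[[1]]$wpack, spec$padding)
  } else {
    geom <- spec$conv[[1]]
    acc <- iconv2d_cpp(as.numeric(spect), spec$input_shape[1],
                       geom$h, geom$w,
                       as.integer(c(layers[[1]]$w)), geom$c_out,
                       spec$kernel, spec$padding)
    acc <- array(acc, dim = c(geom$c_out, geom$h, geom$w))
  }
  x <- threshold_activate(acc, layers[[1]]$thresholds)
  if (spec$conv[[1]]$pool) x <- or_maxpool2x2(x)
  for (l in seq_len(n_conv)[-1]) {
    acc <- binary_conv2d(x, layers[[l]]$wpack, spec$padding)
    x <- threshold_activate(acc, layers[[l]]$thresholds)
    if (spec$conv[[l]]$pool) x <- or_maxpool2x2(x)
  }
  nodes <- flatten_bitplane(x)
  n_fc <- length(spec$fc_nodes)
  for (l in seq_len(n_fc)) {
    li <- layers[[n_conv + l]]
    scores <- binary_fc(nodes, li$wpack)
    if (l < n_fc) {
      nodes <- threshold_activate(scores, li$thresholds)
      nodes <- structure(list(packed = nodes$packed, n = nodes$n, dims = NULL),
                         class = "bitplane")
    }
  }
  cls <- which.max(scores)  # first maximum: ties break toward lowest index
  list(class_index = cls - 1L, label = cls, scores = as.integer(scores))
}

#' Classify a batch of spectrograms
#'
#' @param model a `bnn_model`.
#' @param x a `32 x 32 x N` array (or a list of spectrograms).
#' @return integer vector of predicted labels (1..9).
#' @export
predict_bnn <- function(model, x) {
  if (is.list(x)) {
    return(vapply(x, function(s) forward_bnn(model, s)$label, integer(1)))
  }
  stopifnot(length(dim(x)) == 3)
  vapply(seq_len(dim(x)[3]), function(i) forward_bnn(model, x[, , i])$label,
         integer(1))
}
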