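# Model serialization and memory accounting.
#
# On-disk model format (a directory):
#   weights.bin   -- all layer weights concatenated in layer order, each
#                    tensor flattened in its R array order, packed LSB-first
#                    into little-endian 128-bit words; trailing slack bits 0.
#   manifest.json -- architecture, first-layer mode, input thresholds,
#                    per-layer threshold tables (14-bit signed values with
#                    direction flags and constant-channel markers), bit/word
#                    counts, and the MD5 of weights.bin.

WORD_BITS <- 128L

#' Pack model weights into the 128-bit word stream
#'
#' Concatenates every layer's +/-1 weights (conv layers first, then FC) in
#' R array flatten order into a single bit stream, packed LSB-first into
#' little-endian 128-bit words.  The stream depth is `ceiling(bits / 128)`
#' words; trailing slack bits are zero.
#'
#' @param model a `bnn_model` (or a bare list of +/-1 weight tensors).
#' @return list with `packed` (raw vector, `16 * depth` bytes), `n_bits`,
#'   and `depth` (number of 128-bit words).
#' @export
pack_weights <- function(model) {
  weights <- if (inherits(model, "bnn_model")) {
    lapply(model$layers, `[[`, "w")
  } else {
    model
  }
  bits <- unlist(lapply(weights, function(w) as.integer(c(w) >= 0)))
  n_bits <- length(bits)
  depth <- ceiling(n_bits / WORD_BITS)
  packed <- pack_bits_cpp(bits)
  pad <- depth * (WORD_BITS / 8) - length(packed)
  if (pad > 0) packed <- c(packed, raw(pad))
  list(packed = packed, n_bits = n_bits, depth = as.integer(depth))
}

#' Unpack a weight stream into per-layer tensors
#'
#' Inverse of [pack_weights()] given the architecture.
#'
#' @param packed raw vector from [pack_weights()].
#' @param spec a [network_spec()].
#' @return list of +/-1 weight tensors in layer order.
#' @export
unpack_weights <- function(packed, spec) {
  shapes <- c(
    lapply(spec$conv, function(g) c(g$c_out, g$c_in, spec$kernel, spec$kernel)),
    lapply(spec$fc, function(g) c(g$n_out, g$n_in))
  )
  n_bits <- sum(vapply(shapes, prod, numeric(1)))
  bits <- unpack_bits_cpp(packed, as.integer(n_bits))
  out <- vector("list", length(shapes))
  at <- 0
  for (i in seq_along(shapes)) {
    n <- prod(shapes[[i]])
    v <- 2 * bits[(at + 1):(at + n)] - 1
    out[[i]] <- if (length(shapes[[i]]) == 2) {
      matrix(v, nrow = shapes[[i]][1])
    } else {
      array(v, dim = shapes[[i]])
    }
    at <- at + n
  }
  out
}

#' Write a packed model to disk
#'
#' @param model a `bnn_model`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  pw <- pack_weights(model)
  wfile <- file.path(path, "weights.bin")
  writeBin(pw$packed, wfile)
  spec <- model$spec
  thresholds <- lapply(model$layers, function(L) {
    if (is.null(L$thresholds)) return(NULL)
    list(theta = L$thresholds$theta,
         direction = L$thresholds$direction,
         constant = L$thresholds$constant)
  })
  manifest <- list(
    format = "emgbnn-model-1",
    spec = list(conv_filters = spec$conv_filters,
                fc_nodes = spec$fc_nodes,
                input_shape = spec$input_shape,
                kernel = spec$kernel,
                padding = spec$padding,
                pool_after = spec$pool_after,
                first_layer_mode = spec$first_layer_mode),
    counts = count_parameters(spec),
    weight_words = pw$depth,
    word_bits = WORD_BITS,
    weight_bits = pw$n_bits,
    input_thresholds = model$input_thresholds,
    thresholds = thresholds,
    weights_md5 = unname(tools::md5sum(wfile))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a packed model from disk
#'
#' Verifies the weight-stream hash and the parameter counts against the
#' manifest before reconstructing the model.
#'
#' @param path model directory written by [write_model()].
#' @return a `bnn_model`.
#' @export
read_model <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  wfile <- file.path(path, "weights.bin")
  if (!identical(unname(tools::md5sum(wfile)), manifest$weights_md5)) {
    stop("weight stream hash mismatch; model file corrupt", call. = FALSE)
  }
  ms <- manifest$spec
  spec <- network_spec(conv_filters = ms$conv_filters,
                       fc_nodes = ms$fc_nodes,
                       input_shape = ms$input_shape,
                       kernel = ms$kernel,
                       padding = ms$padding,
                       pool_after = ms$pool_after,
                       first_layer_mode = ms$first_layer_mode)
  if (spec$weight_bits != manifest$weight_bits) {
    stop("manifest weight count inconsistent with architecture", call. = FALSE)
  }
  packed <- readBin(wfile, "raw", n = file.size(wfile))
  weights <- unpack_weights(packed, spec)
  thresholds <- lapply(manifest$thresholds, function(th) {
    if (is.null(th) || length(th) == 0) return(NULL)
    const <- th$constant
    if (is.null(const)) const <- rep(NA_integer_, length(th$theta))
    threshold_params(th$theta, th$direction,
                     suppressWarnings(as.integer(const)))
  })
  bnn_model(spec, weights, thresholds,
            input_thresholds = manifest$input_thresholds)
}

#' Memory accounting for the packed system
#'
#' Reproduces the hardware memory budget: the two 128-bit x 1024 ping-pong
#' buffers that hold the spectrogram and feature maps, the 8-bit x 128
#' window table, the 10-bit x 64 twiddle table, the packed weight stream
#' (128-bit words), and the 14-bit threshold table.  Derived figures use
#' decimal kilobytes (1 KB = 1000 bytes): binary weight storage in KB, the
#' full-precision baseline at 64 bits per weight, and the percentage
#' reduction (rounded to 1 decimal).
#'
#' @param spec a [network_spec()].
#' @param stft an [stft_config()] (fixes the window/twiddle table depths).
#' @return object of class `memory_report`: a data.frame `entries` with
#'   columns `memory`, `width`, `depth`, `bits`, plus `total_bits`,
#'   `binary_weight_kb`, `full_precision_kb`, `reduction_pct`.
#' @export
memory_report <- function(spec = preset_network(1), stft = stft_config()) {
  p <- count_parameters(spec)
  weight_depth <- ceiling(p$weight_bits / WORD_BITS)
  entries <- data.frame(
    memory = c("M1", "M2", "Hamming window", "Twiddle factors",
               "Weights", "Thresholds"),
    width = c(128L, 128L, 8L, 10L, 128L, 14L),
    depth = c(1024L, 1024L, stft$n_fft, stft$n_fft %/% 2L,
              as.integer(weight_depth), as.integer(p$thresholds)),
    stringsAsFactors = FALSE
  )
  entries$bits <- entries$width * entries$depth
  binary_kb <- p$weight_bits / 8 / 1000
  full_kb <- p$weight_bits * 8 / 1000          # 64 bits = 8 bytes per weight
  structure(list(
    entries = entries,
    total_bits = sum(entries$bits),
    binary_weight_kb = binary_kb,
    full_precision_kb = full_kb,
    reduction_pct = round((1 - binary_kb / full_kb) * 100, 1)
  ), class = "memory_report")
}

#' @export
print.memory_report <- function(x, ...) {
  e <- x$entries
  cat("Memory            Width  Depth  Bits\n")
  for (i in seq_len(nrow(e))) {
    cat(sprintf("%-17s %5d %6d  %s\n", e$memory[i], e$width[i], e$depth[i],
                format(e$bits[i], big.mark = ",")))
  }
  cat(sprintf("Total %s bits\n", format(x$total_bits, big.mark = ",")))
  cat(sprintf("Binary weights %.3f KB vs full precision %.3f KB (%.1f%% reduction)\n",
              x$binary_weight_kb, x$full_precision_kb, x$reduction_pct))
  invisible(x)
}
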