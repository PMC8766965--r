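# Network architecture descriptors. A network_spec is an ordered list of
# layer descriptors plus input shape and class count; it drives parameter
# accounting, the cost model, training-engine construction and export.

layer_conv <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                       bias = TRUE, precision = "binary") {
  list(type = "conv", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad), bias = bias, precision = precision)
}

layer_maxpool <- function(kernel, stride = kernel) {
  list(type = "maxpool", kernel = as.integer(kernel), stride = as.integer(stride))
}

layer_fc <- function(n_in, n_out, bias = TRUE, precision = "binary") {
  list(type = "fc", n_in = as.integer(n_in), n_out = as.integer(n_out),
       bias = bias, precision = precision)
}

layer_batchnorm <- function(features) list(type = "batchnorm", features = as.integer(features))

layer_activation <- function(kind = c("binary", "none")) {
  list(type = "activation", kind = match.arg(kind))
}

#' Build a network specification
#'
#' @param layers list of layer descriptors (see [build_alexnet()] for the
#'   constructors in use).
#' @param input_shape integer c(H, W, C).
#' @param n_classes output class count.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(layers, input_shape, n_classes) {
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> input [", paste(x$input_shape, collapse = "x"),
      "], ", length(x$layers), " layers, ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

#' AlexNet-style architecture specification
#'
#' The standard AlexNet body for 224 x 224 x 3 inputs with the output layer
#' restricted to `num_classes` neurons. The reduced variant removes the
#' intermediate 4096 -> 4096 linear layer (16,781,312 parameters), the
#' depth reduction appropriate for binary classification tasks.
#'
#' @param num_classes `>= 2`.
#' @param reduced logical; drop the middle 4096 -> 4096 classifier layer.
#' @param precision weight precision tag for accounting: "fp32", "int8" or
#'   "binary" (applied to all layers).
#' @return a [network_spec()].
#' @export
build_alexnet <- function(num_classes, reduced = FALSE, precision = "fp32") {
  stopifnot(num_classes >= 2)
  p <- precision
  layers <- list(
    layer_conv(3, 64, 11, stride = 4, pad = 2, precision = p),
    layer_maxpool(3, 2),
    layer_conv(64, 192, 5, pad = 2, precision = p),
    layer_maxpool(3, 2),
    layer_conv(192, 384, 3, pad = 1, precision = p),
    layer_conv(384, 256, 3, pad = 1, precision = p),
    layer_conv(256, 256, 3, pad = 1, precision = p),
    layer_maxpool(3, 2),
    layer_fc(9216, 4096, precision = p))
  if (!reduced) layers <- c(layers, list(layer_fc(4096, 4096, precision = p)))
  layers <- c(layers, list(layer_fc(4096, num_classes, precision = p)))
  network_spec(layers, c(224L, 224L, 3L), num_classes)
}

#' Small binarized CNN for patch-scale inputs
#'
#' A compact conv-pool-conv-pool-fc architecture for the 16-32 px inputs
#' used by the classification and slice-detection experiments. Layer order
#' within a block is conv -> maxpool -> batchnorm -> sign, so pooling acts
#' on the integer pre-activations and the whole block folds to an
#' integer-only comparison at export. The reduced variant omits the hidden
#' fully connected layer.
#'
#' @param num_classes `>= 2`.
#' @param input_size spatial input size (square), e.g. 16 or 20.
#' @param reduced logical; omit the hidden fc layer.
#' @param width base channel width of the first conv (default 12).
#' @return a [network_spec()].
#' @export
build_small_cnn <- function(num_classes, input_size = 16L, reduced = FALSE,
                            width = 12L) {
  stopifnot(num_classes >= 2, input_size >= 8)
  w1 <- as.integer(width); w2 <- 2L * w1
  s <- input_size %/% 4L  # two 2x2 pools
  flat <- s * s * w2
  layers <- list(
    layer_conv(3, w1, 3, pad = 1, bias = FALSE),
    layer_maxpool(2),
    layer_batchnorm(w1),
    layer_activation("binary"),
    layer_conv(w1, w2, 3, pad = 1, bias = FALSE),
    layer_maxpool(2),
    layer_batchnorm(w2),
    layer_activation("binary"))
  if (!reduced)
    layers <- c(layers, list(
      layer_fc(flat, 64, bias = FALSE),
      layer_batchnorm(64),
      layer_activation("binary"),
      layer_fc(64, num_classes, bias = FALSE)))
  else
    layers <- c(layers, list(layer_fc(flat, num_classes, bias = FALSE)))
  network_spec(layers, c(as.integer(input_size), as.integer(input_size), 3L),
               num_classes)
}

conv_out_dim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

#' Chain layer shapes through a network specification
#'
#' @param spec a [network_spec()].
#' @param input_shape optional c(H, W, C) override.
#' @return list of per-layer output shapes (c(H, W, C) or feature count).
#' @export
infer_shapes <- function(spec, input_shape = spec$input_shape) {
  shp <- input_shape
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv") {
      if (length(shp) != 3 || shp[3] != l$in_ch)
        stop("layer ", i, ": conv expects ", l$in_ch, " channels, got shape [",
             paste(shp, collapse = ","), "]")
      shp <- c(conv_out_dim(shp[1], l$kernel, l$stride, l$pad),
               conv_out_dim(shp[2], l$kernel, l$stride, l$pad), l$out_ch)
    } else if (l$type == "maxpool") {
      shp <- c(conv_out_dim(shp[1], l$kernel, l$stride, 0L),
               conv_out_dim(shp[2], l$kernel, l$stride, 0L), shp[3])
    } else if (l$type == "fc") {
      if (prod(shp) != l$n_in)
        stop("layer ", i, ": fc expects ", l$n_in, " inputs, got ", prod(shp))
      shp <- l$n_out
    }
    out[[i]] <- shp
  }
  out
}

#' Per-layer parameter counts
#'
#' conv: out*in*k^2 (+out if bias); fc: out*in (+out if bias); pooling,
#' batch norm and activations contribute no counted weights (batch norm is
#' folded into thresholds at export).
#'
#' @param spec a [network_spec()].
#' @return data.frame with columns `layer`, `type`, `params`, plus the grand
#'   total in attribute `"total"`; `sum(x$params)` equals the total.
#' @export
count_params <- function(spec) {
  rows <- lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    p <- switch(l$type,
      conv = l$out_ch * l$in_ch * l$kernel^2 + if (isTRUE(l$bias)) l$out_ch else 0L,
      fc   = l$n_out * l$n_in + if (isTRUE(l$bias)) l$n_out else 0L,
      0L)
    data.frame(layer = i, type = l$type, params = as.numeric(p))
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(layer = integer(0), type = character(0),
                         params = numeric(0))
  attr(out, "total") <- sum(out$params)
  out
}
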