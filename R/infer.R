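# Export of trained networks to an integer-only inference form (batch norm
# folded into integer thresholds), and stochastic inference by presentation
# aggregation: per presentation, the binarized input passes the first layer
# to a sign map a_n; the aggregate A_0 = sign(sum_n a_n) (ties to +1) then
# propagates through the remaining binarized layers.

maxpool_int <- function(a, map) {
  d <- dim(a)
  xr <- array(a, dim = c(d[1], d[2], 1L, d[3] * d[4]))
  col <- im2col(xr, map)
  mx <- col[1, ]
  for (r in seq_len(nrow(col))[-1]) mx <- pmax(mx, col[r, ])
  array(mx, dim = c(map$oh, map$ow, d[3], d[4]))
}

#' Export a trained network to integer-only inference form
#'
#' Groups each weight layer with its pooling and batch-norm companions and
#' folds the batch norm (inference running statistics) into one integer
#' threshold and comparison direction per output unit, so class rankings
#' after export are produced entirely by integer accumulate-and-compare.
#' A negative batch-norm scale reverses the unit's comparison direction
#' (for the pure un-pooled neuron this is equivalent to the weight negation
#' performed by [fold_batchnorm()], but it also stays exact when a max-pool
#' sits between the accumulation and the comparison, where weight negation
#' would turn the max into a min).
#'
#' @param net a trained `sbcnn_net`.
#' @return object of class `sbcnn_exported`: list of stages, each with
#'   binarized weights, optional pooling metadata, integer thresholds
#'   `t_dot` in the \{-1,+1\}-accumulation domain with per-unit direction
#'   `dir`, and the original batch-norm parameters kept for reference-path
#'   checking.
#' @export
export_model <- function(net) {
  stopifnot(inherits(net, "sbcnn_net"))
  stages <- list(); cur <- NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type %in% c("conv", "fc")) {
      if (!is.null(cur)) stages[[length(stages) + 1L]] <- cur
      Wb <- sign_pm1(l$W)
      cur <- list(type = l$type, W = Wb, n = nrow(Wb),
                  out_units = ncol(Wb))
      if (l$type == "conv") {
        cur$map <- l$map; cur$pad <- l$pad; cur$out_ch <- l$out_ch
        cur$in_shape <- l$in_shape
      }
    } else if (l$type == "maxpool") {
      cur$pool <- list(kernel = l$kernel, map = l$map)
    } else if (l$type == "batchnorm") {
      bn <- list(gamma = l$gamma, beta = l$beta,
                 mean = l$run_mean, var = l$run_var, eps = l$eps)
      if (any(bn$gamma == 0)) stop("batch-norm scale gamma must be non-zero to fold")
      # sign(gamma*(s-mean)/sd + beta) == [s >= theta] for gamma > 0,
      # [s <= theta] for gamma < 0. Weights stay untouched: a max-pool may
      # sit between the accumulation and this comparison, and pooling does
      # not commute with weight negation. Ceil/floor make the integer
      # comparison exact (accumulations are integers; padding may break
      # fan-in parity, so the popcount-domain form is not used here).
      sd_ <- sqrt(bn$var + bn$eps)
      theta <- bn$mean - bn$beta * sd_ / bn$gamma
      cur$dir <- ifelse(bn$gamma > 0, 1L, -1L)
      cur$t_dot <- as.integer(ifelse(cur$dir == 1L, ceiling(theta), floor(theta)))
      cur$bn <- bn
    }
  }
  if (!is.null(cur)) stages[[length(stages) + 1L]] <- cur
  structure(list(stages = stages, stats = net$stats, dist = net$dist,
                 spec = net$spec, presentation = net$presentation),
            class = "sbcnn_exported")
}

stage_accumulate <- function(st, a, W = st$W) {
  if (st$type == "conv") {
    B <- dim(a)[4]
    col <- im2col(pad_batch(a, st$pad), st$map)
    s <- array(crossprod(W, col), dim = c(st$out_ch, st$map$oh, st$map$ow, B))
    s <- aperm(s, c(2, 3, 1, 4))
  } else {
    if (!is.matrix(a)) { d <- dim(a); a <- t(matrix(a, nrow = prod(d[-length(d)]))) }
    s <- a %*% W
  }
  if (!is.null(st$pool)) s <- maxpool_int(s, st$pool$map)
  s
}

stage_threshold_int <- function(st, s) {
  if (st$type == "conv") {
    # per-channel threshold/direction broadcast over (H, W, channel, B)
    bc <- function(v) aperm(array(v, dim = c(dim(s)[3], dim(s)[1], dim(s)[2],
                                             dim(s)[4])), c(2, 3, 1, 4))
    ifelse(bc(st$dir) * s >= bc(st$dir * st$t_dot), 1, -1)
  } else {
    ds <- sweep(s, 2, st$dir, "*")
    sweep(ds, 2, st$dir * st$t_dot, function(v, t) ifelse(v >= t, 1, -1))
  }
}

stage_threshold_float <- function(st, s) {
  # reference path: float batch norm (running stats) on the original-weight
  # accumulation, then sign
  bn <- st$bn
  if (st$type == "conv") {
    d <- dim(s)
    sm <- matrix(aperm(s, c(1, 2, 4, 3)), ncol = d[3])
  } else sm <- s
  z <- sweep(sweep(sm, 2, bn$mean, "-"), 2, sqrt(bn$var + bn$eps), "/")
  z <- sweep(sweep(z, 2, bn$gamma, "*"), 2, bn$beta, "+")
  out <- sign_pm1(z)
  if (st$type == "conv")
    out <- aperm(array(out, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  out
}

#' Run binarized input through the exported network body
#'
#' @param model an `sbcnn_exported`.
#' @param x \{-1,+1\} input array (H, W, C, B) (or matrix (B, features) for
#'   fully connected networks).
#' @param path `"integer"`: folded integer thresholds; `"float"`: reference
#'   batch-norm-plus-sign arithmetic (identical results by construction --
#'   the exported thresholds are exact on integer accumulations).
#' @param stages which stages to run (default all).
#' @return final-stage accumulation scores (B x units matrix for the output
#'   stage), or the \{-1,+1\} activation map of the last requested stage.
#' @export
forward_exported <- function(model, x, path = c("integer", "float"),
                             stages = seq_along(model$stages)) {
  path <- match.arg(path)
  a <- x
  for (k in stages) {
    st <- model$stages[[k]]
    s <- stage_accumulate(st, a)
    if (is.null(st$t_dot)) {            # output stage: raw integer scores
      if (!is.matrix(s)) { d <- dim(s); s <- t(matrix(s, nrow = prod(d[-length(d)]))) }
      return(s)
    }
    a <- if (path == "integer") stage_threshold_int(st, s)
         else stage_threshold_float(st, s)
  }
  a
}

#' Aggregate per-presentation sign maps
#'
#' Elementwise sign of the sum of \{-1,+1\} activation maps; a tied (zero)
#' sum resolves to +1, consistent with the package-wide sign(0) = +1
#' convention.
#'
#' @param a_list non-empty list of \{-1,+1\} vectors/arrays, equal shape.
#' @return \{-1,+1\} array of the common shape.
#' @export
aggregate_presentations <- function(a_list) {
  if (length(a_list) == 0) stop("empty presentation list")
  n1 <- length(a_list[[1]])
  if (any(vapply(a_list, length, integer(1)) != n1))
    stop("presentation maps must share one shape")
  sign_pm1(Reduce(`+`, a_list))
}

#' Stochastic inference with presentation aggregation
#'
#' For each of `n_infer` presentations, draws a stochastic binarization of
#' the input, passes it through the first exported layer to a sign map
#' `a_n`, aggregates `A_0 = sign(sum_n a_n)` (ties to +1), and propagates
#' `A_0` through the remaining binarized layers on the integer-only path.
#'
#' @param model an `sbcnn_exported` (or a trained `sbcnn_net`, exported on
#'   the fly).
#' @param x raw image array (H, W, C, B).
#' @param n_infer number of presentations, `>= 1`.
#' @param dist sampling distribution; defaults to the model's.
#' @param seed optional seed for reproducible inference.
#' @return integer score matrix (B x n_classes); higher is stronger.
#' @export
sbcnn_infer <- function(model, x, n_infer = NULL, dist = NULL, seed = NULL) {
  if (inherits(model, "sbcnn_net")) model <- export_model(model)
  stopifnot(inherits(model, "sbcnn_exported"))
  if (is.null(model$stages[[1]]$t_dot))
    stop("model has no folded thresholds; train with batch norm and export")
  if (is.null(n_infer)) n_infer <- model$presentation$n_infer
  if (n_infer < 1) stop("n_infer must be >= 1")
  if (is.null(dist)) dist <- model$dist
  if (!is.null(seed)) set.seed(seed)
  enc <- if (dist == "normal") normalize_channels(x, model$stats)
         else rescale_minmax(x, model$stats)
  asum <- NULL
  for (n in seq_len(n_infer)) {
    bits <- sample_bit(enc, dist)
    a_n <- forward_exported(model, 2 * bits - 1, "integer", stages = 1L)
    asum <- if (is.null(asum)) a_n else asum + a_n
  }
  A0 <- sign_pm1(asum)
  forward_exported(model, A0, "integer",
                   stages = seq_along(model$stages)[-1])
}

# ---- model container ----------------------------------------------------

raw_to_hex <- function(r) paste(as.character(r), collapse = "")
hex_to_raw <- function(h) as.raw(strtoi(substring(h, seq(1, nchar(h), 2),
                                                  seq(2, nchar(h), 2)), 16L))

#' Write an exported model to a JSON container
#'
#' Per-stage packed weight bits (column-major, the byte/bit order of
#' [binary_tensor()]) as hex strings, integer thresholds, and a header with
#' shapes, channel statistics and presentation configuration.
#'
#' @param model an `sbcnn_exported`.
#' @param path output file.
#' @export
write_sbcnn_model <- function(model, path) {
  stages <- lapply(model$stages, function(st) {
    list(type = st$type,
         dims = dim(st$W),
         weights_hex = raw_to_hex(binary_tensor(as.vector(st$W))$payload),
         t_dot = if (is.null(st$t_dot)) NULL else st$t_dot,
         dir = if (is.null(st$dir)) NULL else st$dir,
         pool_kernel = if (is.null(st$pool)) NULL else st$pool$kernel,
         in_shape = if (is.null(st$in_shape)) NULL else st$in_shape,
         pad = if (is.null(st$pad)) NULL else st$pad,
         kernel = if (is.null(st$map)) NULL else
           as.integer(sqrt(nrow(st$W) / st$in_shape[3])))
  })
  obj <- list(format = "sbcnn-model-v1",
              dist = model$dist,
              n_infer = model$presentation$n_infer,
              stats = list(mu = model$stats$mu, sigma = model$stats$sigma,
                           min = model$stats$min, max = model$stats$max),
              stages = stages)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an exported model written by [write_sbcnn_model()]
#'
#' Validates that each stage's packed payload carries exactly
#' `prod(dims)` live bits (fan-in/mask consistency) before unpacking.
#'
#' @param path JSON container path.
#' @return an `sbcnn_exported` (stages carry weights/thresholds/pooling;
#'   reference batch-norm parameters are not round-tripped).
#' @export
read_sbcnn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "sbcnn-model-v1")) stop("unrecognized container")
  stages <- lapply(seq_along(obj$stages), function(i) {
    row <- obj$stages[[i]]
    dims <- as.integer(unlist(row$dims))
    payload <- hex_to_raw(row$weights_hex)
    n <- prod(dims)
    if (length(payload) != ceiling(n / 8))
      stop("stage ", i, ": payload has ", length(payload) * 8,
           " bits but dims imply ", n)
    bits <- as.integer(rawToBits(payload))
    if (length(bits) > n && any(bits[-seq_len(n)] != 0L))
      stop("stage ", i, ": non-zero padding bits in packed payload")
    st <- list(type = row$type,
               W = matrix(2L * bits[seq_len(n)] - 1L, dims[1], dims[2]),
               n = dims[1], out_units = dims[2])
    absent <- function(v) is.null(v) || (is.list(v) && length(v) == 0)
    if (!absent(row$t_dot)) st$t_dot <- as.integer(unlist(row$t_dot))
    if (!absent(row$dir)) st$dir <- as.integer(unlist(row$dir))
    if (st$type == "conv") {
      st$in_shape <- as.integer(unlist(row$in_shape)); st$pad <- as.integer(row$pad)
      k <- as.integer(row$kernel); st$out_ch <- dims[2]
      st$map <- conv_index_map(st$in_shape[1], st$in_shape[2], st$in_shape[3],
                               k, 1L, st$pad)
    }
    if (!absent(row$pool_kernel)) {
      pk <- as.integer(row$pool_kernel)
      st$pool <- list(kernel = pk,
                      map = conv_index_map(st$map$oh, st$map$ow, 1L, pk, pk, 0L))
    }
    st
  })
  stats <- structure(list(mu = unlist(obj$stats$mu), sigma = unlist(obj$stats$sigma),
                          min = unlist(obj$stats$min), max = unlist(obj$stats$max)),
                     class = "channel_stats")
  structure(list(stages = stages, stats = stats, dist = obj$dist,
                 presentation = presentation_config(max(1L, obj$n_infer),
                                                    strategy = "matched")),
            class = "sbcnn_exported")
}
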