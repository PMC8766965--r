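# Bit-packed {-1,+1} tensor arithmetic: the unit of all binarized compute.
#
# Payload convention: logical value +1 <-> bit 1, -1 <-> bit 0, packed into
# bytes (R `raw`), little-endian bit order within each byte (the order used
# by packBits()). Padding bits in the final byte are stored as 0 and excluded
# from every operation through `valid_mask`.

# popcount of each possible byte value 0..255
POPCOUNT8 <- vapply(0:255, function(i) sum(as.integer(intToBits(i)[1:8])), integer(1))

#' Construct a bit-packed binary tensor
#'
#' Packs a vector/array of logical values in \{-1, +1\} into bytes
#' (bit 1 encodes +1). All binarized network compute in this package --
#' XNOR, masked popcount, the thresholded binary neuron -- operates on
#' this representation.
#'
#' @param values numeric/integer vector or array with elements in \{-1, +1\}.
#' @param shape integer vector; defaults to `dim(values)` or length.
#' @return an object of class `binary_tensor` with fields `shape`,
#'   `payload` (raw), `valid_mask` (raw), `n` (live bit count).
#' @export
binary_tensor <- function(values, shape = NULL) {
  v <- as.vector(values)
  if (length(v) < 1L) stop("binary_tensor requires at least one element")
  bad <- which(!(v == 1 | v == -1))
  if (length(bad)) stop("values must be in {-1,+1}; first offender at index ", bad[1])
  if (is.null(shape)) shape <- if (!is.null(dim(values))) dim(values) else length(v)
  if (prod(shape) != length(v)) stop("shape does not match number of elements")
  n <- length(v)
  pad <- (8L - n %% 8L) %% 8L
  bits <- c(as.integer(v > 0), integer(pad))
  mask <- c(rep(1L, n), integer(pad))
  structure(
    list(shape = as.integer(shape),
         payload = packBits(as.integer(bits), type = "raw"),
         valid_mask = packBits(mask, type = "raw"),
         n = n),
    class = "binary_tensor")
}

#' @export
print.binary_tensor <- function(x, ...) {
  cat("<binary_tensor> shape [", paste(x$shape, collapse = " x "),
      "], ", x$n, " live bits in ", length(x$payload), " bytes\n", sep = "")
  invisible(x)
}

#' Unpack a binary tensor back to \{-1, +1\} values
#'
#' Exact inverse of [binary_tensor()]: `unpack(binary_tensor(v))` equals `v`
#' for every valid input, restoring `dim` for multi-dimensional shapes.
#'
#' @param bt a `binary_tensor`.
#' @return integer vector/array with elements in \{-1, +1\}.
#' @export
unpack <- function(bt) {
  stopifnot(inherits(bt, "binary_tensor"))
  bits <- as.integer(rawToBits(bt$payload))[seq_len(bt$n)]
  out <- 2L * bits - 1L
  if (length(bt$shape) > 1L) dim(out) <- bt$shape
  out
}

#' Sign-binarize a real tensor
#'
#' Elementwise `sign` with the fixed convention sign(0) = +1, so binarization
#' is deterministic everywhere. This is the activation used by every
#' binarized layer.
#'
#' @param x finite numeric vector/array.
#' @return a `binary_tensor` of the same shape.
#' @export
binarize_sign <- function(x) {
  nas <- which(is.na(x))
  if (length(nas)) stop("non-finite element at index ", nas[1])
  binary_tensor(ifelse(as.vector(x) >= 0, 1L, -1L),
                shape = if (!is.null(dim(x))) dim(x) else length(x))
}

#' Elementwise XNOR of two binary tensors
#'
#' Output bit is +1 where the inputs agree. In \{-1,+1\} arithmetic this is
#' the elementwise product, which is why popcount(xnor(w, x)) carries the
#' dot product: 2*popcount - n == sum(w*x).
#'
#' @param a,b `binary_tensor`s of identical shape.
#' @return a `binary_tensor`.
#' @export
xnor <- function(a, b) {
  stopifnot(inherits(a, "binary_tensor"), inherits(b, "binary_tensor"))
  if (!identical(a$shape, b$shape)) stop("shape mismatch: [",
    paste(a$shape, collapse = ","), "] vs [", paste(b$shape, collapse = ","), "]")
  # xor gives 1 where bits differ; complement and re-mask padding to 0
  agree <- xor(xor(a$payload, b$payload), as.raw(rep(255L, length(a$payload))))
  structure(list(shape = a$shape, payload = agree & a$valid_mask,
                 valid_mask = a$valid_mask, n = a$n),
            class = "binary_tensor")
}

#' Masked popcount
#'
#' Number of +1 bits among the live bits of a binary tensor; padding bits in
#' the final byte are never counted.
#'
#' @param a a `binary_tensor`.
#' @return integer count in `[0, a$n]`.
#' @export
popcount <- function(a) {
  stopifnot(inherits(a, "binary_tensor"))
  sum(POPCOUNT8[as.integer(a$payload & a$valid_mask) + 1L])
}

#' Popcount-domain neuron threshold
#'
#' @param b integer threshold in the popcount domain (a learned quantity;
#'   it may lie outside `[0, n]`).
#' @param n fan-in (live bit count), `n >= 1`.
#' @return object of class `neuron_threshold`.
#' @export
neuron_threshold <- function(b, n) {
  if (n < 1) stop("fan-in n must be >= 1")
  structure(list(b = as.integer(round(b)), n = as.integer(n)),
            class = "neuron_threshold")
}

#' Thresholded XNOR-popcount neuron
#'
#' Computes `sign(popcount(xnor(w, x)) - b)` with sign(0) = +1. Because
#' popcount(XNOR) = (n + w.x)/2, this equals `sign(w.x - (2b - n))` computed
#' in ordinary +/-1 arithmetic.
#'
#' @param w,x `binary_tensor`s of identical shape (weights and inputs).
#' @param t a [neuron_threshold()] whose `n` equals the live bit count.
#' @return +1 or -1.
#' @export
binary_neuron <- function(w, x, t) {
  stopifnot(inherits(t, "neuron_threshold"))
  if (t$n != w$n) stop("fan-in mismatch: threshold n=", t$n, ", tensor has ", w$n)
  pc <- popcount(xnor(w, x))
  if (pc - t$b >= 0L) 1L else -1L
}

#' Straight-through estimator gradient
#'
#' Surrogate gradient for the sign non-linearity used in binarization-aware
#' training: the upstream gradient passes unchanged where the pre-activation
#' lies in the hard-tanh window `|pre| <= 1` and is zeroed elsewhere.
#'
#' @param upstream real gradient tensor.
#' @param pre_activation real tensor, same shape.
#' @return real tensor, same shape.
#' @export
ste_grad <- function(upstream, pre_activation) {
  if (length(upstream) != length(pre_activation))
    stop("shape mismatch between upstream and pre_activation")
  upstream * (abs(pre_activation) <= 1)
}

#' Fold batch normalization into an integer popcount threshold
#'
#' Absorbs the affine batch-norm transform `gamma*(s - mean)/sqrt(var+eps) +
#' beta` (applied to the +/-1 accumulation `s = w.x`) into the comparison
#' `sign(s - theta)`, then converts to the popcount domain of the binary
#' neuron. Since `s` is integer-valued, `ceiling(theta)` reproduces the float
#' decision exactly under the sign(0) = +1 convention; a negative `gamma`
#' flips the weight signs so the comparison direction is preserved.
#'
#' @param bn_params list with `gamma`, `beta`, `mean`, `var` (scalars or
#'   per-unit vectors) and optionally `eps` (default 1e-5).
#' @param layer list with `n` (fan-in) and optionally `weights`
#'   (fan_in x units matrix of +/-1) to be sign-flipped where `gamma < 0`.
#' @return list with `threshold` (a [neuron_threshold()] when a single unit,
#'   else integer vector of popcount-domain thresholds), `flip` (logical per
#'   unit), and `weights` (possibly negated copy, when supplied).
#' @export
fold_batchnorm <- function(bn_params, layer) {
  g <- bn_params$gamma; be <- bn_params$beta
  mu <- bn_params$mean; v <- bn_params$var
  eps <- if (is.null(bn_params$eps)) 1e-5 else bn_params$eps
  if (any(g == 0)) stop("batch-norm scale gamma must be non-zero to fold")
  n <- layer$n
  sd <- sqrt(v + eps)
  theta <- mu - be * sd / g          # sign(bn(s)) == sign(s - theta) when g > 0
  flip <- g < 0                       # g < 0: s <= theta  <=>  (-s) >= -theta
  theta <- ifelse(flip, -theta, theta)
  # popcount domain: s = 2*pc - n  =>  pc >= (n + theta)/2
  b <- as.integer(ceiling((n + theta) / 2))
  w <- layer$weights
  if (!is.null(w) && any(flip)) w[, flip] <- -w[, flip]
  thr <- if (length(b) == 1L) neuron_threshold(b, n) else b
  # theta_int: exact threshold in the +/-1-accumulation domain, valid even
  # when zero padding makes the accumulation lose fan-in parity
  list(threshold = thr, theta_int = as.integer(ceiling(theta)),
       flip = flip, weights = w, n = n)
}
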