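# Stochastic input binarization: per-channel mean-sigma normalization,
# comparison of pixels against random thresholds (normal or uniform), and
# bitstream aggregation over N_pre presentations.

#' Per-channel normalization statistics
#'
#' Computes the per-channel mean and population standard deviation of a
#' training image set, the parameters of mean-sigma normalization. Also
#' records the per-channel min/max used by the uniform-sampling baseline.
#'
#' @param images a single image array with channels in the last dimension
#'   (e.g. H x W x 3), a batched array with channels in the third of four
#'   dimensions (H x W x 3 x N), or a list of image arrays.
#' @param n_channels expected channel count (default 3 for RGB).
#' @param sigma_floor smallest admissible standard deviation; a constant
#'   channel triggers an error telling the caller to supply a floor.
#' @return object of class `channel_stats`: lists `mu`, `sigma`, `min`,
#'   `max`, each of length `n_channels`.
#' @export
channel_stats <- function(images, n_channels = 3L, sigma_floor = 0) {
  if (!is.list(images)) {
    d <- dim(images)
    if (!is.null(d) && length(d) == 4L && d[3] == n_channels)
      images <- lapply(seq_len(d[4]), function(i) images[, , , i, drop = TRUE])
    else images <- list(images)
  }
  vals <- vector("list", n_channels)
  for (im in images) {
    d <- dim(im)
    if (is.null(d) || d[length(d)] != n_channels)
      stop("each image must have ", n_channels, " channels in its last dimension")
    m <- matrix(as.vector(im), ncol = n_channels)
    for (ch in seq_len(n_channels)) vals[[ch]] <- c(vals[[ch]], m[, ch])
  }
  if (length(vals[[1]]) < 2L) stop("need at least 2 pixels per channel")
  mu <- vapply(vals, mean, numeric(1))
  # population (ddof = 0) standard deviation
  sigma <- vapply(vals, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
  if (any(sigma <= sigma_floor))
    stop("constant (or near-constant) channel: sigma = ",
         signif(min(sigma), 3),
         "; supply a positive `sigma_floor` replacement value")
  structure(list(mu = mu, sigma = sigma,
                 min = vapply(vals, min, numeric(1)),
                 max = vapply(vals, max, numeric(1))),
            class = "channel_stats")
}

#' Mean-sigma normalization
#'
#' `X_r = (X_d - mu_i) / sigma_i` applied per channel (channels in the last
#' array dimension).
#'
#' @param x raw pixel array (last dimension = channels).
#' @param stats a [channel_stats()] object.
#' @return normalized array, same shape.
#' @export
normalize_channels <- function(x, stats) {
  channel_apply(x, stats, function(v, ch) (v - stats$mu[ch]) / stats$sigma[ch])
}

# apply f(values, channel) over the channel dimension: last dim for single
# images (H,W,C), third dim for batches (H,W,C,B)
channel_apply <- function(x, stats, f) {
  stopifnot(inherits(stats, "channel_stats"))
  d <- dim(x); nc <- length(stats$mu)
  out <- x
  if (!is.null(d) && length(d) == 4L && d[3] == nc) {
    for (ch in seq_len(nc)) out[, , ch, ] <- f(x[, , ch, , drop = FALSE], ch)
  } else if (!is.null(d) && d[length(d)] == nc) {
    m <- matrix(as.vector(x), ncol = nc)
    for (ch in seq_len(nc)) m[, ch] <- f(m[, ch], ch)
    out <- array(m, dim = d)
  } else stop("channel dimension mismatch")
  out
}

#' Invert mean-sigma normalization
#' @inheritParams normalize_channels
#' @return raw-scale array.
#' @export
denormalize_channels <- function(x, stats) {
  channel_apply(x, stats, function(v, ch) v * stats$sigma[ch] + stats$mu[ch])
}

#' Rescale pixels to [0, 1] for uniform-threshold sampling
#'
#' Per-channel min-max rescaling over the training-split range recorded in
#' `stats`; out-of-range values clamp to [0, 1].
#' @inheritParams normalize_channels
#' @export
rescale_minmax <- function(x, stats) {
  rng <- pmax(stats$max - stats$min, .Machine$double.eps)
  channel_apply(x, stats, function(v, ch)
    pmin(pmax((v - stats$min[ch]) / rng[ch], 0), 1))
}

#' Draw one stochastic binary sample per pixel
#'
#' For `dist = "normal"` the normalized value is compared against a standard
#' normal threshold, so P(bit = 1) = Phi(x_r) -- equivalent to comparing the
#' raw pixel against a normal draw with that channel's (mu, sigma). For
#' `dist = "uniform"` the input must be min-max rescaled to [0, 1]
#' (see [rescale_minmax()]) and is compared against a uniform draw, so
#' P(bit = 1) equals the rescaled intensity.
#'
#' @param x_r normalized values (`dist = "normal"`) or [0,1]-rescaled values
#'   (`dist = "uniform"`); any shape, vectorized.
#' @param dist `"normal"` or `"uniform"`.
#' @param literal if TRUE, reproduce the saturating literal form in which the
#'   *normalized* value is compared against a normal draw with raw-domain
#'   channel parameters; requires `stats` and a channel index `ch`.
#' @param stats,ch only for `literal = TRUE`.
#' @return integer 0/1 values, same shape as `x_r`.
#' @export
sample_bit <- function(x_r, dist = c("normal", "uniform"),
                       literal = FALSE, stats = NULL, ch = 1L) {
  dist <- match.arg(dist)
  n <- length(x_r)
  thr <- if (literal) {
    if (is.null(stats)) stop("literal sampling requires channel stats")
    stats::rnorm(n, stats$mu[ch], stats$sigma[ch])
  } else if (dist == "normal") stats::rnorm(n) else stats::runif(n)
  out <- as.integer(as.vector(x_r) > thr)
  if (!is.null(dim(x_r))) dim(out) <- dim(x_r)
  out
}

#' Sample a bitstream of N_pre presentations
#'
#' Collects `n_pre` independent binary samples per value and their mean
#' `X_m`, the stochastic-computing representation of the input. The mean is
#' an unbiased estimate of P(bit = 1) with binomial variance p(1-p)/n_pre.
#'
#' @inheritParams sample_bit
#' @param n_pre number of presentations, `>= 1`.
#' @return object of class `bit_stream`: `bits` (n_pre x n_values integer
#'   matrix), `mean` (per-value stream mean), `n_pre`.
#' @export
sample_stream <- function(x_r, n_pre, dist = c("normal", "uniform")) {
  dist <- match.arg(dist)
  if (n_pre < 1) stop("n_pre must be >= 1")
  v <- as.vector(x_r)
  bits <- matrix(0L, nrow = n_pre, ncol = length(v))
  for (j in seq_len(n_pre)) bits[j, ] <- sample_bit(v, dist)
  structure(list(bits = bits, mean = colMeans(bits), n_pre = as.integer(n_pre)),
            class = "bit_stream")
}

#' Fast presentation-mean sampling
#'
#' Draws the bitstream mean `X_m` directly as Binomial(n_pre, p)/n_pre with
#' p = Phi(x_r) (normal) or p = x (uniform, [0,1] input) -- distributionally
#' identical to averaging `n_pre` independent comparator draws, at cost
#' independent of `n_pre`. Used by the training loop, which only consumes
#' the mean.
#'
#' @inheritParams sample_stream
#' @return numeric vector/array of stream means in [0, 1], same shape.
#' @export
sample_stream_mean <- function(x_r, n_pre, dist = c("normal", "uniform")) {
  dist <- match.arg(dist)
  if (n_pre < 1) stop("n_pre must be >= 1")
  p <- if (dist == "normal") stats::pnorm(as.vector(x_r)) else pmin(pmax(as.vector(x_r), 0), 1)
  out <- stats::rbinom(length(p), n_pre, p) / n_pre
  if (!is.null(dim(x_r))) dim(out) <- dim(x_r)
  out
}

#' Behavioural resistive-device noise model
#'
#' Cycle-to-cycle variability of an OxRAM cell's low-resistance state,
#' modelled as a truncated-normal resistance (R > 0) mapped through a
#' monotone resistance-to-voltage function; the mapped values serve as the
#' comparator's random reference thresholds.
#'
#' @param mu_R mean resistance (Ohm).
#' @param sigma_R resistance standard deviation (Ohm), `>= 0`.
#' @param mapping monotone function from resistance to comparator threshold;
#'   default identity up to an affine scale of 1 (threshold == resistance).
#' @return object of class `device_noise_model`.
#' @export
device_noise_model <- function(mu_R, sigma_R, mapping = identity) {
  if (sigma_R < 0) stop("sigma_R must be >= 0")
  structure(list(mu_R = mu_R, sigma_R = sigma_R, mapping = mapping),
            class = "device_noise_model")
}

#' Draw a comparator threshold sequence from a device noise model
#'
#' Resistances are drawn from N(mu_R, sigma_R) truncated to positive values
#' (rejection sampling) and mapped through the model's monotone mapping.
#' With an affine mapping this reproduces normal-threshold sampling, which is
#' how the device realizes the normal-distribution input sampler.
#'
#' @param model a [device_noise_model()].
#' @param n number of thresholds, `>= 1`.
#' @return numeric vector of length `n`.
#' @export
device_threshold_sequence <- function(model, n) {
  stopifnot(inherits(model, "device_noise_model"))
  if (n < 1) stop("n must be >= 1")
  if (model$sigma_R == 0) return(model$mapping(rep(model$mu_R, n)))
  r <- numeric(0)
  while (length(r) < n) {
    cand <- stats::rnorm(n - length(r), model$mu_R, model$sigma_R)
    r <- c(r, cand[cand > 0])
  }
  model$mapping(r)
}
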