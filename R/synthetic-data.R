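# Synthetic data generation: microscopy-like scenes with planted
# high-contrast objects and exact ground-truth boxes, positive/negative
# slice datasets with dihedral augmentation and negative rebalancing, and a
# small multi-class RGB classification set. Statistical stand-ins that
# exercise the pipeline, not photorealistic simulations.

# bilinear upscale of (h, w, c) to (H, W, c)
upsample_bilinear <- function(a, H, W = H) {
  d <- dim(a)
  sy <- (seq_len(H) - 0.5) / H * d[1] + 0.5
  sx <- (seq_len(W) - 0.5) / W * d[2] + 0.5
  y0 <- pmin(pmax(floor(sy), 1), d[1]); y1 <- pmin(y0 + 1, d[1]); fy <- sy - y0
  x0 <- pmin(pmax(floor(sx), 1), d[2]); x1 <- pmin(x0 + 1, d[2]); fx <- sx - x0
  fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
  out <- array(0, dim = c(H, W, d[3]))
  for (ch in seq_len(d[3])) {
    m <- a[, , ch]
    out[, , ch] <- (1 - fy) * ((m[y0, x0] * rep((1 - fx), each = H)) +
                               (m[y0, x1] * rep(fx, each = H))) +
                   fy * ((m[y1, x0] * rep((1 - fx), each = H)) +
                         (m[y1, x1] * rep(fx, each = H)))
  }
  out
}

#' Specification of a synthetic microscopy-like scene
#'
#' @param size image side (square, pixels).
#' @param bg_mean background mean color (RGB in [0,1]).
#' @param noise_std per-pixel Gaussian background noise sd.
#' @param mottle_amp amplitude of low-frequency background mottling.
#' @param shape object model: "dot" (round, plasmodium-like), "rod"
#'   (elongated, bacillus-like) or "ellipse" (egg-like).
#' @param n_objects number of planted objects.
#' @param size_range object diameter range in pixels.
#' @param contrast Mahalanobis distance of the object color from the
#'   background in background-noise units; must be > 0 so planted objects
#'   are detectable by construction.
#' @param color_dir unit direction of the color offset (stain-like: darker
#'   red/green, bluer).
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(size = 160L, bg_mean = c(0.72, 0.64, 0.70),
                       noise_std = 0.04, mottle_amp = 0.03,
                       shape = c("dot", "rod", "ellipse"),
                       n_objects = 4L, size_range = c(11L, 16L),
                       contrast = 6,
                       color_dir = c(-0.40, -0.58, 0.71)) {
  shape <- match.arg(shape)
  if (contrast <= 0) stop("contrast must be > 0: objects must be detectable by construction")
  if (max(size_range) >= size) stop("object sizes must be smaller than the image")
  if (n_objects < 0) stop("n_objects must be >= 0")
  structure(list(size = as.integer(size), bg_mean = bg_mean,
                 noise_std = noise_std, mottle_amp = mottle_amp, shape = shape,
                 n_objects = as.integer(n_objects),
                 size_range = as.integer(size_range), contrast = contrast,
                 color_dir = color_dir / sqrt(sum(color_dir^2))),
            class = "scene_spec")
}

object_mask <- function(shape, sz, angle) {
  r <- sz / 2
  cy <- cx <- (sz + 1) / 2
  yy <- matrix(seq_len(sz), sz, sz) - cy
  xx <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - cx
  u <- cos(angle) * xx + sin(angle) * yy
  v <- -sin(angle) * xx + cos(angle) * yy
  switch(shape,
    dot = (xx^2 + yy^2) <= r^2,
    rod = abs(u) <= r & abs(v) <= pmax(r * 0.28, 1.2),
    ellipse = (u / r)^2 + (v / (0.6 * r))^2 <= 1)
}

#' Generate a synthetic scene with planted objects
#'
#' Background = mean color + low-frequency mottling + per-pixel Gaussian
#' noise; objects are parametric shapes at random non-overlapping positions
#' whose color sits `contrast` noise-standard-deviations away from the
#' background mean. Uses the current RNG state (seed with `set.seed()`).
#'
#' @param spec a [scene_spec()].
#' @param max_retries placement retries per object before giving up.
#' @return list: `image` (size x size x 3 array), `boxes` (data.frame
#'   `x0,y0,x1,y1`, 0-based half-open pixel coordinates).
#' @export
generate_scene <- function(spec, max_retries = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  S <- spec$size
  img <- array(rep(spec$bg_mean, each = S * S), dim = c(S, S, 3))
  mott <- upsample_bilinear(array(stats::rnorm(4 * 4 * 3), dim = c(4, 4, 3)), S, S)
  img <- img + spec$mottle_amp * mott +
    array(stats::rnorm(S * S * 3, sd = spec$noise_std), dim = c(S, S, 3))
  obj_color <- spec$bg_mean + spec$contrast * spec$noise_std * spec$color_dir
  boxes <- NULL
  placed <- list()
  for (k in seq_len(spec$n_objects)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      sz <- sample(spec$size_range[1]:spec$size_range[2], 1)
      x0 <- sample.int(S - sz, 1); y0 <- sample.int(S - sz, 1)  # 1-based top-left
      cand <- c(x0, y0, x0 + sz, y0 + sz)
      clash <- any(vapply(placed, function(b)
        cand[1] < b[3] && b[1] < cand[3] && cand[2] < b[4] && b[2] < cand[4],
        logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place object ", k,
                  " without overlap; reduce n_objects or object size")
    placed[[k]] <- cand
    mask <- object_mask(spec$shape, sz, stats::runif(1, 0, pi))
    ys <- y0:(y0 + sz - 1); xs <- x0:(x0 + sz - 1)
    for (ch in 1:3) {
      sl <- img[ys, xs, ch]
      sl[mask] <- obj_color[ch] + stats::rnorm(sum(mask), sd = spec$noise_std / 2)
      img[ys, xs, ch] <- sl
    }
    # tight box around the mask footprint, 0-based half-open
    ry <- range(which(rowSums(mask) > 0)); rx <- range(which(colSums(mask) > 0))
    boxes <- rbind(boxes, data.frame(
      x0 = x0 + rx[1] - 2, y0 = y0 + ry[1] - 2,
      x1 = x0 + rx[2] - 1, y1 = y0 + ry[2] - 1))
  }
  if (is.null(boxes)) boxes <- data.frame(x0 = numeric(0), y0 = numeric(0),
                                          x1 = numeric(0), y1 = numeric(0))
  list(image = img, boxes = boxes)
}

rot90cc <- function(p) aperm(p, c(2, 1, 3))[rev(seq_len(dim(p)[2])), , , drop = FALSE]
flip_h <- function(p) p[, rev(seq_len(dim(p)[2])), , drop = FALSE]

dihedral8 <- function(p) {
  out <- vector("list", 8)
  q <- p
  for (i in 1:4) { out[[i]] <- q; q <- rot90cc(q) }
  q <- flip_h(p)
  for (i in 5:8) { out[[i]] <- q; q <- rot90cc(q) }
  out
}

area_downsample <- function(p, d) {
  if (d == 1L) return(p)
  dm <- dim(p)
  H <- dm[1] %/% d; W <- dm[2] %/% d
  out <- array(0, dim = c(H, W, dm[3]))
  for (ch in seq_len(dm[3]))
    out[, , ch] <- .colMeans(
      matrix(aperm(array(p[seq_len(H * d), seq_len(W * d), ch],
                         dim = c(d, H, d, W)), c(1, 3, 2, 4)), nrow = d * d),
      d * d, H * W)
  out
}

boxes_intersect <- function(a, bx) {
  # a = c(x0,y0,x1,y1); bx data.frame of boxes; half-open coords
  if (nrow(bx) == 0) return(FALSE)
  any(a[1] < bx$x1 & bx$x0 < a[3] & a[2] < bx$y1 & bx$y0 < a[4])
}

#' Slice scenes into labelled positive/negative patches
#'
#' Positives are crops centered on each ground-truth box (clamped inside
#' the scene), expanded by the 8 dihedral transforms (all 90-degree
#' rotations and flips) when `augment = TRUE`; each dihedral copy is drawn
#' at an independent random offset of at most `jitter` pixels per axis,
#' capped so the patch center stays inside the ground-truth box (offset
#' jitter teaches the classifier the off-center object placements a sliding
#' window produces). Negatives are random crops whose footprint intersects
#' no ground-truth box, each kept with probability `neg_keep_prob` (the
#' rebalancing step). Crops of side `patch_size * downsample` are
#' area-averaged down to `patch_size`.
#'
#' @param scenes list of [generate_scene()] results.
#' @param patch_size output patch side (20 or 30 are typical).
#' @param downsample integer area-averaging factor.
#' @param neg_keep_prob probability of keeping each candidate negative.
#' @param augment apply the dihedral group to positives.
#' @param jitter maximum positive-crop center offset per axis (pixels, in
#'   scene coordinates before downsampling); 0 reproduces exactly centered
#'   crops. The default 3 covers the worst-case offset between an object
#'   center and the nearest window center at the detection stride of 5
#'   (a larger jitter widens the detector's response plateau and merges
#'   neighbouring objects).
#' @param n_neg_per_scene candidate negatives drawn per scene.
#' @param max_tries placement attempts per candidate negative.
#' @return list: `x` (patch array p x p x 3 x N), `y` (1 = negative,
#'   2 = positive), `ratio_before`, `ratio_after` (positive:negative class
#'   ratios before/after augmentation+rebalancing).
#' @export
make_slices <- function(scenes, patch_size = 20L, downsample = 1L,
                        neg_keep_prob = 0.5, augment = TRUE, jitter = 3L,
                        n_neg_per_scene = 24L, max_tries = 80L) {
  crop <- patch_size * downsample
  pos <- list(); neg <- list()
  n_pos_raw <- 0L; n_neg_raw <- 0L
  for (sc in scenes) {
    S <- dim(sc$image)[1]
    if (crop > S) stop("patch (after downsampling) larger than scene")
    for (i in seq_len(nrow(sc$boxes))) {
      b <- sc$boxes[i, ]
      cx <- (b$x0 + b$x1) / 2; cy <- (b$y0 + b$y1) / 2
      # jitter capped so the patch center stays strictly inside the box
      jx <- min(jitter, floor((b$x1 - b$x0 - 1) / 2))
      jy <- min(jitter, floor((b$y1 - b$y0 - 1) / 2))
      crop_at <- function(dx, dy) {
        x0 <- round(min(max(cx + dx - crop / 2, 0), S - crop))   # 0-based
        y0 <- round(min(max(cy + dy - crop / 2, 0), S - crop))
        p <- sc$image[(y0 + 1):(y0 + crop), (x0 + 1):(x0 + crop), , drop = FALSE]
        area_downsample(p, downsample)
      }
      n_pos_raw <- n_pos_raw + 1L
      if (augment) {
        tf <- dihedral8(crop_at(0, 0))   # one centered copy per transform slot
        pos <- c(pos, lapply(seq_len(8), function(t) {
          if (t == 1L) return(tf[[1L]])
          p <- crop_at(sample(-jx:jx, 1), sample(-jy:jy, 1))
          dihedral8(p)[[t]]
        }))
      } else pos <- c(pos, list(crop_at(0, 0)))
    }
    found_any <- FALSE
    for (j in seq_len(n_neg_per_scene)) {
      for (try in seq_len(max_tries)) {
        x0 <- sample.int(S - crop + 1L, 1) - 1L; y0 <- sample.int(S - crop + 1L, 1) - 1L
        cand <- c(x0, y0, x0 + crop, y0 + crop)
        if (!boxes_intersect(cand, sc$boxes)) {
          found_any <- TRUE
          n_neg_raw <- n_neg_raw + 1L
          if (stats::runif(1) < neg_keep_prob) {
            p <- sc$image[(y0 + 1):(y0 + crop), (x0 + 1):(x0 + crop), , drop = FALSE]
            neg <- c(neg, list(area_downsample(p, downsample)))
          }
          break
        }
      }
    }
    if (!found_any && nrow(sc$boxes) < S * S)
      stop("no valid negative location found in a scene; reduce object density")
  }
  patches <- c(neg, pos)
  if (length(patches) == 0) stop("no patches produced")
  x <- array(unlist(patches), dim = c(patch_size, patch_size, 3, length(patches)))
  y <- c(rep(1L, length(neg)), rep(2L, length(pos)))
  list(x = x, y = y,
       ratio_before = n_pos_raw / max(n_neg_raw, 1L),
       ratio_after = length(pos) / max(length(neg), 1L))
}

#' Generate a small multi-class RGB classification set
#'
#' Class templates are smooth random color/texture fields (low-resolution
#' Gaussian fields, bilinearly upscaled) rescaled so the smallest pairwise
#' RMS pixel distance between templates equals `separation`; samples add
#' iid pixel noise of sd `noise_std`. The Bayes error shrinks as
#' `separation / noise_std` grows. Uses the current RNG state.
#'
#' @param n_classes,n_per_class class count and samples per class.
#' @param image_size square image side.
#' @param separation minimum pairwise template RMS distance (> 0).
#' @param noise_std per-pixel noise sd.
#' @return list: `x` (H x W x 3 x N array), `y` (labels 1..n_classes),
#'   `templates` (list of class template arrays).
#' @export
generate_classification_set <- function(n_classes = 3L, n_per_class = 100L,
                                        image_size = 16L, separation = 1,
                                        noise_std = 0.25) {
  if (separation <= 0) stop("separation must be > 0")
  tpl <- lapply(seq_len(n_classes), function(k)
    upsample_bilinear(array(stats::rnorm(4 * 4 * 3, sd = 1), dim = c(4, 4, 3)),
                      image_size, image_size))
  # rescale deviations from the grand mean so min pairwise RMS distance == separation
  gm <- Reduce(`+`, tpl) / n_classes
  dmin <- min(apply(utils::combn(n_classes, 2), 2, function(pr)
    sqrt(mean((tpl[[pr[1]]] - tpl[[pr[2]]])^2))))
  tpl <- lapply(tpl, function(t) gm + (t - gm) * (separation / dmin) + 0.5 - mean(gm))
  N <- n_classes * n_per_class
  x <- array(0, dim = c(image_size, image_size, 3, N))
  y <- integer(N)
  i <- 0L
  for (k in seq_len(n_classes)) for (j in seq_len(n_per_class)) {
    i <- i + 1L
    x[, , , i] <- tpl[[k]] +
      array(stats::rnorm(image_size^2 * 3, sd = noise_std), dim = dim(tpl[[k]]))
    y[i] <- k
  }
  ord <- sample.int(N)
  list(x = x[, , , ord, drop = FALSE], y = y[ord], templates = tpl)
}
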