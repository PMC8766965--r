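# Sliding-window detection: classifier-score heatmap accumulation over
# window pixels, min-max normalization and thresholding, 8-connected
# component box extraction, greedy non-maximal suppression, and greedy
# one-to-one IoU matching against ground truth.
#
# Boxes are data.frames with columns x0, y0, x1, y1 (0-based, half-open
# [x0,x1) x [y0,y1) pixel coordinates, x = column, y = row) and optionally
# score. Images are (H, W, C) arrays indexed [y, x, channel].

#' Construct a detection box table
#' @param x0,y0,x1,y1 coordinates (0-based, half-open); `x1 > x0`, `y1 > y0`.
#' @param score detection scores (finite).
#' @export
detection_boxes <- function(x0, y0, x1, y1, score = rep(0, length(x0))) {
  if (any(x1 <= x0) || any(y1 <= y0)) stop("boxes must have positive extent")
  if (any(!is.finite(score))) stop("scores must be finite")
  data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1, score = score)
}

#' Accumulate a sliding-window classifier heatmap
#'
#' Evaluates the classifier at every window position (stride = window *
#' (1 - overlap), last row/column of windows snapped inside the image) and
#' adds each window's positive-class score to every pixel the window
#' covers. At the default 50% overlap, interior pixels accumulate exactly
#' four window contributions.
#'
#' @param image (H, W, C) array.
#' @param scorer function taking a (window, window, C, n) patch array and
#'   returning n numeric scores (see [make_patch_scorer()]).
#' @param window window side in pixels; must fit inside the image.
#' @param overlap fractional window overlap in [0, 1).
#' @return object of class `heat_map`: `grid` (H x W), `window`, `stride`.
#' @export
sliding_window_heatmap <- function(image, scorer, window, overlap = 0.5) {
  d <- dim(image)
  if (window > d[1] || window > d[2]) stop("window larger than image")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- function(n) unique(c(seq(1L, n - window + 1L, by = stride), n - window + 1L))
  ys <- starts(d[1]); xs <- starts(d[2])
  pos <- expand.grid(y = ys, x = xs)
  patches <- array(0, dim = c(window, window, d[3], nrow(pos)))
  for (i in seq_len(nrow(pos)))
    patches[, , , i] <- image[pos$y[i]:(pos$y[i] + window - 1L),
                              pos$x[i]:(pos$x[i] + window - 1L), , drop = FALSE]
  sc <- scorer(patches)
  grid <- matrix(0, d[1], d[2])
  cover <- matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(pos))) {
    yr <- pos$y[i]:(pos$y[i] + window - 1L); xr <- pos$x[i]:(pos$x[i] + window - 1L)
    grid[yr, xr] <- grid[yr, xr] + sc[i]
    cover[yr, xr] <- cover[yr, xr] + 1L
  }
  structure(list(grid = grid, coverage = cover, window = window,
                 overlap = overlap, stride = stride), class = "heat_map")
}

normalize_heat <- function(grid) {
  rng <- range(grid)
  if (rng[2] - rng[1] <= 0) return(grid * 0)
  (grid - rng[1]) / (rng[2] - rng[1])
}

#' Normalize a heatmap and threshold it to a binary map
#'
#' Normalization to [0, 1] followed by `pixel >= t`. Two normalizations are
#' provided: `"coverage"` (default) divides each pixel's accumulated score
#' by the number of windows covering it, giving the mean covering-window
#' score -- an absolute scale when the classifier emits [0,1] probabilities,
#' so each object is thresholded independently of how strongly the scene's
#' best object responds; `"minmax"` rescales the accumulated map globally
#' by its range (a constant map normalizes to all zeros).
#'
#' @param h a `heat_map` (or plain matrix, in which case min-max is used).
#' @param t threshold in [0, 1].
#' @param method `"coverage"` or `"minmax"`.
#' @return binary (0/1) matrix of the heatmap's dimensions.
#' @export
normalize_and_threshold <- function(h, t = 0.5,
                                    method = c("coverage", "minmax")) {
  method <- match.arg(method)
  if (t < 0 || t > 1) stop("t must be in [0, 1]")
  if (!inherits(h, "heat_map")) return((normalize_heat(h) >= t) * 1L)
  (normalized_grid(h, method) >= t) * 1L
}

normalized_grid <- function(h, method) {
  if (!inherits(h, "heat_map")) return(normalize_heat(h))
  if (method == "coverage") pmin(pmax(h$grid / pmax(h$coverage, 1L), 0), 1)
  else normalize_heat(h$grid)
}

#' Two-level component-local thresholding of a heatmap
#'
#' Coverage-normalizes the heatmap (mean covering-window score), marks
#' coarse candidate regions at the absolute floor `floor_t`, then keeps,
#' within each 8-connected coarse component, only pixels scoring at least
#' `local_frac` of that component's own peak. Peak-relative trimming
#' decouples each object from the scene's strongest response: a single
#' global threshold loses objects whose window-grid alignment halves their
#' accumulated score. Requires a scorer with outputs in [0, 1]
#' (see [make_patch_scorer()]).
#'
#' @param h a `heat_map`.
#' @param floor_t absolute floor on the mean covering-window score.
#' @param local_frac within-component fraction of the component peak.
#' @return binary (0/1) matrix of candidate pixels.
#' @export
local_threshold_map <- function(h, floor_t = 0.25, local_frac = 0.65) {
  stopifnot(inherits(h, "heat_map"))
  g <- normalized_grid(h, "coverage")
  lab <- label_components((g >= floor_t) * 1L)
  out <- matrix(0L, nrow(g), ncol(g))
  if (max(lab) > 0) for (i in seq_len(max(lab))) {
    sel <- lab == i
    out[sel & g >= local_frac * max(g[sel])] <- 1L
  }
  out
}

# 8-connected component labelling by flood fill
label_components <- function(bmap) {
  H <- nrow(bmap); W <- ncol(bmap)
  lab <- matrix(0L, H, W)
  cur <- 0L
  offs <- cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  for (start in which(bmap != 0 & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      py <- (p - 1L) %% H + 1L; px <- (p - 1L) %/% H + 1L
      ny <- py + offs[, 1]; nx <- px + offs[, 2]
      ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
      ni <- ny[ok] + (nx[ok] - 1L) * H
      ni <- ni[bmap[ni] != 0 & lab[ni] == 0L]
      if (length(ni)) { lab[ni] <- cur; queue <- c(queue, ni) }
    }
  }
  lab
}

#' Extract detection boxes from a binary candidate map
#'
#' Labels 8-connected components (diagonal neighbours merge) and returns
#' each component's tight bounding box; the box score is the mean
#' normalized heat over the component's pixels.
#'
#' @param bmap binary matrix from [normalize_and_threshold()] or
#'   [local_threshold_map()].
#' @param heat the `heat_map` the binary map came from (or matrix).
#' @param method normalization used for component scores; match the one
#'   used for thresholding.
#' @param min_area components smaller than this many pixels are dropped
#'   (fragments below the window-stride scale carry no localization signal).
#' @return detection box data.frame (possibly zero rows).
#' @export
extract_boxes <- function(bmap, heat, method = c("coverage", "minmax"),
                          min_area = 1L) {
  method <- match.arg(method)
  grid <- normalized_grid(heat, method)
  lab <- label_components(bmap)
  k <- max(lab)
  if (k == 0L) return(detection_boxes(numeric(0), numeric(0), numeric(0), numeric(0))[0, ])
  out <- lapply(seq_len(k), function(i) {
    sel <- lab == i
    if (sum(sel) < min_area) return(NULL)   # sub-stride fragments are noise
    idx <- which(sel, arr.ind = TRUE)
    data.frame(x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
               x1 = max(idx[, 2]), y1 = max(idx[, 1]),
               score = mean(grid[sel]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(detection_boxes(numeric(0), numeric(0), numeric(0), numeric(0))[0, ])
  do.call(rbind, out)
}

#' Intersection-over-union of axis-aligned boxes
#'
#' @param a single box (data.frame row or named/positional vector
#'   c(x0,y0,x1,y1)).
#' @param b box table (data.frame) or single box; vectorized over `b` rows.
#' @return IoU values in [0, 1].
#' @export
box_iou <- function(a, b) {
  av <- as.numeric(a[c("x0", "y0", "x1", "y1")])
  if (!is.data.frame(b)) b <- as.data.frame(as.list(stats::setNames(
    as.numeric(b[c("x0", "y0", "x1", "y1")]), c("x0", "y0", "x1", "y1"))))
  iw <- pmax(0, pmin(av[3], b$x1) - pmax(av[1], b$x0))
  ih <- pmax(0, pmin(av[4], b$y1) - pmax(av[2], b$y0))
  inter <- iw * ih
  area_a <- (av[3] - av[1]) * (av[4] - av[2])
  area_b <- (b$x1 - b$x0) * (b$y1 - b$y0)
  inter / (area_a + area_b - inter)
}

#' Greedy non-maximal suppression
#'
#' Keeps the highest-scoring box, suppresses every remaining box with IoU
#' strictly greater than `iou_threshold` against a kept box, and repeats.
#'
#' @param boxes detection box data.frame with `score`.
#' @param iou_threshold suppression threshold in [0, 1].
#' @return the kept subset, in descending score order.
#' @export
nms <- function(boxes, iou_threshold = 0.3) {
  if (iou_threshold < 0 || iou_threshold > 1) stop("iou_threshold must be in [0, 1]")
  if (nrow(boxes) == 0) return(boxes)
  ord <- order(boxes$score, decreasing = TRUE)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(boxes)); alive <- rep(TRUE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(boxes)) {
      rest <- which(alive & seq_len(nrow(boxes)) > i)
      if (length(rest)) {
        ious <- box_iou(boxes[i, ], boxes[rest, , drop = FALSE])
        alive[rest[ious > iou_threshold]] <- FALSE
      }
    }
  }
  boxes[keep, , drop = FALSE]
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in descending score order: each prediction is
#' a true positive iff its best-IoU unmatched truth box reaches
#' `iou_threshold`.
#'
#' @param pred detection box data.frame with `score`.
#' @param truth box data.frame (no score needed).
#' @param iou_threshold matching threshold in [0, 1].
#' @return list: `tp`, `fp`, `fn` counts; `labels` logical per prediction
#'   (descending score order) and the matching `scores` vector.
#' @export
match_detections <- function(pred, truth, iou_threshold = 0.3) {
  if (iou_threshold < 0 || iou_threshold > 1) stop("iou_threshold must be in [0, 1]")
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0) return(list(tp = 0L, fp = 0L, fn = nt,
                           labels = logical(0), scores = numeric(0)))
  ord <- order(pred$score, decreasing = TRUE)
  pred <- pred[ord, , drop = FALSE]
  used <- logical(nt)
  labels <- logical(np)
  for (i in seq_len(np)) {
    if (nt == 0) break
    ious <- box_iou(pred[i, ], truth)
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) { labels[i] <- TRUE; used[j] <- TRUE }
  }
  list(tp = sum(labels), fp = sum(!labels), fn = sum(!used),
       labels = labels, scores = pred$score)
}

#' Build a patch scorer from an exported model
#'
#' Wraps [sbcnn_infer()] into the classifier interface of
#' [sliding_window_heatmap()]: the returned function maps a patch batch to
#' a positive-class score. The default `"prob"` output squashes the integer
#' score margin (class 2 minus class 1) through a logistic at the training
#' temperature sqrt(fan-in), giving scores in [0, 1] -- accumulating a
#' bounded score keeps the heatmap's min-max normalization from turning the
#' lower window coverage at image borders into spurious hot zones, which
#' signed margins do. `"margin"` returns the raw integer margin.
#'
#' @param model `sbcnn_exported` (binary classifier: class 2 = positive).
#' @param n_pre presentations per window evaluation.
#' @param dist sampling distribution (defaults to the model's).
#' @param output `"prob"` or `"margin"`.
#' @return function(patches) -> numeric scores.
#' @export
make_patch_scorer <- function(model, n_pre = 8L, dist = NULL,
                              output = c("prob", "margin")) {
  if (inherits(model, "sbcnn_net")) model <- export_model(model)
  output <- match.arg(output)
  tau <- sqrt(model$stages[[length(model$stages)]]$n)
  function(patches) {
    s <- sbcnn_infer(model, patches, n_infer = n_pre, dist = dist)
    m <- s[, 2] - s[, 1]
    if (output == "prob") stats::plogis(m / tau) else m
  }
}

#' End-to-end sliding-window detection on one image
#'
#' Heatmap accumulation, thresholding, 8-connected box extraction and NMS
#' in one call. The default `"local"` mode uses coverage normalization with
#' component-local peak-relative thresholding ([local_threshold_map()]);
#' `"global"` applies one normalize-and-threshold pass at `threshold`.
#'
#' @inheritParams sliding_window_heatmap
#' @param threshold global-mode heatmap threshold in [0, 1].
#' @param nms_iou NMS suppression threshold.
#' @param mode `"local"` (two-level, default) or `"global"`.
#' @param method global-mode normalization, see [normalize_and_threshold()].
#' @param floor_t,local_frac local-mode parameters, see
#'   [local_threshold_map()].
#' @param min_area minimum component area in pixels; defaults to one more
#'   than the squared window stride (sub-stride fragments).
#' @return detection box data.frame.
#' @export
detect_objects <- function(image, scorer, window, overlap = 0.5,
                           threshold = 0.5, nms_iou = 0.3,
                           mode = c("local", "global"),
                           method = c("coverage", "minmax"),
                           floor_t = 0.25, local_frac = 0.65,
                           min_area = NULL) {
  mode <- match.arg(mode); method <- match.arg(method)
  h <- sliding_window_heatmap(image, scorer, window, overlap)
  if (is.null(min_area)) min_area <- h$stride^2 + 1L
  if (mode == "local") {
    bmap <- local_threshold_map(h, floor_t, local_frac)
    boxes <- extract_boxes(bmap, h, "coverage", min_area)
  } else {
    bmap <- normalize_and_threshold(h, threshold, method)
    boxes <- extract_boxes(bmap, h, method, min_area)
  }
  nms(boxes, nms_iou)
}
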