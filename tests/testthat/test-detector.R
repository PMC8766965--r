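# Sliding-window detector primitives: heatmap accumulation, thresholding,
# connected-component box extraction, IoU, NMS and greedy matching.

const_scorer <- function(value) function(patches) rep(value, dim(patches)[4])

test_that("heatmap accumulation counts window coverage correctly", {
  img <- array(0.5, dim = c(20, 20, 3))
  h <- sliding_window_heatmap(img, const_scorer(3), window = 20)
  expect_true(all(h$grid == 3))         # one window covers everything
  img2 <- array(0.5, dim = c(40, 40, 3))
  h2 <- sliding_window_heatmap(img2, const_scorer(1), window = 20, overlap = 0.5)
  expect_equal(h2$stride, 10L)
  # interior pixels accumulate exactly 4 contributions at 50% overlap
  expect_equal(h2$grid[20, 20], 4)
  expect_equal(max(h2$coverage), 4L)
  expect_equal(h2$grid[1, 1], 1)        # corner: single window
  h0 <- sliding_window_heatmap(img2, const_scorer(0), window = 20)
  expect_true(all(h0$grid == 0))
  expect_error(sliding_window_heatmap(img, const_scorer(1), window = 30),
               "window larger")
})

test_that("heatmap accumulation is linear in classifier scores", {
  set.seed(601)
  img <- array(runif(40 * 40 * 3), dim = c(40, 40, 3))
  rscore <- function(patches) colMeans(matrix(patches, ncol = dim(patches)[4]))
  h1 <- sliding_window_heatmap(img, rscore, 20)
  h2 <- sliding_window_heatmap(img, function(p) 2.5 * rscore(p), 20)
  expect_equal(h2$grid, 2.5 * h1$grid)
})

test_that("min-max normalization and thresholding behave at the boundaries", {
  g <- matrix(c(0, 10, 5, 10), 2, 2)
  h <- structure(list(grid = g, coverage = matrix(1L, 2, 2)), class = "heat_map")
  expect_equal(normalize_and_threshold(h, 0.5, "minmax"),
               matrix(c(0, 1, 1, 1), 2, 2))
  expect_true(all(normalize_and_threshold(h, 0, "minmax") == 1))
  const <- structure(list(grid = matrix(4, 3, 3), coverage = matrix(1L, 3, 3)),
                     class = "heat_map")
  expect_true(all(normalize_and_threshold(const, 0.5, "minmax") == 0))
  # thresholding an already-binary map at 0.5 is idempotent
  b <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_and_threshold(b, 0.5), b)
  expect_error(normalize_and_threshold(h, 1.5), "\\[0, 1\\]")
})

test_that("extract_boxes returns tight half-open component boxes", {
  bmap <- matrix(0L, 10, 12)
  bmap[3:6, 4:8] <- 1L                 # rows 3..6 (y), cols 4..8 (x), 1-based
  boxes <- extract_boxes(bmap, bmap)
  expect_equal(nrow(boxes), 1)
  expect_equal(unlist(boxes[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(3, 2, 8, 6))
  expect_equal(nrow(extract_boxes(matrix(0L, 5, 5), matrix(0L, 5, 5))), 0)
})

test_that("diagonal-touching pixels merge under 8-connectivity", {
  bmap <- matrix(0L, 6, 6)
  bmap[2, 2] <- 1L; bmap[3, 3] <- 1L   # touch only diagonally
  boxes <- extract_boxes(bmap, bmap)
  expect_equal(nrow(boxes), 1)
  # two pixels separated by a gap stay distinct components
  bmap2 <- matrix(0L, 6, 6); bmap2[1, 1] <- 1L; bmap2[5, 5] <- 1L
  expect_equal(nrow(extract_boxes(bmap2, bmap2)), 2)
})

test_that("box IoU has its closed-form values", {
  a <- detection_boxes(0, 0, 2, 2)
  expect_equal(box_iou(a, a), 1.0)
  expect_equal(box_iou(a, detection_boxes(5, 5, 7, 7)), 0.0)
  # unit squares offset by half along one axis: IoU = 1/3
  expect_equal(box_iou(detection_boxes(0, 0, 1, 1),
                       detection_boxes(0.5, 0, 1.5, 1)), 1 / 3)
})

test_that("NMS keeps the best of overlapping boxes and all disjoint ones", {
  b <- detection_boxes(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                       score = c(0.9, 0.8))
  kept <- nms(b, 0.3)
  expect_equal(nrow(kept), 1); expect_equal(kept$score, 0.9)
  disj <- detection_boxes(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50),
                          c(10, 10, 10), score = c(0.5, 0.9, 0.1))
  expect_equal(nrow(nms(disj, 0.3)), 3)
})

test_that("NMS matches a brute-force reference on random box sets", {
  brute_nms <- function(boxes, thr) {
    boxes <- boxes[order(boxes$score, decreasing = TRUE), , drop = FALSE]
    kept <- boxes[0, ]
    while (nrow(boxes)) {
      top <- boxes[1, , drop = FALSE]
      kept <- rbind(kept, top)
      boxes <- boxes[-1, , drop = FALSE]
      if (nrow(boxes)) {
        ious <- box_iou(top, boxes)
        boxes <- boxes[ious <= thr, , drop = FALSE]
      }
    }
    kept
  }
  set.seed(602)
  for (rep in 1:300) {
    n <- sample(1:12, 1)
    x0 <- runif(n, 0, 50); y0 <- runif(n, 0, 50)
    b <- detection_boxes(x0, y0, x0 + runif(n, 2, 20), y0 + runif(n, 2, 20),
                         score = round(runif(n), 3))
    thr <- sample(c(0.1, 0.3, 0.5, 0.9), 1)
    got <- nms(b, thr); want <- brute_nms(b, thr)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("NMS output is a subset with pairwise IoU below threshold", {
  set.seed(603)
  x0 <- runif(30, 0, 40); y0 <- runif(30, 0, 40)
  b <- detection_boxes(x0, y0, x0 + 10, y0 + 10, score = runif(30))
  kept <- nms(b, 0.3)
  expect_lte(nrow(kept), 30)
  if (nrow(kept) > 1)
    for (i in 1:(nrow(kept) - 1))
      expect_true(all(box_iou(kept[i, ], kept[-(1:i), , drop = FALSE]) <= 0.3))
})

test_that("greedy matching handles perfect, empty and partial predictions", {
  truth <- detection_boxes(c(0, 30), c(0, 30), c(10, 40), c(10, 40))
  perfect <- cbind(truth[, 1:4], score = c(0.9, 0.8))
  m <- match_detections(perfect, truth, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  m0 <- match_detections(perfect[0, ], truth, 0.5)
  expect_equal(m0$fn, 2L)
  # a duplicate prediction on one truth box is a false positive
  dup <- rbind(perfect, data.frame(x0 = 1, y0 = 1, x1 = 11, y1 = 11, score = 0.7))
  m2 <- match_detections(dup, truth, 0.5)
  expect_equal(c(m2$tp, m2$fp), c(2L, 1L))
})

test_that("greedy matching agrees with exhaustive assignment on small sets", {
  # brute force: try all one-to-one assignments honouring greedy score order
  brute <- function(pred, truth, thr) {
    ord <- order(pred$score, decreasing = TRUE)
    used <- logical(nrow(truth)); tp <- 0L
    for (i in ord) {
      if (!nrow(truth)) break
      ious <- box_iou(pred[i, ], truth)
      ious[used] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= thr) { tp <- tp + 1L; used[j] <- TRUE }
    }
    tp
  }
  set.seed(604)
  for (rep in 1:100) {
    np <- sample(0:5, 1); nt <- sample(1:5, 1)
    mk <- function(n) { x0 <- runif(n, 0, 20); y0 <- runif(n, 0, 20)
      detection_boxes(x0, y0, x0 + runif(n, 3, 10), y0 + runif(n, 3, 10),
                      score = runif(n)) }
    pred <- mk(np); truth <- mk(nt)
    m <- match_detections(pred, truth, 0.3)
    expect_equal(m$tp, brute(pred, truth, 0.3))
    expect_equal(m$tp + m$fn, nt)
    expect_equal(m$tp + m$fp, np)
  }
})
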