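# Network specification, binarization-aware training, export and the
# stochastic inference path.

make_tiny_set <- function(seed = 1, n_classes = 2, n = 30, size = 12) {
  set.seed(seed)
  generate_classification_set(n_classes, n, image_size = size,
                              separation = 1, noise_std = 0.25)
}

test_that("architecture variants have the pinned layer structure", {
  full <- build_alexnet(2)
  types <- vapply(full$layers, `[[`, "", "type")
  expect_equal(sum(types == "conv"), 5)
  expect_equal(sum(types == "fc"), 3)
  red <- build_alexnet(2, reduced = TRUE)
  expect_equal(sum(vapply(red$layers, `[[`, "", "type") == "fc"), 2)
  shapes <- infer_shapes(full)
  expect_equal(shapes[[8]], c(6L, 6L, 256L))     # 9216 classifier input
  expect_error(infer_shapes(network_spec(list(sbcnn:::layer_fc(100, 2)),
                                         c(8, 8, 3), 2)), "expects 100")
})

test_that("presentation_config validates strategy constraints", {
  expect_equal(presentation_config(8)$n_infer, 8L)
  expect_error(presentation_config(8, 16, "matched"), "matched")
  expect_equal(presentation_config(256, 8, "max")$strategy, "max")
  expect_error(presentation_config(0), ">= 1")
})

test_that("aggregate_presentations is an elementwise majority with +1 ties", {
  expect_equal(aggregate_presentations(list(1, 1, -1)), 1)
  expect_equal(aggregate_presentations(list(1, -1)), 1)   # tie -> +1
  expect_error(aggregate_presentations(list()), "empty")
  expect_error(aggregate_presentations(list(c(1, -1), c(1, 1, 1))), "shape")
  set.seed(401)
  for (rep in 1:40) {
    k <- sample(1:9, 1); len <- sample(1:20, 1)
    al <- lapply(seq_len(k), function(i) sample(c(-1, 1), len, TRUE))
    got <- aggregate_presentations(al)
    brute <- vapply(seq_len(len), function(j) {
      pos <- sum(vapply(al, `[[`, numeric(1), j) == 1)
      if (pos >= k - pos) 1 else -1
    }, numeric(1))
    expect_equal(got, brute)
  }
})

test_that("training learns a separable synthetic task to >= 95% accuracy", {
  ds <- make_tiny_set(seed = 402, n = 60)
  spec <- build_small_cnn(2, 12)
  net <- sbcnn_train(spec, ds$x, ds$y, presentation_config(8),
                     epochs = 10, seed = 7)
  expect_true(all(is.finite(net$loss_history)))
  acc <- net_accuracy(net, ds$x, ds$y)
  expect_gte(acc, 0.95)
})

test_that("zero learning rate leaves weights unchanged", {
  ds <- make_tiny_set(seed = 403)
  spec <- build_small_cnn(2, 12)
  set.seed(5); ref <- init_network(spec)
  net <- sbcnn_train(spec, ds$x, ds$y, presentation_config(4),
                     epochs = 2, lr = 0, seed = 5)
  for (i in seq_along(net$layers))
    if (!is.null(net$layers[[i]]$W))
      expect_equal(net$layers[[i]]$W, ref$layers[[i]]$W)
})

test_that("seed-fixed training reproduces the loss trajectory exactly", {
  ds <- make_tiny_set(seed = 404)
  spec <- build_small_cnn(2, 12)
  n1 <- sbcnn_train(spec, ds$x, ds$y, presentation_config(4), epochs = 3, seed = 11)
  n2 <- sbcnn_train(spec, ds$x, ds$y, presentation_config(4), epochs = 3, seed = 11)
  expect_identical(n1$loss_history, n2$loss_history)
})

test_that("stochastic inference is reproducible and concentrates with N", {
  ds <- make_tiny_set(seed = 405, n = 40)
  spec <- build_small_cnn(2, 12)
  net <- sbcnn_train(spec, ds$x, ds$y, presentation_config(8), epochs = 6, seed = 3)
  model <- export_model(net)
  xs <- ds$x[, , , 1:12, drop = FALSE]
  expect_identical(sbcnn_infer(model, xs, n_infer = 8, seed = 42),
                   sbcnn_infer(model, xs, n_infer = 8, seed = 42))
  expect_error(sbcnn_infer(model, xs, n_infer = 0), "n_infer")
  # mean score variance across repeated stochastic runs is non-increasing
  # in N (averaged over all batch entries and outputs for stability)
  vols <- vapply(c(1, 8, 64), function(N) {
    reps <- vapply(1:12, function(r)
      as.vector(sbcnn_infer(model, xs, n_infer = N, seed = 100 + r)),
      numeric(length(xs) / prod(dim(xs)[1:3]) * 2))
    mean(apply(reps, 1, var))
  }, numeric(1))
  expect_true(vols[3] <= vols[1] + 1e-9)
  expect_true(vols[2] <= vols[1] + 1e-9)
})

test_that("saturated inputs reduce to the deterministic all-ones network", {
  ds <- make_tiny_set(seed = 406, n = 20)
  spec <- build_small_cnn(2, 12)
  net <- sbcnn_train(spec, ds$x, ds$y, presentation_config(4), epochs = 2, seed = 9)
  model <- export_model(net)
  # inputs far above the channel means: every sampled bit is 1 w.p. ~1
  sat <- ds$x[, , , 1:4, drop = FALSE] * 0 +
    array(rep(model$stats$mu + 40 * model$stats$sigma, each = 144),
          dim = c(12, 12, 3, 4))
  ones <- array(1, dim = c(12, 12, 3, 4))
  det_ref <- forward_exported(model, ones, "integer")
  for (N in c(1, 5)) {
    got <- sbcnn_infer(model, sat, n_infer = N, seed = 1)
    expect_equal(got, det_ref)
  }
})

test_that("folded integer path and float reference path rank identically", {
  ds <- make_tiny_set(seed = 407, n = 40, n_classes = 3)
  spec <- build_small_cnn(3, 12)
  net <- sbcnn_train(spec, ds$x, ds$y, presentation_config(8), epochs = 4, seed = 13)
  model <- export_model(net)
  set.seed(408)
  x <- array(sample(c(-1, 1), 12 * 12 * 3 * 300, TRUE), c(12, 12, 3, 300))
  si <- forward_exported(model, x, "integer")
  sf <- forward_exported(model, x, "float")
  expect_identical(si, sf)
  expect_true(all(si == round(si)))   # integer-only ranking evidence
})

test_that("network-level first stage agrees with the packed binary neuron", {
  # one output unit of the exported fc stage == binary_neuron on packed bits
  ds <- make_tiny_set(seed = 409, n = 20)
  spec <- build_small_cnn(2, 12)
  net <- sbcnn_train(spec, ds$x, ds$y, presentation_config(4), epochs = 2, seed = 15)
  model <- export_model(net)
  st <- model$stages[[length(model$stages) - 1L]]  # hidden fc stage, no pool
  expect_equal(st$type, "fc")
  set.seed(410)
  x <- sample(c(-1, 1), st$n, TRUE)
  a <- forward_exported(model, matrix(x, nrow = 1),
                        "integer", stages = length(model$stages) - 1L)
  for (u in seq_len(min(5, st$out_units))) {
    s <- sum(st$W[, u] * x)
    pc <- popcount(xnor(binarize_sign(st$W[, u]), binarize_sign(x)))
    expect_equal(2L * pc - st$n, s)
    want <- if (st$dir[u] == 1L) ifelse(s >= st$t_dot[u], 1, -1)
            else ifelse(s <= st$t_dot[u], 1, -1)
    expect_equal(a[1, u], want)
  }
})

test_that("model container round-trips weights, thresholds and behaviour", {
  ds <- make_tiny_set(seed = 411, n = 20)
  spec <- build_small_cnn(2, 12)
  net <- sbcnn_train(spec, ds$x, ds$y, presentation_config(4), epochs = 2, seed = 17)
  model <- export_model(net)
  path <- withr::local_tempfile(fileext = ".json")
  write_sbcnn_model(model, path)
  back <- read_sbcnn_model(path)
  set.seed(412)
  x <- array(sample(c(-1, 1), 12 * 12 * 3 * 20, TRUE), c(12, 12, 3, 20))
  expect_identical(forward_exported(back, x, "integer"),
                   forward_exported(model, x, "integer"))
  expect_identical(sbcnn_infer(back, ds$x[, , , 1:5, drop = FALSE],
                               n_infer = 4, seed = 3),
                   sbcnn_infer(model, ds$x[, , , 1:5, drop = FALSE],
                               n_infer = 4, seed = 3))
})
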