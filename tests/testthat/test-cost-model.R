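# Architecture accounting and the in-memory-computing cost model: parameter
# counts, weight memory per precision, headline savings ratios, operation
# counts, crossbar tile mapping and energy linearity.

test_that("parameter counts match closed-form layer arithmetic", {
  full <- build_alexnet(2)
  red <- build_alexnet(2, reduced = TRUE)
  expect_equal(attr(count_params(full), "total"), 57012034)
  expect_equal(attr(count_params(red), "total"), 40230722)
  expect_equal(57012034 - 40230722, 16781312)  # the removed 4096->4096 layer
  p10 <- count_params(build_alexnet(10))
  expect_equal(p10$params[nrow(p10)], 4096 * 10 + 10)
  # single-layer oracles
  expect_equal(count_params(network_spec(list(
    sbcnn:::layer_conv(3, 64, 11, bias = TRUE)), c(224, 224, 3), 2))$params, 23296)
  expect_equal(count_params(network_spec(list(
    sbcnn:::layer_fc(4096, 2, bias = TRUE)), c(4096), 2))$params, 8194)
  expect_equal(nrow(count_params(network_spec(list(), c(8, 8, 3), 2))), 0)
})

test_that("weight memory reproduces the published table cells in MiB", {
  full <- build_alexnet(2)
  red <- build_alexnet(2, reduced = TRUE)
  expect_equal(round(as.numeric(weight_memory(full, "int8")), 2), 54.37)
  expect_lt(abs(as.numeric(weight_memory(full, "fp32")) - 217.42) / 217.42, 0.001)
  expect_lt(abs(as.numeric(weight_memory(red, "binary")) - 4.79) / 4.79, 0.002)
  expect_error(weight_memory(full, "fp16"))
})

test_that("precision memory ratios are exact: fp32/int8 == 4", {
  for (spec in list(build_alexnet(2), build_alexnet(5, reduced = TRUE),
                    build_small_cnn(3, 16))) {
    expect_equal(as.numeric(weight_memory(spec, "fp32")) /
                   as.numeric(weight_memory(spec, "int8")), 4)
    # int8/binary == 8 up to per-layer byte ceiling
    r <- as.numeric(weight_memory(spec, "int8")) /
      as.numeric(weight_memory(spec, "binary"))
    expect_gt(r, 7.98); expect_lte(r, 8)
  }
})

test_that("headline memory-savings factors round to 45x and 11x", {
  full <- build_alexnet(2)
  red <- build_alexnet(2, reduced = TRUE)
  expect_equal(memory_savings(full, "fp32", red, "binary", round_headline = TRUE), 45)
  expect_equal(memory_savings(full, "int8", red, "binary", round_headline = TRUE), 11)
  expect_equal(memory_savings(full, "int8", full, "int8"), 1.0)
})

test_that("memory is additive over layers", {
  red <- build_alexnet(2, reduced = TRUE)
  by_layer <- attr(weight_memory(red, "binary"), "bytes")
  expect_equal(sum(by_layer) / 2^20, as.numeric(weight_memory(red, "binary")))
  # removing the middle fc changes binary memory by exactly 16,781,312 bits
  full_bits <- sum(count_params(build_alexnet(2))$params)
  red_bits <- sum(count_params(red)$params)
  expect_equal(full_bits - red_bits, 16781312)
})

test_that("operation counts match a naive per-output-element loop", {
  spec <- network_spec(list(sbcnn:::layer_fc(10, 4, bias = FALSE)), c(10), 4)
  expect_equal(count_ops(spec, c(10L), n_pre = 1, stochastic = FALSE)$total, 40)
  small <- build_small_cnn(2, 16)
  shapes <- infer_shapes(small)
  ops <- count_ops(small, n_pre = 1, stochastic = FALSE)
  naive <- 0
  shp <- small$input_shape
  for (i in seq_along(small$layers)) {
    l <- small$layers[[i]]
    if (l$type == "conv") {
      o <- shapes[[i]]
      for_outputs <- o[1] * o[2] * o[3]
      naive <- naive + for_outputs * l$in_ch * l$kernel^2
    } else if (l$type == "fc") naive <- naive + l$n_in * l$n_out
  }
  expect_equal(ops$total, naive)
  # doubling n_pre scales only first-layer and sampling terms
  o8 <- count_ops(small, n_pre = 8); o16 <- count_ops(small, n_pre = 16)
  expect_equal(o16$first_layer_ops, 2 * o8$first_layer_ops)
  expect_equal(o16$sampling_ops, 2 * o8$sampling_ops)
  expect_equal(o16$later_ops, o8$later_ops)
})

test_that("tile mapping follows the 32x32 block rules", {
  m <- map_to_tiles(c(64, 64))
  expect_equal(m$blocks, 4); expect_equal(m$tiles_used, 4); expect_equal(m$cycles, 32)
  expect_equal(map_to_tiles(c(32, 32))$cycles, 32)
  # 1025 blocks exceed the 1024-tile grid: two 32-cycle passes
  m2 <- map_to_tiles(c(32800, 32))
  expect_equal(m2$blocks, 1025); expect_equal(m2$tiles_used, 1024)
  expect_equal(m2$cycles, 64)
  expect_equal(m2$lut_count, 1025)  # one 5-bit LUT per block
})

test_that("tile cycles are monotone in matrix dims and bounded by blocks", {
  set.seed(301)
  for (i in 1:30) {
    r <- sample(1:5000, 1); c <- sample(1:5000, 1)
    m <- map_to_tiles(c(r, c))
    expect_gte(m$cycles, 32)
    expect_lte(m$cycles, m$blocks * 32)
    expect_lte(map_to_tiles(c(r, c))$cycles, map_to_tiles(c(r + 32, c + 32))$cycles)
  }
})

test_that("energy is a linear functional of the op breakdown", {
  small <- build_small_cnn(2, 16)
  ops <- count_ops(small, n_pre = 8)
  zero <- energy_table(0, 0, 0, 0)
  expect_equal(energy_estimate(ops, zero), 0)
  t1 <- energy_table(1e-13, 2e-11, 4e-10, 5e-13)
  t2 <- energy_table(2e-13, 4e-11, 8e-10, 1e-12)
  expect_equal(energy_estimate(ops, t2), 2 * energy_estimate(ops, t1))
  expect_error(energy_table(-1, 0, 0, 0), ">= 0")
})

test_that("relative energy of architectures scales with their op counts", {
  # pin the XNOR energy so the reduced model costs 5.66 uJ, then check the
  # stochastic full model lands near 6.84 uJ: energy ratios track op ratios
  full <- build_alexnet(2, precision = "binary")
  red <- build_alexnet(2, reduced = TRUE, precision = "binary")
  ops_full <- count_ops(full, n_pre = 32)
  ops_red <- count_ops(red, n_pre = 32)
  e_per_op <- 5.66e-6 / (sum(ops_red$per_layer$ops) + ops_red$sampling_ops)
  tab <- energy_table(xnor_acc = e_per_op, sample = e_per_op)
  expect_equal(energy_estimate(ops_red, tab), 5.66, tolerance = 1e-6)
  ratio <- energy_estimate(ops_full, tab) / 5.66
  expect_equal(ratio, (sum(ops_full$per_layer$ops) + ops_full$sampling_ops) /
                 (sum(ops_red$per_layer$ops) + ops_red$sampling_ops))
  expect_gt(ratio, 1)  # removing a 16.8M-parameter layer must save energy
})

test_that("cost_report aggregates params, memory, ops, cycles and energy", {
  rep <- cost_report(build_small_cnn(2, 16), n_pre = 8)
  expect_equal(rep$total_params, attr(count_params(build_small_cnn(2, 16)), "total"))
  expect_equal(unname(rep$memory_mib["fp32"] / rep$memory_mib["int8"]), 4)
  expect_gte(rep$cycles, 32)
  expect_gt(rep$energy_uj, 0)
})
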