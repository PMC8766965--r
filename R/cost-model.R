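# Hardware cost estimation: weight memory per precision, operation counts
# per inference, 32x32 crossbar tile mapping, and energy from a
# user-configurable per-operation energy table.

BYTES_PER_PARAM <- c(fp32 = 4, int8 = 1)  # binary handled by per-layer bit ceil

#' Weight memory of a network at a given precision
#'
#' fp32 stores 4 bytes and int8 one byte per parameter; binary packs 8
#' parameters per byte with a per-layer ceiling to whole bytes. Reported in
#' binary mebibytes (2^20 bytes).
#'
#' @param spec a [network_spec()].
#' @param precision one of "fp32", "int8", "binary".
#' @return memory in MiB; per-layer byte counts in attribute `"bytes"`.
#' @export
weight_memory <- function(spec, precision = c("fp32", "int8", "binary")) {
  precision <- match.arg(precision)
  p <- count_params(spec)$params
  bytes <- switch(precision,
    fp32 = 4 * p,
    int8 = p,
    binary = ceiling(p / 8))
  out <- sum(bytes) / 2^20
  attr(out, "bytes") <- bytes
  out
}

#' Memory savings ratio between two network/precision configurations
#'
#' @param spec_a,spec_b [network_spec()]s.
#' @param prec_a,prec_b precisions, as in [weight_memory()].
#' @param round_headline round to the nearest integer for headline reporting.
#' @return numeric ratio memory(a)/memory(b).
#' @export
memory_savings <- function(spec_a, prec_a, spec_b, prec_b, round_headline = FALSE) {
  denom <- weight_memory(spec_b, prec_b)
  if (denom == 0) stop("zero denominator memory")
  r <- as.numeric(weight_memory(spec_a, prec_a)) / as.numeric(denom)
  if (round_headline) round(r) else r
}

#' Operation count per inference
#'
#' conv MACs per layer: out_h*out_w*out_ch*in_ch*k^2; fc MACs: n_in*n_out.
#' With a stochastic input layer, the first weight layer is evaluated once
#' per presentation, so its MACs (and one sampling operation per input value
#' per presentation) scale by `n_pre`; all later binarized layers count
#' XNOR-accumulates one-for-one with MACs.
#'
#' @param spec a [network_spec()].
#' @param input_shape c(H, W, C); defaults to the spec's.
#' @param n_pre presentations of the stochastic input layer; `n_pre = 1`
#'   with `stochastic = FALSE` gives the plain deterministic count.
#' @param stochastic is the first layer fed by stochastic bitstreams?
#' @return list with `per_layer` (data.frame layer/type/ops), `sampling_ops`,
#'   `first_layer_ops`, `later_ops` and `total`.
#' @export
count_ops <- function(spec, input_shape = spec$input_shape, n_pre = 1L,
                      stochastic = n_pre > 1L) {
  shapes <- infer_shapes(spec, input_shape)
  shp_in <- input_shape
  ops <- numeric(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv") {
      o <- shapes[[i]]
      ops[i] <- prod(o) * l$in_ch * l$kernel^2
    } else if (l$type == "fc") {
      ops[i] <- as.numeric(l$n_in) * l$n_out
    }
  }
  first <- which(ops > 0)[1]
  mult <- if (stochastic) n_pre else 1L
  sampling <- if (stochastic) n_pre * prod(shp_in) else 0
  per_layer <- data.frame(layer = seq_along(ops),
                          type = vapply(spec$layers, `[[`, "", "type"),
                          ops = ops)
  per_layer$ops[first] <- per_layer$ops[first] * mult
  list(per_layer = per_layer,
       sampling_ops = sampling,
       first_layer_ops = per_layer$ops[first],
       later_ops = sum(per_layer$ops[-first]),
       total = sum(per_layer$ops) + sampling)
}

#' Crossbar tile configuration
#'
#' A grid of `grid_rows` x `grid_cols` tiles, each an `tile_rows` x
#' `tile_cols` differential bitcell array computing one row per cycle.
#' Defaults model a 32 x 32 matrix of 32 x 32 arrays.
#' @param tile_rows,tile_cols,grid_rows,grid_cols positive integers.
#' @export
tile_config <- function(tile_rows = 32L, tile_cols = 32L,
                        grid_rows = 32L, grid_cols = 32L) {
  stopifnot(tile_rows >= 1, tile_cols >= 1, grid_rows >= 1, grid_cols >= 1)
  structure(list(tile_rows = as.integer(tile_rows), tile_cols = as.integer(tile_cols),
                 grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols)),
            class = "tile_config")
}

#' Map a weight matrix onto crossbar tiles
#'
#' Block matrix multiplication with block size equal to the tile: the matrix
#' partitions into ceil(rows/32) * ceil(cols/32) blocks; blocks occupy
#' distinct tiles up to the grid capacity (1024 by default); each resident
#' set of blocks computes row-sequentially in 32 cycles, and blocks beyond
#' capacity serialize in additional 32-cycle passes. One 5-bit partial-sum
#' lookup table is assumed per block.
#'
#' @param dims c(rows, cols) of the binary weight matrix.
#' @param cfg a [tile_config()].
#' @return list: `blocks`, `tiles_used`, `passes`, `cycles`, `lut_count`.
#' @export
map_to_tiles <- function(dims, cfg = tile_config()) {
  stopifnot(length(dims) == 2, all(dims >= 1))
  blocks <- ceiling(dims[1] / cfg$tile_rows) * ceiling(dims[2] / cfg$tile_cols)
  capacity <- cfg$grid_rows * cfg$grid_cols
  passes <- ceiling(blocks / capacity)
  list(blocks = blocks,
       tiles_used = min(blocks, capacity),
       passes = passes,
       cycles = passes * cfg$tile_rows,
       lut_count = blocks)
}

#' Per-operation energy table
#'
#' All entries in joules per operation and `>= 0`. The defaults are
#' illustrative placeholders for exploring relative costs; absolute energy
#' claims require platform-measured constants supplied by the user.
#'
#' @param xnor_acc energy per binary XNOR-accumulate.
#' @param int8_mac,fp32_mac energy per int8 / fp32 multiply-accumulate.
#' @param sample energy per stochastic input sample.
#' @export
energy_table <- function(xnor_acc = 5e-13, int8_mac = 5e-11,
                         fp32_mac = 5e-10, sample = 1e-12) {
  e <- c(xnor_acc = xnor_acc, int8_mac = int8_mac,
         fp32_mac = fp32_mac, sample = sample)
  if (any(e < 0)) stop("energy table entries must be >= 0")
  structure(as.list(e), class = "energy_table")
}

#' Energy of an inference from an operation breakdown
#'
#' Linear combination sum(ops_k * energy_k), reported in microjoules.
#'
#' @param ops_breakdown result of [count_ops()].
#' @param table an [energy_table()].
#' @param precision precision of the weight-layer operations: "binary" uses
#'   the XNOR-accumulate energy, "int8"/"fp32" the MAC energies.
#' @return energy in uJ.
#' @export
energy_estimate <- function(ops_breakdown, table = energy_table(),
                            precision = c("binary", "int8", "fp32")) {
  precision <- match.arg(precision)
  stopifnot(inherits(table, "energy_table"))
  per_op <- switch(precision, binary = table$xnor_acc,
                   int8 = table$int8_mac, fp32 = table$fp32_mac)
  j <- sum(ops_breakdown$per_layer$ops) * per_op +
    ops_breakdown$sampling_ops * table$sample
  j * 1e6
}

#' Full cost report for a network
#'
#' @param spec a [network_spec()].
#' @param n_pre presentations (stochastic input) for op counting.
#' @param table an [energy_table()].
#' @param precision weight precision.
#' @return list with parameter counts, memory at each precision (MiB),
#'   op breakdown, tile mapping of the largest layer, and energy (uJ).
#' @export
cost_report <- function(spec, n_pre = 1L, table = energy_table(),
                        precision = "binary") {
  params <- count_params(spec)
  ops <- count_ops(spec, n_pre = n_pre, stochastic = n_pre > 1)
  shapes <- infer_shapes(spec)
  # tile-map each weight layer as (fan_in x out) matrix
  tiles <- lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    if (l$type == "conv") map_to_tiles(c(l$in_ch * l$kernel^2, l$out_ch))
    else if (l$type == "fc") map_to_tiles(c(l$n_in, l$n_out))
    else NULL
  })
  tiles <- tiles[!vapply(tiles, is.null, logical(1))]
  list(params = params,
       total_params = attr(params, "total"),
       memory_mib = c(fp32 = as.numeric(weight_memory(spec, "fp32")),
                      int8 = as.numeric(weight_memory(spec, "int8")),
                      binary = as.numeric(weight_memory(spec, "binary"))),
       ops = ops,
       cycles = sum(vapply(tiles, `[[`, numeric(1), "cycles")),
       energy_uj = energy_estimate(ops, table, precision))
}
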