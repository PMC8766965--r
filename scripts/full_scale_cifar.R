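#!/usr/bin/env Rscript
# Full-scale configuration sketch: trains the SBCNN pipeline on CIFAR-10
# class images and compares matched vs max presentation strategies at the
# published scale. NOT part of the acceptance run -- this takes many CPU
# hours and requires the CIFAR-10 binary batches to be downloaded
# separately (https://www.cs.toronto.edu/~kriz/cifar.html).
#
#   Rscript scripts/full_scale_cifar.R --data cifar-10-batches-bin --seed 1

library(sbcnn)

args <- commandArgs(trailingOnly = TRUE)
data_dir <- "cifar-10-batches-bin"; seed <- 1L
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--data") { data_dir <- args[i + 1L]; i <- i + 2L }
  else if (args[i] == "--seed") { seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

read_cifar_batch <- function(path, n = 10000L) {
  con <- file(path, "rb"); on.exit(close(con))
  raw <- readBin(con, "integer", n * 3073L, size = 1L, signed = FALSE)
  m <- matrix(raw, nrow = 3073L)
  y <- m[1, ] + 1L
  # stored row-major per channel; convert to (H, W, C, N) in [0, 255]
  x <- array(0, dim = c(32, 32, 3, ncol(m)))
  for (ch in 1:3) {
    block <- m[1L + ((ch - 1L) * 1024L + 1L):(ch * 1024L), , drop = FALSE]
    x[, , ch, ] <- aperm(array(block, dim = c(32, 32, ncol(m))), c(2, 1, 3))
  }
  list(x = x, y = y)
}

batches <- lapply(file.path(data_dir, sprintf("data_batch_%d.bin", 1:5)),
                  read_cifar_batch)
train_x <- array(unlist(lapply(batches, `[[`, "x")), dim = c(32, 32, 3, 50000))
train_y <- unlist(lapply(batches, `[[`, "y"))
test <- read_cifar_batch(file.path(data_dir, "test_batch.bin"))

# At full scale the published configuration is the 224-px AlexNet-style
# network trained with N_pre = 32; desk machines should substitute the
# small architecture below and expect qualitatively similar strategy
# orderings, not the published absolute accuracies.
spec <- build_small_cnn(10, 32, width = 32L)

res <- evaluate_strategies(spec, train_x, train_y, test$x, test$y,
                           n_grid = c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L, 256L),
                           n_trials = 5L, n_max = 256L,
                           epochs = 40L, batch_size = 64L, lr = 0.005,
                           base_seed = seed)
write.csv(res$summary, "cifar_strategies.csv", row.names = FALSE)
print(res$summary)
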