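# Binarization-aware training and inference engine.
#
# Networks are trained with real-valued "shadow" weights that are sign-
# binarized on every forward pass; gradients reach the shadow weights via the
# straight-through estimator and shadow weights are clipped to [-1, 1] after
# each update. Batch norm runs in float during training and is folded into
# integer thresholds at export, leaving an integer-only inference path.
#
# Batch layout: activations are arrays (H, W, C, B) for spatial layers and
# matrices (B, features) after flattening.

sign_pm1 <- function(x) ifelse(x >= 0, 1, -1)

# ---- im2col index plumbing ---------------------------------------------

# Linear indices (into one padded image of dim Hp x Wp x C) of every patch
# element: matrix (k*k*C) x (oh*ow), element order (ky, kx, c).
conv_index_map <- function(H, W, C, k, s, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  oh <- conv_out_dim(H, k, s, p); ow <- conv_out_dim(W, k, s, p)
  ky <- rep(seq_len(k), times = k * C)
  kx <- rep(rep(seq_len(k), each = k), times = C)
  kc <- rep(seq_len(C), each = k * k)
  oy <- rep(seq_len(oh), times = ow)
  ox <- rep(seq_len(ow), each = oh)
  iy <- outer(ky, (oy - 1L) * s, "+")              # (k2C, ohow)
  ix <- outer(kx, (ox - 1L) * s, "+")
  idx <- iy + (ix - 1L) * Hp + (kc - 1L) * (Hp * Wp)
  list(idx = idx, Hp = Hp, Wp = Wp, oh = oh, ow = ow, C = C,
       k2C = k * k * C, per_img = Hp * Wp * C)
}

pad_batch <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

im2col <- function(xpad, map) {
  B <- dim(xpad)[4]
  xv <- as.vector(xpad)
  ncol_img <- ncol(map$idx)
  out <- matrix(0, nrow = map$k2C, ncol = ncol_img * B)
  for (b in seq_len(B)) {
    off <- (b - 1L) * map$per_img
    out[, ((b - 1L) * ncol_img + 1L):(b * ncol_img)] <- xv[map$idx + off]
  }
  out
}

# scatter-add of a col-matrix gradient back into the padded input
col2im <- function(dcol, map, B) {
  dx <- numeric(map$per_img * B)
  ncol_img <- ncol(map$idx)
  for (b in seq_len(B)) {
    off <- (b - 1L) * map$per_img
    cols <- ((b - 1L) * ncol_img + 1L):(b * ncol_img)
    for (r in seq_len(map$k2C)) {
      ii <- map$idx[r, ] + off
      dx[ii] <- dx[ii] + dcol[r, cols]
    }
  }
  array(dx, dim = c(map$Hp, map$Wp, map$C, B))
}

unpad_batch <- function(xpad, p, H, W) {
  if (p == 0L) return(xpad)
  xpad[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
}

# ---- network construction ----------------------------------------------

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' Initialise a trainable network from a specification
#'
#' Creates shadow weights (Glorot-uniform, later clipped to [-1,1]) and
#' batch-norm states for every layer of the spec. Uses the current RNG
#' state; seed via `set.seed()` for reproducible initialisation.
#'
#' @param spec a [network_spec()].
#' @return object of class `sbcnn_net`.
#' @export
init_network <- function(spec) {
  shapes <- infer_shapes(spec)
  in_shape <- spec$input_shape
  layers <- vector("list", length(spec$layers))
  shp <- in_shape
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    st <- l
    if (l$type == "conv") {
      fan_in <- l$in_ch * l$kernel^2
      st$W <- matrix(glorot(fan_in, l$out_ch, fan_in * l$out_ch), fan_in, l$out_ch)
      st$map <- conv_index_map(shp[1], shp[2], shp[3], l$kernel, l$stride, l$pad)
      st$in_shape <- shp
    } else if (l$type == "fc") {
      st$W <- matrix(glorot(l$n_in, l$n_out, l$n_in * l$n_out), l$n_in, l$n_out)
    } else if (l$type == "batchnorm") {
      st$gamma <- rep(1, l$features); st$beta <- rep(0, l$features)
      st$run_mean <- rep(0, l$features); st$run_var <- rep(1, l$features)
      st$eps <- 1e-5; st$momentum <- 0.1
    } else if (l$type == "maxpool") {
      st$in_shape <- shp
      st$map <- conv_index_map(shp[1], shp[2], 1L, l$kernel, l$stride, 0L)
    }
    layers[[i]] <- st
    shp <- shapes[[i]]
  }
  structure(list(spec = spec, layers = layers, stats = NULL,
                 presentation = NULL, dist = "normal"),
            class = "sbcnn_net")
}

# ---- forward / backward -------------------------------------------------

forward_net <- function(net, x, train = TRUE) {
  caches <- vector("list", length(net$layers))
  a <- x
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      B <- dim(a)[4]
      xpad <- pad_batch(a, l$pad)
      col <- im2col(xpad, l$map)
      Wb <- sign_pm1(l$W)
      outm <- crossprod(Wb, col)                      # (out_ch, ohow*B)
      o <- array(outm, dim = c(l$out_ch, l$map$oh, l$map$ow, B))
      a_new <- aperm(o, c(2, 3, 1, 4))
      caches[[i]] <- list(col = col, Wb = Wb, B = B)
      a <- a_new
    } else if (l$type == "maxpool") {
      d <- dim(a); B <- d[4]
      # pool each channel independently: fold C*B into the batch axis
      xr <- array(a, dim = c(d[1], d[2], 1L, d[3] * d[4]))
      col <- im2col(xr, l$map)                        # (k^2, oh*ow*C*B)
      mx <- col[1, ]; arg <- rep(1L, ncol(col))
      for (r in seq_len(nrow(col))[-1]) {
        sel <- col[r, ] > mx
        mx[sel] <- col[r, sel]; arg[sel] <- r
      }
      a <- array(mx, dim = c(l$map$oh, l$map$ow, d[3], B))
      caches[[i]] <- list(arg = arg, d_in = d, ncolp = ncol(col))
    } else if (l$type == "fc") {
      if (!is.matrix(a)) {                            # flatten (H,W,C,B) -> (B, HWC)
        d <- dim(a); a <- t(matrix(a, nrow = prod(d[-length(d)])))
        caches[[i]] <- list(flat_from = d)
      } else caches[[i]] <- list(flat_from = NULL)
      Wb <- sign_pm1(l$W)
      caches[[i]]$x <- a; caches[[i]]$Wb <- Wb
      a <- a %*% Wb
    } else if (l$type == "batchnorm") {
      spatial <- !is.matrix(a)
      if (spatial) {
        d <- dim(a)
        xm <- matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*B, C)
      } else xm <- a
      if (train) {
        mu <- colMeans(xm)
        va <- colMeans(xm^2) - mu^2
      } else { mu <- l$run_mean; va <- l$run_var }
      sd_ <- sqrt(va + l$eps)
      xhat <- sweep(sweep(xm, 2, mu, "-"), 2, sd_, "/")
      ym <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      caches[[i]] <- list(xm = xm, xhat = xhat, mu = mu, va = va, sd = sd_,
                          spatial = spatial, d = if (spatial) d else NULL,
                          train = train)
      a <- if (spatial) aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)) else ym
    } else if (l$type == "activation") {
      caches[[i]] <- list(pre = a)
      if (l$kind == "binary") a <- sign_pm1(a)
    }
  }
  list(out = a, caches = caches)
}

backward_net <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  da <- dout
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]; cc <- caches[[i]]
    if (l$type == "activation") {
      if (l$kind == "binary") da <- ste_grad(da, cc$pre)
    } else if (l$type == "batchnorm") {
      dym <- if (cc$spatial) matrix(aperm(da, c(1, 2, 4, 3)), ncol = dim(da)[3]) else da
      N <- nrow(dym)
      dgamma <- colSums(dym * cc$xhat); dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2, l$gamma, "*")
      xc <- sweep(cc$xm, 2, cc$mu, "-")
      dvar <- colSums(dxhat * xc) * (-0.5) * cc$sd^-3
      dmu <- -colSums(dxhat) / cc$sd - 2 * dvar * colMeans(xc)
      dxm <- sweep(dxhat, 2, cc$sd, "/") +
        sweep(xc, 2, 2 * dvar / N, "*") +
        matrix(dmu / N, N, length(dmu), byrow = TRUE)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      da <- if (cc$spatial) aperm(array(dxm, dim = cc$d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)) else dxm
    } else if (l$type == "fc") {
      dW <- crossprod(cc$x, da)
      da <- tcrossprod(da, cc$Wb)
      grads[[i]] <- list(W = dW)   # STE through weight binarization: pass
      if (!is.null(cc$flat_from)) {
        d <- cc$flat_from
        da <- array(t(da), dim = d)
      }
    } else if (l$type == "maxpool") {
      d_in <- cc$d_in
      dmax <- as.vector(da)
      dcol <- matrix(0, nrow = l$kernel^2, ncol = cc$ncolp)
      for (r in seq_len(nrow(dcol))) {
        sel <- cc$arg == r
        dcol[r, sel] <- dmax[sel]
      }
      dxr <- col2im(dcol, l$map, d_in[3] * d_in[4])
      da <- array(dxr, dim = d_in)
    } else if (l$type == "conv") {
      B <- cc$B
      dom <- matrix(aperm(da, c(3, 1, 2, 4)), nrow = l$out_ch)  # (out_ch, ohow*B)
      dW <- tcrossprod(cc$col, dom)          # (fan_in, out_ch)
      dcol <- cc$Wb %*% dom
      dxpad <- col2im(dcol, l$map, B)
      da <- unpad_batch(dxpad, l$pad, l$in_shape[1], l$in_shape[2])
      grads[[i]] <- list(W = dW)
    }
  }
  grads
}

softmax_ce <- function(logits, y, n_classes) {
  B <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z); p <- ez / rowSums(ez)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p; dp[idx] <- dp[idx] - 1
  list(loss = loss, dlogits = dp / B, prob = p)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0)
    else if (l$type == "batchnorm")
      list(mg = l$gamma * 0, vg = l$gamma * 0, mb = l$beta * 0, vb = l$beta * 0)
    else NULL
  })
}

adam_update <- function(val, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(val = val - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

#' Presentation configuration
#'
#' Number of stochastic presentations used at training and inference time,
#' plus the strategy name: `"matched"` (train and infer with the same
#' N_pre) or `"max"` (train at the maximum presentation count, 256 by
#' default, infer at smaller N_pre).
#'
#' @param n_train,n_infer presentation counts, `>= 1`.
#' @param strategy `"matched"` or `"max"`.
#' @export
presentation_config <- function(n_train = 32L, n_infer = n_train,
                                strategy = c("matched", "max")) {
  strategy <- match.arg(strategy)
  if (n_train < 1 || n_infer < 1) stop("presentation counts must be >= 1")
  if (strategy == "matched" && n_train != n_infer)
    stop("matched strategy requires n_train == n_infer")
  structure(list(n_train = as.integer(n_train), n_infer = as.integer(n_infer),
                 strategy = strategy), class = "presentation_config")
}

# ---- training -----------------------------------------------------------

#' Train a stochastic binarized CNN
#'
#' Binarization-aware training: forward passes binarize weights and
#' activations by sign, backward passes use the straight-through estimator,
#' and the Adam optimizer updates real-valued shadow weights that are
#' clipped to [-1, 1] after every step. The stochastic input layer
#' re-samples its bitstream on every forward pass: each pixel is replaced by
#' the mean of `n_train` binary presentations (rescaled to [-1, 1]) drawn
#' with P(bit = 1) = Phi(x_r) for the normal sampler.
#'
#' @param spec a [network_spec()] (small conv/pool/fc architectures).
#' @param x raw image array (H, W, C, N).
#' @param y integer class labels in 1..n_classes.
#' @param presentation a [presentation_config()].
#' @param dist input sampling distribution, "normal" or "uniform".
#' @param stats optional precomputed [channel_stats()] (training split);
#'   computed from `x` when NULL.
#' @param epochs,batch_size,lr optimizer settings.
#' @param seed optional RNG seed for reproducible init/sampling/shuffling.
#' @param verbose print per-epoch loss.
#' @return trained `sbcnn_net` with `$loss_history`.
#' @export
sbcnn_train <- function(spec, x, y, presentation = presentation_config(32L),
                        dist = c("normal", "uniform"), stats = NULL,
                        epochs = 15L, batch_size = 32L, lr = 0.01,
                        seed = NULL, verbose = FALSE) {
  dist <- match.arg(dist)
  if (!is.null(seed)) set.seed(seed)
  K <- spec$n_classes
  if (length(unique(y)) < 2) stop("dataset must contain at least 2 classes")
  net <- init_network(spec)
  net$stats <- if (is.null(stats)) channel_stats(x) else stats
  net$presentation <- presentation; net$dist <- dist
  # input encoding precomputed once (deterministic part)
  enc <- if (dist == "normal") normalize_channels(x, net$stats)
         else rescale_minmax(x, net$stats)
  N <- dim(x)[4]
  opt <- adam_init(net); t_step <- 0L
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, N)]
      xb <- enc[, , , idx, drop = FALSE]
      xm <- sample_stream_mean(xb, presentation$n_train, dist)
      inp <- 2 * xm - 1
      fw <- forward_net(net, inp, train = TRUE)
      fan <- nrow(net$layers[[length(net$layers)]]$W)
      sm <- softmax_ce(fw$out / sqrt(fan), y[idx], K)
      if (!is.finite(sm$loss))
        stop("training diverged (loss = ", sm$loss, ") at epoch ", ep,
             "; reduce the learning rate")
      gr <- backward_net(net, fw$caches, sm$dlogits / sqrt(fan))
      t_step <- t_step + 1L
      for (i in seq_along(net$layers)) {
        l <- net$layers[[i]]; g <- gr[[i]]
        if (!is.null(l$W)) {
          u <- adam_update(l$W, g$W, opt[[i]]$mW, opt[[i]]$vW, lr, t_step)
          net$layers[[i]]$W <- pmin(pmax(u$val, -1), 1)
          opt[[i]]$mW <- u$m; opt[[i]]$vW <- u$v
        } else if (l$type == "batchnorm") {
          cc <- fw$caches[[i]]
          net$layers[[i]]$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * cc$mu
          net$layers[[i]]$run_var <- (1 - l$momentum) * l$run_var + l$momentum * cc$va
          u1 <- adam_update(l$gamma, g$gamma, opt[[i]]$mg, opt[[i]]$vg, lr, t_step)
          net$layers[[i]]$gamma <- u1$val; opt[[i]]$mg <- u1$m; opt[[i]]$vg <- u1$v
          u2 <- adam_update(l$beta, g$beta, opt[[i]]$mb, opt[[i]]$vb, lr, t_step)
          net$layers[[i]]$beta <- u2$val; opt[[i]]$mb <- u2$m; opt[[i]]$vb <- u2$v
        }
      }
      ep_loss <- ep_loss + sm$loss; nb <- nb + 1
    }
    losses <- c(losses, ep_loss / nb)
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, ep_loss / nb))
  }
  net$loss_history <- losses
  net
}

#' Training-set accuracy of a trained network (deterministic mean input)
#' @param net trained `sbcnn_net`; @param x,y data as in [sbcnn_train()].
#' @param n_rep presentations for the evaluation forward pass.
#' @return accuracy in [0, 1].
#' @export
net_accuracy <- function(net, x, y, n_rep = net$presentation$n_train) {
  enc <- if (net$dist == "normal") normalize_channels(x, net$stats)
         else rescale_minmax(x, net$stats)
  xm <- sample_stream_mean(enc, n_rep, net$dist)
  fw <- forward_net(net, 2 * xm - 1, train = FALSE)
  mean(max.col(fw$out, ties.method = "first") == y)
}
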