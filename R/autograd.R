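# Minimal reverse-mode autodiff over dense arrays. Nodes live on a tape in
# creation order; backward() walks the tape in reverse, calling each node's
# vector-Jacobian product and accumulating gradients on the parents.
# Feature maps are (H, W, C) or (H, W, C, N) arrays; the C++ kernels treat a
# missing 4th dim as N = 1.

newTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256)
  t$k <- 0L
  t$pcache <- new.env(parent = emptyenv())
  t
}

addNode <- function(tape, value, parents = NULL, vjp = NULL, pname = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value; n$parents <- parents; n$vjp <- vjp
  n$grad <- NULL; n$pname <- pname
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$k]] <- n
  n
}

constNode <- function(tape, value) addNode(tape, value)

# parameter leaf, cached per tape so shared weights accumulate gradients
paramNode <- function(tape, params, name) {
  if (!is.null(tape$pcache[[name]])) return(tape$pcache[[name]])
  v <- params[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  n <- addNode(tape, v, pname = name)
  tape$pcache[[name]] <- n
  n
}

accumGrad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# backpropagate from a scalar loss node; returns named list of parameter grads
backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq(tape$k, 1L)) {
    n <- tape$nodes[[i]]
    if (is.null(n) || is.null(n$grad) || is.null(n$vjp)) next
    gs <- n$vjp(n$grad)
    for (j in seq_along(n$parents)) {
      if (!is.null(gs[[j]])) accumGrad(n$parents[[j]], gs[[j]])
    }
  }
  grads <- list()
  for (i in seq_len(tape$k)) {
    n <- tape$nodes[[i]]
    if (!is.null(n$pname) && !is.null(n$grad)) grads[[n$pname]] <- n$grad
  }
  grads
}

# ---- array ops ------------------------------------------------------------

dim4 <- function(x) { d <- dim(x); if (length(d) == 3) c(d, 1L) else d }

agConv <- function(tape, x, params, name, stride = 1L, pad = NULL) {
  W <- paramNode(tape, params, paste0(name, ".W"))
  b <- paramNode(tape, params, paste0(name, ".b"))
  kh <- dim(W$value)[1]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  r <- cpp_conv2d_fwd_col(x$value, W$value, b$value, as.integer(stride),
                          as.integer(pad))
  xd <- dim4array(dim(x$value)); Wv <- W$value; col <- r$col
  addNode(tape, r$y, parents = list(x, W, b), vjp = function(gy) {
    g <- cpp_conv2d_bwd_col(col, Wv, gy, as.integer(xd), as.integer(stride),
                            as.integer(pad))
    gx <- g$gx
    if (length(dim(x$value)) == 3) dim(gx) <- dim(x$value)
    list(gx, g$gw, g$gb)
  })
}

agConvT2 <- function(tape, x, params, name) {
  W <- paramNode(tape, params, paste0(name, ".W"))
  b <- paramNode(tape, params, paste0(name, ".b"))
  y <- cpp_convT2_fwd(x$value, W$value, b$value)
  xv <- x$value; Wv <- W$value
  addNode(tape, y, parents = list(x, W, b), vjp = function(gy) {
    g <- cpp_convT2_bwd(xv, Wv, gy)
    list(g$gx, g$gw, g$gb)
  })
}

agRelu <- function(tape, x) {
  mask <- x$value > 0
  y <- x$value * mask
  addNode(tape, y, parents = list(x), vjp = function(gy) list(gy * mask))
}

agAdd <- function(tape, a, b) {
  addNode(tape, a$value + b$value, parents = list(a, b),
          vjp = function(gy) list(gy, gy))
}

# batch normalization over (H, W, N) per channel, batch statistics always
agBN <- function(tape, x, params, name, eps = 1e-5) {
  gamma <- paramNode(tape, params, paste0(name, ".gamma"))
  beta <- paramNode(tape, params, paste0(name, ".beta"))
  r <- cpp_bn_fwd(x$value, gamma$value, beta$value, eps)
  xv <- x$value; gv <- gamma$value; mu <- r$mu; inv <- r$inv
  addNode(tape, r$y, parents = list(x, gamma, beta), vjp = function(gy) {
    g <- cpp_bn_bwd(xv, gy, gv, mu, inv)
    list(g$gx, g$dgamma, g$dbeta)
  })
}

agMaxpool <- function(tape, x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool_fwd(x$value, as.integer(k), as.integer(stride),
                       as.integer(pad))
  xd <- dim(x$value)
  arg <- r$arg
  addNode(tape, r$y, parents = list(x), vjp = function(gy) {
    list(cpp_maxpool_bwd(gy, arg, as.integer(dim4array(xd))))
  })
}

dim4array <- function(d) if (length(d) == 3) c(d, 1L) else d

# stride-2 subsampling (1x1 pooling with stride 2)
agSubsample2 <- function(tape, x) {
  d <- dim4(x$value)
  ih <- seq(1, d[1], 2); iw <- seq(1, d[2], 2)
  xv <- array(x$value, d)
  y <- xv[ih, iw, , , drop = FALSE]
  if (length(dim(x$value)) == 3) dim(y) <- dim(y)[1:3]
  addNode(tape, y, parents = list(x), vjp = function(gy) {
    gx <- array(0, d)
    gx[ih, iw, , ] <- gy
    if (length(dim(x$value)) == 3) dim(gx) <- d[1:3]
    list(gx)
  })
}

# 2x nearest-neighbour upsampling
agUpsample2 <- function(tape, x) {
  d <- dim4(x$value)
  xv <- array(x$value, d)
  y <- xv[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
          drop = FALSE]
  if (length(dim(x$value)) == 3) dim(y) <- dim(y)[1:3]
  addNode(tape, y, parents = list(x), vjp = function(gy) {
    g <- array(gy, c(2 * d[1], 2 * d[2], d[3], d[4]))
    o1 <- seq(1, 2 * d[1], 2); o2 <- seq(2, 2 * d[1], 2)
    e1 <- seq(1, 2 * d[2], 2); e2 <- seq(2, 2 * d[2], 2)
    gx <- g[o1, e1, , , drop = FALSE] + g[o2, e1, , , drop = FALSE] +
          g[o1, e2, , , drop = FALSE] + g[o2, e2, , , drop = FALSE]
    if (length(dim(x$value)) == 3) dim(gx) <- d[1:3]
    list(gx)
  })
}

# ROI align of a single-level (H, W, C) map; boxes are fixed (no box grad)
agRoiAlign <- function(tape, feat, boxes, d, samples = 2L) {
  fd <- dim(feat$value)
  y <- cpp_roialign_fwd(feat$value, boxes, as.integer(d), as.integer(samples))
  addNode(tape, y, parents = list(feat), vjp = function(gy) {
    list(cpp_roialign_bwd(gy, boxes, as.integer(fd), as.integer(d),
                          as.integer(samples)))
  })
}

# concatenate patch batches along the ROI axis, reordering to `order`
agConcatN <- function(tape, nodes, order = NULL) {
  vals <- lapply(nodes, function(n) n$value)
  ns <- sapply(vals, function(v) dim4(v)[4])
  d <- dim4(vals[[1]])
  y <- array(0, c(d[1], d[2], d[3], sum(ns)))
  at <- cumsum(c(0, ns))
  for (i in seq_along(vals))
    y[, , , (at[i] + 1):at[i + 1]] <- vals[[i]]
  if (!is.null(order)) y <- y[, , , order, drop = FALSE]
  inv <- if (!is.null(order)) order(order) else NULL
  addNode(tape, y, parents = nodes, vjp = function(gy) {
    if (!is.null(inv)) gy <- gy[, , , inv, drop = FALSE]
    lapply(seq_along(ns), function(i)
      gy[, , , (at[i] + 1):at[i + 1], drop = FALSE])
  })
}

# subset ROIs (4th axis)
agSelectN <- function(tape, x, idx) {
  d <- dim4(x$value)
  y <- array(x$value, d)[, , , idx, drop = FALSE]
  addNode(tape, y, parents = list(x), vjp = function(gy) {
    gx <- array(0, d)
    for (t in seq_along(idx))   # loop so duplicated indices accumulate
      gx[, , , idx[t]] <- gx[, , , idx[t]] + gy[, , , t]
    list(gx)
  })
}

# flatten patches (d, d, C, N) to an N x (d*d*C) matrix
agFlattenN <- function(tape, x) {
  d <- dim4(x$value)
  y <- t(matrix(x$value, d[1] * d[2] * d[3], d[4]))
  addNode(tape, y, parents = list(x), vjp = function(gy) {
    gx <- t(gy)
    dim(gx) <- d
    list(gx)
  })
}

agDense <- function(tape, x, params, name) {
  W <- paramNode(tape, params, paste0(name, ".W"))
  b <- paramNode(tape, params, paste0(name, ".b"))
  y <- sweep(x$value %*% W$value, 2, b$value, "+")
  xv <- x$value; Wv <- W$value
  addNode(tape, y, parents = list(x, W, b), vjp = function(gy) {
    list(gy %*% t(Wv), crossprod(xv, gy), colSums(gy))
  })
}

# gather scalar map entries by flat index (used for RPN logits/deltas)
agGatherFlat <- function(tape, x, idx) {
  d <- dim(x$value)
  y <- x$value[idx]
  addNode(tape, y, parents = list(x), vjp = function(gy) {
    gx <- array(0, d)
    gx[idx] <- gy
    list(gx)
  })
}

# ---- losses ---------------------------------------------------------------

# mean binary cross-entropy on logits
agSigmoidCE <- function(tape, logits, labels) {
  z <- logits$value
  p <- 1 / (1 + exp(-z))
  loss <- mean(pmax(z, 0) - z * labels + log1p(exp(-abs(z))))
  n <- length(z)
  addNode(tape, loss, parents = list(logits),
          vjp = function(gy) list(gy * (p - labels) / n))
}

# mean softmax cross-entropy; labels are 1-based class indices
agSoftmaxCE <- function(tape, logits, labels) {
  z <- logits$value
  zs <- z - apply(z, 1, max)
  ez <- exp(zs)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), labels)], 1e-12)))
  addNode(tape, loss, parents = list(logits), vjp = function(gy) {
    g <- p
    g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
    list(gy * g / n)
  })
}

# smooth L1, summed over coordinates, averaged over rows
agSmoothL1 <- function(tape, pred, target) {
  dlt <- pred$value - target
  a <- abs(dlt)
  l <- ifelse(a < 1, 0.5 * dlt^2, a - 0.5)
  n <- nrow(rbind(pred$value))
  loss <- sum(l) / n
  addNode(tape, loss, parents = list(pred), vjp = function(gy) {
    g <- ifelse(a < 1, dlt, sign(dlt))
    list(gy * g / n)
  })
}

# root-mean-square error per ROI, averaged over ROIs
agRMSE <- function(tape, pred, target, eps = 1e-12) {
  d <- dim4(pred$value)
  N <- d[4]; S <- d[1] * d[2] * d[3]
  diffs <- array(pred$value - target, c(S, N))
  mse <- colMeans(diffs^2)
  r <- sqrt(mse + eps)
  loss <- mean(sqrt(mse))
  addNode(tape, loss, parents = list(pred), vjp = function(gy) {
    g <- sweep(diffs, 2, 1 / (N * S * r), "*")
    dim(g) <- dim(pred$value)
    list(gy * g)
  })
}

# weighted sum of scalar nodes
agWeightedSum <- function(tape, nodes, weights) {
  vals <- sapply(nodes, function(n) n$value)
  addNode(tape, sum(vals * weights), parents = nodes,
          vjp = function(gy) as.list(gy * weights))
}
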