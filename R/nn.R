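## Minimal 1-D convolutional network engine with hand-written reverse-mode
## gradients, built on base BLAS matrix operations (im2col convolutions).
## Shapes: batched signals are (batch, time, channels); dense activations are
## (batch, units). Layers are plain lists tagged by $type; a network is a
## list of layers, where a residual block nests two layer sequences
## ($main, $skip) joined by an additive skip and a post-add ReLU.
##
## The engine exists because the contrastive encoder is the package's core
## and must be trainable; it is deliberately small (conv / batch-norm / ReLU
## / max-pool / dropout / dense / global-average-pool) and every backward
## pass is checked against finite differences in the test suite.

## ---- layer constructors (weights drawn from the current RNG stream) -------

layerConv <- function(cin, cout, kernel, stride, tin) {
  if (tin %% stride != 0) {
    pclrError(sprintf("conv: input length %d not divisible by stride %d", tin, stride),
              "pclr_config_error")
  }
  tout <- tin %/% stride
  pad <- max((tout - 1L) * stride + kernel - tin, 0L)
  padl <- pad %/% 2L
  idx <- outer((0:(tout - 1L)) * stride, seq_len(kernel), "+") # padded indices
  W <- matrix(rnorm(kernel * cin * cout, 0, sqrt(2 / (kernel * cin))),
              kernel * cin, cout)
  list(type = "conv", cin = cin, cout = cout, kernel = kernel, stride = stride,
       tin = tin, tout = tout, pad = pad, padl = padl, colIdx = as.vector(idx),
       W = W, b = numeric(cout))
}

layerBN <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       gamma = rep(1, c), beta = numeric(c),
       rmu = numeric(c), rvar = rep(1, c))
}

layerReLU <- function() list(type = "relu")

layerDropout <- function(rate) list(type = "dropout", rate = rate)

layerMaxPool <- function(pool, tin) {
  if (tin %% pool != 0) {
    pclrError(sprintf("maxpool: input length %d not divisible by pool %d", tin, pool),
              "pclr_config_error")
  }
  list(type = "maxpool", pool = pool, tin = tin, tout = tin %/% pool)
}

layerGAP <- function() list(type = "gap")

layerDense <- function(din, dout) {
  list(type = "dense", din = din, dout = dout,
       W = matrix(rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

resBlock <- function(cin, cout, kernel, down, tin) {
  main <- list(
    layerConv(cin, cout, kernel, down, tin),
    layerBN(cout), layerReLU(),
    layerConv(cout, cout, kernel, 1L, tin %/% down),
    layerBN(cout)
  )
  skip <- list()
  if (down > 1L) skip <- c(skip, list(layerMaxPool(down, tin)))
  if (cin != cout) skip <- c(skip, list(layerConv(cin, cout, 1L, 1L, tin %/% down)))
  list(type = "resblock", main = main, skip = skip, tout = tin %/% down)
}

## ---- forward ---------------------------------------------------------------

layerForward <- function(layer, X, training, needGrad, dropoutRate = 0) {
  switch(layer$type,
    conv = {
      d <- dim(X)
      B <- d[1]
      if (d[2] != layer$tin || d[3] != layer$cin) {
        pclrError(sprintf("conv: expected input %d x %d, got %d x %d",
                          layer$tin, layer$cin, d[2], d[3]), "pclr_config_error")
      }
      if (layer$pad > 0) {
        Xp <- array(0, c(B, layer$tin + layer$pad, layer$cin))
        Xp[, layer$padl + seq_len(layer$tin), ] <- X
      } else Xp <- X
      cols <- Xp[, layer$colIdx, , drop = FALSE]
      dim(cols) <- c(B * layer$tout, layer$kernel * layer$cin)
      Y <- cols %*% layer$W
      Y <- Y + rep(layer$b, each = nrow(Y))
      dim(Y) <- c(B, layer$tout, layer$cout)
      list(out = Y, cache = if (needGrad) list(cols = cols, B = B) else NULL,
           layer = layer)
    },
    bn = {
      d <- dim(X)
      C <- d[length(d)]
      n <- prod(d[-length(d)])
      Xm <- X
      dim(Xm) <- c(n, C)
      if (training) {
        mu <- colMeans(Xm)
        v <- pmax(colMeans(Xm * Xm) - mu^2, 0)
        layer$rmu <- layer$momentum * layer$rmu + (1 - layer$momentum) * mu
        layer$rvar <- layer$momentum * layer$rvar + (1 - layer$momentum) * v
      } else {
        mu <- layer$rmu
        v <- layer$rvar
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- (Xm - rep(mu, each = n)) * rep(invstd, each = n)
      Y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
      dim(Y) <- d
      list(out = Y,
           cache = if (needGrad) list(xhat = xhat, invstd = invstd, n = n, d = d) else NULL,
           layer = layer)
    },
    relu = {
      mask <- X > 0
      list(out = X * mask, cache = if (needGrad) list(mask = mask) else NULL,
           layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (runif(length(X)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(X)
        list(out = X * mask, cache = if (needGrad) list(mask = mask) else NULL,
             layer = layer)
      } else {
        list(out = X, cache = if (needGrad) list(mask = NULL) else NULL, layer = layer)
      }
    },
    maxpool = {
      d <- dim(X)
      B <- d[1]; C <- d[3]; p <- layer$pool; tout <- layer$tout
      if (d[2] != layer$tin) {
        pclrError(sprintf("maxpool: expected length %d, got %d", layer$tin, d[2]),
                  "pclr_config_error")
      }
      Xr <- X
      dim(Xr) <- c(B, p, tout, C)
      Y <- Xr[, 1, , , drop = FALSE]
      dim(Y) <- c(B, tout, C)
      arg <- array(1L, c(B, tout, C))
      if (p > 1) for (j in 2:p) {
        cand <- Xr[, j, , , drop = FALSE]
        dim(cand) <- c(B, tout, C)
        m <- cand > Y
        Y[m] <- cand[m]
        arg[m] <- j
      }
      list(out = Y, cache = if (needGrad) list(arg = arg, d = d) else NULL,
           layer = layer)
    },
    gap = {
      d <- dim(X)
      Y <- colMeans(aperm(X, c(2, 1, 3))) # (B, C)
      list(out = Y, cache = if (needGrad) list(d = d) else NULL, layer = layer)
    },
    dense = {
      Y <- X %*% layer$W
      Y <- Y + rep(layer$b, each = nrow(Y))
      list(out = Y, cache = if (needGrad) list(X = X) else NULL, layer = layer)
    },
    resblock = {
      r1 <- seqForward(layer$main, X, training, needGrad, dropoutRate)
      r2 <- seqForward(layer$skip, X, training, needGrad, dropoutRate)
      pre <- r1$out + r2$out
      mask <- pre > 0
      layer$main <- r1$layers
      layer$skip <- r2$layers
      list(out = pre * mask,
           cache = if (needGrad) list(main = r1$caches, skip = r2$caches, mask = mask) else NULL,
           layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

seqForward <- function(layers, X, training, needGrad, dropoutRate = 0) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layerForward(layers[[i]], X, training, needGrad, dropoutRate)
    X <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

## ---- backward --------------------------------------------------------------

layerBackward <- function(layer, cache, dY) {
  switch(layer$type,
    conv = {
      B <- cache$B
      dYm <- dY
      dim(dYm) <- c(B * layer$tout, layer$cout)
      dW <- crossprod(cache$cols, dYm)
      db <- colSums(dYm)
      dXcol <- tcrossprod(dYm, layer$W)
      dim(dXcol) <- c(B, layer$tout, layer$kernel, layer$cin)
      tinp <- layer$tin + layer$pad
      dXp <- array(0, c(B, tinp, layer$cin))
      for (k in seq_len(layer$kernel)) {
        pidx <- (0:(layer$tout - 1L)) * layer$stride + k
        dXp[, pidx, ] <- dXp[, pidx, ] + dXcol[, , k, ]
      }
      dX <- dXp[, layer$padl + seq_len(layer$tin), , drop = FALSE]
      list(dX = dX, grads = list(W = dW, b = db))
    },
    bn = {
      n <- cache$n
      C <- length(layer$gamma)
      dYm <- dY
      dim(dYm) <- c(n, C)
      dgamma <- colSums(dYm * cache$xhat)
      dbeta <- colSums(dYm)
      dxhat <- dYm * rep(layer$gamma, each = n)
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cache$xhat)
      dX <- (dxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
        rep(cache$invstd, each = n)
      dim(dX) <- cache$d
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dX = dY * cache$mask, grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    maxpool = {
      d <- cache$d
      B <- d[1]; C <- d[3]; p <- layer$pool; tout <- layer$tout
      dXr <- array(0, c(B, p, tout, C))
      for (j in seq_len(p)) {
        tmp <- array(0, c(B, tout, C))
        m <- cache$arg == j
        tmp[m] <- dY[m]
        dXr[, j, , ] <- tmp
      }
      dim(dXr) <- d
      list(dX = dXr, grads = NULL)
    },
    gap = {
      d <- cache$d
      dX <- aperm(array(as.vector(dY) / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
      list(dX = dX, grads = NULL)
    },
    dense = {
      dW <- crossprod(cache$X, dY)
      db <- colSums(dY)
      dX <- tcrossprod(dY, layer$W)
      list(dX = dX, grads = list(W = dW, b = db))
    },
    resblock = {
      dPre <- dY * cache$mask
      rm <- seqBackward(layer$main, cache$main, dPre)
      rs <- seqBackward(layer$skip, cache$skip, dPre)
      list(dX = rm$dX + rs$dX, grads = list(main = rm$grads, skip = rs$grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

seqBackward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layerBackward(layers[[i]], caches[[i]], dY)
    dY <- r$dX
    grads[i] <- list(r$grads) # keep NULL slots for parameter-free layers
  }
  list(dX = dY, grads = grads)
}

## ---- Adam optimizer (grads mirror the layer nesting) -----------------------

adamStep <- function(layers, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  step1 <- function(layer, g, s) {
    if (is.null(g)) return(list(layer = layer, s = s))
    if (identical(layer$type, "resblock")) {
      rm <- walk(layer$main, g$main, if (is.null(s)) NULL else s$main)
      rs <- walk(layer$skip, g$skip, if (is.null(s)) NULL else s$skip)
      layer$main <- rm$layers
      layer$skip <- rs$layers
      return(list(layer = layer, s = list(main = rm$state, skip = rs$state)))
    }
    if (is.null(s)) s <- list(m = lapply(g, function(x) x * 0),
                              v = lapply(g, function(x) x * 0))
    for (nm in names(g)) {
      s$m[[nm]] <- beta1 * s$m[[nm]] + (1 - beta1) * g[[nm]]
      s$v[[nm]] <- beta2 * s$v[[nm]] + (1 - beta2) * g[[nm]]^2
      layer[[nm]] <- layer[[nm]] -
        lr * (s$m[[nm]] / bc1) / (sqrt(s$v[[nm]] / bc2) + eps)
    }
    list(layer = layer, s = s)
  }
  walk <- function(ls, gs, ss) {
    if (is.null(ss)) ss <- vector("list", length(ls))
    for (i in seq_along(ls)) {
      r <- step1(ls[[i]], gs[[i]], ss[[i]])
      ls[[i]] <- r$layer
      ss[i] <- list(r$s) # keep NULL slots for parameter-free layers
    }
    list(layers = ls, state = ss)
  }
  walk(layers, grads, state)
}

## ---- utilities -------------------------------------------------------------

countParams <- function(layers) {
  n <- 0
  for (layer in layers) {
    n <- n + switch(layer$type,
      conv = length(layer$W) + length(layer$b),
      dense = length(layer$W) + length(layer$b),
      bn = 2L * layer$c,
      resblock = countParams(layer$main) + countParams(layer$skip),
      0L
    )
  }
  n
}

describeLayers <- function(layers, indent = "") {
  out <- character()
  for (layer in layers) {
    out <- c(out, switch(layer$type,
      conv = sprintf("%sConv1D %d->%d, kernel %d, stride %d (T %d->%d)", indent,
                     layer$cin, layer$cout, layer$kernel, layer$stride,
                     layer$tin, layer$tout),
      bn = sprintf("%sBatchNorm (%d channels)", indent, layer$c),
      relu = sprintf("%sReLU", indent),
      dropout = sprintf("%sDropout (rate %.2f)", indent, layer$rate),
      maxpool = sprintf("%sMaxPool1D %d (T %d->%d)", indent, layer$pool,
                        layer$tin, layer$tout),
      gap = sprintf("%sGlobalAveragePooling1D", indent),
      dense = sprintf("%sDense %d->%d", indent, layer$din, layer$dout),
      resblock = c(sprintf("%sResidualBlock (T->%d):", indent, layer$tout),
                   describeLayers(layer$main, paste0(indent, "  | ")),
                   sprintf("%s  skip:", indent),
                   if (length(layer$skip)) describeLayers(layer$skip, paste0(indent, "  | "))
                   else paste0(indent, "  | identity"),
                   sprintf("%s  add + ReLU", indent))
    ))
  }
  out
}
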