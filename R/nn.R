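# Minimal MLP engine: linear -> batch norm -> LeakyReLU(0.01) -> dropout for
# every hidden layer, linear output layer. Hand-written forward/backward over
# BLAS matmuls, Adam optimizer, deterministic given the R RNG state.
#
# A network is a plain list:
#   list(inDim, outDim, hidden, trainable, layers = list(...))
# and each layer is
#   list(kind = "hidden"|"output", W, b, gamma, beta, runMean, runVar)
# with W of shape (in x out). Batch norm uses population variance for both
# normalization and running statistics (momentum 0.1, eps 1e-5).

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1
.LRELU_SLOPE <- 0.01

.rowsAdd <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)
.rowsMul <- function(M, v) M * matrix(v, nrow(M), length(v), byrow = TRUE)

# fan-in-scaled uniform init, consumes the current RNG stream
.mlpNew <- function(inDim, hidden, outDim, dropout = 0.2) {
  dims <- c(inDim, hidden, outDim)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    din <- dims[i]; dout <- dims[i + 1L]
    bound <- 1 / sqrt(din)
    L <- list(kind = if (i < length(layers)) "hidden" else "output",
              W = matrix(stats::runif(din * dout, -bound, bound), din, dout),
              b = stats::runif(dout, -bound, bound))
    if (L$kind == "hidden") {
      L$gamma <- rep(1, dout); L$beta <- rep(0, dout)
      L$runMean <- rep(0, dout); L$runVar <- rep(1, dout)
    }
    layers[[i]] <- L
  }
  list(inDim = inDim, outDim = outDim, hidden = hidden,
       dropout = dropout, trainable = TRUE, layers = layers)
}

# forward pass; train=TRUE uses batch statistics + dropout and updates
# running statistics in the returned net. Returns list(out, caches, net).
.mlpForward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net$layers))
  H <- X
  n <- nrow(X)
  for (i in seq_along(net$layers)) {
    L <- net$layers[[i]]
    Z <- .rowsAdd(H %*% L$W, L$b)
    if (L$kind == "output") {
      caches[[i]] <- list(Xin = H, train = train)
      H <- Z
      next
    }
    if (train) {
      mu <- .colMeans(Z, n, ncol(Z))
      v <- .colMeans(Z * Z, n, ncol(Z)) - mu^2
      v <- pmax(v, 0)
      istd <- 1 / sqrt(v + .BN_EPS)
      xhat <- .rowsMul(.rowsAdd(Z, -mu), istd)
      net$layers[[i]]$runMean <- (1 - .BN_MOMENTUM) * L$runMean +
        .BN_MOMENTUM * mu
      net$layers[[i]]$runVar <- (1 - .BN_MOMENTUM) * L$runVar +
        .BN_MOMENTUM * v
    } else {
      istd <- 1 / sqrt(L$runVar + .BN_EPS)
      xhat <- .rowsMul(.rowsAdd(Z, -L$runMean), istd)
    }
    Y <- .rowsAdd(.rowsMul(xhat, L$gamma), L$beta)
    A <- ifelse(Y > 0, Y, .LRELU_SLOPE * Y)
    if (train && net$dropout > 0) {
      mask <- (matrix(stats::runif(length(A)), nrow(A), ncol(A)) >=
                 net$dropout) / (1 - net$dropout)
      O <- A * mask
    } else {
      mask <- NULL
      O <- A
    }
    caches[[i]] <- list(Xin = H, xhat = xhat, istd = istd, Y = Y,
                        mask = mask, train = train)
    H <- O
  }
  list(out = H, caches = caches, net = net)
}

# backward pass for dLoss/dOut; returns list(dX, grads). grads is NULL when
# paramGrads=FALSE (frozen networks: only the input gradient is propagated).
.mlpBackward <- function(net, caches, dOut, paramGrads = TRUE) {
  grads <- if (paramGrads) vector("list", length(net$layers)) else NULL
  dH <- dOut
  for (i in rev(seq_along(net$layers))) {
    L <- net$layers[[i]]
    cache <- caches[[i]]
    if (L$kind == "hidden") {
      dA <- if (!is.null(cache$mask)) dH * cache$mask else dH
      dY <- dA * ifelse(cache$Y > 0, 1, .LRELU_SLOPE)
      if (paramGrads) {
        dgamma <- colSums(dY * cache$xhat)
        dbeta <- colSums(dY)
      }
      dXhat <- .rowsMul(dY, L$gamma)
      if (cache$train) {
        n <- nrow(dXhat)
        m1 <- .colMeans(dXhat, n, ncol(dXhat))
        m2 <- .colMeans(dXhat * cache$xhat, n, ncol(dXhat))
        dZ <- .rowsMul(dXhat - .rowsAdd(.rowsMul(cache$xhat, m2), m1),
                       cache$istd)
      } else {
        dZ <- .rowsMul(dXhat, cache$istd)
      }
    } else {
      dZ <- dH
    }
    if (paramGrads) {
      g <- list(W = crossprod(cache$Xin, dZ), b = colSums(dZ))
      if (L$kind == "hidden") { g$gamma <- dgamma; g$beta <- dbeta }
      grads[[i]] <- g
    }
    dH <- tcrossprod(dZ, L$W)
  }
  list(dX = dH, grads = grads)
}

# elementwise accumulation of two grad lists
.gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  mapply(function(ga, gb) mapply(`+`, ga, gb, SIMPLIFY = FALSE),
         a, b, SIMPLIFY = FALSE)
}

.adamInit <- function(net) {
  st <- lapply(net$layers, function(L) {
    nm <- if (L$kind == "hidden") c("W", "b", "gamma", "beta") else c("W", "b")
    lapply(stats::setNames(nm, nm), function(p)
      list(m = L[[p]] * 0, v = L[[p]] * 0))
  })
  list(layers = st, t = 0L)
}

.adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(state$layers[[i]])) {
      s <- state$layers[[i]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * g[[p]]
      s$v <- beta2 * s$v + (1 - beta2) * g[[p]]^2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      state$layers[[i]][[p]] <- s
    }
  }
  list(net = net, state = state)
}

# learnable parameter count (weights, biases, batch-norm scale/shift)
.mlpParamCount <- function(net) {
  sum(vapply(net$layers, function(L) {
    n <- length(L$W) + length(L$b)
    if (L$kind == "hidden") n <- n + length(L$gamma) + length(L$beta)
    n
  }, numeric(1)))
}
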