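# Independently coded brute-force oracles (plain loops and textbook
# formulas, no package internals), shared by the metric unit tests and the
# oracle-equivalence acceptance tests.

oraclePcc <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / n
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  if (sx == 0 || sy == 0) 0 else cv / (sx * sy)
}

oracleSsim <- function(x, y) {
  mm <- function(v) if (max(v) == min(v)) rep(0, length(v))
                    else (v - min(v)) / (max(v) - min(v))
  x <- mm(x); y <- mm(y)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + 0.01) * (2 * cxy + 0.03)) /
    ((mx^2 + my^2 + 0.01) * (vx + vy + 0.03))
}

oracleZ <- function(v) {
  s <- sqrt(sum((v - mean(v))^2) / length(v))
  if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
}

oracleRmse <- function(x, y) {
  z1 <- oracleZ(x); z2 <- oracleZ(y)
  sqrt(sum((z1 - z2)^2) / length(x))
}

# Wasserstein-1 via direct integration of |F1 - F2| between breakpoints
oracleWasserstein <- function(x, y) {
  z1 <- oracleZ(x); z2 <- oracleZ(y)
  pts <- sort(unique(c(z1, z2)))
  if (length(pts) == 1) return(0)
  acc <- 0
  for (i in seq_len(length(pts) - 1)) {
    t <- pts[i]
    acc <- acc + abs(mean(z1 <= t) - mean(z2 <= t)) * (pts[i + 1] - pts[i])
  }
  acc
}

oracleJs <- function(x, y) {
  lo <- min(c(x, y)); if (lo < 0) { x <- x - lo; y <- y - lo }
  p <- x / sum(x); q <- y / sum(y); m <- (p + q) / 2
  kl <- 0
  for (i in seq_along(p)) {
    if (q[i] > 0) kl <- kl + 0.5 * q[i] * log2(q[i] / m[i])
    if (p[i] > 0) kl <- kl + 0.5 * p[i] * log2(p[i] / m[i])
  }
  kl
}

oracleMoran <- function(v, coords, k = 6) {
  n <- length(v)
  z <- v - mean(v)
  if (sum(z^2) == 0) return(0)
  num <- 0; wtot <- 0
  for (i in 1:n) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, 2, byrow = TRUE))^2))
    d[i] <- Inf
    nb <- order(d)[1:k]
    for (j in nb) { num <- num + (1 / k) * z[i] * z[j]; wtot <- wtot + 1 / k }
  }
  (n / wtot) * num / sum(z^2)
}

oracleAri <- function(a, b) {
  n <- length(a)
  bothSame <- 0; aSame <- 0; bSame <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) bothSame <- bothSame + 1
    if (sa) aSame <- aSame + 1
    if (sb) bSame <- bSame + 1
  }
  exp0 <- aSame * bSame / tot
  mx <- (aSame + bSame) / 2
  if (mx == exp0) 1 else (bothSame - exp0) / (mx - exp0)
}

oracleNmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  H <- function(labs, u) {
    p <- sapply(u, function(l) sum(labs == l) / n)
    -sum(p[p > 0] * log(p[p > 0]))
  }
  mi <- 0
  for (l in ua) for (s in ub) {
    nls <- sum(a == l & b == s)
    if (nls > 0)
      mi <- mi + (nls / n) * log(nls * n / (sum(a == l) * sum(b == s)))
  }
  ha <- H(a, ua); hb <- H(b, ub)
  if (ha + hb == 0) 1 else 2 * mi / (ha + hb)
}

# cluster-balanced silhouette: per-sample widths, then cluster means, then
# the mean over clusters
oracleSilhouette <- function(labs, emb) {
  n <- length(labs)
  cl <- unique(labs)
  D <- as.matrix(dist(emb))
  s <- numeric(n)
  for (i in 1:n) {
    own <- labs == labs[i]
    nOwn <- sum(own) - 1
    ai <- if (nOwn > 0) sum(D[i, own]) / nOwn else 0
    bi <- min(sapply(cl[cl != labs[i]], function(cc) mean(D[i, labs == cc])))
    s[i] <- if (nOwn == 0) 0 else (bi - ai) / max(ai, bi)
  }
  mean(sapply(cl, function(cc) mean(s[labs == cc])))
}

# independent layer walker: learnable parameters of an MLP whose hidden
# layers carry batch-norm scale/shift
walkParams <- function(inDim, hidden, outDim) {
  dims <- c(inDim, hidden, outDim)
  total <- 0
  for (i in seq_len(length(dims) - 1)) {
    din <- dims[i]; dout <- dims[i + 1]
    total <- total + din * dout + dout
    if (i < length(dims) - 1) total <- total + 2 * dout
  }
  total
}
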