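# Metric suite vs independently coded brute-force oracles and installed
# reference implementations.

# --- tests -----------------------------------------------------------------

test_that("pcc matches its oracle and handles degenerate vectors", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  expect_equal(pcc(x, y), oraclePcc(x, y), tolerance = 1e-12)
  expect_equal(pcc(x, y), cor(x, y), tolerance = 1e-12)  # library cross-check
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(rep(2, 5), 1:5), 0)
  expect_error(pcc(1:3, 1:4), "length")
})

test_that("ssim matches a step-by-step hand evaluation", {
  x <- c(0, 1, 2); y <- c(2, 1, 0)
  expect_equal(ssim(x, y), oracleSsim(x, y), tolerance = 1e-12)
  z <- c(0.3, 0.8, 0.1, 0.9)
  expect_equal(ssim(z, z), 1, tolerance = 1e-12)
})

test_that("rmse on z-scores is affine-invariant and matches its oracle", {
  x <- c(1, 2, 3); y <- c(1, 3, 2)
  expect_equal(rmseZ(x, y), oracleRmse(x, y), tolerance = 1e-12)
  expect_equal(rmseZ(x, x), 0)
  expect_equal(rmseZ(x, 5 * x + 3), 0, tolerance = 1e-12)
})

test_that("wasserstein on z-scores equals the CDF integral", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(wassersteinZ(x, y), oracleWasserstein(x, y),
                 tolerance = 1e-10)
  }
  expect_equal(wassersteinZ(1:5, 1:5), 0)
  expect_gte(wassersteinZ(rnorm(6), rnorm(6)), 0)
})

test_that("JS divergence is bounded, symmetric and exact on disjoint support", {
  expect_equal(jsDivergence(c(1, 0), c(0, 1)), 1)   # closed form, base 2
  expect_equal(jsDivergence(c(2, 3, 5), c(2, 3, 5)), 0)
  set.seed(2)
  x <- runif(10); y <- runif(10)
  expect_equal(jsDivergence(x, y), jsDivergence(y, x), tolerance = 1e-12)
  expect_equal(jsDivergence(x, y), oracleJs(x, y), tolerance = 1e-12)
  expect_warning(v <- jsDivergence(c(0, 0), c(1, 2)), "zero-sum")
  expect_equal(v, 1)
})

test_that("Moran's I matches a brute-force double loop and known patterns", {
  set.seed(3)
  coords <- matrix(runif(40), 20, 2)
  v <- rnorm(20)
  expect_equal(moransI(v, coords), oracleMoran(v, coords), tolerance = 1e-10)
  expect_equal(moransI(rep(1, 20), coords), 0)
  # two separated blobs with opposite values: strong positive autocorrelation
  blob <- rbind(matrix(runif(20, 0, 0.2), 10, 2),
                matrix(runif(20, 0.8, 1.0), 10, 2))
  vals <- c(rep(1, 10), rep(-1, 10)) + rnorm(20, sd = 0.05)
  expect_gt(moransI(vals, blob), 0.5)
  # permuting a smooth field reduces I
  set.seed(4)
  perm <- sample(20)
  expect_lt(moransI(vals[perm], blob), moransI(vals, blob))
  expect_error(moransI(1:3, matrix(0, 3, 2), k = 6), "k\\+1")
})

test_that("Moran shift summary is exact under identity and reacts to smoothing", {
  set.seed(5)
  coords <- matrix(runif(60), 30, 2)
  m <- matrix(rpois(30 * 3, 4), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- moranShiftSummary(m, m, coords)
  expect_true(all(s@perGene == 0))
  expect_equal(s@fractionWithin, 1)
  expect_equal(s@tolerance, 0.10)
  # spatial smoothing of one gene raises its autocorrelation
  sm <- m
  W <- exp(-as.matrix(dist(coords))^2 / 0.05)
  W <- W / rowSums(W)
  sm[, "a"] <- as.numeric(W %*% m[, "a"])
  s2 <- moranShiftSummary(m, sm, coords)
  expect_gt(s2@perGene["a"], 0)
})

test_that("neighborhood recall: identity is perfect, permutation is chance", {
  set.seed(6)
  A <- matrix(rnorm(200 * 10), 200, 10)
  r <- neighborhoodRecall(A, A, k = 15, m = 45)
  expect_equal(r@mean, 1)
  expect_true(all(r@perCell == 1))
  # random row permutation: expected overlap ~ m/(n-1)
  recs <- replicate(5, {
    B <- A[sample(nrow(A)), ]
    neighborhoodRecall(A, B, k = 15, m = 45)@mean
  })
  expect_equal(mean(recs), 45 / 199, tolerance = 0.5)  # Monte-Carlo band
  expect_error(neighborhoodRecall(A[1:30, ], A[1:30, ], k = 15, m = 45),
               "more cells")
})

test_that("clustering scores agree with exhaustive pair counting and mclust", {
  set.seed(7)
  a <- sample(1:3, 25, replace = TRUE)
  b <- sample(1:3, 25, replace = TRUE)
  cs <- clusteringScores(a, b)
  expect_equal(cs$ari, oracleAri(b, a), tolerance = 1e-10)
  skip_if_not_installed("mclust")
  expect_equal(cs$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-10)
  # identical labelings and label-permutation invariance
  expect_equal(clusteringScores(a, a)$ari, 1)
  expect_equal(clusteringScores(a, a)$nmi, 1)
  relabel <- c(2, 3, 1)[a]
  expect_equal(clusteringScores(a, relabel)$ari, 1)
  expect_equal(clusteringScores(a, relabel)$nmi, 1, tolerance = 1e-10)
})

test_that("silhouette follows the cluster-balanced definition", {
  set.seed(8)
  emb <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  labs <- rep(1:2, each = 10)
  s <- clusteringScores(labs, labs, emb)$silhouette
  # brute-force: per-sample s then per-cluster means
  D <- as.matrix(dist(emb))
  svals <- sapply(1:20, function(i) {
    own <- labs == labs[i]
    ai <- sum(D[i, own]) / (sum(own) - 1)
    bi <- mean(D[i, !own])
    (bi - ai) / max(ai, bi)
  })
  expect_equal(s, mean(c(mean(svals[1:10]), mean(svals[11:20]))),
               tolerance = 1e-10)
  expect_gt(s, 0.5)
  # equal cluster sizes: balanced mean equals the plain per-sample mean,
  # cross-checked against the cluster package
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(labs, dist(emb))
  expect_equal(s, mean(sil[, "sil_width"]), tolerance = 1e-10)
  expect_error(clusteringScores(labs, rep(1, 20), emb), "single cluster")
})

test_that("precision-recall AUC behaves on simple rankings", {
  expect_equal(prAuc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(prAuc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)),
               mean(c(1 / 3, 2 / 4)))
  expect_error(prAuc(1:3, c(FALSE, FALSE, FALSE)), "empty")
})

test_that("evaluateImputation composes the per-gene metrics exactly", {
  set.seed(9)
  n <- 30; g <- 6
  measured <- matrix(rpois(n * g, 4), n, g,
                     dimnames = list(NULL, paste0("g", 1:g)))
  imputed <- measured + matrix(rnorm(n * g, sd = 0.5), n, g)
  imputed <- pmax(imputed, 0)
  rep <- evaluateImputation(measured, imputed)
  pg <- perGeneMetrics(rep)
  for (i in seq_len(nrow(pg))) {
    gn <- pg$gene[i]
    expect_equal(pg$pcc[i], pcc(measured[, gn], imputed[, gn]))
    expect_equal(pg$ssim[i], ssim(measured[, gn], imputed[, gn]))
    expect_equal(pg$rmse[i], rmseZ(measured[, gn], imputed[, gn]))
    expect_equal(pg$wasserstein[i],
                 wassersteinZ(measured[, gn], imputed[, gn]))
    expect_equal(pg$js[i], jsDivergence(measured[, gn], imputed[, gn]))
  }
  expect_equal(unname(metricAverages(rep)["pcc"]), mean(pg$pcc))
  # all-zero measured genes are excluded and listed
  measured[, "g2"] <- 0
  rep2 <- evaluateImputation(measured, imputed)
  expect_false("g2" %in% perGeneMetrics(rep2)$gene)
  expect_identical(reportDiagnostics(rep2)$excludedGenes, "g2")
  measured0 <- measured; measured0[] <- 0
  expect_error(evaluateImputation(measured0, imputed), "no evaluable")
})
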