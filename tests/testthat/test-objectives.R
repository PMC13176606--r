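# Loss formulas: reconstruction, cycle, identity, adversarial, hinge, and
# their weighted combination, each against hand or brute-force oracles.

core <- function(name) get(name, asNamespace("cycleImpute"))

test_that("reconstruction loss equals the brute-force mean of squares", {
  expect_equal(reconstructionLoss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  expect_equal(reconstructionLoss(c(0, 0), c(1, 1)), 1.0)
  set.seed(5)
  x <- matrix(rnorm(12), 4, 3); y <- matrix(rnorm(12), 4, 3)
  acc <- 0
  for (i in 1:4) for (j in 1:3) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(reconstructionLoss(x, y), acc / 12, tolerance = 1e-12)
  expect_error(reconstructionLoss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("per-cell Pearson identity core matches a hand oracle", {
  icc <- core(".identityCorrCore")
  # 2 cells x 3 shared genes, brute force per cell then averaged
  D <- rbind(c(1, 2, 4), c(3, 1, 2))
  Tg <- rbind(c(2, 3, 7), c(1, 0, 5))
  rhos <- sapply(1:2, function(i) {
    u <- D[i, ] - mean(D[i, ]); v <- Tg[i, ] - mean(Tg[i, ])
    sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  })
  expect_equal(icc(D, Tg)$loss, 1 - mean(rhos), tolerance = 1e-10)
  # perfect agreement -> 0; perfect anti-correlation -> 2 per direction
  expect_equal(icc(D, D)$loss, 0, tolerance = 1e-12)
  expect_equal(icc(-D, D)$loss, 2, tolerance = 1e-12)
  # zero-variance row counts rho = 0 (loss 1 for that cell)
  Dz <- rbind(c(1, 1, 1), c(3, 1, 2))
  expect_equal(icc(Dz, Tg)$loss, 1 - mean(c(0, rhos[2])), tolerance = 1e-12)
})

test_that("identity loss spans [0,4] and hits 4 when anti-correlated", {
  icc <- core(".identityCorrCore")
  D <- matrix(rnorm(12), 4, 3)
  # both directions anti-correlated: total = 2 + 2 = 4
  total <- icc(-D, D)$loss + icc(-D, D)$loss
  expect_equal(total, 4, tolerance = 1e-10)
  expect_error(identityLoss(stubBundle(), matrix(0, 2, 2), matrix(0, 2, 2),
                            new("SharedGeneMap", sharedNames = character(),
                                stIdx = integer(), scIdx = integer())),
               "requires shared genes")
})

test_that("identity gradient is exactly zero off the shared columns", {
  b <- trainedFixture()$bundle
  pp <- trainedFixture()$pp
  sm <- sharedMap(pp)
  xSt <- exprValues(pp@st)[1:20, , drop = FALSE]
  xSc <- exprValues(pp@sc)[1:20, , drop = FALSE]
  base <- identityLoss(b, xSt, xSc, sm)
  # perturb decoded-output columns outside the shared set by perturbing the
  # measured target at non-shared columns: construct via the core instead
  icc <- core(".identityCorrCore")
  mlpF <- core(".mlpForward")
  z12 <- mlpF(b@nets$transSt2Sc, mlpF(b@nets$encSt, xSt)$out)$out
  dec <- mlpF(b@nets$decSc, z12)$out
  r0 <- icc(dec[, sm@scIdx, drop = FALSE], xSt[, sm@stIdx, drop = FALSE])
  nonShared <- setdiff(seq_len(ncol(dec)), sm@scIdx)[1]
  dec2 <- dec; dec2[, nonShared] <- dec2[, nonShared] + 5
  r1 <- icc(dec2[, sm@scIdx, drop = FALSE], xSt[, sm@stIdx, drop = FALSE])
  expect_identical(r0$loss, r1$loss)
  expect_true(is.finite(base))
})

test_that("hinge loss reproduces hand-computable score patterns", {
  hinge <- core(".hingeCore")
  # margins satisfied: real >= 1, fake <= -1
  expect_equal(hinge(c(1, 2, 1.5), c(-1, -3)), 0)
  # all scores zero: 1 + 1 per domain
  expect_equal(hinge(c(0, 0), c(0, 0, 0)) + hinge(0, 0), 4)
  # brute force on random scores
  set.seed(8)
  r <- rnorm(6); f <- rnorm(5)
  expect_equal(hinge(r, f),
               mean(pmax(0, 1 - r)) + mean(pmax(0, 1 + f)),
               tolerance = 1e-12)
})

test_that("translator GAN loss is the negated mean discriminator score", {
  b <- stubBundle()
  # override discriminators with constant-output stubs via direct scoring
  set.seed(2)
  zSt <- matrix(rnorm(5 * 8), 5, 8); zSc <- matrix(rnorm(7 * 8), 7, 8)
  g <- translatorGanLoss(b, zSt, zSc)
  mlpF <- core(".mlpForward")
  fakeSt <- mlpF(b@nets$transSc2St, zSc)$out
  fakeSc <- mlpF(b@nets$transSt2Sc, zSt)$out
  expected <- -mean(mlpF(b@nets$discSt, fakeSt)$out) -
    mean(mlpF(b@nets$discSc, fakeSc)$out)
  expect_equal(g, expected, tolerance = 1e-10)
})

test_that("cycle loss with identity translators equals pure AE reconstruction", {
  b <- stubBundle()
  set.seed(3)
  xSt <- matrix(runif(9 * 10), 9, 10)
  xSc <- matrix(runif(9 * 12), 9, 12)
  mlpF <- core(".mlpForward")
  aeSt <- mean((mlpF(b@nets$decSt, mlpF(b@nets$encSt, xSt)$out)$out - xSt)^2)
  aeSc <- mean((mlpF(b@nets$decSc, mlpF(b@nets$encSc, xSc)$out)$out - xSc)^2)
  expect_equal(cycleLoss(b, xSt, xSc), aeSt + aeSc, tolerance = 1e-10)
  expect_gte(cycleLoss(b, xSt, xSc), 0)
})

test_that("weighted total follows the published lambda defaults", {
  parts <- list(identity = 2, cycle = 3, ganTranslator = 10)
  expect_equal(totalTranslatorLoss(parts), 6)  # 1*2 + 1*3 + 0.1*10
  expect_equal(totalTranslatorLoss(list(identity = 0, cycle = 0,
                                        ganTranslator = 0)), 0)
  # linear scaling of a single weight
  w2 <- LossWeights(lambdaId = 2)
  expect_equal(totalTranslatorLoss(parts, w2) - totalTranslatorLoss(parts),
               parts$identity)
  lb <- lossBreakdown(cycle = 3, identity = 2, ganTranslator = 10)
  expect_equal(lb$totalTranslator, 6)
})

test_that("bundle-level losses are finite on finite inputs", {
  fx <- trainedFixture()
  b <- fx$bundle
  xSt <- exprValues(fx$pp@st)[1:15, b@stGenes, drop = FALSE]
  xSc <- exprValues(fx$pp@sc)[1:15, , drop = FALSE]
  sm <- buildSharedMap(new("ExpressionMatrix", values = xSt,
                           stage = "normalized"), fx$pp@sc)
  zSt <- encodeCells(b, xSt, "ST"); zSc <- encodeCells(b, xSc, "SC")
  vals <- c(cycleLoss(b, xSt, xSc),
            identityLoss(b, xSt, xSc, sm),
            translatorGanLoss(b, zSt, zSc),
            discriminatorHingeLoss(b, zSt, zSc))
  expect_true(all(is.finite(vals)))
  expect_gte(vals[4], 0)
  expect_true(vals[2] >= 0 && vals[2] <= 4)
})
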