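# Fold planning, leakage guards, aggregation and ablation mechanics.

test_that("141 shared genes split into folds of sizes 29/28/28/28/28", {
  genes <- paste0("g", 1:141)
  plan <- makeFoldPlan(genes, nFolds = 5, seed = 2)
  expect_setequal(lengths(foldGenes(plan)), c(29, 28, 28, 28, 28))
  expect_setequal(unlist(foldGenes(plan)), genes)
  expect_equal(anyDuplicated(unlist(foldGenes(plan))), 0)
})

test_that("fold plans are deterministic and handle the singleton edge", {
  genes <- paste0("g", 1:17)
  p1 <- makeFoldPlan(genes, 5, seed = 9)
  p2 <- makeFoldPlan(genes, 5, seed = 9)
  expect_identical(foldGenes(p1), foldGenes(p2))
  p3 <- makeFoldPlan(paste0("g", 1:5), 5, seed = 1)
  expect_true(all(lengths(foldGenes(p3)) == 1))
  expect_error(makeFoldPlan(paste0("g", 1:4), 5), "at least 5")
})

test_that("partitions stay disjoint, exhaustive and near-equal for many sizes", {
  for (n in c(5, 8, 23, 60, 141)) {
    plan <- makeFoldPlan(paste0("g", seq_len(n)), 5, seed = n)
    sz <- lengths(foldGenes(plan))
    expect_lte(diff(range(sz)), 1)
    expect_setequal(unlist(foldGenes(plan)), paste0("g", seq_len(n)))
  }
})

test_that("the leakage guard fires when a held-out gene reaches training", {
  fx <- trainedFixture()
  pp <- fx$pp
  held <- sharedNames(pp)[1:2]
  old <- setLeakageAudit(held)
  on.exit(setLeakageAudit(old))
  # ST matrix still containing a held-out gene must be refused
  expect_error(pretrainAutoencoders(fx$bundleInit, pp, fx$cfg),
               "leakage guard")
  expect_error(encodeCells(fx$bundle, pp@st, "ST"), "leakage guard")
  # SC-side data may legitimately contain held-out genes
  expect_silent(encodeCells(fx$bundle, pp@sc, "SC"))
})

test_that("one fold trains leak-free and reports exactly its own genes", {
  sim <- simulatePair(SimConfig(nStCells = 120, nScCells = 160,
                                nGenesTotal = 60, overlapFraction = 0.7,
                                latentRank = 3, seed = 13))
  pp <- preprocessPair(sim$data)
  cfg <- TrainingConfig(aeEpochs = 2, transEpochs = 2, batchSize = 48,
                        widthScale = 0.05, seed = 4)
  plan <- makeFoldPlan(sharedMap(pp), nFolds = 5, seed = 4)
  rep <- suppressWarnings(runFold(pp, plan, 2, cfg))
  held <- foldGenes(plan)[[2]]
  expect_setequal(perGeneMetrics(rep)$gene, held)
  b <- attr(rep, "bundle")
  # the fold's ST input width is the full panel minus the fold
  expect_equal(length(b@stGenes),
               ncol(exprValues(pp@st)) - length(held))
  expect_false(any(tolower(held) %in% tolower(b@stGenes)))
  # audit disarmed after the run
  expect_null(getOption("cycleImpute.auditGenes"))
})

test_that("aggregated CV covers each shared gene exactly once", {
  sim <- simulatePair(SimConfig(nStCells = 100, nScCells = 140,
                                nGenesTotal = 50, overlapFraction = 0.7,
                                latentRank = 3, seed = 17))
  pp <- preprocessPair(sim$data)
  cfg <- TrainingConfig(aeEpochs = 2, transEpochs = 2, batchSize = 48,
                        widthScale = 0.05, seed = 6)
  agg <- suppressWarnings(runCV(pp, cfg, nFolds = 5))
  pg <- perGeneMetrics(agg)
  expect_setequal(pg$gene, sharedNames(pp))
  expect_equal(anyDuplicated(pg$gene), 0)
  expect_equal(unname(metricAverages(agg)["pcc"]),
               mean(pg$pcc[is.finite(pg$pcc)]))
})

test_that("sparsity masking zeroes the requested nonzero count", {
  m <- tinyExpr(20, 10, seed = 3)
  nz0 <- sum(exprValues(m) != 0)
  for (f in c(0, 0.25, 0.5, 0.9)) {
    masked <- maskStEntries(m, f, seed = 5)
    expect_equal(sum(exprValues(masked) != 0), nz0 - round(f * nz0))
  }
  # masking only touches nonzero entries
  masked <- maskStEntries(m, 0.5, seed = 5)
  expect_true(all(exprValues(masked)[exprValues(m) == 0] == 0))
})

test_that("degenerate ablation settings reproduce the plain CV", {
  sim <- simulatePair(SimConfig(nStCells = 90, nScCells = 120,
                                nGenesTotal = 40, overlapFraction = 0.8,
                                latentRank = 3, seed = 19))
  pp <- preprocessPair(sim$data)
  cfg <- TrainingConfig(aeEpochs = 2, transEpochs = 2, batchSize = 48,
                        widthScale = 0.05, seed = 8)
  plain <- suppressWarnings(runCV(pp, cfg, nFolds = 5))
  ov <- suppressWarnings(ablateOverlap(pp, cfg, fractions = 1.0, nFolds = 5))
  expect_equal(ov$pcc, unname(metricAverages(plain)["pcc"]),
               tolerance = 1e-12)
  sp <- suppressWarnings(ablateSparsity(sim$data, cfg, fractions = 0,
                                        nFolds = 5))
  expect_equal(sp$pcc, unname(metricAverages(plain)["pcc"]),
               tolerance = 1e-12)
})

test_that("overlap fractions leaving too few genes are skipped with warning", {
  sim <- simulatePair(SimConfig(nStCells = 90, nScCells = 120,
                                nGenesTotal = 40, overlapFraction = 0.8,
                                latentRank = 3, seed = 19))
  pp <- preprocessPair(sim$data)
  cfg <- TrainingConfig(aeEpochs = 1, transEpochs = 1, batchSize = 48,
                        widthScale = 0.05, seed = 8)
  expect_warning(out <- ablateOverlap(pp, cfg, fractions = 0.05, nFolds = 5),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("the per-gene-mean baseline scores zero correlation by convention", {
  fx <- trainedFixture()
  base <- baselineMeanReport(fx$pp, sharedNames(fx$pp)[1:5])
  expect_equal(unname(metricAverages(base)["pcc"]), 0)
})
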