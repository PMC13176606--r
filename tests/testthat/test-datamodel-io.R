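# Expression I/O, shared-gene mapping, and artifact round trips.

test_that("CSV parsing yields the declared cells, genes and values", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2", "1,0", "2,3", "0,4"), p)
  m <- readExpression(p, "csv")
  expect_identical(geneNames(m), c("g1", "g2"))
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(procStage(m), "raw")
  expect_equal(exprValues(m)[2, ], c(g1 = 2, g2 = 3))
})

test_that("MTX densification preserves the stored nonzeros", {
  d <- withr::local_tempdir()
  m0 <- matrix(0, 4, 3, dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  m0[cbind(c(1, 2, 3, 4, 2), c(1, 2, 3, 1, 3))] <- c(5, 1, 2, 7, 4)
  writeExpression(ExpressionMatrix(m0), file.path(d, "x.mtx"), "mtx")
  m <- readExpression(file.path(d, "x.mtx"), "mtx")
  expect_equal(sum(exprValues(m) != 0), 5)
  expect_equal(exprValues(m), m0)
})

test_that("negative values are rejected at load time", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2", "1,0", "2,-1"), p)
  expect_error(readExpression(p, "csv"), "negative")
})

test_that("duplicate gene names keep the best-detected column with a warning", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gA,GA,gB", "1,0,1", "2,0,0", "0,5,2"), p)
  expect_warning(m <- readExpression(p, "csv"), "duplicate")
  expect_equal(ncol(exprValues(m)), 2)
  # first gA column has detection 2/3 vs 1/3: it wins
  expect_true("gA" %in% geneNames(m))
  expect_equal(unname(exprValues(m)[, "gA"]), c(1, 2, 0))
})

test_that("expression round-trips losslessly through all on-disk formats", {
  set.seed(10)
  for (fmt in c("csv", "tsv", "mtx", "h5ad")) {
    d <- withr::local_tempdir()
    v <- matrix(rpois(5 * 7, 2), 5, 7,
                dimnames = list(paste0("c", 1:5), paste0("g", 1:7)))
    m0 <- ExpressionMatrix(v)
    f <- file.path(d, paste0("x.", fmt))
    writeExpression(m0, f, fmt)
    m1 <- readExpression(f, fmt)
    expect_equal(exprValues(m1), v, info = fmt)
  }
})

test_that("h5ad coordinates survive a round trip", {
  skip_if_not_installed("rhdf5")
  d <- withr::local_tempdir()
  m <- tinyExpr(5, 3)
  xy <- matrix(runif(10), 5, 2)
  f <- file.path(d, "x.h5ad")
  writeExpression(m, f, "h5ad", coords = xy)
  m1 <- readExpression(f, "h5ad")
  expect_equal(unname(attr(m1, "coords")), unname(xy))
})

test_that("shared-gene mapping is case-insensitive, ST-ordered and symmetric", {
  st <- tinyExpr(4, 3); colnames(st@values) <- c("A", "B", "C")
  sc <- tinyExpr(4, 3, seed = 2); colnames(sc@values) <- c("b", "c", "D")
  sm <- buildSharedMap(st, sc)
  expect_identical(sharedNames(sm), c("B", "C"))
  expect_identical(sm@stIdx, c(2L, 3L))
  expect_identical(sm@scIdx, c(1L, 2L))
  # symmetry of content under swap
  sm2 <- buildSharedMap(sc, st)
  expect_setequal(tolower(sharedNames(sm2)), tolower(sharedNames(sm)))
  # two genes differing only by case still match
  st2 <- tinyExpr(4, 2); colnames(st2@values) <- c("a", "B")
  sc2 <- tinyExpr(4, 2, seed = 3); colnames(sc2@values) <- c("A", "b")
  expect_length(sharedNames(buildSharedMap(st2, sc2)), 2)
})

test_that("disjoint panels give an empty shared map plus a warning", {
  st <- tinyExpr(4, 2); colnames(st@values) <- c("x1", "x2")
  sc <- tinyExpr(4, 2, seed = 2); colnames(sc@values) <- c("y1", "y2")
  expect_warning(sm <- buildSharedMap(st, sc), "no shared genes")
  expect_length(sharedNames(sm), 0)
})

test_that("metric reports round-trip bit-exactly", {
  pg <- data.frame(gene = c("a", "b", "c"),
                   pcc = c(pi, 1 / 3, -0.1234567890123456),
                   ssim = runif(3), rmse = runif(3),
                   wasserstein = runif(3), js = runif(3),
                   stringsAsFactors = FALSE)
  avg <- vapply(pg[-1], mean, numeric(1))
  rep0 <- new("MetricReport", perGene = pg, averages = avg,
              diagnostics = list(note = "x", vals = c(exp(1), sqrt(2))))
  p <- withr::local_tempfile(fileext = ".json")
  writeReport(rep0, p)
  rep1 <- readReport(p)
  expect_identical(perGeneMetrics(rep1), pg)
  expect_identical(unname(metricAverages(rep1)), unname(avg))
  expect_identical(reportDiagnostics(rep1)$vals, c(exp(1), sqrt(2)))
})

test_that("model bundles round-trip with bit-identical weights", {
  b0 <- buildBundle(9, 11, seed = 4, widthScale = 0.02,
                    stGenes = paste0("s", 1:9), scGenes = paste0("r", 1:11))
  p <- withr::local_tempfile(fileext = ".json")
  writeModel(b0, p)
  b1 <- readModel(p)
  expect_identical(b1@nets$encSt$layers[[1]]$W, b0@nets$encSt$layers[[1]]$W)
  for (nm in names(b0@nets))
    expect_identical(b1@nets[[nm]]$layers, b0@nets[[nm]]$layers, info = nm)
  expect_identical(b1@stGenes, b0@stGenes)
  x <- matrix(runif(3 * 9), 3, 9)
  expect_identical(latentVectors(encodeCells(b1, x, "ST")),
                   latentVectors(encodeCells(b0, x, "ST")))
})

test_that("truncated artifacts raise format errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"per_gene": {"gene": ["a"]', p)  # truncated JSON
  expect_error(readReport(p), "malformed")
  writeLines('{"something": 1}', p)
  expect_error(readModel(p), "not a cycleImpute model")
})
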