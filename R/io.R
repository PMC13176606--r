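# Readers/writers for expression matrices, reports and model bundles.
#
# All numeric round trips are bit-exact: reports serialize doubles through
# "%.17g", model weights through base64-encoded IEEE-754 doubles.

.dedupGenes <- function(values) {
  # Duplicate gene names (case-insensitive): keep the column with the highest
  # detection rate, drop the rest, warn once per dropped column.
  key <- tolower(colnames(values))
  if (!anyDuplicated(key)) return(values)
  det <- colMeans(values != 0)
  keep <- rep(TRUE, ncol(values))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(det[idx])]
    drop <- setdiff(idx, best)
    keep[drop] <- FALSE
    warning(sprintf(
      "duplicate gene name '%s': kept column %d (detection %.3f), dropped %s",
      colnames(values)[best], best, det[best],
      paste(drop, collapse = ",")), call. = FALSE)
  }
  values[, keep, drop = FALSE]
}

#' Read an expression matrix from disk
#'
#' Supported dialects: dense CSV/TSV (cells as rows, header row of gene
#' names, optional leading cell-ID column), MatrixMarket MTX with sidecar
#' gene/cell name files, and h5ad-style HDF5 (expression in \code{/X},
#' gene/cell names in \code{var}/\code{obs}, coordinates under
#' \code{obsm/spatial}). Negative entries are rejected; duplicate gene names
#' are resolved by keeping the column with the highest detection rate.
#'
#' @param path file path.
#' @param format one of \code{"csv"}, \code{"tsv"}, \code{"mtx"},
#'   \code{"h5ad"}; guessed from the extension when missing.
#' @param genesFile,cellsFile sidecar name files for MTX (default
#'   \code{genes.txt} / \code{cells.txt} next to the matrix).
#' @param transpose set TRUE when an on-disk table is genes x cells.
#' @return An \linkS4class{ExpressionMatrix} at stage \code{"raw"}. For h5ad
#'   inputs with a spatial slot, the coordinate matrix is attached as
#'   attribute \code{"coords"}.
#' @export
readExpression <- function(path,
                           format = c("csv", "tsv", "mtx", "h5ad"),
                           genesFile = NULL, cellsFile = NULL,
                           transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx", h5ad = "h5ad", h5 = "h5ad",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  format <- match.arg(format)
  coords <- NULL
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(df) >= 1 && !is.numeric(df[[1]])) {
      ids <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
    } else ids <- paste0("cell", seq_len(nrow(df)))
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
      stop("non-numeric column(s) in ", path, ": ",
           paste(names(df)[bad], collapse = ", "))
    values <- as.matrix(df)
    rownames(values) <- ids
  } else if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    if (is.null(genesFile)) genesFile <- file.path(dirname(path), "genes.txt")
    if (is.null(cellsFile)) cellsFile <- file.path(dirname(path), "cells.txt")
    if (!file.exists(genesFile) || !file.exists(cellsFile))
      stop("MTX requires sidecar name files: ", genesFile, ", ", cellsFile)
    genes <- readLines(genesFile)
    cells <- readLines(cellsFile)
    values <- as.matrix(m)
    if (nrow(values) != length(cells) || ncol(values) != length(genes))
      stop(sprintf("MTX shape %dx%d does not match %d cells / %d genes",
                   nrow(values), ncol(values), length(cells), length(genes)))
    dimnames(values) <- list(cells, genes)
  } else { # h5ad
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("reading h5ad requires the rhdf5 package")
    values <- .readH5adX(path)
    coords <- attr(values, "coords")
    attr(values, "coords") <- NULL
  }
  if (transpose) values <- t(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("non-finite expression values in ", path)
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at cell %d, gene %d in %s",
                 idx[1], idx[2], path))
  }
  values <- .dedupGenes(values)
  m <- ExpressionMatrix(values, stage = "raw")
  if (!is.null(coords)) attr(m, "coords") <- coords
  m
}

.readH5adX <- function(path) {
  ls <- rhdf5::h5ls(path)
  readName <- function(group) {
    # AnnData index convention: attribute "_index" names the id column
    cands <- c(file.path(group, "_index"), file.path(group, "index"))
    for (cn in cands) {
      if (any(ls$group == group & file.path(group, ls$name) == cn))
        return(as.character(rhdf5::h5read(path, cn)))
    }
    NULL
  }
  xinfo <- ls[ls$name == "X" & ls$group == "/", , drop = FALSE]
  if (nrow(xinfo) == 0) stop("no /X entry in ", path)
  if (xinfo$otype == "H5I_GROUP") {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    attrs <- rhdf5::h5readAttributes(path, "X")
    shp <- as.integer(attrs$shape)
    enc <- if (!is.null(attrs$`encoding-type`)) attrs$`encoding-type`
           else "csr_matrix"
    if (grepl("csr", enc)) {
      sm <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                                 dims = c(shp[1], shp[2]))
    } else {
      sm <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                 dims = c(shp[1], shp[2]))
    }
    values <- as.matrix(sm)
  } else {
    values <- as.matrix(rhdf5::h5read(path, "X"))
    # HDF5 is row-major; rhdf5 returns dims reversed relative to AnnData
    values <- t(values)
  }
  cells <- readName("/obs")
  genes <- readName("/var")
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(values)))
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  dimnames(values) <- list(cells, genes)
  if (any(ls$group == "/obsm" & ls$name == "spatial")) {
    xy <- rhdf5::h5read(path, "obsm/spatial")
    xy <- if (nrow(values) %in% dim(xy) && dim(xy)[1] != nrow(values))
      t(xy) else as.matrix(xy)
    attr(values, "coords") <- xy
  }
  values
}

#' Write an expression matrix to disk
#'
#' Inverse of \code{\link{readExpression}} for the same three dialects.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @param format \code{"csv"}, \code{"tsv"}, \code{"mtx"} or \code{"h5ad"}.
#' @param coords optional ST coordinate matrix (stored for h5ad under
#'   \code{obsm/spatial}; ignored otherwise).
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(m, path, format = c("csv", "tsv", "mtx", "h5ad"),
                            coords = NULL) {
  format <- match.arg(format)
  v <- exprValues(m)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(v, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(colnames(v), file.path(dirname(path), "genes.txt"))
    writeLines(rownames(v), file.path(dirname(path), "cells.txt"))
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("writing h5ad requires the rhdf5 package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    # store transposed so that AnnData-convention readers see cells x genes
    rhdf5::h5write(t(v), path, "X")
    rhdf5::h5createGroup(path, "obs")
    rhdf5::h5write(rownames(v), path, "obs/_index")
    rhdf5::h5createGroup(path, "var")
    rhdf5::h5write(colnames(v), path, "var/_index")
    if (!is.null(coords) && nrow(coords)) {
      rhdf5::h5createGroup(path, "obsm")
      rhdf5::h5write(as.matrix(coords), path, "obsm/spatial")
    }
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Build the shared-gene map between an ST and an SC matrix
#'
#' Matching is case-insensitive exact string match on gene symbols (no
#' ortholog or alias resolution); the shared set is ordered by ST column
#' order. An empty intersection is permitted but signalled with a warning,
#' since translator training requires shared genes for the identity loss.
#'
#' @param st,sc \linkS4class{ExpressionMatrix} objects.
#' @return A \linkS4class{SharedGeneMap}.
#' @export
buildSharedMap <- function(st, sc) {
  stn <- geneNames(st); scn <- geneNames(sc)
  stKey <- tolower(stn); scKey <- tolower(scn)
  pos <- match(stKey, scKey)
  keep <- which(!is.na(pos))
  if (length(keep) == 0)
    warning("no shared genes between ST and SC panels; ",
            "training will fail at the identity loss", call. = FALSE)
  new("SharedGeneMap", sharedNames = stn[keep], stIdx = as.integer(keep),
      scIdx = as.integer(pos[keep]))
}

## ---- report serialization ------------------------------------------------

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a MetricReport
#'
#' The JSON file stores every double as a 17-significant-digit decimal
#' string, so \code{readReport(writeReport(x))} reproduces all numeric
#' fields bit-exactly.
#'
#' @param report a \linkS4class{MetricReport}.
#' @param path output (input) file path.
#' @return \code{writeReport}: \code{path} invisibly; \code{readReport}: the
#'   reconstructed \linkS4class{MetricReport}.
#' @export
writeReport <- function(report, path) {
  pg <- report@perGene
  obj <- list(
    per_gene = c(list(gene = as.character(pg$gene)),
                 lapply(pg[.METRIC_COLS], .fmt17)),
    averages = as.list(.fmt17(report@averages[.METRIC_COLS])),
    diagnostics = .encodeDiag(report@diagnostics))
  names(obj$averages) <- .METRIC_COLS
  txt <- jsonlite::toJSON(obj, auto_unbox = FALSE, null = "null")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to ", path)
  invisible(path)
}

.encodeDiag <- function(d) {
  rapply(d, how = "replace", f = function(x)
    if (is.double(x)) .fmt17(x) else x)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed report file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (!all(c("per_gene", "averages") %in% names(obj)))
    stop("not a metric report: ", path)
  pg <- data.frame(gene = as.character(obj$per_gene$gene),
                   stringsAsFactors = FALSE)
  for (cn in .METRIC_COLS) pg[[cn]] <- as.numeric(obj$per_gene[[cn]])
  avg <- vapply(obj$averages[.METRIC_COLS], as.numeric, numeric(1))
  diag <- rapply(as.list(obj$diagnostics), how = "replace", f = function(x) {
    y <- suppressWarnings(as.numeric(x))
    if (is.character(x) && !anyNA(y)) y else x
  })
  new("MetricReport", perGene = pg, averages = avg, diagnostics = diag)
}

## ---- model serialization -------------------------------------------------

.encodeArray <- function(a) {
  list(dim = dim(a) %||% length(a),
       data = jsonlite::base64_enc(writeBin(as.numeric(a), raw(),
                                            size = 8, endian = "little")))
}

.decodeArray <- function(e) {
  x <- readBin(jsonlite::base64_dec(e$data), what = "numeric", size = 8,
               n = prod(unlist(e$dim)), endian = "little")
  d <- unlist(e$dim)
  if (length(d) > 1) dim(x) <- d
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a ModelBundle
#'
#' A single JSON archive holding the training configuration and, per
#' network, every weight array base64-encoded as IEEE-754 doubles, making
#' the round trip bit-exact.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param path archive path.
#' @return \code{writeModel}: \code{path} invisibly; \code{readModel}: the
#'   reconstructed \linkS4class{ModelBundle}.
#' @export
writeModel <- function(bundle, path) {
  encNet <- function(net) {
    list(inDim = net$inDim, outDim = net$outDim, hidden = net$hidden,
         dropout = net$dropout, trainable = net$trainable,
         layers = lapply(net$layers, function(L)
           lapply(L[.LAYER_PARAMS[L$kind][[1]]], .encodeArray)),
         kinds = vapply(net$layers, `[[`, character(1), "kind"))
  }
  cfg <- bundle@config
  obj <- list(
    format = "cycleImpute-model-v1",
    config = list(aeEpochs = cfg@aeEpochs, transEpochs = cfg@transEpochs,
                  batchSize = cfg@batchSize, aeLr = cfg@aeLr,
                  transLr = cfg@transLr, discLr = cfg@discLr,
                  lambdaId = cfg@weights@lambdaId,
                  lambdaCyc = cfg@weights@lambdaCyc,
                  lambdaGan = cfg@weights@lambdaGan,
                  seed = cfg@seed, widthScale = cfg@widthScale),
    latentDims = bundle@latentDims,
    stGenes = bundle@stGenes, scGenes = bundle@scGenes,
    frozen = bundle@frozen,
    nets = lapply(bundle@nets, encNet))
  ok <- tryCatch({
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write model to ", path)
  invisible(path)
}

.LAYER_PARAMS <- list(
  hidden = c("W", "b", "gamma", "beta", "runMean", "runVar"),
  output = c("W", "b"))

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed model archive ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (!identical(obj$format, "cycleImpute-model-v1"))
    stop("not a cycleImpute model archive: ", path)
  decNet <- function(en) {
    layers <- mapply(function(L, kind) {
      c(list(kind = kind), lapply(L, .decodeArray))
    }, en$layers, unlist(en$kinds), SIMPLIFY = FALSE)
    list(inDim = en$inDim, outDim = en$outDim,
         hidden = as.integer(unlist(en$hidden)), dropout = en$dropout,
         trainable = en$trainable, layers = layers)
  }
  cfg <- obj$config
  config <- TrainingConfig(
    aeEpochs = cfg$aeEpochs, transEpochs = cfg$transEpochs,
    batchSize = cfg$batchSize, aeLr = cfg$aeLr, transLr = cfg$transLr,
    discLr = cfg$discLr,
    weights = LossWeights(cfg$lambdaId, cfg$lambdaCyc, cfg$lambdaGan),
    seed = cfg$seed, widthScale = cfg$widthScale)
  new("ModelBundle", nets = lapply(obj$nets, decNet), config = config,
      latentDims = lapply(obj$latentDims, as.numeric),
      stGenes = as.character(unlist(obj$stGenes)),
      scGenes = as.character(unlist(obj$scGenes)),
      frozen = isTRUE(obj$frozen))
}
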