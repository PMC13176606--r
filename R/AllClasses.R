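#' @import methods
NULL

.STAGES <- c("raw", "filtered", "clipped", "normalized")

#' ExpressionMatrix: a cells-by-genes expression matrix with a processing stage
#'
#' Rows are cells, columns are genes; all values are non-negative at every
#' processing stage (square-root normalization preserves sign). Gene names and
#' cell identifiers live in the matrix dimnames and are unique after loading.
#'
#' @slot values numeric matrix, cells x genes, non-negative, with unique
#'   rownames (cell IDs) and colnames (gene names).
#' @slot stage one of \code{"raw"}, \code{"filtered"}, \code{"clipped"},
#'   \code{"normalized"}.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(values = "matrix", stage = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (length(object@stage) != 1L || !object@stage %in% .STAGES)
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.STAGES, collapse = ", ")))
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry cell IDs (rownames) and gene names (colnames)")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate cell IDs")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate gene names")
  }
  if (is.numeric(v) && length(v) && any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  if (is.numeric(v) && length(v) && any(v < 0))
    msg <- c(msg, "negative expression values are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values cells x genes numeric matrix.
#' @param geneNames,cellIds optional dimension names; taken from the matrix
#'   dimnames when omitted, generated (\code{cell1...}, \code{g1...}) when
#'   absent there too.
#' @param stage processing stage flag (default \code{"raw"}).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, geneNames = NULL, cellIds = NULL,
                             stage = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(geneNames)) colnames(values) <- geneNames
  if (!is.null(cellIds)) rownames(values) <- cellIds
  if (is.null(colnames(values)))
    colnames(values) <- paste0("g", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  new("ExpressionMatrix", values = values, stage = stage)
}

#' SharedGeneMap: alignment of the genes common to an ST/SC pair
#'
#' Positions are 1-based column indices into the ST and SC matrices; entry i
#' of both index vectors points at the same gene under the case-insensitive
#' matching policy. Ordered by ST column order.
#'
#' @slot sharedNames shared gene names (ST spelling).
#' @slot stIdx,scIdx integer column positions into the ST / SC matrices.
#' @exportClass SharedGeneMap
setClass("SharedGeneMap",
  representation(sharedNames = "character", stIdx = "integer",
                 scIdx = "integer"))

setValidity("SharedGeneMap", function(object) {
  n <- length(object@sharedNames)
  msg <- character()
  if (length(object@stIdx) != n || length(object@scIdx) != n)
    msg <- c(msg, "sharedNames, stIdx, scIdx must have equal length")
  if (anyDuplicated(object@stIdx) || anyDuplicated(object@scIdx))
    msg <- c(msg, "duplicate indices in shared map")
  if (n && (any(object@stIdx < 1L) || any(object@scIdx < 1L)))
    msg <- c(msg, "indices must be positive")
  if (length(msg)) msg else TRUE
})

#' PairedDataset: an ST matrix with coordinates plus an SC reference
#'
#' @slot st ST \linkS4class{ExpressionMatrix}.
#' @slot stCoords numeric matrix of 2-D spatial coordinates, one row per ST
#'   cell (may have zero rows when coordinates are unavailable; coordinate
#'   dependent diagnostics are then disabled).
#' @slot sc SC reference \linkS4class{ExpressionMatrix}.
#' @slot shared \linkS4class{SharedGeneMap} aligning the common genes.
#' @exportClass PairedDataset
setClass("PairedDataset",
  representation(st = "ExpressionMatrix", stCoords = "matrix",
                 sc = "ExpressionMatrix", shared = "SharedGeneMap"))

setValidity("PairedDataset", function(object) {
  msg <- character()
  sm <- object@shared
  stv <- object@st@values; scv <- object@sc@values
  if (length(sm@sharedNames)) {
    if (max(sm@stIdx) > ncol(stv) || max(sm@scIdx) > ncol(scv))
      msg <- c(msg, "shared map indices out of range")
    else if (!all(tolower(colnames(stv)[sm@stIdx]) ==
                  tolower(colnames(scv)[sm@scIdx])))
      msg <- c(msg, "shared map misaligned: names at paired indices differ")
  }
  if (nrow(object@stCoords) > 0) {
    if (nrow(object@stCoords) != nrow(stv))
      msg <- c(msg, "coordinate rows must match ST cell count")
    if (ncol(object@stCoords) != 2L)
      msg <- c(msg, "coordinates must have 2 columns")
    if (any(!is.finite(object@stCoords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (object@st@stage != object@sc@stage)
    msg <- c(msg, "st and sc must be at the same processing stage")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedDataset
#'
#' @param st,sc \linkS4class{ExpressionMatrix} objects for the spatial and
#'   single-cell modalities.
#' @param stCoords 2-column matrix of ST coordinates or \code{NULL}.
#' @param shared optional \linkS4class{SharedGeneMap}; rebuilt with
#'   \code{\link{buildSharedMap}} when omitted.
#' @return A \linkS4class{PairedDataset}.
#' @export
PairedDataset <- function(st, sc, stCoords = NULL, shared = NULL) {
  if (is.null(stCoords)) stCoords <- matrix(numeric(0), 0, 2)
  stCoords <- as.matrix(stCoords)
  if (is.null(shared)) shared <- buildSharedMap(st, sc)
  new("PairedDataset", st = st, stCoords = stCoords, sc = sc,
      shared = shared)
}

#' Preprocessing thresholds
#'
#' Defaults follow the published pipeline: genes with detection rate < 0.05
#' and cells with detection rate < 0.1 are removed, 2000 highly variable
#' genes are kept for the SC reference, and per-feature values above the mean
#' plus 2 standard deviations are clipped before square-root normalization.
#'
#' @slot geneMinDetection,cellMinDetection detection-rate thresholds in [0,1].
#' @slot nHVG number of highly variable SC genes to keep.
#' @slot clipSD standard-deviation multiplier for outlier clipping.
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(geneMinDetection = "numeric", cellMinDetection = "numeric",
                 nHVG = "numeric", clipSD = "numeric"),
  prototype(geneMinDetection = 0.05, cellMinDetection = 0.1,
            nHVG = 2000, clipSD = 2.0))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  for (f in c("geneMinDetection", "cellMinDetection")) {
    x <- slot(object, f)
    if (length(x) != 1 || x < 0 || x > 1)
      msg <- c(msg, sprintf("%s must be a fraction in [0,1]", f))
  }
  if (object@nHVG < 1) msg <- c(msg, "nHVG must be >= 1")
  if (object@clipSD <= 0) msg <- c(msg, "clipSD must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PreprocessConfig-class
#' @param geneMinDetection,cellMinDetection,nHVG,clipSD see slots.
#' @return A \code{PreprocessConfig}.
#' @export
PreprocessConfig <- function(geneMinDetection = 0.05, cellMinDetection = 0.1,
                             nHVG = 2000, clipSD = 2.0) {
  new("PreprocessConfig", geneMinDetection = geneMinDetection,
      cellMinDetection = cellMinDetection, nHVG = nHVG, clipSD = clipSD)
}

#' Loss weights for the translator objective
#'
#' The translator loss is
#' \eqn{\lambda_{ID} L_{ID} + \lambda_{cyc} L_{cyc} + \lambda_{GAN} L_{GAN}}
#' with published defaults (1, 1, 0.1).
#'
#' @slot lambdaId,lambdaCyc,lambdaGan non-negative weights.
#' @exportClass LossWeights
setClass("LossWeights",
  representation(lambdaId = "numeric", lambdaCyc = "numeric",
                 lambdaGan = "numeric"),
  prototype(lambdaId = 1.0, lambdaCyc = 1.0, lambdaGan = 0.1))

setValidity("LossWeights", function(object) {
  if (object@lambdaId < 0 || object@lambdaCyc < 0 || object@lambdaGan < 0)
    "loss weights must be non-negative" else TRUE
})

#' @rdname LossWeights-class
#' @param lambdaId,lambdaCyc,lambdaGan see slots.
#' @return A \code{LossWeights}.
#' @export
LossWeights <- function(lambdaId = 1.0, lambdaCyc = 1.0, lambdaGan = 0.1) {
  new("LossWeights", lambdaId = lambdaId, lambdaCyc = lambdaCyc,
      lambdaGan = lambdaGan)
}

#' Training configuration
#'
#' Published defaults: 100 autoencoder epochs and 50 translator epochs with
#' Adam, batch size 512, learning rate 1e-3 for autoencoders and translators
#' and 5e-4 for the discriminators.
#'
#' @slot aeEpochs,transEpochs epoch counts for the two training stages.
#' @slot batchSize minibatch size (>= 2; batch statistics need 2 rows).
#' @slot aeLr,transLr,discLr Adam learning rates.
#' @slot weights \linkS4class{LossWeights}.
#' @slot seed master seed; fans out to weight init, samplers and dropout.
#' @slot widthScale multiplier on all hidden/latent widths (1 = published
#'   architecture); smaller values give faithful scaled-down models for
#'   desk-scale experiments.
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(aeEpochs = "numeric", transEpochs = "numeric",
                 batchSize = "numeric", aeLr = "numeric", transLr = "numeric",
                 discLr = "numeric", weights = "LossWeights",
                 seed = "numeric", widthScale = "numeric"),
  prototype(aeEpochs = 100, transEpochs = 50, batchSize = 512,
            aeLr = 1e-3, transLr = 1e-3, discLr = 5e-4,
            weights = new("LossWeights"), seed = 1, widthScale = 1))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@aeEpochs < 1 || object@transEpochs < 1)
    msg <- c(msg, "epoch counts must be >= 1")
  if (object@batchSize < 2) msg <- c(msg, "batchSize must be >= 2")
  if (object@aeLr <= 0 || object@transLr <= 0 || object@discLr <= 0)
    msg <- c(msg, "learning rates must be > 0")
  if (object@widthScale <= 0 || object@widthScale > 1)
    msg <- c(msg, "widthScale must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainingConfig-class
#' @param aeEpochs,transEpochs,batchSize,aeLr,transLr,discLr,weights,seed,widthScale
#'   see slots.
#' @return A \code{TrainingConfig}.
#' @export
TrainingConfig <- function(aeEpochs = 100, transEpochs = 50, batchSize = 512,
                           aeLr = 1e-3, transLr = 1e-3, discLr = 5e-4,
                           weights = LossWeights(), seed = 1,
                           widthScale = 1) {
  new("TrainingConfig", aeEpochs = aeEpochs, transEpochs = transEpochs,
      batchSize = batchSize, aeLr = aeLr, transLr = transLr,
      discLr = discLr, weights = weights, seed = seed,
      widthScale = widthScale)
}

#' ModelBundle: the eight trained networks plus their configuration
#'
#' Holds both domain autoencoders (encoder/decoder), the two latent-space
#' translators, and the two hinge-loss discriminators, together with the
#' gene panels seen at training time (used to validate imputation inputs).
#'
#' @slot nets named list of the eight networks (\code{encSt}, \code{decSt},
#'   \code{encSc}, \code{decSc}, \code{transSt2Sc}, \code{transSc2St},
#'   \code{discSt}, \code{discSc}).
#' @slot config the \linkS4class{TrainingConfig} that produced them.
#' @slot latentDims list with elements \code{st} and \code{sc}.
#' @slot stGenes,scGenes gene panels of the two input spaces.
#' @slot frozen TRUE once autoencoder weights are frozen for stage 2.
#' @exportClass ModelBundle
setClass("ModelBundle",
  representation(nets = "list", config = "TrainingConfig",
                 latentDims = "list", stGenes = "character",
                 scGenes = "character", frozen = "logical"))

.NET_NAMES <- c("encSt", "decSt", "encSc", "decSc",
                "transSt2Sc", "transSc2St", "discSt", "discSc")

setValidity("ModelBundle", function(object) {
  msg <- character()
  if (!all(.NET_NAMES %in% names(object@nets)))
    msg <- c(msg, "bundle must contain the eight named networks")
  else {
    dSt <- object@latentDims$st; dSc <- object@latentDims$sc
    ok <- object@nets$encSt$outDim == dSt &&
      object@nets$transSt2Sc$inDim == dSt &&
      object@nets$discSt$inDim == dSt &&
      object@nets$decSt$inDim == dSt &&
      object@nets$encSc$outDim == dSc &&
      object@nets$transSc2St$inDim == dSc &&
      object@nets$discSc$inDim == dSc &&
      object@nets$decSc$inDim == dSc &&
      object@nets$transSt2Sc$outDim == dSc &&
      object@nets$transSc2St$outDim == dSt
    if (!ok) msg <- c(msg, "latent dimensions inconsistent across networks")
  }
  if (length(msg)) msg else TRUE
})

#' LatentEmbedding: per-cell latent vectors with domain and provenance tags
#'
#' @slot vectors cells x latent-dim matrix.
#' @slot domain \code{"ST"} or \code{"SC"} (the space the vectors live in).
#' @slot provenance \code{"encoded"}, \code{"translated"} or \code{"cycled"}.
#' @exportClass LatentEmbedding
setClass("LatentEmbedding",
  representation(vectors = "matrix", domain = "character",
                 provenance = "character"))

setValidity("LatentEmbedding", function(object) {
  msg <- character()
  if (!object@domain %in% c("ST", "SC")) msg <- c(msg, "domain must be ST or SC")
  if (!object@provenance %in% c("encoded", "translated", "cycled"))
    msg <- c(msg, "provenance must be encoded/translated/cycled")
  if (length(msg)) msg else TRUE
})

#' FoldPlan: partition of the shared genes for gene-holdout cross-validation
#'
#' @slot folds list of disjoint held-out gene-name sets whose union is the
#'   shared gene set; fold sizes differ by at most one.
#' @slot seed seed that produced the shuffle.
#' @exportClass FoldPlan
setClass("FoldPlan", representation(folds = "list", seed = "numeric"))

setValidity("FoldPlan", function(object) {
  all_genes <- unlist(object@folds)
  if (anyDuplicated(all_genes)) return("folds are not disjoint")
  sizes <- lengths(object@folds)
  if (length(sizes) && diff(range(sizes)) > 1)
    return("fold sizes must differ by at most 1")
  TRUE
})

#' MetricReport: per-gene evaluation metrics with averages and diagnostics
#'
#' @slot perGene data.frame keyed by \code{gene} with columns \code{pcc},
#'   \code{ssim}, \code{rmse}, \code{wasserstein}, \code{js}.
#' @slot averages named numeric vector: arithmetic means of the finite
#'   per-gene entries for the five metrics.
#' @slot diagnostics list; may hold \code{deltaMoransSummary},
#'   \code{neighborhoodRecall}, \code{clusteringScores},
#'   \code{excludedGenes}.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(perGene = "data.frame", averages = "numeric",
                 diagnostics = "list"))

.METRIC_COLS <- c("pcc", "ssim", "rmse", "wasserstein", "js")

setValidity("MetricReport", function(object) {
  msg <- character()
  if (!all(c("gene", .METRIC_COLS) %in% names(object@perGene)))
    msg <- c(msg, "perGene must have columns gene, pcc, ssim, rmse, wasserstein, js")
  else if (nrow(object@perGene)) {
    avg <- vapply(.METRIC_COLS, function(cn) {
      x <- object@perGene[[cn]]; mean(x[is.finite(x)])
    }, numeric(1))
    if (any(abs(avg - object@averages[.METRIC_COLS]) > 1e-8, na.rm = TRUE))
      msg <- c(msg, "averages must equal the per-gene column means")
  }
  if (length(msg)) msg else TRUE
})

#' Summary of the spatial-autocorrelation shift of imputed genes
#'
#' Per-gene difference in Moran's I between imputed and measured expression,
#' a diagnostic for spurious spatial-pattern inflation.
#'
#' @slot perGene named numeric vector of \eqn{\Delta I} values.
#' @slot median,mean summary statistics of the shift.
#' @slot fractionWithin fraction of genes with \eqn{|\Delta I| \le} tolerance.
#' @slot tolerance band half-width (default 0.10).
#' @exportClass MoranShiftSummary
setClass("MoranShiftSummary",
  representation(perGene = "numeric", median = "numeric", mean = "numeric",
                 fractionWithin = "numeric", tolerance = "numeric"))

#' Latent-space neighborhood recall
#'
#' Fraction of each cell's k nearest neighbors (cosine distance, source
#' latent space) recovered among the m nearest neighbors of its translated
#' or cycle-translated embedding.
#'
#' @slot perCell per-cell recall fractions in [0,1].
#' @slot mean arithmetic mean recall.
#' @slot k,m neighborhood sizes (defaults 15 and 45).
#' @slot mode \code{"one_way"} or \code{"cycle"}.
#' @exportClass NeighborhoodRecallResult
setClass("NeighborhoodRecallResult",
  representation(perCell = "numeric", mean = "numeric", k = "numeric",
                 m = "numeric", mode = "character"))

#' Synthetic-data configuration
#'
#' Parameters of the paired ST/SC simulator: a shared low-rank latent
#' program drives both modalities, ST factors vary smoothly over 2-D space,
#' and each modality adds its own noise (dropout, Poisson sampling,
#' library-size jitter).
#'
#' @slot nStCells,nScCells,nGenesTotal counts.
#' @slot overlapFraction fraction of ST panel genes also present in SC.
#' @slot latentRank rank of the shared factor model.
#' @slot spatialSmoothness Gaussian-kernel length scale of ST factors (in
#'   units of the unit-square coordinate frame).
#' @slot stDropout,scDropout per-entry zeroing probabilities.
#' @slot noiseSd log-scale multiplicative noise SD added to the means.
#' @slot librarySizeCv coefficient of variation of per-cell library size.
#' @slot seed RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nStCells = "numeric", nScCells = "numeric",
                 nGenesTotal = "numeric", overlapFraction = "numeric",
                 latentRank = "numeric", spatialSmoothness = "numeric",
                 stDropout = "numeric", scDropout = "numeric",
                 noiseSd = "numeric", librarySizeCv = "numeric",
                 seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nStCells < 1 || object@nScCells < 1 || object@nGenesTotal < 1)
    msg <- c(msg, "counts must be >= 1")
  for (f in c("overlapFraction", "stDropout", "scDropout")) {
    x <- slot(object, f)
    if (x < 0 || x > 1) msg <- c(msg, sprintf("%s must be in [0,1]", f))
  }
  if (object@latentRank > object@nGenesTotal)
    msg <- c(msg, "latentRank must be <= nGenesTotal")
  if (object@latentRank < 1) msg <- c(msg, "latentRank must be >= 1")
  if (object@spatialSmoothness <= 0) msg <- c(msg, "spatialSmoothness must be > 0")
  if (object@noiseSd < 0 || object@librarySizeCv < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nStCells,nScCells,nGenesTotal,overlapFraction,latentRank,spatialSmoothness,stDropout,scDropout,noiseSd,librarySizeCv,seed
#'   see slots.
#' @return A \code{SimConfig}.
#' @export
SimConfig <- function(nStCells = 2000, nScCells = 3000, nGenesTotal = 300,
                      overlapFraction = 0.6, latentRank = 8,
                      spatialSmoothness = 0.2, stDropout = 0.1,
                      scDropout = 0.3, noiseSd = 0.1, librarySizeCv = 0.2,
                      seed = 1) {
  new("SimConfig", nStCells = nStCells, nScCells = nScCells,
      nGenesTotal = nGenesTotal, overlapFraction = overlapFraction,
      latentRank = latentRank, spatialSmoothness = spatialSmoothness,
      stDropout = stDropout, scDropout = scDropout, noiseSd = noiseSd,
      librarySizeCv = librarySizeCv, seed = seed)
}
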