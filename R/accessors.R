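# Accessors and show methods for the core classes.

#' @rdname ExpressionMatrix
#' @param object an object.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname ExpressionMatrix
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname ExpressionMatrix
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))
#' @rdname ExpressionMatrix
#' @export
setMethod("geneNames", "ExpressionMatrix",
          function(object) colnames(object@values))

#' @rdname ExpressionMatrix
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @rdname ExpressionMatrix
#' @export
setMethod("cellIds", "ExpressionMatrix",
          function(object) rownames(object@values))

#' @rdname ExpressionMatrix
#' @export
setGeneric("procStage", function(object) standardGeneric("procStage"))
#' @rdname ExpressionMatrix
#' @export
setMethod("procStage", "ExpressionMatrix", function(object) object@stage)

setMethod("show", "ExpressionMatrix", function(object) {
  v <- object@values
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [stage: %s]\n",
              nrow(v), ncol(v), object@stage))
  nz <- if (length(v)) mean(v != 0) else NA_real_
  cat(sprintf("  nonzero fraction: %.3f\n", nz))
})

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' @rdname SharedGeneMap-class
#' @param object an object.
#' @export
setGeneric("sharedNames", function(object) standardGeneric("sharedNames"))
#' @rdname SharedGeneMap-class
#' @export
setMethod("sharedNames", "SharedGeneMap", function(object) object@sharedNames)
#' @rdname SharedGeneMap-class
#' @export
setMethod("sharedNames", "PairedDataset",
          function(object) object@shared@sharedNames)

setMethod("show", "SharedGeneMap", function(object) {
  cat(sprintf("SharedGeneMap: %d shared genes\n", length(object@sharedNames)))
})

#' @rdname PairedDataset
#' @param object an object.
#' @export
setGeneric("stMatrix", function(object) standardGeneric("stMatrix"))
#' @rdname PairedDataset
#' @export
setMethod("stMatrix", "PairedDataset", function(object) object@st)

#' @rdname PairedDataset
#' @export
setGeneric("scMatrix", function(object) standardGeneric("scMatrix"))
#' @rdname PairedDataset
#' @export
setMethod("scMatrix", "PairedDataset", function(object) object@sc)

#' @rdname PairedDataset
#' @export
setGeneric("stCoordinates", function(object) standardGeneric("stCoordinates"))
#' @rdname PairedDataset
#' @export
setMethod("stCoordinates", "PairedDataset", function(object) object@stCoords)

#' @rdname PairedDataset
#' @export
setGeneric("sharedMap", function(object) standardGeneric("sharedMap"))
#' @rdname PairedDataset
#' @export
setMethod("sharedMap", "PairedDataset", function(object) object@shared)

setMethod("show", "PairedDataset", function(object) {
  cat("PairedDataset\n  ST: ")
  show(object@st)
  cat("  SC: ")
  show(object@sc)
  cat(sprintf("  shared genes: %d; coordinates: %s\n",
              length(object@shared@sharedNames),
              if (nrow(object@stCoords)) "yes" else "absent"))
})

#' @rdname LatentEmbedding-class
#' @param object an object.
#' @export
setGeneric("latentVectors", function(object) standardGeneric("latentVectors"))
#' @rdname LatentEmbedding-class
#' @export
setMethod("latentVectors", "LatentEmbedding", function(object) object@vectors)

#' @rdname LatentEmbedding-class
#' @export
setGeneric("latentDomain", function(object) standardGeneric("latentDomain"))
#' @rdname LatentEmbedding-class
#' @export
setMethod("latentDomain", "LatentEmbedding", function(object) object@domain)

#' @rdname LatentEmbedding-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname LatentEmbedding-class
#' @export
setMethod("provenance", "LatentEmbedding", function(object) object@provenance)

setMethod("show", "LatentEmbedding", function(object) {
  cat(sprintf("LatentEmbedding: %d cells x %d dims [%s space, %s]\n",
              nrow(object@vectors), ncol(object@vectors), object@domain,
              object@provenance))
})

#' @rdname FoldPlan-class
#' @param object an object.
#' @export
setGeneric("foldGenes", function(object) standardGeneric("foldGenes"))
#' @rdname FoldPlan-class
#' @export
setMethod("foldGenes", "FoldPlan", function(object) object@folds)

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds, sizes %s (seed %s)\n",
              length(object@folds),
              paste(lengths(object@folds), collapse = "/"),
              format(object@seed)))
})

#' @rdname MetricReport-class
#' @param object an object.
#' @export
setGeneric("perGeneMetrics", function(object) standardGeneric("perGeneMetrics"))
#' @rdname MetricReport-class
#' @export
setMethod("perGeneMetrics", "MetricReport", function(object) object@perGene)

#' @rdname MetricReport-class
#' @export
setGeneric("metricAverages", function(object) standardGeneric("metricAverages"))
#' @rdname MetricReport-class
#' @export
setMethod("metricAverages", "MetricReport", function(object) object@averages)

#' @rdname MetricReport-class
#' @export
setGeneric("reportDiagnostics",
           function(object) standardGeneric("reportDiagnostics"))
#' @rdname MetricReport-class
#' @export
setMethod("reportDiagnostics", "MetricReport",
          function(object) object@diagnostics)

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d genes\n", nrow(object@perGene)))
  if (length(object@averages)) {
    a <- object@averages
    cat(sprintf("  mean PCC %.3f | SSIM %.3f | RMSE %.3f | W %.3f | JS %.3f\n",
                a["pcc"], a["ssim"], a["rmse"], a["wasserstein"], a["js"]))
  }
})

setMethod("show", "MoranShiftSummary", function(object) {
  cat(sprintf(
    "MoranShiftSummary: %d genes; median dI %.4f, mean %.4f, %.1f%% within +/-%.2f\n",
    length(object@perGene), object@median, object@mean,
    100 * object@fractionWithin, object@tolerance))
})

setMethod("show", "NeighborhoodRecallResult", function(object) {
  cat(sprintf("NeighborhoodRecall (%s, k=%d, m=%d): mean %.3f over %d cells\n",
              object@mode, object@k, object@m, object@mean,
              length(object@perCell)))
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf(
    "ModelBundle: ST %d genes -> latent %d | SC %d genes -> latent %d [%s]\n",
    length(object@stGenes), object@latentDims$st,
    length(object@scGenes), object@latentDims$sc,
    if (object@frozen) "autoencoders frozen" else "autoencoders trainable"))
})
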