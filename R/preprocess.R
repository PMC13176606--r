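# The four-step preprocessing pipeline: detection-rate filtering (genes then
# cells), dispersion-based HVG selection for the SC reference, per-feature
# outlier clipping at mean + k*SD, and square-root normalization.

#' Filter genes by detection rate
#'
#' The detection rate of a gene is the fraction of cells in which it is
#' nonzero. Genes with rate strictly below the threshold are dropped
#' (default 0.05); column order of survivors is preserved.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param threshold detection-rate cutoff in [0,1].
#' @return Filtered \linkS4class{ExpressionMatrix} (stage \code{"filtered"}).
#' @export
filterGenes <- function(m, threshold = 0.05) {
  v <- exprValues(m)
  if (ncol(v) == 0) stop("empty matrix")
  rate <- colMeans(v != 0)
  keep <- rate >= threshold
  if (!any(keep))
    stop("all genes fall below detection rate ", threshold,
         "; relax the threshold")
  new("ExpressionMatrix", values = v[, keep, drop = FALSE],
      stage = "filtered")
}

#' Filter cells by detection rate
#'
#' The detection rate of a cell is the fraction of genes nonzero within that
#' cell; cells with rate strictly below the threshold (default 0.1) are
#' removed, preserving order. ST coordinate rows are removed in lockstep by
#' \code{\link{preprocessPair}}.
#'
#' @inheritParams filterGenes
#' @return Filtered \linkS4class{ExpressionMatrix}.
#' @export
filterCells <- function(m, threshold = 0.1) {
  v <- exprValues(m)
  if (nrow(v) == 0) stop("empty matrix")
  rate <- rowMeans(v != 0)
  keep <- rate >= threshold
  if (!any(keep))
    stop("all cells fall below detection rate ", threshold,
         "; relax the threshold")
  new("ExpressionMatrix", values = v[keep, , drop = FALSE],
      stage = "filtered")
}

.dispersion <- function(v) {
  # dispersion (var/mean) of log1p values; deterministic HVG ranking with
  # ties broken by gene name order
  lv <- log1p(v)
  mu <- colMeans(lv)
  s2 <- colMeans(lv^2) - mu^2
  ifelse(mu > 0, s2 / mu, 0)
}

#' Select highly variable genes for the SC reference
#'
#' Keeps the union of the top-n genes by dispersion of log1p-transformed
#' values and all shared genes: shared genes are force-retained because the
#' identity loss needs them in the SC feature space. When n is at least the
#' gene count, all genes are kept. Gene order is preserved.
#'
#' @param sc SC \linkS4class{ExpressionMatrix}.
#' @param n number of HVGs (default 2000).
#' @param shared optional \linkS4class{SharedGeneMap}; its SC-side genes are
#'   always retained.
#' @return The reduced \linkS4class{ExpressionMatrix}.
#' @export
selectHVG <- function(sc, n = 2000, shared = NULL) {
  v <- exprValues(sc)
  if (n >= ncol(v)) return(sc)
  disp <- .dispersion(v)
  ord <- order(-disp, colnames(v))
  keep <- rep(FALSE, ncol(v))
  keep[ord[seq_len(n)]] <- TRUE
  if (!is.null(shared) && length(shared@scIdx)) keep[shared@scIdx] <- TRUE
  new("ExpressionMatrix", values = v[, keep, drop = FALSE],
      stage = sc@stage)
}

#' Clip per-feature outliers
#'
#' Every entry above \eqn{\mu_g + k \sigma_g} (population standard
#' deviation, computed across cells on the current values) is replaced by
#' that cap; entries at or below it are untouched. A constant feature has
#' \eqn{\sigma = 0} and is unchanged.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param k SD multiplier (default 2).
#' @return Clipped \linkS4class{ExpressionMatrix} (stage \code{"clipped"}).
#' @export
clipOutliers <- function(m, k = 2.0) {
  v <- exprValues(m)
  mu <- colMeans(v)
  sd <- sqrt(pmax(colMeans(v^2) - mu^2, 0))
  cap <- mu + k * sd
  capM <- matrix(cap, nrow(v), ncol(v), byrow = TRUE)
  v <- pmin(v, capM)
  new("ExpressionMatrix", values = v, stage = "clipped")
}

#' Square-root normalization
#'
#' Replaces every entry by its square root, a mild variance-stabilizing
#' transformation for skewed non-negative expression values.
#'
#' @param m an \linkS4class{ExpressionMatrix} (non-negative by construction).
#' @return Normalized matrix (stage \code{"normalized"}).
#' @export
sqrtNormalize <- function(m) {
  v <- exprValues(m)
  if (any(v < 0)) stop("negative values cannot be sqrt-normalized")
  new("ExpressionMatrix", values = sqrt(v), stage = "normalized")
}

#' Run the full preprocessing pipeline on a paired dataset
#'
#' Applies, in order: gene filtering (both modalities), cell filtering
#' (both; ST coordinates subset in lockstep), HVG selection (SC only, with
#' shared genes force-retained), outlier clipping (both, statistics on
#' pre-sqrt values), square-root normalization (both). The shared gene map
#' is rebuilt after every gene-set change. A second application is not
#' idempotent (clipping statistics change after sqrt) but is well-defined.
#'
#' @param p a \linkS4class{PairedDataset} with both matrices at stage
#'   \code{"raw"}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return The preprocessed \linkS4class{PairedDataset} (stage
#'   \code{"normalized"}).
#' @export
preprocessPair <- function(p, cfg = PreprocessConfig()) {
  st <- filterGenes(p@st, cfg@geneMinDetection)
  sc <- filterGenes(p@sc, cfg@geneMinDetection)

  stCells <- cellIds(st)
  st <- filterCells(st, cfg@cellMinDetection)
  sc <- filterCells(sc, cfg@cellMinDetection)
  coords <- p@stCoords
  if (nrow(coords)) {
    keep <- match(cellIds(st), stCells)
    coords <- coords[keep, , drop = FALSE]
  }

  shared <- buildSharedMap(st, sc)
  sc <- selectHVG(sc, cfg@nHVG, shared)
  shared <- buildSharedMap(st, sc)

  st <- clipOutliers(st, cfg@clipSD)
  sc <- clipOutliers(sc, cfg@clipSD)
  st <- sqrtNormalize(st)
  sc <- sqrtNormalize(sc)

  new("PairedDataset", st = st, stCoords = coords, sc = sc,
      shared = buildSharedMap(st, sc))
}
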