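# Evaluation metrics for imputed gene expression: per-gene PCC, SSIM,
# z-scored RMSE, 1-D Wasserstein on z-scores, Jensen-Shannon divergence;
# Moran's I and its imputed-minus-measured shift; latent neighborhood
# recall; ARI/NMI/silhouette; precision-recall AUC utility.
#
# Conventions (applied consistently): population standard deviations; a
# constant vector has PCC and SSIM 0 (flagged, never NaN); JS uses base-2
# logarithms so it lives in [0,1].

.checkPair <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted vectors differ in length")
  if (length(measured) < 2) stop("need at least 2 cells")
}

#' Per-gene Pearson correlation
#'
#' \eqn{Cov(x, \hat x) / (\sigma_x \sigma_{\hat x})} across cells; a
#' zero-variance vector yields 0 by convention.
#'
#' @param measured,predicted per-cell expression vectors of one gene, in
#'   the same cell order.
#' @return Correlation in [-1, 1].
#' @export
pcc <- function(measured, predicted) {
  .checkPair(measured, predicted)
  n <- length(measured)
  mx <- mean(measured); my <- mean(predicted)
  sx <- sqrt(mean(measured^2) - mx^2)
  sy <- sqrt(mean(predicted^2) - my^2)
  if (sx == 0 || sy == 0) return(0)
  (mean(measured * predicted) - mx * my) / (sx * sy)
}

.minmax <- function(x) {
  r <- max(x) - min(x)
  if (r == 0) rep(0, length(x)) else (x - min(x)) / r
}

#' Structural similarity of two expression vectors
#'
#' Both vectors are min-max normalized independently (a constant vector
#' maps to all zeros), then
#' \deqn{SSIM = \frac{(2\mu\hat\mu + C_1)(2 Cov + C_2)}
#'                   {(\mu^2 + \hat\mu^2 + C_1)(\sigma^2 + \hat\sigma^2 + C_2)}}
#' with \eqn{C_1 = 0.01}, \eqn{C_2 = 0.03}, population moments.
#'
#' @inheritParams pcc
#' @return SSIM value (1 for identical non-constant vectors).
#' @export
ssim <- function(measured, predicted) {
  .checkPair(measured, predicted)
  C1 <- 0.01; C2 <- 0.03
  x <- .minmax(measured); y <- .minmax(predicted)
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
  cxy <- mean(x * y) - mx * my
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

.zscore <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean(x^2) - mu^2)
  if (s < 1e-12) rep(0, length(x)) else (x - mu) / s
}

#' Root-mean-square error on z-scored vectors
#'
#' Both vectors are z-scored independently (population SD with an epsilon
#' guard: a constant vector maps to zeros) before the RMS difference, so
#' the metric is invariant to independent affine rescaling and measures how
#' well cell-to-cell variation is recovered.
#'
#' @inheritParams pcc
#' @return Non-negative RMSE.
#' @export
rmseZ <- function(measured, predicted) {
  .checkPair(measured, predicted)
  sqrt(mean((.zscore(measured) - .zscore(predicted))^2))
}

#' 1-D Wasserstein distance between z-scored expression distributions
#'
#' The integrated absolute difference of the two empirical CDFs; for two
#' equal-length samples this equals the mean absolute difference of the
#' sorted z-scores.
#'
#' @inheritParams pcc
#' @return Non-negative distance.
#' @export
wassersteinZ <- function(measured, predicted) {
  .checkPair(measured, predicted)
  mean(abs(sort(.zscore(measured)) - sort(.zscore(predicted))))
}

#' Jensen-Shannon divergence between expression distributions across cells
#'
#' Each vector is normalized to a probability distribution over cells;
#' with mixture \eqn{m = (p + \hat p)/2},
#' \eqn{JS = \frac12 KL(\hat p \| m) + \frac12 KL(p \| m)} under base-2
#' logarithms (so JS is in [0,1]), with \eqn{0 \log(0/\cdot) = 0}. Vectors
#' containing negatives are first shifted by the global minimum of the
#' pair; a zero-sum vector returns the maximal value 1 with a warning.
#'
#' @inheritParams pcc
#' @return Divergence in [0, 1].
#' @export
jsDivergence <- function(measured, predicted) {
  .checkPair(measured, predicted)
  lo <- min(measured, predicted)
  if (lo < 0) { measured <- measured - lo; predicted <- predicted - lo }
  sx <- sum(measured); sy <- sum(predicted)
  if (sx <= 0 || sy <= 0) {
    warning("zero-sum vector in jsDivergence; returning maximal divergence 1")
    return(1)
  }
  p <- measured / sx
  q <- predicted / sy
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(q, m) + 0.5 * kl(p, m)
}

# row-standardized k-nearest-neighbor weight matrix (Euclidean coordinates);
# ties broken by index order for determinism
.knnWeights <- function(coords, k) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    W[i, nb] <- 1 / k
  }
  W
}

#' Moran's I spatial autocorrelation
#'
#' Classical Moran's I with row-standardized k-nearest-neighbor weights
#' (default k = 6) over Euclidean coordinates: whether nearby cells carry
#' similar values. A constant vector returns 0 by convention.
#'
#' @param values per-cell numeric vector.
#' @param coords 2-column coordinate matrix, rows aligned with
#'   \code{values}.
#' @param k number of neighbors (needs at least k+1 cells).
#' @return Moran's I statistic.
#' @export
moransI <- function(values, coords, k = 6) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (nrow(coords) != n) stop("coordinate rows must match value length")
  if (n < k + 1) stop("need at least k+1 cells for Moran's I")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) return(0)
  W <- .knnWeights(coords, k)
  # row-standardized: sum of weights = n, so the n/S0 prefactor is 1
  sum(z * (W %*% z)) / denom
}

#' Spatial-autocorrelation shift of imputed genes
#'
#' Per gene, \eqn{\Delta I = I(\mathrm{imputed}) - I(\mathrm{measured})};
#' reports the median and mean shift and the fraction of genes within
#' \eqn{|\Delta I| \le} \code{tolerance} (default 0.10). A diagnostic for
#' spurious spatial-pattern inflation in imputed expression.
#'
#' @param measured,imputed cells x genes matrices with aligned columns.
#' @param coords ST coordinate matrix.
#' @param genes optional subset of column names to summarize.
#' @param k neighbors for \code{\link{moransI}}.
#' @param tolerance band half-width.
#' @return A \linkS4class{MoranShiftSummary}.
#' @export
moranShiftSummary <- function(measured, imputed, coords, genes = NULL,
                              k = 6, tolerance = 0.10) {
  if (is.null(genes)) genes <- colnames(measured)
  genes <- intersect(genes, intersect(colnames(measured), colnames(imputed)))
  if (!length(genes)) stop("no genes to summarize")
  dI <- vapply(genes, function(g)
    moransI(imputed[, g], coords, k) - moransI(measured[, g], coords, k),
    numeric(1))
  new("MoranShiftSummary", perGene = dI, median = stats::median(dI),
      mean = mean(dI), fractionWithin = mean(abs(dI) <= tolerance),
      tolerance = tolerance)
}

# cosine k-nearest-neighbor lists (self excluded), deterministic ties
.cosineNeighbors <- function(M, k) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(M / nrm)
  diag(S) <- -Inf
  t(apply(S, 1, function(s) order(-s)[seq_len(k)]))
}

#' Latent-space neighborhood recall
#'
#' For each cell, the fraction of its k nearest neighbors (cosine distance)
#' in the original latent space that are found among the m nearest
#' neighbors of its translated (or cycle-translated) embedding. Defaults
#' k = 15, m = 45: the wider recovery window tolerates small rank changes
#' while still probing local structure preservation.
#'
#' @param original,mapped \linkS4class{LatentEmbedding}s (or matrices) with
#'   equal row counts; \code{mapped} is the translated or cycled embedding
#'   of the same cells.
#' @param k,m neighborhood sizes, k < m < number of cells.
#' @param mode label recorded in the result (\code{"one_way"} or
#'   \code{"cycle"}); inferred from \code{mapped}'s provenance when
#'   available.
#' @return A \linkS4class{NeighborhoodRecallResult}.
#' @export
neighborhoodRecall <- function(original, mapped, k = 15, m = 45,
                               mode = NULL) {
  if (is.null(mode))
    mode <- if (is(mapped, "LatentEmbedding") &&
                provenance(mapped) == "cycled") "cycle" else "one_way"
  A <- if (is(original, "LatentEmbedding")) latentVectors(original)
       else as.matrix(original)
  B <- if (is(mapped, "LatentEmbedding")) latentVectors(mapped)
       else as.matrix(mapped)
  if (nrow(A) != nrow(B)) stop("row counts differ")
  n <- nrow(A)
  if (n <= m) stop("need more cells than m")
  if (k >= m) stop("k must be < m")
  nbA <- .cosineNeighbors(A, k)
  nbB <- .cosineNeighbors(B, m)
  recall <- vapply(seq_len(n), function(i)
    length(intersect(nbA[i, ], nbB[i, ])) / k, numeric(1))
  new("NeighborhoodRecallResult", perCell = recall, mean = mean(recall),
      k = k, m = m, mode = mode)
}

.entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Clustering agreement and separation scores
#'
#' ARI by pair counting over the contingency table, NMI as
#' \eqn{2 MI / (H(Y) + H(\hat Y))} (natural logs cancel), and the
#' silhouette coefficient as the mean over clusters of the per-cluster mean
#' of \eqn{(b-a)/\max(a,b)} with Euclidean distances on the embedding.
#'
#' @param labelsTrue,labelsPred equal-length label vectors.
#' @param embedding optional cells x dims matrix for the silhouette; when
#'   absent the silhouette is NA.
#' @return Named list \code{ari}, \code{nmi}, \code{silhouette}.
#' @export
clusteringScores <- function(labelsTrue, labelsPred, embedding = NULL) {
  if (length(labelsTrue) != length(labelsPred))
    stop("label vectors differ in length")
  n <- length(labelsTrue)
  tab <- table(labelsPred, labelsTrue)
  comb2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(tab |> colSums()))
  expected <- a * b / comb2(n)
  maxIdx <- (a + b) / 2
  ari <- if (maxIdx == expected) 1 else (sumIj - expected) / (maxIdx - expected)

  hT <- .entropy(colSums(tab)); hP <- .entropy(rowSums(tab))
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + (nij / n) * log(nij * n / (rowSums(tab)[i] * colSums(tab)[j]))
  }
  nmi <- if (hT + hP == 0) 1 else unname(2 * mi / (hT + hP))

  sil <- NA_real_
  if (!is.null(embedding)) {
    labs <- as.character(labelsPred)
    cl <- unique(labs)
    if (length(cl) < 2) stop("silhouette undefined for a single cluster")
    D <- as.matrix(stats::dist(embedding))
    s <- vapply(seq_len(n), function(i) {
      own <- labs == labs[i]
      nOwn <- sum(own) - 1
      ai <- if (nOwn > 0) sum(D[i, own]) / nOwn else 0
      bi <- min(vapply(setdiff(cl, labs[i]), function(cc)
        mean(D[i, labs == cc]), numeric(1)))
      if (nOwn == 0) 0 else (bi - ai) / max(ai, bi)
    }, numeric(1))
    # cluster-balanced mean: average the per-cluster means
    sil <- mean(vapply(cl, function(cc) mean(s[labs == cc]), numeric(1)))
  }
  list(ari = ari, nmi = nmi, silhouette = sil)
}

#' Area under the precision-recall curve
#'
#' Threshold-free recovery score against an externally supplied reference
#' set (e.g. spatially variable genes called on measured data): genes are
#' ranked by \code{scores} and AUPRC is computed by step-wise summation.
#'
#' @param scores numeric ranking scores (higher = more confident).
#' @param labels logical (or 0/1) reference membership, same length.
#' @return AUPRC in [0, 1].
#' @export
prAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!any(labels)) stop("reference set is empty")
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Evaluate imputation against measured expression
#'
#' Computes the five per-gene metrics (PCC, SSIM, z-RMSE, Wasserstein, JS)
#' on the training-supervision scale (sqrt-normalized values) for the named
#' held-out genes, plus their arithmetic means. Genes whose measured vector
#' is all zeros are excluded and listed under
#' \code{diagnostics$excludedGenes}.
#'
#' @param measured,imputed cells x genes matrices with aligned cells;
#'   columns are matched by (case-insensitive) gene name.
#' @param genes gene names to evaluate (default: all shared columns).
#' @return A \linkS4class{MetricReport}.
#' @export
evaluateImputation <- function(measured, imputed, genes = NULL) {
  mcol <- colnames(measured); icol <- colnames(imputed)
  if (is.null(genes)) genes <- mcol[tolower(mcol) %in% tolower(icol)]
  mIdx <- match(tolower(genes), tolower(mcol))
  iIdx <- match(tolower(genes), tolower(icol))
  if (anyNA(mIdx) || anyNA(iIdx))
    stop("genes absent from measured/imputed matrices: ",
         paste(genes[is.na(mIdx) | is.na(iIdx)], collapse = ", "))
  excluded <- genes[colSums(measured[, mIdx, drop = FALSE] != 0) == 0]
  keep <- setdiff(genes, excluded)
  if (!length(keep)) stop("no evaluable genes (all measured vectors zero)")
  rows <- lapply(keep, function(g) {
    x <- measured[, mIdx[match(g, genes)]]
    y <- imputed[, iIdx[match(g, genes)]]
    data.frame(gene = g, pcc = pcc(x, y), ssim = ssim(x, y),
               rmse = rmseZ(x, y), wasserstein = wassersteinZ(x, y),
               js = jsDivergence(x, y), stringsAsFactors = FALSE)
  })
  pg <- do.call(rbind, rows)
  avg <- vapply(.METRIC_COLS, function(cn) {
    v <- pg[[cn]]; mean(v[is.finite(v)])
  }, numeric(1))
  new("MetricReport", perGene = pg, averages = avg,
      diagnostics = list(excludedGenes = excluded))
}
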