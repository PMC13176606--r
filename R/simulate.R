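# Paired ST/SC simulator: a shared low-rank latent program drives both
# modalities through an exponential link; SC cells draw factors i.i.d.,
# ST cells draw them from a spatially smooth Gaussian-process approximation
# (random Fourier features) over random 2-D coordinates. Counts are Poisson
# draws of the scaled means with modality-specific dropout and
# multiplicative library-size jitter.

#' Simulate a paired ST/SC dataset with known ground truth
#'
#' The gene panel splits into an ST panel (half the genes) of which
#' \code{overlapFraction} are shared with the SC panel; the SC panel holds
#' everything except the ST-only genes, so SC-only genes exist as
#' imputation targets. Deterministic given \code{cfg@seed}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param meanScale multiplier on all expression means (1 keeps desk-scale
#'   count depths; larger values emulate deeply sequenced cells where
#'   Poisson noise is negligible).
#' @return List with \code{data} (a raw \linkS4class{PairedDataset}) and
#'   \code{truth} (latent factors, loadings, noiseless means, panels).
#' @export
simulatePair <- function(cfg = SimConfig(), meanScale = 1) {
  methods::validObject(cfg)
  set.seed(as.integer(cfg@seed))
  G <- cfg@nGenesTotal
  R <- cfg@latentRank
  genes <- paste0("gene", seq_len(G))

  # loadings: unit-norm-ish rows, clipped so the exponential link stays tame
  L <- matrix(stats::rnorm(G * R, sd = 1 / sqrt(R)), G, R)
  L <- pmin(pmax(L, -3 / sqrt(R)), 3 / sqrt(R))
  intercepts <- stats::rnorm(G, mean = log(8), sd = 0.7)

  # SC factors i.i.d.; ST factors from a random-Fourier-feature GP draw
  Fsc <- matrix(stats::rnorm(cfg@nScCells * R), cfg@nScCells, R)
  coords <- matrix(stats::runif(cfg@nStCells * 2), cfg@nStCells, 2)
  D <- 64L
  omega <- matrix(stats::rnorm(D * 2, sd = 1 / cfg@spatialSmoothness), D, 2)
  phi <- stats::runif(D, 0, 2 * pi)
  Phi <- sqrt(2 / D) * cos(coords %*% t(omega) +
                             matrix(phi, cfg@nStCells, D, byrow = TRUE))
  Fst <- Phi %*% matrix(stats::rnorm(D * R), D, R)
  Fst <- scale(Fst)[, , drop = FALSE]  # unit-variance smooth factors
  attr(Fst, "scaled:center") <- NULL; attr(Fst, "scaled:scale") <- NULL

  meanFor <- function(F) {
    M <- exp(.rowsAdd(F %*% t(L), intercepts)) * meanScale
    colnames(M) <- genes
    M
  }
  meanSt <- meanFor(Fst)
  meanSc <- meanFor(Fsc)
  rownames(meanSt) <- paste0("stcell", seq_len(cfg@nStCells))
  rownames(meanSc) <- paste0("sccell", seq_len(cfg@nScCells))

  # gene panels
  stPanelSize <- max(2L, floor(G / 2))
  stPanel <- sort(sample.int(G, stPanelSize))
  nShared <- round(cfg@overlapFraction * stPanelSize)
  sharedIdx <- sort(sample(stPanel, nShared))
  stOnly <- setdiff(stPanel, sharedIdx)
  scPanel <- sort(setdiff(seq_len(G), stOnly))

  observe <- function(meanMat, panel, dropout, nCells, prefix) {
    M <- meanMat[, panel, drop = FALSE]
    if (cfg@noiseSd > 0)
      M <- M * exp(matrix(stats::rnorm(length(M), sd = cfg@noiseSd) -
                            cfg@noiseSd^2 / 2, nrow(M), ncol(M)))
    if (cfg@librarySizeCv > 0) {
      s2 <- log(1 + cfg@librarySizeCv^2)
      lib <- stats::rlnorm(nCells, meanlog = -s2 / 2, sdlog = sqrt(s2))
      M <- M * lib
    }
    counts <- matrix(stats::rpois(length(M), M), nrow(M), ncol(M))
    if (dropout > 0)
      counts[matrix(stats::runif(length(counts)) < dropout,
                    nrow(counts), ncol(counts))] <- 0
    dimnames(counts) <- list(paste0(prefix, seq_len(nCells)),
                             genes[panel])
    counts
  }
  stCounts <- observe(meanSt, stPanel, cfg@stDropout, cfg@nStCells, "stcell")
  scCounts <- observe(meanSc, scPanel, cfg@scDropout, cfg@nScCells, "sccell")

  st <- ExpressionMatrix(stCounts, stage = "raw")
  sc <- ExpressionMatrix(scCounts, stage = "raw")
  rownames(coords) <- rownames(stCounts)
  data <- new("PairedDataset", st = st, stCoords = coords, sc = sc,
              shared = buildSharedMap(st, sc))
  truth <- list(factorsSt = Fst, factorsSc = Fsc, loadings = L,
                intercepts = intercepts, coords = coords,
                noiselessSt = meanSt, noiselessSc = meanSc,
                stPanel = genes[stPanel], scPanel = genes[scPanel],
                sharedGenes = genes[sharedIdx], config = cfg)
  list(data = data, truth = truth)
}

#' Benign study conditions for the simulator
#'
#' 2000 ST cells, 3000 SC cells, 300 genes, 60\% ST-panel overlap, a rank-8
#' shared latent program and mild modality noise: the regime in which
#' imputation is expected to clearly beat the per-gene-mean baseline.
#'
#' @param seed RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @export
easyRegime <- function(seed = 1) {
  SimConfig(nStCells = 2000, nScCells = 3000, nGenesTotal = 300,
            overlapFraction = 0.6, latentRank = 8, spatialSmoothness = 0.2,
            stDropout = 0.1, scDropout = 0.3, noiseSd = 0.1,
            librarySizeCv = 0.2, seed = seed)
}

#' Degraded study conditions
#'
#' Same scale as \code{\link{easyRegime}} but only 10\% shared-gene overlap
#' and heavy (0.7) dropout in both modalities: the regime where performance
#' is expected to fall.
#'
#' @param seed RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @export
hardRegime <- function(seed = 1) {
  SimConfig(nStCells = 2000, nScCells = 3000, nGenesTotal = 300,
            overlapFraction = 0.1, latentRank = 8, spatialSmoothness = 0.2,
            stDropout = 0.7, scDropout = 0.7, noiseSd = 0.1,
            librarySizeCv = 0.2, seed = seed)
}

#' Noiseless ST-side expression for held-out genes
#'
#' Returns the simulator's noiseless ST-cell means for the requested genes,
#' enabling oracle-grade recovery scoring beyond the noisy measured values.
#'
#' @param sim the \code{truth} element returned by
#'   \code{\link{simulatePair}}.
#' @param foldGenes gene names within the simulated ST panel.
#' @return Numeric matrix, ST cells x fold genes.
#' @export
groundTruthHeldout <- function(sim, foldGenes) {
  unknown <- setdiff(foldGenes, sim$stPanel)
  if (length(unknown))
    stop("genes not in the simulated ST panel: ",
         paste(unknown, collapse = ", "))
  sim$noiselessSt[, foldGenes, drop = FALSE]
}
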