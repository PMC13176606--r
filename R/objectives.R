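# Training objectives: reconstruction MSE, cycle loss, shared-gene Pearson
# identity loss, translator adversarial loss, discriminator hinge loss, and
# their weighted combination. Each has a pure array-level core (used both by
# the training loop with hand-derived gradients and by the test oracles) and
# an evaluation-mode bundle-level wrapper.

#' Mean-squared-error reconstruction loss
#'
#' Mean of squared elementwise differences over all entries.
#'
#' @param x,xHat numeric arrays of identical shape.
#' @return A single non-negative real.
#' @export
reconstructionLoss <- function(x, xHat) {
  if (!identical(dim(x), dim(xHat)) && length(x) != length(xHat))
    stop("shape mismatch in reconstructionLoss")
  mean((x - xHat)^2)
}

# per-cell Pearson between rows of `decoded` and rows of `target`
# (restricted columns already applied). Zero-variance rows contribute
# rho = 0 with zero gradient. Returns loss = 1 - mean(rho) and, when
# grad=TRUE, dLoss/dDecoded.
.identityCorrCore <- function(decoded, target, grad = FALSE) {
  n <- nrow(decoded)
  uc <- decoded - rowMeans(decoded)
  vc <- target - rowMeans(target)
  su2 <- rowSums(uc^2)
  sv2 <- rowSums(vc^2)
  ok <- su2 > 0 & sv2 > 0
  denom <- sqrt(su2 * sv2)
  rho <- ifelse(ok, rowSums(uc * vc) / ifelse(ok, denom, 1), 0)
  out <- list(loss = 1 - mean(rho), rho = rho)
  if (grad) {
    g <- matrix(0, n, ncol(decoded))
    if (any(ok)) {
      gi <- (vc / denom - (rho / su2) * uc)
      gi[!ok, ] <- 0
      g <- -gi / n
    }
    out$grad <- g
  }
  out
}

#' Shared-gene identity loss
#'
#' For each direction, translated latents are decoded in the target domain
#' and compared with the source cell's expression restricted to the shared
#' gene columns via per-cell Pearson correlation \eqn{\rho}, averaged over
#' cells; the loss is \eqn{(1-\rho_{ST \to SC}) + (1-\rho_{SC \to ST})}.
#' Only shared output columns carry gradient; a cell with a zero-variance
#' shared vector contributes \eqn{\rho = 0} (loss 1) rather than NaN.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param xSt,xSc normalized expression matrices (cells x genes) of the two
#'   domains.
#' @param shared a \linkS4class{SharedGeneMap} indexing into the columns of
#'   \code{xSt} / \code{xSc}.
#' @param perGene use the per-gene-across-cells Pearson orientation instead
#'   of the default per-cell orientation (sensitivity switch).
#' @return A single real in [0, 4].
#' @export
identityLoss <- function(bundle, xSt, xSc, shared, perGene = FALSE) {
  if (length(shared@sharedNames) == 0)
    stop("identity loss requires shared genes")
  z12 <- .mlpForward(bundle@nets$transSt2Sc,
                     .mlpForward(bundle@nets$encSt, xSt)$out)$out
  z21 <- .mlpForward(bundle@nets$transSc2St,
                     .mlpForward(bundle@nets$encSc, xSc)$out)$out
  decSc <- .mlpForward(bundle@nets$decSc, z12)$out
  decSt <- .mlpForward(bundle@nets$decSt, z21)$out
  a <- decSc[, shared@scIdx, drop = FALSE]
  b <- xSt[, shared@stIdx, drop = FALSE]
  cc <- decSt[, shared@stIdx, drop = FALSE]
  d <- xSc[, shared@scIdx, drop = FALSE]
  if (perGene) { a <- t(a); b <- t(b); cc <- t(cc); d <- t(d) }
  .identityCorrCore(a, b)$loss + .identityCorrCore(cc, d)$loss
}

#' Cycle-consistency loss
#'
#' Encodes each domain, translates to the other latent space and back, and
#' decodes in the source domain; returns the sum of the two MSEs between the
#' cycle reconstruction and the original expression.
#'
#' @inheritParams identityLoss
#' @return A single non-negative real.
#' @export
cycleLoss <- function(bundle, xSt, xSc) {
  zSt <- .mlpForward(bundle@nets$encSt, xSt)$out
  zSc <- .mlpForward(bundle@nets$encSc, xSc)$out
  xStCyc <- .mlpForward(bundle@nets$decSt,
    .mlpForward(bundle@nets$transSc2St,
      .mlpForward(bundle@nets$transSt2Sc, zSt)$out)$out)$out
  xScCyc <- .mlpForward(bundle@nets$decSc,
    .mlpForward(bundle@nets$transSt2Sc,
      .mlpForward(bundle@nets$transSc2St, zSc)$out)$out)$out
  reconstructionLoss(xStCyc, xSt) + reconstructionLoss(xScCyc, xSc)
}

# pure hinge core over raw scores for one domain:
# mean(max(0, 1-real)) + mean(max(0, 1+fake))
.hingeCore <- function(real, fake) {
  mean(pmax(0, 1 - real)) + mean(pmax(0, 1 + fake))
}

#' Discriminator hinge loss
#'
#' Sum over both domains of
#' \eqn{E[\max(0, 1 - C(z_{real}))] + E[\max(0, 1 + C(z_{fake}))]},
#' where the fake embeddings are translator outputs treated as constants
#' (no gradient flows into the translators from this loss).
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param zSt,zSc real encoded \linkS4class{LatentEmbedding}s (or bare
#'   matrices) of the two domains.
#' @return A single non-negative real.
#' @export
discriminatorHingeLoss <- function(bundle, zSt, zSc) {
  zStv <- if (is(zSt, "LatentEmbedding")) latentVectors(zSt) else zSt
  zScv <- if (is(zSc, "LatentEmbedding")) latentVectors(zSc) else zSc
  fakeSt <- .mlpForward(bundle@nets$transSc2St, zScv)$out
  fakeSc <- .mlpForward(bundle@nets$transSt2Sc, zStv)$out
  realStScore <- drop(.mlpForward(bundle@nets$discSt, zStv)$out)
  fakeStScore <- drop(.mlpForward(bundle@nets$discSt, fakeSt)$out)
  realScScore <- drop(.mlpForward(bundle@nets$discSc, zScv)$out)
  fakeScScore <- drop(.mlpForward(bundle@nets$discSc, fakeSc)$out)
  .hingeCore(realStScore, fakeStScore) + .hingeCore(realScScore, fakeScScore)
}

#' Translator adversarial loss
#'
#' \eqn{-E[C_{ST}(T_{SC \to ST}(z_{SC}))] - E[C_{SC}(T_{ST \to SC}(z_{ST}))]}:
#' the translators are rewarded when the discriminators score their outputs
#' highly.
#'
#' @inheritParams discriminatorHingeLoss
#' @return A single real (unbounded).
#' @export
translatorGanLoss <- function(bundle, zSt, zSc) {
  zStv <- if (is(zSt, "LatentEmbedding")) latentVectors(zSt) else zSt
  zScv <- if (is(zSc, "LatentEmbedding")) latentVectors(zSc) else zSc
  fakeSt <- .mlpForward(bundle@nets$transSc2St, zScv)$out
  fakeSc <- .mlpForward(bundle@nets$transSt2Sc, zStv)$out
  -mean(.mlpForward(bundle@nets$discSt, fakeSt)$out) -
    mean(.mlpForward(bundle@nets$discSc, fakeSc)$out)
}

#' Weighted total translator loss
#'
#' \eqn{\lambda_{ID} L_{ID} + \lambda_{cyc} L_{cyc} + \lambda_{GAN} L_{GAN}}
#' with published defaults \eqn{\lambda_{ID} = 1, \lambda_{cyc} = 1,
#' \lambda_{GAN} = 0.1}.
#'
#' @param parts named list (or \code{lossBreakdown()}) with elements
#'   \code{identity}, \code{cycle}, \code{ganTranslator}.
#' @param weights a \linkS4class{LossWeights}.
#' @return The weighted sum.
#' @export
totalTranslatorLoss <- function(parts, weights = LossWeights()) {
  weights@lambdaId * parts$identity + weights@lambdaCyc * parts$cycle +
    weights@lambdaGan * parts$ganTranslator
}

#' Assemble a loss breakdown record
#'
#' @param reconSt,reconSc,cycle,identity,ganTranslator,hingeDiscriminator
#'   individual loss terms.
#' @param weights a \linkS4class{LossWeights} used to fill
#'   \code{totalTranslator}.
#' @return Named list with all terms plus \code{totalTranslator}.
#' @export
lossBreakdown <- function(reconSt = NA_real_, reconSc = NA_real_,
                          cycle = NA_real_, identity = NA_real_,
                          ganTranslator = NA_real_,
                          hingeDiscriminator = NA_real_,
                          weights = LossWeights()) {
  parts <- list(reconSt = reconSt, reconSc = reconSc, cycle = cycle,
                identity = identity, ganTranslator = ganTranslator,
                hingeDiscriminator = hingeDiscriminator)
  parts$totalTranslator <- totalTranslatorLoss(parts, weights)
  parts
}
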