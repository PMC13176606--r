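# The eight networks: two encoder-decoder pairs, two latent translators,
# two discriminators, with the published layer widths.

.ENC_HIDDEN <- c(2048, 1024, 512)
.DEC_HIDDEN <- c(512, 1024, 2048)
.T_ST2SC_HIDDEN <- c(512, 512, 512, 1024, 1024)
.T_SC2ST_HIDDEN <- c(512, 256, 256, 128, 128)
.DISC_HIDDEN <- c(256, 128, 128, 64)
.LATENT_ST <- 256
.LATENT_SC <- 512

#' Build the eight-network model bundle
#'
#' Instantiates the published architecture: both encoders use hidden layers
#' (2048, 1024, 512) mapping to latent dimension 256 (ST) / 512 (SC);
#' decoders mirror them with (512, 1024, 2048); the ST-to-SC translator uses
#' hidden layers (512, 512, 512, 1024, 1024), the SC-to-ST translator
#' (512, 256, 256, 128, 128); both discriminators use (256, 128, 128, 64)
#' and emit one unbounded score per cell. Every hidden layer is linear ->
#' batch norm -> LeakyReLU(0.01) -> dropout(0.2); output layers are linear.
#' Weights are drawn fan-in-scaled uniform from the seed, so the same seed
#' gives bit-identical initial weights.
#'
#' @param stInDim,scInDim input gene counts of the two domains.
#' @param seed RNG seed for weight initialization.
#' @param widthScale optional multiplier (0,1] applied to every hidden and
#'   latent width, for faithful scaled-down models in desk-scale
#'   experiments; 1 reproduces the published architecture.
#' @param stGenes,scGenes optional gene panels recorded for input
#'   validation at imputation time.
#' @param config optional \linkS4class{TrainingConfig} stored with the
#'   bundle.
#' @return A \linkS4class{ModelBundle}.
#' @export
buildBundle <- function(stInDim, scInDim, seed = 1, widthScale = 1,
                        stGenes = character(), scGenes = character(),
                        config = NULL) {
  stopifnot(stInDim >= 1, scInDim >= 1)
  if (is.null(config))
    config <- TrainingConfig(seed = seed, widthScale = widthScale)
  ws <- function(d) pmax(1L, as.integer(round(d * widthScale)))
  dSt <- ws(.LATENT_ST); dSc <- ws(.LATENT_SC)
  set.seed(as.integer(seed))
  nets <- list(
    encSt = .mlpNew(stInDim, ws(.ENC_HIDDEN), dSt),
    decSt = .mlpNew(dSt, ws(.DEC_HIDDEN), stInDim),
    encSc = .mlpNew(scInDim, ws(.ENC_HIDDEN), dSc),
    decSc = .mlpNew(dSc, ws(.DEC_HIDDEN), scInDim),
    transSt2Sc = .mlpNew(dSt, ws(.T_ST2SC_HIDDEN), dSc),
    transSc2St = .mlpNew(dSc, ws(.T_SC2ST_HIDDEN), dSt),
    discSt = .mlpNew(dSt, ws(.DISC_HIDDEN), 1L),
    discSc = .mlpNew(dSc, ws(.DISC_HIDDEN), 1L))
  new("ModelBundle", nets = nets, config = config,
      latentDims = list(st = dSt, sc = dSc),
      stGenes = stGenes, scGenes = scGenes, frozen = FALSE)
}

#' Learnable parameter counts of the eight networks
#'
#' Counts weights, biases and batch-norm scale/shift parameters per network.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @return Named numeric vector of parameter counts.
#' @export
parameterCounts <- function(bundle) {
  vapply(bundle@nets, .mlpParamCount, numeric(1))
}

.domainNet <- function(bundle, domain, role) {
  domain <- match.arg(domain, c("ST", "SC"))
  key <- paste0(role, if (domain == "ST") "St" else "Sc")
  bundle@nets[[key]]
}

#' Encode expression into a domain's latent space
#'
#' Evaluation-mode forward pass (dropout off, running batch-norm
#' statistics), hence a deterministic pure function of weights and input;
#' single-cell batches are valid.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param x an \linkS4class{ExpressionMatrix} at stage \code{"normalized"}
#'   (or a bare numeric matrix on the training scale).
#' @param domain \code{"ST"} or \code{"SC"}.
#' @return A \linkS4class{LatentEmbedding} with provenance
#'   \code{"encoded"}.
#' @export
encodeCells <- function(bundle, x, domain = c("ST", "SC")) {
  domain <- match.arg(domain)
  if (is(x, "ExpressionMatrix")) {
    if (procStage(x) != "normalized")
      stop("expression must be at stage 'normalized' before encoding")
    if (domain == "ST") .auditCheck(geneNames(x), "encodeCells")
    x <- exprValues(x)
  }
  net <- .domainNet(bundle, domain, "enc")
  if (ncol(x) != net$inDim)
    stop(sprintf("input has %d genes but the %s encoder expects %d",
                 ncol(x), domain, net$inDim))
  z <- .mlpForward(net, x, train = FALSE)$out
  rownames(z) <- rownames(x)
  new("LatentEmbedding", vectors = z, domain = domain,
      provenance = "encoded")
}

#' Decode latent vectors back to expression
#'
#' Evaluation-mode decoder forward pass; outputs are floored at zero (the
#' clamp is applied only at inference, never inside loss computation, so
#' that gradients are not zeroed during training).
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param z a \linkS4class{LatentEmbedding} (or bare matrix).
#' @param domain decoder domain, \code{"ST"} or \code{"SC"}.
#' @return Numeric matrix, cells x genes of the chosen domain.
#' @export
decodeLatent <- function(bundle, z, domain = c("ST", "SC")) {
  domain <- match.arg(domain)
  zv <- if (is(z, "LatentEmbedding")) latentVectors(z) else z
  net <- .domainNet(bundle, domain, "dec")
  if (ncol(zv) != net$inDim)
    stop(sprintf("latent has %d dims but the %s decoder expects %d",
                 ncol(zv), domain, net$inDim))
  out <- pmax(.mlpForward(net, zv, train = FALSE)$out, 0)
  rownames(out) <- rownames(zv)
  genes <- if (domain == "ST") bundle@stGenes else bundle@scGenes
  if (length(genes) == ncol(out)) colnames(out) <- genes
  out
}

#' Translate a latent embedding into the other domain's latent space
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param z a \linkS4class{LatentEmbedding} whose domain must match the
#'   translator's source side.
#' @param direction \code{"ST2SC"} or \code{"SC2ST"}.
#' @return A \linkS4class{LatentEmbedding} in the target domain with
#'   provenance \code{"translated"} (or \code{"cycled"} when the input was
#'   already translated, i.e. after a round trip).
#' @export
translateLatent <- function(bundle, z, direction = c("ST2SC", "SC2ST")) {
  direction <- match.arg(direction)
  src <- if (direction == "ST2SC") "ST" else "SC"
  dst <- if (direction == "ST2SC") "SC" else "ST"
  if (latentDomain(z) != src)
    stop(sprintf("translator %s expects a %s-space embedding, got %s",
                 direction, src, latentDomain(z)))
  net <- if (direction == "ST2SC") bundle@nets$transSt2Sc
         else bundle@nets$transSc2St
  out <- .mlpForward(net, latentVectors(z), train = FALSE)$out
  rownames(out) <- rownames(latentVectors(z))
  prov <- if (provenance(z) %in% c("translated", "cycled")) "cycled"
          else "translated"
  new("LatentEmbedding", vectors = out, domain = dst, provenance = prov)
}

#' Score latent vectors with a domain discriminator
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param z a \linkS4class{LatentEmbedding} living in \code{domain}'s latent
#'   space (real or translated).
#' @param domain which discriminator to apply.
#' @return Numeric vector of unbounded real scores, one per cell.
#' @export
discriminateLatent <- function(bundle, z, domain = c("ST", "SC")) {
  domain <- match.arg(domain)
  if (latentDomain(z) != domain)
    stop(sprintf("discriminator %s expects %s-space embeddings, got %s",
                 domain, domain, latentDomain(z)))
  net <- .domainNet(bundle, domain, "disc")
  drop(.mlpForward(net, latentVectors(z), train = FALSE)$out)
}
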