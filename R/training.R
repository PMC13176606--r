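# Two-stage training: independent autoencoder pretraining, then
# frozen-autoencoder adversarial translator training, plus imputation.

.checkTrainInput <- function(data) {
  if (procStage(data@st) != "normalized" ||
      procStage(data@sc) != "normalized")
    stop("dataset must be preprocessed (stage 'normalized') before training")
}

#' Pretrain the two autoencoders (stage 1)
#'
#' Each domain's encoder-decoder pair is trained independently on its own
#' reconstruction MSE with Adam; the ST autoencoder never sees SC data and
#' vice versa. One epoch makes \eqn{\lceil \max(n_{ST}, n_{SC}) / B \rceil}
#' steps over independently shuffled samplers, recycling the smaller
#' domain; trailing batches of size 1 are dropped (batch statistics are
#' undefined on a single row).
#'
#' @param bundle a freshly built \linkS4class{ModelBundle} whose input
#'   dimensions match the data.
#' @param data a preprocessed \linkS4class{PairedDataset}.
#' @param cfg a \linkS4class{TrainingConfig}.
#' @return List with elements \code{bundle} (updated networks) and
#'   \code{trace} (per-epoch data.frame of reconstruction losses).
#' @export
pretrainAutoencoders <- function(bundle, data, cfg = TrainingConfig()) {
  .checkTrainInput(data)
  .auditCheck(geneNames(data@st), "pretrainAutoencoders")
  xSt <- exprValues(data@st)
  xSc <- exprValues(data@sc)
  if (ncol(xSt) != bundle@nets$encSt$inDim ||
      ncol(xSc) != bundle@nets$encSc$inDim)
    stop("bundle input dimensions do not match the dataset")
  B <- cfg@batchSize
  nSt <- nrow(xSt); nSc <- nrow(xSc)
  steps <- ceiling(max(nSt, nSc) / B)
  states <- lapply(bundle@nets[c("encSt", "decSt", "encSc", "decSc")],
                   .adamInit)
  set.seed(.subSeed(cfg@seed, 1L))
  trace <- data.frame()

  for (epoch in seq_len(cfg@aeEpochs)) {
    ordSt <- sample.int(nSt)
    ordSc <- sample.int(nSc)
    lossSt <- lossSc <- c()
    for (s in seq_len(steps)) {
      pos <- ((s - 1L) * B + 1L):min(s * B, max(nSt, nSc))
      if (length(pos) < 2L) next
      for (dom in c("st", "sc")) {
        if (dom == "st") {
          idx <- .cycleIdx(ordSt, pos); x <- xSt[idx, , drop = FALSE]
          encNm <- "encSt"; decNm <- "decSt"
        } else {
          idx <- .cycleIdx(ordSc, pos); x <- xSc[idx, , drop = FALSE]
          encNm <- "encSc"; decNm <- "decSc"
        }
        fe <- .mlpForward(bundle@nets[[encNm]], x, train = TRUE)
        bundle@nets[[encNm]] <- fe$net
        fd <- .mlpForward(bundle@nets[[decNm]], fe$out, train = TRUE)
        bundle@nets[[decNm]] <- fd$net
        loss <- mean((fd$out - x)^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite reconstruction loss (%s) at epoch %d step %d",
                       dom, epoch, s))
        dOut <- 2 * (fd$out - x) / length(x)
        bd <- .mlpBackward(bundle@nets[[decNm]], fd$caches, dOut)
        be <- .mlpBackward(bundle@nets[[encNm]], fe$caches, bd$dX)
        up <- .adamStep(bundle@nets[[decNm]], bd$grads, states[[decNm]],
                        cfg@aeLr)
        bundle@nets[[decNm]] <- up$net; states[[decNm]] <- up$state
        up <- .adamStep(bundle@nets[[encNm]], be$grads, states[[encNm]],
                        cfg@aeLr)
        bundle@nets[[encNm]] <- up$net; states[[encNm]] <- up$state
        if (dom == "st") lossSt <- c(lossSt, loss) else lossSc <- c(lossSc, loss)
      }
    }
    trace <- rbind(trace, data.frame(
      epoch = epoch, stage = "ae", reconSt = mean(lossSt),
      reconSc = mean(lossSc), cycle = NA_real_, identity = NA_real_,
      ganTranslator = NA_real_, hingeDiscriminator = NA_real_,
      totalTranslator = NA_real_, valPcc = NA_real_))
  }
  bundle@config <- cfg
  list(bundle = bundle, trace = trace)
}

#' Freeze the autoencoder weights (between stage 1 and stage 2)
#'
#' Flags all encoder/decoder parameters non-trainable; subsequent
#' optimization steps leave them bit-identical (frozen networks run in
#' evaluation mode during stage 2, so running statistics do not move
#' either).
#'
#' @param bundle a \linkS4class{ModelBundle} after pretraining.
#' @return The bundle with \code{frozen = TRUE}.
#' @export
freezeAutoencoders <- function(bundle) {
  for (nm in c("encSt", "decSt", "encSc", "decSc"))
    bundle@nets[[nm]]$trainable <- FALSE
  bundle@frozen <- TRUE
  bundle
}

#' Adversarial translator training (stage 2)
#'
#' With the autoencoders frozen, each step samples one ST and one SC batch,
#' first updates both discriminators on the hinge loss (translator outputs
#' detached), then updates both translators on the weighted sum of identity,
#' cycle and adversarial losses. Translators use \code{transLr}
#' (default 1e-3), discriminators the smaller \code{discLr} (default 5e-4).
#'
#' @param bundle a frozen \linkS4class{ModelBundle}.
#' @param data a preprocessed \linkS4class{PairedDataset}; its shared map
#'   must be non-empty (the identity loss requires shared genes).
#' @param cfg a \linkS4class{TrainingConfig}.
#' @param monitor optional \code{function(bundle)} evaluated after each
#'   epoch; its numeric result is recorded in the trace column
#'   \code{valPcc} (e.g. a held-out-gene validation correlation).
#' @return List with elements \code{bundle} and \code{trace}.
#' @export
trainTranslators <- function(bundle, data, cfg = TrainingConfig(),
                             monitor = NULL) {
  .checkTrainInput(data)
  if (!bundle@frozen)
    stop("autoencoders must be frozen before translator training")
  shared <- data@shared
  if (length(shared@sharedNames) == 0)
    stop("translator training requires a non-empty shared gene set")
  .auditCheck(geneNames(data@st), "trainTranslators")
  xStAll <- exprValues(data@st)
  xScAll <- exprValues(data@sc)
  B <- cfg@batchSize
  nSt <- nrow(xStAll); nSc <- nrow(xScAll)
  steps <- ceiling(max(nSt, nSc) / B)
  W <- cfg@weights
  states <- lapply(bundle@nets[c("transSt2Sc", "transSc2St",
                                 "discSt", "discSc")], .adamInit)
  set.seed(.subSeed(cfg@seed, 2L))
  trace <- data.frame()

  for (epoch in seq_len(cfg@transEpochs)) {
    ordSt <- sample.int(nSt)
    ordSc <- sample.int(nSc)
    rec <- list(cycle = c(), identity = c(), gan = c(), hinge = c(),
                total = c())
    for (s in seq_len(steps)) {
      pos <- ((s - 1L) * B + 1L):min(s * B, max(nSt, nSc))
      if (length(pos) < 2L) next
      xSt <- xStAll[.cycleIdx(ordSt, pos), , drop = FALSE]
      xSc <- xScAll[.cycleIdx(ordSc, pos), , drop = FALSE]
      zSt <- .mlpForward(bundle@nets$encSt, xSt)$out
      zSc <- .mlpForward(bundle@nets$encSc, xSc)$out

      ## --- discriminator update (fakes detached) ---
      fkSc <- .mlpForward(bundle@nets$transSt2Sc, zSt, train = TRUE)
      bundle@nets$transSt2Sc <- fkSc$net
      fkSt <- .mlpForward(bundle@nets$transSc2St, zSc, train = TRUE)
      bundle@nets$transSc2St <- fkSt$net
      fakeSc <- fkSc$out
      fakeSt <- fkSt$out
      hinge <- 0
      for (d in c("St", "Sc")) {
        dn <- paste0("disc", d)
        zReal <- if (d == "St") zSt else zSc
        zFake <- if (d == "St") fakeSt else fakeSc
        fr <- .mlpForward(bundle@nets[[dn]], zReal, train = TRUE)
        bundle@nets[[dn]] <- fr$net
        ff <- .mlpForward(bundle@nets[[dn]], zFake, train = TRUE)
        bundle@nets[[dn]] <- ff$net
        sr <- drop(fr$out); sf <- drop(ff$out)
        hinge <- hinge + .hingeCore(sr, sf)
        dSr <- matrix(-(1 - sr > 0) / length(sr), ncol = 1)
        dSf <- matrix((1 + sf > 0) / length(sf), ncol = 1)
        gr <- .mlpBackward(bundle@nets[[dn]], fr$caches, dSr)$grads
        gf <- .mlpBackward(bundle@nets[[dn]], ff$caches, dSf)$grads
        up <- .adamStep(bundle@nets[[dn]], .gradAdd(gr, gf), states[[dn]],
                        cfg@discLr)
        bundle@nets[[dn]] <- up$net; states[[dn]] <- up$state
      }

      ## --- translator update ---
      T1 <- bundle@nets$transSt2Sc; T2 <- bundle@nets$transSc2St
      f1 <- .mlpForward(T1, zSt, train = TRUE); T1 <- f1$net
      f2 <- .mlpForward(T2, zSc, train = TRUE); T2 <- f2$net
      f3 <- .mlpForward(T2, f1$out, train = TRUE); T2 <- f3$net  # ST cycle hop
      f4 <- .mlpForward(T1, f2$out, train = TRUE); T1 <- f4$net  # SC cycle hop
      fDecStCyc <- .mlpForward(bundle@nets$decSt, f3$out)
      fDecScCyc <- .mlpForward(bundle@nets$decSc, f4$out)
      fDecScId <- .mlpForward(bundle@nets$decSc, f1$out)
      fDecStId <- .mlpForward(bundle@nets$decSt, f2$out)
      fDiscSc <- .mlpForward(bundle@nets$discSc, f1$out, train = TRUE)
      fDiscSt <- .mlpForward(bundle@nets$discSt, f2$out, train = TRUE)

      cyc <- mean((fDecStCyc$out - xSt)^2) + mean((fDecScCyc$out - xSc)^2)
      id1 <- .identityCorrCore(fDecScId$out[, shared@scIdx, drop = FALSE],
                               xSt[, shared@stIdx, drop = FALSE], grad = TRUE)
      id2 <- .identityCorrCore(fDecStId$out[, shared@stIdx, drop = FALSE],
                               xSc[, shared@scIdx, drop = FALSE], grad = TRUE)
      idLoss <- id1$loss + id2$loss
      gan <- -mean(fDiscSc$out) - mean(fDiscSt$out)
      total <- W@lambdaId * idLoss + W@lambdaCyc * cyc + W@lambdaGan * gan
      if (!is.finite(total))
        stop(sprintf("non-finite translator loss at epoch %d step %d",
                     epoch, s))

      # cycle-loss path gradients (through frozen decoders, dX only)
      dCycSt <- W@lambdaCyc * 2 * (fDecStCyc$out - xSt) / length(xSt)
      dCycSc <- W@lambdaCyc * 2 * (fDecScCyc$out - xSc) / length(xSc)
      dZc1 <- .mlpBackward(bundle@nets$decSt, fDecStCyc$caches, dCycSt,
                           paramGrads = FALSE)$dX
      dZc2 <- .mlpBackward(bundle@nets$decSc, fDecScCyc$caches, dCycSc,
                           paramGrads = FALSE)$dX
      b3 <- .mlpBackward(T2, f3$caches, dZc1)           # grads T2 (ST cycle)
      b4 <- .mlpBackward(T1, f4$caches, dZc2)           # grads T1 (SC cycle)

      # identity-loss path: gradient only at shared output columns
      dIdSc <- matrix(0, nrow(xSt), ncol(xScAll))
      dIdSc[, shared@scIdx] <- W@lambdaId * id1$grad
      dIdSt <- matrix(0, nrow(xSc), ncol(xStAll))
      dIdSt[, shared@stIdx] <- W@lambdaId * id2$grad
      dZid1 <- .mlpBackward(bundle@nets$decSc, fDecScId$caches, dIdSc,
                            paramGrads = FALSE)$dX
      dZid2 <- .mlpBackward(bundle@nets$decSt, fDecStId$caches, dIdSt,
                            paramGrads = FALSE)$dX

      # adversarial path (through discriminators, dX only)
      n1 <- nrow(fDiscSc$out); n2 <- nrow(fDiscSt$out)
      dZg1 <- .mlpBackward(bundle@nets$discSc, fDiscSc$caches,
                           matrix(-W@lambdaGan / n1, n1, 1),
                           paramGrads = FALSE)$dX
      dZg2 <- .mlpBackward(bundle@nets$discSt, fDiscSt$caches,
                           matrix(-W@lambdaGan / n2, n2, 1),
                           paramGrads = FALSE)$dX

      b1 <- .mlpBackward(T1, f1$caches, b3$dX + dZid1 + dZg1)
      b2 <- .mlpBackward(T2, f2$caches, b4$dX + dZid2 + dZg2)

      up <- .adamStep(T1, .gradAdd(b1$grads, b4$grads),
                      states$transSt2Sc, cfg@transLr)
      bundle@nets$transSt2Sc <- up$net; states$transSt2Sc <- up$state
      up <- .adamStep(T2, .gradAdd(b2$grads, b3$grads),
                      states$transSc2St, cfg@transLr)
      bundle@nets$transSc2St <- up$net; states$transSc2St <- up$state

      rec$cycle <- c(rec$cycle, cyc); rec$identity <- c(rec$identity, idLoss)
      rec$gan <- c(rec$gan, gan); rec$hinge <- c(rec$hinge, hinge)
      rec$total <- c(rec$total, total)
    }
    val <- if (is.null(monitor)) NA_real_ else as.numeric(monitor(bundle))
    trace <- rbind(trace, data.frame(
      epoch = epoch, stage = "translator", reconSt = NA_real_,
      reconSc = NA_real_, cycle = mean(rec$cycle),
      identity = mean(rec$identity), ganTranslator = mean(rec$gan),
      hingeDiscriminator = mean(rec$hinge),
      totalTranslator = mean(rec$total), valPcc = val))
  }
  bundle@config <- cfg
  list(bundle = bundle, trace = trace)
}

#' Impute SC-panel genes for ST cells
#'
#' The inference path: ST expression is encoded into the ST latent space,
#' translated into the SC latent space, and decoded with the SC decoder,
#' giving predictions for every SC-panel gene (including genes never
#' measured in ST). Evaluation mode throughout; outputs floored at 0.
#'
#' @param bundle a trained \linkS4class{ModelBundle}.
#' @param st an \linkS4class{ExpressionMatrix} preprocessed with exactly the
#'   training-time ST gene columns.
#' @return Numeric matrix, ST cells x SC genes.
#' @export
imputeGenes <- function(bundle, st) {
  v <- if (is(st, "ExpressionMatrix")) exprValues(st) else st
  if (length(bundle@stGenes)) {
    missing <- setdiff(bundle@stGenes, colnames(v))
    extra <- setdiff(colnames(v), bundle@stGenes)
    if (length(missing) || length(extra))
      stop(sprintf("gene set mismatch with training: missing [%s], extra [%s]",
                   paste(missing, collapse = ","),
                   paste(extra, collapse = ",")))
    v <- v[, bundle@stGenes, drop = FALSE]
  }
  z <- .mlpForward(bundle@nets$encSt, v)$out
  zt <- .mlpForward(bundle@nets$transSt2Sc, z)$out
  out <- pmax(.mlpForward(bundle@nets$decSc, zt)$out, 0)
  rownames(out) <- rownames(v)
  if (length(bundle@scGenes) == ncol(out)) colnames(out) <- bundle@scGenes
  out
}
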