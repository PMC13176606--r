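# Gene-holdout cross-validation: fold planning, per-fold training with a
# leakage guard, aggregation, and the overlap/sparsity ablation protocols.

#' Partition the shared genes into disjoint holdout folds
#'
#' Seeded uniform shuffle followed by near-equal chunks; remainder genes
#' are distributed one per fold from the front, so fold sizes differ by at
#' most one. Deterministic given the seed.
#'
#' @param shared a \linkS4class{SharedGeneMap} (or character vector of
#'   shared gene names).
#' @param nFolds number of folds (default 5).
#' @param seed shuffle seed.
#' @return A \linkS4class{FoldPlan}.
#' @export
makeFoldPlan <- function(shared, nFolds = 5, seed = 1) {
  genes <- if (is(shared, "SharedGeneMap")) shared@sharedNames
           else as.character(shared)
  if (length(genes) < nFolds)
    stop(sprintf("need at least %d shared genes for %d folds (have %d)",
                 nFolds, nFolds, length(genes)))
  set.seed(.subSeed(seed, 3L))
  shuffled <- sample(genes)
  base <- length(genes) %/% nFolds
  extra <- length(genes) %% nFolds
  sizes <- rep(base, nFolds) + c(rep(1, extra), rep(0, nFolds - extra))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  folds <- mapply(function(a, b) shuffled[a:b], starts, ends,
                  SIMPLIFY = FALSE)
  new("FoldPlan", folds = folds, seed = seed)
}

# drop named genes from the ST side of a paired dataset and rebuild the map
.dropStGenes <- function(data, genes) {
  v <- exprValues(data@st)
  keep <- !(tolower(colnames(v)) %in% tolower(genes))
  st <- new("ExpressionMatrix", values = v[, keep, drop = FALSE],
            stage = data@st@stage)
  new("PairedDataset", st = st, stCoords = data@stCoords, sc = data@sc,
      shared = buildSharedMap(st, data@sc))
}

#' Train and evaluate one holdout fold
#'
#' Removes the fold's genes from the ST columns, builds a fresh
#' \linkS4class{ModelBundle} and runs the full two-stage training inside
#' the fold, then imputes and evaluates only the fold's genes against the
#' measured ST values. The leakage audit is armed for the whole fold: a
#' held-out gene reaching any ST training tensor is a hard failure.
#'
#' @param data a preprocessed \linkS4class{PairedDataset}.
#' @param plan a \linkS4class{FoldPlan} over \code{data}'s shared genes.
#' @param foldIndex which fold to hold out.
#' @param cfg a \linkS4class{TrainingConfig}.
#' @return A \linkS4class{MetricReport} for the fold's genes, with the
#'   trained bundle attached as attribute \code{"bundle"} and the training
#'   trace as attribute \code{"trace"}.
#' @export
runFold <- function(data, plan, foldIndex, cfg = TrainingConfig()) {
  heldout <- plan@folds[[foldIndex]]
  reduced <- .dropStGenes(data, heldout)
  if (length(reduced@shared@sharedNames) == 0)
    stop("fold removes every shared gene; translator training impossible")
  old <- setLeakageAudit(heldout)
  on.exit(setLeakageAudit(old), add = TRUE)

  foldSeed <- .subSeed(cfg@seed, 100L + foldIndex)
  bundle <- buildBundle(ncol(exprValues(reduced@st)),
                        ncol(exprValues(reduced@sc)),
                        seed = foldSeed, widthScale = cfg@widthScale,
                        stGenes = geneNames(reduced@st),
                        scGenes = geneNames(reduced@sc), config = cfg)
  foldCfg <- cfg; foldCfg@seed <- foldSeed
  st1 <- pretrainAutoencoders(bundle, reduced, foldCfg)
  bundle <- freezeAutoencoders(st1$bundle)
  st2 <- trainTranslators(bundle, reduced, foldCfg)
  bundle <- st2$bundle

  imputed <- imputeGenes(bundle, reduced@st)
  measured <- exprValues(data@st)
  report <- evaluateImputation(measured, imputed, genes = heldout)
  attr(report, "bundle") <- bundle
  attr(report, "trace") <- rbind(st1$trace, st2$trace)
  report
}

#' Full gene-holdout cross-validation
#'
#' Runs \code{\link{runFold}} for every fold of a fresh
#' \code{\link{makeFoldPlan}} and concatenates the per-gene rows, so each
#' shared gene is evaluated exactly once; averages are recomputed over the
#' aggregate table. Deterministic given the seed.
#'
#' @param data a preprocessed \linkS4class{PairedDataset} with at least
#'   \code{nFolds} shared genes.
#' @param cfg a \linkS4class{TrainingConfig}.
#' @param seed fold-plan and training seed (defaults to \code{cfg@seed}).
#' @param nFolds number of folds (default 5).
#' @return An aggregated \linkS4class{MetricReport}; per-fold reports are
#'   attached as attribute \code{"folds"}.
#' @export
runCV <- function(data, cfg = TrainingConfig(), seed = cfg@seed,
                  nFolds = 5) {
  cfg@seed <- seed
  plan <- makeFoldPlan(data@shared, nFolds = nFolds, seed = seed)
  reports <- lapply(seq_len(nFolds), function(k) runFold(data, plan, k, cfg))
  pg <- do.call(rbind, lapply(reports, perGeneMetrics))
  avg <- vapply(.METRIC_COLS, function(cn) {
    v <- pg[[cn]]; mean(v[is.finite(v)])
  }, numeric(1))
  out <- new("MetricReport", perGene = pg, averages = avg,
             diagnostics = list(
               excludedGenes = unlist(lapply(reports, function(r)
                 reportDiagnostics(r)$excludedGenes))))
  attr(out, "folds") <- reports
  attr(out, "plan") <- plan
  out
}

#' Per-gene-mean baseline for held-out genes
#'
#' Predicts every held-out gene by a constant (the gene's SC reference
#' mean), the weakest sensible predictor: under the zero-variance
#' convention its PCC is 0 for every gene. Used as the floor that trained
#' imputation must beat.
#'
#' @param data a preprocessed \linkS4class{PairedDataset}.
#' @param genes held-out gene names.
#' @return A \linkS4class{MetricReport} for the baseline predictions.
#' @export
baselineMeanReport <- function(data, genes) {
  measured <- exprValues(data@st)
  sc <- exprValues(data@sc)
  scIdx <- match(tolower(genes), tolower(colnames(sc)))
  mu <- ifelse(is.na(scIdx), 0, colMeans(sc)[scIdx])
  imputed <- matrix(rep(mu, each = nrow(measured)), nrow(measured),
                    length(genes), dimnames = list(rownames(measured), genes))
  evaluateImputation(measured, imputed, genes = genes)
}

#' Shared-gene overlap ablation
#'
#' Restricts the shared genes available during training to nested subsets
#' (a single seeded priority order, truncated per fraction and kept in
#' original shared-map order, so fraction 1.0 reproduces the plain CV).
#' Non-retained shared genes are removed from the ST panel entirely — they
#' are unavailable during training, exactly as a smaller measured panel
#' would be; evaluation folds are drawn from the retained set only.
#'
#' @param data a preprocessed \linkS4class{PairedDataset}.
#' @param cfg a \linkS4class{TrainingConfig}.
#' @param fractions retained fractions (default the published grid).
#' @param seed seed for the priority order and the CV runs.
#' @param nFolds folds per CV run.
#' @return data.frame with one row per fraction: the five averaged metrics;
#'   fractions leaving fewer than \code{nFolds} genes are skipped with a
#'   warning.
#' @export
ablateOverlap <- function(data, cfg = TrainingConfig(),
                          fractions = c(0.10, 0.25, 0.50, 0.75, 1.00),
                          seed = cfg@seed, nFolds = 5) {
  shared <- data@shared@sharedNames
  set.seed(.subSeed(seed, 4L))
  priority <- sample(shared)
  out <- data.frame()
  for (f in fractions) {
    nKeep <- round(f * length(shared))
    retained <- shared[shared %in% priority[seq_len(nKeep)]]
    if (length(retained) < nFolds) {
      warning(sprintf("fraction %.2f leaves %d shared genes (< %d folds); skipped",
                      f, length(retained), nFolds))
      next
    }
    dropped <- setdiff(shared, retained)
    d <- if (length(dropped)) .dropStGenes(data, dropped) else data
    rep <- runCV(d, cfg, seed = seed, nFolds = nFolds)
    out <- rbind(out, data.frame(fraction = f, nShared = length(retained),
                                 t(metricAverages(rep))))
  }
  out
}

#' Randomly zero a fraction of the nonzero ST entries
#'
#' @param st an \linkS4class{ExpressionMatrix}.
#' @param fraction fraction of nonzero entries to zero (rounded count).
#' @param seed RNG seed.
#' @return The masked matrix at the same stage.
#' @export
maskStEntries <- function(st, fraction, seed = 1) {
  v <- exprValues(st)
  nz <- which(v != 0)
  nMask <- round(fraction * length(nz))
  if (nMask > 0) {
    set.seed(.subSeed(seed, 5L))
    v[sample(nz, nMask)] <- 0
  }
  new("ExpressionMatrix", values = v, stage = st@stage)
}

#' ST sparsity ablation
#'
#' Masks a growing fraction of the raw ST matrix's nonzero entries (seeded,
#' before preprocessing statistics are computed), re-runs preprocessing and
#' the full gene-holdout CV per fraction. Fraction 0 reproduces the plain
#' pipeline.
#'
#' @param rawData an unprocessed \linkS4class{PairedDataset} (stage
#'   \code{"raw"}).
#' @param cfg a \linkS4class{TrainingConfig}.
#' @param ppCfg a \linkS4class{PreprocessConfig}.
#' @param fractions masking grid (default the published one).
#' @param seed seed shared by masking and CV.
#' @param nFolds folds per CV run.
#' @return data.frame of averaged metrics per fraction.
#' @export
ablateSparsity <- function(rawData, cfg = TrainingConfig(),
                           ppCfg = PreprocessConfig(),
                           fractions = c(0, 0.25, 0.50, 0.75, 0.90),
                           seed = cfg@seed, nFolds = 5) {
  out <- data.frame()
  for (f in fractions) {
    masked <- new("PairedDataset",
                  st = maskStEntries(rawData@st, f, seed),
                  stCoords = rawData@stCoords, sc = rawData@sc,
                  shared = rawData@shared)
    pp <- preprocessPair(masked, ppCfg)
    if (length(pp@shared@sharedNames) < nFolds) {
      warning(sprintf("fraction %.2f leaves too few shared genes; skipped", f))
      next
    }
    rep <- runCV(pp, cfg, seed = seed, nFolds = nFolds)
    out <- rbind(out, data.frame(fraction = f,
                                 nShared = length(pp@shared@sharedNames),
                                 t(metricAverages(rep))))
  }
  out
}
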