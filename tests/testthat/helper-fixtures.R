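# Shared fixtures: tiny deterministic matrices, a desk-scale simulated pair,
# and a cached trained model reused across test files.

tinyExpr <- function(n = 6, g = 4, seed = 1, prefix = "g") {
  set.seed(seed)
  v <- matrix(rpois(n * g, 3), n, g,
              dimnames = list(paste0("c", seq_len(n)),
                              paste0(prefix, seq_len(g))))
  ExpressionMatrix(v)
}

# a paired dataset small enough for fast preprocessing tests
tinyPair <- function(seed = 2) {
  sim <- simulatePair(SimConfig(nStCells = 60, nScCells = 80,
                                nGenesTotal = 40, overlapFraction = 0.6,
                                latentRank = 3, seed = seed))
  sim
}

# hand-built bundle with equal latent dims and identity translators, for
# harness tests that need translator stubs
stubBundle <- function(inSt = 10, inSc = 12, d = 8, seed = 3) {
  set.seed(seed)
  ns <- asNamespace("cycleImpute")
  mlpNew <- get(".mlpNew", ns)
  idNet <- function(d) list(inDim = d, outDim = d, hidden = integer(0),
                            dropout = 0, trainable = TRUE,
                            layers = list(list(kind = "output", W = diag(d),
                                               b = rep(0, d))))
  nets <- list(encSt = mlpNew(inSt, c(16), d), decSt = mlpNew(d, c(16), inSt),
               encSc = mlpNew(inSc, c(16), d), decSc = mlpNew(d, c(16), inSc),
               transSt2Sc = idNet(d), transSc2St = idNet(d),
               discSt = mlpNew(d, c(8), 1), discSc = mlpNew(d, c(8), 1))
  new("ModelBundle", nets = nets, config = TrainingConfig(),
      latentDims = list(st = d, sc = d), stGenes = character(),
      scGenes = character(), frozen = FALSE)
}

# one small trained model, computed once per test session
trainedFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- simulatePair(SimConfig(nStCells = 250, nScCells = 350,
                                  nGenesTotal = 80, overlapFraction = 0.6,
                                  latentRank = 4, seed = 21))
    pp <- preprocessPair(sim$data)
    tc <- TrainingConfig(aeEpochs = 12, transEpochs = 8, batchSize = 64,
                         widthScale = 0.12, seed = 5)
    b <- buildBundle(ncol(exprValues(pp@st)), ncol(exprValues(pp@sc)),
                     seed = 5, widthScale = tc@widthScale,
                     stGenes = geneNames(pp@st), scGenes = geneNames(pp@sc))
    s1 <- pretrainAutoencoders(b, pp, tc)
    s2 <- trainTranslators(freezeAutoencoders(s1$bundle), pp, tc)
    cache <<- list(sim = sim, pp = pp, cfg = tc, bundle = s2$bundle,
                   traceAe = s1$trace, traceTr = s2$trace,
                   bundleInit = b, bundleFrozen = freezeAutoencoders(s1$bundle))
    cache
  }
})
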