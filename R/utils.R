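# Internal helpers: leakage audit, seeding.

# Gene-holdout leakage guard. When option "cycleImpute.auditGenes" holds a
# set of held-out gene names, any ST tensor whose columns intersect that set
# (case-insensitively) triggers a hard failure the moment it reaches an
# encoder or a training entry point.
.auditCheck <- function(genes, context) {
  held <- getOption("cycleImpute.auditGenes", NULL)
  if (is.null(held) || !length(genes)) return(invisible(TRUE))
  bad <- intersect(tolower(genes), tolower(held))
  if (length(bad))
    stop(sprintf("leakage guard: held-out gene(s) %s reached %s",
                 paste(bad, collapse = ", "), context), call. = FALSE)
  invisible(TRUE)
}

#' Enable or disable the gene-holdout leakage audit
#'
#' While enabled, any spatial expression tensor containing one of the named
#' held-out genes aborts training immediately. Used by \code{\link{runFold}};
#' exported so instrumented runs can be audited externally.
#'
#' @param genes character vector of held-out gene names, or \code{NULL} to
#'   disable.
#' @return The previous audit set, invisibly.
#' @export
setLeakageAudit <- function(genes = NULL) {
  old <- getOption("cycleImpute.auditGenes", NULL)
  options(cycleImpute.auditGenes = genes)
  invisible(old)
}

# deterministic sub-seed derivation, kept below 2^31
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 104729) %% .Machine$integer.max)
}

# shuffled-order batch recycling: positions into the (larger) epoch index
# space mapped onto a domain's shuffled order
.cycleIdx <- function(ord, positions) ord[((positions - 1L) %% length(ord)) + 1L]
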