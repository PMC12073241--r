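# Shared fixture builders and a cache for the heavier simulation loops
# (several test files assert different summaries of the same
# parameter-recovery experiment; run it once per session).

makePanel <- function(..., meta = NULL) {
  rows <- list(...)
  calls <- do.call(rbind, rows)
  rownames(calls) <- names(rows)
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("g%02d", seq_len(ncol(calls)))
  MarkerPanel(calls, meta)
}

# balanced one-environment GI table
balancedGi <- function(nGeno, nRep, gEff, repEff = rep(0, nRep),
                       noiseSd = 0, mu = 0.4) {
  d <- expand.grid(genotype_id = sprintf("g%02d", seq_len(nGeno)),
                   replicate = seq_len(nRep), stringsAsFactors = FALSE)
  d$gi <- mu + gEff[match(d$genotype_id, sprintf("g%02d", seq_len(nGeno)))] +
    repEff[d$replicate] + rnorm(nrow(d), 0, noiseSd)
  d
}

.simCache <- new.env(parent = emptyenv())

# 50-seed parameter/effect recovery experiment at the default study
# dimensions (200 genotypes x 4 environments x 2 replicates, generating
# components g 0.031, e 0.015, gxe 0.018, eps 0.003, major locus effect
# -0.14 at tolerant frequency 0.58)
recoveryExperiment <- function(nSeeds = 50) {
  key <- paste0("recovery", nSeeds)
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  res <- lapply(seq_len(nSeeds), function(s) {
    sim <- simulateStudy(simulationConfig(), seed = s)
    gi <- buildPhenotypeTable(sim$plots)
    af <- fitAcrossEnv(gi)
    assoc <- singleMarkerRegression(af$blup, dropHeterozygotes(sim$panel),
                                    "qtl4A_major")
    c(varComp(af$vc), h2 = heritability(af$vc),
      effect = assoc$effect)
  })
  out <- do.call(rbind, res)
  .simCache[[key]] <- out
  out
}
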