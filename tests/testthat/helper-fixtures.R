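# Shared fixtures, built in code. The heavy bootstrap-stability run of
# the default 18-sample cohort is computed once per session and cached,
# since several checks (model selection, profile recovery, stability
# curve shape, runtime) interrogate the same analysis.

smallGeneModel <- function() defaultGeneModel(nGenes = 3000L, seed = 99L)

# Small cohort: nSig signatures, fixed per-sample load, fast to analyze.
smallConfig <- function(seed = 1L, nSig = 3L, load = 500, ...) {
  sigs <- referenceSignatures()[, seq_len(nSig), drop = FALSE]
  simulationConfig(signatures = sigs,
                   exposureAlpha = setNames(rep(0.6, nSig), colnames(sigs)),
                   loadRange = c(load / 30, load / 30),
                   geneModel = smallGeneModel(), seed = seed, ...)
}

writeTinyMaf <- function(path, rows) {
  header <- "Sample\tChrom\tPos\tRef\tAlt\tVAF\tGene\tContext"
  writeLines(c(header, rows), path)
}

# Best cosine match of each reference profile among extracted columns.
recoveryCosines <- function(w, refs) {
  vapply(colnames(refs), function(r)
    max(apply(w, 2, function(col) cosineSimilarity(col, refs[, r]))),
    numeric(1))
}

.heavy_cache <- new.env(parent = emptyenv())

# Default-condition cohort analysed over k = 1..10 at 100 bootstraps.
heavySelection <- function() {
  if (is.null(.heavy_cache$sel)) {
    cfg <- simulationConfig(seed = 1L)
    sim <- simulateCohort(cfg)
    catal <- buildCatalog(sim$table)
    t0 <- proc.time()
    sel <- selectK(catal, kRange = 1:10, nBootstrap = 100L, seed = 1L)
    .heavy_cache$elapsed <- unname((proc.time() - t0)[3])
    .heavy_cache$sel <- sel
    .heavy_cache$sim <- sim
  }
  .heavy_cache
}

# Cohort with the REV3L driver pattern: mutated in exactly 3 of 7
# sensitive patients, none of the 11 resistant.
rev3lCohort <- function(seed = 3L) {
  cfg <- simulationConfig(
    seed = seed, geneModel = smallGeneModel(),
    drivers = list(list(gene = "REV3L", group = "sensitive",
                        nPatients = 3L)))
  simulateCohort(cfg)
}
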