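## End-to-end orchestration: catalog -> summaries -> signature number
## selection/extraction -> annotation + platinum scoring -> VAF filter ->
## SMG (overall + subgroups) -> enrichment, with every number written to
## a TSV and a run manifest that makes reruns verifiable.

#' Run the full analysis pipeline
#'
#' Executes, in order: MAF parsing, 96-channel catalog, per-sample
#' summary statistics (mutation rate, Ti/Tv, VAF spectrum), signature
#' number selection by bootstrap stability, signature annotation and
#' platinum scoring, VAF filtering, significantly-mutated-gene scans
#' (overall and per response group), and patient-level group enrichment
#' for the subgroup-specific genes. All module outputs are written as
#' TSVs into `outDir` together with a human-readable `summary.txt` and a
#' `manifest.json` (tool version, seed, input digests, parameters), so a
#' rerun with equal inputs and seed reproduces the directory.
#'
#' @param maf path to the MAF-like mutation TSV.
#' @param genes path to the gene model TSV (`gene`, `coding_length`).
#' @param groups path to the sample-group TSV (`sample`, `group`), or
#'   `NULL` to skip subgroup analyses.
#' @param refs path to a reference-signature TSV (default: the bundled
#'   synthetic set).
#' @param outDir output directory (created).
#' @param seed master seed.
#' @param kRange,nBootstrap,stabilityMin signature-selection parameters
#'   (see [selectK()]).
#' @param vafMin,fdrMax,minPatients,exomeMb filtering/SMG parameters.
#' @return Invisibly, a list with the in-memory results (`catalog`,
#'   `selection`, `annotation`, `smg`, `enrichment`, paths).
#' @export
runPipeline <- function(maf, genes, groups = NULL, refs = NULL,
                        outDir = "platisig-run", seed = 1L,
                        kRange = 1:10, nBootstrap = 100L,
                        stabilityMin = 0.8, vafMin = 0.2, fdrMax = 0.2,
                        minPatients = 2L, exomeMb = 30) {
  table <- readMaf(maf)
  if (nrow(mutationRecords(table)) == 0L)
    stop("no records in input MAF", call. = FALSE)
  if (!is.null(groups)) {
    g <- readGroups(groups)
    table <- MutationTable(mutationRecords(table), groups = g,
                           report = table@report)
  }
  gm <- readGeneModel(genes)
  ref_sig <- referenceSignatures(refs)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  catalog <- buildCatalog(table)
  writeCatalog(catalog, file.path(outDir, "catalog.tsv"))

  rate <- mutationRate(table, exomeMb = exomeMb)
  titv <- titvRatio(table, perSample = TRUE)
  vafs <- vafSpectrum(table)
  summ <- data.frame(sample_id = names(rate$rates),
                     n_mutations = as.integer(rate$rates * exomeMb),
                     mutations_per_mb = rate$rates,
                     titv = titv$per_sample$ratio[
                       match(names(rate$rates),
                             titv$per_sample$sample_id)],
                     row.names = NULL)
  write.table(summ, file.path(outDir, "sample_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sel <- selectK(catalog, kRange = kRange, stabilityMin = stabilityMin,
                 nBootstrap = nBootstrap, seed = seed)
  write.table(sel$curve, file.path(outDir, "stability_curve.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  best <- sel$extractions[[as.character(sel$k)]]
  ann <- annotateSignatures(best, ref_sig)
  ann$platinum_score <- apply(signatureProfiles(best), 2, platinumScore)
  write.table(ann, file.path(outDir, "signature_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(channel = channelLabels(),
                         signatureProfiles(best), check.names = FALSE),
              file.path(outDir, "signature_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = rownames(signatureExposures(best)),
                         signatureExposures(best), check.names = FALSE),
              file.path(outDir, "signature_exposures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  filtered <- filterVariants(table, vafMin = vafMin)
  smg <- if (length(sampleGroups(table))) {
    subgroupDiscovery(filtered, gm, fdrMax = fdrMax,
                      minPatients = minPatients, exomeMb = exomeMb)
  } else {
    list(overall = smgScan(filtered, gm, fdrMax = fdrMax,
                           minPatients = minPatients, exomeMb = exomeMb))
  }
  smg_tab <- do.call(rbind, smg[vapply(smg, is.data.frame, logical(1))])
  write.table(smg_tab, file.path(outDir, "smg.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  enrichment <- NULL
  if (length(sampleGroups(table))) {
    cand <- unique(c(unlist(smg$subgroup_only), smg$overall$gene))
    if (length(cand)) {
      enrichment <- do.call(rbind, lapply(cand, function(g) {
        e <- groupEnrichment(filtered, g)
        data.frame(gene = g,
                   a11 = e$table[1, 1], a12 = e$table[1, 2],
                   a21 = e$table[2, 1], a22 = e$table[2, 2],
                   p = e$p, direction = e$odds_direction,
                   stringsAsFactors = FALSE)
      }))
      write.table(enrichment, file.path(outDir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  .writeSummary(outDir, rate, titv, vafs, sel, ann, smg_tab, enrichment)
  .writeManifest(outDir, maf, genes, groups, seed,
                 list(kRange = range(kRange), nBootstrap = nBootstrap,
                      stabilityMin = stabilityMin, vafMin = vafMin,
                      fdrMax = fdrMax, minPatients = minPatients,
                      exomeMb = exomeMb))
  invisible(list(catalog = catalog, selection = sel, annotation = ann,
                 smg = smg, enrichment = enrichment, outDir = outDir))
}

.fmtP <- function(p) signif(p, 2)

.writeSummary <- function(outDir, rate, titv, vafs, sel, ann, smg_tab,
                          enrichment) {
  con <- file(file.path(outDir, "summary.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("Cohort summary")
  w("  samples: ", length(rate$rates))
  w("  mutation rate (mutations/Mb): median ", round(rate$median, 1),
    ", range ", round(rate$range[1], 1), "-", round(rate$range[2], 1))
  w("  Ti/Tv: median ", round(titv$median, 2))
  w("  SNVs with VAF < 20%: ", round(100 * vafs$overall, 1), "%")
  w("")
  w("Signatures")
  w("  selected k = ", sel$k, if (sel$flagged)
    " (no k reached the stability threshold)" else "")
  for (i in seq_len(nrow(sel$curve)))
    w("    k=", sel$curve$k[i], "  stability=",
      round(sel$curve$stability[i], 3), "  KL error=",
      signif(sel$curve$reconstruction_error[i], 5))
  for (i in seq_len(nrow(ann)))
    w("  ", ann$signature[i], " -> ", ann$label[i],
      " (cosine ", round(ann$cosine[i], 3),
      ", platinum score ", round(ann$platinum_score[i], 3), ")")
  w("")
  w("Significantly mutated genes (q < FDR threshold)")
  if (NROW(smg_tab)) {
    for (i in seq_len(nrow(smg_tab)))
      w("  ", smg_tab$gene[i], " [", smg_tab$scope[i], "] patients=",
        smg_tab$n_mutated_patients[i], " p=", .fmtP(smg_tab$p_value[i]),
        " q=", .fmtP(smg_tab$q_value[i]))
  } else w("  none")
  if (!is.null(enrichment)) {
    w("")
    w("Group enrichment (patient level, Fisher exact)")
    for (i in seq_len(nrow(enrichment)))
      w("  ", enrichment$gene[i], ": [[", enrichment$a11[i], ",",
        enrichment$a12[i], "],[", enrichment$a21[i], ",",
        enrichment$a22[i], "]] p=", sprintf("%.2f", enrichment$p[i]),
        " toward ", enrichment$direction[i])
  }
}

.writeManifest <- function(outDir, maf, genes, groups, seed, params) {
  digest <- function(p) if (is.null(p)) NULL else
    unname(tools::md5sum(normalizePath(p)))
  manifest <- list(
    tool = "platisig",
    version = as.character(utils::packageVersion("platisig")),
    seed = seed,
    inputs = list(maf = digest(maf), genes = digest(genes),
                  groups = digest(groups)),
    parameters = params,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
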