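## Synthetic cohorts with the statistical structure the pipeline assumes:
## per-sample mutation loads drawn log-uniformly over the cohort's
## dynamic range, signature mixtures drawn from a Dirichlet, channels
## drawn from the signature profiles, origin-specific VAF betas (platinum
## mutations predominantly subclonal), and planted driver genes.

#' Default synthetic gene model
#'
#' Generates a coding-gene table whose total length matches the exome
#' size, so that assigning every simulated mutation a gene with
#' probability proportional to coding length is consistent with a
#' per-base background rate over the whole exome. A handful of genes of
#' interest (REV3L, TP53, CDKN2A, FBXW7, KRAS, EPYC) carry fixed
#' realistic coding lengths; the remainder are log-normal.
#'
#' @param nGenes total number of genes (default 18000).
#' @param exomeMb exome size in Mb the lengths sum to (default 30).
#' @param seed integer seed.
#' @return data.frame with `gene`, `coding_length`.
#' @export
defaultGeneModel <- function(nGenes = 18000L, exomeMb = 30, seed = 1L) {
  named <- c(REV3L = 9282L, TP53 = 1182L, CDKN2A = 471L, FBXW7 = 2121L,
             KRAS = 567L, EPYC = 966L)
  set.seed(seed)
  n_anon <- nGenes - length(named)
  len <- round(exp(rnorm(n_anon, log(1400), 0.6)))
  len <- pmax(len, 90L)
  target <- exomeMb * 1e6 - sum(named)
  len <- pmax(round(len * target / sum(len)), 90L)
  data.frame(gene = c(names(named), sprintf("G%05d", seq_len(n_anon))),
             coding_length = c(unname(named), len),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulateCohort()]. Defaults
#' describe an 18-sample cohort split 7 (sensitive) / 11 (resistant),
#' mutation loads log-uniform over 4.8-80.9 mutations/Mb on a 30 Mb
#' exome, mixtures of the five bundled reference signatures drawn from a
#' sparse symmetric Dirichlet(0.6) — per-tumor signature activity is
#' strongly heterogeneous, as in real cohorts, so each signature
#' dominates a subset of samples — and origin-specific VAF betas —
#' Beta(1.2, 13) for platinum-origin mutations (about 92% of mass below
#' VAF 0.2) and Beta(6, 4) for clonal mutations.
#'
#' @param nSamples number of samples.
#' @param groupSizes named integer vector of group sizes summing to
#'   `nSamples`.
#' @param signatures 96 x k matrix of normalized signature profiles with
#'   column names (default: the bundled reference set).
#' @param exposureAlpha Dirichlet concentration per signature (named as
#'   `signatures` columns).
#' @param loadRange mutations/Mb range for the log-uniform load draw.
#' @param exomeMb exome size in Mb.
#' @param vafBeta list with `platinum` and `clonal` Beta(shape1, shape2)
#'   pairs; the `platinum` beta applies to mutations originating from the
#'   signature named `"platinum"`, the `clonal` beta to all others and to
#'   planted drivers.
#' @param drivers list of planted drivers; each element a list with
#'   `gene`, `group`, and either `prob` (per-patient Bernoulli) or
#'   `nPatients` (mutate exactly the first n patients of the group), plus
#'   optional `mutationsPerPatient` (default 1). Driver mutations carry
#'   VAF > 0.2 so they survive the SMG filter.
#' @param geneModel data.frame (`gene`, `coding_length`) used to assign
#'   genes to background mutations proportionally to length (driver
#'   genes excluded from background assignment).
#' @param seed integer master seed.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSamples = 18L,
                             groupSizes = c(sensitive = 7L, resistant = 11L),
                             signatures = referenceSignatures(),
                             exposureAlpha = NULL,
                             loadRange = c(4.8, 80.9),
                             exomeMb = 30,
                             vafBeta = list(platinum = c(1.2, 13),
                                            clonal = c(6, 4)),
                             drivers = list(),
                             geneModel = NULL,
                             seed = 1L) {
  if (sum(groupSizes) != nSamples)
    stop("group sizes must sum to nSamples", call. = FALSE)
  if (any(abs(colSums(signatures) - 1) > 1e-6))
    stop("signature profiles must be normalized to sum 1", call. = FALSE)
  if (is.null(exposureAlpha))
    exposureAlpha <- setNames(rep(0.6, ncol(signatures)),
                              colnames(signatures))
  stopifnot(length(exposureAlpha) == ncol(signatures),
            all(exposureAlpha > 0),
            all(loadRange > 0), length(loadRange) == 2L)
  for (d in drivers) {
    stopifnot(is.list(d), !is.null(d$gene), !is.null(d$group))
    if (!is.null(d$prob)) stopifnot(d$prob >= 0, d$prob <= 1)
  }
  if (is.null(geneModel)) geneModel <- defaultGeneModel(seed = seed)
  structure(list(nSamples = as.integer(nSamples), groupSizes = groupSizes,
                 signatures = signatures, exposureAlpha = exposureAlpha,
                 loadRange = loadRange, exomeMb = exomeMb,
                 vafBeta = vafBeta, drivers = drivers,
                 geneModel = geneModel, seed = as.integer(seed)),
            class = "SimulationConfig")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  sweep(x, 1, rowSums(x), "/")
}

## Decompose channel indices into (pyrimidine-strand ref, alt, context).
.channelParts <- function(idx) {
  si <- (idx - 1L) %/% 16L + 1L
  fi <- ((idx - 1L) %% 16L) %/% 4L + 1L
  ti <- (idx - 1L) %% 4L + 1L
  sub <- .SUBS[si]
  list(ref = substr(sub, 1, 1), alt = substr(sub, 3, 3),
       context = paste0(.BASES[fi], substr(sub, 1, 1), .BASES[ti]))
}

#' Simulate a mutation cohort with ground truth
#'
#' Per sample: draws a mutation load (log-uniform over
#' `loadRange * exomeMb`, rounded), a signature mixture from the
#' Dirichlet, and for each mutation an originating signature (by the
#' mixture), a 96-channel (by that signature's profile), a
#' reference-strand representation (uniformly one of the two strands), a
#' gene (proportional to coding length, driver genes excluded) and a VAF
#' from the origin-specific beta. Planted drivers then add patient-level
#' mutations (VAF drawn uniform on 0.25-0.8, surviving the SMG filter) in
#' the designated group. Fully reproducible from `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return List with `table` (a [`MutationTable-class`]) and `truth`
#'   (exposure matrix, per-record origin signature, planted drivers with
#'   affected samples, VAF parameters, per-sample loads, seed).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  sig <- config$signatures
  k <- ncol(sig)
  n <- config$nSamples
  ids <- sprintf("T%02d", seq_len(n))
  groups <- setNames(rep(names(config$groupSizes), config$groupSizes), ids)

  loads <- exp(runif(n, log(config$loadRange[1]), log(config$loadRange[2])))
  nmut <- as.integer(round(loads * config$exomeMb))
  expo <- .rdirichlet(n, config$exposureAlpha)
  dimnames(expo) <- list(ids, colnames(sig))

  driver_genes <- vapply(config$drivers, `[[`, "", "gene")
  gm <- config$geneModel
  bg <- gm[!gm$gene %in% driver_genes, , drop = FALSE]

  recs <- vector("list", n)
  origins <- vector("list", n)
  for (s in seq_len(n)) {
    m <- nmut[s]
    orig <- sample.int(k, m, replace = TRUE, prob = expo[s, ])
    chan <- integer(m)
    for (j in seq_len(k)) {
      sel <- orig == j
      if (any(sel))
        chan[sel] <- sample.int(96L, sum(sel), replace = TRUE,
                                prob = sig[, j])
    }
    parts <- .channelParts(chan)
    flip <- runif(m) < 0.5
    ref <- parts$ref; alt <- parts$alt; ctx <- parts$context
    ref[flip] <- .complement(ref[flip])
    alt[flip] <- .complement(alt[flip])
    ctx[flip] <- reverseComplement(ctx[flip])
    plat <- colnames(sig)[orig] == "platinum"
    vb <- config$vafBeta
    vaf <- numeric(m)
    vaf[plat] <- rbeta(sum(plat), vb$platinum[1], vb$platinum[2])
    vaf[!plat] <- rbeta(sum(!plat), vb$clonal[1], vb$clonal[2])
    gene <- bg$gene[sample.int(nrow(bg), m, replace = TRUE,
                               prob = bg$coding_length)]
    recs[[s]] <- data.frame(
      sample_id = rep(ids[s], m),
      chrom = paste0("chr", sample.int(22L, m, replace = TRUE)),
      pos = sample.int(100000000L, m, replace = TRUE),
      ref = ref, alt = alt, vaf = round(vaf, 4), gene = gene,
      context = ctx, variant_class = rep("SNV", m),
      stringsAsFactors = FALSE)
    origins[[s]] <- colnames(sig)[orig]
  }

  driver_truth <- list()
  for (d in config$drivers) {
    members <- names(groups)[groups == d$group]
    hit <- if (!is.null(d$nPatients)) {
      members[seq_len(min(d$nPatients, length(members)))]
    } else {
      members[runif(length(members)) < d$prob]
    }
    mpp <- if (is.null(d$mutationsPerPatient)) 1L
           else as.integer(d$mutationsPerPatient)
    for (s in hit) {
      m <- mpp
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = rep(s, m),
        chrom = rep("chr6", m),
        pos = sample.int(100000000L, m, replace = TRUE),
        ref = rep("C", m), alt = rep("T", m),
        vaf = round(runif(m, 0.25, 0.8), 4),
        gene = rep(d$gene, m), context = rep("ACA", m),
        variant_class = rep("SNV", m), stringsAsFactors = FALSE)
      origins[[length(origins) + 1L]] <- rep("driver", m)
    }
    driver_truth[[d$gene]] <- list(gene = d$gene, group = d$group,
                                   samples = hit,
                                   mutationsPerPatient = mpp)
  }

  records <- do.call(rbind, recs)
  table <- MutationTable(records, groups = groups,
                         report = list(n_records = nrow(records)))
  truth <- list(exposures = expo, origins = unlist(origins),
                drivers = driver_truth, vafBeta = config$vafBeta,
                loads_per_mb = setNames(loads, ids),
                nmut = setNames(nmut, ids), seed = config$seed)
  list(table = table, truth = truth)
}

#' Write a MutationTable as a MAF-like TSV
#'
#' Columns `Sample`, `Chrom`, `Pos`, `Ref`, `Alt`, `VAF`, `Gene`,
#' `Context` (round-trips through [readMaf()]).
#'
#' @param table a [`MutationTable-class`].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(table, path) {
  df <- mutationRecords(table)
  out <- data.frame(Sample = df$sample_id, Chrom = df$chrom, Pos = df$pos,
                    Ref = df$ref, Alt = df$alt, VAF = df$vaf,
                    Gene = df$gene, Context = df$context,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the standard synthetic fixture suite
#'
#' Generates and writes four seeded test cohorts:
#' \describe{
#'   \item{cohort_main}{18 samples, mixtures of the five bundled
#'     signatures including platinum (signature-recovery fixture).}
#'   \item{cohort_null}{18 samples, no planted drivers (null fixture for
#'     the SMG test).}
#'   \item{cohort_rev3l}{18 samples with a REV3L driver planted in
#'     exactly 3 of the 7 sensitive patients and none of the 11 resistant
#'     patients, reproducing the 3/7 vs 0/11 contingency.}
#'   \item{cohort_tiny}{3 samples with fixed loads 20, 35 and 50 from a
#'     single signature — hand-checkable catalog column sums.}
#' }
#' Each cohort gets `<name>.maf.tsv`, `<name>.groups.tsv` and a
#' `<name>.truth.json` sidecar; the gene model is written once.
#'
#' @param outDir writable output directory (created if needed).
#' @param seed master seed (default 1).
#' @return Named list of the generated config objects, invisibly; files
#'   on disk as described.
#' @export
makeFixtureSuite <- function(outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gm <- defaultGeneModel(seed = seed)
  configs <- list(
    cohort_main = simulationConfig(seed = seed, geneModel = gm),
    cohort_null = simulationConfig(seed = seed + 1L, geneModel = gm),
    cohort_rev3l = simulationConfig(
      seed = seed + 2L, geneModel = gm,
      drivers = list(list(gene = "REV3L", group = "sensitive",
                          nPatients = 3L))),
    cohort_tiny = simulationConfig(
      nSamples = 3L, groupSizes = c(sensitive = 1L, resistant = 2L),
      signatures = referenceSignatures()[, "platinum", drop = FALSE],
      exposureAlpha = c(platinum = 1),
      loadRange = c(35 / 30, 35 / 30),  # placeholder; loads fixed below
      seed = seed + 3L, geneModel = gm))
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    sim <- if (nm == "cohort_tiny") .tinyCohort(cfg) else simulateCohort(cfg)
    writeMaf(sim$table, file.path(outDir, paste0(nm, ".maf.tsv")))
    g <- sampleGroups(sim$table)
    write.table(data.frame(sample = names(g), group = unname(g)),
                file.path(outDir, paste0(nm, ".groups.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- sim$truth
    truth$exposures <- as.data.frame(truth$exposures)
    jsonlite::write_json(truth, file.path(outDir, paste0(nm, ".truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  write.table(gm, file.path(outDir, "gene_model.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(configs)
}

## Tiny 3-sample worked example: fixed loads 20/35/50 from the platinum
## profile alone, so catalog column sums are exactly the loads.
.tinyCohort <- function(cfg) {
  loads <- c(20L, 35L, 50L)
  set.seed(cfg$seed)
  sig <- cfg$signatures
  recs <- lapply(seq_along(loads), function(s) {
    m <- loads[s]
    chan <- sample.int(96L, m, replace = TRUE, prob = sig[, 1])
    parts <- .channelParts(chan)
    data.frame(sample_id = sprintf("T%02d", s), chrom = "chr1",
               pos = sample.int(1000000L, m), ref = parts$ref,
               alt = parts$alt,
               vaf = round(rbeta(m, cfg$vafBeta$platinum[1],
                                 cfg$vafBeta$platinum[2]), 4),
               gene = NA_character_, context = parts$context,
               variant_class = "SNV", stringsAsFactors = FALSE)
  })
  ids <- sprintf("T%02d", seq_along(loads))
  groups <- setNames(rep(names(cfg$groupSizes), cfg$groupSizes), ids)
  list(table = MutationTable(do.call(rbind, recs), groups = groups),
       truth = list(loads = setNames(loads, ids), seed = cfg$seed))
}
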