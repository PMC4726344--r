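## Significantly mutated genes and group enrichment. The background model
## is a single-category convolution of per-sample binomial counts: gene
## mutations in sample s ~ Binomial(coding_length, r_s) with r_s the
## sample's per-base mutation rate; the exact distribution of the cohort
## total is obtained by convolving the per-sample pmfs. This is a
## coverage-free simplification of the MuSiC-style convolution test (no
## per-category stratification, no per-gene covered-base counts, neither
## being recoverable downstream of a MAF); a category extension would
## slot in by convolving per-category totals.

#' Filter variants by minimum VAF
#'
#' Keeps records with VAF strictly greater than `vafMin` ("more than
#' 20%"): a record at exactly the threshold is excluded. Records with
#' missing VAF are dropped and tallied in the table's report.
#'
#' @param table a [`MutationTable-class`].
#' @param vafMin threshold (default 0.2).
#' @return Filtered [`MutationTable-class`]; `report$n_dropped_missing_vaf`
#'   and `report$n_dropped_low_vaf` record the removals.
#' @export
filterVariants <- function(table, vafMin = 0.2) {
  df <- mutationRecords(table)
  miss <- is.na(df$vaf)
  keep <- !miss & df$vaf > vafMin
  rep2 <- table@report
  rep2$n_dropped_missing_vaf <- sum(miss)
  rep2$n_dropped_low_vaf <- sum(!miss & !keep)
  MutationTable(df[keep, , drop = FALSE], groups = sampleGroups(table),
                report = rep2)
}

#' Per-sample per-base background mutation rates
#'
#' @param table a [`MutationTable-class`] (already VAF-filtered for SMG
#'   use).
#' @param exomeMb exome size in Mb (default 30).
#' @return Named numeric vector of per-base rates (mutations divided by
#'   `exomeMb * 1e6`), one per sample.
#' @export
backgroundRates <- function(table, exomeMb = 30) {
  mutationRate(table, exomeMb = exomeMb)$rates / 1e6
}

#' Exact convolution test for a gene's cohort-wide mutation count
#'
#' Models the gene's mutation count in sample s as
#' `Binomial(geneLength, rates[s])` and computes the exact upper-tail
#' probability `P(total >= observedTotal)` of the cohort total by
#' iterative convolution of the per-sample probability mass functions
#' (only the mass below `observedTotal` is needed, so the convolution is
#' truncated there with no tail-mass loss).
#'
#' @param observedTotal observed cohort-wide mutation count (>= 0).
#' @param geneLength gene coding length in bases (>= 1).
#' @param rates per-sample per-base rates, each in \[0, 1\].
#' @return The p-value in (0, 1\].
#' @export
convolutionTest <- function(observedTotal, geneLength, rates) {
  stopifnot(observedTotal >= 0, geneLength >= 1)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (observedTotal == 0) return(1)
  # pmf of the running total on 0..observedTotal-1
  supp <- 0:(observedTotal - 1)
  pmf <- c(1, numeric(observedTotal - 1))
  for (r in rates) {
    b <- dbinom(supp, size = geneLength, prob = r)
    new <- numeric(observedTotal)
    for (j in seq_along(supp)) {
      if (pmf[j] == 0) next
      reach <- seq_len(observedTotal - j + 1L)
      new[j + reach - 1L] <- new[j + reach - 1L] + pmf[j] * b[reach]
    }
    pmf <- new
  }
  # 1 - sum(pmf) cancels at ~1e-16; floor at double precision of the
  # complement so the p-value stays in (0, 1]
  max(1 - sum(pmf), .Machine$double.eps)
}

#' Significantly mutated gene scan
#'
#' Tests every gene mutated in at least `minPatients` distinct patients
#' of the scope against the convolution background model
#' ([convolutionTest()]), adjusts the p-values by Benjamini-Hochberg over
#' the tested genes only, and reports genes with `q < fdrMax` sorted by
#' p-value.
#'
#' @param table a VAF-filtered [`MutationTable-class`].
#' @param genes data.frame with columns `gene` and `coding_length`.
#' @param scope optional character vector of sample ids restricting the
#'   cohort (default: all samples).
#' @param scopeLabel label stored in the result rows (default
#'   `"overall"`).
#' @param fdrMax FDR threshold (default 0.2).
#' @param minPatients minimum mutated patients per gene (default 2).
#' @param exomeMb exome size for the background rates (default 30).
#' @param all if `TRUE`, return all tested genes, not only those passing
#'   `fdrMax`.
#' @return data.frame with `gene`, `n_mutated_patients`, `n_mutations`,
#'   `p_value`, `q_value`, `scope`; attribute `n_unknown_genes` counts
#'   mutated genes absent from `genes` (excluded with a warning).
#' @export
smgScan <- function(table, genes, scope = NULL, scopeLabel = "overall",
                    fdrMax = 0.2, minPatients = 2L, exomeMb = 30,
                    all = FALSE) {
  df <- mutationRecords(table)
  if (is.null(scope)) scope <- sampleIds(table)
  if (!length(scope)) stop("scope must be non-empty", call. = FALSE)
  df <- df[df$sample_id %in% scope, , drop = FALSE]
  sub <- MutationTable(df, report = list())
  rates <- backgroundRates(sub, exomeMb = exomeMb)
  rates <- rates[match(scope, names(rates))]
  rates[is.na(rates)] <- 0

  known <- !is.na(df$gene) & df$gene %in% genes$gene
  n_unknown <- length(unique(df$gene[!is.na(df$gene) & !known]))
  if (n_unknown > 0)
    warning(n_unknown, " mutated gene(s) absent from the gene model; excluded")
  df <- df[known, , drop = FALSE]

  pat <- tapply(df$sample_id, df$gene, function(s) length(unique(s)))
  tot <- tapply(df$sample_id, df$gene, length)
  test_genes <- names(pat)[pat >= minPatients]
  res <- data.frame(gene = character(0), n_mutated_patients = integer(0),
                    n_mutations = integer(0), p_value = numeric(0),
                    q_value = numeric(0), scope = character(0),
                    stringsAsFactors = FALSE)
  if (length(test_genes)) {
    len <- genes$coding_length[match(test_genes, genes$gene)]
    p <- vapply(seq_along(test_genes), function(i)
      convolutionTest(tot[[test_genes[i]]], len[i], rates), numeric(1))
    q <- p.adjust(p, method = "BH")
    res <- data.frame(gene = test_genes,
                      n_mutated_patients = as.integer(pat[test_genes]),
                      n_mutations = as.integer(tot[test_genes]),
                      p_value = p, q_value = q,
                      scope = scopeLabel,
                      stringsAsFactors = FALSE, row.names = NULL)
    res <- res[order(res$p_value, res$gene), , drop = FALSE]
    if (!all) res <- res[res$q_value < fdrMax, , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "n_unknown_genes") <- n_unknown
  res
}

#' Subgroup-specific significantly mutated genes
#'
#' Runs [smgScan()] on the overall cohort and on each response group, and
#' reports genes significant in a subgroup but not in the overall cohort.
#'
#' @param table a VAF-filtered [`MutationTable-class`] with sample groups.
#' @param genes gene model data.frame (`gene`, `coding_length`).
#' @param ... passed to [smgScan()] (`fdrMax`, `minPatients`, `exomeMb`).
#' @return List with `overall`, one entry per group label, and
#'   `subgroup_only` (named list of genes significant in that group but
#'   not overall).
#' @export
subgroupDiscovery <- function(table, genes, ...) {
  groups <- sampleGroups(table)
  if (!length(groups))
    stop("sample groups are required for subgroup discovery", call. = FALSE)
  res <- list(overall = smgScan(table, genes, scopeLabel = "overall", ...))
  for (g in unique(groups)) {
    res[[g]] <- smgScan(table, genes, scope = names(groups)[groups == g],
                        scopeLabel = g, ...)
  }
  overall_genes <- res$overall$gene
  res$subgroup_only <- lapply(unique(groups), function(g)
    setdiff(res[[g]]$gene, overall_genes))
  names(res$subgroup_only) <- unique(groups)
  res
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities
#' (margins fixed) of all tables whose point probability does not exceed
#' that of the observed table, within relative tolerance 1e-7 — the
#' conventional point-probability rule, not tail doubling.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return The p-value in (0, 1\].
#' @examples
#' fisherTwoSided(matrix(c(3, 0, 4, 11), 2))  # 35/816, prints as 0.04
#' @export
fisherTwoSided <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("table entries must be non-negative", call. = FALSE)
  if (any(abs(table - round(table)) > 1e-8))
    stop("table entries must be integers", call. = FALSE)
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 + r2 == 0 || r1 == 0 || r2 == 0 || c1 == 0 || sum(table[, 2]) == 0)
    return(1)
  a <- table[1, 1]
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' Patient-level group enrichment of a gene
#'
#' Builds the 2x2 table (mutated / unmutated patients x response group) —
#' a patient counts once regardless of mutation multiplicity — and
#' applies [fisherTwoSided()].
#'
#' @param table a [`MutationTable-class`] with sample groups.
#' @param gene gene symbol; if absent from the table the mutated row is
#'   zero and p = 1.
#' @return List with `gene`, `table` (2x2, columns = groups), `p`
#'   (two-sided) and `odds_direction` (group with the higher mutated
#'   fraction, or `"none"`).
#' @export
groupEnrichment <- function(table, gene) {
  groups <- sampleGroups(table)
  if (!length(groups))
    stop("sample groups are required for enrichment", call. = FALSE)
  df <- mutationRecords(table)
  glev <- unique(groups)
  mut_samples <- unique(df$sample_id[!is.na(df$gene) & df$gene == gene])
  tab <- vapply(glev, function(g) {
    members <- names(groups)[groups == g]
    m <- sum(members %in% mut_samples)
    c(mutated = m, unmutated = length(members) - m)
  }, numeric(2))
  p <- fisherTwoSided(tab)
  frac <- tab["mutated", ] / colSums(tab)
  dir <- if (length(unique(frac)) == 1L) "none" else glev[which.max(frac)]
  list(gene = gene, table = tab, p = p, odds_direction = dir)
}

#' Per-gene mutation-frequency comparison of two cohorts
#'
#' For each gene present in both count tables, applies [fisherTwoSided()]
#' to `[[mutated_a, n_a - mutated_a], [mutated_b, n_b - mutated_b]]`.
#'
#' @param countsA,countsB data.frames with columns `gene`, `mutated`, `n`
#'   (`n >= mutated >= 0`).
#' @return data.frame with `gene`, `mutated_a`, `n_a`, `mutated_b`,
#'   `n_b`, `p`; genes missing from one cohort are skipped with a
#'   warning.
#' @export
cohortComparison <- function(countsA, countsB) {
  stopifnot(all(c("gene", "mutated", "n") %in% names(countsA)),
            all(c("gene", "mutated", "n") %in% names(countsB)))
  shared <- intersect(countsA$gene, countsB$gene)
  skipped <- setdiff(union(countsA$gene, countsB$gene), shared)
  if (length(skipped))
    warning("gene(s) missing from one cohort skipped: ",
            paste(skipped, collapse = ", "))
  ia <- match(shared, countsA$gene); ib <- match(shared, countsB$gene)
  p <- vapply(seq_along(shared), function(i) {
    ma <- countsA$mutated[ia[i]]; na <- countsA$n[ia[i]]
    mb <- countsB$mutated[ib[i]]; nb <- countsB$n[ib[i]]
    stopifnot(na >= ma, nb >= mb, ma >= 0, mb >= 0)
    fisherTwoSided(matrix(c(ma, mb, na - ma, nb - mb), 2L))
  }, numeric(1))
  data.frame(gene = shared,
             mutated_a = countsA$mutated[ia], n_a = countsA$n[ia],
             mutated_b = countsB$mutated[ib], n_b = countsB$n[ib],
             p = p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a gene model table
#'
#' @param path TSV with columns `gene` and `coding_length`.
#' @return data.frame with unique gene names and positive lengths.
#' @export
readGeneModel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("gene", "coding_length") %in% names(df)),
            !anyDuplicated(df$gene), all(df$coding_length >= 1))
  df[, c("gene", "coding_length")]
}
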