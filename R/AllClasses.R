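## Central S4 containers. Records travel as a plain data.frame inside
## MutationTable (one somatic variant per row, MAF-like); the catalog is a
## channels x samples integer matrix, the Bioconductor features-x-samples
## orientation.

.RECORD_COLS <- c("sample_id", "chrom", "pos", "ref", "alt",
                  "vaf", "gene", "context", "variant_class")

#' @title MutationTable: a cohort of somatic mutation records
#'
#' @description One somatic variant per row with sample, locus, alleles,
#' variant allele frequency (VAF), gene symbol and trinucleotide context,
#' plus an optional partition of samples into response groups. This is the
#' universal input of the pipeline.
#'
#' @slot records data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `vaf`, `gene`, `context`, `variant_class`
#'   (`SNV`/`insertion`/`deletion`); extra columns are preserved.
#' @slot groups named character vector mapping every sample to a group
#'   label (e.g. `sensitive`/`resistant`), or empty when no grouping.
#' @slot report list of parse/filter tallies (e.g. rows dropped).
#'
#' @exportClass MutationTable
setClass("MutationTable",
         slots = c(records = "data.frame",
                   groups = "character",
                   report = "list"),
         prototype = prototype(groups = character(0), report = list()))

setValidity("MutationTable", function(object) {
  df <- object@records
  msg <- character(0)
  miss <- setdiff(.RECORD_COLS, names(df))
  if (length(miss))
    return(paste("missing record column(s):", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$pos < 1, na.rm = TRUE)) msg <- c(msg, "pos must be >= 1")
    bad_vaf <- !is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1)
    if (any(bad_vaf)) msg <- c(msg, "vaf must lie in [0, 1]")
    snv <- df$variant_class == "SNV"
    if (any(snv & (nchar(df$ref) != 1L | nchar(df$alt) != 1L)))
      msg <- c(msg, "SNV ref and alt must be single bases")
    if (any(snv & df$ref == df$alt))
      msg <- c(msg, "SNV ref and alt must differ")
    has_ctx <- snv & !is.na(df$context)
    if (any(has_ctx & nchar(df$context) != 3L))
      msg <- c(msg, "context must be a trinucleotide")
    bad_mid <- has_ctx & nchar(df$context) == 3L &
      substr(df$context, 2, 2) != df$ref
    if (any(bad_mid))
      msg <- c(msg, paste("context middle base != ref at row(s):",
                          paste(head(which(bad_mid), 10), collapse = ", ")))
  }
  g <- object@groups
  if (length(g)) {
    uncovered <- setdiff(unique(df$sample_id), names(g))
    if (length(uncovered))
      msg <- c(msg, paste("groups do not cover sample(s):",
                          paste(head(uncovered, 10), collapse = ", ")))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a MutationTable
#'
#' @param records data.frame of mutation records (see
#'   [`MutationTable-class`]). Columns `vaf`, `gene`, `context` may be
#'   omitted and are filled with `NA`; `variant_class` is inferred from
#'   allele lengths when absent (single-base ref/alt: SNV; longer alt:
#'   insertion; longer ref: deletion).
#' @param groups optional named character vector `sample_id -> group`.
#' @param report optional list of parse tallies.
#' @return A [`MutationTable-class`] object.
#' @examples
#' df <- data.frame(sample_id = "S1", chrom = "chr1", pos = 100,
#'                  ref = "C", alt = "A", vaf = 0.15, gene = "TP53",
#'                  context = "ACA")
#' MutationTable(df)
#' @export
MutationTable <- function(records, groups = character(0), report = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("vaf", "gene", "context"))
    if (!col %in% names(records)) records[[col]] <- NA
  records$vaf <- as.numeric(records$vaf)
  records$gene <- as.character(records$gene)
  records$context <- as.character(records$context)
  records$pos <- as.integer(records$pos)
  if (!"variant_class" %in% names(records))
    records$variant_class <- .inferVariantClass(records$ref, records$alt)
  records <- records[, c(.RECORD_COLS,
                         setdiff(names(records), .RECORD_COLS)),
                     drop = FALSE]
  new("MutationTable", records = records,
      groups = groups, report = report)
}

.inferVariantClass <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' @title MutationCatalog: 96-trinucleotide mutation counts
#'
#' @description Non-negative integer counts of SNVs per 96-trinucleotide
#' channel (rows, fixed order; see [channelLabels()]) and per sample
#' (columns). Column sums equal the number of channel-resolvable SNVs per
#' sample.
#'
#' @slot counts integer matrix, 96 channels x samples, rownames =
#'   [channelLabels()], colnames = sample ids.
#'
#' @exportClass MutationCatalog
setClass("MutationCatalog", slots = c(counts = "matrix"))

setValidity("MutationCatalog", function(object) {
  m <- object@counts
  if (nrow(m) != 96L) return("counts must have 96 rows")
  if (!identical(rownames(m), channelLabels()))
    return("rownames must equal channelLabels()")
  if (is.null(colnames(m))) return("counts must have sample colnames")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) return("counts must be integers")
  TRUE
})

#' Construct a MutationCatalog from a counts matrix
#'
#' @param counts non-negative integer matrix; either 96 channels x samples
#'   (rownames = channel labels) or its transpose, which is flipped
#'   automatically.
#' @return A [`MutationCatalog-class`].
#' @export
MutationCatalog <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 96L && ncol(counts) == 96L) counts <- t(counts)
  if (is.null(rownames(counts))) rownames(counts) <- channelLabels()
  storage.mode(counts) <- "double"
  new("MutationCatalog", counts = counts)
}

#' @title SignatureExtraction: de novo signatures at a fixed rank
#'
#' @description Result of bootstrap-stabilized KL-NMF at one signature
#' number k: consensus signature profiles (normalized 96-vectors),
#' per-sample exposures refit to the original catalog, silhouette-based
#' stability, and the generalized Kullback-Leibler reconstruction error.
#'
#' @slot k integer, number of signatures.
#' @slot profiles 96 x k matrix, columns sum to 1.
#' @slot exposures samples x k non-negative matrix (mutation counts
#'   attributed to each signature).
#' @slot stability mean silhouette width over pooled bootstrap profiles,
#'   in \[-1, 1\] (1 by convention at k = 1).
#' @slot perSignatureStability k silhouette means, one per cluster.
#' @slot reconstructionError generalized KL divergence of the refit.
#' @slot nBootstrap number of bootstrap replicates pooled.
#' @slot seed master seed of the run.
#' @slot degenerate TRUE if profile clustering kept an empty cluster
#'   after bounded retries (stability then reported as -1 for it).
#'
#' @exportClass SignatureExtraction
setClass("SignatureExtraction",
         slots = c(k = "integer",
                   profiles = "matrix",
                   exposures = "matrix",
                   stability = "numeric",
                   perSignatureStability = "numeric",
                   reconstructionError = "numeric",
                   nBootstrap = "integer",
                   seed = "integer",
                   degenerate = "logical"),
         prototype = prototype(degenerate = FALSE))

setValidity("SignatureExtraction", function(object) {
  msg <- character(0)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (any(object@profiles < -1e-12)) msg <- c(msg, "profiles must be >= 0")
  if (any(abs(colSums(object@profiles) - 1) > 1e-9))
    msg <- c(msg, "profile columns must sum to 1")
  if (any(object@exposures < -1e-9)) msg <- c(msg, "exposures must be >= 0")
  if (!is.na(object@stability) &&
      (object@stability < -1 - 1e-9 || object@stability > 1 + 1e-9))
    msg <- c(msg, "stability must lie in [-1, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
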