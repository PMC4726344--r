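## Parsing MAF-like tables, building 96-channel catalogs and the cohort
## summary statistics (mutation rate, Ti/Tv, VAF spectrum).

.COLUMN_ALIASES <- list(
  sample_id = c("sample", "sample_id", "tumor_sample_barcode"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "position", "start", "start_position"),
  ref = c("ref", "reference_allele", "ref_allele"),
  alt = c("alt", "alternate_allele", "alt_allele", "tumor_seq_allele2"),
  vaf = c("vaf", "allele_frequency", "allele_freq", "t_vaf"),
  gene = c("gene", "hugo_symbol", "gene_symbol"),
  context = c("context", "trinucleotide", "trinucleotide_context"))

#' Read a MAF-like somatic mutation table
#'
#' Parses a tab-separated table with a header naming at least sample,
#' chromosome, 1-based position, reference and alternate alleles
#' (case-insensitive; common MAF aliases such as `Tumor_Sample_Barcode`
#' and `Hugo_Symbol` are recognized). Optional columns: `VAF`, `Gene`,
#' `Context`; extra columns are preserved. Variant class is inferred from
#' allele lengths (both single bases: SNV; longer alt: insertion; longer
#' ref: deletion). When no context column is present and `fasta` is
#' given, the trinucleotide context of each SNV is looked up from the
#' reference sequence at `pos - 1 .. pos + 1`.
#'
#' @param path path to the TSV file.
#' @param fasta optional path to a FASTA file (or a named character
#'   vector of sequences) used to resolve SNV contexts.
#' @return A [`MutationTable-class`]; its `report` tallies
#'   `n_records`, `n_snv`, `n_indel`, `n_missing_vaf` and
#'   `n_unmappable_context` (contexts containing ambiguous bases).
#' @export
readMaf <- function(path, fasta = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(df))
  pick <- function(key) {
    hit <- which(lc %in% .COLUMN_ALIASES[[key]])
    if (length(hit)) hit[1] else NA_integer_
  }
  idx <- vapply(names(.COLUMN_ALIASES), pick, integer(1))
  for (key in c("sample_id", "chrom", "pos", "ref", "alt"))
    if (is.na(idx[[key]]))
      stop("missing required column: ", key, call. = FALSE)
  rec <- data.frame(
    sample_id = as.character(df[[idx[["sample_id"]]]]),
    chrom = as.character(df[[idx[["chrom"]]]]),
    pos = as.integer(df[[idx[["pos"]]]]),
    ref = toupper(as.character(df[[idx[["ref"]]]])),
    alt = toupper(as.character(df[[idx[["alt"]]]])),
    vaf = if (!is.na(idx[["vaf"]])) as.numeric(df[[idx[["vaf"]]]]) else NA_real_,
    gene = if (!is.na(idx[["gene"]])) as.character(df[[idx[["gene"]]]]) else NA_character_,
    context = if (!is.na(idx[["context"]])) toupper(as.character(df[[idx[["context"]]]])) else NA_character_,
    stringsAsFactors = FALSE)
  extra <- df[, setdiff(seq_along(df), idx[!is.na(idx)]), drop = FALSE]
  if (ncol(extra)) rec <- cbind(rec, extra)
  rec$variant_class <- .inferVariantClass(rec$ref, rec$alt)

  snv <- rec$variant_class == "SNV"
  if (!is.null(fasta) && any(snv & is.na(rec$context)))
    rec$context[snv & is.na(rec$context)] <-
      .contextFromFasta(fasta, rec$chrom[snv & is.na(rec$context)],
                        rec$pos[snv & is.na(rec$context)])

  bad <- snv & !is.na(rec$context) & nchar(rec$context) == 3L &
    !grepl("[^ACGTN]", rec$ref) &
    substr(rec$context, 2, 2) != rec$ref
  if (any(bad))
    stop("SNV context middle base does not match ref at row(s): ",
         paste(head(which(bad), 10), collapse = ", "), call. = FALSE)

  report <- list(
    n_records = nrow(rec),
    n_snv = sum(snv),
    n_indel = sum(!snv),
    n_missing_vaf = sum(is.na(rec$vaf)),
    n_unmappable_context = sum(snv & !is.na(rec$context) &
                                 grepl("N", rec$context)))
  MutationTable(rec, report = report)
}

.contextFromFasta <- function(fasta, chrom, pos) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs <- vapply(seq_along(seqs), function(i) as.character(seqs[[i]]),
                   character(1), USE.NAMES = FALSE) |>
      setNames(names(seqs))
  } else {
    seqs <- fasta
  }
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    if (!ch %in% names(seqs)) next
    sel <- chrom == ch
    out[sel] <- substring(seqs[[ch]], pos[sel] - 1L, pos[sel] + 1L)
  }
  toupper(out)
}

#' Read a sample-to-group assignment table
#'
#' @param path TSV with columns `sample` and `group` (header required).
#' @return Named character vector `sample -> group`.
#' @export
readGroups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("sample", "group") %in% names(df)))
  setNames(as.character(df$group), as.character(df$sample))
}

#' Build the 96-channel catalog of a cohort
#'
#' Counts the SNVs of every sample in the 96-trinucleotide channels (see
#' [channelOf()]). Indels are excluded; SNVs whose context contains an
#' ambiguous base are excluded and tallied in the `"excluded"` attribute;
#' samples without SNVs appear as all-zero columns.
#'
#' @param table a [`MutationTable-class`]; every SNV must carry a context.
#' @return A [`MutationCatalog-class`] (channels x samples).
#' @export
buildCatalog <- function(table) {
  df <- mutationRecords(table)
  snv <- df[df$variant_class == "SNV", , drop = FALSE]
  if (nrow(snv) && anyNA(snv$context))
    stop(sum(is.na(snv$context)),
         " SNV record(s) lack a trinucleotide context; supply a context ",
         "column or a FASTA to readMaf()", call. = FALSE)
  chans <- if (nrow(snv)) channelOf(snv$ref, snv$alt, snv$context)
           else character(0)
  keep <- !is.na(chans)
  m <- table(factor(chans[keep], levels = channelLabels()),
             factor(snv$sample_id[keep], levels = sampleIds(table)))
  m <- matrix(as.numeric(m), nrow = 96L,
              dimnames = list(channelLabels(), sampleIds(table)))
  out <- MutationCatalog(m)
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Per-sample and cohort mutation rates
#'
#' Coding mutations (SNVs and indels) per megabase, assuming the exome
#' covers `exomeMb` megabases of protein-coding sequence.
#'
#' @param table a [`MutationTable-class`].
#' @param exomeMb exome size in Mb (default 30).
#' @return List with `rates` (named per-sample mutations/Mb), `median`
#'   and `range` over samples.
#' @examples
#' # a sample with 411 coding mutations has 411/30 = 13.7 mutations/Mb
#' @export
mutationRate <- function(table, exomeMb = 30) {
  stopifnot(exomeMb > 0)
  df <- mutationRecords(table)
  ids <- sampleIds(table)
  n <- table(factor(df$sample_id, levels = ids))
  rates <- setNames(as.numeric(n) / exomeMb, ids)
  list(rates = rates,
       median = median(rates),
       range = if (length(rates)) range(rates) else c(NA_real_, NA_real_))
}

#' Transition/transversion ratio
#'
#' Transitions are `C>T`, `T>C`, `G>A`, `A>G`; the other eight stranded
#' substitutions are transversions. Only SNVs are considered.
#'
#' @param table a [`MutationTable-class`].
#' @param perSample if `TRUE`, return per-sample ratios and the cohort
#'   median.
#' @return For `perSample = FALSE` a single ratio (with attribute
#'   `infinite = TRUE` when there are no transversions); otherwise a list
#'   with `per_sample` (data.frame: sample_id, transitions,
#'   transversions, ratio, infinite) and `median`.
#' @export
titvRatio <- function(table, perSample = FALSE) {
  df <- mutationRecords(table)
  snv <- df[df$variant_class == "SNV", , drop = FALSE]
  is_ti <- paste0(snv$ref, ">", snv$alt) %in% .TRANSITIONS
  ratio1 <- function(ti, tv) if (tv == 0) Inf else ti / tv
  if (!perSample) {
    r <- ratio1(sum(is_ti), sum(!is_ti))
    return(structure(r, infinite = is.infinite(r)))
  }
  ids <- sampleIds(table)
  ti <- tapply(is_ti, factor(snv$sample_id, levels = ids), sum,
               default = 0)
  tv <- tapply(!is_ti, factor(snv$sample_id, levels = ids), sum,
               default = 0)
  ratio <- mapply(ratio1, ti, tv)
  list(per_sample = data.frame(sample_id = ids,
                               transitions = as.integer(ti),
                               transversions = as.integer(tv),
                               ratio = as.numeric(ratio),
                               infinite = is.infinite(ratio),
                               row.names = NULL),
       median = median(ratio))
}

#' Fraction of SNVs below a VAF threshold
#'
#' Overall fraction of SNVs with variant allele frequency strictly below
#' `threshold`, and the same fraction within each of the six
#' pyrimidine-referenced substitution classes (so the class-specific
#' low-VAF burden of C>A transversions can be reported). SNVs with
#' missing VAF are excluded and counted.
#'
#' @param table a [`MutationTable-class`].
#' @param threshold VAF threshold in (0, 1], default 0.2.
#' @return List with `overall`, `by_class` (named over the six classes,
#'   `NaN` where a class is absent), `n_snv` (with VAF) and
#'   `n_missing_vaf`.
#' @export
vafSpectrum <- function(table, threshold = 0.2) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  df <- mutationRecords(table)
  snv <- df[df$variant_class == "SNV", , drop = FALSE]
  miss <- is.na(snv$vaf)
  snv <- snv[!miss, , drop = FALSE]
  low <- snv$vaf < threshold
  cls <- .substitutionClass(snv$ref, snv$alt)
  by_class <- vapply(.SUBS, function(s) {
    sel <- !is.na(cls) & cls == s
    if (!any(sel)) NaN else mean(low[sel])
  }, numeric(1))
  list(overall = if (nrow(snv)) mean(low) else NaN,
       by_class = by_class,
       n_snv = nrow(snv),
       n_missing_vaf = sum(miss))
}

#' Write / read a 96-channel catalog as TSV
#'
#' The file has a `channel` column (labels as in [channelLabels()]) and
#' one column per sample.
#'
#' @param catalog a [`MutationCatalog-class`].
#' @param path output (input) file path.
#' @return `writeCatalog` returns `path` invisibly; `readCatalog` a
#'   [`MutationCatalog-class`].
#' @export
writeCatalog <- function(catalog, path) {
  df <- data.frame(channel = channelLabels(), counts(catalog),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stopifnot(identical(rownames(m), channelLabels()))
  MutationCatalog(m)
}
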