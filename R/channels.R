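## The 96-trinucleotide classification: six pyrimidine-referenced
## substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each split by the
## 5' and 3' bases flanking the mutated position. Channel order is
## substitution-major, then 5' base A,C,G,T, then 3' base A,C,G,T — the
## de facto community convention, so bundled reference profiles align by
## index.

.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")
.TRANSITIONS <- c("C>T", "T>C", "G>A", "A>G")

.channelLabels <- local({
  labs <- NULL
  function() {
    if (is.null(labs)) {
      grid <- expand.grid(three = .BASES, five = .BASES, sub = .SUBS,
                          stringsAsFactors = FALSE)
      labs <<- paste0(grid$five, "[", grid$sub, "]", grid$three)
    }
    labs
  }
})

#' The fixed 96 channel labels
#'
#' Labels of the 96-trinucleotide classification in package order:
#' substitution-major (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`), then 5'
#' base `A,C,G,T`, then 3' base `A,C,G,T`; e.g. `"A[C>A]A"` is channel 1.
#'
#' @return Character vector of length 96.
#' @examples
#' channelLabels()[1:4]
#' @export
channelLabels <- function() .channelLabels()

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverseComplement("TGG")  # "CCA"
#' @export
reverseComplement <- function(x) {
  out <- vapply(strsplit(.complement(x), ""), function(s)
    paste(rev(s), collapse = ""), character(1))
  unname(out)
}

#' Map a mutation to its 96-trinucleotide channel
#'
#' Mutations with a purine (A/G) reference base are projected onto the
#' reverse-complement strand so the returned channel always carries a
#' pyrimidine (C/T) reference; the mapping is total over all 192 stranded
#' single-base substitutions. Contexts containing `N` (or other ambiguous
#' bases) are unmappable and yield `NA`.
#'
#' @param ref,alt single reference/alternate bases (vectors recycle
#'   against `context`).
#' @param context 3-letter reference-strand trinucleotide centered on the
#'   mutated base; its middle base must equal `ref`.
#' @return Character vector of channel labels (see [channelLabels()]),
#'   `NA` where the context is ambiguous.
#' @examples
#' channelOf("C", "A", "CCA")  # "C[C>A]A"
#' channelOf("G", "T", "TGG")  # "C[C>A]A" via the reverse complement
#' @export
channelOf <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  context <- toupper(rep_len(as.character(context), n))
  core <- !is.na(ref) & !is.na(alt) & ref %in% .BASES & alt %in% .BASES
  if (any(core & ref == alt))
    stop("ref and alt must differ for an SNV")
  ok_ctx <- !is.na(context) & nchar(context) == 3L &
    !grepl("[^ACGT]", context)
  mid <- substr(context, 2, 2)
  bad_mid <- core & ok_ctx & mid != ref
  if (any(bad_mid))
    stop("context middle base does not match ref at position(s): ",
         paste(head(which(bad_mid), 10), collapse = ", "))
  mappable <- core & ok_ctx
  out <- rep(NA_character_, n)
  if (any(mappable)) {
    r <- ref[mappable]; a <- alt[mappable]; ctx <- context[mappable]
    flip <- r %in% c("A", "G")
    r[flip] <- .complement(r[flip])
    a[flip] <- .complement(a[flip])
    ctx[flip] <- reverseComplement(ctx[flip])
    out[mappable] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]",
                            substr(ctx, 3, 3))
  }
  out
}

## Pyrimidine-referenced substitution class (no context needed); NA for
## ambiguous bases.
.substitutionClass <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% .BASES & alt %in% .BASES & ref != alt
  flip <- ok & ref %in% c("A", "G")
  ref[flip] <- .complement(ref[flip])
  alt[flip] <- .complement(alt[flip])
  out <- ifelse(ok, paste0(ref, ">", alt), NA_character_)
  out
}
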