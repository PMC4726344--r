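#' @importFrom BiocGenerics counts
NULL

#' Accessors for platisig containers
#'
#' `mutationRecords()` returns the record data.frame; `sampleIds()` the
#' distinct sample identifiers in first-appearance order; `sampleGroups()`
#' the named group vector (empty when ungrouped); `counts()` the
#' 96 x samples channel count matrix of a catalog;
#' `signatureProfiles()`/`signatureExposures()`/`stability()` the slots of
#' a [`SignatureExtraction-class`].
#'
#' @param object a platisig object.
#' @param x a platisig object (for `sampleIds`).
#' @return See description; matrices and vectors carry dimnames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mutationRecords", function(object) standardGeneric("mutationRecords"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("signatureProfiles", function(object) standardGeneric("signatureProfiles"))

#' @rdname accessors
#' @export
setGeneric("signatureExposures", function(object) standardGeneric("signatureExposures"))

#' @rdname accessors
#' @export
setGeneric("stability", function(object) standardGeneric("stability"))

#' @rdname accessors
#' @export
setMethod("mutationRecords", "MutationTable", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("sampleIds", "MutationTable", function(x) {
  ids <- unique(x@records$sample_id)
  if (length(x@groups)) unique(c(ids, names(x@groups))) else ids
})

#' @rdname accessors
#' @export
setMethod("sampleGroups", "MutationTable", function(object) object@groups)

#' @rdname accessors
#' @aliases counts,MutationCatalog-method
#' @export
setMethod("counts", "MutationCatalog", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("sampleIds", "MutationCatalog", function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setMethod("signatureProfiles", "SignatureExtraction", function(object) object@profiles)

#' @rdname accessors
#' @export
setMethod("signatureExposures", "SignatureExtraction", function(object) object@exposures)

#' @rdname accessors
#' @export
setMethod("stability", "SignatureExtraction", function(object) object@stability)

setMethod("show", "MutationTable", function(object) {
  df <- object@records
  cat("MutationTable with", nrow(df), "records over",
      length(sampleIds(object)), "samples\n")
  cls <- table(df$variant_class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  if (length(object@groups)) {
    g <- table(object@groups)
    cat("  groups: ", paste(names(g), g, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "MutationCatalog", function(object) {
  m <- object@counts
  cat("MutationCatalog: 96 channels x", ncol(m), "samples;",
      "total SNVs =", sum(m), "\n")
})

setMethod("show", "SignatureExtraction", function(object) {
  cat("SignatureExtraction: k =", object@k,
      "| stability =", round(object@stability, 3),
      "| KL reconstruction error =",
      signif(object@reconstructionError, 5), "\n")
  cat("  bootstraps =", object@nBootstrap, "| seed =", object@seed, "\n")
  if (object@degenerate) cat("  WARNING: degenerate clustering\n")
})
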