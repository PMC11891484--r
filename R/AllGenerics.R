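#' Accessors for VariantPanel objects
#'
#' \code{genotypes()} returns the integer ALT-allele (after polarization:
#' derived-allele) dosage matrix, sites x samples, \code{NA} = missing;
#' \code{depths()} the per-genotype depth matrix (or \code{NULL});
#' \code{refAllele()}, \code{altAllele()}, \code{qualScores()} and
#' \code{ancestralAllele()} the per-site metadata; \code{positions()} the
#' 1-based coordinates and \code{chromosomes()} their chromosome names;
#' \code{filterReport()} the per-step removal counts recorded by
#' [filterVariants()] and \code{polarizationReport()} the drop counts
#' recorded by [polarizeVariants()].
#'
#' @param x a [VariantPanel-class]
#' @return see details above
#' @name panel-accessors
#' @aliases genotypes depths refAllele altAllele qualScores ancestralAllele
#'   positions chromosomes filterReport polarizationReport
NULL

#' @rdname panel-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname panel-accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname panel-accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname panel-accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname panel-accessors
#' @export
setGeneric("qualScores", function(x) standardGeneric("qualScores"))
#' @rdname panel-accessors
#' @export
setGeneric("ancestralAllele", function(x) standardGeneric("ancestralAllele"))
#' @rdname panel-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname panel-accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname panel-accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))
#' @rdname panel-accessors
#' @export
setGeneric("polarizationReport", function(x) standardGeneric("polarizationReport"))

#' @rdname panel-accessors
setMethod("genotypes", "VariantPanel", function(x) assay(x, "gt"))
#' @rdname panel-accessors
setMethod("depths", "VariantPanel", function(x) {
  if ("dp" %in% names(assays(x))) assay(x, "dp") else NULL
})
#' @rdname panel-accessors
setMethod("refAllele", "VariantPanel", function(x) rowData(x)$ref)
#' @rdname panel-accessors
setMethod("altAllele", "VariantPanel", function(x) rowData(x)$alt)
#' @rdname panel-accessors
setMethod("qualScores", "VariantPanel", function(x) rowData(x)$qual)
#' @rdname panel-accessors
setMethod("ancestralAllele", "VariantPanel", function(x) rowData(x)$aa)
#' @rdname panel-accessors
setMethod("positions", "VariantPanel", function(x) start(rowRanges(x)))
#' @rdname panel-accessors
setMethod("chromosomes", "VariantPanel",
          function(x) as.character(seqnames(rowRanges(x))))
#' @rdname panel-accessors
setMethod("filterReport", "VariantPanel",
          function(x) metadata(x)$filterReport)
#' @rdname panel-accessors
setMethod("polarizationReport", "VariantPanel",
          function(x) metadata(x)$polarization)
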