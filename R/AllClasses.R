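#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData rowData
NULL

#' Multi-sample SNP panel
#'
#' A \code{VariantPanel} holds a biallelic-SNP genotype panel as a
#' \linkS4class{RangedSummarizedExperiment}: one row per site, one column per
#' sample.  Assay \code{"gt"} is the integer count of ALT alleles (0, 1, 2, or
#' \code{NA} for missing / non-biallelic calls); assay \code{"dp"} (optional)
#' is per-genotype sequencing depth.  Row metadata carries \code{ref},
#' \code{alt} (comma-joined when multi-allelic), \code{qual}, the number of
#' ALT alleles \code{nAlt}, and the ancestral allele \code{aa} when known
#' (VCF INFO/AA or a sidecar table).
#'
#' Sites must be sorted by position within each chromosome; this is enforced
#' by the validity method so every downstream window and gap computation can
#' rely on it.
#'
#' @seealso [readVcfPanel()], [filterVariants()], [polarizeVariants()]
#' @export
setClass("VariantPanel", contains = "RangedSummarizedExperiment")

setValidity("VariantPanel", function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("ref", "alt", "qual", "nAlt")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (!"gt" %in% names(assays(object)))
    msg <- c(msg, "assay 'gt' is required")
  if (nrow(object) > 1L) {
    chr <- as.character(seqnames(rowRanges(object)))
    pos <- start(rowRanges(object))
    same <- chr[-1L] == chr[-length(chr)]
    if (any(same & pos[-1L] <= pos[-length(pos)]))
      msg <- c(msg, "positions must be strictly increasing within each chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Ancestrally polarized SNP panel
#'
#' A \code{PolarizedVariantPanel} is a [VariantPanel-class] restricted to
#' sites whose reference allele equals the ancestral allele, so the \code{gt}
#' assay reads directly as the derived-allele dosage (0/1/2).  Sites where
#' the ancestral state is missing, equals ALT, or is neither allele are
#' dropped (not re-oriented) by [polarizeVariants()]; the per-category drop
#' counts live in \code{metadata(x)$polarization}.
#'
#' @export
setClass("PolarizedVariantPanel", contains = "VariantPanel")

setValidity("PolarizedVariantPanel", function(object) {
  rd <- rowData(object)
  if (!"aa" %in% colnames(rd))
    return("rowData must contain the ancestral allele column 'aa'")
  if (nrow(object) && !all(rd$aa == rd$ref, na.rm = FALSE))
    return("all retained sites must have ancestral == ref")
  TRUE
})

#' Runs-of-homozygosity scanner parameters
#'
#' Mirrors the PLINK \code{--homozyg} parameterisation.  The four headline
#' knobs (\code{minSnps}, \code{minKb}, \code{densityKbPerSnp},
#' \code{maxGapKb}) default to the scanner settings
#' \code{--homozyg-snp 10 --homozyg-kb 100 --homozyg-density 10
#' --homozyg-gap 100}; the window machinery (\code{windowSnps},
#' \code{windowMaxHet}, \code{windowMaxMissing}, \code{hitThreshold})
#' defaults to that tool's defaults (50 / 1 / 5 / 0.05).
#'
#' @slot minSnps minimum SNPs (non-missing) per reported segment
#' @slot minKb minimum segment length, kb
#' @slot densityKbPerSnp maximum average kb per SNP inside a segment
#' @slot maxGapKb inter-SNP gap that splits a candidate segment, kb
#' @slot windowSnps scanning window size, SNPs
#' @slot windowMaxHet maximum heterozygous calls for a window to count as homozygous
#' @slot windowMaxMissing maximum missing calls per homozygous window
#' @slot hitThreshold minimum fraction of overlapping homozygous windows for a SNP to be "in" a run
#' @export
setClass("RohParams",
  representation(minSnps = "integer", minKb = "numeric",
                 densityKbPerSnp = "numeric", maxGapKb = "numeric",
                 windowSnps = "integer", windowMaxHet = "integer",
                 windowMaxMissing = "integer", hitThreshold = "numeric"),
  prototype(minSnps = 10L, minKb = 100, densityKbPerSnp = 10, maxGapKb = 100,
            windowSnps = 50L, windowMaxHet = 1L, windowMaxMissing = 5L,
            hitThreshold = 0.05))

setValidity("RohParams", function(object) {
  vals <- c(object@minSnps, object@minKb, object@densityKbPerSnp,
            object@maxGapKb, object@windowSnps, object@hitThreshold)
  if (any(vals <= 0)) return("all scanner parameters must be positive")
  if (object@hitThreshold > 1) return("hitThreshold must lie in (0, 1]")
  if (object@windowMaxHet < 0 || object@windowMaxMissing < 0)
    return("window het/missing tolerances must be non-negative")
  TRUE
})

#' @rdname RohParams-class
#' @param minSnps,minKb,densityKbPerSnp,maxGapKb,windowSnps,windowMaxHet,windowMaxMissing,hitThreshold see slots
#' @return a \code{RohParams} object
#' @examples
#' RohParams()                 # the published scanner settings
#' RohParams(minKb = 200)
#' @export
RohParams <- function(minSnps = 10L, minKb = 100, densityKbPerSnp = 10,
                      maxGapKb = 100, windowSnps = 50L, windowMaxHet = 1L,
                      windowMaxMissing = 5L, hitThreshold = 0.05) {
  new("RohParams", minSnps = as.integer(minSnps), minKb = minKb,
      densityKbPerSnp = densityKbPerSnp, maxGapKb = maxGapKb,
      windowSnps = as.integer(windowSnps),
      windowMaxHet = as.integer(windowMaxHet),
      windowMaxMissing = as.integer(windowMaxMissing),
      hitThreshold = hitThreshold)
}

#' Variant filter settings
#'
#' The filter cascade applied by [filterVariants()], in order: site quality,
#' biallelic SNPs only, per-genotype depth masking, site missingness, minor
#' allele frequency.  Defaults reproduce the cascade
#' \code{--minQ 30 --min-alleles 2 --max-alleles 2 --minDP 8 --maxDP 47
#' --max-missing 0.9 --maf 0.01}.  Depth bounds are fixed integers, never
#' derived from the realised mean depth, so a given configuration is
#' deterministic across panels.
#'
#' @slot minQual minimum site QUAL
#' @slot minDp,maxDp inclusive per-genotype depth bounds; calls outside are set missing
#' @slot maxMissingFraction drop sites whose missing-call fraction exceeds this
#' @slot minMaf drop sites with minor allele frequency strictly below this
#' @export
setClass("FilterParams",
  representation(minQual = "numeric", minDp = "numeric", maxDp = "numeric",
                 maxMissingFraction = "numeric", minMaf = "numeric"),
  prototype(minQual = 30, minDp = 8, maxDp = 47,
            maxMissingFraction = 0.1, minMaf = 0.01))

setValidity("FilterParams", function(object) {
  if (object@maxMissingFraction < 0 || object@maxMissingFraction > 1)
    return("maxMissingFraction must lie in [0, 1]")
  if (object@minMaf < 0 || object@minMaf > 0.5)
    return("minMaf must lie in [0, 0.5]")
  if (object@minDp > object@maxDp) return("minDp must be <= maxDp")
  TRUE
})

#' @rdname FilterParams-class
#' @param minQual,minDp,maxDp,maxMissingFraction,minMaf see slots
#' @return a \code{FilterParams} object
#' @export
FilterParams <- function(minQual = 30, minDp = 8, maxDp = 47,
                         maxMissingFraction = 0.1, minMaf = 0.01) {
  new("FilterParams", minQual = minQual, minDp = minDp, maxDp = maxDp,
      maxMissingFraction = maxMissingFraction, minMaf = minMaf)
}

#' Watterson effective-population-size estimate
#'
#' Bundles every intermediate of the estimator chain
#' \eqn{S = N_{SNP}/L_{genome}}, \eqn{\theta_W = S/a_n} with
#' \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, and \eqn{N_e = \theta_W/(4\mu)},
#' where \eqn{n} counts sampled haploid sequences (2 x diploid individuals)
#' and \eqn{\mu} is the per-site per-year mutation rate (use
#' [perGenerationRate()] to convert explicitly; nothing converts silently).
#'
#' @slot nSnp segregating-site count
#' @slot lGenome genome length surveyed, bp
#' @slot nSeq sampled sequence (haploid) count
#' @slot aN harmonic number \eqn{a_n}
#' @slot S per-site proportion of segregating sites
#' @slot theta Watterson's \eqn{\theta} per site
#' @slot mu mutation rate per site per year
#' @slot Ne effective population size (diploid individuals)
#' @seealso [wattersonNe()]
#' @export
setClass("NeEstimate",
  representation(nSnp = "numeric", lGenome = "numeric", nSeq = "integer",
                 aN = "numeric", S = "numeric", theta = "numeric",
                 mu = "numeric", Ne = "numeric"))

setMethod("show", "NeEstimate", function(object) {
  cat("Watterson N_e estimate\n")
  cat(sprintf("  N_SNP     : %s\n", format(object@nSnp, big.mark = ",")))
  cat(sprintf("  L_genome  : %s bp\n", format(object@lGenome, big.mark = ",")))
  cat(sprintf("  n (seqs)  : %d\n", object@nSeq))
  cat(sprintf("  a_n       : %.6g\n", object@aN))
  cat(sprintf("  S         : %.6g\n", object@S))
  cat(sprintf("  theta_W   : %.6g per site\n", object@theta))
  cat(sprintf("  mu        : %.3g per site per year\n", object@mu))
  cat(sprintf("  N_e       : %.4g\n", object@Ne))
})

setMethod("show", "VariantPanel", function(object) {
  cat(sprintf("%s: %d sites x %d samples\n", class(object),
              nrow(object), ncol(object)))
  if (nrow(object)) {
    chr <- unique(as.character(seqnames(rowRanges(object))))
    cat(sprintf("  chromosomes: %s\n",
                paste(utils::head(chr, 5), collapse = ", ")))
  }
  if (!is.null(metadata(object)$filterReport))
    cat("  filtered: yes (see filterReport())\n")
  if (is(object, "PolarizedVariantPanel"))
    cat("  polarized: ancestral == REF at every site\n")
})
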