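#' Apply the variant-filter cascade
#'
#' Filters run strictly in order: (1) site QUAL below \code{minQual}; (2)
#' non-biallelic or non-SNP records; (3) per-genotype depth masking — calls
#' with depth outside \code{[minDp, maxDp]} are set missing (no site is
#' removed at this step); (4) sites whose missing-call fraction exceeds
#' \code{maxMissingFraction}; (5) sites with minor allele frequency below
#' \code{minMaf}.  The cascade is idempotent and per-step removals plus
#' survivors always sum to the input site count.
#'
#' @param x a [VariantPanel-class]
#' @param params a [FilterParams-class]
#' @return the filtered panel; the per-step report (named integer vector
#'   with elements \code{qual}, \code{biallelic}, \code{missingness},
#'   \code{maf}, \code{retained}) is stored in \code{metadata()} and read by
#'   [filterReport()]
#' @examples
#' sim <- simulatePopulations(simConfig(seed = 1))
#' fp <- filterVariants(sim$panel, FilterParams(minQual = 0, minMaf = 0,
#'                                              maxMissingFraction = 1))
#' filterReport(fp)
#' @export
filterVariants <- function(x, params = FilterParams()) {
  stopifnot(is(x, "VariantPanel"), is(params, "FilterParams"))
  nIn <- nrow(x)
  report <- c(qual = 0L, biallelic = 0L, missingness = 0L, maf = 0L,
              retained = 0L)

  # (1) site quality
  q <- qualScores(x)
  keep <- !is.na(q) & q >= params@minQual
  keep[is.na(q)] <- TRUE      # records with QUAL "." are not testable; keep
  report["qual"] <- sum(!keep)
  x <- x[keep, ]

  # (2) biallelic single-base SNPs only
  rd <- rowData(x)
  keep <- rd$nAlt == 1L & nchar(rd$ref) == 1L & nchar(rd$alt) == 1L &
    rd$ref %in% c("A", "C", "G", "T") & rd$alt %in% c("A", "C", "G", "T")
  report["biallelic"] <- sum(!keep)
  x <- x[keep, ]

  # (3) depth mask: genotype-level, removes nothing by itself
  gt <- genotypes(x)
  dp <- depths(x)
  if (!is.null(dp)) {
    mask <- !is.na(dp) & (dp < params@minDp | dp > params@maxDp)
    gt[mask] <- NA_integer_
    SummarizedExperiment::assay(x, "gt") <- gt
  }

  # (4) site missingness after masking
  if (nrow(x)) {
    missFrac <- rowMeans(is.na(gt))
    keep <- missFrac <= params@maxMissingFraction
    report["missingness"] <- sum(!keep)
    x <- x[keep, ]
    gt <- gt[keep, , drop = FALSE]
  }

  # (5) minor allele frequency on non-missing calls
  if (nrow(x)) {
    nCalled <- rowSums(!is.na(gt))
    p <- rowSums(gt, na.rm = TRUE) / (2 * pmax(nCalled, 1L))
    maf <- pmin(p, 1 - p)
    keep <- nCalled > 0L & maf >= params@minMaf
    report["maf"] <- sum(!keep)
    x <- x[keep, ]
  }

  report["retained"] <- nrow(x)
  stopifnot(sum(report) == nIn)
  metadata(x)$filterReport <- report
  x
}

#' Polarize a panel by ancestral allele
#'
#' Retains only sites whose reference allele matches the ancestral state, so
#' the ALT dosage reads directly as derived-allele dosage.  Sites where the
#' ancestral allele equals ALT are \emph{dropped, not re-oriented} — the
#' convention for building a derived-allele panel by excluding sites with
#' reference alleles inconsistent with ancestral states — as are sites whose
#' ancestral state is missing or is neither REF nor ALT.
#'
#' @param x a [VariantPanel-class]
#' @param ancestral optional data.frame (\code{chrom}, \code{pos},
#'   \code{aa}) overriding / supplying ancestral alleles; by default the
#'   INFO/AA values carried by the panel are used
#' @return a [PolarizedVariantPanel-class]; drop counts (named vector with
#'   \code{retained}, \code{refNotAncestral}, \code{unpolarizable}) in
#'   \code{metadata()$polarization}, read by [polarizationReport()]
#' @export
polarizeVariants <- function(x, ancestral = NULL) {
  stopifnot(is(x, "VariantPanel"))
  aa <- ancestralAllele(x)
  if (!is.null(ancestral)) {
    key <- paste(ancestral$chrom, ancestral$pos)
    idx <- match(paste(chromosomes(x), positions(x)), key)
    aa <- ifelse(is.na(idx), NA_character_, ancestral$aa[idx])
  }
  aa <- toupper(aa)
  ref <- refAllele(x)
  alt <- altAllele(x)
  isRef <- !is.na(aa) & aa == ref
  isAlt <- !is.na(aa) & aa == alt
  report <- c(retained = sum(isRef),
              refNotAncestral = sum(isAlt),
              unpolarizable = sum(!isRef & !isAlt))
  if (!any(isRef))
    warning("no site with ancestral == REF; polarized panel is empty",
            call. = FALSE)
  out <- x[isRef, ]
  rowData(out)$aa <- aa[isRef]
  metadata(out)$polarization <- report
  new("PolarizedVariantPanel", out)
}
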