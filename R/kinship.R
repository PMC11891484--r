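#' KING-robust kinship for one pair
#'
#' The between-family robust estimator, computed over sites where both
#' samples are called:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{2\,\min(N_{Aa}^{(i)}, N_{Aa}^{(j)})}
#'   + \frac12 - \frac{N_{Aa}^{(i)} + N_{Aa}^{(j)}}{4\,\min(N_{Aa}^{(i)}, N_{Aa}^{(j)})}}
#' where \eqn{N_{Aa}^{(\cdot)}} are the single-sample heterozygote counts,
#' \eqn{N_{Aa,Aa}} the both-heterozygous count and \eqn{N_{AA,aa}} the
#' opposing-homozygote count.  It is robust to population structure because
#' no allele-frequency estimate enters.  Sites with panel minor allele
#' frequency below \code{minMaf} are excluded by default (estimator
#' stability); the estimate is invariant to swapping allele labels at any
#' site.
#'
#' @param x a [VariantPanel-class]
#' @param i,j sample names
#' @param minSites minimum mutually called polymorphic sites (else error)
#' @param minMaf MAF cutoff (set 0 to disable)
#' @return one-row data.frame: ID1, ID2, N_SNP, HetHet, IBS0, ibs0Rate,
#'   Kinship, InfType
#' @export
kingRobust <- function(x, i, j, minSites = 100L, minMaf = 0.05) {
  kingPairs(x, samples = c(i, j), minSites = minSites, minMaf = minMaf)
}

#' KING-robust kinship for all sample pairs
#'
#' @param x a [VariantPanel-class]
#' @param samples optional subset (default all panel samples)
#' @param minSites minimum mutually called polymorphic sites per pair
#' @param minMaf panel MAF cutoff applied before pair counting
#' @param thresholds passed to [classifyRelationship()]
#' @return data.frame, one row per unordered pair
#' @export
kingPairs <- function(x, samples = NULL, minSites = 100L, minMaf = 0.05,
                      thresholds = kingThresholds()) {
  gt <- genotypes(x)
  if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
  nCalled <- rowSums(!is.na(gt))
  p <- rowSums(gt, na.rm = TRUE) / (2 * pmax(nCalled, 1L))
  maf <- pmin(p, 1 - p)
  gt <- gt[nCalled > 0L & maf >= minMaf & maf > 0, , drop = FALSE]
  ns <- ncol(gt)
  ids <- colnames(gt)
  H <- matrix(0, nrow(gt), ns); H[which(gt == 1L)] <- 1      # het
  A <- matrix(0, nrow(gt), ns); A[which(gt == 2L)] <- 1      # hom-alt
  R <- matrix(0, nrow(gt), ns); R[which(gt == 0L)] <- 1      # hom-ref
  M <- matrix(0, nrow(gt), ns); M[which(!is.na(gt))] <- 1    # called
  hetHet <- crossprod(H)
  ibs0 <- crossprod(A, R) + crossprod(R, A)
  nPair <- crossprod(M)
  hetI <- crossprod(H, M)        # [i, j] = het count of i over sites called in both
  out <- list()
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    nab <- nPair[a, b]
    if (nab < minSites)
      stop(sprintf("pair %s-%s has only %d mutually called sites (< %d)",
                   ids[a], ids[b], nab, minSites), call. = FALSE)
    nI <- hetI[a, b]; nJ <- hetI[b, a]
    mn <- min(nI, nJ)
    if (mn == 0) {
      phi <- NA_real_; lab <- "undefined"
    } else {
      phi <- (hetHet[a, b] - 2 * ibs0[a, b]) / (2 * mn) + 0.5 -
        (nI + nJ) / (4 * mn)
      lab <- classifyRelationship(phi, ibs0[a, b] / nab, thresholds)
    }
    out[[length(out) + 1L]] <- data.frame(
      ID1 = ids[a], ID2 = ids[b], N_SNP = nab,
      HetHet = hetHet[a, b], IBS0 = ibs0[a, b],
      ibs0Rate = ibs0[a, b] / nab, Kinship = phi, InfType = lab)
  }
  do.call(rbind, out)
}

#' Relationship-degree thresholds
#'
#' The powers-of-two midpoints used by KING: duplicate/MZ above
#' \eqn{2^{-3/2}}, first degree down to \eqn{2^{-5/2}}, second to
#' \eqn{2^{-7/2}}, third to \eqn{2^{-9/2}}; the parent-offspring /
#' full-sibling split within first degree falls to the opposing-homozygote
#' rate (PO pairs cannot show opposing homozygotes absent genotype error).
#'
#' @param ibs0PoMax maximum IBS0 rate for a first-degree pair to be called PO
#' @return named list of cutoffs
#' @export
kingThresholds <- function(ibs0PoMax = 0.005) {
  list(dup = 2^(-3/2), first = 2^(-5/2), second = 2^(-7/2),
       third = 2^(-9/2), ibs0PoMax = ibs0PoMax)
}

#' Classify a kinship estimate into a relationship degree
#'
#' @param phi kinship estimate
#' @param ibs0Rate opposing-homozygote rate for the pair
#' @param thresholds from [kingThresholds()]
#' @return one of \code{"Dup/MZ"}, \code{"PO"}, \code{"FS"}, \code{"2nd"},
#'   \code{"3rd"}, \code{"unrelated"}
#' @export
classifyRelationship <- function(phi, ibs0Rate, thresholds = kingThresholds()) {
  if (is.na(phi)) return("undefined")
  t <- thresholds
  if (phi > t$dup) return("Dup/MZ")
  if (phi > t$first)
    return(if (ibs0Rate < t$ibs0PoMax) "PO" else "FS")
  if (phi > t$second) return("2nd")
  if (phi > t$third) return("3rd")
  "unrelated"
}
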