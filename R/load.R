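#' Per-individual derived-allele counts by mutation class
#'
#' Counts derived alleles over the sites of each class — each heterozygous
#' site once, each homozygous-derived site twice — plus the homozygous load
#' (2 x number of homozygous-derived genotypes).  Missing genotypes
#' contribute 0 (the fixed-denominator convention; no per-individual
#' rescaling).
#'
#' @param x a [PolarizedVariantPanel-class]
#' @param classification data.frame from [classifyMutations()], or any
#'   data.frame with logical class columns aligned to panel rows via
#'   \code{chrom}/\code{pos}
#' @param classes class column names to count (a \code{total} class over all
#'   panel sites is always added)
#' @return data.frame: sample, class, nDerived, nHom, homLoad
#' @export
derivedCounts <- function(x, classification,
                          classes = c("DEL", "RADICAL", "LOF")) {
  gt <- genotypes(x)
  idx <- match(paste(chromosomes(x), positions(x)),
               paste(classification$chrom, classification$pos))
  out <- list()
  for (cl in c(classes, "total")) {
    inClass <- if (cl == "total") rep(TRUE, nrow(gt)) else {
      flag <- classification[[cl]][idx]
      !is.na(flag) & flag
    }
    sub <- gt[inClass, , drop = FALSE]
    nDer <- colSums(sub, na.rm = TRUE)
    nHom <- colSums(sub == 2L, na.rm = TRUE)
    out[[cl]] <- data.frame(sample = colnames(gt), class = cl,
                            nDerived = as.integer(nDer),
                            nHom = as.integer(nHom),
                            homLoad = 2L * as.integer(nHom),
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Population mean derived-allele ratio
#'
#' \deqn{p = \frac{1}{n}\sum_{i=1}^{n} \frac{N_{derived}^{(i)}}{2\,N_{SNPs}^{total}}}
#' — the mean, over a population's \eqn{n} individuals, of each
#' individual's derived-allele count divided by twice the total SNP
#' universe used for deleterious-mutation annotation.
#'
#' @param nDerived per-individual derived-allele counts for one population
#' @param nSnpsTotal size of the polarized SNP universe (> 0)
#' @return numeric p in \code{[0, 1]}
#' @export
meanDerivedRatio <- function(nDerived, nSnpsTotal) {
  if (!length(nDerived)) stop("no individuals", call. = FALSE)
  if (nSnpsTotal <= 0) stop("nSnpsTotal must be positive", call. = FALSE)
  mean(nDerived / (2 * nSnpsTotal))
}

#' Purging-efficiency relative ratio R_p
#'
#' \eqn{R_p = p^{class} / p^{total}}: the class-specific mean derived-allele
#' ratio corrected by the all-SNP ratio.  Values below 1 indicate a
#' relative deficit of class-derived alleles — stronger purging of that
#' mutation class.
#'
#' @param pClass,pTotal mean derived-allele ratios (\code{pTotal > 0})
#' @return numeric ratio
#' @export
relativeRatio <- function(pClass, pTotal) {
  if (any(pTotal <= 0)) stop("pTotal must be positive", call. = FALSE)
  pClass / pTotal
}

#' Per-population load summary with R_p
#'
#' Combines [derivedCounts()], [meanDerivedRatio()] and [relativeRatio()]
#' into the population table: per population and class, the mean derived
#' ratio \eqn{p^{class}}, the all-SNP \eqn{p^{total}} and
#' \eqn{R_p = p^{class}/p^{total}}.
#'
#' @param x a [PolarizedVariantPanel-class]
#' @param classification data.frame from [classifyMutations()]
#' @param popmap data.frame from [readPopmap()]
#' @param nSnpsTotal SNP universe size; defaults to the panel site count
#' @param classes class columns to summarise
#' @return data.frame: population, n, class, pClass, pTotal, Rp
#' @export
loadSummary <- function(x, classification, popmap,
                        nSnpsTotal = nrow(x),
                        classes = c("DEL", "RADICAL", "LOF")) {
  counts <- derivedCounts(x, classification, classes)
  counts$population <- popmap$population[match(counts$sample, popmap$sample)]
  pops <- unique(counts$population)
  out <- list()
  for (pop in pops) {
    tot <- counts[counts$population == pop & counts$class == "total", ]
    pTotal <- meanDerivedRatio(tot$nDerived, nSnpsTotal)
    for (cl in classes) {
      sub <- counts[counts$population == pop & counts$class == cl, ]
      pClass <- meanDerivedRatio(sub$nDerived, nSnpsTotal)
      out[[length(out) + 1L]] <- data.frame(
        population = pop, n = nrow(sub), class = cl,
        pClass = pClass, pTotal = pTotal,
        Rp = relativeRatio(pClass, pTotal))
    }
  }
  do.call(rbind, out)
}

#' Cross-cluster sharing of class sites
#'
#' A cluster "carries" a site when at least one member holds a derived
#' allele there.  Per class this reports sites private to exactly one
#' cluster, sites carried by every cluster, and sites homozygous-derived in
#' more than \code{k} individuals.
#'
#' @param x a [PolarizedVariantPanel-class]
#' @param classification data.frame from [classifyMutations()]
#' @param clusterMap data.frame with \code{sample} and \code{cluster}
#' @param k homozygous-sharing individual threshold (strictly more than)
#' @param classes class columns to analyse
#' @return list with \code{summary} (per class: nSites, sharedAll,
#'   homSharedOverK, and private counts per cluster) and \code{perSite}
#'   carrier counts
#' @export
sharingAnalysis <- function(x, classification, clusterMap, k = 50,
                            classes = c("DEL", "RADICAL", "LOF")) {
  gt <- genotypes(x)
  idx <- match(paste(chromosomes(x), positions(x)),
               paste(classification$chrom, classification$pos))
  clusters <- sort(unique(clusterMap$cluster))
  byCl <- lapply(clusters, function(cl)
    clusterMap$sample[clusterMap$cluster == cl])
  summary <- list(); perSite <- list()
  for (cl in classes) {
    flag <- classification[[cl]][idx]
    rows <- which(!is.na(flag) & flag)
    sub <- gt[rows, , drop = FALSE]
    carried <- vapply(byCl, function(mem)
      rowSums(sub[, mem, drop = FALSE] >= 1L, na.rm = TRUE) > 0L,
      logical(nrow(sub)))
    carried <- matrix(carried, nrow = length(rows),
                      dimnames = list(NULL, clusters))
    nCarry <- rowSums(carried)
    homN <- rowSums(sub == 2L, na.rm = TRUE)
    privateBy <- colSums(carried & nCarry == 1L)
    summary[[cl]] <- data.frame(
      class = cl, nSites = length(rows),
      sharedAll = sum(nCarry == length(clusters)),
      private = sum(nCarry == 1L),
      homSharedOverK = sum(homN > k),
      t(privateBy))
    perSite[[cl]] <- data.frame(class = cl,
                                chrom = chromosomes(x)[rows],
                                pos = positions(x)[rows],
                                nClustersCarrying = nCarry,
                                nHomIndividuals = homN)
  }
  list(summary = do.call(rbind, summary), perSite = do.call(rbind, perSite))
}

#' Correlation between mutation load and population size
#'
#' Pearson product-moment correlation between per-individual class counts
#' and their population's effective (or census) size — the per-individual
#' scatter convention — with the analytic two-sided p-value from
#' \code{stats::cor.test}.
#'
#' @param counts data.frame with \code{sample}, \code{nDerived} (one class)
#'   and \code{population}
#' @param popSize named vector: population -> N_e or N_c
#' @return list: R, p, n (points used); both \code{NA} when a margin has
#'   zero variance
#' @export
loadSizeCorrelation <- function(counts, popSize) {
  sz <- popSize[counts$population]
  ok <- !is.na(sz) & !is.na(counts$nDerived)
  y <- counts$nDerived[ok]; s <- as.numeric(sz[ok])
  if (length(y) < 3) stop("need >= 3 points", call. = FALSE)
  if (stats::var(y) == 0 || stats::var(s) == 0)
    return(list(R = NA_real_, p = NA_real_, n = length(y)))
  ct <- stats::cor.test(s, y)
  list(R = unname(ct$estimate), p = ct$p.value, n = length(y))
}
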