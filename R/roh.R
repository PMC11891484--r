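#' Detect runs of homozygosity for one sample
#'
#' PLINK-style scanning-window detector.  A window of \code{windowSnps}
#' consecutive SNPs is "homozygous" when it holds at most
#' \code{windowMaxHet} heterozygous and \code{windowMaxMissing} missing
#' calls; each SNP's hit rate is the fraction of windows overlapping it
#' that are homozygous, and SNPs with hit rate >= \code{hitThreshold} seed
#' candidate runs.  Candidates split wherever the gap between consecutive
#' SNPs reaches \code{maxGapKb}; surviving segments must hold at least
#' \code{minSnps} non-missing SNPs, span at least \code{minKb}, and keep
#' their average spacing at or under \code{densityKbPerSnp}.  Chromosomes
#' shorter than one window are scanned as a single window.
#'
#' @param geno genotype vector for one sample: 0/2 homozygous, 1
#'   heterozygous, \code{NA} missing
#' @param pos strictly increasing 1-based positions (bp); unsorted input is
#'   an error
#' @param params a [RohParams-class]
#' @param chrom chromosome label for the output
#' @param sample sample label for the output
#' @return data.frame: sample, chrom, start, end, lengthBp, nSnps, nHet
#' @export
detectRoh <- function(geno, pos, params = RohParams(), chrom = "chr",
                      sample = "sample") {
  n <- length(geno)
  stopifnot(length(pos) == n)
  if (n > 1L && any(diff(pos) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  empty <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), lengthBp = integer(),
                      nSnps = integer(), nHet = integer())
  if (n == 0L) return(empty)

  hit <- .rohHits(geno, params)
  runs <- .splitRuns(which(hit), pos, params@maxGapKb * 1000)
  segs <- lapply(runs, function(idx) {
    g <- geno[idx]
    nSnps <- sum(!is.na(g))
    len <- pos[idx[length(idx)]] - pos[idx[1L]] + 1L
    if (nSnps < params@minSnps) return(NULL)
    if (len < params@minKb * 1000) return(NULL)
    if (len / nSnps > params@densityKbPerSnp * 1000) return(NULL)
    data.frame(sample = sample, chrom = chrom,
               start = pos[idx[1L]], end = pos[idx[length(idx)]],
               lengthBp = len, nSnps = nSnps,
               nHet = sum(g == 1L, na.rm = TRUE))
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

# per-SNP hit flags from the scanning windows
.rohHits <- function(geno, params) {
  n <- length(geno)
  win <- min(params@windowSnps, n)
  nWin <- n - win + 1L
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  cumHet <- c(0L, cumsum(het))
  cumMis <- c(0L, cumsum(mis))
  w <- seq_len(nWin)
  homWin <- (cumHet[w + win] - cumHet[w]) <= params@windowMaxHet &
            (cumMis[w + win] - cumMis[w]) <= params@windowMaxMissing
  # SNP k is covered by windows max(1, k-win+1) .. min(nWin, k)
  cumHom <- c(0L, cumsum(homWin))
  k <- seq_len(n)
  lo <- pmax(1L, k - win + 1L)
  hi <- pmin(nWin, k)
  nCov <- hi - lo + 1L
  nHom <- cumHom[hi + 1L] - cumHom[lo]
  nHom / nCov >= params@hitThreshold
}

# split an increasing index set into runs of consecutive SNPs whose
# inter-SNP distance stays below gapBp
.splitRuns <- function(idx, pos, gapBp) {
  if (!length(idx)) return(list())
  brk <- which(diff(idx) > 1L | diff(pos[idx]) >= gapBp)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(idx))
  mapply(function(s, e) idx[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Detect ROH for every sample in a panel
#'
#' Runs [detectRoh()] per sample and chromosome.  Genotypes are treated as
#' hom/het/missing regardless of polarization.
#'
#' @param x a [VariantPanel-class]
#' @param params a [RohParams-class]
#' @return data.frame of segments in PLINK \code{.hom}-like layout
#' @export
detectRohPanel <- function(x, params = RohParams()) {
  gt <- genotypes(x)
  chrom <- chromosomes(x)
  pos <- positions(x)
  out <- list()
  for (s in colnames(gt)) {
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      out[[length(out) + 1L]] <-
        detectRoh(gt[sel, s], pos[sel], params, chrom = ch, sample = s)
    }
  }
  do.call(rbind, out)
}

#' Genome fraction in runs of homozygosity
#'
#' \eqn{F_{ROH} = \sum L_{ROH} / L_{auto}} over a sample's segments (already
#' filtered by the scanner to the minimum length / SNP-count thresholds).
#'
#' @param segments data.frame from [detectRoh()] (one sample)
#' @param lAuto total autosomal reference length, bp (> 0)
#' @return numeric in \code{[0, 1]}
#' @export
froh <- function(segments, lAuto) {
  if (lAuto <= 0) stop("lAuto must be positive", call. = FALSE)
  if (!nrow(segments)) return(0)
  sum(as.numeric(segments$lengthBp)) / lAuto
}

#' Length-class decomposition of ROH segments
#'
#' Classifies segments as short / medium / long.  Boundaries default to
#' short = [minimum, 200) kb, medium = [200, 400] kb, long = (400, Inf) kb,
#' and are configurable.  Reports per-class counts, cumulative lengths, and
#' both count and length fractions (each summing to 1 when segments exist).
#'
#' @param segments data.frame with a \code{lengthBp} column
#' @param shortMaxKb,mediumMaxKb class boundaries in kb; short is
#'   \code{< shortMaxKb}, medium \code{[shortMaxKb, mediumMaxKb]}, long
#'   \code{> mediumMaxKb}
#' @return data.frame: class, count, countFraction, lengthBp, lengthFraction
#' @export
classifyRohLengths <- function(segments, shortMaxKb = 200, mediumMaxKb = 400) {
  len <- as.numeric(segments$lengthBp)
  cls <- ifelse(len < shortMaxKb * 1000, "short",
         ifelse(len <= mediumMaxKb * 1000, "medium", "long"))
  lev <- c("short", "medium", "long")
  cnt <- vapply(lev, function(l) sum(cls == l), numeric(1))
  tot <- vapply(lev, function(l) sum(len[cls == l]), numeric(1))
  data.frame(class = lev, count = as.integer(cnt),
             countFraction = if (sum(cnt)) cnt / sum(cnt) else rep(0, 3),
             lengthBp = tot,
             lengthFraction = if (sum(tot)) tot / sum(tot) else rep(0, 3),
             row.names = NULL)
}

#' Per-sample ROH summary
#'
#' @param segments data.frame from [detectRohPanel()]
#' @param lAuto reference length, bp
#' @param shortMaxKb,mediumMaxKb boundaries passed to [classifyRohLengths()]
#' @return data.frame: sample, nSegments, totalBp, Froh, nShort, nMedium, nLong
#' @export
rohSummary <- function(segments, lAuto, shortMaxKb = 200, mediumMaxKb = 400) {
  samples <- unique(segments$sample)
  out <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    cls <- classifyRohLengths(seg, shortMaxKb, mediumMaxKb)
    data.frame(sample = s, nSegments = nrow(seg),
               totalBp = sum(as.numeric(seg$lengthBp)),
               Froh = froh(seg, lAuto),
               nShort = cls$count[cls$class == "short"],
               nMedium = cls$count[cls$class == "medium"],
               nLong = cls$count[cls$class == "long"])
  })
  do.call(rbind, out)
}
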