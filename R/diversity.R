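#' Windowed nucleotide diversity
#'
#' Tiles each chromosome with non-overlapping windows of \code{windowBp}
#' and reports, per window, the number of variants, segregating sites and
#' per-site nucleotide diversity
#' \deqn{\pi = \sum_{sites} 2 n_{alt}(n - n_{alt}) / (n(n-1)) / windowBp,}
#' where \eqn{n} is the non-missing allele count at the site.  Windows with
#' no SNPs report \eqn{\pi = 0}.  This is the unbiased per-site pairwise
#' difference, the sliding-window \code{--window-pi} convention.
#'
#' @param x a [VariantPanel-class] (typically polarized)
#' @param samples optional character vector restricting to a sample subset
#' @param windowBp window size, bp (> 0)
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to panel seqlengths, else the last SNP position rounded up to a window
#' @return data.frame: chrom, start, end, nVariants, S, pi
#' @export
windowedPi <- function(x, samples = NULL, windowBp = 1e5, chromLengths = NULL) {
  if (windowBp <= 0) stop("windowBp must be positive", call. = FALSE)
  gt <- genotypes(x)
  if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
  chrom <- chromosomes(x)
  pos <- positions(x)
  nCalled <- rowSums(!is.na(gt))
  n <- 2L * nCalled
  nAlt <- rowSums(gt, na.rm = TRUE)
  sitePi <- ifelse(n >= 2L, 2 * nAlt * (n - nAlt) / (n * pmax(n - 1L, 1L)), 0)
  seg <- nAlt > 0L & nAlt < n
  if (is.null(chromLengths)) {
    sl <- GenomeInfoDb::seqlengths(rowRanges(x))
    if (length(sl) && !all(is.na(sl))) chromLengths <- sl
  }
  out <- lapply(unique(chrom), function(ch) {
    sel <- chrom == ch
    len <- if (!is.null(chromLengths) && ch %in% names(chromLengths) &&
               !is.na(chromLengths[ch])) chromLengths[[ch]]
           else ceiling(max(pos[sel]) / windowBp) * windowBp
    nWin <- max(1L, ceiling(len / windowBp))
    win <- pmin(ceiling(pos[sel] / windowBp), nWin)
    idx <- seq_len(nWin)
    data.frame(chrom = ch,
               start = (idx - 1L) * windowBp + 1,
               end = idx * windowBp,
               nVariants = tabulate(win, nWin),
               S = tabulate(win[seg[sel]], nWin),
               pi = as.numeric(tapplySum(sitePi[sel], win, nWin)) / windowBp)
  })
  do.call(rbind, out)
}

# sum v by integer group 1..n (tapply without factor overhead, zeros kept)
tapplySum <- function(v, g, n) {
  out <- numeric(n)
  if (length(v)) {
    s <- rowsum(v, g)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Tajima's D
#'
#' The classic statistic contrasting mean pairwise diversity with the
#' segregating-site estimator:
#' \deqn{D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}}
#' with the standard constants \eqn{a_1 = \sum_{i=1}^{n-1} 1/i},
#' \eqn{a_2 = \sum 1/i^2}, \eqn{b_1 = (n+1)/(3(n-1))},
#' \eqn{b_2 = 2(n^2+n+3)/(9n(n-1))}, \eqn{c_1 = b_1 - 1/a_1},
#' \eqn{c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2}, \eqn{e_1 = c_1/a_1},
#' \eqn{e_2 = c_2/(a_1^2 + a_2)}.
#'
#' @param S segregating-site count (\code{S = 0} returns \code{NA})
#' @param piHat mean pairwise differences (sum over sites of per-site
#'   heterozygosity, not divided by length)
#' @param n allele (sequence) count, >= 4
#' @return numeric D
#' @export
tajimasD <- function(S, piHat, n) {
  if (n < 4) stop("tajimasD needs n >= 4", call. = FALSE)
  if (is.na(S) || S < 1) return(NA_real_)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Windowed Tajima's D for a panel
#'
#' Convenience wrapper computing, per [windowedPi()] window, \eqn{\hat\pi}
#' as the sum of per-site unbiased heterozygosities and S as the segregating
#' site count, then [tajimasD()] with n = 2 x median number of called
#' samples in the window.
#'
#' @inheritParams windowedPi
#' @return data.frame: chrom, start, end, S, piHat, D
#' @export
windowedTajimasD <- function(x, samples = NULL, windowBp = 1e5,
                             chromLengths = NULL) {
  w <- windowedPi(x, samples, windowBp, chromLengths)
  gt <- genotypes(x)
  if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
  n <- 2L * round(stats::median(rowSums(!is.na(gt))))
  w$piHat <- w$pi * windowBp
  w$D <- vapply(seq_len(nrow(w)), function(i)
    if (n >= 4) tajimasD(w$S[i], w$piHat[i], n) else NA_real_, numeric(1))
  w[, c("chrom", "start", "end", "S", "piHat", "D")]
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Returns matrix with columns a, b, c; sites where either population has
# < 2 called diploids, or both are monomorphic, carry NA.
.wcComponents <- function(gt, idxA, idxB) {
  comp <- function(sub) {
    nCalled <- rowSums(!is.na(sub))
    p <- rowSums(sub, na.rm = TRUE) / (2 * pmax(nCalled, 1L))
    h <- rowSums(sub == 1L, na.rm = TRUE) / pmax(nCalled, 1L)
    list(n = nCalled, p = p, h = h)
  }
  A <- comp(gt[, idxA, drop = FALSE])
  B <- comp(gt[, idxB, drop = FALSE])
  r <- 2
  nbar <- (A$n + B$n) / 2
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  usable <- A$n >= 2 & B$n >= 2 & (pbar > 0 & pbar < 1)
  a[!usable] <- NA; b[!usable] <- NA; cc[!usable] <- NA
  cbind(a = a, b = b, c = cc)
}

#' Weir-Cockerham FST between two populations
#'
#' Per-site \eqn{\hat\theta} variance components (Weir & Cockerham 1984)
#' aggregated as the weighted ratio of sums \eqn{\sum a / \sum(a+b+c)} —
#' the "weighted FST" convention — per window and genome-wide.  Negative
#' estimates are reported as computed.  Sites monomorphic across both
#' populations, or with fewer than two called diploids in either, are
#' skipped.
#'
#' @param x a [VariantPanel-class]
#' @param popA,popB character vectors of sample names
#' @param windowBp optional window size for per-window values
#' @return list with \code{global} (weighted FST), \code{meanSite} (mean of
#'   per-site ratios) and, when \code{windowBp} is given, \code{windows}
#'   data.frame
#' @export
wcFst <- function(x, popA, popB, windowBp = NULL) {
  gt <- genotypes(x)
  comp <- .wcComponents(gt, match(popA, colnames(gt)), match(popB, colnames(gt)))
  num <- comp[, "a"]
  den <- comp[, "a"] + comp[, "b"] + comp[, "c"]
  ok <- !is.na(den) & den > 0
  global <- sum(num[ok]) / sum(den[ok])
  meanSite <- mean(num[ok] / den[ok])
  out <- list(global = global, meanSite = meanSite)
  if (!is.null(windowBp)) {
    chrom <- chromosomes(x)
    pos <- positions(x)
    win <- paste(chrom, ceiling(pos / windowBp))
    wnum <- rowsum(ifelse(ok, num, 0), win)
    wden <- rowsum(ifelse(ok, den, 0), win)
    key <- do.call(rbind, strsplit(rownames(wnum), " "))
    widx <- as.integer(key[, 2L])
    out$windows <- data.frame(chrom = key[, 1L],
                              start = (widx - 1L) * windowBp + 1,
                              end = widx * windowBp,
                              fst = as.numeric(wnum / wden))
  }
  out
}

#' Individual inbreeding coefficient F
#'
#' The method-of-moments estimator reported by \code{--het} style tools:
#' over the individual's non-missing calls at sites polymorphic in the full
#' panel, \eqn{F = (O_{hom} - E_{hom}) / (L - E_{hom})}, where
#' \eqn{E_{hom} = \sum_{sites} 1 - 2p(1-p) \cdot n/(n-1)} uses the
#' panel-wide ALT frequency \eqn{p} and allele count \eqn{n} at each site.
#'
#' @param x a [VariantPanel-class]
#' @param sample sample name, or \code{NULL} for all samples
#' @return data.frame: sample, oHom, eHom, nSites, F
#' @export
individualF <- function(x, sample = NULL) {
  gt <- genotypes(x)
  nCalled <- rowSums(!is.na(gt))
  n <- 2L * nCalled
  p <- rowSums(gt, na.rm = TRUE) / pmax(n, 1L)
  poly <- p > 0 & p < 1 & n >= 2
  gt <- gt[poly, , drop = FALSE]
  p <- p[poly]; n <- n[poly]
  eSite <- 1 - 2 * p * (1 - p) * n / (n - 1)
  who <- if (is.null(sample)) colnames(gt) else sample
  out <- lapply(who, function(s) {
    g <- gt[, s]
    ok <- !is.na(g)
    oHom <- sum(g[ok] != 1L)
    eHom <- sum(eSite[ok])
    L <- sum(ok)
    f <- if (abs(L - eHom) < .Machine$double.eps^0.5) NA_real_
         else (oHom - eHom) / (L - eHom)
    data.frame(sample = s, oHom = oHom, eHom = eHom, nSites = L, F = f)
  })
  do.call(rbind, out)
}

#' Population-level F_IS
#'
#' Mean of the [individualF()] coefficients over each population's members.
#'
#' @param x a [VariantPanel-class]
#' @param popmap data.frame from [readPopmap()]
#' @return data.frame: population, n, Fis
#' @export
populationFis <- function(x, popmap) {
  f <- individualF(x)
  f$population <- popmap$population[match(f$sample, popmap$sample)]
  agg <- stats::aggregate(F ~ population, f, mean)
  cnt <- stats::aggregate(sample ~ population, f, length)
  data.frame(population = agg$population, n = cnt$sample, Fis = agg$F)
}

#' Linkage-disequilibrium decay
#'
#' For every same-chromosome site pair within \code{maxDistBp}, computes
#' genotype \eqn{r^2} — the squared Pearson correlation of dosage vectors
#' over samples called at both sites — and averages it in distance bins of
#' \code{binBp}.  Monomorphic members of a pair are skipped.
#'
#' @param x a [VariantPanel-class]
#' @param samples optional sample subset
#' @param maxDistBp maximum pair distance, bp
#' @param binBp bin width, bp
#' @return data.frame: binStart, binEnd, mid, meanR2, nPairs
#' @export
ldDecay <- function(x, samples = NULL, maxDistBp = 5e4, binBp = 1e3) {
  gt <- genotypes(x)
  if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
  chrom <- chromosomes(x)
  pos <- positions(x)
  nBins <- ceiling(maxDistBp / binBp)
  sumR2 <- numeric(nBins)
  cnt <- integer(nBins)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    p <- pos[sel]
    G <- gt[sel, , drop = FALSE]
    for (i in seq_along(sel)) {
      j <- which(p > p[i] & p - p[i] <= maxDistBp)
      for (k in j) {
        ok <- !is.na(G[i, ]) & !is.na(G[k, ])
        gi <- G[i, ok]; gk <- G[k, ok]
        if (length(gi) < 2L || stats::var(gi) == 0 || stats::var(gk) == 0) next
        r2 <- stats::cor(gi, gk)^2
        b <- ceiling((p[k] - p[i]) / binBp)
        sumR2[b] <- sumR2[b] + r2
        cnt[b] <- cnt[b] + 1L
      }
    }
  }
  data.frame(binStart = (seq_len(nBins) - 1L) * binBp + 1,
             binEnd = seq_len(nBins) * binBp,
             mid = (seq_len(nBins) - 0.5) * binBp,
             meanR2 = ifelse(cnt > 0, sumR2 / pmax(cnt, 1L), NA_real_),
             nPairs = cnt)
}

#' Half-decay distance of LD
#'
#' The midpoint of the first distance bin whose mean \eqn{r^2} has fallen
#' to half of the maximum bin mean, the usual summary of how fast LD decays.
#'
#' @param bins data.frame from [ldDecay()]
#' @return distance in bp (\code{NA} if LD never halves within range)
#' @export
halfDecayDistance <- function(bins) {
  ok <- !is.na(bins$meanR2)
  if (!any(ok)) return(NA_real_)
  half <- max(bins$meanR2[ok]) / 2
  hit <- which(ok & bins$meanR2 <= half)
  if (!length(hit)) return(NA_real_)
  bins$mid[hit[1L]]
}
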