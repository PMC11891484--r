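# Shared fixture builders and independent brute-force oracles.

# panel from explicit per-site vectors; gt is sites x samples
makePanel <- function(gt, chrom = "chr1", pos = NULL, ref = NULL, alt = NULL,
                      qual = NULL, aa = NULL, dp = NULL, spacing = 1000) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(colnames(gt))) colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  if (is.null(pos)) pos <- seq_len(n) * spacing
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  if (is.null(qual)) qual <- rep(100, n)
  VariantPanel(chrom = rep(chrom, length.out = n), pos = pos, ref = ref,
               alt = alt, qual = qual, gt = gt, aa = aa, dp = dp)
}

# --- ROH oracle -------------------------------------------------------------
# Exhaustive interval search: recompute per-SNP hit flags naively, find all
# intervals that are maximal under the hereditary constraints (every SNP hit,
# all internal gaps below the split distance), then apply the min-SNP /
# min-length / density thresholds.  Independent of the package's linear scan.
rohOracle <- function(geno, pos, params) {
  n <- length(geno)
  win <- min(params@windowSnps, n)
  nWin <- n - win + 1L
  homWin <- vapply(seq_len(nWin), function(w) {
    g <- geno[w:(w + win - 1L)]
    sum(g == 1L, na.rm = TRUE) <= params@windowMaxHet &&
      sum(is.na(g)) <= params@windowMaxMissing
  }, logical(1))
  hit <- vapply(seq_len(n), function(k) {
    ws <- intersect(seq_len(nWin), (k - win + 1L):k)
    mean(homWin[ws]) >= params@hitThreshold
  }, logical(1))
  gapBp <- params@maxGapKb * 1000
  okInterval <- function(i, j) {
    if (!all(hit[i:j])) return(FALSE)
    if (j > i && any(diff(pos[i:j]) >= gapBp)) return(FALSE)
    TRUE
  }
  segs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!okInterval(i, j)) next
    maximal <- (i == 1L || !okInterval(i - 1L, j)) &&
      (j == n || !okInterval(i, j + 1L))
    if (!maximal) next
    nSnps <- sum(!is.na(geno[i:j]))
    len <- pos[j] - pos[i] + 1L
    if (nSnps < params@minSnps) next
    if (len < params@minKb * 1000) next
    if (len / nSnps > params@densityKbPerSnp * 1000) next
    segs[[length(segs) + 1L]] <- c(start = pos[i], end = pos[j])
  }
  if (!length(segs))
    return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, segs))
}

# random ROH fixture: mixed hom stretches, het noise, missing calls
rohRandomFixture <- function(seed, nSnps = 200L) {
  set.seed(seed)
  pos <- sort(sample.int(2e6, nSnps))
  g <- sample(c(0L, 1L, 2L, NA), nSnps, TRUE, prob = c(.35, .3, .3, .05))
  nRuns <- sample(0:3, 1)
  for (r in seq_len(nRuns)) {
    a <- sample.int(nSnps - 20L, 1)
    b <- min(nSnps, a + sample(15:80, 1))
    idx <- a:b
    g[idx] <- sample(c(0L, 2L), length(idx), TRUE)
    if (stats::runif(1) < 0.5)          # sprinkle a het / missing call
      g[sample(idx, 1)] <- sample(c(1L, NA), 1)
  }
  list(geno = g, pos = pos)
}

# --- pi oracle --------------------------------------------------------------
# mean pairwise difference per site over all haplotype pairs, by exhaustive
# comparison; hap is haplotypes x sites (0/1)
piPairwiseOracle <- function(hap) {
  nh <- nrow(hap)
  tot <- 0
  for (a in seq_len(nh - 1L)) for (b in (a + 1L):nh)
    tot <- tot + sum(hap[a, ] != hap[b, ])
  tot / (nh * (nh - 1L) / 2L)
}

# --- recombining selfing pedigree for F_ROH ---------------------------------
# crossover gamete from a diploid (two haplotypes over positions on one
# chromosome); used to build inbred vs outbred individuals with realistic
# homozygosity tracts
recombGamete <- function(h1, h2, pos, chromLen, xoverRate = 2e-6) {
  nx <- stats::rpois(1, xoverRate * chromLen)
  start <- sample(0:1, 1)
  if (nx == 0) return(if (start == 0) h1 else h2)
  cuts <- sort(stats::runif(nx, 0, chromLen))
  seg <- findInterval(pos, cuts)
  ifelse((start + seg) %% 2 == 0, h1, h2)
}

selfedIndividual <- function(freq, pos, chromLen, nGenerations, seed) {
  set.seed(seed)
  h1 <- stats::rbinom(length(freq), 1L, freq)
  h2 <- stats::rbinom(length(freq), 1L, freq)
  for (g in seq_len(nGenerations)) {
    n1 <- recombGamete(h1, h2, pos, chromLen)
    n2 <- recombGamete(h1, h2, pos, chromLen)
    h1 <- n1; h2 <- n2
  }
  h1 + h2
}

outbredIndividual <- function(freq, seed) {
  set.seed(seed)
  stats::rbinom(length(freq), 1L, freq) + stats::rbinom(length(freq), 1L, freq)
}

# --- independent Grantham recomputation -------------------------------------
# straight re-derivation from the published residue properties; kept separate
# from the package's vectorised implementation
granthamOracle <- function() {
  props <- list(
    S = c(1.42, 9.2, 32),    R = c(0.65, 10.5, 124), L = c(0, 4.9, 111),
    P = c(0.39, 8.0, 32.5),  T = c(0.71, 8.6, 61),   A = c(0, 8.1, 31),
    V = c(0, 5.9, 84),       G = c(0.74, 9.0, 3),    I = c(0, 5.2, 111),
    F = c(0, 5.2, 132),      Y = c(0.20, 6.2, 136),  C = c(2.75, 5.5, 55),
    H = c(0.58, 10.4, 96),   Q = c(0.89, 10.5, 85),  N = c(1.33, 11.6, 56),
    K = c(0.33, 11.3, 119),  D = c(1.38, 13.0, 54),  E = c(0.92, 12.3, 83),
    M = c(0, 5.7, 105),      W = c(0.13, 5.4, 170))
  raw <- function(x, y)
    sqrt(1.833 * (x[1] - y[1])^2 + 0.1018 * (x[2] - y[2])^2 +
         0.000399 * (x[3] - y[3])^2)
  aa <- names(props)
  m <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (i in 1:20) for (j in 1:20) m[i, j] <- raw(props[[i]], props[[j]])
  m * 100 / mean(m[upper.tri(m)])
}
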