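classDf <- function(chrom, pos, ...) {
  flags <- list(...)
  cbind(data.frame(chrom = chrom, pos = pos), as.data.frame(flags))
}

test_that("derived-allele counting follows the het=1 / hom=2 rule", {
  # individual het at 3 and hom-derived at 2 of 5 DEL sites
  gt <- cbind(a = c(1L, 1L, 1L, 2L, 2L, 0L),
              b = c(0L, 0L, 0L, 0L, 0L, 0L))
  vp <- asPolarizedPanel(gt)
  cls <- classDf("chr1", positions(vp), DEL = c(rep(TRUE, 5), FALSE))
  dc <- derivedCounts(vp, cls, classes = "DEL")
  a <- dc[dc$sample == "a" & dc$class == "DEL", ]
  expect_equal(a$nDerived, 7L)
  expect_equal(a$homLoad, 4L)
  b <- dc[dc$sample == "b" & dc$class == "DEL", ]
  expect_equal(b$nDerived, 0L)       # all-ancestral individual
  # 5 homozygous deleterious genotypes -> homozygous load 10
  gt2 <- cbind(c = c(rep(2L, 5), 0L), d = rep(0L, 6))
  dc2 <- derivedCounts(asPolarizedPanel(gt2), cls, classes = "DEL")
  expect_equal(dc2$homLoad[dc2$sample == "c" & dc2$class == "DEL"], 10L)
})

test_that("mean derived ratio and R_p reproduce their defining arithmetic", {
  expect_equal(meanDerivedRatio(c(3, 1), 10), 0.1)
  expect_equal(meanDerivedRatio(20, 10), 1)        # hom-derived at all 10 sites
  expect_equal(meanDerivedRatio(rep(c(3, 1), 4), 10), 0.1)  # duplication-invariant
  expect_equal(relativeRatio(0.2, 0.2), 1)
  expect_equal(relativeRatio(0.1, 0.2), 0.5)
  expect_error(relativeRatio(0.1, 0), "positive")
})

test_that("population load summary wires counts, p and R_p together", {
  set.seed(4)
  gt <- matrix(rbinom(50 * 6, 2, 0.3), 50, 6,
               dimnames = list(NULL, paste0("i", 1:6)))
  vp <- asPolarizedPanel(gt)
  cls <- classDf("chr1", positions(vp), DEL = rep(c(TRUE, FALSE), 25))
  pm <- data.frame(sample = paste0("i", 1:6),
                   population = rep(c("P1", "P2"), each = 3))
  ls <- loadSummary(vp, cls, pm, classes = "DEL")
  expect_equal(nrow(ls), 2L)
  # hand recomputation for P1
  delSites <- which(rep(c(TRUE, FALSE), 25))
  pClass <- mean(colSums(gt[delSites, 1:3]) / (2 * 50))
  pTotal <- mean(colSums(gt[, 1:3]) / (2 * 50))
  expect_equal(ls$pClass[ls$population == "P1"], pClass)
  expect_equal(ls$Rp[ls$population == "P1"], pClass / pTotal)
})

test_that("sharing analysis equals exhaustive per-site enumeration", {
  # 3 clusters x 2 samples, 6 class sites with hand-designed carriers
  gt <- rbind(
    c(1L, 0L, 0L, 0L, 0L, 0L),   # private to cluster A
    c(0L, 0L, 2L, 0L, 0L, 0L),   # private to B
    c(1L, 0L, 1L, 0L, 2L, 0L),   # shared by all
    c(0L, 1L, 0L, 2L, 0L, 1L),   # shared by all
    c(0L, 0L, 1L, 1L, 0L, 0L),   # B only (both members)
    c(2L, 2L, 0L, 0L, 2L, 2L))   # A and C
  colnames(gt) <- paste0("i", 1:6)
  vp <- asPolarizedPanel(gt)
  cls <- classDf("chr1", positions(vp), DEL = rep(TRUE, 6))
  cm <- data.frame(sample = paste0("i", 1:6),
                   cluster = rep(c("A", "B", "C"), each = 2))
  sh <- sharingAnalysis(vp, cls, cm, k = 2, classes = "DEL")
  s <- sh$summary
  expect_equal(s$nSites, 6L)
  expect_equal(s$sharedAll, 2L)
  expect_equal(s$private, 3L)
  expect_equal(s$homSharedOverK, 1L)      # site 6: 4 hom individuals > 2
  expect_equal(s$A + s$B + s$C, 3L)       # per-cluster private partition
  expect_equal(sh$perSite$nClustersCarrying, c(1L, 1L, 3L, 3L, 1L, 2L))
})

test_that("load-size correlation matches its analytic and permutation nulls", {
  # strictly decreasing in Ne -> R = -1
  counts <- data.frame(sample = paste0("s", 1:5), nDerived = c(50, 40, 30, 20, 10),
                       population = paste0("P", 1:5))
  ne <- stats::setNames(c(100, 200, 300, 400, 500), paste0("P", 1:5))
  r <- loadSizeCorrelation(counts, ne)
  expect_equal(r$R, -1)
  # zero variance -> undefined
  flat <- counts; flat$nDerived <- 7
  expect_true(is.na(loadSizeCorrelation(flat, ne)$R))
  # permutation p agrees with the analytic p within Monte-Carlo error
  set.seed(8)
  counts2 <- data.frame(sample = paste0("s", 1:30),
                        nDerived = rbinom(30, 100, 0.3) - seq(0, 7.25, 0.25),
                        population = paste0("P", 1:30))
  ne2 <- stats::setNames(seq(100, by = 50, length.out = 30), paste0("P", 1:30))
  r2 <- loadSizeCorrelation(counts2, ne2)
  obs <- abs(r2$R)
  perm <- replicate(10000, abs(cor(sample(counts2$nDerived), as.numeric(ne2))))
  pPerm <- mean(perm >= obs)
  expect_equal(pPerm, r2$p, tolerance = 0.03)
})

test_that("randomly labelled neutral classes show no derived-allele bias", {
  # R_p keeps the fixed all-SNP denominator, so its raw expectation for a
  # random label set equals the labelled fraction of sites; dividing by that
  # fraction must centre on 1 (no enrichment or deficit).
  set.seed(15)
  rps <- replicate(30, {
    gt <- matrix(rbinom(200 * 8, 2, runif(200, 0.05, 0.5)), 200, 8)
    colnames(gt) <- paste0("i", 1:8)
    vp <- asPolarizedPanel(gt)
    lab <- sample(c(TRUE, FALSE), 200, TRUE)
    cls <- classDf("chr1", positions(vp), RAND = lab)
    pm <- data.frame(sample = paste0("i", 1:8), population = "P")
    loadSummary(vp, cls, pm, classes = "RAND")$Rp / mean(lab)
  })
  expect_equal(mean(rps), 1, tolerance = 3 * sd(rps) / sqrt(length(rps)) + 0.02)
})
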