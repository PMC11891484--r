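smallCfg <- function(seed, ...) {
  simConfig(seed = seed,
            demes = list(list(name = "A", N = 40L)),
            genome = data.frame(chrom = "chr1", length = 2e4),
            mu = 2e-5, generations = 150L, ...)
}

test_that("the same seed yields byte-identical simulator output", {
  d1 <- tempfile(); d2 <- tempfile()
  simulatePopulations(smallCfg(42), dir = d1)
  simulatePopulations(smallCfg(42), dir = d2)
  for (f in c("panel.vcf", "popmap.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  diff <- simulatePopulations(smallCfg(43))
  expect_false(identical(genotypes(diff$panel),
                         genotypes(simulatePopulations(smallCfg(42))$panel)))
})

test_that("simulator files parse cleanly through the package readers", {
  d <- tempfile()
  sim <- simulatePopulations(smallCfg(9), dir = d)
  expect_no_warning(p <- readVcfPanel(sim$vcf))
  expect_no_warning(pm <- readPopmap(sim$popmapFile))
  expect_equal(unname(genotypes(p)), unname(genotypes(sim$panel)))
  expect_equal(pm$sample, colnames(genotypes(sim$panel)))
  expect_no_warning(pol <- polarizeVariants(p))
  expect_equal(nrow(pol), nrow(p))     # AA == REF everywhere by construction
})

test_that("every emitted site carries exactly one truth class label", {
  sim <- simulatePopulations(simConfig(
    seed = 3, demes = list(list(name = "A", N = 40L)),
    genome = data.frame(chrom = "chr1", length = 2e4),
    mu = 2e-5, generations = 120L,
    classes = data.frame(label = c("del", "lof"), fraction = c(0.3, 0.1),
                         s = c(0.05, 0.2), h = c(0.3, 0.3))))
  expect_equal(nrow(sim$truth$sites), nrow(sim$panel))
  expect_true(all(sim$truth$sites$label %in% c("del", "lof", "neutral")))
  expect_equal(sim$truth$sites$pos, positions(sim$panel))
})

test_that("deme splits with no migration accumulate FST with time", {
  fstAt <- function(tSplit) {
    cfg <- simConfig(
      seed = 1000 + tSplit,
      demes = list(list(name = "A", N = 40L),
                   list(name = "B", N = 40L,
                        origin = list(parent = "A", gen = 400L - tSplit))),
      genome = data.frame(chrom = "chr1", length = 2e4),
      mu = 2e-5, recomb = 5e-5, generations = 400L)
    sim <- simulatePopulations(cfg)
    pm <- sim$popmap
    wcFst(sim$panel, pm$sample[pm$population == "A"],
          pm$sample[pm$population == "B"])$global
  }
  f <- vapply(c(20L, 100L, 350L), fstAt, numeric(1))
  expect_true(all(diff(f) > 0))
  expect_gt(f[3], 0.3)
})

test_that("heterozygosity decays at ~1/(2N) per generation in a closed deme", {
  N <- 30L; T <- 60L
  hets <- vapply(701:715, function(seed) {
    sim <- simulatePopulations(simConfig(
      seed = seed, demes = list(list(name = "A", N = N)),
      genome = data.frame(chrom = "chr1", length = 1e4),
      mu = 0, generations = T, sampleSizes = c(A = N),
      initSites = list(n = 300L, freq = 0.5)))
    gt <- genotypes(sim$panel)
    # population heterozygosity over surviving + fixed/lost sites (those -> 0)
    p <- rowSums(gt) / (2 * ncol(gt))
    sum(2 * p * (1 - p)) / 300
  }, numeric(1))
  expected <- 0.5 * (1 - 1 / (2 * N))^T
  se <- sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 4 * se + 0.02)
})

test_that("stronger selection lowers equilibrium derived-allele frequency", {
  sim <- simulatePopulations(simConfig(
    seed = 21, demes = list(list(name = "A", N = 60L)),
    genome = data.frame(chrom = "chr1", length = 4e4),
    mu = 2e-5, generations = 400L, sampleSizes = c(A = 60L),
    classes = data.frame(label = c("s_weak", "s_strong"),
                         fraction = c(0.3, 0.3),
                         s = c(0.05, 0.5), h = c(0.5, 0.5))))
  gt <- genotypes(sim$panel)
  lab <- sim$truth$sites$label
  meanFreq <- function(l) mean(rowSums(gt[lab == l, , drop = FALSE]) /
                                 (2 * ncol(gt)))
  expect_gt(meanFreq("neutral"), meanFreq("s_weak"))
  expect_gt(meanFreq("s_weak"), meanFreq("s_strong"))
})

test_that("pedigree genotypes obey Mendelian structure", {
  f <- simulateFounderPanel(12, 3000, seed = 31)
  ped <- simulatePedigree(f, c("MZ", "PO", "FS"), seed = 32)
  gt <- ped$gt
  expect_identical(gt[, "p01_a"], gt[, "p01_b"])        # MZ: identical
  # PO share >= 1 allele at every site: never opposing homozygotes
  opposing <- (gt[, "p02_a"] == 0L & gt[, "p02_b"] == 2L) |
              (gt[, "p02_a"] == 2L & gt[, "p02_b"] == 0L)
  expect_equal(sum(opposing), 0L)
  expect_error(simulatePedigree(f, rep("FS", 10), seed = 1), "founders")
})

test_that("synthetic scores hit the deleterious band at the stated rate", {
  sites <- data.frame(chrom = "c", pos = seq_len(1000),
                      label = rep(c("del", "neutral"), 500))
  sAll <- assignSyntheticScores(sites, seed = 7, pDel = 1)
  expect_true(all(sAll$score[sites$label == "del"] < 0.05))
  expect_true(all(sAll$score[sites$label == "neutral"] >= 0.05))
  s90 <- assignSyntheticScores(sites, seed = 8, pDel = 0.9)
  recall <- mean(s90$score[sites$label == "del"] < 0.05)
  expect_equal(recall, 0.9, tolerance = 3 * sqrt(0.9 * 0.1 / 500))
  expect_identical(assignSyntheticScores(sites, seed = 8),
                   assignSyntheticScores(sites, seed = 8))
})

test_that("neutral single-deme diversity approaches 4N mu", {
  pis <- vapply(801:810, function(seed) {
    sim <- simulatePopulations(simConfig(
      seed = seed, demes = list(list(name = "A", N = 40L)),
      genome = data.frame(chrom = "chr1", length = 2e4),
      mu = 2e-5, generations = 500L, sampleSizes = c(A = 40L)))
    w <- windowedPi(sim$panel, windowBp = 2e4, chromLengths = c(chr1 = 2e4))
    sum(w$pi)
  }, numeric(1))
  expected <- 4 * 40 * 2e-5        # 0.0032
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 4 * se + 0.1 * expected)
})
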