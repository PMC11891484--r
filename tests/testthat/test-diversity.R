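test_that("windowed pi matches the hand-evaluated single-site value", {
  # one site, 2 diploids (n = 4 alleles), nAlt = 2, 100-bp window
  vp <- makePanel(matrix(c(1L, 1L), 1, 2), pos = 50L)
  w <- windowedPi(vp, windowBp = 100)
  expect_equal(w$pi, 2 * 2 * 2 / (4 * 3) / 100)
  expect_equal(w$pi, 2 / 300, tolerance = 1e-12)
})

test_that("monomorphic windows report zero diversity", {
  vp <- makePanel(matrix(0L, 5, 4))
  w <- windowedPi(vp, windowBp = 1e4)
  expect_true(all(w$pi == 0))
})

test_that("pi is invariant to sample order and chrom relabeling", {
  set.seed(42)
  gt <- matrix(sample(0:2, 60, TRUE), 10, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  vp1 <- makePanel(gt)
  vp2 <- makePanel(gt[, sample(6)], chrom = "renamed")
  expect_equal(windowedPi(vp1, windowBp = 1e5)$pi,
               windowedPi(vp2, windowBp = 1e5)$pi)
})

test_that("windowed pi equals the exhaustive haplotype-pair oracle", {
  set.seed(7)
  for (rep in 1:20) {
    nHap <- 2L * sample(2:5, 1)       # <= 10 haplotypes
    nSites <- sample(5:50, 1)
    hap <- matrix(rbinom(nHap * nSites, 1, runif(1, 0.1, 0.9)), nHap, nSites)
    gt <- hap[seq(1, nHap, 2), , drop = FALSE] +
          hap[seq(2, nHap, 2), , drop = FALSE]
    vp <- makePanel(t(gt), pos = seq_len(nSites), spacing = 1)
    w <- windowedPi(vp, windowBp = nSites, chromLengths = c(chr1 = nSites))
    expect_equal(w$pi[1] * nSites, piPairwiseOracle(hap), tolerance = 1e-10)
  }
})

test_that("Tajima's D behaves per the published constants", {
  # numerator identity: D = 0 whenever piHat * a1 = S
  a1 <- sum(1 / (1:9))                 # n = 10
  expect_equal(tajimasD(S = 5, piHat = 5 / a1, n = 10), 0)
  expect_true(is.na(tajimasD(S = 0, piHat = 0.3, n = 10)))
  # n = 4, S = 2, piHat = 1.5: frozen against an independent evaluation
  n <- 4; S <- 2; piHat <- 1.5
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimasD(2, 1.5, 4), expected)
  expect_equal(tajimasD(2, 1.5, 4), 3.1945328, tolerance = 1e-6)
})

test_that("Weir-Cockerham FST hits its algebraic limits", {
  # identical allele frequencies and het rates in both pops -> ~0
  # (the estimator is unbiased around 0, with a small-sample term ~ -1/n)
  set.seed(17)
  half <- matrix(sample(0:2, 40 * 30, TRUE), 40, 30)
  gt <- cbind(half, half)
  colnames(gt) <- paste0("s", 1:60)
  vp <- makePanel(gt)
  r <- wcFst(vp, paste0("s", 1:30), paste0("s", 31:60))
  expect_lt(abs(r$global), 0.05)
  # fixed difference, large n -> theta -> 1
  nBig <- 30
  gt2 <- matrix(c(rep(0L, nBig), rep(2L, nBig)), 1)
  vp2 <- makePanel(gt2)
  r2 <- wcFst(vp2, paste0("s", 1:nBig), paste0("s", nBig + 1:nBig))
  expect_gt(r2$global, 0.95)
})

test_that("Weir-Cockerham FST equals a scalar from-scratch evaluation", {
  gt <- rbind(c(0L, 1L, 2L, 2L, 1L, 1L),
              c(1L, 1L, 0L, 0L, 0L, 1L),
              c(2L, 2L, 1L, 0L, 0L, 0L))
  vp <- makePanel(gt)
  got <- wcFst(vp, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  # independent scalar evaluation of the 1984 variance components
  num <- 0; den <- 0
  for (site in 1:3) {
    gA <- gt[site, 1:3]; gB <- gt[site, 4:6]
    nA <- 3; nB <- 3; r <- 2
    pA <- sum(gA) / (2 * nA); pB <- sum(gB) / (2 * nB)
    hA <- mean(gA == 1); hB <- mean(gB == 1)
    nbar <- (nA + nB) / 2
    nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (r * nbar)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  expect_equal(got$global, num / den, tolerance = 1e-12)
})

test_that("splitting one population at random gives near-zero FST", {
  set.seed(99)
  gt <- matrix(rbinom(200 * 20, 2, 0.3), 200, 20,
               dimnames = list(NULL, paste0("s", 1:20)))
  vp <- makePanel(gt)
  fst <- replicate(10, {
    pick <- sample(20, 10)
    wcFst(vp, paste0("s", pick), paste0("s", setdiff(1:20, pick)))$global
  })
  expect_lt(abs(mean(fst)), 0.02)
})

test_that("individual F spans its limits and matches the hand formula", {
  # fully homozygous individual -> F = 1
  set.seed(3)
  gt <- cbind(a = sample(c(0L, 2L), 50, TRUE),
              b = sample(0:2, 50, TRUE), c = sample(0:2, 50, TRUE),
              d = sample(0:2, 50, TRUE))
  vp <- makePanel(gt)
  expect_equal(individualF(vp, "a")$F, 1)
  # fully heterozygous individual at p = 0.5 sites: hand evaluation
  gt2 <- cbind(a = rep(1L, 40), b = rep(1L, 40),
               c = rep(0L, 40), d = rep(2L, 40))   # p = 0.5 at every site
  vp2 <- makePanel(gt2)
  n <- 8
  eSite <- 1 - 2 * 0.5 * 0.5 * n / (n - 1)
  expect_equal(individualF(vp2, "a")$F, (0 - 40 * eSite) / (40 - 40 * eSite))
  expect_lt(individualF(vp2, "a")$F, 0)
})

test_that("Hardy-Weinberg genotypes give F near zero", {
  set.seed(11)
  nS <- 4000
  p <- runif(nS, 0.2, 0.8)
  gt <- sapply(1:12, function(i) rbinom(nS, 2, p))
  colnames(gt) <- paste0("s", 1:12)
  f <- individualF(makePanel(gt))
  expect_true(all(abs(f$F) < 0.05))
  expect_lt(abs(mean(f$F)), 0.02)
})

test_that("LD decay: duplicated sites give r2 = 1 and binning is sane", {
  set.seed(21)
  g <- sample(0:2, 30, TRUE)
  gt <- rbind(g, g)
  vp <- makePanel(gt, pos = c(100L, 600L))
  bins <- ldDecay(vp, maxDistBp = 1000, binBp = 250)
  expect_equal(bins$meanR2[2], 1)      # distance 500 -> bin 2
  expect_equal(bins$nPairs[2], 1L)
})

test_that("independent sites decay to the 1/n r2 bias floor", {
  set.seed(31)
  n <- 40
  gt <- matrix(rbinom(200 * n, 2, 0.5), 200, n)
  vp <- makePanel(gt, pos = seq_len(200) * 10L)
  bins <- ldDecay(vp, maxDistBp = 2000, binBp = 2000)
  expect_equal(bins$meanR2[1], 1 / n, tolerance = 0.35)
})

test_that("half-decay distance is the first bin at half maximum", {
  bins <- data.frame(mid = c(50, 150, 250, 350),
                     meanR2 = c(0.8, 0.5, 0.39, 0.2))
  expect_equal(halfDecayDistance(bins), 250)
  bins$meanR2 <- c(0.4, 0.39, 0.38, 0.37)
  expect_true(is.na(halfDecayDistance(bins)))
})
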