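plantedPanel <- function(toy) {
  pl <- toy$planted[order(toy$planted$chrom, toy$planted$pos), ]
  vp <- VariantPanel(chrom = pl$chrom, pos = pl$pos, ref = pl$ref,
                     alt = pl$alt, qual = rep(100, nrow(pl)),
                     gt = matrix(1L, nrow(pl), 2,
                                 dimnames = list(NULL, c("s1", "s2"))))
  list(panel = vp, planted = pl)
}

test_that("every planted effect category is recovered on both strands", {
  toy <- makeToyGeneModels(seed = 3)
  pp <- plantedPanel(toy)
  eff <- annotateEffects(pp$panel, toy$gms, toy$ref)
  expect_equal(eff$category, pp$planted$expected)
  # strand sanity: the minus-strand stop-gain is a genomic C>T
  mg <- eff[eff$chrom == "tgB" & eff$category == "stop-gain", ]
  expect_equal(mg$ref, "C")
  expect_equal(mg$alt, "T")
})

test_that("gene models and reference round-trip through GFF3/FASTA files", {
  d <- tempfile(); dir.create(d)
  toy <- makeToyGeneModels(seed = 3, dir = d)
  gms2 <- readGeneModels(toy$gff3)
  ref2 <- readReference(toy$fasta)
  pp <- plantedPanel(toy)
  eff <- annotateEffects(pp$panel, gms2, ref2)
  expect_equal(eff$category, pp$planted$expected)
})

test_that("reference-mismatching sites are flagged and excluded", {
  toy <- makeToyGeneModels(seed = 3)
  # claim a wrong REF base inside the CDS of t1
  wrongRef <- setdiff(c("A", "C", "G", "T"),
                      c(substr(as.character(toy$ref[["tgA"]]), 139, 139), "A"))[1]
  vp <- VariantPanel(chrom = "tgA", pos = 139L, ref = wrongRef, alt = "A",
                     qual = 100, gt = matrix(1L, 1, 1,
                                             dimnames = list(NULL, "s1")))
  eff <- annotateEffects(vp, toy$gms, toy$ref)
  expect_true(eff$refMismatch)
  expect_true(is.na(eff$category))
})

test_that("minus-strand annotation equals annotating the reverse complement", {
  toy <- makeToyGeneModels(seed = 3)
  L <- 1000L
  # map gene g2 (tgB, minus) onto the reverse-complemented chromosome as plus
  rcSeq <- Biostrings::reverseComplement(toy$ref[["tgB"]])
  rcRef <- Biostrings::DNAStringSet(stats::setNames(list(rcSeq), "tgBrc"))
  tx <- data.frame(txId = "t2rc", geneId = "g2rc", chrom = "tgBrc",
                   strand = "+", start = L - 500L + 1L, end = L - 201L + 1L)
  exons <- list(t2rc = data.frame(start = L - 500L + 1L, end = L - 201L + 1L))
  cds <- list(t2rc = data.frame(start = L - 470L + 1L, end = L - 231L + 1L))
  gmsRc <- geneModelSet(tx, exons, cds)
  pl <- toy$planted[toy$planted$chrom == "tgB" &
                    toy$planted$pos %in% c(461L, 462L, 465L), ]
  pl <- pl[order(pl$pos), ]
  comp <- function(b) chartr("ACGT", "TGCA", b)
  rcPos <- L - pl$pos + 1L
  ord <- order(rcPos)
  vp <- VariantPanel(chrom = "tgBrc", pos = rcPos[ord],
                     ref = comp(pl$ref)[ord], alt = comp(pl$alt)[ord],
                     qual = rep(100, 3),
                     gt = matrix(1L, 3, 1, dimnames = list(NULL, "s1")))
  effRc <- annotateEffects(vp, gmsRc, rcRef)
  expect_equal(effRc$category, pl$expected[ord])
})

test_that("Grantham distances reproduce the published chemistry", {
  aa <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
          "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
  # diagonal and symmetry over all pairs
  expect_true(all(granthamDistance(aa, aa) == 0))
  m <- granthamMatrix(rounded = FALSE)
  expect_equal(m, t(m))
  # normalization: mean over the 190 unordered pairs is 100
  expect_equal(mean(m[upper.tri(m)]), 100, tolerance = 1e-9)
  # dual route: independent from-scratch recomputation
  expect_equal(m, granthamOracle(), tolerance = 1e-9)
  # published anchor entries, +/- 1 after rounding
  anchors <- rbind(
    c("L", "I", 5),   c("C", "W", 215), c("D", "E", 45), c("R", "K", 26),
    c("F", "Y", 22),  c("M", "L", 15),  c("S", "T", 58), c("A", "G", 60),
    c("W", "G", 184), c("Y", "F", 22),  c("H", "Q", 24), c("N", "D", 23),
    c("V", "I", 29),  c("S", "P", 74),  c("E", "Q", 29), c("A", "P", 27),
    c("T", "M", 81),  c("C", "S", 112), c("R", "W", 101), c("G", "V", 109))
  for (k in seq_len(nrow(anchors))) {
    got <- granthamDistance(anchors[k, 1], anchors[k, 2])
    expect_lte(abs(got - as.numeric(anchors[k, 3])), 1)
  }
  expect_error(granthamDistance("B", "A"), "nonstandard")
})

test_that("mutation classes combine effect, Grantham and score evidence", {
  eff <- data.frame(
    site = 1:4, chrom = "c", pos = c(10L, 20L, 30L, 40L),
    ref = "A", alt = "T",
    category = c("nonsynonymous", "nonsynonymous", "stop-gain", "synonymous"),
    txId = "t", refAA = c("C", "D", "W", "L"), altAA = c("W", "E", "*", "L"),
    codonIndex = 1:4,
    grantham = c(granthamDistance("C", "W"), granthamDistance("D", "E"),
                 NA, NA),
    refMismatch = FALSE)
  scores <- data.frame(chrom = "c", pos = c(20L, 30L), score = c(0.30, 0.01))
  cls <- classifyMutations(eff, scores)
  expect_true(cls$RADICAL[1])                      # Cys->Trp, 215 > 150
  expect_false(cls$RADICAL[2] || isTRUE(cls$DEL[2]))  # Asp->Glu 45, score 0.3
  expect_true(cls$LOF[3] && cls$DEL[3])            # stop-gain, score 0.01
  expect_true(is.na(cls$DEL[1]))                   # unscored -> unknown
  expect_false(cls$LOF[4])
})

test_that("class percentages are exact at two decimals", {
  cf <- classFractions(c(DEL = 19699L, RADICAL = 5600L, LOF = 1499L,
                         HOMOZYGOUS = 10364L, SHARED = 2175L), 23290L)
  expect_equal(cf$percent, c(84.58, 24.04, 6.44, 44.50, 9.34))
  one <- classFractions(c(ALL = 77L), 77L)
  expect_equal(one$percent, 100)
  expect_error(classFractions(c(a = 1L), 0), "positive")
})

test_that("disjoint category percentages always sum to 100", {
  toy <- makeToyGeneModels(seed = 3)
  pp <- plantedPanel(toy)
  eff <- annotateEffects(pp$panel, toy$gms, toy$ref)
  tab <- table(eff$category)
  cf <- classFractions(stats::setNames(as.integer(tab), names(tab)), sum(tab))
  expect_equal(sum(cf$percent), 100, tolerance = 0.05)
})
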