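#' Toy gene models with planted variant effects
#'
#' Builds a deterministic two-chromosome reference with one plus-strand
#' two-exon gene and one minus-strand single-exon gene, plus a table of
#' planted SNPs covering every effect category the annotator emits
#' (start-loss, stop-gain, stop-loss, splicing, radical and mild
#' nonsynonymous, synonymous, UTRs, intronic, up/downstream, intergenic).
#' Filler sequence is random from \code{seed}; every base the planted
#' effects depend on is written explicitly.
#'
#' @param seed integer seed for filler bases
#' @param dir optional directory; when given writes \code{toy.fa} and
#'   \code{toy.gff3}
#' @return list: \code{ref} (\code{DNAStringSet}), \code{gms}
#'   (\code{GeneModelSet}), \code{planted} (data.frame chrom, pos, ref,
#'   alt, expected), and file paths when written
#' @export
makeToyGeneModels <- function(seed = 1, dir = NULL) {
  set.seed(seed)
  rb <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

  # chrom tgA: gene g1 (+), exons 101-220 / 281-400, CDS 131-220 + 281-370
  codA <- c("ATG", "GCT", "TGG", "TGT", "GAT", "CTG",
            rep("GGA", 53), "TGA")                      # 60 codons
  cdsA <- strsplit(paste(codA, collapse = ""), "")[[1L]]
  stopifnot(length(cdsA) == 180L)
  segA <- rb(3000)
  segA[131:220] <- cdsA[1:90]
  segA[281:370] <- cdsA[91:180]
  segA[221:222] <- c("G", "T")    # canonical donor
  segA[279:280] <- c("A", "G")    # canonical acceptor

  # chrom tgB: gene g2 (-), exon 201-500, CDS 231-470
  codB <- c("ATG", "TGG", "CTG", rep("GCA", 76), "TAA") # 80 codons
  cdsB <- strsplit(paste(codB, collapse = ""), "")[[1L]]
  stopifnot(length(cdsB) == 240L)
  segB <- rb(1000)
  segB[231:470] <- rev(chartr("ACGT", "TGCA", cdsB))

  ref <- Biostrings::DNAStringSet(c(tgA = paste(segA, collapse = ""),
                                    tgB = paste(segB, collapse = "")))

  tx <- data.frame(txId = c("t1", "t2"), geneId = c("g1", "g2"),
                   chrom = c("tgA", "tgB"), strand = c("+", "-"),
                   start = c(101L, 201L), end = c(400L, 500L),
                   stringsAsFactors = FALSE)
  exons <- list(t1 = data.frame(start = c(101L, 281L), end = c(220L, 400L)),
                t2 = data.frame(start = 201L, end = 500L))
  cds <- list(t1 = data.frame(start = c(131L, 281L), end = c(220L, 370L)),
              t2 = data.frame(start = 231L, end = 470L))
  gms <- geneModelSet(tx, exons, cds)

  altOf <- function(chromSeq, pos, alt = NULL) {
    r <- chromSeq[pos]
    if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), r)[1L]
    c(r, alt)
  }
  plant <- function(chrom, pos, alt, expected) {
    seq0 <- if (chrom == "tgA") segA else segB
    ra <- altOf(seq0, pos, alt)
    data.frame(chrom = chrom, pos = pos, ref = ra[1L], alt = ra[2L],
               expected = expected, stringsAsFactors = FALSE)
  }
  planted <- rbind(
    plant("tgA", 133L, "A", "start-loss"),      # ATG -> ATA
    plant("tgA", 139L, "A", "stop-gain"),       # TGG -> TGA
    plant("tgA", 142L, "G", "nonsynonymous"),   # TGT -> TGG, Cys->Trp (radical)
    plant("tgA", 145L, "A", "nonsynonymous"),   # GAT -> GAA, Asp->Glu (mild)
    plant("tgA", 148L, "A", "synonymous"),      # CTG -> CTA
    plant("tgA", 370L, "C", "stop-loss"),       # TGA -> TGC
    plant("tgA", 221L, "A", "splicing"),        # donor +1
    plant("tgA", 250L, NULL, "intronic"),
    plant("tgA", 110L, NULL, "UTR5"),
    plant("tgA", 380L, NULL, "UTR3"),
    plant("tgA", 50L, NULL, "upstream"),
    plant("tgA", 900L, NULL, "downstream"),
    plant("tgA", 2500L, NULL, "intergenic"),
    plant("tgB", 465L, "T", "stop-gain"),       # coding TGG -> TGA on - strand
    plant("tgB", 462L, "T", "synonymous"),      # coding CTG -> CTA
    plant("tgB", 461L, "G", "nonsynonymous"),   # coding GCA -> CCA, Ala->Pro
    plant("tgB", 480L, NULL, "UTR5"),
    plant("tgB", 210L, NULL, "UTR3"))

  out <- list(ref = ref, gms = gms, planted = planted)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$fasta <- file.path(dir, "toy.fa")
    Biostrings::writeXStringSet(ref, out$fasta)
    out$gff3 <- file.path(dir, "toy.gff3")
    writeGeneModelsGff3(tx, exons, cds,
                        chromLen = c(tgA = 3000L, tgB = 1000L), out$gff3)
  }
  out
}

#' Write gene models as GFF3
#'
#' Minimal deterministic GFF3 emitter (gene / mRNA / exon / CDS with
#' phases) whose output round-trips through [readGeneModels()].
#'
#' @param tx,exons,cds as accepted by [geneModelSet()]
#' @param chromLen named chromosome lengths for the sequence-region pragmas
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeGeneModelsGff3 <- function(tx, exons, cds, chromLen, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(chromLen), chromLen))
  f <- function(chrom, type, s, e, strand, phase, attrs)
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, s, e, strand, phase, attrs)
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    lines <- c(lines,
      f(t$chrom, "gene", t$start, t$end, t$strand, ".",
        sprintf("ID=%s", t$geneId)),
      f(t$chrom, "mRNA", t$start, t$end, t$strand, ".",
        sprintf("ID=%s;Parent=%s", t$txId, t$geneId)))
    ex <- exons[[t$txId]]
    for (k in seq_len(nrow(ex)))
      lines <- c(lines, f(t$chrom, "exon", ex$start[k], ex$end[k], t$strand,
                          ".", sprintf("Parent=%s", t$txId)))
    cd <- cds[[t$txId]]
    cd <- cd[order(cd$start, decreasing = (t$strand == "-")), , drop = FALSE]
    phase <- 0L
    for (k in seq_len(nrow(cd))) {
      lines <- c(lines, f(t$chrom, "CDS", cd$start[k], cd$end[k], t$strand,
                          as.character(phase), sprintf("Parent=%s", t$txId)))
      phase <- (3L - ((cd$end[k] - cd$start[k] + 1L - phase) %% 3L)) %% 3L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic deleteriousness scores with known truth
#'
#' Emulates a SIFT-style score table: sites whose true class label is in
#' \code{delClasses} receive a score below 0.05 with probability
#' \code{pDel} (otherwise, and for all other sites, Uniform(0.05, 1)).
#' Reproducible from the seed.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{label}
#'   (e.g. \code{truth$sites} from [simulatePopulations()])
#' @param seed integer seed
#' @param pDel probability a truly deleterious site scores < 0.05
#' @param delClasses labels treated as truly deleterious
#' @return data.frame: chrom, pos, score
#' @export
assignSyntheticScores <- function(sites, seed, pDel = 0.9,
                                  delClasses = c("del")) {
  set.seed(seed)
  n <- nrow(sites)
  isDel <- sites$label %in% delClasses
  low <- isDel & stats::runif(n) < pDel
  score <- stats::runif(n, 0.05, 1)
  score[low] <- stats::runif(sum(low), 0, 0.05)
  data.frame(chrom = sites$chrom, pos = sites$pos, score = score,
             stringsAsFactors = FALSE)
}
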