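#' Construct a VariantPanel from vectors and a genotype matrix
#'
#' Low-level constructor used by the readers and the simulator.  Genotypes
#' are ALT-allele dosages (0/1/2, \code{NA} missing).
#'
#' @param chrom,pos,ref,alt,qual per-site vectors (positions 1-based)
#' @param gt integer dosage matrix, sites x samples, with sample column names
#' @param dp optional depth matrix of matching dimension
#' @param aa optional ancestral-allele character vector (\code{NA} = unknown)
#' @param nAlt optional ALT-allele count per site (default: 1 + commas in \code{alt})
#' @param seqlengths optional named chromosome lengths (bp)
#' @return a [VariantPanel-class]
#' @export
VariantPanel <- function(chrom, pos, ref, alt, qual, gt, dp = NULL, aa = NULL,
                         nAlt = NULL, seqlengths = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (is.null(aa)) aa <- rep(NA_character_, length(pos))
  if (is.null(nAlt)) nAlt <- 1L + lengths(regmatches(alt, gregexpr(",", alt, fixed = TRUE)))
  gr <- GRanges(chrom, IRanges(pos, pos))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  mcols(gr) <- DataFrame(ref = as.character(ref), alt = as.character(alt),
                         qual = as.numeric(qual), nAlt = as.integer(nAlt),
                         aa = as.character(aa))
  assays <- list(gt = gt)
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    storage.mode(dp) <- "integer"
    assays$dp <- dp
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = gr)
  new("VariantPanel", se)
}

.checkSorted <- function(chrom, pos) {
  if (length(pos) < 2L) return(invisible(TRUE))
  same <- chrom[-1L] == chrom[-length(chrom)]
  bad <- which(same & pos[-1L] <= pos[-length(pos)])
  if (length(bad))
    stop(sprintf("VCF records out of order: %s:%d follows %s:%d",
                 chrom[bad[1L] + 1L], pos[bad[1L] + 1L],
                 chrom[bad[1L]], pos[bad[1L]]), call. = FALSE)
  invisible(TRUE)
}

# "0/1"-style GT string -> ALT dosage; any allele index > 1 (multi-allelic
# call) and any missing allele yield NA.
.gtToDosage <- function(gtChar) {
  u <- unique(as.vector(gtChar))
  code <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".") || !length(al)) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai) || any(ai > 1L)) return(NA_integer_)
    sum(ai)
  }, integer(1))
  m <- matrix(code[match(as.vector(gtChar), u)], nrow = nrow(gtChar),
              dimnames = dimnames(gtChar))
  m
}

#' Read a multi-sample VCF into a VariantPanel
#'
#' Parses with \code{VariantAnnotation::readVcf}.  One panel row per VCF
#' data line; \code{./.} becomes a missing genotype; multi-allelic records
#' are kept and flagged (\code{nAlt > 1}) so the filter cascade can count
#' them; genotypes carrying an allele index above 1 are encoded missing.
#' Unsorted positions are an error naming the first offending record.
#'
#' @param path VCF 4.x file with a GT FORMAT field
#' @return a [VariantPanel-class]
#' @export
readVcfPanel <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!"GT" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF has no GT genotype field", call. = FALSE)
  rr <- rowRanges(vcf)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  .checkSorted(chrom, pos)
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(as.list(altList), function(a) paste(as.character(a), collapse = ","),
                character(1))
  gtChar <- VariantAnnotation::geno(vcf)$GT
  gtChar[gtChar == "."] <- NA_character_
  gt <- .gtToDosage(gtChar)
  info <- VariantAnnotation::info(vcf)
  aa <- if ("AA" %in% colnames(info)) as.character(info$AA) else NULL
  dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$DP else NULL
  sl <- GenomeInfoDb::seqlengths(rr)
  if (all(is.na(sl))) sl <- NULL
  VariantPanel(chrom, pos, ref = as.character(VariantAnnotation::ref(vcf)),
               alt = alt, qual = VariantAnnotation::qual(vcf), gt = gt,
               dp = dp, aa = aa, nAlt = S4Vectors::elementNROWS(altList),
               seqlengths = sl)
}

#' Write a VariantPanel as a VCF 4.2 text file
#'
#' Emits a minimal, deterministic VCF (GT, optional DP, INFO/AA when
#' ancestral alleles are recorded).  Dosages map back to unphased genotype
#' strings (\code{0/0}, \code{0/1}, \code{1/1}, \code{./.}); the round trip
#' through [readVcfPanel()] is the identity on positions, alleles and
#' genotypes.  Multi-allelic rows are written with their comma-joined ALT
#' but their (undefined) dosage genotypes as missing.
#'
#' @param x a [VariantPanel-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeVcfPanel <- function(x, path) {
  gt <- genotypes(x)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popgenload")
  sl <- GenomeInfoDb::seqlengths(rowRanges(x))
  if (length(sl) && !all(is.na(sl)))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sl), sl))
  hasAA <- any(!is.na(ancestralAllele(x)))
  if (hasAA)
    hdr <- c(hdr, "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">")
  hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  dp <- depths(x)
  if (!is.null(dp))
    hdr <- c(hdr, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  gtStr <- matrix("./.", nrow(gt), ncol(gt))
  gtStr[!is.na(gt) & gt == 0L] <- "0/0"
  gtStr[!is.na(gt) & gt == 1L] <- "0/1"
  gtStr[!is.na(gt) & gt == 2L] <- "1/1"
  if (!is.null(dp)) {
    dpStr <- ifelse(is.na(dp), ".", as.character(dp))
    gtStr <- matrix(paste(gtStr, dpStr, sep = ":"), nrow(gt))
  }
  qual <- qualScores(x)
  qualStr <- ifelse(is.na(qual), ".", formatC(qual, format = "g", digits = 8))
  aa <- ancestralAllele(x)
  infoStr <- if (hasAA) ifelse(is.na(aa), ".", paste0("AA=", aa)) else rep(".", nrow(gt))
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  body <- paste(chromosomes(x), positions(x), ".", refAllele(x), altAllele(x),
                qualStr, "PASS", infoStr, fmt, sep = "\t")
  if (nrow(gt)) {
    gtCols <- apply(gtStr, 1L, paste, collapse = "\t")
    body <- paste(body, gtCols, sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Tab-separated with a header; required columns \code{sample} and
#' \code{population}, optional \code{cluster} and \code{county}.  Sample ids
#' must be unique — every genotype column belongs to exactly one population.
#'
#' @param path TSV file
#' @return data.frame with one row per sample
#' @export
readPopmap <- function(path) {
  pm <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "population")
  if (!all(need %in% names(pm)))
    stop("popmap needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(pm$sample))
    stop("duplicated sample ids in popmap", call. = FALSE)
  pm
}

#' Assemble a gene-model set
#'
#' Internal representation used by [annotateEffects()]: per-transcript
#' strand plus genomically ascending exon and CDS intervals.  Transcripts
#' whose concatenated CDS length is not a multiple of 3, or that lack CDS,
#' are skipped with a collected warning (slot \code{$skipped}).
#'
#' @param tx data.frame with columns txId, geneId, chrom, strand, start, end
#' @param exons,cds named lists (by txId) of data.frames with start/end columns
#' @return object of class \code{GeneModelSet}
#' @export
geneModelSet <- function(tx, exons, cds) {
  skipped <- character()
  keep <- logical(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    id <- tx$txId[i]
    cd <- cds[[id]]
    if (is.null(cd) || !nrow(cd)) {
      skipped <- c(skipped, sprintf("%s: no CDS", id)); next
    }
    len <- sum(cd$end - cd$start + 1L)
    if (len %% 3L != 0L) {
      skipped <- c(skipped, sprintf("%s: CDS length %d not a multiple of 3", id, len))
      next
    }
    keep[i] <- TRUE
  }
  for (s in skipped) warning(s, call. = FALSE)
  ord <- function(d) d[order(d$start), , drop = FALSE]
  structure(list(
    tx = tx[keep, , drop = FALSE],
    exons = lapply(exons[tx$txId[keep]], ord),
    cds = lapply(cds[tx$txId[keep]], ord),
    skipped = skipped), class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat(sprintf("GeneModelSet: %d transcripts (%d skipped)\n",
              nrow(x$tx), length(x$skipped)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Imports via \code{rtracklayer::import} and assembles the
#' gene/mRNA/exon/CDS hierarchy.  Features with missing Parent links and
#' transcripts whose CDS length is not divisible by 3 are skipped with
#' warnings, mirroring how effect annotators treat broken models.
#'
#' @param path GFF3 file
#' @return a \code{GeneModelSet}
#' @export
readGeneModels <- function(path) {
  g <- rtracklayer::import(path)
  type <- as.character(g$type)
  mrna <- g[type %in% c("mRNA", "transcript")]
  if (!length(mrna)) stop("no mRNA features in ", path, call. = FALSE)
  txId <- as.character(mrna$ID)
  parent <- vapply(as.list(mrna$Parent), function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  tx <- data.frame(txId = txId, geneId = parent,
                   chrom = as.character(seqnames(mrna)),
                   strand = as.character(BiocGenerics::strand(mrna)),
                   start = start(mrna), end = end(mrna),
                   stringsAsFactors = FALSE)
  pick <- function(what) {
    feats <- g[type == what]
    pl <- as.list(feats$Parent)
    orphan <- lengths(pl) == 0L
    if (any(orphan))
      warning(sum(orphan), " ", what, " feature(s) without Parent skipped",
              call. = FALSE)
    feats <- feats[!orphan]
    par <- vapply(as.list(feats$Parent), function(p) as.character(p)[1L], character(1))
    split(data.frame(start = start(feats), end = end(feats)), par)
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  geneModelSet(tx, exons, cds)
}

#' Read a reference genome FASTA
#'
#' @param path FASTA file (possibly multi-record)
#' @return a \code{Biostrings::DNAStringSet} named by the first header token
#' @export
readReference <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' Read a per-variant deleteriousness score table
#'
#' TSV with columns \code{chrom}, \code{pos}, \code{score} — the SIFT-style
#' scores consumed by [classifyMutations()] (score < 0.05 = deleterious).
#'
#' @param path TSV file
#' @return data.frame
#' @export
readScoreTable <- function(path) {
  st <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "score")
  if (!all(need %in% names(st)))
    stop("score table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  st
}
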