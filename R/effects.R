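# category precedence when a site hits several transcripts or several
# feature contexts (highest first)
.effectPrecedence <- c("splicing", "stop-gain", "stop-loss", "start-loss",
                       "nonsynonymous", "synonymous", "UTR5", "UTR3",
                       "intronic", "upstream", "downstream", "intergenic")

#' Annotate SNP coding effects from gene models
#'
#' Locates each biallelic SNP in the transcript structure and assigns a
#' single category per site using the precedence splicing > stop-gain >
#' stop-loss > start-loss > nonsynonymous > synonymous > UTR > intronic >
#' upstream/downstream > intergenic.  Coding changes are translated with
#' the standard nuclear code on the coding strand; "splicing" means within
#' 2 bp of an intron boundary (the canonical GT/AG dinucleotides);
#' upstream/downstream means within \code{flankBp} of the transcript span.
#' Sites whose panel REF disagrees with the reference sequence are flagged
#' \code{refMismatch} and excluded from coding calls.
#'
#' @param x a [VariantPanel-class]
#' @param gms a \code{GeneModelSet} from [readGeneModels()] / [geneModelSet()]
#' @param ref named \code{DNAStringSet} reference from [readReference()]
#' @param flankBp upstream/downstream flank, bp
#' @return data.frame: site, chrom, pos, ref, alt, category, txId, refAA,
#'   altAA, codonIndex, grantham (nonsynonymous only), refMismatch
#' @export
annotateEffects <- function(x, gms, ref, flankBp = 1000) {
  chrom <- chromosomes(x)
  pos <- positions(x)
  refAl <- refAllele(x)
  altAl <- altAllele(x)
  txCache <- lapply(seq_len(nrow(gms$tx)), function(i) .txContext(gms, i, ref))
  names(txCache) <- gms$tx$txId
  out <- vector("list", length(pos))
  for (s in seq_along(pos)) {
    calls <- list()
    mismatch <- FALSE
    for (tc in txCache) {
      if (tc$chrom != chrom[s]) next
      if (pos[s] < tc$start - flankBp || pos[s] > tc$end + flankBp) next
      cl <- .classifySiteInTx(pos[s], refAl[s], altAl[s], tc, flankBp)
      if (isTRUE(cl$refMismatch)) { mismatch <- TRUE; next }
      if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
    }
    if (mismatch && !length(calls)) {
      out[[s]] <- data.frame(site = s, chrom = chrom[s], pos = pos[s],
                             ref = refAl[s], alt = altAl[s],
                             category = NA_character_, txId = NA_character_,
                             refAA = NA_character_, altAA = NA_character_,
                             codonIndex = NA_integer_, grantham = NA_real_,
                             refMismatch = TRUE)
      next
    }
    if (!length(calls)) {
      best <- list(category = "intergenic", txId = NA_character_,
                   refAA = NA_character_, altAA = NA_character_,
                   codonIndex = NA_integer_)
    } else {
      ranks <- vapply(calls, function(cl)
        match(cl$category, .effectPrecedence), integer(1))
      best <- calls[[which.min(ranks)]]
    }
    gd <- if (best$category == "nonsynonymous")
      granthamDistance(best$refAA, best$altAA) else NA_real_
    out[[s]] <- data.frame(site = s, chrom = chrom[s], pos = pos[s],
                           ref = refAl[s], alt = altAl[s],
                           category = best$category, txId = best$txId,
                           refAA = best$refAA, altAA = best$altAA,
                           codonIndex = best$codonIndex, grantham = gd,
                           refMismatch = FALSE)
  }
  do.call(rbind, out)
}

# Precompute per-transcript context: CDS positions in translation order,
# CDS sequence on the coding strand, intron intervals, exon/CDS interval
# tables.
.txContext <- function(gms, i, ref) {
  tx <- gms$tx[i, ]
  cds <- gms$cds[[tx$txId]]
  exons <- gms$exons[[tx$txId]]
  if (is.null(exons)) exons <- cds
  chromSeq <- ref[[tx$chrom]]
  # genomic positions of CDS bases, 5'->3' on the coding strand
  gpos <- unlist(lapply(seq_len(nrow(cds)), function(k) cds$start[k]:cds$end[k]))
  gpos <- sort(gpos)
  bases <- strsplit(as.character(Biostrings::subseq(chromSeq, 1, length(chromSeq))), "")[[1L]]
  cdsBases <- bases[gpos]
  if (tx$strand == "-") {
    gpos <- rev(gpos)
    cdsBases <- rev(chartr("ACGT", "TGCA", cdsBases))
  }
  introns <- NULL
  if (nrow(exons) > 1L) {
    ex <- exons[order(exons$start), ]
    introns <- data.frame(start = ex$end[-nrow(ex)] + 1L,
                          end = ex$start[-1L] - 1L)
    introns <- introns[introns$end >= introns$start, , drop = FALSE]
  }
  list(txId = tx$txId, chrom = tx$chrom, strand = tx$strand,
       start = tx$start, end = tx$end, cds = cds, exons = exons,
       introns = introns, gpos = gpos, cdsBases = cdsBases)
}

.classifySiteInTx <- function(pos, refAl, altAl, tc, flankBp) {
  res <- function(category, refAA = NA_character_, altAA = NA_character_,
                  codonIndex = NA_integer_)
    list(category = category, txId = tc$txId, refAA = refAA, altAA = altAA,
         codonIndex = codonIndex)
  inSpan <- pos >= tc$start && pos <= tc$end
  if (!inSpan) {
    before <- pos < tc$start
    upstream <- (tc$strand == "+") == before
    return(res(if (upstream) "upstream" else "downstream"))
  }
  # splice: within 2 bp of an intron boundary, intron side
  if (!is.null(tc$introns) && nrow(tc$introns)) {
    for (k in seq_len(nrow(tc$introns))) {
      is0 <- tc$introns$start[k]; ie <- tc$introns$end[k]
      if ((pos >= is0 && pos <= min(is0 + 1L, ie)) ||
          (pos <= ie && pos >= max(ie - 1L, is0)))
        return(res("splicing"))
    }
  }
  ci <- match(pos, tc$gpos)      # index along coding sequence, 1-based
  if (!is.na(ci)) {
    strandBase <- function(b) if (tc$strand == "-") chartr("ACGT", "TGCA", b) else b
    # panel REF is genome-strand; cdsBases are coding-strand
    if (strandBase(refAl) != tc$cdsBases[ci])
      return(list(refMismatch = TRUE))
    codonIdx <- (ci - 1L) %/% 3L + 1L
    within <- (ci - 1L) %% 3L + 1L
    codon <- tc$cdsBases[(codonIdx - 1L) * 3L + 1:3]
    altCodon <- codon
    altCodon[within] <- strandBase(altAl)
    refAA <- .translateCodon(paste(codon, collapse = ""))
    altAA <- .translateCodon(paste(altCodon, collapse = ""))
    if (codonIdx == 1L && paste(codon, collapse = "") == "ATG" &&
        paste(altCodon, collapse = "") != "ATG")
      return(res("start-loss", refAA, altAA, codonIdx))
    if (refAA != "*" && altAA == "*") return(res("stop-gain", refAA, altAA, codonIdx))
    if (refAA == "*" && altAA != "*") return(res("stop-loss", refAA, altAA, codonIdx))
    if (refAA == altAA) return(res("synonymous", refAA, altAA, codonIdx))
    return(res("nonsynonymous", refAA, altAA, codonIdx))
  }
  # inside transcript but not CDS: exon (UTR) or intron
  inExon <- any(pos >= tc$exons$start & pos <= tc$exons$end)
  if (inExon) {
    cdsLo <- min(tc$cds$start); cdsHi <- max(tc$cds$end)
    five <- if (tc$strand == "+") pos < cdsLo else pos > cdsHi
    return(res(if (five) "UTR5" else "UTR3"))
  }
  res("intronic")
}

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Assemble DEL / RADICAL / LOF mutation classes
#'
#' Flags each annotated site for the three deleterious-mutation classes:
#' \itemize{
#'   \item DEL — SIFT-style deleteriousness score < 0.05 (\code{NA} when no
#'     score is available; such sites are excluded from DEL counts);
#'   \item RADICAL — nonsynonymous with Grantham distance strictly > 150;
#'   \item LOF — stop-gain, stop-loss, start-loss or splice change.
#' }
#' Flags are independent: one site can carry several.
#'
#' @param effects data.frame from [annotateEffects()]
#' @param siftScores optional data.frame (\code{chrom}, \code{pos},
#'   \code{score}), e.g. from [readScoreTable()]
#' @return \code{effects} with logical columns \code{DEL}, \code{RADICAL},
#'   \code{LOF} and numeric \code{sift} added
#' @export
classifyMutations <- function(effects, siftScores = NULL) {
  sift <- rep(NA_real_, nrow(effects))
  if (!is.null(siftScores)) {
    idx <- match(paste(effects$chrom, effects$pos),
                 paste(siftScores$chrom, siftScores$pos))
    sift <- siftScores$score[idx]
  }
  effects$sift <- sift
  effects$DEL <- ifelse(is.na(sift), NA, sift < 0.05)
  effects$RADICAL <- !is.na(effects$category) &
    effects$category == "nonsynonymous" &
    !is.na(effects$grantham) & effects$grantham > 150
  effects$LOF <- !is.na(effects$category) &
    effects$category %in% c("stop-gain", "stop-loss", "start-loss", "splicing")
  effects
}

#' Per-class counts and percentages
#'
#' Percentages are \code{100 * count / total}, reported to two decimals —
#' the convention for quoting class composition of a mutation set.  Class
#' flags may overlap, so percentages can sum past 100.
#'
#' @param counts named integer vector of per-class counts
#' @param total classified-mutation universe size (> 0)
#' @return data.frame: class, count, percent
#' @examples
#' classFractions(c(DEL = 19699, RADICAL = 5600, LOF = 1499), 23290)
#' @export
classFractions <- function(counts, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  data.frame(class = names(counts), count = as.integer(counts),
             percent = round(100 * as.numeric(counts) / total, 2),
             row.names = NULL)
}
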