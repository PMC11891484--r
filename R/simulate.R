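#' Configuration for the forward simulator
#'
#' Describes the study design the generator emulates: one or more demes
#' with optional bottleneck schedules and split origins, island-model
#' migration, a genome of one or more chromosomes, an infinite-sites
#' mutation process partitioned into selection classes, and per-deme sample
#' sizes.  A single seed governs all randomness.
#'
#' @param seed integer seed (mandatory)
#' @param demes list of deme descriptions; each a list with \code{name},
#'   \code{N} (diploid size), optional \code{bottlenecks} (data.frame
#'   \code{gen}, \code{N}: from generation \code{gen} on, size becomes
#'   \code{N}) and optional \code{origin} (list \code{parent}, \code{gen}:
#'   the deme first exists at \code{gen}, founded from \code{parent})
#' @param migration per-generation probability that an offspring's parents
#'   come from another (uniformly chosen) existing deme
#' @param genome data.frame with \code{chrom} and \code{length} (bp)
#' @param mu mutation rate per site per generation
#' @param recomb recombination rate per bp per generation
#' @param classes data.frame \code{label}, \code{fraction}, \code{s},
#'   \code{h}: each new mutation joins class \code{label} with probability
#'   \code{fraction}; genotype fitness is 1, \eqn{1-hs}, \eqn{1-s} for
#'   ancestral-hom / het / derived-hom.  The remaining fraction is neutral.
#' @param sampleSizes named integer vector (deme -> diploids sampled);
#'   default \code{min(N, 25)} each
#' @param generations number of generations to run
#' @param initSites optional list(\code{n}, \code{freq}, \code{label}):
#'   standing neutral variation planted at generation 0 at the given
#'   derived-allele frequency (used e.g. for heterozygosity-decay checks)
#' @return validated config list of class \code{SimConfig}
#' @export
simConfig <- function(seed,
                      demes = list(list(name = "deme1", N = 100L)),
                      migration = 0,
                      genome = data.frame(chrom = "chr1", length = 5e4),
                      mu = 1e-5, recomb = 1e-7,
                      classes = data.frame(label = character(),
                                           fraction = numeric(),
                                           s = numeric(), h = numeric()),
                      sampleSizes = NULL,
                      generations = 1000L,
                      initSites = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (nrow(classes) && sum(classes$fraction) > 1 + 1e-12)
    stop("class fractions must sum to <= 1", call. = FALSE)
  if (mu < 0 || recomb < 0 || migration < 0 || migration > 1)
    stop("rates must be non-negative (migration in [0,1])", call. = FALSE)
  names(demes) <- vapply(demes, `[[`, character(1), "name")
  if (is.null(sampleSizes))
    sampleSizes <- vapply(demes, function(d) min(d$N, 25L), numeric(1))
  structure(list(seed = as.integer(seed), demes = demes,
                 migration = migration, genome = genome, mu = mu,
                 recomb = recomb, classes = classes,
                 sampleSizes = sampleSizes,
                 generations = as.integer(generations),
                 initSites = initSites),
            class = "SimConfig")
}

# deme sizes in force at generation g (0 for not-yet-existing demes)
.demeSizesAt <- function(cfg, g) {
  vapply(cfg$demes, function(d) {
    if (!is.null(d$origin) && g < d$origin$gen) return(0L)
    N <- d$N
    if (!is.null(d$bottlenecks) && nrow(d$bottlenecks)) {
      hit <- d$bottlenecks$gen <= g
      if (any(hit)) N <- d$bottlenecks$N[max(which(hit))]
    }
    as.integer(N)
  }, integer(1))
}

# log-fitness of each diploid given haplotypes and class labels
.logFitness <- function(H, classIdx, classes) {
  nInd <- nrow(H) %/% 2L
  logw <- numeric(nInd)
  if (!nrow(classes)) return(logw)
  odd <- seq(1L, nrow(H), by = 2L)
  for (k in seq_len(nrow(classes))) {
    s <- classes$s[k]; h <- classes$h[k]
    if (s == 0) next
    cols <- which(classIdx == k)
    if (!length(cols)) next
    D <- H[odd, cols, drop = FALSE] + H[odd + 1L, cols, drop = FALSE]
    logw <- logw + rowSums(D == 1L) * log(1 - h * s) +
      rowSums(D == 2L) * log(pmax(1 - s, .Machine$double.xmin))
  }
  logw
}

# one gamete per entry of `parents` (diploid indices into H)
.makeGametes <- function(H, parents, chromOf, posInChrom, chromLen, recomb) {
  nG <- length(parents)
  S <- ncol(H)
  G <- matrix(0L, nG, S)
  if (!S || !nG) return(G)
  for (c in seq_along(chromLen)) {
    cols <- which(chromOf == c)
    if (!length(cols)) next
    nx <- stats::rpois(nG, recomb * chromLen[c])
    hap <- sample.int(2L, nG, replace = TRUE) - 1L
    base <- 2L * (parents - 1L) + 1L
    simple <- nx == 0L
    if (any(simple))
      G[simple, cols] <- H[base[simple] + hap[simple], cols, drop = FALSE]
    for (g in which(!simple)) {
      cuts <- sort(stats::runif(nx[g], 0, chromLen[c]))
      seg <- findInterval(posInChrom[cols], cuts)
      useHap <- (hap[g] + seg) %% 2L
      h1 <- H[base[g], cols]; h2 <- H[base[g] + 1L, cols]
      G[g, cols] <- ifelse(useHap == 0L, h1, h2)
    }
  }
  G
}

#' Wright-Fisher forward simulation of structured populations
#'
#' Discrete-generation diploid simulation with per-class selection
#' (fitness 1 / \eqn{1-hs} / \eqn{1-s}), island-model migration, deme
#' splits, bottleneck schedules, Poisson recombination and infinite-sites
#' mutation.  Output genotypes are ancestrally polarized by construction
#' (the ancestral allele is the simulation's 0 allele and is written as
#' REF with an INFO/AA tag), with per-site class labels returned as ground
#' truth.  Fully reproducible: the same seed yields byte-identical files.
#'
#' @param cfg a [simConfig()] object
#' @param dir optional output directory; when given, writes
#'   \code{panel.vcf}, \code{popmap.tsv} and \code{truth.json}
#' @return list: \code{panel} (a [PolarizedVariantPanel-class]),
#'   \code{popmap} (data.frame), \code{truth} (site class labels, fixation
#'   counts per class, deme parameters, expected equilibrium diversity
#'   \eqn{4N\mu}), and file paths when \code{dir} is given
#' @export
simulatePopulations <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  chromLen <- cfg$genome$length
  offsets <- c(0, cumsum(as.numeric(chromLen)))[seq_along(chromLen)]
  Ltot <- sum(chromLen)
  nClass <- nrow(cfg$classes)
  classLabels <- c(cfg$classes$label, "neutral")
  classProb <- c(cfg$classes$fraction, 1 - sum(cfg$classes$fraction))

  sizes <- .demeSizesAt(cfg, 0L)
  if (any(sizes[vapply(cfg$demes, function(d) is.null(d$origin), logical(1))] <= 0))
    stop("initial deme sizes must be positive", call. = FALSE)
  deme <- rep(seq_along(sizes), sizes)
  nInd <- length(deme)
  H <- matrix(0L, 2L * nInd, 0L)
  chromOf <- integer(0); posInChrom <- numeric(0); classIdx <- integer(0)
  fixedCount <- stats::setNames(integer(nClass + 1L), classLabels)

  if (!is.null(cfg$initSites)) {
    nI <- cfg$initSites$n
    chromOf <- sample.int(length(chromLen), nI, replace = TRUE,
                          prob = chromLen / Ltot)
    posInChrom <- integer(nI)
    for (c in unique(chromOf)) {     # unique positions within each chromosome
      sel <- chromOf == c
      posInChrom[sel] <- sample.int(chromLen[c], sum(sel))
    }
    classIdx <- rep(nClass + 1L, nI)
    H <- matrix(stats::rbinom(2L * nInd * nI, 1L, cfg$initSites$freq),
                2L * nInd, nI)
    storage.mode(H) <- "integer"
  }

  drawPositions <- function(n, existingKey) {
    ch <- integer(n); pp <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        c0 <- sample.int(length(chromLen), 1L, prob = chromLen / Ltot)
        p0 <- sample.int(chromLen[c0], 1L)
        key <- offsets[c0] + p0
        if (!(key %in% existingKey)) { existingKey <- c(existingKey, key); break }
      }
      ch[i] <- c0; pp[i] <- p0
    }
    list(chrom = ch, pos = pp)
  }

  for (g in seq_len(cfg$generations)) {
    sizesNew <- .demeSizesAt(cfg, g)
    if (all(sizesNew == 0)) stop("all demes extinct", call. = FALSE)
    existing <- which(sizes > 0)
    logw <- .logFitness(H, classIdx, cfg$classes)
    w <- exp(logw - max(logw))

    demeNew <- rep(seq_along(sizesNew), sizesNew)
    nIndNew <- length(demeNew)
    mothers <- integer(nIndNew); fathers <- integer(nIndNew)
    for (d in which(sizesNew > 0)) {
      off <- which(demeNew == d)
      if (sizes[d] > 0) {
        src <- rep(d, length(off))
        if (cfg$migration > 0 && length(existing) > 1L) {
          mig <- stats::runif(length(off)) < cfg$migration
          others <- setdiff(existing, d)
          src[mig] <- others[sample.int(length(others), sum(mig), replace = TRUE)]
        }
      } else {
        # deme founded this generation: parents from its origin deme
        par <- cfg$demes[[d]]$origin$parent
        src <- rep(match(par, names(cfg$demes)), length(off))
      }
      for (s0 in unique(src)) {
        sel <- off[src == s0]
        pool <- which(deme == s0)
        pw <- w[pool]
        if (all(pw == 0)) pw <- rep(1, length(pool))
        mothers[sel] <- pool[sample.int(length(pool), length(sel),
                                        replace = TRUE, prob = pw)]
        fathers[sel] <- pool[sample.int(length(pool), length(sel),
                                        replace = TRUE, prob = pw)]
      }
    }
    Gm <- .makeGametes(H, mothers, chromOf, posInChrom, chromLen, cfg$recomb)
    Gp <- .makeGametes(H, fathers, chromOf, posInChrom, chromLen, cfg$recomb)
    H <- matrix(0L, 2L * nIndNew, ncol(Gm))
    H[seq(1L, 2L * nIndNew, 2L), ] <- Gm
    H[seq(2L, 2L * nIndNew, 2L), ] <- Gp
    deme <- demeNew; sizes <- sizesNew; nInd <- nIndNew

    nNew <- stats::rpois(1L, cfg$mu * Ltot * 2L * nInd)
    if (nNew > 0) {
      npos <- drawPositions(nNew, offsets[chromOf] + posInChrom)
      newCols <- matrix(0L, 2L * nInd, nNew)
      newCols[cbind(sample.int(2L * nInd, nNew, replace = TRUE), seq_len(nNew))] <- 1L
      H <- cbind(H, newCols)
      chromOf <- c(chromOf, npos$chrom)
      posInChrom <- c(posInChrom, npos$pos)
      classIdx <- c(classIdx, sample.int(nClass + 1L, nNew, replace = TRUE,
                                         prob = classProb))
    }
    if (ncol(H)) {
      cs <- colSums(H)
      fixed <- cs == nrow(H)
      if (any(fixed)) {
        tb <- table(factor(classLabels[classIdx[fixed]], levels = classLabels))
        fixedCount <- fixedCount + as.integer(tb)
      }
      keep <- cs > 0L & !fixed
      H <- H[, keep, drop = FALSE]
      chromOf <- chromOf[keep]; posInChrom <- posInChrom[keep]
      classIdx <- classIdx[keep]
    }
  }

  # sample individuals per deme
  sampled <- integer(0); popLab <- character(0)
  for (d in seq_along(sizes)) {
    if (sizes[d] == 0) next
    k <- min(cfg$sampleSizes[[names(cfg$demes)[d]]], sizes[d])
    pool <- which(deme == d)
    sampled <- c(sampled, sort(sample(pool, k)))
    popLab <- c(popLab, rep(names(cfg$demes)[d], k))
  }
  sampleIds <- sprintf("%s_i%02d", popLab, stats::ave(seq_along(sampled),
                                                      popLab, FUN = seq_along))
  ord <- order(chromOf, posInChrom)
  chromOf <- chromOf[ord]; posInChrom <- posInChrom[ord]
  classIdx <- classIdx[ord]
  H <- H[, ord, drop = FALSE]
  dosage <- H[2L * sampled - 1L, , drop = FALSE] + H[2L * sampled, , drop = FALSE]
  gt <- t(dosage)
  colnames(gt) <- sampleIds

  baseChoices <- c("A", "C", "G", "T")
  refB <- baseChoices[sample.int(4L, length(chromOf), replace = TRUE)]
  altB <- vapply(refB, function(b)
    sample(setdiff(baseChoices, b), 1L), character(1))
  chromNames <- as.character(cfg$genome$chrom)
  sl <- stats::setNames(as.integer(chromLen), chromNames)
  panel <- VariantPanel(chrom = chromNames[chromOf], pos = as.integer(posInChrom),
                        ref = refB, alt = unname(altB),
                        qual = rep(100, length(chromOf)), gt = gt,
                        aa = refB, seqlengths = sl)
  metadata(panel)$polarization <- c(retained = nrow(panel),
                                    refNotAncestral = 0L, unpolarizable = 0L)
  panel <- new("PolarizedVariantPanel", panel)

  popmap <- data.frame(sample = sampleIds, population = popLab,
                       cluster = popLab, stringsAsFactors = FALSE)
  firstN <- cfg$demes[[1L]]$N
  truth <- list(
    seed = cfg$seed,
    classLabel = classLabels[classIdx],
    sites = data.frame(chrom = chromNames[chromOf],
                       pos = as.integer(posInChrom),
                       label = classLabels[classIdx]),
    fixedPerClass = as.list(fixedCount),
    demeSizes = stats::setNames(as.list(sizes), names(cfg$demes)),
    expectedPi = 4 * firstN * cfg$mu)

  out <- list(panel = panel, popmap = popmap, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$vcf <- file.path(dir, "panel.vcf")
    out$popmapFile <- file.path(dir, "popmap.tsv")
    out$truthFile <- file.path(dir, "truth.json")
    writeVcfPanel(panel, out$vcf)
    utils::write.table(popmap, out$popmapFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(seed = cfg$seed, sites = truth$sites,
                              fixedPerClass = truth$fixedPerClass,
                              demeSizes = truth$demeSizes,
                              expectedPi = truth$expectedPi),
                         out$truthFile, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Founder haplotype panel with unlinked sites
#'
#' Draws site frequencies from the neutral site-frequency spectrum
#' (density proportional to \eqn{1/p}) truncated to
#' \code{[minMaf, 1 - minMaf]} and founder haplotypes as independent
#' Bernoulli draws — the standard unlinked founder panel for pedigree
#' simulation.
#'
#' @param nFounders diploid founder count
#' @param nSites site count
#' @param minMaf frequency truncation
#' @param seed integer seed
#' @return list: \code{H} (2 x nFounders) x nSites 0/1 matrix, \code{freq}
#' @export
simulateFounderPanel <- function(nFounders, nSites, minMaf = 0.05, seed) {
  set.seed(seed)
  a <- minMaf; b <- 1 - minMaf
  u <- stats::runif(nSites)
  freq <- a * (b / a)^u
  H <- matrix(stats::rbinom(2L * nFounders * nSites, 1L,
                            rep(freq, each = 2L * nFounders)),
              2L * nFounders, nSites)
  storage.mode(H) <- "integer"
  list(H = H, freq = freq)
}

.gameteFrom <- function(H, ind) {
  h1 <- H[2L * ind - 1L, ]; h2 <- H[2L * ind, ]
  pick <- stats::rbinom(length(h1), 1L, 0.5)
  ifelse(pick == 0L, h1, h2)
}

#' Simulate pedigree-related genotypes
#'
#' Builds, from a founder haplotype panel, one pair of individuals per
#' requested relationship by Mendelian gamete sampling (independent
#' assortment per site; no mutation):
#' \code{"MZ"} duplicated individual, \code{"PO"} parent-offspring,
#' \code{"FS"} full siblings, \code{"HS"} half siblings (second degree),
#' \code{"UN"} unrelated founders' offspring.  Each pair consumes fresh
#' founders, so different pairs are unrelated.
#'
#' @param founders list from [simulateFounderPanel()] (enough founders: 3
#'   per requested pair)
#' @param relationships character vector of pair types
#' @param seed integer seed
#' @return list: \code{gt} (sites x individuals dosage matrix),
#'   \code{pairs} data.frame (\code{id1}, \code{id2}, \code{relation})
#' @export
simulatePedigree <- function(founders, relationships, seed) {
  set.seed(seed)
  H <- founders$H
  nF <- nrow(H) %/% 2L
  need <- 3L * length(relationships)
  if (nF < need)
    stop(sprintf("need >= %d founders for %d pairs", need,
                 length(relationships)), call. = FALSE)
  nextF <- 0L
  takeF <- function() { nextF <<- nextF + 1L; nextF }
  cols <- list(); pairs <- list(); ids <- character(0)
  addInd <- function(g, id) {
    cols[[length(cols) + 1L]] <<- g
    ids <<- c(ids, id)
  }
  child <- function(a, b) .gameteFrom(H, a) + .gameteFrom(H, b)
  for (r in seq_along(relationships)) {
    rel <- relationships[r]
    f1 <- takeF(); f2 <- takeF(); f3 <- takeF()
    id1 <- sprintf("p%02d_a", r); id2 <- sprintf("p%02d_b", r)
    switch(rel,
      MZ = { g <- child(f1, f2); addInd(g, id1); addInd(g, id2) },
      PO = { addInd(H[2L * f1 - 1L, ] + H[2L * f1, ], id1)
             addInd(child(f1, f2), id2) },
      FS = { addInd(child(f1, f2), id1); addInd(child(f1, f2), id2) },
      HS = { addInd(child(f1, f2), id1); addInd(child(f1, f3), id2) },
      UN = { addInd(H[2L * f1 - 1L, ] + H[2L * f1, ], id1)
             addInd(H[2L * f2 - 1L, ] + H[2L * f2, ], id2) },
      stop("unknown relationship: ", rel, call. = FALSE))
    pairs[[r]] <- data.frame(id1 = id1, id2 = id2, relation = rel)
  }
  gt <- do.call(cbind, cols)
  storage.mode(gt) <- "integer"
  colnames(gt) <- ids
  list(gt = gt, pairs = do.call(rbind, pairs))
}

#' Genotype matrix -> polarized panel helper
#'
#' Wraps a plain dosage matrix (sites x samples) as a
#' [PolarizedVariantPanel-class] with synthetic A->T sites at unit spacing
#' (or supplied positions), for feeding matrix-level simulators into the
#' panel-based statistics.
#'
#' @param gt dosage matrix, sites x samples (column names = sample ids)
#' @param chrom chromosome label
#' @param pos optional positions (default \code{spacingBp} apart)
#' @param spacingBp spacing when \code{pos} is not given
#' @return a [PolarizedVariantPanel-class]
#' @export
asPolarizedPanel <- function(gt, chrom = "chr1", pos = NULL, spacingBp = 100) {
  nS <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(nS) * spacingBp
  p <- VariantPanel(chrom = rep(chrom, nS), pos = pos,
                    ref = rep("A", nS), alt = rep("T", nS),
                    qual = rep(100, nS), gt = gt, aa = rep("A", nS))
  new("PolarizedVariantPanel", p)
}
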