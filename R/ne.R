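#' Harmonic number a_n
#'
#' \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, the Watterson normalising constant for
#' a sample of \eqn{n} sequences.
#'
#' @param n sequence count, >= 2
#' @return exact partial sum
#' @examples
#' harmonicNumber(2)    # 1
#' harmonicNumber(454)  # ~6.6942
#' @export
harmonicNumber <- function(n) {
  if (n < 2) stop("harmonicNumber needs n >= 2", call. = FALSE)
  sum(1 / seq_len(n - 1L))
}

#' Watterson-theta effective population size
#'
#' The estimator chain \eqn{S = N_{SNP}/L_{genome}} (proportion of
#' segregating sites), \eqn{\theta_W = S/a_n}, \eqn{N_e = \theta_W/(4\mu)}.
#' \code{n} counts \emph{haploid sequences} — twice the number of diploid
#' individuals — and \code{mu} is per site per year; every intermediate is
#' reported in the returned [NeEstimate-class].
#'
#' @param nSnp segregating-SNP count (0 gives \eqn{N_e = 0})
#' @param lGenome genome length surveyed, bp
#' @param n sampled sequence count (2 x individuals)
#' @param mu mutation rate per site per year
#' @return a [NeEstimate-class]
#' @examples
#' wattersonNe(4775335, 662.38e6, 454, 4.66e-9)
#' @export
wattersonNe <- function(nSnp, lGenome, n, mu) {
  if (lGenome <= 0 || n < 2 || mu <= 0 || nSnp < 0)
    stop("inputs must be positive (nSnp may be 0)", call. = FALSE)
  aN <- harmonicNumber(n)
  S <- nSnp / lGenome
  theta <- S / aN
  new("NeEstimate", nSnp = as.numeric(nSnp), lGenome = as.numeric(lGenome),
      nSeq = as.integer(n), aN = aN, S = S, theta = theta, mu = mu,
      Ne = theta / (4 * mu))
}

#' Mutation rate from synonymous divergence
#'
#' \eqn{\mu = K_S / (2T)}: per-site per-year rate from the synonymous
#' substitution peak \eqn{K_S} between paralogs/orthologs and the
#' divergence time \eqn{T} in years.
#'
#' @param Ks synonymous substitutions per site
#' @param T divergence time, years (> 0)
#' @return rate per site per year
#' @export
muFromKs <- function(Ks, T) {
  if (T <= 0) stop("T must be positive", call. = FALSE)
  Ks / (2 * T)
}

#' Insertion / divergence time from K_S
#'
#' The inverse conversion \eqn{T = K_S / (2\mu)}, as used to date LTR
#' retrotransposon insertions from the divergence of their two LTRs.
#'
#' @param Ks substitutions per site between the diverged copies
#' @param mu rate per site per year (> 0)
#' @return time in years
#' @export
insertionTime <- function(Ks, mu) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  Ks / (2 * mu)
}

#' Per-generation mutation rate
#'
#' Explicit conversion \eqn{\mu_{gen} = \mu_{year} \cdot g}; nothing in the
#' package converts between the two time scales silently.
#'
#' @param muYear rate per site per year
#' @param generationTime generation time, years (> 0)
#' @return rate per site per generation
#' @export
perGenerationRate <- function(muYear, generationTime) {
  if (generationTime <= 0) stop("generationTime must be positive", call. = FALSE)
  muYear * generationTime
}
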