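# Amino-acid composition (c), polarity (p) and molecular volume (v) — the
# three physicochemical properties behind the Grantham (1974) chemical
# distance between residues.
.granthamProps <- data.frame(
  aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
         "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c = c(1.42, 0.65, 0.00, 0.39, 0.71, 0.00, 0.00, 0.74, 0.00, 0.00,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0.00, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE)

.granthamAlpha <- 1.833
.granthamBeta <- 0.1018
.granthamGamma <- 0.000399

# rho scales the raw chemical distance so that the mean over the 190
# unordered residue pairs equals 100, the published normalization.
.granthamRho <- local({
  pr <- .granthamProps
  raw <- outer(seq_len(20), seq_len(20), function(i, j)
    sqrt(.granthamAlpha * (pr$c[i] - pr$c[j])^2 +
         .granthamBeta * (pr$p[i] - pr$p[j])^2 +
         .granthamGamma * (pr$v[i] - pr$v[j])^2))
  100 / mean(raw[upper.tri(raw)])
})

#' Grantham distance between amino acids
#'
#' The chemical difference
#' \deqn{D = \rho\,[\alpha (c_1-c_2)^2 + \beta (p_1-p_2)^2 + \gamma (v_1-v_2)^2]^{1/2}}
#' built from residue composition, polarity and volume, with
#' \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018}, \eqn{\gamma = 0.000399} and
#' \eqn{\rho} normalising the mean over the 190 unordered pairs to 100.  A
#' nonsynonymous change with \eqn{D > 150} is conventionally called a
#' radical missense substitution.
#'
#' @param aa1,aa2 one-letter codes of standard amino acids (vectorised)
#' @return numeric distance(s); 0 on the diagonal, symmetric
#' @examples
#' granthamDistance("L", "I")   # ~5, the most conservative change
#' granthamDistance("C", "W")   # ~215, the most radical
#' @export
granthamDistance <- function(aa1, aa2) {
  i <- match(toupper(aa1), .granthamProps$aa)
  j <- match(toupper(aa2), .granthamProps$aa)
  if (anyNA(i) || anyNA(j))
    stop("nonstandard amino acid: ",
         paste(unique(c(aa1[is.na(i)], aa2[is.na(j)])), collapse = ", "),
         call. = FALSE)
  pr <- .granthamProps
  .granthamRho * sqrt(
    .granthamAlpha * (pr$c[i] - pr$c[j])^2 +
    .granthamBeta * (pr$p[i] - pr$p[j])^2 +
    .granthamGamma * (pr$v[i] - pr$v[j])^2)
}

#' Full 20 x 20 Grantham distance matrix
#'
#' @param rounded round to integers (the form the matrix is usually quoted in)
#' @return symmetric numeric matrix with one-letter row/column names
#' @export
granthamMatrix <- function(rounded = TRUE) {
  aa <- .granthamProps$aa
  m <- outer(aa, aa, granthamDistance)
  dimnames(m) <- list(aa, aa)
  if (rounded) round(m) else m
}
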