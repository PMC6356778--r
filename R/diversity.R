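## Diversity estimation: per-site nucleotide diversity, individual
## heterozygosity (proportional excess over Hardy-Weinberg expectation),
## and a depth-aware genomic relationship matrix with diagonal rescaling.

#' Per-site nucleotide diversity
#'
#' Standard unbiased per-site estimator \eqn{\pi = 2 n_0 n_1 / (n (n - 1))}
#' over the \eqn{n = n_0 + n_1} called allele copies of a biallelic site:
#' the probability that two allele copies drawn without replacement differ.
#' Sites with fewer than two called alleles are skipped (value \code{NA}).
#'
#' @param x a [GenotypeCalls-class], or an integer dosage vector for a
#'   single site.
#' @return Numeric vector of per-site values in \[0, 1\].
#' @examples
#' sitePi(c(0L, 1L, 1L, 2L))  # n0 = 4, n1 = 4 over 8 copies
#' @export
setGeneric("sitePi", function(x) standardGeneric("sitePi"))

#' @rdname sitePi
#' @export
setMethod("sitePi", "numeric", function(x) {
  x <- x[!is.na(x)]
  n <- 2 * length(x)
  if (n < 2) return(NA_real_)
  n1 <- sum(x)
  2 * n1 * (n - n1) / (n * (n - 1))
})

#' @rdname sitePi
#' @export
setMethod("sitePi", "GenotypeCalls", function(x) {
  dos <- dosages(x)
  called <- !is.na(dos)
  n <- 2 * rowSums(called)
  n1 <- rowSums(dos, na.rm = TRUE)
  pi <- ifelse(n >= 2, 2 * n1 * (n - n1) / (n * pmax(n - 1, 1)), NA_real_)
  stats::setNames(pi, siteInfo(x)$pos)
})

#' Individual heterozygosity as proportional excess
#'
#' For individual i over its non-missing sites,
#' \deqn{H_{S,i} = (O_i - E_i) / E_i}
#' where \eqn{O_i} counts observed heterozygous genotypes and
#' \eqn{E_i = \sum_k 2 p_k (1 - p_k) n_k / (n_k - 1)} accumulates the
#' small-sample Hardy-Weinberg expectation from the sample allele
#' frequencies.  Positive values mean excess heterozygosity, negative a
#' deficit (this is \eqn{-F} in the method-of-moments sense, so allele
#' dropout drives it negative).
#'
#' @param calls a [GenotypeCalls-class].
#' @return Named numeric vector, one value per individual (\code{NA} when
#'   an individual has no callable site).
#' @export
individualHs <- function(calls) {
  stopifnot(is(calls, "GenotypeCalls"))
  dos <- dosages(calls)
  called <- !is.na(dos)
  nAll <- 2 * rowSums(called)
  p <- rowSums(dos, na.rm = TRUE) / pmax(nAll, 1L)
  eSite <- ifelse(nAll >= 2, 2 * p * (1 - p) * nAll / pmax(nAll - 1, 1), 0)
  O <- colSums(dos == 1L, na.rm = TRUE)
  E <- colSums(eSite * called)
  hs <- ifelse(E > 0, (O - E) / E, NA_real_)
  hs[colSums(called) == 0L] <- NA_real_
  stats::setNames(hs, colnames(dos))
}

#' Depth-aware genomic relationship matrix
#'
#' Dosage-based relatedness: for individuals i and j the off-diagonal entry
#' is the mean over their shared (both non-missing) sites k of
#' \deqn{(x_{ik} - 2 p_k)(x_{jk} - 2 p_k) / (2 p_k (1 - p_k))}
#' with \eqn{p_k} the sample alt-allele frequency.  The diagonal cannot use
#' the called dosage (genotyping noise would cancel out of the product), so
#' it uses the read-ratio dosage \eqn{\hat x = 2 a / d} (a = alt reads,
#' d = depth) whose binomial sampling noise inflates the expectation by
#' exactly \eqn{1/d} per site under Hardy-Weinberg; the estimator subtracts
#' that term (\code{depthCorrect = FALSE} reports the uncorrected
#' diagonal).  Pairs sharing fewer than \code{minSharedSites} sites are
#' flagged low-confidence.
#'
#' @param calls a filtered [GenotypeCalls-class] with depths.
#' @param minSharedSites minimum shared sites per pair (default 50).
#' @param depthCorrect subtract the \eqn{1/d} depth-inflation term from the
#'   diagonal (default TRUE).
#' @return A [RelatednessResult-class] (raw matrix only; apply
#'   [scaleRelatedness()] for the unit-diagonal form).
#' @export
relatednessMatrix <- function(calls, minSharedSites = 50L,
                              depthCorrect = TRUE) {
  stopifnot(is(calls, "GenotypeCalls"))
  dos <- dosages(calls)
  dep <- depths(calls)
  adep <- altDepths(calls)
  called <- !is.na(dos)
  nAll <- 2 * rowSums(called)
  p <- rowSums(dos, na.rm = TRUE) / pmax(nAll, 1L)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic site reached the relatedness estimator ",
         "(filter contract breach)")
  denom <- 2 * p * (1 - p)
  Z <- (dos - 2 * p) / sqrt(denom)
  Z[!called] <- 0
  nShared <- crossprod(called)
  M <- crossprod(Z) / pmax(nShared, 1L)
  ## diagonal from read-ratio dosages
  useD <- called & dep > 0L
  xhat <- ifelse(useD, 2 * adep / pmax(dep, 1L), NA_real_)
  zhat2 <- (xhat - 2 * p)^2 / denom
  zhat2[!useD] <- 0
  nD <- colSums(useD)
  diagRaw <- colSums(zhat2) / pmax(nD, 1L)
  if (depthCorrect) {
    invd <- ifelse(useD, 1 / dep, 0)
    diagRaw <- diagRaw - colSums(invd) / pmax(nD, 1L)
  }
  diag(M) <- diagRaw
  M <- (M + t(M)) / 2
  low <- nShared < minSharedSites
  diag(low) <- FALSE
  methods::new("RelatednessResult", raw = M, scaled = matrix(numeric(0), 0, 0),
               D = numeric(0), nShared = nShared, lowConfidence = low)
}

#' Rescale a relatedness matrix to unit self-relatedness
#'
#' Applies \eqn{M_S = D M_O D} with \eqn{D_{ii} = 1 / \sqrt{M_{O,ii}}},
#' i.e. \eqn{M_{S,ij} = M_{O,ij} / \sqrt{M_{O,ii} M_{O,jj}}}, so every
#' diagonal entry of the scaled matrix equals 1.
#'
#' @param x a [RelatednessResult-class] or a symmetric matrix with strictly
#'   positive diagonal.
#' @return Same type as the input: a matrix, or the result object with its
#'   \code{scaled} slot and \code{D} filled in.
#' @examples
#' scaleRelatedness(matrix(c(4, 2, 2, 1), 2))
#' @export
setGeneric("scaleRelatedness", function(x) standardGeneric("scaleRelatedness"))

#' @rdname scaleRelatedness
#' @export
setMethod("scaleRelatedness", "matrix", function(x) {
  d <- diag(x)
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    ids <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
    stop("non-positive self-relatedness for individual(s): ",
         paste(ids, collapse = ", "))
  }
  D <- 1 / sqrt(d)
  x * tcrossprod(D)
})

#' @rdname scaleRelatedness
#' @export
setMethod("scaleRelatedness", "RelatednessResult", function(x) {
  x@scaled <- scaleRelatedness(x@raw)
  x@D <- 1 / sqrt(diag(x@raw))
  methods::validObject(x)
  x
})

#' Summary diversity report for one genotype set
#'
#' @param calls a filtered [GenotypeCalls-class].
#' @param relatedness optional precomputed scaled [RelatednessResult-class].
#' @return List with per-site \code{pi}, mean \code{meanPi}, per-individual
#'   \code{hs}, \code{meanHs}, and when relatedness is supplied the scaled
#'   off-diagonal values and their mean.
#' @export
diversityReport <- function(calls, relatedness = NULL) {
  pi <- sitePi(calls)
  hs <- individualHs(calls)
  out <- list(pi = pi, meanPi = mean(pi, na.rm = TRUE),
              hs = hs, meanHs = mean(hs, na.rm = TRUE))
  if (!is.null(relatedness)) {
    S <- scaledRelatedness(relatedness)
    off <- S[upper.tri(S)]
    out$scaledR <- S
    out$meanR <- mean(off)
  }
  out
}
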