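## Cross-reference comparison statistics: tag-set intersection, Spearman
## rank correlation, Mantel permutation test.

#' Tag-pair set intersection between two mapping runs
#'
#' Compares the sets of tag-pair sequence identities that attained unique
#' mapped status against two references.  Matching is by sequence, not
#' coordinate, since coordinates are not comparable across references.
#' The shared percentage uses the first run's own mapped set as the
#' denominator: \code{100 * |A intersect B| / |A|}; comparing a run with
#' itself therefore yields exactly 100.
#'
#' @param runA,runB character vectors of mapped tag-pair identities (e.g.
#'   from a [mapTagPairs()] result via its mapped rows), or
#'   [mapTagPairs()] results themselves.
#' @return List with \code{countA}, \code{countB}, \code{intersection} and
#'   \code{percentShared}.
#' @examples
#' pancompareTags(c("a", "b", "c", "d"), c("a", "b", "x"))
#' @export
pancompareTags <- function(runA, runB) {
  asSet <- function(r) {
    if (is.data.frame(r)) .mappedTagSet(r) else unique(as.character(r))
  }
  a <- asSet(runA); b <- asSet(runB)
  if (!length(a)) stop("empty comparison run: percent shared is undefined")
  inter <- length(intersect(a, b))
  list(countA = length(a), countB = length(b), intersection = inter,
       percentShared = 100 * inter / length(a))
}

#' Spearman rank correlation with large-sample p-value
#'
#' Pearson correlation of mid-ranks (ties allowed); two-sided p-value from
#' the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return List with \code{rho}, \code{p}, \code{n} and \code{flagged}
#'   (TRUE with \code{NA} statistics when either vector is constant).
#' @examples
#' spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # rho = 0.8
#' @export
spearmanRho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  }
  r <- stats::cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = r, p = p, n = n, flagged = FALSE)
}

#' Mantel permutation test for similarity of two square matrices
#'
#' Observed statistic: Pearson correlation of the off-diagonal elements.
#' The null distribution is built by permuting the rows and columns of the
#' second matrix simultaneously; the one-sided p-value carries the +1
#' correction: \code{p = (1 + #(perm >= obs)) / (iterations + 1)}.
#'
#' @param A,B square matrices with identical dimensions and individual
#'   ordering (symmetric; diagonals excluded).
#' @param iterations permutation count (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @return List with \code{statistic}, \code{p}, \code{iterations}.
#' @export
mantelTest <- function(A, B, iterations = 1000L, seed = NULL) {
  if (!is.matrix(A) || !is.matrix(B) || any(dim(A) != dim(B)) ||
      nrow(A) != ncol(A))
    stop("A and B must be square matrices of identical dimensions")
  n <- nrow(A)
  off <- which(row(A) != col(A))
  obs <- stats::cor(A[off], B[off])
  doPerm <- function() {
    count <- 0L
    for (b in seq_len(iterations)) {
      perm <- sample.int(n)
      Bp <- B[perm, perm]
      if (stats::cor(A[off], Bp[off]) >= obs) count <- count + 1L
    }
    count
  }
  count <- if (is.null(seed)) doPerm() else withr::with_seed(seed, doPerm())
  list(statistic = obs, p = (1 + count) / (iterations + 1),
       iterations = as.integer(iterations))
}
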