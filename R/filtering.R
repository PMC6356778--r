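## Post-discovery filter cascades: site filters -> LD pruning -> distance
## thinning.  The cascade order is fixed and each stage's post-condition is
## audited on every run.

#' Filter parameters for either pipeline mode
#'
#' GBS: biallelic sites, mean call depth of at least 5 across genotyped
#' individuals, at most 10 percent missing genotypes, LD pruning at
#' r-squared 0.8 in a 1000-site window, thinning to one SNP per 64 bp (the
#' tag length).  Resequencing adds a minor-allele-frequency threshold
#' (> 0.05) and a stricter mean depth (> 10); thinning is one marker per
#' 150 bp (the read length).
#'
#' @param mode \code{"gbs"} or \code{"reseq"}.
#' @param biallelic drop sites with more than two alleles.
#' @param minMeanDepth,meanDepthStrict mean-depth threshold and whether it
#'   is exclusive.
#' @param mafGt exclusive MAF threshold (\code{NULL} to skip; GBS applies
#'   its MAF rule at discovery).
#' @param maxMissing maximum fraction of missing genotypes per site.
#' @param ldR2 r-squared threshold for LD pruning.
#' @param ldWindow LD window in sites.
#' @param thinBp minimum spacing between retained sites.
#' @return validated parameter list.
#' @export
filterParams <- function(mode = c("gbs", "reseq"), biallelic = TRUE,
                         minMeanDepth = NULL, meanDepthStrict = NULL,
                         mafGt = NULL, maxMissing = 0.10, ldR2 = 0.8,
                         ldWindow = 1000L, thinBp = NULL) {
  mode <- match.arg(mode)
  if (is.null(minMeanDepth)) minMeanDepth <- if (mode == "gbs") 5 else 10
  if (is.null(meanDepthStrict)) meanDepthStrict <- mode == "reseq"
  if (is.null(mafGt) && mode == "reseq") mafGt <- 0.05
  if (is.null(thinBp)) thinBp <- if (mode == "gbs") 64L else 150L
  stopifnot(maxMissing >= 0, maxMissing <= 1, ldR2 >= 0, ldR2 <= 1,
            ldWindow >= 1, thinBp >= 1)
  list(mode = mode, biallelic = biallelic, minMeanDepth = minMeanDepth,
       meanDepthStrict = meanDepthStrict, mafGt = mafGt,
       maxMissing = maxMissing, ldR2 = ldR2,
       ldWindow = as.integer(ldWindow), thinBp = as.integer(thinBp))
}

#' Per-site filters (biallelic, MAF, mean depth, missingness)
#'
#' @param calls a [GenotypeCalls-class].
#' @param params a [filterParams()] list.
#' @return Filtered [GenotypeCalls-class], site order preserved.
#' @export
filterSites <- function(calls, params) {
  stopifnot(is(calls, "GenotypeCalls"))
  if (!params$mode %in% c("gbs", "reseq")) stop("unknown filter mode")
  if (!nrow(calls)) return(calls)
  info <- siteInfo(calls)
  dos <- dosages(calls)
  dep <- depths(calls)
  keep <- rep(TRUE, nrow(calls))
  if (params$biallelic) keep <- keep & info$nAlleles == 2L
  called <- !is.na(dos)
  nCalled <- rowSums(called)
  meanDep <- ifelse(nCalled > 0, rowSums(dep * called, na.rm = TRUE) /
                      pmax(nCalled, 1L), 0)
  keep <- keep & (if (params$meanDepthStrict) meanDep > params$minMeanDepth
                  else meanDep >= params$minMeanDepth)
  miss <- 1 - rowMeans(called)
  keep <- keep & miss <= params$maxMissing
  if (!is.null(params$mafGt)) keep <- keep & info$maf > params$mafGt
  calls[which(keep), ]
}

#' Greedy LD pruning
#'
#' Left-to-right scan: a candidate site is removed when its squared Pearson
#' dosage correlation (pairwise-complete) with any of the last
#' \code{window} retained sites exceeds \code{r2}; undefined correlations
#' (monomorphic overlap, fewer than 2 complete pairs) never trigger
#' removal.  Counting the window over retained sites makes the operation
#' idempotent.
#'
#' @param calls a [GenotypeCalls-class].
#' @param r2 threshold (default 0.8).
#' @param window window size in retained sites (default 1000).
#' @return Pruned [GenotypeCalls-class].
#' @export
ldPrune <- function(calls, r2 = 0.8, window = 1000L) {
  stopifnot(is(calls, "GenotypeCalls"))
  if (nrow(calls) < 2L) return(calls)
  keep <- .cpp_ld_prune(dosages(calls), r2, as.integer(window))
  calls[which(keep), ]
}

#' Distance thinning
#'
#' Greedy scan keeping the first site of any run of sites closer than
#' \code{minBp}; every retained adjacent pair ends at least \code{minBp}
#' apart.  Sites must be position-sorted within scaffold.
#'
#' @param calls a [GenotypeCalls-class] (or a numeric position vector, in
#'   which case the kept indices are returned).
#' @param minBp minimum spacing in bp.
#' @return Thinned object of the input type.
#' @export
distanceThin <- function(calls, minBp) {
  thin1 <- function(pos) {
    if (is.unsorted(pos)) stop("positions must be sorted for thinning")
    keep <- logical(length(pos))
    last <- -Inf
    for (i in seq_along(pos)) {
      if (pos[i] - last >= minBp) { keep[i] <- TRUE; last <- pos[i] }
    }
    keep
  }
  if (is.numeric(calls)) return(which(thin1(calls)))
  stopifnot(is(calls, "GenotypeCalls"))
  if (!nrow(calls)) return(calls)
  info <- siteInfo(calls)
  keep <- unlist(lapply(split(seq_len(nrow(calls)), info$scaffold),
                        function(ii) ii[thin1(info$pos[ii])]),
                 use.names = FALSE)
  calls[sort(keep), ]
}

## post-condition audits ----------------------------------------------------

.auditThin <- function(calls, minBp) {
  info <- siteInfo(calls)
  ok <- vapply(split(info$pos, info$scaffold),
               function(p) all(diff(p) >= minBp) || length(p) < 2L,
               logical(1L))
  all(ok)
}

## fixed-point check: pruning the pruned set must change nothing
.auditLd <- function(calls, r2, window) {
  if (nrow(calls) < 2L) return(TRUE)
  all(.cpp_ld_prune(dosages(calls), r2, as.integer(window)))
}

#' Apply the full filter cascade
#'
#' Fixed order: per-site filters, then distance thinning, then LD pruning.
#' Pruning only removes sites, so the thinning spacing survives it; with
#' the LD pass last, both post-conditions (minimum spacing and no retained
#' in-window pair above the r-squared threshold) hold on the final set and
#' the cascade is idempotent.  Both are still verified on the result (an
#' internal error is raised if either audit fails), and a per-stage audit
#' table is attached.
#'
#' @param calls a [GenotypeCalls-class].
#' @param params a [filterParams()] list.
#' @param audit verify post-conditions (default TRUE).
#' @return Filtered [GenotypeCalls-class]; \code{metadata()$filterAudit}
#'   holds a data.frame of per-stage input/output counts.
#' @export
filterCascade <- function(calls, params, audit = TRUE) {
  n0 <- nrow(calls)
  f1 <- filterSites(calls, params)
  f2 <- distanceThin(f1, params$thinBp)
  f3 <- ldPrune(f2, params$ldR2, params$ldWindow)
  if (audit && nrow(f3)) {
    if (!.auditThin(f3, params$thinBp))
      stop("thinning audit failed: retained sites closer than minimum spacing")
    if (!.auditLd(f3, params$ldR2, params$ldWindow))
      stop("LD audit failed: retained in-window pair exceeds r2 threshold")
  }
  auditTab <- data.frame(
    stage = c("discovery", "site_filters", "distance_thin", "ld_prune"),
    sites = c(n0, nrow(f1), nrow(f2), nrow(f3)))
  S4Vectors::metadata(f3)$filterAudit <- auditTab
  S4Vectors::metadata(f3)$filterParams <- params
  f3
}
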