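## SNP discovery under the two contrasted paradigms:
##   - tag-wise: SNPs are differences AMONG tag pairs across individuals;
##     the reference base is never consulted.
##   - pileup:   SNPs are differences BETWEEN reads and the reference.

#' GBS discovery parameters
#'
#' @param kmerLength tag/k-mer length used at tag building (recorded).
#' @param minKmer minimum k-mer length (recorded for fidelity with the
#'   upstream tag-building convention; the mapper's seed length plays the
#'   equivalent role here).
#' @param minPhred minimum base quality at tag construction.
#' @param minTagCount population-wide minimum count of a distinct tag-pair
#'   sequence at a locus.
#' @param mnMAF minimum minor-allele frequency for an emitted site.
#' @param mnLCov minimum fraction of individuals with at least one tag at
#'   the locus.
#' @return validated parameter list.
#' @export
gbsDiscoveryParams <- function(kmerLength = 64L, minKmer = 20L,
                               minPhred = 30L, minTagCount = 10L,
                               mnMAF = 0.05, mnLCov = 0.75) {
  stopifnot(mnMAF >= 0, mnMAF <= 1, mnLCov >= 0, mnLCov <= 1,
            minTagCount >= 0)
  list(kmerLength = as.integer(kmerLength), minKmer = as.integer(minKmer),
       minPhred = as.integer(minPhred), minTagCount = as.integer(minTagCount),
       mnMAF = mnMAF, mnLCov = mnLCov)
}

#' Resequencing discovery parameters
#'
#' Thresholds applied downstream by [filterCascade()]; \code{phredGt} is
#' used at pileup time (bases below it are ignored).
#'
#' @param mafGt minor-allele-frequency threshold (exclusive).
#' @param meanDepthGt mean-depth threshold (exclusive).
#' @param phredGt base-quality threshold for pileup inclusion.
#' @return validated parameter list.
#' @export
reseqDiscoveryParams <- function(mafGt = 0.05, meanDepthGt = 10,
                                 phredGt = 20L) {
  stopifnot(mafGt >= 0, mafGt <= 1, meanDepthGt >= 0)
  list(mafGt = mafGt, meanDepthGt = meanDepthGt,
       phredGt = as.integer(phredGt))
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Group mapped tag pairs into loci
#'
#' Uniquely mapped tag pairs are grouped by their mapped coordinates
#' (scaffold, forward and reverse mate positions, forward strand); distinct
#' tag-pair sequences whose population-wide read count falls below
#' \code{minTagCount} are dropped.  Ambiguously mapped pairs never reach
#' this stage ([mapTagPairs()] marks them unmapped).
#'
#' @param pairMap result of [mapTagPairs()].
#' @param minTagCount population-wide minimum tag count (default 10).
#' @return data.frame of surviving tag rows with a \code{locusKey} column;
#'   attributes \code{tagLength} and \code{nLoci}.
#' @export
groupTagsByLocus <- function(pairMap, minTagCount = 10L) {
  m <- pairMap[pairMap$mapped, , drop = FALSE]
  if (!nrow(m)) {
    out <- cbind(m, locusKey = character(0))
    attr(out, "tagLength") <- attr(pairMap, "tagLength")
    attr(out, "nLoci") <- 0L
    return(out)
  }
  m$locusKey <- paste(m$scaffold, m$posF, m$posR, m$strandF, sep = ":")
  tagKey <- paste(m$locusKey, m$fwd, m$rev, sep = "|")
  tot <- rowsum(m$count, tagKey)
  keep <- tot[tagKey, 1L] >= minTagCount
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tagLength") <- attr(pairMap, "tagLength")
  attr(out, "nLoci") <- length(unique(out$locusKey))
  out
}

#' Call SNPs from differences among tag pairs
#'
#' Within each tag locus, the distinct tag-pair sequences are compared
#' position by position across individuals; the reference base is never
#' consulted.  A site is emitted when at least two tag alleles segregate
#' among individuals, the minor-allele frequency reaches \code{mnMAF}, and
#' the fraction of individuals with at least one tag at the locus reaches
#' \code{mnLCov}.  An individual's genotype comes from its own tag alleles
#' (both seen = heterozygous); its call depth is its total tag count at the
#' locus.  Alleles are reported on the reference strand; the locus major
#' allele serves as the site's "ref" allele.
#'
#' @param loci result of [groupTagsByLocus()].
#' @param individuals full vector of individual ids in the dataset (the
#'   denominator of locus coverage).
#' @param params a [gbsDiscoveryParams()] list.
#' @return A [GenotypeCalls-class] (mode \code{"gbs"}) sorted by position.
#' @export
callSnpsTagwise <- function(loci, individuals,
                            params = gbsDiscoveryParams()) {
  tagLen <- attr(loci, "tagLength")
  if (is.null(tagLen)) stop("loci lack the tagLength attribute")
  nInd <- length(individuals)
  res <- list()
  if (nrow(loci)) for (lk in unique(loci$locusKey)) {
    l <- loci[loci$locusKey == lk, , drop = FALSE]
    covInds <- unique(l$individual)
    if (length(covInds) / nInd < params$mnLCov) next
    pairSeq <- paste(l$fwd, l$rev, sep = "")
    useq <- unique(pairSeq)
    if (length(useq) < 2L) next
    chars <- do.call(rbind, strsplit(useq, "", fixed = TRUE))
    poly <- which(apply(chars, 2L, function(col) length(unique(col)) > 1L))
    if (!length(poly)) next
    ui <- match(pairSeq, useq)
    indFac <- factor(l$individual, levels = covInds)
    indDepth <- rowsum(l$count, indFac)[, 1L]
    scaffold <- l$scaffold[1L]
    posF <- l$posF[1L]; posR <- l$posR[1L]
    strandF <- l$strandF[1L]
    strandR <- l$strandR[1L]
    for (j in poly) {
      tagAllele <- chars[, j]
      ## per-individual allele sets and alt-allele read counts
      alleleByInd <- lapply(split(seq_len(nrow(l)), indFac), function(rows)
        unique(tagAllele[ui[rows]]))
      nAllelesInd <- lengths(alleleByInd)
      called <- nAllelesInd >= 1L & nAllelesInd <= 2L
      ## population allele counts: hom -> 2 copies, het -> 1 + 1
      copies <- unlist(lapply(alleleByInd[called], function(a)
        if (length(a) == 1L) c(a, a) else a), use.names = FALSE)
      tabAll <- sort(table(copies), decreasing = TRUE)
      if (length(tabAll) < 2L) next
      tot <- sum(tabAll)
      maf <- (tot - tabAll[1L]) / tot
      if (maf < params$mnMAF) next
      major <- names(tabAll)[1L]
      altA <- names(tabAll)[2L]
      dos <- rep(NA_integer_, nInd)
      dep <- rep(0L, nInd)
      adep <- rep(0L, nInd)
      mi <- match(covInds, individuals)
      dos[mi] <- vapply(seq_along(covInds), function(k) {
        a <- alleleByInd[[k]]
        if (length(a) > 2L) return(NA_integer_)
        sum(c(a, a)[seq_len(2L)] == altA)
      }, integer(1L))
      dep[mi] <- indDepth
      altTags <- tagAllele == altA
      adep[mi] <- vapply(split(seq_len(nrow(l)), indFac), function(rows)
        sum(l$count[rows][altTags[ui[rows]]]), numeric(1L))
      ## map the tag column to a reference coordinate and strand
      if (j <= tagLen) {
        if (strandF == "+") { pos <- posF + j - 1L; flip <- FALSE }
        else { pos <- posF + tagLen - j; flip <- TRUE }
        side <- "F"
      } else {
        jr <- j - tagLen
        if (is.na(strandR) || strandR == "-") { pos <- posR + tagLen - jr; flip <- TRUE }
        else { pos <- posR + jr - 1L; flip <- FALSE }
        side <- "R"
      }
      refA <- if (flip) .COMP[[major]] else major
      altOut <- if (flip) .COMP[[altA]] else altA
      res[[length(res) + 1L]] <- list(
        scaffold = scaffold, pos = pos, side = side, ref = refA,
        alt = altOut, nAlleles = length(tabAll), maf = as.numeric(maf),
        dos = dos, dep = dep, adep = adep)
    }
  }
  .assembleCalls(res, individuals, "gbs")
}

.assembleCalls <- function(res, individuals, mode) {
  nInd <- length(individuals)
  if (!length(res)) {
    empty <- matrix(NA_integer_, 0L, nInd,
                    dimnames = list(NULL, individuals))
    return(genotypeCalls(empty, empty, empty,
                         data.frame(scaffold = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    nAlleles = integer(0), maf = numeric(0)),
                         individuals, mode))
  }
  info <- data.frame(scaffold = vapply(res, `[[`, "", "scaffold"),
                     pos = vapply(res, `[[`, 0L, "pos"),
                     ref = vapply(res, `[[`, "", "ref"),
                     alt = vapply(res, `[[`, "", "alt"),
                     nAlleles = vapply(res, `[[`, 0L, "nAlleles"),
                     maf = vapply(res, `[[`, 0, "maf"),
                     stringsAsFactors = FALSE)
  ord <- order(info$scaffold, info$pos,
               vapply(res, function(r) r$side %||% "F", ""))
  dup <- duplicated(info[ord, c("scaffold", "pos")])
  ord <- ord[!dup]
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  grab <- function(field) {
    m <- do.call(rbind, lapply(res[ord], `[[`, field))
    storage.mode(m) <- "integer"
    colnames(m) <- individuals
    m
  }
  genotypeCalls(grab("dos"), grab("dep"), grab("adep"), info, individuals,
                mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-posterior genotype from allele counts
#'
#' Binomial read-sampling model with symmetric error \code{e} and a uniform
#' prior over the three genotypes ref/ref, ref/alt, alt/alt: a ref read has
#' probability \code{1 - e}, \code{(1 - e + e/3) / 2} and \code{e/3} under
#' the three genotypes (alt reads symmetric); other-base reads have
#' probability \code{e/3} under every genotype except that a heterozygote
#' emits them at \code{e/3} as well, so they only penalise the total.
#' Ties resolve towards the fewer-alt genotype.
#'
#' @param nRef,nAlt,nOther read counts (vectors recycle).
#' @param errorRate per-base error probability.
#' @return Integer alt dosage (0, 1, 2); \code{NA} where total depth is 0.
#' @examples
#' callGenotype(5, 5, 0, 0.01)   # heterozygote
#' callGenotype(9, 1, 0, 0.01)   # likely hom ref
#' @export
callGenotype <- function(nRef, nAlt, nOther = 0L, errorRate = 0.001) {
  e <- max(errorRate, 1e-12)
  n <- pmax(length(nRef), length(nAlt), length(nOther))
  nRef <- rep_len(nRef, n); nAlt <- rep_len(nAlt, n)
  nOther <- rep_len(nOther, n)
  lErr <- log(e / 3)
  lHit <- log1p(-e)
  lHet <- log((1 - e + e / 3) / 2)
  l0 <- nRef * lHit + (nAlt + nOther) * lErr
  l1 <- (nRef + nAlt) * lHet + nOther * lErr
  l2 <- nAlt * lHit + (nRef + nOther) * lErr
  out <- max.col(cbind(l0, l1, l2), ties.method = "first") - 1L
  out[nRef + nAlt + nOther == 0L] <- NA_integer_
  as.integer(out)
}

#' Call SNPs from read-versus-reference pileups
#'
#' Stacks each individual's uniquely mapped reads on the reference,
#' collects per-site base counts, and calls the maximum-posterior genotype
#' (see [callGenotype()]).  A site is emitted when any individual's called
#' genotype differs from the reference base; individuals with zero depth at
#' an emitted site are missing.  The site's alt allele is the non-reference
#' base with the highest population read count; additional non-reference
#' bases with substantial support (at least 10 percent of the site's reads,
#' minimum 2) raise \code{nAlleles} above 2, and such sites are removed
#' later by the biallelic filter.
#'
#' @param readSet result of [simulateReseqReads()] (or a compatible named
#'   list; the \code{errorRate} attribute supplies the error model).
#' @param reference the [ReferenceGenome-class] the reads were mapped to.
#' @param alignments optional named list (per individual) of
#'   [mapCollection()] results over \code{c(fwd, rev)}; computed here when
#'   missing.
#' @param params a [reseqDiscoveryParams()] list.
#' @param mapParams a [mapParams()] list used when alignments are computed
#'   internally.
#' @return A [GenotypeCalls-class] (mode \code{"reseq"}); metadata records
#'   the per-individual alignment rates.
#' @export
callSnpsPileup <- function(readSet, reference, alignments = NULL,
                           params = reseqDiscoveryParams(),
                           mapParams = refdivsim::mapParams()) {
  stopifnot(is(reference, "ReferenceGenome"))
  if (length(reference@sequences) != 1L)
    stop("pileup calling expects a single-scaffold reference")
  scafName <- names(reference@sequences)[1L]
  refStr <- as.character(reference@sequences[[1L]])
  L <- nchar(refStr)
  individuals <- names(readSet)
  errorRate <- attr(readSet, "errorRate") %||% 0.001
  idx <- NULL
  perInd <- vector("list", length(individuals))
  alnRate <- numeric(length(individuals))
  for (i in seq_along(individuals)) {
    rs <- readSet[[i]]
    reads <- c(rs$fwd, rs$rev)
    if (!length(reads)) {
      perInd[[i]] <- list(depth = integer(L), pos = integer(0),
                          base = integer(0), count = integer(0))
      alnRate[i] <- NA_real_
      next
    }
    a <- if (!is.null(alignments)) alignments[[individuals[i]]]
    if (is.null(a)) {
      if (is.null(idx)) idx <- buildRefIndex(reference, mapParams)
      a <- mapCollection(reads, idx)
    }
    pc <- .pileupOne(reads, a, refStr, scafName)
    perInd[[i]] <- pc$counts
    alnRate[i] <- pc$alignmentRate
  }
  .pileupFromCounts(perInd, reference, individuals, errorRate, alnRate)
}

## stack one individual's uniquely mapped reads
.pileupOne <- function(reads, alignments, refStr, scafName) {
  a <- alignments
  bad <- a$status == "unique" & a$scaffold != scafName
  if (any(bad, na.rm = TRUE)) stop("alignment/reference scaffold mismatch")
  keep <- a$status == "unique"
  st <- ifelse(keep, a$pos, NA_integer_)
  sd <- ifelse(keep & a$strand == "-", -1L, 1L)
  list(counts = .cpp_pileup_counts(refStr, reads, as.integer(st),
                                   as.integer(sd)),
       alignmentRate = mean(keep))
}

## genotype assembly from per-individual pileup summaries
.pileupFromCounts <- function(perInd, reference, individuals, errorRate,
                              alnRate = rep(NA_real_, length(individuals))) {
  scafName <- names(reference@sequences)[1L]
  refStr <- as.character(reference@sequences[[1L]])
  ## candidate sites: positions where some individual could call non-ref
  cand <- integer(0)
  for (i in seq_along(perInd)) {
    p <- perInd[[i]]
    if (!length(p$pos)) next
    strong <- p$count >= 2L | p$count >= p$depth[p$pos]
    cand <- c(cand, p$pos[strong])
  }
  cand <- sort(unique(cand))
  C <- length(cand)
  nInd <- length(individuals)
  if (C == 0L) return(.assembleCalls(list(), individuals, "reseq"))
  depthM <- matrix(0L, C, nInd)
  baseCount <- matrix(0L, C, 4L)          # population counts per base
  altM <- array(0L, c(C, nInd, 4L))       # per-ind non-ref counts per base
  for (i in seq_along(perInd)) {
    p <- perInd[[i]]
    depthM[, i] <- p$depth[cand]
    if (!length(p$pos)) next
    hit <- match(p$pos, cand)
    ok <- !is.na(hit)
    if (any(ok)) {
      ix <- cbind(hit[ok], p$base[ok] + 1L)
      baseCount[ix] <- baseCount[ix] + p$count[ok]
      altM[cbind(hit[ok], i, p$base[ok] + 1L)] <- p$count[ok]
    }
  }
  refCode <- .seqToCodes(refStr)[cand]
  ## ref base never appears in the sparse non-ref lists; zero its column
  baseCount[cbind(seq_len(C), refCode)] <- 0L
  altCode <- max.col(baseCount, ties.method = "first")
  altCount <- altM[cbind(rep(seq_len(C), nInd),
                         rep(seq_len(nInd), each = C),
                         rep(altCode, nInd))]
  altCount <- matrix(altCount, C, nInd)
  nonrefTot <- matrix(rowSums(altM, dims = 2L), C, nInd)
  nRef <- depthM - nonrefTot
  nOther <- nonrefTot - altCount
  dos <- matrix(callGenotype(nRef, altCount, nOther, errorRate), C, nInd)
  emit <- which(rowSums(dos > 0L, na.rm = TRUE) > 0L)
  if (!length(emit)) return(.assembleCalls(list(), individuals, "reseq"))
  dos <- dos[emit, , drop = FALSE]
  dep <- depthM[emit, , drop = FALSE]
  adep <- altCount[emit, , drop = FALSE]
  totDepth <- rowSums(dep)
  nAlleles <- 1L + rowSums(baseCount[emit, , drop = FALSE] >=
                             pmax(2, 0.1 * totDepth))
  f <- rowMeans(dos, na.rm = TRUE) / 2
  info <- data.frame(scaffold = scafName, pos = cand[emit],
                     ref = .DNA[refCode[emit]], alt = .DNA[altCode[emit]],
                     nAlleles = as.integer(nAlleles),
                     maf = pmin(f, 1 - f), stringsAsFactors = FALSE)
  colnames(dos) <- colnames(dep) <- colnames(adep) <- individuals
  out <- genotypeCalls(dos, dep, adep, info, individuals, "reseq")
  S4Vectors::metadata(out)$alignmentRate <- stats::setNames(alnRate, individuals)
  out
}
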