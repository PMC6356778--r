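## End-to-end comparison across the reference divergence ladder.

#' Result of a full ladder comparison
#'
#' @slot report one row per pipeline mode x reference: mapping summary,
#'   unfiltered/filtered SNP counts, mean diversity statistics, tag-share
#'   percentages and cross-reference correlation/Mantel results.
#' @slot config the [SimConfig-class] that produced the run.
#' @slot details list of per-stage artifacts (pedigree, expected
#'   relatedness, filtered calls, scaled relatedness matrices, H_S vectors,
#'   tag sets, filter audits).
#' @export
setClass("PipelineReport", slots = c(report = "data.frame",
                                     config = "SimConfig",
                                     details = "list"))

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport (", nrow(object@report), " mode x reference rows)\n",
      sep = "")
  print(object@report, digits = 4, row.names = FALSE)
})

#' @rdname PipelineReport-class
#' @param x a PipelineReport.
#' @export
pipelineReport <- function(x) x@report

#' Run both discovery pipelines across the reference ladder
#'
#' Performs one complete simulated experiment: generates the focal genome,
#' pedigree and true genotypes; derives the diverged references; simulates
#' GBS tag pairs and resequencing reads once from the focal-derived
#' individuals; maps both read types to every reference; calls SNPs
#' tag-wise (GBS) and by pileup (resequencing); applies both filter
#' cascades; and computes nucleotide diversity, individual heterozygosity,
#' scaled relatedness, tag-set intersections with the focal run, Spearman
#' correlations of H_S and relatedness against the focal run, and Mantel
#' tests of the scaled relatedness matrices.  Fully reproducible from the
#' configuration seed.  The resequencing reads are simulated per individual
#' and mapped to all references before being discarded, so memory stays
#' modest at the default 1 Mb / 30-individual scale.
#'
#' @param config a [SimConfig-class].
#' @param modes pipeline modes to run (default both).
#' @param mantelIterations permutations for the Mantel tests.
#' @param mapping a [mapParams()] list.
#' @param outdir optional directory; when given, references (FASTA), truth
#'   tables (TSV), the report and filter audits (TSV) and per-run VCFs are
#'   written beneath it.
#' @param verbose print stage progress.
#' @return A [PipelineReport-class].
#' @export
runComparison <- function(config, modes = c("gbs", "reseq"),
                          mantelIterations = 1000L,
                          mapping = mapParams(), outdir = NULL,
                          verbose = FALSE) {
  stopifnot(is(config, "SimConfig"))
  modes <- match.arg(modes, several.ok = TRUE)
  say <- function(...) if (verbose) message(...)

  say("simulating focal genome, pedigree and genotypes")
  genome <- generateGenome(config)
  ped <- simulatePedigree(config)
  pop <- assignVariants(genome, ped, config)
  inds <- pop@individuals
  A <- expectedRelatedness(ped)

  dl <- config@divergenceLevels
  anchor <- if (length(dl)) unname(dl[ceiling(length(dl) / 2)]) else 1
  refs <- c(list(focal = genome),
            stats::setNames(lapply(seq_along(dl), function(i) {
              divergeReference(genome, names(dl)[i], dl[i],
                               indelRate = config@refIndelRate * dl[i] / anchor,
                               seed = .opSeed(config, 30L + i))
            }), names(dl)))
  refNames <- names(refs)

  details <- list(pedigree = ped, expectedRelatedness = A,
                  population = pop, gbs = list(), reseq = list())
  rows <- list()

  if ("gbs" %in% modes) {
    say("GBS: digesting and simulating tag pairs")
    cut <- digestGenome(genome, config@gbsMotif)
    tags <- simulateGbsTags(pop, genome, cut, config)
    gbsP <- gbsDiscoveryParams(kmerLength = config@tagLength)
    fpar <- filterParams("gbs", thinBp = config@tagLength)
    for (rn in refNames) {
      say("GBS: mapping and calling against ", rn)
      idx <- buildRefIndex(refs[[rn]], mapping)
      pm <- mapTagPairs(tags, idx)
      tagSet <- .mappedTagSet(pm)
      loci <- groupTagsByLocus(pm, gbsP$minTagCount)
      calls <- callSnpsTagwise(loci, inds, gbsP)
      filt <- filterCascade(calls, fpar)
      rr <- if (nrow(filt) >= 2L) scaleRelatedness(relatednessMatrix(filt))
      details$gbs[[rn]] <- list(
        tagSet = tagSet, nMappedTagPairs = length(tagSet),
        unfiltered = nrow(calls), calls = filt, relatedness = rr,
        hs = individualHs(filt),
        audit = S4Vectors::metadata(filt)$filterAudit)
    }
  }

  if ("reseq" %in% modes) {
    say("reseq: simulating reads and building pileups")
    idxs <- lapply(refs, buildRefIndex, params = mapping)
    perInd <- lapply(refNames, function(...) vector("list", length(inds)))
    names(perInd) <- refNames
    alnRate <- matrix(NA_real_, length(inds), length(refNames),
                      dimnames = list(inds, refNames))
    for (i in seq_along(inds)) {
      rs <- simulateReseqReads(pop, genome, config, individuals = inds[i])
      reads <- c(rs[[1L]]$fwd, rs[[1L]]$rev)
      for (rn in refNames) {
        if (!length(reads)) {
          L <- sum(Biostrings::width(refs[[rn]]@sequences))
          perInd[[rn]][[i]] <- list(depth = integer(L), pos = integer(0),
                                    base = integer(0), count = integer(0))
          next
        }
        a <- mapCollection(reads, idxs[[rn]])
        pc <- .pileupOne(reads, a,
                         as.character(refs[[rn]]@sequences[[1L]]),
                         names(refs[[rn]]@sequences)[1L])
        perInd[[rn]][[i]] <- pc$counts
        alnRate[i, rn] <- pc$alignmentRate
      }
    }
    rm(idxs)
    fpar <- filterParams("reseq", thinBp = config@readLength)
    rp <- reseqDiscoveryParams()
    for (rn in refNames) {
      say("reseq: calling and filtering against ", rn)
      calls <- .pileupFromCounts(perInd[[rn]], refs[[rn]], inds,
                                 config@errorRate, alnRate[, rn])
      perInd[[rn]] <- NULL
      filt <- filterCascade(calls, fpar)
      rr <- if (nrow(filt) >= 2L) scaleRelatedness(relatednessMatrix(filt))
      details$reseq[[rn]] <- list(
        alignmentRate = mean(alnRate[, rn], na.rm = TRUE),
        alignmentRates = alnRate[, rn],
        unfiltered = nrow(calls), calls = filt, relatedness = rr,
        hs = individualHs(filt),
        audit = S4Vectors::metadata(filt)$filterAudit)
    }
  }

  ## comparison statistics against the focal run
  offVec <- function(S) S[upper.tri(S)]
  for (mode in modes) {
    dd <- details[[mode]]
    focal <- dd[["focal"]]
    for (k in seq_along(refNames)) {
      rn <- refNames[k]
      d <- dd[[rn]]
      row <- data.frame(mode = mode, reference = rn,
                        divergence = refDivergence(refs[[rn]]),
                        mappedTagPairs = NA_integer_,
                        alignmentRate = NA_real_,
                        unfilteredSNPs = d$unfiltered,
                        filteredSNPs = nrow(d$calls),
                        pctTagsShared = NA_real_,
                        meanPi = mean(sitePi(d$calls), na.rm = TRUE),
                        meanHs = mean(d$hs, na.rm = TRUE),
                        meanHsDeltaPct = NA_real_,
                        meanR = NA_real_, rsHs = NA_real_, pHs = NA_real_,
                        rsR = NA_real_, pR = NA_real_,
                        mantelR = NA_real_, mantelP = NA_real_)
      if (mode == "gbs") {
        row$mappedTagPairs <- d$nMappedTagPairs
        row$pctTagsShared <-
          pancompareTags(d$tagSet, focal$tagSet)$percentShared
      } else {
        row$alignmentRate <- 100 * d$alignmentRate
      }
      if (!is.null(d$relatedness))
        row$meanR <- mean(offVec(scaledRelatedness(d$relatedness)))
      fHs <- focal$hs
      if (!is.null(fHs) && sum(stats::complete.cases(d$hs, fHs)) >= 3) {
        sc <- spearmanRho(d$hs, fHs)
        row$rsHs <- sc$rho; row$pHs <- sc$p
      }
      row$meanHsDeltaPct <- 100 * (row$meanHs - mean(fHs, na.rm = TRUE)) /
        abs(mean(fHs, na.rm = TRUE))
      if (!is.null(d$relatedness) && !is.null(focal$relatedness)) {
        Sd <- scaledRelatedness(d$relatedness)
        Sf <- scaledRelatedness(focal$relatedness)
        sc <- spearmanRho(offVec(Sd), offVec(Sf))
        row$rsR <- sc$rho; row$pR <- sc$p
        mt <- mantelTest(Sf, Sd, iterations = mantelIterations,
                         seed = .opSeed(config, 90L + k))
        row$mantelR <- mt$statistic; row$mantelP <- mt$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  out <- methods::new("PipelineReport", report = report, config = config,
                      details = details)
  if (!is.null(outdir)) .writeRunArtifacts(out, refs, outdir)
  out
}
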