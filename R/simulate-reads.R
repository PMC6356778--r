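## GBS tag-pair and paired-end resequencing read simulation.

.phredChar <- function(errorRate) {
  q <- if (errorRate <= 0) 40L else min(40L, as.integer(round(-10 * log10(errorRate))))
  intToUtf8(33L + q)
}

#' Simulate GBS tag pairs
#'
#' For every individual and every cut-site locus of the focal genome, draws
#' a Poisson(\code{meanTagDepth}) number of reads; each read samples one of
#' the individual's two haplotypes, so the tag sequences are the focal
#' windows flanking the cut site with that haplotype's alt alleles applied,
#' plus per-base sequencing errors.  The forward tag starts at the cut site
#' and reads rightwards; the reverse tag is the reverse complement of the
#' window ending at the motif end (it starts at the cut site from the other
#' side).  Loci whose windows run off the scaffold are skipped (reported via
#' a message).
#'
#' @param pop a [PopulationGenotypes-class].
#' @param genome the focal [ReferenceGenome-class] (tags are sequenced from
#'   the organism, i.e. from focal-derived haplotypes).
#' @param cutSites data.frame from [digestGenome()] on the focal genome.
#' @param config a [SimConfig-class].
#' @param individuals subset of individual ids (default all).
#' @return data.frame with columns \code{individual}, \code{locus} (index
#'   into the retained cut-site table), \code{cutPos}, \code{fwd},
#'   \code{rev}, \code{count}; attribute \code{"cutPos"} maps locus index
#'   to 1-based cut-site position.
#' @export
simulateGbsTags <- function(pop, genome, cutSites, config,
                            individuals = pop@individuals) {
  stopifnot(is(pop, "PopulationGenotypes"), is(genome, "ReferenceGenome"),
            is(config, "SimConfig"))
  if (refDivergence(genome) != 0)
    stop("cut sites and tags must come from the focal genome")
  if (length(genome@sequences) != 1L)
    stop("tag simulation expects a single-scaffold genome")
  refStr <- as.character(genome@sequences[[1L]])
  cutPos <- sort(unique(cutSites$pos))
  motifLen <- nchar(config@gbsMotif)
  tagLen <- config@tagLength
  withr::with_seed(.opSeed(config, 40L), {
    res <- vector("list", length(individuals))
    skipped <- integer(0)
    for (i in seq_along(individuals)) {
      ind <- individuals[i]
      va <- .hapVariants(pop, ind, "A")
      vb <- .hapVariants(pop, ind, "B")
      r <- .cpp_simulate_tag_pairs(refStr, va$pos0, va$alt, vb$pos0, vb$alt,
                                   cutPos - 1L, tagLen, motifLen,
                                   config@meanTagDepth, config@errorRate)
      skipped <- union(skipped, r$skippedLoci)
      if (length(r$locus))
        res[[i]] <- data.frame(individual = ind, locus = r$locus,
                               cutPos = cutPos[r$locus], fwd = r$fwd,
                               rev = r$rev, count = r$count,
                               stringsAsFactors = FALSE)
    }
    if (length(skipped))
      message(length(skipped), " cut-site locus/loci skipped (tag window ",
              "exceeds scaffold end)")
    out <- do.call(rbind, res)
    if (is.null(out))
      out <- data.frame(individual = character(0), locus = integer(0),
                        cutPos = integer(0), fwd = character(0),
                        rev = character(0), count = integer(0))
    attr(out, "cutPos") <- cutPos
    attr(out, "tagLength") <- tagLen
    attr(out, "motifLength") <- motifLen
    out
  })
}

#' Simulate paired-end resequencing reads
#'
#' Fragments of fixed length are placed uniformly on a uniformly chosen
#' haplotype, giving approximately Poisson per-site coverage at the
#' configured genome-wide mean depth; both 150 bp mates receive per-base
#' errors at the configured rate.  Quality strings are constant at the
#' Phred score matching the error rate.
#'
#' @param pop a [PopulationGenotypes-class].
#' @param genome the focal [ReferenceGenome-class].
#' @param config a [SimConfig-class].
#' @param individuals subset of individual ids (default all).  Reads for a
#'   given individual are identical whether or not other individuals are
#'   simulated in the same call, so large runs can be processed in chunks.
#' @return Named list (one element per individual) of lists with
#'   \code{fwd}, \code{rev} (character vectors), \code{start} (1-based true
#'   fragment origin) and \code{hap}; attributes \code{errorRate},
#'   \code{qualChar}, \code{readLength}.
#' @export
simulateReseqReads <- function(pop, genome, config,
                               individuals = pop@individuals) {
  stopifnot(is(pop, "PopulationGenotypes"), is(genome, "ReferenceGenome"),
            is(config, "SimConfig"))
  if (refDivergence(genome) != 0)
    stop("reads are sequenced from focal-derived haplotypes")
  if (length(genome@sequences) != 1L)
    stop("read simulation expects a single-scaffold genome")
  refStr <- as.character(genome@sequences[[1L]])
  L <- nchar(refStr)
  meanPairs <- L * config@meanReadDepth / (2 * config@readLength)
  out <- vector("list", length(individuals))
  names(out) <- individuals
  for (i in seq_along(individuals)) {
    ind <- individuals[i]
    j <- match(ind, pop@individuals)
    out[[i]] <- withr::with_seed(.opSeed(config, 200L + j), {
      nPairs <- stats::rpois(1L, meanPairs)
      if (nPairs == 0L) {
        list(fwd = character(0), rev = character(0), start = integer(0),
             hap = integer(0))
      } else {
        va <- .hapVariants(pop, ind, "A")
        vb <- .hapVariants(pop, ind, "B")
        .cpp_simulate_read_pairs(refStr, va$pos0, va$alt, vb$pos0, vb$alt,
                                 nPairs, config@readLength,
                                 config@fragmentLength, config@errorRate)
      }
    })
  }
  attr(out, "errorRate") <- config@errorRate
  attr(out, "qualChar") <- .phredChar(config@errorRate)
  attr(out, "readLength") <- config@readLength
  out
}
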