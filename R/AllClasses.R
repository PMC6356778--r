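#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Holds every tunable parameter of the simulation study: the focal genome,
#' the pedigreed population segregating on it, the ladder of diverged
#' reference genomes, and the two sequencing strategies (GBS tag pairs and
#' paired-end resequencing).
#'
#' @slot genomeLength focal genome length in bp.
#' @slot gcContent GC fraction of the focal genome.
#' @slot nFounders,nFamilies,offspringPerFamily pedigree shape; families are
#'   formed first from founder couples, and once founders are exhausted later
#'   families draw parents from the offspring of two distinct earlier
#'   families, giving a multi-generation pedigree with graded relatedness.
#' @slot theta per-site probability that a focal-genome site segregates in
#'   the founders.
#' @slot alleleFreqRange range of the uniform law for founder minor-allele
#'   frequencies.
#' @slot divergenceLevels named, strictly increasing per-site substitution
#'   proportions of the diverged references (defaults mirror congeneric,
#'   confamilial and conordinal relationships).
#' @slot refIndelRate per-site small-indel probability in a diverged
#'   reference at the middle (confamilial) rung; the pipeline scales the
#'   rate linearly with substitution divergence across rungs.
#' @slot gbsMotif IUPAC recognition motif of the restriction enzyme
#'   (ApeKI = \code{"GCWGC"}).
#' @slot tagLength GBS tag length in bp.
#' @slot meanTagDepth mean reads per tag locus per individual.
#' @slot readLength,meanReadDepth,fragmentLength resequencing read length,
#'   genome-wide mean coverage, and fragment (insert) length.
#' @slot errorRate per-base sequencing error probability.
#' @slot seed integer seed governing all randomness.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimConfig", slots = c(
  genomeLength = "numeric",
  gcContent = "numeric",
  nFounders = "integer",
  nFamilies = "integer",
  offspringPerFamily = "integer",
  theta = "numeric",
  alleleFreqRange = "numeric",
  divergenceLevels = "numeric",
  refIndelRate = "numeric",
  gbsMotif = "character",
  tagLength = "integer",
  meanTagDepth = "numeric",
  readLength = "integer",
  meanReadDepth = "numeric",
  fragmentLength = "integer",
  errorRate = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  chkFrac <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      msg <<- c(msg, sprintf("%s must lie in [0, 1]", nm))
  }
  if (object@genomeLength < 1) msg <- c(msg, "genomeLength must be positive")
  chkFrac(object@gcContent, "gcContent")
  chkFrac(object@theta, "theta")
  chkFrac(object@errorRate, "errorRate")
  chkFrac(object@alleleFreqRange, "alleleFreqRange")
  if (length(object@alleleFreqRange) != 2 ||
      diff(object@alleleFreqRange) < 0)
    msg <- c(msg, "alleleFreqRange must be an increasing pair")
  if (object@nFounders < 2L) msg <- c(msg, "need at least 2 founders")
  if (object@nFamilies < 0L || object@offspringPerFamily < 0L)
    msg <- c(msg, "family counts must be non-negative")
  d <- object@divergenceLevels
  if (length(d)) {
    if (is.null(names(d)) || any(!nzchar(names(d))))
      msg <- c(msg, "divergenceLevels must be named")
    if (any(d < 0) || any(d > 0.25))
      msg <- c(msg, "divergence proportions must lie in [0, 0.25]")
    if (any(diff(d) <= 0))
      msg <- c(msg, "divergenceLevels must be strictly increasing")
  }
  chkFrac(object@refIndelRate, "refIndelRate")
  if (object@tagLength < 1L || object@readLength < 1L)
    msg <- c(msg, "tagLength and readLength must be positive")
  if (object@fragmentLength < object@readLength)
    msg <- c(msg, "fragmentLength must be >= readLength")
  if (object@meanTagDepth < 0 || object@meanReadDepth < 0)
    msg <- c(msg, "depths must be non-negative")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@gbsMotif))
    msg <- c(msg, "gbsMotif must be an IUPAC DNA string")
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults describe the study conditions: a 1 Mb focal genome at avian GC
#' content carrying one segregating site per 200 bp, a 30-individual
#' multi-generation pedigree (8 founders, 11 families of 2), a divergence
#' ladder at 0.005 / 0.035 / 0.07 substitutions per site standing in for
#' congeneric, confamilial and conordinal references, 64 bp ApeKI tag pairs
#' at 15x tag depth, and 150 bp paired-end resequencing at 15x coverage with
#' Q30-equivalent base errors.
#'
#' @param genomeLength,gcContent focal genome size (bp) and GC fraction.
#' @param nFounders,nFamilies,offspringPerFamily pedigree shape (see
#'   [simulatePedigree()]).
#' @param theta per-site polymorphism probability in the founders.
#' @param alleleFreqRange uniform range for founder minor-allele frequencies.
#' @param divergenceLevels named increasing substitution proportions.
#' @param refIndelRate per-site indel probability at the confamilial rung.
#' @param gbsMotif,tagLength,meanTagDepth GBS settings.
#' @param readLength,meanReadDepth,fragmentLength resequencing settings.
#' @param errorRate per-base sequencing error probability.
#' @param seed integer seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(genomeLength = 1e5, seed = 7)
#' cfg
#' @export
simConfig <- function(genomeLength = 1e6,
                      gcContent = 0.42,
                      nFounders = 8L,
                      nFamilies = 11L,
                      offspringPerFamily = 2L,
                      theta = 0.005,
                      alleleFreqRange = c(0.05, 0.5),
                      divergenceLevels = c(congeneric = 0.005,
                                           confamilial = 0.035,
                                           conordinal = 0.07),
                      refIndelRate = 2e-4,
                      gbsMotif = "GCWGC",
                      tagLength = 64L,
                      meanTagDepth = 15,
                      readLength = 150L,
                      meanReadDepth = 15,
                      fragmentLength = 350L,
                      errorRate = 0.001,
                      seed = 1L) {
  new("SimConfig",
      genomeLength = as.numeric(genomeLength), gcContent = gcContent,
      nFounders = as.integer(nFounders), nFamilies = as.integer(nFamilies),
      offspringPerFamily = as.integer(offspringPerFamily),
      theta = theta, alleleFreqRange = as.numeric(alleleFreqRange),
      divergenceLevels = divergenceLevels, refIndelRate = refIndelRate,
      gbsMotif = gbsMotif, tagLength = as.integer(tagLength),
      meanTagDepth = meanTagDepth, readLength = as.integer(readLength),
      meanReadDepth = meanReadDepth,
      fragmentLength = as.integer(fragmentLength),
      errorRate = errorRate, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## ReferenceGenome
## ---------------------------------------------------------------------------

#' Reference genome at a known divergence from the focal genome
#'
#' @slot label reference label (\code{"focal"} or a divergence-rung name).
#' @slot sequences a [Biostrings::DNAStringSet] of scaffolds.
#' @slot divergence per-site substitution proportion relative to the focal
#'   genome (0 for the focal genome itself).
#' @export
setClass("ReferenceGenome", slots = c(
  label = "character",
  sequences = "DNAStringSet",
  divergence = "numeric"
))

setValidity("ReferenceGenome", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(object@divergence) != 1L || object@divergence < 0 ||
      object@divergence > 0.25)
    msg <- c(msg, "divergence must be a single value in [0, 0.25]")
  if (identical(object@label, "focal") && object@divergence != 0)
    msg <- c(msg, "the focal genome must have divergence 0")
  if (length(object@sequences)) {
    freq <- Biostrings::alphabetFrequency(object@sequences, collapse = TRUE)
    if (sum(freq) - sum(freq[c("A", "C", "G", "T")]) > 0)
      msg <- c(msg, "sequences must use the alphabet {A, C, G, T}")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree of simulated individuals
#'
#' A table of individuals with either zero (founders) or two recorded
#' parents.  Rows are stored in generational order (parents precede their
#' offspring), which also guarantees acyclicity.
#'
#' @slot tab data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (\code{NA} for founders) and \code{family} (\code{NA} for founders).
#' @export
setClass("Pedigree", slots = c(tab = "data.frame"))

setValidity("Pedigree", function(object) {
  t <- object@tab
  msg <- character()
  need <- c("id", "sire", "dam", "family")
  if (!all(need %in% names(t))) return("tab needs columns id, sire, dam, family")
  if (anyDuplicated(t$id)) msg <- c(msg, "duplicated individual ids")
  half <- xor(is.na(t$sire), is.na(t$dam))
  if (any(half)) msg <- c(msg, "individuals must have 0 or 2 parents")
  for (i in seq_len(nrow(t))) {
    if (!is.na(t$sire[i])) {
      prev <- t$id[seq_len(i - 1L)]
      if (!(t$sire[i] %in% prev) || !(t$dam[i] %in% prev))
        msg <- c(msg, sprintf("parents of %s do not precede it", t$id[i]))
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

## ---------------------------------------------------------------------------
## PopulationGenotypes
## ---------------------------------------------------------------------------

#' True phased genotypes of the simulated population
#'
#' Ground truth produced by gene-dropping founder haplotypes through the
#' pedigree: variant site table plus two haplotype indicator matrices
#' (1 = alt allele).
#'
#' @slot sites data.frame with columns \code{pos} (1-based, strictly
#'   increasing), \code{ref}, \code{alt}, \code{p} (founder alt-allele
#'   frequency the site was drawn with).
#' @slot hapA,hapB integer matrices (sites x individuals) of 0/1 alt-allele
#'   indicators for the two haplotypes.
#' @slot individuals individual ids (column order of the matrices).
#' @export
setClass("PopulationGenotypes", slots = c(
  sites = "data.frame",
  hapA = "matrix",
  hapB = "matrix",
  individuals = "character"
))

setValidity("PopulationGenotypes", function(object) {
  msg <- character()
  s <- object@sites
  if (!all(c("pos", "ref", "alt", "p") %in% names(s)))
    return("sites needs columns pos, ref, alt, p")
  if (is.unsorted(s$pos, strictly = TRUE))
    msg <- c(msg, "site positions must be strictly increasing")
  for (h in list(object@hapA, object@hapB)) {
    if (nrow(h) != nrow(s) || ncol(h) != length(object@individuals))
      msg <- c(msg, "haplotype matrix dimensions disagree with sites/individuals")
    else if (length(h) && !all(h %in% c(0L, 1L)))
      msg <- c(msg, "haplotype matrices must be 0/1")
  }
  if (length(msg)) unique(msg) else TRUE
})

## ---------------------------------------------------------------------------
## GenotypeCalls
## ---------------------------------------------------------------------------

#' Called genotypes with per-call depth
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' discovery output of either pipeline: assays \code{dosage} (alt-allele
#' dosage 0/1/2, \code{NA} missing), \code{depth} (reads supporting the
#' call) and \code{altDepth} (reads carrying the alt allele), with the site
#' table in \code{rowData} (\code{scaffold}, \code{pos}, \code{ref},
#' \code{alt}, \code{nAlleles}, \code{maf}).
#'
#' @export
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("dosage", "depth", "altDepth") %in% a))
    msg <- c(msg, "assays dosage, depth and altDepth are required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("scaffold", "pos", "ref", "alt", "nAlleles", "maf")
  if (!all(need %in% names(rd)))
    msg <- c(msg, paste("rowData needs columns", paste(need, collapse = ", ")))
  if ("dosage" %in% a) {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (length(d) && !all(d %in% c(0L, 1L, 2L) | is.na(d)))
      msg <- c(msg, "dosage must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCalls object
#'
#' @param dosage,depth,altDepth sites x individuals matrices.
#' @param siteInfo data.frame with columns scaffold, pos, ref, alt,
#'   nAlleles, maf.
#' @param individuals column ids.
#' @param mode \code{"gbs"} or \code{"reseq"}, recorded in metadata.
#' @return A [GenotypeCalls-class] object.
#' @export
genotypeCalls <- function(dosage, depth, altDepth, siteInfo,
                          individuals = colnames(dosage),
                          mode = c("gbs", "reseq")) {
  mode <- match.arg(mode)
  storage.mode(dosage) <- "integer"
  storage.mode(depth) <- "integer"
  storage.mode(altDepth) <- "integer"
  colnames(dosage) <- colnames(depth) <- colnames(altDepth) <- individuals
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(dosage = dosage, depth = depth,
                                   altDepth = altDepth),
    rowData = S4Vectors::DataFrame(siteInfo),
    colData = S4Vectors::DataFrame(row.names = individuals))
  out <- methods::new("GenotypeCalls", se)
  S4Vectors::metadata(out)$mode <- mode
  out
}

## ---------------------------------------------------------------------------
## RelatednessResult
## ---------------------------------------------------------------------------

#' Raw and scaled pairwise relatedness matrices
#'
#' @slot raw the depth-aware genomic relationship matrix M_O.
#' @slot scaled the rescaled matrix M_S = D M_O D with unit diagonal
#'   (empty until [scaleRelatedness()] is applied).
#' @slot D diagonal scaling coefficients 1/sqrt(diag(M_O)).
#' @slot nShared pairwise count of sites non-missing in both individuals.
#' @slot lowConfidence logical matrix flagging pairs with fewer than the
#'   minimum number of shared sites.
#' @export
setClass("RelatednessResult", slots = c(
  raw = "matrix",
  scaled = "matrix",
  D = "numeric",
  nShared = "matrix",
  lowConfidence = "matrix"
))

setValidity("RelatednessResult", function(object) {
  msg <- character()
  if (nrow(object@raw) != ncol(object@raw))
    msg <- c(msg, "raw matrix must be square")
  if (!isSymmetric(unname(object@raw), tol = 1e-8))
    msg <- c(msg, "raw matrix must be symmetric")
  if (length(object@scaled) &&
      !isSymmetric(unname(object@scaled), tol = 1e-8))
    msg <- c(msg, "scaled matrix must be symmetric")
  if (length(msg)) msg else TRUE
})
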