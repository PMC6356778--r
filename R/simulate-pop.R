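## Pedigree construction, gene dropping, expected additive relatedness.

#' Simulate a pedigree with close and distant relatives
#'
#' Builds a deterministic pedigree: founders are paired into couples and the
#' first \code{floor(nFounders / 2)} families are founder crosses; any
#' further families draw their two parents from the offspring of two
#' distinct earlier families (oldest available first), yielding a
#' multi-generation design.  This produces the mixture the study design
#' targets: parent-offspring and full-sib pairs near relatedness 0.5,
#' second-degree and cousin pairs at 0.25 / 0.125, and unrelated lineages
#' near 0 - hence a bimodal relatedness distribution with graded structure
#' in between.
#'
#' @param config a [SimConfig-class]; uses \code{nFounders},
#'   \code{nFamilies}, \code{offspringPerFamily}.
#' @return A [Pedigree-class].
#' @examples
#' simulatePedigree(simConfig(nFounders = 4, nFamilies = 2,
#'                            offspringPerFamily = 3))
#' @export
simulatePedigree <- function(config) {
  stopifnot(is(config, "SimConfig"))
  nf <- config@nFounders
  nfam <- config@nFamilies
  noff <- config@offspringPerFamily
  if (nf < 2L && nfam > 0L) stop("insufficient founders to form any family")
  id <- sprintf("F%02d", seq_len(nf))
  tab <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    family = NA_integer_, stringsAsFactors = FALSE)
  ## pool of (id, family-of-origin) available to become parents
  pool <- data.frame(id = id, origin = seq_len(nf) + 1000L)  # founders: own "origin"
  ## founder couples first: origins 1001, 1002 pair up, etc.
  coupleOf <- function(pool, used) {
    avail <- pool[!(pool$id %in% used), , drop = FALSE]
    if (nrow(avail) < 2L) return(NULL)
    a <- avail[1L, ]
    b <- avail[avail$origin != a$origin, , drop = FALSE]
    if (!nrow(b)) return(NULL)
    c(a$id, b$id[1L])
  }
  used <- character(0)
  for (f in seq_len(nfam)) {
    par <- coupleOf(pool, used)
    if (is.null(par))
      stop("insufficient founders/offspring to form family ", f,
           " with parents from distinct families")
    used <- c(used, par)
    if (noff > 0L) {
      kids <- sprintf("O%d_%d", f, seq_len(noff))
      tab <- rbind(tab, data.frame(id = kids, sire = par[1L], dam = par[2L],
                                   family = f, stringsAsFactors = FALSE))
      pool <- rbind(pool, data.frame(id = kids, origin = f))
    }
  }
  methods::new("Pedigree", tab = tab)
}

#' Expected additive relationship matrix from a pedigree
#'
#' Recursive (tabular) computation of the expected additive relatedness:
#' \code{A[i,i] = 1 + A[sire,dam]/2}, \code{A[i,j] = (A[j,sire] +
#' A[j,dam])/2}, founders unrelated and non-inbred.
#'
#' @param pedigree a [Pedigree-class] (rows ordered parents-first; a cyclic
#'   pedigree cannot be constructed).
#' @return Symmetric matrix with individual ids as dimnames.
#' @examples
#' ped <- simulatePedigree(simConfig(nFounders = 4, nFamilies = 2,
#'                                   offspringPerFamily = 1))
#' expectedRelatedness(ped)
#' @export
expectedRelatedness <- function(pedigree) {
  stopifnot(is(pedigree, "Pedigree"))
  t <- pedigree@tab
  n <- nrow(t)
  A <- matrix(0, n, n, dimnames = list(t$id, t$id))
  idx <- stats::setNames(seq_len(n), t$id)
  for (i in seq_len(n)) {
    if (is.na(t$sire[i])) {
      A[i, i] <- 1
    } else {
      s <- idx[[t$sire[i]]]; d <- idx[[t$dam[i]]]
      if (i > 1L) for (j in seq_len(i - 1L)) {
        A[i, j] <- A[j, i] <- 0.5 * (A[j, s] + A[j, d])
      }
      A[i, i] <- 1 + 0.5 * A[s, d]
    }
  }
  A
}

#' Place variant sites and gene-drop genotypes through the pedigree
#'
#' Each focal-genome site becomes polymorphic with probability \code{theta};
#' its founder alt-allele frequency is drawn from the configured uniform
#' law.  Founder haplotypes are i.i.d. Bernoulli(p) per site; every
#' offspring inherits one uniformly chosen allele from each parent per site
#' (no linkage/recombination model, appropriate for the sparse site
#' densities simulated here).
#'
#' @param genome the focal [ReferenceGenome-class].
#' @param pedigree a [Pedigree-class].
#' @param config a [SimConfig-class].
#' @return A [PopulationGenotypes-class]; \code{hapA} carries the paternal,
#'   \code{hapB} the maternal haplotype.
#' @export
assignVariants <- function(genome, pedigree, config) {
  stopifnot(is(genome, "ReferenceGenome"), is(pedigree, "Pedigree"),
            is(config, "SimConfig"))
  if (refDivergence(genome) != 0)
    stop("variants must be assigned on the focal genome")
  if (length(genome@sequences) != 1L)
    stop("population simulation expects a single-scaffold genome")
  t <- pedigree@tab
  n <- nrow(t)
  withr::with_seed(.opSeed(config, 2L), {
    L <- sum(Biostrings::width(genome@sequences))
    pos <- which(stats::runif(L) < config@theta)
    S <- length(pos)
    seqChars <- .seqToCodes(as.character(genome@sequences[[1L]]))
    refCode <- seqChars[pos]
    altCode <- ((refCode - 1L + sample.int(3L, S, replace = TRUE)) %% 4L) + 1L
    p <- stats::runif(S, config@alleleFreqRange[1], config@alleleFreqRange[2])
    hapA <- matrix(0L, S, n, dimnames = list(NULL, t$id))
    hapB <- matrix(0L, S, n, dimnames = list(NULL, t$id))
    idx <- stats::setNames(seq_len(n), t$id)
    for (i in seq_len(n)) {
      if (is.na(t$sire[i])) {
        hapA[, i] <- as.integer(stats::runif(S) < p)
        hapB[, i] <- as.integer(stats::runif(S) < p)
      } else {
        s <- idx[[t$sire[i]]]; d <- idx[[t$dam[i]]]
        fromA <- stats::runif(S) < 0.5
        hapA[, i] <- ifelse(fromA, hapA[, s], hapB[, s])
        fromA <- stats::runif(S) < 0.5
        hapB[, i] <- ifelse(fromA, hapA[, d], hapB[, d])
      }
    }
    sites <- data.frame(pos = pos, ref = .DNA[refCode], alt = .DNA[altCode],
                        p = p, stringsAsFactors = FALSE)
    methods::new("PopulationGenotypes", sites = sites, hapA = hapA,
                 hapB = hapB, individuals = t$id)
  })
}

## variant positions (0-based) and alt bases carried by one haplotype
.hapVariants <- function(pop, ind, hap = c("A", "B")) {
  hap <- match.arg(hap)
  h <- if (hap == "A") pop@hapA else pop@hapB
  j <- match(ind, pop@individuals)
  if (is.na(j)) stop("unknown individual: ", ind)
  carrier <- which(h[, j] == 1L)
  list(pos0 = pop@sites$pos[carrier] - 1L, alt = pop@sites$alt[carrier])
}
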