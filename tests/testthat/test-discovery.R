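# Tag-wise and pileup SNP calling.

# a small synthetic tag table mapped to its own source genome
makeTagWorld <- function(theta = 0.01, seed = 21, errorRate = 0,
                         meanTagDepth = 30, n = 6) {
  cfg <- simConfig(genomeLength = 6e4, nFounders = n, nFamilies = 0,
                   offspringPerFamily = 0, theta = theta,
                   meanTagDepth = meanTagDepth, errorRate = errorRate,
                   seed = seed)
  g <- generateGenome(cfg)
  ped <- simulatePedigree(cfg)
  pop <- assignVariants(g, ped, cfg)
  cut <- digestGenome(g, "GCWGC")
  tags <- simulateGbsTags(pop, g, cut, cfg)
  pm <- mapTagPairs(tags, g)
  list(cfg = cfg, g = g, pop = pop, tags = tags, pm = pm)
}

test_that("locus grouping drops rare tags and keeps shared cut sites", {
  w <- makeTagWorld()
  loci <- groupTagsByLocus(w$pm, minTagCount = 10L)
  # tags below the population-wide count threshold are gone
  key <- paste(loci$locusKey, loci$fwd, loci$rev)
  tot <- tapply(loci$count, key, sum)
  expect_true(all(tot >= 10))
  # a count-9 tag is excluded at threshold 10, kept at 9
  pm1 <- w$pm[w$pm$mapped, ][1:2, ]
  pm1$count <- c(9L, 20L)
  pm1$fwd[1] <- paste0("T", substr(pm1$fwd[1], 2, 64))  # make it distinct
  attr(pm1, "tagLength") <- 64L
  expect_identical(nrow(groupTagsByLocus(pm1, 10L)), 1L)
  expect_identical(nrow(groupTagsByLocus(pm1, 9L)), 2L)
  # individuals sharing a cut site share one locus
  l1 <- loci[loci$locusKey == loci$locusKey[1], ]
  expect_gte(length(unique(l1$individual)), 2L)
})

test_that("tag-wise caller emits sites only where tags differ", {
  # no variants: all tags identical at each locus, no sites
  w0 <- makeTagWorld(theta = 0)
  loci0 <- groupTagsByLocus(w0$pm)
  c0 <- callSnpsTagwise(loci0, w0$pop@individuals)
  expect_identical(nrow(c0), 0L)
  # with variants: emitted genotypes match the simulated truth
  w <- makeTagWorld(theta = 0.02, seed = 22)
  loci <- groupTagsByLocus(w$pm)
  calls <- callSnpsTagwise(loci, w$pop@individuals)
  expect_gt(nrow(calls), 0L)
  info <- siteInfo(calls)
  truth <- w$pop@sites
  hit <- match(info$pos, truth$pos)
  expect_false(anyNA(hit))  # error-free: every site is a true variant
  trueDos <- (w$pop@hapA + w$pop@hapB)[hit, , drop = FALSE]
  est <- dosages(calls)
  # the caller reports dosages relative to the locus minor allele, which may
  # be either the simulated ref or alt; orient before comparing.  The
  # population-wide minimum tag count can drop one allele of an individual
  # whose tag also carries a rare private variant (allele dropout), so we
  # demand high concordance and no opposite-homozygote errors rather than
  # perfection.
  nOK <- 0L; nTot <- 0L
  for (k in seq_len(nrow(info))) {
    td <- trueDos[k, ]
    ed <- est[k, ]
    ok <- !is.na(ed)
    if (info$alt[k] == truth$ref[hit[k]]) ed <- 2L - ed
    expect_true(all(abs(ed[ok] - td[ok]) <= 1L))
    nOK <- nOK + sum(ed[ok] == td[ok]); nTot <- nTot + sum(ok)
  }
  expect_gt(nOK / nTot, 0.97)
})

test_that("tag-wise MAF and locus-coverage thresholds are enforced", {
  w <- makeTagWorld(theta = 0.02, seed = 23, n = 10)
  loci <- groupTagsByLocus(w$pm)
  calls <- callSnpsTagwise(loci, w$pop@individuals)
  info <- siteInfo(calls)
  expect_true(all(info$maf >= 0.05))
  # low-frequency variant rejected: singleton het among 10 individuals has
  # MAF 0.05... use mnMAF above it
  strict <- callSnpsTagwise(loci, w$pop@individuals,
                            gbsDiscoveryParams(mnMAF = 0.3))
  expect_true(all(siteInfo(strict)$maf >= 0.3))
  expect_lt(nrow(strict), nrow(calls))
  # locus coverage: pretend twice as many individuals exist; coverage halves
  # and every locus fails mnLCov = 0.75
  fake <- c(w$pop@individuals, paste0("ghost", 1:10))
  none <- callSnpsTagwise(loci, fake)
  expect_identical(nrow(none), 0L)
})

test_that("maximum-posterior genotypes match brute-force enumeration", {
  set.seed(24)
  n <- 300
  dep <- sample(1:40, n, TRUE)
  nAlt <- rbinom(n, dep, runif(n))
  nOther <- rbinom(n, dep - nAlt, 0.05)
  nRef <- dep - nAlt - nOther
  err <- 10^runif(n, -4, -1.3)
  bruteCall <- function(nR, nA, nO, e) {
    # per-read likelihood products over the three genotypes
    pRead <- function(g) {
      pr <- switch(g, rr = c(1 - e, e / 3, e / 3),
                   ra = c((1 - e + e / 3) / 2, (1 - e + e / 3) / 2, e / 3),
                   aa = c(e / 3, 1 - e, e / 3))
      prod(rep(pr, times = c(nR, nA, nO)))
    }
    ls <- c(pRead("rr"), pRead("ra"), pRead("aa"))
    which.max(ls) - 1L
  }
  expected <- mapply(bruteCall, nRef, nAlt, nOther, err)
  got <- callGenotype(nRef, nAlt, nOther, err[1])
  # callGenotype takes a scalar error; loop to honour per-triple error
  got <- vapply(seq_len(n), function(i)
    callGenotype(nRef[i], nAlt[i], nOther[i], err[i]), integer(1))
  expect_identical(got, as.integer(expected))
  expect_identical(callGenotype(5, 5, 0, 0.01), 1L)
  expect_true(is.na(callGenotype(0, 0, 0, 0.01)))
})

test_that("pileup calling is exact on clean focal data", {
  cfg <- simConfig(genomeLength = 5e4, nFounders = 4, nFamilies = 2,
                   offspringPerFamily = 2, theta = 0.01, errorRate = 0,
                   meanReadDepth = 20, seed = 25)
  g <- generateGenome(cfg)
  ped <- simulatePedigree(cfg)
  pop <- assignVariants(g, ped, cfg)
  rs <- simulateReseqReads(pop, g, cfg)
  calls <- callSnpsPileup(rs, g)
  info <- siteInfo(calls)
  truth <- pop@sites
  # no false positives: every emitted site is a true simulated variant
  hit <- match(info$pos, truth$pos)
  expect_false(anyNA(hit))
  # genotype concordance at depth >= 4 (>= 2 expected per haplotype)
  trueDos <- (pop@hapA + pop@hapB)[hit, , drop = FALSE]
  est <- dosages(calls)
  dp <- depths(calls)
  ok <- !is.na(est) & dp >= 4L
  expect_identical(est[ok], trueDos[ok])
  # individuals with zero depth at an emitted site are missing
  expect_true(all(is.na(est[dp == 0L])))
})

test_that("pileup emits nothing when reads equal the reference", {
  cfg <- simConfig(genomeLength = 2e4, nFounders = 2, nFamilies = 0,
                   offspringPerFamily = 0, theta = 0, errorRate = 0,
                   meanReadDepth = 10, seed = 26)
  g <- generateGenome(cfg)
  pop <- assignVariants(g, simulatePedigree(cfg), cfg)
  rs <- simulateReseqReads(pop, g, cfg)
  expect_identical(nrow(callSnpsPileup(rs, g)), 0L)
})
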