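# Generator contracts: genome, pedigree, gene dropping, divergence, digestion,
# tag and read simulation.

test_that("focal genome honours length, alphabet, GC content and seed", {
  g <- generateGenome(simConfig(genomeLength = 1000, seed = 42))
  s <- as.character(refSequences(g)[[1]])
  expect_identical(nchar(s), 1000L)
  expect_true(grepl("^[ACGT]+$", s))
  g2 <- generateGenome(simConfig(genomeLength = 1000, seed = 42))
  expect_identical(s, as.character(refSequences(g2)[[1]]))
  # GC fraction inside the central 99.9% binomial interval for n = 1e5
  g3 <- generateGenome(simConfig(genomeLength = 1e5, gcContent = 0.5, seed = 7))
  nGC <- sum(Biostrings::alphabetFrequency(refSequences(g3))[1, c("C", "G")])
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 1e5, 0.5)
  expect_gte(nGC, bounds[1])
  expect_lte(nGC, bounds[2])
})

test_that("pedigree has the expected shape and degenerate cases", {
  ped <- simulatePedigree(simConfig(nFounders = 4, nFamilies = 2,
                                    offspringPerFamily = 3))
  t <- pedigreeTable(ped)
  expect_identical(nrow(t), 10L)
  expect_identical(sum(!is.na(t$sire)), 6L)
  expect_identical(length(founders(ped)), 4L)
  # founders only
  p0 <- simulatePedigree(simConfig(nFounders = 4, nFamilies = 2,
                                   offspringPerFamily = 0))
  expect_identical(nrow(pedigreeTable(p0)), 4L)
  # no individual is its own ancestor: parents always precede (validity);
  # a table violating that is rejected
  bad <- data.frame(id = c("a", "b"), sire = c("b", NA), dam = c("b", NA),
                    family = c(1L, NA))
  expect_error(new("Pedigree", tab = bad), "precede")
  expect_error(simulatePedigree(simConfig(nFounders = 2, nFamilies = 4,
                                          offspringPerFamily = 0)),
               "insufficient")
})

test_that("multi-generation families draw parents from distinct families", {
  ped <- simulatePedigree(simConfig(nFounders = 4, nFamilies = 4,
                                    offspringPerFamily = 2))
  t <- pedigreeTable(ped)
  kidsOf <- function(id) t$family[match(id, t$id)]
  for (f in 3:4) {
    par <- t[which(t$family == f), c("sire", "dam")][1, ]
    expect_false(identical(kidsOf(par$sire), kidsOf(par$dam)))
  }
})

test_that("gene dropping respects theta and Mendelian inheritance", {
  cfg <- tinyConfig(theta = 0)
  g <- generateGenome(cfg)
  ped <- simulatePedigree(cfg)
  expect_identical(nrow(assignVariants(g, ped, cfg)@sites), 0L)

  cfg <- simConfig(genomeLength = 2e5, theta = 0.005, nFounders = 4,
                   nFamilies = 3, offspringPerFamily = 2, seed = 3)
  g <- generateGenome(cfg)
  ped <- simulatePedigree(cfg)
  pop <- assignVariants(g, ped, cfg)
  # site count inside the central 99.9% binomial interval
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 2e5, 0.005)
  expect_gte(nrow(pop@sites), bounds[1])
  expect_lte(nrow(pop@sites), bounds[2])
  expect_false(is.unsorted(pop@sites$pos, strictly = TRUE))
  # Mendelian: every offspring allele occurs in the corresponding parent
  t <- pedigreeTable(ped)
  for (i in which(!is.na(t$sire))) {
    s <- match(t$sire[i], pop@individuals)
    d <- match(t$dam[i], pop@individuals)
    expect_true(all(pop@hapA[, i] == pop@hapA[, s] |
                    pop@hapA[, i] == pop@hapB[, s]))
    expect_true(all(pop@hapB[, i] == pop@hapA[, d] |
                    pop@hapB[, i] == pop@hapB[, d]))
  }
})

test_that("expected relatedness reproduces pedigree identities", {
  cfg <- simConfig(nFounders = 4, nFamilies = 2, offspringPerFamily = 2)
  ped <- simulatePedigree(cfg)
  A <- expectedRelatedness(ped)
  expect_true(isSymmetric(A))
  f <- founders(ped)
  expect_true(all(A[f, f][upper.tri(diag(4))] == 0))
  expect_true(all(diag(A) == 1))
  t <- pedigreeTable(ped)
  kid <- t$id[!is.na(t$sire)][1]
  expect_equal(A[kid, t$sire[match(kid, t$id)]], 0.5)
  sibs <- t$id[which(t$family == 1L)]
  expect_equal(A[sibs[1], sibs[2]], 0.5)
  # grandparent-grandchild = 0.25 via a three-generation pedigree
  ped3 <- simulatePedigree(simConfig(nFounders = 4, nFamilies = 3,
                                     offspringPerFamily = 2))
  t3 <- pedigreeTable(ped3)
  gkid <- t3$id[which(t3$family == 3)][1]
  gpar <- t3$sire[match(t3$sire[match(gkid, t3$id)], t3$id)]
  A3 <- expectedRelatedness(ped3)
  expect_equal(A3[gkid, gpar], 0.25)
})

test_that("reference divergence matches the requested proportion", {
  g <- generateGenome(simConfig(genomeLength = 1e5, seed = 5))
  expect_error(divergeReference(g, "x", 0.5), "0.25")
  d0 <- divergeReference(g, "same", 0)
  expect_identical(as.character(refSequences(d0)[[1]]),
                   as.character(refSequences(g)[[1]]))
  d <- divergeReference(g, "congeneric", 0.03, indelRate = 0, seed = 9)
  a <- strsplit(as.character(refSequences(g)[[1]]), "")[[1]]
  b <- strsplit(as.character(refSequences(d)[[1]]), "")[[1]]
  expect_identical(length(a), length(b))
  hd <- sum(a != b)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 1e5, 0.03)
  expect_gte(hd, bounds[1])
  expect_lte(hd, bounds[2])
  expect_identical(refDivergence(d), 0.03)
  # indels change length
  di <- divergeReference(g, "indel", 0.01, indelRate = 1e-3, seed = 9)
  expect_false(nchar(as.character(refSequences(di)[[1]])) == 1e5)
})

test_that("digestion finds IUPAC motif occurrences on both strands", {
  expect_identical(digestGenome(refFromString("AAGCAGCAA"))$pos, 3L)
  expect_identical(digestGenome(refFromString("GCTGC"))$pos, 1L)
  expect_identical(nrow(digestGenome(refFromString("ATTATTATTA"))), 0L)
  # non-palindromic motif is also found as its reverse complement
  hits <- digestGenome(refFromString("AACCCTAAA"), motif = "GGG")
  expect_identical(hits$strand, "-")
})

test_that("tag simulation applies variants, depth and errors as configured", {
  cfg <- tinyConfig(theta = 0, errorRate = 0, seed = 2)
  g <- generateGenome(cfg)
  ped <- simulatePedigree(cfg)
  pop <- assignVariants(g, ped, cfg)
  cut <- digestGenome(g, "GCWGC")
  tags <- simulateGbsTags(pop, g, cut, cfg)
  # error-free, variant-free tags equal the focal windows exactly
  s <- as.character(refSequences(g)[[1]])
  i <- which.max(tags$count)
  p <- tags$cutPos[i]
  expect_identical(tags$fwd[i], substr(s, p, p + 63))
  expect_identical(tags$rev[i],
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(s, p + 5 - 64, p + 4)))))
  # zero depth -> no tags
  cfg0 <- tinyConfig(meanTagDepth = 0)
  pop0 <- assignVariants(g, simulatePedigree(cfg0), cfg0)
  expect_identical(nrow(simulateGbsTags(pop0, g, cut, cfg0)), 0L)
  # determinism
  tags2 <- simulateGbsTags(pop, g, cut, cfg)
  expect_identical(tags, tags2)
})

test_that("heterozygous tag alleles appear at binomially balanced depth", {
  # one individual, one site inside a tag window, huge depth
  cfg <- simConfig(genomeLength = 5e4, nFounders = 2, nFamilies = 0,
                   offspringPerFamily = 0, theta = 0.01,
                   meanTagDepth = 400, errorRate = 0, seed = 8)
  g <- generateGenome(cfg)
  ped <- simulatePedigree(cfg)
  pop <- assignVariants(g, ped, cfg)
  cut <- digestGenome(g, "GCWGC")
  tags <- simulateGbsTags(pop, g, cut, cfg)
  # find a locus where the first individual is heterozygous inside the window
  het <- which(pop@hapA[, 1] != pop@hapB[, 1])
  pos <- pop@sites$pos[het]
  found <- FALSE
  for (p in unique(tags$cutPos)) {
    inWin <- pos[pos >= p & pos < p + 64]
    if (length(inWin) != 1L) next
    t1 <- tags[tags$cutPos == p & tags$individual == pop@individuals[1], ]
    if (sum(t1$count) < 200) next
    alleles <- substr(t1$fwd, inWin - p + 1L, inWin - p + 1L)
    cnt <- tapply(t1$count, alleles, sum)
    if (length(cnt) != 2L) next
    n <- sum(cnt)
    bounds <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5)
    expect_gte(min(cnt), bounds[1])
    expect_lte(max(cnt), bounds[2])
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("read simulation delivers Poisson-like coverage and exact reads", {
  cfg <- simConfig(genomeLength = 1e5, nFounders = 2, nFamilies = 0,
                   offspringPerFamily = 0, theta = 0, errorRate = 0,
                   meanReadDepth = 15, seed = 4)
  g <- generateGenome(cfg)
  pop <- assignVariants(g, simulatePedigree(cfg), cfg)
  rs <- simulateReseqReads(pop, g, cfg, individuals = pop@individuals[1])
  r <- rs[[1]]
  # mean coverage within 3 standard errors of 15
  totalBases <- (length(r$fwd) + length(r$rev)) * 150
  meanCov <- totalBases / 1e5
  # nPairs ~ Poisson(L * depth / 300); 3 SE on the implied mean coverage
  sePairs <- sqrt(1e5 * 15 / 300)
  expect_lt(abs(meanCov - 15), 3 * sePairs * 300 / 1e5)
  # with no errors and no variants every read is an exact genome substring
  s <- as.character(refSequences(g)[[1]])
  idx <- seq_len(20)
  expect_true(all(substring(s, r$start[idx], r$start[idx] + 149) ==
                    r$fwd[idx]))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r$rev[idx])))
  expect_true(all(substring(s, r$start[idx] + 350 - 150,
                            r$start[idx] + 349) == rc))
  # depth 0 -> no reads
  cfg0 <- simConfig(genomeLength = 1e4, nFounders = 2, nFamilies = 0,
                    offspringPerFamily = 0, theta = 0, meanReadDepth = 0)
  pop0 <- assignVariants(generateGenome(cfg0), simulatePedigree(cfg0), cfg0)
  rs0 <- simulateReseqReads(pop0, generateGenome(cfg0), cfg0,
                            individuals = pop0@individuals[1])
  expect_identical(length(rs0[[1]]$fwd), 0L)
  # determinism
  rs2 <- simulateReseqReads(pop, g, cfg, individuals = pop@individuals[1])
  expect_identical(r$fwd, rs2[[1]]$fwd)
  expect_identical(r$rev, rs2[[1]]$rev)
})
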