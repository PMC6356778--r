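# Diversity statistics: per-site pi, individual heterozygosity, the
# depth-aware relatedness matrix and its rescaling.

test_that("per-site pi follows the unbiased pairwise-difference estimator", {
  expect_identical(sitePi(c(0L, 0L, 0L)), 0)          # monomorphic
  # n0 = 2, n1 = 2: 6 allele pairs, 4 differ -> 2/3
  expect_equal(sitePi(c(1L, 1L)), 2 / 3)
  # large n at p = 0.5 approaches 0.5
  expect_equal(sitePi(rep(1L, 5000)), 0.5, tolerance = 1e-3)
  expect_true(is.na(sitePi(c(NA_integer_, NA_integer_))))  # n < 2 skipped
  gc <- callsFromMatrices(rbind(c(1L, 1L), c(0L, 0L)))
  expect_equal(unname(sitePi(gc)), c(2 / 3, 0))
})

test_that("individual heterozygosity is the proportional excess over HWE", {
  # O = E gives 0: two individuals, one site, both het -> p = 0.5,
  # E = 2 * .5 * .5 * 4/3 = 2/3 per site
  dos <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L))
  hs <- individualHs(callsFromMatrices(dos))
  expect_equal(unname(hs), rep((3 - 2) / 2, 2))  # O=3, E=3*(2/3)=2 -> 0.5
  # direct substitution: individual het at every site where E = half the
  # sites gives H_S = 1 (construct E = S/2 via p solving 2pq*n/(n-1) = 1/2)
  # easier: verify the formula numerically against a hand computation
  dos2 <- rbind(c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L))
  gc2 <- callsFromMatrices(dos2)
  p <- rowMeans(dos2) / 2
  E <- sum(2 * p * (1 - p) * 8 / 7)
  hsExp <- (c(2, 1, 1, 0) - E) / E
  expect_equal(unname(individualHs(gc2)), hsExp)
  # fewer hets than expected is negative
  dos3 <- rbind(c(0L, 2L, 0L, 2L), c(2L, 0L, 2L, 0L))
  expect_true(all(individualHs(callsFromMatrices(dos3)) < 0))
  # an individual with no callable site is NA
  dos4 <- rbind(c(1L, NA), c(1L, NA))
  expect_true(is.na(individualHs(callsFromMatrices(dos4))[2]))
})

test_that("relatedness scaling yields a unit diagonal and exact identities", {
  expect_identical(scaleRelatedness(diag(3)), diag(3))
  expect_equal(scaleRelatedness(matrix(c(4, 2, 2, 1), 2)),
               matrix(1, 2, 2))
  m <- matrix(c(2, 0.3, 0.3, 0.5), 2)
  s <- scaleRelatedness(m)
  expect_equal(diag(s), c(1, 1))
  expect_equal(s[1, 2], 0.3 / sqrt(2 * 0.5))
  bad <- matrix(c(-1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(scaleRelatedness(bad), "a")
})

test_that("duplicate samples look self-related and founders unrelated", {
  set.seed(41)
  # n is kept moderately large: with sample allele frequencies the GRM rows
  # centre to zero, biasing unrelated pairs by about -1/(n-1)
  S <- 3000; n <- 40
  p <- runif(S, 0.1, 0.5)
  # founders: independent genotypes; last column duplicates the first
  dos <- matrix(rbinom(S * n, 2, p), S, n)
  dos[, n] <- dos[, 1]
  poly <- rowSums(dos) > 0 & rowSums(dos) < 2 * n  # drop monomorphic draws
  dos <- dos[poly, ]; S <- nrow(dos)
  dep <- matrix(40L, S, n)
  adep <- matrix(rbinom(S * n, 40, as.vector(dos) / 2), S, n)
  gc <- callsFromMatrices(dos, dep = dep, adep = adep)
  rr <- relatednessMatrix(gc)
  M <- rawRelatedness(rr)
  # duplicate pair approaches self-relatedness
  expect_lt(abs(M[1, n] - M[1, 1]), 0.1)
  # unrelated founders: mean off-diagonal near zero
  off <- M[upper.tri(M)][-(n - 1)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("diagonal depth correction equals mean(1/d)", {
  set.seed(42)
  for (d in c(5L, 10L, 30L)) {
    S <- 2000; n <- 6
    p <- runif(S, 0.15, 0.5)
    dos <- matrix(rbinom(S * n, 2, p), S, n)
    poly <- rowSums(dos) > 0 & rowSums(dos) < 2 * n
    dos <- dos[poly, ]; S <- nrow(dos)
    dep <- matrix(d, S, n)
    adep <- matrix(rbinom(S * n, d, as.vector(dos) / 2), S, n)
    gc <- callsFromMatrices(dos, dep = dep, adep = adep)
    raw <- relatednessMatrix(gc, depthCorrect = FALSE)
    cor_ <- relatednessMatrix(gc, depthCorrect = TRUE)
    gap <- diag(rawRelatedness(raw)) - diag(rawRelatedness(cor_))
    expect_equal(unname(gap), rep(1 / d, n), tolerance = 1e-8)
    # and the corrected diagonal is near 1 for non-inbred genotypes
    expect_lt(abs(mean(diag(rawRelatedness(cor_))) - 1), 0.15)
  }
})

test_that("monomorphic sites are rejected by the estimator", {
  dos <- rbind(c(0L, 0L, 0L), c(1L, 0L, 1L))
  expect_error(relatednessMatrix(callsFromMatrices(dos)), "contract")
})

test_that("low-confidence pairs are flagged by shared-site count", {
  set.seed(43)
  dos <- cbind(matrix(rbinom(60 * 3, 2, 0.4), 60, 3), 1L)
  dos[, 1] <- 1L      # a het column keeps every site polymorphic
  dos[1:40, 4] <- NA  # only 20 shared sites with everyone
  gc <- callsFromMatrices(dos)
  rr <- relatednessMatrix(gc, minSharedSites = 50L)
  expect_true(all(rr@lowConfidence[1:3, 4]))
  expect_false(any(rr@lowConfidence[1:3, 1:3]))
})

test_that("mean pi at MAF-filtered sites matches the allele-frequency law", {
  # independent Monte-Carlo oracle: draw site frequencies from the
  # configured law, drop alleles through the same pedigree with a separate
  # minimal gene-dropper, apply the MAF filter, average the pi estimator
  cfg <- simConfig(genomeLength = 4e5, theta = 0.01, seed = 61)
  ped <- simulatePedigree(cfg)
  t <- pedigreeTable(ped)
  S <- 40000
  set.seed(62)
  p <- runif(S, 0.05, 0.5)
  hap <- array(0L, c(S, nrow(t), 2))
  for (i in seq_len(nrow(t))) {
    if (is.na(t$sire[i])) {
      hap[, i, 1] <- rbinom(S, 1, p); hap[, i, 2] <- rbinom(S, 1, p)
    } else {
      s <- match(t$sire[i], t$id); d <- match(t$dam[i], t$id)
      pick <- rbinom(S, 1, 0.5) + 1L
      hap[, i, 1] <- hap[cbind(seq_len(S), s, pick)]
      pick <- rbinom(S, 1, 0.5) + 1L
      hap[, i, 2] <- hap[cbind(seq_len(S), d, pick)]
    }
  }
  n1 <- rowSums(hap[, , 1]) + rowSums(hap[, , 2])
  n <- 2L * nrow(t)
  maf <- pmin(n1, n - n1) / n
  keep <- maf > 0.05
  oracle <- mean(2 * n1[keep] * (n - n1[keep]) / (n * (n - 1)))

  # package path: gene-drop, build calls from truth, filter on MAF, average
  g <- generateGenome(cfg)
  pop <- assignVariants(g, ped, cfg)
  dos <- pop@hapA + pop@hapB
  f <- rowMeans(dos) / 2
  gc <- callsFromMatrices(dos, dep = matrix(20L, nrow(dos), ncol(dos)),
                          adep = dos * 10L, pos = pop@sites$pos)
  gc <- gc[which(pmin(f, 1 - f) > 0.05), ]
  expect_equal(mean(sitePi(gc), na.rm = TRUE), oracle, tolerance = 0.02)
})
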