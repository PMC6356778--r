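# Seed-and-extend mapper: hit placement, tie handling, strand logic,
# brute-force equivalence, SAM output.

test_that("exact substrings map uniquely at their true position", {
  set.seed(11)
  g <- refFromString(randomDna(5000))
  s <- as.character(refSequences(g)[[1]])
  st <- c(1L, 101L, 2500L, 4937L)
  q <- substring(s, st, st + 63L)
  a <- mapCollection(q, g)
  expect_true(all(a$status == "unique"))
  expect_identical(a$pos, st)
  expect_true(all(a$nm == 0L))
  expect_true(all(a$strand == "+"))
  expect_identical(alignmentRate(a), 1)
})

test_that("reverse-complement queries map to the minus strand, same window", {
  set.seed(12)
  g <- refFromString(randomDna(3000))
  s <- as.character(refSequences(g)[[1]])
  q <- substr(s, 501, 600)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  a <- mapCollection(rc, g)
  expect_identical(a$status, "unique")
  expect_identical(a$pos, 501L)
  expect_identical(a$strand, "-")
})

test_that("queries occurring at two positions are ambiguous and excluded", {
  set.seed(13)
  core <- randomDna(80)
  g <- refFromString(paste0(randomDna(500), core, randomDna(500), core,
                            randomDna(500)))
  a <- mapCollection(core, g)
  expect_identical(a$status, "ambiguous")
  expect_true(is.na(a$pos))
  expect_identical(alignmentRate(a), 0)
})

test_that("mismatch allowance is ceiling(fraction x length)", {
  set.seed(14)
  g <- refFromString(randomDna(4000))
  s <- as.character(refSequences(g)[[1]])
  q <- substr(s, 1001, 1064)  # 64 bp: allowance is ceiling(6.4) = 7
  mutate <- function(q, k) {
    v <- strsplit(q, "")[[1]]
    pos <- round(seq(1, 64, length.out = k))
    v[pos] <- chartr("ACGT", "CGTA", v[pos])  # always a different base
    paste(v, collapse = "")
  }
  q7 <- mutate(q, 7)
  q8 <- mutate(q, 8)
  a <- mapCollection(c(q7, q8), g)
  expect_identical(a$status[1], "unique")
  expect_lte(a$nm[1], 7L)
  expect_identical(a$status[2], "unmapped")
})

test_that("mapper equals the brute-force oracle on small genomes", {
  set.seed(15)
  for (rep in 1:3) {
    g <- refFromString(randomDna(8000))
    s <- as.character(refSequences(g)[[1]])
    qs <- character(0)
    for (div in c(0, 0.05, 0.12)) {
      st <- sample(8000 - 150, 20)
      q <- substring(s, st, st + 149)
      if (div > 0) q <- vapply(q, function(x) {
        v <- strsplit(x, "")[[1]]
        hit <- runif(150) < div
        v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), TRUE)
        paste(v, collapse = "")
      }, "", USE.NAMES = FALSE)
      qs <- c(qs, q)
    }
    qs <- c(qs, vapply(1:10, function(i) randomDna(150), ""))  # unrelated
    m <- mapCollection(qs, g)
    b <- bruteForceMap(qs, g)
    expect_identical(m$status, b$status)
    expect_identical(m$pos, b$pos)
    expect_identical(m$strand[m$status == "unique"],
                     b$strand[b$status == "unique"])
    expect_identical(m$nm, b$nm)
  }
})

test_that("tag-pair mapping requires both mates unique on one scaffold", {
  set.seed(16)
  g <- refFromString(randomDna(6000))
  s <- as.character(refSequences(g)[[1]])
  tags <- data.frame(individual = "I01", locus = 1:3,
                     cutPos = c(1000L, 2000L, 3000L),
                     fwd = substring(s, c(1000, 2000, 3000),
                                     c(1063, 2063, 3063)),
                     rev = as.character(Biostrings::reverseComplement(
                       Biostrings::DNAStringSet(
                         substring(s, c(941, 1941, 2941),
                                   c(1004, 2004, 3004))))),
                     count = c(12L, 12L, 12L))
  attr(tags, "tagLength") <- 64L
  # break one reverse mate so it cannot map
  tags$rev[2] <- randomDna(64)
  pm <- mapTagPairs(tags, g)
  expect_identical(pm$mapped, c(TRUE, FALSE, TRUE))
  expect_identical(pm$posF[1], 1000L)
})

test_that("SAM output follows the minimal dialect", {
  set.seed(17)
  g <- refFromString(randomDna(2000))
  s <- as.character(refSequences(g)[[1]])
  qs <- c(ok = substr(s, 301, 400), bad = randomDna(100))
  a <- mapCollection(qs, g)
  f <- tempfile(fileext = ".sam")
  writeSam(a, qs, g, f)
  lines <- readLines(f)
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:2000$", lines)))
  rec <- strsplit(grep("^ok\t", lines, value = TRUE), "\t")[[1]]
  expect_identical(rec[2], "0")          # FLAG forward
  expect_identical(rec[3], "chr1")
  expect_identical(rec[4], "301")        # 1-based POS
  expect_identical(rec[5], "60")         # MAPQ for unique
  expect_identical(rec[6], "100M")
  expect_identical(rec[12], "NM:i:0")
  rec2 <- strsplit(grep("^bad\t", lines, value = TRUE), "\t")[[1]]
  expect_identical(rec2[2], "4")
  expect_identical(rec2[3], "*")
})
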