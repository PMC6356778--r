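# Small shared fixtures, built in code.

tinyConfig <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(genomeLength = 5e4, nFounders = 4L, nFamilies = 3L,
                   offspringPerFamily = 2L, theta = 0.01, seed = seed)
  defaults[names(args)] <- args
  do.call(simConfig, defaults)
}

# reference genome straight from a string
refFromString <- function(s, label = "focal", divergence = 0) {
  new("ReferenceGenome", label = label,
      sequences = Biostrings::DNAStringSet(c(chr1 = s)),
      divergence = divergence)
}

# random DNA string
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# GenotypeCalls straight from matrices with minimal site info
callsFromMatrices <- function(dos, dep = NULL, adep = NULL,
                              pos = NULL, nAlleles = 2L, mode = "reseq") {
  S <- nrow(dos)
  if (is.null(dep)) dep <- matrix(10L, S, ncol(dos))
  if (is.null(adep)) adep <- dos * 5L
  if (is.null(pos)) pos <- seq_len(S) * 1000L
  f <- rowMeans(dos, na.rm = TRUE) / 2
  info <- data.frame(scaffold = "chr1", pos = as.integer(pos),
                     ref = "A", alt = "G",
                     nAlleles = rep_len(as.integer(nAlleles), S),
                     maf = pmin(f, 1 - f))
  ids <- colnames(dos)
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(ncol(dos)))
  genotypeCalls(dos, dep, adep, info, ids, mode)
}
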