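## Focal genome generation, reference divergence, in-silico digestion.

.DNA <- c("A", "C", "G", "T")

.seqToCodes <- function(s) {
  map <- integer(128)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  map[utf8ToInt(s)]
}

.codesToSeq <- function(v) {
  pts <- c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"), utf8ToInt("T"))
  intToUtf8(pts[v])
}

#' Generate the focal reference genome
#'
#' Draws an i.i.d. random DNA sequence of the configured length and GC
#' content.  Deterministic given the configuration seed.
#'
#' @param config a [SimConfig-class].
#' @return A [ReferenceGenome-class] labelled \code{"focal"} with a single
#'   scaffold \code{"chr1"}.
#' @examples
#' g <- generateGenome(simConfig(genomeLength = 1000, seed = 42))
#' g
#' @export
generateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  gc <- config@gcContent
  if (gc < 0 || gc > 1) stop("invalid GC fraction")
  L <- config@genomeLength
  seq <- withr::with_seed(.opSeed(config, 0L), {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(.DNA, L, replace = TRUE, prob = probs), collapse = "")
  })
  new("ReferenceGenome", label = "focal",
      sequences = Biostrings::DNAStringSet(c(chr1 = seq)),
      divergence = 0)
}

#' Derive a diverged reference genome
#'
#' Substitutes each site independently with the given probability (always to
#' a different base) and optionally introduces small indels (1-3 bp), to
#' stand in for a reference genome from a related species.
#'
#' @param focal the focal [ReferenceGenome-class].
#' @param label label of the derived reference.
#' @param divergence per-site substitution proportion, in \[0, 0.25\].
#' @param indelRate per-site probability of initiating a small indel
#'   (default 0; the pipeline passes a rate that scales with divergence).
#' @param seed integer seed (default derives from label and divergence so
#'   repeated calls are reproducible).
#' @return A [ReferenceGenome-class] with \code{divergence} recorded.
#' @examples
#' g <- generateGenome(simConfig(genomeLength = 2000, seed = 1))
#' d <- divergeReference(g, "congeneric", 0.01)
#' refDivergence(d)
#' @export
divergeReference <- function(focal, label, divergence, indelRate = 0,
                             seed = NULL) {
  stopifnot(is(focal, "ReferenceGenome"))
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.25)
    stop("divergence proportion must lie in [0, 0.25]")
  if (is.null(seed))
    seed <- as.integer((sum(utf8ToInt(label)) * 7919 +
                        round(divergence * 1e6)) %% 2147483647)
  seqs <- withr::with_seed(seed, {
    lapply(as.character(focal@sequences), function(s) {
      v <- .seqToCodes(s)
      L <- length(v)
      if (divergence > 0) {
        hit <- which(stats::runif(L) < divergence)
        if (length(hit)) {
          shift <- sample.int(3L, length(hit), replace = TRUE)
          v[hit] <- ((v[hit] - 1L + shift) %% 4L) + 1L
        }
      }
      if (indelRate > 0) {
        ev <- which(stats::runif(L) < indelRate)
        if (length(ev)) {
          ins <- stats::runif(length(ev)) < 0.5
          len <- sample.int(3L, length(ev), replace = TRUE)
          pieces <- vector("list", 2L * length(ev) + 1L)
          last <- 1L
          pi <- 1L
          for (k in seq_along(ev)) {
            p <- ev[k]
            if (p < last) next
            pieces[[pi]] <- v[seq2(last, p - 1L)]
            pi <- pi + 1L
            if (ins[k]) {
              pieces[[pi]] <- sample.int(4L, len[k], replace = TRUE)
              pi <- pi + 1L
              last <- p
            } else {
              last <- min(L + 1L, p + len[k])
            }
          }
          pieces[[pi]] <- v[seq2(last, L)]
          v <- unlist(pieces, use.names = FALSE)
        }
      }
      .codesToSeq(v)
    })
  })
  new("ReferenceGenome", label = label,
      sequences = Biostrings::DNAStringSet(unlist(seqs)),
      divergence = divergence)
}

## integer sequence that is empty when from > to
seq2 <- function(from, to) if (from > to) integer(0) else from:to

#' Locate restriction cut sites
#'
#' Reports every occurrence of the recognition motif on both strands.  The
#' default ApeKI motif GCWGC is its own reverse complement, so a forward
#' scan covers both strands; for non-palindromic motifs, reverse-strand
#' matches are reported at the forward coordinate of the matched window.
#'
#' @param genome a [ReferenceGenome-class].
#' @param motif IUPAC recognition motif (default \code{"GCWGC"}).
#' @return data.frame with columns \code{scaffold}, \code{pos} (1-based
#'   motif start) and \code{strand}, sorted by position.
#' @examples
#' g <- new("ReferenceGenome", label = "focal",
#'          sequences = Biostrings::DNAStringSet(c(chr1 = "AAGCAGCAA")),
#'          divergence = 0)
#' digestGenome(g)
#' @export
digestGenome <- function(genome, motif = "GCWGC") {
  stopifnot(is(genome, "ReferenceGenome"))
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif)) stop("invalid IUPAC motif")
  pat <- Biostrings::DNAString(motif)
  rc <- Biostrings::reverseComplement(pat)
  out <- lapply(seq_along(genome@sequences), function(i) {
    subj <- genome@sequences[[i]]
    fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
    res <- data.frame(pos = fwd, strand = rep("+", length(fwd)))
    if (as.character(rc) != as.character(pat)) {
      rev <- Biostrings::start(Biostrings::matchPattern(rc, subj, fixed = FALSE))
      res <- rbind(res, data.frame(pos = rev, strand = rep("-", length(rev))))
    }
    if (!nrow(res)) return(cbind(scaffold = character(0), res))
    res <- res[order(res$pos), , drop = FALSE]
    cbind(scaffold = names(genome@sequences)[i], res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
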