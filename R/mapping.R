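## Deterministic seed-and-extend mapping (stand-in for a general-purpose
## short-read aligner), with a brute-force oracle for validation.

#' Mapping parameters
#'
#' @param seedLength exact-match seed length (upper bound; shorter
#'   pigeonhole seeds are used internally whenever needed to keep the
#'   search exhaustive).
#' @param maxMismatchFraction a hit is accepted when its Hamming distance
#'   is at most \code{ceiling(maxMismatchFraction * length)}.
#' @return validated parameter list.
#' @export
mapParams <- function(seedLength = 20L, maxMismatchFraction = 0.10) {
  if (seedLength < 1L) stop("seedLength must be positive")
  if (maxMismatchFraction < 0 || maxMismatchFraction >= 1)
    stop("maxMismatchFraction must lie in [0, 1)")
  structure(list(seedLength = as.integer(seedLength),
                 maxMismatchFraction = maxMismatchFraction),
            class = "MapParams")
}

## Concatenate scaffolds with N spacers so one index serves them all.
## Returns list(concat, offsets, names, spacer).
.concatRef <- function(reference, spacer = 200L) {
  seqs <- as.character(reference@sequences)
  if (!length(seqs)) stop("empty reference")
  pad <- strrep("N", spacer)
  concat <- paste(seqs, collapse = pad)
  w <- nchar(seqs)
  offsets <- cumsum(c(0L, utils::head(w + spacer, -1L)))
  list(concat = concat, offsets = offsets, names = names(seqs), widths = w)
}

#' Build a reusable mapping index for a reference
#'
#' @param reference a [ReferenceGenome-class].
#' @param params a [mapParams()] list.
#' @return Opaque index object accepted by [mapCollection()].
#' @export
buildRefIndex <- function(reference, params = mapParams()) {
  cr <- .concatRef(reference)
  ptr <- .cpp_build_ref_index(cr$concat, params$seedLength)
  structure(list(ptr = ptr, ref = cr, params = params,
                 label = reference@label),
            class = "RefIndex")
}

.globalToScaffold <- function(cr, start0) {
  scafIdx <- findInterval(start0, cr$offsets)
  local <- start0 - cr$offsets[scafIdx] + 1L
  list(scaffold = cr$names[scafIdx], pos = local)
}

#' Map a collection of queries to a reference
#'
#' Seed-and-extend alignment: exact seed hits propose candidate positions
#' which are extended ungapped over the full query on both strands and
#' scored by Hamming distance.  A query is \code{unique} when a single
#' best-scoring position exists within the mismatch allowance,
#' \code{ambiguous} when several positions tie for best (such queries are
#' excluded downstream), and \code{unmapped} otherwise.  The pigeonhole
#' seeding scheme makes the result identical to a brute-force scan of
#' every offset on both strands (see [bruteForceMap()]); the mapper
#' involves no randomness.
#'
#' @param queries character vector or \code{DNAStringSet}.
#' @param reference a [ReferenceGenome-class], or a prebuilt index from
#'   [buildRefIndex()].
#' @param params a [mapParams()] list (ignored when an index is supplied).
#' @return data.frame with columns \code{query}, \code{status},
#'   \code{scaffold}, \code{pos} (1-based leftmost), \code{strand},
#'   \code{nm}; attribute \code{"alignmentRate"} = uniquely mapped / total.
#' @examples
#' ref <- generateGenome(simConfig(genomeLength = 5000, seed = 3))
#' q <- substr(as.character(refSequences(ref)[[1]]), 101, 164)
#' mapCollection(q, ref)
#' @export
mapCollection <- function(queries, reference, params = mapParams()) {
  if (is(queries, "XStringSet")) queries <- as.character(queries)
  if (!length(queries)) stop("no queries supplied")
  if (is(reference, "RefIndex")) {
    idx <- reference
  } else {
    stopifnot(is(reference, "ReferenceGenome"))
    idx <- buildRefIndex(reference, params)
  }
  r <- .cpp_map_batch(idx$ptr, queries, idx$params$maxMismatchFraction)
  status <- c("unmapped", "unique", "ambiguous")[r$status + 1L]
  scaffold <- rep(NA_character_, length(queries))
  pos <- rep(NA_integer_, length(queries))
  ok <- which(r$status == 1L)
  if (length(ok)) {
    conv <- .globalToScaffold(idx$ref, r$start[ok])
    scaffold[ok] <- conv$scaffold
    pos[ok] <- conv$pos
  }
  out <- data.frame(query = if (is.null(names(queries)))
                      seq_along(queries) else names(queries),
                    status = status, scaffold = scaffold, pos = pos,
                    strand = ifelse(r$strand == 1L, "+", "-"), nm = r$nm,
                    stringsAsFactors = FALSE)
  attr(out, "alignmentRate") <- mean(status == "unique")
  attr(out, "reference") <- idx$label
  out
}

#' Alignment rate of a mapping result
#' @param alignments result of [mapCollection()] or [bruteForceMap()].
#' @return Fraction of queries with a unique best hit.
#' @export
alignmentRate <- function(alignments) attr(alignments, "alignmentRate")

#' Brute-force alignment oracle
#'
#' Scores every offset on both strands by Hamming distance, with the same
#' acceptance and tie rules as [mapCollection()].  Intended for validating
#' the mapper on small references; cost is O(queries x genome).
#'
#' @inheritParams mapCollection
#' @return Same shape as [mapCollection()].
#' @export
bruteForceMap <- function(queries, reference, params = mapParams()) {
  if (is(queries, "XStringSet")) queries <- as.character(queries)
  stopifnot(is(reference, "ReferenceGenome"))
  cr <- .concatRef(reference)
  r <- .cpp_brute_map(cr$concat, queries, params$maxMismatchFraction)
  status <- c("unmapped", "unique", "ambiguous")[r$status + 1L]
  scaffold <- rep(NA_character_, length(queries))
  pos <- rep(NA_integer_, length(queries))
  ok <- which(r$status == 1L)
  if (length(ok)) {
    conv <- .globalToScaffold(cr, r$start[ok])
    scaffold[ok] <- conv$scaffold
    pos[ok] <- conv$pos
  }
  out <- data.frame(query = if (is.null(names(queries)))
                      seq_along(queries) else names(queries),
                    status = status, scaffold = scaffold, pos = pos,
                    strand = ifelse(r$strand == 1L, "+", "-"), nm = r$nm,
                    stringsAsFactors = FALSE)
  attr(out, "alignmentRate") <- mean(status == "unique")
  out
}

#' Map GBS tag pairs
#'
#' Maps the distinct forward and reverse tag sequences of a tag table and
#' applies the pairing rule: a tag pair counts as mapped only when both
#' mates map uniquely to the same scaffold within 1 kb of each other.
#'
#' @param tags tag table from [simulateGbsTags()].
#' @param reference a [ReferenceGenome-class] or prebuilt [buildRefIndex()].
#' @param params a [mapParams()] list.
#' @param maxInsert maximum distance between mate positions (default 1000).
#' @return \code{tags} with added columns \code{mapped}, \code{scaffold},
#'   \code{posF}, \code{posR}, \code{strandF}; attribute
#'   \code{"nMappedTagPairs"} counts mapped tag rows weighted by nothing
#'   (distinct tag-pair sequences per individual are rows).
#' @export
mapTagPairs <- function(tags, reference, params = mapParams(),
                        maxInsert = 1000L) {
  uf <- unique(tags$fwd)
  ur <- unique(tags$rev)
  if (is(reference, "RefIndex")) idx <- reference
  else idx <- buildRefIndex(reference, params)
  mf <- mapCollection(uf, idx)
  mr <- mapCollection(ur, idx)
  fi <- match(tags$fwd, uf)
  ri <- match(tags$rev, ur)
  okF <- mf$status[fi] == "unique"
  okR <- mr$status[ri] == "unique"
  sameScaf <- !is.na(mf$scaffold[fi]) & !is.na(mr$scaffold[ri]) &
    mf$scaffold[fi] == mr$scaffold[ri]
  near <- abs(mf$pos[fi] - mr$pos[ri]) <= maxInsert
  mapped <- okF & okR & sameScaf & !is.na(near) & near
  out <- tags
  out$mapped <- mapped
  out$scaffold <- ifelse(mapped, mf$scaffold[fi], NA_character_)
  out$posF <- ifelse(mapped, mf$pos[fi], NA_integer_)
  out$posR <- ifelse(mapped, mr$pos[ri], NA_integer_)
  out$strandF <- ifelse(mapped, mf$strand[fi], NA_character_)
  out$strandR <- ifelse(mapped, mr$strand[ri], NA_character_)
  attr(out, "tagLength") <- attr(tags, "tagLength")
  attr(out, "reference") <- if (is(reference, "RefIndex")) reference$label
                            else reference@label
  out
}

## distinct mapped tag-pair sequence identities of a mapTagPairs() result
.mappedTagSet <- function(pairMap) {
  unique(paste(pairMap$fwd[pairMap$mapped], pairMap$rev[pairMap$mapped],
               sep = "|"))
}

#' Write alignments as SAM
#'
#' Minimal SAM dialect: \code{@SQ} header lines; FLAG (0 forward, 16
#' reverse, 4 unmapped/ambiguous), RNAME, 1-based POS, MAPQ 60 for unique
#' hits, CIGAR \code{<L>M}, and an NM tag with the mismatch count.
#'
#' @param alignments result of [mapCollection()].
#' @param queries the query sequences that were mapped (same order).
#' @param reference the [ReferenceGenome-class] mapped against.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeSam <- function(alignments, queries, reference, file) {
  if (is(queries, "XStringSet")) queries <- as.character(queries)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(reference@sequences))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference@sequences)[i],
                       Biostrings::width(reference@sequences)[i]), con)
  a <- alignments
  uniq <- a$status == "unique"
  flag <- ifelse(uniq & a$strand == "-", 16L, ifelse(uniq, 0L, 4L))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                   as.character(a$query), flag,
                   ifelse(uniq, a$scaffold, "*"),
                   ifelse(uniq, a$pos, 0L),
                   ifelse(uniq, 60L, 0L),
                   ifelse(uniq, paste0(nchar(queries), "M"), "*"),
                   queries, ifelse(is.na(a$nm), 0L, a$nm))
  writeLines(lines, con)
  invisible(file)
}
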