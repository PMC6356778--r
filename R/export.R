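## Plain-file interfaces: FASTA / FASTQ / TSV / VCF / report artifacts.

#' Write a reference genome as FASTA
#' @param genome a [ReferenceGenome-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeReferenceFasta <- function(genome, file) {
  Biostrings::writeXStringSet(genome@sequences, file)
  invisible(file)
}

#' Write simulated tag pairs as paired FASTQ
#'
#' Tag rows are expanded to reads (one record per read count) with mate
#' suffixes \code{/1} and \code{/2}; constant quality at the configured
#' error rate.
#'
#' @param tags result of [simulateGbsTags()].
#' @param prefix output path prefix; files \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq} are written.
#' @param qualChar quality character (default Q30).
#' @return The two file paths, invisibly.
#' @export
writeTagFastq <- function(tags, prefix, qualChar = .phredChar(0.001)) {
  idx <- rep(seq_len(nrow(tags)), tags$count)
  ids <- sprintf("%s_L%d_%d", tags$individual[idx], tags$locus[idx],
                 stats::ave(idx, idx, FUN = seq_along))
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  .writeFastq(ids, tags$fwd[idx], qualChar, f1, "/1")
  .writeFastq(ids, tags$rev[idx], qualChar, f2, "/2")
  invisible(c(f1, f2))
}

#' Write simulated resequencing reads as paired FASTQ
#' @param readSet result of [simulateReseqReads()].
#' @param prefix output path prefix (per-individual mate files are
#'   written as \code{<prefix>_<individual>_[12].fastq}).
#' @return Written paths, invisibly.
#' @export
writeReadFastq <- function(readSet, prefix) {
  qc <- attr(readSet, "qualChar") %||% .phredChar(0.001)
  out <- character(0)
  for (ind in names(readSet)) {
    rs <- readSet[[ind]]
    ids <- sprintf("%s_%d", ind, seq_along(rs$fwd))
    f1 <- sprintf("%s_%s_1.fastq", prefix, ind)
    f2 <- sprintf("%s_%s_2.fastq", prefix, ind)
    .writeFastq(ids, rs$fwd, qc, f1, "/1")
    .writeFastq(ids, rs$rev, qc, f2, "/2")
    out <- c(out, f1, f2)
  }
  invisible(out)
}

.writeFastq <- function(ids, seqs, qualChar, file, suffix = "") {
  qual <- strrep(qualChar, nchar(seqs))
  writeLines(paste0("@", ids, suffix, "\n", seqs, "\n+\n", qual), file)
}

#' Write genotype calls as VCF 4.2 (GT and DP per sample)
#'
#' Uses \pkg{VariantAnnotation} when available; the file carries one
#' record per site with genotype and per-call depth.
#'
#' @param calls a [GenotypeCalls-class].
#' @param file output path (\code{.vcf}).
#' @return The written path, invisibly.
#' @export
exportVcf <- function(calls, file) {
  stopifnot(is(calls, "GenotypeCalls"))
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("exportVcf requires the VariantAnnotation package")
  info <- siteInfo(calls)
  dos <- dosages(calls)
  gt <- matrix("./.", nrow(dos), ncol(dos), dimnames = dimnames(dos))
  gt[!is.na(dos) & dos == 0L] <- "0/0"
  gt[!is.na(dos) & dos == 1L] <- "0/1"
  gt[!is.na(dos) & dos == 2L] <- "1/1"
  dp <- depths(calls)
  rr <- GenomicRanges::GRanges(info$scaffold,
                               IRanges::IRanges(info$pos, width = 1L))
  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_len(ncol(dos)),
                                   row.names = colnames(dos)),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(info$ref),
      ALT = methods::as(as.list(Biostrings::DNAStringSet(info$alt)),
                        "DNAStringSetList"),
      QUAL = rep(NA_real_, nrow(info)),
      FILTER = rep("PASS", nrow(info))),
    geno = S4Vectors::SimpleList(GT = gt, DP = dp))
  VariantAnnotation::geno(VariantAnnotation::header(vcf)) <-
    S4Vectors::DataFrame(Number = c("1", "1"), Type = c("String", "Integer"),
                         Description = c("Genotype", "Read depth"),
                         row.names = c("GT", "DP"))
  VariantAnnotation::writeVcf(vcf, file)
  invisible(file)
}

#' Write genotype calls as a TSV table
#' @param calls a [GenotypeCalls-class].
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeCallsTsv <- function(calls, file) {
  info <- siteInfo(calls)
  dos <- dosages(calls)
  utils::write.table(cbind(info, as.data.frame(dos)), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

## full artifact tree for runComparison(outdir=)
.writeRunArtifacts <- function(result, refs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result@report, file.path(outdir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ped <- pedigreeTable(result@details$pedigree)
  utils::write.table(ped, file.path(outdir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  A <- result@details$expectedRelatedness
  utils::write.table(data.frame(id = rownames(A), A, check.names = FALSE),
                     file.path(outdir, "expected_relatedness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pop <- result@details$population
  utils::write.table(pop@sites, file.path(outdir, "true_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (rn in names(refs)) {
    rd <- file.path(outdir, rn)
    dir.create(rd, showWarnings = FALSE)
    writeReferenceFasta(refs[[rn]], file.path(rd, paste0(rn, ".fasta")))
    for (mode in c("gbs", "reseq")) {
      d <- result@details[[mode]][[rn]]
      if (is.null(d)) next
      writeCallsTsv(d$calls, file.path(rd, paste0(mode, "_filtered.tsv")))
      if (requireNamespace("VariantAnnotation", quietly = TRUE))
        try(exportVcf(d$calls, file.path(rd, paste0(mode, "_filtered.vcf"))),
            silent = TRUE)
      utils::write.table(d$audit, file.path(rd, paste0(mode, "_audit.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(outdir)
}
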