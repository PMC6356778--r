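## Accessors and show methods.

#' @rdname ReferenceGenome-class
#' @export
setMethod("refLabel", "ReferenceGenome", function(x) x@label)

#' @rdname ReferenceGenome-class
#' @export
setMethod("refSequences", "ReferenceGenome", function(x) x@sequences)

#' @rdname ReferenceGenome-class
#' @export
setMethod("refDivergence", "ReferenceGenome", function(x) x@divergence)

setMethod("show", "ReferenceGenome", function(object) {
  cat(sprintf("ReferenceGenome '%s': %d scaffold(s), %s bp, divergence %.4g\n",
              object@label, length(object@sequences),
              format(sum(Biostrings::width(object@sequences)), big.mark = ","),
              object@divergence))
})

#' @rdname Pedigree-class
#' @export
setMethod("pedigreeTable", "Pedigree", function(x) x@tab)

#' @rdname Pedigree-class
#' @export
setMethod("founders", "Pedigree", function(x) x@tab$id[is.na(x@tab$sire)])

#' @rdname Pedigree-class
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@tab))

setMethod("show", "Pedigree", function(object) {
  t <- object@tab
  cat(sprintf("Pedigree: %d individuals (%d founders, %d families)\n",
              nrow(t), sum(is.na(t$sire)),
              length(unique(stats::na.omit(t$family)))))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  genome: %s bp, GC %.2f\n",
              format(object@genomeLength, big.mark = ","), object@gcContent))
  cat(sprintf("  pedigree: %d founders, %d families x %d offspring\n",
              object@nFounders, object@nFamilies, object@offspringPerFamily))
  cat(sprintf("  theta: %g, founder MAF U(%g, %g)\n", object@theta,
              object@alleleFreqRange[1], object@alleleFreqRange[2]))
  cat(sprintf("  divergence ladder: %s\n",
              paste(sprintf("%s=%g", names(object@divergenceLevels),
                            object@divergenceLevels), collapse = ", ")))
  cat(sprintf("  GBS: motif %s, %d bp tags, %gx tag depth\n", object@gbsMotif,
              object@tagLength, object@meanTagDepth))
  cat(sprintf("  reseq: 2x%d bp, %gx coverage, %d bp fragments\n",
              object@readLength, object@meanReadDepth, object@fragmentLength))
  cat(sprintf("  error rate: %g, seed: %d\n", object@errorRate, object@seed))
})

setMethod("show", "PopulationGenotypes", function(object) {
  cat(sprintf("PopulationGenotypes: %d variant sites x %d individuals\n",
              nrow(object@sites), length(object@individuals)))
})

#' @rdname GenotypeCalls-class
#' @export
setMethod("dosages", "GenotypeCalls", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("depths", "GenotypeCalls", function(x)
  SummarizedExperiment::assay(x, "depth"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("altDepths", "GenotypeCalls", function(x)
  SummarizedExperiment::assay(x, "altDepth"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("siteInfo", "GenotypeCalls", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname RelatednessResult-class
#' @export
setMethod("rawRelatedness", "RelatednessResult", function(x) x@raw)

#' @rdname RelatednessResult-class
#' @export
setMethod("scaledRelatedness", "RelatednessResult", function(x) {
  if (!length(x@scaled)) stop("no scaled matrix; apply scaleRelatedness() first")
  x@scaled
})

setMethod("show", "RelatednessResult", function(object) {
  cat(sprintf("RelatednessResult: %d individuals%s\n", nrow(object@raw),
              if (length(object@scaled)) " (scaled)" else " (raw only)"))
  off <- object@raw[upper.tri(object@raw)]
  cat(sprintf("  raw off-diagonal mean %.3f, diagonal mean %.3f\n",
              mean(off), mean(diag(object@raw))))
})
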