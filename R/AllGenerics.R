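## Generics, accessors and show methods.

#' @rdname DomainSegmentation-class
#' @param object,x a package object.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname DomainSegmentation-class
#' @export
setMethod("segmentTable", "DomainSegmentation", function(x) x@segments)

#' @rdname DomainSegmentation-class
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @rdname DomainSegmentation-class
#' @export
setMethod("refLength", "DomainSegmentation", function(x) x@refLength)

#' Per-residue labels of a segmentation or domain map
#'
#' For a \code{DomainSegmentation}, expands the segment table into one label
#' per reference residue; for a \code{DomainMap}, returns the per-query-residue
#' labels.
#'
#' @param x a DomainSegmentation or DomainMap.
#' @return Character vector of domain labels.
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' @rdname residueLabels
#' @export
setMethod("residueLabels", "DomainSegmentation", function(x) {
  s <- x@segments
  rep(s$label, s$end - s$start + 1L)
})

#' @rdname residueLabels
#' @export
setMethod("residueLabels", "DomainMap", function(x) x@labels)

#' @rdname DomainMap-class
#' @param x a DomainMap.
#' @export
setGeneric("isStructured", function(x) standardGeneric("isStructured"))

#' @rdname DomainMap-class
#' @export
setMethod("isStructured", "DomainMap", function(x) x@structured)

#' @rdname DomainMap-class
#' @export
setGeneric("isPore", function(x) standardGeneric("isPore"))

#' @rdname DomainMap-class
#' @export
setMethod("isPore", "DomainMap", function(x) x@pore)

#' Residue counts per domain and partition
#'
#' @param x a DomainSegmentation or DomainMap.
#' @return Named list with per-domain counts (`domains`) and per-partition
#'   counts (`partitions`: structured, unstructured, pore, nonpore, CL, CT).
#' @export
setGeneric("domainLengths", function(x) standardGeneric("domainLengths"))

.lengthsFromLabels <- function(lab) {
  dom <- vapply(.DOMAIN_LABELS, function(d) sum(lab == d), integer(1))
  list(domains = dom,
       partitions = c(
         structured = sum(lab %in% .STRUCTURED_LABELS),
         unstructured = sum(lab %in% .UNSTRUCTURED_LABELS),
         pore = sum(lab %in% .PORE_LABELS),
         nonpore = sum(lab %in% .NONPORE_LABELS),
         CL = sum(lab == "CL"),
         CT = sum(lab == "CT")))
}

#' @rdname domainLengths
#' @export
setMethod("domainLengths", "DomainSegmentation",
          function(x) .lengthsFromLabels(residueLabels(x)))

#' @rdname domainLengths
#' @export
setMethod("domainLengths", "DomainMap",
          function(x) .lengthsFromLabels(x@labels))

#' @rdname ResidueAlignmentMap-class
#' @param x a ResidueAlignmentMap.
#' @export
setGeneric("alignmentMap", function(x) standardGeneric("alignmentMap"))

#' @rdname ResidueAlignmentMap-class
#' @export
setMethod("alignmentMap", "ResidueAlignmentMap", function(x) x@map)

#' @rdname WeightedAlignment-class
#' @param x a WeightedAlignment.
#' @export
setGeneric("seqWeights", function(x) standardGeneric("seqWeights"))

#' @rdname WeightedAlignment-class
#' @export
setMethod("seqWeights", "WeightedAlignment", function(x) x@weights)

#' @rdname WeightedAlignment-class
#' @export
setGeneric("effectiveSequences", function(x) standardGeneric("effectiveSequences"))

#' @rdname WeightedAlignment-class
#' @export
setMethod("effectiveSequences", "WeightedAlignment", function(x) x@Meff)

#' @rdname WeightedAlignment-class
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname WeightedAlignment-class
#' @export
setMethod("alignmentMatrix", "WeightedAlignment", function(x) x@aln)

#' @rdname ConservationProfile-class
#' @param x a ConservationProfile.
#' @export
setGeneric("DiValues", function(x) standardGeneric("DiValues"))

#' @rdname ConservationProfile-class
#' @export
setMethod("DiValues", "ConservationProfile",
          function(x) stats::setNames(x@Di, x@positions))

#' @rdname SectorDecomposition-class
#' @param x a SectorDecomposition.
#' @export
setGeneric("icResidues", function(x) standardGeneric("icResidues"))

#' @rdname SectorDecomposition-class
#' @export
setMethod("icResidues", "SectorDecomposition",
          function(x) lapply(x@icResidues, function(i) x@positions[i]))

#' @rdname SectorDecomposition-class
#' @export
setGeneric("sectorResidues", function(x) standardGeneric("sectorResidues"))

#' @rdname SectorDecomposition-class
#' @export
setMethod("sectorResidues", "SectorDecomposition", function(x) x@sectorResidues)

#' @rdname SectorDecomposition-class
#' @export
setGeneric("nSignificantModes", function(x) standardGeneric("nSignificantModes"))

#' @rdname SectorDecomposition-class
#' @export
setMethod("nSignificantModes", "SectorDecomposition", function(x) x@k)

#' @rdname EnrichmentResult-class
#' @param x an EnrichmentResult or TTestResult.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname EnrichmentResult-class
#' @export
setMethod("pValue", "EnrichmentResult", function(x) x@pValue)

#' @rdname TTestResult-class
#' @export
setMethod("pValue", "TTestResult", function(x) x@pValue)

## ---- show methods -------------------------------------------------------

setMethod("show", "DomainSegmentation", function(object) {
  cat("DomainSegmentation over", object@refLength, "reference residues\n")
  s <- object@segments
  cat(paste0(" ", s$label, " [", s$start, "-", s$end, "]", collapse = "\n"),
      "\n")
})

setMethod("show", "ResidueAlignmentMap", function(object) {
  n <- length(object@map)
  cat("ResidueAlignmentMap:", object@queryId, "->", object@refId, "\n",
      n, "query residues,", sum(!is.na(object@map)), "mapped; score",
      format(object@score), "\n")
})

setMethod("show", "DomainMap", function(object) {
  L <- domainLengths(object)
  cat("DomainMap for", object@queryId, "(", length(object@labels),
      "residues )\n structured:", L$partitions["structured"],
      " unstructured:", L$partitions["unstructured"],
      " pore:", L$partitions["pore"],
      " nonpore:", L$partitions["nonpore"], "\n")
})

setMethod("show", "WeightedAlignment", function(object) {
  cat("WeightedAlignment:", nrow(object@aln), "sequences x",
      ncol(object@aln), "columns\n")
  if (length(object@weights))
    cat(" Meff =", format(object@Meff, digits = 4),
        "; mean pairwise identity =",
        format(object@meanPairwiseIdentity, digits = 3), "\n")
  else cat(" (weights not yet computed)\n")
})

setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile over", length(object@positions), "positions;",
      "mean Di =", format(mean(object@Di), digits = 4), "\n")
})

setMethod("show", "SectorDecomposition", function(object) {
  cat("SectorDecomposition:", nrow(object@Ctilde), "positions;",
      object@k, "significant eigenmodes;",
      length(object@sectors), "sector(s)\n")
  if (length(object@sectors))
    for (i in seq_along(object@sectors))
      cat(" sector", i, ": ICs",
          paste(object@sectors[[i]], collapse = ","), "-",
          length(object@sectorResidues[[i]]), "residues\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult (", object@partition, ")\n", sep = "")
  print(object@table)
  cat(" two-sided exact p =", format(object@pValue, digits = 4), "\n",
      "ratios:", paste(names(object@ratios), "=",
                       format(object@ratios, digits = 3), collapse = "; "),
      "\n")
})

setMethod("show", "TTestResult", function(object) {
  cat("Unpaired t-test: t =", format(object@statistic, digits = 4),
      ", df =", object@df, ", p =", format(object@pValue, digits = 4), "\n")
})
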