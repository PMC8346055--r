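## S4 class definitions and validity methods.

.DOMAIN_LABELS <- c("NT", "M1", "E1", "CL", "M2", "M3", "E2", "M4", "CT")
.STRUCTURED_LABELS <- c("NT", "M1", "E1", "M2", "M3", "E2", "M4")
.PORE_LABELS <- c("NT", "M1", "E1", "M2")
.NONPORE_LABELS <- c("M3", "E2", "M4")
.UNSTRUCTURED_LABELS <- c("CL", "CT")

#' Domain label sets
#'
#' Canonical connexin domain labels and their partition sets. The pore
#' partition (NT, M1, E1, M2) lines the channel lumen; the non-pore
#' partition (M3, E2, M4) faces the channel periphery; CL and CT are the
#' structurally unresolved (unstructured) domains.
#'
#' @return Character vector of labels.
#' @export
#' @rdname domainLabelSets
domainLabels <- function() .DOMAIN_LABELS

#' @export
#' @rdname domainLabelSets
structuredLabels <- function() .STRUCTURED_LABELS

#' @export
#' @rdname domainLabelSets
poreLabels <- function() .PORE_LABELS

#' @export
#' @rdname domainLabelSets
nonPoreLabels <- function() .NONPORE_LABELS

#' @export
#' @rdname domainLabelSets
unstructuredLabels <- function() .UNSTRUCTURED_LABELS

#' DomainSegmentation: structure-derived domain boundaries
#'
#' Ordered, contiguous segments (label, start, end) covering residues
#' 1..refLength of the reference connexin (sheep Cx46 numbering by default).
#'
#' @slot segments data.frame with columns label, start, end.
#' @slot refLength integer, reference protein length.
#' @export
setClass("DomainSegmentation",
  representation(segments = "data.frame", refLength = "integer"))

setValidity("DomainSegmentation", function(object) {
  s <- object@segments
  msgs <- character()
  if (!all(c("label", "start", "end") %in% names(s)))
    return("segments must have columns label, start, end")
  if (!all(s$label %in% .DOMAIN_LABELS))
    msgs <- c(msgs, paste("unknown domain label:",
                          paste(setdiff(s$label, .DOMAIN_LABELS), collapse = ", ")))
  if (nrow(s) > 0) {
    if (s$start[1] != 1L)
      msgs <- c(msgs, "first segment must start at residue 1")
    if (s$end[nrow(s)] != object@refLength)
      msgs <- c(msgs, "last segment must end at refLength")
    if (any(s$end < s$start))
      msgs <- c(msgs, "segment end before start")
    if (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)] + 1L))
      msgs <- c(msgs, "segments must be contiguous and non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' ResidueAlignmentMap: query-to-reference residue mapping
#'
#' Result of a pairwise global alignment of a query connexin against the
#' reference. `map[i]` is the reference residue aligned to query residue i,
#' or NA when the query residue is aligned to a gap (insertion relative to
#' the reference). The mapping is colinear: strictly increasing over mapped
#' positions.
#'
#' @slot queryId,refId character sequence identifiers.
#' @slot map integer vector, one entry per query residue (NA = gap).
#' @slot refLength integer length of the reference sequence.
#' @slot score numeric alignment score.
#' @slot alignedQuery,alignedRef character, gapped alignment rows.
#' @export
setClass("ResidueAlignmentMap",
  representation(queryId = "character", refId = "character",
                 map = "integer", refLength = "integer",
                 score = "numeric",
                 alignedQuery = "character", alignedRef = "character"))

setValidity("ResidueAlignmentMap", function(object) {
  m <- object@map[!is.na(object@map)]
  msgs <- character()
  if (length(m) && any(diff(m) <= 0))
    msgs <- c(msgs, "alignment map must be strictly increasing (colinear)")
  if (length(m) && (min(m) < 1L || max(m) > object@refLength))
    msgs <- c(msgs, "mapped reference indices out of range")
  if (length(msgs)) msgs else TRUE
})

#' DomainMap: per-residue domain annotation of a query connexin
#'
#' @slot labels character vector, one domain label per query residue.
#' @slot structured logical per residue.
#' @slot pore logical per residue; NA for unstructured residues.
#' @slot segmentation the reference DomainSegmentation used.
#' @slot queryId character.
#' @export
setClass("DomainMap",
  representation(labels = "character", structured = "logical",
                 pore = "logical", segmentation = "DomainSegmentation",
                 queryId = "character"))

setValidity("DomainMap", function(object) {
  n <- length(object@labels)
  msgs <- character()
  if (length(object@structured) != n || length(object@pore) != n)
    msgs <- c(msgs, "labels, structured and pore must have equal length")
  if (!all(object@labels %in% .DOMAIN_LABELS))
    msgs <- c(msgs, "unknown domain label in map")
  str_ok <- object@structured == (object@labels %in% .STRUCTURED_LABELS)
  if (!all(str_ok))
    msgs <- c(msgs, "structured flags inconsistent with labels")
  pore_exp <- ifelse(object@labels %in% .STRUCTURED_LABELS,
                     object@labels %in% .PORE_LABELS, NA)
  if (!identical(as.logical(pore_exp), object@pore))
    msgs <- c(msgs, "pore flags inconsistent with labels")
  if (length(msgs)) msgs else TRUE
})

#' SCAConfig: parameters of the conservation/coupling analysis
#'
#' @slot backgroundFreqs numeric(20) background distribution q, sums to 1.
#' @slot lambda numeric pseudocount fraction in (0,1); default 0.03.
#' @slot deltaWeight numeric sequence-weight identity threshold; default 0.8.
#' @slot refIdMin,refIdMax numeric fractional-identity bounds to the
#'   reference for keeping a sequence; defaults 0.2 and 0.85.
#' @slot maxGapSeq,maxGapCol numeric maximum gap fraction per sequence and
#'   per column; defaults 0.4 and 0.2.
#' @slot nRandomTrials integer randomization trials for the eigenmode null;
#'   default 10.
#' @slot icTail numeric tail fraction of the loading CDF defining IC
#'   residues; default 0.05.
#' @slot includeFirstMode logical; include the first (global conservation)
#'   eigenmode among candidates for significance/ICA. Default FALSE.
#' @slot icaTol,icaMaxIter ICA convergence tolerance and iteration cap.
#' @export
setClass("SCAConfig",
  representation(backgroundFreqs = "numeric", lambda = "numeric",
                 deltaWeight = "numeric", refIdMin = "numeric",
                 refIdMax = "numeric", maxGapSeq = "numeric",
                 maxGapCol = "numeric", nRandomTrials = "integer",
                 icTail = "numeric", includeFirstMode = "logical",
                 icaTol = "numeric", icaMaxIter = "integer"))

setValidity("SCAConfig", function(object) {
  msgs <- character()
  if (length(object@backgroundFreqs) != 20L ||
      abs(sum(object@backgroundFreqs) - 1) > 1e-8 ||
      any(object@backgroundFreqs <= 0))
    msgs <- c(msgs, "backgroundFreqs must be 20 positive values summing to 1")
  if (object@lambda <= 0 || object@lambda >= 1)
    msgs <- c(msgs, "lambda must be in (0,1)")
  if (object@deltaWeight <= 0 || object@deltaWeight >= 1)
    msgs <- c(msgs, "deltaWeight must be in (0,1)")
  if (object@refIdMin >= object@refIdMax)
    msgs <- c(msgs, "refIdMin must be below refIdMax")
  if (object@icTail <= 0 || object@icTail >= 1)
    msgs <- c(msgs, "icTail must be in (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' WeightedAlignment: filtered MSA with sequence weights
#'
#' Alignment restricted to reference-mapped (structured) columns, with
#' per-sequence weights w_s = 1 / (number of sequences at fractional
#' identity >= delta, self included) and effective sequence count
#' Meff = sum(w_s).
#'
#' @slot aln character matrix (sequences x columns) over the amino-acid +
#'   gap alphabet.
#' @slot refPositions integer reference residue index of each column.
#' @slot referenceId character id of the reference row.
#' @slot weights numeric per-sequence weights (length 0 until computed).
#' @slot Meff numeric effective sequence count (NA until computed).
#' @slot meanPairwiseIdentity numeric average pairwise fractional identity.
#' @export
setClass("WeightedAlignment",
  representation(aln = "matrix", refPositions = "integer",
                 referenceId = "character", weights = "numeric",
                 Meff = "numeric", meanPairwiseIdentity = "numeric"))

setValidity("WeightedAlignment", function(object) {
  msgs <- character()
  if (ncol(object@aln) != length(object@refPositions))
    msgs <- c(msgs, "refPositions must have one entry per column")
  if (length(object@weights)) {
    if (length(object@weights) != nrow(object@aln))
      msgs <- c(msgs, "one weight per sequence required")
    if (any(object@weights <= 0 | object@weights > 1))
      msgs <- c(msgs, "weights must lie in (0, 1]")
    if (!is.na(object@Meff) &&
        (object@Meff < 1 - 1e-9 ||
         object@Meff > nrow(object@aln) + 1e-9))
      msgs <- c(msgs, "Meff must lie in [1, number of sequences]")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConservationProfile: per-position Kullback-Leibler conservation
#'
#' @slot positions integer reference residue indices.
#' @slot freqs numeric matrix (positions x 20) of regularised weighted
#'   amino-acid frequencies.
#' @slot Di numeric per-position relative entropy vs the background.
#' @slot background numeric(20) background distribution used.
#' @slot lambda numeric pseudocount used.
#' @export
setClass("ConservationProfile",
  representation(positions = "integer", freqs = "matrix", Di = "numeric",
                 background = "numeric", lambda = "numeric"))

setValidity("ConservationProfile", function(object) {
  msgs <- character()
  if (nrow(object@freqs) != length(object@positions) ||
      length(object@Di) != length(object@positions))
    msgs <- c(msgs, "freqs and Di must align with positions")
  if (any(object@Di < -1e-12))
    msgs <- c(msgs, "Di must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SectorDecomposition: eigenmodes, ICs and sectors of the coupling matrix
#'
#' @slot Ctilde numeric symmetric coupling matrix (positions x positions).
#' @slot positions integer reference residue index per matrix row.
#' @slot eigenvalues numeric, descending.
#' @slot eigenvectors numeric matrix, columns matching eigenvalues.
#' @slot nullMax numeric maximum eigenvalue of each randomization trial.
#' @slot k integer number of significant eigenmodes.
#' @slot icLoadings numeric matrix (positions x k) of IC loadings.
#' @slot icResidues list of integer vectors, matrix row indices per IC.
#' @slot sectors list of integer vectors, IC indices per sector.
#' @slot sectorResidues list of integer vectors, reference residue
#'   positions per sector (union of the sector's ICs).
#' @export
setClass("SectorDecomposition",
  representation(Ctilde = "matrix", positions = "integer",
                 eigenvalues = "numeric", eigenvectors = "matrix",
                 nullMax = "numeric", k = "integer",
                 icLoadings = "matrix", icResidues = "list",
                 sectors = "list", sectorResidues = "list"))

setValidity("SectorDecomposition", function(object) {
  msgs <- character()
  p <- nrow(object@Ctilde)
  if (ncol(object@Ctilde) != p)
    msgs <- c(msgs, "Ctilde must be square")
  if (length(object@positions) != p)
    msgs <- c(msgs, "positions must label every matrix row")
  if (object@k > p)
    msgs <- c(msgs, "more significant modes than positions")
  if (length(object@sectors) &&
      !setequal(unlist(object@sectors), seq_len(ncol(object@icLoadings))))
    msgs <- c(msgs, "every IC must belong to exactly one sector")
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentResult: 2x2 partition enrichment with exact test
#'
#' Rows are cohorts (disease, population); columns are in-partition and
#' out-partition counts of unique missense variants.
#'
#' @slot table integer 2x2 matrix.
#' @slot partition character partition name.
#' @slot pValue numeric two-sided exact p-value.
#' @slot ratios numeric per-cohort in/out count ratio (Inf when the
#'   out-partition count is 0 and in-partition > 0; NaN for 0/0).
#' @slot densities numeric 2x2 matrix of counts per residue.
#' @export
setClass("EnrichmentResult",
  representation(table = "matrix", partition = "character",
                 pValue = "numeric", ratios = "numeric",
                 densities = "matrix"))

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (!all(dim(object@table) == c(2L, 2L)))
    msgs <- c(msgs, "table must be 2x2")
  if (any(object@table < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1 + 1e-12))
    msgs <- c(msgs, "p-value must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' TTestResult: pooled-variance unpaired t-test summary
#'
#' @slot means numeric group means.
#' @slot n integer group sizes.
#' @slot statistic numeric t statistic.
#' @slot df numeric degrees of freedom (n1 + n2 - 2).
#' @slot pValue numeric two-sided p-value.
#' @export
setClass("TTestResult",
  representation(means = "numeric", n = "integer", statistic = "numeric",
                 df = "numeric", pValue = "numeric"))
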