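## Structure-referenced domain mapping of query connexins and variants.

#' Construct a DomainSegmentation
#'
#' @param labels Character vector of domain labels (subset of
#'   [domainLabels()]), in N- to C-terminal order.
#' @param starts,ends Integer vectors of 1-based inclusive reference
#'   residue bounds; segments must be contiguous from 1 to the reference
#'   length.
#' @return A [DomainSegmentation-class] object.
#' @examples
#' DomainSegmentation(c("NT", "CT"), c(1L, 11L), c(10L, 40L))
#' @export
DomainSegmentation <- function(labels, starts, ends) {
  methods::new("DomainSegmentation",
               segments = data.frame(label = as.character(labels),
                                     start = as.integer(starts),
                                     end = as.integer(ends)),
               refLength = as.integer(max(ends)))
}

#' Read a domain segmentation config
#'
#' Accepts TSV (columns label, start, end; `#` comment lines allowed) or
#' JSON (array of objects with those fields).
#'
#' @param file Path to the config file.
#' @return A [DomainSegmentation-class].
#' @export
readSegmentation <- function(file) {
  if (grepl("\\.json$", file)) {
    d <- jsonlite::fromJSON(file)
  } else {
    d <- utils::read.delim(file, comment.char = "#",
                           stringsAsFactors = FALSE)
  }
  DomainSegmentation(d$label, d$start, d$end)
}

#' Write a domain segmentation config
#'
#' @param seg A [DomainSegmentation-class].
#' @param file Output path (.tsv or .json).
#' @return Invisibly, the path.
#' @export
writeSegmentation <- function(seg, file) {
  s <- segmentTable(seg)
  if (grepl("\\.json$", file))
    jsonlite::write_json(s, file, dataframe = "rows", auto_unbox = TRUE)
  else
    utils::write.table(s, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Default reference segmentation (sheep Cx46 numbering)
#'
#' An editable, approximate segmentation of the 440-residue sheep Cx46
#' reference into NT, M1, E1, CL, M2, M3, E2, M4 and CT, shipped as plain
#' text in `inst/extdata/cx46_sheep_segmentation.tsv`. Boundaries are data,
#' not code: replace them with structure-derived values via
#' [readSegmentation()] when an authoritative annotation is available.
#'
#' @return A [DomainSegmentation-class].
#' @export
defaultSegmentation <- function() {
  readSegmentation(system.file("extdata", "cx46_sheep_segmentation.tsv",
                               package = "cxvariants", mustWork = TRUE))
}

#' Global pairwise alignment of a query connexin to the reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties and a
#' standard substitution matrix, yielding a colinear query-to-reference
#' residue map and the overall percent identity (matches / aligned columns,
#' double gaps impossible in a pairwise alignment).
#'
#' @param query,ref Protein sequences: character strings or
#'   [Biostrings::AAString] objects; standard residues only.
#' @param substitutionMatrix Name of the matrix (default "BLOSUM62").
#' @param gapOpening,gapExtension Affine gap penalties (defaults 10, 0.5).
#' @param queryId,refId Identifiers recorded in the result.
#' @return A [ResidueAlignmentMap-class].
#' @export
alignQueryToReference <- function(query, ref,
                                  substitutionMatrix = "BLOSUM62",
                                  gapOpening = 10, gapExtension = 0.5,
                                  queryId = "query", refId = "reference") {
  query <- toupper(as.character(query))
  ref <- toupper(as.character(ref))
  if (!nzchar(query) || !nzchar(ref))
    stop("sequences must be non-empty", call. = FALSE)
  .checkAA(strsplit(query, "")[[1]], "query residue")
  .checkAA(strsplit(ref, "")[[1]], "reference residue")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  residueAlignmentMap(aq, ar, queryId = queryId, refId = refId,
                      score = Biostrings::score(pa))
}

#' Build a ResidueAlignmentMap from a gapped alignment pair
#'
#' Used both by [alignQueryToReference()] and to ingest precomputed
#' pairwise alignments (e.g. extracted from a multiple alignment).
#'
#' @param alignedQuery,alignedRef Equal-length gapped sequences.
#' @param queryId,refId Identifiers.
#' @param score Optional alignment score to record.
#' @return A [ResidueAlignmentMap-class].
#' @export
residueAlignmentMap <- function(alignedQuery, alignedRef,
                                queryId = "query", refId = "reference",
                                score = NA_real_) {
  qc <- strsplit(toupper(alignedQuery), "")[[1]]
  rc <- strsplit(toupper(alignedRef), "")[[1]]
  if (length(qc) != length(rc))
    stop("aligned sequences must have equal width", call. = FALSE)
  qi <- cumsum(qc != "-")
  ri <- cumsum(rc != "-")
  keep <- qc != "-"
  map <- ifelse(rc[keep] != "-", ri[keep], NA_integer_)
  methods::new("ResidueAlignmentMap",
               queryId = queryId, refId = refId,
               map = as.integer(map), refLength = sum(rc != "-"),
               score = as.numeric(score),
               alignedQuery = paste(qc, collapse = ""),
               alignedRef = paste(rc, collapse = ""))
}

#' Percent identity of an alignment, overall or within a reference mask
#'
#' Overall: matches / aligned columns (excluding double gaps). With a mask,
#' identity is computed over the columns whose reference residue lies in
#' the mask (query gaps at those columns count as mismatches). Percentages
#' are rounded half-up to integers.
#'
#' @param amap A [ResidueAlignmentMap-class].
#' @param refMask Optional integer vector of reference residue indices; by
#'   convention the structured residues of a segmentation.
#' @return Integer percent identity.
#' @export
percentIdentity <- function(amap, refMask = NULL) {
  qc <- strsplit(amap@alignedQuery, "")[[1]]
  rc <- strsplit(amap@alignedRef, "")[[1]]
  match <- qc == rc & qc != "-"
  if (is.null(refMask)) {
    cols <- qc != "-" | rc != "-"
  } else {
    if (!length(refMask)) stop("empty reference mask", call. = FALSE)
    ri <- cumsum(rc != "-")
    cols <- rc != "-" & ri %in% refMask
  }
  if (!sum(cols)) stop("no aligned columns in mask", call. = FALSE)
  as.integer(roundHalfUp(100 * sum(match & cols) / sum(cols)))
}

#' Identity within the structured domains
#'
#' Convenience wrapper around [percentIdentity()] using the structured
#' residues of a segmentation as the reference mask.
#'
#' @param amap A [ResidueAlignmentMap-class].
#' @param seg A [DomainSegmentation-class].
#' @return Integer percent identity over structured-domain columns.
#' @export
regionIdentity <- function(amap, seg) {
  lab <- residueLabels(seg)
  percentIdentity(amap, refMask = which(lab %in% structuredLabels()))
}

#' Build a per-residue domain map for a query connexin
#'
#' Each query residue inherits the domain label of its aligned reference
#' residue. Residues aligned to gaps (insertions) inherit the shared label
#' of the two flanking mapped residues when those agree, else the label of
#' the nearest preceding mapped residue. Query residues before the first
#' mapped residue are labelled NT; residues after the last mapped residue
#' (CT extension beyond the reference) are labelled CT.
#'
#' @param amap A [ResidueAlignmentMap-class].
#' @param seg A [DomainSegmentation-class] covering the reference.
#' @return A [DomainMap-class].
#' @export
buildDomainMap <- function(amap, seg) {
  if (refLength(seg) != amap@refLength)
    stop("segmentation covers ", refLength(seg),
         " residues but the alignment reference has ", amap@refLength,
         call. = FALSE)
  refLab <- residueLabels(seg)
  map <- amap@map
  n <- length(map)
  lab <- character(n)
  mapped <- which(!is.na(map))
  if (!length(mapped))
    stop("alignment maps no query residue onto the reference", call. = FALSE)
  ## nearest mapped neighbour indices for every query residue
  prevIdx <- cummax(ifelse(!is.na(map), seq_len(n), 0L))
  nextIdx <- rev(n + 1L - cummax(rev(ifelse(!is.na(map), n + 1L - seq_len(n), 0L))))
  for (i in seq_len(n)) {
    if (!is.na(map[i])) {
      lab[i] <- refLab[map[i]]
    } else if (prevIdx[i] == 0L) {
      lab[i] <- "NT"
    } else if (nextIdx[i] > n) {
      lab[i] <- "CT"
    } else {
      ## flanking mapped residues sharing a label means the insertion sits
      ## inside that segment; otherwise fall back to the preceding label.
      ## Both cases resolve to the nearest preceding mapped label.
      lab[i] <- refLab[map[prevIdx[i]]]
    }
  }
  structured <- lab %in% structuredLabels()
  pore <- ifelse(structured, lab %in% poreLabels(), NA)
  methods::new("DomainMap", labels = lab, structured = structured,
               pore = as.logical(pore), segmentation = seg,
               queryId = amap@queryId)
}

#' Annotate missense variants with domain and partition membership
#'
#' @param missense A missense-only variant DataFrame (see
#'   [selectMissense()]).
#' @param dmap A [DomainMap-class] for the variants' protein.
#' @return A list with `variants` (the input with added columns domain,
#'   structured, pore) and `counts` (per-domain and per-partition unique
#'   variant counts).
#' @export
locateVariantDomains <- function(missense, dmap) {
  if (nrow(missense) && any(missense$type != "missense"))
    stop("locateVariantDomains expects missense-only input", call. = FALSE)
  n <- length(dmap@labels)
  bad <- missense$position > n | missense$position < 1L
  if (any(bad))
    stop("variant position out of range for ", dmap@queryId, ": ",
         paste(missense$label[bad], collapse = ", "), call. = FALSE)
  out <- missense
  out$domain <- dmap@labels[missense$position]
  out$structured <- dmap@structured[missense$position]
  out$pore <- dmap@pore[missense$position]
  counts <- .lengthsFromLabels(out$domain)
  list(variants = out, counts = counts)
}

#' Write per-residue domain annotation as TSV
#'
#' @param dmap A [DomainMap-class].
#' @param file Output path.
#' @param sequence Optional query protein sequence (adds an `aa` column).
#' @return Invisibly, the path.
#' @export
writeResidueAnnotation <- function(dmap, file, sequence = NULL) {
  n <- length(dmap@labels)
  d <- data.frame(residue = seq_len(n),
                  aa = if (is.null(sequence)) NA_character_
                       else strsplit(toupper(as.character(sequence)), "")[[1]],
                  domain = dmap@labels,
                  structured = dmap@structured,
                  pore = dmap@pore)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export per-residue values into the B-factor column of a PDB file
#'
#' Writes numeric per-residue codes (e.g. domain codes or sector
#' membership) into the temperature-factor column so any molecular viewer
#' can colour the structure by them. Requires the bio3d package.
#'
#' @param pdbIn Path to the input PDB.
#' @param pdbOut Path for the annotated PDB.
#' @param values Named numeric vector: names are residue numbers.
#' @param chain Optional chain identifier filter.
#' @return Invisibly, `pdbOut`.
#' @export
exportBFactors <- function(pdbIn, pdbOut, values, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("exportBFactors requires the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(pdbIn)
  resno <- pdb$atom$resno
  sel <- if (is.null(chain)) rep(TRUE, nrow(pdb$atom))
         else pdb$atom$chain == chain
  b <- pdb$atom$b
  idx <- match(as.character(resno), names(values))
  repl <- sel & !is.na(idx)
  b[repl] <- unname(values[idx[repl]])
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = pdbOut)
  invisible(pdbOut)
}
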