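## Variant catalog: HGVS p. parsing, typing, tabulation, cohort overlap.

.VTYPES <- c("missense", "synonymous", "stop_gained", "stop_lost",
             "start_lost", "frameshift", "inframe_indel")
.COHORTS <- c("disease", "population")

## Internal: one amino-acid token (3-letter, 1-letter, Ter or *) -> 1-letter.
.aaToken1 <- function(tok, label) {
  if (tok %in% c("*", "X", "Ter")) return("*")
  if (nchar(tok) == 3L) {
    tok <- paste0(toupper(substr(tok, 1, 1)), tolower(substr(tok, 2, 3)))
    out <- unname(.AA3TO1[tok])
    if (is.na(out))
      stop("non-standard amino-acid code '", tok, "' in variant label '",
           label, "'", call. = FALSE)
    return(out)
  }
  if (nchar(tok) == 1L && toupper(tok) %in% aminoAcids())
    return(toupper(tok))
  stop("non-standard amino-acid code '", tok, "' in variant label '",
       label, "'", call. = FALSE)
}

#' Parse a protein-level variant label
#'
#' Accepts HGVS p. notation (three-letter or one-letter, with or without the
#' `p.` prefix and parentheses) and short forms, e.g. `p.Asn220Asp`,
#' `N220D`, `W4*`, `S251fs`, `K45_G47del`, `M1?`, `*360W`. The variant type
#' is assigned from the substitution pattern: same residue = synonymous,
#' different residue = missense, to stop = stop_gained, from stop =
#' stop_lost, initiator Met disrupted = start_lost, `fs` = frameshift,
#' del/ins/dup without fs = inframe_indel. Intronic/splice/UTR (c. or g.)
#' constructs are rejected.
#'
#' @param label Character, the variant label.
#' @param gene Character gene symbol.
#' @param cohort One of `"disease"` or `"population"`.
#' @param allele_frequency Optional numeric in `[0, 1]`.
#' @param source Optional free-text citation.
#' @return A one-row [S4Vectors::DataFrame] with columns gene, cohort,
#'   label (normalised short form), position, ref, alt, type, multiResidue,
#'   allele_frequency, source.
#' @examples
#' parseVariantLabel("p.Asn220Asp", "GJA8", "population")
#' parseVariantLabel("W4*", "GJA1", "disease")
#' @export
parseVariantLabel <- function(label, gene, cohort,
                              allele_frequency = NA_real_,
                              source = NA_character_) {
  rec <- .parseVariantCore(label, cohort, allele_frequency)
  S4Vectors::DataFrame(
    gene = gene, cohort = rec$cohort, label = rec$label,
    position = rec$position, ref = rec$ref, alt = rec$alt,
    type = rec$type, multiResidue = rec$multiResidue,
    allele_frequency = allele_frequency, source = source)
}

## Internal: parse one label into a plain list (fast path for bulk use).
.parseVariantCore <- function(label, cohort, allele_frequency = NA_real_) {
  cohort <- match.arg(cohort, .COHORTS)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  raw <- label
  x <- gsub("[[:space:]]", "", label)
  if (grepl("^[cgmn]\\.", x))
    stop("nucleotide-level label '", raw,
         "' not supported; supply protein-level (p.) notation",
         call. = FALSE)
  x <- sub("^p\\.", "", x)
  x <- gsub("[()]", "", x)

  AA <- "([A-Za-z]{3}|[A-Z]|\\*)"
  pos <- ref <- alt <- NA
  type <- NA_character_
  multi <- FALSE

  if (grepl("fs", x)) {
    ## frameshift: anchor residue + position, anything after "fs" ignored
    m <- regmatches(x, regexec(paste0("^", AA, "([0-9]+)[A-Za-z]*fs.*$"), x))[[1]]
    if (!length(m))
      stop("unparseable frameshift label '", raw, "'", call. = FALSE)
    ref <- .aaToken1(m[2], raw); pos <- as.integer(m[3])
    type <- "frameshift"
  } else if (grepl("(del|ins|dup)", x)) {
    one <- regmatches(x, regexec(
      paste0("^", AA, "([0-9]+)(del|dup|ins)[A-Za-z]*$"), x))[[1]]
    rng <- regmatches(x, regexec(
      paste0("^", AA, "([0-9]+)_", AA, "([0-9]+)(del|dup|ins|delins)[A-Za-z]*$"), x))[[1]]
    if (length(one)) {
      ref <- .aaToken1(one[2], raw); pos <- as.integer(one[3])
    } else if (length(rng)) {
      ref <- .aaToken1(rng[2], raw); pos <- as.integer(rng[3])
      pos2 <- as.integer(rng[5])
      if (pos2 < pos)
        stop("inverted residue range in '", raw, "'", call. = FALSE)
      multi <- TRUE
    } else stop("unparseable indel label '", raw, "'", call. = FALSE)
    type <- "inframe_indel"
  } else if (grepl("^(Met1|M1)\\?$", x)) {
    ref <- "M"; pos <- 1L; type <- "start_lost"
  } else {
    m <- regmatches(x, regexec(paste0("^", AA, "([0-9]+)", AA, "$"), x))[[1]]
    if (!length(m))
      stop("unparseable variant label '", raw, "'", call. = FALSE)
    rt <- m[2]; pos <- as.integer(m[3]); at <- m[4]
    ref <- .aaToken1(rt, raw); alt <- .aaToken1(at, raw)
    if (ref == "*" && alt == "*")
      stop("unparseable variant label '", raw, "'", call. = FALSE)
    type <- if (ref == "*") "stop_lost"
      else if (alt == "*") "stop_gained"
      else if (pos == 1L && ref == "M" && alt != "M") "start_lost"
      else if (ref == alt) "synonymous"
      else "missense"
  }
  if (is.na(pos) || pos < 1L)
    stop("variant label '", raw, "' lacks a valid 1-based position",
         call. = FALSE)

  norm <- switch(type,
    frameshift = paste0(ref, pos, "fs"),
    inframe_indel = x,
    start_lost = if (is.na(alt)) paste0("M1?") else paste0(ref, pos, alt),
    paste0(ref, pos, alt))
  if (!is.na(allele_frequency) &&
      (allele_frequency < 0 || allele_frequency > 1))
    stop("allele_frequency must lie in [0, 1]", call. = FALSE)

  list(cohort = cohort, label = norm, position = pos, ref = ref,
       alt = if (is.na(alt)) NA_character_ else alt,
       type = type, multiResidue = multi)
}

#' Parse many variant labels into a variant table
#'
#' Vectorised front end to [parseVariantLabel()]; deduplicates on the
#' uniqueness key (gene, cohort, normalised label).
#'
#' @param labels Character vector of variant labels.
#' @param genes Character vector (recycled) of gene symbols.
#' @param cohorts Character vector (recycled), `"disease"`/`"population"`.
#' @param allele_frequencies,sources Optional vectors (recycled).
#' @return A [S4Vectors::DataFrame], one row per unique variant.
#' @export
parseVariants <- function(labels, genes, cohorts,
                          allele_frequencies = NA_real_,
                          sources = NA_character_) {
  n <- length(labels)
  genes <- rep_len(genes, n)
  cohorts <- rep_len(cohorts, n)
  allele_frequencies <- rep_len(allele_frequencies, n)
  sources <- rep_len(sources, n)
  recs <- lapply(seq_len(n), function(i)
    .parseVariantCore(labels[i], cohorts[i], allele_frequencies[i]))
  out <- S4Vectors::DataFrame(
    gene = genes,
    cohort = vapply(recs, `[[`, "", "cohort"),
    label = vapply(recs, `[[`, "", "label"),
    position = vapply(recs, `[[`, 1L, "position"),
    ref = vapply(recs, `[[`, "", "ref"),
    alt = vapply(recs, function(r)
      if (is.na(r$alt)) NA_character_ else r$alt, ""),
    type = vapply(recs, `[[`, "", "type"),
    multiResidue = vapply(recs, `[[`, TRUE, "multiResidue"),
    allele_frequency = allele_frequencies, source = sources)
  dedupVariants(out)
}

#' Deduplicate a variant table on its uniqueness key
#'
#' The uniqueness key is (gene, cohort, normalised label); the first
#' occurrence is kept.
#'
#' @param variants A variant DataFrame as returned by [parseVariants()].
#' @return The deduplicated DataFrame.
#' @export
dedupVariants <- function(variants) {
  key <- paste(variants$gene, variants$cohort, variants$label, sep = "\r")
  variants[!duplicated(key), , drop = FALSE]
}

#' Read a variant table from TSV
#'
#' Expects header columns `gene`, `cohort`, `hgvs_p` and optionally
#' `allele_frequency` and `source`.
#'
#' @param file Path to a tab-separated file.
#' @return A parsed, deduplicated variant DataFrame.
#' @export
readVariantTable <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("gene", "cohort", "hgvs_p")
  if (!all(need %in% names(d)))
    stop("variant TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  parseVariants(d$hgvs_p, d$gene, d$cohort,
                if ("allele_frequency" %in% names(d))
                  as.numeric(d$allele_frequency) else NA_real_,
                if ("source" %in% names(d)) as.character(d$source)
                else NA_character_)
}

#' Write a variant table as TSV
#'
#' @param variants A variant DataFrame.
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
writeVariantTable <- function(variants, file) {
  utils::write.table(as.data.frame(variants), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Tabulate unique variants by type
#'
#' Counts unique variants per type, per gene and pooled, with percentages of
#' the (optionally synonymous-free) total.
#'
#' @param variants A variant DataFrame.
#' @param dropSynonymous Remove synonymous records before computing counts
#'   and percentages (used when comparing against a cohort that cannot
#'   contain synonymous changes).
#' @return A data.frame with columns gene ("pooled" row group included),
#'   type, count, percent.
#' @export
tabulateVariantTypes <- function(variants, dropSynonymous = FALSE) {
  variants <- dedupVariants(variants)
  if (dropSynonymous)
    variants <- variants[variants$type != "synonymous", , drop = FALSE]
  tab1 <- function(v, gene) {
    cnt <- vapply(.VTYPES, function(t) sum(v$type == t), integer(1))
    tot <- sum(cnt)
    data.frame(gene = gene, type = .VTYPES, count = unname(cnt),
               percent = if (tot > 0) unname(100 * cnt / tot) else
                 rep(0, length(cnt)))
  }
  pergene <- lapply(sort(unique(variants$gene)), function(g)
    tab1(variants[variants$gene == g, , drop = FALSE], g))
  out <- do.call(rbind, c(pergene, list(tab1(variants, "pooled"))))
  rownames(out) <- NULL
  out
}

#' Keep only missense variants
#'
#' Order-stable filter to the missense records; idempotent.
#'
#' @param variants A variant DataFrame.
#' @return The missense-only DataFrame.
#' @export
selectMissense <- function(variants) {
  variants[variants$type == "missense", , drop = FALSE]
}

#' Positional overlap between disease and population missense variants
#'
#' Finds residue positions carrying at least one missense variant in both
#' cohorts (per gene), counts the variants of each cohort at those shared
#' positions, and counts identical substitutions (same gene, position,
#' reference and alternate residue in both cohorts).
#'
#' @param disease,population Missense-only variant DataFrames over the same
#'   gene set.
#' @return A list with elements `sharedPositions` (data.frame gene,
#'   position), `diseaseVariantsAtShared`, `populationVariantsAtShared` and
#'   `identicalSubstitutions`.
#' @export
computeOverlap <- function(disease, population) {
  for (v in list(disease, population))
    if (nrow(v) && any(v$type != "missense"))
      stop("computeOverlap expects missense-only inputs", call. = FALSE)
  if ((nrow(disease) && any(is.na(disease$gene))) ||
      (nrow(population) && any(is.na(population$gene))))
    stop("gene key required to avoid cross-gene position collisions",
         call. = FALSE)
  dpos <- unique(paste(disease$gene, disease$position, sep = "\r"))
  ppos <- unique(paste(population$gene, population$position, sep = "\r"))
  shared <- intersect(dpos, ppos)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  sharedPositions <- data.frame(
    gene = vapply(parts, `[`, "", 1L),
    position = as.integer(vapply(parts, `[`, "", 2L)))
  dAt <- sum(paste(disease$gene, disease$position, sep = "\r") %in% shared)
  pAt <- sum(paste(population$gene, population$position, sep = "\r") %in% shared)
  dsub <- paste(disease$gene, disease$position, disease$ref, disease$alt,
                sep = "\r")
  psub <- paste(population$gene, population$position, population$ref,
                population$alt, sep = "\r")
  ident <- length(intersect(unique(dsub), unique(psub)))
  list(sharedPositions = sharedPositions[order(sharedPositions$gene,
                                               sharedPositions$position), ,
                                         drop = FALSE],
       diseaseVariantsAtShared = dAt,
       populationVariantsAtShared = pAt,
       identicalSubstitutions = ident)
}

#' Write a type tabulation or overlap report
#'
#' @param x Result of [tabulateVariantTypes()] or [computeOverlap()].
#' @param file Output path; format chosen by extension (.json or .tsv).
#' @return Invisibly, the path written.
#' @export
writeReport <- function(x, file) {
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else if (is.data.frame(x)) {
    utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    flat <- data.frame(
      key = c("shared_positions", "disease_variants_at_shared",
              "population_variants_at_shared", "identical_substitutions"),
      value = c(nrow(x$sharedPositions), x$diseaseVariantsAtShared,
                x$populationVariantsAtShared, x$identicalSubstitutions))
    utils::write.table(flat, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}
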