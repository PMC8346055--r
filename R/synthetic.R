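## Seeded synthetic generators: MSAs with planted co-varying residue
## groups, and variant cohorts with controlled per-partition enrichment.
## These emulate the shape of the real inputs (a multi-species connexin
## alignment and curated variant tables) without claiming biological
## realism; sequences are exchangeable (no phylogeny) and coupling follows
## a two-state group-switching model.

.AA1TO3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
             "*" = "Ter")

#' Generate a synthetic alignment with planted co-varying groups
#'
#' Uncoupled columns are drawn independently per sequence: the column
#' consensus with probability `conservation[j]`, otherwise a draw from the
#' background distribution. Each coupled group has two group-consensus
#' states (one residue per column each); per sequence the group picks a
#' state by a fair coin, and each of its columns adopts the state residue
#' with probability `strength` (else falls back to the independent draw).
#' Gaps are introduced independently per cell at `gapRate`. A gapless
#' `reference` row carrying the consensus is prepended when
#' `includeReference` is TRUE.
#'
#' @param nSequences,nColumns Alignment dimensions.
#' @param conservation Per-column consensus probability in `[0, 1]`
#'   (recycled).
#' @param coupledGroups List of `list(columns =, strength =)`; column sets
#'   must be disjoint.
#' @param gapRate Per-cell gap probability; default 0.
#' @param background Background amino-acid distribution.
#' @param includeReference Prepend the consensus as row "reference".
#' @param seed Optional integer seed.
#' @return List with `alignment` (named character vector of gapped rows)
#'   and `truth` (consensus, group columns/states, parameters).
#' @export
generateMSA <- function(nSequences, nColumns, conservation = 0.5,
                        coupledGroups = list(), gapRate = 0,
                        background = backgroundFrequencies(),
                        includeReference = TRUE, seed = NULL) {
  stopifnot(nSequences >= 1, nColumns >= 1,
            all(conservation >= 0 & conservation <= 1),
            gapRate >= 0, gapRate < 1)
  cols <- unlist(lapply(coupledGroups, `[[`, "columns"))
  if (anyDuplicated(cols))
    stop("coupled groups must use disjoint column sets", call. = FALSE)
  if (length(cols) && (max(cols) > nColumns || min(cols) < 1))
    stop("coupled group columns out of range", call. = FALSE)
  .withSeed(seed, {
    aa <- aminoAcids()
    cons <- sample(aa, nColumns, replace = TRUE, prob = background)
    ci <- rep_len(conservation, nColumns)
    groups <- lapply(coupledGroups, function(g) {
      sA <- cons[g$columns]
      sB <- vapply(sA, function(a)
        sample(setdiff(aa, a), 1L), character(1))
      list(columns = as.integer(g$columns), strength = g$strength,
           stateA = unname(sA), stateB = unname(sB))
    })
    m <- matrix("", nSequences, nColumns)
    for (s in seq_len(nSequences)) {
      indep <- ifelse(stats::runif(nColumns) < ci, cons,
                      sample(aa, nColumns, replace = TRUE,
                             prob = background))
      row <- indep
      for (g in groups) {
        state <- if (stats::runif(1) < 0.5) g$stateA else g$stateB
        take <- stats::runif(length(g$columns)) < g$strength
        row[g$columns[take]] <- state[take]
      }
      m[s, ] <- row
    }
    if (gapRate > 0)
      m[matrix(stats::runif(length(m)) < gapRate, nrow(m))] <- "-"
    rownames(m) <- sprintf("seq%04d", seq_len(nSequences))
    aln <- apply(m, 1, paste, collapse = "")
    if (includeReference)
      aln <- c(reference = paste(cons, collapse = ""), aln)
    list(alignment = aln,
         truth = list(consensus = paste(cons, collapse = ""),
                      conservation = ci, groups = groups,
                      gapRate = gapRate, seed = seed))
  })
}

#' Default variant-type mixtures for synthetic cohorts
#'
#' Disease cohorts are dominated by missense changes with no synonymous
#' records; population cohorts carry roughly one-third synonymous
#' variants, mirroring the make-up of curated disease lists and gnomAD
#' coding variants.
#'
#' @param cohort `"disease"` or `"population"`.
#' @return Named probability vector over the seven variant types.
#' @export
defaultTypeMixture <- function(cohort = c("disease", "population")) {
  cohort <- match.arg(cohort)
  if (cohort == "disease")
    c(missense = 0.87, synonymous = 0, stop_gained = 0.06,
      stop_lost = 0, start_lost = 0.005, frameshift = 0.05,
      inframe_indel = 0.015)
  else
    c(missense = 0.59, synonymous = 0.35, stop_gained = 0.02,
      stop_lost = 0.005, start_lost = 0.005, frameshift = 0.02,
      inframe_indel = 0.01)
}

## Internal: sample one unique variant of a given type. Returns a list
## with the long-form HGVS label plus the parsed fields (so bulk
## generation does not have to round-trip through the parser; tests
## assert that the round trip is the identity).
.sampleVariantRecord <- function(type, protein, posProb, used) {
  L <- length(protein)
  aa <- aminoAcids()
  for (attempt in seq_len(200L)) {
    pos <- NA_integer_; ref <- NA_character_; alt <- NA_character_
    hgvs <- switch(type,
      missense = {
        ## a substitution of the initiator Met is start_lost, not missense
        pp <- posProb
        if (protein[1] == "M") pp[1] <- 0
        pos <- sample.int(L, 1L, prob = pp)
        ref <- protein[pos]
        alt <- sample(setdiff(aa, ref), 1L)
        paste0("p.", .AA1TO3[ref], pos, .AA1TO3[alt])
      },
      synonymous = {
        pos <- sample.int(L, 1L)
        ref <- alt <- protein[pos]
        paste0("p.", .AA1TO3[ref], pos, .AA1TO3[alt])
      },
      stop_gained = {
        pos <- sample(2:L, 1L)
        ref <- protein[pos]; alt <- "*"
        paste0("p.", .AA1TO3[ref], pos, "Ter")
      },
      stop_lost = {
        pos <- L + 1L; ref <- "*"; alt <- sample(aa, 1L)
        paste0("p.Ter", pos, .AA1TO3[alt])
      },
      start_lost = {
        pos <- 1L; ref <- "M"
        "p.Met1?"
      },
      frameshift = {
        pos <- sample(2:L, 1L)
        ref <- protein[pos]
        paste0("p.", .AA1TO3[ref], pos, "fs")
      },
      inframe_indel = {
        pos <- sample(2:L, 1L)
        ref <- protein[pos]
        paste0("p.", .AA1TO3[ref], pos, sample(c("del", "dup"), 1L))
      })
    norm <- switch(type,
      frameshift = paste0(ref, pos, "fs"),
      inframe_indel = sub("^p\\.", "", hgvs),
      start_lost = "M1?",
      paste0(ref, pos, alt))
    if (!(norm %in% used))
      return(list(hgvs = hgvs, label = norm, position = pos, ref = ref,
                  alt = alt, type = type))
    ## degenerate types (start_lost has a single possible label) cannot
    ## yield a new draw: give up immediately instead of looping
    if (type == "start_lost") break
  }
  NULL
}

#' Generate disease and population variant cohorts
#'
#' Missense positions are sampled with per-residue probability
#' proportional to the partition odds multiplier (structured residues get
#' weight `odds`, unstructured weight 1), substitutions uniformly over the
#' 19 alternatives, uniqueness enforced by rejection. Defaults encode the
#' study contrast: disease cohorts strongly enriched in structured domains
#' (odds 6) and population cohorts depleted (odds 1/3).
#'
#' @param seg A [DomainSegmentation-class] defining the protein length and
#'   partitions.
#' @param nDisease,nPopulation Unique variants per cohort (defaults 60 and
#'   300).
#' @param oddsDisease,oddsPopulation Structured:unstructured odds
#'   multipliers (defaults 6 and 1/3).
#' @param typeMixtureDisease,typeMixturePopulation Probability vectors
#'   over the seven variant types; see [defaultTypeMixture()].
#' @param gene Gene symbol recorded on every variant.
#' @param protein Optional protein sequence (character string); sampled
#'   from the background distribution when NULL.
#' @param seed Optional integer seed.
#' @return List with `variants` (typed DataFrame, both cohorts; identical
#'   to parsing the labels), `hgvs` (the long-form HGVS p. labels, same
#'   order), `protein` (the sequence used) and `truth` (parameters).
#' @export
generateCohorts <- function(seg, nDisease = 60L, nPopulation = 300L,
                            oddsDisease = 6, oddsPopulation = 1 / 3,
                            typeMixtureDisease = defaultTypeMixture("disease"),
                            typeMixturePopulation = defaultTypeMixture("population"),
                            gene = "SYNCX", protein = NULL, seed = NULL) {
  stopifnot(oddsDisease > 0, oddsPopulation > 0)
  L <- refLength(seg)
  if (nDisease > L * 19 || nPopulation > L * 19)
    stop("more unique missense variants requested than length x 19 allows",
         call. = FALSE)
  .withSeed(seed, {
    if (is.null(protein)) {
      protein <- sample(aminoAcids(), L, replace = TRUE,
                        prob = backgroundFrequencies())
      protein[1] <- "M"
    } else {
      protein <- strsplit(toupper(as.character(protein)), "")[[1]]
      if (length(protein) != L)
        stop("protein length must equal the segmentation length",
             call. = FALSE)
    }
    structured <- residueLabels(seg) %in% structuredLabels()
    gen <- function(n, odds, mixture, cohort) {
      mixture <- mixture / sum(mixture)
      posProb <- ifelse(structured, odds, 1)
      types <- sample(names(mixture), n, replace = TRUE, prob = mixture)
      used <- character(n)
      recs <- vector("list", n)
      for (i in seq_len(n)) {
        r <- NULL
        type <- types[i]
        for (retry in seq_len(50L)) {
          r <- .sampleVariantRecord(type, protein, posProb,
                                    used[seq_len(i - 1L)])
          if (!is.null(r)) break
          ## type exhausted (e.g. a second start_lost): redraw the type
          type <- sample(names(mixture), 1L, prob = mixture)
        }
        if (is.null(r))
          stop("could not draw a unique variant; cohort too large for ",
               "the protein", call. = FALSE)
        recs[[i]] <- r
        used[i] <- r$label
      }
      recs
    }
    recs <- c(gen(nDisease, oddsDisease, typeMixtureDisease, "disease"),
              gen(nPopulation, oddsPopulation, typeMixturePopulation,
                  "population"))
    variants <- S4Vectors::DataFrame(
      gene = gene,
      cohort = rep(c("disease", "population"), c(nDisease, nPopulation)),
      label = vapply(recs, `[[`, "", "label"),
      position = vapply(recs, `[[`, 1L, "position"),
      ref = vapply(recs, `[[`, "", "ref"),
      alt = vapply(recs, `[[`, "", "alt"),
      type = vapply(recs, `[[`, "", "type"),
      multiResidue = FALSE,
      allele_frequency = NA_real_, source = NA_character_)
    list(variants = variants,
         hgvs = vapply(recs, `[[`, "", "hgvs"),
         protein = paste(protein, collapse = ""),
         truth = list(nDisease = nDisease, nPopulation = nPopulation,
                      oddsDisease = oddsDisease,
                      oddsPopulation = oddsPopulation, seed = seed))
  })
}

#' Write a reproducible fixture bundle
#'
#' Writes a synthetic MSA (aligned FASTA + ground-truth JSON), variant
#' cohorts (TSV per cohort), the protein sequence (FASTA) and the
#' segmentation (JSON) into a directory. Re-running with the same seed
#' reproduces byte-identical files.
#'
#' @param dir Output directory (created if missing).
#' @param seg A [DomainSegmentation-class]; default [defaultSegmentation()].
#' @param msaArgs,cohortArgs Argument lists forwarded to [generateMSA()] /
#'   [generateCohorts()]. When `msaArgs` omits `nColumns` it defaults to
#'   the number of structured positions in `seg`, so the bundle feeds
#'   [runPipeline()] directly.
#' @param seed Integer seed governing both generators.
#' @return Named character vector of the files written.
#' @export
writeFixtures <- function(dir, seg = defaultSegmentation(),
                          msaArgs = list(nSequences = 80),
                          cohortArgs = list(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(msaArgs$nColumns))
    msaArgs$nColumns <- sum(residueLabels(seg) %in% structuredLabels())
  msa <- do.call(generateMSA, c(msaArgs, list(seed = seed)))
  coh <- do.call(generateCohorts, c(list(seg = seg), cohortArgs,
                                    list(seed = seed + 1L)))
  paths <- c(
    msa = file.path(dir, "msa.fasta"),
    msa_truth = file.path(dir, "msa_truth.json"),
    disease = file.path(dir, "variants_disease.tsv"),
    population = file.path(dir, "variants_population.tsv"),
    protein = file.path(dir, "protein.fasta"),
    segmentation = file.path(dir, "segmentation.json"))
  writeAlignedFasta(msa$alignment, paths["msa"])
  jsonlite::write_json(msa$truth, paths["msa_truth"], auto_unbox = TRUE,
                       digits = NA)
  v <- as.data.frame(coh$variants)
  v$hgvs_p <- coh$hgvs
  for (co in c("disease", "population")) {
    d <- v[v$cohort == co, c("gene", "cohort", "hgvs_p",
                             "allele_frequency", "source")]
    utils::write.table(d, paths[[co]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(synthetic_protein = coh$protein)),
    paths["protein"])
  writeSegmentation(seg, paths["segmentation"])
  paths
}
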