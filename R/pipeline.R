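## End-to-end orchestration: variant catalog -> domain map -> enrichment
## (-> conservation/coupling when an MSA is supplied), with every
## intermediate table written to disk and a machine-readable run manifest.

#' Read a pipeline run configuration
#'
#' JSON (or YAML, when the yaml package is installed) mirroring the
#' arguments of [runPipeline()]: paths `disease_variants`,
#' `population_variants`, `segmentation`, optional `query_sequence`,
#' `reference_sequence`, `msa`, `msa_reference_id`, plus `partitions`,
#' `out_dir`, `seed` and an `sca` block of [scaConfig()] overrides.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

## Internal: relabel SCA result positions when the MSA columns are the
## structured reference positions in order (lookup[i] = reference residue
## of MSA reference position i).
.remapSCAPositions <- function(res, lookup) {
  mp <- function(p) as.integer(lookup[p])
  res$alignment@refPositions <- mp(res$alignment@refPositions)
  res$profile@positions <- mp(res$profile@positions)
  dimnames(res$Ctilde) <- list(mp(as.integer(rownames(res$Ctilde))),
                               mp(as.integer(colnames(res$Ctilde))))
  if (!is.null(res$decomposition)) {
    d <- res$decomposition
    d@positions <- mp(d@positions)
    d@sectorResidues <- lapply(d@sectorResidues, function(p) sort(mp(p)))
    dimnames(d@Ctilde) <- dimnames(res$Ctilde)
    res$decomposition <- d
  }
  res
}

## Internal: run a stage with failure attribution.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full variant-distribution pipeline
#'
#' Executes variant parsing/typing, domain mapping, partition enrichment
#' and (when an MSA is supplied) the conservation/coupling analysis, and
#' writes: variant type tabulations, the per-residue domain annotation,
#' annotated variants, the cohort overlap report, one enrichment table per
#' partition, the Di profile with the disease-vs-population Di t-test, the
#' coupling matrix, sector report and sector enrichment, and a manifest
#' with package version, seed and input checksums.
#'
#' @param config A list (see [readRunConfig()]) or a path to a config
#'   file.
#' @return Invisibly, a named list of output paths plus the key results
#'   (`enrichment`, `overlap`, `sca`, `diTest`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config must name out_dir", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) NULL else as.integer(config$seed)
  log <- function(...) message("[cxvariants] ", ...)

  inputs <- unlist(config[c("disease_variants", "population_variants",
                            "segmentation", "query_sequence",
                            "reference_sequence", "msa")])
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  seg <- .stage("segmentation", readSegmentation(config$segmentation))

  variants <- .stage("variant_catalog", {
    dv <- readVariantTable(config$disease_variants)
    pv <- readVariantTable(config$population_variants)
    rbind(dv, pv)
  })
  outputs <- list()
  tab <- tabulateVariantTypes(variants)
  outputs$type_tabulation <- file.path(outDir, "type_tabulation.tsv")
  writeReport(tab, outputs$type_tabulation)
  tabNoSyn <- tabulateVariantTypes(variants, dropSynonymous = TRUE)
  outputs$type_tabulation_nosyn <-
    file.path(outDir, "type_tabulation_nosyn.tsv")
  writeReport(tabNoSyn, outputs$type_tabulation_nosyn)

  missense <- selectMissense(variants)
  overlap <- computeOverlap(missense[missense$cohort == "disease", ],
                            missense[missense$cohort == "population", ])
  outputs$overlap <- file.path(outDir, "overlap.json")
  writeReport(overlap, outputs$overlap)

  dmapResult <- .stage("domain_map", {
    if (!is.null(config$query_sequence) &&
        !is.null(config$reference_sequence)) {
      qs <- readAlignedFasta(config$query_sequence)[1]
      rs <- readAlignedFasta(config$reference_sequence)[1]
      amap <- alignQueryToReference(gsub("-", "", qs), gsub("-", "", rs),
                                    queryId = names(qs), refId = names(rs))
    } else {
      ## query taken as the reference protein itself
      L <- refLength(seg)
      fake <- paste(rep("A", L), collapse = "")
      amap <- residueAlignmentMap(fake, fake, queryId = "reference",
                                  refId = "reference")
      if (!is.null(config$query_sequence)) {
        qs <- readAlignedFasta(config$query_sequence)[1]
        q <- gsub("-", "", qs)
        amap <- residueAlignmentMap(q, q, queryId = names(qs),
                                    refId = "reference")
        if (nchar(q) != refLength(seg))
          stop("query length differs from the segmentation; supply a ",
               "reference_sequence to align against", call. = FALSE)
      }
    }
    dmap <- buildDomainMap(amap, seg)
    list(amap = amap, dmap = dmap)
  })
  dmap <- dmapResult$dmap
  outputs$residue_annotation <- file.path(outDir, "residue_annotation.tsv")
  writeResidueAnnotation(dmap, outputs$residue_annotation)

  annotated <- .stage("variant_annotation",
                      locateVariantDomains(missense, dmap)$variants)
  outputs$annotated_variants <- file.path(outDir, "annotated_variants.tsv")
  writeVariantTable(annotated, outputs$annotated_variants)

  partitions <- config$partitions
  if (is.null(partitions))
    partitions <- c("structured_vs_unstructured", "pore_vs_nonpore",
                    "CL_vs_CT")
  L <- domainLengths(dmap)$partitions
  plen <- list(structured_vs_unstructured = unname(L[c("structured",
                                                       "unstructured")]),
               pore_vs_nonpore = unname(L[c("pore", "nonpore")]),
               CL_vs_CT = unname(L[c("CL", "CT")]))
  enrich <- .stage("enrichment_stats", {
    res <- lapply(setdiff(partitions, "sector_vs_nonsector"), function(p)
      enrichmentTest(annotated, p, plen[[p]]))
    names(res) <- setdiff(partitions, "sector_vs_nonsector")
    res
  })
  for (p in names(enrich)) {
    outputs[[paste0("enrichment_", p)]] <-
      file.path(outDir, paste0("enrichment_", p, ".tsv"))
    writeEnrichment(enrich[[p]], outputs[[paste0("enrichment_", p)]])
  }

  sca <- NULL
  diTest <- NULL
  if (!is.null(config$msa)) {
    sca <- .stage("conservation_covariation", {
      msa <- readAlignedFasta(config$msa)
      refId <- config$msa_reference_id
      if (is.null(refId)) refId <- names(msa)[1]
      cfg <- do.call(scaConfig, as.list(config$sca))
      refLen <- nchar(gsub("-", "", msa[refId]))
      lab <- residueLabels(seg)
      structPos <- which(lab %in% structuredLabels())
      if (refLen == refLength(seg)) {
        runSCA(msa, refId, seg = seg, cfg = cfg, seed = seed)
      } else if (refLen == length(structPos)) {
        ## MSA already restricted to the structured positions, in order
        .remapSCAPositions(
          runSCA(msa, refId, seg = NULL, cfg = cfg, seed = seed),
          structPos)
      } else {
        stop("MSA reference has ", refLen, " residues; expected the full ",
             "reference length (", refLength(seg), ") or the structured ",
             "positions only (", length(structPos), ")")
      }
    })
    outputs$di_profile <- file.path(outDir, "di_profile.tsv")
    writeConservationProfile(sca$profile, outputs$di_profile)
    outputs$coupling_matrix <- file.path(outDir, "coupling_matrix.tsv")
    writeCouplingMatrix(sca$Ctilde, outputs$coupling_matrix)

    ## disease vs population Di at structured variant positions
    di <- DiValues(sca$profile)
    amap <- dmapResult$amap
    refPosOf <- function(pos) amap@map[pos]
    str <- annotated[annotated$structured, , drop = FALSE]
    dPos <- refPosOf(str$position[str$cohort == "disease"])
    pPos <- refPosOf(str$position[str$cohort == "population"])
    dDi <- di[as.character(dPos[!is.na(dPos)])]
    pDi <- di[as.character(pPos[!is.na(pPos)])]
    dDi <- dDi[!is.na(dDi)]; pDi <- pDi[!is.na(pDi)]
    if (length(dDi) >= 2 && length(pDi) >= 2) {
      diTest <- unpairedTTest(dDi, pDi)
      outputs$di_ttest <- file.path(outDir, "di_ttest.json")
      jsonlite::write_json(
        list(mean_disease = diTest@means[1],
             mean_population = diTest@means[2],
             n_disease = diTest@n[1], n_population = diTest@n[2],
             t = diTest@statistic, df = diTest@df, p = diTest@pValue),
        outputs$di_ttest, auto_unbox = TRUE, digits = NA)
    } else log("too few structured variant positions for the Di t-test")

    if (!is.null(sca$decomposition)) {
      outputs$sector_report <- file.path(outDir, "sector_report.json")
      writeSectorReport(sca$decomposition, outputs$sector_report)
      mask <- sectorMembership(sca$decomposition, amap)
      secEnr <- enrichmentTest(annotated, "sector_vs_nonsector",
                               c(sum(mask), sum(dmap@structured) - sum(mask)),
                               sectorMask = mask)
      enrich$sector_vs_nonsector <- secEnr
      outputs$enrichment_sector <- file.path(outDir,
                                             "enrichment_sector_vs_nonsector.tsv")
      writeEnrichment(secEnr, outputs$enrichment_sector)
    } else log("no significant eigenmodes; sector sections skipped")
  } else log("no MSA supplied; conservation/sector sections skipped")

  manifest <- list(
    package = "cxvariants",
    version = as.character(utils::packageVersion("cxvariants")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = lapply(outputs, function(f)
      unname(tools::md5sum(f))),
    timestamp = format(Sys.time(), tz = "UTC"))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)

  invisible(c(outputs, list(manifest = manifestPath, enrichment = enrich,
                            overlap = overlap, sca = sca,
                            diTest = diTest)))
}
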