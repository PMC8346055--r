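## Partition enrichment statistics: exact Fisher test, ratios, densities,
## pooled t-test.

.PARTITIONS <- c("structured_vs_unstructured", "pore_vs_nonpore",
                 "CL_vs_CT", "sector_vs_nonsector")

#' Build a 2x2 cohort-by-partition contingency table
#'
#' Rows are cohorts (disease, population); columns are counts of unique
#' missense variants inside and outside the partition. `pore_vs_nonpore`
#' and `sector_vs_nonsector` are restricted to structured-domain variants;
#' `CL_vs_CT` is restricted to unstructured-domain variants.
#'
#' @param annotated A variant DataFrame carrying `cohort` plus the
#'   domain-annotation columns added by [locateVariantDomains()].
#' @param partition One of "structured_vs_unstructured", "pore_vs_nonpore",
#'   "CL_vs_CT", "sector_vs_nonsector".
#' @param sectorMask Logical vector over query residues (TRUE = sector),
#'   required for `sector_vs_nonsector`; see [sectorMembership()].
#' @return Integer 2x2 matrix with dimnames.
#' @export
contingencyCounts <- function(annotated, partition, sectorMask = NULL) {
  partition <- match.arg(partition, .PARTITIONS)
  need <- c("cohort", "position", "domain", "structured", "pore")
  if (!all(need %in% names(annotated)))
    stop("variants lack domain annotation; run locateVariantDomains() first",
         call. = FALSE)
  v <- annotated
  inPart <- switch(partition,
    structured_vs_unstructured = v$structured,
    pore_vs_nonpore = { v <- v[v$structured, , drop = FALSE]; v$pore },
    CL_vs_CT = { v <- v[!v$structured, , drop = FALSE]; v$domain == "CL" },
    sector_vs_nonsector = {
      if (is.null(sectorMask))
        stop("sector_vs_nonsector requires a sectorMask", call. = FALSE)
      v <- v[v$structured, , drop = FALSE]
      if (nrow(v) && max(v$position) > length(sectorMask))
        stop("sectorMask shorter than variant positions", call. = FALSE)
      sectorMask[v$position]
    })
  tab <- matrix(0L, 2, 2,
                dimnames = list(cohort = c("disease", "population"),
                                partition = c("in", "out")))
  for (co in c("disease", "population")) {
    sel <- v$cohort == co
    tab[co, "in"] <- sum(sel & inPart)
    tab[co, "out"] <- sum(sel & !inPart)
  }
  tab
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by point-probability ordering: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (within relative tolerance 1e-7). Computed in log space from
#' log-factorial sums.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(5, 5, 5, 5), 2))   # 1
#' fisherExactTwoSided(matrix(c(10, 0, 0, 10), 2)) # 2/choose(20,10)
#' @export
fisherExactTwoSided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("a 2x2 table is required", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (N == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  obs <- logp[xs == a]
  keep <- logp <= obs + log1p(1e-7)
  min(1, sum(exp(logp[keep])))
}

#' In/out count ratio for one cohort
#'
#' @param table 2x2 matrix from [contingencyCounts()].
#' @param cohort `"disease"` or `"population"` (or row index).
#' @return in-count / out-count; `0` when in = 0, `Inf` when out = 0 with
#'   in > 0, `NaN` for 0/0 (flagged undefined).
#' @export
distributionRatio <- function(table, cohort) {
  row <- if (is.character(cohort)) table[cohort, ] else table[cohort, ]
  unname(row[1] / row[2])
}

#' Length-normalised variant densities
#'
#' @param counts Numeric vector (or matrix) of variant counts.
#' @param lengths Strictly positive residue counts of the matching
#'   domains/partitions.
#' @return counts / lengths, elementwise.
#' @export
normalizedDensity <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  counts / lengths
}

#' Partition enrichment of disease vs population variants
#'
#' Assembles the contingency table, exact two-sided p-value, per-cohort
#' in/out ratios and length-normalised densities into one result.
#'
#' @inheritParams contingencyCounts
#' @param partitionLengths Numeric length-2 vector: residues inside and
#'   outside the partition (e.g. from [domainLengths()]).
#' @return An [EnrichmentResult-class].
#' @export
enrichmentTest <- function(annotated, partition, partitionLengths,
                           sectorMask = NULL) {
  tab <- contingencyCounts(annotated, partition, sectorMask)
  p <- fisherExactTwoSided(tab)
  ratios <- c(disease = distributionRatio(tab, "disease"),
              population = distributionRatio(tab, "population"))
  dens <- sweep(tab, 2, partitionLengths, "/")
  methods::new("EnrichmentResult", table = tab, partition = partition,
               pValue = p, ratios = ratios, densities = dens)
}

#' Unpaired Student's t-test (pooled variance)
#'
#' Two-sided pooled-variance t-test with df = n1 + n2 - 2. When both groups
#' have zero variance and equal means the p-value is 1 by contract.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @return A [TTestResult-class].
#' @export
unpairedTTest <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  m1 <- mean(group1); m2 <- mean(group2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  methods::new("TTestResult", means = c(m1, m2), n = c(n1, n2),
               statistic = t, df = as.numeric(df), pValue = p)
}

#' Serialise an EnrichmentResult
#'
#' @param x An [EnrichmentResult-class].
#' @param file Output path (.json or .tsv).
#' @return Invisibly, the path.
#' @export
writeEnrichment <- function(x, file) {
  obj <- list(partition = x@partition,
              table = list(disease = as.integer(x@table[1, ]),
                           population = as.integer(x@table[2, ])),
              p_value = x@pValue,
              ratio_disease = x@ratios[["disease"]],
              ratio_population = x@ratios[["population"]],
              density_disease = as.numeric(x@densities[1, ]),
              density_population = as.numeric(x@densities[2, ]))
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  } else {
    d <- data.frame(partition = x@partition,
                    cohort = rownames(x@table),
                    inside = x@table[, 1], outside = x@table[, 2],
                    ratio = unname(x@ratios),
                    density_in = x@densities[, 1],
                    density_out = x@densities[, 2],
                    p_value = x@pValue)
    utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
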