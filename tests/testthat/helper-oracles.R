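## Independent oracles and small shared fixtures for the test suite.
## Everything here re-derives expected values by a different route than
## the package implementation (enumeration, brute force, base R).

## Exhaustive-enumeration two-sided Fisher p for a 2x2 table, computed
## with exact binomial coefficients (point-probability ordering, same
## 1e-7 relative tie tolerance as the contract states).
fisherOracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (N == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pmf <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  obs <- pmf[xs == a]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

## Brute-force global alignment score: enumerate every alignment of two
## short sequences; a maximal gap run of length L costs open + ext * L.
oracleAlignScore <- function(q, r, open = 10, ext = 0.5, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, lastGap) {
    if (i > length(qc) && j > length(rc)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(qc) && j <= length(rc))
      rec(i + 1L, j + 1L, score + mat[qc[i], rc[j]], 0L)
    if (i <= length(qc))                      # gap in the reference
      rec(i + 1L, j, score - ext - if (lastGap == 1L) 0 else open, 1L)
    if (j <= length(rc))                      # gap in the query
      rec(i, j + 1L, score - ext - if (lastGap == 2L) 0 else open, 2L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

## Brute-force O(N^2) sequence weights: fractional identity = matching
## non-gap characters / width.
oracleWeights <- function(m, delta = 0.8) {
  n <- nrow(m)
  w <- numeric(n)
  for (s in seq_len(n)) {
    nb <- 0L
    for (t in seq_len(n)) {
      id <- sum(m[s, ] == m[t, ] & m[s, ] != "-") / ncol(m)
      if (t == s || id >= delta) nb <- nb + 1L   # self always counts
    }
    w[s] <- 1 / nb
  }
  w
}

## A small 9-segment segmentation used across tests: length 40,
## structured residues 5..28 (24), unstructured 1..4 + 29..40 (16).
smallSeg <- function() {
  DomainSegmentation(
    labels = c("NT", "M1", "E1", "M2", "CL", "M3", "E2", "M4", "CT"),
    starts = c(1L, 5L, 8L, 11L, 14L, 18L, 21L, 24L, 29L),
    ends   = c(4L, 7L, 10L, 13L, 17L, 20L, 23L, 28L, 40L))
}

## An annotated variant table over smallSeg()-like maps, built from
## explicit positions so tests control partition membership exactly.
makeAnnotated <- function(positionsDisease, positionsPopulation,
                          seg = smallSeg()) {
  n1 <- length(positionsDisease); n2 <- length(positionsPopulation)
  v <- S4Vectors::DataFrame(
    gene = "TESTG",
    cohort = rep(c("disease", "population"), c(n1, n2)),
    label = paste0("A", c(positionsDisease, positionsPopulation), "G"),
    position = as.integer(c(positionsDisease, positionsPopulation)),
    ref = "A", alt = "G", type = "missense", multiResidue = FALSE,
    allele_frequency = NA_real_, source = NA_character_)
  L <- refLength(seg)
  ident <- paste(rep("A", L), collapse = "")
  amap <- residueAlignmentMap(ident, ident)
  dmap <- buildDomainMap(amap, seg)
  locateVariantDomains(v, dmap)$variants
}

## Jaccard index of two integer sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
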