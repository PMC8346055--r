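test_that("filterAlignment applies the column and sequence filters in order", {
  cfg <- scaConfig(refIdMin = 0.2, refIdMax = 0.85, maxGapSeq = 0.4,
                   maxGapCol = 0.25)
  msa <- c(
    reference = "ACDEFGHIKL",
    good      = "ACDEFGHIKV",   # id 0.9 > refIdMax, but see below
    ok        = "ACDEFWYWYW",   # id 0.5
    gappy     = "AC-E---I--",   # gap fraction 0.6 > maxGapSeq
    faroff    = "WWWWWWWWWW")   # id 0 < refIdMin
  wal <- filterAlignment(msa, "reference", cfg = cfg)
  expect_setequal(rownames(alignmentMatrix(wal)), c("reference", "ok"))
  expect_equal(wal@refPositions, 1:10)

  ## reference gaps define the column restriction
  msa2 <- c(reference = "AC-EF", other = "ACDEF", other2 = "ACWEF")
  wal2 <- filterAlignment(msa2, "reference")
  expect_equal(ncol(alignmentMatrix(wal2)), 4L)
  expect_equal(wal2@refPositions, c(1L, 2L, 3L, 4L))

  ## a segmentation restricts to structured reference positions
  seg <- DomainSegmentation(c("M1", "CL"), c(1L, 3L), c(2L, 5L))
  msaSeg <- c(reference = "ACDEF", s1 = "ACWEF", s2 = "WCDEW")
  wal3 <- filterAlignment(msaSeg, "reference", seg = seg,
                          cfg = scaConfig(refIdMax = 1))
  expect_equal(wal3@refPositions, 1:2)
  expect_equal(ncol(alignmentMatrix(wal3)), 2L)

  ## gap-heavy columns are dropped after the sequence filters
  msa3 <- c(reference = "ACDEF", s1 = "AC-EF", s2 = "AC-EF", s3 = "ACDEF")
  wal4 <- filterAlignment(msa3, "reference",
                          cfg = scaConfig(maxGapCol = 0.2, refIdMax = 1))
  expect_equal(wal4@refPositions, c(1L, 2L, 4L, 5L))

  expect_error(filterAlignment(msa2, "nope"), "not found")
})

test_that("computeWeights matches the brute-force oracle and its invariants", {
  set.seed(5)
  aa <- aminoAcids()
  for (rep in 1:5) {
    m <- matrix(sample(c(aa, "-"), 25 * 8, TRUE,
                       prob = c(rep(0.0475, 20), 0.05)), 25, 8)
    rownames(m) <- paste0("s", 1:25)
    wal <- computeWeights(methods::new(
      "WeightedAlignment", aln = m, refPositions = 1:8,
      referenceId = "s1", weights = numeric(0), Meff = NA_real_,
      meanPairwiseIdentity = NA_real_), delta = 0.8)
    expect_equal(seqWeights(wal), oracleWeights(m, 0.8), tolerance = 1e-12)
    expect_true(all(seqWeights(wal) > 0 & seqWeights(wal) <= 1))
    expect_gte(effectiveSequences(wal), 1)
    expect_lte(effectiveSequences(wal), nrow(m))
  }
})

test_that("Meff is invariant to duplicating a sequence whose neighbours are its copies", {
  set.seed(8)
  aa <- aminoAcids()
  ## pairwise-dissimilar sequences: all weights 1, Meff = N
  base <- t(vapply(1:6, function(i) sample(aa, 15, TRUE), character(15)))
  rownames(base) <- paste0("s", 1:6)
  mkwal <- function(m) computeWeights(methods::new(
    "WeightedAlignment", aln = m, refPositions = 1:ncol(m),
    referenceId = rownames(m)[1], weights = numeric(0), Meff = NA_real_,
    meanPairwiseIdentity = NA_real_))
  w0 <- mkwal(base)
  expect_equal(effectiveSequences(w0), 6)
  ## duplicating s1 once: the pair split weight 1/2 + 1/2
  dup1 <- rbind(base, s1b = base[1, ])
  expect_equal(effectiveSequences(mkwal(dup1)), 6, tolerance = 1e-12)
  ## triplicating: 3 x 1/3
  dup2 <- rbind(dup1, s1c = base[1, ])
  expect_equal(effectiveSequences(mkwal(dup2)), 6, tolerance = 1e-12)
})

test_that("positionFrequencies matches a direct recomputation and sums to 1", {
  set.seed(12)
  aa <- aminoAcids()
  m <- matrix(sample(c(aa, "-"), 30 * 6, TRUE), 30, 6)
  rownames(m) <- paste0("s", 1:30)
  wal <- computeWeights(methods::new(
    "WeightedAlignment", aln = m, refPositions = 1:6, referenceId = "s1",
    weights = numeric(0), Meff = NA_real_,
    meanPairwiseIdentity = NA_real_))
  cfg <- scaConfig(lambda = 0.03)
  f <- positionFrequencies(wal, cfg)
  expect_equal(dim(f), c(6L, 20L))
  expect_equal(unname(rowSums(f)), rep(1, 6), tolerance = 1e-12)
  w <- seqWeights(wal)
  q <- cfg@backgroundFreqs
  for (i in c(1L, 4L)) {
    nonGap <- m[, i] != "-"
    raw <- vapply(aa, function(a) sum(w[nonGap & m[, i] == a]),
                  numeric(1)) / sum(w[nonGap])
    expect_equal(unname(f[i, ]), unname(0.97 * raw + 0.03 * q),
                 tolerance = 1e-12)
  }
})

test_that("conservationDi satisfies its closed forms and positivity", {
  q <- backgroundFrequencies()
  expect_equal(conservationDi(unname(q), q), 0)
  onehot <- c(1, rep(0, 19))
  expect_equal(conservationDi(onehot, rep(1 / 20, 20)), log(20))
  expect_equal(conservationDi(onehot, q), log(1 / q[["A"]]))
  set.seed(3)
  for (rep in 1:20) {
    f <- rexp(20); f <- f / sum(f)
    expect_gte(conservationDi(f, q), 0)
  }
  ## matrix form agrees with the vector form
  F <- rbind(onehot, unname(q))
  expect_equal(conservationDi(F, q),
               c(conservationDi(onehot, q), 0))
})

test_that("scaMatrix is symmetric, non-negative, and eigen-reconstructs", {
  set.seed(21)
  msa <- generateMSA(100, 25, conservation = 0.4, seed = 21)
  wal <- computeWeights(filterAlignment(msa$alignment, "reference"))
  Ct <- scaMatrix(wal)
  expect_equal(Ct, t(Ct))
  expect_true(all(Ct >= 0))
  eig <- eigen(Ct, symmetric = TRUE)
  rec <- eig$vectors %*% diag(eig$values) %*% t(eig$vectors)
  expect_lt(max(abs(rec - Ct)), 1e-8)
  expect_equal(sum(diag(Ct)), sum(eig$values), tolerance = 1e-8)
})

test_that("perfectly covarying columns couple far above independent ones", {
  set.seed(33)
  aa <- aminoAcids()
  n <- 300
  ## columns 1-2: two joint states; columns 3-6: independent uniform draws
  state <- sample(c(TRUE, FALSE), n, TRUE)
  m <- cbind(ifelse(state, "A", "C"), ifelse(state, "D", "E"),
             matrix(sample(aa, n * 4, TRUE), n, 4))
  rownames(m) <- paste0("s", seq_len(n))
  wal <- computeWeights(methods::new(
    "WeightedAlignment", aln = m, refPositions = 1:6, referenceId = "s1",
    weights = numeric(0), Meff = NA_real_,
    meanPairwiseIdentity = NA_real_))
  Ct <- scaMatrix(wal)
  offdiag <- Ct[upper.tri(Ct)]
  expect_equal(which.max(offdiag), 1L)          # the (1,2) entry
  others <- Ct[upper.tri(Ct)][-1]
  expect_gt(Ct[1, 2], 10 * max(others))
})

test_that("significantModes is seed-deterministic and counts against the null max", {
  msa <- generateMSA(80, 20, conservation = 0.5, seed = 14)
  wal <- computeWeights(filterAlignment(msa$alignment, "reference"))
  Ct <- scaMatrix(wal)
  cfg <- scaConfig(nRandomTrials = 5L)
  a <- significantModes(Ct, wal, cfg, seed = 99)
  b <- significantModes(Ct, wal, cfg, seed = 99)
  expect_identical(a$nullMax, b$nullMax)
  expect_equal(length(a$nullMax), 5L)
  expect_equal(a$values, sort(a$values, decreasing = TRUE))
  expect_equal(a$k, sum(a$values[-1] > max(a$nullMax)))
  cfg2 <- scaConfig(nRandomTrials = 5L, includeFirstMode = TRUE)
  a2 <- significantModes(Ct, wal, cfg2, seed = 99)
  expect_equal(a2$k, sum(a$values > max(a2$nullMax)))
})

test_that("extractSectors recovers a planted two-group structure", {
  msa <- generateMSA(250, 100, conservation = 0.3,
                     coupledGroups = list(
                       list(columns = 11:15, strength = 0.9),
                       list(columns = 61:65, strength = 0.9)),
                     seed = 42)
  cfg <- scaConfig(includeFirstMode = TRUE)
  res <- runSCA(msa$alignment, "reference", cfg = cfg, seed = 42)
  expect_gte(res$modes$k, 2)
  decomp <- res$decomposition
  expect_s4_class(decomp, "SectorDecomposition")
  sr <- sectorResidues(decomp)
  j1 <- max(vapply(sr, jaccard, 0, b = 11:15))
  j2 <- max(vapply(sr, jaccard, 0, b = 61:65))
  expect_gte(j1, 0.8)
  expect_gte(j2, 0.8)
  ## IC loadings are oriented with the largest-magnitude entry positive
  for (j in seq_len(ncol(decomp@icLoadings)))
    expect_gt(decomp@icLoadings[
      which.max(abs(decomp@icLoadings[, j])), j], 0)
  ## each IC selects ceiling(icTail * p) residues
  p <- nrow(res$Ctilde)
  expect_true(all(lengths(icResidues(decomp)) == ceiling(0.05 * p)))
  ## sector residues are unions of their ICs' residues
  for (s in seq_along(decomp@sectors)) {
    un <- sort(unique(unlist(icResidues(decomp)[decomp@sectors[[s]]])))
    expect_equal(sr[[s]], un)
  }
})

test_that("sectorMembership maps sector positions through an alignment map", {
  msa <- generateMSA(250, 100, conservation = 0.3,
                     coupledGroups = list(
                       list(columns = 11:15, strength = 0.9)),
                     seed = 5)
  res <- runSCA(msa$alignment, "reference",
                cfg = scaConfig(includeFirstMode = TRUE), seed = 5)
  decomp <- res$decomposition
  sectorPos <- sort(unique(unlist(sectorResidues(decomp))))
  mask <- sectorMembership(decomp, queryLength = 100L)
  expect_equal(which(mask), sectorPos)
  ## through a map with a 2-residue N-terminal insertion in the query
  ref <- paste(rep("A", 100), collapse = "")
  amap <- residueAlignmentMap(paste0("AA", ref), paste0("--", ref))
  mask2 <- sectorMembership(decomp, amap)
  expect_equal(which(mask2), sectorPos + 2L)
  expect_error(sectorMembership(decomp), "amap or queryLength")
})

test_that("runSCA output pieces are mutually consistent", {
  msa <- generateMSA(120, 30, conservation = 0.5, seed = 77)
  res <- runSCA(msa$alignment, "reference", seed = 77)
  wal <- res$alignment
  expect_equal(length(seqWeights(wal)), nrow(alignmentMatrix(wal)))
  expect_equal(effectiveSequences(wal), sum(seqWeights(wal)))
  expect_gt(wal@meanPairwiseIdentity, 0)
  expect_lt(wal@meanPairwiseIdentity, 1)
  expect_equal(length(DiValues(res$profile)), ncol(alignmentMatrix(wal)))
  expect_equal(dim(res$Ctilde), rep(ncol(alignmentMatrix(wal)), 2))
  expect_equal(names(DiValues(res$profile)),
               as.character(res$profile@positions))
})

test_that("aligned FASTA round-trips", {
  msa <- c(ref = "ACD-E", s1 = "ACDEE")
  f <- tempfile(fileext = ".fasta")
  writeAlignedFasta(msa, f)
  back <- readAlignedFasta(f)
  expect_equal(back, msa)
})
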