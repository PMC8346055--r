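## Conservation and statistical coupling analysis of a connexin MSA:
## alignment filtering, sequence weighting, Kullback-Leibler conservation,
## conservation-weighted covariation matrix, eigenmode significance against
## a column-permutation null, independent components and sectors.

#' Construct an SCAConfig
#'
#' @param backgroundFreqs Background amino-acid distribution q (20 values,
#'   indexed by [aminoAcids()]); default [backgroundFrequencies()].
#' @param lambda Pseudocount fraction; default 0.03.
#' @param deltaWeight Sequence-weight identity threshold; default 0.8.
#' @param refIdMin,refIdMax Fractional-identity bounds to the reference for
#'   keeping a sequence; defaults 0.2 and 0.85 (the raised upper bound
#'   keeps closely related paralogue pairs such as the two lens connexins).
#' @param maxGapSeq,maxGapCol Maximum gap fraction per sequence / per
#'   column; defaults 0.4 and 0.2.
#' @param nRandomTrials Randomization trials for the eigenmode null;
#'   default 10.
#' @param icTail Tail fraction of the loading CDF defining IC residues;
#'   default 0.05.
#' @param includeFirstMode Include the first (global conservation)
#'   eigenmode among significance/ICA candidates; default FALSE.
#' @param icaTol,icaMaxIter ICA convergence tolerance (1e-8) and iteration
#'   cap (1000).
#' @return An [SCAConfig-class].
#' @export
scaConfig <- function(backgroundFreqs = backgroundFrequencies(),
                      lambda = 0.03, deltaWeight = 0.8,
                      refIdMin = 0.2, refIdMax = 0.85,
                      maxGapSeq = 0.4, maxGapCol = 0.2,
                      nRandomTrials = 10L, icTail = 0.05,
                      includeFirstMode = FALSE,
                      icaTol = 1e-8, icaMaxIter = 1000L) {
  methods::new("SCAConfig",
               backgroundFreqs = unname(backgroundFreqs), lambda = lambda,
               deltaWeight = deltaWeight, refIdMin = refIdMin,
               refIdMax = refIdMax, maxGapSeq = maxGapSeq,
               maxGapCol = maxGapCol,
               nRandomTrials = as.integer(nRandomTrials), icTail = icTail,
               includeFirstMode = includeFirstMode, icaTol = icaTol,
               icaMaxIter = as.integer(icaMaxIter))
}

#' Read an aligned FASTA file
#'
#' @param file Path to an aligned FASTA (equal-width rows, `-` gaps).
#' @return Named character vector of gapped sequences.
#' @export
readAlignedFasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' Write an alignment as FASTA
#'
#' @param seqs Named character vector (or WeightedAlignment) to write.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeAlignedFasta <- function(seqs, file) {
  if (methods::is(seqs, "WeightedAlignment"))
    seqs <- apply(alignmentMatrix(seqs), 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), file)
  invisible(file)
}

#' Filter an MSA to reference-mapped structured columns and usable rows
#'
#' In order: (1) columns are restricted to those where the reference row is
#' non-gap and (when a segmentation is given) the reference residue lies in
#' a structured segment; (2) sequences are dropped when their gap fraction
#' exceeds `maxGapSeq` or their fractional identity to the reference falls
#' outside `[refIdMin, refIdMax]` (the reference itself is always kept);
#' (3) columns with gap fraction above `maxGapCol` are dropped. Fractional
#' identity is the number of matching non-gap characters divided by the
#' restricted alignment width.
#'
#' @param msa Aligned sequences: named character vector, character matrix,
#'   or Biostrings object.
#' @param referenceId Name of the reference row (must be present).
#' @param seg Optional [DomainSegmentation-class]; structured segments
#'   define the retained reference positions. NULL keeps all reference
#'   non-gap columns.
#' @param cfg An [SCAConfig-class].
#' @return A [WeightedAlignment-class] (weights not yet computed).
#' @export
filterAlignment <- function(msa, referenceId, seg = NULL,
                            cfg = scaConfig()) {
  m <- .asAlnMatrix(msa)
  if (is.null(rownames(m)) || !(referenceId %in% rownames(m)))
    stop("reference id '", referenceId, "' not found in the alignment",
         call. = FALSE)
  refRow <- m[referenceId, ]
  refPos <- cumsum(refRow != "-")
  keepCol <- refRow != "-"
  if (!is.null(seg)) {
    lab <- residueLabels(seg)
    if (sum(refRow != "-") != refLength(seg))
      stop("reference row has ", sum(refRow != "-"),
           " residues but the segmentation covers ", refLength(seg),
           call. = FALSE)
    keepCol <- keepCol & lab[pmax(refPos, 1L)] %in% structuredLabels()
  }
  m <- m[, keepCol, drop = FALSE]
  refPositions <- refPos[keepCol]

  ## sequence filters
  gapFrac <- rowMeans(m == "-")
  refIdent <- .identityToRow(m, m[referenceId, ])
  keepSeq <- gapFrac <= cfg@maxGapSeq &
    refIdent >= cfg@refIdMin & refIdent <= cfg@refIdMax
  keepSeq[rownames(m) == referenceId] <- TRUE
  m <- m[keepSeq, , drop = FALSE]
  if (!nrow(m)) stop("all sequences filtered out", call. = FALSE)

  ## column gap filter
  colGap <- colMeans(m == "-")
  m <- m[, colGap <= cfg@maxGapCol, drop = FALSE]
  refPositions <- refPositions[colGap <= cfg@maxGapCol]
  if (!ncol(m)) stop("all columns filtered out", call. = FALSE)

  methods::new("WeightedAlignment", aln = m,
               refPositions = as.integer(refPositions),
               referenceId = referenceId,
               weights = numeric(0), Meff = NA_real_,
               meanPairwiseIdentity = NA_real_)
}

#' Compute sequence weights and the effective sequence count
#'
#' Each sequence receives weight 1 / (number of sequences, itself
#' included, with fractional identity >= delta); Meff is the sum of the
#' weights. Also records the average pairwise fractional identity of the
#' alignment.
#'
#' @param wal A [WeightedAlignment-class].
#' @param delta Identity threshold; defaults to the value used by
#'   [scaConfig()] (0.8).
#' @return The input with `weights`, `Meff` and `meanPairwiseIdentity`
#'   filled in.
#' @export
computeWeights <- function(wal, delta = 0.8) {
  m <- wal@aln
  n <- nrow(m)
  if (!n) stop("empty alignment", call. = FALSE)
  sim <- .pairwiseIdentity(m)
  ## a sequence is always its own neighbour (its nominal self-identity
  ## can fall below delta when it carries gaps)
  diag(sim) <- 1
  neighbours <- rowSums(sim >= delta)
  w <- 1 / neighbours
  meanPid <- if (n > 1) mean(sim[upper.tri(sim)]) else 1
  methods::initialize(wal, weights = unname(w), Meff = sum(w),
                      meanPairwiseIdentity = meanPid)
}

#' Regularised weighted amino-acid frequencies per position
#'
#' f_i^a = (1 - lambda) * (sum_s w_s 1[x_si = a] / Meff_i) + lambda * q_a,
#' where Meff_i sums the weights of sequences that are non-gap at column i.
#' Gaps are excluded from the 20-state simplex (each column renormalised
#' over its non-gapped sequences).
#'
#' @param wal A weighted [WeightedAlignment-class] (see [computeWeights()]).
#' @param cfg An [SCAConfig-class] (lambda and background q).
#' @return Numeric matrix (positions x 20), rows summing to 1.
#' @export
positionFrequencies <- function(wal, cfg = scaConfig()) {
  if (!length(wal@weights))
    stop("weights not computed; call computeWeights() first", call. = FALSE)
  m <- wal@aln
  w <- wal@weights
  q <- cfg@backgroundFreqs
  aa <- aminoAcids()
  p <- ncol(m)
  raw <- matrix(0, p, 20, dimnames = list(NULL, aa))
  for (a in seq_along(aa))
    raw[, a] <- colSums(w * (m == aa[a]))
  meffI <- colSums(w * (m != "-"))
  raw <- raw / ifelse(meffI > 0, meffI, 1)
  raw[meffI == 0, ] <- rep(q, each = sum(meffI == 0))
  f <- (1 - cfg@lambda) * raw + cfg@lambda * rep(q, each = p)
  f
}

#' Kullback-Leibler conservation score
#'
#' Di = sum_a f_a log(f_a / q_a) (natural log); 0 iff f = q, and ln(20)
#' for a fully conserved residue under a uniform background.
#'
#' @param f Frequency vector (20) or matrix (positions x 20).
#' @param q Background distribution (20 values).
#' @return Numeric Di value(s), >= 0.
#' @export
conservationDi <- function(f, q = backgroundFrequencies()) {
  q <- unname(q)
  if (is.matrix(f)) {
    term <- f * log(sweep(f, 2, q, "/"))
    term[f == 0] <- 0            # x log x -> 0 limit
    as.numeric(rowSums(term))
  } else {
    term <- f * log(f / q)
    term[f == 0] <- 0
    sum(term)
  }
}

#' Per-position conservation profile of a weighted alignment
#'
#' @param wal A weighted [WeightedAlignment-class].
#' @param cfg An [SCAConfig-class].
#' @return A [ConservationProfile-class].
#' @export
conservationProfile <- function(wal, cfg = scaConfig()) {
  f <- positionFrequencies(wal, cfg)
  di <- conservationDi(f, cfg@backgroundFreqs)
  methods::new("ConservationProfile", positions = wal@refPositions,
               freqs = f, Di = pmax(di, 0),
               background = cfg@backgroundFreqs, lambda = cfg@lambda)
}

## Internal: N x (p*20) binary indicator of the alignment, column layout
## (position i, amino acid a) -> (i-1)*20 + a.
.alnIndicator <- function(m) {
  n <- nrow(m); p <- ncol(m)
  aa <- aminoAcids()
  X <- matrix(0, n, p * 20L)
  code <- match(m, aa)           # NA for gaps
  hit <- which(!is.na(code))
  rows <- ((hit - 1L) %% n) + 1L
  cols <- ((hit - 1L) %/% n) + 1L
  X[cbind(rows, (cols - 1L) * 20L + code[hit])] <- 1
  X
}

#' Conservation-weighted covariation matrix
#'
#' Raw weighted covariances C_ij^ab = f_ij^ab - f_i^a f_j^b are reduced to
#' one coupling value per position pair by the Frobenius norm of the
#' positionally weighted tensor phi_i^a phi_j^b C_ij^ab, where
#' phi_i^a = ln[f_i^a (1 - q_a) / ((1 - f_i^a) q_a)] is the gradient of
#' the binary relative entropy at the regularised frequency. The diagonal
#' is retained. Joint and marginal frequencies inside the covariance use
#' raw weighted counts normalised by Meff (so statistically independent
#' columns give vanishing coupling); the pseudocount enters only through
#' phi.
#'
#' @param wal A weighted [WeightedAlignment-class].
#' @param cfg An [SCAConfig-class].
#' @return Symmetric non-negative numeric matrix (positions x positions).
#' @export
scaMatrix <- function(wal, cfg = scaConfig()) {
  if (ncol(wal@aln) < 2)
    stop("at least two positions are required", call. = FALSE)
  if (!length(wal@weights))
    stop("weights not computed; call computeWeights() first", call. = FALSE)
  p <- ncol(wal@aln)
  w <- wal@weights
  meff <- sum(w)
  X <- .alnIndicator(wal@aln)
  f1 <- colSums(X * w) / meff
  C <- crossprod(X * sqrt(w)) / meff
  C <- C - tcrossprod(f1)
  f <- positionFrequencies(wal, cfg)
  q <- cfg@backgroundFreqs
  phiMat <- log(f * rep(1 - q, each = p) / ((1 - f) * rep(q, each = p)))
  phi <- as.numeric(t(phiMat))     # layout (i-1)*20 + a
  C <- phi * C
  C <- t(phi * t(C))
  C <- C * C
  grp <- rep(seq_len(p), each = 20L)
  B <- rowsum(C, grp)
  Ct <- sqrt(t(rowsum(t(B), grp)))
  Ct <- (Ct + t(Ct)) / 2           # enforce exact symmetry
  dimnames(Ct) <- list(wal@refPositions, wal@refPositions)
  Ct
}

## Internal: run `expr` under a temporary seed, restoring RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Significant eigenmodes of the coupling matrix
#'
#' Eigendecomposition of the coupling matrix compared against a null built
#' by independently permuting each alignment column across sequences
#' (destroying inter-column correlation while preserving composition) and
#' rebuilding the matrix, `nRandomTrials` times. The number of significant
#' modes k counts the true eigenvalues exceeding the largest eigenvalue
#' seen in any null trial; the first (global conservation) mode is excluded
#' from the count unless `includeFirstMode` is set.
#'
#' @param Ct Coupling matrix from [scaMatrix()].
#' @param wal The weighted [WeightedAlignment-class] it came from.
#' @param cfg An [SCAConfig-class].
#' @param seed Optional integer seed for the permutation null.
#' @return List with `values` (descending eigenvalues), `vectors`,
#'   `nullMax` (per-trial maximum null eigenvalue) and `k`.
#' @export
significantModes <- function(Ct, wal, cfg = scaConfig(), seed = NULL) {
  eig <- eigen(Ct, symmetric = TRUE)
  nullMax <- .withSeed(seed, {
    vapply(seq_len(cfg@nRandomTrials), function(t) {
      m <- wal@aln
      for (j in seq_len(ncol(m)))
        m[, j] <- m[sample.int(nrow(m)), j]
      walPerm <- methods::initialize(wal, aln = m)
      max(eigen(scaMatrix(walPerm, cfg), symmetric = TRUE,
                only.values = TRUE)$values)
    }, numeric(1))
  })
  cand <- if (cfg@includeFirstMode) eig$values else eig$values[-1]
  list(values = eig$values, vectors = eig$vectors, nullMax = nullMax,
       k = sum(cand > max(nullMax)))
}

## Internal: symmetric fixed-point ICA (tanh contrast) on k signals given
## as columns of V (p x k). Returns the k x k unmixing applied to the
## whitened signals, as loadings (p x k).
.fastICA <- function(V, tol = 1e-8, maxIter = 1000L) {
  k <- ncol(V)
  Z <- t(scale(V, center = TRUE, scale = FALSE))   # k x p signals
  p <- ncol(Z)
  ## whiten
  cv <- tcrossprod(Z) / p
  e <- eigen(cv, symmetric = TRUE)
  K <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-15)), k) %*%
    t(e$vectors)
  Z <- K %*% Z
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  decorrelate <- function(W) {
    s <- tcrossprod(W)
    es <- eigen(s, symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-15)), k) %*%
      t(es$vectors) %*% W
  }
  W <- decorrelate(W)
  for (it in seq_len(maxIter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    W1 <- G %*% t(Z) / p - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- decorrelate(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
    if (it == maxIter)
      stop("ICA did not converge within ", maxIter,
           " iterations; try another seed", call. = FALSE)
  }
  t(W %*% Z)                                      # p x k loadings
}

#' Independent components and sector grouping
#'
#' Rotates the top-k eigenvectors into independent components by symmetric
#' fixed-point ICA (tanh contrast), orients each loading vector so its
#' largest-magnitude entry is positive, selects each IC's residues as the
#' top `icTail` fraction of its empirical loading distribution, and groups
#' ICs into sectors by average-linkage clustering of the mean inter-IC
#' coupling (mean of the coupling matrix between the two ICs' residue
#' sets), cutting the dendrogram at the number of groups that maximises
#' the ratio of within- to between-group mean coupling. A sector's residue
#' set is the union of its ICs' residue sets.
#'
#' @param modes Result of [significantModes()].
#' @param Ct The coupling matrix.
#' @param cfg An [SCAConfig-class].
#' @param seed Optional seed for the ICA initialisation.
#' @param positions Integer reference positions labelling the matrix rows.
#' @param nSectors Optional override forcing the number of sectors.
#' @return A [SectorDecomposition-class].
#' @export
extractSectors <- function(modes, Ct, cfg = scaConfig(), seed = NULL,
                           positions = as.integer(rownames(Ct)),
                           nSectors = NULL) {
  k <- modes$k
  if (k < 1) stop("no significant eigenmodes (k = 0)", call. = FALSE)
  p <- nrow(Ct)
  idx <- if (cfg@includeFirstMode) seq_len(k) else seq_len(k) + 1L
  V <- modes$vectors[, idx, drop = FALSE]
  loadings <- if (k == 1L) V else
    .withSeed(seed, .fastICA(V, cfg@icaTol, cfg@icaMaxIter))
  ## orient: largest-magnitude loading positive
  for (j in seq_len(k))
    if (loadings[which.max(abs(loadings[, j])), j] < 0)
      loadings[, j] <- -loadings[, j]
  nTop <- max(1L, ceiling(cfg@icTail * p))
  icRes <- lapply(seq_len(k), function(j)
    sort(order(loadings[, j], decreasing = TRUE)[seq_len(nTop)]))

  ## mean inter-IC coupling (self term = mean within-IC off-diagonal)
  S <- matrix(0, k, k)
  for (u in seq_len(k)) for (v in seq_len(k)) {
    block <- Ct[icRes[[u]], icRes[[v]], drop = FALSE]
    if (u == v) {
      n <- length(icRes[[u]])
      S[u, v] <- if (n > 1) (sum(block) - sum(diag(block))) / (n * (n - 1))
                 else 0
    } else S[u, v] <- mean(block)
  }

  if (k == 1L) {
    sectors <- list(1L)
  } else {
    d <- stats::as.dist(max(S) - S)
    hc <- stats::hclust(d, method = "average")
    ms <- if (!is.null(nSectors)) nSectors else {
      ratio <- vapply(2:k, function(m) {
        g <- stats::cutree(hc, k = m)
        same <- outer(g, g, "==")
        within <- mean(S[same])
        between <- mean(S[!same])
        if (between <= 0) Inf else within / between
      }, numeric(1))
      (2:k)[which.max(ratio)]
    }
    g <- stats::cutree(hc, k = ms)
    sectors <- split(seq_len(k), g)
    names(sectors) <- NULL
  }
  sectorRes <- lapply(sectors, function(ics)
    sort(unique(positions[unlist(icRes[ics])])))

  methods::new("SectorDecomposition", Ctilde = Ct,
               positions = as.integer(positions),
               eigenvalues = modes$values, eigenvectors = modes$vectors,
               nullMax = modes$nullMax, k = as.integer(k),
               icLoadings = loadings, icResidues = icRes,
               sectors = sectors, sectorResidues = sectorRes)
}

#' Per-residue sector membership of a query protein
#'
#' Maps the union of all sector residue positions (reference numbering)
#' through a query-to-reference alignment map onto the query, yielding the
#' boolean sector mask consumed by [contingencyCounts()] for the
#' sector-vs-nonsector partition.
#'
#' @param decomp A [SectorDecomposition-class].
#' @param amap A [ResidueAlignmentMap-class] for the query; NULL treats the
#'   query as the reference itself.
#' @param queryLength Query protein length when `amap` is NULL.
#' @return Logical vector, one entry per query residue.
#' @export
sectorMembership <- function(decomp, amap = NULL, queryLength = NULL) {
  sectorPos <- sort(unique(unlist(decomp@sectorResidues)))
  if (is.null(amap)) {
    if (is.null(queryLength))
      stop("supply amap or queryLength", call. = FALSE)
    out <- logical(queryLength)
    out[sectorPos[sectorPos <= queryLength]] <- TRUE
    return(out)
  }
  !is.na(amap@map) & amap@map %in% sectorPos
}

#' Run the full conservation/coupling analysis
#'
#' Convenience wrapper: filter, weight, profile, coupling matrix,
#' eigenmode significance and sector extraction.
#'
#' @param msa Aligned sequences (see [filterAlignment()]).
#' @param referenceId Reference row name.
#' @param seg Optional [DomainSegmentation-class].
#' @param cfg An [SCAConfig-class].
#' @param seed Optional integer seed (permutation null and ICA).
#' @return List with `alignment` (WeightedAlignment), `profile`
#'   (ConservationProfile), `Ctilde`, `modes` and, when k >= 1,
#'   `decomposition` (SectorDecomposition; NULL otherwise).
#' @export
runSCA <- function(msa, referenceId, seg = NULL, cfg = scaConfig(),
                   seed = NULL) {
  wal <- filterAlignment(msa, referenceId, seg, cfg)
  wal <- computeWeights(wal, cfg@deltaWeight)
  prof <- conservationProfile(wal, cfg)
  Ct <- scaMatrix(wal, cfg)
  modes <- significantModes(Ct, wal, cfg,
                            seed = if (is.null(seed)) NULL else seed)
  decomp <- if (modes$k >= 1)
    extractSectors(modes, Ct, cfg,
                   seed = if (is.null(seed)) NULL else seed + 1L,
                   positions = wal@refPositions)
  else NULL
  list(alignment = wal, profile = prof, Ctilde = Ct, modes = modes,
       decomposition = decomp)
}

#' Write a conservation profile as TSV
#'
#' @param profile A [ConservationProfile-class].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeConservationProfile <- function(profile, file) {
  utils::write.table(
    data.frame(position = profile@positions, Di = profile@Di),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a sector decomposition as JSON
#'
#' @param decomp A [SectorDecomposition-class].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeSectorReport <- function(decomp, file) {
  obj <- list(
    n_positions = nrow(decomp@Ctilde),
    eigenvalues = decomp@eigenvalues,
    null_max_eigenvalues = decomp@nullMax,
    n_significant_modes = decomp@k,
    ic_residues = lapply(icResidues(decomp), as.integer),
    sectors = lapply(decomp@sectors, as.integer),
    sector_residues = lapply(decomp@sectorResidues, as.integer))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a coupling matrix as TSV
#'
#' @param Ct Matrix from [scaMatrix()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeCouplingMatrix <- function(Ct, file) {
  utils::write.table(Ct, file, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(file)
}
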