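## Shared constants and small numeric helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in the conventional
#' alphabetical order used throughout the package (frequency vectors and
#' matrices are indexed in this order).
#'
#' @return Character vector of length 20.
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Background amino-acid frequencies
#'
#' A standard database-wide amino-acid composition used as the background
#' distribution q for conservation scores and positional weights. Indexed
#' by [aminoAcids()]; sums to 1.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
backgroundFrequencies <- function() {
  q <- c(A = 0.073, C = 0.025, D = 0.050, E = 0.061, F = 0.042,
         G = 0.072, H = 0.023, I = 0.053, K = 0.064, L = 0.089,
         M = 0.023, N = 0.043, P = 0.052, Q = 0.040, R = 0.052,
         S = 0.073, T = 0.056, V = 0.063, W = 0.013, Y = 0.033)
  q / sum(q)
}

## Mapping between three-letter and one-letter codes, including stop.
.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
             Ter = "*")

#' Round half away from zero
#'
#' Deterministic half-up rounding for reporting integer percentages
#' (base round() ties to even, which disagrees with conventional
#' hand-rounded printed values).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Internal: validate a vector of one-letter amino acids.
.checkAA <- function(aa, what = "amino acid") {
  bad <- !(aa %in% aminoAcids())
  if (any(bad)) {
    stop("non-standard ", what, " code: ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(aa)
}

## Internal: character matrix from an alignment-like object. Accepts a
## character matrix, a named character vector of equal-length strings, or a
## Biostrings XStringSet / AAMultipleAlignment.
.asAlnMatrix <- function(x) {
  if (is.matrix(x) && is.character(x)) return(x)
  if (methods::is(x, "AAMultipleAlignment")) {
    x <- Biostrings::unmasked(x)
  }
  if (methods::is(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    w <- unique(nchar(x))
    if (length(w) != 1L)
      stop("alignment rows differ in width; supply an aligned FASTA",
           call. = FALSE)
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
    return(toupper(m))
  }
  stop("cannot interpret object of class ", class(x)[1L], " as an alignment",
       call. = FALSE)
}

## Internal: fractional identity between rows of an alignment matrix and one
## row (or all pairs). Identity = matching non-gap characters / alignment
## width. Gaps never count as matches.
.identityToRow <- function(m, row) {
  hits <- sweep(m == rep(row, each = nrow(m)), 2, row != "-", "&")
  rowSums(hits) / ncol(m)
}

## Internal: all-pairs fractional identity matrix (match count / width).
.pairwiseIdentity <- function(m) {
  n <- nrow(m); p <- ncol(m)
  aa <- c(aminoAcids(), "-")
  ## one-hot encode per letter, gaps excluded from matches
  sim <- matrix(0, n, n)
  for (a in aminoAcids()) {
    ind <- (m == a) * 1
    sim <- sim + tcrossprod(ind)
  }
  sim / p
}
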