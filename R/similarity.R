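## Bit-vector similarity and distance metrics over fingerprints, and the
## all-vs-all matrix tool. With A = |a|, B = |b|, C = |a AND b|:
##   Tanimoto            C / (A + B - C)
##   Tversky(alpha,beta) C / (C + alpha (A - C) + beta (B - C))
##   Cosine              C / sqrt(A B)
##   Manhattan           A + B - 2C
##   Euclidean           sqrt(A + B - 2C)
##   SquareEuclidean     A + B - 2C
##   HalfSquareEuclidean (A + B - 2C) / 2
##   Soergel             (A + B - 2C) / (A + B - C)
## The first argument of Tversky is the reference: with alpha = 1 and
## beta = 0 the value is the fraction of the reference's interactions
## recapitulated in the model. Similarities on two all-zero vectors take
## the 0/0 -> 0 convention, with a warning.

SIFT_METRICS <- c("Tanimoto", "Cosine", "Manhattan", "Euclidean",
                  "SquareEuclidean", "HalfSquareEuclidean", "Soergel",
                  "Tversky")

asBits <- function(x) {
  if (is(x, "SIFt")) x <- siftBits(x)
  x <- as.integer(x)
  if (any(is.na(x)) || !all(x %in% c(0L, 1L)))
    siftStop("siftna_usage_error", "fingerprints must be binary 0/1 vectors")
  x
}

#' Similarity or distance between two binary fingerprints
#'
#' Computes one of the eight supported bit-vector metrics from the set-bit
#' counts A, B and the overlap C. Tversky is asymmetric for
#' \code{alpha != beta}; its first argument is the reference fingerprint,
#' and the common choice \code{alpha = 1, beta = 0} measures the fraction
#' of reference interactions recapitulated in the model. For the
#' similarity metrics (Tanimoto, Cosine, Tversky) two all-zero vectors
#' yield 0 with a warning (0/0 convention).
#'
#' @param a,b Binary vectors (or [SIFt-class] objects) of equal length;
#'   \code{a} is the Tversky reference.
#' @param metric One of \code{Tanimoto}, \code{Cosine}, \code{Manhattan},
#'   \code{Euclidean}, \code{SquareEuclidean}, \code{HalfSquareEuclidean},
#'   \code{Soergel}, \code{Tversky}.
#' @param alpha,beta Tversky weights (defaults 1 and 0).
#' @param verbose If TRUE, attach the counts A, B, C as an attribute.
#' @return A single numeric value.
#' @examples
#' fingerprintSimilarity(c(1,1,0,0,1,0), c(1,0,1,0,1,0), "Tanimoto")
#' @export
fingerprintSimilarity <- function(a, b, metric = "Tanimoto", alpha = 1,
                                  beta = 0, verbose = FALSE) {
  if (!metric %in% SIFT_METRICS)
    siftStop("siftna_usage_error", "unknown metric '%s'; supported: %s",
             metric, paste(SIFT_METRICS, collapse = ", "))
  if (alpha < 0 || beta < 0)
    siftStop("siftna_usage_error", "Tversky weights must be non-negative")
  a <- asBits(a); b <- asBits(b)
  if (length(a) != length(b))
    siftStop("siftna_length_error", "fingerprint lengths differ (%d vs %d)",
             length(a), length(b))
  A <- sum(a); B <- sum(b); C <- sum(a & b)
  zeroZero <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s of two all-zero fingerprints defined as 0", what))
      return(0)
    }
    num / den
  }
  val <- switch(metric,
    Tanimoto = zeroZero(C, A + B - C, "Tanimoto"),
    Tversky = zeroZero(C, C + alpha * (A - C) + beta * (B - C), "Tversky"),
    Cosine = zeroZero(C, sqrt(A) * sqrt(B), "Cosine"),
    Manhattan = A + B - 2 * C,
    Euclidean = sqrt(A + B - 2 * C),
    SquareEuclidean = A + B - 2 * C,
    HalfSquareEuclidean = (A + B - 2 * C) / 2,
    Soergel = if (A + B - C == 0) 0 else (A + B - 2 * C) / (A + B - C))
  if (verbose) attr(val, "counts") <- c(A = A, B = B, C = C)
  val
}

#' All-vs-all fingerprint distance matrix
#'
#' Computes the square matrix of one metric over a set of fingerprints
#' sharing one manifest. Rows and columns are labelled by ligand
#' identifier. The matrix is symmetric for every metric except Tversky
#' with \code{alpha != beta} (rows are the reference).
#'
#' @param sifts List of [SIFt-class] objects, or a 0/1 matrix with one
#'   fingerprint per row (e.g. from [readSiftTSV()]).
#' @param metric,alpha,beta As in [fingerprintSimilarity()].
#' @param path Optional TSV output path (header row/column of ligand ids).
#' @return Numeric matrix.
#' @export
distanceMatrix <- function(sifts, metric = "Tanimoto", alpha = 1, beta = 0,
                           path = NULL) {
  if (is.list(sifts) && length(sifts) && is(sifts[[1]], "SIFt")) {
    ref <- sifts[[1]]
    for (s in sifts)
      if (!identical(s@manifest, ref@manifest) ||
          !identical(s@channels, ref@channels))
        siftStop("siftna_manifest_error",
                 "fingerprints do not share a residue manifest")
    m <- do.call(rbind, lapply(sifts, siftBits))
    rownames(m) <- vapply(sifts, ligandLabel, "")
  } else {
    m <- as.matrix(sifts)
    if (is.null(rownames(m))) rownames(m) <- paste0("fp", seq_len(nrow(m)))
  }
  if (!nrow(m))
    siftStop("siftna_usage_error", "need at least one fingerprint")
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- suppressWarnings(
      fingerprintSimilarity(m[i, ], m[j, ], metric, alpha, beta))
  if (!is.null(path)) {
    tab <- data.frame(ligand_id = rownames(out), out, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
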