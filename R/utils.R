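## Internal helpers: condition signalling, vector geometry.

siftStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "siftna_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) siftStop("siftna_geometry_error", "zero-length vector")
  v / n
}

## Angle at vertex b of the triangle a-b-c, in degrees.
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

## Angle between two direction vectors folded to [0, 90] degrees
## (ring normals have no sign convention).
foldedAngle <- function(u, v) {
  cosang <- abs(sum(unit(u) * unit(v)))
  acos(pmin(1, cosang)) * 180 / pi
}

## Dihedral angle a-b-c-d in degrees, in [0, 180].
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracmaCross(b1, b2)
  n2 <- pracmaCross(b2, b3)
  x <- sum(n1 * n2)
  m1 <- pracmaCross(n1, unit(b2))
  y <- sum(m1 * n2)
  abs(atan2(y, x) * 180 / pi)
}

pracmaCross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## All pairwise distances between two n x 3 coordinate matrices.
crossDist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

emptyDf <- function(...) {
  cols <- list(...)
  structure(as.data.frame(cols, stringsAsFactors = FALSE), row.names = integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
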