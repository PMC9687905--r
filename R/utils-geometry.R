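#' @keywords internal
#' @importFrom rlang .data abort warn inform
#' @importFrom stats predict
"_PACKAGE"

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

## Vector geometry helpers. All coordinates are Cartesian angstroms; atoms are
## rows of 3-column matrices so the hydrogen-bond criteria can be evaluated for
## many candidates at once.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

## Row-wise Euclidean distances between two n x 3 matrices.
row_dist <- function(p, q) {
  sqrt(rowSums((p - q)^2))
}

## Row-wise angle (degrees) at vertex `b` of the triples a-b-c. Degenerate rows
## (zero-length arm) return NA.
row_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  cosang[nu < 1e-9 | nv < 1e-9] <- NA_real_
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

## Place atom D given three reference atoms A-B-C, a bond length C-D, the
## angle B-C-D (degrees) and the dihedral A-B-C-D (degrees). Standard internal
## coordinate (NeRF) construction used to build idealized residue geometry.
place_internal <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(
    -length * cos(ang),
    length * sin(ang) * cos(dih),
    length * sin(ang) * sin(dih)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Deterministic derived seeds: one master seed fans out to per-split,
## per-fold and init seeds by fixed offsets, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729 + 12345) %%
    2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
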