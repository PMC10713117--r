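## Internal helpers shared across modules.

#' Element order used throughout the package
#'
#' Column order of every one-hot atom-type encoding: C, H, O, N, S, Se.
#' @return Character vector of the six element symbols.
#' @export
elementOrder <- function() c("C", "H", "O", "N", "S", "Se")

## Default van der Waals radii (Angstrom), indexed by elementOrder().
.vdwDefaults <- c(C = 1.70, H = 1.10, O = 1.52, N = 1.55, S = 1.80, Se = 1.90)

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## Derive a stream-specific 31-bit sub-seed from a master seed.
deriveSeed <- function(seed, ...) {
  ks <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in ks) x <- (x * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(x)
}

## Half-up rounding: the masking arithmetic uses round(m*g) with .5 up.
roundHalfUp <- function(x) floor(x + 0.5)

## Pairwise squared Euclidean distances between rows of A (n x d) and B (m x d).
pairwiseSqDist <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

## Stable row-normalization to unit vectors.
normalizeRows <- function(X, eps = 1e-12) {
  n <- sqrt(rowSums(X * X))
  X / pmax(n, eps)
}
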