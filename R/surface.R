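## Surface construction: smooth distance function over van der Waals spheres,
## level-set sampling at the working resolution, normals from the SDF
## gradient, multi-scale mean/Gaussian curvature, and raw chemical features.

## Per-atom vdW radii for a chain under a config.
.atomRadii <- function(chain, cfg) {
  cfg@vdwRadii[elementSymbols(chain)]
}

#' Smooth distance function
#'
#' The molecular surface is modeled as the zero level set of a soft-min over
#' per-atom signed sphere distances,
#' `SDF(x) = -sigma * log( sum_k exp(-(|x - a_k| - r_k) / sigma) )`,
#' where `r_k` is the van der Waals radius of atom k and `sigma` the
#' smoothing width. Negative inside, positive outside; for a single atom it
#' reduces exactly to `|x - a| - r`.
#'
#' @param queries Q x 3 matrix of query points (Angstrom).
#' @param chain An [AtomCloud-class].
#' @param cfg A [SurfaceConfig-class].
#' @return Numeric vector of Q signed distances (Angstrom).
#' @export
surfaceDistance <- function(queries, chain, cfg = SurfaceConfig()) {
  queries <- rbind(queries)
  dimnames(queries) <- NULL
  if (nAtoms(chain) < 1L) stop("empty chain")
  sig <- cfg@smoothingSigma
  D <- sqrt(pairwiseSqDist(queries, atomCoords(chain)))
  E <- -(sweep(D, 2L, .atomRadii(chain, cfg))) / sig
  mx <- apply(E, 1L, max)
  unname(-sig * (mx + log(rowSums(exp(E - mx)))))
}

#' Gradient of the smooth distance function
#'
#' Exact analytic gradient: the softmax-weighted sum of unit vectors from
#' the atoms to the query. Its normalization gives the outward surface
#' normal.
#'
#' @inheritParams surfaceDistance
#' @return Q x 3 matrix of gradients.
#' @export
surfaceDistanceGradient <- function(queries, chain, cfg = SurfaceConfig()) {
  queries <- rbind(queries)
  dimnames(queries) <- NULL
  if (nAtoms(chain) < 1L) stop("empty chain")
  sig <- cfg@smoothingSigma
  A <- atomCoords(chain)
  D <- sqrt(pairwiseSqDist(queries, A))
  if (any(D < 1e-9))
    stop("undefined gradient: query coincides with an atom center")
  E <- -(sweep(D, 2L, .atomRadii(chain, cfg))) / sig
  mx <- apply(E, 1L, max)
  W <- exp(E - mx)
  W <- W / rowSums(W)
  WD <- W / D
  unname(queries * rowSums(WD) - WD %*% A)
}

#' Sample the surface level set
#'
#' Seeds 20 candidate points per atom uniformly in the shell
#' `[r_k, r_k + 1.5*sigma]`, Newton-projects each onto the zero level set
#' along the SDF gradient (at most 10 iterations), discards candidates with
#' `|SDF| > levelTolerance` or vanishing gradient, then thins to at most one
#' point per occupied cell of a cubic grid of side `resolution` anchored at
#' the origin (keeping the candidate nearest its cell center; ties by
#' candidate order). Deterministic given the seed.
#'
#' @param chain An [AtomCloud-class].
#' @param cfg A [SurfaceConfig-class].
#' @param seed Integer seed for candidate generation.
#' @return N x 3 matrix of on-surface points.
#' @export
sampleSurface <- function(chain, cfg = SurfaceConfig(), seed = 0L) {
  if (nAtoms(chain) < 1L) stop("empty chain")
  nCand <- 20L
  A <- atomCoords(chain)
  r <- .atomRadii(chain, cfg)
  sig <- cfg@smoothingSigma
  M <- nrow(A)
  X <- withSeed(seed, {
    u <- matrix(rnorm(3L * M * nCand), ncol = 3L)
    u <- normalizeRows(u)
    rad <- runif(M * nCand, rep(r, each = nCand), rep(r + 1.5 * sig, each = nCand))
    A[rep(seq_len(M), each = nCand), , drop = FALSE] + rad * u
  })
  for (it in 1:10) {
    f <- surfaceDistance(X, chain, cfg)
    gmat <- tryCatch(surfaceDistanceGradient(X, chain, cfg), error = function(e) NULL)
    if (is.null(gmat)) {
      ## a candidate landed exactly on an atom center: nudge and retry once
      X <- X + 1e-6
      gmat <- surfaceDistanceGradient(X, chain, cfg)
      f <- surfaceDistance(X, chain, cfg)
    }
    g2 <- rowSums(gmat^2)
    stepOK <- g2 > 1e-12
    X[stepOK, ] <- X[stepOK, , drop = FALSE] -
      (f[stepOK] / g2[stepOK]) * gmat[stepOK, , drop = FALSE]
  }
  f <- surfaceDistance(X, chain, cfg)
  gn <- sqrt(rowSums(surfaceDistanceGradient(X, chain, cfg)^2))
  keep <- abs(f) <= cfg@levelTolerance & gn >= 1e-6
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0L) stop("empty surface: no candidate converged onto the level set")
  ## 1 A grid thinning, grid anchored at the origin
  res <- cfg@resolution
  cell <- floor(X / res)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  ctr <- (cell + 0.5) * res
  d2c <- rowSums((X - ctr)^2)
  ord <- order(key, d2c, method = "radix")
  sel <- ord[!duplicated(key[ord])]
  X[sort(sel), , drop = FALSE]
}

## Orthonormal tangent basis for a unit normal.
.tangentBasis <- function(n) {
  a <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  cbind(e1, e2)
}

#' Multi-scale mean and Gaussian curvature
#'
#' For every point and every scale s, fits the weighted quadric
#' `z = (a x^2 + 2 b x y + c y^2) / 2` (augmented with a radial quartic
#' term that absorbs the fourth-order truncation bias of the height
#' function) in the point's tangent frame over neighbors within `3 s`,
#' with Gaussian weights `exp(-d^2 / (2 s^2))`. Mean and Gaussian
#' curvature follow from the shape operator `[[a, b], [b, c]]` with the
#' sign fixed so a sphere of radius R with outward normals gives
#' `H = +1/R`, `K = +1/R^2`. Scales with fewer than 6 usable neighbors
#' yield zeros.
#'
#' @param points N x 3 surface points.
#' @param normals N x 3 unit normals.
#' @param cfg A [SurfaceConfig-class]; `curvatureScales` sets the scales.
#' @return N x (2 * number of scales) matrix, columns interleaved
#'   `(H_1, K_1, H_2, K_2, ...)` by ascending scale.
#' @export
estimateCurvatures <- function(points, normals, cfg = SurfaceConfig()) {
  points <- rbind(points)
  normals <- rbind(normals)
  if (nrow(points) != nrow(normals))
    stop("points and normals must have the same length")
  n <- nrow(points)
  scales <- cfg@curvatureScales
  out <- matrix(0, n, 2L * length(scales))
  if (n < 2L) return(out)
  D2 <- pairwiseSqDist(points, points)
  for (si in seq_along(scales)) {
    s <- scales[si]
    rad2 <- (3 * s)^2
    for (i in seq_len(n)) {
      nb <- which(D2[i, ] <= rad2 & D2[i, ] > 1e-12)
      if (length(nb) < 6L) next
      B <- .tangentBasis(normals[i, ])
      rel <- sweep(points[nb, , drop = FALSE], 2L, points[i, ])
      x <- rel %*% B[, 1L]
      y <- rel %*% B[, 2L]
      z <- rel %*% normals[i, ]
      w <- exp(-D2[i, nb] / (2 * s^2))
      ## weighted LS for (a, b, c) in z = (a x^2 + 2 b x y + c y^2) / 2.
      ## A radial quartic term absorbs the fourth-order truncation bias of
      ## the height function (on a sphere it would otherwise inflate K by
      ## ~10% at the default scales); curvatures still come from the
      ## quadratic coefficients alone.
      r2 <- x * x + y * y
      Phi <- cbind(0.5 * x * x, x * y, 0.5 * y * y, r2 * r2)
      WP <- Phi * w
      XtX <- crossprod(WP, Phi)
      Xtz <- crossprod(WP, z)
      abc <- tryCatch(solve(XtX, Xtz), error = function(e) NULL)
      if (is.null(abc)) next
      a <- abc[1L]; b <- abc[2L]; c <- abc[3L]
      ## outward normal + sphere calibration: H = -(a+c)/2, K = ac - b^2
      out[i, 2L * si - 1L] <- -(a + c) / 2
      out[i, 2L * si] <- a * c - b * b
    }
  }
  out
}

#' Raw chemical features: nearest-atom types and distances
#'
#' For every surface point, gathers its `nChemNeighbors` (16) nearest atoms
#' by Euclidean distance (ascending; ties by atom index) and records per
#' neighbor the one-hot element type followed by the distance. Chains with
#' fewer atoms than neighbor slots are padded by cycling through the sorted
#' neighbor list.
#'
#' @param points N x 3 surface points.
#' @param chain An [AtomCloud-class].
#' @param cfg A [SurfaceConfig-class].
#' @return List with `features` (N x 16 x 7 array) and `idx` (N x 16 atom
#'   indices).
#' @export
chemicalFeatures <- function(points, chain, cfg = SurfaceConfig()) {
  points <- rbind(points)
  if (nAtoms(chain) < 1L) stop("empty chain")
  n <- nrow(points)
  k <- cfg@nChemNeighbors
  M <- nAtoms(chain)
  D <- sqrt(pairwiseSqDist(points, atomCoords(chain)))
  types <- atomTypes(chain)
  feat <- array(0, dim = c(n, k, 7L))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], method = "radix")  # stable: ties by atom index
    sel <- ord[((seq_len(k) - 1L) %% M) + 1L]
    idx[i, ] <- sel
    feat[i, , 1:6] <- types[sel, , drop = FALSE]
    feat[i, , 7L] <- D[i, sel]
  }
  list(features = feat, idx = idx)
}

#' Build the annotated surface cloud of a chain
#'
#' Runs the full surface pipeline: level-set sampling, rejection of chains
#' whose raw surface exceeds `maxPoints`, seeded subsampling to exactly
#' `targetPoints` (without replacement; with replacement iff the raw
#' surface is smaller than the target), normals from the normalized SDF
#' gradient, multi-scale curvatures and raw chemical features.
#'
#' @param chain A centered [AtomCloud-class] that passed [filterElements()].
#' @param cfg A [SurfaceConfig-class].
#' @param seed Integer seed controlling sampling and subsampling.
#' @return A [SurfaceCloud-class], or a [Rejection-class] with reason
#'   `"too_many_points"` when the raw surface is larger than `maxPoints`.
#' @export
buildSurface <- function(chain, cfg = SurfaceConfig(), seed = 0L) {
  stopifnot(is(chain, "AtomCloud"))
  raw <- sampleSurface(chain, cfg, seed = deriveSeed(seed, 1L))
  nRaw <- nrow(raw)
  if (nRaw > cfg@maxPoints)
    return(Rejection("too_many_points", as.character(nRaw)))
  sel <- withSeed(deriveSeed(seed, 2L),
                  sample.int(nRaw, cfg@targetPoints,
                             replace = nRaw < cfg@targetPoints))
  pts <- raw[sel, , drop = FALSE]
  normals <- normalizeRows(surfaceDistanceGradient(pts, chain, cfg))
  curv <- estimateCurvatures(pts, normals, cfg)
  chem <- chemicalFeatures(pts, chain, cfg)
  new("SurfaceCloud", points = pts, normals = normals, curvatures = curv,
      chemRaw = chem$features, chemNeighborIdx = chem$idx, config = cfg,
      seed = as.integer(seed), chainID = chainID(chain))
}
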