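## Patchification: farthest point sampling of patch centers, KNN patch
## membership, and random patch masking for masked-autoencoder pretraining.

#' Farthest point sampling
#'
#' Greedy maximally-spread subset: the first center is the point farthest
#' from the cloud centroid (ties to the lowest index); each subsequent
#' center maximizes its minimum distance to the already-chosen centers
#' (ties to the lowest index). Deterministic.
#'
#' @param points N x 3 matrix.
#' @param g Number of centers (<= N).
#' @return Integer vector of g point indices, in selection order.
#' @export
farthestPointSample <- function(points, g) {
  points <- rbind(points)
  n <- nrow(points)
  if (g > n) stop("g must be <= number of points")
  if (g < 1L) stop("g must be >= 1")
  ctr <- colMeans(points)
  d0 <- sqrt(rowSums(sweep(points, 2L, ctr)^2))
  sel <- integer(g)
  sel[1L] <- which.max(d0)          # which.max ties -> lowest index
  minD <- sqrt(rowSums(sweep(points, 2L, points[sel[1L], ])^2))
  if (g > 1L) for (j in 2:g) {
    sel[j] <- which.max(minD)
    dNew <- sqrt(rowSums(sweep(points, 2L, points[sel[j], ])^2))
    minD <- pmin(minD, dNew)
  }
  sel
}

#' Group a point cloud into KNN patches around given centers
#'
#' Patch i holds the k' nearest points to center i by Euclidean distance,
#' ascending, ties by point index; the center itself is always member 1.
#' Patches may overlap. The returned [PatchSet-class] has all mask flags
#' off.
#'
#' @param points N x 3 matrix.
#' @param centerIdx Indices of the patch centers (e.g. from
#'   [farthestPointSample()]).
#' @param kPrime Patch size (<= N).
#' @return A [PatchSet-class] with `maskRatio = 0`.
#' @export
knnGroup <- function(points, centerIdx, kPrime) {
  points <- rbind(points)
  n <- nrow(points)
  if (kPrime > n) stop("kPrime must be <= number of points")
  centerIdx <- as.integer(centerIdx)
  members <- matrix(0L, length(centerIdx), kPrime)
  for (i in seq_along(centerIdx)) {
    d <- sqrt(rowSums(sweep(points, 2L, points[centerIdx[i], ])^2))
    d[centerIdx[i]] <- -1            # the center is its own nearest neighbor
    ord <- order(d, method = "radix") # stable: ties by point index
    members[i, ] <- ord[seq_len(kPrime)]
  }
  new("PatchSet", centerIdx = centerIdx, members = members,
      mask = rep(FALSE, length(centerIdx)), maskRatio = 0)
}

#' Randomly mask a proportion of patches
#'
#' Marks exactly `round(m * g)` patches (half-up rounding) as masked,
#' chosen uniformly without replacement under the given seed. `m = 0`
#' returns an unmasked patch set, the fine-tuning/inference mode in which
#' no patches are hidden.
#'
#' @param patchset A [PatchSet-class].
#' @param m Mask ratio in `[0, 1)`.
#' @param seed Integer seed.
#' @return The patch set with updated `mask` and `maskRatio`.
#' @export
applyMask <- function(patchset, m, seed = 0L) {
  stopifnot(is(patchset, "PatchSet"))
  if (m < 0 || m >= 1) stop("mask ratio m must be in [0, 1)")
  g <- nPatches(patchset)
  nMask <- roundHalfUp(m * g)
  mask <- rep(FALSE, g)
  if (nMask > 0L)
    mask[withSeed(seed, sample.int(g, nMask))] <- TRUE
  out <- patchset
  out@mask <- mask
  out@maskRatio <- m
  out
}
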