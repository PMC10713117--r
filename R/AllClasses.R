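#' @import methods
NULL

## ---------------------------------------------------------------------------
## Rejection: a value (not an error) returned when a filter discards an input,
## e.g. a chain with a disallowed element or an oversized surface cloud.
## ---------------------------------------------------------------------------

#' Rejection marker
#'
#' Filters such as [filterElements()] and [buildSurface()] signal a discarded
#' input by returning a `Rejection` value rather than raising an error, so a
#' pipeline over many chains can keep going and record why each chain fell out.
#'
#' @slot reason Short machine-readable reason, e.g. `"element"` or
#'   `"too_many_points"`.
#' @slot detail Human-readable detail, e.g. the offending element symbol.
#' @export
setClass("Rejection",
  representation(reason = "character", detail = "character"))

#' @rdname Rejection-class
#' @param reason,detail See slots.
#' @export
Rejection <- function(reason, detail = "") {
  new("Rejection", reason = reason, detail = as.character(detail))
}

#' Test whether a value is a rejection marker
#' @param x Any object.
#' @return `TRUE` if `x` is a [Rejection-class] value.
#' @export
isRejected <- function(x) is(x, "Rejection")

setMethod("show", "Rejection", function(object) {
  cat("Rejection:", object@reason,
      if (nzchar(object@detail)) paste0("(", object@detail, ")"), "\n")
})

## ---------------------------------------------------------------------------
## AtomCloud: one protein chain as centered coordinates + one-hot elements.
## ---------------------------------------------------------------------------

#' Atom cloud of one protein chain
#'
#' Cartesian atom coordinates (Angstrom) of a single chain together with a
#' one-hot element encoding over the order C, H, O, N, S, Se. Coordinates are
#' centered by [centerAtoms()]; parsing returns uncentered clouds.
#'
#' @slot coords M x 3 numeric matrix of coordinates (Angstrom).
#' @slot types M x 6 one-hot matrix over [elementOrder()].
#' @slot chainID Chain identifier.
#' @slot source Provenance label (file name, `"synthetic"`, fixture kind...).
#' @export
setClass("AtomCloud",
  representation(coords = "matrix", types = "matrix",
                 chainID = "character", source = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@coords) < 1L) msg <- c(msg, "M must be >= 1")
    if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
    if (ncol(object@types) != 6L) msg <- c(msg, "types must have 6 columns")
    if (nrow(object@types) != nrow(object@coords))
      msg <- c(msg, "coords and types must have the same number of rows")
    if (nrow(object@types) > 0L) {
      if (any(abs(rowSums(object@types) - 1) > 1e-12))
        msg <- c(msg, "each one-hot row must sum to exactly 1")
      if (any(object@types != 0 & object@types != 1))
        msg <- c(msg, "types must be one-hot (0/1)")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname AtomCloud-class
#' @param coords,types,chainID,source See slots; `types` may also be a
#'   character vector of element symbols, which is one-hot encoded.
#' @export
AtomCloud <- function(coords, types, chainID = "A", source = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.character(types)) types <- oneHotElements(types)
  types <- as.matrix(types)
  storage.mode(types) <- "double"
  dimnames(coords) <- NULL
  dimnames(types) <- NULL
  new("AtomCloud", coords = coords, types = types,
      chainID = chainID, source = source)
}

## One-hot encode a vector of element symbols (C,H,O,N,S,Se).
oneHotElements <- function(elements) {
  ord <- elementOrder()
  idx <- match(elements, ord)
  if (anyNA(idx))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  m <- matrix(0, length(elements), 6L)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' @describeIn AtomCloud-class Number of atoms M.
#' @param object,x An `AtomCloud`.
#' @export
nAtoms <- function(x) nrow(x@coords)

#' @describeIn AtomCloud-class M x 3 coordinate matrix.
#' @export
atomCoords <- function(x) x@coords

#' @describeIn AtomCloud-class M x 6 one-hot type matrix.
#' @export
atomTypes <- function(x) x@types

#' @describeIn AtomCloud-class Chain identifier.
#' @export
chainID <- function(x) x@chainID

#' @describeIn AtomCloud-class Element symbol of every atom.
#' @export
elementSymbols <- function(x) elementOrder()[max.col(x@types, "first")]

setMethod("show", "AtomCloud", function(object) {
  tab <- table(factor(elementSymbols(object), levels = elementOrder()))
  cat(sprintf("AtomCloud chain '%s': %d atoms (%s)\n",
              object@chainID, nAtoms(object),
              paste(sprintf("%s:%d", names(tab), tab)[tab > 0],
                    collapse = " ")))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

## ---------------------------------------------------------------------------
## SurfaceConfig: everything the surface construction pipeline needs.
## ---------------------------------------------------------------------------

#' Surface construction parameters
#'
#' @slot smoothingSigma Soft-min temperature sigma of the smooth distance
#'   function (Angstrom, default 0.5).
#' @slot resolution Sampling resolution / grid-thinning cell size
#'   (Angstrom, default 1.0).
#' @slot levelTolerance Maximum |SDF| for a point to count as on-surface
#'   (Angstrom, default 0.05).
#' @slot targetPoints Number of points each surface cloud is subsampled to
#'   (default 2048).
#' @slot maxPoints Chains whose raw surface exceeds this many points are
#'   rejected (default 20000).
#' @slot curvatureScales Scales (Angstrom) at which mean/Gaussian curvature
#'   is estimated; default `c(1, 2, 3, 5, 10)`.
#' @slot nChemNeighbors Number of nearest atoms in the raw chemical feature
#'   (default 16).
#' @slot vdwRadii Named per-element van der Waals radii (Angstrom).
#' @export
setClass("SurfaceConfig",
  representation(smoothingSigma = "numeric", resolution = "numeric",
                 levelTolerance = "numeric", targetPoints = "integer",
                 maxPoints = "integer", curvatureScales = "numeric",
                 nChemNeighbors = "integer", vdwRadii = "numeric"),
  prototype(smoothingSigma = 0.5, resolution = 1.0, levelTolerance = 0.05,
            targetPoints = 2048L, maxPoints = 20000L,
            curvatureScales = c(1, 2, 3, 5, 10), nChemNeighbors = 16L,
            vdwRadii = c(C = 1.70, H = 1.10, O = 1.52, N = 1.55,
                         S = 1.80, Se = 1.90)),
  validity = function(object) {
    msg <- character()
    if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
    if (object@smoothingSigma <= 0) msg <- c(msg, "smoothingSigma must be > 0")
    if (is.unsorted(object@curvatureScales, strictly = TRUE))
      msg <- c(msg, "curvatureScales must be strictly increasing")
    if (object@nChemNeighbors < 1L) msg <- c(msg, "nChemNeighbors must be >= 1")
    if (!all(elementOrder() %in% names(object@vdwRadii)))
      msg <- c(msg, "vdwRadii must name all of C,H,O,N,S,Se")
    if (length(msg)) msg else TRUE
  })

#' @rdname SurfaceConfig-class
#' @param smoothingSigma,resolution,levelTolerance,targetPoints,maxPoints,curvatureScales,nChemNeighbors,vdwRadii
#'   See slots.
#' @export
SurfaceConfig <- function(smoothingSigma = 0.5, resolution = 1.0,
                          levelTolerance = 0.05, targetPoints = 2048L,
                          maxPoints = 20000L,
                          curvatureScales = c(1, 2, 3, 5, 10),
                          nChemNeighbors = 16L, vdwRadii = .vdwDefaults) {
  new("SurfaceConfig", smoothingSigma = smoothingSigma,
      resolution = resolution, levelTolerance = levelTolerance,
      targetPoints = as.integer(targetPoints),
      maxPoints = as.integer(maxPoints),
      curvatureScales = as.numeric(curvatureScales),
      nChemNeighbors = as.integer(nChemNeighbors),
      vdwRadii = vdwRadii)
}

setMethod("show", "SurfaceConfig", function(object) {
  cat(sprintf(paste0("SurfaceConfig: sigma=%.2f A, res=%.2f A, tol=%.2f A, ",
                     "target=%d, max=%d, scales=[%s], %d chem neighbors\n"),
              object@smoothingSigma, object@resolution, object@levelTolerance,
              object@targetPoints, object@maxPoints,
              paste(object@curvatureScales, collapse = ","),
              object@nChemNeighbors))
})

## ---------------------------------------------------------------------------
## SurfaceCloud: the annotated surface point cloud of one chain.
## ---------------------------------------------------------------------------

#' Annotated protein surface point cloud
#'
#' Points sampled on the zero level set of the smooth distance function, each
#' carrying a unit outward normal, mean/Gaussian curvature at five scales
#' (interleaved H1,K1,H2,K2,... by ascending scale) and a raw chemical
#' feature: the one-hot types and distances of its 16 nearest atoms, sorted
#' by ascending distance.
#'
#' @slot points N x 3 coordinates (Angstrom).
#' @slot normals N x 3 unit normals.
#' @slot curvatures N x 10 curvature matrix.
#' @slot chemRaw N x 16 x 7 array: per neighbor the 6 one-hot channels then
#'   the Euclidean distance.
#' @slot chemNeighborIdx N x 16 atom indices of the gathered neighbors.
#' @slot config The [SurfaceConfig-class] used to build the cloud.
#' @slot seed Integer seed used for sampling/subsampling.
#' @slot chainID Chain identifier inherited from the atom cloud.
#' @export
setClass("SurfaceCloud",
  representation(points = "matrix", normals = "matrix",
                 curvatures = "matrix", chemRaw = "array",
                 chemNeighborIdx = "matrix", config = "SurfaceConfig",
                 seed = "integer", chainID = "character"),
  validity = function(object) {
    n <- nrow(object@points)
    k <- object@config@nChemNeighbors
    msg <- character()
    if (ncol(object@points) != 3L) msg <- c(msg, "points must be N x 3")
    if (!all(dim(object@normals) == c(n, 3L)))
      msg <- c(msg, "normals must be N x 3")
    if (n > 0L && any(abs(sqrt(rowSums(object@normals^2)) - 1) > 1e-6))
      msg <- c(msg, "normals must have unit length within 1e-6")
    if (nrow(object@curvatures) != n ||
        ncol(object@curvatures) != 2L * length(object@config@curvatureScales))
      msg <- c(msg, "curvatures must be N x 2*(number of scales)")
    if (!all(dim(object@chemRaw) == c(n, k, 7L)))
      msg <- c(msg, "chemRaw must be N x nChemNeighbors x 7")
    if (n > 0L) {
      d <- object@chemRaw[, , 7L, drop = FALSE]
      dim(d) <- c(n, k)
      if (k > 1L && any(d[, -1L, drop = FALSE] - d[, -k, drop = FALSE] < -1e-9))
        msg <- c(msg, "chem distances must be non-decreasing over neighbors")
      oh <- apply(object@chemRaw[, , 1:6, drop = FALSE], c(1, 2), sum)
      if (any(abs(oh - 1) > 1e-9))
        msg <- c(msg, "each neighbor one-hot must sum to 1")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn SurfaceCloud-class Number of surface points N.
#' @param object,x A `SurfaceCloud`.
#' @export
nPoints <- function(x) nrow(x@points)

#' @describeIn SurfaceCloud-class N x 3 point coordinates.
#' @export
surfacePoints <- function(x) x@points

#' @describeIn SurfaceCloud-class N x 3 unit normals.
#' @export
surfaceNormals <- function(x) x@normals

#' @describeIn SurfaceCloud-class N x 10 curvature matrix.
#' @export
surfaceCurvatures <- function(x) x@curvatures

#' @describeIn SurfaceCloud-class N x 16 x 7 raw chemical feature array.
#' @export
chemRaw <- function(x) x@chemRaw

#' @describeIn SurfaceCloud-class N x 16 neighbor atom indices.
#' @export
chemNeighborIdx <- function(x) x@chemNeighborIdx

#' @describeIn SurfaceCloud-class Per-point flattened input feature: the
#'   16 x 7 raw chemical block (row-major over neighbors) concatenated with
#'   the 10 curvature channels, giving 122 columns with the default config.
#' @export
pointFeatures <- function(x) {
  n <- nPoints(x)
  k <- dim(x@chemRaw)[2L]
  chem <- matrix(aperm(x@chemRaw, c(3L, 2L, 1L)), nrow = n, byrow = TRUE)
  cbind(chem, x@curvatures)
}

setMethod("show", "SurfaceCloud", function(object) {
  cat(sprintf(
    "SurfaceCloud '%s': %d points, %d curvature channels, chem %d x %d, seed %d\n",
    object@chainID, nPoints(object), ncol(object@curvatures),
    dim(object@chemRaw)[2L], dim(object@chemRaw)[3L], object@seed))
})

## ---------------------------------------------------------------------------
## PatchSet: FPS centers + KNN membership + mask flags.
## ---------------------------------------------------------------------------

#' Patch decomposition of a surface point cloud
#'
#' g patch centers chosen by farthest point sampling, each patch holding the
#' k' nearest surface points (the center is always member 1), plus boolean
#' mask flags covering round(m*g) patches.
#'
#' @slot centerIdx Length-g point indices of the patch centers.
#' @slot members g x k' matrix of member point indices.
#' @slot mask Length-g logical mask flags.
#' @slot maskRatio The mask ratio m in [0, 1).
#' @export
setClass("PatchSet",
  representation(centerIdx = "integer", members = "matrix",
                 mask = "logical", maskRatio = "numeric"),
  validity = function(object) {
    g <- length(object@centerIdx)
    msg <- character()
    if (nrow(object@members) != g) msg <- c(msg, "members must have g rows")
    if (length(object@mask) != g) msg <- c(msg, "mask must have length g")
    if (g > 0L && any(object@members[, 1L] != object@centerIdx))
      msg <- c(msg, "member 1 of each patch must be its center")
    if (object@maskRatio < 0 || object@maskRatio >= 1)
      msg <- c(msg, "maskRatio must be in [0, 1)")
    if (sum(object@mask) != roundHalfUp(object@maskRatio * g))
      msg <- c(msg, "masked count must equal round(m*g)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PatchSet-class Number of patches g.
#' @param object,x A `PatchSet`.
#' @export
nPatches <- function(x) length(x@centerIdx)

#' @describeIn PatchSet-class Patch size k'.
#' @export
patchSize <- function(x) ncol(x@members)

#' @describeIn PatchSet-class Center point indices.
#' @export
patchCenterIdx <- function(x) x@centerIdx

#' @describeIn PatchSet-class g x k' member index matrix.
#' @export
patchMembers <- function(x) x@members

#' @describeIn PatchSet-class Logical mask flags.
#' @export
patchMask <- function(x) x@mask

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: g=%d patches of k'=%d points, %d masked (m=%.2f)\n",
              nPatches(object), patchSize(object), sum(object@mask),
              object@maskRatio))
})

## ---------------------------------------------------------------------------
## ModelConfig: network hyperparameters.
## ---------------------------------------------------------------------------

#' Masked-autoencoder network configuration
#'
#' @slot d Token width (default 384).
#' @slot encoderDepth,encoderHeads Transformer encoder depth/heads (12, 6).
#' @slot decoderDepth,decoderHeads Masked decoder depth/heads (4, 6); the
#'   decoder always uses four self-attention blocks by default.
#' @slot mlpRatio Width multiplier of the transformer MLPs (default 4).
#' @slot chemDim Width of the learned per-point chemical feature (fixed 6).
#' @slot fusedDim Width of the fused chemical+geometric feature (fixed 16).
#' @slot g,kPrime,m Patch count, patch size and mask ratio.
#' @slot nClasses Number of classes for the pocket head (default 7).
#' @slot descriptorDim Width of the PPI descriptors (default 64).
#' @slot mpHidden Hidden width of the message-passing MLPs (default 32).
#' @slot tokHidden Hidden width of the tokenizer/positional MLPs (default 128).
#' @export
setClass("ModelConfig",
  representation(d = "integer", encoderDepth = "integer",
                 encoderHeads = "integer", decoderDepth = "integer",
                 decoderHeads = "integer", mlpRatio = "numeric",
                 chemDim = "integer", fusedDim = "integer",
                 g = "integer", kPrime = "integer", m = "numeric",
                 nClasses = "integer", descriptorDim = "integer",
                 mpHidden = "integer", tokHidden = "integer"),
  prototype(d = 384L, encoderDepth = 12L, encoderHeads = 6L,
            decoderDepth = 4L, decoderHeads = 6L, mlpRatio = 4,
            chemDim = 6L, fusedDim = 16L, g = 128L, kPrime = 32L, m = 0.6,
            nClasses = 7L, descriptorDim = 64L, mpHidden = 32L,
            tokHidden = 128L),
  validity = function(object) {
    msg <- character()
    if (object@d %% object@encoderHeads != 0L)
      msg <- c(msg, "d must be divisible by encoderHeads")
    if (object@d %% object@decoderHeads != 0L)
      msg <- c(msg, "d must be divisible by decoderHeads")
    if (object@chemDim != 6L) msg <- c(msg, "chemDim is fixed at 6")
    if (object@fusedDim != 16L) msg <- c(msg, "fusedDim is fixed at 16")
    if (object@m < 0 || object@m >= 1) msg <- c(msg, "m must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' @rdname ModelConfig-class
#' @param d,encoderDepth,encoderHeads,decoderDepth,decoderHeads,mlpRatio,g,kPrime,m,nClasses,descriptorDim,mpHidden,tokHidden
#'   See slots.
#' @export
ModelConfig <- function(d = 384L, encoderDepth = 12L, encoderHeads = 6L,
                        decoderDepth = 4L, decoderHeads = 6L, mlpRatio = 4,
                        g = 128L, kPrime = 32L, m = 0.6, nClasses = 7L,
                        descriptorDim = 64L, mpHidden = 32L,
                        tokHidden = 128L) {
  new("ModelConfig", d = as.integer(d),
      encoderDepth = as.integer(encoderDepth),
      encoderHeads = as.integer(encoderHeads),
      decoderDepth = as.integer(decoderDepth),
      decoderHeads = as.integer(decoderHeads), mlpRatio = mlpRatio,
      chemDim = 6L, fusedDim = 16L, g = as.integer(g),
      kPrime = as.integer(kPrime), m = m, nClasses = as.integer(nClasses),
      descriptorDim = as.integer(descriptorDim),
      mpHidden = as.integer(mpHidden), tokHidden = as.integer(tokHidden))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0("ModelConfig: d=%d, encoder %dx%dh, decoder %dx%dh, ",
                     "mlp x%g, g=%d, k'=%d, m=%.2f, %d classes\n"),
              object@d, object@encoderDepth, object@encoderHeads,
              object@decoderDepth, object@decoderHeads, object@mlpRatio,
              object@g, object@kPrime, object@m, object@nClasses))
})

## ---------------------------------------------------------------------------
## MAEModel: configuration + parameter store.
## ---------------------------------------------------------------------------

#' Masked-autoencoder model
#'
#' Holds a [ModelConfig-class] and the named list of parameter arrays of the
#' tokenizer, transformer encoder, masked decoder and task heads. Created by
#' [maeModel()]; updated in place-on-copy by the training loops.
#'
#' @slot config A [ModelConfig-class].
#' @slot params Named list of numeric parameter matrices.
#' @slot initSeed Seed used to initialize the parameters.
#' @export
setClass("MAEModel",
  representation(config = "ModelConfig", params = "list",
                 initSeed = "integer"))

#' @describeIn MAEModel-class The model's [ModelConfig-class].
#' @param object,x An `MAEModel`.
#' @export
modelConfig <- function(x) x@config

#' @describeIn MAEModel-class Named list of parameter arrays.
#' @export
modelParams <- function(x) x@params

setMethod("show", "MAEModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("MAEModel: %d parameters in %d arrays\n",
              np, length(object@params)))
  show(object@config)
})

## ---------------------------------------------------------------------------
## TokenSequence: patch tokens + positions (+ CLS) and encoder outputs.
## ---------------------------------------------------------------------------

#' Token sequence of a patchified surface
#'
#' @slot tokens q x d patch token embeddings.
#' @slot positions q x d encoder-side positional encodings (MLP of centers).
#' @slot cls 0 x d or 1 x d matrix; the learnable CLS slot when present.
#' @slot encoded Encoder outputs; q x d (or (q+1) x d with CLS first), or a
#'   0 x d matrix before encoding.
#' @export
setClass("TokenSequence",
  representation(tokens = "matrix", positions = "matrix",
                 cls = "matrix", encoded = "matrix"),
  validity = function(object) {
    if (!all(dim(object@tokens) == dim(object@positions)))
      "tokens and positions must have identical shape" else TRUE
  })

setMethod("show", "TokenSequence", function(object) {
  cat(sprintf("TokenSequence: %d tokens x d=%d, CLS=%s, encoded=%s\n",
              nrow(object@tokens), ncol(object@tokens),
              if (nrow(object@cls)) "yes" else "no",
              if (nrow(object@encoded)) "yes" else "no"))
})

## ---------------------------------------------------------------------------
## TrainState: training bookkeeping.
## ---------------------------------------------------------------------------

#' Training state and loss log
#'
#' @slot epochLosses Mean loss per completed epoch.
#' @slot bestEpoch 1-based index of the minimal-loss epoch (ties earliest).
#' @slot settings Optimizer settings (lr, batch, epochs, weight decay...).
#' @slot seed Global training seed.
#' @slot checkpoints List of per-epoch parameter snapshots (possibly trimmed
#'   to the best epoch only).
#' @export
setClass("TrainState",
  representation(epochLosses = "numeric", bestEpoch = "integer",
                 settings = "list", seed = "integer", checkpoints = "list"),
  validity = function(object) {
    if (length(object@epochLosses) &&
        object@bestEpoch != which.min(object@epochLosses))
      "bestEpoch must be the argmin of epochLosses (ties earliest)" else TRUE
  })

#' @describeIn TrainState-class Per-epoch mean losses.
#' @param object,x A `TrainState`.
#' @export
epochLosses <- function(x) x@epochLosses

#' @describeIn TrainState-class Best (minimal-loss) epoch id.
#' @export
bestEpoch <- function(x) x@bestEpoch

setMethod("show", "TrainState", function(object) {
  n <- length(object@epochLosses)
  cat(sprintf("TrainState: %d epochs, best epoch %d (loss %.4g)\n",
              n, object@bestEpoch,
              if (n) object@epochLosses[object@bestEpoch] else NA_real_))
})
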