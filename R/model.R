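## The masked-autoencoder network: message-passing point encoder, patch
## tokenizer with max pooling, learnable positional MLPs, pre-norm
## transformer encoder with optional CLS token, masked decoder with a
## coordinate prediction head, chamfer reconstruction loss, and the three
## downstream heads (binding site, pocket class, PPI descriptors).

#' Construct a masked-autoencoder model
#'
#' Initializes all parameter arrays (tokenizer, message-passing point
#' encoder, encoder/decoder transformers, positional MLPs, CLS and mask
#' tokens, task heads) with seeded Gaussian weights of scale
#' `1/sqrt(fan_in)`.
#'
#' @param cfg A [ModelConfig-class].
#' @param seed Integer seed for the initialization.
#' @return An [MAEModel-class].
#' @export
maeModel <- function(cfg = ModelConfig(), seed = 0L) {
  stopifnot(is(cfg, "ModelConfig"))
  params <- withSeed(seed, {
    p <- list()
    d <- cfg@d
    h <- cfg@mpHidden
    ## point encoder: shared neighbor embedding + 3 message-passing blocks
    p <- .initLinear(p, "pe.embed1", 7L, h)
    p <- .initLinear(p, "pe.embed2", h, h)
    for (b in 1:3) {
      p <- .initLinear(p, sprintf("pe.mp%d.1", b), cfg@chemDim + h, h)
      p <- .initLinear(p, sprintf("pe.mp%d.2", b), h, cfg@chemDim)
    }
    ## tokenizer MLP (fused 16 -> d) applied per point before max pooling
    p <- .initLinear(p, "tok1", cfg@fusedDim, cfg@tokHidden)
    p <- .initLinear(p, "tok2", cfg@tokHidden, d)
    ## positional MLPs (3 -> tokHidden -> d), separate encoder/decoder sets
    p <- .initLinear(p, "pos.enc1", 3L, cfg@tokHidden)
    p <- .initLinear(p, "pos.enc2", cfg@tokHidden, d)
    p <- .initLinear(p, "pos.dec1", 3L, cfg@tokHidden)
    p <- .initLinear(p, "pos.dec2", cfg@tokHidden, d)
    ## CLS token and its learnable position
    p$cls.token <- matrix(rnorm(d, sd = 0.02), 1L, d)
    p$cls.pos <- matrix(rnorm(d, sd = 0.02), 1L, d)
    ## transformer encoder
    for (l in seq_len(cfg@encoderDepth))
      p <- .initBlock(p, sprintf("enc.l%d", l), d, cfg@mlpRatio)
    p <- .initLayerNorm(p, "enc.lnf", d)
    ## masked decoder
    p <- .initLinear(p, "dec.proj", d, d)
    p$dec.mask <- matrix(rnorm(d, sd = 0.02), 1L, d)
    for (l in seq_len(cfg@decoderDepth))
      p <- .initBlock(p, sprintf("dec.l%d", l), d, cfg@mlpRatio)
    p <- .initLayerNorm(p, "dec.lnf", d)
    p <- .initLinear(p, "dec.head", d, 3L * cfg@kPrime, sd = 0.01 / sqrt(d))
    ## task heads
    p <- .initLinear(p, "site1", 2L * d + cfg@fusedDim, cfg@tokHidden)
    p <- .initLinear(p, "site2", cfg@tokHidden, 1L)
    p <- .initLinear(p, "pocket1", 2L * d, cfg@tokHidden)
    p <- .initLinear(p, "pocket2", cfg@tokHidden, cfg@nClasses)
    if (cfg@descriptorDim != d)
      p <- .initLinear(p, "desc.proj", d, cfg@descriptorDim)
    p$ppi.scale <- matrix(5, 1L, 1L)
    p$ppi.bias <- matrix(0, 1L, 1L)
    p
  })
  new("MAEModel", config = cfg, params = params, initSeed = as.integer(seed))
}

## ---- node-level forwards (used by both inference and training) ---------

## chemRaw (N x 16 x 7 array) -> (N*16) x 7 flat matrix, neighbors of one
## point on consecutive rows.
.flattenChem <- function(chemRaw) {
  n <- dim(chemRaw)[1L]
  k <- dim(chemRaw)[2L]
  ap <- aperm(chemRaw, c(2L, 1L, 3L))
  dim(ap) <- c(n * k, dim(chemRaw)[3L])
  ap
}

## Message-passing point encoder: N x 16 x 7 -> N x 6 node.
.fwdPointEncoder <- function(tape, P, cfg, chemRaw) {
  n <- dim(chemRaw)[1L]
  k <- dim(chemRaw)[2L]
  flat <- adLeaf(tape, .flattenChem(chemRaw))
  emb <- adRelu(tape, .mlp2F(tape, P, "pe.embed1", "pe.embed2", flat))
  expandIdx <- rep(seq_len(n), each = k)
  L <- adLeaf(tape, matrix(1, n, cfg@chemDim))   # all-one initial local feature
  for (b in 1:3) {
    Lexp <- adRowsSelect(tape, L, expandIdx)
    msg <- .mlp2F(tape, P, sprintf("pe.mp%d.1", b), sprintf("pe.mp%d.2", b),
                  adConcatCols(tape, Lexp, emb))
    L <- adAdd(tape, L, adMeanPoolGroups(tape, msg, k))
  }
  L
}

## Tokenize the given patch member rows (q x k' index matrix) of the fused
## per-point feature: shared MLP then channel-wise max pool.
.fwdTokenize <- function(tape, P, cfg, fused, members) {
  idx <- as.vector(t(members))     # patch-major ordering
  pts <- adRowsSelect(tape, fused, idx)
  h <- .mlp2F(tape, P, "tok1", "tok2", pts)
  adMaxPoolGroups(tape, h, ncol(members))
}

.fwdPos <- function(tape, P, side, centers) {
  C <- adLeaf(tape, centers)
  .mlp2F(tape, P, paste0("pos.", side, "1"), paste0("pos.", side, "2"), C)
}

## Transformer encoder over tokens+positions; returns list(H, hCls).
.fwdEncode <- function(tape, P, cfg, tokens, positions, useCls) {
  X <- adAdd(tape, tokens, positions)
  if (useCls) {
    clsRow <- adAdd(tape, P$cls.token, P$cls.pos)
    X <- adConcatRows(tape, clsRow, X)
  }
  H <- .transformerF(tape, P, "enc", X, cfg@encoderDepth, cfg@encoderHeads)
  q <- nrow(tokens$val)
  if (useCls)
    list(H = adRowsSelect(tape, H, 1L + seq_len(q)),
         hCls = adRowsSelect(tape, H, 1L))
  else list(H = H, hCls = NULL)
}

## Masked decoder: visible encodings + shared mask tokens -> predicted
## center-relative coordinates for the masked patches, (mg*k') x 3 node
## with the k' points of one patch on consecutive rows.
.fwdDecode <- function(tape, P, cfg, hVisible, visCenters, maskCenters) {
  nMask <- nrow(maskCenters)
  if (nMask < 1L) stop("decoder requires at least one masked patch")
  vis <- adAdd(tape, .linearF(tape, P, "dec.proj", hVisible),
               .fwdPos(tape, P, "dec", visCenters))
  msk <- adAdd(tape, adRowsSelect(tape, P$dec.mask, rep(1L, nMask)),
               .fwdPos(tape, P, "dec", maskCenters))
  X <- adConcatRows(tape, vis, msk)
  H <- .transformerF(tape, P, "dec", X, cfg@decoderDepth, cfg@decoderHeads)
  Hm <- adRowsSelect(tape, H, nrow(visCenters) + seq_len(nMask))
  flat <- .linearF(tape, P, "dec.head", Hm)       # nMask x (3 k')
  ## one patch row -> k' x 3 block; stack patches over rows
  parts <- vector("list", nMask)
  for (i in seq_len(nMask))
    parts[[i]] <- adReshape(tape, adRowsSelect(tape, flat, i), cfg@kPrime, 3L)
  out <- parts[[1L]]
  if (nMask > 1L) for (i in 2:nMask) out <- adConcatRows(tape, out, parts[[i]])
  out
}

## Chamfer loss node over per-patch predicted/target point sets (lists of
## k x 3 matrices in the same center-relative frame). Nearest-neighbor
## assignments are computed from current values; gradients flow through
## the predicted coordinates.
.chamferNode <- function(tape, predNodes, targets) {
  stopifnot(length(predNodes) == length(targets))
  total <- NULL
  for (i in seq_along(predNodes)) {
    Pn <- predNodes[[i]]
    Tm <- targets[[i]]
    if (nrow(Pn$val) == 0L || nrow(Tm) == 0L) stop("empty patch in chamfer loss")
    D <- pairwiseSqDist(Tm, Pn$val)
    idxA <- max.col(-D, ties.method = "first")          # nearest pred per target
    idxB <- max.col(-t(D), ties.method = "first")       # nearest target per pred
    dA <- adSub(tape, adLeaf(tape, Tm), adRowsSelect(tape, Pn, idxA))
    termA <- adScale(tape, adSumAll(tape, adMul(tape, dA, dA)), 1 / nrow(Tm))
    dB <- adSub(tape, Pn, adLeaf(tape, Tm[idxB, , drop = FALSE]))
    termB <- adScale(tape, adSumAll(tape, adMul(tape, dB, dB)), 1 / nrow(Pn$val))
    s <- adAdd(tape, termA, termB)
    total <- if (is.null(total)) s else adAdd(tape, total, s)
  }
  total
}

## Inverse-distance interpolation weights from the 3 nearest patch centers.
.interpWeights <- function(points, centers) {
  n <- nrow(points)
  g <- nrow(centers)
  k <- min(3L, g)
  D <- sqrt(pairwiseSqDist(points, centers))
  W <- matrix(0, n, g)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], method = "radix")[seq_len(k)]
    d <- D[i, ord]
    if (d[1L] < 1e-9) {
      W[i, ord[1L]] <- 1
    } else {
      w <- 1 / d
      W[i, ord] <- w / sum(w)
    }
  }
  W
}

## Binding-site head: per-point logits from interpolated tokens, the
## point's fused feature and the global max-pooled token.
.fwdHeadSite <- function(tape, P, cfg, H, points, centers, fused) {
  W <- .interpWeights(points, centers)
  interp <- adMatmul(tape, adLeaf(tape, W), H)
  globalTok <- adMaxPoolGroups(tape, H, nrow(H$val))
  gExp <- adRowsSelect(tape, globalTok, rep(1L, nrow(points)))
  feat <- adConcatCols(tape, adConcatCols(tape, interp, fused), gExp)
  .mlp2F(tape, P, "site1", "site2", feat)
}

## Pocket head: CLS state + max-pooled tokens -> class logits.
.fwdHeadPocket <- function(tape, P, cfg, hCls, H) {
  pooled <- adMaxPoolGroups(tape, H, nrow(H$val))
  .mlp2F(tape, P, "pocket1", "pocket2", adConcatCols(tape, hCls, pooled))
}

## Descriptor head: interpolated tokens (optionally projected) L2-normalized.
.fwdHeadDescriptor <- function(tape, P, cfg, H, points, centers) {
  W <- .interpWeights(points, centers)
  interp <- adMatmul(tape, adLeaf(tape, W), H)
  if (cfg@descriptorDim != cfg@d)
    interp <- .linearF(tape, P, "desc.proj", interp)
  adL2NormalizeRows(tape, interp)
}

## Full encoder forward from a surface cloud + patch set (no masking).
## Returns nodes: fused (N x 16), H (g x d), hCls (1 x d or NULL).
.fwdSurfaceEncode <- function(tape, P, cfg, surf, patchset, useCls) {
  chem <- .fwdPointEncoder(tape, P, cfg, chemRaw(surf))
  fused <- adConcatCols(tape, chem, adLeaf(tape, surfaceCurvatures(surf)))
  tokens <- .fwdTokenize(tape, P, cfg, fused, patchMembers(patchset))
  centers <- surfacePoints(surf)[patchCenterIdx(patchset), , drop = FALSE]
  pos <- .fwdPos(tape, P, "enc", centers)
  enc <- .fwdEncode(tape, P, cfg, tokens, pos, useCls)
  list(fused = fused, H = enc$H, hCls = enc$hCls, centers = centers)
}

## ---- exported value-mode operations ------------------------------------

#' Learned per-point chemical feature
#'
#' Runs the message-passing point encoder: each of the 16 neighbor
#' (one-hot type, distance) rows is embedded by a shared MLP, then three
#' message-passing blocks update a per-point local feature (initialized to
#' all ones) by mean-aggregating per-neighbor messages and adding the
#' result residually. Mean aggregation makes the output invariant to
#' neighbor-slot permutations.
#'
#' @param model An [MAEModel-class].
#' @param chemRaw N x 16 x 7 raw chemical feature array.
#' @return N x 6 matrix of learned chemical features.
#' @export
pointEncoder <- function(model, chemRaw) {
  if (length(dim(chemRaw)) != 3L || dim(chemRaw)[3L] != 7L)
    stop("chemRaw must be an N x k x 7 array")
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  .fwdPointEncoder(tape, P, model@config, chemRaw)$val
}

#' Fuse chemical and geometric per-point features
#'
#' Channel-wise concatenation, chemical channels first.
#'
#' @param chem N x 6 learned chemical features.
#' @param curv N x 10 curvature features.
#' @return N x 16 fused feature matrix.
#' @export
fuseFeatures <- function(chem, curv) {
  chem <- rbind(chem)
  curv <- rbind(curv)
  if (nrow(chem) != nrow(curv)) stop("chem and curv must have the same length")
  cbind(chem, curv)
}

#' Tokenize patches
#'
#' Applies the shared tokenizer MLP to the fused feature of every member
#' point of each requested patch and max-pools channel-wise over the k'
#' members, yielding one d-dimensional token per patch. During pretraining
#' only unmasked patches are tokenized (`visibleOnly = TRUE`).
#'
#' @param model An [MAEModel-class].
#' @param patchset A [PatchSet-class].
#' @param fused N x 16 fused feature matrix.
#' @param visibleOnly Tokenize only unmasked patches.
#' @return A [TokenSequence-class] with tokens only (positions zero).
#' @export
tokenize <- function(model, patchset, fused, visibleOnly = TRUE) {
  members <- patchMembers(patchset)
  if (visibleOnly) members <- members[!patchMask(patchset), , drop = FALSE]
  if (nrow(members) == 0L) stop("no patches to tokenize")
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  toks <- .fwdTokenize(tape, P, model@config, adLeaf(tape, fused), members)$val
  new("TokenSequence", tokens = toks,
      positions = matrix(0, nrow(toks), ncol(toks)),
      cls = matrix(0, 0L, ncol(toks)), encoded = matrix(0, 0L, ncol(toks)))
}

#' Positional encoding of patch centers
#'
#' Two-layer MLP (3 -> 128 -> d) of the center coordinates, added to the
#' tokens before the transformer. Encoder and decoder sides use separate
#' weight sets.
#'
#' @param model An [MAEModel-class].
#' @param centers q x 3 center coordinates (centered Angstrom frame).
#' @param side `"enc"` or `"dec"`.
#' @return q x d positional encoding matrix.
#' @export
posEncode <- function(model, centers, side = c("enc", "dec")) {
  side <- match.arg(side)
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  .fwdPos(tape, P, side, rbind(centers))$val
}

#' Transformer encoding of a token sequence
#'
#' Pre-norm transformer of `encoderDepth` blocks (multi-head self-attention
#' plus an MLP of ratio `mlpRatio`). With `useCls` a learnable CLS token
#' (with its own learnable position) is prepended; its output summarizes
#' the surface for classification and is never passed to the decoder.
#'
#' @param model An [MAEModel-class].
#' @param tokens,positions q x d matrices of identical shape.
#' @param useCls Prepend the CLS token.
#' @return List with `H` (q x d encoded tokens) and `hCls` (1 x d or NULL).
#' @export
encodeTokens <- function(model, tokens, positions, useCls = FALSE) {
  if (!all(dim(tokens) == dim(positions)))
    stop("tokens and positions must have identical shape")
  if (ncol(tokens) != model@config@d)
    stop("token width does not match config d")
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  enc <- .fwdEncode(tape, P, model@config, adLeaf(tape, tokens),
                    adLeaf(tape, positions), useCls)
  list(H = enc$H$val, hCls = if (useCls) enc$hCls$val else NULL)
}

#' Decode masked patches
#'
#' The decoder receives the projected visible-patch encodings plus one
#' shared learnable mask token per masked patch, each with decoder-side
#' positional encodings of its patch center, runs four self-attention
#' blocks, and maps every masked slot through a linear head to k' predicted
#' coordinates expressed relative to the patch center.
#'
#' @param model An [MAEModel-class].
#' @param hVisible v x d encoded visible tokens.
#' @param visCenters v x 3 visible patch centers.
#' @param maskCenters mg x 3 masked patch centers (at least one).
#' @return mg x k' x 3 array of center-relative predicted coordinates.
#' @export
decodeMasked <- function(model, hVisible, visCenters, maskCenters) {
  maskCenters <- rbind(maskCenters)
  if (nrow(maskCenters) < 1L) stop("decoder requires at least one masked patch")
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  flat <- .fwdDecode(tape, P, model@config, adLeaf(tape, hVisible),
                     rbind(visCenters), maskCenters)$val
  k <- model@config@kPrime
  out <- array(0, dim = c(nrow(maskCenters), k, 3L))
  for (i in seq_len(nrow(maskCenters)))
    out[i, , ] <- flat[(i - 1L) * k + seq_len(k), ]
  out
}

#' Chamfer reconstruction loss
#'
#' Sum over masked patches of the two directional mean-of-minimum squared
#' Euclidean distances between the predicted and target point sets:
#' `L = sum_i [ mean_{x in T_i} min_{y in P_i} |x-y|^2
#'            + mean_{x in P_i} min_{y in T_i} |x-y|^2 ]`.
#'
#' @param pred,target Lists of k x 3 matrices (one per patch, same length),
#'   or single matrices for the one-patch case, in a common (center-
#'   relative) frame.
#' @return Scalar loss.
#' @export
chamferLoss <- function(pred, target) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(target)) target <- list(target)
  if (length(pred) != length(target))
    stop("pred and target must have the same number of patches")
  total <- 0
  for (i in seq_along(pred)) {
    Pm <- rbind(pred[[i]])
    Tm <- rbind(target[[i]])
    if (nrow(Pm) == 0L || nrow(Tm) == 0L) stop("empty patch in chamfer loss")
    D <- pairwiseSqDist(Tm, Pm)
    total <- total + mean(apply(D, 1L, min)) + mean(apply(D, 2L, min))
  }
  total
}

#' Per-point binding-site logits
#'
#' Interpolates the encoded patch tokens at every surface point (inverse-
#' distance weights over the 3 nearest patch centers, normalized to sum to
#' one), concatenates the point's fused 16-D feature and the global
#' max-pooled token, and maps the result through an MLP to one logit per
#' point.
#'
#' @param model An [MAEModel-class].
#' @param encoded g x d encoded patch tokens (no CLS row).
#' @param patchset An unmasked [PatchSet-class].
#' @param points N x 3 surface points.
#' @param fused N x 16 fused features.
#' @return Numeric vector of N logits.
#' @export
headSite <- function(model, encoded, patchset, points, fused) {
  if (any(patchMask(patchset))) stop("headSite requires an unmasked patchset")
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  centers <- rbind(points)[patchCenterIdx(patchset), , drop = FALSE]
  out <- .fwdHeadSite(tape, P, model@config, adLeaf(tape, encoded),
                      rbind(points), centers, adLeaf(tape, fused))
  as.vector(out$val)
}

#' Pocket classification logits
#'
#' Concatenates the encoded CLS state with the channel-wise max pool of
#' the other tokens and maps through an MLP to `nClasses` logits.
#'
#' @param model An [MAEModel-class].
#' @param hCls 1 x d encoded CLS state (requires CLS-enabled encoding).
#' @param encoded g x d encoded patch tokens.
#' @return Numeric vector of `nClasses` logits.
#' @export
headPocket <- function(model, hCls, encoded) {
  if (is.null(hCls)) stop("headPocket requires the CLS token")
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  out <- .fwdHeadPocket(tape, P, model@config, adLeaf(tape, rbind(hCls)),
                        adLeaf(tape, encoded))
  as.vector(out$val)
}

#' Per-point interaction descriptors
#'
#' Interpolates encoded tokens at every point (3-NN inverse-distance
#' weights), optionally projects to `descriptorDim`, and L2-normalizes.
#' The binding score of two points is the scaled dot product of their
#' descriptors.
#'
#' @param model An [MAEModel-class].
#' @param encoded g x d encoded patch tokens.
#' @param patchset An unmasked [PatchSet-class].
#' @param points N x 3 surface points.
#' @return N x descriptorDim matrix of unit-norm descriptors.
#' @export
headDescriptor <- function(model, encoded, patchset, points) {
  if (any(patchMask(patchset)))
    stop("headDescriptor requires an unmasked patchset")
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  centers <- rbind(points)[patchCenterIdx(patchset), , drop = FALSE]
  .fwdHeadDescriptor(tape, P, model@config, adLeaf(tape, encoded),
                     rbind(points), centers)$val
}
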