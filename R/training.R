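## Training: AdamW, the masked-reconstruction pretraining loop, best-epoch
## selection, the three fine-tuning procedures, and the evaluation metrics.

## ---- optimizer ---------------------------------------------------------

.adamInit <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(v) array(0, dim(v)))
  e$v <- lapply(params, function(v) array(0, dim(v)))
  e$t <- 0L
  e
}

## One AdamW step; decoupled weight decay on weight matrices (".W") only.
.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0.01) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    upd <- (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
    if (endsWith(nm, ".W")) upd <- upd + weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}

.trainDefaults <- function(settings, lr = 1e-3) {
  base <- list(lr = lr, epochs = 50L, batch = 16L, weightDecay = 0.01,
               schedule = "constant", valFraction = 0.25, maxPairs = 64L)
  base[names(settings)] <- settings
  base
}

.epochLr <- function(s, epoch) {
  if (identical(s$schedule, "cosine"))
    s$lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(1L, s$epochs)))
  else s$lr
}

## ---- patchification helper --------------------------------------------

#' Patchify a surface cloud
#'
#' FPS centers + KNN membership with the model's g and k'; mask flags off.
#'
#' @param surf A [SurfaceCloud-class].
#' @param cfg A [ModelConfig-class] supplying g and k'.
#' @return An unmasked [PatchSet-class].
#' @export
patchify <- function(surf, cfg) {
  pts <- surfacePoints(surf)
  knnGroup(pts, farthestPointSample(pts, cfg@g), cfg@kPrime)
}

## Center-relative target coordinates of the given patches.
.patchTargets <- function(points, patchset, which) {
  lapply(which, function(i) {
    mem <- patchMembers(patchset)[i, ]
    ctr <- points[patchCenterIdx(patchset)[i], ]
    sweep(points[mem, , drop = FALSE], 2L, ctr)
  })
}

## ---- pretraining -------------------------------------------------------

#' Masked-autoencoder pretraining
#'
#' Per step: patchify, mask round(m*g) patches with a fresh per-sample
#' per-epoch seed, tokenize and encode the visible patches (CLS included
#' in the forward but never decoded), decode the masked patches and take
#' an AdamW step on the chamfer reconstruction loss of Eq-style
#' sum-over-patches form. Defaults follow AdamW with initial learning rate
#' 1e-3, batch 16 and 50 epochs; at small dataset sizes `batch = 1` turns
#' every sample into one step. Fully reproducible given the seed.
#'
#' @param surfaces Non-empty list of [SurfaceCloud-class] objects, all with
#'   the same number of points.
#' @param cfg A [ModelConfig-class]; `m` must be positive.
#' @param settings Named list overriding `lr`, `epochs`, `batch`,
#'   `weightDecay`, `schedule` ("constant" or "cosine").
#' @param seed Global training seed.
#' @param keepCheckpoints `"best"` (default) keeps the minimal-loss
#'   parameter snapshot, `"all"` one per epoch, `"none"` none.
#' @param model Optional [MAEModel-class] to start from (defaults to a
#'   fresh seeded initialization).
#' @return List with `state` (a [TrainState-class]), `model` (final
#'   weights) and `best` (an [MAEModel-class] carrying the minimal-loss
#'   weights, when checkpoints are kept).
#' @export
pretrain <- function(surfaces, cfg = ModelConfig(), settings = list(),
                     seed = 0L, keepCheckpoints = c("best", "all", "none"),
                     model = NULL) {
  keepCheckpoints <- match.arg(keepCheckpoints)
  if (length(surfaces) == 0L) stop("empty dataset")
  if (cfg@m <= 0) stop("pretraining requires a positive mask ratio m")
  s <- .trainDefaults(settings, lr = 1e-3)
  if (is.null(model)) model <- maeModel(cfg, seed = deriveSeed(seed, 77L))
  params <- model@params
  opt <- .adamInit(params)
  patchsets <- lapply(surfaces, patchify, cfg = cfg)
  nS <- length(surfaces)
  losses <- numeric(0)
  ckpts <- list()
  bestLoss <- Inf
  bestParams <- params
  for (epoch in seq_len(s$epochs)) {
    ord <- withSeed(deriveSeed(seed, 9000L, epoch), sample.int(nS))
    lr <- .epochLr(s, epoch)
    epochLoss <- 0
    nStep <- 0L
    accum <- NULL
    inBatch <- 0L
    for (si in seq_along(ord)) {
      i <- ord[si]
      surf <- surfaces[[i]]
      ps <- applyMask(patchsets[[i]], cfg@m, seed = deriveSeed(seed, epoch, i))
      res <- .pretrainForward(params, cfg, surf, ps)
      if (!is.finite(res$loss))
        stop(sprintf("NaN/Inf loss at epoch %d sample %d", epoch, i))
      epochLoss <- epochLoss + res$loss
      nStep <- nStep + 1L
      accum <- if (is.null(accum)) res$grads
               else mapply(`+`, accum, res$grads, SIMPLIFY = FALSE)
      inBatch <- inBatch + 1L
      if (inBatch >= s$batch || si == length(ord)) {
        accum <- lapply(accum, `/`, inBatch)
        params <- .adamStep(params, accum, opt, lr,
                            weightDecay = s$weightDecay)
        accum <- NULL
        inBatch <- 0L
      }
    }
    losses <- c(losses, epochLoss / nStep)
    if (keepCheckpoints == "all") ckpts[[epoch]] <- params
    if (losses[epoch] < bestLoss) {
      bestLoss <- losses[epoch]
      if (keepCheckpoints != "none") bestParams <- params
    }
  }
  state <- new("TrainState", epochLosses = losses,
               bestEpoch = which.min(losses),
               settings = s, seed = as.integer(seed), checkpoints = ckpts)
  final <- model
  final@params <- params
  best <- model
  best@params <- if (keepCheckpoints == "all")
    ckpts[[which.min(losses)]] else bestParams
  list(state = state, model = final, best = best)
}

## One pretraining forward/backward; returns loss value and gradients.
.pretrainForward <- function(params, cfg, surf, patchset) {
  tape <- adTape()
  P <- .paramNodes(tape, params)
  mask <- patchMask(patchset)
  vis <- which(!mask)
  msk <- which(mask)
  pts <- surfacePoints(surf)
  chem <- .fwdPointEncoder(tape, P, cfg, chemRaw(surf))
  fused <- adConcatCols(tape, chem, adLeaf(tape, surfaceCurvatures(surf)))
  tokens <- .fwdTokenize(tape, P, cfg, fused,
                         patchMembers(patchset)[vis, , drop = FALSE])
  centers <- pts[patchCenterIdx(patchset), , drop = FALSE]
  pos <- .fwdPos(tape, P, "enc", centers[vis, , drop = FALSE])
  enc <- .fwdEncode(tape, P, cfg, tokens, pos, useCls = TRUE)
  predFlat <- .fwdDecode(tape, P, cfg, enc$H,
                         centers[vis, , drop = FALSE],
                         centers[msk, , drop = FALSE])
  k <- cfg@kPrime
  predNodes <- lapply(seq_along(msk), function(j)
    adRowsSelect(tape, predFlat, (j - 1L) * k + seq_len(k)))
  targets <- .patchTargets(pts, patchset, msk)
  loss <- .chamferNode(tape, predNodes, targets)
  adBackward(tape, loss)
  list(loss = loss$val[1L], grads = .collectGrads(P, params))
}

#' Select the best pretraining epoch
#'
#' The epoch with minimal recorded reconstruction loss; ties go to the
#' earliest epoch.
#'
#' @param state A [TrainState-class] with at least one epoch.
#' @return 1-based epoch id.
#' @export
selectBest <- function(state) {
  if (length(state@epochLosses) == 0L) stop("empty loss log")
  which.min(state@epochLosses)
}

## ---- losses ------------------------------------------------------------

## Balanced index sample: all of the minority class plus an equally sized
## seeded without-replacement sample of the majority class.
.balancedIdx <- function(labels, seed) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("balanced loss requires both classes")
  nmin <- min(length(pos), length(neg))
  withSeed(seed, {
    if (length(pos) > nmin) pos <- pos[sample.int(length(pos), nmin)]
    if (length(neg) > nmin) neg <- neg[sample.int(length(neg), nmin)]
  })
  c(pos, neg)
}

#' Balanced binary cross-entropy
#'
#' Subsamples the majority class (seeded, without replacement) down to the
#' minority count and returns the mean binary cross-entropy with logits
#' over the balanced set.
#'
#' @param logits Numeric vector of logits.
#' @param labels 0/1 vector, both classes present.
#' @param seed Integer seed for the majority subsample.
#' @return Scalar loss.
#' @export
balancedCrossEntropy <- function(logits, labels, seed = 0L) {
  idx <- .balancedIdx(labels, seed)
  z <- logits[idx]
  y <- labels[idx]
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

## ---- metrics -----------------------------------------------------------

#' ROC-AUC (rank statistic)
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted one half; computed from average ranks (equivalent to
#' exhaustive pair counting).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return Value in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  pos <- labels == 1
  nP <- sum(pos)
  nN <- sum(!pos)
  if (nP == 0L || nN == 0L) stop("ROC-AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Binary classification metrics at a threshold
#'
#' @param predictions Predicted probabilities (or scores).
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: `accuracy`, `recall`, `f1`.
#' @export
classificationMetrics <- function(predictions, labels, threshold = 0.5) {
  if (length(predictions) == 0L) stop("empty input")
  pred <- as.integer(predictions >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(accuracy = (tp + tn) / length(labels), recall = recall, f1 = f1)
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recalls.
#'
#' @param predictions Predicted class ids.
#' @param labels True class ids; every class in `0:(nClasses-1)` (or the
#'   corresponding 1-based set) must appear.
#' @param nClasses Number of classes.
#' @return Value in [0, 1].
#' @export
balancedAccuracy <- function(predictions, labels, nClasses) {
  classes <- sort(unique(labels))
  if (length(classes) != nClasses)
    stop("every labeled class must have at least one example")
  mean(vapply(classes, function(cl)
    mean(predictions[labels == cl] == cl), 1.0))
}

## ---- fine-tuning -------------------------------------------------------

## Stratified holdout indices (at least one per class when stratify is set).
.splitHoldout <- function(n, frac, seed, strata = NULL) {
  withSeed(seed, {
    if (is.null(strata)) {
      k <- max(1L, round(frac * n))
      sort(sample.int(n, k))
    } else {
      unlist(lapply(unique(strata), function(cl) {
        idx <- which(strata == cl)
        k <- max(1L, round(frac * length(idx)))
        sort(idx[sample.int(length(idx), k)])
      }))
    }
  })
}

#' Fine-tune for binding-site identification
#'
#' Initializes the encoder from a pretrained model (or a fresh one for the
#' from-scratch baseline) and trains encoder + site head end-to-end with
#' the balanced binary cross-entropy, reporting ROC-AUC, accuracy, recall
#' and F1 on a held-out subset.
#'
#' @param dataset List of `list(surface = SurfaceCloud, labels = 0/1
#'   vector)` entries with labels aligned to the surface points.
#' @param model An [MAEModel-class] used as initialization.
#' @param settings Named list overriding `lr` (default 1e-4), `epochs`
#'   (default 50), `valFraction` (default 0.25), `weightDecay`.
#' @param seed Integer seed (splits, balancing, shuffling).
#' @return List with `model`, `metrics` (held-out ROC-AUC/accuracy/recall/
#'   F1), `history` (per-epoch mean training loss) and `holdout` indices.
#' @export
finetuneSite <- function(dataset, model, settings = list(), seed = 0L) {
  s <- .trainDefaults(settings, lr = 1e-4)
  cfg <- model@config
  for (d in dataset)
    if (length(d$labels) != nPoints(d$surface))
      stop("labels are not aligned with the surface points")
  for (d in dataset)
    if (length(unique(d$labels)) < 2L)
      stop("balanced loss requires both classes in every sample")
  hold <- .splitHoldout(length(dataset), s$valFraction, deriveSeed(seed, 1L))
  trainIdx <- setdiff(seq_along(dataset), hold)
  params <- model@params
  opt <- .adamInit(params)
  patchsets <- lapply(dataset, function(d) patchify(d$surface, cfg))
  history <- numeric(0)
  for (epoch in seq_len(s$epochs)) {
    ord <- trainIdx[withSeed(deriveSeed(seed, 8000L, epoch),
                             sample.int(length(trainIdx)))]
    lr <- .epochLr(s, epoch)
    el <- 0
    for (i in ord) {
      surf <- dataset[[i]]$surface
      labels <- dataset[[i]]$labels
      tape <- adTape()
      P <- .paramNodes(tape, params)
      fw <- .fwdSurfaceEncode(tape, P, cfg, surf, patchsets[[i]], useCls = FALSE)
      logits <- .fwdHeadSite(tape, P, cfg, fw$H, surfacePoints(surf),
                             fw$centers, fw$fused)
      idx <- .balancedIdx(labels, deriveSeed(seed, epoch, i))
      sel <- adRowsSelect(tape, logits, idx)
      loss <- adBCEWithLogits(tape, sel, labels[idx])
      adBackward(tape, loss)
      if (!is.finite(loss$val[1L])) stop("NaN/Inf fine-tuning loss")
      el <- el + loss$val[1L]
      params <- .adamStep(params, .collectGrads(P, params), opt, lr,
                          weightDecay = s$weightDecay)
    }
    history <- c(history, el / length(ord))
  }
  out <- model
  out@params <- params
  ## held-out evaluation, pooled over surfaces
  scores <- numeric(0)
  truth <- integer(0)
  for (i in hold) {
    surf <- dataset[[i]]$surface
    z <- .siteLogits(out, surf, patchsets[[i]])
    scores <- c(scores, 1 / (1 + exp(-z)))
    truth <- c(truth, dataset[[i]]$labels)
  }
  metrics <- c(list(rocAuc = rocAuc(scores, truth)),
               classificationMetrics(scores, truth))
  list(model = out, metrics = metrics, history = history, holdout = hold)
}

## Value-mode site logits for one surface.
.siteLogits <- function(model, surf, patchset = NULL) {
  cfg <- model@config
  if (is.null(patchset)) patchset <- patchify(surf, cfg)
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  fw <- .fwdSurfaceEncode(tape, P, cfg, surf, patchset, useCls = FALSE)
  out <- .fwdHeadSite(tape, P, cfg, fw$H, surfacePoints(surf),
                      fw$centers, fw$fused)
  as.vector(out$val)
}

#' Fine-tune for ligand-pocket classification
#'
#' CLS-enabled encoding; the pocket head is trained with the standard
#' softmax cross-entropy; balanced accuracy is reported on a stratified
#' held-out subset.
#'
#' @param dataset List of `list(surface = SurfaceCloud, class = integer in
#'   0..nClasses-1)`.
#' @param model An [MAEModel-class] initialization.
#' @param settings As in [finetuneSite()].
#' @param seed Integer seed.
#' @return List with `model`, `balancedAccuracy`, `history`, `holdout`.
#' @export
finetunePocket <- function(dataset, model, settings = list(), seed = 0L) {
  s <- .trainDefaults(settings, lr = 1e-4)
  cfg <- model@config
  classes <- vapply(dataset, function(d) as.integer(d$class), 1L)
  if (any(classes < 0L | classes >= cfg@nClasses))
    stop("class out of range 0..nClasses-1")
  hold <- .splitHoldout(length(dataset), s$valFraction, deriveSeed(seed, 1L),
                        strata = classes)
  trainIdx <- setdiff(seq_along(dataset), hold)
  params <- model@params
  opt <- .adamInit(params)
  patchsets <- lapply(dataset, function(d) patchify(d$surface, cfg))
  history <- numeric(0)
  for (epoch in seq_len(s$epochs)) {
    ord <- trainIdx[withSeed(deriveSeed(seed, 8000L, epoch),
                             sample.int(length(trainIdx)))]
    lr <- .epochLr(s, epoch)
    el <- 0
    for (i in ord) {
      tape <- adTape()
      P <- .paramNodes(tape, params)
      fw <- .fwdSurfaceEncode(tape, P, cfg, dataset[[i]]$surface,
                              patchsets[[i]], useCls = TRUE)
      logits <- .fwdHeadPocket(tape, P, cfg, fw$hCls, fw$H)
      loss <- adSoftmaxCrossEntropy(tape, logits, classes[i] + 1L)
      adBackward(tape, loss)
      if (!is.finite(loss$val[1L])) stop("NaN/Inf fine-tuning loss")
      el <- el + loss$val[1L]
      params <- .adamStep(params, .collectGrads(P, params), opt, lr,
                          weightDecay = s$weightDecay)
    }
    history <- c(history, el / length(ord))
  }
  out <- model
  out@params <- params
  preds <- vapply(hold, function(i) {
    z <- .pocketLogits(out, dataset[[i]]$surface, patchsets[[i]])
    which.max(z) - 1L
  }, 1L)
  ba <- balancedAccuracy(preds, classes[hold],
                         nClasses = length(unique(classes[hold])))
  list(model = out, balancedAccuracy = ba, history = history, holdout = hold)
}

.pocketLogits <- function(model, surf, patchset = NULL) {
  cfg <- model@config
  if (is.null(patchset)) patchset <- patchify(surf, cfg)
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  fw <- .fwdSurfaceEncode(tape, P, cfg, surf, patchset, useCls = TRUE)
  as.vector(.fwdHeadPocket(tape, P, cfg, fw$hCls, fw$H)$val)
}

#' Fine-tune for PPI descriptor matching
#'
#' Trains the encoder so that descriptors of interacting point pairs score
#' high: per step, a 1:1 balanced seeded sample of positive (interacting)
#' pairs and random negative pairs is scored by the scaled dot product of
#' the two points' unit descriptors and pushed through a binary
#' cross-entropy. ROC-AUC over held-out pair scores is reported.
#'
#' @param dataset List of `list(surfaceA, surfaceB, posPairs)` entries,
#'   `posPairs` an n x 2 index matrix (point in A, point in B) with at
#'   least one row.
#' @param model An [MAEModel-class] initialization.
#' @param settings As in [finetuneSite()]; `maxPairs` caps the per-step
#'   positive sample (default 64).
#' @param seed Integer seed.
#' @return List with `model`, `rocAuc`, `history`, `holdout`.
#' @export
finetunePpi <- function(dataset, model, settings = list(), seed = 0L) {
  s <- .trainDefaults(settings, lr = 1e-4)
  cfg <- model@config
  for (d in dataset)
    if (is.null(d$posPairs) || nrow(rbind(d$posPairs)) < 1L)
      stop("every sample needs at least one positive pair")
  hold <- .splitHoldout(length(dataset), s$valFraction, deriveSeed(seed, 1L))
  trainIdx <- setdiff(seq_along(dataset), hold)
  params <- model@params
  opt <- .adamInit(params)
  psA <- lapply(dataset, function(d) patchify(d$surfaceA, cfg))
  psB <- lapply(dataset, function(d) patchify(d$surfaceB, cfg))
  history <- numeric(0)
  for (epoch in seq_len(s$epochs)) {
    ord <- trainIdx[withSeed(deriveSeed(seed, 8000L, epoch),
                             sample.int(length(trainIdx)))]
    lr <- .epochLr(s, epoch)
    el <- 0
    for (i in ord) {
      d <- dataset[[i]]
      pairs <- .samplePairs(d, deriveSeed(seed, epoch, i), s$maxPairs,
                            nPoints(d$surfaceA), nPoints(d$surfaceB))
      tape <- adTape()
      P <- .paramNodes(tape, params)
      fwA <- .fwdSurfaceEncode(tape, P, cfg, d$surfaceA, psA[[i]], useCls = FALSE)
      fwB <- .fwdSurfaceEncode(tape, P, cfg, d$surfaceB, psB[[i]], useCls = FALSE)
      dA <- .fwdHeadDescriptor(tape, P, cfg, fwA$H, surfacePoints(d$surfaceA),
                               fwA$centers)
      dB <- .fwdHeadDescriptor(tape, P, cfg, fwB$H, surfacePoints(d$surfaceB),
                               fwB$centers)
      scores <- .pairScoreNode(tape, P, dA, dB, pairs$idx)
      loss <- adBCEWithLogits(tape, scores, pairs$y)
      adBackward(tape, loss)
      if (!is.finite(loss$val[1L])) stop("NaN/Inf fine-tuning loss")
      el <- el + loss$val[1L]
      params <- .adamStep(params, .collectGrads(P, params), opt, lr,
                          weightDecay = s$weightDecay)
    }
    history <- c(history, el / length(ord))
  }
  out <- model
  out@params <- params
  scores <- numeric(0)
  truth <- integer(0)
  for (i in hold) {
    d <- dataset[[i]]
    pairs <- .samplePairs(d, deriveSeed(seed, 4242L, i), s$maxPairs,
                          nPoints(d$surfaceA), nPoints(d$surfaceB))
    sc <- .pairScores(out, d, psA[[i]], psB[[i]], pairs$idx)
    scores <- c(scores, sc)
    truth <- c(truth, pairs$y)
  }
  list(model = out, rocAuc = rocAuc(scores, truth), history = history,
       holdout = hold)
}

## Balanced 1:1 positive/negative pair sample for one complex.
.samplePairs <- function(d, seed, maxPairs, nA, nB) {
  pos <- rbind(d$posPairs)
  withSeed(seed, {
    nPos <- min(nrow(pos), maxPairs)
    pos <- pos[sample.int(nrow(pos), nPos), , drop = FALSE]
    neg <- cbind(sample.int(nA, nPos, replace = TRUE),
                 sample.int(nB, nPos, replace = TRUE))
  })
  list(idx = rbind(pos, neg), y = rep(c(1L, 0L), each = nrow(pos)))
}

## Scaled dot-product scores of descriptor row pairs (node version).
.pairScoreNode <- function(tape, P, dA, dB, idx) {
  a <- adRowsSelect(tape, dA, idx[, 1L])
  b <- adRowsSelect(tape, dB, idx[, 2L])
  ones <- adLeaf(tape, matrix(1, ncol(a$val), 1L))
  dots <- adMatmul(tape, adMul(tape, a, b), ones)
  adAddBias(tape, adMatmul(tape, dots, P$ppi.scale), P$ppi.bias)
}

## Value-mode pair scores for evaluation.
.pairScores <- function(model, d, psA, psB, idx) {
  cfg <- model@config
  tape <- adTape()
  P <- .paramNodes(tape, model@params)
  fwA <- .fwdSurfaceEncode(tape, P, cfg, d$surfaceA, psA, useCls = FALSE)
  fwB <- .fwdSurfaceEncode(tape, P, cfg, d$surfaceB, psB, useCls = FALSE)
  dA <- .fwdHeadDescriptor(tape, P, cfg, fwA$H, surfacePoints(d$surfaceA),
                           fwA$centers)
  dB <- .fwdHeadDescriptor(tape, P, cfg, fwB$H, surfacePoints(d$surfaceB),
                           fwB$centers)
  as.vector(.pairScoreNode(tape, P, dA, dB, idx)$val)
}
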