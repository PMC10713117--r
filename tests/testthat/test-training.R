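test_that("best-epoch selection takes the earliest minimal loss", {
  mk <- function(l) new("TrainState", epochLosses = l,
                        bestEpoch = which.min(l), settings = list(),
                        seed = 0L, checkpoints = list())
  expect_equal(selectBest(mk(c(1.0, 0.7, 0.8))), 2L)
  expect_equal(selectBest(mk(c(0.5, 0.5))), 1L)
  expect_equal(selectBest(mk(c(0.9, 0.6, 0.3))), 3L)
  expect_error(selectBest(mk(numeric(0))), "empty")
})

test_that("balanced cross-entropy balances then averages", {
  ## all-zero logits give log(2) regardless of balance
  expect_equal(balancedCrossEntropy(rep(0, 40), rep(c(0, 1), 20), seed = 1),
               log(2), tolerance = 1e-12)
  ## perfectly separated large logits drive the loss to zero
  z <- c(rep(-30, 50), rep(30, 50))
  y <- c(rep(0, 50), rep(1, 50))
  expect_lt(balancedCrossEntropy(z, y, seed = 1), 1e-3)
  ## 10 positives / 90 negatives: exactly 20 samples enter the mean
  expect_length(surfmae:::.balancedIdx(c(rep(1, 10), rep(0, 90)), seed = 2),
                20L)
  expect_error(balancedCrossEntropy(rnorm(5), rep(1, 5)), "both classes")
  ## invariant in expectation to duplicating the majority class
  set.seed(3)
  z <- rnorm(60)
  y <- c(rep(1, 20), rep(0, 40))
  base <- mean(vapply(1:200, function(s) balancedCrossEntropy(z, y, s), 1.0))
  dup <- mean(vapply(1:200, function(s)
    balancedCrossEntropy(c(z, z[21:60]), c(y, y[21:60]), s), 1.0))
  expect_equal(base, dup, tolerance = 0.05)
})

test_that("ROC-AUC equals exhaustive pair counting", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(-5, -1, 2, 7), c(0, 0, 1, 1)), 1.0)
  expect_equal(rocAuc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(rocAuc(rnorm(4), rep(1, 4)), "both classes")
  pairCount <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    s <- round(rnorm(n), 1)            # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(rocAuc(s, y), pairCount(s, y), tolerance = 1e-12)
  }
})

test_that("confusion-matrix metrics and balanced accuracy are exact", {
  ## TP=2, FP=1, FN=2, TN=10: accuracy 12/15, recall 2/4, F1 = 4/7
  pred <- c(0.9, 0.8, 0.7, 0.2, 0.3, rep(0.1, 10))
  lab <- c(1, 1, 0, 1, 1, rep(0, 10))
  m <- classificationMetrics(pred, lab)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 4 / 7)
  p <- classificationMetrics(c(0.9, 0.1), c(1, 0))
  expect_equal(unlist(p), c(accuracy = 1, recall = 1, f1 = 1))
  z <- classificationMetrics(rep(0.1, 4), c(1, 1, 0, 0))
  expect_equal(z$recall, 0)
  expect_equal(z$f1, 0)
  ## balanced accuracy: per-class recalls 1.0 and 0.5 average to 0.75
  expect_equal(balancedAccuracy(c(1, 1, 2, 1), c(1, 1, 2, 2), 2L), 0.75)
  set.seed(5)
  lab <- rep(1:3, each = 10)
  prd <- sample(1:3, 30, replace = TRUE)
  expect_equal(balancedAccuracy(prd, lab, 3L), mean(prd == lab))
  ## 7-class diagonal (3,3,3,3,3,3,0) of 3-per-class truth
  lab7 <- rep(1:7, each = 3)
  prd7 <- lab7
  prd7[lab7 == 7] <- 1
  expect_equal(balancedAccuracy(prd7, lab7, 7L), 6 / 7)
  expect_error(balancedAccuracy(prd7, rep(1:6, each = 3), 7L), "every labeled")
})

test_that("pretraining is seeded, masks the stated count and logs losses", {
  cfg <- tinyModelConfig()
  scfg <- tinySurfaceConfig()
  surfs <- synthSurfaceDataset(2, scfg, seed = 1)
  ps <- patchify(surfs[[1]], cfg)
  expect_equal(sum(patchMask(applyMask(ps, 0.6, seed = 3))), 19L)  # round(19.2)
  r1 <- pretrain(surfs, cfg, settings = list(epochs = 3L, batch = 1L), seed = 7)
  r2 <- pretrain(surfs, cfg, settings = list(epochs = 3L, batch = 1L), seed = 7)
  expect_identical(epochLosses(r1$state), epochLosses(r2$state))
  expect_length(epochLosses(r1$state), 3L)
  expect_equal(bestEpoch(r1$state), which.min(epochLosses(r1$state)))
  expect_error(pretrain(list(), cfg), "empty dataset")
  expect_error(pretrain(surfs, ModelConfig(m = 0)), "positive mask ratio")
})

test_that("fine-tuning rejects malformed datasets", {
  cfg <- tinyModelConfig()
  surfs <- synthSurfaceDataset(2, tinySurfaceConfig(), seed = 2)
  mod <- maeModel(cfg, seed = 0)
  bad <- list(list(surface = surfs[[1]], labels = c(0, 1)))
  expect_error(finetuneSite(bad, mod), "not aligned")
  const <- list(list(surface = surfs[[1]],
                     labels = rep(1L, nPoints(surfs[[1]]))))
  expect_error(finetuneSite(const, mod), "both classes")
  expect_error(finetunePocket(list(list(surface = surfs[[1]], class = 9L)),
                              mod), "out of range")
  expect_error(finetunePpi(list(list(surfaceA = surfs[[1]],
                                     surfaceB = surfs[[2]],
                                     posPairs = matrix(0, 0, 2))), mod),
               "positive pair")
})

test_that("pocket fine-tuning learns the generative class at desk scale", {
  ds <- synthPocketDataset(6, tinySurfaceConfig(), seed = 4)
  expect_length(ds, 42L)
  mod <- maeModel(tinyModelConfig(), seed = 2)
  ft <- finetunePocket(ds, mod, settings = list(epochs = 12L, lr = 1e-3),
                       seed = 1)
  expect_gt(ft$balancedAccuracy, 1 / 7 + 0.2)
  ## degenerate single-class evaluation reduces to that class's recall
  expect_equal(balancedAccuracy(c(2, 2, 3), rep(2, 3), 1L), 2 / 3)
})

test_that("PPI descriptor fine-tuning separates contact pairs", {
  ds <- synthPpiDataset(8, tinySurfaceConfig(256L), seed = 6)
  expect_gte(length(ds), 6L)
  expect_true(all(vapply(ds, function(d) nrow(d$posPairs), 1L) >= 1L))
  mod <- maeModel(tinyModelConfig(), seed = 2)
  ft <- finetunePpi(ds, mod, settings = list(epochs = 15L, lr = 1e-3),
                    seed = 1)
  expect_gt(ft$rocAuc, 0.8)
  ## every training step samples negatives 1:1 with positives
  pr <- surfmae:::.samplePairs(ds[[1]], seed = 3, maxPairs = 64L,
                               nPoints(ds[[1]]$surfaceA),
                               nPoints(ds[[1]]$surfaceB))
  expect_equal(sum(pr$y == 1), sum(pr$y == 0))
})

test_that("self-paired identical surfaces drop below log(2) quickly", {
  surfs <- synthSurfaceDataset(2, tinySurfaceConfig(), seed = 8)
  self <- lapply(surfs, function(s) {
    list(surfaceA = s, surfaceB = s,
         posPairs = cbind(1:nPoints(s), 1:nPoints(s)))
  })
  mod <- maeModel(tinyModelConfig(), seed = 3)
  ft <- finetunePpi(self, mod, settings = list(epochs = 100L, lr = 1e-3),
                    seed = 2)
  expect_lt(min(ft$history), log(2))
  expect_lte(which(ft$history < log(2))[1L], 100L)
})
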