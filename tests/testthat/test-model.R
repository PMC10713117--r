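## Shared tiny instances for the architecture tests.
.mdl <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tinyModelConfig()
      surf <- buildSurface(synthChain(20, seed = 0), tinySurfaceConfig(),
                           seed = 0)
      mod <- maeModel(cfg, seed = 1)
      cache <<- list(cfg = cfg, surf = surf, mod = mod,
                     ps = patchify(surf, cfg))
    }
    cache
  }
})

test_that("point encoder emits 6-D features from 3 message-passing blocks", {
  x <- .mdl()
  chem <- pointEncoder(x$mod, chemRaw(x$surf))
  expect_equal(dim(chem), c(nPoints(x$surf), 6L))
  ## exactly three message-passing blocks exist in the parameter store
  nms <- names(modelParams(x$mod))
  expect_true(all(c("pe.mp1.1.W", "pe.mp2.1.W", "pe.mp3.1.W") %in% nms))
  expect_false(any(grepl("^pe\\.mp4", nms)))
  ## permuting the neighbor slots of one point leaves its output unchanged
  cr <- chemRaw(x$surf)
  perm <- sample(16L)
  cr[5L, , ] <- cr[5L, perm, ]
  chem2 <- pointEncoder(x$mod, cr)
  expect_equal(chem2[5L, ], chem[5L, ], tolerance = 1e-6)
})

test_that("feature fusion concatenates chemical then geometric channels", {
  set.seed(1)
  chem <- matrix(rnorm(30), 5L)
  curv <- matrix(rnorm(50), 5L)
  f <- fuseFeatures(chem, curv)
  expect_equal(dim(f), c(5L, 16L))
  expect_identical(f[, 1:6], chem)
  expect_identical(fuseFeatures(chem, curv * 0)[, 7:16], matrix(0, 5L, 10L))
  expect_error(fuseFeatures(chem, curv[1:3, ]), "same length")
})

test_that("tokenizer max-pooling is idempotent and order-invariant", {
  x <- .mdl()
  chem <- pointEncoder(x$mod, chemRaw(x$surf))
  fused <- fuseFeatures(chem, surfaceCurvatures(x$surf))
  ts <- tokenize(x$mod, x$ps, fused, visibleOnly = FALSE)
  expect_equal(dim(ts@tokens), c(x$cfg@g, x$cfg@d))
  ## permute members within each patch
  psPerm <- x$ps
  set.seed(2)
  for (i in seq_len(nPatches(psPerm))) {
    perm <- c(1L, 1L + sample(patchSize(psPerm) - 1L))
    psPerm@members[i, ] <- psPerm@members[i, perm]
  }
  tsPerm <- tokenize(x$mod, psPerm, fused, visibleOnly = FALSE)
  expect_equal(tsPerm@tokens, ts@tokens, tolerance = 1e-6)
  ## duplicating every member leaves the max-pooled token unchanged
  psDup <- x$ps
  psDup@members <- cbind(x$ps@members, x$ps@members)
  tsDup <- tokenize(x$mod, psDup, fused, visibleOnly = FALSE)
  expect_equal(tsDup@tokens, ts@tokens, tolerance = 1e-12)
  ## masking arithmetic: g = 128, m = 0.6 leaves 51 tokens
  set.seed(3)
  pts <- matrix(rnorm(3 * 200, sd = 5), 200L)
  big <- knnGroup(pts, farthestPointSample(pts, 128L), 8L)
  big <- applyMask(big, 0.6, seed = 1)
  fusedBig <- matrix(rnorm(200 * 16), 200L)
  cfgBig <- ModelConfig(d = 32L, encoderDepth = 1L, encoderHeads = 2L,
                        decoderDepth = 2L, decoderHeads = 2L,
                        g = 128L, kPrime = 8L, m = 0.6)
  tsBig <- tokenize(maeModel(cfgBig, seed = 0), big, fusedBig)
  expect_equal(nrow(tsBig@tokens), 51L)
})

test_that("positional encoding is a per-side deterministic MLP of width d", {
  x <- .mdl()
  ctrs <- rbind(c(0, 0, 0), c(1, 2, 3), c(1, 2, 3))
  pe <- posEncode(x$mod, ctrs, "enc")
  expect_equal(dim(pe), c(3L, x$cfg@d))
  expect_equal(pe[2L, ], pe[3L, ])
  pd <- posEncode(x$mod, ctrs, "dec")
  expect_gt(max(abs(pe - pd)), 1e-3)   # separate weight sets
})

test_that("transformer encoding preserves counts and is permutation-equivariant", {
  x <- .mdl()
  set.seed(4)
  toks <- matrix(rnorm(10 * x$cfg@d), 10L)
  pos <- matrix(rnorm(10 * x$cfg@d), 10L)
  enc <- encodeTokens(x$mod, toks, pos, useCls = FALSE)
  expect_equal(dim(enc$H), c(10L, x$cfg@d))
  encCls <- encodeTokens(x$mod, toks, pos, useCls = TRUE)
  expect_equal(dim(encCls$hCls), c(1L, x$cfg@d))
  perm <- sample(10L)
  enc2 <- encodeTokens(x$mod, toks[perm, ], pos[perm, ], useCls = FALSE)
  expect_equal(enc2$H, enc$H[perm, ], tolerance = 1e-8)
  ## default config instantiates encoderDepth attention blocks
  dflt <- maeModel(ModelConfig(), seed = 0)
  nms <- names(modelParams(dflt))
  expect_true("enc.l12.q.W" %in% nms)
  expect_false("enc.l13.q.W" %in% nms)
  expect_true("dec.l4.q.W" %in% nms)   # four decoder self-attention blocks
  expect_false("dec.l5.q.W" %in% nms)
  expect_error(encodeTokens(x$mod, toks[, 1:10], pos[, 1:10]), "width")
})

test_that("masked decoding returns center-relative patch predictions", {
  x <- .mdl()
  cfg <- x$cfg
  nv <- 13L
  mg <- 19L
  set.seed(5)
  h <- matrix(rnorm(nv * cfg@d), nv)
  visC <- matrix(rnorm(nv * 3), nv)
  mskC <- matrix(rnorm(mg * 3), mg)
  pred <- decodeMasked(x$mod, h, visC, mskC)
  expect_equal(dim(pred), c(mg, cfg@kPrime, 3L))
  ## zeroing the linear head collapses predictions onto the patch centers
  mod0 <- x$mod
  mod0@params$dec.head.W[] <- 0
  mod0@params$dec.head.b[] <- 0
  pred0 <- decodeMasked(mod0, h, visC, mskC)
  expect_true(all(pred0 == 0))
  expect_error(decodeMasked(x$mod, h, visC, mskC[0, , drop = FALSE]),
               "at least one masked patch")
})

test_that("chamfer loss equals the brute-force double loop", {
  ## identity and hand-computed cases
  expect_equal(chamferLoss(diag(3), diag(3)), 0)
  expect_equal(chamferLoss(rbind(c(0, 0, 0)), rbind(c(1, 0, 0))), 2)
  expect_equal(chamferLoss(rbind(c(0, 0, 0), c(2, 0, 0)), rbind(c(1, 0, 0))),
               1 + (1 + 1) / 2)
  ## brute-force oracle over 100 random patch pairs
  brute <- function(P, T) {
    a <- mean(apply(T, 1L, function(x) min(colSums((t(P) - x)^2))))
    b <- mean(apply(P, 1L, function(x) min(colSums((t(T) - x)^2))))
    a + b
  }
  set.seed(6)
  for (rep in 1:100) {
    P <- matrix(rnorm(3 * sample(1:8, 1)), ncol = 3L)
    T <- matrix(rnorm(3 * sample(1:8, 1)), ncol = 3L)
    expect_equal(chamferLoss(P, T), brute(P, T), tolerance = 1e-6)
    ## the two directional terms swap under pred <-> target
    expect_equal(chamferLoss(P, T), chamferLoss(T, P), tolerance = 1e-12)
  }
  ## multi-patch form sums per-patch losses
  Ps <- list(matrix(rnorm(9), 3L), matrix(rnorm(6), 2L))
  Ts <- list(matrix(rnorm(12), 4L), matrix(rnorm(9), 3L))
  expect_equal(chamferLoss(Ps, Ts),
               brute(Ps[[1]], Ts[[1]]) + brute(Ps[[2]], Ts[[2]]),
               tolerance = 1e-6)
  expect_error(chamferLoss(matrix(0, 0, 3), diag(3)), "empty patch")
})

test_that("task heads have the stated shapes and symmetries", {
  x <- .mdl()
  cfg <- x$cfg
  chem <- pointEncoder(x$mod, chemRaw(x$surf))
  fused <- fuseFeatures(chem, surfaceCurvatures(x$surf))
  ts <- tokenize(x$mod, x$ps, fused, visibleOnly = FALSE)
  ctrs <- surfacePoints(x$surf)[patchCenterIdx(x$ps), ]
  enc <- encodeTokens(x$mod, ts@tokens, posEncode(x$mod, ctrs, "enc"),
                      useCls = TRUE)
  ## site head
  logits <- headSite(x$mod, enc$H, x$ps, surfacePoints(x$surf), fused)
  expect_length(logits, nPoints(x$surf))
  W <- surfmae:::.interpWeights(surfacePoints(x$surf), ctrs)
  expect_equal(unname(rowSums(W)), rep(1, nPoints(x$surf)))
  masked <- applyMask(x$ps, 0.5, seed = 1)
  expect_error(headSite(x$mod, enc$H, masked, surfacePoints(x$surf), fused),
               "unmasked")
  ## pocket head
  pk <- headPocket(x$mod, enc$hCls, enc$H)
  expect_length(pk, 7L)
  perm <- sample(nrow(enc$H))
  expect_equal(headPocket(x$mod, enc$hCls, enc$H[perm, ]), pk,
               tolerance = 1e-10)
  expect_error(headPocket(x$mod, NULL, enc$H), "CLS")
  ## descriptor head
  desc <- headDescriptor(x$mod, enc$H, x$ps, surfacePoints(x$surf))
  expect_equal(dim(desc), c(nPoints(x$surf), cfg@descriptorDim))
  expect_true(all(abs(sqrt(rowSums(desc^2)) - 1) < 1e-6))
  expect_identical(desc, headDescriptor(x$mod, enc$H, x$ps,
                                        surfacePoints(x$surf)))
})

test_that("pretraining forwards stay finite over random masks", {
  x <- .mdl()
  pars <- modelParams(x$mod)
  for (s in 1:100) {
    ps <- applyMask(x$ps, x$cfg@m, seed = s)
    loss <- surfmae:::.pretrainForward(pars, x$cfg, x$surf, ps)$loss
    expect_true(is.finite(loss))
  }
})
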