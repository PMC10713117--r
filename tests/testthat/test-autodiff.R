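## Finite-difference checks of the reverse-mode engine: every operation the
## network uses appears in at least one of these graphs.

fdGrad <- function(lossFn, x, h = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (lossFn(xp) - lossFn(xm)) / (2 * h)
  }
  g
}

expectGradMatch <- function(lossFn, x, tol = 1e-5) {
  res <- lossFn(x, wantGrad = TRUE)
  fd <- fdGrad(function(v) lossFn(v), x)
  expect_equal(res$grad, fd, tolerance = tol)
}

test_that("MLP with layer norm, gelu and pools backpropagates exactly", {
  ad <- asNamespace("surfmae")
  set.seed(1)
  W1 <- matrix(rnorm(12 * 6, sd = 0.5), 6L)
  gamma <- matrix(runif(12, 0.5, 1.5), 1L)
  beta <- matrix(rnorm(12, sd = 0.1), 1L)
  X <- matrix(rnorm(8 * 6), 8L)
  lossFn <- function(w, wantGrad = FALSE) {
    tape <- ad$adTape()
    Wn <- ad$adLeaf(tape, w)
    Xn <- ad$adLeaf(tape, X)
    H <- ad$adGelu(tape, ad$adMatmul(tape, Xn, Wn))
    H <- ad$adLayerNorm(tape, H, ad$adLeaf(tape, gamma), ad$adLeaf(tape, beta))
    H <- ad$adRelu(tape, H)
    Hm <- ad$adMaxPoolGroups(tape, H, 4L)      # 2 groups of 4 rows
    Ha <- ad$adMeanPoolGroups(tape, H, 2L)
    out <- ad$adMeanAll(tape, ad$adConcatRows(tape, Hm, Ha))
    if (!wantGrad) return(out$val[1L])
    ad$adBackward(tape, out)
    list(val = out$val[1L], grad = Wn$grad)
  }
  expectGradMatch(lossFn, W1)
})

test_that("attention-style graph backpropagates exactly", {
  ad <- asNamespace("surfmae")
  set.seed(2)
  X <- matrix(rnorm(6 * 8), 6L)
  W <- matrix(rnorm(8 * 8, sd = 0.4), 8L)
  lossFn <- function(w, wantGrad = FALSE) {
    tape <- ad$adTape()
    Wn <- ad$adLeaf(tape, w)
    Xn <- ad$adLeaf(tape, X)
    Q <- ad$adMatmul(tape, Xn, Wn)
    K <- ad$adSliceCols(tape, Q, 1:4)
    V <- ad$adSliceCols(tape, Q, 5:8)
    S <- ad$adScale(tape, ad$adMatmul(tape, ad$adSliceCols(tape, Q, 1:4),
                                      ad$adTranspose(tape, K)), 0.5)
    A <- ad$adSoftmaxRows(tape, S)
    O <- ad$adMatmul(tape, A, V)
    O <- ad$adL2NormalizeRows(tape, O)
    sel <- ad$adRowsSelect(tape, O, c(1L, 1L, 3L, 5L))
    out <- ad$adMeanAll(tape, ad$adMul(tape, sel, sel))
    if (!wantGrad) return(out$val[1L])
    ad$adBackward(tape, out)
    list(val = out$val[1L], grad = Wn$grad)
  }
  expectGradMatch(lossFn, W, tol = 1e-4)
})

test_that("loss heads backpropagate exactly", {
  ad <- asNamespace("surfmae")
  set.seed(3)
  z <- matrix(rnorm(10), 10L, 1L)
  y <- rep(c(0, 1), 5)
  lossBce <- function(v, wantGrad = FALSE) {
    tape <- ad$adTape()
    Z <- ad$adLeaf(tape, v)
    out <- ad$adBCEWithLogits(tape, ad$adSigmoid(tape, Z), y)
    if (!wantGrad) return(out$val[1L])
    ad$adBackward(tape, out)
    list(val = out$val[1L], grad = Z$grad)
  }
  expectGradMatch(lossBce, z)
  L <- matrix(rnorm(5 * 3), 5L)
  lab <- c(1L, 3L, 2L, 1L, 3L)
  lossCe <- function(v, wantGrad = FALSE) {
    tape <- ad$adTape()
    Z <- ad$adLeaf(tape, v)
    out <- ad$adSoftmaxCrossEntropy(tape, Z, lab)
    if (!wantGrad) return(out$val[1L])
    ad$adBackward(tape, out)
    list(val = out$val[1L], grad = Z$grad)
  }
  expectGradMatch(lossCe, L)
})

test_that("whole pretraining loss gradient matches finite differences", {
  cfg <- microModelConfig()
  scfg <- tinySurfaceConfig(64L)
  surf <- buildSurface(synthChain(10, seed = 2), scfg, seed = 2)
  mod <- maeModel(cfg, seed = 3)
  pars <- modelParams(mod)
  ps <- applyMask(patchify(surf, cfg), 0.5, seed = 4)
  ref <- surfmae:::.pretrainForward(pars, cfg, surf, ps)
  set.seed(9)
  for (nm in sample(names(pars), 20L)) {
    i <- sample.int(length(pars[[nm]]), 1L)
    h <- 1e-5
    p2 <- pars
    p2[[nm]][i] <- p2[[nm]][i] + h
    lp <- surfmae:::.pretrainForward(p2, cfg, surf, ps)$loss
    p2[[nm]][i] <- p2[[nm]][i] - 2 * h
    lm <- surfmae:::.pretrainForward(p2, cfg, surf, ps)$loss
    fd <- (lp - lm) / (2 * h)
    an <- ref$grads[[nm]][i]
    expect_lt(abs(fd - an) / max(1e-4, abs(fd), abs(an)), 1e-3)
  }
})
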