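## Parameter initialization and forward builders for the network blocks.
## All forwards operate on autodiff nodes; parameters enter a forward pass
## as leaf nodes created by .paramNodes().

.initLinear <- function(params, name, fanIn, fanOut, sd = NULL) {
  if (is.null(sd)) sd <- 1 / sqrt(fanIn)
  params[[paste0(name, ".W")]] <- matrix(rnorm(fanIn * fanOut, sd = sd),
                                         fanIn, fanOut)
  params[[paste0(name, ".b")]] <- matrix(0, 1L, fanOut)
  params
}

.initLayerNorm <- function(params, name, d) {
  params[[paste0(name, ".g")]] <- matrix(1, 1L, d)
  params[[paste0(name, ".b")]] <- matrix(0, 1L, d)
  params
}

.initBlock <- function(params, prefix, d, mlpRatio) {
  params <- .initLayerNorm(params, paste0(prefix, ".ln1"), d)
  for (nm in c("q", "k", "v", "o"))
    params <- .initLinear(params, paste0(prefix, ".", nm), d, d)
  params <- .initLayerNorm(params, paste0(prefix, ".ln2"), d)
  hidden <- as.integer(round(mlpRatio * d))
  params <- .initLinear(params, paste0(prefix, ".mlp1"), d, hidden)
  params <- .initLinear(params, paste0(prefix, ".mlp2"), hidden, d)
  params
}

## Wrap every parameter array as a leaf node on the tape.
.paramNodes <- function(tape, params) {
  lapply(params, function(v) adLeaf(tape, v))
}

## Collect gradients after backward; absent gradients become zeros.
.collectGrads <- function(P, params) {
  out <- params
  for (nm in names(params)) {
    g <- P[[nm]]$grad
    out[[nm]] <- if (is.null(g)) array(0, dim(params[[nm]])) else g
  }
  out
}

.linearF <- function(tape, P, name, X) {
  adAddBias(tape, adMatmul(tape, X, P[[paste0(name, ".W")]]),
            P[[paste0(name, ".b")]])
}

.mlp2F <- function(tape, P, name1, name2, X, act = adRelu) {
  .linearF(tape, P, name2, act(tape, .linearF(tape, P, name1, X)))
}

.layerNormF <- function(tape, P, name, X) {
  adLayerNorm(tape, X, P[[paste0(name, ".g")]], P[[paste0(name, ".b")]])
}

## One pre-norm transformer block: X + MHSA(LN(X)); X + MLP(LN(X)).
.blockF <- function(tape, P, prefix, X, heads) {
  d <- ncol(X$val)
  dh <- d %/% heads
  Xn <- .layerNormF(tape, P, paste0(prefix, ".ln1"), X)
  Q <- .linearF(tape, P, paste0(prefix, ".q"), Xn)
  K <- .linearF(tape, P, paste0(prefix, ".k"), Xn)
  V <- .linearF(tape, P, paste0(prefix, ".v"), Xn)
  headsOut <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- adSliceCols(tape, Q, cols)
    Kh <- adSliceCols(tape, K, cols)
    Vh <- adSliceCols(tape, V, cols)
    S <- adScale(tape, adMatmul(tape, Qh, adTranspose(tape, Kh)), 1 / sqrt(dh))
    headsOut[[h]] <- adMatmul(tape, adSoftmaxRows(tape, S), Vh)
  }
  O <- headsOut[[1L]]
  if (heads > 1L) for (h in 2:heads) O <- adConcatCols(tape, O, headsOut[[h]])
  X <- adAdd(tape, X, .linearF(tape, P, paste0(prefix, ".o"), O))
  Xn2 <- .layerNormF(tape, P, paste0(prefix, ".ln2"), X)
  M <- .mlp2F(tape, P, paste0(prefix, ".mlp1"), paste0(prefix, ".mlp2"),
              Xn2, act = adGelu)
  adAdd(tape, X, M)
}

## Stack of pre-norm blocks with a final layer norm.
.transformerF <- function(tape, P, prefix, X, depth, heads) {
  for (l in seq_len(depth))
    X <- .blockF(tape, P, sprintf("%s.l%d", prefix, l), X, heads)
  .layerNormF(tape, P, paste0(prefix, ".lnf"), X)
}
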