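## A small reverse-mode automatic differentiation engine over dense
## matrices. Every value is a 2-D double matrix (scalars are 1 x 1). A tape
## records nodes in creation order; adBackward() walks it in reverse,
## accumulating gradients into each node's parents via its `back` closure.
## Only the operations the network needs are implemented, each with an
## explicit adjoint; a finite-difference gradient check covers them in the
## test suite.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  t
}

.adPush <- function(tape, val, back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$back <- back
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

## Leaf node (parameter or constant input).
adLeaf <- function(tape, val) {
  v <- as.matrix(val)
  storage.mode(v) <- "double"
  .adPush(tape, v)
}

.acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

## Backpropagate from a scalar loss node through the whole tape.
adBackward <- function(tape, loss) {
  loss$grad <- matrix(1, nrow(loss$val), ncol(loss$val))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd$grad)
  }
}

## ---- arithmetic --------------------------------------------------------

adMatmul <- function(tape, A, B) {
  .adPush(tape, A$val %*% B$val, function(G) {
    .acc(A, G %*% t(B$val))
    .acc(B, crossprod(A$val, G))
  })
}

adAdd <- function(tape, A, B) {
  .adPush(tape, A$val + B$val, function(G) { .acc(A, G); .acc(B, G) })
}

## A (n x d) plus a bias row b (1 x d), broadcast over rows.
adAddBias <- function(tape, A, b) {
  .adPush(tape, sweep(A$val, 2L, b$val, "+"), function(G) {
    .acc(A, G)
    .acc(b, matrix(colSums(G), 1L))
  })
}

adSub <- function(tape, A, B) {
  .adPush(tape, A$val - B$val, function(G) { .acc(A, G); .acc(B, -G) })
}

adMul <- function(tape, A, B) {
  .adPush(tape, A$val * B$val, function(G) {
    .acc(A, G * B$val)
    .acc(B, G * A$val)
  })
}

adScale <- function(tape, A, s) {
  .adPush(tape, A$val * s, function(G) .acc(A, G * s))
}

## ---- nonlinearities ----------------------------------------------------

adRelu <- function(tape, A) {
  .adPush(tape, pmax(A$val, 0), function(G) .acc(A, G * (A$val > 0)))
}

adGelu <- function(tape, A) {
  x <- A$val
  .adPush(tape, x * stats::pnorm(x), function(G)
    .acc(A, G * (stats::pnorm(x) + x * stats::dnorm(x))))
}

adSigmoid <- function(tape, A) {
  s <- 1 / (1 + exp(-A$val))
  .adPush(tape, s, function(G) .acc(A, G * s * (1 - s)))
}

adSoftmaxRows <- function(tape, A) {
  mx <- apply(A$val, 1L, max)
  e <- exp(A$val - mx)
  S <- e / rowSums(e)
  .adPush(tape, S, function(G)
    .acc(A, S * (G - rowSums(G * S))))
}

## ---- normalization -----------------------------------------------------

adLayerNorm <- function(tape, X, gamma, beta, eps = 1e-5) {
  x <- X$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gamma$val, "*"), 2L, beta$val, "+")
  .adPush(tape, y, function(G) {
    .acc(gamma, matrix(colSums(G * xhat), 1L))
    .acc(beta, matrix(colSums(G), 1L))
    dxhat <- sweep(G, 2L, gamma$val, "*")
    .acc(X, inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)))
  })
}

adL2NormalizeRows <- function(tape, A, eps = 1e-12) {
  x <- A$val
  n <- pmax(sqrt(rowSums(x * x)), eps)
  y <- x / n
  .adPush(tape, y, function(G)
    .acc(A, G / n - y * (rowSums(G * x) / (n * n))))
}

## ---- shape / gather ops ------------------------------------------------

adRowsSelect <- function(tape, A, idx) {
  idx <- as.integer(idx)
  .adPush(tape, A$val[idx, , drop = FALSE], function(G) {
    Z <- matrix(0, nrow(A$val), ncol(A$val))
    rs <- rowsum(G, idx)
    Z[as.integer(rownames(rs)), ] <- rs
    .acc(A, Z)
  })
}

adSliceCols <- function(tape, A, cols) {
  .adPush(tape, A$val[, cols, drop = FALSE], function(G) {
    Z <- matrix(0, nrow(A$val), ncol(A$val))
    Z[, cols] <- G
    .acc(A, Z)
  })
}

adConcatCols <- function(tape, A, B) {
  ca <- ncol(A$val)
  .adPush(tape, cbind(A$val, B$val), function(G) {
    .acc(A, G[, seq_len(ca), drop = FALSE])
    .acc(B, G[, -seq_len(ca), drop = FALSE])
  })
}

adConcatRows <- function(tape, A, B) {
  ra <- nrow(A$val)
  .adPush(tape, rbind(A$val, B$val), function(G) {
    .acc(A, G[seq_len(ra), , drop = FALSE])
    .acc(B, G[-seq_len(ra), , drop = FALSE])
  })
}

adTranspose <- function(tape, A) {
  .adPush(tape, t(A$val), function(G) .acc(A, t(G)))
}

adReshape <- function(tape, A, nr, nc) {
  onr <- nrow(A$val)
  onc <- ncol(A$val)
  .adPush(tape, matrix(A$val, nr, nc), function(G)
    .acc(A, matrix(G, onr, onc)))
}

## Mean over consecutive row groups of size gs: (ng*gs) x d -> ng x d.
adMeanPoolGroups <- function(tape, A, gs) {
  ng <- nrow(A$val) / gs
  stopifnot(ng == as.integer(ng))
  grp <- rep(seq_len(ng), each = gs)
  .adPush(tape, rowsum(A$val, grp) / gs, function(G)
    .acc(A, G[grp, , drop = FALSE] / gs))
}

## Channel-wise max over consecutive row groups of size gs.
adMaxPoolGroups <- function(tape, A, gs) {
  x <- A$val
  ng <- nrow(x) / gs
  stopifnot(ng == as.integer(ng))
  d <- ncol(x)
  val <- matrix(0, ng, d)
  arg <- matrix(0L, ng, d)    # within-group argmax row (ties: first)
  for (j in seq_len(d)) {
    m <- matrix(x[, j], gs, ng)
    w <- max.col(t(m), ties.method = "first")
    arg[, j] <- w
    val[, j] <- m[cbind(w, seq_len(ng))]
  }
  .adPush(tape, val, function(G) {
    Z <- matrix(0, nrow(x), d)
    rows <- (rep(seq_len(ng), d) - 1L) * gs + as.vector(arg)
    Z[cbind(rows, rep(seq_len(d), each = ng))] <- as.vector(G)
    .acc(A, Z)
  })
}

## ---- reductions / losses -----------------------------------------------

adSumAll <- function(tape, A) {
  .adPush(tape, matrix(sum(A$val), 1L, 1L), function(G)
    .acc(A, matrix(G[1L], nrow(A$val), ncol(A$val))))
}

adMeanAll <- function(tape, A) adScale(tape, adSumAll(tape, A), 1 / length(A$val))

## Mean binary cross-entropy with logits; y is a 0/1 vector.
adBCEWithLogits <- function(tape, logits, y) {
  z <- logits$val
  n <- length(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  .adPush(tape, matrix(loss, 1L, 1L), function(G)
    .acc(logits, matrix((1 / (1 + exp(-z)) - y) / n,
                        nrow(z), ncol(z)) * G[1L]))
}

## Mean softmax cross-entropy; labels are 1-based class ids.
adSoftmaxCrossEntropy <- function(tape, logits, labels) {
  z <- logits$val
  B <- nrow(z)
  mx <- apply(z, 1L, max)
  lse <- mx + log(rowSums(exp(z - mx)))
  loss <- mean(lse - z[cbind(seq_len(B), labels)])
  .adPush(tape, matrix(loss, 1L, 1L), function(G) {
    P <- exp(z - lse)
    P[cbind(seq_len(B), labels)] <- P[cbind(seq_len(B), labels)] - 1
    .acc(logits, P / B * G[1L])
  })
}
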