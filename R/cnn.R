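# One-dimensional CNN for per-pixel spectral classification: architecture,
# vectorized forward/backward passes (im2col convolutions) and Adam updates.

#' @include AllClasses.R specs.R
NULL

#' Flattened feature length of the network
#'
#' Shape propagation through the two conv/pool stages: each size-2 pool
#' (stride 2) floors the length, so
#' `flatten = conv2Filters * floor(floor(nBands / pool) / pool)`; 704 for
#' the default 45-band input.
#'
#' @param nBands input spectrum length.
#' @param conv2Filters filters of the second convolution.
#' @param pool pooling size/stride.
#' @return Integer flatten length.
#' @export
flattenLength <- function(nBands, conv2Filters = 64, pool = 2) {
  as.integer(conv2Filters * ((nBands %/% pool) %/% pool))
}

#' Build the 1D-CNN
#'
#' Instantiates the per-pixel spectral classifier:
#' conv(32, k3, s1, pad1) - ReLU - maxpool(2, s2) - dropout(0.25) -
#' conv(64, k3, s1, pad1) - ReLU - maxpool(2, s2) - dropout(0.25) -
#' flatten - dense(128) - ReLU - dense(128) - ReLU - linear(nClasses).
#' Weights are He-initialized from the given seed.
#'
#' @param nBands input spectrum length (>= 4; two pools halve it twice).
#' @param classLabels class names, output-unit order (default: the four
#'   species plus `"grey"` background).
#' @param conv1Filters,conv2Filters convolution filter counts.
#' @param kernel convolution kernel size (stride 1, padding
#'   `(kernel - 1) / 2`).
#' @param pool max-pool size and stride.
#' @param dropout dropout probability after each pool (training only).
#' @param denseUnits width of the two dense layers.
#' @param seed initialization seed.
#' @return An untrained [ConvNet1D-class].
#' @examples
#' m <- buildModel()
#' flattenLength(nBands(m))  # 704
#' @export
buildModel <- function(nBands = 45,
                       classLabels = c("brown_a", "brown_b", "red_a",
                                       "red_b", "grey"),
                       conv1Filters = 32, conv2Filters = 64, kernel = 3,
                       pool = 2, dropout = 0.25, denseUnits = 128,
                       seed = 1L) {
  nBands <- as.integer(nBands)
  if (nBands < 4)
    stop("nBands must be >= 4: two pooling layers would collapse the input")
  nClasses <- length(classLabels)
  flat <- flattenLength(nBands, conv2Filters, pool)
  he <- function(nIn, nOut) matrix(stats::rnorm(nIn * nOut,
                                                sd = sqrt(2 / nIn)),
                                   nIn, nOut)
  params <- .withSeed(seed, list(
    W1 = he(kernel * 1L, conv1Filters), b1 = numeric(conv1Filters),
    W2 = he(kernel * conv1Filters, conv2Filters), b2 = numeric(conv2Filters),
    W3 = he(flat, denseUnits), b3 = numeric(denseUnits),
    W4 = he(denseUnits, denseUnits), b4 = numeric(denseUnits),
    W5 = he(denseUnits, nClasses), b5 = numeric(nClasses)
  ))
  new("ConvNet1D", nBands = nBands, nClasses = as.integer(nClasses),
      classLabels = classLabels,
      hyper = list(conv1Filters = as.integer(conv1Filters),
                   conv2Filters = as.integer(conv2Filters),
                   kernel = as.integer(kernel), pool = as.integer(pool),
                   dropout = dropout, denseUnits = as.integer(denseUnits)),
      params = params, trained = FALSE,
      history = data.frame(epoch = integer(), trainLoss = numeric(),
                           valLoss = numeric()))
}

# im2col for [N, L, C] with kernel 3 and pad 1: (N*L) x (3C) patch matrix.
.im2col <- function(X, N, L, C, kernel) {
  if (C == 1L && kernel == 3L) {
    X <- matrix(X, N, L)
    return(cbind(as.vector(cbind(numeric(N), X[, -L, drop = FALSE])),
                 as.vector(X),
                 as.vector(cbind(X[, -1L, drop = FALSE], numeric(N)))))
  }
  padL <- (kernel - 1L) %/% 2L
  Xp <- array(0, dim = c(N, L + 2L * padL, C))
  Xp[, padL + seq_len(L), ] <- X
  M <- matrix(0, N * L, kernel * C)
  for (k in seq_len(kernel))
    M[, (k - 1L) * C + seq_len(C)] <-
      matrix(Xp[, k:(k + L - 1L), ], N * L, C)
  M
}

# col2im: accumulate patch-matrix gradients back to [N, L, C].
.col2im <- function(dM, N, L, C, kernel) {
  padL <- (kernel - 1L) %/% 2L
  dXp <- array(0, dim = c(N, L + 2L * padL, C))
  for (k in seq_len(kernel))
    dXp[, k:(k + L - 1L), ] <- dXp[, k:(k + L - 1L), ] +
      array(dM[, (k - 1L) * C + seq_len(C)], c(N, L, C))
  dXp[, padL + seq_len(L), , drop = FALSE]
}

# Max pool (size = stride = pool) along L of [N, L, C]; returns pooled
# array and the argmax selector for the backward pass. The pool = 2 case
# (the architecture default) is fully vectorized.
.maxpool <- function(A, pool) {
  d <- dim(A)
  L2 <- d[2] %/% pool
  if (pool == 2L) {
    A1 <- A[, seq(1L, 2L * L2, by = 2L), , drop = FALSE]
    A2 <- A[, seq(2L, 2L * L2, by = 2L), , drop = FALSE]
    first <- A1 >= A2
    P <- A2
    P[first] <- A1[first]
    return(list(P = P, amax = first, Lin = d[2], pool = 2L))
  }
  P <- array(-Inf, dim = c(d[1], L2, d[3]))
  amax <- array(1L, dim = c(d[1], L2, d[3]))
  for (j in seq_len(pool)) {
    Aj <- A[, seq(j, L2 * pool, by = pool), , drop = FALSE]
    better <- Aj > P
    P[better] <- Aj[better]
    amax[better] <- j
  }
  list(P = P, amax = amax, Lin = d[2], pool = pool)
}

.unpool <- function(dP, amax, pool, Lin) {
  d <- dim(dP)
  dA <- array(0, dim = c(d[1], Lin, d[3]))
  if (pool == 2L) {
    Podd <- dP
    Podd[!amax] <- 0
    Pev <- dP
    Pev[amax] <- 0
    dA[, seq(1L, 2L * d[2], by = 2L), ] <- Podd
    dA[, seq(2L, 2L * d[2], by = 2L), ] <- Pev
    return(dA)
  }
  for (j in seq_len(pool)) {
    sel <- amax == j
    slab <- array(0, dim = d)
    slab[sel] <- dP[sel]
    dA[, seq(j, d[2] * pool, by = pool), ] <- slab
  }
  dA
}

# Z + per-column bias without sweep()'s overhead.
.addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward pass. X: N x nBands. training toggles dropout (RNG-consuming).
# Returns logits and, if wantCache, intermediates for the backward pass.
.cnnForward <- function(model, X, training = FALSE, wantCache = training) {
  h <- model@hyper; p <- model@params
  N <- nrow(X); L <- ncol(X)
  kern <- h$kernel
  drop <- function(A) {
    if (!training || h$dropout <= 0) return(list(A = A, mask = NULL))
    mask <- array((stats::runif(length(A)) >= h$dropout) / (1 - h$dropout),
                  dim = dim(A))
    list(A = A * mask, mask = mask)
  }
  M1 <- .im2col(array(X, c(N, L, 1L)), N, L, 1L, kern)
  Z1 <- .addBias(M1 %*% p$W1, p$b1)
  A1 <- array(pmax(Z1, 0), c(N, L, h$conv1Filters))
  pl1 <- .maxpool(A1, h$pool)
  dr1 <- drop(pl1$P)
  L1 <- dim(pl1$P)[2]
  M2 <- .im2col(dr1$A, N, L1, h$conv1Filters, kern)
  Z2 <- .addBias(M2 %*% p$W2, p$b2)
  A2 <- array(pmax(Z2, 0), c(N, L1, h$conv2Filters))
  pl2 <- .maxpool(A2, h$pool)
  dr2 <- drop(pl2$P)
  L2 <- dim(pl2$P)[2]
  Xf <- matrix(dr2$A, N, L2 * h$conv2Filters)
  H1 <- pmax(.addBias(Xf %*% p$W3, p$b3), 0)
  H2 <- pmax(.addBias(H1 %*% p$W4, p$b4), 0)
  logits <- .addBias(H2 %*% p$W5, p$b5)
  if (!wantCache) return(list(logits = logits))
  list(logits = logits, M1 = M1, Z1 = Z1, pl1 = pl1, dr1 = dr1, M2 = M2,
       Z2 = Z2, pl2 = pl2, dr2 = dr2, Xf = Xf, H1 = H1, H2 = H2, N = N,
       L = L, L1 = L1, L2 = L2)
}

.softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# Cross-entropy loss and parameter gradients for a batch.
.cnnBackward <- function(model, cache, yIdx) {
  h <- model@hyper; p <- model@params
  N <- cache$N
  P <- .softmax(cache$logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(N), yIdx)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(N), yIdx)] <- dZ[cbind(seq_len(N), yIdx)] - 1
  dZ <- dZ / N
  g <- list()
  g$W5 <- crossprod(cache$H2, dZ); g$b5 <- colSums(dZ)
  dH2 <- dZ %*% t(p$W5) * (cache$H2 > 0)
  g$W4 <- crossprod(cache$H1, dH2); g$b4 <- colSums(dH2)
  dH1 <- dH2 %*% t(p$W4) * (cache$H1 > 0)
  g$W3 <- crossprod(cache$Xf, dH1); g$b3 <- colSums(dH1)
  dXf <- dH1 %*% t(p$W3)
  dP2 <- array(dXf, c(N, cache$L2, h$conv2Filters))
  if (!is.null(cache$dr2$mask)) dP2 <- dP2 * cache$dr2$mask
  dA2 <- .unpool(dP2, cache$pl2$amax, h$pool, cache$pl2$Lin)
  dZ2 <- matrix(dA2, N * cache$L1, h$conv2Filters) * (cache$Z2 > 0)
  g$W2 <- crossprod(cache$M2, dZ2); g$b2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(p$W2)
  dP1 <- .col2im(dM2, N, cache$L1, h$conv1Filters, h$kernel)
  if (!is.null(cache$dr1$mask)) dP1 <- dP1 * cache$dr1$mask
  dA1 <- .unpool(dP1, cache$pl1$amax, h$pool, cache$pl1$Lin)
  dZ1 <- matrix(dA1, N * cache$L, h$conv1Filters) * (cache$Z1 > 0)
  g$W1 <- crossprod(cache$M1, dZ1); g$b1 <- colSums(dZ1)
  list(loss = loss, grads = g)
}

# One Adam step; state holds first/second moments and the step counter.
.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    gv <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gv
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gv^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
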