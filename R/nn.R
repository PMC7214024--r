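## Dense-matrix implementation of the sequence classifier:
##   token indices -> embedding -> 1-D convolution (valid padding, ReLU)
##   -> temporal max-pooling -> bidirectional LSTM -> temporal max over the
##   LSTM outputs -> dropout -> dense sigmoid.
## Forward, full backpropagation (including BPTT through both LSTM
## directions) and Adam are written against base matrix algebra so training
## runs on any BLAS. Shapes use B = batch, L = maxLen, De = embedding dim,
## F = filters, k = kernel, T1 = L - k + 1, T2 = floor(T1 / pool),
## H = LSTM units per direction.

.sigmoid <- function(x) 1 / (1 + exp(-x))

## evaluate expr with a temporary RNG state so callers' streams are untouched
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.glorot <- function(nIn, nOut, n = nIn * nOut) {
  lim <- sqrt(6 / (nIn + nOut))
  matrix(stats::runif(nIn * nOut, -lim, lim), nIn, nOut)
}

.nnInitWeights <- function(cfg, enc, seed = cfg$seed) {
  A <- length(enc$alphabet)
  De <- cfg$embeddingDim; k <- cfg$convKernel; Fc <- cfg$convFilters
  H <- cfg$lstmUnits
  .withSeed(seed, {
    w <- list(
      Emb = matrix(stats::runif((A + 1) * De, -0.05, 0.05), A + 1, De),
      Wc = .glorot(k * De, Fc),
      bc = numeric(Fc),
      WxF = .glorot(Fc, 4 * H), WhF = .glorot(H, 4 * H), bF = numeric(4 * H),
      WxB = .glorot(Fc, 4 * H), WhB = .glorot(H, 4 * H), bB = numeric(4 * H),
      Wd = .glorot(2 * H, 1), bd = numeric(1)
    )
    # forget-gate bias 1 stabilizes early training
    w$bF[(H + 1):(2 * H)] <- 1
    w$bB[(H + 1):(2 * H)] <- 1
    w
  })
}

## LSTM forward over an input array X (B, T, D); returns outputs (B, T, H)
## plus per-step activations for BPTT
.lstmForward <- function(X, Wx, Wh, b) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- nrow(Wh)
  H4 <- 4 * H
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hout <- array(0, c(B, Tn, H))
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- X[, t, , drop = TRUE]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, nrow = B)
    Z <- Xt %*% Wx + h %*% Wh
    Z <- sweep(Z, 2, b, "+")
    i <- .sigmoid(Z[, 1:H, drop = FALSE])
    f <- .sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(Z[, (3 * H + 1):H4, drop = FALSE])
    cPrev <- cc
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    hPrev <- h
    h <- o * tc
    Hout[, t, ] <- h
    steps[[t]] <- list(i = i, f = f, g = g, o = o, cPrev = cPrev,
                       hPrev = hPrev, tc = tc)
  }
  list(Hout = Hout, steps = steps)
}

## BPTT matching .lstmForward; dHout (B, T, H) are upstream gradients on the
## per-step outputs. Returns parameter gradients and input gradients.
.lstmBackward <- function(X, Wx, Wh, fwd, dHout) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * H)
  dX <- array(0, dim(X))
  dhNext <- matrix(0, B, H)
  dcNext <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    st <- fwd$steps[[t]]
    dh <- dHout[, t, , drop = TRUE] + dhNext
    if (is.null(dim(dh))) dh <- matrix(dh, nrow = B)
    do <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dcNext
    di <- dc * st$g
    df <- dc * st$cPrev
    dg <- dc * st$i
    dcNext <- dc * st$f
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    Xt <- X[, t, , drop = TRUE]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, nrow = B)
    dWx <- dWx + crossprod(Xt, dZ)
    dWh <- dWh + crossprod(st$hPrev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(Wx)
    dhNext <- dZ %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

## full forward pass; X is an integer matrix (B, L) of token indices (0 pad)
.nnForward <- function(w, cfg, X, training = FALSE) {
  B <- nrow(X); L <- ncol(X)
  De <- cfg$embeddingDim; k <- cfg$convKernel; Fc <- cfg$convFilters
  P <- cfg$poolSize; H <- cfg$lstmUnits
  T1 <- L - k + 1L
  T2 <- T1 %/% P
  if (T2 < 1) stop("maxLen too short for convKernel and poolSize")

  idx <- as.vector(X) + 1L                 # column-major: row r = b + (l-1)*B
  Xe <- w$Emb[idx, , drop = FALSE]         # (B*L) x De

  Xu <- matrix(0, B * T1, k * De)
  for (j in seq_len(k)) {
    rows <- rep(seq_len(B), T1) + (rep(seq_len(T1), each = B) + j - 2L) * B
    Xu[, ((j - 1L) * De + 1L):(j * De)] <- Xe[rows, , drop = FALSE]
  }
  Z1 <- sweep(Xu %*% w$Wc, 2, w$bc, "+")   # (B*T1) x F, row r = b + (t-1)*B
  A1 <- pmax(Z1, 0)
  A1a <- A1
  dim(A1a) <- c(B, T1, Fc)

  Pool <- array(-Inf, c(B, T2, Fc))
  Arg <- array(1L, c(B, T2, Fc))
  tBase <- seq.int(0L, by = P, length.out = T2)
  for (j in seq_len(P)) {
    slice <- A1a[, tBase + j, , drop = FALSE]
    upd <- slice > Pool
    Arg[upd] <- j
    Pool[upd] <- slice[upd]
  }

  fwdF <- .lstmForward(Pool, w$WxF, w$WhF, w$bF)
  PoolRev <- Pool[, rev(seq_len(T2)), , drop = FALSE]
  fwdB <- .lstmForward(PoolRev, w$WxB, w$WhB, w$bB)
  Ob <- fwdB$Hout[, rev(seq_len(T2)), , drop = FALSE]
  Of <- fwdF$Hout

  M <- matrix(-Inf, B, 2 * H)
  ArgT <- matrix(1L, B, 2 * H)
  for (t in seq_len(T2)) {
    Ot <- cbind(matrix(Of[, t, ], nrow = B), matrix(Ob[, t, ], nrow = B))
    upd <- Ot > M
    ArgT[upd] <- t
    M[upd] <- Ot[upd]
  }

  dropMask <- NULL
  Md <- M
  if (training && cfg$dropout > 0) {
    dropMask <- matrix(
      (stats::runif(B * 2 * H) >= cfg$dropout) / (1 - cfg$dropout), B, 2 * H)
    Md <- M * dropMask
  }
  pre <- as.vector(Md %*% w$Wd) + w$bd
  p <- .sigmoid(pre)

  list(p = p, cache = list(
    B = B, L = L, T1 = T1, T2 = T2, idx = idx, Xu = Xu, Z1 = Z1,
    Arg = Arg, Pool = Pool, fwdF = fwdF, fwdB = fwdB, PoolRev = PoolRev,
    ArgT = ArgT, Md = Md, dropMask = dropMask))
}

## backward pass; dpre = dLoss/d(pre-activation of the sigmoid head), length B
.nnBackward <- function(w, cfg, cache, dpre) {
  B <- cache$B; L <- cache$L; T1 <- cache$T1; T2 <- cache$T2
  De <- cfg$embeddingDim; k <- cfg$convKernel; Fc <- cfg$convFilters
  P <- cfg$poolSize; H <- cfg$lstmUnits

  dpre <- matrix(dpre, ncol = 1)
  g <- list()
  g$Wd <- crossprod(cache$Md, dpre)
  g$bd <- sum(dpre)
  dMd <- dpre %*% t(w$Wd)
  dM <- if (is.null(cache$dropMask)) dMd else dMd * cache$dropMask

  dOf <- array(0, c(B, T2, H))
  dOb <- array(0, c(B, T2, H))
  for (t in seq_len(T2)) {
    sel <- cache$ArgT == t
    if (!any(sel)) next
    dOt <- matrix(0, B, 2 * H)
    dOt[sel] <- dM[sel]
    dOf[, t, ] <- dOf[, t, ] + dOt[, 1:H, drop = FALSE]
    dOb[, t, ] <- dOb[, t, ] + dOt[, (H + 1):(2 * H), drop = FALSE]
  }

  bF <- .lstmBackward(cache$Pool, w$WxF, w$WhF, cache$fwdF, dOf)
  dObRev <- dOb[, rev(seq_len(T2)), , drop = FALSE]
  bB <- .lstmBackward(cache$PoolRev, w$WxB, w$WhB, cache$fwdB, dObRev)
  g$WxF <- bF$dWx; g$WhF <- bF$dWh; g$bF <- bF$db
  g$WxB <- bB$dWx; g$WhB <- bB$dWh; g$bB <- bB$db
  dPool <- bF$dX + bB$dX[, rev(seq_len(T2)), , drop = FALSE]

  dA1a <- array(0, c(B, T1, Fc))
  tBase <- seq.int(0L, by = P, length.out = T2)
  for (j in seq_len(P)) {
    sel <- cache$Arg == j
    if (!any(sel)) next
    tmp <- array(0, c(B, T2, Fc))
    tmp[sel] <- dPool[sel]
    dA1a[, tBase + j, ] <- dA1a[, tBase + j, ] + tmp
  }
  dA1 <- dA1a
  dim(dA1) <- c(B * T1, Fc)
  dZ1 <- dA1 * (cache$Z1 > 0)

  g$Wc <- crossprod(cache$Xu, dZ1)
  g$bc <- colSums(dZ1)
  dXu <- dZ1 %*% t(w$Wc)

  dXe <- matrix(0, B * L, De)
  for (j in seq_len(k)) {
    rows <- rep(seq_len(B), T1) + (rep(seq_len(T1), each = B) + j - 2L) * B
    dXe[rows, ] <- dXe[rows, ] + dXu[, ((j - 1L) * De + 1L):(j * De), drop = FALSE]
  }
  rs <- rowsum(dXe, group = cache$idx)
  dEmb <- matrix(0, nrow(w$Emb), De)
  dEmb[as.integer(rownames(rs)), ] <- rs
  g$Emb <- dEmb

  g[names(w)]
}

.adamInit <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

.adamStep <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clipNorm = NULL) {
  if (!is.null(clipNorm)) {
    gn <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
    if (is.finite(gn) && gn > clipNorm)
      g <- lapply(g, function(x) x * (clipNorm / gn))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

.bceLoss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
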