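# Differentiable layer primitives with explicit backward passes. Token
# matrices are (N*T) x C with rows ordered sample-fastest, then token;
# token t of a (H, W) grid is t = h + (w - 1) * H (column-major). Every
# forward returns a cache consumed by the matching backward; gradients are
# exact analytic derivatives (validated against finite differences in the
# test suite).

.layoutCache <- new.env(parent = emptyenv())

initLinear <- function(inD, outD, bias = TRUE) {
  l <- list(W = matrix(rnorm(inD * outD) * 0.02, inD, outD))
  if (bias) l$b <- numeric(outD)
  l
}

linForward <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(X))
  Y
}

linBackward <- function(dY, X, W, bias = TRUE) {
  out <- list(dX = tcrossprod(dY, W), dW = crossprod(X, dY))
  if (bias) out$db <- .colSums(dY, nrow(dY), ncol(dY))
  out
}

lnForward <- function(X, g, b, eps = 1e-5) {
  R <- nrow(X); C <- ncol(X)
  mu <- .rowMeans(X, R, C)
  xc <- X - mu
  v <- .rowMeans(xc * xc, R, C)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * rep(g, each = R) + rep(b, each = R)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

lnBackward <- function(dy, cache) {
  R <- nrow(dy); C <- ncol(dy)
  xhat <- cache$xhat
  dxhat <- dy * rep(cache$g, each = R)
  m1 <- .rowMeans(dxhat, R, C)
  m2 <- .rowMeans(dxhat * xhat, R, C)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = .colSums(dy * xhat, R, C), db = .colSums(dy, R, C))
}

# ---- window partition machinery --------------------------------------------

# Index bundle for shifted-window partitioning of an H x W token grid,
# padded up to multiples of ws. perm maps window-order positions to token
# ids (0 = padding); rowperm maps to rows of the (N*T) token matrix;
# mask is (wsz2, wsz2, nw) additive attention mask (or NULL); biasIdx
# indexes a (2*wsTab-1)^2 relative-position bias table.
windowIndex <- function(H, W, ws, shift, N, wsTab = ws) {
  key <- paste(H, W, ws, shift, N, wsTab, sep = "|")
  if (!is.null(.layoutCache[[key]])) return(.layoutCache[[key]])
  Hp <- ceiling(H / ws) * ws
  Wp <- ceiling(W / ws) * ws
  nwh <- Hp %/% ws; nww <- Wp %/% ws
  nw <- nwh * nww
  wsz2 <- ws * ws
  band <- function(o, Lp) {
    if (shift == 0L) return(rep(1L, length(o)))
    ifelse(o <= Lp - ws, 1L, ifelse(o <= Lp - shift, 2L, 3L))
  }
  # rolled coordinates: position (h', w') holds original (oh, ow)
  hp <- seq_len(Hp); wp <- seq_len(Wp)
  oh <- ((hp - 1L + shift) %% Hp) + 1L
  ow <- ((wp - 1L + shift) %% Wp) + 1L
  tokGrid <- outer(oh, ow, function(a, b)
    ifelse(a <= H & b <= W, a + (b - 1L) * H, 0L))
  regGrid <- outer(band(oh, Hp), band(ow, Wp), function(a, b) a * 4L + b)
  # padding positions get unique region ids so they only attend themselves
  padIds <- which(tokGrid == 0L)
  regGrid[padIds] <- -seq_along(padIds)
  perm <- integer(wsz2 * nw)
  regs <- integer(wsz2 * nw)
  k <- 0L
  for (wj in seq_len(nww)) for (wi in seq_len(nwh)) {
    rows <- ((wi - 1L) * ws + 1L):(wi * ws)
    cols <- ((wj - 1L) * ws + 1L):(wj * ws)
    perm[k + seq_len(wsz2)] <- as.vector(tokGrid[rows, cols])
    regs[k + seq_len(wsz2)] <- as.vector(regGrid[rows, cols])
    k <- k + wsz2
  }
  needMask <- shift > 0L || any(perm == 0L)
  mask <- NULL
  if (needMask) {
    mask <- array(0, c(wsz2, wsz2, nw))
    for (w in seq_len(nw)) {
      r <- regs[((w - 1L) * wsz2 + 1L):(w * wsz2)]
      mask[, , w] <- ifelse(outer(r, r, "!="), -1e9, 0)
    }
  }
  # rows of the token matrix, ordered (position, sample, window)
  base <- matrix(perm, wsz2, nw)
  b3 <- aperm(array(rep(as.vector(base), times = N), c(wsz2, nw, N)),
              c(1L, 3L, 2L))
  n3 <- array(rep(rep(seq_len(N), each = wsz2), times = nw),
              c(wsz2, N, nw))
  rowperm <- as.integer(ifelse(b3 > 0L, (b3 - 1L) * N + n3, 0L))
  # relative position bias index into a (2*wsTab-1)^2 table
  lh <- rep(seq_len(ws), times = ws)   # local coords, column-major
  lw <- rep(seq_len(ws), each = ws)
  dh <- outer(lh, lh, "-"); dw <- outer(lw, lw, "-")
  biasIdx <- (dh + wsTab - 1L) * (2L * wsTab - 1L) + (dw + wsTab) # 1-based
  out <- list(ws = ws, wsz2 = wsz2, nw = nw, perm = perm,
              rowperm = rowperm, mask = mask, biasIdx = biasIdx)
  .layoutCache[[key]] <- out
  out
}

gatherRows <- function(X, rowperm) {
  if (!anyNA(rowperm) && rowperm[1L] > 0L && all(rowperm > 0L))
    return(X[rowperm, , drop = FALSE])
  Xw <- X[pmax(rowperm, 1L), , drop = FALSE]
  Xw[rowperm == 0L, ] <- 0
  Xw
}


scatterRows <- function(Xw, rowperm, nOut) {
  out <- matrix(0, nOut, ncol(Xw))
  valid <- rowperm > 0L
  out[rowperm[valid], ] <- Xw[valid, , drop = FALSE]
  out
}

# ---- windowed multi-head self-attention block ------------------------------

# Each residual branch carries a learnable per-channel scale (LayerScale,
# init 0.1): the block starts close to the identity, which keeps early
# gradients flowing to the patch embedding and stabilises from-scratch
# training at small data scale.
initBlock <- function(C, nHeads, mlpRatio, wsTab) {
  hidden <- as.integer(round(C * mlpRatio))
  list(
    ln1_g = rep(1, C), ln1_b = numeric(C),
    qkv = initLinear(C, 3L * C),
    relBias = matrix(0, (2L * wsTab - 1L)^2, nHeads),
    proj = initLinear(C, C),
    ls1 = rep(0.1, C),
    ln2_g = rep(1, C), ln2_b = numeric(C),
    mlp1 = initLinear(C, hidden),
    mlp2 = initLinear(hidden, C),
    ls2 = rep(0.1, C),
    nHeads = nHeads
  )
}

attnForward <- function(X, H, W, N, p, ws, shift, wsTab) {
  C <- ncol(X)
  nh <- p$nHeads
  hd <- C %/% nh
  scale <- 1 / sqrt(hd)
  ln1 <- lnForward(X, p$ln1_g, p$ln1_b)
  qkv <- linForward(ln1$y, p$qkv$W, p$qkv$b)
  wi <- windowIndex(H, W, ws, shift, N, wsTab)
  qkvW <- gatherRows(qkv, wi$rowperm)
  wsz2 <- wi$wsz2
  bias <- array(0, c(wsz2, wsz2, nh))
  for (h in seq_len(nh))
    bias[, , h] <- matrix(p$relBias[wi$biasIdx, h], wsz2, wsz2)
  mask <- if (is.null(wi$mask)) array(0, c(0L, 0L, 0L)) else wi$mask
  core <- .attnCoreForward(qkvW, bias, mask, wsz2, nh, hd, N, scale)
  A <- core$A
  attnOut <- scatterRows(core$O, wi$rowperm, nrow(X))
  Y <- linForward(attnOut, p$proj$W, p$proj$b)
  out <- X + Y * rep(p$ls1, each = nrow(Y))
  mlpLn <- lnForward(out, p$ln2_g, p$ln2_b)
  h1 <- linForward(mlpLn$y, p$mlp1$W, p$mlp1$b)
  ph <- pnorm(h1)
  a1 <- h1 * ph
  h2 <- linForward(a1, p$mlp2$W, p$mlp2$b)
  final <- out + h2 * rep(p$ls2, each = nrow(h2))
  list(out = final,
       cache = list(ln1 = ln1, qkvW = qkvW, A = A, attnOut = attnOut,
                    wi = wi, scale = scale, hd = hd, nh = nh, C = C,
                    mid = out, mlpLn = mlpLn, h1 = h1, ph = ph, a1 = a1,
                    Y = Y, h2 = h2, X = X, N = N))
}

attnBackward <- function(dfinal, p, cache) {
  C <- cache$C; nh <- cache$nh; hd <- cache$hd
  wi <- cache$wi; wsz2 <- wi$wsz2
  g <- list()
  R <- nrow(dfinal)
  # MLP branch (through its residual scale)
  g$ls2 <- colSums(dfinal * cache$h2)
  dh2 <- dfinal * rep(p$ls2, each = R)
  l2 <- linBackward(dh2, cache$a1, p$mlp2$W)
  g$mlp2 <- list(W = l2$dW, b = l2$db)
  dh1 <- l2$dX * (cache$ph + cache$h1 * dnorm(cache$h1))
  l1 <- linBackward(dh1, cache$mlpLn$y, p$mlp1$W)
  g$mlp1 <- list(W = l1$dW, b = l1$db)
  lb2 <- lnBackward(l1$dX, cache$mlpLn$cache)
  g$ln2_g <- lb2$dg; g$ln2_b <- lb2$db
  dmid <- dfinal + lb2$dx
  # attention projection (through its residual scale)
  g$ls1 <- colSums(dmid * cache$Y)
  dY <- dmid * rep(p$ls1, each = R)
  lp <- linBackward(dY, cache$attnOut, p$proj$W)
  g$proj <- list(W = lp$dW, b = lp$db)
  dO <- gatherRows(lp$dX, wi$rowperm)
  core <- .attnCoreBackward(dO, cache$qkvW, cache$A, wsz2, nh, hd,
                            cache$N, cache$scale)
  dqkvW <- core$dqkvW
  dBias <- core$dBias
  # scatter relative-position bias gradient into the table
  dRel <- matrix(0, nrow(p$relBias), nh)
  idxVec <- as.vector(wi$biasIdx)
  for (h in seq_len(nh)) {
    acc <- rowsum(as.vector(dBias[, , h]), idxVec)
    dRel[as.integer(rownames(acc)), h] <- acc
  }
  g$relBias <- dRel
  dqkv <- scatterRows(dqkvW, wi$rowperm, nrow(cache$X))
  lq <- linBackward(dqkv, cache$ln1$y, p$qkv$W)
  g$qkv <- list(W = lq$dW, b = lq$db)
  lb1 <- lnBackward(lq$dX, cache$ln1$cache)
  g$ln1_g <- lb1$dg; g$ln1_b <- lb1$db
  dX <- dmid + lb1$dx
  list(dx = dX, grads = g)
}

# ---- patch embedding -------------------------------------------------------

patchIndex <- function(H, W, P) {
  key <- paste("pe", H, W, P, sep = "|")
  if (!is.null(.layoutCache[[key]])) return(.layoutCache[[key]])
  Hg <- H %/% P; Wg <- W %/% P
  Tn <- Hg * Wg
  ppc <- P * P * 3L
  colidx <- matrix(0L, ppc, Tn)
  t <- 0L
  for (wg in seq_len(Wg)) for (hg in seq_len(Hg)) {
    t <- t + 1L
    hs <- (hg - 1L) * P + seq_len(P)
    ws_ <- (wg - 1L) * P + seq_len(P)
    j <- 0L
    for (cc in 1:3) for (w in ws_) for (h in hs) {
      j <- j + 1L
      colidx[j, t] <- h + (w - 1L) * H + (cc - 1L) * H * W
    }
  }
  out <- list(colidx = colidx, Hg = Hg, Wg = Wg, ppc = ppc)
  .layoutCache[[key]] <- out
  out
}

patchEmbedForward <- function(images, p, P) {
  d <- dim(images)
  N <- d[1L]; H <- d[2L]; W <- d[3L]
  if (H %% P != 0L || W %% P != 0L)
    stop("image size must be divisible by the patch size")
  pi_ <- patchIndex(H, W, P)
  # standardize pixel intensities ([0,1] -> roughly zero-mean unit-variance)
  Im <- (images - 0.5) / 0.25
  dim(Im) <- c(N, H * W * 3L)
  M <- Im[, as.vector(pi_$colidx), drop = FALSE]
  dim(M) <- c(N, pi_$ppc, pi_$Hg * pi_$Wg)
  M <- aperm(M, c(1L, 3L, 2L))
  dim(M) <- c(N * pi_$Hg * pi_$Wg, pi_$ppc)
  X0 <- linForward(M, p$proj$W, p$proj$b)
  ln <- lnForward(X0, p$ln_g, p$ln_b)
  list(out = ln$y, H = pi_$Hg, W = pi_$Wg,
       cache = list(M = M, ln = ln))
}

patchEmbedBackward <- function(dy, p, cache) {
  lb <- lnBackward(dy, cache$ln$cache)
  ll <- linBackward(lb$dx, cache$M, p$proj$W)
  list(grads = list(proj = list(W = ll$dW, b = ll$db),
                    ln_g = lb$dg, ln_b = lb$db))
}

# ---- patch merging (2x downsample, C -> 2C) --------------------------------

mergeIndex <- function(H, W, N) {
  key <- paste("pm", H, W, N, sep = "|")
  if (!is.null(.layoutCache[[key]])) return(.layoutCache[[key]])
  Hn <- H %/% 2L; Wn <- W %/% 2L
  Tn <- Hn * Wn
  hg <- rep(seq_len(Hn), times = Wn)
  wg <- rep(seq_len(Wn), each = Hn)
  toks <- list(
    (2L * hg - 1L) + (2L * wg - 2L) * H,
    (2L * hg)      + (2L * wg - 2L) * H,
    (2L * hg - 1L) + (2L * wg - 1L) * H,
    (2L * hg)      + (2L * wg - 1L) * H
  )
  rows <- lapply(toks, function(tk) {
    as.integer(rep((tk - 1L) * N, each = N) + rep(seq_len(N), times = Tn))
  })
  out <- list(rows = rows, Hn = Hn, Wn = Wn)
  .layoutCache[[key]] <- out
  out
}

mergeForward <- function(X, H, W, N, p) {
  mi <- mergeIndex(H, W, N)
  Xm <- cbind(X[mi$rows[[1L]], , drop = FALSE],
              X[mi$rows[[2L]], , drop = FALSE],
              X[mi$rows[[3L]], , drop = FALSE],
              X[mi$rows[[4L]], , drop = FALSE])
  ln <- lnForward(Xm, p$ln_g, p$ln_b)
  Y <- ln$y %*% p$red$W
  list(out = Y, H = mi$Hn, W = mi$Wn,
       cache = list(Xm = Xm, ln = ln, mi = mi, nIn = nrow(X)))
}

mergeBackward <- function(dy, p, cache) {
  dln <- dy %*% t(p$red$W)
  dW <- crossprod(cache$ln$y, dy)
  lb <- lnBackward(dln, cache$ln$cache)
  C <- ncol(cache$Xm) %/% 4L
  dX <- matrix(0, cache$nIn, C)
  for (k in 1:4) {
    ch <- ((k - 1L) * C + 1L):(k * C)
    dX[cache$mi$rows[[k]], ] <- lb$dx[, ch, drop = FALSE]
  }
  list(dx = dX, grads = list(red = list(W = dW),
                             ln_g = lb$dg, ln_b = lb$db))
}
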