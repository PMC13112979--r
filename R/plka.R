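# Progressive multi-kernel lesion attention: three parallel depthwise
# convolution branches (kernel sizes 3/5/7, or a dilated variant), sum
# fusion, squeeze-style per-channel branch attention, and dynamically
# weighted recombination.

ensureBatch <- function(x) {
  if (length(dim(x)) == 3L) {
    dim(x) <- c(1L, dim(x))
    attr(x, "hadBatch") <- FALSE
  }
  x
}

# Depthwise k x k convolution with bias and dilation, zero padding, shape
# preserving. x: (N, H, W, C); kernel: (k, k, C).
depthwiseConv <- function(x, kernel, bias, dilation = 1L) {
  d <- dim(x)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  k <- dim(kernel)[1L]
  ctr <- (k + 1L) %/% 2L
  out <- array(rep(bias, each = N * H * W), d)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    kv <- kernel[i, j, ]
    if (all(kv == 0)) next
    oy <- (i - ctr) * dilation
    ox <- (j - ctr) * dilation
    hr <- max(1L, 1L - oy):min(H, H - oy)
    wr <- max(1L, 1L - ox):min(W, W - ox)
    if (hr[1L] > hr[length(hr)] || wr[1L] > wr[length(wr)]) next
    sl <- x[, hr + oy, wr + ox, , drop = FALSE]
    out[, hr, wr, ] <- out[, hr, wr, , drop = FALSE] +
      sl * rep(kv, each = N * length(hr) * length(wr))
  }
  out
}

# Gradients of depthwiseConv w.r.t. input, kernel and bias.
depthwiseConvBackward <- function(dout, x, kernel, dilation = 1L) {
  d <- dim(x)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  k <- dim(kernel)[1L]
  ctr <- (k + 1L) %/% 2L
  dx <- array(0, d)
  dk <- array(0, dim(kernel))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    oy <- (i - ctr) * dilation
    ox <- (j - ctr) * dilation
    hr <- max(1L, 1L - oy):min(H, H - oy)
    wr <- max(1L, 1L - ox):min(W, W - ox)
    if (hr[1L] > hr[length(hr)] || wr[1L] > wr[length(wr)]) next
    dsl <- dout[, hr, wr, , drop = FALSE]
    xsl <- x[, hr + oy, wr + ox, , drop = FALSE]
    m <- N * length(hr) * length(wr)
    dk[i, j, ] <- colSums(matrix(dsl * xsl, m, C))
    kv <- kernel[i, j, ]
    dx[, hr + oy, wr + ox, ] <- dx[, hr + oy, wr + ox, , drop = FALSE] +
      dsl * rep(kv, each = m)
  }
  db <- colSums(matrix(dout, N * H * W, C))
  list(dx = dx, dk = dk, db = db)
}

#' Initialise multi-kernel lesion attention parameters
#'
#' Three depthwise convolution branches plus a two-layer bottleneck that
#' produces per-channel softmax weights over the branches
#' (squeeze-and-excite style, reduction ratio `reduction`). With
#' `dilated = TRUE` the branches use 3x3 kernels at dilation rates 1/2/3
#' instead of kernel sizes 3/5/7 (same receptive fields).
#'
#' @param C channel count of the feature map.
#' @param kernels integer kernel sizes for the three branches.
#' @param dilated logical; use the dilated variant.
#' @param reduction bottleneck ratio r (default 4).
#' @param seed integer seed for the random initialisation.
#' @return parameter list consumed by [plkaForward()] and friends.
#' @export
plkaInit <- function(C, kernels = c(3L, 5L, 7L), dilated = FALSE,
                     reduction = 4L, seed = 1L) {
  if (length(kernels) != 3L || any(kernels %% 2L == 0L))
    stop("kernels must be three odd sizes")
  C <- as.integer(C)
  kernels <- as.integer(kernels)
  reduction <- as.integer(reduction)
  Cr <- max(1L, C %/% reduction)
  withSeed(seed, {
    conv <- lapply(if (dilated) c(3L, 3L, 3L) else kernels, function(k)
      list(k = array(rnorm(k * k * C) * 0.1, c(k, k, C)), b = numeric(C)))
    list(C = C, kernels = kernels, dilated = dilated,
         dilations = if (dilated) c(1L, 2L, 3L) else c(1L, 1L, 1L),
         conv = conv,
         fc1 = initLinear(C, Cr),
         fc2 = initLinear(Cr, 3L * C))
  })
}

#' Identity-configured lesion attention parameters
#'
#' First branch is a depthwise identity kernel (centre tap 1), the other
#' branches are zero, and the branch-attention expand layer is biased so the
#' softmax saturates on the first branch; `plkaForward` is then the identity
#' map (up to a relative error below 1e-9).
#'
#' @inheritParams plkaInit
#' @return parameter list.
#' @export
plkaIdentityParams <- function(C, kernels = c(3L, 5L, 7L)) {
  p <- plkaInit(C, kernels, seed = 0L)
  for (i in 1:3) {
    p$conv[[i]]$k[] <- 0
    p$conv[[i]]$b[] <- 0
  }
  k1 <- kernels[1L]
  ctr <- (k1 + 1L) %/% 2L
  p$conv[[1L]]$k[ctr, ctr, ] <- 1
  p$fc1$W[] <- 0; p$fc1$b[] <- 0
  p$fc2$W[] <- 0; p$fc2$b[] <- 0
  p$fc2$b[seq_len(C)] <- 20
  p
}

#' Parallel multi-kernel convolution branches
#'
#' Applies the three depthwise branches to a feature map and returns the
#' branch outputs together with their elementwise sum.
#'
#' @param x feature map, `(H, W, C)` or `(N, H, W, C)`.
#' @param params from [plkaInit()].
#' @return list with `u3`, `u5`, `u7` (same shape as `x`) and `uSum`.
#' @export
multiBranchConv <- function(x, params) {
  x <- ensureBatch(x)
  if (dim(x)[2L] < 1L || dim(x)[3L] < 1L) stop("empty spatial dimensions")
  u <- lapply(1:3, function(i)
    depthwiseConv(x, params$conv[[i]]$k, params$conv[[i]]$b,
                  params$dilations[i]))
  list(u3 = u[[1L]], u5 = u[[2L]], u7 = u[[3L]],
       uSum = u[[1L]] + u[[2L]] + u[[3L]])
}

#' Per-channel branch attention weights
#'
#' Global average pooling of the summed branch features, a two-layer
#' bottleneck (ReLU in between), and a softmax across the three branches
#' independently for every channel.
#'
#' @param uSum summed branch features `(N, H, W, C)` (or without batch dim).
#' @param params from [plkaInit()].
#' @return list of matrices `a`, `b`, `c` (N x C), summing to 1 per entry.
#' @export
branchAttention <- function(uSum, params) {
  uSum <- ensureBatch(uSum)
  d <- dim(uSum)
  N <- d[1L]; C <- d[4L]
  gap <- colMeans(matrix(aperm(uSum, c(2L, 3L, 1L, 4L)),
                         d[2L] * d[3L], N * C))
  gap <- matrix(gap, N, C)
  z1 <- linForward(gap, params$fc1$W, params$fc1$b)
  a1 <- pmax(z1, 0)
  z2 <- linForward(a1, params$fc2$W, params$fc2$b)
  checkFinite(z2, "branch attention logits")
  la <- z2[, seq_len(C), drop = FALSE]
  lb <- z2[, C + seq_len(C), drop = FALSE]
  lc <- z2[, 2L * C + seq_len(C), drop = FALSE]
  m <- pmax(la, lb, lc)
  ea <- exp(la - m); eb <- exp(lb - m); ec <- exp(lc - m)
  s <- ea + eb + ec
  list(a = ea / s, b = eb / s, c = ec / s,
       cache = list(gap = gap, z1 = z1, a1 = a1, dims = d))
}

broadcastChannels <- function(mat, dims) {
  # expand an (N, C) matrix over the spatial axes of (N, H, W, C)
  N <- dims[1L]; sp <- dims[2L] * dims[3L]; C <- dims[4L]
  out <- array(0, c(N, sp, C))
  for (c in seq_len(C)) out[, , c] <- matrix(mat[, c], N, sp)
  dim(out) <- dims
  out
}

#' Dynamically weighted branch recombination
#'
#' `Y = a * u3 + b * u5 + c * u7` with per-channel broadcasting; since the
#' weights are a per-channel convex combination, every output element lies
#' in the convex hull of the branch values at that position.
#'
#' @param branches list from [multiBranchConv()].
#' @param weights list from [branchAttention()].
#' @return feature map of the input shape.
#' @export
fuseBranches <- function(branches, weights) {
  u3 <- ensureBatch(branches$u3)
  u5 <- ensureBatch(branches$u5)
  u7 <- ensureBatch(branches$u7)
  d <- dim(u3)
  if (ncol(weights$a) != d[4L]) stop("channel counts disagree")
  u3 * broadcastChannels(weights$a, d) +
    u5 * broadcastChannels(weights$b, d) +
    u7 * broadcastChannels(weights$c, d)
}

#' Full lesion-attention forward pass
#'
#' Composition of [multiBranchConv()], [branchAttention()] and
#' [fuseBranches()]; preserves the feature-map shape.
#'
#' @inheritParams multiBranchConv
#' @return feature map of the input shape.
#' @export
plkaForward <- function(x, params) {
  had3 <- length(dim(x)) == 3L
  x <- ensureBatch(x)
  br <- multiBranchConv(x, params)
  w <- branchAttention(br$uSum, params)
  y <- fuseBranches(br, w)
  if (had3) dim(y) <- dim(y)[-1L]
  y
}

# Forward with cache, used inside the network.
plkaForwardCached <- function(x, params) {
  br <- multiBranchConv(x, params)
  w <- branchAttention(br$uSum, params)
  y <- fuseBranches(br, w)
  list(out = y, cache = list(x = x, br = br, w = w))
}

plkaBackward <- function(dy, params, cache) {
  d <- dim(cache$x)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  sp <- H * W
  br <- cache$br; w <- cache$w
  # d wrt branch maps through the weighted sum
  du <- list(dy * broadcastChannels(w$a, d),
             dy * broadcastChannels(w$b, d),
             dy * broadcastChannels(w$c, d))
  # d wrt the per-channel weights
  sumNC <- function(arr) {
    m <- matrix(aperm(arr, c(2L, 3L, 1L, 4L)), sp, N * C)
    matrix(colSums(m), N, C)
  }
  dla_ <- sumNC(dy * br$u3)
  dlb_ <- sumNC(dy * br$u5)
  dlc_ <- sumNC(dy * br$u7)
  a <- w$a; b <- w$b; cc <- w$c
  dot <- a * dla_ + b * dlb_ + cc * dlc_
  dz2 <- cbind(a * (dla_ - dot), b * (dlb_ - dot), cc * (dlc_ - dot))
  l2 <- linBackward(dz2, w$cache$a1, params$fc2$W)
  da1 <- l2$dX * (w$cache$z1 > 0)
  l1 <- linBackward(da1, w$cache$gap, params$fc1$W)
  dgap <- l1$dX                              # N x C
  duSum <- broadcastChannels(dgap / sp, d)
  grads <- list(conv = vector("list", 3L),
                fc1 = list(W = l1$dW, b = l1$db),
                fc2 = list(W = l2$dW, b = l2$db))
  dx <- array(0, d)
  for (i in 1:3) {
    dui <- du[[i]] + duSum
    cb <- depthwiseConvBackward(dui, cache$x, params$conv[[i]]$k,
                                params$dilations[i])
    dx <- dx + cb$dx
    grads$conv[[i]] <- list(k = cb$dk, b = cb$db)
  }
  list(dx = dx, grads = grads)
}
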