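# Multi-kernel lesion attention: branch convolutions, channel-wise branch
# softmax, weighted fusion, and the composed forward with its gradients.

test_that("branch convolutions preserve shape and sum correctly", {
  set.seed(31)
  x <- array(rnorm(2 * 5 * 7 * 6), c(2, 5, 7, 6))
  p <- plkaInit(6, seed = 31)
  br <- multiBranchConv(x, p)
  expect_equal(dim(br$u3), dim(x))
  expect_equal(br$uSum, br$u3 + br$u5 + br$u7, tolerance = 1e-12)
  # zero weights and biases give zero branches
  p0 <- p
  for (i in 1:3) { p0$conv[[i]]$k[] <- 0; p0$conv[[i]]$b[] <- 0 }
  br0 <- multiBranchConv(x, p0)
  expect_true(all(br0$uSum == 0))
  # identity kernel on the 3x3 branch reproduces the input
  p0$conv[[1]]$k[2, 2, ] <- 1
  expect_equal(multiBranchConv(x, p0)$u3, x, tolerance = 1e-12)
})

test_that("depthwise convolution matches a direct nested-loop oracle", {
  set.seed(32)
  x <- array(rnorm(1 * 4 * 5 * 2), c(1, 4, 5, 2))
  k <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  b <- rnorm(2)
  out <- RetiGrade:::depthwiseConv(x, k, b)
  oracle <- array(0, dim(x))
  for (h in 1:4) for (w in 1:5) for (c in 1:2) {
    acc <- b[c]
    for (i in 1:3) for (j in 1:3) {
      hh <- h + i - 2; ww <- w + j - 2
      if (hh >= 1 && hh <= 4 && ww >= 1 && ww <= 5)
        acc <- acc + k[i, j, c] * x[1, hh, ww, c]
    }
    oracle[1, h, w, c] <- acc
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("branch attention is a per-channel softmax over three branches", {
  set.seed(33)
  C <- 8
  x <- array(rnorm(2 * 4 * 4 * C), c(2, 4, 4, C))
  p <- plkaInit(C, seed = 33)
  br <- multiBranchConv(x, p)
  w <- branchAttention(br$uSum, p)
  expect_equal(w$a + w$b + w$c, matrix(1, 2, C), tolerance = 1e-6)
  expect_true(all(w$a >= 0 & w$b >= 0 & w$c >= 0))
  # hand oracle: GAP -> fc1 -> ReLU -> fc2 -> per-channel softmax
  gap <- t(vapply(1:2, function(n) colMeans(matrix(br$uSum[n, , , ], 16, C)),
                  numeric(C)))
  z1 <- gap %*% p$fc1$W + rep(p$fc1$b, each = 2)
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% p$fc2$W + rep(p$fc2$b, each = 2)
  for (n in 1:2) for (c in 1:C) {
    l <- z2[n, c(c, C + c, 2 * C + c)]
    sm <- exp(l - max(l)); sm <- sm / sum(sm)
    expect_equal(c(w$a[n, c], w$b[n, c], w$c[n, c]), unname(sm),
                 tolerance = 1e-6)
  }
  # zero FC weights: equal thirds
  p0 <- p; p0$fc1$W[] <- 0; p0$fc1$b[] <- 0; p0$fc2$W[] <- 0; p0$fc2$b[] <- 0
  w0 <- branchAttention(br$uSum, p0)
  expect_true(all(abs(w0$a - 1 / 3) < 1e-12))
  # +20 bias on the first branch saturates its weight
  p0$fc2$b[seq_len(C)] <- 20
  wsat <- branchAttention(br$uSum, p0)
  expect_true(all(wsat$a > 1 - 1e-6))
})

test_that("fusion is a per-channel convex combination of the branches", {
  set.seed(34)
  C <- 4
  x <- array(rnorm(2 * 3 * 3 * C), c(2, 3, 3, C))
  p <- plkaInit(C, seed = 34)
  br <- multiBranchConv(x, p)
  oneHot <- list(a = matrix(1, 2, C), b = matrix(0, 2, C),
                 c = matrix(0, 2, C))
  expect_equal(fuseBranches(br, oneHot), br$u3)
  thirds <- list(a = matrix(1 / 3, 2, C), b = matrix(1 / 3, 2, C),
                 c = matrix(1 / 3, 2, C))
  expect_equal(fuseBranches(br, thirds), br$uSum / 3, tolerance = 1e-12)
  # random weights: elementwise oracle and convex-hull containment
  w <- branchAttention(br$uSum, p)
  y <- fuseBranches(br, w)
  for (n in 1:2) for (c in 1:C) {
    oracle <- br$u3[n, , , c] * w$a[n, c] + br$u5[n, , , c] * w$b[n, c] +
      br$u7[n, , , c] * w$c[n, c]
    expect_equal(y[n, , , c], oracle, tolerance = 1e-6)
    lo <- pmin(br$u3[n, , , c], br$u5[n, , , c], br$u7[n, , , c])
    hi <- pmax(br$u3[n, , , c], br$u5[n, , , c], br$u7[n, , , c])
    expect_true(all(y[n, , , c] >= lo - 1e-9 & y[n, , , c] <= hi + 1e-9))
  }
})

test_that("composed forward preserves shape, has identity and zero modes", {
  set.seed(35)
  C <- 6
  for (hw in list(c(1, 1), c(2, 3), c(6, 6))) {
    x <- array(rnorm(2 * hw[1] * hw[2] * C), c(2, hw[1], hw[2], C))
    p <- plkaInit(C, seed = 35)
    expect_equal(dim(plkaForward(x, p)), dim(x))
  }
  x <- array(rnorm(2 * 6 * 6 * C), c(2, 6, 6, C))
  # identity configuration
  expect_equal(plkaForward(x, plkaIdentityParams(C)), x, tolerance = 1e-6)
  # zero input with zero biases maps to zero even though weights sum to 1
  p0 <- plkaInit(C, seed = 35)
  for (i in 1:3) p0$conv[[i]]$b[] <- 0
  expect_true(all(plkaForward(array(0, dim(x)), p0) == 0))
  # composition equals the three-stage pipeline
  p <- plkaInit(C, seed = 36)
  br <- multiBranchConv(x, p)
  w <- branchAttention(br$uSum, p)
  expect_equal(plkaForward(x, p), fuseBranches(br, w), tolerance = 1e-6)
})

test_that("dilated variant uses 3x3 kernels at growing dilation", {
  p <- plkaInit(8, dilated = TRUE, seed = 37)
  expect_equal(p$dilations, c(1L, 2L, 3L))
  expect_true(all(vapply(p$conv, function(cv) dim(cv$k)[1], 0) == 3))
  x <- array(rnorm(1 * 8 * 8 * 8), c(1, 8, 8, 8))
  expect_equal(dim(plkaForward(x, p)), dim(x))
})

test_that("lesion-attention gradients agree with finite differences", {
  set.seed(38)
  x <- array(rnorm(1 * 4 * 6 * 4), c(1, 4, 6, 4))
  p <- plkaInit(4, seed = 38)
  tgt <- array(rnorm(length(x)), dim(x))
  lossAt <- function(pp, xx) sum(RetiGrade:::plkaForwardCached(xx, pp)$out * tgt)
  fw <- RetiGrade:::plkaForwardCached(x, p)
  bw <- RetiGrade:::plkaBackward(tgt, p, fw$cache)
  eps <- 1e-5
  relErr <- function(a, b) abs(a - b) / pmax(1e-6, abs(a) + abs(b))
  for (i in sample(length(x), 6)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    fd <- (lossAt(p, x1) - lossAt(p, x2)) / (2 * eps)
    expect_lt(relErr(fd, bw$dx[i]), 1e-4)
  }
  for (br in 1:3) {
    i <- sample(length(p$conv[[br]]$k), 1)
    p1 <- p; p1$conv[[br]]$k[i] <- p1$conv[[br]]$k[i] + eps
    p2 <- p; p2$conv[[br]]$k[i] <- p2$conv[[br]]$k[i] - eps
    fd <- (lossAt(p1, x) - lossAt(p2, x)) / (2 * eps)
    expect_lt(relErr(fd, bw$grads$conv[[br]]$k[i]), 1e-4)
  }
  i <- sample(length(p$fc2$W), 1)
  p1 <- p; p1$fc2$W[i] <- p1$fc2$W[i] + eps
  p2 <- p; p2$fc2$W[i] <- p2$fc2$W[i] - eps
  fd <- (lossAt(p1, x) - lossAt(p2, x)) / (2 * eps)
  expect_lt(relErr(fd, bw$grads$fc2$W[i]), 1e-4)
})
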