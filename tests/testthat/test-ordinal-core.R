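# Ordinal coding, losses, and evaluation metrics.

test_that("ordinal encoding produces rank-threshold bits", {
  expect_identical(encodeOrdinal(0, 5), c(0L, 0L, 0L, 0L))
  expect_identical(encodeOrdinal(4, 5), c(1L, 1L, 1L, 1L))
  expect_identical(encodeOrdinal(2, 5), c(1L, 1L, 0L, 0L))
  m <- encodeOrdinal(c(0L, 3L), 5)
  expect_equal(dim(m), c(2L, 4L))
  expect_identical(m[2, ], c(1L, 1L, 1L, 0L))
  # bits non-increasing for every grade and K
  for (K in 2:10) for (g in 0:(K - 1)) {
    bits <- encodeOrdinal(g, K)
    expect_true(all(diff(bits) <= 0))
  }
  expect_error(encodeOrdinal(5, 5), "grade")
  expect_error(encodeOrdinal(-1, 5), "grade")
})

test_that("ordinal decoding counts threshold exceedances", {
  expect_identical(decodeOrdinal(c(0.9, 0.8, 0.4, 0.1)), 2L)
  expect_identical(decodeOrdinal(c(0, 0, 0, 0)), 0L)
  # non-monotone probabilities still decode by count
  expect_identical(decodeOrdinal(c(0.6, 0.2, 0.7, 0.1)), 2L)
  expect_identical(decodeOrdinal(c(0.6, 0.2, 0.7, 0.1), method = "first"), 1L)
  expect_error(decodeOrdinal(numeric()), "non-empty")
})

test_that("encode then decode is the identity for exact bits", {
  for (K in 2:10) for (g in 0:(K - 1)) {
    q <- as.numeric(encodeOrdinal(g, K))
    expect_identical(decodeOrdinal(q), as.integer(g))
    expect_identical(decodeOrdinal(q, method = "first"), as.integer(g))
  }
})

test_that("classification loss matches smoothed cross-entropy", {
  # uniform softmax: loss is log(K) for any target and any smoothing
  expect_equal(classificationLoss(rep(0, 5), 2, eps = 0), log(5),
               tolerance = 1e-12)
  expect_equal(classificationLoss(rep(0, 5), 0, eps = 0.1), log(5),
               tolerance = 1e-12)
  # perfect-prediction limit
  z <- c(-50, -50, 50, -50, -50)
  expect_lt(classificationLoss(z, 2, eps = 0), 1e-9)
  # hand oracle on a random case
  set.seed(4)
  logits <- rnorm(5)
  p <- exp(logits) / sum(exp(logits))
  eps <- 0.1
  target <- rep(eps / 4, 5); target[3] <- 1 - eps
  expect_equal(classificationLoss(logits, 2, eps = eps),
               -sum(target * log(p)), tolerance = 1e-12)
  # batch mean reduction
  L <- classificationLoss(rbind(logits, logits), c(2L, 2L), eps = eps)
  expect_equal(L, -sum(target * log(p)), tolerance = 1e-12)
  expect_error(classificationLoss(c(Inf, 0, 0, 0, 0), 0), "finite")
})

test_that("class costs reweight the loss and renormalize by the batch mean", {
  logits <- rbind(rep(0, 5), rep(0, 5))
  costs <- c(4, 1, 1, 1, 1)
  # both grades weighted: mean(cost*loss)/mean(cost) = log 5 when losses equal
  expect_equal(classificationLoss(logits, c(0L, 1L), eps = 0,
                                  classCosts = costs), log(5),
               tolerance = 1e-12)
  # unequal per-sample losses shift toward the costly class
  z <- rbind(c(3, 0, 0, 0, 0), c(0, 3, 0, 0, 0))
  base <- classificationLoss(z, c(1L, 0L), eps = 0)
  wtd <- classificationLoss(z, c(1L, 0L), eps = 0,
                            classCosts = c(1, 10, 1, 1, 1))
  expect_gt(wtd, base * 0.999)
  expect_error(classificationLoss(z, c(1L, 0L), classCosts = c(1, 2)),
               "classCosts")
})

test_that("ordinal loss is the summed BCE over sub-tasks", {
  expect_equal(ordinalLoss(rep(0, 4), c(1, 0, 0, 0)), 4 * log(2),
               tolerance = 1e-12)
  expect_lt(ordinalLoss(c(50, 50, -50, -50), c(1, 1, 0, 0)), 1e-9)
  sig <- function(x) 1 / (1 + exp(-x))
  hand <- -log(sig(1)) - log(1 - sig(-1)) - 2 * log(0.5)
  expect_equal(ordinalLoss(c(1, -1, 0, 0), c(1, 0, 0, 0)), hand,
               tolerance = 1e-12)
  expect_error(ordinalLoss(c(0, 0), c(1, 0, 0)), "disagree")
  # moving one q toward its bit strictly reduces the loss
  z <- c(0.3, -0.2, 0.1, -0.5); v <- c(1, 1, 0, 0)
  for (k in 1:4) {
    z2 <- z
    z2[k] <- z[k] + if (v[k] == 1) 0.1 else -0.1
    expect_lt(ordinalLoss(z2, v), ordinalLoss(z, v))
  }
})

test_that("joint loss mixes linearly and hits both degenerate ends", {
  expect_equal(jointLoss(2, 4, 0.5), 3)
  expect_equal(jointLoss(2, 4, 1), 2)
  expect_equal(jointLoss(2, 4, 0), 4)
  lam <- runif(5)
  for (l in lam)
    expect_equal(jointLoss(1.3, 0.7, l), l * 1.3 + (1 - l) * 0.7)
  expect_error(jointLoss(1, 1, 1.5), "lambda")
})

test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracyScore(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(accuracyScore(c(0, 1, 2, 3), c(0, 1, 2, 4)), 0.75)
  expect_equal(accuracyScore(c(0, 0), c(1, 1)), 0)
  expect_error(accuracyScore(integer(), integer()), "non-empty")
})

test_that("confusion counts by true row and predicted column", {
  m <- confusionCounts(c(0, 0), c(0, 1), 5)
  expect_equal(m[1, 1], 1L)
  expect_equal(m[1, 2], 1L)
  expect_equal(sum(m), 2L)
  set.seed(7)
  tr <- sample(0:4, 1000, TRUE); pr <- sample(0:4, 1000, TRUE)
  m2 <- confusionCounts(tr, pr, 5)
  expect_equal(unname(rowSums(m2)), unname(tabulate(tr + 1L, 5)))
  expect_equal(sum(m2), 1000L)
  expect_error(confusionCounts(c(0, 9), c(0, 0), 5), "out of")
})

test_that("quadratic weighted kappa matches the direct-formula oracle", {
  expect_equal(quadraticWeightedKappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4), 5), 1)
  expect_equal(quadraticWeightedKappa(c(0, 4), c(4, 0), 5), -1)
  # all labels identical and equal: kappa 1 by convention
  expect_equal(quadraticWeightedKappa(c(2, 2, 2), c(2, 2, 2), 5), 1)
  # one-off disagreement on otherwise constant labels: chance-level 0
  expect_equal(quadraticWeightedKappa(c(2, 2, 2), c(2, 2, 3), 5), 0)
  set.seed(11)
  for (r in 1:50) {
    tr <- sample(0:4, 50, TRUE); pr <- sample(0:4, 50, TRUE)
    expect_equal(quadraticWeightedKappa(tr, pr, 5), directQWK(tr, pr, 5),
                 tolerance = 1e-10)
  }
  # symmetry and permutation invariance
  set.seed(12)
  tr <- sample(0:4, 80, TRUE); pr <- sample(0:4, 80, TRUE)
  expect_equal(quadraticWeightedKappa(tr, pr, 5),
               quadraticWeightedKappa(pr, tr, 5), tolerance = 1e-12)
  o <- sample(80)
  expect_equal(quadraticWeightedKappa(tr[o], pr[o], 5),
               quadraticWeightedKappa(tr, pr, 5), tolerance = 1e-12)
})

test_that("one-vs-rest AUC matches the pairwise oracle and handles ties", {
  set.seed(13)
  tr <- sample(0:4, 120, TRUE)
  sc <- matrix(rnorm(600), 120, 5)
  a <- oneVsRestAUC(tr, sc)
  for (k in 1:5)
    expect_equal(a$perClass[k], pairwiseAUC(tr == k - 1, sc[, k]),
                 tolerance = 1e-10)
  bin <- matrix(0L, 120, 5); bin[cbind(1:120, tr + 1L)] <- 1L
  expect_equal(a$micro, pairwiseAUC(as.vector(bin) == 1L, as.vector(sc)),
               tolerance = 1e-10)
  expect_equal(a$macro, mean(a$perClass), tolerance = 1e-12)
  # constant scores give AUC 0.5 by the midrank convention
  aconst <- oneVsRestAUC(tr, matrix(1, 120, 5))
  expect_true(all(abs(aconst$perClass - 0.5) < 1e-12))
  # perfectly separating scores give AUC 1
  sc2 <- matrix(0, 120, 5); sc2[cbind(1:120, tr + 1L)] <- 1
  expect_true(all(oneVsRestAUC(tr, sc2)$perClass == 1))
  # absent class: NA with a warning, excluded from the macro mean
  tr3 <- rep(c(0L, 1L), 10)
  sc3 <- matrix(rnorm(100), 20, 5)
  expect_warning(a3 <- oneVsRestAUC(tr3, sc3), "undefined")
  expect_true(all(is.na(a3$perClass[3:5])))
  expect_equal(a3$macro, mean(a3$perClass[1:2]))
})

test_that("perfect accuracy implies perfect kappa under label variety", {
  set.seed(14)
  tr <- sample(0:4, 60, TRUE)
  expect_equal(accuracyScore(tr, tr), 1)
  expect_equal(quadraticWeightedKappa(tr, tr, 5), 1)
})
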