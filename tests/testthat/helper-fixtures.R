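# Shared fixtures: a reduced model configuration and small in-memory
# datasets, all built in code at test time.

# Narrow backbone (embed dim 8) for fast forward/backward tests; still four
# stages with the /32 contract and a shifted block in stage 3.
tinyBackbone <- function() {
  backboneConfig("nano", embedDim = 8L, depths = c(1L, 1L, 2L, 1L),
                 heads = c(1L, 2L, 2L, 4L))
}

tinyGraderConfig <- function(spm = TRUE, plka = TRUE) {
  graderConfig(backbone = tinyBackbone(), spm = spm, plka = plka,
               priorDim = 16L)
}

# Small in-memory synthetic dataset.
makeManifest <- function(n, profile = "easy", seed = 1L,
                         props = aptosProportions(), size = 64L) {
  spec <- fundusSpec(n, imageSize = size, profile = profile,
                     classProportions = props, seed = seed)
  generateDataset(spec)
}

# Brute-force ROC AUC by pairwise comparison (ties count one half).
pairwiseAUC <- function(pos, score) {
  ps <- score[pos]; ns <- score[!pos]
  if (!length(ps) || !length(ns)) return(NA_real_)
  (sum(outer(ps, ns, ">")) + 0.5 * sum(outer(ps, ns, "=="))) /
    (length(ps) * length(ns))
}

# Direct-formula quadratic weighted kappa, coded independently of the
# package implementation (explicit double loop over the K x K grid).
directQWK <- function(true, pred, K) {
  n <- length(true)
  O <- matrix(0, K, K)
  for (i in seq_len(n)) O[true[i] + 1, pred[i] + 1] <- O[true[i] + 1, pred[i] + 1] + 1
  rowm <- rowSums(O); colm <- colSums(O)
  num <- 0; den <- 0
  for (i in 1:K) for (j in 1:K) {
    w <- (i - j)^2
    num <- num + w * O[i, j]
    den <- den + w * rowm[i] * colm[j] / n
  }
  1 - num / den
}
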