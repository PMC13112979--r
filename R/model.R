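# Full model assembly: backbone -> semantic prior gating -> multi-kernel
# lesion attention -> global average pooling -> shared trunk -> dual heads.

#' Model configuration
#'
#' Collects the backbone preset and the switches for the two enhancement
#' blocks. Disabling both (`spm = FALSE`, `plka = FALSE`) reduces the model
#' exactly to backbone + pooled dual heads — the ablation baseline is a
#' configuration, not separate code.
#'
#' @param preset backbone preset, `"nano"` or `"tiny"`.
#' @param K number of ordinal classes (default 5).
#' @param spm logical, enable semantic prior modulation.
#' @param plka logical, enable multi-kernel lesion attention.
#' @param priorDim vision-language embedding dimension D (default 512).
#' @param temperature prompt-attention softmax temperature (default 0.07).
#' @param plkaKernels branch kernel sizes (default 3/5/7).
#' @param plkaDilated use 3x3 kernels at dilation 1/2/3 instead.
#' @param plkaReduction bottleneck ratio of the branch attention.
#' @param backbone optional full [backboneConfig()] override.
#' @return configuration list for [buildGrader()].
#' @export
graderConfig <- function(preset = "nano", K = 5L, spm = TRUE, plka = TRUE,
                         priorDim = 512L, temperature = 0.07,
                         plkaKernels = c(3L, 5L, 7L), plkaDilated = FALSE,
                         plkaReduction = 4L, backbone = NULL) {
  list(
    K = as.integer(K),
    backbone = if (is.null(backbone)) backboneConfig(preset) else backbone,
    spm = list(enabled = isTRUE(spm), dim = as.integer(priorDim),
               temperature = temperature),
    plka = list(enabled = isTRUE(plka), kernels = as.integer(plkaKernels),
                dilated = isTRUE(plkaDilated),
                reduction = as.integer(plkaReduction))
  )
}

#' Build a dual-head grading model
#'
#' Initialises all trainable parameters from the seed, embeds the prompt
#' set once through the encoder, and returns a `GraderModel`.
#'
#' @param config from [graderConfig()].
#' @param seed integer initialisation seed.
#' @param prompts clinical prompt strings (default [defaultPrompts()]).
#' @param encoder prior-encoder contract; default is the deterministic
#'   [fixtureEncoder()] derived from `seed`.
#' @return a `GraderModel`.
#' @export
buildGrader <- function(config = graderConfig(), seed = 1L,
                        prompts = defaultPrompts(), encoder = NULL) {
  if (is.null(encoder))
    encoder <- fixtureEncoder(childSeed(seed, "encoder"), config$spm$dim)
  if (encoder$D != config$spm$dim)
    stop("encoder dimension disagrees with config priorDim")
  C <- stageDims(config$backbone)[4L]
  params <- list(backbone = backboneInit(config$backbone,
                                         childSeed(seed, "backbone")))
  if (config$spm$enabled)
    params$spm <- spmInit(C, config$spm$dim, childSeed(seed, "spm"))
  if (config$plka$enabled)
    params$plka <- plkaInit(C, config$plka$kernels, config$plka$dilated,
                            config$plka$reduction, childSeed(seed, "plka"))
  withSeed(childSeed(seed, "heads"), {
    params$trunk <- initLinear(C, C)
    params$headCls <- initLinear(C, config$K)
    params$headOrd <- initLinear(C, config$K - 1L)
  })
  pe <- encoder$embedTexts(prompts)
  new("GraderModel", params = params, config = config, prompts = prompts,
      promptEmbeddings = pe, encoder = encoder, seed = as.integer(seed))
}

# Per-sample semantic contexts (N x D) from the frozen encoder.
semanticContexts <- function(model, images) {
  N <- dim(images)[1L]
  D <- model@config$spm$dim
  ctx <- matrix(0, N, D)
  for (n in seq_len(N)) {
    v <- model@encoder$embedImage(images[n, , , ])
    w <- semanticAttention(v, model@promptEmbeddings,
                           model@config$spm$temperature)
    ctx[n, ] <- semanticContext(w, model@promptEmbeddings)
  }
  ctx
}

#' Forward pass of the grading model
#'
#' Backbone, then (if enabled) semantic gating and lesion attention on the
#' final feature map, global average pooling, a shared affine + GELU trunk,
#' and the two linear heads.
#'
#' @param model a `GraderModel`.
#' @param images `(N, H, W, 3)` or single `(H, W, 3)` array in [0,1]; H, W
#'   divisible by 32.
#' @param train logical; enables stochastic depth if configured.
#' @param withCache keep intermediate activations for a backward pass.
#' @return list with `cls` (N x K logits), `ord` (N x (K-1) logits), and
#'   `cache` when requested.
#' @export
graderForward <- function(model, images, train = FALSE, withCache = FALSE) {
  if (length(dim(images)) == 3L) dim(images) <- c(1L, dim(images))
  p <- model@params
  cfg <- model@config
  bf <- backboneForward(p$backbone, cfg$backbone, images, train)
  feats <- bf$features
  cache <- list(backbone = bf$cache, dims = dim(feats))
  if (cfg$spm$enabled) {
    ctx <- semanticContexts(model, images)
    sf <- spmForward(feats, ctx, p$spm)
    feats <- sf$out
    cache$spm <- sf$cache
  }
  if (cfg$plka$enabled) {
    pf <- plkaForwardCached(feats, p$plka)
    feats <- pf$out
    cache$plka <- pf$cache
  }
  d <- dim(feats)
  N <- d[1L]; sp <- d[2L] * d[3L]; C <- d[4L]
  fm <- feats
  dim(fm) <- c(N, sp, C)
  gap <- matrix(0, N, C)
  for (c in seq_len(C)) gap[, c] <- rowMeans(fm[, , c, drop = FALSE])
  z <- linForward(gap, p$trunk$W, p$trunk$b)
  a <- gelu(z)
  cls <- linForward(a, p$headCls$W, p$headCls$b)
  ord <- linForward(a, p$headOrd$W, p$headOrd$b)
  checkFinite(cls, "classification logits")
  checkFinite(ord, "ordinal logits")
  out <- list(cls = cls, ord = ord)
  if (withCache) {
    cache$gap <- gap; cache$z <- z; cache$a <- a; cache$featDims <- d
    out$cache <- cache
  }
  out
}

# Backward pass: dcls (N x K), dord (N x (K-1)) -> gradient tree parallel
# to model@params.
graderBackward <- function(model, cache, dcls, dord) {
  p <- model@params
  cfg <- model@config
  g <- list()
  lc <- linBackward(dcls, cache$a, p$headCls$W)
  lo <- linBackward(dord, cache$a, p$headOrd$W)
  g$headCls <- list(W = lc$dW, b = lc$db)
  g$headOrd <- list(W = lo$dW, b = lo$db)
  da <- lc$dX + lo$dX
  dz <- da * geluGrad(cache$z)
  lt <- linBackward(dz, cache$gap, p$trunk$W)
  g$trunk <- list(W = lt$dW, b = lt$db)
  dgap <- lt$dX
  d <- cache$featDims
  N <- d[1L]; sp <- d[2L] * d[3L]
  dfeat <- broadcastChannels(dgap / sp, d)
  if (cfg$plka$enabled) {
    pb <- plkaBackward(dfeat, p$plka, cache$plka)
    g$plka <- pb$grads
    dfeat <- pb$dx
  }
  if (cfg$spm$enabled) {
    sb <- spmBackward(dfeat, p$spm, cache$spm)
    g$spm <- sb$grads
    dfeat <- sb$dx
  }
  g$backbone <- backboneBackward(dfeat, p$backbone, cfg$backbone,
                                 cache$backbone)
  g
}

#' Predict grades from model outputs
#'
#' The default rule is the classification-head argmax (ties resolved to the
#' lowest grade). `"ordinal"` decodes the ordinal head by threshold
#' counting. `"consistency_check"` returns the classification argmax and
#' attaches a `disagreement` attribute flagging samples where the two heads
#' disagree by two grades or more — a diagnostic for rank-inconsistent
#' predictions.
#'
#' @param outputs list from [graderForward()] (elements `cls`, `ord`).
#' @param mode `"classification"`, `"ordinal"` or `"consistency_check"`.
#' @param threshold ordinal decode threshold (default 0.5).
#' @return integer vector of grades in `0:(K-1)`.
#' @export
predictGrade <- function(outputs,
                         mode = c("classification", "ordinal",
                                  "consistency_check"),
                         threshold = 0.5) {
  mode <- match.arg(mode)
  cls <- outputs$cls
  if (is.null(dim(cls))) cls <- matrix(cls, nrow = 1L)
  ord <- outputs$ord
  if (is.null(dim(ord))) ord <- matrix(ord, nrow = 1L)
  checkFinite(cls, "logits")
  clsPred <- max.col(cls, ties.method = "first") - 1L
  if (mode == "classification") return(clsPred)
  ordPred <- vapply(seq_len(nrow(ord)), function(i)
    decodeOrdinal(sigmoid(ord[i, ]), threshold), integer(1L))
  if (mode == "ordinal") return(ordPred)
  structure(clsPred, disagreement = abs(clsPred - ordPred) >= 2L)
}

#' Save a model checkpoint
#'
#' Single-file archive holding the weights, the full configuration, the
#' prompts, the seed and (optionally) the training history, with a format
#' version for compatibility checks.
#'
#' @param model a `GraderModel`.
#' @param path output file.
#' @param history optional `TrainHistory`.
#' @export
saveCheckpoint <- function(model, path, history = NULL) {
  saveRDS(list(format = "retigrade-checkpoint", version = 1L,
               model = model, history = history), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveCheckpoint()].
#' @return list with `model` and `history` (possibly NULL).
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "retigrade-checkpoint"))
    stop("not a model checkpoint: ", path)
  if (x$version > 1L)
    stop("checkpoint version ", x$version, " is newer than this package")
  x[c("model", "history")]
}
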