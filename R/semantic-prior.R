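# Semantic prior modulation: prompt-similarity attention, context
# aggregation, and gated channel modulation of the visual feature map. The
# pretrained vision-language encoder sits behind a small contract
# (embedImage / embedTexts) so a deterministic fixture encoder can stand in
# for a real one.

#' Default clinical prompt set
#'
#' Five grade descriptions plus four lesion descriptions. Prompts are
#' configuration, not code: any character vector (or a plain-text file via
#' [loadPrompts()]) can replace them.
#'
#' @return character vector of prompts.
#' @export
defaultPrompts <- function() {
  c("Fundus image with no diabetic retinopathy",
    "Fundus image with mild nonproliferative diabetic retinopathy",
    "Fundus image with moderate nonproliferative diabetic retinopathy",
    "Fundus image with severe nonproliferative diabetic retinopathy",
    "Fundus image with proliferative diabetic retinopathy",
    "Fundus image with microaneurysms",
    "Fundus image with retinal hemorrhages",
    "Fundus image with hard exudates",
    "Fundus image with neovascularization")
}

#' Read a prompt list from a plain-text file (one prompt per line)
#'
#' @param path file path; blank lines and lines starting with `#` are
#'   ignored.
#' @return character vector of prompts.
#' @export
loadPrompts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no prompts found in ", path)
  lines
}

#' Deterministic fixture vision-language encoder
#'
#' A seeded stand-in satisfying the prior-encoder contract: each distinct
#' string maps to an L2-normalized random vector (hash-seeded, so identical
#' strings embed identically across runs and sessions); an image maps to the
#' L2-normalized projection of its 8x8 block-mean downsample (plus a
#' constant coordinate, so even an all-zero image embeds to a well-defined
#' unit vector) through a seeded random matrix. Synthetic by construction;
#' it carries no pretrained semantics and exists so the modulation pathway
#' is exercisable and reproducible without downloads.
#'
#' @param seed integer seed fixing the encoder state.
#' @param D embedding dimension (default 512).
#' @return list with `name`, `D`, `embedImage(image)` and
#'   `embedTexts(texts)`.
#' @export
fixtureEncoder <- function(seed = 1L, D = 512L) {
  D <- as.integer(D)
  if (D < 2L) stop("D must be at least 2")
  grid <- 8L
  inDim <- grid * grid * 3L + 1L
  proj <- withSeed(childSeed(seed, "fixture-image-proj"),
                  matrix(rnorm(D * inDim) / sqrt(inDim), D, inDim))
  embedImage <- function(image) {
    if (length(dim(image)) != 3L) stop("image must be an (H, W, C) array")
    small <- resizeBilinear(image, grid, grid)
    x <- c(as.vector(small), 1)
    l2norm(as.vector(proj %*% x))
  }
  embedTexts <- function(texts) {
    emb <- t(vapply(texts, function(s) {
      withSeed(childSeed(seed, paste0("fixture-text:", s)),
               l2norm(rnorm(D)))
    }, numeric(D)))
    rownames(emb) <- NULL
    emb
  }
  list(name = "fixture", D = D, seed = as.integer(seed),
       embedImage = embedImage, embedTexts = embedTexts)
}

#' Prompt-similarity attention weights
#'
#' Softmax over the scaled cosine similarities between a global visual
#' embedding and the prompt embeddings: `softmax(v . T' / tau)`.
#'
#' @param v L2-normalized visual embedding (length D).
#' @param promptEmbeddings K' x D matrix of L2-normalized text embeddings.
#' @param temperature softmax temperature `tau > 0` (default 0.07, the
#'   conventional contrastive-encoder value).
#' @return length-K' probability vector.
#' @export
semanticAttention <- function(v, promptEmbeddings, temperature = 0.07) {
  if (temperature <= 0) stop("temperature must be positive")
  if (length(v) != ncol(promptEmbeddings))
    stop("embedding dimensions disagree")
  sims <- as.vector(promptEmbeddings %*% v)
  softmaxRows(sims / temperature)
}

#' Aggregate the semantic context vector
#'
#' Attention-weighted sum of the prompt embeddings; by construction the
#' context lies in the convex hull of the prompt embeddings.
#'
#' @param weights length-K' probability vector.
#' @param promptEmbeddings K' x D matrix.
#' @return length-D context vector.
#' @export
semanticContext <- function(weights, promptEmbeddings) {
  if (length(weights) != nrow(promptEmbeddings))
    stop("weights and promptEmbeddings disagree in length")
  as.vector(crossprod(promptEmbeddings, weights))
}

#' Gated residual channel modulation
#'
#' Projects the semantic context to the channel dimension, squashes it to a
#' gate `g = sigmoid(W c + b)` in (0,1)^C, and modulates the feature map as
#' `F * g + F` (per-channel broadcast). The residual form means the block
#' can only amplify a channel (by a factor in (1,2)), never suppress it
#' below identity.
#'
#' @param featureMap array with channels last: `(H, W, C)` or `(N, H, W, C)`.
#' @param context length-D semantic context vector.
#' @param weight C x D projection matrix.
#' @param bias length-C bias.
#' @return array of the same shape as `featureMap`.
#' @export
gatedModulation <- function(featureMap, context, weight, bias) {
  nd <- length(dim(featureMap))
  if (!nd %in% c(3L, 4L)) stop("featureMap must be (H,W,C) or (N,H,W,C)")
  C <- dim(featureMap)[nd]
  if (ncol(weight) != length(context) || nrow(weight) != C ||
      length(bias) != C)
    stop("projection dimensions disagree with featureMap channels")
  g <- sigmoid(as.vector(weight %*% context) + bias)
  mult <- 1 + g
  out <- featureMap * rep(mult, each = prod(dim(featureMap)[-nd]))
  out
}

# --- internal SPM layer used inside the network ------------------------------

spmInit <- function(C, D, seed) {
  withSeed(seed, list(
    W = matrix(rnorm(C * D) * 0.02, C, D),
    b = numeric(C)
  ))
}

# features: (N, H, W, C); contexts: N x D (one semantic context per sample).
# Returns modulated features plus a cache for the backward pass.
spmForward <- function(features, contexts, params) {
  d <- dim(features)
  N <- d[1L]; C <- d[4L]
  pre <- contexts %*% t(params$W) + rep(params$b, each = N)  # N x C
  g <- sigmoid(pre)
  mult <- 1 + g                                               # N x C
  sp <- d[2L] * d[3L]
  X <- features
  dim(X) <- c(N, sp, C)
  # expand mult (N x C) along the spatial axis
  multExp <- array(0, c(N, sp, C))
  for (c in seq_len(C)) multExp[, , c] <- matrix(mult[, c], N, sp)
  out <- as.array(X) * multExp
  dim(out) <- d
  list(out = out, cache = list(X = X, g = g, contexts = contexts, dims = d))
}

spmBackward <- function(dout, params, cache) {
  d <- cache$dims
  N <- d[1L]; C <- d[4L]; sp <- d[2L] * d[3L]
  dY <- dout
  dim(dY) <- c(N, sp, C)
  g <- cache$g
  mult <- 1 + g
  dX <- array(0, c(N, sp, C))
  dmult <- matrix(0, N, C)
  for (c in seq_len(C)) {
    m <- matrix(mult[, c], N, sp)
    dYc <- matrix(dY[, , c], N, sp)
    Xc <- matrix(cache$X[, , c], N, sp)
    dX[, , c] <- dYc * m
    dmult[, c] <- rowSums(dYc * Xc)
  }
  dpre <- dmult * g * (1 - g)                    # N x C
  dW <- t(dpre) %*% cache$contexts               # C x D
  db <- colSums(dpre)
  dim(dX) <- d
  list(dx = dX, grads = list(W = dW, b = db))
}
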