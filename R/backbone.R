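# Hierarchical shifted-window attention backbone: patch embedding, four
# stages of windowed multi-head self-attention blocks (window shifted by
# half a window on alternating blocks), patch merging between stages, and a
# final layer norm. Honors the /32 feature-map contract: an H x W input
# yields an H/32 x W/32 x C final feature map.

#' Backbone configuration
#'
#' Two presets: `"nano"` (embed dim 16, depths 2/2/2/2, < 1M parameters,
#' trainable on one CPU; the test profile) and `"tiny"` (embed dim 96,
#' depths 2/2/6/2, the canonical ~28M four-stage layout). Any field can be
#' overridden. The patch size (4) times the three 2x mergings gives the
#' overall /32 downsampling.
#'
#' @param preset `"nano"` or `"tiny"`.
#' @param ... field overrides (`patchSize`, `embedDim`, `depths`, `heads`,
#'   `windowSize`, `mlpRatio`, `dropPath`).
#' @return named list of backbone hyperparameters.
#' @export
backboneConfig <- function(preset = c("nano", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    nano = list(preset = "nano", patchSize = 4L, embedDim = 16L,
                depths = c(2L, 2L, 2L, 2L), heads = c(1L, 2L, 4L, 8L),
                windowSize = 4L, mlpRatio = 2, dropPath = 0),
    tiny = list(preset = "tiny", patchSize = 4L, embedDim = 96L,
                depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                windowSize = 7L, mlpRatio = 4, dropPath = 0.1))
  over <- list(...)
  cfg[names(over)] <- over
  if (length(cfg$depths) != 4L || length(cfg$heads) != 4L)
    stop("backbone must have 4 stages")
  if (cfg$patchSize * 8L != 32L)
    stop("patch size and three 2x mergings must compose to /32")
  cfg
}

stageDims <- function(cfg) {
  as.integer(cfg$embedDim) * c(1L, 2L, 4L, 8L)
}

backboneInit <- function(cfg, seed = 1L) {
  withSeed(seed, {
    dims <- stageDims(cfg)
    p <- list(
      patch = list(proj = initLinear(cfg$patchSize^2 * 3L, dims[1L]),
                   ln_g = rep(1, dims[1L]), ln_b = numeric(dims[1L])),
      stages = lapply(1:4, function(s)
        lapply(seq_len(cfg$depths[s]), function(i)
          initBlock(dims[s], cfg$heads[s], cfg$mlpRatio, cfg$windowSize))),
      merges = lapply(1:3, function(s)
        list(red = initLinear(4L * dims[s], 2L * dims[s], bias = FALSE),
             ln_g = rep(1, 4L * dims[s]), ln_b = numeric(4L * dims[s]))),
      norm_g = rep(1, dims[4L]), norm_b = numeric(dims[4L])
    )
    p
  })
}

# images: (N, H, W, 3) array in [0,1]. Returns final feature map
# (N, H/32, W/32, C4) plus the cache needed for the backward pass.
backboneForward <- function(params, cfg, images, train = FALSE) {
  if (length(dim(images)) != 4L) stop("images must be (N, H, W, 3)")
  d <- dim(images)
  N <- d[1L]
  if (d[2L] %% 32L != 0L || d[3L] %% 32L != 0L)
    stop("input height and width must be divisible by 32")
  pe <- patchEmbedForward(images, params$patch, cfg$patchSize)
  X <- pe$out; H <- pe$H; W <- pe$W
  cache <- list(pe = pe, stages = vector("list", 4L),
                merges = vector("list", 3L), N = N)
  nBlocksTotal <- sum(cfg$depths)
  blockNo <- 0L
  for (s in 1:4) {
    wsEff <- min(cfg$windowSize, H, W)
    blocks <- vector("list", cfg$depths[s])
    for (i in seq_len(cfg$depths[s])) {
      blockNo <- blockNo + 1L
      shift <- if (i %% 2L == 0L && (H > wsEff || W > wsEff))
        wsEff %/% 2L else 0L
      dropRate <- cfg$dropPath * (blockNo - 1L) / max(1L, nBlocksTotal - 1L)
      if (train && dropRate > 0 && runif(1L) < dropRate) {
        blocks[[i]] <- list(skipped = TRUE)
        next
      }
      bf <- attnForward(X, H, W, N, params$stages[[s]][[i]], wsEff, shift,
                        cfg$windowSize)
      X <- bf$out
      blocks[[i]] <- list(skipped = FALSE, cache = bf$cache,
                          ws = wsEff, shift = shift)
    }
    cache$stages[[s]] <- blocks
    if (s < 4L) {
      mf <- mergeForward(X, H, W, N, params$merges[[s]])
      cache$merges[[s]] <- mf$cache
      X <- mf$out; H <- mf$H; W <- mf$W
    }
  }
  ln <- lnForward(X, params$norm_g, params$norm_b)
  cache$finalLn <- ln
  feats <- ln$y
  dim(feats) <- c(N, H, W, ncol(ln$y))
  list(features = feats, H = H, W = W, cache = cache)
}

backboneBackward <- function(dfeat, params, cfg, cache) {
  d <- dim(dfeat)
  N <- cache$N
  dX <- dfeat
  dim(dX) <- c(prod(d[1:3]), d[4L])
  g <- list(stages = vector("list", 4L), merges = vector("list", 3L))
  lb <- lnBackward(dX, cache$finalLn$cache)
  g$norm_g <- lb$dg; g$norm_b <- lb$db
  dX <- lb$dx
  for (s in 4:1) {
    if (s < 4L) {
      mb <- mergeBackward(dX, params$merges[[s]], cache$merges[[s]])
      g$merges[[s]] <- mb$grads
      dX <- mb$dx
    }
    blocks <- cache$stages[[s]]
    gs <- vector("list", length(blocks))
    for (i in rev(seq_along(blocks))) {
      if (isTRUE(blocks[[i]]$skipped)) { gs[i] <- list(NULL); next }
      ab <- attnBackward(dX, params$stages[[s]][[i]], blocks[[i]]$cache)
      gs[[i]] <- ab$grads
      dX <- ab$dx
    }
    g$stages[[s]] <- gs
  }
  peb <- patchEmbedBackward(dX, params$patch, cache$pe$cache)
  g$patch <- peb$grads
  g
}

#' Build a standalone backbone
#'
#' Returns the initialised backbone together with a `forward(images)`
#' closure mapping an `(N, H, W, 3)` (or `(H, W, 3)`) image array to the
#' final `(N, H/32, W/32, C)` feature map. Deterministic given the seed.
#'
#' @param config from [backboneConfig()].
#' @param seed integer seed for weight initialisation.
#' @return list with `params`, `config` and `forward`.
#' @export
buildBackbone <- function(config = backboneConfig("nano"), seed = 1L) {
  params <- backboneInit(config, seed)
  forward <- function(images) {
    if (length(dim(images)) == 3L) dim(images) <- c(1L, dim(images))
    backboneForward(params, config, images)$features
  }
  list(params = params, config = config, forward = forward)
}

#' Count parameters in a parameter tree
#'
#' Trainable leaves are double-precision arrays; integer and logical fields
#' in a parameter tree are structural metadata and are not counted.
#'
#' @param x a parameter list (nested lists of numeric arrays), a backbone
#'   from [buildBackbone()], or a `GraderModel`.
#' @return total number of scalar parameters.
#' @export
countParams <- function(x) {
  if (is(x, "GraderModel")) x <- x@params
  if (is.list(x) && !is.null(x$params) && !is.null(x$forward)) x <- x$params
  n <- 0
  walk <- function(e) {
    if (is.double(e)) n <<- n + length(e)
    else if (is.list(e)) for (el in e) walk(el)
  }
  walk(x)
  n
}
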