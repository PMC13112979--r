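#' @import methods
#' @importFrom stats rnorm runif pnorm dnorm
#' @importFrom Rcpp evalCpp
#' @useDynLib RetiGrade, .registration = TRUE
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Used wherever determinism must not disturb the global
# stream (fixture encoder, per-string prompt embeddings).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

# Deterministic 31-bit polynomial hash of a character string.
stringHash <- function(s) {
  codes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

# Derive a child seed from a base seed and a stream tag, kept below 2^31.
childSeed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + stringHash(tag)) %% 2147483647)
}

#' Row-wise softmax
#'
#' Numerically stable softmax along the rows of a matrix (or over a vector).
#'
#' @param x numeric vector or matrix (softmax per row).
#' @return object of the same shape with non-negative entries; each row sums
#'   to one.
#' @export
softmaxRows <- function(x) {
  if (is.null(dim(x))) {
    z <- x - max(x)
    e <- exp(z)
    return(e / sum(e))
  }
  z <- x - apply(x, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Exact GELU and its derivative.
gelu <- function(x) x * pnorm(x)
geluGrad <- function(x) pnorm(x) + x * dnorm(x)

# L2-normalize a vector; an all-zero vector raises.
l2norm <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot L2-normalize a zero vector")
  v / n
}

checkFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(TRUE)
}

#' Bilinear image resize
#'
#' Resizes an `(H, W, C)` array to a new height and width by bilinear
#' interpolation.
#'
#' @param img `(H, W, C)` numeric array.
#' @param newH,newW target dimensions.
#' @return resized `(newH, newW, C)` array.
#' @export
resizeBilinear <- function(img, newH, newW) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  if (H == newH && W == newW) return(img)
  ys <- (seq_len(newH) - 0.5) * H / newH + 0.5
  xs <- (seq_len(newW) - 0.5) * W / newW + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xs), 1L), W); x1 <- pmin(x0 + 1L, W)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(newH, newW, C))
  WY <- matrix(wy, newH, newW)
  WX <- matrix(wx, newH, newW, byrow = TRUE)
  for (c in seq_len(C)) {
    ch <- img[, , c]
    a <- ch[y0, x0]; b <- ch[y0, x1]; cc <- ch[y1, x0]; dd <- ch[y1, x1]
    out[, , c] <- (1 - WY) * ((1 - WX) * a + WX * b) +
      WY * ((1 - WX) * cc + WX * dd)
  }
  out
}
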