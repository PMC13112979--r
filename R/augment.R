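# Training-time augmentation: flips, small rotations with reflect padding,
# and colour jitter. All randomness comes from the caller's RNG stream, so
# a fixed seed reproduces the augmented stream exactly.

#' Flip an image
#'
#' @param img `(H, W, C)` array.
#' @param axis `"horizontal"` (mirror left-right) or `"vertical"`.
#' @return flipped array; applying the same flip twice is the identity.
#' @export
flipImage <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
  else img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]
}

reflectIndex <- function(i, n) {
  # fold arbitrary indices into [1, n] by mirror reflection
  p <- (i - 1) %% (2 * n)
  p <- ifelse(p < 0, p + 2 * n, p)
  ifelse(p < n, p + 1, 2 * n - p)
}

#' Rotate an image about its centre
#'
#' Bilinear resampling with reflect padding at the borders.
#'
#' @param img `(H, W, C)` array in [0,1].
#' @param angle rotation in degrees (counter-clockwise).
#' @return rotated array of the same shape.
#' @export
rotateImage <- function(img, angle) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  if (abs(angle) < 1e-9) return(img)
  th <- -angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- cy + yy * cos(th) - xx * sin(th)
  sx <- cx + yy * sin(th) + xx * cos(th)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- reflectIndex(y0, H); iy1 <- reflectIndex(y0 + 1, H)
  ix0 <- reflectIndex(x0, W); ix1 <- reflectIndex(x0 + 1, W)
  # linear indices shared across channels
  l00 <- c(iy0 + (ix0 - 1) * H); l01 <- c(iy0 + (ix1 - 1) * H)
  l10 <- c(iy1 + (ix0 - 1) * H); l11 <- c(iy1 + (ix1 - 1) * H)
  w00 <- c((1 - fy) * (1 - fx)); w01 <- c((1 - fy) * fx)
  w10 <- c(fy * (1 - fx)); w11 <- c(fy * fx)
  out <- array(0, d)
  for (c in seq_len(d[3L])) {
    ch <- c(img[, , c])
    out[, , c] <- w00 * ch[l00] + w01 * ch[l01] + w10 * ch[l10] +
      w11 * ch[l11]
  }
  out
}

#' Default augmentation flags
#'
#' Independent 0.5-probability horizontal and vertical flips, rotation
#' uniform in +/- `maxAngle` degrees, and brightness/contrast/saturation
#' jitter of +/- `jitterAmount`.
#'
#' @param hflip,vflip,rotate,jitter logicals enabling each transform.
#' @param maxAngle rotation range in degrees (default 15).
#' @param jitterAmount relative jitter magnitude (default 0.1).
#' @return flag list for [augmentImage()].
#' @export
augmentFlags <- function(hflip = TRUE, vflip = TRUE, rotate = TRUE,
                         jitter = TRUE, maxAngle = 15, jitterAmount = 0.1) {
  list(hflip = hflip, vflip = vflip, rotate = rotate, jitter = jitter,
       maxAngle = maxAngle, jitterAmount = jitterAmount)
}

#' Randomly augment an image
#'
#' Applies the transforms enabled in `flags`, drawing from the current RNG
#' stream; with all flags off this is the identity. The label is unchanged
#' by construction. Output is clipped to [0,1] and keeps the input shape.
#'
#' @param img `(H, W, 3)` array in [0,1].
#' @param flags from [augmentFlags()].
#' @return augmented array.
#' @export
augmentImage <- function(img, flags = augmentFlags()) {
  if (isTRUE(flags$hflip) && runif(1L) < 0.5)
    img <- flipImage(img, "horizontal")
  if (isTRUE(flags$vflip) && runif(1L) < 0.5)
    img <- flipImage(img, "vertical")
  if (isTRUE(flags$rotate))
    img <- rotateImage(img, runif(1L, -flags$maxAngle, flags$maxAngle))
  if (isTRUE(flags$jitter)) {
    a <- flags$jitterAmount
    img <- img * (1 + runif(1L, -a, a))                       # brightness
    m <- mean(img)
    img <- (img - m) * (1 + runif(1L, -a, a)) + m             # contrast
    gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
    fs <- 1 + runif(1L, -a, a)                                # saturation
    for (c in 1:3) img[, , c] <- gray + (img[, , c] - gray) * fs
  }
  pmin(pmax(img, 0), 1)
}
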