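# Synthetic fundus-like image generation with ordinal lesion structure:
# circular field of view, reddish radial base, bright optic disc, dark
# curvilinear vessels, and grade-dependent lesions (dark microaneurysm-like
# dots, bright exudate-like blobs). The lesion encoding is a stand-in with
# no claim of clinical realism; it provides a monotone, multi-scale visual
# signal so the grading pipeline is exercisable without downloads.

#' APTOS-like class proportions
#'
#' Grade proportions of the APTOS 2019 training set
#' (counts 1805/370/999/193/295 of 3662): heavy majority of healthy eyes,
#' scarce severe grades.
#'
#' @return length-5 proportion vector summing to 1.
#' @export
aptosProportions <- function() {
  counts <- c(1805, 370, 999, 193, 295)
  counts / sum(counts)
}

#' Per-grade lesion model
#'
#' Count and size ranges for the two lesion primitives, all monotone
#' non-decreasing in grade and zero at grade 0. The `"easy"` profile has
#' well-separated count ranges and is cleanly learnable; the `"hard"`
#' profile overlaps adjacent ranges so neighbouring grades are genuinely
#' confusable. Radii are in pixels at a 64-px image and scale linearly with
#' image size.
#'
#' @param profile `"easy"` or `"hard"`.
#' @return list of 5 per-grade parameter lists (`dots`, `blobs`, `dotR`,
#'   `blobR` ranges).
#' @export
lesionModel <- function(profile = c("easy", "hard")) {
  profile <- match.arg(profile)
  mk <- function(dots, blobs, dotR, blobR)
    list(dots = dots, blobs = blobs, dotR = dotR, blobR = blobR)
  if (profile == "easy")
    list(mk(c(0, 0), c(0, 0), c(2.0, 3.0), c(3.5, 5.0)),
         mk(c(3, 5), c(0, 1), c(2.0, 3.0), c(3.5, 5.0)),
         mk(c(8, 12), c(1, 2), c(2.2, 3.2), c(4.0, 5.5)),
         mk(c(15, 20), c(3, 4), c(2.4, 3.4), c(4.5, 6.0)),
         mk(c(25, 32), c(5, 7), c(2.6, 3.6), c(5.0, 6.5)))
  else
    list(mk(c(0, 0), c(0, 0), c(2.0, 3.0), c(3.5, 5.0)),
         mk(c(1, 6), c(0, 1), c(2.0, 3.0), c(3.5, 5.0)),
         mk(c(4, 12), c(0, 2), c(2.1, 3.1), c(3.8, 5.2)),
         mk(c(8, 18), c(1, 3), c(2.2, 3.2), c(4.0, 5.5)),
         mk(c(14, 26), c(2, 5), c(2.3, 3.3), c(4.2, 5.8)))
}

#' Synthetic dataset specification
#'
#' @param nImages number of images.
#' @param imageSize square side in pixels (>= 32, default 64).
#' @param profile lesion/noise difficulty, `"easy"` or `"hard"`.
#' @param classProportions length-5 proportions (default APTOS-like).
#' @param noiseSd Gaussian pixel noise; defaults to 0.02 (easy) / 0.12
#'   (hard).
#' @param seed integer generator seed.
#' @return a `FundusSpec`.
#' @export
fundusSpec <- function(nImages, imageSize = 64L,
                       profile = c("easy", "hard"),
                       classProportions = aptosProportions(),
                       noiseSd = NULL, seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(noiseSd)) noiseSd <- if (profile == "easy") 0.02 else 0.12
  new("FundusSpec", nImages = as.integer(nImages),
      imageSize = as.integer(imageSize),
      classProportions = classProportions,
      lesionModel = lesionModel(profile),
      noiseSd = noiseSd, seed = as.integer(seed))
}

# Largest-remainder apportionment of n among proportions (exact counts).
apportionCounts <- function(n, props) {
  quota <- n * props / sum(props)
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

# Paint soft disks onto 3-channel image channels. centers: matrix (n, 2)
# of (y, x); returns updated image and number of painted pixels.
paintDisks <- function(img, centers, radii, colour, alpha = 0.9) {
  s <- dim(img)[1L]
  painted <- 0L
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    cy <- centers[i, 1L]; cx <- centers[i, 2L]
    yr <- max(1L, floor(cy - r)):min(s, ceiling(cy + r))
    xr <- max(1L, floor(cx - r)):min(s, ceiling(cx + r))
    if (!length(yr) || !length(xr)) next
    dy <- outer(yr - cy, rep(1, length(xr)))
    dx <- outer(rep(1, length(yr)), xr - cx)
    w <- pmax(0, 1 - (dy^2 + dx^2) / r^2)  # soft radial falloff
    sel <- w > 0
    painted <- painted + sum(sel)
    for (ch in 1:3) {
      patch <- img[yr, xr, ch]
      img[yr, xr, ch] <- patch * (1 - alpha * w) + colour[ch] * alpha * w
    }
  }
  list(img = img, painted = painted)
}

#' Render one synthetic fundus image
#'
#' Deterministic given `seed`: a circular field of view on black, a reddish
#' radial-gradient base, a bright optic-disc ellipse, 2-4 dark curvilinear
#' vessels, grade-dependent lesions drawn from the lesion model, and
#' Gaussian pixel noise, clipped to [0,1]. Lesion counts are drawn by
#' inverse-CDF from the per-grade ranges, so with a common seed the counts
#' are monotone in grade.
#'
#' @param grade integer severity grade in 0..4.
#' @param size square image side in pixels (>= 32).
#' @param seed integer seed for this image.
#' @param model per-grade lesion model from [lesionModel()].
#' @param noiseSd Gaussian pixel-noise standard deviation.
#' @return `(size, size, 3)` array in [0,1] with attribute `drawLog`, a
#'   list recording dot/blob counts and painted lesion pixels.
#' @export
renderFundus <- function(grade, size = 64L, seed = 1L,
                         model = lesionModel("easy"), noiseSd = 0.02) {
  size <- as.integer(size)
  if (size < 32L) stop("size must be at least 32")
  if (grade < 0L || grade > 4L) stop("grade must be in 0..4")
  gm <- model[[grade + 1L]]
  sc <- size / 64
  withSeed(seed, {
    # lesion counts first (inverse-CDF draw; monotone in grade for a
    # common seed because the ranges are monotone)
    u1 <- runif(1L); u2 <- runif(1L)
    nDots <- gm$dots[1L] + floor(u1 * (gm$dots[2L] - gm$dots[1L] + 1))
    nBlobs <- gm$blobs[1L] + floor(u2 * (gm$blobs[2L] - gm$blobs[1L] + 1))
    nDots <- min(nDots, gm$dots[2L]); nBlobs <- min(nBlobs, gm$blobs[2L])
    ctr <- (size + 1) / 2
    R <- 0.48 * size
    yy <- matrix(seq_len(size), size, size)
    xx <- t(yy)
    rr <- sqrt((yy - ctr)^2 + (xx - ctr)^2)
    fov <- rr <= R
    shade <- pmax(0, 1 - 0.55 * (rr / R)^2)
    img <- array(0, c(size, size, 3L))
    img[, , 1L] <- 0.72 * shade
    img[, , 2L] <- 0.40 * shade
    img[, , 3L] <- 0.22 * shade
    # optic disc: bright ellipse near the temporal (right) margin, as in
    # a right-eye macula-centred photograph; jittered a little
    th <- runif(1L, -pi / 12, pi / 12)
    dc <- c(ctr + 0.55 * R * sin(th), ctr + 0.55 * R * cos(th))
    da <- 0.115 * size; db <- 0.09 * size
    dd <- ((yy - dc[1L]) / db)^2 + ((xx - dc[2L]) / da)^2
    dw <- pmax(0, 1 - dd)
    for (ch in 1:3) {
      col <- c(0.97, 0.88, 0.55)[ch]
      img[, , ch] <- img[, , ch] * (1 - 0.95 * dw) + col * 0.95 * dw
    }
    # vessels: dark random-walk strokes fanning out from the disc at
    # roughly regular angles (arcade-like), 3-4 of them
    nv <- sample(3:4, 1L)
    for (v in seq_len(nv)) {
      ang <- 2 * pi * v / nv + runif(1L, -0.4, 0.4)
      steps <- as.integer(1.4 * size)
      turn <- cumsum(rnorm(steps, 0, 0.10))
      py <- dc[1L] + cumsum(sin(ang + turn))
      px <- dc[2L] + cumsum(cos(ang + turn))
      keep <- py >= 2 & py <= size - 1 & px >= 2 & px <= size - 1
      py <- py[keep]; px <- px[keep]
      if (!length(py)) next
      wv <- max(1, round(sc))
      for (dy in -wv:wv) for (dx in -wv:wv) {
        if (dy^2 + dx^2 > wv^2 + 0.5) next
        idx <- cbind(round(py) + dy, round(px) + dx)
        ok <- idx[, 1L] >= 1 & idx[, 1L] <= size &
              idx[, 2L] >= 1 & idx[, 2L] <= size
        idx <- idx[ok, , drop = FALSE]
        img[cbind(idx, 1L)] <- 0.38
        img[cbind(idx, 2L)] <- 0.12
        img[cbind(idx, 3L)] <- 0.08
      }
    }
    lesionPixels <- 0L
    # dark dots (microaneurysm-like)
    if (nDots > 0) {
      ang <- runif(nDots, 0, 2 * pi)
      rad <- sqrt(runif(nDots)) * 0.85 * R
      centers <- cbind(ctr + rad * sin(ang), ctr + rad * cos(ang))
      radii <- runif(nDots, gm$dotR[1L], gm$dotR[2L]) * sc
      pd <- paintDisks(img, centers, radii, c(0.22, 0.05, 0.04))
      img <- pd$img
      lesionPixels <- lesionPixels + pd$painted
    }
    # bright blobs (exudate-like)
    if (nBlobs > 0) {
      ang <- runif(nBlobs, 0, 2 * pi)
      rad <- sqrt(runif(nBlobs)) * 0.8 * R
      centers <- cbind(ctr + rad * sin(ang), ctr + rad * cos(ang))
      radii <- runif(nBlobs, gm$blobR[1L], gm$blobR[2L]) * sc
      pb <- paintDisks(img, centers, radii, c(0.98, 0.95, 0.62))
      img <- pb$img
      lesionPixels <- lesionPixels + pb$painted
    }
    img <- img + array(rnorm(length(img), 0, noiseSd), dim(img))
    img <- pmin(pmax(img, 0), 1)
    img <- img * array(rep(fov, 3L), dim(img))
    attr(img, "drawLog") <- list(dots = as.integer(nDots),
                                 blobs = as.integer(nBlobs),
                                 lesionPixels = as.integer(lesionPixels))
    img
  })
}

#' Generate a labelled synthetic dataset
#'
#' Grades are assigned by largest-remainder apportionment of the class
#' proportions (exact deterministic counts, not multinomial draws). With an
#' output directory, PNG images plus a `labels.csv` in the APTOS dialect
#' (`id_code,diagnosis`) are written; otherwise images are kept in memory
#' on the manifest. Rerunning with the same spec reproduces the dataset
#' bit for bit.
#'
#' @param spec a `FundusSpec`.
#' @param outDir optional output directory (created if missing).
#' @return a `FundusManifest`.
#' @export
generateDataset <- function(spec, outDir = NULL) {
  counts <- apportionCounts(spec@nImages, spec@classProportions)
  grades <- rep(0:4, counts)
  ids <- sprintf("syn_%05d", seq_along(grades))
  records <- data.frame(id_code = ids, diagnosis = as.integer(grades),
                        stringsAsFactors = FALSE)
  images <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
  } else {
    images <- vector("list", length(ids))
    names(images) <- ids
  }
  for (i in seq_along(ids)) {
    img <- renderFundus(grades[i], spec@imageSize,
                        seed = childSeed(spec@seed, paste0("img", i)),
                        model = spec@lesionModel, noiseSd = spec@noiseSd)
    attr(img, "drawLog") <- NULL
    if (is.null(outDir)) images[[i]] <- img
    else png::writePNG(img, file.path(outDir, paste0(ids[i], ".png")))
  }
  if (!is.null(outDir))
    write.csv(records, file.path(outDir, "labels.csv"), row.names = FALSE,
              quote = FALSE)
  new("FundusManifest", records = records, images = images,
      dir = if (is.null(outDir)) "" else outDir, split = "none")
}

#' Load a manifest from a directory with labels.csv
#'
#' @param dir directory holding `labels.csv` (`id_code,diagnosis`) and the
#'   referenced PNG images.
#' @return a `FundusManifest`.
#' @export
loadManifest <- function(dir) {
  path <- file.path(dir, "labels.csv")
  if (!file.exists(path)) stop("no labels.csv in ", dir)
  records <- read.csv(path, stringsAsFactors = FALSE)
  new("FundusManifest", records = records, images = NULL, dir = dir,
      split = "none")
}

# Fetch image i of a manifest as an (H, W, 3) array in [0,1].
getImage <- function(manifest, i) {
  id <- manifest@records$id_code[i]
  if (!is.null(manifest@images)) return(manifest@images[[id]])
  img <- png::readPNG(file.path(manifest@dir, paste0(id, ".png")))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3]
  img
}

#' Stratified train/test split
#'
#' Splits per class at `trainFrac` (rounding toward train), shuffling
#' within class by the seed. The two manifests are disjoint and exhaustive.
#' A class with a single sample goes to train with a warning.
#'
#' @param manifest a `FundusManifest`.
#' @param trainFrac training fraction (default 0.8).
#' @param seed shuffle seed.
#' @return list with elements `train` and `test` (`FundusManifest`s).
#' @export
stratifiedSplit <- function(manifest, trainFrac = 0.8, seed = 1L) {
  r <- manifest@records
  trainIdx <- integer()
  withSeed(childSeed(seed, "split"), {
    for (g in sort(unique(r$diagnosis))) {
      idx <- which(r$diagnosis == g)
      if (length(idx) == 1L) {
        warning(sprintf("class %d has a single sample; assigned to train", g))
        trainIdx <- c(trainIdx, idx)
        next
      }
      idx <- sample(idx)
      nTrain <- ceiling(trainFrac * length(idx))
      trainIdx <- c(trainIdx, idx[seq_len(nTrain)])
    }
  })
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_len(nrow(r)), trainIdx)
  sub <- function(idx, tag) {
    new("FundusManifest",
        records = r[idx, , drop = FALSE],
        images = if (is.null(manifest@images)) NULL
                 else manifest@images[r$id_code[idx]],
        dir = manifest@dir, split = tag)
  }
  list(train = sub(trainIdx, "train"), test = sub(testIdx, "test"))
}
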