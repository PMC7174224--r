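#' Preprocessing parameters
#'
#' Constants controlling foreground segmentation of a bulk-saffron image:
#' a Gaussian low-pass filter, a strict grayscale intensity threshold, an
#' area filter on connected components, and a morphological opening with a
#' discrete disk. The defaults are the constants of the reference protocol
#' (threshold 20, 3000-pixel component filter, 5-pixel structuring radius)
#' which assume full-resolution camera images; desk-scale synthetic scenes
#' use [scaledPreprocessParams()].
#'
#' @param smoothingKernelSize odd positive integer, Gaussian kernel side.
#' @param smoothingSigma Gaussian standard deviation in pixels.
#' @param intensityThreshold keep pixels with grayscale intensity strictly
#'   greater than this value.
#' @param minComponentArea connected components with fewer pixels are removed.
#' @param structuringRadius radius of the disk \eqn{\{(x,y): x^2+y^2 \le r^2\}}
#'   used for the opening.
#' @return A named list of validated parameters.
#' @export
#' @examples
#' preprocessParams()
preprocessParams <- function(smoothingKernelSize = 5L, smoothingSigma = 1.0,
                             intensityThreshold = 20L, minComponentArea = 3000L,
                             structuringRadius = 5L) {
  if (smoothingKernelSize %% 2L == 0L || smoothingKernelSize < 1L)
    stop("smoothingKernelSize must be an odd positive integer")
  stopifnot(smoothingSigma > 0, minComponentArea > 0, structuringRadius > 0)
  list(smoothingKernelSize = as.integer(smoothingKernelSize),
       smoothingSigma = smoothingSigma,
       intensityThreshold = as.integer(intensityThreshold),
       minComponentArea = as.integer(minComponentArea),
       structuringRadius = as.integer(structuringRadius))
}

#' @rdname preprocessParams
#' @details \code{scaledPreprocessParams} rescales the pixel-count constants
#'   for a 512 x 512 synthetic canvas (the reference constants were chosen
#'   for 3024 x 4032 photographs): component filter 60 px, structuring
#'   radius 2.
#' @export
scaledPreprocessParams <- function(smoothingKernelSize = 5L, smoothingSigma = 1.0,
                                   intensityThreshold = 20L,
                                   minComponentArea = 60L, structuringRadius = 2L) {
  preprocessParams(smoothingKernelSize, smoothingSigma, intensityThreshold,
                   minComponentArea, structuringRadius)
}

#' Grayscale intensity (luma) of an RGB image
#'
#' Conventional Rec. 601 luma, \eqn{0.299 R + 0.587 G + 0.114 B}, rounded to
#' integers. This single definition is the "intensity" used by the foreground
#' threshold and the grayscale input of all texture features.
#'
#' @param image H x W x 3 array in 0..255, or an H x W matrix (returned
#'   unchanged apart from rounding).
#' @return H x W integer-valued matrix in 0..255.
#' @export
#' @examples
#' toGray(array(c(255, 0, 0), dim = c(1, 1, 3)))  # pure red -> 76
toGray <- function(image) {
  if (is.matrix(image)) return(round(image))
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Low-pass smoothing of an RGB image
#'
#' Channel-wise convolution with a normalized Gaussian kernel (replicated
#' borders). Constant images are fixed points; high-spatial-frequency energy
#' is strictly reduced for any non-constant input.
#'
#' @param image H x W x 3 array in 0..255.
#' @param params a [preprocessParams()] list.
#' @return Smoothed H x W x 3 numeric array in 0..255.
#' @export
smoothImage <- function(image, params = preprocessParams()) {
  k <- params$smoothingKernelSize
  if (k %% 2L == 0L) stop("smoothing kernel size must be odd")
  half <- (k - 1L) / 2L
  g <- stats::dnorm(-half:half, sd = params$smoothingSigma)
  g <- g / sum(g)
  out <- array(0, dim = dim(image))
  for (ch in 1:3)
    out[, , ch] <- .sepConvolve(image[, , ch] * 1.0, g)
  out[] <- pmin(255, pmax(0, as.vector(out)))
  out
}

# separable convolution with a symmetric 1-D kernel, replicated borders;
# the Gaussian kernel factorizes, so two 1-D passes equal the 2-D filter
.sepConvolve <- function(m, g) {
  half <- (length(g) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  ri <- c(rep(1L, half), 1:H, rep(H, half))
  ci <- c(rep(1L, half), 1:W, rep(W, half))
  p <- m[ri, , drop = FALSE]
  acc <- matrix(0, H, W)
  for (s in seq_along(g))
    acc <- acc + g[s] * p[s:(s + H - 1L), , drop = FALSE]
  p <- acc[, ci, drop = FALSE]
  acc <- matrix(0, H, W)
  for (s in seq_along(g))
    acc <- acc + g[s] * p[, s:(s + W - 1L), drop = FALSE]
  acc
}

#' Foreground mask by strict intensity threshold
#'
#' A pixel belongs to the foreground iff its grayscale intensity is strictly
#' greater than the threshold (default 20); a uniform image at the threshold
#' value yields an all-false mask.
#'
#' @inheritParams smoothImage
#' @return H x W logical matrix.
#' @export
foregroundMask <- function(image, params = preprocessParams()) {
  toGray(image) > params$intensityThreshold
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged through a connected-components pass on the label graph
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs))
    memb <- igraph::components(g)$membership
    lab[] <- c(0L, memb)[lab + 1L]
  }
  lab
}

#' Remove small connected components
#'
#' Deletes every 8-connected foreground component with strictly fewer than
#' \code{minComponentArea} pixels; a component of exactly that area is kept.
#' No foreground pixels are ever created.
#'
#' @param mask H x W logical matrix.
#' @param params a [preprocessParams()] list.
#' @return H x W logical matrix.
#' @export
removeSmallComponents <- function(mask, params = preprocessParams()) {
  if (!any(mask)) return(mask)
  lab <- .label8(mask)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= params$minComponentArea])
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out & mask
}

# discrete disk structuring element as 0/1 matrix
.diskBrush <- function(r) {
  d <- -r:r
  (outer(d^2, d^2, "+") <= r^2) * 1
}

#' Morphological opening of the foreground mask
#'
#' Erosion followed by dilation with the discrete disk
#' \eqn{\{(x,y): x^2 + y^2 \le r^2\}}. The mask is zero-padded before each
#' operation so the image border behaves as background (textbook opening).
#' Objects thinner than the disk diameter are removed.
#'
#' @inheritParams removeSmallComponents
#' @return H x W logical matrix.
#' @export
morphRefine <- function(mask, params = preprocessParams()) {
  r <- params$structuringRadius
  brush <- .diskBrush(r)
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2 * r, W + 2 * r)
  pad[(r + 1):(r + H), (r + 1):(r + W)] <- mask * 1
  opened <- EBImage::dilate(EBImage::erode(pad, brush), brush)
  opened[(r + 1):(r + H), (r + 1):(r + W)] > 0
}

#' Tight crop window of a binary mask
#'
#' The bounding box of the true pixels, as 0-based, half-open intervals
#' \code{[rowMin, rowMax) x [colMin, colMax)}. Cropping and recomputing the
#' window is idempotent.
#'
#' @param mask H x W logical matrix with at least one true pixel.
#' @return A list \code{(rowMin, rowMax, colMin, colMax)}.
#' @export
#' @examples
#' m <- matrix(FALSE, 60, 100); m[11:50, 21:80] <- TRUE
#' unlist(cropWindow(m))  # 10 50 20 80
cropWindow <- function(mask) {
  if (!any(mask)) stop("no saffron found: foreground mask is empty")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  list(rowMin = min(rows) - 1L, rowMax = max(rows),
       colMin = min(cols) - 1L, colMax = max(cols))
}

#' Apply a crop window to an image or mask
#'
#' @param x H x W matrix or H x W x C array.
#' @param window a [cropWindow()] list.
#' @return The cropped object.
#' @export
applyCrop <- function(x, window) {
  ri <- (window$rowMin + 1L):window$rowMax
  ci <- (window$colMin + 1L):window$colMax
  if (is.matrix(x)) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Full preprocessing pipeline
#'
#' Smooth, threshold the foreground, remove small components, open with a
#' disk, and crop image and mask to the tight bounding box of the refined
#' foreground.
#'
#' @param image H x W x 3 array in 0..255.
#' @param params a [preprocessParams()] list.
#' @return list with \code{image} (cropped smoothed image), \code{mask}
#'   (cropped final foreground), \code{window} (the [cropWindow()]), and
#'   \code{qc} (named counts: foreground pixels at each stage).
#' @export
preprocessImage <- function(image, params = preprocessParams()) {
  sm <- smoothImage(image, params)
  m1 <- foregroundMask(sm, params)
  m2 <- removeSmallComponents(m1, params)
  m3 <- morphRefine(m2, params)
  if (!any(m3)) stop("no saffron found: empty foreground after preprocessing")
  win <- cropWindow(m3)
  list(image = applyCrop(sm, win),
       mask = applyCrop(m3, win),
       window = win,
       qc = c(thresholded = sum(m1), filtered = sum(m2), final = sum(m3)))
}
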