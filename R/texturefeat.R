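#' Texture analysis parameters
#'
#' Controls for the texture feature block: GLCM quantization levels,
#' offsets (distances x angles), local filter window sizes, histogram bin
#' counts, and the number of bins used by the Table-style histogram
#' statistics. The default registry totals exactly 99 features.
#'
#' @param glcmLevels gray levels for GLCM quantization.
#' @param glcmDistances integer offsets in pixels.
#' @param glcmAngles offset angles in degrees (subset of 0, 45, 90, 135).
#' @param entropyWindow odd window side of the local entropy filter.
#' @param entropyLevels gray levels of the local entropy histogram.
#' @param stdWindow odd window side of the local standard-deviation filter.
#' @param histogramBins bins of the grayscale histogram block.
#' @param table1Levels bins used by [table1Stats()] on value collections.
#' @return A named list of validated parameters.
#' @export
#' @examples
#' length(textureFeatureNames(textureParams()))  # 99
textureParams <- function(glcmLevels = 8L, glcmDistances = c(1L, 2L),
                          glcmAngles = c(0, 45, 90, 135),
                          entropyWindow = 9L, entropyLevels = 8L,
                          stdWindow = 3L, histogramBins = 25L,
                          table1Levels = 64L) {
  stopifnot(glcmLevels >= 2, all(glcmDistances >= 1),
            all(glcmAngles %in% c(0, 45, 90, 135)),
            entropyWindow %% 2 == 1, stdWindow %% 2 == 1,
            histogramBins >= 1, table1Levels >= 1)
  list(glcmLevels = as.integer(glcmLevels),
       glcmDistances = as.integer(glcmDistances),
       glcmAngles = as.numeric(glcmAngles),
       entropyWindow = as.integer(entropyWindow),
       entropyLevels = as.integer(entropyLevels),
       stdWindow = as.integer(stdWindow),
       histogramBins = as.integer(histogramBins),
       table1Levels = as.integer(table1Levels))
}

# uniform quantization of [0,255] into `levels` bins -> integer codes 1..levels
.quantize <- function(gray, levels) {
  q <- floor(gray * levels / 256) + 1L
  q[q > levels] <- levels
  q[q < 1L] <- 1L
  q
}

# symmetric (mirror) padding by h pixels on each side
.padSym <- function(m, h) {
  if (h == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  m[c(h:1, 1:H, H:(H - h + 1L)), c(h:1, 1:W, W:(W - h + 1L)), drop = FALSE]
}

# column-wise cumulative sums without apply(): one global cumsum, then the
# per-column offsets are subtracted
.colCumsum <- function(m) {
  cs <- matrix(cumsum(m), nrow(m), ncol(m))
  tot <- cs[nrow(m), ]
  sweep(cs, 2, c(0, tot[-length(tot)]), "-")
}

# w x w box sums at every pixel via a zero-padded integral image,
# symmetric boundary padding
.boxSum <- function(m, w) {
  h <- (w - 1L) %/% 2L
  p <- .padSym(m, h)
  S <- t(.colCumsum(t(.colCumsum(p))))
  S <- rbind(0, cbind(0, S))
  H <- nrow(m); W <- ncol(m)
  S[(1:H) + w, (1:W) + w, drop = FALSE] - S[1:H, (1:W) + w, drop = FALSE] -
    S[(1:H) + w, 1:W, drop = FALSE] + S[1:H, 1:W, drop = FALSE]
}

# angle (degrees) -> (row, col) pixel offset at given distance
.angleOffset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported GLCM angle: ", angle))
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs (pixel, pixel + offset) whose members both lie in the mask,
#' after uniform quantization of [0, 255] into \code{levels} bins. The count
#' matrix is symmetrized (each pair contributes in both directions) and
#' normalized to sum to one.
#'
#' @param gray H x W matrix in 0..255.
#' @param distance offset length in pixels.
#' @param angle offset angle in degrees (0, 45, 90, 135).
#' @param levels number of quantized gray levels (>= 2).
#' @param mask optional H x W logical mask; both pixels of a pair must lie
#'   inside it.
#' @return A [Glcm] object.
#' @export
#' @examples
#' g <- glcm(matrix(c(0, 0, 255, 255), 2, 2, byrow = TRUE), angle = 0, levels = 2)
#' glcmMatrix(g)   # 0.5 on both diagonal cells
glcm <- function(gray, distance = 1L, angle = 0, levels = 8L, mask = NULL) {
  stopifnot(levels >= 2)
  H <- nrow(gray); W <- ncol(gray)
  off <- .angleOffset(angle, as.integer(distance))
  if (abs(off[1]) >= H || abs(off[2]) >= W) stop("offset exceeds image size")
  q <- .quantize(gray, levels)
  r1 <- max(1L, 1L - off[1]):min(H, H - off[1])
  c1 <- max(1L, 1L - off[2]):min(W, W - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- rep(TRUE, length(a))
  if (!is.null(mask)) {
    ma <- mask[r1, c1, drop = FALSE]
    mb <- mask[r1 + off[1], c1 + off[2], drop = FALSE]
    keep <- as.vector(ma & mb)
  }
  if (!any(keep)) stop("no valid pixel pair for this offset and mask")
  counts <- matrix(tabulate((as.vector(a)[keep] - 1L) * levels +
                              as.vector(b)[keep], nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)
  new("Glcm", p = counts / sum(counts), levels = as.integer(levels),
      distance = as.integer(distance), angle = as.numeric(angle))
}

#' The four co-occurrence statistics
#'
#' Contrast \eqn{\sum (i-j)^2 p(i,j)}, correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)}, energy
#' \eqn{\sum p(i,j)^2} and homogeneity \eqn{\sum p(i,j)/(1+|i-j|)}. For a
#' degenerate matrix with zero marginal deviation the correlation is defined
#' as 0 (with a warning).
#'
#' @param g a [Glcm] object (or a plain probability matrix).
#' @return Named numeric vector \code{(contrast, correlation, energy,
#'   homogeneity)}.
#' @export
glcmStats <- function(g) {
  p <- if (is.matrix(g)) g else g@p
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mui <- sum(seq_len(L) * pi_); muj <- sum(seq_len(L) * pj_)
  sdi <- sqrt(sum((seq_len(L) - mui)^2 * pi_))
  sdj <- sqrt(sum((seq_len(L) - muj)^2 * pj_))
  corr <- if (sdi == 0 || sdj == 0) {
    warning("degenerate co-occurrence matrix: correlation undefined, using 0")
    0
  } else sum((i - mui) * (j - muj) * p) / (sdi * sdj)
  c(contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))))
}

#' Local entropy filter
#'
#' Per-pixel Shannon entropy (bits) of the quantized gray-level histogram in
#' a square window, with symmetric boundary padding. Bounded above by
#' \code{log2(levels)}.
#'
#' @param gray H x W matrix in 0..255.
#' @param window odd window side (default 9).
#' @param levels histogram levels (default 8).
#' @return H x W numeric matrix of entropies.
#' @export
localEntropy <- function(gray, window = 9L, levels = 8L) {
  if (window %% 2L == 0L) stop("window must be odd")
  q <- .quantize(gray, levels)
  n <- window^2
  ent <- matrix(0, nrow(gray), ncol(gray))
  for (l in seq_len(levels)) {
    cnt <- .boxSum((q == l) * 1, window)
    p <- cnt / n
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent
}

#' Local standard-deviation filter
#'
#' Per-pixel population standard deviation over a square window (symmetric
#' boundary padding): a window holding equal numbers of 0 and 255 yields
#' 127.5.
#'
#' @param gray H x W matrix in 0..255.
#' @param window odd window side (default 3).
#' @return H x W nonnegative numeric matrix.
#' @export
localStd <- function(gray, window = 3L) {
  if (window %% 2L == 0L) stop("window must be odd")
  n <- window^2
  ex <- .boxSum(gray, window) / n
  v <- .boxSum(gray^2, window) / n - ex^2
  v[v < 0] <- 0
  sqrt(v)
}

# clockwise 3x3 neighbor offsets from the top-left, weighted 2^0 .. 2^7
.LBP_OFFSETS <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                      c(1, 1), c(1, 0), c(1, -1), c(0, -1))

#' Basic 3 x 3 local binary patterns
#'
#' Each interior pixel is coded by thresholding its 8 neighbors at the center
#' value (neighbor >= center counts as 1, so ties count) and summing the
#' weights \eqn{2^0..2^7} assigned clockwise from the top-left neighbor.
#' Border pixels are excluded (coded \code{NA}). Codes are invariant to
#' adding a constant to every pixel.
#'
#' @param gray H x W matrix (H, W >= 3).
#' @return H x W integer matrix of codes 0..255, \code{NA} on the border.
#' @export
lbp <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  stopifnot(H >= 3, W >= 3)
  center <- gray[2:(H - 1), 2:(W - 1), drop = FALSE]
  code <- matrix(0L, H - 2, W - 2)
  for (k in 1:8) {
    o <- .LBP_OFFSETS[k, ]
    nb <- gray[(2 + o[1]):(H - 1 + o[1]), (2 + o[2]):(W - 1 + o[2]), drop = FALSE]
    code <- code + as.integer(2^(k - 1)) * (nb >= center)
  }
  out <- matrix(NA_integer_, H, W)
  out[2:(H - 1), 2:(W - 1)] <- code
  out
}

# map of 8-bit LBP codes to the 10 rotation-invariant-uniform bins:
# uniform patterns (<= 2 circular transitions) -> number of set bits (0..8),
# all others -> 9
.lbpRiu2Map <- function() {
  vapply(0:255, function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    trans <- sum(bits != bits[c(2:8, 1)])
    if (trans <= 2L) sum(bits) else 9L
  }, integer(1))
}

#' Histogram distribution statistics
#'
#' Seven statistics of the normalized histogram of a value collection:
#' mean, standard deviation, smoothness \eqn{1 - 1/(1+\sigma^2)}, third
#' central moment, uniformity \eqn{\sum p_i^2}, entropy
#' \eqn{-\sum p_i \log_2 p_i} and the gray-level range (span of nonempty
#' bins). Moments are taken over bin centers, so with fine binning they agree
#' with direct moments of the raw values.
#'
#' @param values nonempty numeric vector.
#' @param levels number of equal-width histogram bins.
#' @param range length-2 bin support; defaults to \code{range(values)}.
#' @return Named numeric vector of length 7.
#' @export
#' @examples
#' table1Stats(rep(5, 10), levels = 8, range = c(0, 255))
table1Stats <- function(values, levels = 64L, range = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty value collection")
  if (is.null(range)) range <- base::range(values)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    idx <- rep(1L, length(values)); levels <- 1L; centers <- lo
  } else {
    idx <- pmin(floor((values - lo) / (hi - lo) * levels) + 1L, levels)
    centers <- lo + (seq_len(levels) - 0.5) * (hi - lo) / levels
  }
  p <- tabulate(idx, nbins = levels) / length(values)
  mu <- sum(centers * p)
  sigma2 <- sum((centers - mu)^2 * p)
  nz <- p > 0
  c(mean = mu,
    sd = sqrt(sigma2),
    smoothness = 1 - 1 / (1 + sigma2),
    third_moment = sum((centers - mu)^3 * p),
    uniformity = sum(p^2),
    entropy = -sum(p[nz] * log2(p[nz])),
    range = max(centers[nz]) - min(centers[nz]))
}

#' 25-bin normalized gray histogram
#'
#' Equal-width bins over [0, 255] (rightmost bin closed), normalized to sum
#' to one.
#'
#' @param values numeric vector of gray values in 0..255.
#' @param bins number of bins (default 25).
#' @return Numeric vector of bin probabilities.
#' @export
histogram25 <- function(values, bins = 25L) {
  values <- values[!is.na(values)]
  stopifnot(length(values) > 0)
  idx <- pmin(floor(values * bins / 256) + 1L, bins)
  tabulate(idx, nbins = bins) / length(values)
}

.T1 <- c("mean", "sd", "smoothness", "third_moment", "uniformity",
         "entropy", "range")

#' Names of the texture feature registry
#'
#' The fixed, ordered names of the 99 texture features: 4 GLCM statistics for
#' every distance x angle offset (32), the 7 histogram statistics of the
#' local-entropy, local-STD and LBP maps (21), the same 7 statistics of the
#' grayscale foreground (7), the 25-bin gray histogram (25), the 10-bin
#' rotation-invariant-uniform LBP histogram (10), and the 4 GLCM statistics
#' averaged over all offsets (4).
#'
#' @param params a [textureParams()] list.
#' @return Character vector (length 99 under the defaults).
#' @export
textureFeatureNames <- function(params = textureParams()) {
  glcmNames <- as.vector(vapply(params$glcmDistances, function(d)
    vapply(params$glcmAngles, function(a)
      paste0("tex.glcm.d", d, ".a", a, ".", names(glcmStats(diag(2) / 2))),
      character(4)), character(4 * length(params$glcmAngles))))
  c(glcmNames,
    paste0("tex.entropy.", .T1), paste0("tex.std.", .T1), paste0("tex.lbp.", .T1),
    paste0("tex.gray.", .T1),
    sprintf("tex.hist.b%02d", seq_len(params$histogramBins)),
    c(sprintf("tex.lbpriu.u%d", 0:8), "tex.lbpriu.nonuniform"),
    paste0("tex.glcm.avg.", names(glcmStats(diag(2) / 2))))
}

#' The 99-entry texture feature block
#'
#' Assembles the texture feature registry for one preprocessed, cropped
#' grayscale image. Co-occurrence matrices count only pairs with both pixels
#' in the mask; filter maps are computed over the cropped rectangle and their
#' statistics are then taken over mask pixels only, so the black background
#' never dominates the histogram statistics.
#'
#' @param gray cropped H x W grayscale matrix in 0..255.
#' @param mask cropped H x W logical foreground mask.
#' @param params a [textureParams()] list.
#' @return Named numeric vector (length 99 under the defaults).
#' @export
textureFeatureBlock <- function(gray, mask = NULL, params = textureParams()) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  stopifnot(any(mask))
  out <- numeric(0)

  allStats <- matrix(NA_real_, 0, 4)
  for (d in params$glcmDistances) for (a in params$glcmAngles) {
    s <- glcmStats(glcm(gray, d, a, params$glcmLevels, mask))
    allStats <- rbind(allStats, s)
    names(s) <- paste0("tex.glcm.d", d, ".a", a, ".", names(s))
    out <- c(out, s)
  }

  ent <- localEntropy(gray, params$entropyWindow, params$entropyLevels)
  std <- localStd(gray, params$stdWindow)
  lb <- lbp(gray)
  lbVals <- lb[mask & !is.na(lb)]
  if (!length(lbVals)) lbVals <- as.vector(lb[!is.na(lb)])

  s1 <- table1Stats(ent[mask], params$table1Levels)
  s2 <- table1Stats(std[mask], params$table1Levels)
  s3 <- table1Stats(lbVals, params$table1Levels, range = c(0, 255))
  s4 <- table1Stats(gray[mask], params$table1Levels, range = c(0, 255))
  names(s1) <- paste0("tex.entropy.", .T1); names(s2) <- paste0("tex.std.", .T1)
  names(s3) <- paste0("tex.lbp.", .T1); names(s4) <- paste0("tex.gray.", .T1)
  out <- c(out, s1, s2, s3, s4)

  h <- histogram25(gray[mask], params$histogramBins)
  names(h) <- sprintf("tex.hist.b%02d", seq_along(h))
  out <- c(out, h)

  riu <- .lbpRiu2Map()[lbVals + 1L]
  hr <- tabulate(riu + 1L, nbins = 10L) / length(riu)
  names(hr) <- c(sprintf("tex.lbpriu.u%d", 0:8), "tex.lbpriu.nonuniform")
  out <- c(out, hr)

  avg <- colMeans(allStats)
  names(avg) <- paste0("tex.glcm.avg.", c("contrast", "correlation", "energy",
                                          "homogeneity"))
  c(out, avg)
}
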