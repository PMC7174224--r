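#' Color analysis parameters
#'
#' The hue window that selects yellow/white "foreign matter" (style and
#' debris) among foreground pixels, plus the achromatic-white rule. Hue is on
#' the [0, 1] hexcone scale; the default window [0.045, 0.279] (closed on
#' both ends) spans orange-yellow through yellow-green. White pixels have
#' ill-defined hue, so pixels with saturation below \code{whiteSatMax} and
#' brightness above \code{whiteValMin} (fraction of 255) are also counted as
#' foreign matter.
#'
#' @param hueMin,hueMax closed hue window, 0 <= hueMin < hueMax <= 1.
#' @param whiteSatMax saturation ceiling of the white rule.
#' @param whiteValMin brightness floor of the white rule (fraction of 255).
#' @return A named list of validated parameters.
#' @export
#' @examples
#' colorParams()
colorParams <- function(hueMin = 0.045, hueMax = 0.279,
                        whiteSatMax = 0.1, whiteValMin = 0.8) {
  stopifnot(hueMin >= 0, hueMin < hueMax, hueMax <= 1)
  list(hueMin = hueMin, hueMax = hueMax,
       whiteSatMax = whiteSatMax, whiteValMin = whiteValMin)
}

# the 18 color channels, in their fixed printed order
COLOR_CHANNELS <- c("R", "G", "B", "H", "S", "r", "Lstar", "astar", "bstar",
                    "C", "I", "E", "Y", "Cb", "Cr", "Yp", "Ip", "Q")

# sRGB (0..255) -> CIELAB under D65, the standard sRGB gamma + XYZ transform;
# agrees with grDevices::convertColor to ~1e-4 but vectorizes much faster
.srgbToLab <- function(R, G, B) {
  lin <- function(u) {
    u <- u / 255
    big <- u > 0.04045
    u[!big] <- u[!big] / 12.92
    u[big] <- ((u[big] + 0.055) / 1.055)^2.4
    u
  }
  r <- lin(R); g <- lin(G); b <- lin(B)
  X <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  Y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  Z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  f <- function(t) {
    big <- t > (6 / 29)^3
    t[big] <- t[big]^(1 / 3)
    t[!big] <- t[!big] / (3 * (6 / 29)^2) + 4 / 29
    t
  }
  fx <- f(X / 0.95047); fy <- f(Y); fz <- f(Z / 1.08883)
  cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

# single hue/saturation/value definition shared by toChannels and
# yellowWhiteMask (hexcone HSV on the [0,1] scale)
.hsvMaps <- function(image) {
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Decompose an RGB image into 18 color channel maps
#'
#' Channels, in fixed order: R, G, B (0..255); H, S (hexcone hue/saturation,
#' [0, 1]); r (chromaticity R/(R+G+B), [0, 1]); L*, a*, b* (CIELAB, D65);
#' C (chroma, \eqn{\sqrt{a^{*2} + b^{*2}}}); I (HSI intensity, (R+G+B)/3);
#' E (Euclidean RGB norm, \eqn{\sqrt{R^2+G^2+B^2}/\sqrt 3}); Y, Cb, Cr
#' (full-range digital-video transform); Yp, Ip, Q (NTSC YIQ; Yp numerically
#' equals the luma Y — the duplication is kept deliberately so that the 18
#' channel means plus 3 composition percentages total 21 color features).
#'
#' @param image H x W x 3 array in 0..255.
#' @param hsv optional precomputed hue/saturation/value maps (internal reuse).
#' @return Named list of 18 H x W numeric matrices.
#' @export
#' @examples
#' ch <- toChannels(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' ch$H[1, 1]; ch$r[1, 1]; ch$S[1, 1]   # 0, 1, 1 for pure red
toChannels <- function(image, hsv = NULL) {
  R <- image[, , 1] * 1.0; G <- image[, , 2] * 1.0; B <- image[, , 3] * 1.0
  if (is.null(hsv)) hsv <- .hsvMaps(image)
  tot <- R + G + B
  rchrom <- R / tot
  rchrom[tot == 0] <- 1 / 3
  lab <- .srgbToLab(as.vector(R), as.vector(G), as.vector(B))
  d <- dim(R)
  Lstar <- matrix(lab[, 1], d[1], d[2])
  astar <- matrix(lab[, 2], d[1], d[2])
  bstar <- matrix(lab[, 3], d[1], d[2])
  Y  <- 0.299 * R + 0.587 * G + 0.114 * B
  Cb <- 128 - 0.168736 * R - 0.331264 * G + 0.5 * B
  Cr <- 128 + 0.5 * R - 0.418688 * G - 0.081312 * B
  Ip <- 0.595716 * R - 0.274453 * G - 0.321263 * B
  Q  <- 0.211456 * R - 0.522591 * G + 0.311135 * B
  list(R = R, G = G, B = B, H = hsv$h, S = hsv$s, r = rchrom,
       Lstar = Lstar, astar = astar, bstar = bstar,
       C = sqrt(astar^2 + bstar^2), I = tot / 3,
       E = sqrt(R^2 + G^2 + B^2) / sqrt(3),
       Y = Y, Cb = Cb, Cr = Cr, Yp = Y, Ip = Ip, Q = Q)
}

#' Segment yellow/white foreign matter by hue window
#'
#' A foreground pixel is selected iff its hue lies in the closed window
#' \code{[hueMin, hueMax]}, or it satisfies the achromatic-white rule
#' (saturation < \code{whiteSatMax} and brightness > \code{whiteValMin}).
#' The hue map is the same single definition used by [toChannels()].
#'
#' @param image H x W x 3 array in 0..255.
#' @param params a [colorParams()] list.
#' @param foreground H x W logical foreground mask aligned with the image.
#' @param hsv optional precomputed hue/saturation/value maps (internal reuse).
#' @return H x W logical matrix, a subset of \code{foreground}.
#' @export
yellowWhiteMask <- function(image, params = colorParams(), foreground = NULL,
                            hsv = NULL) {
  if (is.null(foreground)) foreground <- matrix(TRUE, dim(image)[1], dim(image)[2])
  stopifnot(all(dim(foreground) == dim(image)[1:2]))
  if (is.null(hsv)) hsv <- .hsvMaps(image)
  inWindow <- hsv$h >= params$hueMin & hsv$h <= params$hueMax
  white <- hsv$s < params$whiteSatMax & hsv$v > params$whiteValMin
  (inWindow | white) & foreground
}

#' Composition percentages of a segmented scene
#'
#' Given the foreground mask and the foreign-matter (yellow/white) mask,
#' computes the percentage of foreign matter in the total mass, the
#' percentage of stigma (red) pixels, and the foreign-to-stigma ratio as a
#' percentage. The first two always sum to exactly 100.
#'
#' @param foreground,foreign logical masks with \code{foreign} a subset of
#'   \code{foreground}; \code{foreground} must be nonempty.
#' @return Named numeric vector \code{(foreign_pct, stigma_pct,
#'   foreign_to_stigma_pct)}. If every foreground pixel is foreign the ratio
#'   is \code{Inf} with a warning.
#' @export
#' @examples
#' fg <- matrix(TRUE, 10, 100); fr <- fg & FALSE; fr[, 1:25] <- TRUE
#' composition(fg, fr)  # 25, 75, 33.33
composition <- function(foreground, foreign) {
  nf <- sum(foreground)
  if (nf == 0) stop("foreground is empty; no composition defined")
  no <- sum(foreign & foreground)
  foreignPct <- 100 * no / nf
  stigmaPct <- 100 - foreignPct
  ratio <- if (nf == no) {
    warning("all foreground pixels are foreign matter; ratio is infinite")
    Inf
  } else 100 * no / (nf - no)
  c(foreign_pct = foreignPct, stigma_pct = stigmaPct,
    foreign_to_stigma_pct = ratio)
}

#' The 21-entry color feature block
#'
#' The mean of each of the 18 color channels over foreground pixels, followed
#' by the 3 composition percentages. Background pixels never influence the
#' means.
#'
#' @param image cropped H x W x 3 array in 0..255 (after preprocessing).
#' @param foreground cropped H x W logical foreground mask.
#' @param params a [colorParams()] list.
#' @return Named numeric vector of length 21 with names prefixed
#'   \code{color.}.
#' @export
colorFeatureBlock <- function(image, foreground, params = colorParams()) {
  stopifnot(any(foreground))
  hsv <- .hsvMaps(image)   # shared by the channel maps and the hue window
  ch <- toChannels(image, hsv = hsv)
  means <- vapply(ch, function(m) mean(m[foreground]), numeric(1))
  comp <- composition(foreground,
                      yellowWhiteMask(image, params, foreground, hsv = hsv))
  out <- c(means, comp)
  names(out) <- paste0("color.", c(COLOR_CHANNELS, names(comp)))
  out
}
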