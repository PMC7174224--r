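#' Construct synthetic scene parameters
#'
#' Builds a validated [SceneParams] object. Defaults describe a desk-scale
#' 512 x 512 scene of dark-red filaments on a near-black background with a
#' mild illumination gradient and Gaussian sensor noise.
#'
#' @param classLabel one of \code{saffronClasses()}.
#' @param nFilaments number of filament units.
#' @param filamentLength,filamentWidth length-2 ranges in pixels.
#' @param breakProbability probability a filament is rendered broken.
#' @param tripletJoin draw filaments in joined triplets (Pushal morphology).
#' @param styleFraction target fraction of foreground pixels in style color.
#' @param stigmaColor,styleColor RGB triples in 0..255.
#' @param backgroundLevel background gray level (0..20).
#' @param noiseSd sensor noise standard deviation.
#' @param illuminationGradient relative brightness falloff across columns.
#' @param width,height canvas size (>= 256).
#' @param seed integer seed; fixes the scene bit-exactly.
#' @return A [SceneParams] object.
#' @export
#' @examples
#' sceneParams("Sargol", styleFraction = 0, seed = 7)
sceneParams <- function(classLabel = "Negin",
                        nFilaments = 14L,
                        filamentLength = c(140, 220),
                        filamentWidth = c(7, 11),
                        breakProbability = 0.05,
                        tripletJoin = FALSE,
                        styleFraction = 0.02,
                        stigmaColor = c(150, 22, 28),
                        styleColor = c(225, 180, 70),
                        backgroundLevel = 8L,
                        noiseSd = 3,
                        illuminationGradient = 0.15,
                        width = 512L, height = 512L,
                        seed = 1L) {
  new("SceneParams",
      classLabel = classLabel,
      nFilaments = as.integer(nFilaments),
      filamentLength = as.numeric(filamentLength),
      filamentWidth = as.numeric(filamentWidth),
      breakProbability = breakProbability,
      tripletJoin = tripletJoin,
      styleFraction = styleFraction,
      stigmaColor = as.numeric(stigmaColor),
      styleColor = as.numeric(styleColor),
      backgroundLevel = as.integer(backgroundLevel),
      noiseSd = noiseSd,
      illuminationGradient = illuminationGradient,
      width = as.integer(width), height = as.integer(height),
      seed = as.integer(seed))
}

#' Class-default scene parameters
#'
#' Scene presets emulating the three commercial grades: Pushal as joined
#' filament triplets with a noticeable style fraction at the filament base,
#' Negin as long intact separate filaments with almost no style, Sargol as
#' short broken fragments. By construction mean filament area is larger for
#' Negin than Sargol, and mean style fraction is highest for Pushal.
#'
#' @param classLabel one of \code{saffronClasses()}.
#' @param seed integer seed.
#' @param ... overrides forwarded to [sceneParams()].
#' @return A [SceneParams] object.
#' @export
#' @examples
#' classSceneParams("Pushal", seed = 1)
classSceneParams <- function(classLabel, seed = 1L, ...) {
  defaults <- switch(classLabel,
    Pushal = list(nFilaments = 15L, filamentLength = c(100, 180),
                  filamentWidth = c(7, 11), breakProbability = 0.05,
                  tripletJoin = TRUE, styleFraction = 0.15),
    Negin  = list(nFilaments = 14L, filamentLength = c(140, 220),
                  filamentWidth = c(7, 11), breakProbability = 0.05,
                  tripletJoin = FALSE, styleFraction = 0.02),
    Sargol = list(nFilaments = 26L, filamentLength = c(45, 85),
                  filamentWidth = c(6, 9), breakProbability = 0.6,
                  tripletJoin = FALSE, styleFraction = 0.01),
    stop("unknown class label: ", classLabel))
  override <- list(...)
  defaults[names(override)] <- override
  do.call(sceneParams, c(list(classLabel = classLabel, seed = seed), defaults))
}

# integer (row, col) offsets of a discrete disc {x^2 + y^2 <= r^2}
.discOffsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# stamp discs of given radius at the supplied (row, col) points; returns the
# linear indices painted (unique, clipped to canvas)
.stampIndices <- function(pts, radius, H, W) {
  off <- .discOffsets(radius)
  rr <- round(rep(pts[, 1], each = nrow(off)) + off$dr)
  cc <- round(rep(pts[, 2], each = nrow(off)) + off$dc)
  keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  unique((cc[keep] - 1L) * H + rr[keep])
}

# quadratic Bezier spine points between p0 and p2 with control p1
.bezier <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

#' Render one synthetic bulk-saffron image
#'
#' Draws filaments as curved capsules (discs stamped along random quadratic
#' Bezier spines) in a dark-red stigma color, adds yellow style pixels until
#' the target style fraction is met (at the base of the joined triplets for
#' Pushal scenes, as loose short debris otherwise), then applies a linear
#' illumination gradient and i.i.d. Gaussian sensor noise clipped to 0..255.
#' Ground-truth pixel counts are taken from the internal label mask before
#' noise, so they are exact.
#'
#' @param params a [SceneParams] object.
#' @return A list with elements \code{image} (H x W x 3 integer array,
#'   0..255), \code{truth} (list with \code{foregroundPixels},
#'   \code{stylePixels}, \code{styleFraction} and a per-filament geometry
#'   data frame) and \code{labelMask} (H x W integer matrix: 0 background,
#'   1 stigma, 2 style).
#' @export
#' @examples
#' scene <- generateImage(sceneParams("Sargol", styleFraction = 0, seed = 7))
#' scene$truth$stylePixels   # 0: no style rendered
generateImage <- function(params) {
  validObject(params)
  set.seed(params@seed)
  H <- params@height; W <- params@width
  label <- matrix(0L, H, W)
  colR <- matrix(params@backgroundLevel, H, W)
  colG <- matrix(params@backgroundLevel, H, W)
  colB <- matrix(params@backgroundLevel, H, W)

  paint <- function(idx, color, code) {
    if (!length(idx)) return(invisible())
    label[idx] <<- code
    colR[idx] <<- color[1]; colG[idx] <<- color[2]; colB[idx] <<- color[3]
    invisible()
  }

  jitterColor <- function(base) pmin(255, pmax(0, base * runif(1, 0.85, 1.15)))

  # filament spine endpoints kept away from borders so style tails fit
  randBase <- function() c(runif(1, 0.12 * H, 0.88 * H), runif(1, 0.12 * W, 0.88 * W))

  tripletBases <- list()   # for Pushal style tails: list(base, unitdir, width)
  filamentLog <- list()

  drawFilament <- function(p0, theta, len, w) {
    d <- c(cos(theta), sin(theta))
    perp <- c(-d[2], d[1])
    bow <- runif(1, -0.25, 0.25) * len
    p1 <- p0 + d * len / 2 + perp * bow
    p2 <- p0 + d * len
    t0 <- 0; t1 <- 1
    if (runif(1) < params@breakProbability) {     # broken fragment
      t0 <- runif(1, 0, 0.4); t1 <- t0 + runif(1, 0.25, 0.5)
    }
    pts <- .bezier(p0, p1, p2, max(8L, ceiling(2 * len)))
    pts <- pts[seq(max(1, floor(t0 * nrow(pts))), ceiling(t1 * nrow(pts))), , drop = FALSE]
    idx <- .stampIndices(pts, w / 2, H, W)
    paint(idx, jitterColor(params@stigmaColor), 1L)
    filamentLog[[length(filamentLog) + 1L]] <<-
      data.frame(length = len * (t1 - t0), width = w, area = length(idx))
    invisible(d)
  }

  nf <- params@nFilaments
  if (params@tripletJoin) {
    nTrip <- ceiling(nf / 3)
    for (g in seq_len(nTrip)) {
      base <- randBase()
      theta0 <- runif(1, 0, 2 * pi)
      w <- runif(1, params@filamentWidth[1], params@filamentWidth[2])
      for (k in -1:1) {
        len <- runif(1, params@filamentLength[1], params@filamentLength[2])
        drawFilament(base, theta0 + k * 0.35 + rnorm(1, 0, 0.05), len, w)
      }
      d0 <- c(cos(theta0), sin(theta0))
      tripletBases[[g]] <- list(base = base, dir = d0, width = w, tail = 0)
    }
  } else {
    for (j in seq_len(nf)) {
      len <- runif(1, params@filamentLength[1], params@filamentLength[2])
      w <- runif(1, params@filamentWidth[1], params@filamentWidth[2])
      drawFilament(randBase(), runif(1, 0, 2 * pi), len, w)
    }
  }

  # add style pixels until the rendered fraction reaches the target
  f <- params@styleFraction
  if (f > 0) {
    styleCol <- params@styleColor
    chunkLen <- 12
    stalled <- 0L
    for (iter in seq_len(600L)) {
      fg <- sum(label > 0L); st <- sum(label == 2L)
      if (fg > 0 && st / fg >= f - 0.005) break
      before <- st
      if (params@tripletJoin && length(tripletBases)) {
        g <- ((iter - 1L) %% length(tripletBases)) + 1L
        tb <- tripletBases[[g]]
        s0 <- tb$tail; s1 <- s0 + chunkLen
        pts <- cbind(tb$base[1] - tb$dir[1] * seq(s0, s1, length.out = 2 * chunkLen),
                     tb$base[2] - tb$dir[2] * seq(s0, s1, length.out = 2 * chunkLen))
        tripletBases[[g]]$tail <- s1
        paint(.stampIndices(pts, tb$width / 2, H, W), jitterColor(styleCol), 2L)
      } else {
        len <- runif(1, 8, 18)
        w <- runif(1, params@filamentWidth[1], params@filamentWidth[2])
        p0 <- randBase(); theta <- runif(1, 0, 2 * pi)
        pts <- .bezier(p0, p0 + c(cos(theta), sin(theta)) * len / 2,
                       p0 + c(cos(theta), sin(theta)) * len, 2 * ceiling(len))
        paint(.stampIndices(pts, w / 2, H, W), jitterColor(styleCol), 2L)
      }
      stalled <- if (sum(label == 2L) == before) stalled + 1L else 0L
      if (stalled >= 25L) break
    }
  }

  fg <- sum(label > 0L); st <- sum(label == 2L)
  truth <- list(
    foregroundPixels = fg,
    stylePixels = st,
    styleFraction = if (fg > 0) st / fg else 0,
    filaments = if (length(filamentLog)) do.call(rbind, filamentLog)
                else data.frame(length = numeric(), width = numeric(), area = numeric())
  )

  # illumination gradient (multiplicative across columns), then sensor noise
  grad <- matrix(1 - params@illuminationGradient * (seq_len(W) - 1) / (W - 1),
                 H, W, byrow = TRUE)
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- colR * grad; img[, , 2] <- colG * grad; img[, , 3] <- colB * grad
  if (params@noiseSd > 0)
    img <- img + array(rnorm(length(img), 0, params@noiseSd), dim = dim(img))
  img[] <- round(pmin(255, pmax(0, as.vector(img))))
  storage.mode(img) <- "integer"

  list(image = img, truth = truth, labelMask = label)
}

#' Generate a labeled synthetic dataset
#'
#' Renders \code{counts[cls]} scenes per class using class-default (or
#' user-supplied) scene parameters. Child seeds are derived deterministically
#' from the master seed, so the whole dataset is bit-reproducible. If
#' \code{dir} is given each image is written as a PNG and the manifest
#' records its path.
#'
#' @param counts named integer vector (names from \code{saffronClasses()}).
#' @param seed master integer seed.
#' @param paramsByClass optional named list of [SceneParams] templates; the
#'   per-image seed is substituted into the template.
#' @param dir optional output directory for PNG files.
#' @return list with \code{manifest} (data frame: sample_id, path, class,
#'   style_fraction, seed) and \code{scenes} (list of [generateImage()]
#'   results, named by sample_id).
#' @export
#' @examples
#' ds <- generateDataset(c(Pushal = 2, Negin = 2, Sargol = 2), seed = 3)
#' table(ds$manifest$class)
generateDataset <- function(counts, seed = 1L, paramsByClass = NULL, dir = NULL) {
  stopifnot(all(counts >= 0), all(names(counts) %in% SAFFRON_CLASSES))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(); scenes <- list(); i <- 0L
  for (cls in names(counts)) {
    for (j in seq_len(counts[[cls]])) {
      i <- i + 1L
      childSeed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
      p <- if (!is.null(paramsByClass) && !is.null(paramsByClass[[cls]])) {
        tmpl <- paramsByClass[[cls]]; tmpl@seed <- childSeed; tmpl
      } else classSceneParams(cls, seed = childSeed)
      sc <- generateImage(p)
      id <- sprintf("%s_%03d", tolower(cls), j)
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, paste0(id, ".png"))
        writeSaffronImage(sc$image, path)
      }
      manifest[[i]] <- data.frame(sample_id = id, path = path, class = cls,
                                  style_fraction = sc$truth$styleFraction,
                                  seed = childSeed, stringsAsFactors = FALSE)
      scenes[[id]] <- sc
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest)
              else data.frame(sample_id = character(), path = character(),
                              class = character(), style_fraction = numeric(),
                              seed = integer(), stringsAsFactors = FALSE)
  list(manifest = manifest, scenes = scenes)
}

#' Read and write 8-bit RGB images
#'
#' Thin wrappers around the PNG codec mapping between files and the H x W x 3
#' integer arrays (0..255) used throughout the package.
#'
#' @param image H x W x 3 numeric/integer array in 0..255.
#' @param path file path.
#' @return \code{readSaffronImage} returns an H x W x 3 integer array;
#'   \code{writeSaffronImage} returns \code{path} invisibly.
#' @export
writeSaffronImage <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname writeSaffronImage
#' @export
readSaffronImage <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  img <- round(a * 255)
  storage.mode(img) <- "integer"
  img
}
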