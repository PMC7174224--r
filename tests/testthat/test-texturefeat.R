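test_that("co-occurrence matrices match direct pair enumeration", {
  img <- matrix(c(0, 0, 255, 255), 2, 2, byrow = TRUE)
  p <- glcmMatrix(glcm(img, distance = 1, angle = 0, levels = 2))
  expect_equal(p, matrix(c(0.5, 0, 0, 0.5), 2, 2), tolerance = 1e-12)

  const <- matrix(100, 4, 4)
  pc <- glcmMatrix(glcm(const, 1, 0, levels = 8))
  expect_equal(sum(pc != 0), 1)
  expect_equal(max(pc), 1)

  set.seed(21)
  offs <- expand.grid(d = c(1L, 2L), a = c(0, 45, 90, 135))
  for (rep in 1:10) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    for (r in seq_len(nrow(offs))) {
      g <- glcm(img, offs$d[r], offs$a[r], levels = 8)
      off <- saffronvision:::.angleOffset(offs$a[r], offs$d[r])
      expect_equal(glcmMatrix(g), naiveGlcm(img, off[1], off[2], 8),
                   tolerance = 1e-10)
      expect_equal(sum(glcmMatrix(g)), 1, tolerance = 1e-12)
    }
  }
})

test_that("the four statistics agree with brute-force double sums", {
  p1 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  s1 <- glcmStats(p1)
  expect_equal(unname(s1), c(0, 1, 0.5, 1), tolerance = 1e-12)

  p2 <- matrix(0.25, 2, 2)
  s2 <- glcmStats(p2)
  expect_equal(unname(s2["contrast"]), 0.5)
  expect_equal(unname(s2["energy"]), 0.25)
  expect_equal(unname(s2["homogeneity"]), 0.75)
  expect_equal(unname(s2["correlation"]), 0)

  expect_warning(s3 <- glcmStats(glcm(matrix(7, 3, 3), 1, 0, levels = 4)),
                 "degenerate")
  expect_equal(unname(s3["contrast"]), 0)

  set.seed(8)
  for (rep in 1:10) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    g <- glcm(img, 1, 45, levels = 8)
    expect_equal(glcmStats(g), naiveGlcmStats(glcmMatrix(g)),
                 tolerance = 1e-10)
  }
})

test_that("statistic bounds and rotation invariance hold on random images", {
  set.seed(13)
  for (rep in 1:8) {
    img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    perAngle <- t(vapply(c(0, 45, 90, 135), function(a)
      glcmStats(glcm(img, 1, a, levels = 8)), numeric(4)))
    expect_true(all(perAngle[, "contrast"] >= 0))
    expect_true(all(perAngle[, "energy"] > 0 & perAngle[, "energy"] <= 1))
    expect_true(all(perAngle[, "homogeneity"] > 0 & perAngle[, "homogeneity"] <= 1))
    expect_true(all(abs(perAngle[, "correlation"]) <= 1 + 1e-12))

    # rotating the image by 90 degrees permutes the per-angle statistics
    rot <- t(img)[nrow(img):1, ]
    perAngleRot <- t(vapply(c(0, 45, 90, 135), function(a)
      glcmStats(glcm(rot, 1, a, levels = 8)), numeric(4)))
    expect_equal(perAngle[order(perAngle[, 1], perAngle[, 2]), ],
                 perAngleRot[order(perAngleRot[, 1], perAngleRot[, 2]), ],
                 tolerance = 1e-10)
  }
})

test_that("masked co-occurrence counts only pairs inside the mask", {
  img <- matrix(c(0, 255, 0, 255), 2, 2, byrow = TRUE)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE)
  p <- glcmMatrix(glcm(img, 1, 0, levels = 2, mask = mask))
  expect_equal(p, matrix(c(0, 0.5, 0.5, 0), 2, 2))  # single pair (0,255)
  expect_error(glcm(img, 1, 0, levels = 2, mask = mask & FALSE), "no valid")
})

test_that("local entropy matches the exact window histogram", {
  expect_true(all(localEntropy(matrix(50, 12, 12)) == 0))

  chk <- outer(1:20, 1:20, function(i, j) ((i + j) %% 2) * 255)
  ent <- localEntropy(chk, window = 3, levels = 8)
  # each interior 3x3 window holds 4 and 5 pixels of the two levels
  expected <- -(4 / 9) * log2(4 / 9) - (5 / 9) * log2(5 / 9)
  expect_equal(ent[10, 10], expected, tolerance = 1e-12)
  expect_true(all(ent <= log2(8) + 1e-12))
  expect_error(localEntropy(chk, window = 4), "odd")
})

test_that("local standard deviation matches direct window computation", {
  expect_true(all(localStd(matrix(9, 10, 10)) == 0))

  stripes <- outer(1:12, 1:12, function(i, j) (j %% 2) * 255)
  sd3 <- localStd(stripes, window = 3)
  # interior window at an even column holds 6 zeros and 3 bright pixels
  vals <- as.vector(stripes[5:7, 5:7])
  expect_equal(sd3[6, 6], popSd(vals), tolerance = 1e-9)
  # doubling the contrast doubles the map
  expect_equal(localStd(stripes / 2, 3) * 2, sd3, tolerance = 1e-9)
})

test_that("basic LBP codes follow the clockwise weighting and tie rule", {
  m <- matrix(0, 3, 3); m[2, 2] <- 255
  expect_equal(lbp(m)[2, 2], 0L)

  expect_true(all(lbp(matrix(42, 5, 5))[2:4, 2:4] == 255L))

  # hand-computed: only the top-left neighbor (weight 1) and right neighbor
  # (weight 8) are >= center
  m2 <- matrix(c(9, 1, 1,
                 1, 5, 9,
                 1, 1, 1), 3, 3, byrow = TRUE)
  expect_equal(lbp(m2)[2, 2], 1L + 8L)

  set.seed(4)
  img <- matrix(sample(0:200, 49, replace = TRUE), 7, 7)
  expect_equal(lbp(img), lbp(img + 10))
  expect_true(all(is.na(lbp(img)[1, ])))
})

test_that("histogram statistics match their closed forms", {
  s <- table1Stats(rep(42, 50), levels = 16, range = c(0, 255))
  expect_equal(unname(s[c("sd", "smoothness", "third_moment")]), c(0, 0, 0))
  expect_equal(unname(s["uniformity"]), 1)
  expect_equal(unname(s["entropy"]), 0)
  expect_equal(unname(s["range"]), 0)

  L <- 8
  u <- table1Stats(0:(L - 1), levels = L, range = c(0, L - 1))
  expect_equal(unname(u["uniformity"]), 1 / L)
  expect_equal(unname(u["entropy"]), log2(L))

  sym <- c(rep(1, 5), rep(3, 5))
  expect_equal(unname(table1Stats(sym, levels = 4,
                                  range = c(0, 4))["third_moment"]), 0,
               tolerance = 1e-12)

  # bin-center moments approach raw moments when binning is fine
  set.seed(99)
  x <- runif(1000, 0, 255)
  s2 <- table1Stats(x, levels = 256, range = c(0, 255))
  expect_equal(unname(s2["mean"]), mean(x), tolerance = 1)
  expect_equal(unname(s2["sd"]), popSd(x), tolerance = 1)

  expect_error(table1Stats(numeric(0)), "empty")
})

test_that("the 25-bin histogram is normalized with a closed last bin", {
  h <- histogram25(rep(7, 10))
  expect_equal(sum(h), 1)
  expect_equal(h[1], 1)

  expect_equal(which(histogram25(255) == 1), 25L)

  ramp <- histogram25(0:255)
  expect_true(all(abs(ramp - 0.04) <= 0.005))

  set.seed(2)
  expect_equal(sum(histogram25(runif(500, 0, 255))), 1, tolerance = 1e-12)
})

test_that("the texture block has exactly 99 stable, deterministic entries", {
  set.seed(31)
  gray <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  mask <- matrix(TRUE, 64, 64); mask[1:5, ] <- FALSE
  b1 <- textureFeatureBlock(gray, mask)
  b2 <- textureFeatureBlock(gray, mask)
  expect_length(b1, 99)
  expect_identical(b1, b2)
  expect_identical(names(b1), textureFeatureNames())
  expect_equal(anyDuplicated(names(b1)), 0)
  expect_length(featureRegistry(), 120)
})
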