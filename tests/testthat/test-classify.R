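# small separable feature sets used across these tests
makeClusters <- function(n = 10, p = 6, gap = 12, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = gap), n, p),
             matrix(rnorm(n * p, mean = -gap), n, p))
  y <- factor(rep(c("A", "B", "C"), each = n))
  list(X = X, y = y)
}

test_that("the suite enumerates the 22 named presets", {
  suite <- modelSuite()
  expect_length(suite, 22)
  ids <- vapply(suite, function(s) s@id, character(1))
  expect_equal(anyDuplicated(ids), 0)
  names_ <- vapply(suite, function(s) s@name, character(1))
  expect_true(all(c("Quadratic SVM", "Subspace Discriminant", "Fine Tree",
                    "Coarse Gaussian SVM", "Weighted KNN", "RUSBoost Trees")
                  %in% names_))
  fam <- table(vapply(suite, function(s) s@family, character(1)))
  expect_equal(as.vector(fam[c("tree", "discriminant", "svm", "knn",
                               "ensemble")]),
               c(3, 2, 6, 6, 5))
})

test_that("stratified folds preserve class proportions and determinism", {
  y <- rep(c("A", "B", "C"), each = 10)
  f <- stratifiedFolds(y, k = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  tab <- table(f, y)
  expect_true(all(tab == 2))

  f2 <- stratifiedFolds(c("A", "A", "B", "B"), k = 2, seed = 9)
  expect_true(all(table(f2, c("A", "A", "B", "B")) == 1))

  expect_identical(stratifiedFolds(y, 5, seed = 42),
                   stratifiedFolds(y, 5, seed = 42))
  expect_error(stratifiedFolds(c("A", "A", "B"), k = 2), "at least k")
})

test_that("the majority baseline scores at the balanced chance rate", {
  set.seed(7)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- factor(rep(c("A", "B", "C"), each = 20))
  r <- runCV(X, y, majorityBaseline(), cvConfig(k = 5, repetitions = 10,
                                                seed = 3))
  expect_length(accuracies(r), 10)
  expect_lt(abs(meanAccuracy(r) - 100 / 3), 3)
})

test_that("1-NN separates widely separated clusters perfectly", {
  d <- makeClusters(gap = 15, seed = 2)
  r <- runCV(d$X, d$y, modelSuite()$fine_knn,
             cvConfig(k = 5, repetitions = 3, seed = 5))
  expect_equal(meanAccuracy(r), 100)
  # reported mean/SD are recomputable from the per-repetition list
  expect_equal(meanAccuracy(r), mean(accuracies(r)), tolerance = 1e-9)
  expect_equal(sdAccuracy(r), sd(accuracies(r)), tolerance = 1e-9)
})

test_that("every sample is predicted exactly once per repetition", {
  d <- makeClusters(gap = 3, seed = 4)
  r <- runCV(d$X, d$y, modelSuite()$medium_knn,
             cvConfig(k = 5, repetitions = 2, seed = 8))
  for (rep in 1:2) {
    expect_false(anyNA(r@predictions[[rep]]))
    expect_false(anyNA(r@scores[[rep]]))
    expect_equal(rowSums(r@scores[[rep]]), rep(1, 30), tolerance = 1e-9)
  }
})

test_that("the full experiment is bit-reproducible under a fixed seed", {
  d <- makeClusters(gap = 4, seed = 6)
  cfg <- cvConfig(k = 5, repetitions = 3, seed = 11)
  for (id in c("medium_knn", "bagged_trees", "subspace_discriminant")) {
    r1 <- runCV(d$X, d$y, modelSuite()[[id]], cfg)
    r2 <- runCV(d$X, d$y, modelSuite()[[id]], cfg)
    expect_identical(accuracies(r1), accuracies(r2))
    expect_identical(r1@predictions, r2@predictions)
  }
})

test_that("standardization is fit on the training folds only", {
  d <- makeClusters(gap = 4, seed = 9)
  cfg <- cvConfig(k = 5, repetitions = 1, seed = 13)
  spec <- modelSuite()$fine_knn
  r <- runCV(d$X, d$y, spec, cfg)

  # replicate fold 1 by hand with the same derived seed
  foldSeed <- as.integer((as.numeric(cfg$seed) + 1 * 99991) %% 2147483647)
  folds <- stratifiedFolds(d$y, cfg$k, foldSeed)
  te <- folds == 1
  mu <- colMeans(d$X[!te, ]); sdv <- apply(d$X[!te, ], 2, sd)
  Xtr <- scale(d$X[!te, ], mu, sdv); Xte <- scale(d$X[te, ], mu, sdv)
  manual <- saffronvision:::.predictKnn(Xtr, d$y[!te], Xte, k = 1)
  manualLab <- levels(d$y)[max.col(manual, ties.method = "first")]
  expect_equal(as.character(r@predictions[[1]][te]), manualLab)

  # and differs from what global standardization would produce on skewed data
  set.seed(10)
  X2 <- d$X; X2[te, 1] <- X2[te, 1] + 100   # test-fold-only contamination
  muG <- colMeans(X2); sdG <- apply(X2, 2, sd)
  expect_false(isTRUE(all.equal(muG[1], colMeans(X2[!te, , drop = FALSE])[1])))
})

test_that("pseudoinverse discriminants agree with the classical fit when it exists", {
  skip_if_not_installed("MASS")
  d <- makeClusters(n = 20, p = 4, gap = 2, seed = 12)
  fit <- saffronvision:::.fitDiscriminant(d$X, d$y, "linear")
  mine <- saffronvision:::.predictDiscriminant(fit, d$X)
  ref <- MASS::lda(d$X, d$y)
  refPost <- predict(ref, d$X)$posterior
  expect_equal(levels(d$y)[max.col(mine)],
               as.character(predict(ref, d$X)$class))
  expect_equal(unname(mine), unname(refPost[, colnames(mine)]),
               tolerance = 1e-6)
})

test_that("hand-rolled kNN agrees with class::knn on the Euclidean metric", {
  skip_if_not_installed("class")
  d <- makeClusters(n = 15, p = 5, gap = 2, seed = 14)
  idx <- c(1:10, 16:25, 31:40)
  Xtr <- d$X[idx, ]; ytr <- d$y[idx]; Xte <- d$X[-idx, ]
  for (k in c(1, 5)) {
    mine <- saffronvision:::.predictKnn(Xtr, ytr, Xte, k = k)
    mineLab <- levels(ytr)[max.col(mine, ties.method = "first")]
    ref <- as.character(class::knn(Xtr, Xte, ytr, k = k))
    expect_equal(mineLab, ref)
  }
})

test_that("degenerate discriminant input is handled, not crashed", {
  # p >> n: classical qda is impossible, the pseudoinverse route must run
  set.seed(15)
  X <- matrix(rnorm(30 * 50), 30, 50)
  y <- factor(rep(c("A", "B", "C"), each = 10))
  r <- runCV(X, y, modelSuite()$quadratic_discriminant,
             cvConfig(k = 5, repetitions = 1, seed = 2))
  expect_length(r@failures, 0)
  expect_false(is.na(accuracies(r)[1]))
})

test_that("missing feature values are rejected", {
  X <- matrix(rnorm(30), 10, 3); X[3, 2] <- NA
  expect_error(runCV(X, factor(rep(1:2, 5)), modelSuite()$fine_knn),
               "missing")
})
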