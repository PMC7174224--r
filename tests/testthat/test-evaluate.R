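test_that("confusion matrices count true x predicted pairs", {
  cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"),
                        classes = c("A", "B"))
  expect_equal(unname(cm), matrix(c(1, 0, 1, 1), 2, 2))

  pred <- c("Pushal", "Negin", "Sargol")
  cmP <- confusionMatrix(pred, pred)
  expect_equal(unname(diag(cmP)), rep(1, 3))
  expect_equal(rownames(cmP), saffronClasses())

  set.seed(1)
  y <- sample(c("A", "B", "C"), 60, replace = TRUE)
  p <- sample(c("A", "B", "C"), 60, replace = TRUE)
  cm2 <- confusionMatrix(y, p, classes = c("A", "B", "C"))
  expect_equal(sum(diag(cm2)) / sum(cm2), mean(y == p))

  expect_error(confusionMatrix("A", "D", classes = c("A", "B")), "outside")
})

test_that("TP+FN and PP+FD are 100 for every class of every matrix", {
  perfect <- diag(c(5, 7, 9)); rownames(perfect) <- colnames(perfect) <- saffronClasses()
  r <- classRates(perfect)
  expect_equal(r$tp_rate, rep(100, 3))
  expect_equal(r$fd_rate, rep(0, 3))

  set.seed(33)
  for (i in 1:50) {
    cm <- fuzzConfusion()
    r <- classRates(cm)
    expect_equal(r$tp_rate + r$fn_rate, rep(100, 3), tolerance = 1e-9)
    expect_equal(r$pp_rate + r$fd_rate, rep(100, 3), tolerance = 1e-9)
    expect_true(all(r$tp_rate >= 0 & r$tp_rate <= 100))
  }

  degenerate <- matrix(c(2, 1, 0, 0), 2, 2)  # no prediction for class 2
  expect_warning(rd <- classRates(degenerate), "no predictions")
  expect_true(is.na(rd$pp_rate[2]))
})

test_that("ROC/AUC equals pair concordance and behaves at the extremes", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.1), c("A", "A", "B", "B"), "A")$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c("A", "B"), 5), "A")$auc, 0.5)

  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)   # rounded to force ties
    r <- rocAuc(scores, labels, "pos")
    expect_equal(r$auc, concordanceAuc(scores, labels, "pos"),
                 tolerance = 1e-12)
    expect_equal(rocAuc(-scores, labels, "pos")$auc, 1 - r$auc,
                 tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }

  expect_error(rocAuc(1:3, c("A", "A", "A"), "A"), "positive and negative")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- rnorm(40)
  labels <- sample(c("pos", "neg"), 40, replace = TRUE)
  mine <- rocAuc(scores, labels, "pos")$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("neg", "pos"),
    direction = "<"))))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("one-way ANOVA matches two-pass sums of squares", {
  eq <- anovaOneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(eq$F, 0)

  set.seed(23)
  jit <- list(a = rnorm(5, 0, 1e-3), b = rnorm(5, 10, 1e-3))
  sep <- anovaOneway(jit)
  expect_lt(sep$p, 1e-6)

  for (i in 1:10) {
    groups <- lapply(1:4, function(g) rnorm(6, mean = g / 2))
    names(groups) <- paste0("g", 1:4)
    mine <- anovaOneway(groups)
    ref <- naiveAnova(groups)
    expect_equal(mine$F, ref$F, tolerance = 1e-9)
    expect_equal(mine$ssBetween + mine$ssWithin, ref$sst, tolerance = 1e-9)
    expect_equal(mine$errorMeanSquare, ref$ssw / mine$dfWithin,
                 tolerance = 1e-9)
  }
})

test_that("Duncan grouping separates clusters and merges equals", {
  means <- c(m1 = 50, m2 = 50, m3 = 50)
  d <- duncanGroups(means, nPerGroup = 10, errorMeanSquare = 1, dfWithin = 27)
  expect_equal(unname(groupLetters(d)), rep("a", 3))

  # two clusters far beyond any critical range
  means2 <- c(a1 = 90, a2 = 89.8, b1 = 50, b2 = 50.3)
  d2 <- duncanGroups(means2, nPerGroup = 10, errorMeanSquare = 0.5,
                     dfWithin = 36)
  lt <- groupLetters(d2)
  expect_equal(unname(lt[c("a1", "a2")]), c("a", "a"))
  expect_equal(unname(lt[c("b2", "b1")]), c("b", "b"))

  # critical range check by direct quantile computation for the 2-span
  r2 <- qtukey(0.95, 2, 36) * sqrt(0.5 / 10)
  expect_lt(abs(diff(means2[c("a1", "a2")])), r2)
  expect_gt(means2[["a2"]] - means2[["b2"]], r2)

  expect_error(duncanGroups(means2, nPerGroup = c(10, 9, 10, 10),
                            errorMeanSquare = 1, dfWithin = 35),
               "balanced")
})

test_that("Duncan letters are order-preserving (no letter spans an outside mean)", {
  set.seed(29)
  for (i in 1:10) {
    k <- 8
    means <- setNames(rnorm(k, 70, 5), paste0("g", 1:k))
    d <- duncanGroups(means, nPerGroup = 10, errorMeanSquare = 4,
                      dfWithin = 72)
    lets <- strsplit(d@letters, "")
    for (ch in unique(unlist(lets))) {
      idx <- which(vapply(lets, function(x) ch %in% x, logical(1)))
      expect_equal(idx, seq(min(idx), max(idx)))  # contiguous in sorted order
    }
  }
})

test_that("pooled CV evaluation ties accuracies, rates and AUCs together", {
  set.seed(35)
  X <- rbind(matrix(rnorm(30 * 4), 30, 4),
             matrix(rnorm(30 * 4, 3), 30, 4))
  y <- factor(rep(c("A", "B"), each = 30))
  r <- runCV(X, y, modelSuite()$medium_knn,
             cvConfig(k = 5, repetitions = 2, seed = 21))
  ev <- evaluateCvResult(r)
  expect_equal(100 * sum(diag(ev$confusion)) / sum(ev$confusion),
               accuracies(r)[1], tolerance = 1e-9)
  expect_equal(ev$rates$tp_rate + ev$rates$fn_rate, rep(100, 2))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_equal(unname(ev$auc["overall"]),
               mean(ev$auc[c("A", "B")]), tolerance = 1e-12)
})
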