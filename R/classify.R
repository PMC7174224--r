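#' The 22-classifier suite
#'
#' Frozen hyperparameter presets for the five model families used in the
#' benchmark: 3 decision trees (maximum 100/20/4 splits), 2 Gaussian
#' discriminants (linear/quadratic, pseudoinverse covariance), 6 SVMs
#' (linear, quadratic and cubic polynomial kernels; Gaussian kernels at
#' scale \eqn{\sqrt{P}/4}, \eqn{\sqrt P} and \eqn{4\sqrt P} for
#' Fine/Medium/Coarse, P = feature count), 6 kNN variants (k = 1/10/100;
#' k = 10 with cosine metric, Minkowski-3 metric, and squared-inverse
#' distance weighting) and 5 ensembles of 30 learners (boosted trees, bagged
#' trees, random-subspace discriminant and random-subspace 1-NN with
#' subspace dimension \eqn{\lceil P/2 \rceil}, and random-undersampling
#' boosted trees).
#'
#' @return Named list of 22 [ModelSpec] objects.
#' @export
#' @examples
#' length(modelSuite())
#' vapply(modelSuite(), function(s) s@family, character(1))
modelSuite <- function() {
  sp <- function(id, name, family, ...)
    new("ModelSpec", id = id, name = name, family = family, params = list(...))
  specs <- list(
    sp("fine_tree", "Fine Tree", "tree", maxSplits = 100L),
    sp("medium_tree", "Medium Tree", "tree", maxSplits = 20L),
    sp("coarse_tree", "Coarse Tree", "tree", maxSplits = 4L),
    sp("linear_discriminant", "Linear Discriminant", "discriminant",
       type = "linear"),
    sp("quadratic_discriminant", "Quadratic Discriminant", "discriminant",
       type = "quadratic"),
    sp("linear_svm", "Linear SVM", "svm", kernel = "linear"),
    sp("quadratic_svm", "Quadratic SVM", "svm", kernel = "polynomial",
       degree = 2L),
    sp("cubic_svm", "Cubic SVM", "svm", kernel = "polynomial", degree = 3L),
    sp("fine_gaussian_svm", "Fine Gaussian SVM", "svm", kernel = "radial",
       scaleFactor = 0.25),
    sp("medium_gaussian_svm", "Medium Gaussian SVM", "svm", kernel = "radial",
       scaleFactor = 1),
    sp("coarse_gaussian_svm", "Coarse Gaussian SVM", "svm", kernel = "radial",
       scaleFactor = 4),
    sp("fine_knn", "Fine KNN", "knn", k = 1L, metric = "euclidean"),
    sp("medium_knn", "Medium KNN", "knn", k = 10L, metric = "euclidean"),
    sp("coarse_knn", "Coarse KNN", "knn", k = 100L, metric = "euclidean"),
    sp("cosine_knn", "Cosine KNN", "knn", k = 10L, metric = "cosine"),
    sp("cubic_knn", "Cubic KNN", "knn", k = 10L, metric = "minkowski3"),
    sp("weighted_knn", "Weighted KNN", "knn", k = 10L, metric = "euclidean",
       weight = "squaredinverse"),
    sp("boosted_trees", "Boosted Trees", "ensemble", method = "boost",
       nLearners = 30L, learnRate = 0.1, maxDepth = 5L),
    sp("bagged_trees", "Bagged Trees", "ensemble", method = "bag",
       nLearners = 30L),
    sp("subspace_discriminant", "Subspace Discriminant", "ensemble",
       method = "subspace", learner = "discriminant", nLearners = 30L),
    sp("subspace_knn", "Subspace KNN", "ensemble", method = "subspace",
       learner = "knn", nLearners = 30L),
    sp("rusboost_trees", "RUSBoost Trees", "ensemble", method = "rusboost",
       nLearners = 30L, learnRate = 0.1, maxDepth = 5L))
  names(specs) <- vapply(specs, function(s) s@id, character(1))
  specs
}

#' Dummy majority-class baseline
#'
#' Always predicts the most frequent training class; its class scores are the
#' training class frequencies. Used for cross-validation sanity checks; not a
#' member of [modelSuite()].
#'
#' @return A [ModelSpec] with family \code{baseline}.
#' @export
majorityBaseline <- function() {
  new("ModelSpec", id = "majority", name = "Majority Baseline",
      family = "baseline", params = list())
}

# families whose features are z-scored inside each training fold
.STANDARDIZED_FAMILIES <- c("svm", "knn", "discriminant")
.standardizes <- function(spec) {
  spec@family %in% .STANDARDIZED_FAMILIES ||
    (spec@family == "ensemble" && identical(spec@params$method, "subspace"))
}

## ---- Gaussian discriminant with pseudoinverse covariance -----------------

# eigendecomposition-based pseudoinverse pieces of a covariance matrix
.covPseudo <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  tol <- max(e$values, 0) * 1e-10
  keep <- e$values > tol
  list(vec = e$vectors[, keep, drop = FALSE],
       inv = 1 / e$values[keep],
       logdet = sum(log(e$values[keep])))
}

.fitDiscriminant <- function(X, y, type = c("linear", "quadratic")) {
  type <- match.arg(type)
  classes <- levels(y)
  mus <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  priors <- as.numeric(table(y)[classes]) / length(y)
  if (type == "linear") {
    Sw <- Reduce(`+`, lapply(classes, function(cl) {
      Xc <- scale(X[y == cl, , drop = FALSE], center = TRUE, scale = FALSE)
      crossprod(Xc)
    })) / max(1, nrow(X) - length(classes))
    covs <- rep(list(.covPseudo(Sw)), length(classes))
  } else {
    covs <- lapply(classes, function(cl) {
      Xc <- scale(X[y == cl, , drop = FALSE], center = TRUE, scale = FALSE)
      .covPseudo(crossprod(Xc) / max(1, sum(y == cl) - 1))
    })
  }
  list(classes = classes, mus = mus, covs = covs, priors = priors, type = type)
}

.predictDiscriminant <- function(fit, X) {
  K <- length(fit$classes)
  delta <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    Z <- sweep(X, 2, fit$mus[[k]]) %*% fit$covs[[k]]$vec
    maha <- as.vector((Z^2) %*% fit$covs[[k]]$inv)
    delta[, k] <- -0.5 * maha - 0.5 * fit$covs[[k]]$logdet + log(fit$priors[k])
  }
  colnames(delta) <- fit$classes
  .softmaxScores(delta)
}

# numerically safe softmax, rows to probabilities
.softmaxScores <- function(delta) {
  m <- apply(delta, 1, max)
  e <- exp(delta - m)
  e / rowSums(e)
}

## ---- distance-based k-nearest neighbors ----------------------------------

.knnDistance <- function(Xtr, Xte, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else if (metric == "cosine") {
    ntr <- sqrt(rowSums(Xtr^2)); nte <- sqrt(rowSums(Xte^2))
    ntr[ntr == 0] <- 1; nte[nte == 0] <- 1
    1 - (Xte %*% t(Xtr)) / outer(nte, ntr)
  } else if (metric == "minkowski3") {
    t(apply(Xte, 1, function(x)
      colSums(abs(t(Xtr) - x)^3)^(1 / 3)))
  } else stop("unknown metric: ", metric)
}

.predictKnn <- function(Xtr, ytr, Xte, k, metric = "euclidean",
                        weight = "none") {
  k <- min(k, nrow(Xtr))
  D <- .knnDistance(Xtr, Xte, metric)
  classes <- levels(ytr)
  scores <- matrix(0, nrow(Xte), length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Xte))) {
    ord <- order(D[i, ])[seq_len(k)]
    w <- if (weight == "squaredinverse")
      1 / pmax(D[i, ord], 1e-12)^2 else rep(1, k)
    for (j in seq_len(k))
      scores[i, as.character(ytr[ord[j]])] <-
        scores[i, as.character(ytr[ord[j]])] + w[j]
  }
  scores / rowSums(scores)
}

## ---- trees and ensembles --------------------------------------------------

# grow a deep tree, then prune back to at most maxSplits splits
.fitTree <- function(X, y, maxSplits, weights = NULL) {
  df <- data.frame(y = y, X)
  fit <- rpart::rpart(y ~ ., data = df, weights = weights, method = "class",
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 5,
                                                     minbucket = 2,
                                                     maxdepth = 30))
  cpt <- fit$cptable
  if (max(cpt[, "nsplit"]) > maxSplits) {
    ok <- cpt[cpt[, "nsplit"] <= maxSplits, , drop = FALSE]
    fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"])
  }
  fit
}

.predictTree <- function(fit, X) {
  predict(fit, newdata = data.frame(X), type = "prob")
}

# SAMME multiclass boosting over depth-limited trees; optionally with random
# undersampling of the majority classes at each iteration (RUSBoost)
.fitBoost <- function(X, y, nLearners = 30L, learnRate = 0.1, maxDepth = 5L,
                      rus = FALSE) {
  n <- length(y); K <- nlevels(y)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(cp = 0, xval = 0, minsplit = 5, minbucket = 2,
                               maxdepth = maxDepth)
  for (m in seq_len(nLearners)) {
    if (rus) {
      nmin <- min(table(y))
      idx <- unlist(lapply(levels(y), function(cl) {
        cand <- which(y == cl)
        if (length(cand) <= nmin) cand
        else sample(cand, nmin, prob = w[cand] / sum(w[cand]))
      }))
      df <- data.frame(y = y[idx], X[idx, , drop = FALSE])
      fit <- rpart::rpart(y ~ ., data = df, method = "class", control = ctrl)
    } else {
      df <- data.frame(y = y, X)
      fit <- rpart::rpart(y ~ ., data = df, weights = w * n, method = "class",
                          control = ctrl)
    }
    pred <- factor(predict(fit, newdata = data.frame(X), type = "class"),
                   levels = levels(y))
    mis <- pred != y
    err <- sum(w[mis]) / sum(w)
    if (err >= 1 - 1 / K) { w <- rep(1 / n, n); next }
    err <- max(err, 1e-10)
    alpha <- learnRate * (log((1 - err) / err) + log(K - 1))
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas, classes = levels(y))
}

.predictBoost <- function(fit, X) {
  K <- length(fit$classes)
  votes <- matrix(0, nrow(X), K, dimnames = list(NULL, fit$classes))
  for (m in seq_along(fit$learners)) {
    pred <- predict(fit$learners[[m]], newdata = data.frame(X), type = "class")
    votes[cbind(seq_len(nrow(X)), match(pred, fit$classes))] <-
      votes[cbind(seq_len(nrow(X)), match(pred, fit$classes))] + fit$alphas[m]
  }
  .softmaxScores(votes)
}

# random-subspace ensemble over linear discriminant or 1-NN base learners
.fitSubspace <- function(X, y, learner, nLearners = 30L) {
  P <- ncol(X)
  dim <- ceiling(P / 2)
  members <- lapply(seq_len(nLearners), function(m) {
    feat <- sort(sample.int(P, dim))
    base <- if (learner == "discriminant")
      .fitDiscriminant(X[, feat, drop = FALSE], y, "linear")
    else list(Xtr = X[, feat, drop = FALSE], ytr = y)
    list(feat = feat, base = base)
  })
  list(members = members, learner = learner, classes = levels(y))
}

.predictSubspace <- function(fit, X) {
  acc <- 0
  for (mb in fit$members) {
    s <- if (fit$learner == "discriminant")
      .predictDiscriminant(mb$base, X[, mb$feat, drop = FALSE])
    else .predictKnn(mb$base$Xtr, mb$base$ytr, X[, mb$feat, drop = FALSE],
                     k = 1L)
    acc <- acc + s
  }
  acc / length(fit$members)
}

## ---- unified fit/predict ---------------------------------------------------

# fit spec on (Xtr, ytr), return out-of-fold scores for Xte; class columns in
# levels(ytr) order
.fitPredict <- function(spec, Xtr, ytr, Xte) {
  classes <- levels(ytr)
  scores <- switch(spec@family,
    baseline = {
      freq <- as.numeric(table(ytr)[classes]) / length(ytr)
      matrix(freq, nrow(Xte), length(classes), byrow = TRUE,
             dimnames = list(NULL, classes))
    },
    tree = .predictTree(.fitTree(Xtr, ytr, spec@params$maxSplits), Xte),
    discriminant = .predictDiscriminant(
      .fitDiscriminant(Xtr, ytr, spec@params$type), Xte),
    svm = {
      p <- spec@params
      gamma <- if (identical(p$kernel, "radial"))
        1 / (p$scaleFactor^2 * ncol(Xtr)) else 1 / ncol(Xtr)
      fit <- e1071::svm(x = Xtr, y = ytr, kernel = p$kernel,
                        degree = p$degree %||% 3L, gamma = gamma, coef0 = 1,
                        cost = 1, probability = TRUE, scale = FALSE)
      pr <- attr(predict(fit, Xte, probability = TRUE), "probabilities")
      pr[, classes, drop = FALSE]
    },
    knn = .predictKnn(Xtr, ytr, Xte, spec@params$k, spec@params$metric,
                      spec@params$weight %||% "none"),
    ensemble = {
      p <- spec@params
      switch(p$method,
        boost = .predictBoost(.fitBoost(Xtr, ytr, p$nLearners, p$learnRate,
                                        p$maxDepth), Xte),
        rusboost = .predictBoost(.fitBoost(Xtr, ytr, p$nLearners, p$learnRate,
                                           p$maxDepth, rus = TRUE), Xte),
        bag = {
          fit <- randomForest::randomForest(x = Xtr, y = ytr,
                                            ntree = p$nLearners)
          predict(fit, Xte, type = "prob")[, classes, drop = FALSE]
        },
        subspace = .predictSubspace(
          .fitSubspace(Xtr, ytr, p$learner, p$nLearners), Xte),
        stop("unknown ensemble method"))
    },
    stop("unknown model family: ", spec@family))
  scores <- scores[, classes, drop = FALSE]
  labels <- factor(classes[max.col(scores, ties.method = "first")],
                   levels = classes)
  list(labels = labels, scores = scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validation configuration
#'
#' @param k number of folds (>= 2).
#' @param repetitions number of independent repeated partitions.
#' @param seed master integer seed.
#' @return A named list.
#' @export
cvConfig <- function(k = 5L, repetitions = 10L, seed = 1L) {
  stopifnot(k >= 2, repetitions >= 1)
  list(k = as.integer(k), repetitions = as.integer(repetitions),
       seed = as.integer(seed))
}

#' Stratified fold assignment
#'
#' Partitions samples into k folds preserving class proportions: within each
#' class the (shuffled) members are dealt round-robin, so per-class fold
#' counts differ by at most one. Deterministic given the seed.
#'
#' @param labels factor (or vector) of class labels; every class must have at
#'   least \code{k} members.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
#' @examples
#' table(stratifiedFolds(rep(c("A", "B", "C"), each = 10), k = 5, seed = 1),
#'       rep(c("A", "B", "C"), each = 10))
stratifiedFolds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    stop("every class must have at least k members for stratified k-fold")
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

#' Repeated stratified cross-validation of one classifier
#'
#' For each repetition a fresh stratified k-fold partition is drawn (the
#' repetition index perturbs the master seed deterministically). Within each
#' fold, features are z-scored using training-fold statistics only for the
#' distance- and kernel-based families (SVM, kNN, discriminants, subspace
#' ensembles); tree-based models use raw features. Out-of-fold predictions
#' are pooled, and the repetition's accuracy is the pooled correct fraction
#' on the percent scale. A model-fit failure marks the repetition invalid
#' (accuracy \code{NA}) and is recorded.
#'
#' @param x numeric matrix (samples x features) or a
#'   \code{SummarizedExperiment} with features in rows and the class column
#'   \code{class} in \code{colData}.
#' @param labels factor of class labels (ignored if \code{x} is a
#'   \code{SummarizedExperiment}).
#' @param spec a [ModelSpec].
#' @param config a [cvConfig()] list.
#' @return A [CvResult].
#' @export
runCV <- function(x, labels = NULL, spec, config = cvConfig()) {
  if (is(x, "SummarizedExperiment")) {
    labels <- SummarizedExperiment::colData(x)$class
    x <- t(SummarizedExperiment::assay(x))
  }
  X <- as.matrix(x)
  if (anyNA(X)) stop("feature table contains missing values")
  y <- factor(labels)
  n <- nrow(X)
  accs <- rep(NA_real_, config$repetitions)
  predictions <- vector("list", config$repetitions)
  scoresList <- vector("list", config$repetitions)
  failures <- character(0)
  for (r in seq_len(config$repetitions)) {
    foldSeed <- as.integer((as.numeric(config$seed) + r * 99991) %% 2147483647)
    folds <- stratifiedFolds(y, config$k, foldSeed)
    pred <- factor(rep(NA_character_, n), levels = levels(y))
    sc <- matrix(NA_real_, n, nlevels(y), dimnames = list(NULL, levels(y)))
    bad <- FALSE
    for (f in seq_len(config$k)) {
      te <- folds == f
      Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (.standardizes(spec)) {
        mu <- colMeans(Xtr)
        sdv <- apply(Xtr, 2, stats::sd)
        sdv[sdv == 0 | !is.finite(sdv)] <- 1
        Xtr <- scale(Xtr, mu, sdv); Xte <- scale(Xte, mu, sdv)
      }
      set.seed(as.integer((foldSeed + f * 7919) %% 2147483647))
      res <- tryCatch(.fitPredict(spec, Xtr, y[!te], Xte),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("rep %d fold %d: %s", r, f,
                                        conditionMessage(res)))
        bad <- TRUE
        break
      }
      pred[te] <- res$labels
      sc[te, ] <- res$scores
    }
    if (!bad) {
      accs[r] <- 100 * mean(pred == y)
      predictions[[r]] <- pred
      scoresList[[r]] <- sc
    }
  }
  new("CvResult", modelId = spec@id, modelName = spec@name,
      accuracies = accs, predictions = predictions, scores = scoresList,
      labels = y, failures = failures)
}
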