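#' Confusion matrix with fixed class order
#'
#' Rows are true classes, columns predicted classes. When all labels are
#' commercial saffron grades the fixed order Pushal, Negin, Sargol is used;
#' otherwise pass \code{classes} explicitly. Labels outside the class set are
#' an error.
#'
#' @param trueLabels,predictedLabels equal-length label vectors.
#' @param classes character vector fixing the class order.
#' @return C x C integer matrix of counts.
#' @export
#' @examples
#' confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), classes = c("A", "B"))
confusionMatrix <- function(trueLabels, predictedLabels, classes = NULL) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  if (is.null(classes)) {
    u <- unique(c(trueLabels, predictedLabels))
    classes <- if (all(u %in% SAFFRON_CLASSES)) SAFFRON_CLASSES else sort(u)
  }
  if (!all(c(trueLabels, predictedLabels) %in% classes))
    stop("labels outside the declared class set")
  table(factor(trueLabels, levels = classes),
        factor(predictedLabels, levels = classes)) |>
    unclass() |> as.matrix()
}

#' Per-class TP/FN/PP/FD rates
#'
#' True-positive rate (recall), false-negative rate, positive predictive rate
#' (precision) and false-discovery rate per class, as percentages. By
#' construction TP + FN = 100 and PP + FD = 100 for every class. A class with
#' no true samples (or no predictions) has undefined recall (precision) and
#' is reported as \code{NA} with a warning.
#'
#' @param cm square confusion matrix (rows true, columns predicted).
#' @return data.frame with columns \code{class, tp_rate, fn_rate, pp_rate,
#'   fd_rate}.
#' @export
classRates <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  rs <- rowSums(cm); cs <- colSums(cm)
  if (any(rs == 0)) warning("class with no true samples: TP/FN rate undefined")
  if (any(cs == 0)) warning("class with no predictions: PP/FD rate undefined")
  tp <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  pp <- ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_)
  data.frame(class = classes, tp_rate = tp, fn_rate = 100 - tp,
             pp_rate = pp, fd_rate = 100 - pp, row.names = NULL)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps thresholds over the class-membership score, grouping tied scores,
#' and integrates by the trapezoid rule; with this tie handling the AUC
#' equals the concordance probability (ties count one half). Requires both
#' positive and negative samples.
#'
#' @param scores numeric vector of scores (larger = more positive).
#' @param labels label vector.
#' @param positiveClass the label treated as positive.
#' @return list with \code{curve} (data.frame \code{fpr, tpr}, from (0,0) to
#'   (1,1)) and \code{auc}.
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.1), c("A", "A", "B", "B"), "A")$auc  # 1
rocAuc <- function(scores, labels, positiveClass) {
  stopifnot(all(is.finite(scores)))
  pos <- labels == positiveClass
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0)
    stop("both positive and negative samples are required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(p); fpCum <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tpCum[last] / nP)
  fpr <- c(0, fpCum[last] / nN)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition over a list of per-group
#' observations (here: per-repetition classifier accuracies), fitted through
#' \code{stats::aov}. If the within-group variance is zero while all group
#' means are equal the F statistic is undefined and returned as \code{NA}.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list with \code{F, dfBetween, dfWithin, errorMeanSquare, p,
#'   ssBetween, ssWithin}.
#' @export
anovaOneway <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  tab <- anova(aov(values ~ g))
  ssb <- tab[1, "Sum Sq"]; ssw <- tab[2, "Sum Sq"]
  ems <- tab[2, "Mean Sq"]
  f <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
  if (ssw == 0 && ssb == 0) { f <- NA_real_; p <- NA_real_ }
  list(F = f, dfBetween = tab[1, "Df"], dfWithin = tab[2, "Df"],
       errorMeanSquare = ems, p = p, ssBetween = ssb, ssWithin = ssw)
}

# studentized range quantile; stats::qtukey occasionally fails to converge at
# the low protection-level probabilities, so fall back to inverting ptukey
.qtukeyRobust <- function(p, nmeans, df) {
  q <- suppressWarnings(qtukey(p, nmeans, df))
  if (is.finite(q)) return(q)
  uniroot(function(x) ptukey(x, nmeans, df) - p,
          lower = 1e-8, upper = 1e3, tol = 1e-9)$root
}

#' Duncan's multiple range test
#'
#' Stepwise multiple-range grouping of ordered group means. For a stretch of
#' \eqn{r} adjacent ordered means the least significant range is
#' \eqn{q_{1-(1-\alpha)^{r-1}}(r, df) \sqrt{EMS / n}}, with the studentized
#' range quantile computed numerically. Ranges are examined from the widest
#' down; a range lying inside a stretch already declared homogeneous is not
#' tested (the bridging rule). Groups sharing a letter are not significantly
#' different.
#'
#' @param means named numeric vector of group means.
#' @param nPerGroup common group size (the design must be balanced).
#' @param errorMeanSquare,dfWithin error mean square and its degrees of
#'   freedom from [anovaOneway()].
#' @param alpha nominal two-mean significance level.
#' @return A [DuncanResult].
#' @export
duncanGroups <- function(means, nPerGroup, errorMeanSquare, dfWithin,
                         alpha = 0.05) {
  if (length(nPerGroup) != 1L)
    stop("unbalanced group sizes: Duncan's test requires a balanced design")
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  homog <- list()
  contained <- function(i, j)
    any(vapply(homog, function(h) h[1] <= i && j <= h[2], logical(1)))
  if (k >= 2) {
    for (span in k:2) {
      Rr <- .qtukeyRobust((1 - alpha)^(span - 1), span, dfWithin) *
        sqrt(errorMeanSquare / nPerGroup)
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1L
        if (contained(i, j)) next
        if (m[i] - m[j] <= Rr) homog[[length(homog) + 1L]] <- c(i, j)
      }
    }
  }
  for (i in seq_len(k)) if (!contained(i, i))
    homog[[length(homog) + 1L]] <- c(i, i)
  starts <- vapply(homog, `[`, numeric(1), 1)
  homog <- homog[order(starts)]
  lett <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(homog, function(h) h[1] <= i && i <= h[2],
                                logical(1)))], collapse = "")
  }, character(1))
  new("DuncanResult", means = m, letters = lett, alpha = alpha,
      errorMeanSquare = errorMeanSquare, dfWithin = as.numeric(dfWithin),
      nPerGroup = as.integer(nPerGroup))
}

#' Pooled evaluation of a cross-validated classifier
#'
#' Builds the pooled confusion matrix and rate table of one repetition of a
#' [CvResult] (the first by default), and one-vs-rest AUCs from its pooled
#' out-of-fold class scores, with the overall AUC as their unweighted mean.
#'
#' @param result a [CvResult].
#' @param repetition which repetition's pooled predictions to use.
#' @return list with \code{confusion}, \code{rates} and \code{auc} (named
#'   vector: per class plus \code{overall}).
#' @export
evaluateCvResult <- function(result, repetition = 1L) {
  pred <- result@predictions[[repetition]]
  if (is.null(pred)) stop("repetition ", repetition, " is invalid (fit failure)")
  classes <- levels(result@labels)
  cm <- confusionMatrix(result@labels, pred, classes = classes)
  sc <- result@scores[[repetition]]
  aucs <- vapply(classes, function(cl)
    rocAuc(sc[, cl], result@labels, cl)$auc, numeric(1))
  list(confusion = cm, rates = classRates(cm),
       auc = c(aucs, overall = mean(aucs)))
}
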