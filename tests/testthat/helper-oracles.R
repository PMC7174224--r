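# Independent brute-force oracles used across test files. These deliberately
# re-derive quantities by direct enumeration, never by calling the package
# functions they check.

# co-occurrence by explicit pair enumeration over every pixel
naiveGlcm <- function(gray, dr, dc, levels) {
  q <- floor(gray * levels / 256) + 1
  q[q > levels] <- levels
  counts <- matrix(0, levels, levels)
  H <- nrow(gray); W <- ncol(gray)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 >= 1 && i2 <= H && j2 >= 1 && j2 <= W) {
      counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
      counts[q[i2, j2], q[i, j]] <- counts[q[i2, j2], q[i, j]] + 1
    }
  }
  counts / sum(counts)
}

# the four statistics by plain double loops over all cells
naiveGlcmStats <- function(p) {
  L <- nrow(p)
  mui <- 0; muj <- 0
  for (i in 1:L) for (j in 1:L) { mui <- mui + i * p[i, j]; muj <- muj + j * p[i, j] }
  vi <- 0; vj <- 0
  for (i in 1:L) for (j in 1:L) {
    vi <- vi + (i - mui)^2 * p[i, j]; vj <- vj + (j - muj)^2 * p[i, j]
  }
  contrast <- 0; corr <- 0; energy <- 0; homog <- 0
  for (i in 1:L) for (j in 1:L) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    energy <- energy + p[i, j]^2
    homog <- homog + p[i, j] / (1 + abs(i - j))
    if (vi > 0 && vj > 0)
      corr <- corr + (i - mui) * (j - muj) * p[i, j] / sqrt(vi * vj)
  }
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog)
}

# AUC as the concordance probability over all positive-negative pairs
concordanceAuc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# two-pass one-way ANOVA sums of squares
naiveAnova <- function(groups) {
  values <- unlist(groups)
  gm <- mean(values)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(values) - length(groups)
  list(F = (ssb / dfb) / (ssw / dfw), ssb = ssb, ssw = ssw,
       sst = sum((values - gm)^2))
}

# random confusion matrix with nonzero row and column sums
fuzzConfusion <- function(C = 3) {
  repeat {
    cm <- matrix(rpois(C * C, lambda = 8), C, C)
    if (all(rowSums(cm) > 0) && all(colSums(cm) > 0)) return(cm)
  }
}

# population standard deviation (divide by n)
popSd <- function(x) sqrt(mean((x - mean(x))^2))
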