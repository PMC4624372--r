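# Brute-force oracles, kept deliberately independent of the package's
# implementation paths: direct transcriptions of the defining formulas.

# Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j) * m / j, capped at 1.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Welch two-sample t statistic and two-sided p.
bruteWelch <- function(x1, x2) {
  v1 <- var(x1) / length(x1)
  v2 <- var(x2) / length(x2)
  t <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x1) - 1) + v2^2 / (length(x2) - 1))
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Balanced two-way ANOVA with interaction via the sums-of-squares
# decomposition.
bruteTwoWayAnova <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- table(a, b)
  stopifnot(length(unique(as.vector(n))) == 1)  # balanced
  ncell <- n[1, 1]
  g <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  ssa <- ncell * nlevels(b) * sum((ma - g)^2)
  ssb <- ncell * nlevels(a) * sum((mb - g)^2)
  cellOf <- interaction(a, b)
  ssab <- 0
  for (la in levels(a)) for (lb in levels(b)) {
    cm <- mean(y[a == la & b == lb])
    ssab <- ssab + ncell * (cm - ma[[la]] - mb[[lb]] + g)^2
  }
  sse <- sum((y - ave(y, cellOf))^2)
  dfe <- length(y) - nlevels(a) * nlevels(b)
  Fa <- (ssa / (nlevels(a) - 1)) / (sse / dfe)
  Fb <- (ssb / (nlevels(b) - 1)) / (sse / dfe)
  Fab <- (ssab / ((nlevels(a) - 1) * (nlevels(b) - 1))) / (sse / dfe)
  c(F_a = Fa, F_b = Fb, F_ab = Fab, df2 = dfe)
}

# Naive agglomerative complete-linkage clustering; returns merge heights.
bruteCompleteLinkageHeights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestH <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < bestH) {
        bestH <- h
        best <- c(i, j)
      }
    }
    heights <- c(heights, bestH)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Top3 by the literal rule: sort peptides by cross-sample mean, take the
# first three, average per sample.
bruteTop3 <- function(pepMatrix) {
  means <- rowMeans(pepMatrix)
  top <- order(-means, rownames(pepMatrix))[seq_len(min(3, nrow(pepMatrix)))]
  colMeans(pepMatrix[top, , drop = FALSE])
}

# Median-of-log-ratio scaling factors to a given reference column.
bruteNormFactors <- function(a, ref) {
  apply(a, 2, function(col) {
    ok <- a[, ref] > 0 & col > 0
    exp(median(log(a[ok, ref]) - log(col[ok])))
  })
}

# Outlier scores by direct transcription of the defining formula.
bruteOutlierScores <- function(prox, cls) {
  cls <- factor(cls)
  out <- rep(NA_real_, nrow(prox))
  for (cl in levels(cls)) {
    i <- which(cls == cl)
    if (length(i) < 2) next
    r <- sapply(i, function(ii)
      length(i) / max(sum(prox[ii, setdiff(i, ii)]^2), .Machine$double.xmin))
    dev <- r - median(r)
    m <- mad(r)
    out[i] <- if (m > 0) dev / m else ifelse(dev == 0, 0, sign(dev) * Inf)
  }
  out
}

# A small noise-free generator configuration shared across tests.
quietConfig <- function(seed = 1, ...) {
  simConfig(seed = seed, noiseCV = 0, sampleScaleSD = 0, ...)
}

# Run the quantification chain up to the secreted matrix.
secretedMatrix <- function(sim, k = 3) {
  pq <- top3Quantify(sim$peptides, sim$metadata)
  pq <- filterMinPeptides(pq, k)
  pq <- normaliseAbundances(pq, "reference_set", sim$reference)
  subsetReference(pq, sim$reference)
}
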