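sepData <- function(seed, n = 20, p = 10, gap = 10) {
  # one perfectly separating feature among noise
  set.seed(seed)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("P%05d", 1:p), sprintf("M%02d", 1:n)))
  y <- factor(rep(c("high", "low"), each = n / 2))
  X[1, ] <- ifelse(y == "high", gap, 0) + rnorm(n, sd = 0.1)
  list(X = abs(X), y = y)
}

test_that("a perfectly separating feature dominates OOB error and importance", {
  hits <- logical(40)
  errs <- numeric(40)
  for (s in seq_along(hits)) {
    d <- sepData(s)
    fit <- fitRF(d$X, d$y, ntree = 300, seed = deriveSeed(1, s))
    errs[s] <- fit$oob_error
    hits[s] <- names(which.max(fit$vi)) == "P00001"
  }
  expect_lt(mean(errs), 0.5)          # far below chance on average
  expect_gte(mean(hits), 0.95)
})

test_that("null data yields OOB error near the base rate and near-zero VI", {
  nseed <- 200
  errs <- numeric(nseed)
  for (s in seq_len(nseed)) {
    set.seed(deriveSeed(5, s))
    n <- 80
    X <- matrix(rlnorm(15 * n), 15, n,
                dimnames = list(sprintf("P%05d", 1:15), sprintf("M%02d", 1:n)))
    y <- factor(rep(c("a", "b"), each = n / 2))
    errs[s] <- fitRF(X, y, ntree = 150, seed = deriveSeed(6, s))$oob_error
  }
  mcse <- sd(errs) / sqrt(nseed)
  expect_lt(abs(mean(errs) - 0.5), 3 * mcse + 0.02)
})

test_that("single-tree forests obey the OOB contract", {
  d <- sepData(3)
  fit <- fitRF(d$X, d$y, ntree = 1, seed = 9)
  # proximity from one tree is 0/1-valued
  expect_true(all(fit$proximity %in% c(0, 1)))
  # OOB error computed only over that tree's OOB samples
  expect_true(any(is.na(fit$predicted)))
  ok <- !is.na(fit$predicted)
  expect_equal(fit$oob_error, mean(fit$predicted[ok] != d$y[ok]))
})

test_that("degenerate class sizes are rejected", {
  d <- sepData(4)
  expect_error(fitRF(d$X, factor(rep("a", 20)), ntree = 10), "2 classes")
  y <- factor(c("a", rep("b", 19)))
  expect_error(fitRF(d$X, y, ntree = 10), "at least 2 samples")
})

test_that("mtry tuning starts at round(sqrt(p)) and finds the grid argmin", {
  d <- sepData(11, p = 31)
  expect_equal(unclass(tuneMtry(d$X[1, , drop = FALSE], d$y))[1], 1L)
  tuned <- tuneMtry(d$X, d$y, ntree = 300, seed = 2)
  ev <- attr(tuned, "evaluated")
  expect_equal(ev$mtry[1], 6L)  # round(sqrt(31))
  # oracle: refit every visited candidate and take the argmin
  oracle <- vapply(ev$mtry, function(m)
    fitRF(d$X, d$y, ntree = 300, mtry = m,
          seed = deriveSeed(2, m))$oob_error, numeric(1))
  best <- ev$mtry[order(oracle, ev$mtry)][1]
  expect_equal(as.integer(tuned), best)
})

test_that("replicated RF with one replicate equals the single fit", {
  sim <- simulatePeptideTable(simConfig(seed = 19))
  sec <- secretedMatrix(sim)
  cfg <- rfConfig(nTrees = 200, nReplicates = 1, nPermutations = 0,
                  mtry = 5, seed = 77)
  rep1 <- replicatedRF(sec, colData(sec)$sc_level, cfg)
  single <- fitRF(sec, colData(sec)$sc_level, ntree = 200, mtry = 5,
                  seed = deriveSeed(77, 1))
  expect_equal(medianOOBError(rep1), single$oob_error)
  expect_equal(unname(rep1@confusion), unname(single$confusion))
  vi <- viTable(rep1)
  expect_equal(vi$vi_mean[match(names(single$vi), vi$accession)],
               unname(single$vi))
})

test_that("mean proximity is a valid similarity and the error is stable under column permutation", {
  sim <- simulatePeptideTable(simConfig(seed = 43))
  sec <- secretedMatrix(sim)
  y <- colData(sec)$sc_level
  cfg <- rfConfig(nTrees = 300, nReplicates = 40, nPermutations = 0,
                  mtry = 5, seed = 5)
  f1 <- replicatedRF(sec, y, cfg)
  p <- proximityMatrix(f1)
  expect_equal(p, t(p))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(diag(p)), rep(1, ncol(sec)))
  # feature order must not matter beyond Monte-Carlo noise
  perm <- rev(seq_len(nrow(sec)))
  f2 <- replicatedRF(abundances(sec)[perm, ], y, cfg)
  expect_lt(abs(medianOOBError(f1) - medianOOBError(f2)), 2 / 30 + 1e-9)
})

test_that("permutation p is 0 when no permutation reaches a perfect observed error", {
  d <- sepData(21)
  cfg <- rfConfig(nTrees = 300, nReplicates = 1, nPermutations = 50,
                  mtry = 3, seed = 13)
  obs <- fitRF(d$X, d$y, ntree = 300, mtry = 3,
               seed = deriveSeed(13, 1))$oob_error
  expect_equal(obs, 0)
  pv <- permutationPValue(d$X, d$y, obs, cfg)
  perr <- attr(pv, "permutation_errors")
  expect_true(all(perr > 0))
  expect_equal(unname(pv["p"]), 0)
  expect_equal(unname(pv["p_smoothed"]), 1 / 51)
})

test_that("the VI threshold rule reproduces the published 7-protein set", {
  ref <- referenceVITable()
  sel <- importantProteins(ref[, c("accession", "vi_mean")])
  expect_length(sel, 7)
  expect_identical(sel, ref$accession[1:7])
  # magnitude-free: any positive rescaling selects the same set
  sel2 <- importantProteins(setNames(2.7 * ref$vi_mean, ref$accession))
  expect_identical(sel2, sel)
})

test_that("VI selection matches a brute-force filter on random scores", {
  expect_identical(importantProteins(c(a = 2, b = 2, c = 2)), character(0))
  set.seed(55)
  for (rep in 1:25) {
    vi <- setNames(rnorm(12), paste0("P", 1:12))
    thr <- abs(min(vi))
    expect_setequal(importantProteins(vi), names(vi)[vi > thr])
  }
})

test_that("outlier scores follow the defining formula", {
  # all-ones proximity within class: raw n/(n-1), scores 0, none flagged
  p1 <- matrix(1, 6, 6)
  cls <- rep(c("a", "b"), each = 3)
  os <- outlierScores(p1, cls)
  expect_equal(os$raw, rep(3 / 2, 6))
  expect_equal(os$score, rep(0, 6))
  expect_false(any(os$flagged))

  # constructed 6-sample fixture: one sample nearly disconnected from its
  # class exceeds the threshold, the rest stay below
  prox <- matrix(0.02, 6, 6)
  close <- c(0.80, 0.85, 0.90, 0.82, 0.88, 0.86, 0.84, 0.87, 0.83, 0.86)
  k <- 1
  for (i in 1:4) for (j in (i + 1):5) {
    prox[i, j] <- prox[j, i] <- close[k]
    k <- k + 1
  }
  prox[6, 1:5] <- prox[1:5, 6] <- 0.01
  diag(prox) <- 1
  os2 <- outlierScores(prox, rep("a", 6))
  expect_true(os2$flagged[6])
  expect_false(any(os2$flagged[1:5]))
  expect_equal(os2$score, bruteOutlierScores(prox, rep("a", 6)))

  # random symmetric proximities match the independent reimplementation
  set.seed(77)
  for (rep in 1:10) {
    m <- matrix(runif(64), 8, 8)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    cls2 <- rep(c("x", "y"), each = 4)
    expect_equal(outlierScores(m, cls2)$score, bruteOutlierScores(m, cls2))
  }

  # class of size one is not evaluable
  os3 <- outlierScores(p1, c("a", rep("b", 5)))
  expect_false(os3$evaluable[1])
  expect_true(is.na(os3$score[1]))
})

test_that("classical MDS of a proximity matrix preserves structure", {
  # two perfectly separated blocks collapse to two points on axis 1
  blocks <- kronecker(diag(2), matrix(1, 3, 3))
  colnames(blocks) <- rownames(blocks) <- paste0("M", 1:6)
  xy <- mdsFromProximity(blocks)
  expect_lt(max(abs(xy[1:3, 1] - xy[1, 1])), 1e-8)
  expect_lt(max(abs(xy[4:6, 1] - xy[4, 1])), 1e-8)
  expect_gt(abs(xy[1, 1] - xy[4, 1]), 0.5)
  # sign convention: first non-zero loading positive
  expect_gt(xy[1, 1], 0)

  # 3-point configuration with a known planar embedding: pairwise distances
  # reproduced to 1e-8
  pts <- rbind(c(0, 0), c(0.3, 0), c(0.1, 0.25))
  D <- as.matrix(dist(pts))
  xy3 <- mdsFromProximity(1 - D)
  expect_equal(as.matrix(dist(xy3)), D, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_warning(mdsFromProximity(1 - as.matrix(dist(cbind(1:3))), k = 3),
                 "axes")
})
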