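#' @importFrom randomForest randomForest importance
NULL

# Accept a ProteinQuant (proteins x samples) or a plain matrix and return
# the samples x features matrix that classifiers expect.
.featureMatrix <- function(x) {
  if (is(x, "ProteinQuant")) t(abundances(x)) else {
    stopifnot(is.matrix(x))
    t(x)
  }
}

.checkClasses <- function(y) {
  y <- factor(y)
  tab <- table(y)
  if (length(tab) < 2L) stop("need at least 2 classes")
  if (any(tab < 2L))
    stop("every class needs at least 2 samples (violated by: ",
         paste(names(tab)[tab < 2L], collapse = ", "), ")")
  y
}

#' Fit a single random-forest classification model
#'
#' One random-forest model (via the \pkg{randomForest} engine, the same used
#' in the original analyses of this design): `ntree` fully grown trees on
#' bootstrap resamples, `mtry` features considered per split.  Returns the
#' out-of-bag (OOB) error rate (fraction of samples whose majority vote over
#' the trees in which they were OOB mismatches the true label; samples never
#' OOB are excluded, which only matters at very small `ntree`), per-feature
#' variable importance as mean decrease in OOB accuracy (raw, in percentage
#' points, and the SE-scaled variant), and the sample proximity matrix
#' (fraction of trees in which two samples share a terminal node).
#'
#' @param x [ProteinQuant-class] or protein x sample matrix.
#' @param y class labels (factor or character), one per sample.
#' @param ntree trees per model.
#' @param mtry features per split; default `floor(sqrt(p))`.
#' @param seed integer seed.
#' @return list with `oob_error`, `confusion` (named `correct`/`incorrect`),
#'   `vi` and `vi_scaled` (named numeric), `proximity`, `predicted`.
#' @export
fitRF <- function(x, y, ntree = 10000L, mtry = NULL, seed = 1L) {
  X <- .featureMatrix(x)
  y <- .checkClasses(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  rf <- randomForest(X, y, ntree = ntree, mtry = mtry,
                     importance = TRUE, proximity = TRUE)
  pred <- rf$predicted
  ok <- !is.na(pred)
  err <- mean(pred[ok] != y[ok])
  list(
    oob_error = err,
    confusion = c(correct = sum(pred[ok] == y[ok]),
                  incorrect = sum(pred[ok] != y[ok])),
    vi = 100 * importance(rf, type = 1, scale = FALSE)[, 1],
    vi_scaled = importance(rf, type = 1, scale = TRUE)[, 1],
    proximity = rf$proximity,
    predicted = pred
  )
}

#' Tune the number of features tried per split
#'
#' Stepwise search for the `mtry` minimising OOB error: starting from
#' `round(sqrt(p))`, candidates are repeatedly halved and doubled while the
#' relative OOB improvement is at least `improve` (5% by default).  Each
#' candidate is evaluated with one forest under a seed derived from `seed`
#' and the candidate value, so the search is deterministic.  Ties go to the
#' smallest `mtry`.
#'
#' @param x,y,ntree,seed as in [fitRF()].
#' @param improve minimum relative OOB improvement to keep stepping.
#' @return the selected `mtry` (integer) with attribute `evaluated`, a
#'   data.frame of the candidates tried and their OOB errors.
#' @export
tuneMtry <- function(x, y, ntree = 1000L, improve = 0.05, seed = 1L) {
  X <- .featureMatrix(x)
  p <- ncol(X)
  if (p == 1L) return(structure(1L, evaluated = data.frame(
    mtry = 1L, oob = NA_real_)))
  y <- .checkClasses(y)
  evalErr <- function(m)
    fitRF(X_t, y, ntree = ntree, mtry = m, seed = deriveSeed(seed, m))$oob_error
  X_t <- t(X)  # fitRF expects protein x sample
  m0 <- max(1L, min(p, as.integer(round(sqrt(p)))))
  errs <- c()
  errs[as.character(m0)] <- evalErr(m0)
  for (dir in c(-1, 1)) {
    mprev <- m0
    errprev <- errs[[as.character(m0)]]
    repeat {
      m <- if (dir < 0) max(1L, as.integer(floor(mprev / 2)))
           else min(p, as.integer(ceiling(mprev * 2)))
      if (m == mprev) break
      err <- evalErr(m)
      errs[as.character(m)] <- err
      gain <- if (errprev > 0) 1 - err / errprev else -Inf
      if (gain < improve) break
      mprev <- m
      errprev <- err
    }
  }
  cand <- as.integer(names(errs))
  o <- order(unname(errs), cand)
  structure(cand[o[1]],
            evaluated = data.frame(mtry = cand, oob = unname(errs)))
}

#' Replicated random-forest analysis
#'
#' Because a random forest is stochastic, the model is refit
#' `config@nReplicates` times under independently derived seeds.  The OOB
#' classification error is reported as the (lower) median across replicates,
#' with the confusion counts of the replicate attaining it; per-protein
#' variable importance is averaged across replicates with a 95% CI
#' (percentile by default); the proximity matrix is the mean across
#' replicates, and feeds classical MDS and the outlier scores; the
#' per-sample predicted class is the majority OOB prediction across
#' replicates (ties broken by class-label order).  If
#' `config@nPermutations > 0` the permutation significance of the median
#' error is computed with [permutationPValue()].  `mtry` is tuned once per
#' analysis when not fixed in the config.
#'
#' @param x [ProteinQuant-class] or protein x sample matrix.
#' @param y class labels, one per sample.
#' @param config an [RFConfig-class] object.
#' @return an [RFSummary-class] object.
#' @examples
#' sim <- simulatePeptideTable(simConfig(seed = 1))
#' pq <- subsetReference(
#'   normaliseAbundances(filterMinPeptides(top3Quantify(sim$peptides,
#'                                                      sim$metadata)),
#'                       "reference_set", sim$reference),
#'   sim$reference)
#' fit <- replicatedRF(pq, colData(pq)$sc_level,
#'                     rfConfig(nTrees = 100, nReplicates = 5,
#'                              nPermutations = 0, seed = 1))
#' fit
#' @export
replicatedRF <- function(x, y, config = rfConfig()) {
  validObject(config)
  y <- .checkClasses(y)
  Xp <- if (is(x, "ProteinQuant")) abundances(x) else x
  mtry <- config@mtry
  if (is.na(mtry))
    mtry <- as.integer(tuneMtry(Xp, y, ntree = min(config@nTrees, 1000L),
                                seed = deriveSeed(config@seed, 0L)))
  n <- ncol(Xp)
  nr <- config@nReplicates
  errs <- numeric(nr)
  viSum <- viSqSum <- NULL
  viMat <- matrix(NA_real_, nr, nrow(Xp), dimnames = list(NULL, rownames(Xp)))
  viScaledSum <- 0
  proxSum <- matrix(0, n, n)
  votes <- matrix(0L, n, nlevels(y), dimnames = list(colnames(Xp), levels(y)))
  confusions <- vector("list", nr)
  for (r in seq_len(nr)) {
    fit <- fitRF(Xp, y, ntree = config@nTrees, mtry = mtry,
                 seed = deriveSeed(config@seed, r))
    errs[r] <- fit$oob_error
    viMat[r, ] <- fit$vi
    viScaledSum <- viScaledSum + fit$vi_scaled
    proxSum <- proxSum + fit$proximity
    confusions[[r]] <- fit$confusion
    ok <- !is.na(fit$predicted)
    idx <- cbind(which(ok), as.integer(fit$predicted[ok]))
    votes[idx] <- votes[idx] + 1L
  }
  medErr <- lowerMedian(errs)
  medRep <- which(errs == medErr)[1]

  viMean <- colMeans(viMat)
  ci <- if (config@ciType == "percentile") {
    apply(viMat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  } else {
    sds <- apply(viMat, 2, stats::sd)
    rbind(viMean - 1.96 * sds, viMean + 1.96 * sds)
  }
  viTab <- data.frame(
    accession = rownames(Xp),
    vi_mean = unname(viMean),
    vi_ci_low = unname(ci[1, ]), vi_ci_high = unname(ci[2, ]),
    vi_scaled_mean = unname(viScaledSum / nr),
    stringsAsFactors = FALSE)
  viTab <- viTab[order(-viTab$vi_mean), ]
  rownames(viTab) <- NULL

  prox <- proxSum / nr
  prox <- (prox + t(prox)) / 2
  diag(prox) <- 1
  dimnames(prox) <- list(colnames(Xp), colnames(Xp))
  predicted <- levels(y)[apply(votes, 1, which.max)]

  cfg <- config
  cfg@mtry <- as.integer(mtry)
  out <- new("RFSummary",
    medianOOBError = medErr,
    confusion = confusions[[medRep]],
    replicateErrors = errs,
    pValue = NA_real_, pValueSmoothed = NA_real_,
    viTable = viTab,
    importantSet = importantProteins(viTab),
    proximity = prox,
    mdsCoords = mdsFromProximity(prox),
    outlierTable = outlierScores(prox, y,
                                 threshold = config@outlierThreshold),
    predictedClass = predicted,
    classLabels = as.character(y),
    config = cfg)
  if (config@nPermutations > 0L) {
    pp <- permutationPValue(Xp, y, medErr, cfg)
    out@pValue <- pp[["p"]]
    out@pValueSmoothed <- pp[["p_smoothed"]]
  }
  validObject(out)
  out
}

#' Permutation significance of an observed classification error
#'
#' For each of `config@nPermutations` permutations, the class labels are
#' shuffled uniformly at random and a single forest is fit; the p-value is
#' the fraction of permuted models whose OOB error is at or below the
#' observed error.  A `(count + 1) / (n + 1)` smoothed variant is also
#' returned (never exactly zero).
#'
#' @param x [ProteinQuant-class] or protein x sample matrix.
#' @param y the true class labels.
#' @param observedError the observed (median replicated) OOB error.
#' @param config an [RFConfig-class] object; `mtry` should be the value used
#'   for the observed model.
#' @return named numeric vector `c(p =, p_smoothed =)` with attribute
#'   `permutation_errors`.
#' @export
permutationPValue <- function(x, y, observedError, config = rfConfig()) {
  validObject(config)
  y <- .checkClasses(y)
  Xp <- if (is(x, "ProteinQuant")) abundances(x) else x
  mtry <- config@mtry
  if (is.na(mtry)) mtry <- max(1L, floor(sqrt(nrow(Xp))))
  nperm <- config@nPermutations
  errs <- numeric(nperm)
  for (k in seq_len(nperm)) {
    s <- deriveSeed(config@seed, 100000L + k)
    set.seed(s)
    yp <- sample(y)
    # a permutation can empty no class, so class sizes stay valid
    errs[k] <- fitRF(Xp, yp, ntree = config@nTrees, mtry = mtry,
                     seed = deriveSeed(s, 1L))$oob_error
  }
  hits <- sum(errs <= observedError + 1e-12)
  structure(c(p = hits / nperm, p_smoothed = (hits + 1) / (nperm + 1)),
            permutation_errors = errs)
}

#' Variable-importance selection rule
#'
#' A protein is called important for differentiating samples when its mean
#' variable-importance score is strictly greater than the absolute value of
#' the lowest mean score across all proteins (a data-driven noise threshold:
#' scores at least as far above zero as the most negative score is below).
#'
#' @param vi named numeric vector of mean VI scores, or a data.frame with
#'   columns `accession` and `vi_mean` (as in [viTable()]).
#' @return character vector of selected accessions, ordered by descending
#'   score.
#' @examples
#' importantProteins(c(A = 5, B = 1, C = -2))  # threshold 2 -> "A"
#' @export
importantProteins <- function(vi) {
  if (is.data.frame(vi)) vi <- stats::setNames(vi$vi_mean, vi$accession)
  if (!length(vi)) stop("empty variable-importance table")
  threshold <- abs(min(vi))
  sel <- vi[vi > threshold]
  names(sel)[order(-sel)]
}

#' Proximity-based outlier scores
#'
#' The raw outlierness of sample i is `n_class(i)` divided by the sum of its
#' squared proximities to the other members of its class; samples far from
#' all classmates in the forest get large values.  Raw scores are
#' standardised within class by subtracting the class median and dividing by
#' the class MAD; samples whose standardised score exceeds `threshold`
#' (default 10) are flagged.  When the class MAD is 0, zero deviations
#' standardise to 0.  Classes of size 1 are not evaluable.
#'
#' @param proximity symmetric sample x sample proximity matrix.
#' @param cls class labels, one per sample.
#' @param threshold flagging cutoff on the standardised score.
#' @return data.frame with `sample_id`, `class`, `raw`, `score`, `flagged`,
#'   `evaluable`.
#' @export
outlierScores <- function(proximity, cls, threshold = 10) {
  stopifnot(nrow(proximity) == ncol(proximity),
            length(cls) == nrow(proximity))
  cls <- factor(cls)
  n <- nrow(proximity)
  ids <- rownames(proximity) %||% as.character(seq_len(n))
  raw <- score <- rep(NA_real_, n)
  evaluable <- rep(TRUE, n)
  for (cl in levels(cls)) {
    i <- which(cls == cl)
    if (length(i) < 2L) {
      evaluable[i] <- FALSE
      next
    }
    p2 <- proximity[i, i, drop = FALSE]^2
    denom <- rowSums(p2) - diag(p2)
    denom[denom == 0] <- 1
    r <- length(i) / denom
    dev <- r - stats::median(r)
    m <- stats::mad(r)
    s <- if (m > 0) dev / m else
      ifelse(dev == 0, 0, sign(dev) * Inf)
    raw[i] <- r
    score[i] <- s
  }
  data.frame(sample_id = ids, class = as.character(cls),
             raw = raw, score = score,
             flagged = !is.na(score) & score > threshold,
             evaluable = evaluable, stringsAsFactors = FALSE)
}

#' Classical MDS embedding of a proximity matrix
#'
#' Torgerson (classical) multidimensional scaling of the dissimilarity
#' `D = 1 - proximity`: double-centre `-D^2/2` and take the top-k
#' eigenvectors scaled by the square root of their eigenvalues (via
#' [stats::cmdscale()]).  Axes are sign-fixed so that the first non-zero
#' loading of each axis is positive.  If fewer than `k` positive eigenvalues
#' exist, the available axes are returned with a warning.
#'
#' @param proximity symmetric matrix with values in `[0, 1]`.
#' @param k number of axes requested.
#' @return sample x k coordinate matrix (columns `MDS1`, `MDS2`, ...).
#' @export
mdsFromProximity <- function(proximity, k = 2L) {
  stopifnot(nrow(proximity) == ncol(proximity))
  if (max(abs(proximity - t(proximity))) > 1e-8)
    stop("proximity must be symmetric")
  d <- stats::as.dist(1 - proximity)
  kmax <- min(k, nrow(proximity) - 1L)
  fit <- suppressWarnings(stats::cmdscale(d, k = kmax, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k)
    warning("only ", ncol(pts), " positive-eigenvalue axes available (",
            k, " requested)")
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  rownames(pts) <- rownames(proximity)
  pts
}
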