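#' Per-protein two-sample t-tests
#'
#' A two-sided two-sample t-test per protein on normalised (untransformed)
#' abundances, comparing the two levels of a grouping factor (high vs low
#' sperm competition in the study design).  The Welch unequal-variance form
#' is the default; `var.equal = TRUE` gives the pooled-variance form.
#' Proteins with zero variance in both groups (including all-constant rows)
#' get `t = 0`, `p = 1` and are flagged as degenerate.
#'
#' The t statistic is signed high-level minus low-level (the factor's second
#' level is taken as the baseline when levels are `c("high", "low")`;
#' otherwise the first level is the reference group).
#'
#' @param x [ProteinQuant-class] or protein x sample matrix.
#' @param labels two-level grouping, one per sample.
#' @param var.equal pooled-variance t-test instead of Welch.
#' @param log10Transform test log10 abundances instead (sensitivity
#'   analysis); zeros are excluded per protein.
#' @return data.frame with `accession`, `t`, `df`, `p_value`, `degenerate`.
#' @export
perProteinTTest <- function(x, labels, var.equal = FALSE,
                            log10Transform = FALSE) {
  a <- if (is(x, "ProteinQuant")) abundances(x) else x
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly two levels")
  if (all(c("high", "low") %in% levels(g)))
    g <- factor(g, levels = c("high", "low"))
  if (any(table(g) < 2L)) stop("both groups need at least 2 samples")
  if (log10Transform) {
    a <- log10(a)
    a[!is.finite(a)] <- NA
  }
  res <- t(apply(a, 1, function(v) {
    x1 <- v[g == levels(g)[1]]
    x2 <- v[g == levels(g)[2]]
    if (isTRUE(stats::var(x1, na.rm = TRUE) == 0) &&
        isTRUE(stats::var(x2, na.rm = TRUE) == 0))
      return(c(0, NA, 1, 1))
    tt <- stats::t.test(x1, x2, var.equal = var.equal)
    c(unname(tt$statistic), unname(tt$parameter), tt$p.value, 0)
  }))
  data.frame(accession = rownames(a), t = res[, 1], df = res[, 2],
             p_value = res[, 3], degenerate = res[, 4] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' (`q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1), mapped back to input
#' order; delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bhFDR <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Per-protein one-way ANOVA screen
#'
#' Fixed-effects one-way ANOVA per protein across a grouping (the screening
#' analysis of standard label-free packages).  With two groups the F test is
#' algebraically the pooled-variance t-test (`F = t^2`).  Degenerate rows
#' (no residual variation, or an undefined statistic) get `p = 1` with a
#' flag.
#'
#' @param x [ProteinQuant-class] or protein x sample matrix.
#' @param groups grouping, one per sample (>= 2 levels).
#' @param log10Transform analyse log10 abundances (zeros excluded).
#' @return data.frame with `accession`, `F`, `p_value`, `degenerate`.
#' @export
perProteinANOVA <- function(x, groups, log10Transform = FALSE) {
  a <- if (is(x, "ProteinQuant")) abundances(x) else x
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (log10Transform) {
    a <- log10(a)
    a[!is.finite(a)] <- NA
  }
  res <- t(apply(a, 1, function(v) {
    out <- tryCatch({
      ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
      c(unname(ft$statistic), ft$p.value, 0)
    }, error = function(e) c(NA_real_, 1, 1))
    if (!is.finite(out[2])) out <- c(out[1], 1, 1)
    out
  }))
  data.frame(accession = rownames(a), F = res[, 1], p_value = res[, 2],
             degenerate = res[, 3] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-mean fold changes
#'
#' Ratio of arithmetic group means, high-SC over low-SC; direction is `up`
#' when the ratio exceeds 1, `down` below 1.  A zero low-SC mean leaves the
#' fold change undefined (`NA`, flagged).
#'
#' @param x [ProteinQuant-class] or protein x sample matrix.
#' @param labels two-level grouping (levels `high`/`low`, or the first level
#'   is taken as numerator).
#' @return data.frame with `accession`, `fold_change`, `direction`,
#'   `undefined`.
#' @export
foldChanges <- function(x, labels) {
  a <- if (is(x, "ProteinQuant")) abundances(x) else x
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly two levels")
  if (all(c("high", "low") %in% levels(g)))
    g <- factor(g, levels = c("high", "low"))
  mHigh <- rowMeans(a[, g == levels(g)[1], drop = FALSE])
  mLow <- rowMeans(a[, g == levels(g)[2], drop = FALSE])
  fc <- ifelse(mLow > 0, mHigh / mLow, NA_real_)
  data.frame(accession = rownames(a), fold_change = fc,
             direction = ifelse(is.na(fc), NA_character_,
                                ifelse(fc > 1, "up",
                                       ifelse(fc < 1, "down", "none"))),
             undefined = is.na(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-abundance screen with t-tests, FDR, ANOVA and fold changes
#'
#' Combines the per-protein statistics into one table: Welch t-test p with
#' Benjamini-Hochberg q, one-way ANOVA p, fold change with direction, and a
#' `screened` flag for proteins passing the ANOVA screen (`anova_p < alpha`
#' and at least `minPeptides` quantified peptides).
#'
#' @param x a [ProteinQuant-class] object.
#' @param labels two-level grouping, one per sample.
#' @param alpha screening significance level.
#' @param minPeptides minimum peptide count for the screen.
#' @param var.equal,log10Transform passed to the per-protein tests.
#' @return data.frame with one row per protein.
#' @export
screenDifferential <- function(x, labels, alpha = 0.05, minPeptides = 3L,
                               var.equal = FALSE, log10Transform = FALSE) {
  stopifnot(is(x, "ProteinQuant"))
  tt <- perProteinTTest(x, labels, var.equal = var.equal,
                        log10Transform = log10Transform)
  av <- perProteinANOVA(x, labels, log10Transform = log10Transform)
  fc <- foldChanges(x, labels)
  data.frame(
    accession = tt$accession,
    peptide_count = unname(peptideCounts(x)),
    t = tt$t, p_value = tt$p_value, q_value = bhFDR(tt$p_value),
    anova_p = av$p_value,
    fold_change = fc$fold_change, direction = fc$direction,
    screened = av$p_value < alpha &
      peptideCounts(x) >= minPeptides & !av$degenerate,
    stringsAsFactors = FALSE)
}

#' Prepare a matrix for a clustered heatmap
#'
#' Per-protein (row) centring and unit-variance scaling of the group-mean
#' abundance matrix, followed by agglomerative hierarchical clustering of
#' rows and columns with Euclidean distance and complete linkage.
#' Zero-variance rows are dropped with a warning (they cannot be scaled).
#'
#' @param x [ProteinQuant-class] or protein x sample matrix.
#' @param groups grouping whose per-level means form the columns (e.g. the
#'   four 2x2 treatment cells); `NULL` keeps per-sample columns.
#' @return list with `scaled` (row-scaled matrix), `rowOrder` and `colOrder`
#'   (leaf-order labels), and the `hclust` objects `rowHclust`, `colHclust`.
#' @export
clusterPrep <- function(x, groups = NULL) {
  a <- if (is(x, "ProteinQuant")) abundances(x) else x
  if (!is.null(groups)) {
    g <- factor(groups)
    a <- vapply(levels(g),
                function(l) rowMeans(a[, g == l, drop = FALSE]),
                numeric(nrow(a)))
  }
  if (nrow(a) < 2L) stop("need at least 2 rows to cluster")
  sds <- apply(a, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance row(s)")
    a <- a[sds > 0, , drop = FALSE]
  }
  scaled <- t(scale(t(a)))
  rowH <- stats::hclust(stats::dist(scaled), method = "complete")
  colH <- stats::hclust(stats::dist(t(scaled)), method = "complete")
  list(scaled = scaled,
       rowOrder = rownames(scaled)[rowH$order],
       colOrder = colnames(scaled)[colH$order],
       rowHclust = rowH, colHclust = colH)
}
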