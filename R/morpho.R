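#' Cell means and standard errors of morphometric measures
#'
#' Arithmetic mean and SEM (SD / sqrt(n)) per 2x2 treatment cell per
#' measure, the summary conventionally tabulated for sperm-production
#' parameters.  Single-observation cells get an undefined SEM (`NA`,
#' flagged).
#'
#' @param table morphometric data.frame with `sc_level`, `mr_level` and the
#'   measure columns.
#' @param measures character vector of measure columns; defaults to every
#'   numeric column.
#' @return data.frame with `measure`, `sc_level`, `mr_level`, `n`, `mean`,
#'   `sem`, `sem_undefined`.
#' @export
groupSummaries <- function(table, measures = NULL) {
  stopifnot(all(c("sc_level", "mr_level") %in% names(table)))
  if (is.null(measures))
    measures <- names(table)[vapply(table, is.numeric, logical(1))]
  cell <- interaction(table$sc_level, table$mr_level, drop = TRUE)
  out <- lapply(measures, function(m) {
    n <- as.vector(tapply(table[[m]], cell, length))
    mu <- as.vector(tapply(table[[m]], cell, mean))
    sdv <- as.vector(tapply(table[[m]], cell, stats::sd))
    sem <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
    data.frame(measure = m,
               sc_level = sub("\\..*$", "", levels(cell)),
               mr_level = sub("^.*\\.", "", levels(cell)),
               n = n, mean = mu, sem = sem,
               sem_undefined = n <= 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-way factorial ANOVA of a morphometric measure
#'
#' Fixed-effects 2x2 ANOVA (general linear model) with interaction:
#' `measure ~ SC * MR`.  With the balanced design of this study, sequential
#' (Type I) sums of squares coincide with Type III.  A constant response
#' yields all `F = 0` with `p = 1`.
#'
#' @param table morphometric data.frame (see [groupSummaries()]).
#' @param measure name of the measure column.
#' @param logTransform analyse `log(measure)`.
#' @return data.frame with `term` (`SC`, `MR`, `SC:MR`), `df1`, `df2`, `F`,
#'   `p_value`.
#' @export
factorialAnova <- function(table, measure, logTransform = FALSE) {
  stopifnot(measure %in% names(table))
  d <- data.frame(y = table[[measure]],
                  sc = factor(table$sc_level), mr = factor(table$mr_level))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(d$sc) < 2L || nlevels(d$mr) < 2L ||
      any(table(d$sc, d$mr) == 0))
    stop("empty cell in the 2x2 design")
  if (logTransform) d$y <- log(d$y)
  if (stats::var(d$y) == 0)
    return(data.frame(term = c("SC", "MR", "SC:MR"), df1 = 1L,
                      df2 = nrow(d) - 4L, F = 0, p_value = 1,
                      stringsAsFactors = FALSE))
  aovt <- stats::anova(stats::lm(y ~ sc * mr, data = d))
  dfres <- aovt["Residuals", "Df"]
  f <- aovt[c("sc", "mr", "sc:mr"), "F value"]
  p <- aovt[c("sc", "mr", "sc:mr"), "Pr(>F)"]
  degen <- !is.finite(f)
  f[degen] <- 0
  p[degen] <- 1
  data.frame(term = c("SC", "MR", "SC:MR"),
             df1 = aovt[c("sc", "mr", "sc:mr"), "Df"], df2 = dfres,
             F = f, p_value = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mixed-model likelihood-ratio test with an enclosure random effect
#'
#' Males housed in the same enclosure share a common environment, so the
#' factorial analysis is backed up by a linear mixed model with a random
#' enclosure intercept: `measure ~ SC + MR + (1 | enclosure)` (the
#' interaction is tested against the additive model).  The significance of
#' a fixed term is assessed by a likelihood-ratio test between
#' maximum-likelihood fits with and without that term (chi-squared, 1 df);
#' variance components are reported from the REML refit.  A singular fit
#' (zero enclosure variance) is reported but the LRT is still computed.
#'
#' @param table morphometric data.frame with an `enclosure_id` column.
#' @param measure name of the measure column.
#' @param term fixed term to test: `"sc"`, `"mr"` or `"sc:mr"`.
#' @param logTransform analyse `log(measure)`.
#' @return data.frame (one row) with `term`, `chisq`, `df`, `p_value`,
#'   `singular`, `enclosure_sd`, `residual_sd`.
#' @export
mixedModelLRT <- function(table, measure, term = c("sc", "mr", "sc:mr"),
                          logTransform = FALSE) {
  term <- match.arg(term)
  stopifnot(measure %in% names(table),
            "enclosure_id" %in% names(table))
  d <- data.frame(y = table[[measure]],
                  sc = factor(table$sc_level), mr = factor(table$mr_level),
                  enclosure = factor(table$enclosure_id))
  d <- d[stats::complete.cases(d), ]
  if (logTransform) d$y <- log(d$y)
  forms <- switch(term,
    "sc" = c(full = y ~ sc + mr + (1 | enclosure),
             reduced = y ~ mr + (1 | enclosure)),
    "mr" = c(full = y ~ sc + mr + (1 | enclosure),
             reduced = y ~ sc + (1 | enclosure)),
    "sc:mr" = c(full = y ~ sc * mr + (1 | enclosure),
                reduced = y ~ sc + mr + (1 | enclosure)))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(forms$full, data = d, REML = FALSE, control = ctrl)
  reduced <- lme4::lmer(forms$reduced, data = d, REML = FALSE,
                        control = ctrl)
  chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(reduced))))
  fullREML <- lme4::lmer(forms$full, data = d, REML = TRUE, control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(fullREML))
  data.frame(term = toupper(term), chisq = chisq, df = 1L,
             p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
             singular = lme4::isSingular(full),
             enclosure_sd = vc$sdcor[vc$grp == "enclosure"],
             residual_sd = vc$sdcor[vc$grp == "Residual"],
             stringsAsFactors = FALSE)
}
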