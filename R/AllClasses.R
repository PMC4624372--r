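#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' SimConfig: parameters of the synthetic study generator
#'
#' Describes the statistical structure of a 2x2 sperm-competition (SC) by
#' mating-rate (MR) label-free proteomics study: a proteome of `nProteins`
#' proteins spanning `dynamicRangeOrders` orders of abundance magnitude, of
#' which `nSecreted` are secreted (ejaculated) proteins; variable peptide
#' counts per protein; per-sample loading (scaling) factors; multiplicative
#' log-normal noise; and treatment fold changes planted on a subset of the
#' secreted proteins.  A companion block of slots parameterises the
#' morphometric generator (cell means/SDs per measure, optional enclosure
#' random intercept).
#'
#' The seed fully determines the output of both generators.
#'
#' @slot nProteins number of proteins in the simulated proteome.
#' @slot nSecreted number of secreted proteins; these receive the reference
#'   accessions and form the returned reference set.
#' @slot dynamicRangeOrders decades spanned by base protein abundances
#'   (log-uniform).
#' @slot peptideGeomProb success probability of the shifted geometric
#'   distribution (minimum 1) used for peptides per protein.
#' @slot groupSizes named integer vector of samples per 2x2 cell, names
#'   `high.low`, `high.high`, `low.low`, `low.high` (SC level first, then MR).
#' @slot enclosureSize named numeric vector `c(high = , low = )`: males per
#'   enclosure at each sperm-competition level.
#' @slot plantedEffects named numeric vector, accession -> fold change
#'   (high-SC over low-SC abundance ratio); accessions must be secreted.
#' @slot noiseCV multiplicative coefficient of variation of the per
#'   (peptide, sample) log-normal noise.
#' @slot sampleScaleSD sdlog of the log-normal per-sample scaling factors.
#' @slot peptideFactorSD sdlog of the log-normal per-peptide response factors.
#' @slot seed integer master seed.
#' @slot morphoGroupSize males per 2x2 cell in the morphometric table.
#' @slot morphoMeans measure x cell matrix of morphometric cell means.
#' @slot morphoSDs measure x cell matrix of within-cell SDs (>= 0).
#' @slot morphoEnclosureSD enclosure random-intercept SD, expressed as a
#'   multiple of the within-cell SD of each measure (0 = no enclosure effect).
#'
#' @seealso [simConfig()] for the user-facing constructor with study defaults.
#' @export
setClass("SimConfig",
  representation(
    nProteins = "integer",
    nSecreted = "integer",
    dynamicRangeOrders = "numeric",
    peptideGeomProb = "numeric",
    groupSizes = "integer",
    enclosureSize = "numeric",
    plantedEffects = "numeric",
    noiseCV = "numeric",
    sampleScaleSD = "numeric",
    peptideFactorSD = "numeric",
    seed = "integer",
    morphoGroupSize = "integer",
    morphoMeans = "matrix",
    morphoSDs = "matrix",
    morphoEnclosureSD = "numeric"
  )
)

.CELLS <- c("high.low", "high.high", "low.low", "low.high")

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
  if (object@nSecreted > object@nProteins)
    msg <- c(msg, "nSecreted must not exceed nProteins")
  if (object@nSecreted < 1L) msg <- c(msg, "nSecreted must be >= 1")
  if (!identical(names(object@groupSizes), .CELLS))
    msg <- c(msg, sprintf("groupSizes must be named %s",
                          paste(.CELLS, collapse = ", ")))
  if (any(object@groupSizes < 2L)) msg <- c(msg, "group sizes must be >= 2")
  if (!all(c("high", "low") %in% names(object@enclosureSize)))
    msg <- c(msg, "enclosureSize must have elements 'high' and 'low'")
  if (any(object@enclosureSize < 1)) msg <- c(msg, "enclosureSize must be >= 1")
  if (length(object@plantedEffects) &&
      (is.null(names(object@plantedEffects)) ||
       any(!nzchar(names(object@plantedEffects)))))
    msg <- c(msg, "plantedEffects must be named by accession")
  if (any(object@plantedEffects <= 0))
    msg <- c(msg, "all planted fold changes must be > 0")
  if (object@noiseCV < 0) msg <- c(msg, "noiseCV must be >= 0")
  if (object@peptideGeomProb <= 0 || object@peptideGeomProb >= 1)
    msg <- c(msg, "peptideGeomProb must be in (0, 1)")
  if (!identical(colnames(object@morphoMeans), .CELLS) ||
      !identical(colnames(object@morphoSDs), .CELLS))
    msg <- c(msg, "morphoMeans/morphoSDs columns must be the four 2x2 cells")
  if (any(object@morphoSDs < 0))
    msg <- c(msg, "morphometric within-cell SDs must be >= 0")
  if (object@morphoEnclosureSD < 0)
    msg <- c(msg, "morphoEnclosureSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ProteinQuant: a protein x sample abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `abundance`
#' assay (non-negative label-free protein abundances), per-protein peptide
#' counts in `rowData()$peptide_count`, sample metadata (SC level, MR level,
#' enclosure) in `colData()`, and the normalisation state recorded in
#' `metadata()$normalisation` (one of `"none"`, `"all_proteins"`,
#' `"reference_set"`).
#'
#' @seealso [top3Quantify()], which constructs the object;
#'   [abundances()], [peptideCounts()], [normalisationMode()] accessors.
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else if (any(assay(object, "abundance") < 0, na.rm = TRUE))
    msg <- c(msg, "abundances must be non-negative")
  if (!"peptide_count" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'peptide_count'")
  else if (any(rowData(object)$peptide_count < 1L))
    msg <- c(msg, "peptide_count must be >= 1")
  nm <- metadata(object)$normalisation
  if (is.null(nm) ||
      !nm %in% c("none", "all_proteins", "reference_set"))
    msg <- c(msg, "metadata()$normalisation must be one of none, all_proteins, reference_set")
  if (is.null(rownames(object)))
    msg <- c(msg, "rownames (accessions) are required")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinQuant object
#'
#' @param abundance numeric protein x sample matrix with accession rownames
#'   and sample-ID colnames.
#' @param peptideCount integer vector, distinct quantified peptides per
#'   protein (same order as rows).
#' @param colData optional `DataFrame`/data.frame of sample metadata.
#' @param normalisation normalisation state to record.
#' @return a [ProteinQuant-class] object.
#' @export
ProteinQuant <- function(abundance, peptideCount,
                         colData = NULL,
                         normalisation = c("none", "all_proteins",
                                           "reference_set")) {
  normalisation <- match.arg(normalisation)
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(row.names = colnames(abundance))
  } else {
    colData <- S4Vectors::DataFrame(colData)
    rownames(colData) <- colnames(abundance)
  }
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = S4Vectors::DataFrame(peptide_count = as.integer(peptideCount)),
    colData = colData
  )
  metadata(se)$normalisation <- normalisation
  new("ProteinQuant", se)
}

#' RFConfig: settings for a replicated random-forest analysis
#'
#' Defaults follow the study design: 10,000 trees per model, 1,000 model
#' replicates, 1,000 label permutations, `mtry` tuned automatically, and an
#' outlier-score threshold of 10.
#'
#' @slot nTrees trees per random-forest model.
#' @slot nReplicates number of independently seeded model replicates.
#' @slot nPermutations label-permuted models for the significance test
#'   (0 disables the permutation test).
#' @slot mtry features tried per split; `NA` means tune automatically.
#' @slot outlierThreshold standardised outlier-score cutoff.
#' @slot ciType `"percentile"` or `"normal"` 95% CIs for variable importance.
#' @slot seed integer master seed; replicate and permutation seeds are derived
#'   from it by a counter scheme.
#' @export
setClass("RFConfig",
  representation(
    nTrees = "integer", nReplicates = "integer", nPermutations = "integer",
    mtry = "integer", outlierThreshold = "numeric", ciType = "character",
    seed = "integer"
  )
)

setValidity("RFConfig", function(object) {
  msg <- character()
  if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@nPermutations < 0L) msg <- c(msg, "nPermutations must be >= 0")
  if (!is.na(object@mtry) && object@mtry < 1L)
    msg <- c(msg, "mtry must be >= 1 (or NA for automatic tuning)")
  if (!object@ciType %in% c("percentile", "normal"))
    msg <- c(msg, "ciType must be 'percentile' or 'normal'")
  if (length(msg)) msg else TRUE
})

#' @rdname RFConfig-class
#' @param nTrees,nReplicates,nPermutations,mtry,outlierThreshold,ciType,seed
#'   see the class slots.
#' @return an `RFConfig` object.
#' @export
rfConfig <- function(nTrees = 10000L, nReplicates = 1000L,
                     nPermutations = 1000L, mtry = NA_integer_,
                     outlierThreshold = 10, ciType = "percentile",
                     seed = 1L) {
  new("RFConfig",
      nTrees = as.integer(nTrees), nReplicates = as.integer(nReplicates),
      nPermutations = as.integer(nPermutations),
      mtry = as.integer(mtry), outlierThreshold = outlierThreshold,
      ciType = ciType, seed = as.integer(seed))
}

#' RFSummary: result of a replicated random-forest analysis
#'
#' @slot medianOOBError lower-median out-of-bag error rate across replicates
#'   (fraction in \[0, 1\]).
#' @slot confusion named integer vector `c(correct, incorrect)` at the
#'   replicate attaining the median error.
#' @slot replicateErrors per-replicate OOB error rates.
#' @slot pValue permutation tail probability (proportion of label-permuted
#'   models with OOB error at or below the observed median).
#' @slot pValueSmoothed the (count + 1) / (n + 1) smoothed variant.
#' @slot viTable data.frame of per-protein variable importance: mean decrease
#'   in OOB accuracy in percentage points (`vi_mean`, with 95% CI) and the
#'   SE-scaled variant (`vi_scaled_mean`), averaged across replicates.
#' @slot importantSet accessions whose mean VI exceeds the absolute value of
#'   the lowest mean VI.
#' @slot proximity sample x sample mean proximity matrix.
#' @slot mdsCoords sample x 2 classical MDS coordinates from `1 - proximity`.
#' @slot outlierTable per-sample raw and standardised outlier scores.
#' @slot predictedClass per-sample majority OOB prediction across replicates.
#' @slot classLabels the true class labels.
#' @slot config the `RFConfig` used (with the tuned `mtry` filled in).
#' @export
setClass("RFSummary",
  representation(
    medianOOBError = "numeric", confusion = "integer",
    replicateErrors = "numeric",
    pValue = "numeric", pValueSmoothed = "numeric",
    viTable = "data.frame", importantSet = "character",
    proximity = "matrix", mdsCoords = "matrix",
    outlierTable = "data.frame",
    predictedClass = "character", classLabels = "character",
    config = "RFConfig"
  )
)

setValidity("RFSummary", function(object) {
  msg <- character()
  p <- object@proximity
  if (nrow(p) && (max(abs(p - t(p))) > 1e-8 ||
                  any(p < -1e-8) || any(p > 1 + 1e-8) ||
                  max(abs(diag(p) - 1)) > 1e-8))
    msg <- c(msg, "proximity must be symmetric with unit diagonal in [0,1]")
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (!all(object@importantSet %in% object@viTable$accession))
    msg <- c(msg, "importantSet must be a subset of viTable accessions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nProteins, "proteins (",
      object@nSecreted, "secreted ) over",
      object@dynamicRangeOrders, "decades\n")
  cat("  samples per cell:",
      paste(names(object@groupSizes), object@groupSizes, collapse = ", "),
      "\n")
  cat("  planted effects:",
      if (length(object@plantedEffects))
        paste(names(object@plantedEffects),
              sprintf("%.3g", object@plantedEffects), collapse = ", ")
      else "none", "\n")
  cat("  noise CV:", object@noiseCV, " seed:", object@seed, "\n")
})

setMethod("show", "ProteinQuant", function(object) {
  cat("ProteinQuant:", nrow(object), "proteins x", ncol(object), "samples\n")
  cat("  normalisation:", metadata(object)$normalisation, "\n")
  cat("  peptide counts: min", min(peptideCounts(object)),
      "median", stats::median(peptideCounts(object)),
      "max", max(peptideCounts(object)), "\n")
  callNextMethod()
})

setMethod("show", "RFSummary", function(object) {
  n <- sum(object@confusion)
  cat("RFSummary (", object@config@nReplicates, "replicates x",
      object@config@nTrees, "trees )\n")
  cat(sprintf("  median OOB error: %.2f%% (%d correct : %d incorrect)\n",
              100 * object@medianOOBError,
              object@confusion[["correct"]], object@confusion[["incorrect"]]))
  if (!is.na(object@pValue))
    cat(sprintf("  permutation P = %.4g (smoothed %.4g, %d permutations)\n",
                object@pValue, object@pValueSmoothed,
                object@config@nPermutations))
  cat("  important proteins (", length(object@importantSet), "):",
      paste(object@importantSet, collapse = ", "), "\n")
})
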