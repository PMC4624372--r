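#' Top3 peptide-to-protein quantification
#'
#' Estimates the abundance of each protein in each sample as the arithmetic
#' mean of its three most abundant peptides, the standard Top3 rule of
#' label-free LC-MS quantification.  Peptides are ranked once per protein by
#' their mean abundance across all samples (ties broken by peptide ID), so
#' the same peptide set is averaged in every sample and the measure is
#' comparable across samples.  Proteins with fewer than three peptides use
#' all available peptides; the number of distinct quantified peptides is
#' recorded per protein for the downstream minimum-peptide filter.  Missing
#' (peptide, sample) combinations are treated as abundance 0.
#'
#' @param peptides data.frame with columns `accession`, `peptide_id`,
#'   `sample_id`, `abundance` (non-negative); `(accession, peptide_id,
#'   sample_id)` must be unique.
#' @param metadata optional data.frame of sample metadata with a `sample_id`
#'   column; fixes the sample order and populates `colData()`.
#' @return a [ProteinQuant-class] object (normalisation state `"none"`).
#' @examples
#' sim <- simulatePeptideTable(simConfig(seed = 1))
#' pq <- top3Quantify(sim$peptides, sim$metadata)
#' pq
#' @export
top3Quantify <- function(peptides, metadata = NULL) {
  req <- c("accession", "peptide_id", "sample_id", "abundance")
  if (!is.data.frame(peptides) || !all(req %in% names(peptides)))
    stop("peptides must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(peptides) == 0L) stop("peptide table is empty")
  if (any(peptides$abundance < 0)) stop("abundances must be non-negative")
  key <- paste(peptides$accession, peptides$peptide_id, peptides$sample_id)
  if (anyDuplicated(key))
    stop("(accession, peptide_id, sample_id) must be unique")

  samples <- if (!is.null(metadata)) as.character(metadata$sample_id) else
    unique(peptides$sample_id)
  if (!all(peptides$sample_id %in% samples))
    stop("peptide table contains samples absent from metadata")
  pepkey <- paste(peptides$accession, peptides$peptide_id, sep = "\r")
  peps <- unique(data.frame(accession = peptides$accession,
                            key = pepkey, stringsAsFactors = FALSE))
  accessions <- unique(peptides$accession)

  # peptide x sample matrix, absent combinations 0
  pm <- matrix(0, nrow(peps), length(samples),
               dimnames = list(peps$key, samples))
  pm[cbind(match(pepkey, peps$key),
           match(peptides$sample_id, samples))] <- peptides$abundance

  ab <- matrix(0, length(accessions), length(samples),
               dimnames = list(accessions, samples))
  counts <- integer(length(accessions))
  rowsBy <- split(seq_len(nrow(peps)), peps$accession)
  for (i in seq_along(accessions)) {
    rows <- rowsBy[[accessions[i]]]
    counts[i] <- length(rows)
    means <- rowMeans(pm[rows, , drop = FALSE])
    top <- rows[order(-means, peps$key[rows])][seq_len(min(3L, length(rows)))]
    ab[i, ] <- colMeans(pm[top, , drop = FALSE])
  }

  cd <- if (!is.null(metadata)) metadata[match(samples, metadata$sample_id), ,
                                         drop = FALSE] else NULL
  ProteinQuant(ab, counts, colData = cd, normalisation = "none")
}

#' Filter proteins by minimum peptide count
#'
#' Retains exactly the proteins quantified with at least `k` distinct
#' peptides (default 3, the high-confidence quantification rule), preserving
#' row order.
#'
#' @param x a [ProteinQuant-class] object.
#' @param k minimum number of peptides (>= 1).
#' @return the filtered [ProteinQuant-class] object.
#' @export
filterMinPeptides <- function(x, k = 3L) {
  stopifnot(is(x, "ProteinQuant"), k >= 1L)
  x[peptideCounts(x) >= k, ]
}

# Reference run: the sample whose log-ratio distributions to all other
# samples have minimal total variance (ties -> first in column order).
# Only proteins positive in both members of a pair contribute.
.referenceRun <- function(a) {
  la <- log(a)
  la[!is.finite(la)] <- NA
  tot <- vapply(seq_len(ncol(a)), function(r) {
    d <- la[, r] - la
    sum(vapply(seq_len(ncol(a)), function(s) {
      v <- stats::var(d[, s], na.rm = TRUE)
      if (is.na(v)) 0 else v
    }, numeric(1))[-r])
  }, numeric(1))
  which.min(tot)
}

#' Normalise a protein abundance matrix between samples
#'
#' Removes per-sample loading differences by median-log-ratio scaling to a
#' reference run, the deterministic analogue of the normalisation performed
#' by standard label-free packages.  The reference run is the sample whose
#' log-ratio distributions to the other samples have minimal total variance
#' (ties broken by sample order).  For each sample the scaling factor is the
#' exponential of the median, over the normalisation protein set, of the
#' log-ratio of reference-run abundance to that sample's abundance
#' (zero-abundance proteins are excluded from the median); all abundances in
#' the sample are multiplied by the factor.  Afterwards the median log-ratio
#' over the normalisation set between any sample and the reference run is 0,
#' and the operation is idempotent.
#'
#' The normalisation set is either all proteins in the matrix
#' (`mode = "all_proteins"`) or the intersection with a reference set of
#' ejaculated proteins (`mode = "reference_set"`), the conservative choice
#' when treatments may shift the secreted fraction of the proteome.
#'
#' @param x a [ProteinQuant-class] object.
#' @param mode normalisation mode.
#' @param reference character vector of accessions (required for
#'   `"reference_set"`).
#' @return a [ProteinQuant-class] object with the recorded mode and the
#'   per-sample factors in `metadata()$norm_factors`.
#' @export
normaliseAbundances <- function(x, mode = c("all_proteins", "reference_set"),
                                reference = NULL) {
  stopifnot(is(x, "ProteinQuant"))
  mode <- match.arg(mode)
  a <- abundances(x)
  set <- rownames(a)
  if (mode == "reference_set") {
    if (is.null(reference)) stop("mode 'reference_set' requires a reference")
    set <- intersect(set, reference)
    if (!length(set))
      stop("reference set has empty intersection with matrix accessions")
  }
  an <- a[set, , drop = FALSE]
  ref <- .referenceRun(an)
  lref <- log(an[, ref])
  factors <- vapply(seq_len(ncol(an)), function(s) {
    ls <- log(an[, s])
    ok <- is.finite(lref) & is.finite(ls)
    if (!any(ok))
      stop("sample '", colnames(an)[s],
           "' has no non-zero abundances in the normalisation set")
    exp(stats::median(lref[ok] - ls[ok]))
  }, numeric(1))
  out <- x
  assay(out, "abundance") <- sweep(a, 2, factors, `*`)
  metadata(out)$normalisation <- mode
  metadata(out)$norm_factors <- stats::setNames(factors, colnames(a))
  metadata(out)$norm_reference_run <- colnames(an)[ref]
  validObject(out)
  out
}

#' Restrict a matrix to a reference protein set
#'
#' Keeps the proteins in the intersection of the matrix accessions with a
#' reference set (e.g. the ejaculated-protein list), in matrix order.  This
#' is the step that focuses the analysis on secreted proteins that could act
#' within the female reproductive tract.
#'
#' @param x a [ProteinQuant-class] object (normally filtered and normalised).
#' @param reference character vector of accessions.
#' @return the subset [ProteinQuant-class] object.
#' @export
subsetReference <- function(x, reference) {
  stopifnot(is(x, "ProteinQuant"))
  keep <- rownames(x) %in% reference
  if (!any(keep))
    stop("reference set has empty intersection with matrix accessions")
  x[keep, ]
}
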