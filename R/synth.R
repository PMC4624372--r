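#' Construct a synthetic-study configuration
#'
#' Defaults reproduce the structure of the study design: 383 proteins over
#' six orders of abundance magnitude, 31 of them secreted; peptides per
#' protein from a shifted geometric law (minimum 1; secreted proteins are
#' well-covered and carry at least 3) calibrated so that the expected number
#' of proteins with at least three peptides matches the observed retention
#' (147 of 383) of the three-peptide filter; 30 proteomics
#' samples in a 2x2 sperm-competition (SC) by mating-rate (MR) design (7 per
#' high-SC cell, 8 per low-SC cell) nested in enclosures of four (high SC)
#' or two (low SC) males; log-normal per-sample loading factors; per
#' (peptide, sample) multiplicative noise with CV 0.6, calibrated so that
#' after Top3 averaging the protein-level between-male CV is roughly 35%,
#' the variability implied by the study's per-protein t statistics for the
#' planted proteins; and planted
#' high-/low-SC fold changes on five secreted proteins in the directions
#' reported for this system (SVS 6, SVS 5 and CEACAM 10 up; cathepsin D and
#' annexin A5 down) with magnitudes in the 1.2-1.6x range.  Morphometric
#' defaults are the published cell means and SEM-derived SDs for body mass,
#' paired testes mass, epididymal sperm count, daily sperm production and
#' seminal-vesicles mass, with 8 males per cell.
#'
#' @param nProteins,nSecreted,dynamicRangeOrders,peptideGeomProb,groupSizes,enclosureSize,plantedEffects,noiseCV,sampleScaleSD,peptideFactorSD,seed,morphoGroupSize,morphoMeans,morphoSDs,morphoEnclosureSD
#'   see [SimConfig-class]; any subset may be overridden.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7, noiseCV = 0)
#' cfg
#' @export
simConfig <- function(nProteins = 383L,
                      nSecreted = 31L,
                      dynamicRangeOrders = 6,
                      peptideGeomProb = 1 - sqrt(116 / 352),
                      groupSizes = c(high.low = 7L, high.high = 7L,
                                     low.low = 8L, low.high = 8L),
                      enclosureSize = c(high = 4, low = 2),
                      plantedEffects = c(Q64356 = 1.6, P30933 = 1.5,
                                         Q61400 = 1.4, P18242 = 1 / 1.6,
                                         P48036 = 1 / 1.4),
                      noiseCV = 0.6,
                      sampleScaleSD = 0.2,
                      peptideFactorSD = 0.5,
                      seed = 1L,
                      morphoGroupSize = 8L,
                      morphoMeans = NULL,
                      morphoSDs = NULL,
                      morphoEnclosureSD = 0) {
  if (is.null(morphoMeans)) morphoMeans <- .defaultMorphoMeans()
  if (is.null(morphoSDs)) morphoSDs <- .defaultMorphoSDs()
  new("SimConfig",
      nProteins = as.integer(nProteins), nSecreted = as.integer(nSecreted),
      dynamicRangeOrders = dynamicRangeOrders,
      peptideGeomProb = peptideGeomProb,
      groupSizes = stats::setNames(as.integer(groupSizes), names(groupSizes)),
      enclosureSize = enclosureSize, plantedEffects = plantedEffects,
      noiseCV = noiseCV, sampleScaleSD = sampleScaleSD,
      peptideFactorSD = peptideFactorSD, seed = as.integer(seed),
      morphoGroupSize = as.integer(morphoGroupSize),
      morphoMeans = morphoMeans, morphoSDs = morphoSDs,
      morphoEnclosureSD = morphoEnclosureSD)
}

.MEASURES <- c("body_mass_start", "body_mass_end", "paired_testes_mass",
               "epididymal_sperm_count", "daily_sperm_production",
               "seminal_vesicles_mass")

# Published cell means; columns are SC.MR cells (high.low = high SC, low MR).
.defaultMorphoMeans <- function() {
  m <- rbind(
    body_mass_start        = c(15.76, 16.31, 15.88, 16.18),
    body_mass_end          = c(20.14, 20.11, 19.83, 18.99),
    paired_testes_mass     = c(0.196, 0.188, 0.169, 0.174),
    epididymal_sperm_count = c(6.72, 6.69, 5.36, 5.78),
    daily_sperm_production = c(3.04, 3.50, 2.82, 2.60),
    seminal_vesicles_mass  = c(0.151, 0.139, 0.117, 0.115)
  )
  colnames(m) <- .CELLS
  m
}

# Within-cell SDs recovered from published SEMs at n = 8 per cell.
.defaultMorphoSDs <- function() {
  sem <- rbind(
    body_mass_start        = c(0.74, 0.78, 0.56, 0.42),
    body_mass_end          = c(0.83, 0.89, 0.68, 0.78),
    paired_testes_mass     = c(0.007, 0.009, 0.006, 0.012),
    epididymal_sperm_count = c(0.32, 0.47, 0.27, 0.46),
    daily_sperm_production = c(0.24, 0.33, 0.14, 0.16),
    seminal_vesicles_mass  = c(0.015, 0.013, 0.012, 0.012)
  )
  colnames(sem) <- .CELLS
  sem * sqrt(8)
}

# Sample sheet for a 2x2 design with enclosures nested in cells.
.makeSampleSheet <- function(groupSizes, enclosureSize, prefix = "M") {
  sc <- sub("\\..*$", "", names(groupSizes))
  mr <- sub("^.*\\.", "", names(groupSizes))
  rows <- list()
  enclosure <- 0L
  id <- 0L
  for (cell in seq_along(groupSizes)) {
    g <- groupSizes[cell]
    esz <- enclosureSize[[sc[cell]]]
    encl <- rep(seq_len(ceiling(g / esz)), each = esz)[seq_len(g)] + enclosure
    enclosure <- max(encl)
    rows[[cell]] <- data.frame(
      sample_id = sprintf("%s%02d", prefix, id + seq_len(g)),
      sc_level = sc[cell], mr_level = mr[cell],
      enclosure_id = sprintf("E%02d", encl),
      stringsAsFactors = FALSE)
    id <- id + g
  }
  do.call(rbind, rows)
}

# Accessions for a simulated proteome: secreted proteins take the reference
# accessions (padded with generated ones if more are requested), the rest are
# generated placeholders.  All follow the classic UniProt 6-character form.
.simAccessions <- function(nProteins, nSecreted) {
  ref <- secretedReferenceSet()
  secreted <- if (nSecreted <= length(ref)) ref[seq_len(nSecreted)] else
    c(ref, sprintf("P9%04d", seq_len(nSecreted - length(ref))))
  others <- sprintf("P0%04d", seq_len(nProteins - nSecreted))
  list(secreted = secreted, all = c(secreted, others))
}

#' Simulate a peptide-level label-free abundance table
#'
#' Generates a long-format peptide table with the statistical structure the
#' downstream analysis assumes.  Protein base abundances are log-uniform over
#' the configured decades; each protein carries `k >= 1` peptides (shifted
#' geometric) with fixed per-peptide response factors; the abundance of a
#' peptide in a sample is
#' `base x peptide factor x treatment fold effect x sample scaling x noise`,
#' where the fold effect applies only to planted secreted proteins in
#' high-SC samples, sample scaling factors are log-normal (so normalisation
#' has real work to do) and the noise is log-normal with the configured
#' coefficient of variation (mean 1).
#'
#' @param config a [SimConfig-class] object.
#' @return list with elements `peptides` (data.frame: `accession`,
#'   `peptide_id`, `sample_id`, `abundance`), `metadata` (data.frame:
#'   `sample_id`, `sc_level`, `mr_level`, `enclosure_id`) and `reference`
#'   (character vector of secreted accessions).
#' @examples
#' sim <- simulatePeptideTable(simConfig(seed = 1))
#' head(sim$peptides)
#' @export
simulatePeptideTable <- function(config) {
  validObject(config)
  acc <- .simAccessions(config@nProteins, config@nSecreted)
  bad <- setdiff(names(config@plantedEffects), acc$secreted)
  if (length(bad))
    stop("planted accessions not among secreted proteins: ",
         paste(bad, collapse = ", "))
  meta <- .makeSampleSheet(config@groupSizes, config@enclosureSize)
  nsamp <- nrow(meta)

  set.seed(config@seed)
  base <- 10^stats::runif(config@nProteins, 0, config@dynamicRangeOrders) * 1e3
  k <- 1L + stats::rgeom(config@nProteins, config@peptideGeomProb)
  # secreted proteins are well-covered in this tissue: at least 3 peptides,
  # so the reference set always survives the minimum-peptide filter
  k[seq_len(config@nSecreted)] <- k[seq_len(config@nSecreted)] + 2L
  npep <- sum(k)
  pf <- stats::rlnorm(npep, 0, config@peptideFactorSD)
  scale <- stats::rlnorm(nsamp, 0, config@sampleScaleSD)

  prot <- rep(seq_len(config@nProteins), k)
  pepnum <- sequence(k)
  effect <- rep(1, config@nProteins)
  effect[match(names(config@plantedEffects), acc$all)] <- config@plantedEffects

  m <- (base[prot] * pf) %o% scale
  high <- meta$sc_level == "high"
  m[, high] <- m[, high] * effect[prot]
  if (config@noiseCV > 0) {
    sdlog <- sqrt(log1p(config@noiseCV^2))
    noise <- matrix(stats::rlnorm(npep * nsamp, -sdlog^2 / 2, sdlog),
                    npep, nsamp)
    m <- m * noise
  }

  peptides <- data.frame(
    accession = rep(acc$all[prot], nsamp),
    peptide_id = rep(sprintf("%s_pep%02d", acc$all[prot], pepnum), nsamp),
    sample_id = rep(meta$sample_id, each = npep),
    abundance = as.vector(m),
    stringsAsFactors = FALSE)
  list(peptides = peptides, metadata = meta, reference = acc$secreted)
}

#' Simulate a morphometric table
#'
#' Draws per-male sperm-production and seminal-fluid investment measures from
#' normal distributions whose cell means and SDs default to the published
#' values for this study system, optionally with an enclosure random
#' intercept (males sharing an enclosure get a shared normal offset with SD
#' `morphoEnclosureSD` times the within-cell SD of each measure).
#'
#' @param config a [SimConfig-class] object.
#' @return data.frame with one row per male: `subject_id`, `sc_level`,
#'   `mr_level`, `enclosure_id` and the six measures (body mass at start and
#'   end in g, paired testes mass in g, epididymal sperm count in millions,
#'   daily sperm production in millions/testis/day, seminal vesicles mass
#'   in g).
#' @examples
#' head(simulateMorphometrics(simConfig(seed = 1)))
#' @export
simulateMorphometrics <- function(config) {
  validObject(config)
  g <- config@morphoGroupSize
  meta <- .makeSampleSheet(
    stats::setNames(rep(g, 4L), .CELLS), config@enclosureSize, prefix = "S")
  names(meta)[1] <- "subject_id"
  cell <- paste(meta$sc_level, meta$mr_level, sep = ".")

  set.seed(deriveSeed(config@seed, 900001L))
  for (meas in rownames(config@morphoMeans)) {
    mu <- config@morphoMeans[meas, cell]
    sdv <- config@morphoSDs[meas, cell]
    val <- stats::rnorm(nrow(meta), mu, sdv)
    if (config@morphoEnclosureSD > 0) {
      encl <- unique(meta$enclosure_id)
      esd <- config@morphoEnclosureSD *
        tapply(sdv, meta$enclosure_id, mean)[encl]
      shift <- stats::rnorm(length(encl), 0, esd)
      val <- val + shift[match(meta$enclosure_id, encl)]
    }
    meta[[meas]] <- val
  }
  meta
}
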