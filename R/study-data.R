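#' Locate user-supplied study data
#'
#' The original study's quantified data (peptide-level and Top3 CSV exports
#' of the two normalisations, and the morphometric spreadsheet) are
#' distributed as journal supplementary downloads and are not redistributed
#' with this package.  To run the reproduction checks against them, download
#' the supplements, export the tables as CSV in the formats of
#' [readQuantMatrix()] / [readSampleMetadata()] / [readMorphoTable()], and
#' place them under `<package>/extdata/study-data/` (or pass explicit
#' paths):
#'
#' * `top3_all_proteins.csv` - 383-protein Top3 matrix, normalised to all
#'   proteins, with peptide counts.
#' * `top3_ejaculated.csv` - 31-protein Top3 matrix, normalised to the
#'   ejaculated reference set.
#' * `sample_metadata.csv` - `sample_id`, `sc_level`, `mr_level`,
#'   `enclosure_id` for the 30 proteomics samples.
#' * `morphometrics.csv` - per-male morphometric measures with a
#'   `treatment` code column (e.g. `4m2f`).
#'
#' @param name file name under the study-data directory.
#' @return the file path.  `hasStudyData()` reports whether it exists.
#' @export
studyDataFile <- function(name) {
  file.path(system.file("extdata", package = "SFPquant", mustWork = TRUE),
            "study-data", name)
}

#' @rdname studyDataFile
#' @export
hasStudyData <- function(name) {
  file.exists(studyDataFile(name))
}

#' @rdname studyDataFile
#' @param normalisation recorded normalisation state of the matrix loaded.
#' @export
readStudyTop3 <- function(name, normalisation = "reference_set") {
  path <- studyDataFile(name)
  if (!file.exists(path))
    stop("study data file not available: ", path,
         "\nSee ?studyDataFile for how to supply the published tables.")
  readQuantMatrix(path, normalisation = normalisation)
}
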