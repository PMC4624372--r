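#' Read and write the pipeline's tabular formats
#'
#' Plain-text interchange used throughout: peptide tables and morphometric
#' tables as comma-separated CSV, protein matrices as CSV with the accession
#' in the first column (and the peptide count in the second), reference sets
#' as newline-delimited accession lists (blank lines and `#` comments
#' ignored), result tables as TSV with numbers at 6 significant digits so
#' runs diff cleanly.
#'
#' @param path file path.
#' @param x the object to write.
#' @name io
NULL

#' @rdname io
#' @export
readPeptideTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(accession = "character",
                                 peptide_id = "character",
                                 sample_id = "character"))
}

#' @rdname io
#' @export
writePeptideTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readSampleMetadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
writeSampleMetadata <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param normalisation normalisation state to record on the object read.
#' @export
readQuantMatrix <- function(path, normalisation = "none") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "accession" || names(d)[2] != "peptide_count")
    stop("expected columns: accession, peptide_count, then sample IDs")
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d$accession
  ProteinQuant(m, d$peptide_count, normalisation = normalisation)
}

#' @rdname io
#' @export
writeQuantMatrix <- function(x, path) {
  stopifnot(is(x, "ProteinQuant"))
  d <- data.frame(accession = rownames(x),
                  peptide_count = unname(peptideCounts(x)),
                  signif(abundances(x), 6),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readReferenceSet <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  if (!length(x)) stop("reference set is empty")
  bad <- x[!isUniprotAccession(x)]
  if (length(bad))
    warning("accessions not in UniProt form: ",
            paste(utils::head(bad, 5), collapse = ", "))
  x
}

#' @rdname io
#' @export
writeReferenceSet <- function(x, path) {
  writeLines(x, path)
  invisible(path)
}

#' @rdname io
#' @export
readMorphoTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("treatment" %in% names(d) &&
      !all(c("sc_level", "mr_level") %in% names(d))) {
    tc <- parseTreatmentCode(d$treatment)
    d$sc_level <- tc$sc_level
    d$mr_level <- tc$mr_level
  }
  d
}

#' @rdname io
#' @export
writeMorphoTable <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, 6)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a treatment code of the form "4m2f"
#'
#' Treatment cells are conventionally coded by the number of males and
#' females whose cues a subject received: four males = high sperm
#' competition, two = low; four females = high mating rate, two = low.
#'
#' @param code character vector like `"4m2f"`.
#' @return data.frame with `sc_level` and `mr_level`.
#' @export
parseTreatmentCode <- function(code) {
  m <- regmatches(code, regexec("^([0-9]+)m([0-9]+)f$", tolower(code)))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("unparseable treatment code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  males <- as.integer(vapply(m, `[`, "", 2))
  females <- as.integer(vapply(m, `[`, "", 3))
  data.frame(sc_level = ifelse(males >= 4, "high", "low"),
             mr_level = ifelse(females >= 4, "high", "low"),
             stringsAsFactors = FALSE)
}

# TSV writer with explicit 6-significant-digit precision.
writeResultTSV <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(signif(v, 6), format = "g",
                                               digits = 6))
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
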