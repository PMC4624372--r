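#' Accessors for ProteinQuant and RFSummary objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a [ProteinQuant-class] or [RFSummary-class] object.
#' @return `abundances()`: the numeric protein x sample matrix;
#'   `peptideCounts()`: named integer vector of distinct quantified peptides
#'   per protein; `normalisationMode()`: one of `"none"`, `"all_proteins"`,
#'   `"reference_set"`; `medianOOBError()`, `permutationP()`: numbers;
#'   `viTable()`, `outlierScoreTable()`: data.frames; `importantSet()`:
#'   character vector; `proximityMatrix()`, `mdsCoords()`: matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setMethod("abundances", "ProteinQuant", function(x) assay(x, "abundance"))

#' @rdname accessors
#' @export
setGeneric("peptideCounts", function(x) standardGeneric("peptideCounts"))

#' @rdname accessors
#' @export
setMethod("peptideCounts", "ProteinQuant", function(x) {
  stats::setNames(rowData(x)$peptide_count, rownames(x))
})

#' @rdname accessors
#' @export
setGeneric("normalisationMode",
           function(x) standardGeneric("normalisationMode"))

#' @rdname accessors
#' @export
setMethod("normalisationMode", "ProteinQuant",
          function(x) metadata(x)$normalisation)

#' @rdname accessors
#' @export
setGeneric("medianOOBError", function(x) standardGeneric("medianOOBError"))

#' @rdname accessors
#' @export
setMethod("medianOOBError", "RFSummary", function(x) x@medianOOBError)

#' @rdname accessors
#' @export
setGeneric("permutationP", function(x) standardGeneric("permutationP"))

#' @rdname accessors
#' @export
setMethod("permutationP", "RFSummary", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("viTable", function(x) standardGeneric("viTable"))

#' @rdname accessors
#' @export
setMethod("viTable", "RFSummary", function(x) x@viTable)

#' @rdname accessors
#' @export
setGeneric("importantSet", function(x) standardGeneric("importantSet"))

#' @rdname accessors
#' @export
setMethod("importantSet", "RFSummary", function(x) x@importantSet)

#' @rdname accessors
#' @export
setGeneric("proximityMatrix", function(x) standardGeneric("proximityMatrix"))

#' @rdname accessors
#' @export
setMethod("proximityMatrix", "RFSummary", function(x) x@proximity)

#' @rdname accessors
#' @export
setGeneric("mdsCoords", function(x) standardGeneric("mdsCoords"))

#' @rdname accessors
#' @export
setMethod("mdsCoords", "RFSummary", function(x) x@mdsCoords)

#' @rdname accessors
#' @export
setGeneric("outlierScoreTable",
           function(x) standardGeneric("outlierScoreTable"))

#' @rdname accessors
#' @export
setMethod("outlierScoreTable", "RFSummary", function(x) x@outlierTable)
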