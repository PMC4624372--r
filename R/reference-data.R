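#' The secreted (ejaculated) seminal-vesicle protein reference set
#'
#' The 31 seminal-vesicle proteins known to be transferred to the female at
#' ejaculation that overlap the quantified seminal-vesicle proteome of the
#' house mouse (*Mus musculus domesticus*).  These UniProt accessions define
#' the reference-set normalisation mode and the secreted subset analysed by
#' the random-forest classifier.  They are also the default accessions the
#' synthetic generator assigns to its secreted proteins.
#'
#' @return character vector of 31 UniProt accessions.
#' @seealso [referenceVITable()] for the published per-protein summary these
#'   accessions index.
#' @export
secretedReferenceSet <- function() {
  referenceVITable()$accession
}

#' Published variable-importance and t-test summary for the secreted proteins
#'
#' Per-protein reference values reported for the sperm-competition
#' classification of the 31 secreted seminal-vesicle proteins: mean
#' variable-importance score with 95% CI (from 1,000 replicated
#' random-forest models) and the per-protein t-test p and
#' Benjamini-Hochberg q value.  Rows are ordered by descending variable
#' importance.  Shipped as a plain-text table under `extdata/`; used to
#' validate the variable-importance selection rule and the FDR step against
#' published numbers, and to fix the accession list of the reference set.
#'
#' @return data.frame with columns `accession`, `protein`, `vi_mean`,
#'   `vi_ci_low`, `vi_ci_high`, `t_p`, `t_q`.
#' @export
referenceVITable <- function() {
  path <- system.file("extdata", "secreted_vi_ttest.tsv",
                      package = "SFPquant", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
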