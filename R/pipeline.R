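#' Run the full analysis chain on one set of inputs
#'
#' Executes the stages in study order: Top3 quantification, minimum-peptide
#' filter, normalisation to the ejaculated-protein reference set, reference
#' subset, replicated random-forest classification per label (sperm
#' competition, mating rate, and optionally enclosure as a negative
#' control), the univariate differential screen, and (when a morphometric
#' table is supplied) the factorial and mixed-model analyses.  All result
#' tables are written as TSV/CSV with 6-significant-digit numbers plus a
#' machine-readable JSON manifest (package version, seed, config hash), so
#' that two runs with the same seed produce byte-identical outputs.
#'
#' @param peptides peptide table (see [top3Quantify()]).
#' @param metadata sample metadata with `sample_id`, `sc_level`, `mr_level`,
#'   `enclosure_id`.
#' @param reference character vector of ejaculated-protein accessions.
#' @param morpho optional morphometric table (see [simulateMorphometrics()]).
#' @param outDir output directory (created if needed).
#' @param rfSettings an [RFConfig-class]; its seed is the master seed of the
#'   run.
#' @param labels which class labels to fit forests for.
#' @param minPeptides minimum peptide count for the filter.
#' @return invisibly, a list with the `ProteinQuant` objects, the
#'   `RFSummary` per label, the univariate table, the morphometric results
#'   and the manifest.
#' @export
runPipeline <- function(peptides, metadata, reference, morpho = NULL,
                        outDir, rfSettings = rfConfig(),
                        labels = c("sc", "mr"), minPeptides = 3L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[", name, "] ...")
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  quant <- stage("quantify", {
    pq <- top3Quantify(peptides, metadata)
    pq <- filterMinPeptides(pq, minPeptides)
    normaliseAbundances(pq, "reference_set", reference)
  })
  secreted <- stage("subset", subsetReference(quant, reference))
  writeQuantMatrix(secreted, file.path(outDir, "secreted_quant.csv"))

  labcols <- c(sc = "sc_level", mr = "mr_level", enclosure = "enclosure_id")
  rf <- list()
  for (lab in labels) {
    y <- colData(secreted)[[labcols[[lab]]]]
    rf[[lab]] <- stage(paste0("rf-", lab),
                       replicatedRF(secreted, y, rfSettings))
    writeResultTSV(
      cbind(viTable(rf[[lab]]),
            important = viTable(rf[[lab]])$accession %in%
              importantSet(rf[[lab]])),
      file.path(outDir, sprintf("rf_%s_vi.tsv", lab)))
    writeResultTSV(
      data.frame(sample_id = rownames(proximityMatrix(rf[[lab]])),
                 signif(proximityMatrix(rf[[lab]]), 6),
                 check.names = FALSE),
      file.path(outDir, sprintf("rf_%s_proximity.tsv", lab)))
    writeResultTSV(
      data.frame(sample_id = rownames(mdsCoords(rf[[lab]])),
                 signif(mdsCoords(rf[[lab]]), 6), check.names = FALSE),
      file.path(outDir, sprintf("rf_%s_mds.tsv", lab)))
  }

  uni <- stage("univariate",
               screenDifferential(secreted, colData(secreted)$sc_level,
                                  minPeptides = minPeptides))
  writeResultTSV(uni, file.path(outDir, "univariate.tsv"))

  morphoRes <- NULL
  if (!is.null(morpho)) {
    morphoRes <- stage("morpho", {
      meas <- intersect(.MEASURES, names(morpho))
      anv <- do.call(rbind, lapply(meas, function(m)
        cbind(measure = m, factorialAnova(morpho, m))))
      lrt <- do.call(rbind, lapply(meas, function(m)
        cbind(measure = m, mixedModelLRT(morpho, m, "sc"))))
      list(summaries = groupSummaries(morpho, meas), anova = anv,
           mixed = lrt)
    })
    writeResultTSV(morphoRes$summaries,
                   file.path(outDir, "morpho_summaries.tsv"))
    writeResultTSV(morphoRes$anova, file.path(outDir, "morpho_anova.tsv"))
    writeResultTSV(morphoRes$mixed, file.path(outDir, "morpho_mixed.tsv"))
  }

  cfgjson <- jsonlite::toJSON(list(
    n_trees = rfSettings@nTrees, n_replicates = rfSettings@nReplicates,
    n_permutations = rfSettings@nPermutations,
    mtry = if (is.na(rfSettings@mtry)) "auto" else rfSettings@mtry,
    labels = labels, min_peptides = minPeptides), auto_unbox = TRUE)
  manifest <- list(
    package = "SFPquant",
    version = as.character(utils::packageVersion("SFPquant")),
    seed = rfSettings@seed,
    config = jsonlite::fromJSON(cfgjson),
    config_hash = .stringHash(as.character(cfgjson)),
    results = list(
      median_oob_error = lapply(rf, medianOOBError),
      permutation_p = lapply(rf, permutationP),
      n_important = lapply(rf, function(f) length(importantSet(f)))
    ))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(quant = quant, secreted = secreted, rf = rf,
                 univariate = uni, morpho = morphoRes,
                 manifest = manifest))
}

# Deterministic content hash (polynomial rolling hash mod a Mersenne prime),
# dependency-free; used only to tag the manifest with its configuration.
.stringHash <- function(s) {
  b <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (x in b) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}
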