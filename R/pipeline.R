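## Build the run manifest: input checksums, config hash, per-stage counts.
.runManifest <- function(inputs, cfg, trace) {
  cfgList <- list(mafThresholdAD = cfg@mafThresholdAD,
                  mafThresholdAR = cfg@mafThresholdAR,
                  consequenceWhitelist = cfg@consequenceWhitelist,
                  missingMafPolicy = cfg@missingMafPolicy,
                  missingGenotypePolicy = cfg@missingGenotypePolicy,
                  arCarrierScope = cfg@arCarrierScope,
                  relevanceGenes = cfg@relevanceGenes,
                  lofGenes = cfg@lofGenes, pm2Bound = cfg@pm2Bound,
                  bs1Bound = cfg@bs1Bound, minSegregations = cfg@minSegregations)
  files <- inputs[vapply(inputs, function(p) is.character(p) && file.exists(p), logical(1))]
  list(tool = "cleftsift",
       version = as.character(packageVersion("cleftsift")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config_hash = hashObject(cfgList),
       input_checksums = lapply(files, function(p) unname(tools::md5sum(p))),
       stage_counts = setNames(as.list(trace$kept), trace$stage))
}

#' Run the full per-family pipeline: cascade then classification
#'
#' Accepts either file paths (annotated VCF + PED) or in-memory objects
#' ([VariantSet-class] + [Pedigree-class]), applies the four-stage cascade
#' and the ACMG-style classifier, and optionally writes the per-family
#' candidate and trace TSVs plus a run manifest (input checksums, config
#' hash, per-stage attrition counts — counts only, no genotypes, as a
#' pedigree-privacy precaution). Re-running with identical inputs and
#' configuration reproduces byte-identical candidate and trace tables.
#'
#' @param vcf path to the family VCF, or a [VariantSet-class].
#' @param ped path to the PED file, or a [Pedigree-class].
#' @param model inheritance model for the family (`"AD"`/`"AR"`); ignored
#'   when `ped` is a [Pedigree-class] that already carries one.
#' @param cfg a [FilterConfig-class].
#' @param family optional family id when the PED file holds several.
#' @param outDir optional output directory for
#'   `<family>_candidates.tsv`, `<family>_trace.tsv`,
#'   `<family>_manifest.json`.
#' @return list with `candidates` (classified data.frame, including
#'   `denovo_flag`), `trace`, `pedigree` and `manifest`.
#' @export
#' @examples
#' paths <- emitDataset(simulationConfig(seed = 3, nBackground = 30), tempdir())
#' res <- runFamily(paths$vcf, paths$ped, model = "AR")
#' res$trace
runFamily <- function(vcf, ped, model = NULL, cfg = filterConfig(),
                      family = NULL, outDir = NULL) {
  inputs <- list(vcf = if (is.character(vcf)) vcf else NULL,
                 ped = if (is.character(ped)) ped else NULL)
  if (is.character(vcf)) {
    vcf <- tryCatch(readAnnotatedVcf(vcf),
                    error = function(e) stop("stage formats_io (VCF): ",
                                             conditionMessage(e), call. = FALSE))
  }
  if (is.character(ped)) {
    rows <- tryCatch(readPed(ped),
                     error = function(e) stop("stage formats_io (PED): ",
                                              conditionMessage(e), call. = FALSE))
    ped <- tryCatch(validatePedigree(rows, vcfSamples = sampleIds(vcf),
                                     model = model %||% NA_character_,
                                     family = family),
                    error = function(e) stop("stage pedigree_model: ",
                                             conditionMessage(e), call. = FALSE))
  } else if (!is.null(model) && is.na(inheritanceModel(ped))) {
    ped@model <- model
  }
  res <- tryCatch(runCascade(vcf, ped, cfg),
                  error = function(e) stop("stage variant_filtering: ",
                                           conditionMessage(e), call. = FALSE))
  classified <- tryCatch(classifyCandidates(res$candidates, ped, cfg),
                         error = function(e) stop("stage classification: ",
                                                  conditionMessage(e), call. = FALSE))
  classified$denovo_flag <- res$denovoFlag
  manifest <- .runManifest(inputs, cfg, res$trace)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fam <- familyId(ped)
    write.table(classified, file.path(outDir, paste0(fam, "_candidates.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$trace, file.path(outDir, paste0(fam, "_trace.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, paste0(fam, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  list(candidates = classified, trace = res$trace, pedigree = ped,
       manifest = manifest)
}

#' Run a cohort of families and summarize gene/pathway contributions
#'
#' Each family spec is a list with either `vcf`/`ped` paths or
#' `variants`/`pedigree` objects, plus optional `model` and `family`.
#' Per-family results are classified with [runFamily()] and aggregated with
#' [summarizeCohort()].
#'
#' @param familySpecs list of family specs as above.
#' @param cfg a [FilterConfig-class].
#' @param pathwayMap named gene-to-pathway vector ([genePathwayMap()]).
#' @param totalFamilies cohort denominator; defaults to
#'   `length(familySpecs)`.
#' @param outDir optional directory for per-family outputs and the cohort
#'   summary TSV/JSON.
#' @return list with `summary` (a [CohortSummary-class]), `classified`
#'   (row-bound per-family candidate tables) and `traces`.
#' @export
runCohort <- function(familySpecs, cfg = filterConfig(),
                      pathwayMap = genePathwayMap(),
                      totalFamilies = length(familySpecs), outDir = NULL) {
  abortIf(length(familySpecs) < 1L, "need at least one family")
  results <- lapply(familySpecs, function(fs) {
    runFamily(vcf = fs$variants %||% fs$vcf, ped = fs$pedigree %||% fs$ped,
              model = fs$model, cfg = cfg, family = fs$family, outDir = outDir)
  })
  classified <- do.call(rbind, lapply(results, `[[`, "candidates"))
  if (is.null(classified))
    classified <- data.frame(family_id = character(), gene = character(),
                             verdict = character(), stringsAsFactors = FALSE)
  summary <- summarizeCohort(classified, pathwayMap, totalFamilies)
  if (!is.null(outDir)) writeCohortSummary(summary, outDir)
  list(summary = summary,
       classified = classified,
       traces = setNames(lapply(results, `[[`, "trace"),
                         vapply(results, function(r) familyId(r$pedigree), "")))
}
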