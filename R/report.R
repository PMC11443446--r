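plpVerdicts <- function() c("Pathogenic", "Likely pathogenic")

#' Roll per-gene family hits up to pathways
#'
#' A pathway's count is the number of *distinct* families with a P/LP hit in
#' any gene mapped to that pathway, so a family with hits in two genes of
#' one pathway contributes once.
#'
#' @param familyGene data.frame with columns `family_id` and `gene` (one row
#'   per family x gene P/LP hit).
#' @param pathwayMap named character vector from [genePathwayMap()].
#' @return data.frame `pathway`, `families`.
#' @export
pathwayRollup <- function(familyGene, pathwayMap) {
  genes <- toupper(familyGene$gene)
  missing <- setdiff(unique(genes), names(pathwayMap))
  abortIf(length(missing) > 0, "gene(s) missing from the pathway map: ",
          paste(missing, collapse = ", "))
  pw <- pathwayMap[genes]
  df <- unique(data.frame(family_id = familyGene$family_id, pathway = unname(pw),
                          stringsAsFactors = FALSE))
  if (!nrow(df))
    return(data.frame(pathway = character(), families = integer(),
                      stringsAsFactors = FALSE))
  agg <- as.data.frame(table(df$pathway), stringsAsFactors = FALSE)
  names(agg) <- c("pathway", "families")
  agg$families <- as.integer(agg$families)
  agg[order(-agg$families, agg$pathway), , drop = FALSE]
}

#' Summarize classified candidates at the cohort level
#'
#' Counts families carrying at least one pathogenic/likely pathogenic
#' candidate — overall, per gene and per pathway (each family counted at
#' most once per gene and per pathway) — and reports percentages of the
#' total cohort rounded half-up to two decimals.
#'
#' @param classified data.frame of classified candidates across the cohort;
#'   needs columns `family_id`, `gene`, `verdict` (as produced by
#'   [classifyCandidates()] / [runFamily()]).
#' @param pathwayMap named character vector from [genePathwayMap()]; every
#'   gene with a P/LP hit must be present.
#' @param totalFamilies number of families in the cohort (the denominator;
#'   families contributing no candidates still count here).
#' @return a [CohortSummary-class].
#' @export
#' @examples
#' hits <- data.frame(
#'   family_id = c("f1", "f2", "f3", "f4", "f5", "f6", "f7"),
#'   gene = c("PTCH1", "PTCH1", "GLI2", "IRF6", "PLEKHA5", "CREBBP", "FZD6"),
#'   verdict = "Likely pathogenic")
#' summarizeCohort(hits, genePathwayMap(), totalFamilies = 30)
summarizeCohort <- function(classified, pathwayMap = genePathwayMap(),
                            totalFamilies) {
  totalFamilies <- as.integer(totalFamilies)
  abortIf(totalFamilies < 1L, "totalFamilies must be >= 1")
  need <- c("family_id", "gene", "verdict")
  abortIf(!all(need %in% colnames(classified)),
          "classified table needs columns: ", paste(need, collapse = ", "))
  plp <- classified[classified$verdict %in% plpVerdicts(), need, drop = FALSE]
  plp$gene <- toupper(plp$gene)
  pct <- function(n) roundHalfUp(100 * n / totalFamilies, 2)
  nPlp <- length(unique(plp$family_id))
  fg <- unique(plp[, c("family_id", "gene")])
  perGene <- if (nrow(fg)) {
    agg <- as.data.frame(table(fg$gene), stringsAsFactors = FALSE)
    names(agg) <- c("gene", "families")
    agg$families <- as.integer(agg$families)
    agg <- agg[order(-agg$families, agg$gene), , drop = FALSE]
    agg$percent <- pct(agg$families)
    agg
  } else data.frame(gene = character(), families = integer(),
                    percent = numeric(), stringsAsFactors = FALSE)
  perPathway <- pathwayRollup(fg, pathwayMap)
  perPathway$percent <- if (nrow(perPathway)) pct(perPathway$families) else numeric()
  rownames(perGene) <- rownames(perPathway) <- NULL
  new("CohortSummary", totalFamilies = totalFamilies,
      familiesWithPlp = nPlp, percentWithPlp = pct(nPlp),
      perGene = perGene, perPathway = perPathway)
}

#' Write a cohort summary to TSV and JSON
#'
#' @param summary a [CohortSummary-class].
#' @param outDir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeCohortSummary <- function(summary, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genePath <- file.path(outDir, "cohort_per_gene.tsv")
  pwPath <- file.path(outDir, "cohort_per_pathway.tsv")
  jsonPath <- file.path(outDir, "cohort_summary.json")
  write.table(summary@perGene, genePath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary@perPathway, pwPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    total_families = summary@totalFamilies,
    families_with_plp = summary@familiesWithPlp,
    percent_with_plp = summary@percentWithPlp,
    per_gene = summary@perGene, per_pathway = summary@perPathway),
    jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(per_gene = genePath, per_pathway = pwPath, json = jsonPath))
}
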