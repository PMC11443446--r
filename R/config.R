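#' Default consequence whitelist
#'
#' Sequence-Ontology-style terms retained by the consequence filter:
#' variants altering the protein sequence (missense, nonsense, start-loss,
#' in-frame and frameshift insertions/deletions) or splicing.
#'
#' @return character vector of terms.
#' @export
defaultConsequenceWhitelist <- function() {
  c("missense_variant", "stop_gained", "start_lost",
    "frameshift_variant", "inframe_insertion", "inframe_deletion",
    "splice_donor_variant", "splice_acceptor_variant", "splice_region_variant")
}

## Terms we recognise but deliberately exclude; anything else triggers an
## unknown-vocabulary warning in consequenceFilter.
knownNonQualifyingConsequences <- function() {
  c("synonymous_variant", "stop_lost", "stop_retained_variant",
    "intron_variant", "intergenic_variant", "5_prime_UTR_variant",
    "3_prime_UTR_variant", "upstream_gene_variant", "downstream_gene_variant",
    "non_coding_transcript_exon_variant", "regulatory_region_variant")
}

#' Curated craniofacial/OFC gene-relevance list
#'
#' Loads the curated list of genes implicated in orofacial clefting or
#' craniofacial development (one upper-case symbol per line, `#` comments
#' allowed). The shipped default is a literature-curated stand-in for a
#' phenotype-driven screen (e.g. Phenolyzer-style gene ranking); its content
#' is a data input, editable without touching code.
#'
#' @param path optional path to an alternative list file.
#' @return character vector of upper-cased gene symbols.
#' @export
relevanceGenes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ofc_relevance_genes.txt",
                                package = "cleftsift", mustWork = TRUE)
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  toupper(x[nzchar(x)])
}

#' Gene-to-pathway map for cohort reporting
#'
#' Two-column tab-separated file (`gene`, `pathway`); each gene maps to
#' exactly one morphogenic process/pathway. The shipped default covers the
#' canonical lip/palate development pathways (Hedgehog, WNT, TGF-beta,
#' epithelial-related) plus entries needed by the simulator defaults.
#'
#' @param path optional path to an alternative map.
#' @return named character vector: `pathway` keyed by upper-cased gene.
#' @export
genePathwayMap <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_pathway_map.tsv",
                                package = "cleftsift", mustWork = TRUE)
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  abortIf(!all(c("gene", "pathway") %in% colnames(df)),
          "gene-pathway map needs 'gene' and 'pathway' columns")
  dup <- duplicated(toupper(df$gene))
  abortIf(any(dup), "gene mapped to more than one pathway: ",
          paste(unique(toupper(df$gene)[dup]), collapse = ", "))
  setNames(df$pathway, toupper(df$gene))
}

#' Genes with an established loss-of-function disease mechanism
#'
#' Gates the PVS1 evidence code: a null variant only counts as very strong
#' pathogenic evidence in a gene where loss of function is a known mechanism.
#'
#' @param path optional path to an alternative list (one symbol per line).
#' @return character vector of upper-cased gene symbols.
#' @export
lofMechanismGenes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lof_mechanism_genes.txt",
                                package = "cleftsift", mustWork = TRUE)
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  toupper(x[nzchar(x)])
}

#' Build a filtering/classification configuration
#'
#' @param mafThresholdAD exclude variants with population MAF strictly above
#'   this under AD inheritance (default 0.005 = 0.5%).
#' @param mafThresholdAR as above under AR inheritance (default 0.05 = 5%).
#' @param consequenceWhitelist retained consequence terms.
#' @param missingMafPolicy `"keep"` (default: novel variants pass the MAF
#'   filter) or `"drop"`.
#' @param missingGenotypePolicy `"noninformative"` (default) or `"strict"`;
#'   see [segregationFilter()].
#' @param arCarrierScope `"parents"` (default) or `"all"`; see
#'   [segregationFilter()].
#' @param relevanceGenes curated relevance gene symbols
#'   (default: [relevanceGenes()]).
#' @param lofGenes LoF-mechanism gene symbols (default:
#'   [lofMechanismGenes()]).
#' @param pm2Bound PM2 rarity bound; `NA` (default) reuses the active
#'   model's MAF threshold.
#' @param bs1Bound lower MAF bound for BS1 (default 0.01).
#' @param minSegregations informative meioses required for PP1 (default 3).
#' @return a [FilterConfig-class].
#' @export
#' @examples
#' cfg <- filterConfig()
#' cfg
filterConfig <- function(mafThresholdAD = 0.005, mafThresholdAR = 0.05,
                         consequenceWhitelist = defaultConsequenceWhitelist(),
                         missingMafPolicy = c("keep", "drop"),
                         missingGenotypePolicy = c("noninformative", "strict"),
                         arCarrierScope = c("parents", "all"),
                         relevanceGenes = cleftsift::relevanceGenes(),
                         lofGenes = lofMechanismGenes(),
                         pm2Bound = NA_real_, bs1Bound = 0.01,
                         minSegregations = 3L) {
  new("FilterConfig", mafThresholdAD = mafThresholdAD,
      mafThresholdAR = mafThresholdAR,
      consequenceWhitelist = consequenceWhitelist,
      missingMafPolicy = match.arg(missingMafPolicy),
      missingGenotypePolicy = match.arg(missingGenotypePolicy),
      arCarrierScope = match.arg(arCarrierScope),
      relevanceGenes = toupper(relevanceGenes), lofGenes = toupper(lofGenes),
      pm2Bound = pm2Bound, bs1Bound = bs1Bound,
      minSegregations = as.integer(minSegregations))
}

#' Read a cohort configuration file
#'
#' YAML (or JSON) file assigning each family exactly one inheritance model
#' and optionally overriding filter thresholds and fixture paths:
#'
#' ```yaml
#' families: {fam30: AR, fam01: AD}
#' maf_threshold_ad: 0.005
#' maf_threshold_ar: 0.05
#' consequence_whitelist: [missense_variant, stop_gained]
#' missing_maf_policy: keep
#' missing_genotype_policy: noninformative
#' ar_carrier_scope: parents
#' relevance_gene_list: genes.txt      # relative to the config file
#' gene_pathway_map: pathways.tsv
#' ```
#'
#' @param path path to the YAML config.
#' @return list with `models` (named character vector of `"AD"`/`"AR"` per
#'   family), `config` (a [FilterConfig-class]) and `pathwayMap`.
#' @export
readCohortConfig <- function(path) {
  abortIf(!file.exists(path), "config file not found: ", path)
  y <- yaml::read_yaml(path)
  abortIf(is.null(y$families) || !length(y$families),
          "config must assign at least one family an inheritance model")
  models <- toupper(unlist(y$families))
  abortIf(!all(models %in% c("AD", "AR")),
          "every family must be assigned exactly one model, AD or AR")
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(dirname(path), p)
  }
  relPath <- resolve(y$relevance_gene_list)
  mapPath <- resolve(y$gene_pathway_map)
  cfg <- filterConfig(
    mafThresholdAD = y$maf_threshold_ad %||% 0.005,
    mafThresholdAR = y$maf_threshold_ar %||% 0.05,
    consequenceWhitelist = unlist(y$consequence_whitelist) %||% defaultConsequenceWhitelist(),
    missingMafPolicy = y$missing_maf_policy %||% "keep",
    missingGenotypePolicy = y$missing_genotype_policy %||% "noninformative",
    arCarrierScope = y$ar_carrier_scope %||% "parents",
    relevanceGenes = relevanceGenes(relPath),
    lofGenes = lofMechanismGenes(resolve(y$lof_gene_list)),
    pm2Bound = y$pm2_bound %||% NA_real_,
    bs1Bound = y$bs1_bound %||% 0.01,
    minSegregations = y$min_segregations %||% 3L)
  list(models = models, config = cfg, pathwayMap = genePathwayMap(mapPath))
}
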