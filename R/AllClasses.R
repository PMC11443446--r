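#' @title Core S4 classes
#' @name cleftsift-classes
#' @description S4 containers used throughout the pipeline: `RawVariantSite`
#'   (one VCF record before multiallelic normalization), `VariantSet`
#'   (normalized biallelic variants with annotations and a genotype-dosage
#'   assay), `Pedigree`, `FilterConfig` and `CohortSummary`.
NULL

#' RawVariantSite: one VCF record prior to biallelic normalization
#'
#' Thin container for a single (possibly multiallelic) VCF site: coordinates,
#' REF and the full ALT list, the raw INFO annotations, and per-sample
#' genotypes as allele-index pairs. [splitMultiallelic()] turns one of these
#' into one biallelic site per alternate allele.
#'
#' @slot chrom chromosome label.
#' @slot pos 1-based, REF-anchored position (VCF convention).
#' @slot ref reference allele.
#' @slot alts character vector of alternate alleles (length >= 1).
#' @slot info named list of INFO annotations; per-allele (`Number=A`) fields
#'   are vectors of length `length(alts)`.
#' @slot geno integer matrix, 2 rows x samples: allele indices
#'   (0 = REF, k = k-th ALT), `NA` for missing calls.
#' @export
setClass("RawVariantSite",
  representation(chrom = "character", pos = "integer", ref = "character",
                 alts = "character", info = "list", geno = "matrix"))

setValidity("RawVariantSite", function(object) {
  msg <- character()
  if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1L)
    msg <- c(msg, "pos must be a single integer >= 1")
  if (!nzchar(object@ref)) msg <- c(msg, "ref must be nonempty")
  if (length(object@alts) < 1L || any(!nzchar(object@alts)))
    msg <- c(msg, "alts must be nonempty strings")
  g <- object@geno
  if (nrow(g) != 2L) msg <- c(msg, "geno must have 2 rows (allele pair)")
  bad <- !is.na(g) & (g < 0L | g > length(object@alts))
  if (any(bad)) msg <- c(msg, "genotype allele indices must be in 0..length(alts) or NA")
  if (length(msg)) msg else TRUE
})

#' RawVariantSite constructor
#'
#' @param chrom,pos,ref,alts site coordinates and alleles.
#' @param info named list of INFO annotations.
#' @param geno integer matrix 2 x samples of allele indices (colnames are
#'   sample ids), or `NULL` for a site with no genotypes.
#' @return a [RawVariantSite-class] object.
#' @export
RawVariantSite <- function(chrom, pos, ref, alts, info = list(), geno = NULL) {
  if (is.null(geno)) geno <- matrix(integer(), nrow = 2L, ncol = 0L)
  storage.mode(geno) <- "integer"
  new("RawVariantSite", chrom = as.character(chrom), pos = as.integer(pos),
      ref = as.character(ref), alts = as.character(alts), info = info, geno = geno)
}

setMethod("show", "RawVariantSite", function(object) {
  cat(sprintf("RawVariantSite %s:%d %s>%s (%d sample%s)\n", object@chrom,
              object@pos, object@ref, paste(object@alts, collapse = ","),
              ncol(object@geno), if (ncol(object@geno) == 1L) "" else "s"))
})

# ---------------------------------------------------------------------------

#' VariantSet: normalized biallelic variants with annotations and genotypes
#'
#' A `RangedSummarizedExperiment` whose rows are biallelic variant records and
#' whose columns are the genotyped samples. The single assay, `"dosage"`,
#' holds alternate-allele dosage: 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing. Row metadata carries the
#' annotations the filtering cascade consumes: `ref`, `alt` (exactly one
#' alternate allele per record), `gene`, `consequence` (Sequence-Ontology
#' style term), `maf` (population minor-allele frequency; `NA` means absent
#' from the population database, which is distinct from 0), and `predictors`
#' (a character matrix of in-silico calls, `"damaging"`/`"tolerated"`/`NA`).
#'
#' @export
setClass("VariantSet", contains = "RangedSummarizedExperiment")

setValidity("VariantSet", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  if (any(!is.na(d) & !(d %in% 0:2)))
    msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  rd <- rowData(object)
  need <- c("ref", "alt", "gene", "consequence", "maf")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("missing rowData columns: ", paste(miss, collapse = ", ")))
  if ("alt" %in% colnames(rd) && any(grepl(",", rd$alt, fixed = TRUE)))
    msg <- c(msg, "records must be biallelic (one alt each); run splitMultiallelic first")
  if ("maf" %in% colnames(rd)) {
    m <- rd$maf
    if (any(!is.na(m) & (m < 0 | m > 1)))
      msg <- c(msg, "maf must lie in [0,1] when present")
  }
  if (length(msg)) msg else TRUE
})

#' VariantSet constructor
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions.
#' @param ref,alt reference and (single) alternate alleles.
#' @param gene gene symbols.
#' @param consequence Sequence-Ontology-style consequence terms.
#' @param maf population minor-allele frequencies in `[0,1]`; `NA` = absent
#'   from the frequency database (treated as novel/rare downstream).
#' @param dosage integer matrix variants x samples of alternate-allele dosage
#'   (0/1/2, `NA` missing) with sample ids as column names.
#' @param predictors optional character matrix variants x predictors of
#'   in-silico calls (`"damaging"`, `"tolerated"`, `NA`).
#' @return a [VariantSet-class].
#' @export
#' @examples
#' vs <- VariantSet(chrom = "1", pos = 100L, ref = "A", alt = "G",
#'                  gene = "IRF6", consequence = "missense_variant", maf = 0.001,
#'                  dosage = matrix(c(1L, 0L), 1, 2,
#'                                  dimnames = list(NULL, c("p1", "p2"))))
#' genotypes(vs)
VariantSet <- function(chrom, pos, ref, alt, gene, consequence,
                       maf = NA_real_, dosage, predictors = NULL) {
  n <- length(pos)
  if (is.null(dim(dosage))) dosage <- matrix(as.integer(dosage), nrow = n)
  storage.mode(dosage) <- "integer"
  maf <- rep_len(as.numeric(maf), n)
  if (is.null(predictors)) predictors <- matrix(character(), nrow = n, ncol = 0L)
  gr <- GRanges(as.character(chrom), IRanges(as.integer(pos), width = nchar(ref)))
  mcols(gr) <- DataFrame(ref = as.character(ref), alt = as.character(alt),
                         gene = as.character(gene),
                         consequence = as.character(consequence),
                         maf = maf, predictors = I(predictors))
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowRanges = gr)
  new("VariantSet", se)
}

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet with %d variant%s x %d sample%s\n",
              nrow(object), if (nrow(object) == 1L) "" else "s",
              ncol(object), if (ncol(object) == 1L) "" else "s"))
  if (nrow(object)) {
    df <- asVariantTable(object)
    print(utils::head(df, 5L), row.names = FALSE)
    if (nrow(df) > 5L) cat(sprintf("... and %d more\n", nrow(df) - 5L))
  }
})

# ---------------------------------------------------------------------------

#' Pedigree: a validated single-family pedigree graph
#'
#' Members are stored as a data.frame with one row per individual: `id`,
#' `father`, `mother` (`"0"` marks a founder/unknown parent), `sex`
#' (`male`/`female`/`unknown`), `affection`
#' (`affected`/`unaffected`/`unknown`) and `genotyped` (has a sample column
#' in the family VCF). Parentage must be acyclic and each non-founder must
#' have both parents inside the family (or both unknown).
#'
#' @slot familyId family identifier.
#' @slot members data.frame as described above.
#' @slot model assigned inheritance model, `"AD"`, `"AR"` or `NA`.
#' @export
setClass("Pedigree",
  representation(familyId = "character", members = "data.frame", model = "character"))

setValidity("Pedigree", function(object) {
  m <- object@members
  msg <- character()
  need <- c("id", "father", "mother", "sex", "affection", "genotyped")
  if (!all(need %in% colnames(m)))
    return(paste0("members must have columns ", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id)) msg <- c(msg, "duplicate individual ids")
  for (col in c("father", "mother")) {
    known <- m[[col]] != "0"
    bad <- known & !(m[[col]] %in% m$id)
    if (any(bad))
      msg <- c(msg, sprintf("%s id(s) not present in family: %s", col,
                            paste(unique(m[[col]][bad]), collapse = ", ")))
  }
  if (any((m$father == "0") != (m$mother == "0")))
    msg <- c(msg, "non-founders must have both parents in the family (or both unknown)")
  if (!all(m$affection %in% c("affected", "unaffected", "unknown")))
    msg <- c(msg, "affection must be affected/unaffected/unknown")
  if (!all(m$sex %in% c("male", "female", "unknown")))
    msg <- c(msg, "sex must be male/female/unknown")
  if (!is.na(object@model) && !object@model %in% c("AD", "AR"))
    msg <- c(msg, "model must be AD, AR or NA")
  cyc <- .findParentageCycle(m)
  if (!is.null(cyc))
    msg <- c(msg, paste0("parentage cycle involving: ", paste(cyc, collapse = " -> ")))
  if (length(msg)) msg else TRUE
})

## Depth-first search over parent links; returns ids on a cycle or NULL.
.findParentageCycle <- function(m) {
  parents <- setNames(Map(function(f, mo) setdiff(c(f, mo), "0"), m$father, m$mother), m$id)
  state <- setNames(rep(0L, nrow(m)), m$id) # 0 unseen, 1 in stack, 2 done
  visit <- function(id, path) {
    if (state[[id]] == 1L) return(c(path, id))
    if (state[[id]] == 2L) return(NULL)
    state[[id]] <<- 1L
    for (p in parents[[id]]) {
      res <- visit(p, c(path, id))
      if (!is.null(res)) return(res)
    }
    state[[id]] <<- 2L
    NULL
  }
  for (id in m$id) {
    res <- visit(id, character())
    if (!is.null(res)) return(res)
  }
  NULL
}

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree '%s' (%s model): %d members, %d affected, %d genotyped\n",
              object@familyId,
              if (is.na(object@model)) "unassigned" else object@model,
              nrow(m), sum(m$affection == "affected"), sum(m$genotyped)))
})

# ---------------------------------------------------------------------------

#' FilterConfig: thresholds and policies for the filtering cascade
#'
#' @slot mafThresholdAD exclude variants with population MAF strictly above
#'   this under the AD model (default 0.005, i.e. 0.5%).
#' @slot mafThresholdAR as above for the AR model (default 0.05, i.e. 5%).
#' @slot consequenceWhitelist Sequence-Ontology-style terms retained by the
#'   consequence filter.
#' @slot missingMafPolicy `"keep"` (default; novel variants absent from the
#'   frequency database are of interest) or `"drop"`.
#' @slot missingGenotypePolicy `"noninformative"` (default; an ungenotyped or
#'   missing call neither supports nor vetoes segregation) or `"strict"`
#'   (every constrained member must have a non-missing genotype).
#' @slot arCarrierScope `"parents"` (default; only obligate-carrier parents
#'   of affected individuals must be heterozygous under AR, other unaffected
#'   members must merely not be homozygous-alternate) or `"all"` (every
#'   genotyped unaffected member must be heterozygous).
#' @slot relevanceGenes curated phenotype-relevance gene symbols (upper-cased).
#' @slot lofGenes genes for which loss of function is an established disease
#'   mechanism (gates PVS1).
#' @slot pm2Bound rarity bound for PM2; `NA` (default) means reuse the
#'   model's own MAF threshold.
#' @slot bs1Bound lower MAF bound for BS1 (frequency higher than expected for
#'   the disorder but below the BA1 stand-alone 5%).
#' @slot minSegregations minimum informative meioses for PP1.
#' @export
setClass("FilterConfig",
  representation(mafThresholdAD = "numeric", mafThresholdAR = "numeric",
                 consequenceWhitelist = "character",
                 missingMafPolicy = "character",
                 missingGenotypePolicy = "character",
                 arCarrierScope = "character",
                 relevanceGenes = "character", lofGenes = "character",
                 pm2Bound = "numeric", bs1Bound = "numeric",
                 minSegregations = "integer"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  ad <- object@mafThresholdAD; ar <- object@mafThresholdAR
  if (!(ad > 0 && ad <= ar && ar < 1))
    msg <- c(msg, "need 0 < mafThresholdAD <= mafThresholdAR < 1")
  if (!object@missingMafPolicy %in% c("keep", "drop"))
    msg <- c(msg, "missingMafPolicy must be 'keep' or 'drop'")
  if (!object@missingGenotypePolicy %in% c("noninformative", "strict"))
    msg <- c(msg, "missingGenotypePolicy must be 'noninformative' or 'strict'")
  if (!object@arCarrierScope %in% c("parents", "all"))
    msg <- c(msg, "arCarrierScope must be 'parents' or 'all'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  MAF exclusion: > %.4g (AD), > %.4g (AR); missing MAF -> %s\n",
              object@mafThresholdAD, object@mafThresholdAR, object@missingMafPolicy))
  cat(sprintf("  consequence whitelist: %d terms\n", length(object@consequenceWhitelist)))
  cat(sprintf("  genotype policy: %s; AR carrier scope: %s\n",
              object@missingGenotypePolicy, object@arCarrierScope))
  cat(sprintf("  relevance genes: %d; LoF-mechanism genes: %d\n",
              length(object@relevanceGenes), length(object@lofGenes)))
})

# ---------------------------------------------------------------------------

#' CohortSummary: cohort-level gene and pathway contribution statistics
#'
#' @slot totalFamilies number of families in the cohort.
#' @slot familiesWithPlp number of families carrying at least one
#'   pathogenic/likely pathogenic (P/LP) candidate.
#' @slot percentWithPlp `100 * familiesWithPlp / totalFamilies`, rounded
#'   half-up to 2 decimals.
#' @slot perGene data.frame `gene`, `families`, `percent`.
#' @slot perPathway data.frame `pathway`, `families`, `percent`.
#' @export
setClass("CohortSummary",
  representation(totalFamilies = "integer", familiesWithPlp = "integer",
                 percentWithPlp = "numeric", perGene = "data.frame",
                 perPathway = "data.frame"))

setValidity("CohortSummary", function(object) {
  msg <- character()
  if (object@familiesWithPlp > object@totalFamilies)
    msg <- c(msg, "familiesWithPlp cannot exceed totalFamilies")
  for (nm in c("perGene", "perPathway")) {
    df <- slot(object, nm)
    cnt <- df$families
    if (length(cnt) && any(cnt > object@totalFamilies))
      msg <- c(msg, sprintf("%s family counts exceed totalFamilies", nm))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary: %d/%d families (%0.2f%%) with P/LP candidates\n",
              object@familiesWithPlp, object@totalFamilies, object@percentWithPlp))
  if (nrow(object@perGene)) {
    cat("Per gene:\n"); print(object@perGene, row.names = FALSE)
  }
  if (nrow(object@perPathway)) {
    cat("Per pathway:\n"); print(object@perPathway, row.names = FALSE)
  }
})
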