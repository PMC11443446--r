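#' Population-frequency (MAF) filter
#'
#' Excludes variants whose population minor-allele frequency strictly
#' exceeds the model-specific threshold: by default MAF > 0.5% under
#' autosomal dominant and MAF > 5% under autosomal recessive inheritance
#' ("higher than" is read strictly, so a boundary value is retained).
#' Variants with no recorded MAF pass by default — novel variants absent
#' from population databases are exactly the ones family studies are after —
#' unless `missingMafPolicy` is `"drop"`.
#'
#' @param vs a [VariantSet-class].
#' @param model `"AD"` or `"AR"`.
#' @param cfg a [FilterConfig-class].
#' @return logical vector, `TRUE` = keep, one element per variant.
#' @export
mafFilter <- function(vs, model, cfg = filterConfig()) {
  model <- match.arg(model, c("AD", "AR"))
  thr <- if (model == "AD") cfg@mafThresholdAD else cfg@mafThresholdAR
  maf <- populationMaf(vs)
  keep <- maf <= thr
  keep[is.na(maf)] <- cfg@missingMafPolicy == "keep"
  unname(keep)
}

#' Protein-altering / splicing consequence filter
#'
#' Keeps variants whose consequence term is on the configured whitelist
#' (missense, nonsense, start-loss, in-frame and frameshift indels,
#' splice-site/region by default). Terms outside the known vocabulary are
#' dropped with a warning so annotation drift is visible rather than silent.
#'
#' @inheritParams mafFilter
#' @return logical keep vector.
#' @export
consequenceFilter <- function(vs, cfg = filterConfig()) {
  term <- consequence(vs)
  known <- c(cfg@consequenceWhitelist, knownNonQualifyingConsequences())
  unknown <- setdiff(unique(term), known)
  if (length(unknown))
    warning("dropping variants with unrecognised consequence term(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  unname(term %in% cfg@consequenceWhitelist)
}

## Per-row "all genotyped members in `ids` have dosage == value", with the
## missing-genotype policy applied. Vacuously TRUE when ids is empty.
.rowsAllEqual <- function(G, ids, value, strict) {
  if (!length(ids)) return(rep(TRUE, nrow(G)))
  M <- G[, ids, drop = FALSE]
  ok <- rowSums(M != value, na.rm = TRUE) == 0L
  if (strict) ok <- ok & rowSums(is.na(M)) == 0L
  ok
}

.rowsNoneEqual <- function(G, ids, value, strict) {
  if (!length(ids)) return(rep(TRUE, nrow(G)))
  M <- G[, ids, drop = FALSE]
  ok <- rowSums(M == value, na.rm = TRUE) == 0L
  if (strict) ok <- ok & rowSums(is.na(M)) == 0L
  ok
}

#' Mendelian segregation filter
#'
#' Applies the family's inheritance model to the genotype vector of each
#' variant:
#'
#' * **AD** — keep iff every genotyped affected member is heterozygous and
#'   every genotyped unaffected member is homozygous reference.
#' * **AR** — keep iff every genotyped affected member is
#'   homozygous-alternate, every genotyped obligate carrier
#'   ([obligateCarriers()]) is heterozygous, and no genotyped unaffected
#'   member is homozygous-alternate. With `arCarrierScope = "all"` the
#'   stronger reading is applied: every genotyped unaffected member must be
#'   heterozygous.
#'
#' Individuals with unknown affection are non-informative. Missing genotypes
#' follow `missingGenotypePolicy`: `"noninformative"` (default) removes that
#' member from the constraint; `"strict"` drops any variant whose
#' constrained members are not all genotyped. A variant genotyped in no
#' affected member is dropped with a warning. Note an AD-consistent pattern
#' in which no affected individual has an affected parent is retained here
#' (the rule as stated admits de-novo-like patterns); such calls are flagged
#' downstream, not silently removed.
#'
#' @inheritParams mafFilter
#' @param ped a validated [Pedigree-class] with its model assigned.
#' @return logical keep vector.
#' @export
segregationFilter <- function(vs, ped, cfg = filterConfig()) {
  model <- inheritanceModel(ped)
  abortIf(is.na(model), "pedigree has no assigned inheritance model")
  G <- genotypes(vs)
  strict <- cfg@missingGenotypePolicy == "strict"
  gset <- genotypedIds(ped)
  gset <- intersect(gset, colnames(G))
  A <- intersect(affectedIds(ped), gset)
  U <- intersect(unaffectedIds(ped), gset)
  if (!length(A)) {
    warning(sprintf("family %s: no genotyped affected member; dropping all variants",
                    familyId(ped)), call. = FALSE)
    return(rep(FALSE, nrow(G)))
  }
  ## at least one affected member must actually carry an observed genotype
  informative <- rowSums(!is.na(G[, A, drop = FALSE])) > 0L
  if (model == "AD") {
    keep <- .rowsAllEqual(G, A, 1L, strict) & .rowsAllEqual(G, U, 0L, strict)
  } else {
    O <- intersect(obligateCarriers(ped), gset)
    keep <- .rowsAllEqual(G, A, 2L, strict)
    if (cfg@arCarrierScope == "all") {
      keep <- keep & .rowsAllEqual(G, U, 1L, strict)
    } else {
      keep <- keep & .rowsAllEqual(G, O, 1L, strict) &
        .rowsNoneEqual(G, setdiff(U, O), 2L, strict)
    }
  }
  unname(keep & informative)
}

#' Phenotype-relevance gene filter
#'
#' Keeps variants whose gene symbol (case-folded) belongs to the curated
#' craniofacial/OFC relevance list.
#'
#' @inheritParams mafFilter
#' @param geneSet character vector of relevance gene symbols; defaults to
#'   the config's list.
#' @return logical keep vector.
#' @export
relevanceFilter <- function(vs, geneSet = NULL, cfg = filterConfig()) {
  geneSet <- toupper(geneSet %||% cfg@relevanceGenes)
  abortIf(!length(geneSet), "relevance gene set is empty: configuration error")
  unname(toupper(geneSymbol(vs)) %in% geneSet)
}

#' Run the four-stage filtering cascade for one family
#'
#' Applies, in order: (a1) model-specific MAF filter, (a2) protein-altering
#' consequence whitelist, (a3) Mendelian segregation under the family's
#' model, (a4) curated gene-relevance screen. The stages are conjunctive so
#' the surviving set is order-independent; the attrition trace is defined by
#' this canonical order and exposes the candidate count both before and
#' after the relevance screen.
#'
#' @inheritParams segregationFilter
#' @return list with elements `candidates` (the surviving
#'   [VariantSet-class]), `trace` (data.frame `stage`, `kept` with rows
#'   `input`, `maf`, `consequence`, `segregation`, `relevance`) and
#'   `denovoFlag` (logical per candidate: AD pattern with no affected parent
#'   of any affected member, flagged for review).
#' @export
#' @examples
#' sim <- simulateFamilyDataset(simulationConfig(seed = 1, nBackground = 50))
#' res <- runCascade(sim$variants, sim$pedigree)
#' res$trace
runCascade <- function(vs, ped, cfg = filterConfig()) {
  model <- inheritanceModel(ped)
  abortIf(is.na(model), "pedigree has no assigned inheritance model")
  keep1 <- mafFilter(vs, model, cfg)
  s1 <- vs[keep1, ]
  keep2 <- consequenceFilter(s1, cfg)
  s2 <- s1[keep2, ]
  keep3 <- if (nrow(s2)) segregationFilter(s2, ped, cfg) else logical(0)
  s3 <- s2[keep3, ]
  keep4 <- if (nrow(s3)) relevanceFilter(s3, cfg = cfg) else logical(0)
  s4 <- s3[keep4, ]
  trace <- data.frame(
    stage = c("input", "maf", "consequence", "segregation", "relevance"),
    kept = c(nrow(vs), nrow(s1), nrow(s2), nrow(s3), nrow(s4)),
    stringsAsFactors = FALSE)
  denovo <- if (model == "AD" && nrow(s4)) {
    rep(suggestModel(ped) != "AD", nrow(s4))
  } else rep(FALSE, nrow(s4))
  list(candidates = s4, trace = trace, denovoFlag = denovo)
}
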