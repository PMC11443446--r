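#' In-silico predictor consensus
#'
#' Majority vote over the non-absent predictor calls for one variant:
#' strictly more than half `"damaging"` gives `possibly_pathogenic`,
#' strictly more than half `"tolerated"` gives `possibly_benign`, anything
#' else (including an exact tie) is `inconclusive`.
#'
#' @param calls character vector (or 1-row matrix) of predictor calls,
#'   values `"damaging"`, `"tolerated"` or `NA`.
#' @return one of `"possibly_pathogenic"`, `"inconclusive"`,
#'   `"possibly_benign"`.
#' @export
#' @examples
#' insilicoConsensus(c("damaging", "damaging", "damaging", "tolerated"))
insilicoConsensus <- function(calls) {
  calls <- as.character(calls)
  calls <- calls[!is.na(calls)]
  abortIf(!length(calls), "no predictor calls present")
  nd <- sum(calls == "damaging")
  nt <- sum(calls == "tolerated")
  n <- nd + nt
  if (nd * 2L > n) "possibly_pathogenic"
  else if (nt * 2L > n) "possibly_benign"
  else "inconclusive"
}

#' Consequence terms counting as null (loss-of-function) for PVS1
#'
#' @return character vector of terms.
#' @export
pvs1Consequences <- function() {
  c("stop_gained", "frameshift_variant", "splice_donor_variant",
    "splice_acceptor_variant", "start_lost")
}

#' Assign annotation-derivable ACMG evidence codes
#'
#' Only criteria computable from the variant annotations and the pedigree are
#' assigned; criteria requiring external case/functional databases (PS1,
#' PS3, PM5, PS4, ...) are out of scope:
#'
#' * `PVS1` — null consequence ([pvs1Consequences()]) in a gene where loss
#'   of function is an established mechanism (`cfg@lofGenes`);
#' * `PM2` — population MAF absent or below the rarity bound
#'   (`cfg@pm2Bound`, defaulting to the active model's cascade threshold);
#' * `PP1` — the variant co-segregates with disease under the family's
#'   model ([segregationFilter()]) with at least `cfg@minSegregations`
#'   informative meioses;
#' * `PP3` — in-silico consensus `possibly_pathogenic`;
#' * `BA1` — MAF above 5% (stand-alone benign);
#' * `BS1` — MAF above `cfg@bs1Bound` but not BA1-grade;
#' * `BP4` — in-silico consensus `possibly_benign`.
#'
#' @param vs a [VariantSet-class] (typically cascade survivors).
#' @param ped the family [Pedigree-class].
#' @param cfg a [FilterConfig-class].
#' @return list of character vectors, one evidence set per variant.
#' @export
assignEvidence <- function(vs, ped, cfg = filterConfig()) {
  model <- inheritanceModel(ped)
  pm2Bound <- if (is.na(cfg@pm2Bound)) {
    if (identical(model, "AR")) cfg@mafThresholdAR else cfg@mafThresholdAD
  } else cfg@pm2Bound
  maf <- populationMaf(vs)
  cons <- consequence(vs)
  gene <- toupper(geneSymbol(vs))
  pred <- predictorCalls(vs)
  seg <- if (!is.na(model)) segregationFilter(vs, ped, cfg) else rep(FALSE, nrow(vs))
  meioses <- informativeMeioses(ped)
  lapply(seq_len(nrow(vs)), function(i) {
    codes <- character()
    if (cons[i] %in% pvs1Consequences() && gene[i] %in% cfg@lofGenes)
      codes <- c(codes, "PVS1")
    if (is.na(maf[i]) || maf[i] < pm2Bound) codes <- c(codes, "PM2")
    if (seg[i] && meioses >= cfg@minSegregations) codes <- c(codes, "PP1")
    consensus <- if (ncol(pred) && any(!is.na(pred[i, ])))
      insilicoConsensus(pred[i, ]) else "inconclusive"
    if (consensus == "possibly_pathogenic") codes <- c(codes, "PP3")
    if (consensus == "possibly_benign") codes <- c(codes, "BP4")
    if (!is.na(maf[i])) {
      if (maf[i] > 0.05) codes <- c(codes, "BA1")
      else if (maf[i] > cfg@bs1Bound) codes <- c(codes, "BS1")
    }
    codes
  })
}

#' ACMG combining-rule table
#'
#' Loads the encoded combination rules (a versioned JSON fixture). Each
#' verdict maps to a list of minimum evidence-count patterns over the
#' strength categories PVS/PS/PM/PP/BA/BS/BP; a pattern matches when every
#' stated category count is met or exceeded.
#'
#' @param path optional path to an alternative rule file.
#' @return nested list as described.
#' @export
acmgRules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "acmg_combining_rules.json",
                                package = "cleftsift", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

## evidence code -> strength category
.evidenceCategory <- function(codes) {
  cat <- sub("[0-9_].*$", "", sub("_any$", "", codes))
  ## PVS1 -> PVS, PS_any -> PS, PM2 -> PM, PP1/PP3 -> PP, BA1 -> BA, ...
  table(factor(cat, levels = c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")))
}

#' Combine ACMG evidence codes into a five-tier verdict
#'
#' Pure function of the evidence set. Pathogenic-direction and
#' benign-direction codes are each resolved through the combining-rule
#' table; the presence of evidence in both directions is treated as
#' conflicting and yields an uncertain-significance verdict (conservative
#' reading of the guideline's conflict clause).
#'
#' @param codes character vector of evidence codes (subset of `PVS1`,
#'   `PS_any`, `PM2`, `PP1`, `PP3`, `BA1`, `BS1`, `BP4`).
#' @param rules rule table from [acmgRules()].
#' @return list with `verdict` (one of `Pathogenic`, `Likely pathogenic`,
#'   `VUS`, `Likely benign`, `Benign`) and `rationale` (short text).
#' @export
#' @examples
#' combineAcmg(c("PVS1", "PM2"))$verdict
combineAcmg <- function(codes, rules = acmgRules()) {
  codes <- unique(codes)
  counts <- .evidenceCategory(codes)
  pathCats <- c("PVS", "PS", "PM", "PP"); benCats <- c("BA", "BS", "BP")
  hasPath <- sum(counts[pathCats]) > 0L
  hasBen <- sum(counts[benCats]) > 0L
  if (hasPath && hasBen) {
    return(list(verdict = "VUS",
                rationale = sprintf("conflicting evidence (%s)", paste(codes, collapse = ","))))
  }
  matches <- function(pattern) {
    all(vapply(names(pattern), function(cat)
      counts[[cat]] >= pattern[[cat]], logical(1)))
  }
  firstMatch <- function(verdict) {
    for (pattern in rules[[verdict]]) if (matches(pattern)) return(TRUE)
    FALSE
  }
  verdict <- if (firstMatch("pathogenic")) "Pathogenic"
  else if (firstMatch("likely_pathogenic")) "Likely pathogenic"
  else if (firstMatch("benign")) "Benign"
  else if (firstMatch("likely_benign")) "Likely benign"
  else "VUS"
  rationale <- if (length(codes)) paste(codes, collapse = ",") else "no evidence"
  list(verdict = verdict, rationale = rationale)
}

#' Classify cascade survivors
#'
#' Runs [assignEvidence()] and [combineAcmg()] over every variant and
#' returns the classified candidate table.
#'
#' @inheritParams assignEvidence
#' @param rules rule table from [acmgRules()].
#' @return data.frame: variant annotation columns plus `consensus`,
#'   `evidence` (comma-joined codes), `verdict`.
#' @export
classifyCandidates <- function(vs, ped, cfg = filterConfig(), rules = acmgRules()) {
  tab <- asVariantTable(vs)
  pred <- predictorCalls(vs)
  tab$consensus <- vapply(seq_len(nrow(vs)), function(i) {
    if (ncol(pred) && any(!is.na(pred[i, ]))) insilicoConsensus(pred[i, ])
    else "inconclusive"
  }, "")
  ev <- assignEvidence(vs, ped, cfg)
  tab$evidence <- vapply(ev, paste, "", collapse = ",")
  tab$verdict <- vapply(ev, function(e) combineAcmg(e, rules)$verdict, "")
  tab$family_id <- rep(familyId(ped), nrow(tab))
  tab
}
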