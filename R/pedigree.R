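#' Validate PED rows into a Pedigree
#'
#' Checks the structural invariants (single family, unique ids, both parents
#' present or both unknown, acyclic parentage) and the study inclusion rule
#' that a multiplex family carries at least `minAffected` affected members
#' (default 2). The `genotyped` flag is set by intersecting individual ids
#' with the VCF sample columns.
#'
#' @param rows data.frame in [readPed()] layout; must contain one family
#'   (or pass `family` to select one).
#' @param vcfSamples character vector of sample ids present in the family
#'   VCF; members outside it are treated as ungenotyped.
#' @param model inheritance model to assign (`"AD"`, `"AR"` or `NA`); the
#'   model always comes from the cohort configuration, never from
#'   [suggestModel()].
#' @param family optional family id to select when `rows` spans several.
#' @param minAffected inclusion threshold on affected members (default 2).
#' @return a validated [Pedigree-class].
#' @export
#' @examples
#' ped <- buildPedigree("fourGenARSecondCousin")
#' obligateCarriers(ped)
#' suggestModel(ped)
validatePedigree <- function(rows, vcfSamples = rows$individual_id,
                             model = NA_character_, family = NULL,
                             minAffected = 2L) {
  if (!is.null(family)) rows <- rows[rows$family_id == family, , drop = FALSE]
  abortIf(nrow(rows) == 0L, "no pedigree rows", if (!is.null(family)) paste0(" for family ", family))
  fam <- unique(rows$family_id)
  abortIf(length(fam) != 1L, "rows span multiple families: ",
          paste(fam, collapse = ", "), "; pass family=")
  members <- data.frame(id = rows$individual_id, father = rows$father_id,
                        mother = rows$mother_id, sex = rows$sex,
                        affection = rows$affection,
                        genotyped = rows$individual_id %in% vcfSamples,
                        stringsAsFactors = FALSE)
  ped <- new("Pedigree", familyId = fam, members = members,
             model = as.character(model))
  nAff <- sum(members$affection == "affected")
  abortIf(nAff < minAffected,
          sprintf("family %s fails the inclusion criterion: %d affected member(s), need >= %d",
                  fam, nAff, minAffected))
  ped
}

#' Obligate carriers under an autosomal recessive model
#'
#' Every unaffected parent of an affected individual must carry exactly one
#' copy of a fully penetrant recessive allele, so the segregation filter
#' requires them heterozygous (the classic pattern: homozygous affected
#' children, heterozygous unaffected parents).
#'
#' @param ped a [Pedigree-class] with `model == "AR"`.
#' @return character vector of obligate-carrier individual ids.
#' @export
obligateCarriers <- function(ped) {
  abortIf(!identical(inheritanceModel(ped), "AR"),
          "obligate carriers are defined under the AR model")
  m <- pedMembers(ped)
  aff <- m[m$affection == "affected", , drop = FALSE]
  parents <- setdiff(unique(c(aff$father, aff$mother)), "0")
  unaff <- m$id[m$affection == "unaffected"]
  intersect(parents, unaff)
}

#' Heuristic inheritance-model suggestion
#'
#' Convenience only — the model applied by the pipeline always comes from
#' the cohort configuration. Returns `"AD"` if any affected individual has
#' an affected parent (vertical transmission), `"AR"` if every affected
#' individual has both parents in the pedigree and both explicitly
#' unaffected (affected offspring of unaffected parents), otherwise
#' `"ambiguous"` (e.g. affected founders, or parents of unknown affection).
#'
#' @param ped a [Pedigree-class].
#' @return `"AD"`, `"AR"` or `"ambiguous"`.
#' @export
suggestModel <- function(ped) {
  m <- pedMembers(ped)
  affection <- setNames(m$affection, m$id)
  aff <- m[m$affection == "affected", , drop = FALSE]
  if (nrow(aff) == 0L) return("ambiguous")
  parentAffected <- function(row) {
    ps <- setdiff(c(row[["father"]], row[["mother"]]), "0")
    any(affection[ps] == "affected")
  }
  if (any(apply(aff, 1L, parentAffected))) return("AD")
  allUnaffectedParents <- all(apply(aff, 1L, function(row) {
    ps <- c(row[["father"]], row[["mother"]])
    all(ps != "0") && all(affection[ps] == "unaffected")
  }))
  if (allUnaffectedParents) "AR" else "ambiguous"
}

#' Count informative meioses
#'
#' Number of observable parent-to-offspring transmissions: genotyped
#' parent-child pairs within the family. Used as the co-segregation depth
#' gate for the PP1 evidence code.
#'
#' @param ped a [Pedigree-class].
#' @return integer count.
#' @export
informativeMeioses <- function(ped) {
  m <- pedMembers(ped)
  gset <- m$id[m$genotyped]
  n <- 0L
  for (i in seq_len(nrow(m))) {
    if (!m$id[i] %in% gset) next
    n <- n + sum(setdiff(c(m$father[i], m$mother[i]), "0") %in% gset)
  }
  n
}

#' Render a pedigree as Graphviz DOT text
#'
#' For visual inspection (`dot -Tpng`); affected individuals are filled,
#' males are boxes, females ellipses.
#'
#' @param ped a [Pedigree-class].
#' @return character scalar of DOT source.
#' @export
pedigreeToDot <- function(ped) {
  m <- pedMembers(ped)
  nodes <- sprintf("  \"%s\" [shape=%s%s];", m$id,
                   ifelse(m$sex == "male", "box", "ellipse"),
                   ifelse(m$affection == "affected", ", style=filled, fillcolor=gray", ""))
  kids <- m[m$father != "0", , drop = FALSE]
  edges <- c(sprintf("  \"%s\" -> \"%s\";", kids$father, kids$id),
             sprintf("  \"%s\" -> \"%s\";", kids$mother, kids$id))
  paste(c(sprintf("digraph \"%s\" {", familyId(ped)), nodes, edges, "}"),
        collapse = "\n")
}
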