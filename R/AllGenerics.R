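#' Accessors for VariantSet and Pedigree objects
#'
#' `genotypes()` returns the dosage assay (variants x samples; 0/1/2/NA),
#' `sampleIds()` the genotyped sample ids, `geneSymbol()`, `consequence()`,
#' `populationMaf()`, `refAllele()`, `altAllele()` and `predictorCalls()` the
#' per-variant annotations. `familyId()`, `pedMembers()` and
#' `inheritanceModel()` access a [Pedigree-class]; `affectedIds()`,
#' `unaffectedIds()`, `genotypedIds()` and `founderIds()` return the role
#' sets the segregation filter consumes.
#'
#' @param x a [VariantSet-class] or [Pedigree-class].
#' @return vectors/matrices as described above.
#' @name accessors
#' @examples
#' ped <- buildPedigree("trio")
#' affectedIds(ped)
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))
#' @rdname accessors
#' @export
setGeneric("consequence", function(x) standardGeneric("consequence"))
#' @rdname accessors
#' @export
setGeneric("populationMaf", function(x) standardGeneric("populationMaf"))
#' @rdname accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname accessors
#' @export
setGeneric("predictorCalls", function(x) standardGeneric("predictorCalls"))
#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setGeneric("pedMembers", function(x) standardGeneric("pedMembers"))
#' @rdname accessors
#' @export
setGeneric("inheritanceModel", function(x) standardGeneric("inheritanceModel"))
#' @rdname accessors
#' @export
setGeneric("affectedIds", function(x) standardGeneric("affectedIds"))
#' @rdname accessors
#' @export
setGeneric("unaffectedIds", function(x) standardGeneric("unaffectedIds"))
#' @rdname accessors
#' @export
setGeneric("genotypedIds", function(x) standardGeneric("genotypedIds"))
#' @rdname accessors
#' @export
setGeneric("founderIds", function(x) standardGeneric("founderIds"))

#' @rdname accessors
#' @export
setMethod("genotypes", "VariantSet", function(x) assay(x, "dosage"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "VariantSet", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("geneSymbol", "VariantSet", function(x) rowData(x)$gene)
#' @rdname accessors
#' @export
setMethod("consequence", "VariantSet", function(x) rowData(x)$consequence)
#' @rdname accessors
#' @export
setMethod("populationMaf", "VariantSet", function(x) rowData(x)$maf)
#' @rdname accessors
#' @export
setMethod("refAllele", "VariantSet", function(x) rowData(x)$ref)
#' @rdname accessors
#' @export
setMethod("altAllele", "VariantSet", function(x) rowData(x)$alt)
#' @rdname accessors
#' @export
setMethod("predictorCalls", "VariantSet", function(x) {
  p <- rowData(x)$predictors
  if (is.null(p)) matrix(character(), nrow = nrow(x), ncol = 0L) else unclass(p)
})

#' @rdname accessors
#' @export
setMethod("familyId", "Pedigree", function(x) x@familyId)
#' @rdname accessors
#' @export
setMethod("pedMembers", "Pedigree", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("inheritanceModel", "Pedigree", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("affectedIds", "Pedigree", function(x)
  x@members$id[x@members$affection == "affected"])
#' @rdname accessors
#' @export
setMethod("unaffectedIds", "Pedigree", function(x)
  x@members$id[x@members$affection == "unaffected"])
#' @rdname accessors
#' @export
setMethod("genotypedIds", "Pedigree", function(x) x@members$id[x@members$genotyped])
#' @rdname accessors
#' @export
setMethod("founderIds", "Pedigree", function(x)
  x@members$id[x@members$father == "0" & x@members$mother == "0"])

#' Variant annotations as a plain data.frame
#'
#' One row per biallelic record with the columns downstream TSV outputs use:
#' `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `maf`.
#'
#' @param x a [VariantSet-class].
#' @return a data.frame with `nrow(x)` rows.
#' @export
asVariantTable <- function(x) {
  data.frame(chrom = as.character(seqnames(x)), pos = start(x),
             ref = refAllele(x), alt = altAllele(x), gene = geneSymbol(x),
             consequence = consequence(x), maf = populationMaf(x),
             stringsAsFactors = FALSE)
}
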