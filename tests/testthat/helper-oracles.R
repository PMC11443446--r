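## Independent brute-force oracles and fixture builders shared across tests.
## These deliberately re-state the rules in plain loops, independent of the
## package's vectorized implementations.

## --- segregation rule, stated directly over one genotype vector -----------
## g: named dosage vector (0/1/2, NA = missing) over genotyped members.
## AD: every genotyped affected het AND every genotyped unaffected hom-ref.
## AR: every genotyped affected hom-alt AND every genotyped obligate-carrier
##     parent het AND no genotyped unaffected hom-alt
##     (scope "all": every genotyped unaffected het).
## Missing genotypes: noninformative drops the member from its constraint;
## strict requires all constrained members non-missing. A variant with no
## observed affected genotype is never kept.
bruteSegregation <- function(g, rows, model, policy = "noninformative",
                             scope = "parents") {
  aff <- rows$individual_id[rows$affection == "affected"]
  unaff <- rows$individual_id[rows$affection == "unaffected"]
  aff <- intersect(aff, names(g)); unaff <- intersect(unaff, names(g))
  if (length(aff) == 0L) return(FALSE)
  if (all(is.na(g[aff]))) return(FALSE)
  carriers <- character()
  for (a in rows$individual_id[rows$affection == "affected"]) {
    r <- rows[rows$individual_id == a, ]
    for (p in c(r$father_id, r$mother_id))
      if (p != "0" && p %in% unaff) carriers <- union(carriers, p)
  }
  ok <- TRUE
  req <- function(ids, test) {
    for (id in ids) {
      v <- g[[id]]
      if (is.na(v)) {
        if (policy == "strict") ok <<- FALSE
      } else if (!test(v)) ok <<- FALSE
    }
  }
  if (model == "AD") {
    req(aff, function(v) v == 1L)
    req(unaff, function(v) v == 0L)
  } else {
    req(aff, function(v) v == 2L)
    if (scope == "all") {
      req(unaff, function(v) v == 1L)
    } else {
      req(intersect(carriers, names(g)), function(v) v == 1L)
      req(setdiff(unaff, carriers), function(v) v != 2L)
    }
  }
  ok
}

## --- ACMG combining rules, stated directly --------------------------------
## Codes restricted to the annotation-derivable set; counts therefore cap at
## PVS<=1, PS<=1, PM<=1, PP<=2, BA<=1, BS<=1, BP<=1.
bruteCombine <- function(codes) {
  pvs <- sum(codes == "PVS1"); ps <- sum(codes == "PS_any")
  pm <- sum(codes == "PM2"); pp <- sum(codes %in% c("PP1", "PP3"))
  ba <- sum(codes == "BA1"); bs <- sum(codes == "BS1"); bp <- sum(codes == "BP4")
  if ((pvs + ps + pm + pp) > 0 && (ba + bs + bp) > 0) return("VUS")
  if (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) return("Pathogenic")
  if (ps >= 2) return("Pathogenic")
  if (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4))) return("Pathogenic")
  if (pvs >= 1 && pm >= 1) return("Likely pathogenic")
  if (ps >= 1 && pm >= 1) return("Likely pathogenic")
  if (ps >= 1 && pp >= 2) return("Likely pathogenic")
  if (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)) return("Likely pathogenic")
  if (ba >= 1 || bs >= 2) return("Benign")
  if ((bs >= 1 && bp >= 1) || bp >= 2) return("Likely benign")
  "VUS"
}

evidenceUniverse <- function() c("PVS1", "PS_any", "PM2", "PP1", "PP3",
                                 "BA1", "BS1", "BP4")

## --- fixture builders ------------------------------------------------------

## nuclear family with 5 members: parents + 3 children, 2 affected children
nuclearPed5 <- function(model) {
  rows <- data.frame(
    family_id = "nuc",
    individual_id = c("FA", "MO", "K1", "K2", "K3"),
    father_id = c("0", "0", "FA", "FA", "FA"),
    mother_id = c("0", "0", "MO", "MO", "MO"),
    sex = c("male", "female", "male", "female", "male"),
    affection = c("unaffected", "unaffected", "affected", "affected", "unaffected"),
    stringsAsFactors = FALSE)
  list(rows = rows, ped = validatePedigree(rows, model = model))
}

## single-variant VariantSet with an explicit genotype vector
variantWithGenotypes <- function(g, gene = "IRF6", consequence = "missense_variant",
                                 maf = 0.001, predictors = NULL) {
  VariantSet(chrom = "1", pos = 1000L, ref = "A", alt = "G", gene = gene,
             consequence = consequence, maf = maf,
             dosage = matrix(as.integer(g), nrow = 1L,
                             dimnames = list(NULL, names(g))),
             predictors = predictors)
}

## small multi-variant VariantSet with controllable annotations; genotypes
## all het in affected / hom-ref elsewhere unless supplied
makeVariantSet <- function(maf, consequence = "missense_variant",
                           gene = "IRF6", samples = c("FA", "MO", "K1"),
                           dosage = NULL) {
  n <- length(maf)
  consequence <- rep_len(consequence, n)
  gene <- rep_len(gene, n)
  if (is.null(dosage))
    dosage <- matrix(rep(rep_len(c(1L, 0L, 1L), length(samples)), each = n),
                     nrow = n, ncol = length(samples),
                     dimnames = list(NULL, samples))
  VariantSet(chrom = rep("1", n), pos = seq_len(n) * 100L,
             ref = rep("A", n), alt = rep("G", n), gene = gene,
             consequence = consequence, maf = maf, dosage = dosage)
}

## enumerate all 3^n genotype vectors over `ids`
allGenotypeVectors <- function(ids) {
  grid <- expand.grid(rep(list(0:2), length(ids)))
  lapply(seq_len(nrow(grid)), function(i)
    setNames(as.integer(grid[i, ]), ids))
}
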