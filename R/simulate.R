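#' Built-in pedigree templates
#'
#' * `"trio"` — autosomal dominant trio: affected father, unaffected
#'   mother, affected child (the smallest structure satisfying the
#'   two-affected inclusion rule with a Mendelian-consistent dominant
#'   transmission).
#' * `"threeGenAD"` — three generations, three affected in a vertical
#'   transmission chain (grandparent, parent, child) plus unaffected
#'   relatives; 7 members.
#' * `"fourGenARSecondCousin"` — four generations, 14 members, exactly two
#'   affected second cousins in the youngest generation, each with
#'   unaffected parents: the classic recessive multiplex structure in which
#'   a founder allele descends down two sibling branches and meets a
#'   carrier marry-in on each side.
#'
#' @param template template name.
#' @return data.frame of PED rows ([readPed()] layout).
#' @export
pedigreeTemplate <- function(template = c("trio", "threeGenAD",
                                          "fourGenARSecondCousin")) {
  template <- match.arg(template)
  row <- function(id, fa, mo, sex, aff)
    data.frame(family_id = paste0("sim_", template), individual_id = id,
               father_id = fa, mother_id = mo, sex = sex, affection = aff,
               stringsAsFactors = FALSE)
  switch(template,
    trio = rbind(
      row("P1", "0", "0", "male", "affected"),
      row("P2", "0", "0", "female", "unaffected"),
      row("K1", "P1", "P2", "male", "affected")),
    threeGenAD = rbind(
      row("F1", "0", "0", "male", "affected"),
      row("F2", "0", "0", "female", "unaffected"),
      row("S1", "F1", "F2", "male", "affected"),
      row("S2", "F1", "F2", "female", "unaffected"),
      row("S1S", "0", "0", "female", "unaffected"),
      row("T1", "S1", "S1S", "male", "affected"),
      row("T2", "S1", "S1S", "female", "unaffected")),
    fourGenARSecondCousin = rbind(
      row("A1", "0", "0", "male", "unaffected"),
      row("A2", "0", "0", "female", "unaffected"),
      row("B1", "A1", "A2", "male", "unaffected"),
      row("B2", "A1", "A2", "male", "unaffected"),
      row("B3", "A1", "A2", "female", "unaffected"),
      row("B1S", "0", "0", "female", "unaffected"),
      row("B2S", "0", "0", "female", "unaffected"),
      row("C1", "B1", "B1S", "male", "unaffected"),
      row("C2", "B2", "B2S", "female", "unaffected"),
      row("C3", "B2", "B2S", "male", "unaffected"),
      row("C1S", "0", "0", "female", "unaffected"),
      row("C2S", "0", "0", "male", "unaffected"),
      row("D1", "C1", "C1S", "male", "affected"),
      row("D2", "C2S", "C2", "female", "affected")))
}

#' Build a pedigree from a template
#'
#' @param template template name; see [pedigreeTemplate()].
#' @param model inheritance model to assign; defaults to the template's
#'   natural model (`AR` for the second-cousin template, `AD` otherwise).
#' @param seed unused (templates are deterministic); accepted for interface
#'   symmetry with the stochastic generators.
#' @return a validated [Pedigree-class] with every member genotyped.
#' @export
#' @examples
#' ped <- buildPedigree("fourGenARSecondCousin")
#' suggestModel(ped)
buildPedigree <- function(template = c("trio", "threeGenAD",
                                       "fourGenARSecondCousin"),
                          model = NULL, seed = NULL) {
  template <- match.arg(template)
  model <- model %||% if (template == "fourGenARSecondCousin") "AR" else "AD"
  validatePedigree(pedigreeTemplate(template), model = model)
}

## members in an order where parents precede children
.topologicalOrder <- function(m) {
  placed <- character()
  ord <- integer()
  remaining <- seq_len(nrow(m))
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      ps <- setdiff(c(m$father[i], m$mother[i]), "0")
      all(ps %in% placed)
    }, logical(1))]
    abortIf(!length(ready), "pedigree is not topologically orderable")
    ord <- c(ord, ready)
    placed <- c(placed, m$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  ord
}

## Gene drop vectorized over variants: founders draw two Bernoulli(maf)
## alleles, children receive one allele per parent chosen uniformly from the
## parent's pair. Returns a variants x members dosage matrix.
.geneDropDosage <- function(ped, mafs) {
  m <- pedMembers(ped)
  nv <- length(mafs)
  a1 <- a2 <- matrix(NA_integer_, nrow = nv, ncol = nrow(m),
                     dimnames = list(NULL, m$id))
  for (i in .topologicalOrder(m)) {
    id <- m$id[i]
    if (m$father[i] == "0") {
      a1[, id] <- rbinom(nv, 1L, mafs)
      a2[, id] <- rbinom(nv, 1L, mafs)
    } else {
      fromFirst <- rbinom(nv, 1L, 0.5) == 1L
      a1[, id] <- ifelse(fromFirst, a1[, m$father[i]], a2[, m$father[i]])
      fromFirst <- rbinom(nv, 1L, 0.5) == 1L
      a2[, id] <- ifelse(fromFirst, a1[, m$mother[i]], a2[, m$mother[i]])
    }
  }
  a1 + a2
}

#' Gene-dropping genotype simulation
#'
#' Draws founder genotypes from Hardy-Weinberg equilibrium at the given
#' allele frequency (hom-alt probability `maf^2`, het `2*maf*(1-maf)`) and
#' transmits one allele per parent to each child, chosen uniformly from the
#' parent's two alleles — so every child allele traces to a parental allele
#' by construction.
#'
#' @param ped a [Pedigree-class].
#' @param maf alternate-allele frequency in (0, 1).
#' @param seed optional integer seed fixing all randomness of this call.
#' @return named integer vector of alternate-allele dosages (0/1/2) per
#'   individual.
#' @export
#' @examples
#' ped <- buildPedigree("trio")
#' geneDrop(ped, maf = 0.2, seed = 7)
geneDrop <- function(ped, maf, seed = NULL) {
  abortIf(!(maf > 0 && maf < 1), "maf must lie strictly in (0, 1)")
  withSeed(seed, {
    d <- .geneDropDosage(ped, maf)
    setNames(as.integer(d[1L, ]), colnames(d))
  })
}

#' Plant a fully segregating causal genotype configuration
#'
#' Constructs the genotype vector the segregation filter demands, with a
#' Mendelian-consistent transmission path:
#'
#' * **AD** — every affected individual heterozygous, everyone else
#'   homozygous reference. Requires every affected non-founder to have an
#'   affected parent (otherwise the dominant allele would have to arise de
#'   novo, which the simulator does not emit).
#' * **AR** — every affected individual homozygous-alternate, both parents
#'   of each affected heterozygous, and a minimal chain of heterozygous
#'   ancestors carrying the allele down to them (shared ancestry is reused
#'   before introducing a new founder allele); all remaining members
#'   homozygous reference. The second-cousin template yields the classic
#'   pattern: two hom-alt affected, four het parents, a het chain through
#'   the shared great-grandparent.
#'
#' The returned configuration passes [segregationFilter()] (default
#' policies) by construction.
#'
#' @param ped a [Pedigree-class].
#' @param model `"AD"` or `"AR"`; must match `inheritanceModel(ped)` when
#'   that is set.
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic.
#' @return named integer dosage vector per individual.
#' @export
plantCausal <- function(ped, model = inheritanceModel(ped), seed = NULL) {
  model <- match.arg(model, c("AD", "AR"))
  if (!is.na(inheritanceModel(ped)))
    abortIf(model != inheritanceModel(ped),
            "model does not match the pedigree's assigned model")
  m <- pedMembers(ped)
  ids <- m$id
  aff <- ids[m$affection == "affected"]
  fa <- setNames(m$father, ids); mo <- setNames(m$mother, ids)
  isFounder <- setNames(fa == "0", ids)
  g <- setNames(rep(0L, length(ids)), ids)

  if (model == "AD") {
    affSet <- aff
    for (a in aff) {
      if (!isFounder[[a]]) {
        ps <- c(fa[[a]], mo[[a]])
        abortIf(!any(ps %in% affSet),
                sprintf("pedigree topologically incompatible with AD planting: affected %s has no affected parent", a))
      }
    }
    g[aff] <- 1L
    return(g)
  }

  ## AR: number of affected descendants per individual, to prefer carrier
  ## paths through shared ancestors
  descendantsOf <- function(id) {
    out <- character(); frontier <- id
    while (length(frontier)) {
      kids <- ids[fa[ids] %in% frontier | mo[ids] %in% frontier]
      kids <- setdiff(kids, out)
      out <- c(out, kids); frontier <- kids
    }
    out
  }
  nAffDesc <- vapply(ids, function(id) sum(descendantsOf(id) %in% aff), 0L)
  markCarrier <- function(id) {
    if (g[[id]] > 0L) return(invisible())
    g[id] <<- 1L
    if (isFounder[[id]]) return(invisible())
    ps <- c(fa[[id]], mo[[id]])
    if (any(g[ps] > 0L)) return(invisible())
    pick <- ps[order(-nAffDesc[ps])][1L]
    markCarrier(pick)
  }
  g[aff] <- 2L
  for (a in aff) {
    if (!isFounder[[a]]) for (p in c(fa[[a]], mo[[a]])) markCarrier(p)
  }
  g
}

#' Check Mendelian consistency of a genotype vector
#'
#' At dosage level: each parent transmits 0 alt alleles if homozygous
#' reference, 1 if homozygous alternate, and 0 or 1 if heterozygous; a
#' child's dosage must be a feasible sum of one transmission per parent.
#' Individuals with missing genotypes (or missing parental genotypes) are
#' skipped.
#'
#' @param ped a [Pedigree-class].
#' @param dosage named integer dosage vector (as from [geneDrop()]) or a
#'   matrix variants x individuals.
#' @return logical: `TRUE` per variant iff every checkable child dosage is
#'   Mendelian-consistent.
#' @export
checkMendelian <- function(ped, dosage) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1L,
                                             dimnames = list(NULL, names(dosage)))
  m <- pedMembers(ped)
  kids <- m[m$father != "0", , drop = FALSE]
  transmit <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  ok <- rep(TRUE, nrow(dosage))
  for (i in seq_len(nrow(kids))) {
    dc <- dosage[, kids$id[i]]
    df <- dosage[, kids$father[i]]
    dm <- dosage[, kids$mother[i]]
    for (v in seq_len(nrow(dosage))) {
      if (any(is.na(c(dc[v], df[v], dm[v])))) next
      feasible <- outer(transmit[[as.character(df[v])]],
                        transmit[[as.character(dm[v])]], `+`)
      if (!dc[v] %in% feasible) ok[v] <- FALSE
    }
  }
  ok
}

#' SimulationConfig constructor
#'
#' Bundles everything one simulated family dataset depends on. The defaults
#' emulate the study conditions of a recessive multiplex NSOFC family:
#' the four-generation second-cousin template, a planted rare missense
#' variant in a relevance-list gene (ECPAS-like), full penetrance, complete
#' genotyping, and background variants whose population frequencies span
#' both sides of the 0.5%/5% thresholds with a mix of whitelisted and
#' non-whitelisted consequences and in-/out-of-list genes.
#'
#' @param seed integer seed fixing all randomness.
#' @param template pedigree template name (see [pedigreeTemplate()]).
#' @param model planted inheritance model, `"AD"` or `"AR"`; defaults to
#'   the template's natural model.
#' @param nBackground number of background (non-causal) variants.
#' @param plantedGene gene symbol of the planted causal variant.
#' @param plantedMaf population MAF recorded for the planted variant
#'   (`NA` = novel/absent; default 0.001).
#' @param plantedConsequence consequence term of the planted variant.
#' @param penetrance probability that a carrier of the risk genotype is
#'   affected (default 1; the filters assume full penetrance, and values
#'   below 1 exist to demonstrate their failure modes).
#' @param missingRate per-genotype missingness probability (default 0).
#' @param relevanceFraction fraction of background variants placed in
#'   relevance-list genes (default 0.3).
#' @param backgroundMafGrid population frequencies sampled for background
#'   variants; spans both sides of both model thresholds and includes `NA`
#'   (novel).
#' @param guaranteeBackgroundFails force every background variant to fail
#'   at least one cascade stage (default `TRUE`), making the planted
#'   variant the unique expected candidate.
#' @return object of class `SimulationConfig` (a validated list).
#' @export
simulationConfig <- function(seed = 1L,
                             template = "fourGenARSecondCousin",
                             model = NULL,
                             nBackground = 500L,
                             plantedGene = "ECPAS",
                             plantedMaf = 0.001,
                             plantedConsequence = "missense_variant",
                             penetrance = 1,
                             missingRate = 0,
                             relevanceFraction = 0.3,
                             backgroundMafGrid = c(NA, 1e-4, 5e-4, 0.001,
                                                   0.005, 0.006, 0.01, 0.04,
                                                   0.05, 0.06, 0.1, 0.2, 0.4),
                             guaranteeBackgroundFails = TRUE) {
  template <- match.arg(template, c("trio", "threeGenAD", "fourGenARSecondCousin"))
  model <- model %||% if (template == "fourGenARSecondCousin") "AR" else "AD"
  abortIf(!(penetrance > 0 && penetrance <= 1), "penetrance must lie in (0, 1]")
  abortIf(missingRate < 0 || missingRate >= 1, "missingRate must lie in [0, 1)")
  structure(list(seed = as.integer(seed), template = template,
                 model = match.arg(model, c("AD", "AR")),
                 nBackground = as.integer(nBackground),
                 plantedGene = plantedGene, plantedMaf = plantedMaf,
                 plantedConsequence = plantedConsequence,
                 penetrance = penetrance, missingRate = missingRate,
                 relevanceFraction = relevanceFraction,
                 backgroundMafGrid = backgroundMafGrid,
                 guaranteeBackgroundFails = guaranteeBackgroundFails),
            class = "SimulationConfig")
}

#' Simulate one annotated family dataset in memory
#'
#' Builds the template pedigree, plants the causal variant with
#' [plantCausal()], gene-drops the background variants, applies penetrance
#' and genotype missingness, and returns the pieces the pipeline consumes
#' plus the ground truth. When `guaranteeBackgroundFails` is set (default),
#' any background variant that would survive all four cascade stages has
#' one affected genotype set to homozygous reference, so the planted
#' variant is the unique expected candidate and recovery can be scored as
#' precision/recall against the truth table.
#'
#' @param config a [simulationConfig()].
#' @param cfg the [FilterConfig-class] the guarantee is evaluated under.
#' @return list with `variants` ([VariantSet-class]), `pedigree`
#'   ([Pedigree-class]), `truth` (data.frame with `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `is_planted_causal`) and `carriers` (named dosage
#'   vector of the planted variant).
#' @export
#' @examples
#' sim <- simulateFamilyDataset(simulationConfig(seed = 42, nBackground = 20))
#' sum(sim$truth$is_planted_causal)
simulateFamilyDataset <- function(config, cfg = filterConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    ped <- buildPedigree(config$template, model = config$model)
    members <- pedMembers(ped)$id
    planted <- plantCausal(ped, config$model)

    nB <- config$nBackground
    relList <- setdiff(cfg@relevanceGenes, toupper(config$plantedGene))
    inList <- rbinom(nB, 1L, config$relevanceFraction) == 1L
    genes <- ifelse(inList, sample(relList, nB, replace = TRUE),
                    sprintf("NOVELG%04d", sample.int(9999L, nB, replace = TRUE)))
    consPool <- c(defaultConsequenceWhitelist(), "synonymous_variant",
                  "intron_variant", "5_prime_UTR_variant", "3_prime_UTR_variant")
    cons <- sample(consPool, nB, replace = TRUE)
    mafs <- sample(config$backgroundMafGrid, nB, replace = TRUE)
    predNames <- c("sift", "polyphen2", "mutationtaster", "provean", "revel")
    pred <- matrix(sample(c("damaging", "tolerated", NA), nB * 5L,
                          replace = TRUE, prob = c(0.35, 0.55, 0.10)),
                   nrow = nB, dimnames = list(NULL, predNames))

    dropMafs <- ifelse(is.na(mafs), 0.05, pmin(pmax(mafs, 0.01), 0.5))
    dosage <- rbind(.geneDropDosage(ped, dropMafs),
                    planted[members])[, members, drop = FALSE]
    dimnames(dosage) <- list(NULL, members)

    chrom <- as.character(sample.int(22L, nB + 1L, replace = TRUE))
    pos <- sample.int(2e8L, nB + 1L)
    bases <- c("A", "C", "G", "T")
    refA <- sample(bases, nB + 1L, replace = TRUE)
    altA <- vapply(refA, function(r) sample(setdiff(bases, r), 1L), "")

    gene <- c(genes, toupper(config$plantedGene))
    consequence <- c(cons, config$plantedConsequence)
    maf <- c(mafs, config$plantedMaf)
    pred <- rbind(pred, c("damaging", "damaging", "damaging", "damaging", "tolerated"))
    isPlanted <- c(rep(FALSE, nB), TRUE)

    vs <- VariantSet(chrom = chrom, pos = pos, ref = refA, alt = altA,
                     gene = gene, consequence = consequence, maf = maf,
                     dosage = dosage, predictors = pred)

    if (isTRUE(config$guaranteeBackgroundFails)) {
      pass <- mafFilter(vs, config$model, cfg) & consequenceFilter(vs, cfg) &
        suppressWarnings(segregationFilter(vs, ped, cfg)) &
        relevanceFilter(vs, cfg = cfg)
      fix <- which(pass & !isPlanted)
      if (length(fix)) {
        a1 <- intersect(affectedIds(ped), genotypedIds(ped))[1L]
        d <- genotypes(vs)
        d[fix, a1] <- 0L
        assay(vs, "dosage") <- d
      }
    }

    if (config$penetrance < 1) {
      m <- pedMembers(ped)
      flip <- m$affection == "affected" & runif(nrow(m)) > config$penetrance
      m$affection[flip] <- "unaffected"
      ped <- new("Pedigree", familyId = familyId(ped), members = m,
                 model = inheritanceModel(ped))
      abortIf(sum(m$affection == "affected") == 0L,
              "no affected members remain after applying penetrance; reseed or raise penetrance")
    }

    if (config$missingRate > 0) {
      d <- genotypes(vs)
      d[runif(length(d)) < config$missingRate] <- NA_integer_
      assay(vs, "dosage") <- d
    }

    ord <- order(as.integer(chrom), pos)
    vs <- vs[ord, ]
    isPlanted <- isPlanted[ord]
    truth <- cbind(asVariantTable(vs)[, c("chrom", "pos", "ref", "alt", "gene")],
                   is_planted_causal = isPlanted)
    list(variants = vs, pedigree = ped, truth = truth,
         carriers = planted)
  })
}

#' Emit a simulated dataset to disk
#'
#' Writes the annotated VCF, PED file and ground-truth JSON for one
#' simulated family. The files round-trip through [readAnnotatedVcf()] and
#' [readPed()].
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if needed).
#' @param cfg [FilterConfig-class] used for the background-failure
#'   guarantee.
#' @return list with `vcf`, `ped`, `truth` paths and the in-memory `sim`
#'   dataset, invisibly.
#' @export
emitDataset <- function(config, outdir, cfg = filterConfig()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateFamilyDataset(config, cfg)
  fam <- familyId(sim$pedigree)
  vcfPath <- file.path(outdir, paste0(fam, ".vcf"))
  pedPath <- file.path(outdir, paste0(fam, ".ped"))
  truthPath <- file.path(outdir, paste0(fam, "_truth.json"))
  writeAnnotatedVcf(sim$variants, vcfPath)
  writePed(pedigreeToRows(sim$pedigree), pedPath)
  jsonlite::write_json(list(family_id = fam, model = config$model,
                            seed = config$seed, truth = sim$truth,
                            carriers = as.list(sim$carriers)),
                       truthPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(vcf = vcfPath, ped = pedPath, truth = truthPath, sim = sim))
}
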