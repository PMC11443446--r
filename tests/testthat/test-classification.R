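test_that("in-silico consensus is a strict-majority vote over non-absent calls", {
  expect_equal(insilicoConsensus(c("damaging", "damaging", "damaging", "damaging", "tolerated")),
               "possibly_pathogenic")
  expect_equal(insilicoConsensus(c("damaging", "tolerated")), "inconclusive")
  expect_equal(insilicoConsensus(c("tolerated", "tolerated", "tolerated")),
               "possibly_benign")
  expect_error(insilicoConsensus(c(NA, NA)), "no predictor calls")

  # derived check against a direct majority count over random call sets
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:7, 1)
    calls <- sample(c("damaging", "tolerated", NA), n, replace = TRUE)
    if (all(is.na(calls))) next
    nd <- sum(calls == "damaging", na.rm = TRUE)
    nt <- sum(calls == "tolerated", na.rm = TRUE)
    want <- if (nd > (nd + nt) / 2) "possibly_pathogenic"
            else if (nt > (nd + nt) / 2) "possibly_benign" else "inconclusive"
    expect_equal(insilicoConsensus(calls), want)
  }
})

test_that("evidence assignment derives PVS1/PM2/PP1/PP3 and the benign mirrors from annotations", {
  arPed <- buildPedigree("fourGenARSecondCousin")
  ids <- pedMembers(arPed)$id
  gSeg <- setNames(rep(0L, length(ids)), ids)
  gSeg[c("D1", "D2")] <- 2L
  gSeg[c("C1", "C1S", "C2", "C2S")] <- 1L
  gSeg[c("A1", "B1", "B2")] <- 1L
  damPred <- matrix(c("damaging", "damaging", "damaging", "tolerated"), nrow = 1,
                    dimnames = list(NULL, c("sift", "polyphen2", "provean", "revel")))

  # rare segregating missense with damaging consensus: the classic
  # recessive-candidate evidence triplet
  vs <- variantWithGenotypes(gSeg, gene = "ECPAS", maf = 0.001,
                             predictors = damPred)
  expect_setequal(assignEvidence(vs, arPed)[[1]], c("PM2", "PP3", "PP1"))

  # common variant: stand-alone benign only
  vsCommon <- variantWithGenotypes(gSeg, gene = "ECPAS", maf = 0.10,
                                   predictors = damPred)
  ev <- assignEvidence(vsCommon, arPed)[[1]]
  expect_setequal(ev[startsWith(ev, "B")], "BA1")

  # null variant in a LoF-mechanism gene, absent from databases,
  # non-segregating genotypes: PVS1 + PM2 exactly
  gBad <- gSeg; gBad["D1"] <- 1L
  vsNull <- variantWithGenotypes(gBad, gene = "IRF6", maf = NA_real_)
  vsNull <- local({ x <- vsNull; SummarizedExperiment::rowData(x)$consequence <- "stop_gained"; x })
  expect_setequal(assignEvidence(vsNull, arPed)[[1]], c("PVS1", "PM2"))

  # intermediate frequency with benign consensus: BS1 + BP4
  tolPred <- matrix(rep("tolerated", 3), nrow = 1,
                    dimnames = list(NULL, c("sift", "polyphen2", "provean")))
  vsMid <- variantWithGenotypes(gBad, gene = "ECPAS", maf = 0.03, predictors = tolPred)
  # PM2's bound defaults to the model threshold (5% under AR), so 3% still
  # earns PM2; with an explicit tighter bound only the benign mirrors remain
  expect_setequal(assignEvidence(vsMid, arPed)[[1]], c("PM2", "BS1", "BP4"))
  tight <- filterConfig(pm2Bound = 0.005)
  expect_setequal(assignEvidence(vsMid, arPed, tight)[[1]], c("BS1", "BP4"))
})

test_that("PP1 requires enough informative meioses", {
  rows <- pedigreeTemplate("fourGenARSecondCousin")
  # only D1 and D2 genotyped: segregation can pass but 0 observable meioses
  thin <- validatePedigree(rows, vcfSamples = c("D1", "D2"), model = "AR")
  g <- c(D1 = 2L, D2 = 2L)
  ev <- assignEvidence(variantWithGenotypes(g, gene = "ECPAS", maf = NA), thin)[[1]]
  expect_false("PP1" %in% ev)
  expect_true("PM2" %in% ev)
})

test_that("ACMG combiner matches the stated combination rules on named cases", {
  expect_equal(combineAcmg(c("PVS1", "PM2"))$verdict, "Likely pathogenic")
  expect_equal(combineAcmg("BA1")$verdict, "Benign")
  expect_equal(combineAcmg(character())$verdict, "VUS")
  expect_equal(combineAcmg(c("PVS1", "PS_any"))$verdict, "Pathogenic")
  expect_equal(combineAcmg(c("PVS1", "PM2", "PP1"))$verdict, "Pathogenic")
  expect_equal(combineAcmg(c("BS1", "BP4"))$verdict, "Likely benign")
  # conflicting directions resolve to uncertain significance
  expect_equal(combineAcmg(c("PVS1", "PM2", "BA1"))$verdict, "VUS")
  expect_equal(combineAcmg(c("PM2", "BP4"))$verdict, "VUS")
})

test_that("exhaustive evidence-subset sweep agrees with an independent statement of the rules", {
  universe <- evidenceUniverse()
  rules <- acmgRules()
  for (mask in 0:(2^length(universe) - 1)) {
    codes <- universe[bitwAnd(mask, 2^(seq_along(universe) - 1)) > 0]
    expect_equal(combineAcmg(codes, rules)$verdict, bruteCombine(codes),
                 label = paste(codes, collapse = "+"))
  }
})

test_that("adding pathogenic-direction evidence never moves a conflict-free verdict toward benign", {
  rank <- c(Benign = 1, `Likely benign` = 2, VUS = 3,
            `Likely pathogenic` = 4, Pathogenic = 5)
  pathCodes <- c("PVS1", "PS_any", "PM2", "PP1", "PP3")
  subsets <- unlist(lapply(0:4, function(k)
    combn(pathCodes, k, simplify = FALSE)), recursive = FALSE)
  for (codes in subsets) {
    base <- rank[combineAcmg(codes)$verdict]
    for (extra in setdiff(pathCodes, codes)) {
      expect_gte(rank[combineAcmg(c(codes, extra))$verdict], base)
    }
  }
})

test_that("classifyCandidates emits a complete classified table", {
  sim <- simulateFamilyDataset(simulationConfig(seed = 7, nBackground = 100,
                                                plantedGene = "PTCH1",
                                                plantedConsequence = "stop_gained",
                                                plantedMaf = NA))
  res <- runCascade(sim$variants, sim$pedigree)
  tab <- classifyCandidates(res$candidates, sim$pedigree)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$gene, "PTCH1")
  expect_true(all(c("PVS1", "PM2") %in% strsplit(tab$evidence, ",")[[1]]))
  expect_true(tab$verdict %in% c("Pathogenic", "Likely pathogenic"))
  expect_equal(tab$family_id, familyId(sim$pedigree))
})
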