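test_that("pedigree templates build valid pedigrees with the advertised structure", {
  trio <- buildPedigree("trio")
  expect_equal(nrow(pedMembers(trio)), 3L)
  expect_equal(suggestModel(trio), "AD")

  ad <- buildPedigree("threeGenAD")
  expect_equal(suggestModel(ad), "AD")

  ar <- buildPedigree("fourGenARSecondCousin")
  expect_equal(suggestModel(ar), "AR")
  m <- pedMembers(ar)
  expect_equal(sum(m$affection == "affected"), 2L)
  # the two affected are second cousins: disjoint parents, disjoint
  # grandparents, shared great-grandparents
  lineage <- function(id, n) {
    out <- id
    for (i in seq_len(n)) out <- unique(unlist(
      lapply(out, function(x) setdiff(c(m$father[m$id == x], m$mother[m$id == x]), "0"))))
    out
  }
  aff <- m$id[m$affection == "affected"]
  expect_length(intersect(lineage(aff[1], 1), lineage(aff[2], 1)), 0L)
  expect_length(intersect(lineage(aff[1], 2), lineage(aff[2], 2)), 0L)
  expect_gt(length(intersect(lineage(aff[1], 3), lineage(aff[2], 3))), 0L)
  # four generations
  expect_equal(max(vapply(m$id, function(x) {
    d <- 1L; cur <- x
    while (m$father[m$id == cur] != "0") { cur <- m$father[m$id == cur]; d <- d + 1L }
    d
  }, 1L)), 4L)
})

test_that("gene-drop founder genotypes follow Hardy-Weinberg within binomial error", {
  ped <- buildPedigree("fourGenARSecondCousin")
  maf <- 0.2
  nrep <- 4000L
  d <- withr::with_seed(424243, cleftsift:::.geneDropDosage(ped, rep(maf, nrep)))
  founders <- founderIds(ped)
  fd <- as.vector(d[, founders])            # 6 founders x nrep draws
  n <- length(fd)
  for (target in list(c(2L, maf^2), c(1L, 2 * maf * (1 - maf)))) {
    p <- target[2]
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(fd == target[1]) - p), tol)
  }
  # child of het x hom-ref parents is het with probability 1/2
  sel <- d[, "A1"] == 1L & d[, "A2"] == 0L
  expect_gt(sum(sel), 500L)
  hetFrac <- mean(d[sel, "B1"] == 1L)
  expect_lt(abs(hetFrac - 0.5), 3 * sqrt(0.25 / sum(sel)))
})

test_that("every gene-dropped child genotype is Mendelian-consistent", {
  ped <- buildPedigree("fourGenARSecondCousin")
  d <- withr::with_seed(77, cleftsift:::.geneDropDosage(ped, runif(500, 0.05, 0.5)))
  expect_true(all(checkMendelian(ped, d)))
  # and checkMendelian does flag violations
  bad <- d[1, , drop = TRUE]
  bad[c("A1", "A2", "B1")] <- c(0L, 0L, 2L)
  expect_false(checkMendelian(ped, bad))
})

test_that("geneDrop is reproducible under a fixed seed", {
  ped <- buildPedigree("trio")
  expect_identical(geneDrop(ped, 0.3, seed = 99), geneDrop(ped, 0.3, seed = 99))
  # frozen regression vector (generated once from this implementation)
  expect_identical(geneDrop(ped, 0.3, seed = 2024),
                   c(P1 = 1L, P2 = 0L, K1 = 0L))
  expect_error(geneDrop(ped, 0), "maf")
})

test_that("plantCausal produces the canonical configurations and always segregates", {
  ar <- buildPedigree("fourGenARSecondCousin")
  g <- plantCausal(ar, "AR")
  expect_equal(unname(g[c("D1", "D2")]), c(2L, 2L))
  expect_equal(unname(g[c("C1", "C1S", "C2", "C2S")]), rep(1L, 4))
  expect_true(all(checkMendelian(ar, g)))

  ad <- buildPedigree("threeGenAD")
  gAd <- plantCausal(ad, "AD")
  expect_true(all(gAd[affectedIds(ad)] == 1L))
  expect_true(all(gAd[unaffectedIds(ad)] == 0L))
  expect_true(all(checkMendelian(ad, gAd)))

  for (tmpl in c("trio", "threeGenAD", "fourGenARSecondCousin")) {
    ped <- buildPedigree(tmpl)
    model <- inheritanceModel(ped)
    gP <- plantCausal(ped, model)
    vs <- variantWithGenotypes(gP)
    expect_true(segregationFilter(vs, ped, filterConfig()), label = tmpl)
    expect_true(all(checkMendelian(ped, gP)), label = tmpl)
  }

  # AD planting on a pedigree where the affected child has no affected
  # parent would require a de novo event: refused
  rows <- pedigreeTemplate("trio")
  rows$affection <- c("unaffected", "unaffected", "affected")
  rows2 <- rbind(rows, data.frame(family_id = rows$family_id[1],
                                  individual_id = "K2", father_id = "P1",
                                  mother_id = "P2", sex = "female",
                                  affection = "affected", stringsAsFactors = FALSE))
  denovo <- validatePedigree(rows2, model = "AD")
  expect_error(plantCausal(denovo, "AD"), "topologically incompatible")
  expect_error(plantCausal(buildPedigree("trio"), "AR"), "does not match")
})

test_that("simulated datasets carry a consistent truth table and Mendelian genotypes", {
  sim <- simulateFamilyDataset(simulationConfig(seed = 31, nBackground = 120))
  expect_equal(nrow(sim$variants), 121L)
  expect_equal(sum(sim$truth$is_planted_causal), 1L)
  planted <- which(sim$truth$is_planted_causal)
  expect_equal(unname(genotypes(sim$variants)[planted, ]),
               unname(sim$carriers[sampleIds(sim$variants)]))
  expect_true(all(checkMendelian(sim$pedigree, genotypes(sim$variants))))
  # annotations span both sides of both thresholds and both gene lists
  maf <- populationMaf(sim$variants)
  expect_true(any(is.na(maf)) && any(maf > 0.05, na.rm = TRUE) &&
                any(maf <= 0.005, na.rm = TRUE))
  inList <- toupper(geneSymbol(sim$variants)) %in% relevanceGenes()
  expect_true(any(inList) && any(!inList))
})

test_that("identical simulation configs emit byte-identical datasets", {
  cfg <- simulationConfig(seed = 12, nBackground = 40)
  d1 <- emitDataset(cfg, file.path(tempdir(), "simA"))
  d2 <- emitDataset(cfg, file.path(tempdir(), "simB"))
  expect_identical(readLines(d1$vcf), readLines(d2$vcf))
  expect_identical(readLines(d1$ped), readLines(d2$ped))
  expect_identical(readLines(d1$truth), readLines(d2$truth))
})

test_that("emitted datasets round-trip through the readers and feed the cascade", {
  d <- emitDataset(simulationConfig(seed = 8, nBackground = 60), tempdir())
  vs <- readAnnotatedVcf(d$vcf)
  rows <- readPed(d$ped)
  ped <- validatePedigree(rows, vcfSamples = sampleIds(vs), model = "AR")
  expect_equal(nrow(vs), 61L)
  expect_equal(genotypes(vs), genotypes(d$sim$variants))
  res <- runCascade(vs, ped)
  truth <- d$sim$truth
  expect_equal(asVariantTable(res$candidates)$pos,
               truth$pos[truth$is_planted_causal])
})

test_that("under genotype missingness the non-informative policy recovers at least as much as strict mode", {
  recalls <- vapply(1:15, function(s) {
    sim <- simulateFamilyDataset(simulationConfig(seed = s, nBackground = 60,
                                                  missingRate = 0.1))
    plantedPos <- sim$truth$pos[sim$truth$is_planted_causal]
    vapply(c("noninformative", "strict"), function(pol) {
      cfg <- filterConfig(missingGenotypePolicy = pol)
      res <- suppressWarnings(runCascade(sim$variants, sim$pedigree, cfg))
      plantedPos %in% asVariantTable(res$candidates)$pos
    }, logical(1))
  }, logical(2))
  expect_gte(mean(recalls["noninformative", ]), mean(recalls["strict", ]))
})

test_that("reduced penetrance can break the full-penetrance segregation assumption", {
  # with penetrance well below 1, some seeds demote planted carriers to
  # unaffected, and the planted variant may fail the segregation stage
  hits <- vapply(1:12, function(s) {
    sim <- tryCatch(
      simulateFamilyDataset(simulationConfig(seed = s, nBackground = 10,
                                             penetrance = 0.5)),
      error = function(e) NULL)
    if (is.null(sim)) return(NA)
    res <- suppressWarnings(runCascade(sim$variants, sim$pedigree))
    sim$truth$pos[sim$truth$is_planted_causal] %in% asVariantTable(res$candidates)$pos
  }, logical(1))
  expect_true(any(!hits, na.rm = TRUE))
})
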