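test_that("PED reading decodes the 6-column dialect and validates referential integrity", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("# comment",
               "fam30\tA1\t0\t0\t1\t1",
               "fam30\tA2\t0\t0\t2\t1",
               "fam30\tD1\tA1\tA2\t1\t2",
               "fam30\tD2\tA1\tA2\t2\t0"), ped)
  rows <- readPed(ped)
  expect_equal(nrow(rows), 4L)
  expect_equal(rows$affection, c("unaffected", "unaffected", "affected", "unknown"))
  expect_equal(rows$sex, c("male", "female", "male", "female"))
  expect_equal(rows$father_id, c("0", "0", "A1", "A1"))

  empty <- tempfile(); writeLines(character(), empty)
  expect_equal(nrow(readPed(empty)), 0L)

  bad <- tempfile(); writeLines(c("fam x 0 0 1 2", "fam y 0 0"), bad)
  expect_error(readPed(bad), "line 2")

  orphan <- tempfile()
  writeLines(c("fam\tkid\tdad\t0\t1\t2", "fam\tsib\t0\t0\t1\t2"), orphan)
  expect_error(readPed(orphan), "father 'dad' not present")

  dup <- tempfile()
  writeLines(c("fam\tx\t0\t0\t1\t2", "fam\tx\t0\t0\t1\t1"), dup)
  expect_error(readPed(dup), "duplicate")
})

test_that("PED round-trips field-identically through writePed/readPed", {
  rows <- pedigreeTemplate("fourGenARSecondCousin")
  expect_gte(nrow(rows), 14L)
  f <- tempfile(fileext = ".ped")
  writePed(rows, f)
  expect_identical(readPed(f), rows)
})

test_that("annotated VCF round-trips through write/read with dosage, MAF-absence and predictors intact", {
  samples <- c("D1", "D2", "C1", "C2")
  pred <- matrix(c("damaging", "damaging", "tolerated", NA,
                   "damaging", "tolerated", NA, NA),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("polyphen2", "provean", "revel", "sift")))
  vs <- VariantSet(chrom = c("8", "9"), pos = c(101L, 202L),
                   ref = c("C", "T"), alt = c("G", "A"),
                   gene = c("ECPAS", "PTCH1"),
                   consequence = c("missense_variant", "stop_gained"),
                   maf = c(0.004, NA),
                   dosage = matrix(c(2L, 2L, 1L, 1L,
                                     1L, NA, 0L, 0L), nrow = 2, byrow = TRUE,
                                   dimnames = list(NULL, samples)),
                   predictors = pred)
  f <- tempfile(fileext = ".vcf")
  writeAnnotatedVcf(vs, f)
  back <- readAnnotatedVcf(f)
  expect_equal(asVariantTable(back), asVariantTable(vs))
  expect_equal(genotypes(back), genotypes(vs))
  # a predictor with no call anywhere is absent, not fabricated
  present <- c("polyphen2", "provean", "revel")
  expect_setequal(colnames(predictorCalls(back)), present)
  expect_equal(predictorCalls(back)[, present], pred[, present], ignore_attr = TRUE)
  # absent MAF is NA, never fabricated as 0
  expect_true(is.na(populationMaf(back)[2]))
})

test_that("VCF reader maps GT codes, handles missing genotypes, and drops non-autosomes by default", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=MAF,Number=A,Type=Float,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##contig=<ID=1>", "##contig=<ID=X>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tD1\tC1",
    "1\t100\t.\tA\tG\t.\tPASS\tGENE=IRF6;CONSEQ=missense_variant;MAF=0.001\tGT\t1/1\t0/1",
    "1\t200\t.\tC\tT\t.\tPASS\tGENE=IRF6;CONSEQ=missense_variant\tGT\t./.\t0|1",
    "X\t300\t.\tG\tA\t.\tPASS\tGENE=FOXE1;CONSEQ=missense_variant;MAF=0.002\tGT\t0/0\t0/0"),
    f)
  vs <- readAnnotatedVcf(f)
  expect_equal(nrow(vs), 2L)  # chrX dropped
  expect_equal(unname(genotypes(vs)[1, ]), c(2L, 1L))     # hom-alt / het
  expect_true(is.na(genotypes(vs)[2, "D1"]))              # ./. is missing
  expect_equal(genotypes(vs)[2, "C1"], c(C1 = 1L))        # phased het
  expect_true(is.na(populationMaf(vs)[2]))
  vsAll <- readAnnotatedVcf(f, autosomesOnly = FALSE)
  expect_equal(nrow(vsAll), 3L)
})

test_that("multiallelic records are split into biallelic sites matching the brute-force recoding table", {
  # brute force over all unordered GT pairs for a 2-alt site
  samples <- sprintf("s%02d", seq_len(6 * 1))
  pairs <- list()
  for (a in 0:2) for (b in a:2) pairs[[length(pairs) + 1L]] <- c(a, b)
  geno <- vapply(pairs, identity, integer(2))
  colnames(geno) <- sprintf("s%02d", seq_along(pairs))
  site <- RawVariantSite("1", 500L, "A", c("C", "T"),
                         info = list(gene = "MSX1", maf = c(0.01, 0.002)),
                         geno = geno)
  split <- splitMultiallelic(site)
  expect_length(split, 2L)
  for (k in 1:2) {
    rec <- split[[k]]
    expect_equal(rec@alts, c("C", "T")[k])
    expect_equal(rec@info$maf, c(0.01, 0.002)[k])
    for (j in seq_along(pairs)) {
      expected <- as.integer(pairs[[j]] == k)  # focal alt -> 1, others -> ref
      expect_equal(unname(rec@geno[, j]), expected,
                   label = sprintf("alt %d pair %d/%d", k, pairs[[j]][1], pairs[[j]][2]))
    }
  }
  # dosage conservation: per-sample alt dosage summed over the split set
  totalAlt <- colSums(geno > 0)
  splitDosage <- Reduce(`+`, lapply(split, function(r) colSums(r@geno)))
  expect_equal(unname(splitDosage), unname(totalAlt))

  # biallelic identity; 3-alt cardinality; arity error
  bi <- RawVariantSite("1", 1L, "A", "G", geno = matrix(c(0L, 1L), 2, 1))
  expect_equal(splitMultiallelic(bi)[[1]]@geno, bi@geno)
  tri <- RawVariantSite("1", 1L, "A", c("C", "G", "T"),
                        geno = matrix(c(1L, 3L), 2, 1))
  expect_length(splitMultiallelic(tri), 3L)
  badArity <- RawVariantSite("1", 1L, "A", c("C", "G"),
                             info = list(maf = c(0.1, 0.2, 0.3)),
                             geno = matrix(c(0L, 1L), 2, 1))
  expect_error(splitMultiallelic(badArity), "arity")
})

test_that("multiallelic VCF records come back as normalized biallelic sites", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=MAF,Number=A,Type=Float,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##contig=<ID=2>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tD1\tC1",
    "2\t100\t.\tA\tC,T\t.\tPASS\tGENE=GLI2;CONSEQ=missense_variant;MAF=0.01,0.002\tGT\t1/2\t0/2"),
    f)
  vs <- readAnnotatedVcf(f)
  expect_equal(nrow(vs), 2L)
  expect_equal(altAllele(vs), c("C", "T"))
  expect_equal(populationMaf(vs), c(0.01, 0.002))
  # GT 1/2 -> het for each split allele; 0/2 -> ref for C, het for T
  expect_equal(unname(genotypes(vs)[, "D1"]), c(1L, 1L))
  expect_equal(unname(genotypes(vs)[, "C1"]), c(0L, 1L))
})

test_that("reader errors on absent required INFO keys and honours the skip policy for per-record gaps", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tD1",
    "1\t100\t.\tA\tG\t.\tPASS\tGENE=IRF6\tGT\t0/1"), f)
  expect_error(readAnnotatedVcf(f), "CONSEQ")

  g <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"c\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tD1",
    "1\t100\t.\tA\tG\t.\tPASS\tGENE=IRF6;CONSEQ=missense_variant\tGT\t0/1",
    "1\t200\t.\tA\tG\t.\tPASS\tGENE=IRF6\tGT\t0/1"), g)
  expect_warning(vs <- readAnnotatedVcf(g, onMissingField = "skip"), "skipping 1")
  expect_equal(nrow(vs), 1L)
  expect_error(suppressWarnings(readAnnotatedVcf(g, onMissingField = "error")),
               "missing required")
})
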