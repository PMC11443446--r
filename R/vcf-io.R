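## Default mapping from pipeline annotation roles to INFO keys.
defaultVcfFields <- function() {
  c(gene = "GENE", consequence = "CONSEQ", maf = "MAF", predictors = "PRED")
}

#' Split a multiallelic site into biallelic records
#'
#' One output record per alternate allele. Genotypes are recoded per allele:
#' the focal alternate keeps index 1, every other alternate is treated as
#' reference for that record, so total alternate dosage per sample is
#' conserved across the split set. Per-allele (`Number=A`) annotations are
#' distributed positionally; scalar annotations are copied. An annotation
#' whose length is neither 1 nor the number of alternates is an arity error.
#'
#' @param site a [RawVariantSite-class].
#' @return list of biallelic [RawVariantSite-class] objects (length = number
#'   of alternate alleles; a biallelic input returns itself in a list).
#' @export
splitMultiallelic <- function(site) {
  stopifnot(is(site, "RawVariantSite"))
  nalt <- length(site@alts)
  lapply(seq_len(nalt), function(k) {
    info <- lapply(site@info, function(v) {
      if (length(v) == 1L) return(v)
      if (length(v) == nalt) return(v[[k]])
      stop(sprintf("annotation arity mismatch at %s:%d: length %d vs %d alts",
                   site@chrom, site@pos, length(v), nalt), call. = FALSE)
    })
    g <- site@geno
    g[] <- ifelse(is.na(g), NA_integer_, ifelse(g == k, 1L, 0L))
    RawVariantSite(site@chrom, site@pos, site@ref, site@alts[k], info, g)
  })
}

## allele-index pair matrix (2 x samples) for a biallelic record -> dosage.
.pairToDosage <- function(geno) {
  d <- colSums(geno)
  d[apply(is.na(geno), 2L, any)] <- NA_integer_
  as.integer(d)
}

## "sift:D|polyphen2:T" -> named character vector of damaging/tolerated.
.parsePredictorString <- function(s) {
  if (is.na(s) || !nzchar(s) || s == ".") return(character())
  parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  nm <- vapply(kv, `[`, "", 1L)
  val <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else NA_character_, "")
  dec <- rep(NA_character_, length(val))
  dec[val %in% c("D", "damaging")] <- "damaging"
  dec[val %in% c("T", "tolerated")] <- "tolerated"
  setNames(dec, nm)
}

#' Read an annotated multi-sample VCF into a VariantSet
#'
#' Parses a VCF 4.x file through `VariantAnnotation::readVcf`, normalizes
#' multiallelic records with [splitMultiallelic()], and assembles a
#' [VariantSet-class] with genotype dosages and the annotations the cascade
#' consumes. Annotation keys are resolved through `fields`, a named map from
#' pipeline roles (`gene`, `consequence`, `maf`, `predictors`) to INFO keys;
#' the population-frequency field name is deliberately configurable because
#' studies differ in which database (global vs. ancestry-matched) they
#' filter against. A record lacking a MAF value keeps `NA` — "absent from
#' the frequency database" is distinct from a MAF of 0.
#'
#' @param path path to a plain or bgzipped VCF with a GT FORMAT field.
#' @param fields named character vector mapping roles to INFO keys; see
#'   `defaultVcfFields()` for the default
#'   (`GENE`/`CONSEQ`/`MAF`/`PRED`).
#' @param onMissingField what to do with records missing a required `gene`
#'   or `consequence` annotation: `"skip"` (default; drop the record with a
#'   warning) or `"error"`.
#' @param autosomesOnly drop records outside chromosomes 1-22 (default
#'   `TRUE`; sex-chromosome inheritance models are out of scope).
#' @param genome genome label passed to `readVcf`.
#' @return a [VariantSet-class] of biallelic records in file order.
#' @export
readAnnotatedVcf <- function(path, fields = defaultVcfFields(),
                             onMissingField = c("skip", "error"),
                             autosomesOnly = TRUE, genome = "unknown") {
  onMissingField <- match.arg(onMissingField)
  abortIf(!file.exists(path), "VCF file not found: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = genome))
  hdrInfo <- rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))
  required <- fields[c("gene", "consequence")]
  missingKeys <- setdiff(stats::na.omit(required), hdrInfo)
  abortIf(length(missingKeys) > 0,
          "required INFO key(s) absent from VCF header: ",
          paste(missingKeys, collapse = ", "))
  gt <- geno(vcf)$GT
  abortIf(is.null(gt), "VCF has no GT FORMAT field")
  inf <- info(vcf)
  chrom <- as.character(seqnames(rowRanges(vcf)))
  pos <- start(rowRanges(vcf))
  refs <- as.character(ref(vcf))
  altsList <- lapply(as.list(alt(vcf)), as.character)
  samples <- colnames(gt)

  getInfo <- function(key, i) {
    if (is.null(key) || is.na(key) || !key %in% colnames(inf)) return(NULL)
    v <- inf[[key]]
    if (is(v, "List") || is.list(v)) unlist(v[i]) %||% NA else v[i]
  }

  sites <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    if (autosomesOnly && !sub("^chr", "", chrom[i]) %in% as.character(1:22)) next
    alleles <- vapply(strsplit(gt[i, ], "[/|]"), function(p) {
      p[p == "."] <- NA_character_
      as.integer(p[1:2])
    }, integer(2))
    colnames(alleles) <- samples
    info <- list()
    for (role in names(fields)) {
      val <- getInfo(fields[[role]], i)
      if (!is.null(val)) info[[role]] <- val
    }
    sites[[i]] <- RawVariantSite(chrom[i], pos[i], refs[i], altsList[[i]],
                                 info = info, geno = alleles)
  }
  sites <- Filter(Negate(is.null), sites)
  records <- unlist(lapply(sites, splitMultiallelic), recursive = FALSE)
  if (!length(records)) {
    return(VariantSet(character(), integer(), character(), character(),
                      character(), character(), numeric(),
                      matrix(integer(), 0L, length(samples),
                             dimnames = list(NULL, samples))))
  }

  getScalar <- function(rec, role, default = NA_character_) {
    v <- rec@info[[role]]
    if (is.null(v) || !length(v) || is.na(v[1L])) default else as.character(v[1L])
  }
  gene <- vapply(records, getScalar, "", role = "gene")
  cons <- vapply(records, getScalar, "", role = "consequence")
  mafv <- vapply(records, function(r) {
    v <- r@info[["maf"]]
    if (is.null(v) || !length(v)) NA_real_ else suppressWarnings(as.numeric(v[1L]))
  }, numeric(1))
  incomplete <- is.na(gene) | is.na(cons)
  if (any(incomplete)) {
    if (onMissingField == "error")
      stop(sprintf("%d record(s) missing required gene/consequence annotation", sum(incomplete)),
           call. = FALSE)
    warning(sprintf("skipping %d record(s) missing gene/consequence annotation", sum(incomplete)),
            call. = FALSE)
    records <- records[!incomplete]
    gene <- gene[!incomplete]; cons <- cons[!incomplete]; mafv <- mafv[!incomplete]
  }
  predNames <- sort(unique(unlist(lapply(records, function(r)
    names(.parsePredictorString(getScalar(r, "predictors")))))))
  pred <- matrix(NA_character_, nrow = length(records), ncol = length(predNames),
                 dimnames = list(NULL, predNames))
  dosage <- matrix(NA_integer_, nrow = length(records), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (j in seq_along(records)) {
    dosage[j, ] <- .pairToDosage(records[[j]]@geno)
    calls <- .parsePredictorString(getScalar(records[[j]], "predictors"))
    if (length(calls)) pred[j, names(calls)] <- calls
  }
  VariantSet(chrom = vapply(records, slot, "", "chrom"),
             pos = vapply(records, slot, 1L, "pos"),
             ref = vapply(records, slot, "", "ref"),
             alt = vapply(records, function(r) r@alts, ""),
             gene = gene, consequence = cons, maf = mafv,
             dosage = dosage, predictors = pred)
}

#' Write a VariantSet as an annotated VCF 4.2 file
#'
#' Emits biallelic records with `GENE`, `CONSEQ`, `MAF` and `PRED` INFO
#' fields (field names taken from `fields`) and per-sample GT genotypes.
#' Records with an absent MAF omit the key entirely rather than writing 0.
#' The output round-trips through [readAnnotatedVcf()].
#'
#' @param vs a [VariantSet-class].
#' @param path output path (plain text).
#' @param fields role-to-INFO-key map as in [readAnnotatedVcf()].
#' @return `path`, invisibly.
#' @export
writeAnnotatedVcf <- function(vs, path, fields = defaultVcfFields()) {
  samples <- sampleIds(vs)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", fields[["gene"]]),
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Sequence Ontology consequence\">", fields[["consequence"]]),
           sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Population minor allele frequency\">", fields[["maf"]]),
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"In-silico predictor calls name:D|name:T\">", fields[["predictors"]]),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           vapply(unique(as.character(seqnames(vs))),
                  function(ch) sprintf("##contig=<ID=%s>", ch), ""),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  d <- genotypes(vs)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(vs))
  gtStr[is.na(d)] <- "./."
  pred <- predictorCalls(vs)
  body <- vapply(seq_len(nrow(vs)), function(i) {
    info <- c(sprintf("%s=%s", fields[["gene"]], geneSymbol(vs)[i]),
              sprintf("%s=%s", fields[["consequence"]], consequence(vs)[i]))
    if (!is.na(populationMaf(vs)[i]))
      info <- c(info, sprintf("%s=%.6g", fields[["maf"]], populationMaf(vs)[i]))
    if (ncol(pred)) {
      calls <- pred[i, ]
      calls <- calls[!is.na(calls)]
      if (length(calls))
        info <- c(info, sprintf("%s=%s", fields[["predictors"]],
                                paste(sprintf("%s:%s", names(calls),
                                              c(damaging = "D", tolerated = "T")[calls]),
                                      collapse = "|")))
    }
    paste(c(as.character(seqnames(vs))[i], start(vs)[i], ".", refAllele(vs)[i],
            altAllele(vs)[i], ".", "PASS", paste(info, collapse = ";"), "GT",
            gtStr[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
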