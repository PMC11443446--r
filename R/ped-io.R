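#' Read a PLINK-style 6-column PED file
#'
#' Whitespace-delimited, one individual per line:
#' family id, individual id, father id, mother id, sex, affection.
#' `"0"` in a parent column marks a founder/unknown parent. Sex is coded
#' 1 = male, 2 = female, other = unknown; affection 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown. Lines starting with `#` are ignored.
#'
#' @param path path to the PED file.
#' @return a data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affection` (decoded labels), one row
#'   per data line, possibly spanning several families.
#' @seealso [writePed()], [validatePedigree()]
#' @export
readPed <- function(path) {
  abortIf(!file.exists(path), "PED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(family_id = character(), individual_id = character(),
                      father_id = character(), mother_id = character(),
                      sex = character(), affection = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- lineno[which(nf < 6L)[1L]]
    stop(sprintf("malformed PED line %d: expected >= 6 whitespace-delimited columns", bad),
         call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  df <- data.frame(family_id = m[, 1], individual_id = m[, 2],
                   father_id = m[, 3], mother_id = m[, 4],
                   sex = c("1" = "male", "2" = "female")[m[, 5]],
                   affection = c("2" = "affected", "1" = "unaffected")[m[, 6]],
                   stringsAsFactors = FALSE)
  df$sex[is.na(df$sex)] <- "unknown"
  df$affection[is.na(df$affection)] <- "unknown"
  for (fam in unique(df$family_id)) {
    sub <- df[df$family_id == fam, ]
    dup <- sub$individual_id[duplicated(sub$individual_id)]
    abortIf(length(dup) > 0, sprintf("duplicate individual id(s) in family %s: %s",
                                     fam, paste(unique(dup), collapse = ", ")))
    for (col in c("father_id", "mother_id")) {
      ref <- sub[[col]]
      bad <- ref != "0" & !(ref %in% sub$individual_id)
      abortIf(any(bad), sprintf("family %s: %s '%s' not present in family",
                                fam, sub("_id$", "", col), ref[bad][1L]))
    }
  }
  df
}

#' Write a PLINK-style 6-column PED file
#'
#' Inverse of [readPed()]: unknown sex is written as 0, unknown affection as
#' 0, so `readPed(writePed(x))` is field-identical for conformant inputs.
#'
#' @param rows data.frame as returned by [readPed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePed <- function(rows, path) {
  sexCode <- c(male = "1", female = "2", unknown = "0")[rows$sex]
  affCode <- c(affected = "2", unaffected = "1", unknown = "0")[rows$affection]
  out <- paste(rows$family_id, rows$individual_id, rows$father_id,
               rows$mother_id, sexCode, affCode, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Pedigree members as PED rows
#'
#' @param ped a [Pedigree-class].
#' @return data.frame in [readPed()] layout.
#' @export
pedigreeToRows <- function(ped) {
  m <- pedMembers(ped)
  data.frame(family_id = familyId(ped), individual_id = m$id,
             father_id = m$father, mother_id = m$mother,
             sex = m$sex, affection = m$affection, stringsAsFactors = FALSE)
}
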