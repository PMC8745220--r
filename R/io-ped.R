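#' Read a 6-column PED pedigree file
#'
#' Standard PLINK-style pedigree: `family_id individual_id father_id
#' mother_id sex affection`, whitespace-delimited, no header. Parent id `0`
#' marks a founder and is stored as `NA`. Sex codes 1 (male), 2 (female),
#' anything else unknown. Affection codes: 2 affected, 1 unaffected,
#' 0 or -9 unknown.
#'
#' @param path Path to the PED file.
#' @return A data.frame of class `pedigree` with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`) and `affection`
#'   (`"affected"`/`"unaffected"`/`"unknown"`).
#' @export
read_ped <- function(path) {
  df <- read.table(path, header = FALSE, colClasses = "character",
                   comment.char = "#")
  if (ncol(df) != 6L) {
    vf_abort(sprintf("PED file must have 6 columns, found %d", ncol(df)),
             "varfunnel_parse_error")
  }
  names(df) <- c("family_id", "individual_id", "father_id", "mother_id",
                 "sex_code", "aff_code")
  pedigree(df$family_id, df$individual_id,
           father_id = ifelse(df$father_id == "0", NA, df$father_id),
           mother_id = ifelse(df$mother_id == "0", NA, df$mother_id),
           sex = c("1" = "male", "2" = "female")[df$sex_code],
           affection = c("2" = "affected", "1" = "unaffected",
                         "0" = "unknown", "-9" = "unknown")[df$aff_code])
}

#' Construct and validate a pedigree
#'
#' @param family_id,individual_id Character vectors, one entry per member.
#' @param father_id,mother_id Parent ids or `NA` for founders.
#' @param sex `"male"`, `"female"` or `"unknown"`/`NA`.
#' @param affection `"affected"`, `"unaffected"` or `"unknown"`/`NA`.
#' @return A data.frame of class `pedigree`.
#' @export
pedigree <- function(family_id, individual_id, father_id = NA,
                     mother_id = NA, sex = "unknown",
                     affection = "unknown") {
  n <- length(individual_id)
  df <- data.frame(
    family_id = as.character(family_id),
    individual_id = as.character(individual_id),
    father_id = as.character(rep_len(father_id, n)),
    mother_id = as.character(rep_len(mother_id, n)),
    sex = ifelse(is.na(s <- rep_len(sex, n)), "unknown", s),
    affection = ifelse(is.na(a <- rep_len(affection, n)), "unknown", a),
    stringsAsFactors = FALSE
  )
  for (fam in unique(df$family_id)) {
    sub <- df[df$family_id == fam, ]
    if (anyDuplicated(sub$individual_id)) {
      vf_abort(sprintf("duplicate individual id in family %s", fam),
               "varfunnel_validation_error")
    }
    parents <- c(sub$father_id, sub$mother_id)
    unknown <- setdiff(parents[!is.na(parents)], sub$individual_id)
    if (length(unknown)) {
      vf_abort(sprintf("family %s refers to unknown parent(s): %s",
                       fam, paste(unknown, collapse = ", ")),
               "varfunnel_validation_error")
    }
  }
  if (!all(df$sex %in% c("male", "female", "unknown"))) {
    vf_abort("sex must be male/female/unknown", "varfunnel_validation_error")
  }
  if (!all(df$affection %in% c("affected", "unaffected", "unknown"))) {
    vf_abort("affection must be affected/unaffected/unknown",
             "varfunnel_validation_error")
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Write a pedigree back to 6-column PED
#'
#' @param ped A `pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    c(male = "1", female = "2", unknown = "0")[ped$sex],
    c(affected = "2", unaffected = "1", unknown = "0")[ped$affection]
  )
  write.table(out, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Is each pedigree member a founder (no parents in the family)?
#' @param ped A `pedigree`.
#' @return Logical vector.
#' @export
is_founder <- function(ped) is.na(ped$father_id) & is.na(ped$mother_id)
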