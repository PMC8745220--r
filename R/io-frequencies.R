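#' Construct and validate a population allele-frequency table
#'
#' One row per (variant, population): the allele count and allele number of
#' the designated tested allele, with `freq = allele_count / allele_number`.
#'
#' @param df A data.frame with columns `variant`, `population`,
#'   `allele_count`, `allele_number` (and optionally a pre-computed `freq`,
#'   which is recomputed from the counts; a discrepancy beyond 1e-6 warns).
#' @return The validated data.frame, class `pop_freq`, with `freq` filled in.
#' @export
pop_freq <- function(df) {
  need <- c("variant", "population", "allele_count", "allele_number")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    vf_abort(sprintf("frequency table is missing columns: %s",
                     paste(miss, collapse = ", ")),
             "varfunnel_validation_error")
  }
  df$allele_count <- as.numeric(df$allele_count)
  df$allele_number <- as.numeric(df$allele_number)
  if (anyNA(df$allele_count) || anyNA(df$allele_number)) {
    vf_abort("allele_count/allele_number must be numeric",
             "varfunnel_parse_error")
  }
  if (any(df$allele_number < 1)) {
    vf_abort("allele_number must be a positive integer",
             "varfunnel_validation_error")
  }
  if (any(df$allele_count < 0 | df$allele_count > df$allele_number)) {
    i <- which(df$allele_count < 0 | df$allele_count > df$allele_number)[1L]
    vf_abort(sprintf("allele_count out of [0, allele_number] at row %d", i),
             "varfunnel_validation_error")
  }
  recomputed <- df$allele_count / df$allele_number
  if (!is.null(df$freq)) {
    given <- as.numeric(df$freq)
    bad <- which(!is.na(given) & abs(given - recomputed) > 1e-6)
    if (length(bad)) {
      warning(sprintf(
        "pop_freq: %d stated freq value(s) disagree with counts by > 1e-6 (first at row %d); counts win",
        length(bad), bad[1L]), call. = FALSE)
    }
  }
  df$freq <- recomputed
  if (anyDuplicated(df[, c("variant", "population")])) {
    vf_abort("duplicate (variant, population) rows",
             "varfunnel_validation_error")
  }
  df <- as.data.frame(df[, c("variant", "population", "allele_count",
                             "allele_number", "freq")],
                      stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("pop_freq", "data.frame")
  df
}

#' Read a population allele-frequency TSV
#'
#' Accepts either `allele_count` + `allele_number` columns or `freq` +
#' `allele_number` (the count is then reconstructed as
#' `round(freq * allele_number)` with a logged rounding residual).
#' A `freq`-only file without `allele_number` is rejected: the downstream
#' z-test needs sample sizes.
#'
#' @param path Path to the TSV file.
#' @return A `pop_freq` data.frame.
#' @export
read_frequencies <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  if (is.null(df$allele_number)) {
    vf_abort("frequency table must carry allele_number (freq alone is not enough)",
             "varfunnel_validation_error")
  }
  if (is.null(df$allele_count)) {
    if (is.null(df$freq)) {
      vf_abort("frequency table needs allele_count or freq",
               "varfunnel_validation_error")
    }
    df$allele_count <- round(df$freq * df$allele_number)
    resid <- max(abs(df$freq * df$allele_number - df$allele_count))
    vf_log("read_frequencies: reconstructed counts from freq (max rounding residual %.4g alleles)",
           resid)
  }
  pop_freq(df)
}

#' Write a population allele-frequency table to TSV
#' @param pf A `pop_freq` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(pf, path) {
  stopifnot(inherits(pf, "pop_freq"))
  write.table(pf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up frequencies of one variant across populations
#' @param pf A `pop_freq` table.
#' @param variant Variant key.
#' @param populations Optional character vector restricting populations.
#' @return The matching rows of `pf`.
#' @export
freq_lookup <- function(pf, variant, populations = NULL) {
  rows <- pf[pf$variant == variant, , drop = FALSE]
  if (!is.null(populations)) {
    rows <- rows[rows$population %in% populations, , drop = FALSE]
  }
  rows
}
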