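#' Read a GWAS-catalog export
#'
#' Parses a tab-separated catalog export with columns `snp_id`, `trait`,
#' `assoc_p` and `mapped_genes`. Multiple mapped symbols per SNP are split on
#' commas, semicolons, and the spaced `" - "` separator the catalog uses for
#' intergenic SNPs (a bare hyphen is *not* a separator, so symbols such as
#' HLA-DRB1 survive). Records whose mapped-gene field is empty after parsing
#' are dropped with a logged count.
#'
#' @param path Path to the TSV export.
#' @return A data.frame with columns `snp_id`, `trait`, `assoc_p` and a
#'   list-column `mapped_genes` of character vectors.
#' @export
read_gwas_catalog <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   check.names = FALSE)
  need <- c("snp_id", "trait", "assoc_p", "mapped_genes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    vf_abort(sprintf("GWAS catalog is missing columns: %s",
                     paste(miss, collapse = ", ")), "varfunnel_parse_error")
  }
  p <- suppressWarnings(as.numeric(df$assoc_p))
  if (anyNA(p)) {
    i <- which(is.na(p))[1L]
    vf_abort(sprintf("non-numeric assoc_p '%s' at row %d", df$assoc_p[i], i),
             "varfunnel_parse_error")
  }
  if (any(p <= 0 | p > 1)) {
    i <- which(p <= 0 | p > 1)[1L]
    vf_abort(sprintf("assoc_p out of (0, 1] at row %d: %g", i, p[i]),
             "varfunnel_validation_error")
  }
  genes <- lapply(strsplit(df$mapped_genes, "\\s*[,;]\\s*|\\s+-\\s+"),
                  function(g) unique(trimws(g[nzchar(trimws(g))])))
  keep <- lengths(genes) > 0L
  if (any(!keep)) {
    vf_log("read_gwas_catalog: dropped %d record(s) with no mapped gene",
           sum(!keep))
  }
  out <- data.frame(snp_id = df$snp_id[keep], trait = df$trait[keep],
                    assoc_p = p[keep], stringsAsFactors = FALSE)
  out$mapped_genes <- genes[keep]
  out
}
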