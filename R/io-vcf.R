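#' Construct and validate a variant table
#'
#' Holds biallelic variants with per-sample diploid alt-allele counts.
#' Positions are 1-based (VCF convention).
#'
#' @param variants A data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `snp_id`.
#' @param geno Integer matrix, variants x samples, entries in
#'   \{0, 1, 2, `NA`\} (count of the alt allele; `NA` = missing call).
#' @return An object of class `variant_table`: list with `variants` (gains a
#'   `key` column in chrom:pos:ref:alt form) and `geno`.
#' @export
variant_table <- function(variants, geno) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    vf_abort(sprintf("variant table is missing columns: %s",
                     paste(miss, collapse = ", ")),
             "varfunnel_validation_error")
  }
  if (is.null(variants$snp_id)) variants$snp_id <- NA_character_
  if (any(grepl(",", variants$alt, fixed = TRUE))) {
    vf_abort("multiallelic record in variant_table; split first",
             "varfunnel_validation_error")
  }
  if (any(variants$pos < 1L | variants$pos != round(variants$pos))) {
    vf_abort("positions must be positive 1-based integers",
             "varfunnel_validation_error")
  }
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants)) {
    vf_abort("genotype matrix rows must match variant rows",
             "varfunnel_validation_error")
  }
  if (is.null(colnames(geno))) {
    vf_abort("genotype matrix must have sample column names",
             "varfunnel_validation_error")
  }
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) {
    vf_abort("genotypes must be alt-allele counts in {0,1,2} or NA",
             "varfunnel_validation_error")
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  rownames(variants) <- NULL
  rownames(geno) <- variants$key
  structure(list(variants = variants, geno = geno), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d samples\n",
              nrow(x$variants), ncol(x$geno)))
  invisible(x)
}

#' Number of variants in a variant table
#' @param vt A `variant_table`.
#' @return Integer count.
#' @export
n_variants <- function(vt) nrow(vt$variants)

#' Subset a variant table by variant index or key
#' @param vt A `variant_table`.
#' @param i Integer/logical index or character vector of variant keys.
#' @return A `variant_table` with the selected rows, in the given order.
#' @export
vt_subset <- function(vt, i) {
  if (is.character(i)) i <- match(i, vt$variants$key)
  variant_table(vt$variants[i, c("chrom", "pos", "ref", "alt", "snp_id"),
                            drop = FALSE],
                vt$geno[i, , drop = FALSE])
}

# Parse one column of GT strings ("0/1", "1|1", "./.", "./1") into alt
# counts relative to alt-allele index `k`. Any missing allele token makes
# the whole call missing (half-calls are conservatively dropped).
parse_gt <- function(gt, k) {
  gt[is.na(gt)] <- "."
  vapply(strsplit(sub(":.*$", "", gt), "[/|]"), function(al) {
    if (length(al) == 0L || anyNA(al) || any(al == "." | al == "")) {
      return(NA_integer_)
    }
    sum(al == as.character(k))
  }, integer(1L))
}

#' Read a multi-sample VCF into a variant table
#'
#' Requires VCF v4.2 text with a GT field. Multiallelic sites are split into
#' one biallelic record per alt allele (with a logged count); `./.` and
#' half-calls map to missing; phased separators are accepted.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param ped Optional `pedigree`; if given, the VCF sample set must equal
#'   the pedigree roster and columns are reordered to match it.
#' @return A `variant_table`.
#' @export
read_vcf <- function(path, ped = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0L || !"FORMAT" %in% colnames(v@gt)) {
    vf_abort("VCF has no genotype (FORMAT) section", "varfunnel_parse_error")
  }
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))) {
    vf_abort("VCF records are missing the GT format field",
             "varfunnel_parse_error")
  }
  if (!all(sub(":.*$", "", v@gt[, "FORMAT"]) == "GT")) {
    vf_abort("GT must be the first FORMAT field", "varfunnel_parse_error")
  }
  samples <- setdiff(colnames(v@gt), "FORMAT")
  if (!is.null(ped)) {
    extra <- setdiff(samples, ped$individual_id)
    missing <- setdiff(ped$individual_id, samples)
    if (length(extra) || length(missing)) {
      vf_abort(sprintf(
        "VCF/PED sample mismatch; not in PED: [%s]; not in VCF: [%s]",
        paste(extra, collapse = ", "), paste(missing, collapse = ", ")),
        "varfunnel_validation_error")
    }
    samples <- ped$individual_id
  }
  gt <- v@gt[, samples, drop = FALSE]
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_multi <- sum(lengths(alts) > 1L)
  if (n_multi > 0L) {
    vf_log("read_vcf: split %d multiallelic site(s) into biallelic records",
           n_multi)
  }
  rows <- vector("list", sum(lengths(alts)))
  genos <- vector("list", sum(lengths(alts)))
  r <- 0L
  for (i in seq_along(alts)) {
    for (k in seq_along(alts[[i]])) {
      r <- r + 1L
      rows[[r]] <- data.frame(
        chrom = unname(fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = unname(fix[i, "REF"]),
        alt = alts[[i]][k],
        snp_id = ifelse(fix[i, "ID"] %in% c(".", NA), NA_character_,
                        unname(fix[i, "ID"])),
        stringsAsFactors = FALSE
      )
      genos[[r]] <- parse_gt(gt[i, ], k)
    }
  }
  geno <- do.call(rbind, genos)
  colnames(geno) <- samples
  variant_table(do.call(rbind, rows), geno)
}

#' Write a variant table as a plain-text VCF v4.2
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=varfunnel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vt$geno)), collapse = "\t")
  ), con)
  gt_string <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  for (i in seq_len(nrow(vt$variants))) {
    g <- vt$geno[i, ]
    calls <- ifelse(is.na(g), "./.", gt_string[as.character(g)])
    writeLines(paste(c(
      vt$variants$chrom[i], vt$variants$pos[i],
      ifelse(is.na(vt$variants$snp_id[i]), ".", vt$variants$snp_id[i]),
      vt$variants$ref[i], vt$variants$alt[i], ".", "PASS", ".", "GT",
      calls), collapse = "\t"), con)
  }
  invisible(path)
}
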