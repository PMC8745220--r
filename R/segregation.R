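#' Define a vertical-transmission (co-segregation) rule
#'
#' Dominant carrier logic: under the defaults a variant passes in a family
#' when every affected member carries at least one alt allele and at least
#' one affected parent-affected child pair both carry (the "vertical"
#' requirement). Unaffected carriers are tolerated by default (incomplete
#' penetrance); exclusion is a flag. A missing genotype in an affected
#' member fails the variant in that family under the default policy
#' (`"fail_variant_in_family"`); missing genotypes in unaffected members are
#' always treated as non-carrier.
#'
#' @param model Genetic model; only `"dominant"` is implemented.
#' @param require_all_affected_carriers Every affected member must carry.
#' @param require_parent_child_transmission Require an affected parent ->
#'   affected child carrier pair.
#' @param exclude_if_unaffected_carrier Fail the family if any unaffected
#'   member carries.
#' @param min_families_passing Overall pass needs at least this many
#'   families passing (default 1).
#' @param missing_policy `"fail_variant_in_family"` (default) or
#'   `"treat_as_noncarrier"`, applied to missing genotypes of affected
#'   members.
#' @return An object of class `transmission_rule`.
#' @export
transmission_rule <- function(model = "dominant",
                              require_all_affected_carriers = TRUE,
                              require_parent_child_transmission = TRUE,
                              exclude_if_unaffected_carrier = FALSE,
                              min_families_passing = 1L,
                              missing_policy = c("fail_variant_in_family",
                                                 "treat_as_noncarrier")) {
  if (!identical(model, "dominant")) {
    vf_abort("only the dominant model is implemented",
             "varfunnel_validation_error")
  }
  missing_policy <- match.arg(missing_policy)
  if (min_families_passing < 1L) {
    vf_abort("min_families_passing must be >= 1",
             "varfunnel_validation_error")
  }
  structure(list(
    model = model,
    require_all_affected_carriers = isTRUE(require_all_affected_carriers),
    require_parent_child_transmission = isTRUE(require_parent_child_transmission),
    exclude_if_unaffected_carrier = isTRUE(exclude_if_unaffected_carrier),
    min_families_passing = as.integer(min_families_passing),
    missing_policy = missing_policy
  ), class = "transmission_rule")
}

#' Evaluate one variant in one family
#'
#' @param genotypes Named vector of alt-allele counts (0/1/2/`NA`) covering
#'   every member of `family`.
#' @param family A `pedigree` restricted to one family.
#' @param rule A [transmission_rule()].
#' @return A list with `verdict` (`"pass"`, `"fail"`, `"not_evaluable"`) and
#'   `reason` (code string).
#' @export
evaluate_family <- function(genotypes, family, rule = transmission_rule()) {
  stopifnot(inherits(family, "pedigree"), inherits(rule, "transmission_rule"))
  ids <- family$individual_id
  if (!all(ids %in% names(genotypes))) {
    vf_abort(sprintf("missing genotype entries for: %s",
                     paste(setdiff(ids, names(genotypes)), collapse = ", ")),
             "varfunnel_validation_error")
  }
  g <- genotypes[ids]
  affected <- family$affection == "affected"
  unaffected <- family$affection == "unaffected"
  if (!any(affected)) {
    return(list(verdict = "not_evaluable", reason = "no_affected_members"))
  }
  if (rule$missing_policy == "fail_variant_in_family" &&
      anyNA(g[affected])) {
    return(list(verdict = "fail", reason = "missing_affected_genotype"))
  }
  # under treat_as_noncarrier, and always for unaffected members, a missing
  # call counts as zero alt alleles
  carrier <- !is.na(g) & g >= 1L
  if (rule$require_all_affected_carriers && !all(carrier[affected])) {
    return(list(verdict = "fail", reason = "affected_noncarrier"))
  }
  if (rule$require_parent_child_transmission) {
    pair_found <- FALSE
    for (i in seq_along(ids)) {
      if (!affected[i] || !carrier[i]) next
      for (par in c(family$father_id[i], family$mother_id[i])) {
        if (is.na(par)) next
        j <- match(par, ids)
        if (affected[j] && carrier[j]) pair_found <- TRUE
      }
    }
    if (!pair_found) {
      return(list(verdict = "fail", reason = "no_affected_transmission_pair"))
    }
  }
  if (rule$exclude_if_unaffected_carrier && any(carrier[unaffected])) {
    return(list(verdict = "fail", reason = "unaffected_carrier"))
  }
  list(verdict = "pass", reason = "segregates")
}

#' Filter a variant table by vertical transmission across families
#'
#' Evaluates every variant in every family and retains exactly the variants
#' whose count of passing families reaches `rule$min_families_passing`.
#'
#' @param vt A `variant_table` whose samples cover the pedigree roster.
#' @param ped A `pedigree` (possibly several families).
#' @param rule A [transmission_rule()].
#' @return A list with `variants` (the filtered `variant_table`) and
#'   `report`, a data.frame with one row per (variant, family): columns
#'   `key`, `family_id`, `verdict`, `reason`, plus the per-variant
#'   `overall` flag.
#' @export
transmission_filter <- function(vt, ped, rule = transmission_rule()) {
  stopifnot(inherits(vt, "variant_table"), inherits(ped, "pedigree"))
  missing_samples <- setdiff(ped$individual_id, colnames(vt$geno))
  if (length(missing_samples)) {
    vf_abort(sprintf("variant table lacks pedigree samples: %s",
                     paste(missing_samples, collapse = ", ")),
             "varfunnel_validation_error")
  }
  fams <- split(seq_len(nrow(ped)), ped$family_id)
  nv <- n_variants(vt)
  rows <- vector("list", length(fams) * max(nv, 1L))
  overall <- logical(nv)
  r <- 0L
  for (i in seq_len(nv)) {
    g <- vt$geno[i, ]
    n_pass <- 0L
    for (fam in names(fams)) {
      sub <- ped[fams[[fam]], , drop = FALSE]
      class(sub) <- c("pedigree", "data.frame")
      res <- evaluate_family(g, sub, rule)
      n_pass <- n_pass + (res$verdict == "pass")
      r <- r + 1L
      rows[[r]] <- data.frame(key = vt$variants$key[i], family_id = fam,
                              verdict = res$verdict, reason = res$reason,
                              stringsAsFactors = FALSE)
    }
    overall[i] <- n_pass >= rule$min_families_passing
  }
  report <- if (r > 0L) do.call(rbind, rows[seq_len(r)]) else
    data.frame(key = character(), family_id = character(),
               verdict = character(), reason = character())
  report$overall <- overall[match(report$key, vt$variants$key)]
  list(variants = vt_subset(vt, which(overall)), report = report)
}

#' Run the gene-set stage of the prioritization funnel
#'
#' Transmission-filtered variants are restricted to genes in the
#' intersection of the GWAS-derived and differential-expression gene sets;
#' stage counts are reported at every step.
#'
#' @param vt A `variant_table`.
#' @param ped A `pedigree`.
#' @param rule A [transmission_rule()].
#' @param gwas_set,de_set `gene_set` objects.
#' @param gene_map Named character vector mapping variant keys to gene
#'   symbols (see [map_variants_to_genes()]); retained variants without a
#'   mapping are dropped with a logged count.
#' @return A list with `variants` (the restricted `variant_table`), `genes`
#'   (symbols hit), `gene_map` (the mapping restricted to the output),
#'   `report` (segregation report) and `counts` (named stage counts:
#'   `input`, `post_transmission`, `unmapped_dropped`,
#'   `post_geneset_variants`, `post_geneset_genes`).
#' @export
variant_funnel <- function(vt, ped, rule, gwas_set, de_set, gene_map) {
  seg <- transmission_filter(vt, ped, rule)
  candidates <- geneset_intersect(gwas_set, de_set)
  keys <- seg$variants$variants$key
  mapped <- keys[keys %in% names(gene_map)]
  n_unmapped <- length(keys) - length(mapped)
  if (n_unmapped > 0L) {
    vf_log("variant_funnel: dropped %d transmission-passing variant(s) with no gene mapping",
           n_unmapped)
  }
  hit <- mapped[gene_map[mapped] %in% candidates$symbols]
  genes <- unique(unname(gene_map[hit]))
  list(
    variants = vt_subset(seg$variants, hit),
    genes = genes,
    gene_map = gene_map[hit],
    report = seg$report,
    counts = c(input = n_variants(vt),
               post_transmission = length(keys),
               unmapped_dropped = n_unmapped,
               post_geneset_variants = length(hit),
               post_geneset_genes = length(genes))
  )
}

#' Map variants to the gene whose transcript span contains them
#'
#' @param vt A `variant_table`.
#' @param models A `transcript_set`.
#' @return Named character vector: variant key -> gene symbol; variants not
#'   contained in any transcript span are absent.
#' @export
map_variants_to_genes <- function(vt, models) {
  out <- character(0)
  spans <- lapply(models, gene_span)
  chroms <- vapply(models, `[[`, "", "chrom")
  for (i in seq_len(n_variants(vt))) {
    pos <- vt$variants$pos[i]
    hit <- which(chroms == vt$variants$chrom[i] &
                   vapply(spans, function(s) pos >= s[1L] && pos <= s[2L],
                          logical(1L)))
    if (length(hit)) {
      out[vt$variants$key[i]] <- models[[hit[1L]]]$gene_id
    }
  }
  out
}

#' Write a segregation report to TSV
#' @param report Report data.frame from [transmission_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segregation_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
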