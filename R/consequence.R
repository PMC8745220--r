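# Three-letter amino-acid codes; the stop codon prints as "Ter" in
# protein notation but is "*" internally.
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter")

# Codon-change string in the published style: unchanged bases lowercase,
# the substituted base uppercase in both codons, e.g. "Ggt/Agt".
format_codon_change <- function(ref_codon, alt_codon, offset) {
  fmt <- function(codon) {
    b <- strsplit(tolower(codon), "")[[1L]]
    b[offset] <- toupper(b[offset])
    paste(b, collapse = "")
  }
  paste(fmt(ref_codon), fmt(alt_codon), sep = "/")
}

#' Classify a single-nucleotide variant against a transcript model
#'
#' Maps the genomic position into transcript space (reverse-complementing
#' alleles on minus-strand genes) and calls the consequence class:
#' \itemize{
#'   \item inside the CDS: the affected codon is compared before/after the
#'     substitution -- same amino acid = `synonymous`, stop codon gained =
#'     `stop_gained`, otherwise `missense`;
#'   \item exonic upstream of the CDS: `utr5`, with `c.-N` notation counting
#'     backwards from the first CDS base;
#'   \item exonic downstream: `utr3` (`c.*N`);
#'   \item inside the gene span but in no exon: `intronic`;
#'   \item outside the span: `intergenic`.
#' }
#'
#' @param model A [transcript_model()].
#' @param pos Genomic 1-based position.
#' @param ref,alt Single-base genomic alleles; `ref` must agree with the
#'   model sequence at the mapped position (else a reference-mismatch
#'   error).
#' @return One-row data.frame with columns `class`, `hgvs_c`, `hgvs_p`
#'   (empty unless coding) and `codon_change` (empty unless coding).
#' @export
classify_variant <- function(model, pos, ref, alt) {
  stopifnot(inherits(model, "transcript_model"))
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    vf_abort("only single-nucleotide substitutions are classified",
             "varfunnel_validation_error")
  }
  res <- function(class, hgvs_c = "", hgvs_p = "", codon_change = "") {
    data.frame(class = class, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
               codon_change = codon_change, stringsAsFactors = FALSE)
  }
  span <- gene_span(model)
  if (pos < span[1L] || pos > span[2L]) return(res("intergenic"))
  tpos <- map_genome_to_transcript(model, pos)
  if (is.na(tpos)) return(res("intronic"))
  tref <- substr(model$sequence, tpos, tpos)
  talt <- if (model$strand == "+") alt else complement_base(alt)
  expected_ref <- if (model$strand == "+") tref else complement_base(tref)
  if (expected_ref != ref) {
    vf_abort(sprintf(
      "reference mismatch at %s:%d (%s): VCF says %s, transcript %s implies %s",
      model$chrom, pos, model$gene_id, ref, model$gene_id, expected_ref),
      "varfunnel_reference_mismatch")
  }
  ct <- cds_bounds_tx(model)
  if (tpos < ct[1L]) {
    return(res("utr5", sprintf("c.-%d%s > %s", ct[1L] - tpos, tref, talt)))
  }
  if (tpos > ct[2L]) {
    return(res("utr3", sprintf("c.*%d%s > %s", tpos - ct[2L], tref, talt)))
  }
  cpos <- tpos - ct[1L] + 1L
  codon_num <- (cpos - 1L) %/% 3L + 1L
  offset <- (cpos - 1L) %% 3L + 1L
  cds <- cds_sequence(model)
  ref_codon <- substr(cds, (codon_num - 1L) * 3L + 1L, codon_num * 3L)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- talt
  ref_aa <- translate_dna(ref_codon)
  alt_aa <- translate_dna(alt_codon)
  klass <- if (ref_aa == alt_aa) "synonymous"
           else if (alt_aa == "*") "stop_gained"
           else "missense"
  res(klass,
      hgvs_c = sprintf("c.%d%s > %s", cpos, tref, talt),
      hgvs_p = sprintf("p.%s%d%s", AA3[[ref_aa]], codon_num, AA3[[alt_aa]]),
      codon_change = format_codon_change(ref_codon, alt_codon, offset))
}

#' Annotate every variant in a table with its molecular consequence
#'
#' @param vt A `variant_table` of single-nucleotide substitutions.
#' @param models A `transcript_set`.
#' @param gene_map Named character vector, variant key -> gene symbol
#'   (default: computed via [map_variants_to_genes()]). Variants with no
#'   mapped gene are classed `intergenic`.
#' @return Data.frame with one row per variant: `key`, `gene`, `class`,
#'   `hgvs_c`, `hgvs_p`, `codon_change`, `nonintronic` (class is neither
#'   intronic nor intergenic).
#' @export
annotate_consequences <- function(vt, models, gene_map = NULL) {
  if (is.null(gene_map)) gene_map <- map_variants_to_genes(vt, models)
  if (n_variants(vt) == 0L) {
    return(data.frame(key = character(), gene = character(),
                      class = character(), hgvs_c = character(),
                      hgvs_p = character(), codon_change = character(),
                      nonintronic = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(n_variants(vt)), function(i) {
    key <- vt$variants$key[i]
    gene <- if (key %in% names(gene_map)) gene_map[[key]] else NA_character_
    if (is.na(gene) || !gene %in% names(models)) {
      cons <- data.frame(class = "intergenic", hgvs_c = "", hgvs_p = "",
                         codon_change = "", stringsAsFactors = FALSE)
    } else {
      cons <- classify_variant(models[[gene]], vt$variants$pos[i],
                               vt$variants$ref[i], vt$variants$alt[i])
    }
    cbind(data.frame(key = key, gene = gene, stringsAsFactors = FALSE), cons)
  })
  out <- do.call(rbind, rows)
  out$nonintronic <- !out$class %in% c("intronic", "intergenic")
  out
}

#' Low-frequency variant filter
#'
#' Retains the variants whose *maximum* allele frequency across the source
#' populations is at or below `maf_max` (boundary inclusive). Variants with
#' no frequency record in any source population are dropped with a warning
#' and counted in the `dropped_no_freq` attribute.
#'
#' @param variants Data.frame with a `key` column (e.g. from
#'   [annotate_consequences()]).
#' @param pf A `pop_freq` table.
#' @param maf_max Inclusive frequency ceiling (default 0.04).
#' @param source_populations Populations whose frequencies are thresholded
#'   (typically the control populations).
#' @return The filtered data.frame, `dropped_no_freq` attribute attached.
#' @export
low_frequency_filter <- function(variants, pf, maf_max = 0.04,
                                 source_populations) {
  stopifnot(inherits(pf, "pop_freq"))
  sub <- pf[pf$population %in% source_populations, , drop = FALSE]
  maxf <- tapply(sub$freq, sub$variant, max)
  known <- variants$key %in% names(maxf)
  if (any(!known)) {
    warning(sprintf(
      "low_frequency_filter: dropped %d variant(s) with no frequency in any source population",
      sum(!known)), call. = FALSE)
  }
  out <- variants[known & maxf[variants$key] <= maf_max, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_no_freq") <- sum(!known)
  out
}

#' Split annotated variants into intronic and nonintronic partitions
#'
#' The partition follows the nonintronic predicate (exonic or UTR
#' consequence); intergenic variants, should any survive to this stage,
#' fall on the intronic (non-exonic) side so the two parts always sum to
#' the input.
#'
#' @param annotated Data.frame from [annotate_consequences()].
#' @return List with data.frames `intronic` and `nonintronic`.
#' @export
split_intronic <- function(annotated) {
  non <- annotated$nonintronic
  list(intronic = annotated[!non, , drop = FALSE],
       nonintronic = annotated[non, , drop = FALSE])
}
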