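# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately takes a different computational route from the
# implementation it checks.

options(varfunnel.quiet = TRUE)

# --- segregation: brute-force re-statement of the transmission rule -------

# Evaluates the rule text directly on explicit member vectors, with none of
# the implementation's shortcuts or early returns.
oracle_family_verdict <- function(geno, fam, rule) {
  ids <- fam$individual_id
  g <- geno[ids]
  aff <- ids[fam$affection == "affected"]
  unaff <- ids[fam$affection == "unaffected"]
  if (length(aff) == 0L) return("not_evaluable")
  if (rule$missing_policy == "fail_variant_in_family" &&
      any(is.na(g[aff]))) {
    return("fail")
  }
  carries <- function(id) !is.na(g[id]) && g[id] >= 1L
  conds <- c(
    if (rule$require_all_affected_carriers) {
      all(vapply(aff, carries, TRUE))
    } else TRUE,
    if (rule$require_parent_child_transmission) {
      pairs <- expand.grid(child = ids, stringsAsFactors = FALSE)
      found <- FALSE
      for (child in ids) {
        row <- fam[fam$individual_id == child, ]
        for (parent in c(row$father_id, row$mother_id)) {
          if (is.na(parent)) next
          child_aff <- child %in% aff
          parent_aff <- parent %in% aff
          if (child_aff && parent_aff && carries(child) && carries(parent)) {
            found <- TRUE
          }
        }
      }
      found
    } else TRUE,
    if (rule$exclude_if_unaffected_carrier) {
      !any(vapply(unaff, carries, TRUE))
    } else TRUE
  )
  if (all(conds)) "pass" else "fail"
}

# --- consequence: full-CDS translation oracle ------------------------------

# Classifies by materializing the per-base genomic coordinate vector of the
# transcript and translating the complete CDS before and after the edit.
oracle_classify <- function(model, pos, ref, alt) {
  tx_pos <- unlist(lapply(seq_len(nrow(model$exons)), function(j)
    seq(model$exons[j, "start"], model$exons[j, "end"])))
  if (model$strand == "-") tx_pos <- rev(tx_pos)
  span <- range(tx_pos)
  if (pos < span[1L] || pos > span[2L]) return("intergenic")
  tpos <- match(pos, tx_pos)
  if (is.na(tpos)) return("intronic")
  in_cds <- tx_pos >= model$cds_start & tx_pos <= model$cds_end
  ct1 <- min(which(in_cds))
  ct2 <- max(which(in_cds))
  if (tpos < ct1) return("utr5")
  if (tpos > ct2) return("utr3")
  seq_chars <- strsplit(model$sequence, "")[[1L]]
  talt <- if (model$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  ref_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(seq_chars[ct1:ct2], collapse = "")),
    no.init.codon = TRUE))
  seq_chars[tpos] <- talt
  alt_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(seq_chars[ct1:ct2], collapse = "")),
    no.init.codon = TRUE))
  if (ref_prot == alt_prot) return("synonymous")
  diff_at <- which(strsplit(ref_prot, "")[[1L]] !=
                     strsplit(alt_prot, "")[[1L]])[1L]
  if (substr(alt_prot, diff_at, diff_at) == "*") "stop_gained" else "missense"
}

# --- small fixture builders ------------------------------------------------

# A four-member nuclear family: affected father, unaffected mother,
# affected child, unaffected child.
quad_family <- function() {
  pedigree(family_id = "Q",
           individual_id = c("dad", "mum", "kid1", "kid2"),
           father_id = c(NA, NA, "dad", "dad"),
           mother_id = c(NA, NA, "mum", "mum"),
           sex = c("male", "female", "male", "female"),
           affection = c("affected", "unaffected", "affected",
                         "unaffected"))
}

# A tiny variant_table over arbitrary samples.
mk_vt <- function(geno, chrom = "chr1") {
  n <- nrow(geno)
  variant_table(
    data.frame(chrom = chrom, pos = seq_len(n) * 100L,
               ref = "A", alt = "G",
               snp_id = sprintf("rs%d", seq_len(n)),
               stringsAsFactors = FALSE),
    geno)
}

# A small expression fixture with exactly the given per-group means/sds
# is hard to force; instead, samples per gene around the given means.
mk_expr <- function(n_genes = 50L, n_per_group = 4L, seed = 99L) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 2L * n_per_group, mean = 8, sd = 0.5),
                 n_genes, 2L * n_per_group,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("S%02d", seq_len(2L * n_per_group))))
  expression_matrix(vals, rep(c("case", "control"), each = n_per_group))
}
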