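# Find a genomic single-nucleotide substitution on `model` with the
# requested consequence class. Coding classes are searched by codon
# enumeration; positional classes by sampling the matching region.
plant_variant_on_model <- function(model, klass, max_tries = 500L) {
  L <- nchar(model$sequence)
  ct <- cds_bounds_tx(model)
  bases <- c("A", "C", "G", "T")
  to_genomic <- function(tpos, talt) {
    tref <- substr(model$sequence, tpos, tpos)
    if (model$strand == "+") {
      list(pos = map_transcript_to_genome(model, tpos), ref = tref,
           alt = talt)
    } else {
      list(pos = map_transcript_to_genome(model, tpos),
           ref = complement_base(tref), alt = complement_base(talt))
    }
  }
  if (klass == "intronic") {
    if (nrow(model$exons) < 2L) {
      vf_abort("cannot plant an intronic variant on a single-exon model",
               "varfunnel_simulation_error")
    }
    j <- sample.int(nrow(model$exons) - 1L, 1L)
    pos <- sample(seq(model$exons[j, "end"] + 1L,
                      model$exons[j + 1L, "start"] - 1L), 1L)
    ref <- sample(bases, 1L)
    return(list(pos = pos, ref = ref,
                alt = sample(setdiff(bases, ref), 1L), class = klass))
  }
  if (klass %in% c("utr5", "utr3")) {
    rng <- if (klass == "utr5") seq_len(ct[1L] - 1L) else
      seq(ct[2L] + 1L, L)
    if (!length(rng)) {
      vf_abort(sprintf("model %s has no %s region", model$gene_id, klass),
               "varfunnel_simulation_error")
    }
    tpos <- if (length(rng) == 1L) rng else sample(rng, 1L)
    tref <- substr(model$sequence, tpos, tpos)
    out <- to_genomic(tpos, sample(setdiff(bases, tref), 1L))
    out$class <- klass
    return(out)
  }
  # coding classes: synonymous / missense / stop_gained
  cds <- cds_sequence(model)
  n_codons <- nchar(cds) %/% 3L
  for (try in seq_len(max_tries)) {
    codon_num <- sample(2:(n_codons - 1L), 1L)  # spare start and stop codons
    offset <- sample.int(3L, 1L)
    ref_codon <- substr(cds, (codon_num - 1L) * 3L + 1L, codon_num * 3L)
    ref_base <- substr(ref_codon, offset, offset)
    for (b in sample(setdiff(bases, ref_base))) {
      alt_codon <- ref_codon
      substr(alt_codon, offset, offset) <- b
      ref_aa <- translate_dna(ref_codon)
      alt_aa <- translate_dna(alt_codon)
      hit <- switch(klass,
                    synonymous = ref_aa == alt_aa,
                    missense = ref_aa != alt_aa && alt_aa != "*",
                    stop_gained = alt_aa == "*")
      if (hit) {
        tpos <- ct[1L] + (codon_num - 1L) * 3L + offset - 1L
        out <- to_genomic(tpos, b)
        out$class <- klass
        return(out)
      }
    }
  }
  vf_abort(sprintf("could not plant a %s variant on %s after %d tries",
                   klass, model$gene_id, max_tries),
           "varfunnel_simulation_error")
}

# The default planted variant plan mirroring the study funnel: 127
# co-segregating variants across 15 disease-GWAS overlap genes (100
# intronic, 20 common nonintronic, 7 low-frequency nonintronic) and 57
# variants across the functional-partner genes (39 intronic, 18
# nonintronic).
default_variant_plan <- function(cfg) {
  uni <- sim_gene_universe(cfg)
  coding_ov <- setdiff(uni$overlap, uni$overlap_ncrna)
  ms_genes <- coding_ov[seq_len(cfg$msgwas_genes_with_variants)]
  lf_classes <- rep(c("missense", "synonymous", "stop_gained", "utr5"),
                    length.out = cfg$msgwas_lowfreq_nonintronic)
  common_classes <- rep(c("synonymous", "missense", "utr3", "utr5"),
                        length.out = cfg$msgwas_common_nonintronic)
  partner_non_classes <- rep(c("synonymous", "missense"),
                             length.out = cfg$partner_nonintronic)
  plan <- rbind(
    data.frame(arm = "ms_gwas", stratum = "lowfreq_nonintronic",
               class = lf_classes, stringsAsFactors = FALSE),
    data.frame(arm = "ms_gwas", stratum = "common_nonintronic",
               class = common_classes, stringsAsFactors = FALSE),
    data.frame(arm = "ms_gwas", stratum = "intronic",
               class = rep("intronic", cfg$msgwas_intronic),
               stringsAsFactors = FALSE),
    data.frame(arm = "functional_partner", stratum = "nonintronic",
               class = partner_non_classes, stringsAsFactors = FALSE),
    data.frame(arm = "functional_partner", stratum = "intronic",
               class = rep("intronic", cfg$partner_intronic),
               stringsAsFactors = FALSE)
  )
  is_ms <- plan$arm == "ms_gwas"
  plan$gene[is_ms] <- rep_len(ms_genes, sum(is_ms))
  plan$gene[!is_ms] <- rep_len(uni$partner, sum(!is_ms))
  plan
}

#' Simulate a complete study: every pipeline input with planted signal
#'
#' Generates, under one master seed, a mutually consistent set of inputs:
#' expression matrix (planted DE genes include the catalog-overlap and
#' functional-partner genes), GWAS-catalog export, transcript models for
#' the variant-bearing genes, a family VCF + PED in which all planned
#' variants co-segregate and background variants provably do not, and
#' population allele-frequency tables with planted case-control
#' differences. When `dir` is given all inputs are written in the formats
#' the readers consume, plus truth tables under `dir/truth/`.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`expression`,
#'   `de_truth`, `catalog`, `catalog_truth`, `models`, `plan`, `vt`, `ped`,
#'   `seg_truth`, `pf`, `freq_truth`, `partner_genes`) and, when `dir` is
#'   given, `paths` (named file paths).
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL) {
  uni <- sim_gene_universe(cfg)
  exprs <- simulate_expression(cfg)
  cat_sim <- simulate_gwas_catalog(cfg)
  models <- simulate_transcripts(cfg)

  # realize the planted variant plan on the transcript models
  set.seed(stream_seed(cfg$seed, 6L))
  plan <- default_variant_plan(cfg)
  seen <- character(0)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    model <- models[[plan$gene[i]]]
    repeat {
      pv <- plant_variant_on_model(model, plan$class[i])
      key <- variant_key(model$chrom, pv$pos, pv$ref, pv$alt)
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    rows[[i]] <- data.frame(chrom = model$chrom, pos = pv$pos, ref = pv$ref,
                            alt = pv$alt, snp_id = sprintf("simrs%04d", i),
                            stringsAsFactors = FALSE)
  }
  planned_variants <- do.call(rbind, rows)
  plan$key <- variant_key(planned_variants$chrom, planned_variants$pos,
                          planned_variants$ref, planned_variants$alt)

  # genotypes: planned variants co-segregate (round-robin family),
  # background variants are rejection-sampled to fail everywhere
  ped <- default_pedigree()
  fams <- unique(ped$family_id)
  rule <- transmission_rule()
  n_pl <- nrow(plan)
  n_bg <- cfg$n_background_variants
  bases <- c("A", "C", "G", "T")
  bg_ref <- sample(bases, n_bg, replace = TRUE)
  bg <- data.frame(
    chrom = "chr20",
    pos = sort(sample.int(60000000L, n_bg) + 10000000L),
    ref = bg_ref,
    alt = vapply(bg_ref, function(b) sample(setdiff(bases, b), 1L), ""),
    snp_id = sprintf("simbg%05d", seq_len(n_bg)),
    stringsAsFactors = FALSE
  )
  variants <- rbind(planned_variants, bg)
  geno <- matrix(NA_integer_, nrow(variants), nrow(ped),
                 dimnames = list(NULL, ped$individual_id))
  fam_of <- rep(NA_character_, nrow(variants))
  for (i in seq_len(n_pl)) {
    fam_of[i] <- fams[(i - 1L) %% length(fams) + 1L]
    geno[i, ] <- planted_genotypes(ped, fam_of[i])
  }
  for (i in seq_len(n_bg)) {
    geno[n_pl + i, ] <- background_genotypes(ped, rule)
  }
  ord <- order(variants$chrom, variants$pos)
  vt <- variant_table(variants[ord, ], geno[ord, , drop = FALSE])
  seg_truth <- data.frame(key = vt$variants$key,
                          planted = (seq_len(nrow(variants)) <= n_pl)[ord],
                          family = fam_of[ord], stringsAsFactors = FALSE)

  # population frequencies for all planned variants
  lowfreq <- plan$stratum == "lowfreq_nonintronic"
  p_ctl <- numeric(n_pl)
  p_ctl[lowfreq] <- runif(sum(lowfreq), cfg$lowfreq_range[1L],
                          cfg$lowfreq_range[2L])
  p_ctl[!lowfreq] <- runif(sum(!lowfreq), cfg$common_range[1L],
                           cfg$common_range[2L])
  p_aff <- p_ctl
  assoc_lf <- which(lowfreq)[seq_len(cfg$n_assoc_msgwas)]
  p_aff[assoc_lf] <- p_ctl[assoc_lf] + cfg$assoc_lowfreq_delta
  partner_non <- which(plan$arm == "functional_partner" &
                         plan$stratum == "nonintronic")
  assoc_fp <- partner_non[seq_len(cfg$n_assoc_partner)]
  p_aff[assoc_fp] <- pmin(p_ctl[assoc_fp] + cfg$assoc_common_delta, 0.95)
  freq_spec <- data.frame(variant = plan$key, p_control = p_ctl,
                          p_affected = p_aff, stringsAsFactors = FALSE)
  freqs <- simulate_frequencies(cfg, spec = freq_spec)

  out <- list(expression = exprs$matrix, de_truth = exprs$truth,
              catalog = cat_sim$records, catalog_truth = cat_sim$truth,
              models = models, plan = plan, vt = vt, ped = ped,
              seg_truth = seg_truth, pf = freqs$pf,
              freq_truth = freqs$truth, partner_genes = uni$partner,
              overlap_ncrna = uni$overlap_ncrna)

  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(
      expression = file.path(dir, "expression.tsv"),
      gwas_catalog = file.path(dir, "gwas_catalog.tsv"),
      vcf = file.path(dir, "families.vcf"),
      ped = file.path(dir, "families.ped"),
      transcripts_tsv = file.path(dir, "transcripts.tsv"),
      transcripts_fasta = file.path(dir, "transcripts.fa"),
      frequencies = file.path(dir, "frequencies.tsv"),
      partner_genes = file.path(dir, "partner_genes.txt")
    )
    write_expression(exprs$matrix, paths$expression)
    write.table(cat_sim$records, paths$gwas_catalog, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_vcf(vt, paths$vcf)
    write_ped(ped, paths$ped)
    write_transcripts(models, paths$transcripts_tsv,
                      paths$transcripts_fasta)
    write_frequencies(freqs$pf, paths$frequencies)
    writeLines(uni$partner, paths$partner_genes)
    write.table(exprs$truth, file.path(dir, "truth", "de_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(cat_sim$truth, file.path(dir, "truth", "catalog_genes.txt"))
    write.table(seg_truth, file.path(dir, "truth", "segregation_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(plan, file.path(dir, "truth", "variant_plan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(freqs$truth, file.path(dir, "truth", "freq_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  invisible(out)
}
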