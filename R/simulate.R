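#' Simulation configuration for the synthetic study
#'
#' One integer seed drives independent sub-streams per generator
#' (expression, catalog, families, frequencies, transcripts) so each stage
#' can be regenerated independently and byte-identically. Defaults emulate
#' the study design the pipeline targets: a ~20,000-gene vascular-wall
#' microarray with 923 differentially expressed genes, a disease GWAS
#' catalog of 805 qualifying SNPs in 543 genes overlapping the
#' differentially expressed set in 18 genes (2 of them ncRNA), three
#' nuclear families totalling 11 members with 7 affected, 127 co-segregating
#' variants in 15 of the overlap genes (7 of them low-frequency and
#' nonintronic), and 57 variants (39 intronic / 18 nonintronic) in 7
#' functional-partner genes, typed against an affected cohort of 1098
#' exomes (2196 alleles) and two control populations.
#'
#' @param seed Integer master seed.
#' @param n_genes,n_case,n_control Expression-matrix dimensions.
#' @param n_de Number of planted differentially expressed genes.
#' @param de_effect Range of planted absolute log2 shifts.
#' @param d0,s0_sq Scaled inverse-chi-square variance prior for per-gene
#'   residual variances (log2-units squared).
#' @param catalog_snps,catalog_genes Qualifying catalog SNPs and the number
#'   of distinct genes they map to.
#' @param catalog_decoys Non-qualifying catalog records (wrong trait or
#'   p above threshold).
#' @param overlap_genes,overlap_ncrna Size of the planted overlap between
#'   the catalog gene set and the DE set, and how many of those are ncRNA.
#' @param n_partner_genes Functional-partner genes (DE but not in catalog).
#' @param msgwas_genes_with_variants How many overlap genes carry
#'   co-segregating variants.
#' @param msgwas_intronic,msgwas_common_nonintronic,msgwas_lowfreq_nonintronic
#'   Planted variant counts in overlap genes by stratum.
#' @param partner_intronic,partner_nonintronic Planted variant counts in
#'   partner genes.
#' @param n_assoc_msgwas,n_assoc_partner How many of the low-frequency
#'   (resp. partner nonintronic) variants carry a true allele-frequency
#'   difference between affected and control populations.
#' @param n_background_variants Non-segregating background variants.
#' @param n_planted_segregating Planted segregating variants for the
#'   standalone [simulate_families()] generator.
#' @param populations Named list of allele numbers (2N) per population;
#'   the first entry is the affected cohort.
#' @param lowfreq_range,common_range Control-population frequency ranges
#'   for low-frequency and common planted variants.
#' @param assoc_lowfreq_delta,assoc_common_delta Planted absolute
#'   frequency differences (affected minus control) for associated
#'   variants.
#' @param exon_range,codon_range,utr_range Transcript-geometry ranges for
#'   random models (exon count; codons including the stop; UTR lengths).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20000L, n_case = 10L, n_control = 10L,
                       n_de = 923L, de_effect = c(1.5, 3),
                       d0 = 4, s0_sq = 0.05,
                       catalog_snps = 805L, catalog_genes = 543L,
                       catalog_decoys = 200L,
                       overlap_genes = 18L, overlap_ncrna = 2L,
                       n_partner_genes = 7L,
                       msgwas_genes_with_variants = 15L,
                       msgwas_intronic = 100L,
                       msgwas_common_nonintronic = 20L,
                       msgwas_lowfreq_nonintronic = 7L,
                       partner_intronic = 39L,
                       partner_nonintronic = 18L,
                       n_assoc_msgwas = 3L,
                       n_assoc_partner = 5L,
                       n_background_variants = 800L,
                       n_planted_segregating = 50L,
                       populations = list(affected = 2196L,
                                          control_tsi = 214L,
                                          control_nfe = 68032L),
                       lowfreq_range = c(0.0005, 0.012),
                       common_range = c(0.12, 0.42),
                       assoc_lowfreq_delta = 0.02,
                       assoc_common_delta = 0.15,
                       exon_range = c(2L, 6L),
                       codon_range = c(120L, 400L),
                       utr_range = c(40L, 200L)) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  stopifnot(cfg$overlap_genes >= cfg$overlap_ncrna,
            cfg$n_de == 0L ||
              cfg$n_de >= cfg$overlap_genes + cfg$n_partner_genes,
            cfg$catalog_genes >= cfg$overlap_genes,
            cfg$msgwas_genes_with_variants <= cfg$overlap_genes,
            cfg$n_assoc_msgwas <= cfg$msgwas_lowfreq_nonintronic,
            cfg$n_assoc_partner <= cfg$partner_nonintronic)
  structure(cfg, class = "sim_config")
}

# Independent, reproducible sub-stream seed (kept well below 2^31).
stream_seed <- function(seed, k) (abs(as.integer(seed)) %% 2000000L) * 1000L + k

# --- gene universe ---------------------------------------------------------

# Gene symbols by role: OVxx = catalog/DE overlap, FPx = functional partner,
# DExxx = other planted DE, CATxxx = other catalog genes, Gxxxxx = filler.
sim_gene_universe <- function(cfg) {
  ov <- sprintf("OV%02d", seq_len(cfg$overlap_genes))
  fp <- sprintf("FP%d", seq_len(cfg$n_partner_genes))
  de_extra <- sprintf("DE%04d",
                      seq_len(max(0L, cfg$n_de - length(ov) - length(fp))))
  cat_extra <- sprintf("CAT%03d",
                       seq_len(cfg$catalog_genes - length(ov)))
  n_fill <- cfg$n_genes - length(ov) - length(fp) - length(de_extra) -
    length(cat_extra)
  if (n_fill < 0L) {
    vf_abort("n_genes too small for the configured gene roles",
             "varfunnel_validation_error")
  }
  list(overlap = ov,
       overlap_ncrna = utils::tail(ov, cfg$overlap_ncrna),
       partner = fp,
       de = utils::head(c(ov, fp, de_extra), cfg$n_de),
       catalog = c(ov, cat_extra),
       all = c(ov, fp, de_extra, cat_extra, sprintf("G%05d", seq_len(n_fill))))
}

# --- expression ------------------------------------------------------------

#' Simulate a log2 expression matrix with planted differential expression
#'
#' Per-gene residual variances are drawn from the scaled inverse-chi-square
#' prior (`d0`, `s0_sq`); baselines are uniform on log2 (2, 14); planted DE
#' genes get an additive log2 shift of random sign and magnitude in
#' `de_effect` in the case group.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene`, `effect`; effect 0 for null genes).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  set.seed(stream_seed(cfg$seed, 1L))
  uni <- sim_gene_universe(cfg)
  genes <- uni$all
  n <- length(genes)
  sigma2 <- cfg$d0 * cfg$s0_sq / rchisq(n, df = cfg$d0)
  mu <- runif(n, 2, 14)
  effect <- numeric(n)
  idx_de <- match(uni$de, genes)
  # planted shifts are calibrated to be detectable at the study's sample
  # size: at least de_effect, and for noisy genes large enough that the
  # observed |log2 difference| clears 1 with ~4.5 sd to spare
  se_delta <- sqrt(sigma2 * (1 / cfg$n_case + 1 / cfg$n_control))
  magnitude <- pmax(runif(length(idx_de), cfg$de_effect[1L],
                          cfg$de_effect[2L]),
                    1 + 4.5 * se_delta[idx_de])
  effect[idx_de] <- sample(c(-1, 1), length(idx_de),
                           replace = TRUE) * magnitude
  n_s <- cfg$n_case + cfg$n_control
  group <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))
  vals <- matrix(rnorm(n * n_s, mean = mu, sd = sqrt(sigma2)), n, n_s)
  vals[, group == "case"] <- vals[, group == "case"] + effect
  dimnames(vals) <- list(genes, sprintf("S%02d", seq_len(n_s)))
  list(matrix = expression_matrix(vals, group),
       truth = data.frame(gene = genes, effect = effect,
                          stringsAsFactors = FALSE))
}

# --- GWAS catalog ----------------------------------------------------------

#' Simulate a GWAS-catalog export with a planted qualifying set
#'
#' `catalog_snps` SNPs under the target trait at p <= 5e-6 mapped onto
#' `catalog_genes` distinct genes (every gene receives at least one SNP; a
#' few records carry two comma-separated symbols to exercise the parser),
#' plus `catalog_decoys` non-qualifying records (above-threshold p or a
#' different trait).
#'
#' @param cfg A [sim_config()].
#' @param trait Trait string for qualifying records.
#' @return List with `records` (data.frame in [read_gwas_catalog()] layout,
#'   `mapped_genes` as a delimited string column ready for writing) and
#'   `truth` (qualifying gene symbols).
#' @export
simulate_gwas_catalog <- function(cfg = sim_config(),
                                  trait = "multiple sclerosis") {
  set.seed(stream_seed(cfg$seed, 2L))
  uni <- sim_gene_universe(cfg)
  genes <- uni$catalog
  gene_of_snp <- c(genes,
                   sample(genes, cfg$catalog_snps - length(genes),
                          replace = TRUE))
  gene_of_snp <- sample(gene_of_snp)
  mapped <- gene_of_snp
  # a handful of multi-gene records; the extra symbol repeats a qualifying
  # gene so the planted set size is unchanged
  multi <- sample(seq_along(mapped), min(20L, length(mapped) %/% 10L))
  mapped[multi] <- paste(mapped[multi], sample(genes, length(multi),
                                               replace = TRUE), sep = ", ")
  qual <- data.frame(
    snp_id = sprintf("rs%07d", sample.int(9999999L, cfg$catalog_snps)),
    trait = trait,
    assoc_p = 10^-runif(cfg$catalog_snps, 5.31, 30),
    mapped_genes = mapped,
    stringsAsFactors = FALSE
  )
  n_dec <- cfg$catalog_decoys
  half <- n_dec %/% 2L
  decoys <- data.frame(
    snp_id = sprintf("rs%07d", sample.int(9999999L, n_dec) + 10000000L),
    trait = c(rep(trait, half), rep("optic neuritis", n_dec - half)),
    assoc_p = c(10^-runif(half, 0.5, 5), 10^-runif(n_dec - half, 2, 12)),
    mapped_genes = sample(c(genes, sprintf("DEC%03d", 1:50)), n_dec,
                          replace = TRUE),
    stringsAsFactors = FALSE
  )
  records <- rbind(qual, decoys)[sample.int(cfg$catalog_snps + n_dec), ]
  rownames(records) <- NULL
  list(records = records, truth = genes)
}

# --- pedigree and genotypes ------------------------------------------------

#' The default three-family pedigree (11 members, 7 affected)
#'
#' Three independent nuclear families with an affected transmitting parent
#' in each: F1 (affected father, two affected children, unaffected mother),
#' F2 (affected mother, one affected and one unaffected child), F3
#' (affected father, one affected child).
#'
#' @return A `pedigree`.
#' @export
default_pedigree <- function() {
  pedigree(
    family_id = c("F1", "F1", "F1", "F1",
                  "F2", "F2", "F2", "F2",
                  "F3", "F3", "F3"),
    individual_id = c("F1_I1", "F1_I2", "F1_II1", "F1_II2",
                      "F2_I1", "F2_I2", "F2_II1", "F2_II2",
                      "F3_I1", "F3_I2", "F3_II1"),
    father_id = c(NA, NA, "F1_I1", "F1_I1",
                  NA, NA, "F2_I1", "F2_I1",
                  NA, NA, "F3_I1"),
    mother_id = c(NA, NA, "F1_I2", "F1_I2",
                  NA, NA, "F2_I2", "F2_I2",
                  NA, NA, "F3_I2"),
    sex = c("male", "female", "male", "female",
            "male", "female", "male", "female",
            "male", "female", "male"),
    affection = c("affected", "unaffected", "affected", "affected",
                  "unaffected", "affected", "affected", "unaffected",
                  "affected", "unaffected", "affected")
  )
}

# Genotypes that segregate by construction in family `fam`: every affected
# member of that family is heterozygous (the alt transmitted from the
# affected parent), everyone else is homozygous reference.
planted_genotypes <- function(ped, fam) {
  g <- setNames(integer(nrow(ped)), ped$individual_id)
  sel <- ped$family_id == fam & ped$affection == "affected"
  g[sel] <- 1L
  g
}

# Founder Hardy-Weinberg genotypes with Mendelian transmission to
# offspring, rejection-sampled until the variant fails the transmission
# rule in every family.
background_genotypes <- function(ped, rule, max_tries = 1000L) {
  fams <- split(seq_len(nrow(ped)), ped$family_id)
  for (try in seq_len(max_tries)) {
    p <- runif(1L, 0.05, 0.4)
    g <- setNames(rep(NA_integer_, nrow(ped)), ped$individual_id)
    founder <- is_founder(ped)
    g[founder] <- rbinom(sum(founder), 2L, p)
    # children in these templates have founder parents, one generation deep
    for (i in which(!founder)) {
      gf <- g[ped$father_id[i]]
      gm <- g[ped$mother_id[i]]
      g[i] <- rbinom(1L, 1L, gf / 2) + rbinom(1L, 1L, gm / 2)
    }
    any_pass <- FALSE
    for (fam in names(fams)) {
      sub <- ped[fams[[fam]], , drop = FALSE]
      class(sub) <- c("pedigree", "data.frame")
      if (evaluate_family(g, sub, rule)$verdict == "pass") any_pass <- TRUE
    }
    if (!any_pass) return(g)
  }
  vf_abort(sprintf(
    "background genotype rejection sampling failed after %d attempts",
    max_tries), "varfunnel_simulation_error")
}

#' Simulate a family VCF + PED with planted co-segregating variants
#'
#' Planted variants obey the default transmission rule by construction
#' (all affected members of one family carry, with a transmitting affected
#' parent-child pair); background variants are drawn from founder
#' Hardy-Weinberg genotypes with Mendelian transmission and rejection
#' sampled (capped at 1000 attempts) to violate the rule in every family.
#'
#' @param cfg A [sim_config()]; `n_planted_segregating` and
#'   `n_background_variants` set the counts.
#' @param rule The [transmission_rule()] the background must violate.
#' @return List with `vt` (a `variant_table`), `ped` (a `pedigree`) and
#'   `truth` (data.frame `key`, `planted`, `family`).
#' @export
simulate_families <- function(cfg = sim_config(),
                              rule = transmission_rule()) {
  set.seed(stream_seed(cfg$seed, 3L))
  ped <- default_pedigree()
  fams <- unique(ped$family_id)
  n_pl <- cfg$n_planted_segregating
  n_bg <- cfg$n_background_variants
  n <- n_pl + n_bg
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  variants <- data.frame(
    chrom = "chr20",
    pos = sort(sample.int(60000000L, n) + 10000000L),
    ref = ref, alt = alt,
    snp_id = sprintf("sim%06d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  planted_idx <- sort(sample.int(n, n_pl))
  fam_of <- character(n)
  geno <- matrix(NA_integer_, n, nrow(ped),
                 dimnames = list(NULL, ped$individual_id))
  for (i in seq_len(n)) {
    if (i %in% planted_idx) {
      fam <- fams[(match(i, planted_idx) - 1L) %% length(fams) + 1L]
      fam_of[i] <- fam
      geno[i, ] <- planted_genotypes(ped, fam)
    } else {
      geno[i, ] <- background_genotypes(ped, rule)
    }
  }
  vt <- variant_table(variants, geno)
  list(vt = vt, ped = ped,
       truth = data.frame(key = vt$variants$key,
                          planted = seq_len(n) %in% planted_idx,
                          family = ifelse(nzchar(fam_of), fam_of, NA),
                          stringsAsFactors = FALSE))
}

# --- population frequencies ------------------------------------------------

#' Simulate population allele-frequency tables with planted differences
#'
#' Allele counts are Binomial(allele_number, p) draws; planted associated
#' variants use a different true p in the affected cohort than in the
#' controls, all others share one p across populations.
#'
#' @param cfg A [sim_config()].
#' @param spec Data.frame with columns `variant`, `p_control` and
#'   `p_affected` (equal for non-associated variants). `NULL` builds a
#'   generic spec: 25 variants of which `n_assoc_partner + n_assoc_msgwas`
#'   carry a planted difference.
#' @return List with `pf` (a `pop_freq` table over the configured
#'   populations) and `truth` (the spec with an `assoc` flag).
#' @export
simulate_frequencies <- function(cfg = sim_config(), spec = NULL) {
  set.seed(stream_seed(cfg$seed, 4L))
  if (is.null(spec)) {
    n <- 25L
    n_assoc <- cfg$n_assoc_msgwas + cfg$n_assoc_partner
    p_ctl <- runif(n, cfg$common_range[1L], cfg$common_range[2L])
    p_aff <- p_ctl
    p_aff[seq_len(n_assoc)] <- pmin(p_ctl[seq_len(n_assoc)] +
                                      cfg$assoc_common_delta, 0.95)
    spec <- data.frame(variant = sprintf("chr9:%d:A:G", seq_len(n) * 1000L),
                       p_control = p_ctl, p_affected = p_aff,
                       stringsAsFactors = FALSE)
  }
  pops <- cfg$populations
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    for (pop in names(pops)) {
      p <- if (pop == names(pops)[1L]) spec$p_affected[i] else
        spec$p_control[i]
      an <- pops[[pop]]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = spec$variant[i], population = pop,
        allele_count = rbinom(1L, an, p), allele_number = an,
        stringsAsFactors = FALSE)
    }
  }
  spec$assoc <- spec$p_affected != spec$p_control
  list(pf = pop_freq(do.call(rbind, rows)), truth = spec)
}

# --- transcripts -----------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")),
                              1L, paste, collapse = ""), STOP_CODONS)

# Random valid CDS: start codon, sense codons, one terminal stop.
random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# Assemble a transcript_model from a spliced sequence laid out over
# `n_exons` exons starting at genomic `offset`; utr5/cds lengths are in
# transcript orientation.
build_transcript <- function(gene_id, chrom, strand, spliced, utr5_len,
                             cds_len, n_exons, offset) {
  L <- nchar(spliced)
  n_exons <- min(n_exons, L)
  cuts <- sort(sample(seq_len(L - 1L), n_exons - 1L))
  widths <- diff(c(0L, cuts, L))
  introns <- if (n_exons > 1L) sample(50:500, n_exons - 1L, replace = TRUE)
             else integer(0)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  cursor <- offset
  for (j in seq_len(n_exons)) {
    starts[j] <- cursor
    ends[j] <- cursor + widths[j] - 1L
    cursor <- ends[j] + 1L + if (j < n_exons) introns[j] else 0L
  }
  exons <- cbind(start = starts, end = ends)
  # genomic position of a transcript coordinate, given the exon layout
  g_of_t <- function(tpos) {
    idx <- if (strand == "+") tpos else L - tpos + 1L
    before <- c(0L, cumsum(widths))
    j <- findInterval(idx - 1L, before)
    starts[j] + (idx - before[j] - 1L)
  }
  ct1 <- utr5_len + 1L
  ct2 <- utr5_len + cds_len
  transcript_model(gene_id, chrom, strand, exons,
                   cds_start = min(g_of_t(ct1), g_of_t(ct2)),
                   cds_end = max(g_of_t(ct1), g_of_t(ct2)),
                   sequence = spliced)
}

#' Simulate random multi-exon transcript models
#'
#' Generates one valid transcript model per requested gene: random strand,
#' exon count, UTR lengths and CDS (start codon, sense codons, one terminal
#' stop), laid out along a chromosome with a moving cursor so gene spans
#' never overlap. The two hand-crafted consequence fixtures
#' ([transcript_fixture_gly482()], [transcript_fixture_utr5()]) are
#' appended when `with_fixtures` is set.
#'
#' @param cfg A [sim_config()].
#' @param gene_ids Character vector of gene symbols needing models; default
#'   is the overlap + partner genes of the configured universe.
#' @param with_fixtures Append the two hand-crafted fixtures (default
#'   FALSE).
#' @return A `transcript_set`.
#' @export
simulate_transcripts <- function(cfg = sim_config(), gene_ids = NULL,
                                 with_fixtures = FALSE) {
  set.seed(stream_seed(cfg$seed, 5L))
  if (is.null(gene_ids)) {
    uni <- sim_gene_universe(cfg)
    gene_ids <- c(uni$overlap, uni$partner)
  }
  chroms <- sprintf("chr%d", 1:22)
  cursor <- setNames(rep(1000000L, length(chroms)), chroms)
  models <- vector("list", length(gene_ids))
  for (i in seq_along(gene_ids)) {
    chrom <- chroms[(i - 1L) %% length(chroms) + 1L]
    strand <- sample(c("+", "-"), 1L)
    n_codons <- sample(cfg$codon_range[1L]:cfg$codon_range[2L], 1L)
    utr5_len <- sample(cfg$utr_range[1L]:cfg$utr_range[2L], 1L)
    utr3_len <- sample(cfg$utr_range[1L]:cfg$utr_range[2L], 1L)
    cds <- random_cds(n_codons)
    spliced <- paste0(
      paste(sample(c("A", "C", "G", "T"), utr5_len, replace = TRUE),
            collapse = ""),
      cds,
      paste(sample(c("A", "C", "G", "T"), utr3_len, replace = TRUE),
            collapse = ""))
    n_exons <- sample(cfg$exon_range[1L]:cfg$exon_range[2L], 1L)
    models[[i]] <- build_transcript(gene_ids[i], chrom, strand, spliced,
                                    utr5_len, 3L * n_codons, n_exons,
                                    cursor[chrom])
    cursor[chrom] <- gene_span(models[[i]])[2L] + 50000L
  }
  names(models) <- gene_ids
  if (with_fixtures) {
    models$FIX_GLY482 <- transcript_fixture_gly482()
    models$FIX_UTR5 <- transcript_fixture_utr5()
  }
  structure(models, class = "transcript_set")
}

#' Hand-crafted minus-strand fixture: Gly482Ser missense geometry
#'
#' A single-exon minus-strand transcript on chr4 whose codon 482 is GGT
#' (glycine) with its first base at genomic position 23814039, so the
#' genomic substitution C>T at that position reads G>A in transcript space
#' and yields the missense call "Ggt/Agt", p.Gly482Ser.
#'
#' @return A `transcript_model`.
#' @export
transcript_fixture_gly482 <- function() {
  n_codons <- 490L
  codons <- rep("CTG", n_codons)
  codons[1L] <- "ATG"
  codons[482L] <- "GGT"
  codons[n_codons] <- "TAA"
  spliced <- paste0(strrep("TCAG", 15L),            # 60 nt 5'-UTR
                    paste(codons, collapse = ""),   # 1470 nt CDS
                    strrep("GATC", 15L))            # 60 nt 3'-UTR
  L <- nchar(spliced)
  g_end <- 23814039L + (60L + 481L * 3L + 1L) - 1L  # variant tpos = 1504
  transcript_model("FIX_GLY482", "chr4", "-",
                   cbind(start = g_end - L + 1L, end = g_end),
                   cds_start = g_end - (60L + 1470L) + 1L,
                   cds_end = g_end - 61L + 1L,
                   sequence = spliced)
}

#' Hand-crafted minus-strand fixture: c.-54 5'-UTR geometry
#'
#' A single-exon minus-strand transcript on chr17 whose CDS begins 54
#' transcript bases downstream of genomic position 40100148; the genomic
#' substitution G>A there reads C>T in transcript space and yields the
#' 5'-UTR call "c.-54C > T".
#'
#' @return A `transcript_model`.
#' @export
transcript_fixture_utr5 <- function() {
  utr5 <- strrep("A", 73L)
  substr(utr5, 20L, 20L) <- "C"
  cds <- paste0("ATG", strrep("CTG", 8L), "TAA")   # 30 nt
  spliced <- paste0(utr5, cds, strrep("G", 40L))
  L <- nchar(spliced)
  g_end <- 40100148L + 20L - 1L                    # variant tpos = 20
  transcript_model("FIX_UTR5", "chr17", "-",
                   cbind(start = g_end - L + 1L, end = g_end),
                   cds_start = g_end - (73L + 30L) + 1L,
                   cds_end = g_end - 74L + 1L,
                   sequence = spliced)
}
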