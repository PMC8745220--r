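#' Build (and validate) a funnel configuration
#'
#' Declarative configuration of the full prioritization funnel. Defaults
#' mirror the published thresholds: catalog p <= 5e-6, fold change >= 2,
#' adjusted p <= 0.05, MAF <= 0.04, family-wise alpha 0.05.
#'
#' @param inputs Named list of input paths: `expression`, `gwas_catalog`,
#'   `vcf`, `ped`, `transcripts_tsv`, `transcripts_fasta`, `frequencies`,
#'   and optionally `partner_genes` (one symbol per line). May be left
#'   empty when `simulate = TRUE`.
#' @param trait Catalog trait to select.
#' @param gwas_p_threshold Inclusive catalog p-value threshold.
#' @param fc_min,p_max,use_adjusted Differential-expression selection rule.
#' @param shrinkage Use empirical-Bayes variance shrinkage (default TRUE);
#'   FALSE gives the ordinary pooled t-test.
#' @param rule List of [transmission_rule()] arguments.
#' @param maf_max Inclusive low-frequency ceiling.
#' @param maf_source `"controls"` (default: threshold the maximum across
#'   control populations) or `"affected"`.
#' @param affected_population Name of the affected cohort in the frequency
#'   table; all other populations are controls.
#' @param alpha,borderline_mult,nominal_level Test-family configuration.
#' @param m_convention `"variants"` (default; multiplicity = distinct
#'   variants tested) or `"variant_comparisons"`.
#' @param simulate Generate inputs with [simulate_study()] first.
#' @param sim List of [sim_config()] overrides used when simulating.
#' @param seed Integer seed (drives simulation; recorded in provenance).
#' @return A list of class `funnel_config`.
#' @export
funnel_config <- function(inputs = list(), trait = "multiple sclerosis",
                          gwas_p_threshold = 5e-6, fc_min = 2,
                          p_max = 0.05, use_adjusted = TRUE,
                          shrinkage = TRUE, rule = list(),
                          maf_max = 0.04,
                          maf_source = c("controls", "affected"),
                          affected_population = "affected",
                          alpha = 0.05, borderline_mult = 5,
                          nominal_level = 0.05,
                          m_convention = c("variants",
                                           "variant_comparisons"),
                          simulate = FALSE, sim = list(), seed = 1L) {
  cfg <- as.list(environment())
  cfg$maf_source <- match.arg(maf_source)
  cfg$m_convention <- match.arg(m_convention)
  validate_config(cfg)
  structure(cfg, class = "funnel_config")
}

#' Read a funnel configuration from a YAML file
#' @param path Path to a YAML file whose keys are [funnel_config()]
#'   arguments.
#' @return A `funnel_config`.
#' @export
read_funnel_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(funnel_config)))
  if (length(unknown)) {
    vf_abort(sprintf("unknown config field(s): %s",
                     paste(unknown, collapse = ", ")),
             "varfunnel_config_error")
  }
  do.call(funnel_config, raw)
}

# Schema checks with field-path error messages.
validate_config <- function(cfg) {
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      vf_abort(sprintf("config field '%s' must be a single number", field),
               "varfunnel_config_error")
    }
  }
  flag <- function(field) {
    if (!is.logical(cfg[[field]]) || length(cfg[[field]]) != 1L) {
      vf_abort(sprintf("config field '%s' must be TRUE/FALSE", field),
               "varfunnel_config_error")
    }
  }
  for (f in c("gwas_p_threshold", "fc_min", "p_max", "maf_max", "alpha",
              "borderline_mult", "nominal_level", "seed")) num1(f)
  for (f in c("use_adjusted", "shrinkage", "simulate")) flag(f)
  if (!is.list(cfg$inputs)) {
    vf_abort("config field 'inputs' must be a named list of paths",
             "varfunnel_config_error")
  }
  if (!is.list(cfg$rule)) {
    vf_abort("config field 'rule' must be a list of transmission_rule arguments",
             "varfunnel_config_error")
  }
  bad_rule <- setdiff(names(cfg$rule), names(formals(transmission_rule)))
  if (length(bad_rule)) {
    vf_abort(sprintf("config field 'rule.%s' is not a transmission_rule argument",
                     bad_rule[1L]), "varfunnel_config_error")
  }
  invisible(cfg)
}

# md5 of the canonical YAML rendering of the configuration.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[sort(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

# Load every configured input from disk.
load_inputs <- function(cfg) {
  need <- c("expression", "gwas_catalog", "vcf", "ped", "transcripts_tsv",
            "transcripts_fasta", "frequencies")
  miss <- setdiff(need, names(cfg$inputs))
  if (length(miss)) {
    vf_abort(sprintf("config field 'inputs' is missing: %s",
                     paste(miss, collapse = ", ")), "varfunnel_config_error")
  }
  ped <- read_ped(cfg$inputs$ped)
  list(
    expression = read_expression(cfg$inputs$expression),
    catalog = read_gwas_catalog(cfg$inputs$gwas_catalog),
    ped = ped,
    vt = read_vcf(cfg$inputs$vcf, ped = ped),
    models = read_transcripts(cfg$inputs$transcripts_tsv,
                              cfg$inputs$transcripts_fasta),
    pf = read_frequencies(cfg$inputs$frequencies),
    partner_genes = if (!is.null(cfg$inputs$partner_genes)) {
      readLines(cfg$inputs$partner_genes)
    }
  )
}

#' Run the full prioritization funnel
#'
#' Executes differential expression -> gene-set intersection -> family
#' transmission filter -> consequence annotation -> low-frequency and
#' nonintronic filters -> case-control allele-frequency tests, writes every
#' intermediate table to `outdir`, and returns the funnel report.
#'
#' @param cfg A [funnel_config()] (or path to a YAML file).
#' @param outdir Output directory (created if needed).
#' @return The funnel report: a list with `stages` (named stage counts),
#'   `tiers` (variant-level tier counts), `m`, `threshold`, `n_families`,
#'   and `provenance` (config hash, seed, input paths). Output files:
#'   `de_table.tsv`, `de_genes.txt`, `gwas_genes.txt`,
#'   `segregation_report.tsv`, `prioritized_variants.tsv`,
#'   `funnel_report.yaml`.
#' @export
run_pipeline <- function(cfg, outdir) {
  if (is.character(cfg)) cfg <- read_funnel_config(cfg)
  stopifnot(inherits(cfg, "funnel_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(cfg$simulate)) {
    sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    sim <- simulate_study(sim_cfg, file.path(outdir, "inputs"))
    cfg$inputs <- sim$paths
  }
  inp <- with_stage("input", load_inputs(cfg))

  # --- differential expression ---------------------------------------------
  de <- with_stage("de", {
    records <- moderated_t(inp$expression,
                           shrink = if (cfg$shrinkage) "fit" else NULL)
    write_de_table(records, file.path(outdir, "de_table.tsv"))
    records
  })
  de_genes <- select_de(de, cfg$fc_min, cfg$p_max, cfg$use_adjusted)
  de_set <- gene_set("de", de_genes,
                     sprintf("FC >= %g, %s p <= %g", cfg$fc_min,
                             if (cfg$use_adjusted) "adjusted" else "raw",
                             cfg$p_max))
  write_geneset(de_set, file.path(outdir, "de_genes.txt"))

  # --- GWAS gene set --------------------------------------------------------
  gwas_set <- with_stage("geneset",
    build_gwas_geneset(inp$catalog, cfg$trait, cfg$gwas_p_threshold))
  write_geneset(gwas_set, file.path(outdir, "gwas_genes.txt"))
  candidates <- geneset_intersect(gwas_set, de_set)

  # --- transmission filter --------------------------------------------------
  rule <- do.call(transmission_rule, cfg$rule)
  seg <- with_stage("segregate", transmission_filter(inp$vt, inp$ped, rule))
  write_segregation_report(seg$report,
                           file.path(outdir, "segregation_report.tsv"))
  gene_map <- map_variants_to_genes(seg$variants, inp$models)
  seg_keys <- seg$variants$variants$key
  input_gene_map <- map_variants_to_genes(inp$vt, inp$models)

  # --- gene-set restriction -------------------------------------------------
  ms_keys <- seg_keys[seg_keys %in% names(gene_map) &
                        gene_map[seg_keys] %in% candidates$symbols]
  # the functional-partner arm: genes from the supplied partner list that
  # are themselves differentially expressed
  partner_de <- intersect(inp$partner_genes %||% character(0), de_genes)
  partner_keys <- seg_keys[seg_keys %in% names(gene_map) &
                             gene_map[seg_keys] %in% partner_de]

  # --- consequence annotation + frequency filters ---------------------------
  control_pops <- setdiff(unique(inp$pf$population), cfg$affected_population)
  maf_pops <- if (cfg$maf_source == "controls") control_pops else
    cfg$affected_population
  ann <- with_stage("annotate", {
    keep <- unique(c(ms_keys, partner_keys))
    annotate_consequences(vt_subset(seg$variants, keep), inp$models,
                          gene_map)
  })
  ms_ann <- ann[ann$key %in% ms_keys, , drop = FALSE]
  ms_lowfreq <- low_frequency_filter(ms_ann, inp$pf, cfg$maf_max, maf_pops)
  ms_pri <- split_intronic(ms_lowfreq)$nonintronic
  partner_ann <- ann[ann$key %in% partner_keys, , drop = FALSE]
  partner_pri <- split_intronic(partner_ann)$nonintronic
  pri <- rbind(
    if (nrow(ms_pri)) cbind(ms_pri, origin = "ms_gwas") else NULL,
    if (nrow(partner_pri)) cbind(partner_pri, origin = "functional_partner")
    else NULL
  )

  # --- allele-frequency tests -----------------------------------------------
  comparisons <- lapply(control_pops, function(p)
    c(cfg$affected_population, p))
  tested_keys <- if (is.null(pri)) character(0) else unique(pri$key)
  m <- if (cfg$m_convention == "variants") NULL else
    length(tested_keys) * length(comparisons)
  tf_cfg <- test_family_config(alpha = cfg$alpha, m = m,
                               borderline_mult = cfg$borderline_mult,
                               nominal_level = cfg$nominal_level)
  tests <- with_stage("aftest",
    run_af_tests(tested_keys, inp$pf, comparisons, tf_cfg))

  # variant-level tier: the tier of the smallest p across comparisons
  tier_levels <- c("significant", "borderline", "nominal", "ns",
                   "not_evaluable")
  variant_tier <- vapply(tested_keys, function(k) {
    sub <- tests[tests$key == k & tests$evaluable, , drop = FALSE]
    if (!nrow(sub)) return("not_evaluable")
    sub$tier[which.min(sub$p_two_sided)]
  }, "")
  tiers <- as.list(table(factor(variant_tier, tier_levels)))

  result <- build_result_table(pri, inp$pf, tests, inp$vt)
  write.table(result, file.path(outdir, "prioritized_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    stages = list(
      input_variants = n_variants(inp$vt),
      input_genes = length(unique(unname(input_gene_map))),
      post_transmission = length(seg_keys),
      post_geneset_variants = length(ms_keys),
      post_geneset_genes = length(unique(unname(gene_map[ms_keys]))),
      post_low_frequency = nrow(ms_lowfreq),
      post_nonintronic = nrow(ms_pri),
      partner_variants = length(partner_keys),
      partner_nonintronic = nrow(partner_pri),
      tested = length(tested_keys)
    ),
    tiers = tiers,
    m = attr(tests, "m"),
    threshold = attr(tests, "threshold"),
    n_families = length(unique(inp$ped$family_id)),
    provenance = list(config_hash = config_hash(unclass(cfg)),
                      seed = cfg$seed,
                      inputs = lapply(cfg$inputs, as.character))
  )
  yaml::write_yaml(report, file.path(outdir, "funnel_report.yaml"))
  report
}

# Wrap a stage so failures abort with the stage name attached.
with_stage <- function(stage, expr) {
  tryCatch(expr, varfunnel_error = function(e) {
    vf_abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
             class(e)[1L])
  })
}

# Association-table-shaped output: one row per prioritized variant with
# per-population MAF columns and per-comparison p/tier columns.
build_result_table <- function(pri, pf, tests, vt) {
  if (is.null(pri) || nrow(pri) == 0L) {
    return(data.frame(key = character(), gene = character(),
                      origin = character(), class = character(),
                      consequence = character()))
  }
  out <- data.frame(key = pri$key, gene = pri$gene, origin = pri$origin,
                    class = pri$class,
                    consequence = trimws(paste(pri$codon_change,
                                               pri$hgvs_p, pri$hgvs_c)),
                    stringsAsFactors = FALSE)
  out$snp_id <- vt$variants$snp_id[match(out$key, vt$variants$key)]
  for (pop in unique(pf$population)) {
    sub <- pf[pf$population == pop, , drop = FALSE]
    out[[paste0("maf_", pop)]] <-
      signif(sub$freq[match(out$key, sub$variant)], 4L)
  }
  for (ctl in unique(tests$pop_control)) {
    sub <- tests[tests$pop_control == ctl, , drop = FALSE]
    i <- match(out$key, sub$key)
    out[[paste0("p_vs_", ctl)]] <- signif(sub$p_two_sided[i], 3L)
    out[[paste0("tier_vs_", ctl)]] <- sub$tier[i]
  }
  out
}

#' Run one pipeline stage with file I/O
#'
#' Stage subcommands compose to the monolithic [run_pipeline()] run:
#' `simulate` writes inputs, `de`/`geneset`/`segregate`/`annotate` write
#' the corresponding intermediate tables, `aftest` requires a file of
#' variant keys (one per line) in `extra$keys`.
#'
#' @param stage One of `"simulate"`, `"de"`, `"geneset"`, `"segregate"`,
#'   `"annotate"`, `"aftest"`.
#' @param cfg A [funnel_config()] (or YAML path).
#' @param outdir Output directory.
#' @param extra Stage-specific extras (currently `keys` for `aftest`).
#' @return The stage's main object, invisibly.
#' @export
run_stage <- function(stage, cfg, outdir, extra = list()) {
  if (is.character(cfg)) cfg <- read_funnel_config(cfg)
  stopifnot(inherits(cfg, "funnel_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = {
      sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
      invisible(simulate_study(sim_cfg, file.path(outdir, "inputs")))
    },
    de = {
      x <- read_expression(cfg$inputs$expression)
      records <- moderated_t(x, shrink = if (cfg$shrinkage) "fit" else NULL)
      write_de_table(records, file.path(outdir, "de_table.tsv"))
      de_set <- gene_set("de",
                         select_de(records, cfg$fc_min, cfg$p_max,
                                   cfg$use_adjusted),
                         sprintf("FC >= %g, %s p <= %g", cfg$fc_min,
                                 if (cfg$use_adjusted) "adjusted" else
                                   "raw", cfg$p_max))
      write_geneset(de_set, file.path(outdir, "de_genes.txt"))
      invisible(records)
    },
    geneset = {
      catalog <- read_gwas_catalog(cfg$inputs$gwas_catalog)
      gs <- build_gwas_geneset(catalog, cfg$trait, cfg$gwas_p_threshold)
      write_geneset(gs, file.path(outdir, "gwas_genes.txt"))
      invisible(gs)
    },
    segregate = {
      ped <- read_ped(cfg$inputs$ped)
      vt <- read_vcf(cfg$inputs$vcf, ped = ped)
      seg <- transmission_filter(vt, ped, do.call(transmission_rule,
                                                  cfg$rule))
      write_segregation_report(seg$report,
                               file.path(outdir, "segregation_report.tsv"))
      write_vcf(seg$variants, file.path(outdir, "segregating.vcf"))
      invisible(seg)
    },
    annotate = {
      ped <- read_ped(cfg$inputs$ped)
      vt <- read_vcf(cfg$inputs$vcf, ped = ped)
      models <- read_transcripts(cfg$inputs$transcripts_tsv,
                                 cfg$inputs$transcripts_fasta)
      ann <- annotate_consequences(vt, models)
      write.table(ann, file.path(outdir, "consequences.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      invisible(ann)
    },
    aftest = {
      pf <- read_frequencies(cfg$inputs$frequencies)
      keys <- extra$keys %||% unique(pf$variant)
      control_pops <- setdiff(unique(pf$population),
                              cfg$affected_population)
      tests <- run_af_tests(keys, pf,
                            lapply(control_pops, function(p)
                              c(cfg$affected_population, p)),
                            test_family_config(cfg$alpha,
                                               borderline_mult =
                                                 cfg$borderline_mult,
                                               nominal_level =
                                                 cfg$nominal_level))
      write.table(tests, file.path(outdir, "af_tests.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      invisible(tests)
    },
    vf_abort(sprintf("unknown stage '%s'", stage), "varfunnel_config_error")
  )
}
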