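test_that("minus-strand codon arithmetic reproduces the printed fixtures", {
  gly <- classify_variant(transcript_fixture_gly482(), 23814039L, "C", "T")
  expect_identical(gly$class, "missense")
  expect_identical(gly$codon_change, "Ggt/Agt")
  expect_identical(gly$hgvs_p, "p.Gly482Ser")

  utr <- classify_variant(transcript_fixture_utr5(), 40100148L, "G", "A")
  expect_identical(utr$class, "utr5")
  expect_identical(utr$hgvs_c, "c.-54C > T")
  expect_identical(utr$hgvs_p, "")
})

test_that("positional classes: intronic, intergenic, utr3, reference mismatch", {
  cfg <- sim_config(seed = 17L, exon_range = c(3L, 5L))
  models <- simulate_transcripts(cfg, gene_ids = sprintf("T%d", 1:4))
  m <- models[[1L]]
  # intron: one past the first exon's end
  intron_pos <- m$exons[1L, "end"] + 1L
  expect_identical(classify_variant(m, intron_pos, "A", "G")$class,
                   "intronic")
  # intergenic: outside the span
  expect_identical(classify_variant(m, gene_span(m)[2L] + 10L, "A",
                                    "G")$class, "intergenic")
  # utr3: planted in the 3'-UTR region
  pv <- varfunnel:::plant_variant_on_model
  v3 <- pv(m, "utr3")
  expect_identical(classify_variant(m, v3$pos, v3$ref, v3$alt)$class,
                   "utr3")
  # wrong ref allele is a reference-mismatch error
  v <- pv(m, "missense")
  wrong <- setdiff(c("A", "C", "G", "T"), c(v$ref, v$alt))[1L]
  expect_error(classify_variant(m, v$pos, wrong, v$alt),
               class = "varfunnel_reference_mismatch")
})

test_that("classification agrees with the full-translation oracle", {
  cfg <- sim_config(seed = 23L)
  models <- simulate_transcripts(cfg, gene_ids = sprintf("T%d", 1:12))
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0L
  for (rep in 1:300) {
    m <- models[[sample.int(length(models), 1L)]]
    span <- gene_span(m)
    pos <- sample(span[1L]:span[2L], 1L)
    tpos <- map_genome_to_transcript(m, pos)
    ref <- if (is.na(tpos)) sample(bases, 1L) else {
      b <- substr(m$sequence, tpos, tpos)
      if (m$strand == "+") b else chartr("ACGT", "TGCA", b)
    }
    alt <- sample(setdiff(bases, ref), 1L)
    got <- classify_variant(m, pos, ref, alt)$class
    expect_identical(got, oracle_classify(m, pos, ref, alt),
                     info = sprintf("%s %s:%d %s>%s", m$gene_id, m$chrom,
                                    pos, ref, alt))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 300L)
})

test_that("classification is strand-consistent on mirrored transcripts", {
  # a plus-strand model and its reverse-complemented minus-strand mirror
  # must classify mirrored substitutions identically
  set.seed(5)
  cds <- varfunnel:::random_cds(60L)
  utr5 <- paste(sample(c("A", "C", "G", "T"), 30L, TRUE), collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "T"), 25L, TRUE), collapse = "")
  spliced <- paste0(utr5, cds, utr3)
  L <- nchar(spliced)
  plus <- transcript_model("P", "chr1", "+",
                           cbind(start = 1000L, end = 1000L + L - 1L),
                           cds_start = 1000L + 30L,
                           cds_end = 1000L + 30L + nchar(cds) - 1L,
                           sequence = spliced)
  minus <- transcript_model("M", "chr1", "-",
                            cbind(start = 1000L, end = 1000L + L - 1L),
                            cds_start = 1000L + 25L,
                            cds_end = 1000L + 25L + nchar(cds) - 1L,
                            sequence = spliced)
  rc <- function(b) chartr("ACGT", "TGCA", b)
  for (tpos in c(5L, 31L, 45L, 100L, L - 10L)) {
    gp <- map_transcript_to_genome(plus, tpos)
    gm <- map_transcript_to_genome(minus, tpos)
    tref <- substr(spliced, tpos, tpos)
    talt <- setdiff(c("A", "C", "G", "T"), tref)[1L]
    cp <- classify_variant(plus, gp, tref, talt)
    cm <- classify_variant(minus, gm, rc(tref), rc(talt))
    expect_identical(cm$class, cp$class, info = sprintf("tpos %d", tpos))
    expect_identical(cm$hgvs_p, cp$hgvs_p)
    expect_identical(cm$codon_change, cp$codon_change)
  }
})

test_that("generated transcripts are valid by construction", {
  models <- simulate_transcripts(sim_config(seed = 3L),
                                 gene_ids = sprintf("V%d", 1:10))
  for (m in models) {
    prot <- translate_cds(m)
    expect_identical(substr(prot, 1L, 1L), "M")
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    # no internal stop
    expect_false(grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)))
  }
  # round-trip through TSV + FASTA
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcripts(models, tsv, fa)
  back <- read_transcripts(tsv, fa)
  expect_identical(names(back), names(models))
  expect_identical(back[[4L]]$exons, models[[4L]]$exons)
  expect_identical(back[[4L]]$sequence, models[[4L]]$sequence)
})

test_that("low-frequency filter thresholds the max control frequency inclusively", {
  pf <- pop_freq(data.frame(
    variant = rep(c("v1", "v2", "v3", "v4"), each = 2L),
    population = rep(c("control_tsi", "control_nfe"), 4L),
    allele_count = c(0, 33, 81, 688, 4, 80, 9, 0),
    allele_number = rep(c(214L, 2000L), 4L)))
  # v1 max freq 0.0165, v2 0.3786..., v3 exactly 0.04, v4 0.042
  vars <- data.frame(key = c("v1", "v2", "v3", "v4", "v5"))
  expect_warning(
    out <- low_frequency_filter(vars, pf, 0.04,
                                c("control_tsi", "control_nfe")),
    "no frequency")
  expect_setequal(out$key, c("v1", "v3"))
  expect_identical(attr(out, "dropped_no_freq"), 1L)
})

test_that("published panel frequencies pass/fail the 0.04 filter as printed", {
  ref <- ijv_variant_reference()
  keep <- ref$maf_affected <= 0.04
  expect_identical(ref$gene[keep], c("DOCK10", "NR1D1", "TMEM130"))
  expect_true(ref$maf_affected[ref$snp_id == "rs113265459"] == 0.0224)
  expect_true(ref$maf_affected[ref$snp_id == "rs1805482"] == 0.3215)
})

test_that("intronic/nonintronic split is an exact partition", {
  ann <- data.frame(key = sprintf("v%d", 1:6),
                    class = c("intronic", "missense", "utr5", "intergenic",
                              "synonymous", "stop_gained"),
                    stringsAsFactors = FALSE)
  ann$nonintronic <- !ann$class %in% c("intronic", "intergenic")
  parts <- split_intronic(ann)
  expect_identical(nrow(parts$intronic) + nrow(parts$nonintronic),
                   nrow(ann))
  expect_setequal(parts$nonintronic$key, c("v2", "v3", "v5", "v6"))
  empty <- split_intronic(ann[0L, ])
  expect_identical(nrow(empty$intronic), 0L)
  expect_identical(nrow(empty$nonintronic), 0L)
})
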