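#' Construct and validate a transcript model
#'
#' Strand-aware exon/CDS geometry plus the spliced transcript sequence,
#' the reference against which variant consequences are called. All genomic
#' coordinates are 1-based inclusive; the sequence is stored 5'->3' in
#' transcript orientation (i.e. already reverse-complemented for minus-strand
#' genes).
#'
#' @param gene_id Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix/data.frame of exon `start`, `end`
#'   (genomic, sorted by coordinate, non-overlapping).
#' @param cds_start,cds_end Genomic coordinates of the translation bounds
#'   (cds_start <= cds_end regardless of strand).
#' @param sequence Spliced transcript sequence (character scalar, ACGT).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, chrom, strand, exons,
                             cds_start, cds_end, sequence) {
  exons <- as.matrix(exons)
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  if (any(exons[, "end"] < exons[, "start"])) {
    vf_abort("exon end before start", "varfunnel_validation_error")
  }
  if (is.unsorted(exons[, "start"], strictly = TRUE) ||
      any(exons[-1L, "start", drop = TRUE] <=
          exons[-nrow(exons), "end", drop = TRUE])) {
    vf_abort("exons must be sorted and non-overlapping",
             "varfunnel_validation_error")
  }
  if (!strand %in% c("+", "-")) {
    vf_abort("strand must be '+' or '-'", "varfunnel_validation_error")
  }
  sequence <- toupper(as.character(sequence))
  widths <- exons[, "end"] - exons[, "start"] + 1L
  if (nchar(sequence) != sum(widths)) {
    vf_abort(sprintf(
      "spliced sequence length (%d) must equal total exon length (%d)",
      nchar(sequence), sum(widths)), "varfunnel_validation_error")
  }
  model <- structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         sequence = sequence),
    class = "transcript_model")
  ct <- cds_bounds_tx(model)
  if (is.na(ct[1L]) || is.na(ct[2L])) {
    vf_abort("CDS bounds must lie within exons", "varfunnel_validation_error")
  }
  if ((ct[2L] - ct[1L] + 1L) %% 3L != 0L) {
    vf_abort("CDS length must be divisible by 3", "varfunnel_validation_error")
  }
  model
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s%s): %d exon(s), %d nt spliced, CDS %d nt\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              nchar(x$sequence), diff(cds_bounds_tx(x)) + 1L))
  invisible(x)
}

# Index of a genomic position along the exons concatenated in genomic
# (plus-strand) order, or NA if the position falls outside every exon.
plus_strand_index <- function(model, pos) {
  w <- model$exons[, "end"] - model$exons[, "start"] + 1L
  before <- c(0L, cumsum(w))
  for (j in seq_len(nrow(model$exons))) {
    if (pos >= model$exons[j, "start"] && pos <= model$exons[j, "end"]) {
      return(before[j] + (pos - model$exons[j, "start"] + 1L))
    }
  }
  NA_integer_
}

#' Map a genomic position into transcript coordinates
#'
#' @param model A `transcript_model`.
#' @param pos Genomic 1-based position.
#' @return 1-based position along the spliced transcript (5'->3' in
#'   transcript orientation), or `NA` if `pos` is not exonic.
#' @export
map_genome_to_transcript <- function(model, pos) {
  idx <- plus_strand_index(model, pos)
  if (is.na(idx)) return(NA_integer_)
  if (model$strand == "+") idx else nchar(model$sequence) - idx + 1L
}

#' Map a transcript position back to the genome
#'
#' Inverse of [map_genome_to_transcript()].
#'
#' @param model A `transcript_model`.
#' @param tpos 1-based transcript position.
#' @return Genomic 1-based position.
#' @export
map_transcript_to_genome <- function(model, tpos) {
  L <- nchar(model$sequence)
  if (tpos < 1L || tpos > L) {
    vf_abort("transcript position out of range", "varfunnel_validation_error")
  }
  idx <- if (model$strand == "+") tpos else L - tpos + 1L
  w <- model$exons[, "end"] - model$exons[, "start"] + 1L
  before <- c(0L, cumsum(w))
  j <- findInterval(idx - 1L, before, rightmost.closed = FALSE)
  model$exons[j, "start"] + (idx - before[j] - 1L)
}

# Transcript-coordinate CDS bounds c(first, last), ascending.
cds_bounds_tx <- function(model) {
  t1 <- map_genome_to_transcript(model, model$cds_start)
  t2 <- map_genome_to_transcript(model, model$cds_end)
  if (is.na(t1) || is.na(t2)) return(c(NA_integer_, NA_integer_))
  c(min(t1, t2), max(t1, t2))
}

#' Extract the coding sequence of a transcript model
#' @param model A `transcript_model`.
#' @return Character scalar: the CDS, 5'->3'.
#' @export
cds_sequence <- function(model) {
  ct <- cds_bounds_tx(model)
  substr(model$sequence, ct[1L], ct[2L])
}

#' Translate the coding sequence (standard nuclear code)
#' @param model A `transcript_model`.
#' @return Character scalar amino-acid sequence (`*` = stop).
#' @export
translate_cds <- function(model) {
  translate_dna(cds_sequence(model))
}

# Translate a DNA string with the standard genetic code; "*" is stop.
translate_dna <- function(dna) {
  if (nchar(dna) %% 3L != 0L) {
    vf_abort("sequence length not divisible by 3", "varfunnel_validation_error")
  }
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

# Complement/reverse-complement single bases or strings.
complement_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

#' Gene span of a transcript model (first to last exonic base, genomic)
#' @param model A `transcript_model`.
#' @return c(start, end).
#' @export
gene_span <- function(model) {
  c(model$exons[1L, "start"], model$exons[nrow(model$exons), "end"])
}

#' Read transcript models from a BED-like TSV plus a spliced-sequence FASTA
#'
#' The TSV carries one transcript per row: `gene_id`, `chrom`, `strand`,
#' `exon_starts`, `exon_ends` (comma-separated 1-based inclusive),
#' `cds_start`, `cds_end`. The FASTA (read with Biostrings) supplies the
#' spliced sequence per gene_id.
#'
#' @param tsv_path Path to the transcript-geometry TSV.
#' @param fasta_path Path to the spliced-sequence FASTA.
#' @return A named list of `transcript_model` objects, class `transcript_set`.
#' @export
read_transcripts <- function(tsv_path, fasta_path) {
  df <- read.delim(tsv_path, header = TRUE, colClasses = "character",
                   check.names = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  models <- lapply(seq_len(nrow(df)), function(i) {
    gid <- df$gene_id[i]
    if (!gid %in% names(seqs)) {
      vf_abort(sprintf("no FASTA sequence for transcript '%s'", gid),
               "varfunnel_validation_error")
    }
    starts <- as.integer(strsplit(df$exon_starts[i], ",")[[1L]])
    ends <- as.integer(strsplit(df$exon_ends[i], ",")[[1L]])
    transcript_model(gid, df$chrom[i], df$strand[i],
                     cbind(start = starts, end = ends),
                     as.integer(df$cds_start[i]), as.integer(df$cds_end[i]),
                     as.character(seqs[[gid]]))
  })
  names(models) <- df$gene_id
  structure(models, class = "transcript_set")
}

#' Write transcript models to TSV + FASTA
#'
#' @param models A `transcript_set` (or plain named list of models).
#' @param tsv_path,fasta_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_transcripts <- function(models, tsv_path, fasta_path) {
  df <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
               exon_starts = paste(m$exons[, "start"], collapse = ","),
               exon_ends = paste(m$exons[, "end"], collapse = ","),
               cds_start = m$cds_start, cds_end = m$cds_end,
               stringsAsFactors = FALSE)
  }))
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(models, `[[`, "", "sequence"))
  names(seqs) <- vapply(models, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  invisible(tsv_path)
}
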