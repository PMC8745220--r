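#' Construct a gene set
#'
#' @param name Non-empty set name.
#' @param symbols Character vector of gene symbols (deduplicated, trimmed;
#'   matching throughout the package is case-sensitive exact).
#' @param provenance Free-text provenance (source file, filter applied).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, symbols, provenance = "") {
  if (!nzchar(name)) vf_abort("gene set name must be non-empty",
                              "varfunnel_validation_error")
  symbols <- unique(trimws(as.character(symbols)))
  symbols <- symbols[nzchar(symbols)]
  structure(list(name = name, symbols = symbols,
                 provenance = as.character(provenance)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Build the disease gene set from a GWAS-catalog export
#'
#' Selects catalog SNPs whose trait matches `trait` (exact, case-insensitive)
#' and whose association p-value is <= `p_threshold` (inclusive), then takes
#' the union of their mapped gene symbols.
#'
#' @param records Data.frame from [read_gwas_catalog()].
#' @param trait Trait string, e.g. `"multiple sclerosis"`.
#' @param p_threshold Inclusive association p-value cutoff (default 5e-6).
#' @return A `gene_set`; attributes `n_snps` and `n_genes` carry the counts
#'   of qualifying SNPs and distinct genes.
#' @export
build_gwas_geneset <- function(records, trait, p_threshold = 5e-6) {
  hit <- tolower(trimws(records$trait)) == tolower(trimws(trait)) &
    records$assoc_p <= p_threshold
  if (!any(hit)) {
    warning(sprintf("no catalog SNPs match trait '%s' at p <= %g",
                    trait, p_threshold), call. = FALSE)
  }
  symbols <- unique(unlist(records$mapped_genes[hit], use.names = FALSE))
  gs <- gene_set(
    name = sprintf("gwas:%s", trait),
    symbols = symbols %||% character(),
    provenance = sprintf("GWAS catalog, trait '%s', p <= %g: %d SNPs, %d genes",
                         trait, p_threshold, sum(hit), length(symbols))
  )
  attr(gs, "n_snps") <- sum(hit)
  attr(gs, "n_genes") <- length(gs$symbols)
  gs
}

#' Intersect two gene sets
#'
#' Commutative, idempotent symbol intersection; provenance is concatenated.
#'
#' @param a,b `gene_set` objects.
#' @return A `gene_set`.
#' @export
geneset_intersect <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  gene_set(sprintf("%s & %s", a$name, b$name),
           intersect(a$symbols, b$symbols),
           provenance = paste(a$provenance, b$provenance, sep = " | "))
}

#' Partition a gene set into coding and ncRNA members
#'
#' @param s A `gene_set`.
#' @param class_map Named character vector mapping every symbol in `s` to
#'   `"coding"` or `"ncRNA"`; unmapped symbols are an error (listed).
#' @return A list with `gene_set` elements `coding` and `ncRNA` (disjoint,
#'   union equal to `s`).
#' @export
partition_by_class <- function(s, class_map) {
  stopifnot(inherits(s, "gene_set"))
  unmapped <- setdiff(s$symbols, names(class_map))
  if (length(unmapped)) {
    vf_abort(sprintf("symbols missing from class_map: %s",
                     paste(unmapped, collapse = ", ")),
             "varfunnel_validation_error")
  }
  cls <- class_map[s$symbols]
  if (!all(cls %in% c("coding", "ncRNA"))) {
    vf_abort("class_map values must be 'coding' or 'ncRNA'",
             "varfunnel_validation_error")
  }
  list(coding = gene_set(paste0(s$name, ":coding"),
                         s$symbols[cls == "coding"], s$provenance),
       ncRNA = gene_set(paste0(s$name, ":ncRNA"),
                        s$symbols[cls == "ncRNA"], s$provenance))
}

#' Write a gene set as one-symbol-per-line text
#'
#' Header comment lines (`# `) carry the name and provenance.
#'
#' @param s A `gene_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geneset <- function(s, path) {
  stopifnot(inherits(s, "gene_set"))
  writeLines(c(sprintf("# name: %s", s$name),
               sprintf("# provenance: %s", s$provenance),
               s$symbols), path)
  invisible(path)
}

#' Read a gene set written by [write_geneset()]
#' @param path Path to the gene-set text file.
#' @return A `gene_set`.
#' @export
read_geneset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  name <- sub("^# name: ", "", grep("^# name: ", hdr, value = TRUE)[1L])
  prov <- sub("^# provenance: ", "",
              grep("^# provenance: ", hdr, value = TRUE)[1L])
  gene_set(if (is.na(name)) basename(path) else name,
           grep("^#", lines, value = TRUE, invert = TRUE),
           if (is.na(prov)) "" else prov)
}
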