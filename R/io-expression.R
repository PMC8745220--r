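#' Construct and validate an expression matrix
#'
#' Container for log2 expression values of genes by samples with a two-group
#' (case/control) design, the input of the differential-expression stage.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). Values are log2 intensities.
#' @param group Character vector, one of `"case"`/`"control"` per sample,
#'   in column order (or named by sample id).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `group`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' em <- expression_matrix(m, c("case", "case", "control", "control"))
#' dim(em$values)
#' @export
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values)) {
    vf_abort("`values` must be a numeric matrix", "varfunnel_validation_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    vf_abort("`values` must have gene rownames and sample colnames",
             "varfunnel_validation_error")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    vf_abort(sprintf("duplicate gene ids: %s",
                     paste(unique(dup), collapse = ", ")),
             "varfunnel_validation_error")
  }
  if (!is.null(names(group))) group <- group[colnames(values)]
  group <- as.character(group)
  if (length(group) != ncol(values) || anyNA(group)) {
    vf_abort("every sample needs a group label", "varfunnel_validation_error")
  }
  if (!all(group %in% c("case", "control"))) {
    vf_abort("group labels must be 'case' or 'control'",
             "varfunnel_validation_error")
  }
  if (any(table(factor(group, c("case", "control"))) < 2L)) {
    vf_abort("need at least 2 samples per group", "varfunnel_validation_error")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    vf_abort(sprintf("non-finite expression value at gene '%s', sample '%s'",
                     rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
             "varfunnel_parse_error")
  }
  structure(list(values = values, group = setNames(group, colnames(values))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' Read a log2 expression matrix from TSV
#'
#' Expected layout: a header row `gene<TAB>sample ids...`, a second header
#' row `#group<TAB>case/control labels...`, then one row per gene. This is
#' exactly the layout written by [write_expression()].
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L) {
    vf_abort("expression file needs a sample header and a #group row",
             "varfunnel_parse_error")
  }
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  grp <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(grp[[1L]], "#group")) {
    vf_abort("second header row must start with '#group'",
             "varfunnel_parse_error")
  }
  samples <- hdr[-1L]
  labels <- grp[-1L]
  if (length(labels) != length(samples)) {
    vf_abort("#group row length does not match the sample header",
             "varfunnel_parse_error")
  }
  df <- read.delim(path, skip = 2L, header = FALSE,
                   colClasses = "character", check.names = FALSE)
  if (ncol(df) != length(samples) + 1L) {
    vf_abort("data rows do not match the sample header width",
             "varfunnel_parse_error")
  }
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    vf_abort(sprintf(
      "non-numeric expression value '%s' at gene '%s' (row %d), sample '%s'",
      vals[bad[1L], bad[2L]], genes[bad[1L]], bad[1L], samples[bad[2L]]),
      "varfunnel_parse_error")
  }
  dimnames(num) <- list(genes, samples)
  expression_matrix(num, setNames(labels, samples))
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x$values)), collapse = "\t"), con)
  writeLines(paste(c("#group", unname(x$group)), collapse = "\t"), con)
  body <- cbind(rownames(x$values),
                format(x$values, trim = TRUE, digits = 15L, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
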