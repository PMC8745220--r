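#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition so callers/tests can discriminate errors.
#' @noRd
vf_abort <- function(msg, class = "varfunnel_error", ...) {
  stop(structure(
    class = c(class, "varfunnel_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Log a per-stage message (records dropped, counts) unless quieted.
#' @noRd
vf_log <- function(...) {
  if (!isTRUE(getOption("varfunnel.quiet", FALSE))) {
    message("[varfunnel] ", sprintf(...))
  }
}

#' Check a scalar probability lies in (0, 1].
#' @noRd
is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) &&
  p > 0 && p <= 1

#' A variant key in the chrom:pos:ref:alt convention used throughout.
#' @noRd
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
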