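#' Pooled two-proportion z-test
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' normal approximation: \eqn{\hat p = (x_1 + x_2)/(n_1 + n_2)},
#' \eqn{z = (x_1/n_1 - x_2/n_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},
#' two-sided \eqn{p = 2\Phi(-|z|)}. The squared statistic equals the
#' Pearson chi-square on the 2x2 allele table without continuity
#' correction. Degenerate tables (pooled proportion 0 or 1) return z = 0,
#' p = 1 with the `degenerate` flag set.
#'
#' @param x1,n1 Allele count and allele number in the first sample.
#' @param x2,n2 Allele count and allele number in the second sample.
#' @return A list with `z`, `p_two_sided`, `degenerate`.
#' @examples
#' two_proportion_z(26, 2196, 1, 214)
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) {
    vf_abort("allele numbers must be >= 1", "varfunnel_validation_error")
  }
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    vf_abort("allele counts must lie in [0, allele number]",
             "varfunnel_validation_error")
  }
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(list(z = 0, p_two_sided = 1, degenerate = TRUE))
  }
  z <- (x1 / n1 - x2 / n2) /
    sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p_two_sided = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests in the family.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 25)  # 0.002
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) vf_abort("m must be >= 1", "varfunnel_validation_error")
  alpha / m
}

#' Configuration of the allele-frequency test family
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of tests; `NULL` (default) means "count distinct
#'   variants", filled in by [run_af_tests()].
#' @param borderline_mult Multiplier defining the borderline band
#'   \eqn{[t, borderline\_mult \cdot t)} above the Bonferroni threshold t
#'   (default 5).
#' @param nominal_level Upper bound of the nominal tier (default 0.05).
#' @return A list of class `test_family_config`.
#' @export
test_family_config <- function(alpha = 0.05, m = NULL, borderline_mult = 5,
                               nominal_level = 0.05) {
  if (!is_prob(alpha) || alpha >= 1) {
    vf_abort("alpha must lie in (0, 1)", "varfunnel_validation_error")
  }
  if (!is.null(m) && m < 1) {
    vf_abort("m must be >= 1", "varfunnel_validation_error")
  }
  structure(list(alpha = alpha, m = m, borderline_mult = borderline_mult,
                 nominal_level = nominal_level),
            class = "test_family_config")
}

#' Assign a significance tier to a p-value
#'
#' Mirrors the three-color convention of the published association table:
#' `significant` for p strictly below the Bonferroni threshold t,
#' `borderline` for p in \eqn{[t, mult \cdot t)}, `nominal` for p in
#' \eqn{[mult \cdot t, nominal\_level)}, else `ns`.
#'
#' @param p P-value(s).
#' @param threshold Bonferroni per-test threshold t.
#' @param borderline_mult Borderline band multiplier (default 5).
#' @param nominal_level Nominal cutoff (default 0.05).
#' @return Character vector of tier labels.
#' @export
af_tier <- function(p, threshold, borderline_mult = 5, nominal_level = 0.05) {
  ifelse(p < threshold, "significant",
         ifelse(p < borderline_mult * threshold, "borderline",
                ifelse(p < nominal_level, "nominal", "ns")))
}

#' Case-control allele-frequency tests across a variant family
#'
#' Runs the pooled two-proportion z-test for every variant and every
#' (affected, control) population comparison, then assigns Bonferroni
#' significance tiers. The multiplicity `m` defaults to the number of
#' distinct variants tested (not variants x comparisons), the convention
#' that gives a 0.002 threshold for a 25-variant family at alpha = 0.05;
#' set `cfg$m` to override.
#'
#' @param keys Character vector of variant keys to test.
#' @param pf A `pop_freq` table covering the populations compared.
#' @param comparisons List of length-2 character vectors
#'   `c(affected_population, control_population)`.
#' @param cfg A [test_family_config()].
#' @return Data.frame with one row per (variant, comparison): `key`,
#'   `pop_affected`, `pop_control`, `p1`, `p2`, `n1`, `n2`, `z`,
#'   `p_two_sided`, `tier`, `evaluable`. Attributes `m` and `threshold`
#'   carry the family size and per-test threshold.
#' @export
run_af_tests <- function(keys, pf, comparisons, cfg = test_family_config()) {
  stopifnot(inherits(pf, "pop_freq"), inherits(cfg, "test_family_config"))
  keys <- unique(keys)
  m <- cfg$m %||% length(keys)
  rows <- list()
  for (key in keys) {
    for (cmp in comparisons) {
      a <- pf[pf$variant == key & pf$population == cmp[1L], , drop = FALSE]
      b <- pf[pf$variant == key & pf$population == cmp[2L], , drop = FALSE]
      if (nrow(a) != 1L || nrow(b) != 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          key = key, pop_affected = cmp[1L], pop_control = cmp[2L],
          p1 = NA_real_, p2 = NA_real_, n1 = NA_real_, n2 = NA_real_,
          z = NA_real_, p_two_sided = NA_real_, tier = "not_evaluable",
          evaluable = FALSE, stringsAsFactors = FALSE)
        next
      }
      zt <- two_proportion_z(a$allele_count, a$allele_number,
                             b$allele_count, b$allele_number)
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, pop_affected = cmp[1L], pop_control = cmp[2L],
        p1 = a$freq, p2 = b$freq,
        n1 = a$allele_number, n2 = b$allele_number,
        z = zt$z, p_two_sided = zt$p_two_sided, tier = NA_character_,
        evaluable = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), pop_affected = character(),
               pop_control = character(), p1 = numeric(), p2 = numeric(),
               n1 = numeric(), n2 = numeric(), z = numeric(),
               p_two_sided = numeric(), tier = character(),
               evaluable = logical())
  threshold <- if (m >= 1L) bonferroni_threshold(cfg$alpha, m) else NA_real_
  ev <- out$evaluable
  out$tier[ev] <- af_tier(out$p_two_sided[ev], threshold,
                          cfg$borderline_mult, cfg$nominal_level)
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  out
}
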