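#' Absolute fold change from log2 group means
#'
#' The fold change is reported as an absolute linear-scale ratio
#' \eqn{2^{|\Delta|}} with \eqn{\Delta = \bar{x}_{case} - \bar{x}_{control}},
#' so it is always \eqn{\ge 1}; the direction records the sign of
#' \eqn{\Delta} (`"up"` = higher in cases; ties break as `"up"`).
#'
#' @param mean_case,mean_control Finite log2 expression means (vectorized).
#' @return A data.frame with columns `fold_change` and `direction`.
#' @examples
#' fold_change(8.31, 6.45)  # 3.63-fold, up
#' @export
fold_change <- function(mean_case, mean_control) {
  if (!all(is.finite(mean_case)) || !all(is.finite(mean_control))) {
    vf_abort("means must be finite", "varfunnel_validation_error")
  }
  delta <- mean_case - mean_control
  data.frame(fold_change = 2^abs(delta),
             direction = ifelse(delta >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Estimate empirical-Bayes variance-shrinkage hyperparameters
#'
#' Fits the scaled inverse-chi-square prior
#' \eqn{\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}} to observed per-gene sample
#' variances by moment matching on the log scale: with
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}, the prior degrees of
#' freedom solve \eqn{\psi'(d_0/2) = \mathrm{var}(e_g) - \overline{\psi'(d_g/2)}}
#' by monotone (Newton) inversion of the trigamma function, and
#' \eqn{s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}}. When the
#' variance excess is non-positive the prior is degenerate:
#' \eqn{d_0 = \infty}, \eqn{s_0^2 = \exp(\bar e)}.
#'
#' @param sample_variances Per-gene pooled sample variances (>= 10 genes
#'   with positive variance required; zero variances are excluded from the
#'   fit with a logged count).
#' @param dg Residual degrees of freedom per gene (scalar or vector).
#' @return A list of class `shrinkage_params` with elements `d0` (prior df,
#'   possibly `Inf`) and `s0_sq` (prior variance).
#' @export
fit_shrinkage <- function(sample_variances, dg) {
  s2 <- as.numeric(sample_variances)
  dg <- rep_len(as.numeric(dg), length(s2))
  if (all(s2 <= 0)) {
    vf_abort("all sample variances are zero", "varfunnel_validation_error")
  }
  keep <- s2 > 0 & is.finite(s2)
  if (sum(!keep) > 0L) {
    vf_log("fit_shrinkage: excluded %d gene(s) with zero/non-finite variance",
           sum(!keep))
  }
  s2 <- s2[keep]
  dg <- dg[keep]
  if (length(s2) < 10L) {
    vf_abort("need at least 10 genes with positive variance",
             "varfunnel_validation_error")
  }
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  excess <- var(e) - mean(trigamma(dg / 2))
  if (!is.finite(excess) || excess <= 0) {
    out <- list(d0 = Inf, s0_sq = exp(mean(e)))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    out <- list(d0 = d0, s0_sq = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(out, class = "shrinkage_params")
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on the monotone
# decreasing trigamma; convexity in 1/y makes the update stable.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Moderated (or ordinary pooled) two-sample t-test per gene
#'
#' Computes for every gene the pooled two-sample t-statistic with the
#' per-gene variance replaced by the empirical-Bayes posterior
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} and
#' \eqn{d_0 + d_g} degrees of freedom. With `shrink = NULL` the ordinary
#' pooled t-test is performed (\eqn{d_0 = 0}). Genes with zero pooled
#' variance and no shrinkage get the limit convention: p = 0 when the means
#' differ, p = 1 when they do not, and are flagged `degenerate`.
#'
#' @param x An [expression_matrix()] (two groups, each n >= 2).
#' @param shrink A `shrinkage_params` object, `NULL` for the ordinary pooled
#'   t, or the string `"fit"` (default) to estimate hyperparameters from the
#'   data via [fit_shrinkage()].
#' @return A data.frame (one row per gene) with columns `gene_id`,
#'   `mean_case`, `mean_control`, `sd_case`, `sd_control`, `fold_change`,
#'   `direction`, `t_stat`, `df`, `p_raw`, `p_adj`, `degenerate`.
#' @export
moderated_t <- function(x, shrink = "fit") {
  stopifnot(inherits(x, "expression_matrix"))
  case <- x$values[, x$group == "case", drop = FALSE]
  ctrl <- x$values[, x$group == "control", drop = FALSE]
  n1 <- ncol(case)
  n0 <- ncol(ctrl)
  m1 <- rowMeans(case)
  m0 <- rowMeans(ctrl)
  v1 <- apply(case, 1L, var)
  v0 <- apply(ctrl, 1L, var)
  dg <- n1 + n0 - 2L
  s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / dg
  if (identical(shrink, "fit")) shrink <- fit_shrinkage(s2, dg)
  if (is.null(shrink)) {
    d0 <- 0
    s0_sq <- 0
  } else {
    stopifnot(inherits(shrink, "shrinkage_params"))
    d0 <- shrink$d0
    s0_sq <- shrink$s0_sq
  }
  post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  df_tot <- d0 + dg
  se <- sqrt(post * (1 / n1 + 1 / n0))
  delta <- m1 - m0
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, ifelse(delta == 0, 0, sign(delta) * Inf),
                   delta / se)
  p_raw <- ifelse(is.infinite(t_stat), 0,
                  2 * pt(-abs(t_stat), df = df_tot))
  p_raw <- pmin(pmax(p_raw, 0), 1)
  p_raw[degenerate & delta == 0] <- 1
  if (any(degenerate)) {
    vf_log("moderated_t: %d gene(s) with zero variance flagged degenerate",
           sum(degenerate))
  }
  fc <- fold_change(m1, m0)
  data.frame(gene_id = rownames(x$values),
             mean_case = m1, mean_control = m0,
             sd_case = sqrt(v1), sd_control = sqrt(v0),
             fold_change = fc$fold_change, direction = fc$direction,
             t_stat = t_stat, df = df_tot, p_raw = p_raw,
             p_adj = benjamini_hochberg(p_raw),
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`: step-up
#' adjustment with cumulative-minimum enforcement, capped at 1, order
#' preserved relative to the input.
#'
#' @param p_values Raw p-values, all in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    vf_abort("p-values must lie in [0, 1]", "varfunnel_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Applies the selection rule: absolute fold change >= `fc_min` AND
#' (adjusted) p <= `p_max`, both boundaries inclusive.
#'
#' @param records Data.frame from [moderated_t()].
#' @param fc_min Minimum absolute fold change (default 2).
#' @param p_max Maximum p-value (default 0.05).
#' @param use_adjusted Use `p_adj` (default) rather than `p_raw`.
#' @return Character vector of selected gene ids.
#' @export
select_de <- function(records, fc_min = 2, p_max = 0.05, use_adjusted = TRUE) {
  p <- if (use_adjusted) records$p_adj else records$p_raw
  records$gene_id[records$fold_change >= fc_min & p <= p_max]
}

#' Write a differential-expression table to TSV
#'
#' Output columns mirror the published case-control layout: gene,
#' regulation, mean +/- SD per group, absolute FC, adjusted p.
#'
#' @param records Data.frame from [moderated_t()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(records, path) {
  out <- data.frame(
    gene = records$gene_id,
    regulation = records$direction,
    case_mean_sd = sprintf("%.2f ± %.2f", records$mean_case,
                           records$sd_case),
    control_mean_sd = sprintf("%.2f ± %.2f", records$mean_control,
                              records$sd_control),
    FC = sprintf("%.2f", records$fold_change),
    p = signif(records$p_adj, 3L),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
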