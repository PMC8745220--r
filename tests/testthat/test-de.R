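test_that("fold change is symmetric with flipped direction, ties break up", {
  fc <- fold_change(8.31, 6.45)
  expect_equal(round(fc$fold_change, 2L), 3.63)
  expect_identical(fc$direction, "up")
  rev <- fold_change(6.45, 8.31)
  expect_equal(rev$fold_change, fc$fold_change)
  expect_identical(rev$direction, "down")
  tie <- fold_change(5, 5)
  expect_equal(tie$fold_change, 1)
  expect_identical(tie$direction, "up")
})

test_that("printed DE panel fold changes recompute from the printed means", {
  ref <- ijv_de_reference()
  fc <- fold_change(ref$mean_ms, ref$mean_c)
  expect_identical(fc$direction, ref$regulation)
  # all rows agree within print-rounding slack of the group means, except
  # TMEM47 whose printed FC is not reconcilable from its printed means
  dev <- abs(fc$fold_change - ref$fc)
  expect_lt(max(dev[ref$gene != "TMEM47"]), 0.04)
  expect_gt(dev[ref$gene == "TMEM47"], 0.05)
})

test_that("moderated t with shrinkage off equals the textbook pooled t", {
  set.seed(42)
  for (rep in 1:5) {
    em <- mk_expr(n_genes = 30L, n_per_group = 3L + rep, seed = rep)
    res <- moderated_t(em, shrink = NULL)
    for (i in c(1L, 17L, 30L)) {
      tt <- t.test(em$values[i, em$group == "case"],
                   em$values[i, em$group == "control"], var.equal = TRUE)
      expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-12)
      expect_equal(res$df[i], unname(tt$parameter))
    }
  }
})

test_that("identical groups give t = 0, p = 1; zero variance is flagged", {
  vals <- matrix(rep(c(5, 6, 7), each = 4L), 3, 4, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), sprintf("S%d", 1:4)))
  em <- expression_matrix(vals, c("case", "case", "control", "control"))
  res <- moderated_t(em, shrink = NULL)
  expect_true(all(res$degenerate))
  expect_equal(res$t_stat, rep(0, 3))
  expect_equal(res$p_raw, rep(1, 3))

  # zero variance with a mean shift: p -> 0 under the limit convention
  vals2 <- vals
  vals2[1L, 1:2] <- 9
  em2 <- expression_matrix(vals2, c("case", "case", "control", "control"))
  res2 <- moderated_t(em2, shrink = NULL)
  expect_identical(res2$p_raw[1L], 0)
  expect_true(res2$degenerate[1L])
})

test_that("large prior df pins the posterior variance at s0^2", {
  em <- mk_expr(n_genes = 20L, n_per_group = 4L, seed = 7L)
  s0_sq <- 0.3
  big <- structure(list(d0 = Inf, s0_sq = s0_sq), class = "shrinkage_params")
  res <- moderated_t(em, shrink = big)
  delta <- res$mean_case - res$mean_control
  expect_equal(res$t_stat, delta / sqrt(s0_sq * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
})

test_that("shrinkage fit matches the independent limma estimator", {
  skip_if_not_installed("limma")
  set.seed(11)
  dg <- 18L
  sigma2 <- 4 * 0.05 / rchisq(3000L, df = 4)
  s2 <- sigma2 * rchisq(3000L, df = dg) / dg
  ours <- fit_shrinkage(s2, dg)
  lf <- limma::fitFDist(s2, df1 = dg)
  expect_equal(ours$d0, lf$df2, tolerance = 1e-3)
  expect_equal(ours$s0_sq, lf$scale, tolerance = 1e-3)
})

test_that("degenerate shrinkage cases are handled", {
  expect_identical(fit_shrinkage(rep(0.5, 100L), 10L)$d0, Inf)
  expect_error(fit_shrinkage(rep(0.2, 5L), 4L),
               class = "varfunnel_validation_error")
  expect_error(fit_shrinkage(rep(0, 50L), 4L),
               class = "varfunnel_validation_error")
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4L))
  set.seed(5)
  for (rep in 1:10) {
    p <- runif(50L)
    adj <- benjamini_hochberg(p)
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "varfunnel_validation_error")
})

test_that("DE selection is boundary-inclusive and monotone in thresholds", {
  rec <- data.frame(gene_id = c("A", "B", "C", "D"),
                    fold_change = c(2.0, 1.99, 5, 2.5),
                    p_raw = c(0.04, 0.0005, 0.2, 0.01),
                    p_adj = c(0.05, 0.001, 0.4, 0.02))
  expect_identical(select_de(rec), c("A", "D"))
  expect_identical(select_de(rec, use_adjusted = FALSE), c("A", "D"))
  set.seed(3)
  rec2 <- data.frame(gene_id = sprintf("G%d", 1:200),
                     fold_change = 2^abs(rnorm(200L)),
                     p_adj = runif(200L))
  rec2$p_raw <- rec2$p_adj
  base <- select_de(rec2)
  expect_true(all(select_de(rec2, fc_min = 3) %in% base))
  expect_true(all(select_de(rec2, p_max = 0.01) %in% base))
})
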