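pe_from_diffs <- function(diffs, genes = sprintf("g%d", seq_len(nrow(diffs)))) {
  rownames(diffs) <- genes
  colnames(diffs) <- sprintf("p%d", seq_len(ncol(diffs)))
  paired_expression(diffs, batch = "b1", stage = "early")
}

test_that("paired log2 fold change is the mean per-pair difference", {
  pe <- pe_from_diffs(rbind(c(2, 2, 2), c(1, -1, 0), c(0.5, 1.5, 2.5)))
  fc <- paired_log2fc(pe)
  expect_equal(unname(fc), c(2, 0, 1.5))
  pe2 <- pe_from_diffs(matrix(c(1, -1), 1))
  expect_equal(unname(paired_log2fc(pe2)), 0)
  pe3 <- pe_from_diffs(matrix(c(0.5, 1.5, 2.5, 3.5), 1))
  expect_equal(unname(paired_log2fc(pe3)), 2)
})

test_that("moderated t follows the shrunken-variance plug-in formula", {
  set.seed(1)
  diffs <- matrix(rnorm(100 * 4), 100, 4)
  diffs[1, ] <- c(2, 2, 2, 2) + rnorm(4, 0, 0.3)
  pe <- pe_from_diffs(diffs)
  res <- moderated_t_paired(pe)
  d0 <- attr(res, "d0"); s02 <- attr(res, "s02")
  g1 <- res[1, ]
  s2 <- stats::var(diffs[1, ])
  s2_post <- (d0 * s02 + 3 * s2) / (d0 + 3)
  expect_equal(g1$t_mod, g1$log2fc / (sqrt(s2_post) / 2), tolerance = 1e-12)
  expect_equal(g1$df_total, d0 + 3)
  expect_equal(g1$p_raw, 2 * pt(-abs(g1$t_mod), d0 + 3), tolerance = 1e-12)
})

test_that("no-shrinkage limit approaches the ordinary paired t", {
  # wildly heterogeneous gene variances force the prior df toward zero, so
  # posterior variances collapse onto the per-gene sample variances: for
  # genes at or above the prior variance the shrinkage ratio
  # (d0*s02/s2 + dg)/(d0 + dg) is within d0/(d0 + dg) of 1
  set.seed(2)
  n <- 400; np <- 6
  scales <- exp(rnorm(n, 0, 4))
  diffs <- matrix(rnorm(n * np), n, np) * scales
  pe <- pe_from_diffs(diffs)
  res <- moderated_t_paired(pe)
  d0 <- attr(res, "d0"); s02 <- attr(res, "s02")
  expect_lt(d0, 0.5)
  t_ord <- apply(diffs, 1, function(x) mean(x) / (sd(x) / sqrt(np)))
  s2 <- apply(diffs, 1, var)
  loose <- which(s2 >= s02)
  expect_gt(length(loose), 50)
  rel <- abs(res$t_mod[loose] - t_ord[loose]) / abs(t_ord[loose])
  expect_lt(max(rel), sqrt(1 + d0 / (np - 1)) - 1 + 1e-6)
})

test_that("homogeneous variances give full shrinkage to the common variance", {
  # equal true variances: observed spread of log s^2 is below its sampling
  # expectation, so the fitted prior df is infinite and all genes share s02
  set.seed(3)
  diffs <- matrix(rnorm(300 * 50), 300, 50)
  pe <- pe_from_diffs(diffs)
  res <- moderated_t_paired(pe)
  if (is.infinite(attr(res, "d0"))) {
    s02 <- attr(res, "s02")
    expect_equal(res$t_mod, res$log2fc / (sqrt(s02) / sqrt(50)),
                 tolerance = 1e-12)
  } else {
    expect_gt(attr(res, "d0"), 100)
  }
})

test_that("moderated t agrees with the empirical-Bayes reference implementation", {
  skip_if_not_installed("limma")
  set.seed(4)
  diffs <- matrix(rnorm(200 * 8, sd = rep(exp(rnorm(200, 0, 0.7)), 8)), 200, 8)
  pe <- pe_from_diffs(diffs)
  res <- moderated_t_paired(pe)
  fit <- limma::eBayes(limma::lmFit(diffs, design = matrix(1, 8, 1)))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p_raw, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("all-constant differences raise a clear estimation error", {
  pe <- pe_from_diffs(matrix(1, 5, 4))
  expect_error(moderated_t_paired(pe), "zero sample variance")
  expect_error(moderated_t_paired(pe_from_diffs(matrix(1, 3, 1))), ">= 2 pairs")
})

test_that("null simulation holds the raw type-I error near its nominal level", {
  sim <- simulate_paired_expression(
    sim_config(n_genes = 1000, n_pairs_per_batch = 10,
               frac_up = 0, frac_down = 0, noise_sd = 1, seed = 17))
  res <- moderated_t_paired(sim$batches[[1]])
  frac <- mean(res$p_raw < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment matches hand computation and its invariants", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_error(adjust_pvalues(c(0.1, 1.2)), "0, 1")
  # monotone and idempotent over random inputs
  set.seed(5)
  for (i in 1:20) {
    p <- runif(30)
    adj <- adjust_pvalues(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # order-preserving
  }
})

test_that("DEG selection splits by sign and excludes zero fold changes", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1, -2, 0, 3),
                    p_adj = c(0.004, 0.004, 0.004, 0.5))
  sel <- select_degs(rec, alpha = 0.005)
  expect_identical(sel$up, "a")
  expect_identical(sel$down, "b")
  expect_false("c" %in% c(sel$up, sel$down))  # zero log2fc excluded
  expect_false("d" %in% c(sel$up, sel$down))  # non-significant excluded
  expect_length(intersect(sel$up, sel$down), 0)
})

test_that("planted directions are recovered on a strong-signal simulation", {
  sim <- simulate_paired_expression(
    sim_config(n_genes = 400, n_pairs_per_batch = 15,
               frac_up = 0.05, frac_down = 0.05,
               effect_mean = 3, noise_sd = 0.5, seed = 23))
  rec <- moderated_t_paired(sim$batches[[1]])
  rec$p_adj <- adjust_pvalues(rec$p_raw)
  sel <- select_degs(rec, alpha = 0.005)
  truth_up <- sim$truth$gene[sim$truth$direction == "up"]
  truth_down <- sim$truth$gene[sim$truth$direction == "down"]
  expect_setequal(sel$up, truth_up)
  expect_setequal(sel$down, truth_down)
})

test_that("fold-change floor preserves sign and spares strong changes", {
  expect_equal(round(clamp_fold_change(3), 2), 5.64)
  expect_equal(clamp_fold_change(7.2), 7.2)
  expect_equal(round(clamp_fold_change(-2), 2), -5.64)
  expect_equal(clamp_fold_change(c(0.1, -8, 6)),
               c(log2(50), -8, 6))
  expect_error(clamp_fold_change(Inf), "finite")
})

test_that("cross-batch intersection behaves as a per-direction set intersection", {
  s1 <- list(up = c("a", "b", "c"), down = c("x"))
  s2 <- list(up = c("b", "c", "d"), down = c("y"))
  s3 <- list(up = c("c", "b"), down = character())
  expect_identical(common_degs(list(s1, s2, s3))$up, c("b", "c"))
  expect_identical(common_degs(list(s1, s2, s3))$down, character())
  expect_identical(common_degs(list(s1, s1))$up, sort(s1$up))  # idempotence
  expect_error(common_degs(list()), "at least one")
})
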