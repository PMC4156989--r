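eff_df <- function(Y, V, label = "d") {
  data.frame(label = label, batch = sprintf("b%d", seq_along(Y)),
             rho = tanh(Y), Y = Y, V = V, N = 3 + 1 / V,
             p_batch = NA_real_, stringsAsFactors = FALSE)
}

test_that("Fisher z transform: fixed point, worked value, oddness, domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  set.seed(10)
  rho <- runif(100, -0.99, 0.99)
  expect_equal(fisher_z(-rho), -fisher_z(rho), tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("inverse transform round-trips and saturates toward 1", {
  expect_equal(inverse_fisher_z(0), 0)
  expect_equal(inverse_fisher_z(fisher_z(0.9)), 0.9, tolerance = 1e-12)
  grid <- seq(-0.999, 0.999, by = 0.003)
  expect_equal(inverse_fisher_z(fisher_z(grid)), grid, tolerance = 1e-12)
  zs <- c(2, 4, 8, 16)
  rhos <- inverse_fisher_z(zs)
  expect_true(all(diff(rhos) > 0) && all(rhos < 1))
})

test_that("variance of z is 1/(N-3) with its boundary error", {
  expect_equal(variance_of_z(4), 1)
  expect_equal(variance_of_z(103), 0.01)
  expect_error(variance_of_z(3), ">= 4")
})

test_that("fixed-effect combination: identities and hand-computed cases", {
  one <- fixed_effect_combine(eff_df(0.3, 0.02))
  expect_equal(one$M, 0.3)
  expect_equal(one$V_M, 0.02)
  eq <- fixed_effect_combine(eff_df(c(0.2, 0.4), c(0.01, 0.01)))
  expect_equal(eq$M, 0.3)
  expect_equal(eq$V_M, 0.005)
  hand <- fixed_effect_combine(eff_df(c(0, 0.6), c(0.01, 0.04)))
  expect_equal(hand$M, 0.12)
  expect_equal(hand$SE_M, sqrt(hand$V_M))
  expect_equal(hand$LL_M, hand$M - 1.96 * hand$SE_M)
  # the two Z formulations coincide: M/SE equals sum(WY)/sqrt(sum(W))
  W <- 1 / c(0.01, 0.04)
  expect_equal(hand$Z, sum(W * c(0, 0.6)) / sqrt(sum(W)), tolerance = 1e-12)
  expect_error(
    fixed_effect_combine(data.frame(label = character(), Y = numeric(),
                                    V = numeric())),
    "no effects")
})

test_that("unweighted combination equals weighted under equal variances", {
  e <- eff_df(c(-0.1, 0.2, 0.5), rep(0.02, 3))
  w <- fixed_effect_combine(e, weighted = TRUE)
  u <- fixed_effect_combine(e, weighted = FALSE)
  expect_equal(u$M, w$M)
  expect_identical(u$model, "unweighted")
  # and differs when variances differ
  e2 <- eff_df(c(-0.1, 0.5), c(0.01, 0.2))
  expect_gt(abs(fixed_effect_combine(e2, weighted = FALSE)$M -
                fixed_effect_combine(e2, weighted = TRUE)$M), 0.01)
})

test_that("Q statistic: null case, hand value, permutation invariance", {
  same <- q_statistic(eff_df(rep(0.3, 4), c(0.01, 0.02, 0.05, 0.1)))
  expect_equal(same$Q, 0)
  expect_equal(same$p_het, 1)
  hand <- q_statistic(eff_df(c(0, 0.6), c(0.01, 0.04)))
  expect_equal(hand$Q, 7.2, tolerance = 1e-12)
  expect_identical(hand$df, 1L)
  e <- eff_df(c(0.1, -0.2, 0.4), c(0.01, 0.03, 0.02))
  perm <- e[c(3, 1, 2), ]
  expect_equal(q_statistic(e)$Q, q_statistic(perm)$Q, tolerance = 1e-12)
  expect_error(q_statistic(eff_df(0.2, 0.01)), "k >= 2")
})

test_that("I-squared definition and flooring", {
  expect_equal(i_squared(1, 1), 0)
  expect_equal(i_squared(4, 1), 75)
  expect_equal(i_squared(0.5, 1), 0)
  expect_equal(i_squared(0, 1), 0)
  expect_error(i_squared(-1, 1), "Q >= 0")
})

test_that("DerSimonian-Laird tau-squared: floor and hand computation", {
  low <- eff_df(c(0.1, 0.11), c(0.05, 0.05))
  expect_equal(tau_squared_dl(low), 0)
  e <- eff_df(c(0, 0.6), c(0.01, 0.04))
  # W = (100, 25): C = 125 - (100^2 + 25^2)/125 = 40; tau2 = (7.2 - 1)/40
  expect_equal(tau_squared_dl(e), 6.2 / 40, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    e <- eff_df(rnorm(4, 0, 0.5), runif(4, 0.01, 0.3))
    expect_gte(tau_squared_dl(e), 0)
  }
})

test_that("random-effects model widens intervals and degenerates to fixed", {
  e <- eff_df(c(0.05, 0.1), c(0.01, 0.02))
  expect_equal(tau_squared_dl(e), 0)  # Q below df here
  r <- random_effect_combine(e)
  f <- fixed_effect_combine(e)
  expect_equal(r$M, f$M, tolerance = 1e-12)
  expect_equal(r$SE_M, f$SE_M, tolerance = 1e-12)
  het <- eff_df(c(-0.8, 0.1, 0.9), c(0.01, 0.01, 0.01))
  expect_gte(random_effect_combine(het)$SE_M,
             fixed_effect_combine(het)$SE_M)
  expect_error(random_effect_combine(eff_df(0.1, 0.01)), "k >= 2")
})

test_that("model selection follows the heterogeneity criterion with its boundary", {
  expect_identical(select_model(0.2), "fixed")
  expect_identical(select_model(0.05), "random")
  expect_identical(select_model(0.1), "fixed")
  expect_identical(select_model(0.0999, threshold = 0.1), "random")
  expect_error(select_model(1.2), "0, 1")
})

test_that("Fisher combined test: null case, worked value, zero flooring", {
  all1 <- fisher_combined_test(c(1, 1, 1))
  expect_equal(all1$F, 0)
  expect_equal(all1$p, 1)
  two <- fisher_combined_test(c(0.05, 0.05))
  expect_equal(round(two$F, 3), 11.983)
  expect_identical(two$df, 4L)
  expect_warning(z <- fisher_combined_test(c(0.5, 0)), "floored")
  expect_true(is.finite(z$F))
  expect_error(fisher_combined_test(numeric()), "no p-values")
})

test_that("implementation matches the straight-from-formula oracle", {
  set.seed(12)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    Y <- rnorm(k, 0, 0.6)
    V <- runif(k, 0.005, 0.5)
    e <- eff_df(Y, V)
    want <- oracle_meta(Y, V)
    f <- fixed_effect_combine(e)
    qs <- q_statistic(e)
    expect_equal(f$M, want$M, tolerance = 1e-10)
    expect_equal(f$V_M, want$V_M, tolerance = 1e-10)
    expect_equal(f$Z, want$Z, tolerance = 1e-10)
    expect_equal(qs$Q, want$Q, tolerance = 1e-10)
    expect_equal(i_squared(qs$Q, qs$df), want$I2, tolerance = 1e-10)
    expect_equal(tau_squared_dl(e), want$tau2, tolerance = 1e-10)
    r <- random_effect_combine(e)
    expect_equal(r$M, want$M_random, tolerance = 1e-10)
    expect_equal(r$V_M, want$V_M_random, tolerance = 1e-10)
  }
})

test_that("agrees with the metafor reference implementation (DL)", {
  skip_if_not_installed("metafor")
  set.seed(13)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    Y <- rnorm(k, -0.3, 0.5)
    V <- runif(k, 0.01, 0.2)
    e <- eff_df(Y, V)
    ref <- metafor::rma(yi = Y, vi = V, method = "DL")
    r <- random_effect_combine(e)
    expect_equal(r$M, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(r$SE_M, ref$se, tolerance = 1e-8)
    expect_equal(r$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(q_statistic(e)$Q, ref$QE, tolerance = 1e-8)
    fixed <- fixed_effect_combine(e)
    ref_f <- metafor::rma(yi = Y, vi = V, method = "FE")
    expect_equal(fixed$M, as.numeric(ref_f$beta), tolerance = 1e-8)
  }
})

test_that("summary effect stays within study range; back-transformed CI in (-1,1)", {
  set.seed(14)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    e <- eff_df(rnorm(k, 0, 1.5), runif(k, 0.005, 1))
    f <- fixed_effect_combine(e)
    expect_gte(f$M, min(e$Y) - 1e-12)
    expect_lte(f$M, max(e$Y) + 1e-12)
    expect_lte(f$V_M, min(e$V) + 1e-12)
    r <- random_effect_combine(e)
    expect_true(r$rho_LL > -1 && r$rho_UL < 1)
    expect_true(f$rho_LL > -1 && f$rho_UL < 1)
  }
})

test_that("single-drug meta-analysis: k = 1 passthrough and identical batches", {
  one <- meta_analyze_drug(data.frame(drug = "d", es = -0.8, p = 0.01,
                                      n = 10, batch = "b1"))
  expect_identical(one$k_studies, 1L)
  expect_equal(one$rho_combined, -0.8, tolerance = 1e-12)
  expect_true(one$rho_LL > -1 && one$rho_UL < 1)

  twin <- meta_analyze_drug(data.frame(drug = "d", es = c(-0.5, -0.5),
                                       p = c(0.02, 0.02), n = c(10, 10),
                                       batch = c("b1", "b2")))
  expect_equal(twin$M, atanh(-0.5), tolerance = 1e-12)
  expect_equal(twin$Q, 0)
  expect_identical(twin$model, "fixed")
})

test_that("model choice responds to between-batch heterogeneity", {
  hom <- meta_analyze_drug(eff_df(c(-0.50, -0.52, -0.49), rep(0.05, 3)))
  expect_identical(hom$model, "fixed")
  het <- meta_analyze_drug(eff_df(c(-0.9, 0.2, 0.9), rep(0.005, 3)))
  expect_identical(het$model, "random")
  expect_lt(het$p_het, 0.1)
  expect_gt(het$tau2, 0)
})

test_that("a strongly reversing drug's effect is recovered across replicates", {
  hits <- 0L
  R <- 500L
  for (r in seq_len(R)) {
    cfg <- drug_sim_config(n_drugs = 1, true_rho = -0.6, n_instances = 50,
                           tau2 = 0, seed = 5000 + r)
    tabs <- simulate_drug_scores(cfg, n_batches = 4)
    res <- meta_analyze_drug(do.call(rbind, tabs))
    if (abs(res$rho_combined - (-0.6)) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits / R, 0.95)
})

test_that("stacked-table meta-analysis orders drugs by combined p", {
  cfg <- drug_sim_config(n_drugs = 6, true_rho = c(-0.7, 0, 0, 0, 0, 0),
                         n_instances = 30, tau2 = 0, seed = 77)
  scores <- do.call(rbind, simulate_drug_scores(cfg, n_batches = 3))
  res <- meta_analyze(scores)
  expect_identical(res$label[1], "drug001")
  expect_true(all(diff(res$p_one_tailed) >= 0))
  expect_identical(nrow(res), 6L)
})
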