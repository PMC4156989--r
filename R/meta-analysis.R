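#' Fisher z transform of a correlation-like score
#'
#' z = 0.5 * ln((1 + rho) / (1 - rho)); the variance-stabilising transform
#' under which per-batch drug enrichment scores are combined.
#'
#' @param rho numeric vector with |rho| < 1.
#' @return Fisher z values.
#' @export
fisher_z <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1))
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  atanh(rho)
}

#' Inverse Fisher z transform
#'
#' rho = (exp(2z) - 1) / (exp(2z) + 1).
#'
#' @param z finite numeric vector.
#' @return Correlations in (-1, 1).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Sampling variance of a Fisher z value
#'
#' V_z = 1 / (N - 3) for a correlation estimated from N observations.
#'
#' @param N integer sample size(s), >= 4.
#' @return Variances.
#' @export
variance_of_z <- function(N) {
  if (any(!is.finite(N)) || any(N <= 3))
    stop("`N` must be >= 4 (variance 1/(N-3) undefined otherwise)",
         call. = FALSE)
  1 / (N - 3)
}

#' Build effect-size records from a drug-score table
#'
#' Transforms each per-batch score to the Fisher z scale with its sampling
#' variance, producing the per-study records the combination functions
#' consume.
#'
#' @param scores data.frame with columns `drug`, `es`, `n` and optionally
#'   `p`, `batch`.
#' @param default_n optional instance count substituted where `n` is missing;
#'   records without a usable `n` are otherwise dropped with a warning.
#' @return data.frame with columns `label`, `batch`, `rho`, `Y`, `V`, `N`,
#'   `p_batch`.
#' @export
effect_sizes <- function(scores, default_n = NULL) {
  stopifnot(is.data.frame(scores), all(c("drug", "es") %in% names(scores)))
  n <- if ("n" %in% names(scores)) scores$n else rep(NA_real_, nrow(scores))
  miss <- !is.finite(n) | n < 4
  if (any(miss)) {
    if (!is.null(default_n)) {
      n[miss] <- default_n
    } else {
      warning(sprintf("%d record(s) without a valid instance count were dropped",
                      sum(miss)), call. = FALSE)
      scores <- scores[!miss, , drop = FALSE]
      n <- n[!miss]
    }
  }
  if (nrow(scores) == 0L)
    stop("no usable effect-size records", call. = FALSE)
  data.frame(
    label = scores$drug,
    batch = if ("batch" %in% names(scores)) scores$batch
            else sprintf("study%d", seq_len(nrow(scores))),
    rho = scores$es,
    Y = fisher_z(scores$es),
    V = variance_of_z(n),
    N = n,
    p_batch = if ("p" %in% names(scores)) scores$p else NA_real_,
    stringsAsFactors = FALSE)
}

meta_result_row <- function(label, k, model, M, V_M, Z, p, Q = NA_real_,
                            df = NA_real_, p_het = NA_real_, I2 = NA_real_,
                            tau2 = NA_real_) {
  SE_M <- sqrt(V_M)
  LL <- M - 1.96 * SE_M
  UL <- M + 1.96 * SE_M
  data.frame(label = label, k_studies = k, model = model,
             M = M, V_M = V_M, SE_M = SE_M, Z = Z, p_one_tailed = p,
             LL_M = LL, UL_M = UL,
             rho_combined = tanh(M), rho_LL = tanh(LL), rho_UL = tanh(UL),
             Q = Q, df = df, p_het = p_het, I2 = I2, tau2 = tau2,
             stringsAsFactors = FALSE)
}

combine_with_weights <- function(effects, W, model, alternative) {
  sumW <- sum(W)
  M <- sum(W * effects$Y) / sumW
  V_M <- 1 / sumW
  SE_M <- sqrt(V_M)
  Z <- M / SE_M   # identical to sum(W*Y)/sqrt(sum(W))
  p <- switch(alternative,
              less = stats::pnorm(Z),
              two.sided = 2 * stats::pnorm(-abs(Z)))
  meta_result_row(label = effects$label[1L], k = nrow(effects),
                  model = model, M = M, V_M = V_M, Z = Z, p = p)
}

#' Fixed-effect (or unweighted) combination of Fisher-z effects
#'
#' Under the fixed-effect model every study estimates one true effect and
#' differences are sampling error: weights are the inverse sampling
#' variances W_i = 1/V_i (or all 1 when `weighted = FALSE`), the summary is
#' M = sum(W_i Y_i) / sum(W_i) with variance V_M = 1 / sum(W_i), and
#' Z = M / SE_M (equal to sum(W_i Y_i) / sqrt(sum(W_i))). The default
#' one-tailed p tests for a negative combined effect, the direction of a
#' signature-reversing drug. The 95% interval is M +/- 1.96 SE_M.
#'
#' @param effects data.frame from [effect_sizes()] (columns `Y`, `V`).
#' @param weighted inverse-variance weights (default) or equal weights.
#' @param alternative `"less"` (default; negative-effect one-tailed p) or
#'   `"two.sided"`.
#' @return One-row data.frame of summary fields (see [meta_analyze_drug()]).
#' @export
fixed_effect_combine <- function(effects, weighted = TRUE,
                                 alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(effects), all(c("Y", "V") %in% names(effects)))
  if (nrow(effects) == 0L) stop("no effects to combine", call. = FALSE)
  if (any(effects$V <= 0)) stop("variances must be positive", call. = FALSE)
  W <- if (weighted) 1 / effects$V else rep(1, nrow(effects))
  combine_with_weights(effects, W,
                       model = if (weighted) "fixed" else "unweighted",
                       alternative = alternative)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum W_i (Y_i - M)^2 with fixed-effect weights W_i = 1/V_i and M the
#' fixed-effect mean; under homogeneity Q ~ chi-square on k-1 df.
#'
#' @param effects data.frame from [effect_sizes()], k >= 2 rows.
#' @param M optional fixed-effect mean (computed if omitted).
#' @return list with `Q`, `df`, `p_het`.
#' @export
q_statistic <- function(effects, M = NULL) {
  stopifnot(is.data.frame(effects), all(c("Y", "V") %in% names(effects)))
  k <- nrow(effects)
  if (k < 2L) stop("heterogeneity requires k >= 2 studies", call. = FALSE)
  W <- 1 / effects$V
  if (is.null(M)) M <- sum(W * effects$Y) / sum(W)
  Q <- sum(W * (effects$Y - M)^2)
  df <- k - 1L
  list(Q = Q, df = df, p_het = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared heterogeneity percentage
#'
#' I2 = max(0, (Q - df) / Q) x 100: the percentage of total variability
#' attributable to between-study heterogeneity rather than sampling error.
#' Values below 25% indicate no heterogeneity, above 75% extreme
#' heterogeneity.
#'
#' @param Q Cochran's Q (>= 0).
#' @param df degrees of freedom (k - 1, >= 1).
#' @return Percentage in `[0, 100)`.
#' @export
i_squared <- function(Q, df) {
  if (Q < 0 || df < 1) stop("need Q >= 0 and df >= 1", call. = FALSE)
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' DerSimonian-Laird between-study variance
#'
#' tau2 = max(0, (Q - df) / C) with C = sum(W_i) - sum(W_i^2)/sum(W_i) and
#' fixed-effect weights W_i = 1/V_i.
#'
#' @param effects data.frame from [effect_sizes()], k >= 2 rows.
#' @param Q,df optional precomputed heterogeneity statistic.
#' @return Non-negative tau-squared estimate.
#' @export
tau_squared_dl <- function(effects, Q = NULL, df = NULL) {
  k <- nrow(effects)
  if (k < 2L) stop("tau-squared requires k >= 2 studies", call. = FALSE)
  W <- 1 / effects$V
  if (is.null(Q) || is.null(df)) {
    qs <- q_statistic(effects)
    Q <- qs$Q; df <- qs$df
  }
  C <- sum(W) - sum(W^2) / sum(W)
  if (C == 0) stop("degenerate weights: C = 0", call. = FALSE)
  max(0, (Q - df) / C)
}

#' Random-effects combination of Fisher-z effects
#'
#' The random-effects model lets the true effect vary across studies with
#' between-study variance tau2 (DerSimonian-Laird estimate unless supplied):
#' weights become W*_i = 1 / (V_i + tau2) and the summary, Z, p and CI follow
#' as in [fixed_effect_combine()]. With tau2 = 0 the result coincides with
#' the fixed-effect one.
#'
#' @param effects data.frame from [effect_sizes()], k >= 2 rows.
#' @param tau2 optional between-study variance; estimated by
#'   [tau_squared_dl()] when `NULL`.
#' @param alternative as in [fixed_effect_combine()].
#' @return One-row data.frame of summary fields (with `tau2` filled).
#' @export
random_effect_combine <- function(effects, tau2 = NULL,
                                  alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (nrow(effects) < 2L)
    stop("random-effects combination requires k >= 2 studies", call. = FALSE)
  if (is.null(tau2)) tau2 <- tau_squared_dl(effects)
  W <- 1 / (effects$V + tau2)
  out <- combine_with_weights(effects, W, model = "random",
                              alternative = alternative)
  out$tau2 <- tau2
  out
}

#' Choose the combination model from the heterogeneity test
#'
#' A heterogeneity p-value at or above the threshold indicates little
#' between-batch variation, so a fixed-effect model is appropriate;
#' otherwise the random-effects model is chosen. The boundary
#' `p_het == threshold` selects fixed.
#'
#' @param p_het heterogeneity p-value in `[0, 1]`.
#' @param threshold significance criterion (default 0.1).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(p_het, threshold = 0.1) {
  if (!is.finite(p_het) || p_het < 0 || p_het > 1)
    stop("`p_het` must lie in [0, 1]", call. = FALSE)
  if (p_het >= threshold) "fixed" else "random"
}

#' Fisher combined probability test
#'
#' F = -2 sum(ln p), chi-square distributed on 2k df under the null of all k
#' individual nulls. Zero p-values (which some drug-score services emit and
#' which would make F infinite) are floored at `eps` with a warning.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]` (zeros floored).
#' @param eps floor applied to zero p-values (default 1e-16).
#' @return list with `F`, `df` (= 2k) and the combined upper-tail `p`.
#' @export
fisher_combined_test <- function(pvalues, eps = 1e-16) {
  if (length(pvalues) == 0L) stop("no p-values to combine", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(pvalues == 0)) {
    warning(sprintf("zero p-value(s) floored at %g", eps), call. = FALSE)
    pvalues[pvalues == 0] <- eps
  }
  F_stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(F = F_stat, df = df,
       p = stats::pchisq(F_stat, df, lower.tail = FALSE))
}

#' Meta-analyze one drug across batches
#'
#' Transforms the drug's per-batch scores to the Fisher z scale, tests
#' heterogeneity (Q, I-squared, DerSimonian-Laird tau-squared), selects the
#' fixed- or random-effects model by the heterogeneity p-value, combines,
#' and back-transforms the summary and its confidence limits to the score
#' scale. A drug observed in a single batch is returned as-is under the
#' fixed-effect model with `k_studies = 1`.
#'
#' @param scores data.frame of this drug's per-batch records (columns `drug`,
#'   `es`, `n`, optionally `p`, `batch`), or an [effect_sizes()] frame.
#' @param weighted inverse-variance weighting (default) or equal weights for
#'   the fixed-effect branch.
#' @param het_p heterogeneity significance criterion (default 0.1).
#' @param alternative one-tailed (negative direction, default) or two-sided.
#' @param default_n see [effect_sizes()].
#' @return One-row data.frame: `label`, `k_studies`, `model`, `M`, `V_M`,
#'   `SE_M`, `Z`, `p_one_tailed`, `LL_M`, `UL_M`, `rho_combined`, `rho_LL`,
#'   `rho_UL`, `Q`, `df`, `p_het`, `I2`, `tau2`.
#' @export
meta_analyze_drug <- function(scores, weighted = TRUE, het_p = 0.1,
                              alternative = c("less", "two.sided"),
                              default_n = NULL) {
  alternative <- match.arg(alternative)
  eff <- if (all(c("Y", "V") %in% names(scores))) scores
         else effect_sizes(scores, default_n = default_n)
  if (length(unique(eff$label)) > 1L)
    stop("`scores` must concern a single drug; see meta_analyze()",
         call. = FALSE)
  k <- nrow(eff)
  if (k == 1L) {
    out <- fixed_effect_combine(eff, weighted = weighted,
                                alternative = alternative)
    return(out)
  }
  qs <- q_statistic(eff)
  i2 <- i_squared(qs$Q, qs$df)
  t2 <- tau_squared_dl(eff, Q = qs$Q, df = qs$df)
  model <- select_model(qs$p_het, threshold = het_p)
  out <- if (model == "random")
    random_effect_combine(eff, tau2 = t2, alternative = alternative)
  else
    fixed_effect_combine(eff, weighted = weighted, alternative = alternative)
  out$Q <- qs$Q
  out$df <- qs$df
  out$p_het <- qs$p_het
  out$I2 <- i2
  out$tau2 <- t2
  out
}

#' Meta-analyze every drug in a stacked score table
#'
#' @param scores data.frame of per-batch records for many drugs (stacked
#'   [simulate_drug_scores()] tables or a read TSV).
#' @inheritParams meta_analyze_drug
#' @return data.frame with one [meta_analyze_drug()] row per drug, ordered by
#'   ascending `p_one_tailed` then label.
#' @export
meta_analyze <- function(scores, weighted = TRUE, het_p = 0.1,
                         alternative = c("less", "two.sided"),
                         default_n = NULL) {
  alternative <- match.arg(alternative)
  eff <- effect_sizes(scores, default_n = default_n)
  res <- do.call(rbind, lapply(split(eff, eff$label), meta_analyze_drug,
                               weighted = weighted, het_p = het_p,
                               alternative = alternative))
  res <- res[order(res$p_one_tailed, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}
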