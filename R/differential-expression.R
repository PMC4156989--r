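#' Per-gene paired log2 fold change
#'
#' The paired design reduces each gene to a vector of per-patient differences
#' (tumor log2 minus normal log2); the fold change is their arithmetic mean.
#'
#' @param expr a [paired_expression()].
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
paired_log2fc <- function(expr) {
  stopifnot(inherits(expr, "paired_expression"))
  if (ncol(expr$diffs) < 1L || nrow(expr$diffs) < 1L)
    stop("expression matrix is empty", call. = FALSE)
  rowMeans(expr$diffs)
}

# Method-of-moments fit of the inverse-chi-square variance prior on
# log(s^2): E[log s^2] and Var[log s^2] are matched through digamma/trigamma
# identities, giving prior df d0 and prior variance s02. Genes with zero
# sample variance carry no information about the prior and are excluded from
# the fit (their posterior variance still shrinks toward s02).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stop("cannot estimate the variance prior: every gene has zero sample ",
         "variance (all-constant differences)", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- if (sum(ok) > 1L) stats::var(e) else 0
  evar <- evar - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone convex),
# the standard stable scheme for this inversion.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Paired moderated-t differential expression
#'
#' Computes, for every gene, the mean paired difference (log2 fold change)
#' and a moderated t-statistic in which the per-gene sample variance is
#' shrunk toward a prior estimated from all genes: with per-gene variance
#' s_g^2 on d_g = n_pairs - 1 degrees of freedom and prior (d0, s0^2)
#' estimated by method of moments on log s_g^2, the posterior variance is
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g) and
#' t_mod = log2fc / (s~_g / sqrt(n_pairs)), referred to a t distribution on
#' d0 + d_g degrees of freedom (normal when d0 is infinite). Shrinkage
#' borrows strength across genes exactly as empirical-Bayes microarray
#' moderation does, stabilising variances at small pair counts.
#'
#' @param expr a [paired_expression()] with at least 2 pairs.
#' @return data.frame with one row per gene: `gene`, `log2fc`, `t_mod`,
#'   `df_total`, `p_raw` (two-sided), `p_adj` (NA; see [adjust_pvalues()]),
#'   `direction` (NA; see [select_degs()]). The prior is attached as
#'   attributes `d0` and `s02`.
#' @export
moderated_t_paired <- function(expr) {
  stopifnot(inherits(expr, "paired_expression"))
  n <- ncol(expr$diffs)
  if (n < 2L)
    stop("need >= 2 pairs to estimate per-gene variance", call. = FALSE)
  dg <- n - 1
  fc <- rowMeans(expr$diffs)
  s2 <- apply(expr$diffs, 1L, stats::var)
  prior <- fit_variance_prior(s2, dg)
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2))
             else (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
  t_mod <- fc / (sqrt(s2_post) / sqrt(n))
  df_total <- prior$d0 + dg
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    gene = expr$genes,
    log2fc = unname(fc),
    t_mod = unname(t_mod),
    df_total = df_total,
    p_raw = unname(p_raw),
    p_adj = NA_real_,
    direction = NA_character_,
    stringsAsFactors = FALSE)
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same length and order).
#' @export
adjust_pvalues <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Select up- and downregulated genes
#'
#' Genes with adjusted p below `alpha` are split by the sign of their log2
#' fold change: positive means upregulated in tumor, negative downregulated.
#' A gene with exactly zero fold change is excluded from both sets.
#'
#' @param records data.frame from [moderated_t_paired()] with `p_adj` filled.
#' @param alpha adjusted-p threshold (default 0.005).
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
select_degs <- function(records, alpha = 0.005) {
  stopifnot(is.data.frame(records),
            all(c("gene", "log2fc", "p_adj") %in% names(records)))
  if (anyNA(records$p_adj))
    stop("`p_adj` must be filled (see adjust_pvalues()) before selection",
         call. = FALSE)
  sig <- records$p_adj < alpha
  list(up = records$gene[sig & records$log2fc > 0],
       down = records$gene[sig & records$log2fc < 0])
}

#' Floor the magnitude of a log2 fold change
#'
#' Connectivity-map query construction expects strongly contrasted
#' signatures; fold changes weaker than the floor are reset to the floor with
#' their sign preserved. The default floor is log2(50) = 5.64.
#'
#' @param log2fc numeric vector of finite log2 fold changes.
#' @param floor magnitude floor (default `log2(50)`).
#' @return Vector with `|value| >= floor` wherever the input was nonzero.
#' @export
clamp_fold_change <- function(log2fc, floor = log2(50)) {
  if (any(!is.finite(log2fc)))
    stop("`log2fc` must be finite", call. = FALSE)
  ifelse(abs(log2fc) < floor, sign(log2fc) * floor, log2fc)
}

#' Intersect per-batch DEG sets
#'
#' The cross-platform signature keeps only genes called in the same direction
#' in every batch of a stage.
#'
#' @param deg_sets list of per-batch results, each a list with character
#'   vectors `up` and `down` (as returned by [select_degs()]).
#' @return list with `up` and `down` intersections.
#' @export
common_degs <- function(deg_sets) {
  if (length(deg_sets) < 1L) stop("need at least one batch", call. = FALSE)
  list(up = sort(Reduce(intersect, lapply(deg_sets, `[[`, "up"))),
       down = sort(Reduce(intersect, lapply(deg_sets, `[[`, "down"))))
}
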