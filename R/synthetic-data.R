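#' Configuration for the paired tumor/normal expression simulator
#'
#' Defines the study conditions for [simulate_paired_expression()]: a
#' multi-batch paired design in which each patient contributes a tumor and a
#' matched normal log2-expression profile. A fixed fraction of genes carries a
#' planted differential effect whose sign (up/down) and magnitude are drawn
#' once and shared across batches, mimicking a common stage-specific disease
#' signature measured on several microarray platforms.
#'
#' The defaults emulate a four-batch early-stage design with 8, 15, 35 and 25
#' patient pairs and twice as many downregulated as upregulated genes.
#'
#' @param n_genes number of genes on the simulated platform.
#' @param n_pairs_per_batch integer vector; patient pairs in each batch. Its
#'   length sets the number of batches.
#' @param frac_up,frac_down fractions of genes planted as up-/downregulated;
#'   `frac_up + frac_down` must not exceed 1.
#' @param effect_mean,effect_sd mean and sd (log2 scale) of the magnitude of
#'   planted tumor-minus-normal shifts. With `effect_sd = 0` every planted
#'   gene shifts by exactly `effect_mean` (sign per direction).
#' @param noise_sd within-pair residual standard deviation (log2 scale);
#'   must be positive.
#' @param effect_jitter_sd optional per-batch jitter sd added to planted
#'   effects; the default 0 keeps effects identical across batches.
#' @param baseline_mean,baseline_sd distribution of the normal-tissue log2
#'   intensities (only affects the tumor/normal matrices, not the paired
#'   differences).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return An object of class `sim_config`.
#' @seealso [simulate_paired_expression()]
#' @export
sim_config <- function(n_genes = 1000L,
                       n_pairs_per_batch = c(8L, 15L, 35L, 25L),
                       frac_up = 0.05,
                       frac_down = 0.10,
                       effect_mean = 2,
                       effect_sd = 0.5,
                       noise_sd = 1,
                       effect_jitter_sd = 0,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_pairs_per_batch <- as.integer(unlist(n_pairs_per_batch))
  if (n_genes < 1L) stop("`n_genes` must be >= 1", call. = FALSE)
  if (length(n_pairs_per_batch) < 1L || any(n_pairs_per_batch < 1L))
    stop("`n_pairs_per_batch` must contain counts >= 1", call. = FALSE)
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1)
    stop("`frac_up` and `frac_down` must be non-negative with sum <= 1",
         call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be > 0", call. = FALSE)
  if (effect_sd < 0 || effect_jitter_sd < 0)
    stop("effect sds must be non-negative", call. = FALSE)
  structure(
    list(n_genes = n_genes,
         n_pairs_per_batch = n_pairs_per_batch,
         n_batches = length(n_pairs_per_batch),
         frac_up = frac_up, frac_down = frac_down,
         effect_mean = effect_mean, effect_sd = effect_sd,
         noise_sd = noise_sd, effect_jitter_sd = effect_jitter_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Paired tumor/normal expression for one batch
#'
#' Container for a batch of paired log2 expression values. Downstream
#' differential-expression functions only consume the per-pair differences
#' (`diffs`, genes x pairs, tumor log2 minus normal log2); the raw `tumor`
#' and `normal` matrices are kept when available so the batch can be written
#' to and re-read from TSV.
#'
#' @param diffs numeric matrix, genes x pairs, with gene symbols as rownames.
#' @param batch batch label.
#' @param stage `"early"` or `"late"`.
#' @param tumor,normal optional matching log2 intensity matrices.
#' @return An object of class `paired_expression`.
#' @export
paired_expression <- function(diffs, batch = "batch1", stage = "early",
                              tumor = NULL, normal = NULL) {
  if (!is.matrix(diffs)) diffs <- as.matrix(diffs)
  if (is.null(rownames(diffs)) || anyNA(rownames(diffs)) ||
      any(!nzchar(rownames(diffs))))
    stop("`diffs` must have complete gene symbols as rownames", call. = FALSE)
  stage <- match.arg(stage, c("early", "late"))
  structure(
    list(genes = rownames(diffs), diffs = diffs,
         batch = as.character(batch), stage = stage,
         tumor = tumor, normal = normal),
    class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  cat(sprintf("paired_expression: %d genes x %d pairs (batch %s, %s stage)\n",
              nrow(x$diffs), ncol(x$diffs), x$batch, x$stage))
  invisible(x)
}

#' Simulate multi-batch paired tumor/normal expression
#'
#' Draws, once and globally, a set of planted up- and downregulated genes and
#' their effect magnitudes, then generates each batch's paired log2 profiles
#' around them: planted genes have a tumor-minus-normal mean shift equal to
#' their (signed) planted effect, null genes a mean shift of zero, and every
#' pair adds i.i.d. Normal(0, `noise_sd`^2) residuals. Planted effects are
#' shared across batches (plus optional per-batch jitter), so the batches
#' carry a common differential signature as multi-platform paired studies of
#' the same disease stage would.
#'
#' @param cfg a [sim_config()].
#' @param stage stage label attached to every batch.
#' @return A list of class `paired_sim` with elements
#'   \describe{
#'     \item{batches}{list of [paired_expression()] objects, one per batch.}
#'     \item{truth}{data.frame (`gene`, `direction`, `effect`) of planted
#'       genes; empty when `frac_up = frac_down = 0`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_paired_expression(sim_config(n_genes = 50,
#'                                              n_pairs_per_batch = c(4, 5),
#'                                              seed = 7))
#' head(sim$truth)
#' @export
simulate_paired_expression <- function(cfg, stage = "early") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_up <- round(cfg$frac_up * cfg$n_genes)
  n_down <- round(cfg$frac_down * cfg$n_genes)
  planted <- if (n_up + n_down > 0L) sample(genes, n_up + n_down) else character()
  up_genes <- planted[seq_len(n_up)]
  down_genes <- setdiff(planted, up_genes)

  # global per-gene shift, shared across batches
  mu <- stats::setNames(numeric(cfg$n_genes), genes)
  if (n_up > 0L)
    mu[up_genes] <- abs(stats::rnorm(n_up, cfg$effect_mean, cfg$effect_sd))
  if (n_down > 0L)
    mu[down_genes] <- -abs(stats::rnorm(n_down, cfg$effect_mean, cfg$effect_sd))

  truth <- data.frame(
    gene = planted,
    direction = c(rep("up", n_up), rep("down", n_down)),
    effect = unname(mu[planted]),
    stringsAsFactors = FALSE)

  batches <- vector("list", cfg$n_batches)
  for (b in seq_len(cfg$n_batches)) {
    np <- cfg$n_pairs_per_batch[b]
    mu_b <- mu
    if (cfg$effect_jitter_sd > 0 && length(planted) > 0L)
      mu_b[planted] <- mu_b[planted] +
        stats::rnorm(length(planted), 0, cfg$effect_jitter_sd)
    normal <- matrix(stats::rnorm(cfg$n_genes * np,
                                  cfg$baseline_mean, cfg$baseline_sd),
                     nrow = cfg$n_genes, ncol = np)
    noise <- matrix(stats::rnorm(cfg$n_genes * np, 0, cfg$noise_sd),
                    nrow = cfg$n_genes, ncol = np)
    diffs <- mu_b + noise
    tumor <- normal + diffs
    patients <- sprintf("B%dP%02d", b, seq_len(np))
    dimnames(diffs) <- list(genes, patients)
    dimnames(tumor) <- list(genes, patients)
    dimnames(normal) <- list(genes, patients)
    batches[[b]] <- paired_expression(diffs, batch = sprintf("batch%d", b),
                                      stage = stage,
                                      tumor = tumor, normal = normal)
  }
  structure(list(batches = batches, truth = truth, config = cfg),
            class = "paired_sim")
}

#' Simulate a protein-protein interaction network with planted communities
#'
#' Wires each planted gene set as a chain of overlapping k-cliques
#' (consecutive cliques share k-1 members), which guarantees the set forms
#' exactly one k-clique-percolation community, then adds background edges
#' independently with probability `background_p` between all remaining gene
#' pairs. No self-loops or duplicate edges are produced.
#'
#' @param genes character vector of node symbols.
#' @param planted list of gene sets (character vectors), each a subset of
#'   `genes` with at least `k` members.
#' @param k clique size used for the planted chains (>= 3).
#' @param background_p background edge probability in `[0, 1)`.
#' @param seed integer seed.
#' @return data.frame with columns `from`, `to` (each row an undirected edge,
#'   `from < to` lexicographically); zero rows when nothing is wired.
#' @export
simulate_ppi <- function(genes, planted = list(), k = 3L,
                         background_p = 0, seed = 1L) {
  k <- as.integer(k)
  if (k < 3L) stop("`k` must be >= 3", call. = FALSE)
  if (background_p < 0 || background_p >= 1)
    stop("`background_p` must lie in [0, 1)", call. = FALSE)
  genes <- as.character(genes)
  for (s in planted) {
    if (!all(s %in% genes))
      stop("planted sets must be subsets of `genes`", call. = FALSE)
    if (length(unique(s)) < k)
      stop("each planted set needs at least `k` distinct genes", call. = FALSE)
  }
  set.seed(as.integer(seed))

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  seen <- new.env(parent = emptyenv())
  from <- character(); to <- character()
  add_edge <- function(a, b) {
    key <- edge_key(a, b)
    if (a != b && !exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      from[[length(from) + 1L]] <<- min(a, b)
      to[[length(to) + 1L]] <<- max(a, b)
    }
  }

  for (s in planted) {
    s <- unique(s)
    n <- length(s)
    for (start in seq_len(max(1L, n - k + 1L))) {
      clique <- s[start:min(start + k - 1L, n)]
      pairs <- utils::combn(clique, 2L)
      for (j in seq_len(ncol(pairs))) add_edge(pairs[1L, j], pairs[2L, j])
    }
  }

  if (background_p > 0 && length(genes) >= 2L) {
    pairs <- utils::combn(sort(genes), 2L)
    draw <- stats::runif(ncol(pairs)) < background_p
    for (j in which(draw)) add_edge(pairs[1L, j], pairs[2L, j])
  }

  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Configuration for the per-batch drug enrichment-score simulator
#'
#' Study conditions for [simulate_drug_scores()]: each drug has a true
#' connectivity ("enrichment") score `true_rho` in (-1, 1); on the Fisher-z
#' scale a batch's observed score is Normal around atanh(true_rho) with
#' variance 1/(N-3) + tau2, i.e. sampling noise for a correlation measured on
#' N instances plus between-batch heterogeneity tau2.
#'
#' @param n_drugs number of drugs.
#' @param true_rho per-drug true score in (-1, 1); recycled to `n_drugs`.
#' @param n_instances per-drug, per-batch instance count N (>= 4); scalar or
#'   vector recycled to `n_drugs`. Defaults to 10, a realistic instance count
#'   for a connectivity-map compound.
#' @param tau2 between-batch variance of the true Fisher-z effect (>= 0).
#' @param seed integer seed.
#' @return An object of class `drug_sim_config`.
#' @export
drug_sim_config <- function(n_drugs = 50L, true_rho = 0,
                            n_instances = 10L, tau2 = 0, seed = 1L) {
  n_drugs <- as.integer(n_drugs)
  if (n_drugs < 1L) stop("`n_drugs` must be >= 1", call. = FALSE)
  true_rho <- rep_len(as.numeric(unlist(true_rho)), n_drugs)
  if (any(abs(true_rho) >= 1))
    stop("`true_rho` values must satisfy |rho| < 1", call. = FALSE)
  n_instances <- rep_len(as.integer(unlist(n_instances)), n_drugs)
  if (any(n_instances < 4L))
    stop("`n_instances` must be >= 4 (variance 1/(N-3) undefined below)",
         call. = FALSE)
  if (tau2 < 0) stop("`tau2` must be >= 0", call. = FALSE)
  structure(
    list(n_drugs = n_drugs, true_rho = true_rho,
         n_instances = n_instances, tau2 = tau2, seed = as.integer(seed)),
    class = "drug_sim_config")
}

#' Simulate per-batch drug enrichment-score tables
#'
#' For every drug and batch, draws an observed Fisher-z value
#' `z_obs ~ Normal(atanh(true_rho), 1/(N-3) + tau2)`, back-transforms it to a
#' score `es = tanh(z_obs)` (strictly inside (-1, 1)), and reports a
#' two-sided normal p-value for `z_obs / sqrt(1/(N-3))`, emulating the
#' drug-score tables a connectivity-map query returns per expression batch.
#'
#' @param cfg a [drug_sim_config()].
#' @param n_batches number of batches (one table each).
#' @param stage stage label attached to every table.
#' @return A list of data.frames (one per batch) with columns
#'   `drug`, `es`, `p`, `n`, `batch`, `stage`.
#' @export
simulate_drug_scores <- function(cfg, n_batches = 4L, stage = "early") {
  stopifnot(inherits(cfg, "drug_sim_config"))
  n_batches <- as.integer(n_batches)
  if (n_batches < 1L) stop("`n_batches` must be >= 1", call. = FALSE)
  set.seed(cfg$seed)
  drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  z_true <- atanh(cfg$true_rho)
  v_samp <- 1 / (cfg$n_instances - 3)
  out <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    z_obs <- stats::rnorm(cfg$n_drugs, z_true, sqrt(v_samp + cfg$tau2))
    out[[b]] <- data.frame(
      drug = drugs,
      es = tanh(z_obs),
      p = 2 * stats::pnorm(-abs(z_obs / sqrt(v_samp))),
      n = cfg$n_instances,
      batch = sprintf("batch%d", b),
      stage = stage,
      stringsAsFactors = FALSE)
  }
  out
}
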