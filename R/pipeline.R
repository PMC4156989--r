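#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Thresholds default to the workflow's canonical values: DEG selection at
#' adjusted p < 0.005, fold-change floor log2(50), clique sizes k = 3..5,
#' enrichment report threshold 0.05, candidate constraint es < 0, per-batch
#' p < 0.1, meta-analysis p < 0.05, heterogeneity criterion 0.1.
#'
#' Input `paths` entries (`expression` — vector of per-batch TSVs, `ppi`,
#' `gmt`, `drug_scores` — vector of per-batch TSVs, `targets`) are optional;
#' any input left unset is generated by the synthetic-data module using the
#' matching `simulate` sub-list (arguments of [sim_config()] /
#' [drug_sim_config()] plus `ppi = list(background_p =, n_planted =)`).
#'
#' @param config a named list of overrides, or the path of a YAML file
#'   containing one.
#' @param ... further overrides applied on top of `config`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' does not exist", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    stage = "early",
    deg_alpha = 0.005,
    fc_floor = log2(50),
    k = c(3L, 4L, 5L),
    ora_alpha = 0.05,
    es_max = 0,
    cmap_p_max = 0.1,
    ma_p_max = 0.05,
    het_p = 0.1,
    weighted = TRUE,
    paths = list(),
    simulate = list())
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, list(...))
  if (cfg$deg_alpha <= 0 || cfg$deg_alpha >= 1)
    stop("`deg_alpha` must lie in (0, 1)", call. = FALSE)
  if (cfg$fc_floor <= 0) stop("`fc_floor` must be positive", call. = FALSE)
  if (any(cfg$k < 3)) stop("clique sizes `k` must be >= 3", call. = FALSE)
  for (f in c("ora_alpha", "cmap_p_max", "ma_p_max", "het_p"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop(sprintf("`%s` must lie in (0, 1]", f), call. = FALSE)
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!all(file.exists(p)))
      stop(sprintf("configured path `paths$%s` does not exist: %s",
                   nm, paste(p[!file.exists(p)], collapse = ", ")),
           call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(fmt, ...) message(sprintf(paste0("[repometa] ", fmt), ...))

#' Run the stage-specific repositioning workflow
#'
#' Executes, in order: paired expression acquisition (read or simulate),
#' per-batch moderated-t differential expression with BH adjustment and
#' up/down selection, cross-batch intersection and fold-change flooring,
#' direction-specific PPI community detection by clique percolation,
#' over-representation analysis of the community-filtered gene sets,
#' candidate filtering and two meta-analysis routes over per-batch drug
#' scores (Fisher-z effect-size combination with heterogeneity-driven model
#' choice, and Fisher combined per-batch p-values), drug ranking, Jaccard
#' comparison of the two candidate lists, and optional target-gene mapping.
#' Every stage's table is written to `out_dir` as TSV, together with a
#' manifest recording the seed, the configuration hash and the package
#' version; rerunning with an identical configuration reproduces identical
#' files.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`degs`, `common`,
#'   `communities`, `census`, `ora`, `meta`, `drug_lists`, `jaccard`,
#'   `targets`, `manifest`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## --- expression ----------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$paths$expression)) {
    pipeline_log("reading %d expression batch(es)",
                 length(cfg$paths$expression))
    batches <- lapply(seq_along(cfg$paths$expression), function(i)
      read_expression_tsv(cfg$paths$expression[i],
                          batch = sprintf("batch%d", i), stage = cfg$stage))
  } else {
    sim_args <- utils::modifyList(
      list(n_genes = 300L, n_pairs_per_batch = c(8L, 10L, 12L),
           effect_mean = 2.5, noise_sd = 0.8, seed = cfg$seed),
      cfg$simulate$expression %||% list())
    pipeline_log("simulating expression (%d genes, %d batches)",
                 sim_args$n_genes, length(sim_args$n_pairs_per_batch))
    sim <- simulate_paired_expression(do.call(sim_config, sim_args),
                                      stage = cfg$stage)
    batches <- sim$batches
    truth <- sim$truth
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
  }

  ## --- differential expression --------------------------------------------
  pipeline_log("differential expression on %d batch(es)", length(batches))
  deg_tables <- lapply(batches, function(b) {
    rec <- moderated_t_paired(b)
    rec$p_adj <- adjust_pvalues(rec$p_raw)
    sel <- select_degs(rec, alpha = cfg$deg_alpha)
    rec$direction <- ifelse(rec$gene %in% sel$up, "up",
                            ifelse(rec$gene %in% sel$down, "down", "none"))
    write_tsv(rec, file.path(out_dir, sprintf("deg_%s.tsv", b$batch)))
    list(records = rec, sel = sel)
  })
  common <- common_degs(lapply(deg_tables, `[[`, "sel"))
  pipeline_log("common DEGs: %d up, %d down",
               length(common$up), length(common$down))

  # exported signature: mean cross-batch fold change, floored in magnitude
  fc_mat <- vapply(deg_tables, function(d)
    stats::setNames(d$records$log2fc, d$records$gene)[c(common$up, common$down)],
    numeric(length(common$up) + length(common$down)))
  sig <- data.frame(
    gene = c(common$up, common$down),
    direction = c(rep("up", length(common$up)),
                  rep("down", length(common$down))),
    log2fc = clamp_fold_change(rowMeans(as.matrix(fc_mat)),
                               floor = cfg$fc_floor),
    stringsAsFactors = FALSE)
  write_tsv(sig, file.path(out_dir, "signature.tsv"))
  write_tsv(data.frame(gene = common$up), file.path(out_dir, "common_up.tsv"))
  write_tsv(data.frame(gene = common$down),
            file.path(out_dir, "common_down.tsv"))

  ## --- PPI and communities -------------------------------------------------
  all_genes <- batches[[1L]]$genes
  if (!is.null(cfg$paths$ppi)) {
    edges <- read_edgelist_tsv(cfg$paths$ppi)
  } else {
    ppi_args <- utils::modifyList(list(background_p = 0.005, n_planted = 8L),
                                  cfg$simulate$ppi %||% list())
    planted <- list()
    if (!is.null(truth)) {
      tu <- truth$gene[truth$direction == "up"]
      td <- truth$gene[truth$direction == "down"]
      if (length(tu) >= 3L)
        planted <- c(planted, list(utils::head(tu, ppi_args$n_planted)))
      if (length(td) >= 3L)
        planted <- c(planted, list(utils::head(td, ppi_args$n_planted)))
    }
    pipeline_log("simulating PPI (%d planted set(s), background_p=%g)",
                 length(planted), ppi_args$background_p)
    edges <- simulate_ppi(all_genes, planted = planted, k = min(cfg$k),
                          background_p = ppi_args$background_p,
                          seed = cfg$seed + 1L)
    write_edgelist_tsv(edges, file.path(out_dir, "ppi.tsv"))
  }
  ppi <- ppi_network(edges)

  communities <- list()
  for (dir_ in c("up", "down")) {
    sub <- induce_direction_subgraph(ppi, common[[dir_]])
    for (kk in cfg$k)
      communities <- c(communities,
                       clique_percolation(sub, k = kk, direction = dir_,
                                          stage = cfg$stage))
  }
  census <- community_census(communities)
  write_communities_tsv(communities, file.path(out_dir, "communities.tsv"))
  write_tsv(census, file.path(out_dir, "census.tsv"))
  filtered <- list(
    up = filter_to_community_genes(common$up, communities),
    down = filter_to_community_genes(common$down, communities))
  pipeline_log("community-filtered genes: %d up, %d down",
               length(filtered$up), length(filtered$down))

  ## --- enrichment ----------------------------------------------------------
  ora_res <- list()
  gmt <- NULL
  if (!is.null(cfg$paths$gmt)) {
    gmt <- read_gmt(cfg$paths$gmt)
  } else if (!is.null(truth)) {
    # synthetic collection: the planted direction sets plus random decoys
    set.seed(cfg$seed + 2L)
    gmt <- c(list(PLANTED_UP = truth$gene[truth$direction == "up"],
                  PLANTED_DOWN = truth$gene[truth$direction == "down"]),
             stats::setNames(lapply(1:8, function(i)
               sample(all_genes, 25L)), sprintf("DECOY_%02d", 1:8)))
  }
  if (!is.null(gmt)) {
    coll <- gene_set_collection(gmt, background = all_genes)
    for (dir_ in c("up", "down")) {
      if (length(filtered[[dir_]]) == 0L) next
      res <- ora(filtered[[dir_]], coll, alpha = cfg$ora_alpha)
      ora_res[[dir_]] <- res
      write_tsv(res, file.path(out_dir, sprintf("ora_%s.tsv", dir_)))
    }
  }

  ## --- drug scores and meta-analysis --------------------------------------
  if (!is.null(cfg$paths$drug_scores)) {
    score_tables <- lapply(cfg$paths$drug_scores, read_drug_scores_tsv)
  } else {
    ds_args <- utils::modifyList(
      list(n_drugs = 30L,
           true_rho = c(rep(-0.6, 5L), rep(0, 25L)),
           n_instances = 10L, tau2 = 0.05, seed = cfg$seed + 3L),
      cfg$simulate$drug_scores %||% list())
    pipeline_log("simulating drug scores (%d drugs, %d batches)",
                 ds_args$n_drugs, length(batches))
    score_tables <- simulate_drug_scores(do.call(drug_sim_config, ds_args),
                                         n_batches = length(batches),
                                         stage = cfg$stage)
    for (i in seq_along(score_tables))
      write_drug_scores_tsv(score_tables[[i]],
                            file.path(out_dir,
                                      sprintf("drug_scores_batch%d.tsv", i)))
  }
  scores <- do.call(rbind, score_tables)

  # route 1: effect-size meta-analysis under the es < es_max constraint
  es_cand <- filter_candidates(scores, es_max = cfg$es_max)
  meta <- meta_analyze(es_cand, weighted = cfg$weighted, het_p = cfg$het_p)
  write_tsv(meta, file.path(out_dir, "meta.tsv"))
  list_es <- rank_by_meta(meta, ma_p_max = cfg$ma_p_max)

  # route 2: Fisher combination of per-batch p-values under es < es_max
  # and p < cmap_p_max
  p_cand <- filter_candidates(scores, es_max = cfg$es_max,
                              cmap_p_max = cfg$cmap_p_max)
  fct <- lapply(split(p_cand, p_cand$drug), function(d)
    data.frame(label = d$drug[1L], k_studies = nrow(d),
               F = fisher_combined_test(d$p)$F,
               p_combined = fisher_combined_test(d$p)$p,
               stringsAsFactors = FALSE))
  fct <- if (length(fct)) do.call(rbind, fct)
         else data.frame(label = character(), k_studies = integer(),
                         F = numeric(), p_combined = numeric())
  fct <- fct[order(fct$p_combined, fct$label), , drop = FALSE]
  rownames(fct) <- NULL
  write_tsv(fct, file.path(out_dir, "fisher_combined.tsv"))
  keep <- fct$p_combined < cfg$ma_p_max
  list_p <- fct$label[keep][order(fct$p_combined[keep], fct$label[keep])]

  drug_lists <- list(ES = list_es, cMapP = list_p)
  write_tsv(data.frame(drug = list_es), file.path(out_dir, "drugs_es.tsv"))
  write_tsv(data.frame(drug = list_p), file.path(out_dir, "drugs_cmapp.tsv"))
  jac <- pairwise_jaccard_matrix(drug_lists)
  jd <- as.data.frame(jac$display)
  jd <- cbind(list = rownames(jd), jd)
  write_tsv(jd, file.path(out_dir, "jaccard.tsv"))
  pipeline_log("candidates: %d (effect size), %d (combined p); JI = %.3f",
               length(list_es), length(list_p), jac$jaccard[1L, 2L])

  ## --- targets -------------------------------------------------------------
  targets <- NULL
  if (!is.null(cfg$paths$targets)) {
    tt <- read_drug_targets_tsv(cfg$paths$targets)
    targets <- map_targets(union(list_es, list_p), tt,
                           up_genes = filtered$up, down_genes = filtered$down)
    write_tsv(targets$by_drug, file.path(out_dir, "targets.tsv"))
    write_tsv(targets$counts, file.path(out_dir, "target_counts.tsv"))
    nb <- export_neighbor_network(
      c(targets$up_genes, targets$down_genes), ppi)
    write_tsv(nb, file.path(out_dir, "target_neighbors.tsv"))
  }

  ## --- manifest ------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- data.frame(
    field = c("config_md5", "seed", "stage", "package_version"),
    value = c(unname(tools::md5sum(cfg_path)), cfg$seed, cfg$stage,
              as.character(utils::packageVersion("repometa"))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(degs = deg_tables, common = common,
                 communities = communities, census = census, ora = ora_res,
                 meta = meta, fisher_combined = fct,
                 drug_lists = drug_lists, jaccard = jac,
                 targets = targets, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
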