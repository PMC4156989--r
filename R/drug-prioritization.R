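#' Filter per-batch drug records by score sign and p-value
#'
#' Signature-reversing candidates must have a strictly negative enrichment
#' score (`es < es_max`, default 0) and, when `cmap_p_max` is given, a
#' per-batch p-value strictly below it.
#'
#' @param scores data.frame with columns `es` and (if `cmap_p_max` is used)
#'   `p`.
#' @param es_max strict upper bound on the score (default 0).
#' @param cmap_p_max optional strict upper bound on the per-batch p-value.
#' @return The qualifying rows of `scores`.
#' @export
filter_candidates <- function(scores, es_max = 0, cmap_p_max = NULL) {
  stopifnot(is.data.frame(scores), "es" %in% names(scores))
  keep <- scores$es < es_max
  if (!is.null(cmap_p_max)) {
    stopifnot("p" %in% names(scores))
    keep <- keep & scores$p < cmap_p_max
  }
  scores[keep, , drop = FALSE]
}

#' Rank drugs by meta-analysis p-value
#'
#' @param meta data.frame from [meta_analyze()] (columns `label`,
#'   `p_one_tailed`).
#' @param ma_p_max strict threshold on the combined p (default 0.05).
#' @return Character vector of drug names ordered by ascending p, ties broken
#'   lexicographically; empty when nothing passes.
#' @export
rank_by_meta <- function(meta, ma_p_max = 0.05) {
  stopifnot(is.data.frame(meta),
            all(c("label", "p_one_tailed") %in% names(meta)))
  keep <- meta[meta$p_one_tailed < ma_p_max, , drop = FALSE]
  keep$label[order(keep$p_one_tailed, keep$label)]
}

#' Jaccard index of two sets
#'
#' |A intersect B| / |A union B|; defined as 0 when both sets are empty.
#'
#' @param A,B character vectors (treated as sets).
#' @return Value in `[0, 1]`.
#' @export
jaccard_index <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) return(0)
  length(intersect(A, B)) / u
}

#' Pairwise intersection counts and Jaccard indices for drug lists
#'
#' Produces the triangular comparison layout used to compare stage- and
#' effect-size-specific candidate lists: intersection counts below the
#' diagonal, Jaccard indices above, diagonal NA.
#'
#' @param lists named list (>= 2) of character vectors.
#' @return list of class `jaccard_matrix` with matrices `count`, `jaccard`
#'   (both full symmetric) and `display` (counts lower / JI upper / NA
#'   diagonal).
#' @export
pairwise_jaccard_matrix <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L,
            !is.null(names(lists)), all(nzchar(names(lists))))
  n <- length(lists)
  cnt <- matrix(0L, n, n, dimnames = list(names(lists), names(lists)))
  ji <- matrix(0, n, n, dimnames = dimnames(cnt))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt[i, j] <- length(intersect(unique(lists[[i]]), unique(lists[[j]])))
    ji[i, j] <- jaccard_index(lists[[i]], lists[[j]])
  }
  disp <- matrix(NA_real_, n, n, dimnames = dimnames(cnt))
  disp[lower.tri(disp)] <- cnt[lower.tri(cnt)]
  disp[upper.tri(disp)] <- ji[upper.tri(ji)]
  structure(list(count = cnt, jaccard = ji, display = disp),
            class = "jaccard_matrix")
}

#' @export
print.jaccard_matrix <- function(x, digits = 3, ...) {
  cat("Drug-list comparison (lower: common drugs, upper: Jaccard index)\n")
  print(round(x$display, digits))
  invisible(x)
}

normalize_symbols <- function(x) toupper(trimws(as.character(x)))

#' Map candidate drugs to up/down community target genes
#'
#' For each drug, intersects its known target genes with the up- and
#' downregulated community gene sets. Drug names and gene symbols are
#' case-insensitively normalized; a drug absent from the target table yields
#' empty target sets with a warning.
#'
#' @param drugs character vector of candidate drug names.
#' @param targets data.frame with columns `drug` and `gene` (one target per
#'   row).
#' @param up_genes,down_genes direction-specific community gene sets.
#' @return list with:
#'   \describe{
#'     \item{by_drug}{data.frame `drug`, `direction` (up/down), `gene`.}
#'     \item{counts}{data.frame `drug`, `n_up`, `n_down`.}
#'     \item{up_genes,down_genes}{sorted unique target genes per direction,
#'       aggregated over all drugs (each gene counted once).}
#'   }
#' @export
map_targets <- function(drugs, targets, up_genes, down_genes) {
  stopifnot(is.data.frame(targets),
            all(c("drug", "gene") %in% names(targets)))
  drugs_norm <- normalize_symbols(drugs)
  tab <- split(normalize_symbols(targets$gene),
               normalize_symbols(targets$drug))
  up_genes <- normalize_symbols(up_genes)
  down_genes <- normalize_symbols(down_genes)

  rows <- list(); counts <- list()
  for (i in seq_along(drugs_norm)) {
    d <- drugs_norm[i]
    tg <- unique(tab[[d]])
    if (is.null(tg)) {
      warning(sprintf("drug '%s' absent from the target table", drugs[i]),
              call. = FALSE)
      tg <- character()
    }
    up_hit <- sort(intersect(tg, up_genes))
    down_hit <- sort(intersect(tg, down_genes))
    if (length(up_hit) + length(down_hit) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d,
        direction = c(rep("up", length(up_hit)),
                      rep("down", length(down_hit))),
        gene = c(up_hit, down_hit), stringsAsFactors = FALSE)
    counts[[i]] <- data.frame(drug = d, n_up = length(up_hit),
                              n_down = length(down_hit),
                              stringsAsFactors = FALSE)
  }
  by_drug <- if (length(rows)) do.call(rbind, rows)
             else data.frame(drug = character(), direction = character(),
                             gene = character(), stringsAsFactors = FALSE)
  list(by_drug = by_drug,
       counts = do.call(rbind, counts),
       up_genes = sort(unique(by_drug$gene[by_drug$direction == "up"])),
       down_genes = sort(unique(by_drug$gene[by_drug$direction == "down"])))
}

#' Export target genes with their first-degree PPI partners
#'
#' Collects every network edge incident to a target gene, annotating each
#' endpoint as `target` or `partner` — the plain-text counterpart of a
#' target-neighborhood network figure. Targets without any incident edge are
#' emitted as isolated-node rows (`to = NA`).
#'
#' @param target_genes character vector of target genes.
#' @param ppi an `igraph` network ([ppi_network()]).
#' @return data.frame with columns `from`, `to`, `from_role`, `to_role`.
#' @export
export_neighbor_network <- function(target_genes, ppi) {
  stopifnot(inherits(ppi, "igraph"))
  target_genes <- unique(as.character(target_genes))
  present <- intersect(target_genes, igraph::V(ppi)$name)
  role <- function(g) ifelse(g %in% target_genes, "target", "partner")

  rows <- list()
  if (length(present) > 0L) {
    inc <- igraph::incident_edges(ppi, present)
    seen <- character()
    for (i in seq_along(present)) {
      ends <- igraph::ends(ppi, inc[[i]])
      for (j in seq_len(nrow(ends))) {
        a <- ends[j, 1L]; b <- ends[j, 2L]
        key <- paste(min(a, b), max(a, b))
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- data.frame(
          from = a, to = b, from_role = role(a), to_role = role(b),
          stringsAsFactors = FALSE)
      }
    }
  }
  deg <- if (length(present)) igraph::degree(ppi, present) else integer()
  isolated <- c(setdiff(target_genes, present), present[deg == 0L])
  for (g in sort(isolated))
    rows[[length(rows) + 1L]] <- data.frame(
      from = g, to = NA_character_, from_role = "target",
      to_role = NA_character_, stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    return(data.frame(from = character(), to = character(),
                      from_role = character(), to_role = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
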