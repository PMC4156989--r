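# TSV readers/writers for the pipeline's external interfaces. All tables are
# tab-separated with a header row, no quoting and no row names, so outputs
# are diffable and byte-stable across reruns.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write one batch of paired expression to TSV
#'
#' Layout: first column `gene`, then paired columns `<patient>_T` /
#' `<patient>_N` of tumor and normal log2 intensities.
#'
#' @param expr a [paired_expression()] carrying `tumor` and `normal`
#'   matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "paired_expression"))
  if (is.null(expr$tumor) || is.null(expr$normal))
    stop("this paired_expression has no tumor/normal matrices to write",
         call. = FALSE)
  patients <- colnames(expr$tumor)
  out <- data.frame(gene = expr$genes, stringsAsFactors = FALSE)
  for (p in patients) {
    out[[paste0(p, "_T")]] <- expr$tumor[, p]
    out[[paste0(p, "_N")]] <- expr$normal[, p]
  }
  write_tsv(out, path)
}

#' Read one batch of paired expression from TSV
#'
#' Expects the [write_expression_tsv()] layout; patient pairing is inferred
#' from the matched `_T` / `_N` column suffixes.
#'
#' @param path input file.
#' @param batch,stage labels for the resulting object.
#' @return A [paired_expression()].
#' @export
read_expression_tsv <- function(path, batch = "batch1", stage = "early") {
  x <- read_tsv(path)
  if (names(x)[1L] != "gene") stop("first column must be `gene`", call. = FALSE)
  tcols <- grep("_T$", names(x), value = TRUE)
  patients <- sub("_T$", "", tcols)
  ncols <- paste0(patients, "_N")
  if (!all(ncols %in% names(x)))
    stop("unmatched tumor/normal column pairs", call. = FALSE)
  tumor <- as.matrix(x[, tcols, drop = FALSE])
  normal <- as.matrix(x[, ncols, drop = FALSE])
  dimnames(tumor) <- dimnames(normal) <- list(x$gene, patients)
  paired_expression(tumor - normal, batch = batch, stage = stage,
                    tumor = tumor, normal = normal)
}

#' Write / read a planted-truth table (gene, direction, effect)
#' @param truth data.frame as produced by [simulate_paired_expression()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_truth_tsv <- function(truth, path) write_tsv(truth, path)

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) read_tsv(path)

#' Write / read an undirected PPI edge list (two-column TSV)
#' @param edges data.frame with columns `from`, `to`.
#' @param path file path.
#' @return `path` (write) or the edge data.frame (read).
#' @export
write_edgelist_tsv <- function(edges, path) write_tsv(edges, path)

#' @rdname write_edgelist_tsv
#' @export
read_edgelist_tsv <- function(path) {
  x <- read_tsv(path)
  if (ncol(x) < 2L) stop("edge list needs two columns", call. = FALSE)
  names(x)[1:2] <- c("from", "to")
  x
}

#' Write / read per-batch drug score tables (drug, es, p, n, batch, stage)
#' @param scores data.frame of drug scores.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_drug_scores_tsv <- function(scores, path) write_tsv(scores, path)

#' @rdname write_drug_scores_tsv
#' @export
read_drug_scores_tsv <- function(path) {
  x <- read_tsv(path)
  need <- c("drug", "es")
  if (!all(need %in% names(x)))
    stop("drug score table needs at least columns `drug` and `es`",
         call. = FALSE)
  x
}

#' Read a drug-to-target-gene table (columns `drug`, `gene`)
#' @param path file path.
#' @return data.frame with columns `drug`, `gene`.
#' @export
read_drug_targets_tsv <- function(path) {
  x <- read_tsv(path)
  if (!all(c("drug", "gene") %in% names(x)))
    stop("target table needs columns `drug` and `gene`", call. = FALSE)
  x
}

#' Write communities to a long-format TSV
#'
#' One row per (community, member): `community_id`, `k`, `direction`,
#' `stage`, `member`.
#'
#' @param communities list of `k_community` objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_communities_tsv <- function(communities, path) {
  if (length(communities) == 0L) {
    return(write_tsv(data.frame(community_id = integer(), k = integer(),
                                direction = character(), stage = character(),
                                member = character()), path))
  }
  rows <- lapply(seq_along(communities), function(i) {
    cm <- communities[[i]]
    data.frame(community_id = i, k = cm$k, direction = cm$direction,
               stage = cm$stage, member = cm$members,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
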