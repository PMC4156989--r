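#' Gene-set collection restricted to a background universe
#'
#' @param sets named list of character vectors (pathway name -> members).
#' @param background character vector: the gene universe (for microarray
#'   work, all genes on the platform). Members outside the background are
#'   dropped; sets left empty after restriction are removed.
#' @return An object of class `gene_set_collection` with elements `sets` and
#'   `background`.
#' @export
gene_set_collection <- function(sets, background) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  background <- unique(as.character(background))
  restricted <- lapply(sets, function(s) intersect(unique(s), background))
  empty <- lengths(restricted) == 0L
  if (any(empty) && length(restricted) > sum(empty))
    restricted <- restricted[!empty]
  if (all(lengths(restricted) == 0L))
    stop("no gene set overlaps the background universe", call. = FALSE)
  structure(list(sets = restricted, background = background),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols.
#'
#' @param path file path.
#' @return Named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): fewer than 3 fields",
                     call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Over-representation analysis
#'
#' Fisher-exact-style enrichment of a query gene set against every pathway in
#' a collection: the p-value is the one-sided hypergeometric tail
#' P(overlap >= observed) given the pathway's effective size within the
#' background, the query size, and the background size. P-values are BH
#' adjusted across all pathways tested, then rows with `p_raw < alpha` are
#' returned ranked by ascending `p_raw`.
#'
#' @param query character vector of genes. Genes outside the collection's
#'   background are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @param alpha raw-p report threshold (default 0.05).
#' @return data.frame with columns `pathway`, `count` (overlap size),
#'   `percent` (overlap / query size x 100), `effective_size` (pathway size
#'   in background), `p_raw`, `p_adj`; sorted by `p_raw` then name.
#' @export
ora <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$background)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the background were dropped",
                    length(outside)), call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L)
    stop("query is empty after restriction to the background", call. = FALSE)

  nb <- length(collection$background)
  nq <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    ov <- length(intersect(query, members))
    ksz <- length(members)
    p <- stats::phyper(ov - 1L, ksz, nb - ksz, nq, lower.tail = FALSE)
    data.frame(pathway = nm, count = ov, percent = 100 * ov / nq,
               effective_size = ksz, p_raw = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  res <- res[res$p_raw < alpha, , drop = FALSE]
  res <- res[order(res$p_raw, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}
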