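#' Build an undirected PPI network from an edge list
#'
#' @param edges data.frame whose first two columns are interacting gene
#'   symbols (one undirected edge per row). Self-loops and duplicate edges
#'   are dropped.
#' @return An `igraph` object (undirected, simple).
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  if (nrow(edges) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Induce the direction-specific PPI subnetwork
#'
#' Keeps only edges whose BOTH endpoints belong to the given
#' direction-specific DEG set (e.g. the "up PPI" over upregulated genes).
#'
#' @param ppi an `igraph` network from [ppi_network()].
#' @param genes character vector of gene symbols.
#' @return The induced `igraph` subgraph.
#' @export
induce_direction_subgraph <- function(ppi, genes) {
  stopifnot(inherits(ppi, "igraph"))
  keep <- intersect(igraph::V(ppi)$name, genes)
  igraph::induced_subgraph(ppi, keep)
}

#' Clique-percolation communities
#'
#' Standard k-clique percolation: every clique of size exactly k is
#' enumerated; two k-cliques are adjacent when they share k-1 nodes;
#' communities are the node unions of connected components of this
#' clique-adjacency relation. Communities may overlap in nodes. Adjacency is
#' resolved by hashing each clique's (k-1)-subsets — two distinct k-cliques
#' share k-1 nodes exactly when they share a (k-1)-subset — and merging with
#' union-find.
#'
#' @param g an `igraph` network.
#' @param k clique size (>= 3).
#' @param direction,stage optional labels attached to every community.
#' @param max_nodes guard on network size (clique enumeration is
#'   exponential in the worst case); default 10000.
#' @return List of `k_community` objects (fields `k`, `members` sorted,
#'   `direction`, `stage`), ordered by decreasing size then lexicographically
#'   smallest member.
#' @export
clique_percolation <- function(g, k = 3L, direction = NA_character_,
                               stage = NA_character_, max_nodes = 10000L) {
  stopifnot(inherits(g, "igraph"))
  k <- as.integer(k)
  if (k < 3L) stop("`k` must be >= 3", call. = FALSE)
  if (igraph::vcount(g) > max_nodes)
    stop("network exceeds `max_nodes` guard for clique enumeration",
         call. = FALSE)
  if (igraph::vcount(g) < k) return(list())

  cl <- igraph::cliques(g, min = k, max = k)
  if (length(cl) == 0L) return(list())
  members <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))

  # union-find over cliques
  parent <- seq_along(members)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }

  subset_owner <- new.env(parent = emptyenv(), size = length(members) * k)
  for (i in seq_along(members)) {
    m <- members[[i]]
    for (drop in seq_len(k)) {
      key <- paste(m[-drop], collapse = "\r")
      j <- get0(key, envir = subset_owner, inherits = FALSE)
      if (is.null(j)) assign(key, i, envir = subset_owner) else union2(i, j)
    }
  }

  roots <- vapply(seq_along(members), find, integer(1))
  comps <- split(seq_along(members), roots)
  comms <- lapply(comps, function(idx)
    structure(list(k = k,
                   members = sort(unique(unlist(members[idx]))),
                   direction = direction, stage = stage),
              class = "k_community"))
  sizes <- vapply(comms, function(cm) length(cm$members), integer(1))
  firsts <- vapply(comms, function(cm) cm$members[1L], character(1))
  unname(comms[order(-sizes, firsts)])
}

#' @export
print.k_community <- function(x, ...) {
  cat(sprintf("k=%d community (%s/%s), %d genes: %s\n", x$k,
              x$direction, x$stage, length(x$members),
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Community census
#'
#' Counts communities and distinct member genes per (k, direction), the
#' summary layout used to report how many k-communities each direction group
#' yields.
#'
#' @param communities list of `k_community` objects.
#' @return data.frame with columns `k`, `direction`, `n_communities`,
#'   `n_distinct_genes`; zero rows when there are no communities.
#' @export
community_census <- function(communities) {
  if (length(communities) == 0L)
    return(data.frame(k = integer(), direction = character(),
                      n_communities = integer(), n_distinct_genes = integer(),
                      stringsAsFactors = FALSE))
  key <- vapply(communities, function(cm)
    paste(cm$k, cm$direction, sep = "\r"), character(1))
  groups <- split(communities, key)
  rows <- lapply(groups, function(gr)
    data.frame(k = gr[[1]]$k, direction = gr[[1]]$direction,
               n_communities = length(gr),
               n_distinct_genes = length(unique(unlist(
                 lapply(gr, `[[`, "members")))),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$k, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a DEG set to community members
#'
#' Genes outside every community are considered weakly connected and dropped
#' before enrichment and drug querying.
#'
#' @param degs character vector of DEGs.
#' @param communities list of `k_community` objects.
#' @return Character vector: `degs` intersected with the union of community
#'   members (sorted).
#' @export
filter_to_community_genes <- function(degs, communities) {
  pool <- unique(c(character(), unlist(lapply(communities, `[[`, "members"))))
  sort(intersect(as.character(degs), pool))
}
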