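# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration / straight loops over the defining
# formulas) and share no code with the package internals.

# Brute-force k-clique percolation on an adjacency matrix with named
# vertices: enumerate every k-subset, keep complete ones, link pairs of
# k-cliques sharing exactly k-1 vertices, and read communities off the
# connected components of that clique graph.
oracle_cpm <- function(adj, k) {
  n <- nrow(adj)
  vnames <- rownames(adj)
  if (n < k) return(list())
  subsets <- utils::combn(n, k)
  is_clique <- logical(ncol(subsets))
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    is_clique[j] <- sum(adj[idx, idx]) == k * (k - 1)
  }
  cl <- subsets[, is_clique, drop = FALSE]
  m <- ncol(cl)
  if (m == 0L) return(list())
  # clique adjacency by (k-1)-overlap
  link <- matrix(FALSE, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a < b && length(intersect(cl[, a], cl[, b])) == k - 1L)
      link[a, b] <- link[b, a] <- TRUE
  }
  # connected components by BFS
  comp <- rep(NA_integer_, m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(link[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lapply(split(seq_len(m), comp), function(idx)
    sort(unique(vnames[as.vector(cl[, idx, drop = FALSE])])))
}

# canonical form of a community list for set-of-sets comparison
canon_communities <- function(comms) {
  sort(unname(vapply(comms, function(m)
    paste(sort(m), collapse = ","), character(1))))
}

members_of <- function(comms) lapply(comms, `[[`, "members")

# random test graph as both igraph and adjacency matrix
random_named_graph <- function(n, p) {
  vnames <- sprintf("v%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(vnames, vnames))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(g = g, adj = adj)
}

# Straight-from-formula meta-analysis oracle: plain loops, no vectorization.
oracle_meta <- function(Y, V) {
  k <- length(Y)
  sw <- 0; swy <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    w <- 1 / V[i]
    sw <- sw + w
    swy <- swy + w * Y[i]
    sw2 <- sw2 + w^2
  }
  M <- swy / sw
  V_M <- 1 / sw
  Z <- M / sqrt(V_M)
  Q <- 0
  for (i in seq_len(k)) Q <- Q + (1 / V[i]) * (Y[i] - M)^2
  df <- k - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  C <- sw - sw2 / sw
  tau2 <- max(0, (Q - df) / C)
  swr <- 0; swyr <- 0
  for (i in seq_len(k)) {
    w <- 1 / (V[i] + tau2)
    swr <- swr + w
    swyr <- swyr + w * Y[i]
  }
  list(M = M, V_M = V_M, Z = Z, Q = Q, I2 = I2, tau2 = tau2,
       M_random = swyr / swr, V_M_random = 1 / swr)
}

# Exhaustive hypergeometric tail: over all C(nb, nq) equally likely query
# draws from a background of size nb whose first ksz genes form the pathway,
# the probability that the overlap is at least `ov`.
oracle_hyper_tail <- function(nb, ksz, nq, ov) {
  draws <- utils::combn(nb, nq)
  hits <- 0L
  for (j in seq_len(ncol(draws))) {
    if (sum(draws[, j] <= ksz) >= ov) hits <- hits + 1L
  }
  hits / ncol(draws)
}
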