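#' Spearman co-occurrence network
#'
#' Builds an undirected simple graph over taxa: an edge joins two taxa when
#' the Spearman correlation of their relative abundances across the
#' stratum's samples satisfies r > `r_min` and P < `p_max` (both strict;
#' positive correlations only). P-values use the large-sample t
#' approximation \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom.
#' Constant taxa are excluded with a warning; isolated nodes are dropped.
#'
#' @param table a [feature_table()] or samples x taxa count matrix (>= 4
#'   samples); correlations are computed on relative abundances.
#' @param r_min correlation threshold (default 0.6).
#' @param p_max significance threshold (default 0.05).
#' @return A `co_network`: list with `graph` (igraph object) and `edges`
#'   (data.frame node_a, node_b, spearman_r, p_value).
#' @export
build_network <- function(table, r_min = 0.6, p_max = 0.05) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  if (nrow(counts) < 4L) stop("build_network needs at least 4 samples")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  ra <- counts / rowSums(counts)
  const <- apply(ra, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning(sum(const), " constant taxa excluded from correlation")
    ra <- ra[, !const, drop = FALSE]
  }
  n <- nrow(ra)
  r <- stats::cor(ra, method = "spearman")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  keep <- r > r_min & p < p_max
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(node_a = colnames(ra)[idx[, 1]],
                      node_b = colnames(ra)[idx[, 2]],
                      spearman_r = r[idx], p_value = p[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  if (nrow(edges)) igraph::E(g)$weight <- edges$spearman_r
  structure(list(graph = g, edges = edges), class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

as_graph <- function(net) {
  if (inherits(net, "co_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a co_network or igraph object")
}

# local clustering with the degree<2 -> 0 convention
local_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[igraph::degree(g) < 2] <- 0
  cc
}

#' Network topology summary
#'
#' Modularity from greedy Louvain community detection (best of `n_restarts`
#' seeded restarts), average degree 2E/N, and mean local clustering
#' coefficient (nodes of degree < 2 contribute 0). Modularity above roughly
#' 0.4 is conventionally read as a modular network.
#'
#' @param net a `co_network` or igraph graph.
#' @param seed integer seed for the community-detection restarts.
#' @param n_restarts Louvain restarts to take the best partition from.
#' @return A list of class `topology_summary`: `modularity`,
#'   `average_degree`, `clustering_coefficient`, `n_nodes`, `n_edges`.
#' @export
topology <- function(net, seed = 1L, n_restarts = 10L) {
  g <- as_graph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    warning("empty network")
    return(structure(list(modularity = NaN, average_degree = NaN,
                          clustering_coefficient = NaN,
                          n_nodes = 0L, n_edges = 0L),
                     class = "topology_summary"))
  }
  gu <- g
  if (!is.null(igraph::E(gu)$weight)) gu <- igraph::delete_edge_attr(gu, "weight")
  best <- -Inf
  set.seed(seed)
  for (i in seq_len(n_restarts)) {
    cl <- igraph::cluster_louvain(gu)
    q <- igraph::modularity(cl)
    if (q > best) best <- q
  }
  structure(list(modularity = best,
                 average_degree = 2 * e / n,
                 clustering_coefficient = mean(local_clustering(g)),
                 n_nodes = n, n_edges = e),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    "topology: %d nodes, %d edges, modularity=%.3f, avg degree=%.2f, clustering=%.3f\n",
    x$n_nodes, x$n_edges, x$modularity, x$average_degree,
    x$clustering_coefficient))
  invisible(x)
}

#' Compare node-level distributions of two networks
#'
#' Two-sample Kolmogorov-Smirnov tests on the per-node degree distribution
#' and, separately, on the local clustering distribution, with asymptotic
#' P-values.
#'
#' @param net_a,net_b `co_network` or igraph objects with >= 2 nodes each.
#' @return data.frame with rows `degree` and `clustering`: `statistic`
#'   (KS D) and `p_value`.
#' @export
compare_degree_distributions <- function(net_a, net_b) {
  ga <- as_graph(net_a); gb <- as_graph(net_b)
  if (igraph::vcount(ga) < 2L || igraph::vcount(gb) < 2L)
    stop("both networks need at least 2 nodes")
  ks <- function(x, y) {
    t <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    c(unname(t$statistic), t$p.value)
  }
  deg <- ks(igraph::degree(ga), igraph::degree(gb))
  cc <- ks(local_clustering(ga), local_clustering(gb))
  data.frame(property = c("degree", "clustering"),
             statistic = c(deg[1], cc[1]), p_value = c(deg[2], cc[2]),
             stringsAsFactors = FALSE)
}

# h-index of a vector of neighbour degrees
h_index <- function(v) {
  if (!length(v)) return(0)
  v <- sort(v, decreasing = TRUE)
  sum(v >= seq_along(v))
}

range_scale <- function(x, lo, hi) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(lo, length(x)))
  lo + (hi - lo) * (x - rng[1]) / diff(rng)
}

#' Integrated Value of Influence (IVI)
#'
#' Composite node-influence score in \[0, 1\] combining six centrality
#' components: degree, local H-index (h-index of neighbour degrees),
#' neighbourhood connectivity (mean neighbour degree), ClusterRank
#' \eqn{s_i = 10^{-c_i} \sum_{j \in \Gamma(i)} (k_j + 1)} with \eqn{c_i}
#' the local clustering coefficient, betweenness centrality, and collective
#' influence \eqn{CI_i = (k_i - 1) \sum_{j : d(i,j) = \ell} (k_j - 1)} at
#' radius \eqn{\ell} = `ci_radius`. Each component is min-max scaled to
#' \[1, 100\]; Hubness = degree + H-index, Spreading = (neighbourhood
#' connectivity + ClusterRank) x (betweenness + collective influence);
#' IVI = Hubness x Spreading, min-max scaled to \[0, 1\] (1 = most
#' influential node). When all raw IVI values are equal (e.g. a complete or
#' two-node graph) every node scores 1 by convention.
#'
#' @param net a `co_network` or igraph object.
#' @param ci_radius path length for collective influence (default 2).
#' @return data.frame of class `ivi_scores`: node, the six raw components,
#'   and `ivi`.
#' @export
ivi <- function(net, ci_radius = 2L) {
  g <- as_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("ivi needs at least 2 nodes")
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  hind <- vapply(adj, function(nb) h_index(deg[as.integer(nb)]), numeric(1))
  ncon <- vapply(adj, function(nb)
    if (length(nb)) mean(deg[as.integer(nb)]) else 0, numeric(1))
  cc <- local_clustering(g)
  crank <- vapply(seq_len(n), function(i) {
    nb <- as.integer(adj[[i]])
    10^(-cc[i]) * sum(deg[nb] + 1)
  }, numeric(1))
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  dmat <- igraph::distances(g, weights = NA)
  ci <- vapply(seq_len(n), function(i) {
    ring <- which(dmat[i, ] == ci_radius)
    (deg[i] - 1) * sum(deg[ring] - 1)
  }, numeric(1))

  comp <- cbind(degree = deg, h_index = hind, neighborhood = ncon,
                clusterrank = crank, betweenness = btw, collective = ci)
  scaled <- apply(comp, 2, range_scale, lo = 1, hi = 100)
  if (n == 1L) scaled <- matrix(scaled, nrow = 1, dimnames = list(NULL, colnames(comp)))
  hub <- scaled[, "degree"] + scaled[, "h_index"]
  spread <- (scaled[, "neighborhood"] + scaled[, "clusterrank"]) *
    (scaled[, "betweenness"] + scaled[, "collective"])
  raw <- hub * spread
  score <- if (diff(range(raw)) == 0) rep(1, n) else range_scale(raw, 0, 1)
  structure(data.frame(node = igraph::V(g)$name %||% as.character(seq_len(n)),
                       comp, ivi = score, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("ivi_scores", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top influential nodes
#'
#' The ceiling of `fraction` x N highest-IVI nodes; ties broken by score,
#' then degree, then lexicographic node identifier.
#'
#' @param scores an `ivi_scores` data.frame from [ivi()].
#' @param fraction fraction of nodes to keep, in (0, 1\] (default 0.10).
#' @return Character vector of node identifiers, ranked.
#' @export
top_influential <- function(scores, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(scores))
  ord <- order(-scores$ivi, -scores$degree, scores$node)
  scores$node[ord][seq_len(k)]
}
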