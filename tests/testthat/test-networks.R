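make_graph <- function(edges, n = NULL, names = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(n) && igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- names %||% letters[seq_len(igraph::vcount(g))]
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("build_network applies strict r and p thresholds", {
  set.seed(71)
  n <- 10
  # constant row totals so relative abundance preserves within-taxon ranks
  a <- 10L * (1:n)
  b <- a + 5L                    # identical rank order to a
  cc <- sample.int(n) * 3L
  d <- 500L - (a + b + cc)
  tab <- cbind(a = a, b = b, c = cc, d = d)
  rownames(tab) <- paste0("s", 1:n)
  stopifnot(all(rowSums(tab) == 500L))
  net <- build_network(tab, r_min = 0.6, p_max = 0.05)
  expect_true(any(net$edges$node_a == "a" & net$edges$node_b == "b"))
  ab <- net$edges[net$edges$node_a == "a" & net$edges$node_b == "b", ]
  expect_equal(ab$spearman_r, 1)
  # r exactly at the threshold is excluded (strict >)
  net2 <- build_network(tab, r_min = 1, p_max = 0.05)
  expect_identical(nrow(net2$edges), 0L)
  expect_error(build_network(tab[1:3, ]), "at least 4")
})

test_that("noise taxa produce few edges", {
  set.seed(72)
  tab <- matrix(rpois(30 * 20, 50), 30, 20,
                dimnames = list(paste0("s", 1:30), paste0("t", 1:20)))
  net <- build_network(tab)
  expect_lt(nrow(net$edges), 0.05 * choose(20, 2))
})

test_that("topology matches hand-computed values", {
  # two disjoint triangles: Q = 0.5 under the perfect 2-community partition
  tri2 <- make_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                           c(4, 5), c(5, 6), c(4, 6)))
  topo <- topology(tri2, seed = 1)
  expect_equal(topo$modularity, 0.5, tolerance = 1e-12)
  expect_equal(topo$clustering_coefficient, 1.0)
  expect_equal(topo$average_degree, 2.0)
  # star K(1,5): clustering 0, average degree 10/6
  star <- make_graph(cbind(1, 2:6))
  ts <- topology(star, seed = 1)
  expect_equal(ts$clustering_coefficient, 0)
  expect_equal(ts$average_degree, 10 / 6)
})

test_that("topology matches brute-force oracles on all small graphs", {
  set.seed(73)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
    adj <- adj + t(adj)
    if (all(adj == 0)) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- letters[1:n]
    topo <- topology(g, seed = 1)
    deg <- rowSums(adj)
    expect_equal(topo$average_degree, sum(deg) / n)
    # brute-force local clustering: closed triples around each node
    cc <- sapply(1:n, function(i) {
      nb <- which(adj[i, ] == 1)
      if (length(nb) < 2) return(0)
      links <- sum(adj[nb, nb]) / 2
      links / choose(length(nb), 2)
    })
    expect_equal(topo$clustering_coefficient, mean(cc), tolerance = 1e-12)
  }
})

test_that("KS comparisons behave at the extremes and match hand ECDFs", {
  tri <- make_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
  r_same <- compare_degree_distributions(tri, tri)
  expect_equal(r_same$statistic, c(0, 0))
  expect_equal(r_same$p_value, c(1, 1))
  # degrees {1,...} vs {5,...}: disjoint supports -> D = 1
  path2 <- make_graph(rbind(c(1, 2)))                    # degrees 1,1
  k6 <- make_graph(t(combn(6, 2)))                        # degrees 5 x6
  r <- compare_degree_distributions(path2, k6)
  expect_equal(r$statistic[1], 1)
  # regular vs hub-and-spoke on 6 nodes: D from hand ECDF
  ring6 <- make_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                            c(6, 1)))                     # degrees 2 x6
  star6 <- make_graph(cbind(1, 2:6))                      # degrees 5,1x5
  r2 <- compare_degree_distributions(ring6, star6)
  # ECDFs: at x=1 F_ring=0, F_star=5/6; at 2 F_ring=1, F_star=5/6 -> D=5/6
  expect_equal(r2$statistic[1], 5 / 6)
})

test_that("ivi ranks hubs first and respects symmetry", {
  star <- make_graph(cbind(1, 2:9))  # K(1,8)
  sc <- ivi(star)
  expect_equal(max(sc$ivi), 1)
  expect_equal(sc$ivi[sc$node == "a"], 1)        # center
  expect_true(all(sc$ivi[sc$node != "a"] == min(sc$ivi)))
  # complete graph: all equal, convention all 1
  k5 <- make_graph(t(combn(5, 2)))
  expect_true(all(ivi(k5)$ivi == 1))
  two <- make_graph(rbind(c(1, 2)))
  expect_true(all(ivi(two)$ivi == 1))
  # isomorphism invariance: relabeled star gives identical sorted scores
  star_r <- make_graph(cbind(5, c(1:4, 6:9)),
                       names = paste0("n", sample(9)))
  expect_equal(sort(ivi(star_r)$ivi), sort(sc$ivi))
})

test_that("top_influential takes ceil(fraction * N) with stable ties", {
  scores <- data.frame(node = sprintf("t%02d", 1:25),
                       degree = rep(1, 25), ivi = rep(0.5, 25))
  top <- top_influential(scores, 0.10)
  expect_length(top, 3L)                    # ceil(2.5)
  expect_identical(top, c("t01", "t02", "t03"))  # lexicographic tie-break
  star <- make_graph(cbind(1, 2:9))
  expect_true("a" %in% top_influential(ivi(star), 0.10))
})
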