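test_that("all seven centralities match brute-force oracles on small graphs", {
  # every labeled connected graph on 4 nodes, plus random connected 5-8 node graphs
  graphs <- list()
  pairs4 <- t(combn(4, 2))
  for (mask in 1:63) {
    sel <- as.logical(bitwAnd(mask, 2^(0:5)))
    A <- matrix(0, 4, 4)
    for (r in which(sel)) { A[pairs4[r, 1], pairs4[r, 2]] <- 1 }
    A <- A + t(A)
    if (all(is.finite(oracle_bfs_dist(A)))) graphs[[length(graphs) + 1]] <- A
  }
  set.seed(7)
  for (n in 5:8) for (r in 1:8)
    graphs[[length(graphs) + 1]] <- random_connected_adj(n, p = 0.45, seed = n * 100 + r)
  for (A in graphs) {
    g <- adj_to_graph(A)
    tab <- compute_centralities(g)
    expect_equal(tab$degree, rowSums(A))
    expect_equal(tab$betweenness, oracle_betweenness(A), tolerance = 1e-10)
    expect_equal(tab$closeness, oracle_harmonic(A), tolerance = 1e-10)
    expect_equal(tab$clustering, oracle_clustering(A), tolerance = 1e-10)
    expect_equal(tab$pagerank, oracle_pagerank(A), tolerance = 1e-6)
    expect_equal(tab$katz, oracle_katz(A), tolerance = 1e-6)
    expect_equal(tab$eigenvector, oracle_eigenvector(A), tolerance = 1e-6)
  }
})

test_that("centrality table has seven metrics, symmetric on K4, star betweenness 6", {
  K4 <- matrix(1, 4, 4) - diag(4)
  tab <- compute_centralities(adj_to_graph(K4))
  expect_length(setdiff(names(tab), "node_id"), 7)
  for (m in setdiff(names(tab), "node_id"))
    expect_equal(diff(range(tab[[m]])), 0)
  # 5-node star: center carries all C(4,2) = 6 leaf pairs
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(compute_centralities(adj_to_graph(star))$betweenness[1], 6)
  one <- cpi_graph(data.frame(id = "c1", kind = "chemical"))
  expect_error(compute_centralities(one), class = "cpifuse_degenerate_graph_error")
})

test_that("centralities handle disconnected graphs finitely", {
  A <- matrix(0, 5, 5); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  tab <- compute_centralities(adj_to_graph(A))
  expect_true(all(is.finite(as.matrix(tab[, -1]))))
  expect_equal(tab$closeness, oracle_harmonic(A))
  expect_equal(tab$eigenvector, oracle_eigenvector(A))
})

test_that("normalize_metrics min-max scales and maps constants to 0.5", {
  tab <- data.frame(node_id = c("a", "b", "c"), degree = c(2, 4, 6),
                    pagerank = c(3, 3, 3), katz = c(0, 0.5, 1))
  nm <- normalize_metrics(tab)
  expect_equal(nm$degree, c(0, 0.5, 1))
  expect_equal(nm$pagerank, c(0.5, 0.5, 0.5))
  expect_equal(nm$katz, c(0, 0.5, 1))  # idempotent on [0,1]-extremes
})

test_that("pair features are the symmetric mean of node metrics", {
  tab <- data.frame(node_id = c("u", "v"),
                    pagerank = c(1, 0), betweenness = c(1, 0), closeness = c(1, 0),
                    eigenvector = c(1, 0), clustering = c(1, 0), degree = c(1, 0),
                    katz = c(1, 0))
  f <- pair_topology_features(tab, "u", "v")
  expect_equal(unname(f), rep(0.5, 7))
  expect_equal(pair_topology_features(tab, "v", "u"), f)
  tab2 <- tab; tab2[2, -1] <- 1
  expect_equal(unname(pair_topology_features(tab2, "u", "v")), rep(1, 7))
  expect_error(pair_topology_features(tab, "u", "zz"), class = "cpifuse_lookup_error")
})

test_that("entropy initialization matches the worked 4-node example", {
  # metric A constant -> H = 0 -> raw 1; metric B hits all 4 bins of a
  # 4-bin histogram -> H = log 4 = log|V| -> raw 0; weights (1, 0)
  tab <- data.frame(node_id = letters[1:4], A = rep(3, 4), B = c(0, 1/3, 2/3, 1))
  w <- entropy_weight_init(tab)  # bins = min(|V|, 20) = 4
  expect_equal(unname(w$w), c(1, 0))
  expect_equal(w$a, 1); expect_equal(w$b, 0)
})

test_that("entropy weights are a simplex, permutation-equivariant, uniform fallback", {
  set.seed(5)
  g <- adj_to_graph(random_connected_adj(8, seed = 55))
  tab <- normalize_metrics(compute_centralities(g))
  w <- entropy_weight_init(tab)
  expect_true(all(w$w >= 0))
  expect_equal(sum(w$w), 1, tolerance = 1e-12)
  perm <- c("node_id", "katz", "degree", "clustering", "eigenvector",
            "closeness", "betweenness", "pagerank")
  w2 <- entropy_weight_init(tab[, perm])
  expect_equal(w2$w[names(w$w)], w$w)
  # all-maximal-entropy table: Z = 0 -> uniform fallback
  tabu <- data.frame(node_id = letters[1:4], A = c(0, 1/3, 2/3, 1), B = c(1, 2/3, 1/3, 0))
  expect_equal(unname(entropy_weight_init(tabu)$w), c(0.5, 0.5))
})

test_that("ctc_score is a dot product; ctc_probability a calibrated sigmoid", {
  w <- structure(list(w = c(1, 0, 0, 0, 0, 0, 0), a = 1, b = 0), class = "ctc_weights")
  f <- c(0.7, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)
  expect_equal(ctc_score(f, w), 0.7)
  expect_equal(ctc_score(rep(0, 7), w), 0)
  w2 <- structure(list(w = c(0.5, 0.5, 0, 0, 0, 0, 0), a = 1, b = 0),
                  class = "ctc_weights")
  expect_equal(ctc_score(c(0.2, 0.6, 0, 0, 0, 0, 0), w2), 0.4)
  expect_error(ctc_score(c(0.5, 0.5), w), class = "cpifuse_contract_error")
  expect_equal(ctc_probability(0, w), 0.5)
  expect_equal(ctc_probability(1, w), 1 / (1 + exp(-1)), tolerance = 1e-10)
  expect_gt(ctc_probability(30, w), 0.999)
  expect_lt(ctc_probability(-30, w), 0.001)
  # monotone in every feature under non-negative weights; symmetric in (u,v)
  set.seed(1)
  wpos <- structure(list(w = runif(7), a = 1, b = 0), class = "ctc_weights")
  f0 <- runif(7)
  for (k in 1:7) {
    f1 <- f0; f1[k] <- f1[k] + 0.1
    expect_gte(ctc_score(f1, wpos), ctc_score(f0, wpos))
  }
})
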