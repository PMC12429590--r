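# Topology branch: seven node centralities, entropy-initialized CTC weights,
# pairwise CTC scores, and the sigmoid topological interaction probability.
#
# All centralities are computed on the undirected, unweighted merged network.
# Conventions fixed for determinism (none are stated by the method itself):
#   - PageRank damping 0.85
#   - Katz attenuation alpha = 0.9 / spectral radius, computed by the
#     convergent series  k = sum_{i>=1} (alpha A)^i 1
#   - eigenvector centrality by per-component power iteration
#     (tol 1e-8, max 1000 iterations), each component scaled to max 1
#   - closeness as normalized harmonic centrality (finite on disconnected
#     graphs; unreachable pairs contribute 0)
#   - local clustering coefficient with isolated/degree-1 nodes set to 0

CENTRALITY_METRICS <- c("pagerank", "betweenness", "closeness", "eigenvector",
                        "clustering", "degree", "katz")

#' Compute the seven node centralities of a CPI graph
#'
#' PageRank, betweenness, closeness (harmonic), eigenvector, local clustering
#' coefficient, degree and Katz centrality, as one column each.
#'
#' @param graph `cpi_graph` with at least two nodes
#' @param damping PageRank damping factor
#' @param katz_frac Katz attenuation as a fraction of `1/spectral radius`
#' @param tol convergence tolerance for iterative solvers
#' @return data.frame with `node_id` plus the seven metric columns
#' @export
compute_centralities <- function(graph, damping = 0.85, katz_frac = 0.9, tol = 1e-8) {
  if (nrow(graph$nodes) < 2)
    stop_cpifuse("centralities need at least two nodes", "cpifuse_degenerate_graph_error")
  ig <- as_igraph(graph)
  n <- igraph::vcount(ig)
  A <- sparse_adjacency(graph)
  tab <- data.frame(
    node_id = igraph::V(ig)$name,
    pagerank = igraph::page_rank(ig, damping = damping)$vector,
    betweenness = igraph::betweenness(ig, directed = FALSE, normalized = FALSE),
    closeness = igraph::harmonic_centrality(ig, normalized = TRUE),
    eigenvector = eigenvector_by_component(A, tol = tol),
    clustering = local_clustering(ig),
    degree = igraph::degree(ig),
    katz = katz_centrality(A, frac = katz_frac, tol = tol),
    stringsAsFactors = FALSE, row.names = NULL)
  tab
}

sparse_adjacency <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  if (nrow(graph$edges) == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n), dimnames = list(ids, ids)))
  i <- match(graph$edges$u, ids); j <- match(graph$edges$v, ids)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n),
                       dimnames = list(ids, ids))
}

local_clustering <- function(ig) {
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  cc
}

# Largest eigenvalue of a symmetric non-negative matrix by shifted power
# iteration: iterating on A + sI keeps the spectrum positive, so bipartite
# graphs (eigenvalues +/- lambda) cannot stall the iteration.
spectral_radius <- function(A, tol = 1e-10, max_iter = 5000) {
  n <- nrow(A)
  if (n == 0 || length(A@x) == 0) return(0)
  shift <- max(Matrix::rowSums(A)) + 1
  x <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + shift * x
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    y <- y / ny
    lam_new <- as.numeric(t(y) %*% (A %*% y)) + shift
    if (abs(lam_new - lam) < tol) return(lam_new - shift)
    lam <- lam_new
    x <- y
  }
  lam - shift
}

katz_centrality <- function(A, frac = 0.9, tol = 1e-8, max_iter = 5000) {
  n <- nrow(A)
  lam <- spectral_radius(A)
  if (lam <= 0) return(rep(0, n))
  alpha <- frac / lam
  # k = sum_{i>=1} (alpha A)^i 1, via s_{t+1} = alpha A (1 + s_t)
  s <- rep(0, n)
  one <- rep(1, n)
  for (it in seq_len(max_iter)) {
    s_new <- alpha * as.numeric(A %*% (one + s))
    if (max(abs(s_new - s)) < tol) return(s_new)
    s <- s_new
  }
  s
}

eigenvector_by_component <- function(A, tol = 1e-8, max_iter = 1000) {
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = NULL)
  comp <- igraph::components(g)$membership
  out <- rep(0, n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) { out[idx] <- 0; next }
    Ac <- A[idx, idx, drop = FALSE]
    x <- rep(1 / sqrt(length(idx)), length(idx))
    for (it in seq_len(max_iter)) {
      # shifted iteration: Perron vector of Ac + I equals that of Ac, and the
      # shift prevents oscillation on bipartite components
      y <- as.numeric(Ac %*% x) + x
      ny <- sqrt(sum(y^2))
      if (ny == 0) { y <- x; break }
      y <- y / ny
      if (max(abs(y - x)) < tol) { x <- y; break }
      x <- y
    }
    out[idx] <- if (max(x) > 0) x / max(x) else x
  }
  out
}

#' Min-max normalize centrality columns to [0, 1]
#'
#' Constant columns map to 0.5 everywhere (no information, neutral value).
#' @param table output of [compute_centralities()]
#' @return table of identical shape, each metric column in `[0,1]`
#' @export
normalize_metrics <- function(table) {
  scalers <- list()
  for (m in intersect(CENTRALITY_METRICS, names(table))) {
    x <- table[[m]]
    rng <- range(x)
    scalers[[m]] <- rng
    table[[m]] <- if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
  }
  attr(table, "normalized") <- TRUE
  attr(table, "scalers") <- scalers
  table
}

# Apply previously fitted min-max scalers (frozen feature pipeline) to a
# freshly computed centrality table, e.g. on a counterfactually perturbed
# graph. Constant columns at fit time keep their neutral 0.5.
apply_normalizers <- function(table, scalers) {
  for (m in intersect(names(scalers), names(table))) {
    rng <- scalers[[m]]
    table[[m]] <- if (diff(rng) == 0) rep(0.5, nrow(table))
      else (table[[m]] - rng[1]) / diff(rng)
  }
  attr(table, "normalized") <- TRUE
  attr(table, "scalers") <- scalers
  table
}

#' Pairwise topology features for a chemical-protein pair
#'
#' The node-to-pair map is the arithmetic mean of the two nodes' normalized
#' metric values: symmetric in (u, v) and bounded in `[0,1]`.
#' @param table normalized centrality table
#' @param u,v node ids present in `table`
#' @return named numeric vector, one entry per metric
#' @export
pair_topology_features <- function(table, u, v) {
  iu <- match(u, table$node_id); iv <- match(v, table$node_id)
  if (is.na(iu) || is.na(iv))
    stop_cpifuse(sprintf("unknown node(s): %s", paste(c(u, v)[is.na(c(iu, iv))], collapse = ", ")),
                 "cpifuse_lookup_error")
  m <- intersect(CENTRALITY_METRICS, names(table))
  stats::setNames((as.numeric(table[iu, m]) + as.numeric(table[iv, m])) / 2, m)
}

# Shannon entropy (nats) of a metric over an equal-width histogram.
metric_entropy <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log(p))
}

#' Entropy-based initialization of the CTC metric weights
#'
#' Each metric's raw weight is `1 - H(f_k)/log|V|`, where `H` is the Shannon
#' entropy (natural log) of the metric over an equal-width histogram with
#' `min(|V|, 20)` bins; weights are normalized to sum to 1. Low-entropy
#' (concentrated) metrics start with large weight. If every raw weight is 0
#' the initialization falls back to uniform.
#'
#' @param table centrality table (any number of metric columns >= 1)
#' @param bins histogram bin count; default `min(|V|, 20)`
#' @return object of class `ctc_weights`: weight vector `w` (sums to 1) plus
#'   the sigmoid calibration affine `(a, b)` initialized at `(1, 0)`
#' @export
entropy_weight_init <- function(table, bins = NULL) {
  metrics <- setdiff(names(table), "node_id")
  n <- nrow(table)
  if (n < 2) stop_cpifuse("need at least 2 nodes", "cpifuse_degenerate_graph_error")
  bins <- bins %||% min(n, 20L)
  if (bins < 2) stop_cpifuse("bins must be >= 2", "cpifuse_config_error")
  raw <- vapply(metrics, function(m) 1 - metric_entropy(table[[m]], bins) / log(n), numeric(1))
  raw <- pmax(raw, 0)  # H <= log(bins) <= log n, so this only trims round-off
  Z <- sum(raw)
  w <- if (Z == 0) rep(1 / length(raw), length(raw)) else raw / Z
  structure(list(w = stats::setNames(w, metrics), a = 1, b = 0, trainable = TRUE),
            class = "ctc_weights")
}

#' @exportS3Method base::print
print.ctc_weights <- function(x, ...) {
  cat("<ctc_weights>\n")
  print(round(x$w, 4))
  cat(sprintf("calibration: a = %.4g, b = %.4g\n", x$a, x$b))
  invisible(x)
}

#' Composite topological characteristic (CTC) score of a pair
#'
#' Weighted sum `sum_k w_k f_k(u,v)` of the pair's normalized centrality
#' features; linear in both arguments.
#' @param features output of [pair_topology_features()]
#' @param weights a `ctc_weights` object (or bare weight vector)
#' @return unitless score
#' @export
ctc_score <- function(features, weights) {
  w <- if (inherits(weights, "ctc_weights")) weights$w else weights
  if (length(w) != length(features))
    stop_cpifuse(sprintf("weight/feature dimension mismatch (%d vs %d)",
                         length(w), length(features)), "cpifuse_contract_error")
  sum(w * features)
}

#' Topological interaction probability
#'
#' Sigmoid of an affine calibration of the CTC score: `sigma(a*s + b)` with
#' learnable `(a, b)` initialized at `(1, 0)`. Strictly increasing in the
#' score, output in (0, 1).
#' @param score CTC score
#' @param weights `ctc_weights` carrying the calibration `(a, b)`
#' @return probability
#' @export
ctc_probability <- function(score, weights) {
  a <- if (inherits(weights, "ctc_weights")) weights$a else 1
  b <- if (inherits(weights, "ctc_weights")) weights$b else 0
  sigmoid(a * score + b)
}
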