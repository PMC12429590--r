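# Independent brute-force oracles used to check the package's operations.
# These are deliberately naive re-derivations from definitions: BFS
# shortest-path enumeration, dense linear algebra, exhaustive counting.

# all-pairs BFS distances on an adjacency matrix
oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# betweenness by exhaustive shortest-path enumeration (counts via DFS on the
# BFS predecessor DAG); unnormalized, undirected convention (pairs s < t)
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_bfs_dist(A)
  count_paths <- function(s, t, via) {
    # enumerate all shortest s->t paths, count those through `via`
    paths <- list(c(s))
    total <- 0; through <- 0
    while (length(paths) > 0) {
      p <- paths[[1]]; paths <- paths[-1]
      v <- p[length(p)]
      if (v == t) {
        total <- total + 1
        if (via %in% p[-c(1, length(p))]) through <- through + 1
        next
      }
      for (w in which(A[v, ] > 0))
        if (is.finite(D[w, t]) && D[s, v] + 1 + D[w, t] == D[s, t])
          paths[[length(paths) + 1]] <- c(p, w)
    }
    c(total, through)
  }
  bt <- numeric(n)
  for (v in seq_len(n))
    for (s in seq_len(n - 1)) for (t in (s + 1):n)
      if (s != v && t != v && is.finite(D[s, t]) && D[s, t] > 1) {
        ct <- count_paths(s, t, v)
        if (ct[1] > 0) bt[v] <- bt[v] + ct[2] / ct[1]
      }
  bt
}

# normalized harmonic closeness
oracle_harmonic <- function(A) {
  D <- oracle_bfs_dist(A)
  n <- nrow(A)
  sapply(seq_len(n), function(v) sum(1 / D[v, -v][is.finite(D[v, -v])]) / (n - 1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / choose(k, 2)
  })
}

oracle_pagerank <- function(A, damping = 0.85, iters = 300) {
  n <- nrow(A)
  deg <- rowSums(A)
  x <- rep(1 / n, n)
  for (i in seq_len(iters)) {
    xs <- sapply(seq_len(n), function(v) {
      nb <- which(A[, v] > 0)
      sum(x[nb] / deg[nb])
    })
    dangling <- sum(x[deg == 0]) / n
    x <- (1 - damping) / n + damping * (xs + dangling)
  }
  x
}

oracle_katz <- function(A, frac = 0.9) {
  lam <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  if (lam <= 0) return(rep(0, nrow(A)))
  alpha <- frac / lam
  as.numeric(solve(diag(nrow(A)) - alpha * A, rep(1, nrow(A)))) - 1
}

# per-component principal eigenvector, each component scaled to max 1
oracle_eigenvector <- function(A) {
  n <- nrow(A)
  D <- oracle_bfs_dist(A)
  out <- numeric(n)
  seen <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    idx <- which(is.finite(D[s, ]))
    seen[idx] <- TRUE
    if (length(idx) == 1) next
    ev <- eigen(A[idx, idx], symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    out[idx] <- v / max(v)
  }
  out
}

oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

oracle_ef <- function(scores, actives, top_frac) {
  N <- length(scores)
  ord <- order(-scores, names(scores), method = "radix")
  top_n <- max(1, floor(top_frac * N))
  hits <- sum(names(scores)[ord[1:top_n]] %in% actives)
  (hits / top_n) / (length(actives) / N)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  p_le <- mean(Vs <= V); p_ge <- mean(Vs >= V)
  min(1, 2 * min(p_le, p_ge))
}

# random connected undirected graph (keeps sampling until connected)
random_connected_adj <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p)
    A <- A + t(A)
    if (all(is.finite(oracle_bfs_dist(A)))) return(A)
  }
}

adj_to_graph <- function(A, kinds = NULL) {
  n <- nrow(A)
  ids <- sprintf("n%02d", seq_len(n))
  if (is.null(kinds)) kinds <- rep(c("chemical", "protein"), length.out = n)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  cpi_graph(data.frame(id = ids, kind = kinds),
            data.frame(u = ids[idx[, 1]], v = ids[idx[, 2]]))
}
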