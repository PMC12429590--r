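# Reference link-prediction baselines, sized per the common benchmark
# settings: a trainable GCN (depth-L, hidden 128, ReLU), a GAT-style
# attention encoder (2 layers, 8 heads, dropout 0.2), and walk-based
# embeddings (dim 128, window 5) fed to a logistic head. The GCN is trained
# end-to-end; the GAT encoder is frozen (seeded weights) with a trained
# head; walk embeddings use the standard window-cooccurrence PPMI
# factorization, a well-known closed-form equivalent of skip-gram training.

norm_adjacency <- function(graph) {
  A <- sparse_adjacency(graph) + Matrix::Diagonal(nrow(graph$nodes))
  d <- Matrix::rowSums(A)
  Dn <- Matrix::Diagonal(x = 1 / sqrt(d))
  Dn %*% A %*% Dn
}

logistic_head_train <- function(H, split, cfg, epochs = 100) {
  emb_pairs <- function(pairs) H[pairs$chem, , drop = FALSE] * H[pairs$prot, , drop = FALSE]
  X_tr <- emb_pairs(split$train); y_tr <- split$train$label
  X_va <- emb_pairs(split$validation); y_va <- split$validation$label
  with_seed(cfg$seed, {
    w <- numeric(ncol(X_tr)); b <- 0
    st <- adam_init(list(w = w, b = b))
    par <- list(w = w, b = b)
    best <- list(par = par, crit = -Inf, epoch = 0)
    for (e in seq_len(epochs)) {
      p <- clamp01(sigmoid(as.numeric(X_tr %*% par$w) + par$b))
      g <- (p - y_tr) / length(y_tr)
      upd <- adam_step(par, list(w = as.numeric(t(X_tr) %*% g), b = sum(g)),
                       st, cosine_lr(cfg$lr, e, epochs), wd = cfg$weight_decay)
      par <- upd$par; st <- upd$state
      p_va <- sigmoid(as.numeric(X_va %*% par$w) + par$b)
      crit <- if (length(unique(y_va)) == 2) evaluate_metrics(y_va, p_va)$auc else -Inf
      if (crit > best$crit + 1e-12) best <- list(par = par, crit = crit, epoch = e)
      if ((e - best$epoch) >= cfg$patience) break
    }
    best$par
  })
}

gcn_train <- function(graph, split, cfg, epochs = 100) {
  Ahat <- norm_adjacency(graph)
  ids <- graph$nodes$id
  n <- length(ids)
  L <- max(1, cfg$depth)
  iu_tr <- match(split$train$chem, ids); iv_tr <- match(split$train$prot, ids)
  iu_va <- match(split$validation$chem, ids); iv_va <- match(split$validation$prot, ids)
  y_tr <- split$train$label; y_va <- split$validation$label
  with_seed(cfg$seed, {
    par <- c(list(E = matrix(stats::rnorm(n * cfg$hidden, sd = 0.1), n, cfg$hidden)),
             lapply(seq_len(L), function(l)
               matrix(stats::rnorm(cfg$hidden^2, sd = sqrt(2 / cfg$hidden)),
                      cfg$hidden, cfg$hidden)))
    names(par) <- c("E", paste0("W", seq_len(L)))
    st <- adam_init(par)
    forward <- function(par) {
      Hs <- vector("list", L + 1)
      Hs[[1]] <- par$E
      for (l in seq_len(L)) {
        Z <- as.matrix(Ahat %*% Hs[[l]]) %*% par[[paste0("W", l)]]
        Hs[[l + 1]] <- if (l < L) relu(Z) else Z
      }
      Hs
    }
    best <- list(par = par, crit = -Inf, epoch = 0)
    for (e in seq_len(epochs)) {
      Hs <- forward(par)
      H <- Hs[[L + 1]]
      sc <- rowSums(H[iu_tr, , drop = FALSE] * H[iv_tr, , drop = FALSE])
      p <- clamp01(sigmoid(sc))
      g <- (p - y_tr) / length(y_tr)
      dH <- matrix(0, n, cfg$hidden)
      acc <- rowsum(rbind(g * H[iv_tr, , drop = FALSE],
                          g * H[iu_tr, , drop = FALSE]), c(iu_tr, iv_tr))
      dH[as.integer(rownames(acc)), ] <- acc
      gr <- stats::setNames(vector("list", L + 1), names(par))
      dZ <- dH
      for (l in rev(seq_len(L))) {
        if (l < L) dZ <- dZ * (Hs[[l + 1]] > 0)
        AH <- as.matrix(Ahat %*% Hs[[l]])
        gr[[paste0("W", l)]] <- t(AH) %*% dZ
        dZ <- as.matrix(Matrix::t(Ahat) %*% (dZ %*% t(par[[paste0("W", l)]])))
      }
      gr$E <- dZ
      upd <- adam_step(par, gr, st, cosine_lr(cfg$lr, e, epochs), wd = cfg$weight_decay)
      par <- upd$par; st <- upd$state
      Hv <- forward(par)[[L + 1]]
      p_va <- sigmoid(rowSums(Hv[iu_va, , drop = FALSE] * Hv[iv_va, , drop = FALSE]))
      crit <- if (length(unique(y_va)) == 2) evaluate_metrics(y_va, p_va)$auc else -Inf
      if (crit > best$crit + 1e-12) best <- list(par = par, crit = crit, epoch = e)
      if ((e - best$epoch) >= cfg$patience) break
    }
    H <- forward(best$par)[[L + 1]]
    rownames(H) <- ids
    list(H = H, score = function(pairs)
      sigmoid(rowSums(H[pairs$chem, , drop = FALSE] * H[pairs$prot, , drop = FALSE])))
  })
}

gat_encode <- function(graph, cfg, heads = 8, layers = 2, dim = 128) {
  A <- sparse_adjacency(graph) + Matrix::Diagonal(nrow(graph$nodes))
  ids <- graph$nodes$id
  n <- length(ids)
  per_head <- dim %/% heads
  with_seed(cfg$seed + 31337, {
    X <- matrix(stats::rnorm(n * 32), n, 32)
    idx <- Matrix::which(A != 0, arr.ind = TRUE)
    for (l in seq_len(layers)) {
      outs <- lapply(seq_len(heads), function(h) {
        W <- matrix(stats::rnorm(ncol(X) * per_head, sd = 1 / sqrt(ncol(X))),
                    ncol(X), per_head)
        a1 <- stats::rnorm(per_head, sd = 0.3); a2 <- stats::rnorm(per_head, sd = 0.3)
        Z <- X %*% W
        e <- as.numeric(Z[idx[, 1], , drop = FALSE] %*% a1 +
                        Z[idx[, 2], , drop = FALSE] %*% a2)
        e <- exp(pmin(ifelse(e > 0, e, 0.2 * e), 30))   # leaky-relu then exp
        den <- rowsum(e, idx[, 1])
        att <- e / den[as.character(idx[, 1]), 1]
        M <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = att, dims = c(n, n))
        relu(as.matrix(M %*% Z))
      })
      X <- do.call(cbind, outs)
    }
    rownames(X) <- ids
    X
  })
}

walk_embeddings <- function(graph, cfg, dim = 128, window = 5,
                            walks_per_node = 10, walk_length = 20, q = 1) {
  ig <- as_igraph(graph)
  ids <- graph$nodes$id
  n <- length(ids)
  adj <- igraph::as_adj_list(ig)
  adj <- lapply(adj, as.integer)
  with_seed(cfg$seed + 101, {
    C <- matrix(0, n, n)
    for (w in seq_len(walks_per_node)) {
      for (start in seq_len(n)) {
        walk <- integer(walk_length)
        walk[1] <- start
        prev <- 0L
        for (t in 2:walk_length) {
          nbrs <- adj[[walk[t - 1]]]
          if (length(nbrs) == 0) { walk <- walk[seq_len(t - 1)]; break }
          if (q != 1 && prev > 0L) {
            wts <- ifelse(nbrs == prev, 1,
                          ifelse(nbrs %in% adj[[prev]], 1, 1 / q))
            walk[t] <- nbrs[sample.int(length(nbrs), 1, prob = wts)]
          } else walk[t] <- nbrs[sample.int(length(nbrs), 1)]
          prev <- walk[t - 1]
        }
        lw <- length(walk)
        for (t in seq_len(lw)) {
          pos <- max(1, t - window):min(lw, t + window)
          for (cx in walk[pos[pos != t]]) C[walk[t], cx] <- C[walk[t], cx] + 1
        }
      }
    }
    tot <- sum(C)
    rs <- pmax(rowSums(C), 1); cs <- pmax(colSums(C), 1)
    P <- log(pmax(C * tot / outer(rs, cs), 1))   # positive PMI
    sv <- svd(P, nu = min(dim, n), nv = 0)
    k <- min(dim, n)
    H <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(k)]), k)
    if (k < dim) H <- cbind(H, matrix(0, n, dim - k))
    rownames(H) <- ids
    H
  })
}

#' Run a reference baseline model
#'
#' `gcn`: depth-`cfg$depth` graph convolutional encoder (hidden 128, ReLU)
#' trained end-to-end on the labeled pairs. `gat`: 2-layer, 8-head
#' attention encoder with a trained logistic head. `node2vec` (return bias
#' q = 0.5) and `deepwalk` (uniform walks): window-5 co-occurrence PPMI
#' embeddings of dimension 128 with a trained logistic head.
#'
#' @param name one of `"gcn"`, `"node2vec"`, `"deepwalk"`, `"gat"`
#' @param graph `cpi_graph`
#' @param split list with labeled `train`, `validation`, `test` data.frames
#' @param cfg `train_config`
#' @return list: `name`, `metrics` (on the test split), `dim`, `heads`
#'   (GAT), `scores` closure
#' @export
run_reference_baseline <- function(name, graph, split, cfg = train_config()) {
  name <- match.arg(name, c("gcn", "node2vec", "deepwalk", "gat"))
  dim_out <- 128L
  if (name == "gcn") {
    fit <- gcn_train(graph, split, cfg)
    score <- fit$score
    dim_out <- ncol(fit$H)
    heads <- NULL
  } else {
    H <- switch(name,
      gat = gat_encode(graph, cfg, heads = 8, layers = 2, dim = dim_out),
      node2vec = walk_embeddings(graph, cfg, dim = dim_out, q = 0.5),
      deepwalk = walk_embeddings(graph, cfg, dim = dim_out, q = 1))
    par <- logistic_head_train(H, split, cfg)
    score <- function(pairs)
      sigmoid(as.numeric((H[pairs$chem, , drop = FALSE] *
                          H[pairs$prot, , drop = FALSE]) %*% par$w) + par$b)
    dim_out <- ncol(H)
    heads <- if (name == "gat") 8L else NULL
  }
  metrics <- evaluate_metrics(split$test$label, score(split$test))
  list(name = name, metrics = metrics, dim = dim_out, heads = heads, scores = score)
}
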