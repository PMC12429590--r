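# Interpretability and robustness protocol: counterfactual topology
# perturbation (delta-p), modality ablation, fusion-weight and depth
# sweeps, enrichment-factor screening, and seed-paired statistics.

#' Counterfactual topology perturbation of a single pair
#'
#' Removes the `k` highest-edge-betweenness edges among those incident to
#' the protein's 2-hop neighborhood (or graph-wide with `scope =
#' "global"`), recomputes centralities and the CTC probability on the
#' perturbed graph with the model's trained weights, re-fuses with the
#' untouched structure and semantic branch probabilities, and reports
#' `delta_p = baseline - perturbed`. Signal-destroying perturbations thus
#' yield positive delta-p.
#'
#' @param model `cpi_model`
#' @param feats `cpi_features`
#' @param graph `cpi_graph` the topology branch was computed on
#' @param pair list or data.frame row with `chem`, `prot`
#' @param k number of edges to remove (`k = 0` is the null perturbation)
#' @param scope `"local"` (protein 2-hop neighborhood) or `"global"`
#' @return list of class `perturbation_result`
#' @export
perturb_topology <- function(model, feats, graph, pair, k,
                             scope = c("local", "global")) {
  scope <- match.arg(scope)
  if (k < 0) stop_cpifuse("k must be >= 0", "cpifuse_config_error")
  pr <- as.data.frame(pair)[, c("chem", "prot")]
  base <- predict_cpi(model, feats, pr)
  if (k == 0)
    return(structure(list(pair = pr, baseline = base$p_fused,
                          perturbed = base$p_fused, delta_p = 0,
                          kind = "edge_removal", k = 0, removed = character(0),
                          flag = NULL), class = "perturbation_result"))
  ig <- as_igraph(graph)
  eb <- igraph::edge_betweenness(ig, directed = FALSE)
  ends <- igraph::as_edgelist(ig)
  if (scope == "local") {
    nb <- names(igraph::ego(ig, order = 2, nodes = pr$prot)[[1]])
    cand <- which(ends[, 1] %in% nb | ends[, 2] %in% nb)
  } else cand <- seq_len(nrow(ends))
  flag <- NULL
  if (k > length(cand)) {
    flag <- sprintf("requested k=%d but only %d candidate edges; removed all", k, length(cand))
    k <- length(cand)
  }
  drop_idx <- cand[order(-eb[cand])][seq_len(k)]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  drop_keys <- key(ends[drop_idx, 1], ends[drop_idx, 2])
  e <- graph$edges
  g2 <- cpi_graph(graph$nodes, e[!(key(e$u, e$v) %in% drop_keys), , drop = FALSE])
  # frozen feature pipeline: the min-max scalers fitted on the intact graph
  # are applied to the perturbed centralities (the counterfactual changes
  # the input, not the fitted preprocessing)
  scalers <- attr(feats$cent, "scalers")
  cent2 <- compute_centralities(g2)
  cent2 <- if (is.null(scalers)) normalize_metrics(cent2)
    else apply_normalizers(cent2, scalers)
  f2 <- pair_topology_features(cent2, pr$chem, pr$prot)
  w <- model$par$ctc
  p_topo2 <- sigmoid(w$a * sum(w$w * f2) + w$b)
  w3 <- model$fusion_weights
  pert <- as.numeric(w3[1] * base$p_struct + w3[2] * base$p_sem + w3[3] * p_topo2)
  structure(list(pair = pr, baseline = base$p_fused, perturbed = pert,
                 delta_p = base$p_fused - pert, kind = "edge_removal", k = k,
                 removed = drop_keys, flag = flag),
            class = "perturbation_result")
}

#' Delta-p distribution across randomly selected proteins
#'
#' Samples `n_proteins` proteins without replacement (deterministic per
#' seed), perturbs the topology around each one's highest-confidence
#' positive partner (or a random chemical when it has none), and summarizes
#' the resulting delta-p values.
#'
#' @param model `cpi_model`
#' @param feats `cpi_features`
#' @param graph `cpi_graph`
#' @param n_proteins number of proteins to sample
#' @param k edges removed per perturbation
#' @param seed integer seed
#' @return list: `delta_p` vector, `median`, `interval` (5th-95th
#'   percentiles), `proteins`
#' @export
delta_p_distribution <- function(model, feats, graph, n_proteins = 50, k = 5, seed = 0) {
  prots <- graph$nodes$id[graph$nodes$kind == "protein"]
  prots <- intersect(prots, rownames(feats$prot_emb))
  if (length(prots) < n_proteins)
    stop_cpifuse(sprintf("only %d proteins available, need %d", length(prots), n_proteins),
                 "cpifuse_sampling_error")
  pos <- positive_pairs(graph)
  chems <- graph$nodes$id[graph$nodes$kind == "chemical"]
  sel <- with_seed(seed, list(p = sample(prots, n_proteins),
                              c = sample(chems, n_proteins, replace = TRUE)))
  dp <- vapply(seq_len(n_proteins), function(i) {
    p <- sel$p[i]
    partners <- pos$chem[pos$prot == p]
    ch <- if (length(partners) > 0) partners[1] else sel$c[i]
    perturb_topology(model, feats, graph,
                     list(chem = ch, prot = p), k = k)$delta_p
  }, numeric(1))
  list(delta_p = dp, median = stats::median(dp),
       interval = stats::quantile(dp, c(0.05, 0.95), names = FALSE),
       proteins = sel$p)
}

#' Ablate the features of one modality (evaluation-time intervention)
#'
#' `semantics`: all semantic vectors zeroed. `structure`: contact graphs
#' replaced by edgeless graphs (re-encoded) and fingerprints zeroed.
#' `topology` is a fusion-level intervention and is handled in
#' [ablate_modality()] by zeroing delta and renormalizing.
#' @param feats `cpi_features`
#' @param modality `"semantics"` or `"structure"`
#' @return modified `cpi_features`
#' @export
ablate_features <- function(feats, modality) {
  if (modality == "semantics") {
    feats$sem[] <- 0
  } else if (modality == "structure") {
    feats$fp[] <- 0
    cgs0 <- lapply(feats$contact_graphs, function(cg) {
      cg$edges <- matrix(integer(), ncol = 2); cg
    })
    emb0 <- t(vapply(cgs0, function(cg) as.numeric(encode_protein(cg, feats$encoder)),
                     numeric(feats$encoder$s_dim)))
    rownames(emb0) <- rownames(feats$prot_emb)
    feats$prot_emb <- emb0
    feats$contact_graphs <- cgs0
  } else stop_cpifuse(sprintf("unknown modality '%s'", modality), "cpifuse_config_error")
  feats
}

#' Scale semantic inputs by a reinforcement factor (speculative)
#'
#' The inverse of the semantic ablation: multiplies every semantic vector by
#' `factor > 1`. No mechanism for "reinforcing" literature support is
#' defined by the underlying protocol, so this is an explicitly speculative
#' intervention exposed for exploratory use only; interpret results with
#' care.
#' @param feats `cpi_features`
#' @param factor scaling factor (> 1)
#' @return modified `cpi_features`
#' @export
reinforce_semantics <- function(feats, factor = 2) {
  if (factor <= 1) stop_cpifuse("reinforcement factor must be > 1", "cpifuse_config_error")
  feats$sem <- feats$sem * factor
  feats
}

#' Evaluate the model with one modality ablated
#'
#' `topology`: the fusion weight delta is forced to 0 and (alpha, beta)
#' renormalized. `semantics`: semantic inputs zeroed. `structure`: contact
#' graphs emptied and fingerprints zeroed. Metrics are recomputed on the
#' given pairs.
#'
#' @param model trained `cpi_model`
#' @param feats `cpi_features`
#' @param pairs labeled pairs (test split)
#' @param modality one of `"topology"`, `"semantics"`, `"structure"`
#' @return metrics list from [evaluate_metrics()]
#' @export
ablate_modality <- function(model, feats, pairs, modality) {
  modality <- match.arg(modality, c("topology", "semantics", "structure"))
  if (modality == "topology") {
    w <- model$fusion_weights
    w2 <- c(w[1], w[2], 0) / (w[1] + w[2])
    return(evaluate(model, pairs, feats, fusion_weights = w2))
  }
  evaluate(model, pairs, ablate_features(feats, modality))
}

#' Sweep the late-fusion weights over the constrained simplex grid
#'
#' Branch probabilities are held fixed (trained heads); AUC is evaluated at
#' every grid point with all components in `[0.1, 0.8]` at the given step
#' and summing to 1.
#'
#' @param model `cpi_model`
#' @param feats `cpi_features`
#' @param pairs labeled pairs
#' @param grid_step grid step (must divide the 0.1..0.8 range)
#' @return data.frame `alpha`, `beta`, `delta`, `auc` (class `sweep_result`)
#' @export
sweep_fusion_weights <- function(model, feats, pairs, grid_step = 0.1) {
  steps <- 0.7 / grid_step
  if (abs(steps - round(steps)) > 1e-9)
    stop_cpifuse("grid_step must divide the [0.1, 0.8] range", "cpifuse_config_error")
  pr <- predict_cpi(model, feats, pairs)
  vals <- seq(0.1, 0.8, by = grid_step)
  grid <- expand.grid(alpha = vals, beta = vals)
  grid$delta <- 1 - grid$alpha - grid$beta
  grid <- grid[grid$delta >= 0.1 - 1e-9 & grid$delta <= 0.8 + 1e-9, , drop = FALSE]
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    p <- grid$alpha[i] * pr$p_struct + grid$beta[i] * pr$p_sem + grid$delta[i] * pr$p_topo
    evaluate_metrics(pairs$label, p)$auc
  }, numeric(1))
  rownames(grid) <- NULL
  structure(grid, class = c("sweep_result", "data.frame"))
}

#' Depth sweep of the topology-path graph-convolutional model
#'
#' Trains the topology-path GCN link predictor (see
#' [run_reference_baseline()]) at each depth and seed on the given labeled
#' pairs and reports mean and sd of test AUC per depth.
#'
#' @param graph `cpi_graph`
#' @param split `pair_split`-style list with labeled `train`, `validation`,
#'   `test`
#' @param depths integer vector of GCN depths
#' @param cfg `train_config`
#' @param seeds integer vector of seeds
#' @return data.frame `depth`, `mean_auc`, `sd_auc` (class `sweep_result`)
#' @export
sweep_depth <- function(graph, split, depths = 1:4, cfg = train_config(), seeds = 0:2) {
  rows <- lapply(depths, function(L) {
    aucs <- vapply(seeds, function(s) {
      cfg2 <- cfg; cfg2$seed <- s; cfg2$depth <- L
      run_reference_baseline("gcn", graph, split, cfg2)$metrics$auc
    }, numeric(1))
    data.frame(depth = L, mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
  })
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"))
}

#' Enrichment factor of a ranked screen
#'
#' `EF = (hits_in_top / top_n) / (n_actives / N)` with
#' `top_n = floor(top_frac * N)`; ties are broken by stable id order.
#'
#' @param scores named numeric vector of candidate scores (names = ids)
#' @param actives character vector of active ids (subset of candidates)
#' @param top_frac fraction of the ranked list counted as "top"
#' @return list: `ef`, `hits`, `top_n`, `n_actives`, `n_candidates`
#' @export
enrichment_factor <- function(scores, actives, top_frac = 0.1) {
  if (length(actives) == 0)
    stop_cpifuse("EF undefined with no actives", "cpifuse_metric_error")
  if (top_frac <= 0 || top_frac > 1)
    stop_cpifuse("top_frac must be in (0, 1]", "cpifuse_config_error")
  if (!all(actives %in% names(scores)))
    stop_cpifuse("actives must be a subset of scored candidates", "cpifuse_contract_error")
  N <- length(scores)
  ord <- order(-scores, names(scores), method = "radix")
  top_n <- max(1L, floor(top_frac * N))
  hits <- sum(names(scores)[ord[seq_len(top_n)]] %in% actives)
  list(ef = (hits / top_n) / (length(actives) / N), hits = hits,
       top_n = top_n, n_actives = length(actives), n_candidates = N)
}

# Exact signed-rank distribution by generating-function convolution over
# doubled ranks (doubling keeps midranks integral).
signed_rank_exact_p <- function(ranks2, W2) {
  dist <- c(1)  # P(sum = 0..) over doubled statistic, unnormalized counts
  for (r in ranks2) {
    new <- c(dist, numeric(r))
    new[(r + 1):(r + length(dist))] <- new[(r + 1):(r + length(dist))] + dist
    dist <- new
  }
  tot <- sum(dist)
  idx <- seq_along(dist) - 1
  p_le <- sum(dist[idx <= W2]) / tot
  p_ge <- sum(dist[idx >= W2]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Exact paired Wilcoxon signed-rank comparison across seeds
#'
#' Zero differences are dropped (Wilcoxon convention), ties get midranks,
#' and the two-sided p-value is exact (full enumeration of the sign-flip
#' null) for n <= 15, with a normal approximation beyond. With all
#' differences zero the result carries `degenerate = TRUE`.
#'
#' @param a,b equal-length numeric vectors of per-seed metric values
#' @return list: `statistic` (V, sum of positive-difference ranks), `p`,
#'   `n_used`, `degenerate`, `exact`
#' @export
paired_seed_comparison <- function(a, b) {
  if (length(a) != length(b) || length(a) < 5)
    stop_cpifuse("need equal-length vectors, n >= 5", "cpifuse_contract_error")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n_used = 0,
                degenerate = TRUE, exact = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  n <- length(d)
  if (n <= 15) {
    p <- signed_rank_exact_p(as.integer(round(2 * r)), round(2 * V))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p <- min(1, 2 * stats::pnorm(-abs(V - mu) / sg))
    exact <- FALSE
  }
  list(statistic = V, p = p, n_used = n, degenerate = FALSE, exact = exact)
}

#' Mean, sd, coefficient of variation and t-based 95% CI across seeds
#'
#' Sample sd (n-1 denominator); `CV% = 100 * sd / mean`; CI half-width
#' `t_{0.975, n-1} * sd / sqrt(n)`.
#' @param values numeric vector of per-seed metric values (n >= 2)
#' @return list: `mean`, `sd`, `cv_pct` (NA with flag when mean is 0),
#'   `ci` (length 2), `ci_halfwidth`, `n`
#' @export
seed_statistics <- function(values) {
  n <- length(values)
  if (n < 2) stop_cpifuse("need at least 2 values", "cpifuse_contract_error")
  m <- mean(values); s <- stats::sd(values)
  hw <- stats::qt(0.975, n - 1) * s / sqrt(n)
  list(mean = m, sd = s,
       cv_pct = if (m == 0) NA_real_ else 100 * s / m,
       cv_undefined = m == 0,
       ci = c(m - hw, m + hw), ci_halfwidth = hw, n = n)
}
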