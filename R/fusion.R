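# Fusion model: per-branch prediction heads, simplex-constrained late
# fusion, negative sampling, BCE training with Adam + cosine decay + early
# stopping on validation AUC, and evaluation metrics.

#' Training configuration
#'
#' Defaults follow the training protocol of the method: Adam with initial
#' learning rate 1e-3 and L2 weight decay 1e-5 applied uniformly, cosine
#' learning-rate decay, dropout 0.2 on all hidden layers, batch size 128,
#' early stopping on validation AUC with patience 10, a 1:3
#' positive:negative sampling ratio, and a 200-epoch hard cap (typical
#' convergence is well before that).
#'
#' @param lr initial learning rate
#' @param weight_decay L2 penalty coefficient
#' @param dropout hidden-layer dropout rate
#' @param batch_size minibatch size
#' @param patience early-stopping patience (epochs without val-AUC gain)
#' @param negative_ratio negatives sampled per positive
#' @param max_epochs epoch cap
#' @param hidden hidden width of the branch heads
#' @param l1_ctc L1 penalty on the CTC metric weights (sparsity)
#' @param seed training seed (init, shuffling, dropout, negative sampling)
#' @param depth message-passing depth of the graph encoders (where used)
#' @param max_steps optional cap on optimizer steps (diagnostics)
#' @return list of class `train_config`
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-5, dropout = 0.2,
                         batch_size = 128, patience = 10, negative_ratio = 3,
                         max_epochs = 200, hidden = 128, l1_ctc = 1e-3,
                         seed = 0, depth = 2, max_steps = Inf) {
  stopifnot(lr > 0, weight_decay >= 0, dropout >= 0, dropout < 1,
            batch_size >= 1, patience >= 1, negative_ratio >= 1, max_epochs >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Simplex fusion weights from three logits
#'
#' Softmax parameterization: weights are strictly positive and sum to 1 by
#' construction, for any finite logits.
#' @param logits numeric(3)
#' @return named numeric(3): `alpha` (structure), `beta` (semantics),
#'   `delta` (topology)
#' @export
simplex_weights <- function(logits) {
  if (length(logits) != 3 || any(!is.finite(logits)))
    stop_cpifuse("need three finite logits", "cpifuse_contract_error")
  z <- exp(logits - max(logits))
  stats::setNames(z / sum(z), c("alpha", "beta", "delta"))
}

#' Late fusion of branch probabilities
#'
#' Convex combination `alpha*p_struct + beta*p_sem + delta*p_ctc`; the
#' result always lies within the closed interval spanned by the inputs.
#' @param p_struct,p_sem,p_ctc branch probabilities in `[0,1]` (vectorized)
#' @param w fusion weights: named numeric(3) or a logits vector passed
#'   through [simplex_weights()] when it does not sum to 1
#' @return fused probability
#' @export
fuse <- function(p_struct, p_sem, p_ctc, w) {
  if (abs(sum(w) - 1) > 1e-9) w <- simplex_weights(w)
  unname(w[1] * p_struct + w[2] * p_sem + w[3] * p_ctc)
}

#' Sample negative chemical-protein pairs
#'
#' Uniform without replacement from the non-interacting chem-prot pairs of
#' the graph (disjoint from all known positive edges), `ratio` negatives per
#' positive, deterministic per seed.
#'
#' @param positives data.frame with `chem`, `prot` columns
#' @param graph `cpi_graph` supplying node sets and the known-edge filter
#' @param ratio negatives per positive
#' @param seed integer seed
#' @return data.frame `chem`, `prot`, `label = 0`
#' @export
negative_sample <- function(positives, graph, ratio = 3, seed = 0) {
  chems <- graph$nodes$id[graph$nodes$kind == "chemical"]
  prots <- graph$nodes$id[graph$nodes$kind == "protein"]
  pos_all <- positive_pairs(graph)
  known <- paste(pos_all$chem, pos_all$prot, sep = "\r")
  m <- ratio * nrow(positives)
  pool <- length(chems) * length(prots) - length(unique(known))
  if (pool < m)
    stop_cpifuse(sprintf("negative pool too small: need %d, have %d (shortfall %d)",
                         m, pool, m - pool), "cpifuse_sampling_error")
  with_seed(seed, {
    got <- character(0)
    while (length(got) < m) {
      k <- max(2 * (m - length(got)), 64)
      cand <- paste(sample(chems, k, replace = TRUE),
                    sample(prots, k, replace = TRUE), sep = "\r")
      cand <- setdiff(cand, known)
      got <- unique(c(got, cand))
    }
    got <- got[seq_len(m)]
    parts <- strsplit(got, "\r", fixed = TRUE)
    data.frame(chem = vapply(parts, `[[`, "", 1), prot = vapply(parts, `[[`, "", 2),
               label = 0L, stringsAsFactors = FALSE)
  })
}

#' Binary cross-entropy loss
#'
#' `-sum(y*log(p) + (1-y)*log(1-p))`. Predictions exactly 0 or 1 are
#' clamped at 1e-12 with a warning.
#' @param labels 0/1 vector
#' @param preds predictions in (0,1)
#' @return non-negative scalar
#' @export
bce_loss <- function(labels, preds) {
  if (any(preds <= 0 | preds >= 1)) {
    warning("predictions at {0,1} clamped to 1e-12 for BCE")
    preds <- clamp01(preds)
  }
  -sum(labels * log(preds) + (1 - labels) * log(1 - preds))
}

#' Classification metrics
#'
#' AUC by the rank (Mann-Whitney) formulation with midranks for ties;
#' precision, recall and F1 at the 0.5 threshold.
#' @param labels 0/1 vector (both classes must be present)
#' @param scores predicted probabilities
#' @param threshold classification threshold
#' @return named list: `auc`, `precision`, `recall`, `f1`, `threshold`, `n`
#' @export
evaluate_metrics <- function(labels, scores, threshold = 0.5) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_cpifuse("metrics undefined with a single class", "cpifuse_metric_error")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  prec <- if (sum(pred == 1) > 0) tp / sum(pred == 1) else 0
  rec <- tp / n1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(auc = auc, precision = prec, recall = rec, f1 = f1,
       threshold = threshold, n = n1 + n0)
}

# ---------------------------------------------------------------------------
# Feature cache: everything the heads consume, precomputed once per dataset.

#' Precompute the modality feature caches for a CPI dataset
#'
#' Computes the normalized seven-metric centrality table and its
#' entropy-based CTC weight initialization, frozen geometric embeddings for
#' every protein structure, hashed fingerprints for every chemical, and the
#' semantic matrix from the embedding store (zero vectors for entities the
#' store does not cover). Branch training then touches only these caches.
#'
#' @param graph `cpi_graph`
#' @param structures named list of `protein_structure` (names = protein ids)
#' @param smiles named character vector of SMILES (names = chemical ids)
#' @param sem_store `embedding_store`
#' @param encoder `encoder_config` for the frozen structure encoder
#' @param nbits fingerprint width
#' @param radius fingerprint radius
#' @param cutoff contact-graph distance cutoff (Angstrom)
#' @return list of class `cpi_features`
#' @export
build_features <- function(graph, structures, smiles, sem_store,
                           encoder = encoder_config(), nbits = 1024,
                           radius = 2, cutoff = 8.0) {
  cent <- normalize_metrics(compute_centralities(graph))
  cent_mat <- as.matrix(cent[, CENTRALITY_METRICS])
  rownames(cent_mat) <- cent$node_id
  ctc_init <- entropy_weight_init(cent)
  prot_ids <- names(structures)
  cgs <- lapply(structures, build_contact_graph, cutoff = cutoff)
  prot_emb <- t(vapply(cgs, function(cg) as.numeric(encode_protein(cg, encoder)),
                       numeric(encoder$s_dim)))
  rownames(prot_emb) <- prot_ids
  chem_ids <- names(smiles)
  fp <- t(vapply(smiles, function(s) fp_dense(ecfp_fingerprint(s, radius, nbits)),
                 numeric(nbits)))
  rownames(fp) <- chem_ids
  ids <- graph$nodes$id
  sem <- t(vapply(ids, function(id) get_embedding(id, sem_store, fallback = "zero"),
                  numeric(sem_store$dim)))
  rownames(sem) <- ids
  # column-standardize semantic inputs (zero stays zero: ablation-safe scale-only)
  csd <- apply(sem, 2, stats::sd)
  sem <- sweep(sem, 2, ifelse(csd > 0, csd, 1), "/")
  structure(list(cent = cent, cent_mat = cent_mat, ctc_init = ctc_init,
                 prot_emb = prot_emb, fp = fp, sem = sem,
                 encoder = encoder, contact_graphs = cgs, cutoff = cutoff,
                 nbits = nbits, sem_dim = sem_store$dim),
            class = "cpi_features")
}

# Per-pair design matrices for a set of labeled pairs.
pair_matrices <- function(feats, pairs) {
  Fm <- (feats$cent_mat[pairs$chem, , drop = FALSE] +
         feats$cent_mat[pairs$prot, , drop = FALSE]) / 2
  list(F = Fm,
       FP = feats$fp[pairs$chem, , drop = FALSE],
       EP = feats$prot_emb[pairs$prot, , drop = FALSE],
       SU = feats$sem[pairs$chem, , drop = FALSE],
       SV = feats$sem[pairs$prot, , drop = FALSE],
       y = if ("label" %in% names(pairs)) pairs$label else rep(NA_real_, nrow(pairs)))
}

init_fusion_params <- function(feats, cfg) {
  ed <- ncol(feats$prot_emb)
  list(ctc = list(w = unname(feats$ctc_init$w), a = 1, b = 0),
       proj = init_mlp(feats$nbits, cfg$hidden, ed),
       headG = init_mlp(2 * ed, cfg$hidden, 1),
       headL = init_mlp(2 * feats$sem_dim, cfg$hidden, 1),
       flog = c(0, 0, 0))   # uniform simplex initialization
}

fusion_forward <- function(par, pm, cfg, training = FALSE) {
  s <- as.numeric(pm$F %*% par$ctc$w)
  p_t <- sigmoid(par$ctc$a * s + par$ctc$b)
  fwP <- mlp_forward(par$proj, pm$FP, cfg$dropout, training)
  Zc <- fwP$out
  Hcat <- cbind(Zc, pm$EP)
  fwG <- mlp_forward(par$headG, Hcat, cfg$dropout, training)
  p_s <- sigmoid(as.numeric(fwG$out))
  Ssem <- cbind(pm$SU, pm$SV)
  fwL <- mlp_forward(par$headL, Ssem, cfg$dropout, training)
  p_l <- sigmoid(as.numeric(fwL$out))
  w3 <- simplex_weights(par$flog)
  phat <- w3[1] * p_s + w3[2] * p_l + w3[3] * p_t
  list(p_struct = p_s, p_sem = p_l, p_topo = p_t, p_fused = as.numeric(phat),
       w3 = w3, s = s, fwP = fwP, fwG = fwG, fwL = fwL, Hcat = Hcat)
}

fusion_backward <- function(par, pm, fw, cfg) {
  B <- length(fw$p_fused)
  p <- clamp01(fw$p_fused)
  g <- (p - pm$y) / (p * (1 - p)) / B
  w3 <- fw$w3
  q <- c(sum(g * fw$p_struct), sum(g * fw$p_sem), sum(g * fw$p_topo))
  dflog <- as.numeric(w3 * (q - sum(w3 * q)))
  # topology branch
  dlt <- g * w3[3] * fw$p_topo * (1 - fw$p_topo)
  gctc <- list(w = par$ctc$a * as.numeric(t(pm$F) %*% dlt) +
                 cfg$l1_ctc * sign(par$ctc$w),
               a = sum(dlt * fw$s), b = sum(dlt))
  # structure branch
  dlg <- matrix(g * w3[1] * fw$p_struct * (1 - fw$p_struct), ncol = 1)
  bg <- mlp_backward(par$headG, fw$fwG, dlg)
  dZc <- bg$dX[, seq_len(ncol(fw$fwP$out)), drop = FALSE]
  bp <- mlp_backward(par$proj, fw$fwP, dZc)
  # semantic branch
  dll <- matrix(g * w3[2] * fw$p_sem * (1 - fw$p_sem), ncol = 1)
  bl <- mlp_backward(par$headL, fw$fwL, dll)
  list(ctc = gctc, proj = bp$g, headG = bg$g, headL = bl$g, flog = dflog)
}

# ---------------------------------------------------------------------------

#' Train the late-fusion CPI model
#'
#' Trains the three branch heads, the CTC weight vector and calibration, and
#' the fusion logits jointly by minibatch Adam on the binary cross-entropy
#' of the fused probability, with cosine learning-rate decay, L2 weight
#' decay, dropout, an L1 penalty on the CTC weights, and early stopping on
#' validation AUC. Fully reproducible per `cfg$seed`.
#'
#' When `graph` is supplied and the training split contains only positives,
#' negatives are resampled once per epoch (seed offset by epoch index) at
#' `cfg$negative_ratio` per positive; validation negatives are drawn once.
#'
#' @param split list with `train` and `validation` data.frames
#'   (`chem`, `prot`, `label`)
#' @param feats `cpi_features` from [build_features()]
#' @param cfg `train_config`
#' @param graph optional `cpi_graph` enabling per-epoch negative resampling
#' @return object of class `cpi_model`: best parameters, per-epoch history
#'   (train loss, validation AUC, learning rate), learned fusion weights
#' @export
train_fusion_model <- function(split, feats, cfg = train_config(), graph = NULL) {
  tr <- split$train; va <- split$validation
  if (nrow(tr) == 0) stop_cpifuse("empty training split", "cpifuse_empty_input_error")
  resample <- !is.null(graph) && all(tr$label == 1)
  if (!resample && length(unique(tr$label)) < 2)
    stop_cpifuse("training labels are single-class", "cpifuse_training_error")
  if (resample) {
    va <- rbind(va, negative_sample(va, graph, cfg$negative_ratio, seed = cfg$seed + 900001))
  }
  pm_va <- pair_matrices(feats, va)
  with_seed(cfg$seed, {
    par <- init_fusion_params(feats, cfg)
    st <- adam_init(par)
    best <- list(par = par, crit = -Inf, epoch = 0)
    hist <- list()
    steps <- 0; stop_now <- FALSE
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- cosine_lr(cfg$lr, epoch, cfg$max_epochs)
      tr_ep <- if (resample)
        rbind(tr, negative_sample(tr, graph, cfg$negative_ratio,
                                  seed = cfg$seed + 7919 * epoch))
        else tr
      pm_tr <- pair_matrices(feats, tr_ep)
      n <- nrow(tr_ep)
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        pm <- lapply(pm_tr[c("F", "FP", "EP", "SU", "SV")],
                     function(M) M[idx, , drop = FALSE])
        pm$y <- pm_tr$y[idx]
        fw <- fusion_forward(par, pm, cfg, training = TRUE)
        ep_loss <- ep_loss + bce_loss(pm$y, clamp01(fw$p_fused))
        gr <- fusion_backward(par, pm, fw, cfg)
        upd <- adam_step(par, gr, st, lr, wd = cfg$weight_decay)
        par <- upd$par; st <- upd$state
        steps <- steps + 1
        if (steps >= cfg$max_steps) { stop_now <- TRUE; break }
      }
      fw_va <- fusion_forward(par, pm_va, cfg, training = FALSE)
      crit <- if (length(unique(pm_va$y)) == 2)
        evaluate_metrics(pm_va$y, fw_va$p_fused)$auc else -ep_loss
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                  val_auc = if (length(unique(pm_va$y)) == 2) crit else NA_real_,
                                  lr = lr)
      if (crit > best$crit + 1e-12) best <- list(par = par, crit = crit, epoch = epoch)
      if (stop_now || (epoch - best$epoch) >= cfg$patience) break
    }
    structure(list(par = best$par, cfg = cfg, history = do.call(rbind, hist),
                   best_epoch = best$epoch, val_auc = best$crit,
                   fusion_weights = simplex_weights(best$par$flog),
                   ctc_weights = structure(list(w = best$par$ctc$w,
                                                a = best$par$ctc$a,
                                                b = best$par$ctc$b,
                                                trainable = TRUE),
                                           class = "ctc_weights")),
              class = "cpi_model")
  })
}

#' @exportS3Method base::print
print.cpi_model <- function(x, ...) {
  cat(sprintf("<cpi_model> %d epochs (best %d), val AUC %.4f\n",
              nrow(x$history), x$best_epoch, x$val_auc))
  cat("fusion weights:", paste(sprintf("%s=%.3f", names(x$fusion_weights),
                                       x$fusion_weights), collapse = ", "), "\n")
  invisible(x)
}

#' Predict interaction probabilities for chemical-protein pairs
#'
#' @param model `cpi_model`
#' @param feats `cpi_features` (possibly ablated; see [ablate_features()])
#' @param pairs data.frame with `chem`, `prot` (optional `label`)
#' @param fusion_weights optional fixed simplex weights overriding the
#'   learned ones (manual-weight mode for robustness analysis)
#' @return data.frame with per-branch and fused probabilities
#' @export
predict_cpi <- function(model, feats, pairs, fusion_weights = NULL) {
  pm <- pair_matrices(feats, pairs)
  fw <- fusion_forward(model$par, pm, model$cfg, training = FALSE)
  w3 <- if (is.null(fusion_weights)) fw$w3 else {
    if (abs(sum(fusion_weights) - 1) > 1e-9)
      stop_cpifuse("manual fusion weights must sum to 1", "cpifuse_config_error")
    fusion_weights
  }
  data.frame(chem = pairs$chem, prot = pairs$prot,
             p_struct = fw$p_struct, p_sem = fw$p_sem, p_topo = fw$p_topo,
             p_fused = as.numeric(w3[1] * fw$p_struct + w3[2] * fw$p_sem +
                                  w3[3] * fw$p_topo),
             stringsAsFactors = FALSE)
}

#' Evaluate a trained model on labeled pairs
#' @param model `cpi_model`
#' @param pairs data.frame with `chem`, `prot`, `label`
#' @param feats `cpi_features`
#' @param fusion_weights optional manual simplex weights
#' @return metrics list from [evaluate_metrics()]
#' @export
evaluate <- function(model, pairs, feats, fusion_weights = NULL) {
  pr <- predict_cpi(model, feats, pairs, fusion_weights)
  evaluate_metrics(pairs$label, pr$p_fused)
}

# ---------------------------------------------------------------------------

#' Early-fusion baseline: one head on concatenated pair features
#'
#' Concatenates the topological pair features, both semantic vectors, the
#' (fixed seeded sign-projection of the) chemical fingerprint and the frozen
#' protein embedding into a single input, and trains one 2-layer head with
#' the same optimizer protocol as the late-fusion model.
#'
#' @inheritParams train_fusion_model
#' @return list of class `cpi_early_model` with `par`, `history`,
#'   `input_dim`, `val_auc` and a `predict(pairs)` closure
#' @export
early_fusion_baseline <- function(split, feats, cfg = train_config(), graph = NULL) {
  tr <- split$train; va <- split$validation
  if (nrow(tr) == 0) stop_cpifuse("empty training split", "cpifuse_empty_input_error")
  resample <- !is.null(graph) && all(tr$label == 1)
  if (resample)
    va <- rbind(va, negative_sample(va, graph, cfg$negative_ratio, seed = cfg$seed + 900001))
  ed <- ncol(feats$prot_emb)
  Pfold <- with_seed(cfg$seed + 424243,
    matrix(sample(c(-1, 1), feats$nbits * ed, replace = TRUE) / sqrt(feats$nbits),
           feats$nbits, ed))
  design <- function(pairs) {
    pm <- pair_matrices(feats, pairs)
    cbind(pm$F, pm$SU, pm$SV, pm$FP %*% Pfold, pm$EP)
  }
  X_va <- design(va)
  d_in <- ncol(X_va)
  with_seed(cfg$seed, {
    par <- init_mlp(d_in, cfg$hidden, 1)
    st <- adam_init(par)
    best <- list(par = par, crit = -Inf, epoch = 0)
    hist <- list()
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- cosine_lr(cfg$lr, epoch, cfg$max_epochs)
      tr_ep <- if (resample)
        rbind(tr, negative_sample(tr, graph, cfg$negative_ratio,
                                  seed = cfg$seed + 7919 * epoch)) else tr
      X <- design(tr_ep); y <- tr_ep$label
      n <- nrow(X); ord <- sample.int(n); ep_loss <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        fwd <- mlp_forward(par, X[idx, , drop = FALSE], cfg$dropout, TRUE)
        p <- clamp01(sigmoid(as.numeric(fwd$out)))
        ep_loss <- ep_loss + bce_loss(y[idx], p)
        dOut <- matrix((p - y[idx]) / length(idx), ncol = 1)
        gr <- mlp_backward(par, fwd, dOut)$g
        upd <- adam_step(par, gr, st, lr, wd = cfg$weight_decay)
        par <- upd$par; st <- upd$state
      }
      p_va <- sigmoid(as.numeric(mlp_forward(par, X_va)$out))
      crit <- if (length(unique(va$label)) == 2)
        evaluate_metrics(va$label, p_va)$auc else -ep_loss
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n, val_auc = crit)
      if (crit > best$crit + 1e-12) best <- list(par = par, crit = crit, epoch = epoch)
      if ((epoch - best$epoch) >= cfg$patience) break
    }
    par <- best$par
    structure(list(par = par, history = do.call(rbind, hist), input_dim = d_in,
                   val_auc = best$crit,
                   predict = function(pairs)
                     sigmoid(as.numeric(mlp_forward(par, design(pairs))$out))),
              class = "cpi_early_model")
  })
}
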