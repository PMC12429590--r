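test_that("simplex weights are positive, sum to 1, and hit the stated limits", {
  w <- simplex_weights(c(0, 0, 0))
  expect_equal(unname(w), rep(1 / 3, 3))
  expect_named(w, c("alpha", "beta", "delta"))
  expect_equal(unname(simplex_weights(c(40, 0, 0))), c(1, 0, 0), tolerance = 1e-15)
  set.seed(2)
  for (i in 1:50) {
    w <- simplex_weights(rnorm(3, sd = 5))
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  expect_error(simplex_weights(c(Inf, 0, 0)), class = "cpifuse_contract_error")
})

test_that("late fusion is the stated convex combination", {
  expect_equal(fuse(0.9, 0.5, 0.1, c(0.5, 0.3, 0.2)), 0.62)
  expect_equal(fuse(0.7, 0.7, 0.7, simplex_weights(rnorm(3))), 0.7)
  expect_equal(fuse(0.9, 0.5, 0.1, c(1, 0, 0)), 0.9)
  # bounded by the branch interval for arbitrary simplex weights
  set.seed(3)
  for (i in 1:50) {
    p <- runif(3); w <- simplex_weights(rnorm(3))
    f <- fuse(p[1], p[2], p[3], w)
    expect_gte(f, min(p)); expect_lte(f, max(p))
  }
})

test_that("fusion gradient wrt each branch equals its simplex weight", {
  w <- simplex_weights(c(0.3, -0.2, 0.5))
  p <- c(0.8, 0.4, 0.6); eps <- 1e-7
  for (b in 1:3) {
    dp <- numeric(3); dp[b] <- eps
    num <- (fuse(p[1] + dp[1], p[2] + dp[2], p[3] + dp[3], w) -
            fuse(p[1] - dp[1], p[2] - dp[2], p[3] - dp[3], w)) / (2 * eps)
    expect_equal(num, unname(w[b]), tolerance = 1e-6)
  }
})

test_that("negative sampling is exact-count, disjoint and deterministic", {
  set.seed(1)
  ids_c <- sprintf("c%02d", 1:20); ids_p <- sprintf("p%02d", 1:20)
  g <- cpi_graph(data.frame(id = c(ids_c, ids_p),
                            kind = rep(c("chemical", "protein"), each = 20)),
                 data.frame(u = rep(ids_c, 2), v = sample(rep(ids_p, 2))))
  e <- g$edges[g$edges$etype == "chem-prot", ]
  pos <- data.frame(chem = pmin(e$u, e$v), prot = pmax(e$u, e$v), label = 1L)
  neg <- negative_sample(pos, g, ratio = 3, seed = 7)
  expect_equal(nrow(neg), 3 * nrow(pos))
  expect_length(intersect(paste(neg$chem, neg$prot), paste(pos$chem, pos$prot)), 0)
  expect_false(anyDuplicated(paste(neg$chem, neg$prot)) > 0)
  expect_identical(neg, negative_sample(pos, g, ratio = 3, seed = 7))
  expect_false(identical(neg, negative_sample(pos, g, ratio = 3, seed = 8)))
  # pool-exhaustion error reports the shortfall
  small <- cpi_graph(data.frame(id = c("c1", "p1", "p2"),
                                kind = c("chemical", "protein", "protein")),
                     data.frame(u = "c1", v = "p1"))
  expect_error(negative_sample(data.frame(chem = "c1", prot = "p1"), small, 3, 0),
               regexp = "shortfall", class = "cpifuse_sampling_error")
})

test_that("bce_loss matches closed forms", {
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-8)
  set.seed(4)
  y <- rbinom(20, 1, 0.5); p <- runif(20, 0.01, 0.99)
  expect_equal(bce_loss(y, p), bce_loss(1 - y, 1 - p))
  expect_gte(bce_loss(y, p), 0)
  expect_warning(bce_loss(1, 1), regexp = "clamped")
})

test_that("evaluate_metrics AUC equals concordant-pair counting with midranks", {
  expect_equal(evaluate_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(evaluate_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_equal(evaluate_metrics(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(evaluate_metrics(y, s)$auc, oracle_auc(y, s))
  }
  m <- evaluate_metrics(c(1, 1, 0, 0), c(0.9, 0.3, 0.6, 0.1))
  expect_equal(m$precision, 0.5); expect_equal(m$recall, 0.5); expect_equal(m$f1, 0.5)
  expect_error(evaluate_metrics(c(1, 1), c(0.2, 0.3)), class = "cpifuse_metric_error")
})

test_that("training reduces loss, is seed-reproducible, and obeys patience", {
  d <- planted_data(sw_named(topology = 1))
  cfg <- train_config(seed = 3, max_epochs = 12, patience = 6, hidden = 32)
  m1 <- train_fusion_model(d$split, d$feats, cfg)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_fusion_model(d$split, d$feats, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)
  expect_lte(nrow(m1$history), 12)
  expect_lte(nrow(m1$history) - m1$best_epoch, cfg$patience)
  # single-class labels refuse to train
  bad <- d$split; bad$train$label <- 1L
  expect_error(train_fusion_model(bad, d$feats, cfg),
               class = "cpifuse_training_error")
})

test_that("per-epoch negative resampling path trains from graph positives", {
  d <- planted_data(sw_named(topology = 1))
  g <- d$ds$graph
  sp <- split_pairs(g, seed = 2)  # positives only
  cfg <- train_config(seed = 3, max_epochs = 4, patience = 3, hidden = 16)
  m <- train_fusion_model(sp, d$feats, cfg, graph = g)
  expect_equal(nrow(m$history), 4)
  expect_true(all(is.finite(m$history$train_loss)))
})

test_that("early-fusion baseline trains on the concatenated design", {
  d <- planted_data(sw_named(topology = 1))
  cfg <- train_config(seed = 2, max_epochs = 8, patience = 4, hidden = 32)
  em <- early_fusion_baseline(d$split, d$feats, cfg)
  # input dim = topo pair (7) + semantic pair (2d) + folded fp (128) + protein (64)
  expect_equal(em$input_dim, 7 + 2 * d$feats$sem_dim + ncol(d$feats$prot_emb) * 2)
  p <- em$predict(d$split$test)
  expect_length(p, nrow(d$split$test))
  expect_true(all(p > 0 & p < 1))
  em2 <- early_fusion_baseline(d$split, d$feats, cfg)
  expect_equal(em2$history, em$history)
})

test_that("L1 regularization drives trained CTC weights toward sparsity", {
  d <- planted_data(sw_named(topology = 1))
  fit_w <- function(l1, s) {
    tc <- train_config(seed = s, max_epochs = 60, patience = 60,
                       hidden = 16, l1_ctc = l1)
    train_fusion_model(d$split, d$feats, tc)$par$ctc$w
  }
  for (s in 2:3) {
    w_plain <- fit_w(0, s)
    w_l1 <- fit_w(0.1, s)
    expect_lt(sum(abs(w_l1)), sum(abs(w_plain)))
    expect_lte(sum(abs(w_l1) > 0.2), sum(abs(w_plain) > 0.2))
  }
})
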