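test_that("null perturbation gives exactly delta_p = 0", {
  r <- planted_model(sw_named(topology = 1), train_seed = 1, patience = 3, max_epochs = 3)
  pair <- r$data$split$test[1, ]
  pr <- perturb_topology(r$model, r$data$feats, r$data$ds$graph, pair, k = 0)
  expect_identical(pr$delta_p, 0)
  expect_equal(pr$baseline, pr$perturbed)
})

test_that("perturbation decouples when the topology fusion weight is zero", {
  r <- planted_model(sw_named(topology = 1), train_seed = 1, patience = 3, max_epochs = 3)
  m0 <- r$model
  m0$par$flog <- c(10, 10, -30)           # delta ~ 0
  m0$fusion_weights <- simplex_weights(m0$par$flog)
  pair <- r$data$split$test[1, ]
  pr <- perturb_topology(m0, r$data$feats, r$data$ds$graph, pair, k = 5)
  expect_lt(abs(pr$delta_p), 1e-9)
})

test_that("excessive k removes all candidate edges and flags it", {
  r <- planted_model(sw_named(topology = 1), train_seed = 1, patience = 3, max_epochs = 3)
  pair <- r$data$split$test[1, ]
  pr <- perturb_topology(r$model, r$data$feats, r$data$ds$graph, pair, k = 10^6)
  expect_false(is.null(pr$flag))
  expect_lt(pr$k, 10^6)
})

test_that("delta_p distribution is deterministic per seed with sane summaries", {
  r <- planted_model(sw_named(topology = 1), train_seed = 1, patience = 3, max_epochs = 3)
  d1 <- delta_p_distribution(r$model, r$data$feats, r$data$ds$graph,
                             n_proteins = 10, k = 3, seed = 5)
  d2 <- delta_p_distribution(r$model, r$data$feats, r$data$ds$graph,
                             n_proteins = 10, k = 3, seed = 5)
  expect_identical(d1, d2)
  expect_length(d1$delta_p, 10)
  expect_lte(d1$interval[1], d1$median)
  expect_gte(d1$interval[2], d1$median)
  expect_error(delta_p_distribution(r$model, r$data$feats, r$data$ds$graph,
                                    n_proteins = 10^5, k = 3, seed = 5),
               class = "cpifuse_sampling_error")
})

test_that("fusion-weight sweep covers exactly the 36-point constrained grid", {
  r <- planted_model(sw_named(topology = 1), train_seed = 1, patience = 3, max_epochs = 3)
  sw <- sweep_fusion_weights(r$model, r$data$feats, r$data$split$test, grid_step = 0.1)
  expect_equal(nrow(sw), 36)
  expect_true(all(abs(sw$alpha + sw$beta + sw$delta - 1) < 1e-9))
  expect_true(all(sw$alpha >= 0.1 - 1e-9 & sw$alpha <= 0.8 + 1e-9))
  expect_error(sweep_fusion_weights(r$model, r$data$feats, r$data$split$test, 0.13),
               class = "cpifuse_config_error")
  # degenerate model: identical branches give a flat surface
  m0 <- r$model
  pr <- predict_cpi(m0, r$data$feats, r$data$split$test)
  # force all branch probabilities equal by evaluating on constant features
  f0 <- r$data$feats
  f0$sem[] <- 0; f0$fp[] <- 0
  f0$cent_mat[] <- 0.5
  f0$prot_emb[] <- colMeans(f0$prot_emb)[col(f0$prot_emb)]
  sw0 <- sweep_fusion_weights(m0, f0, r$data$split$test)
  expect_lt(diff(range(sw0$auc)), 1e-9)
})

test_that("enrichment factor matches exhaustive counting and closed forms", {
  # perfect ranking: 30 actives in 1000, top 10% -> EF = 10
  scores <- stats::setNames(seq(1000, 1, -1) / 1000, sprintf("m%04d", 1:1000))
  actives <- sprintf("m%04d", 1:30)
  ef <- enrichment_factor(scores, actives, 0.1)
  expect_equal(ef$ef, 10)
  expect_equal(ef$hits, 30)
  # hand-worked: 4 actives in 100, 2 in top 20 -> EF 2.5
  s2 <- stats::setNames(c(rep(0.9, 2), rep(0.1, 2), runif(96, 0.2, 0.8)),
                        sprintf("x%03d", 1:100))
  ef2 <- enrichment_factor(s2, sprintf("x%03d", 1:4), 0.2)
  expect_equal(ef2$ef, 2.5)
  # oracle equivalence on random rankings
  set.seed(6)
  for (i in 1:10) {
    N <- sample(50:500, 1)
    sc <- stats::setNames(runif(N), sprintf("c%04d", 1:N))
    act <- sample(names(sc), sample(3:20, 1))
    tf <- sample(c(0.05, 0.1, 0.25), 1)
    expect_equal(enrichment_factor(sc, act, tf)$ef, oracle_ef(sc, act, tf))
  }
  # random permutation: EF -> 1 in expectation
  set.seed(7)
  efs <- replicate(200, {
    sc <- stats::setNames(runif(1000), sprintf("c%04d", 1:1000))
    enrichment_factor(sc, sprintf("c%04d", 1:30), 0.1)$ef
  })
  expect_lt(abs(mean(efs) - 1), 0.2)
  expect_error(enrichment_factor(scores, character(0)), class = "cpifuse_metric_error")
})

test_that("exact Wilcoxon matches brute-force sign enumeration", {
  # n = 5, all one sign: two-sided p = 2/2^5
  r <- paired_seed_comparison(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(r$p, 0.0625)
  expect_true(r$exact)
  # degenerate: identical vectors
  expect_true(paired_seed_comparison(1:5, 1:5)$degenerate)
  # random cases vs enumeration, including ties and zero differences
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    a <- round(runif(n), 1); b <- round(runif(n), 1)
    if (all(a == b)) a[1] <- a[1] + 0.3
    expect_equal(paired_seed_comparison(a, b)$p, oracle_wilcoxon_p(a - b),
                 tolerance = 1e-12, label = paste(a - b, collapse = ","))
  }
  expect_error(paired_seed_comparison(1:4, 2:5), class = "cpifuse_contract_error")
})

test_that("seed statistics match hand arithmetic and the t-quantile", {
  s <- seed_statistics(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1); expect_equal(s$cv_pct, 50)
  s5 <- seed_statistics(c(0.91, 0.92, 0.93, 0.94, 0.95))
  expect_equal(s5$ci_halfwidth, 2.776 * s5$sd / sqrt(5), tolerance = 1e-3)
  sc <- seed_statistics(rep(0.9, 4))
  expect_equal(sc$sd, 0); expect_equal(sc$cv_pct, 0)
  expect_equal(diff(sc$ci), 0)
  s0 <- seed_statistics(c(-1, 1))
  expect_true(s0$cv_undefined)
})

test_that("semantic reinforcement scales inputs and only that", {
  r <- planted_model(sw_named(topology = 1), train_seed = 1, patience = 3, max_epochs = 3)
  f2 <- reinforce_semantics(r$data$feats, factor = 3)
  expect_equal(f2$sem, r$data$feats$sem * 3)
  expect_identical(f2$prot_emb, r$data$feats$prot_emb)
  pr1 <- predict_cpi(r$model, r$data$feats, r$data$split$test[1:5, ])
  pr2 <- predict_cpi(r$model, f2, r$data$split$test[1:5, ])
  expect_identical(pr1$p_topo, pr2$p_topo)     # other branches untouched
  expect_identical(pr1$p_struct, pr2$p_struct)
  expect_error(reinforce_semantics(r$data$feats, 0.5), class = "cpifuse_config_error")
})
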