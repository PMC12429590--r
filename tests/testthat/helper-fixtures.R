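# Shared fixtures. Expensive artifacts (planted datasets, trained models)
# are built lazily and cached for the whole test run; all are pure
# functions of fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

toy_graph <- function() {
  cpi_graph(
    data.frame(id = c("c1", "c2", "p1", "p2", "p3"),
               kind = c("chemical", "chemical", "protein", "protein", "protein")),
    data.frame(u = c("c1", "c1", "c2", "p1", "p2"),
               v = c("p1", "p2", "p2", "p2", "p3"),
               confidence = c(0.9, 0.8, NA, 0.7, NA)))
}

toy_structure <- function(n = 5, spacing = 4) {
  protein_structure(rep("A", n), cbind(spacing * (seq_len(n) - 1), 0, 0),
                    rep(90, n))
}

# desk-scale planted dataset + features, keyed by signal weights
planted_data <- function(sw, data_seed = 11) {
  key <- paste0("data_", paste(sw, collapse = "_"), "_", data_seed)
  fixture(key, function() {
    cfg <- generator_config(n_chem = 150, n_prot = 150, embedding_dim = 8,
                            residue_length = c(30L, 45L), negative_multiple = 3,
                            archetype_spread = 0.1, sem_noise = 0.1,
                            signal_weights = sw, seed = data_seed)
    ds <- generate_cpi_dataset(cfg)
    feats <- build_features(ds$graph, ds$structures, ds$smiles, ds$sem_store,
                            encoder = encoder_config(layers = 2, s_dim = 64, v_dim = 8),
                            nbits = 512)
    list(ds = ds, feats = feats, split = split_dataset(ds))
  })
}

sw_named <- function(topology = 0, semantics = 0, structure = 0) {
  c(topology = topology, semantics = semantics, structure = structure)
}

# trained late-fusion model on a planted dataset, cached per (weights, seed)
planted_model <- function(sw, train_seed, patience = 40, max_epochs = 200) {
  key <- paste0("model_", paste(sw, collapse = "_"), "_", train_seed,
                "_", patience, "_", max_epochs)
  fixture(key, function() {
    d <- planted_data(sw)
    m <- train_fusion_model(d$split, d$feats,
                            train_config(seed = train_seed, hidden = 128,
                                         patience = patience,
                                         max_epochs = max_epochs))
    list(model = m, data = d)
  })
}
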