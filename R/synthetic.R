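# Synthetic data: CPI networks with a target degree profile and planted
# protein hubs, toy C-alpha traces with pLDDT, fragment-grammar chemicals,
# label-correlated semantic embeddings, and labels drawn from a planted
# per-modality log-odds model whose true score is retained as an oracle.
#
# Everything is a pure function of the configuration (seed included), so
# every artifact is reproducible bit for bit.

#' Generator configuration
#'
#' Defaults emulate the sparse dataset shape of the public chemical-protein
#' resources this tool targets: mean interaction degree 2.8 for chemicals
#' and 3.1 for proteins, with a small planted-hub fraction giving the
#' protein side a heavy tail. `effect_scale = 3.0` is a one-off calibration
#' (see the methods vignette) giving single-modality AUC around 0.75 and a
#' Bayes-oracle AUC around 0.97 when all three signal weights are 1.
#'
#' @param n_chem,n_prot node counts (>= 2)
#' @param mean_degree_chem,mean_degree_prot target mean interaction degrees
#' @param hub_fraction fraction of proteins given elevated attachment
#' @param hub_boost degree multiplier for hub proteins
#' @param signal_weights named numeric(3): relative label signal carried by
#'   `topology`, `semantics`, `structure` (>= 0)
#' @param effect_scale global effect-size multiplier on the standardized
#'   modality scores
#' @param embedding_dim semantic embedding dimension
#' @param sem_noise semantic observation noise (sd of the perturbation of
#'   the planted direction)
#' @param residue_length integer(2): residue-count range of generated chains
#' @param n_classes planted protein structure classes
#' @param negative_multiple unlabeled candidate pairs drawn per positive edge
#' @param seed mandatory integer seed
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_chem = 2000, n_prot = 2000,
                             mean_degree_chem = 2.8, mean_degree_prot = 3.1,
                             hub_fraction = 0.05, hub_boost = 6,
                             signal_weights = c(topology = 1, semantics = 1, structure = 1),
                             effect_scale = 3.0, embedding_dim = 64,
                             sem_noise = 0.1, n_archetypes = 8,
                             archetype_spread = 0.1,
                             residue_length = c(40L, 80L),
                             n_classes = 3, negative_multiple = 1, seed) {
  if (missing(seed)) stop_cpifuse("generator seed is mandatory", "cpifuse_config_error")
  stopifnot(n_chem >= 2, n_prot >= 2, all(signal_weights >= 0),
            all(is.finite(signal_weights)), residue_length[1] >= 3,
            residue_length[2] >= residue_length[1])
  if (mean_degree_chem > n_prot - 1 || mean_degree_prot > n_chem - 1 + n_prot - 1)
    stop_cpifuse("infeasible degree targets", "cpifuse_config_error")
  sw <- signal_weights
  if (is.null(names(sw))) names(sw) <- c("topology", "semantics", "structure")
  cfg <- as.list(environment())
  cfg$signal_weights <- sw
  structure(cfg, class = "generator_config")
}

# Integer degree sequence with mean target: floor/ceil mix summing to total.
near_regular_degrees <- function(n, total) {
  base <- total %/% n
  extra <- total - base * n
  c(rep(base + 1L, extra), rep(base, n - extra))
}

#' Generate a synthetic CPI network
#'
#' Bipartite chem-prot edges by stub matching of near-regular chemical
#' degrees against protein degrees with a planted hub set (hub proteins get
#' `hub_boost` times the baseline attachment), plus a sparse small-world
#' protein-protein overlay (ring over a shuffled protein order, 10%
#' rewired) sized so the protein-side mean degree hits its target.
#'
#' @param cfg `generator_config`
#' @return `cpi_graph`
#' @export
generate_cpi_network <- function(cfg) {
  with_seed(cfg$seed, {
    chems <- sprintf("C%04d", seq_len(cfg$n_chem))
    prots <- sprintf("P%04d", seq_len(cfg$n_prot))
    m <- round(cfg$mean_degree_chem * cfg$n_chem)
    deg_c <- sample(near_regular_degrees(cfg$n_chem, m))
    n_hub <- round(cfg$hub_fraction * cfg$n_prot)
    t_p <- m / cfg$n_prot
    hub_deg <- round(cfg$hub_boost * t_p)
    n_hub <- min(n_hub, floor(m / max(hub_deg, 1)))
    rest <- m - n_hub * hub_deg
    deg_p <- sample(c(rep(hub_deg, n_hub),
                      near_regular_degrees(cfg$n_prot - n_hub, rest)))
    stubs_c <- rep(seq_len(cfg$n_chem), deg_c)
    stubs_p <- rep(seq_len(cfg$n_prot), deg_p)
    stubs_p <- sample(stubs_p)
    key <- function(i, j) i * (cfg$n_prot + 1) + j
    e_c <- stubs_c; e_p <- stubs_p
    # resolve multi-edges by reshuffling the duplicated protein stubs
    for (it in 1:200) {
      dup <- duplicated(key(e_c, e_p))
      if (!any(dup)) break
      idx <- which(dup)
      if (length(idx) >= 2) e_p[idx] <- e_p[sample(idx)]
      else e_p[idx] <- sample.int(cfg$n_prot, 1)
    }
    dup <- duplicated(key(e_c, e_p))
    if (any(dup)) { e_c <- e_c[!dup]; e_p <- e_p[!dup] }  # rare residue: drop
    edges <- data.frame(u = chems[e_c], v = prots[e_p], stringsAsFactors = FALSE)
    n_pp <- max(0, round((cfg$mean_degree_prot - length(e_c) / cfg$n_prot) *
                           cfg$n_prot / 2))
    if (n_pp > 0) {
      ring <- sample(prots)
      a <- ring[seq_len(min(n_pp, cfg$n_prot))]
      b <- ring[c(seq_len(min(n_pp, cfg$n_prot))[-1], 1)]
      rew <- stats::runif(length(a)) < 0.1
      b[rew] <- sample(prots, sum(rew), replace = TRUE)
      keep <- a != b
      edges <- rbind(edges, data.frame(u = a[keep], v = b[keep]))
    }
    cpi_graph(data.frame(id = c(chems, prots),
                         kind = rep(c("chemical", "protein"), c(cfg$n_chem, cfg$n_prot))),
              edges)
  })
}

#' Generate toy C-alpha traces with pLDDT
#'
#' Each protein is an ideal alpha-helical trace (consecutive C-alpha spacing
#' ~3.8 A) built from helical segments joined by random reorientations, with
#' clash rejection (no nonadjacent pair under 3 A). The planted structure
#' class biases the amino-acid composition, which is what makes the class
#' recoverable by the structure encoder. pLDDT is high in the core and low
#' at the termini.
#'
#' @param cfg `generator_config`
#' @param classes optional integer vector of planted classes per protein
#' @return named list of `protein_structure` (names `P0001`, ...), with the
#'   class vector as attribute `classes`
#' @export
generate_structures <- function(cfg, classes = NULL) {
  prots <- sprintf("P%04d", seq_len(cfg$n_prot))
  with_seed(cfg$seed + 1, {
    if (is.null(classes))
      classes <- sample.int(cfg$n_classes, cfg$n_prot, replace = TRUE)
    aa20 <- setdiff(AA_ALPHABET, "X")
    # class-specific composition: each class strongly favors its own third
    comp <- lapply(seq_len(cfg$n_classes), function(k) {
      w <- rep(1, 20)
      fav <- ((seq_len(20) + 6 * k) %% 20) + 1
      w[fav[1:7]] <- 8
      w / sum(w)
    })
    out <- lapply(seq_len(cfg$n_prot), function(p) {
      L <- sample(cfg$residue_length[1]:cfg$residue_length[2], 1)
      aa <- sample(aa20, L, replace = TRUE, prob = comp[[classes[p]]])
      coords <- helical_trace(L)
      core <- pmin(seq_len(L) - 1, L - seq_len(L), 8)
      plddt <- pmin(100, pmax(0, ifelse(core >= 8,
                                        stats::rnorm(L, 90, 3),
                                        stats::rnorm(L, 60, 8))))
      protein_structure(aa, coords, plddt)
    })
    names(out) <- prots
    attr(out, "classes") <- classes
    out
  })
}

# Ideal helix segments joined by random rotations, clash-rejected.
helical_trace <- function(L, seg_len = 12L) {
  r <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  coords <- matrix(0, L, 3)
  origin <- c(0, 0, 0)
  R <- diag(3)
  placed <- 0
  t0 <- 0
  while (placed < L) {
    k <- min(seg_len, L - placed)
    for (attempt in 1:50) {
      tt <- t0 + turn * seq_len(k)
      seg <- cbind(r * cos(tt), r * sin(tt), rise * (tt - t0) / turn)
      seg0 <- cbind(r * cos(t0), r * sin(t0), 0)
      local <- sweep(seg, 2, as.numeric(seg0))
      cand <- sweep(local %*% t(R), 2, origin, "+")
      ok <- TRUE
      if (placed > 1) {
        prev <- coords[seq_len(placed), , drop = FALSE]
        dmin <- min(sqrt(outer(rowSums(cand^2), rowSums(prev^2), "+") -
                           2 * cand %*% t(prev)))
        ok <- is.finite(dmin) && dmin >= 3
      }
      if (ok) break
      R <- R %*% random_rotation()
    }
    coords[placed + seq_len(k), ] <- cand
    placed <- placed + k
    origin <- coords[placed, ]
    t0 <- t0 + turn * k
    R <- R %*% random_rotation(max_angle = 0.9)
  }
  coords
}

random_rotation <- function(max_angle = pi) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_angle, max_angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate SMILES strings from a fragment grammar
#'
#' Molecules are linear assemblies of 2-5 pieces drawn from a small grammar
#' of alkyl, aryl, ether, amide and related fragments; ring-closure digits
#' are renumbered per occurrence so every output is a valid SMILES. Outputs
#' are drawn (with replacement) from a seeded library of `library_size`
#' distinct assemblies, mirroring the scaffold reuse of real screening
#' collections; duplicates are therefore expected.
#'
#' @param n number of molecules
#' @param seed integer seed
#' @param library_size number of distinct molecules in the seeded library
#' @return character vector of SMILES (duplicates allowed)
#' @export
generate_chemicals <- function(n, seed = 0, library_size = 48) {
  frags <- c("C", "CC", "CCC", "C(C)C", "O", "N", "C(=O)N", "C(=O)O",
             "S", "CO", "C(F)(F)F", "c%d1ccccc%d1", "C%d1CCCC%d1",
             "c%d1ccncc%d1", "C(=O)")
  terminal <- c("C", "CC", "O", "N", "Cl", "Br", "C#N", "C(=O)O")
  with_seed(seed, {
    lib <- vapply(seq_len(library_size), function(i) {
      k <- sample(2:5, 1)
      ring_no <- 0
      parts <- vapply(seq_len(k), function(j) {
        f <- sample(frags, 1)
        if (grepl("%d", f, fixed = TRUE)) {
          ring_no <<- ring_no + 1
          f <- gsub("%d1", as.character(ring_no %% 9 + 1), f, fixed = TRUE)
        }
        f
      }, character(1))
      paste0(paste(parts, collapse = ""), sample(terminal, 1))
    }, character(1))
    sample(lib, n, replace = n > library_size)
  })
}

#' Generate labels with planted per-modality signal
#'
#' Candidate pairs are the graph's chem-prot edges plus
#' `cfg$negative_multiple` times as many uniformly drawn non-edge pairs.
#' Each candidate's log-odds is
#' `effect_scale * (w_topo*z_topo + w_sem*z_sem + w_struct*z_struct)`,
#' where `z_topo` is the standardized mean pair centrality, `z_sem` the
#' standardized cosine similarity of the pair's planted semantic
#' directions, and `z_struct` a standardized bilinear compatibility between
#' the protein's planted structure class and the chemical's fingerprint
#' bits. Labels are Bernoulli draws of the logistic of the log-odds; the
#' log-odds is retained as the Bayes oracle.
#'
#' @param graph `cpi_graph`
#' @param sem_dirs matrix of planted (noise-free) semantic directions,
#'   rownames = entity ids
#' @param classes integer vector of protein structure classes
#' @param fp fingerprint matrix (rows = chemical ids)
#' @param cfg `generator_config`
#' @return data.frame `chem`, `prot`, `label`, `logodds`
#' @export
generate_labels <- function(graph, sem_dirs, classes, fp, cfg) {
  pos <- positive_pairs(graph)
  cand <- with_seed(cfg$seed + 2, {
    neg <- negative_sample(pos, graph,
                           ratio = max(1, round(cfg$negative_multiple)),
                           seed = cfg$seed + 3)
    rbind(pos[, c("chem", "prot")], neg[, c("chem", "prot")])
  })
  cent <- normalize_metrics(compute_centralities(graph))
  cm <- as.matrix(cent[, CENTRALITY_METRICS]); rownames(cm) <- cent$node_id
  z_topo <- rowMeans((cm[cand$chem, , drop = FALSE] + cm[cand$prot, , drop = FALSE]) / 2)
  cosine <- rowSums(sem_dirs[cand$chem, , drop = FALSE] *
                    sem_dirs[cand$prot, , drop = FALSE])
  prot_idx <- as.integer(sub("^P", "", cand$prot))
  W <- with_seed(cfg$seed + 4,
    matrix(stats::rnorm(ncol(fp) * cfg$n_classes, sd = 1 / sqrt(ncol(fp))),
           ncol(fp), cfg$n_classes))
  compat <- rowSums(fp[cand$chem, , drop = FALSE] * t(W[, classes[prot_idx], drop = FALSE]))
  std <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  sw <- cfg$signal_weights
  logodds <- cfg$effect_scale * (sw[["topology"]] * std(z_topo) +
                                 sw[["semantics"]] * std(cosine) +
                                 sw[["structure"]] * std(compat))
  label <- with_seed(cfg$seed + 5,
                     stats::rbinom(nrow(cand), 1, sigmoid(logodds)))
  data.frame(chem = cand$chem, prot = cand$prot, label = label,
             logodds = logodds, stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a complete synthetic CPI dataset
#'
#' Orchestrates network, structures, chemicals, semantic store and labels.
#' Semantic embeddings are the planted unit directions perturbed by
#' isotropic noise (`cfg$sem_noise`) and renormalized.
#'
#' @param cfg `generator_config`
#' @return list of class `synthetic_dataset`: `graph`, `pairs` (labels +
#'   oracle log-odds), `sem_store`, `sem_dirs`, `structures`, `classes`,
#'   `smiles`, `fp`, `cfg`
#' @export
generate_cpi_dataset <- function(cfg) {
  graph <- generate_cpi_network(cfg)
  structures <- generate_structures(cfg)
  classes <- attr(structures, "classes")
  smiles <- generate_chemicals(cfg$n_chem, seed = cfg$seed + 6)
  names(smiles) <- sprintf("C%04d", seq_len(cfg$n_chem))
  nbits <- 512L
  fp <- t(vapply(smiles, function(s) fp_dense(ecfp_fingerprint(s, 2, nbits)),
                 numeric(nbits)))
  rownames(fp) <- names(smiles)
  ids <- graph$nodes$id
  d <- cfg$embedding_dim
  # planted directions cluster around a small archetype dictionary (literature
  # embeddings group entities by topic); pairwise cosine is then dominated by
  # the archetype pairing, which downstream heads can recover
  sem <- with_seed(cfg$seed + 7, {
    n_arch <- cfg$n_archetypes
    arch <- matrix(stats::rnorm(n_arch * d), n_arch, d)
    arch <- arch / sqrt(rowSums(arch^2))
    ak <- sample.int(n_arch, length(ids), replace = TRUE)
    dirs <- arch[ak, , drop = FALSE] +
      cfg$archetype_spread * matrix(stats::rnorm(length(ids) * d), length(ids), d)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    rownames(dirs) <- ids
    obs <- dirs + cfg$sem_noise * matrix(stats::rnorm(length(ids) * d), length(ids), d)
    obs <- obs / sqrt(rowSums(obs^2))
    rownames(obs) <- ids
    list(dirs = dirs, obs = obs)
  })
  pairs <- generate_labels(graph, sem$dirs, classes, fp, cfg)
  structure(list(graph = graph, pairs = pairs,
                 sem_store = store_from_matrix(sem$obs, provider = "synthetic"),
                 sem_dirs = sem$dirs, structures = structures, classes = classes,
                 smiles = smiles, fp = fp, cfg = cfg),
            class = "synthetic_dataset")
}

#' Split a synthetic dataset's labeled pairs
#' @param ds `synthetic_dataset`
#' @param fractions numeric(3) summing to 1
#' @param seed integer seed (defaults to the generator seed)
#' @return `pair_split`
#' @export
split_dataset <- function(ds, fractions = c(0.7, 0.15, 0.15), seed = NULL) {
  split_pairs(ds$graph, fractions, seed %||% ds$cfg$seed, pairs = ds$pairs)
}

#' Write a synthetic dataset to a directory (TSV + PDB artifacts)
#' @param ds `synthetic_dataset`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_interaction_table(ds$graph, file.path(dir, "edges.tsv"))
  utils::write.table(data.frame(chemical_id = names(ds$smiles), smiles = ds$smiles),
                     file.path(dir, "chemicals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_store(ds$sem_store, file.path(dir, "embeddings.tsv"))
  utils::write.table(ds$pairs[, c("chem", "prot", "label")],
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$pairs, file.path(dir, "oracle.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sdir <- file.path(dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  for (p in names(ds$structures))
    write_pdb(ds$structures[[p]], file.path(sdir, paste0(p, ".pdb")))
  invisible(dir)
}
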