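# Structure branch: residue-level protein contact graphs from predicted
# structures, and a rotation/translation-invariant geometric graph encoder.
#
# Only C-alpha geometry is used. The per-residue confidence (pLDDT, 0-100)
# is read from the B-factor column, the convention of predicted-structure
# archives.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")
AA_ALPHABET <- c(unname(AA3TO1), "X")  # 20 + unknown

#' Read a protein structure (PDB or mmCIF)
#'
#' Extracts the C-alpha trace in chain order, with the B-factor column
#' interpreted as pLDDT. Residues lacking a C-alpha atom are skipped; their
#' count is reported via attribute `n_skipped` and a message.
#'
#' @param path file path; format chosen by extension (`.cif`/`.mmcif` for
#'   mmCIF, otherwise PDB)
#' @return object of class `protein_structure`: data.frame with columns
#'   `aa` (1-letter, `X` for unknown), `x`, `y`, `z` (Angstrom), `plddt`
#' @export
read_structure <- function(path) {
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  res <- if (is_cif) read_structure_cif(path) else read_structure_pdb(path)
  if (nrow(res$df) == 0)
    stop_cpifuse("no C-alpha atoms found in structure", "cpifuse_empty_structure_error")
  if (res$n_skipped > 0)
    message(sprintf("read_structure: skipped %d residue(s) without C-alpha", res$n_skipped))
  if (any(!is.finite(as.matrix(res$df[, c("x", "y", "z")]))))
    stop_cpifuse("non-finite coordinates", "cpifuse_format_error")
  structure(res$df, class = c("protein_structure", "data.frame"),
            n_skipped = res$n_skipped)
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom <- lines[startsWith(lines, "ATOM")]
  if (length(atom) == 0) return(list(df = empty_structure_df(), n_skipped = 0L))
  name <- trimws(substr(atom, 13, 16))
  altloc <- substr(atom, 17, 17)
  resname <- trimws(substr(atom, 18, 20))
  chain <- substr(atom, 22, 22)
  resseq <- trimws(substr(atom, 23, 27))  # includes insertion code
  reskey <- paste(chain, resseq, sep = ":")
  is_ca <- name == "CA" & altloc %in% c(" ", "A", "1")
  all_res <- unique(reskey)
  ca <- atom[is_ca]
  ca_key <- reskey[is_ca]
  keep <- !duplicated(ca_key)
  ca <- ca[keep]; ca_key <- ca_key[keep]
  df <- data.frame(
    aa = unname(ifelse(resname[is_ca][keep] %in% names(AA3TO1),
                       AA3TO1[resname[is_ca][keep]], "X")),
    x = as.numeric(substr(ca, 31, 38)),
    y = as.numeric(substr(ca, 39, 46)),
    z = as.numeric(substr(ca, 47, 54)),
    plddt = as.numeric(substr(ca, 61, 66)),
    stringsAsFactors = FALSE)
  # keep chain order of first appearance
  df <- df[order(match(ca_key, all_res)), , drop = FALSE]
  rownames(df) <- NULL
  list(df = df, n_skipped = length(all_res) - nrow(df))
}

# Minimal mmCIF _atom_site loop reader: enough for predicted-structure files.
read_structure_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0)
    stop_cpifuse("no _atom_site loop in mmCIF file", "cpifuse_format_error")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") || startsWith(ln, "loop_")) break
    body <- c(body, ln)
  }
  toks <- strsplit(body, "[ \t]+")
  need <- c("label_atom_id", "Cartn_x", "Cartn_y", "Cartn_z", "B_iso_or_equiv",
            "label_comp_id", "label_seq_id")
  pos <- match(need, fields)
  if (any(is.na(pos[1:4])))
    stop_cpifuse("mmCIF _atom_site loop lacks required fields", "cpifuse_format_error")
  get <- function(k) vapply(toks, function(t) if (length(t) >= k) t[[k]] else NA_character_, character(1))
  atom_id <- get(pos[1])
  comp <- if (!is.na(pos[6])) get(pos[6]) else rep("UNK", length(atom_id))
  seqid <- if (!is.na(pos[7])) get(pos[7]) else as.character(seq_along(atom_id))
  is_ca <- atom_id == "CA"
  all_res <- unique(seqid)
  keep <- which(is_ca)[!duplicated(seqid[is_ca])]
  df <- data.frame(
    aa = unname(ifelse(comp[keep] %in% names(AA3TO1), AA3TO1[comp[keep]], "X")),
    x = as.numeric(get(pos[2])[keep]),
    y = as.numeric(get(pos[3])[keep]),
    z = as.numeric(get(pos[4])[keep]),
    plddt = if (!is.na(pos[5])) as.numeric(get(pos[5])[keep]) else rep(NA_real_, length(keep)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  list(df = df, n_skipped = length(all_res) - nrow(df))
}

empty_structure_df <- function() {
  data.frame(aa = character(), x = numeric(), y = numeric(), z = numeric(),
             plddt = numeric(), stringsAsFactors = FALSE)
}

#' Assemble a protein_structure from raw vectors
#' @param aa character vector of 1-letter amino acid codes
#' @param coords numeric matrix n x 3 of C-alpha coordinates (Angstrom)
#' @param plddt numeric vector of per-residue confidences (0-100)
#' @return `protein_structure`
#' @export
protein_structure <- function(aa, coords, plddt) {
  stopifnot(nrow(coords) == length(aa), length(plddt) == length(aa))
  if (any(plddt < 0 | plddt > 100)) stop_cpifuse("pLDDT outside [0,100]", "cpifuse_contract_error")
  structure(data.frame(aa = ifelse(aa %in% AA_ALPHABET, aa, "X"),
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       plddt = plddt, stringsAsFactors = FALSE),
            class = c("protein_structure", "data.frame"), n_skipped = 0L)
}

#' Write a C-alpha-only PDB file
#' @param structure `protein_structure`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(structure, path) {
  aa1to3 <- stats::setNames(names(AA3TO1), AA3TO1)
  res3 <- ifelse(structure$aa %in% AA3TO1, aa1to3[structure$aa], "UNK")
  lines <- sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
                   seq_len(nrow(structure)), res3, seq_len(nrow(structure)),
                   structure$x, structure$y, structure$z, structure$plddt)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a residue contact graph
#'
#' Edges connect residue pairs whose C-alpha distance is `<= cutoff`
#' (inclusive boundary). Node features are the 21-letter one-hot amino acid
#' type plus the pLDDT scalar; geometric features (backbone unit vectors,
#' per-edge displacement unit vectors, RBF-encoded distances) feed the
#' encoder.
#'
#' @param structure `protein_structure`
#' @param cutoff contact distance cutoff in Angstrom (default 8.0)
#' @return object of class `contact_graph`
#' @export
build_contact_graph <- function(structure, cutoff = 8.0) {
  n <- nrow(structure)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  edges <- matrix(integer(), ncol = 2)
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    edges <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  }
  aa_idx <- match(structure$aa, AA_ALPHABET)
  onehot <- matrix(0, n, length(AA_ALPHABET),
                   dimnames = list(NULL, AA_ALPHABET))
  onehot[cbind(seq_len(n), aa_idx)] <- 1
  structure(list(n = n, coords = xyz, aa_onehot = onehot,
                 plddt = structure$plddt, edges = unname(edges), cutoff = cutoff),
            class = "contact_graph")
}

#' @exportS3Method base::print
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d residues, %d contacts (cutoff %.1f A)\n",
              x$n, nrow(x$edges), x$cutoff))
  invisible(x)
}

contact_igraph <- function(cg) {
  g <- igraph::make_empty_graph(n = cg$n, directed = FALSE)
  if (nrow(cg$edges) > 0) g <- igraph::add_edges(g, t(cg$edges))
  g
}

#' Encoder configuration for the geometric contact-graph network
#'
#' @param layers message-passing rounds (>= 1)
#' @param s_dim scalar channel width of residue embeddings
#' @param v_dim vector channel count
#' @param n_rbf number of radial basis functions on `[0, rbf_max]` Angstrom
#' @param rbf_max RBF support maximum (matches the contact cutoff)
#' @param seed seed for the frozen encoder weights
#' @param pool `"plddt"` for confidence-weighted mean pooling (weights
#'   pLDDT/100) or `"mean"` for a plain mean
#' @return list of class `encoder_config`
#' @export
encoder_config <- function(layers = 3, s_dim = 128, v_dim = 16, n_rbf = 16,
                           rbf_max = 8, seed = 42, pool = c("plddt", "mean")) {
  if (layers < 1) stop_cpifuse("encoder needs >= 1 layer", "cpifuse_contract_error")
  structure(list(layers = layers, s_dim = s_dim, v_dim = v_dim, n_rbf = n_rbf,
                 rbf_max = rbf_max, seed = seed, pool = match.arg(pool)),
            class = "encoder_config")
}

rbf_expand <- function(d, n_rbf, rbf_max) {
  mu <- seq(0, rbf_max, length.out = n_rbf)
  sg <- (rbf_max / n_rbf)
  exp(-((outer(d, mu, "-"))^2) / (2 * sg^2))
}

encoder_weights <- function(cfg, d_node) {
  with_seed(cfg$seed, {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
    list(
      W_in = g(d_node, cfg$s_dim),
      W_msg = lapply(seq_len(cfg$layers), function(l)
        g(cfg$s_dim + cfg$n_rbf + 2 * cfg$v_dim, cfg$s_dim)),
      W_upd = lapply(seq_len(cfg$layers), function(l) g(2 * cfg$s_dim, cfg$s_dim)),
      W_vmix = lapply(seq_len(cfg$layers), function(l) g(cfg$v_dim, cfg$v_dim)),
      W_gate = lapply(seq_len(cfg$layers), function(l) g(cfg$s_dim, cfg$v_dim))
    )
  })
}

#' Encode a protein contact graph into a fixed-length embedding
#'
#' A frozen (seeded) geometric message-passing network in the
#' geometric-vector-perceptron style: residue scalar channels are updated
#' from neighbor scalars, RBF-encoded edge distances and invariant readouts
#' of the vector channels (norms, and projections onto edge directions);
#' vector channels (initialized from backbone forward/backward unit vectors)
#' are mixed equivariantly. Because every scalar pathway consumes only
#' norms, dot products and distances, the pooled embedding is invariant to
#' rigid rotations and translations of the input coordinates. Pooling is a
#' pLDDT-confidence-weighted mean over residues by default.
#'
#' @param cg `contact_graph`
#' @param params `encoder_config`
#' @return numeric vector of length `params$s_dim` (class `protein_embedding`)
#' @export
encode_protein <- function(cg, params = encoder_config()) {
  cfg <- params
  n <- cg$n
  d_node <- ncol(cg$aa_onehot) + 1
  W <- encoder_weights(cfg, d_node)
  X <- cbind(cg$aa_onehot, cg$plddt / 100)
  S <- X %*% W$W_in                                   # n x s_dim
  # vector channels: backbone forward/backward unit vectors, lifted to v_dim
  Vc <- array(0, c(n, cfg$v_dim, 3))
  if (n >= 2) {
    fwd <- rbind(cg$coords[-1, , drop = FALSE] - cg$coords[-n, , drop = FALSE],
                 c(0, 0, 0))
    bwd <- rbind(c(0, 0, 0),
                 cg$coords[-n, , drop = FALSE] - cg$coords[-1, , drop = FALSE])
    unitize <- function(M) {
      nm <- sqrt(rowSums(M^2)); nm[nm == 0] <- 1; M / nm
    }
    base <- array(0, c(n, 2, 3))
    base[, 1, ] <- unitize(fwd); base[, 2, ] <- unitize(bwd)
    lift <- with_seed(cfg$seed + 1, matrix(stats::rnorm(cfg$v_dim * 2, sd = 1 / sqrt(2)),
                                           cfg$v_dim, 2))
    for (k in 1:3) Vc[, , k] <- base[, , k] %*% t(lift)
  }
  E <- cg$edges
  has_edges <- nrow(E) > 0
  if (has_edges) {
    src <- c(E[, 1], E[, 2]); dst <- c(E[, 2], E[, 1])    # both directions
    disp <- cg$coords[dst, , drop = FALSE] - cg$coords[src, , drop = FALSE]
    dd <- sqrt(rowSums(disp^2))
    eu <- disp / ifelse(dd == 0, 1, dd)
    RBF <- rbf_expand(dd, cfg$n_rbf, cfg$rbf_max)
    deg <- tabulate(dst, nbins = n)
  }
  for (l in seq_len(cfg$layers)) {
    vnorm <- sqrt(apply(Vc^2, c(1, 2), sum))            # n x v_dim, invariant
    if (has_edges) {
      # projection of source vector channels onto the edge direction: invariant
      proj <- Vc[src, , 1, drop = TRUE] * eu[, 1] +
              Vc[src, , 2, drop = TRUE] * eu[, 2] +
              Vc[src, , 3, drop = TRUE] * eu[, 3]
      if (is.null(dim(proj))) proj <- matrix(proj, ncol = cfg$v_dim)
      Min <- cbind(S[src, , drop = FALSE], RBF, proj, vnorm[src, , drop = FALSE])
      Msg <- relu(Min %*% W$W_msg[[l]])
      Agg <- rowsum(Msg, dst, reorder = FALSE)
      ord <- as.integer(rownames(Agg))
      AggF <- matrix(0, n, cfg$s_dim)
      AggF[ord, ] <- Agg / pmax(deg[ord], 1)
    } else AggF <- matrix(0, n, cfg$s_dim)
    S <- relu(cbind(S, AggF) %*% W$W_upd[[l]])
    # equivariant vector update: channel mixing + gated edge directions
    gate <- tanh(S %*% W$W_gate[[l]])                   # n x v_dim
    Vnew <- array(0, c(n, cfg$v_dim, 3))
    for (k in 1:3) Vnew[, , k] <- Vc[, , k] %*% t(W$W_vmix[[l]])
    if (has_edges) {
      for (k in 1:3) {
        contrib <- rowsum(eu[, k] * gate[dst, , drop = FALSE], dst, reorder = FALSE)
        ord <- as.integer(rownames(contrib))
        Vnew[ord, , k] <- Vnew[ord, , k] + contrib / pmax(deg[ord], 1)
      }
    }
    Vc <- Vnew
  }
  wts <- if (cfg$pool == "plddt") cg$plddt / 100 else rep(1, n)
  if (sum(wts) == 0) wts <- rep(1, n)
  emb <- as.numeric(t(S) %*% wts / sum(wts))
  structure(emb, class = "protein_embedding")
}

#' Auxiliary topological signature of a contact graph
#'
#' Mean and max residue degree, mean residue betweenness, and the Shannon
#' entropy (nats) of the contact-degree distribution. The degree-distribution
#' entropy is an explicitly labeled stand-in for a "loop entropy" style
#' descriptor, which has no canonical definition.
#' @param cg `contact_graph`
#' @return named numeric vector
#' @export
structural_topology_signature <- function(cg) {
  if (nrow(cg$edges) == 0)
    return(c(mean_degree = 0, max_degree = 0, mean_betweenness = 0, degree_entropy = 0))
  deg <- tabulate(c(cg$edges[, 1], cg$edges[, 2]), nbins = cg$n)
  g <- contact_igraph(cg)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  p <- table(deg) / cg$n
  c(mean_degree = mean(deg), max_degree = max(deg),
    mean_betweenness = mean(btw), degree_entropy = -sum(p * log(p)))
}
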