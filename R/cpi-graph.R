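# Heterogeneous chemical-protein interaction (CPI) network: data model + I/O.
#
# A cpi_graph holds two node kinds (chemical, protein) and three undirected
# edge types (chem-prot, prot-prot, chem-chem). Confidence scores are carried
# as metadata only; every topology computation treats the graph as undirected
# and unweighted.

EDGE_TYPES <- c("chem-prot", "prot-prot", "chem-chem")
NODE_KINDS <- c("chemical", "protein")

edge_type_for <- function(ku, kv) {
  if (ku == "chemical" && kv == "chemical") return("chem-chem")
  if (ku == "protein" && kv == "protein") return("prot-prot")
  "chem-prot"
}

#' Construct a CPI graph
#'
#' @param nodes data.frame with columns `id` (unique character) and `kind`
#'   (`"chemical"` or `"protein"`).
#' @param edges data.frame with columns `u`, `v` (node ids), optional `etype`
#'   and `confidence` in `[0,1]`. Edges are undirected; endpoints are stored
#'   in lexicographic order, duplicates collapsed, self-edges rejected.
#' @return object of class `cpi_graph`
#' @export
cpi_graph <- function(nodes, edges = NULL) {
  nodes <- data.frame(id = as.character(nodes$id), kind = as.character(nodes$kind),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id))
    stop_cpifuse("duplicate node ids", "cpifuse_consistency_error")
  if (!all(nodes$kind %in% NODE_KINDS))
    stop_cpifuse("node kind must be 'chemical' or 'protein'", "cpifuse_consistency_error")
  if (nrow(nodes) < 1)
    stop_cpifuse("graph needs at least one node", "cpifuse_empty_input_error")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(u = character(), v = character(), etype = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  } else {
    u <- as.character(edges$u); v <- as.character(edges$v)
    conf <- if ("confidence" %in% names(edges)) as.numeric(edges$confidence) else rep(NA_real_, length(u))
    keep <- u != v
    u <- u[keep]; v <- v[keep]; conf <- conf[keep]
    kind <- stats::setNames(nodes$kind, nodes$id)
    if (!all(c(u, v) %in% nodes$id))
      stop_cpifuse("edge endpoint not registered as a node", "cpifuse_consistency_error")
    swap <- u > v
    tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
    et <- mapply(edge_type_for, kind[u], kind[v], USE.NAMES = FALSE)
    key <- paste(u, v, sep = "\r")
    dup <- duplicated(key)
    edges <- data.frame(u = u[!dup], v = v[!dup], etype = et[!dup],
                        confidence = conf[!dup], stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "cpi_graph")
}

#' @exportS3Method base::print
print.cpi_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat(sprintf("<cpi_graph> %d chemicals, %d proteins; edges: %d chem-prot, %d prot-prot, %d chem-chem\n",
              s$n_chemicals, s$n_proteins, s$edges_chem_prot, s$edges_prot_prot, s$edges_chem_chem))
  invisible(x)
}

node_kind <- function(graph, ids) {
  stats::setNames(graph$nodes$kind, graph$nodes$id)[ids]
}

#' Convert to an igraph object (undirected, unweighted)
#' @param graph a `cpi_graph`
#' @return igraph graph whose vertex names are the node ids
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges[, c("u", "v")], directed = FALSE,
                                vertices = graph$nodes$id)
}

#' Read an interaction edge list
#'
#' Supported dialects: `generic` (columns `source_id`, `target_id`,
#' `edge_type`, optional `score` already in `[0,1]`), `stitch`
#' (`chemical`, `protein`, `combined_score` on 0-1000, rescaled by 1/1000,
#' chem-prot edges) and `string` (`protein1`, `protein2`, `combined_score`
#' on 0-1000, prot-prot edges). Malformed rows (missing ids, self-loops,
#' unparseable scores) are dropped and counted in attribute `n_malformed`.
#'
#' @param path TSV file path
#' @param dialect one of `"generic"`, `"stitch"`, `"string"`
#' @return `cpi_graph` with attribute `n_malformed`
#' @export
load_interaction_table <- function(path, dialect = c("generic", "stitch", "string")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- switch(dialect,
    generic = c("source_id", "target_id"),
    stitch  = c("chemical", "protein"),
    string  = c("protein1", "protein2"))
  if (!all(cols %in% names(tab)))
    stop_cpifuse(sprintf("missing required columns for dialect '%s': %s",
                         dialect, paste(setdiff(cols, names(tab)), collapse = ", ")),
                 "cpifuse_format_error")
  u <- as.character(tab[[cols[1]]]); v <- as.character(tab[[cols[2]]])
  score <- if (dialect == "generic") {
    if ("score" %in% names(tab)) suppressWarnings(as.numeric(tab$score)) else rep(NA_real_, nrow(tab))
  } else {
    if ("combined_score" %in% names(tab))
      suppressWarnings(as.numeric(tab$combined_score)) / 1000 else rep(NA_real_, nrow(tab))
  }
  et <- switch(dialect,
    generic = if ("edge_type" %in% names(tab)) as.character(tab$edge_type) else rep("chem-prot", nrow(tab)),
    stitch  = rep("chem-prot", nrow(tab)),
    string  = rep("prot-prot", nrow(tab)))
  ok <- !is.na(u) & !is.na(v) & nzchar(u) & nzchar(v) & u != v & et %in% EDGE_TYPES
  n_bad <- sum(!ok)
  if (n_bad > 0) message(sprintf("load_interaction_table: dropped %d malformed row(s)", n_bad))
  if (!any(ok)) stop_cpifuse("no valid interaction rows", "cpifuse_empty_input_error")
  u <- u[ok]; v <- v[ok]; et <- et[ok]; score <- score[ok]
  # node kinds: prot-prot and chem-chem rows pin both endpoints; chem-prot
  # rows use the source=chemical, target=protein convention unless a pinned
  # assignment overrides it (rows may be written in either orientation)
  pinned <- c(stats::setNames(rep("protein", 2 * sum(et == "prot-prot")),
                              c(u[et == "prot-prot"], v[et == "prot-prot"])),
              stats::setNames(rep("chemical", 2 * sum(et == "chem-chem")),
                              c(u[et == "chem-chem"], v[et == "chem-chem"])))
  if (any(duplicated(names(pinned)))) {
    kp <- tapply(pinned, names(pinned), unique)
    if (any(lengths(kp) > 1))
      stop_cpifuse("node id appears in both prot-prot and chem-chem rows",
                   "cpifuse_consistency_error")
    pinned <- vapply(kp, `[[`, "", 1)
  }
  weak <- c(stats::setNames(rep("chemical", sum(et == "chem-prot")),
                            u[et == "chem-prot"]),
            stats::setNames(rep("protein", sum(et == "chem-prot")),
                            v[et == "chem-prot"]))
  weak <- weak[!duplicated(names(weak))]
  ids <- unique(c(u, v))
  kinds <- ifelse(ids %in% names(pinned), pinned[ids],
                  ifelse(ids %in% names(weak), weak[ids], "chemical"))
  g <- cpi_graph(data.frame(id = ids, kind = kinds),
                 data.frame(u = u, v = v, confidence = score))
  attr(g, "n_malformed") <- n_bad
  g
}

#' Write an interaction table (generic dialect)
#' @param graph a `cpi_graph`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_interaction_table <- function(graph, path) {
  out <- data.frame(source_id = graph$edges$u, target_id = graph$edges$v,
                    edge_type = graph$edges$etype, score = graph$edges$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge CPI, PPI and chemical-chemical networks
#'
#' Union of node and edge sets; edge types are preserved. A node id carrying
#' different kinds across inputs is a consistency error.
#' @param cpi,ppi,cci `cpi_graph` objects (any may be `NULL`)
#' @return merged `cpi_graph`
#' @export
merge_networks <- function(cpi, ppi = NULL, cci = NULL) {
  gs <- Filter(Negate(is.null), list(cpi, ppi, cci))
  nodes <- do.call(rbind, lapply(gs, `[[`, "nodes"))
  first <- !duplicated(nodes$id)
  kind <- stats::setNames(nodes$kind[first], nodes$id[first])
  if (!all(nodes$kind == kind[nodes$id]))
    stop_cpifuse("node id registered with conflicting kinds across networks",
                 "cpifuse_consistency_error")
  edges <- do.call(rbind, lapply(gs, `[[`, "edges"))
  cpi_graph(nodes[first, ], edges)
}

#' Labeled chemical-protein pairs from a graph's chem-prot edges
#' @keywords internal
positive_pairs <- function(graph) {
  e <- graph$edges[graph$edges$etype == "chem-prot", , drop = FALSE]
  kind <- stats::setNames(graph$nodes$kind, graph$nodes$id)
  chem <- ifelse(kind[e$u] == "chemical", e$u, e$v)
  prot <- ifelse(kind[e$u] == "chemical", e$v, e$u)
  data.frame(chem = chem, prot = prot, label = rep(1L, nrow(e)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split chemical-protein pairs into train/validation/test
#'
#' Positives are the graph's chem-prot edges; partitioning is a seeded
#' shuffle, deterministic per seed, with partitions disjoint and exhaustive.
#' Defaults to a 70/15/15 split.
#'
#' @param graph `cpi_graph` with at least one chem-prot edge
#' @param fractions numeric(3) summing to 1
#' @param seed integer seed
#' @param pairs optional data.frame of labeled pairs (`chem`, `prot`,
#'   `label`) to split instead of the graph's positive edges
#' @return list of class `pair_split` with elements `train`, `validation`,
#'   `test`, `seed`
#' @export
split_pairs <- function(graph, fractions = c(0.7, 0.15, 0.15), seed = 0, pairs = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3 || any(fractions < 0))
    stop_cpifuse("fractions must be three non-negative numbers summing to 1",
                 "cpifuse_config_error")
  if (is.null(pairs)) pairs <- positive_pairs(graph)
  n <- nrow(pairs)
  if (n < 1) stop_cpifuse("no chem-prot pairs to split", "cpifuse_empty_input_error")
  idx <- with_seed(seed, sample.int(n))
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  n_va <- min(n_va, n - n_tr)
  sp <- list(train = pairs[idx[seq_len(n_tr)], , drop = FALSE],
             validation = pairs[idx[seq_len(n_va) + n_tr], , drop = FALSE],
             test = pairs[idx[setdiff(seq_len(n), seq_len(n_tr + n_va))], , drop = FALSE],
             seed = seed)
  for (part in c("train", "validation", "test")) rownames(sp[[part]]) <- NULL
  structure(sp, class = "pair_split")
}

#' Summarize a CPI graph
#'
#' Node counts by kind, mean degree by kind (all edge types count toward a
#' node's degree) and edge counts by type. Means are computed in exact
#' rational form (integer degree sums over integer counts) before division.
#'
#' @param graph `cpi_graph`
#' @return named list
#' @export
graph_summary <- function(graph) {
  deg <- stats::setNames(rep(0L, nrow(graph$nodes)), graph$nodes$id)
  if (nrow(graph$edges) > 0) {
    t1 <- table(c(graph$edges$u, graph$edges$v))
    deg[names(t1)] <- as.integer(t1)
  }
  is_chem <- graph$nodes$kind == "chemical"
  n_chem <- sum(is_chem); n_prot <- sum(!is_chem)
  list(
    n_chemicals = n_chem,
    n_proteins = n_prot,
    mean_degree_chemical = if (n_chem > 0) sum(deg[is_chem]) / n_chem else 0,
    mean_degree_protein = if (n_prot > 0) sum(deg[!is_chem]) / n_prot else 0,
    edges_chem_prot = sum(graph$edges$etype == "chem-prot"),
    edges_prot_prot = sum(graph$edges$etype == "prot-prot"),
    edges_chem_chem = sum(graph$edges$etype == "chem-chem"))
}
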