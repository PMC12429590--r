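# Semantic branch: per-entity literature-semantics embeddings behind a
# pluggable provider abstraction with a file-backed store.
#
# The shipped providers are file-backed and synthetic. A transformer-backed
# provider (e.g. a SciBERT-class biomedical language model fine-tuned on a
# chemical-protein co-mention objective: masked-language loss, lr 2e-5,
# batch 16, max sequence length 256, 5 epochs, encoder frozen afterwards)
# can be slotted in by exporting its cached per-entity vectors to the same
# TSV layout; nothing downstream depends on the provider, only on the
# vectors. Default dimension 768 (the hidden size of that model class).

#' Build an embedding store
#'
#' @param table data.frame (or TSV path) whose first column is the entity id
#'   and remaining columns are the vector components, one row per entity
#' @param dim expected dimension; inferred when `NULL`, enforced otherwise
#' @param provider provenance tag
#' @return object of class `embedding_store`
#' @export
build_store <- function(table, dim = NULL, provider = "file") {
  if (is.character(table)) table <- utils::read.delim(table, stringsAsFactors = FALSE)
  if (ncol(table) < 2) stop_cpifuse("store table needs id + vector columns", "cpifuse_format_error")
  ids <- as.character(table[[1]])
  mat <- as.matrix(table[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(!is.finite(mat)))
    stop_cpifuse("ragged or non-numeric embedding rows", "cpifuse_format_error")
  d <- ncol(mat)
  if (!is.null(dim) && d != dim)
    stop_cpifuse(sprintf("vector length %d does not match declared dim %d", d, dim),
                 "cpifuse_format_error")
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, dim = d, provider = provider,
                 version = "1"), class = "embedding_store")
}

#' Build a store directly from an id-keyed matrix
#' @param mat numeric matrix with entity ids as rownames
#' @param provider provenance tag
#' @return `embedding_store`
#' @export
store_from_matrix <- function(mat, provider = "matrix") {
  structure(list(ids = rownames(mat), mat = mat, dim = ncol(mat),
                 provider = provider, version = "1"), class = "embedding_store")
}

#' Write an embedding store to TSV
#'
#' Vectors are written with 17 significant digits, so a write/read
#' round-trip is bit-exact for doubles.
#' @param store `embedding_store`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_store <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("entity_id", paste0("v", seq_len(store$dim))), collapse = "\t"), con)
  body <- vapply(seq_along(store$ids), function(i)
    paste(c(store$ids[i], formatC(store$mat[i, ], format = "g", digits = 17)),
          collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Look up an entity's semantic vector
#'
#' With `fallback = "zero"` a missing entity yields the all-zero vector of
#' the store's dimension — exactly the input used by the semantic-ablation
#' intervention (x_l -> 0).
#'
#' @param entity entity id (or a `NodeRef`-style list with `$id`)
#' @param store `embedding_store`
#' @param fallback `"error"` or `"zero"`
#' @return numeric vector of length `store$dim`
#' @export
get_embedding <- function(entity, store, fallback = c("error", "zero")) {
  fallback <- match.arg(fallback)
  id <- if (is.list(entity)) entity$id else entity
  i <- match(id, store$ids)
  if (is.na(i)) {
    if (fallback == "zero") return(numeric(store$dim))
    stop_cpifuse(sprintf("no embedding for entity '%s'", id), "cpifuse_lookup_error")
  }
  as.numeric(store$mat[i, ])
}

#' Concatenated pair semantic features [x_u || x_v]
#' @param u_vec,v_vec equal-length numeric vectors
#' @return numeric vector of length `2 * length(u_vec)`
#' @export
pair_semantic_features <- function(u_vec, v_vec) {
  if (length(u_vec) != length(v_vec))
    stop_cpifuse("semantic vector dimension mismatch", "cpifuse_contract_error")
  c(u_vec, v_vec)
}
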