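# Chemical fingerprints: a restricted SMILES reader and a Morgan-style
# extended-connectivity (ECFP) hashed bit fingerprint.
#
# The reader covers the organic subset needed here: B C N O P S F Cl Br I,
# aromatic b c n o p s, bracket atoms with charge/H-count, branches, ring
# closures (digits and %nn), and bond symbols - = # : / \. It builds a
# molecular graph; no coordinates, no stereochemistry. Morgan identifiers
# are order-independent by construction, so any SMILES spelling of the same
# connectivity yields the same bit set.

ORGANIC_ATOMS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_ATOMS <- c("b", "c", "n", "o", "p", "s")
ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                   Cl = 17, Br = 35, I = 53)
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                     Cl = 1, Br = 1, I = 1, H = 1)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles SMILES string (restricted organic subset; see file header)
#' @return list with `atoms` (data.frame: element, aromatic, charge,
#'   n_h explicit-H count or NA for implicit) and `bonds` (data.frame:
#'   a1, a2, order; aromatic bonds have order 1.5)
#' @export
parse_smiles <- function(smiles) {
  fail <- function(why) stop_cpifuse(
    sprintf("invalid SMILES '%s': %s", smiles, why), "cpifuse_parse_error")
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) fail("empty")
  chars <- strsplit(smiles, "")[[1]]
  i <- 1; n <- length(chars)
  atoms <- list(); bonds <- list()
  prev_stack <- integer()   # branch stack
  prev <- NA_integer_
  pending_bond <- NA_real_
  rings <- list()           # ring-closure digit -> c(atom, bond order)
  add_atom <- function(element, aromatic, charge = 0L, n_h = NA_integer_) {
    atoms[[length(atoms) + 1]] <<- list(element = element, aromatic = aromatic,
                                        charge = charge, n_h = n_h)
    length(atoms)
  }
  add_bond <- function(a1, a2, order) {
    if (a1 == a2) fail("self-bond")
    bonds[[length(bonds) + 1]] <<- c(a1, a2, order)
  }
  connect <- function(idx) {
    force(idx)  # idx's promise appends the atom; force before reading `atoms`
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && atoms[[idx]]$aromatic) 1.5 else 1
      }
      add_bond(prev, idx, ord)
    }
    pending_bond <<- NA_real_
    prev <<- idx
  }
  ring_closure <- function(key) {
    if (!key %in% names(rings)) {
      rings[[key]] <<- c(prev, pending_bond)
      pending_bond <<- NA_real_
    } else {
      other <- rings[[key]][1]; ord <- rings[[key]][2]
      if (is.na(ord)) ord <- pending_bond
      if (is.na(ord)) ord <- if (atoms[[prev]]$aromatic && atoms[[other]]$aromatic) 1.5 else 1
      add_bond(other, prev, ord)
      rings[[key]] <<- NULL
      pending_bond <<- NA_real_
    }
  }
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1]) else ""
    if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom")
      prev_stack <- c(prev_stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (length(prev_stack) == 0) fail("unmatched ')'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]; i <- i + 1
    } else if (ch %in% c("-", "/", "\\")) { pending_bond <- 1; i <- i + 1
    } else if (ch == "=") { pending_bond <- 2; i <- i + 1
    } else if (ch == "#") { pending_bond <- 3; i <- i + 1
    } else if (ch == ":") { pending_bond <- 1.5; i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1], chars[i + 2])))
        fail("bad %nn ring closure")
      ring_closure(paste0(chars[i + 1], chars[i + 2])); i <- i + 3
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev)) fail("ring digit before any atom")
      ring_closure(ch); i <- i + 1
    } else if (ch == "[") {
      j <- i + 1; buf <- ""
      while (j <= n && chars[j] != "]") { buf <- paste0(buf, chars[j]); j <- j + 1 }
      if (j > n) fail("unmatched '['")
      m <- regmatches(buf, regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z])(H([0-9]?))?(([+-])([0-9]?))?$", buf))[[1]]
      if (length(m) == 0) fail(sprintf("unparseable bracket atom [%s]", buf))
      sym <- m[3]
      aromatic <- sym %in% AROMATIC_ATOMS
      el <- if (aromatic) toupper(sym) else sym
      if (!el %in% names(ATOMIC_NUMBER)) fail(sprintf("unknown element '%s'", el))
      n_h <- if (nzchar(m[4])) { if (nzchar(m[5])) as.integer(m[5]) else 1L } else 0L
      chg <- 0L
      if (nzchar(m[6])) {
        mag <- if (nzchar(m[8])) as.integer(m[8]) else 1L
        chg <- if (m[7] == "+") mag else -mag
      }
      connect(add_atom(el, aromatic, chg, n_h))
      i <- j + 1
    } else if (two %in% ORGANIC_ATOMS) {
      connect(add_atom(two, FALSE)); i <- i + 2
    } else if (ch %in% ORGANIC_ATOMS) {
      connect(add_atom(ch, FALSE)); i <- i + 1
    } else if (ch %in% AROMATIC_ATOMS) {
      connect(add_atom(toupper(ch), TRUE)); i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_real_; i <- i + 1
    } else fail(sprintf("unexpected character '%s' at position %d", ch, i))
  }
  if (length(prev_stack) > 0) fail("unclosed branch")
  if (length(rings) > 0) fail("unclosed ring bond")
  if (length(atoms) == 0) fail("no atoms")
  at <- data.frame(element = vapply(atoms, `[[`, "", "element"),
                   aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
                   charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
                   n_h = vapply(atoms, function(a) as.integer(a$n_h %||% NA_integer_), 0L),
                   stringsAsFactors = FALSE)
  bd <- if (length(bonds) > 0) {
    b <- do.call(rbind, bonds)
    data.frame(a1 = as.integer(b[, 1]), a2 = as.integer(b[, 2]), order = b[, 3])
  } else data.frame(a1 = integer(), a2 = integer(), order = numeric())
  # implicit hydrogens for non-bracket atoms from default valence
  bsum <- rep(0, nrow(at))
  if (nrow(bd) > 0) {
    ords <- ifelse(bd$order == 1.5, 1, bd$order)  # aromatic counts ~1 + ring adj.
    for (r in seq_len(nrow(bd))) {
      bsum[bd$a1[r]] <- bsum[bd$a1[r]] + ords[r]
      bsum[bd$a2[r]] <- bsum[bd$a2[r]] + ords[r]
    }
  }
  arom_bonus <- ifelse(at$aromatic, 1, 0)  # aromatic system consumes one extra valence
  imp <- pmax(0, DEFAULT_VALENCE[at$element] - bsum - arom_bonus + at$charge * 0)
  at$n_h <- ifelse(is.na(at$n_h), as.integer(imp), at$n_h)
  list(atoms = at, bonds = bd)
}

# Deterministic integer hash of a numeric vector; all intermediates stay
# below 2^53 so the arithmetic is exact in doubles.
hash_ints <- function(v) {
  h <- 5381
  for (x in v) {
    h <- (h * 1159241 + (x %% 2147483647) + 7) %% 2147483647
  }
  h
}

#' Morgan/ECFP hashed binary fingerprint
#'
#' Extended-connectivity fingerprint with the standard iterative neighborhood
#' hashing: initial atom identifiers from (atomic number, heavy degree, H
#' count, charge, aromaticity), refined for `radius` rounds over sorted
#' (bond order, neighbor id) lists, all identifiers folded into `nbits` bits.
#' Deterministic, and invariant to SMILES rewriting of the same connectivity.
#'
#' @param smiles SMILES string
#' @param radius neighborhood radius (default 2, i.e. ECFP4-style)
#' @param nbits fingerprint length in bits (default 2048)
#' @return object of class `chem_fingerprint`: list with sorted unique
#'   1-based `bits` and `nbits`
#' @export
ecfp_fingerprint <- function(smiles, radius = 2, nbits = 2048) {
  mol <- parse_smiles(smiles)
  at <- mol$atoms; bd <- mol$bonds
  n <- nrow(at)
  nb <- vector("list", n)
  if (nrow(bd) > 0) for (r in seq_len(nrow(bd))) {
    nb[[bd$a1[r]]] <- rbind(nb[[bd$a1[r]]], c(bd$a2[r], bd$order[r] * 10))
    nb[[bd$a2[r]]] <- rbind(nb[[bd$a2[r]]], c(bd$a1[r], bd$order[r] * 10))
  }
  ids <- vapply(seq_len(n), function(i) hash_ints(c(
    ATOMIC_NUMBER[at$element[i]],
    if (is.null(nb[[i]])) 0L else nrow(nb[[i]]),
    at$n_h[i], at$charge[i], as.integer(at$aromatic[i]))), numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      if (is.null(nb[[i]])) return(hash_ints(c(r, ids[i])))
      env <- cbind(nb[[i]][, 2], ids[nb[[i]][, 1]])
      env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
      hash_ints(c(r, ids[i], as.numeric(t(env))))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  structure(list(bits = sort(unique(as.integer(all_ids %% nbits) + 1L)), nbits = nbits),
            class = "chem_fingerprint")
}

#' Dense 0/1 vector form of a fingerprint
#' @param fp `chem_fingerprint`
#' @return numeric vector of length `fp$nbits`
#' @export
fp_dense <- function(fp) {
  v <- numeric(fp$nbits); v[fp$bits] <- 1; v
}

#' Tanimoto similarity between two fingerprints
#' @param fp1,fp2 `chem_fingerprint` objects with equal `nbits`
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(fp1, fp2) {
  if (fp1$nbits != fp2$nbits)
    stop_cpifuse("fingerprint length mismatch", "cpifuse_contract_error")
  i <- length(intersect(fp1$bits, fp2$bits))
  u <- length(union(fp1$bits, fp2$bits))
  if (u == 0) return(1)
  i / u
}
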