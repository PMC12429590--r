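pdb_fixture <- function(path, bfac = c(91.40, 88.20, 75.00), drop_ca = FALSE) {
  lines <- c(
    sprintf("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00%6.2f           N", bfac[1]),
    sprintf("ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00%6.2f           C", bfac[1]),
    sprintf("ATOM      3  CA  GLY A   2       4.500   2.000   3.000  1.00%6.2f           C", bfac[2]),
    if (!drop_ca)
      sprintf("ATOM      4  CA  TRP A   3       8.000   2.000   3.000  1.00%6.2f           C", bfac[3])
    else
      sprintf("ATOM      4  CB  TRP A   3       8.000   2.000   3.000  1.00%6.2f           C", bfac[3]),
    "END")
  writeLines(lines, path)
  path
}

test_that("read_structure parses PDB C-alpha traces with pLDDT", {
  f <- withr::local_tempfile(fileext = ".pdb")
  pdb_fixture(f)
  st <- read_structure(f)
  expect_equal(nrow(st), 3)
  expect_equal(st$aa, c("A", "G", "W"))
  expect_equal(st$x, c(1, 4.5, 8))
  expect_equal(st$plddt[1], 91.40)   # B-factor column passthrough
  expect_equal(attr(st, "n_skipped"), 0L)
  # residue without CA skipped and counted
  pdb_fixture(f, drop_ca = TRUE)
  expect_message(st2 <- read_structure(f), "skipped 1")
  expect_equal(nrow(st2), 2)
  expect_equal(attr(st2, "n_skipped"), 1L)
  writeLines("REMARK nothing here", f)
  expect_error(read_structure(f), class = "cpifuse_empty_structure_error")
})

test_that("read_structure parses minimal mmCIF", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.label_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.B_iso_or_equiv",
    "ATOM CA MET 1 0.0 0.0 0.0 90.1",
    "ATOM CB MET 1 1.0 0.0 0.0 90.1",
    "ATOM CA LYS 2 3.8 0.0 0.0 85.5",
    "#"), f)
  st <- read_structure(f)
  expect_equal(nrow(st), 2)
  expect_equal(st$aa, c("M", "K"))
  expect_equal(st$plddt, c(90.1, 85.5))
})

test_that("write_pdb/read_structure round-trips generated structures", {
  cfg <- generator_config(n_chem = 6, n_prot = 6, residue_length = c(10L, 12L), seed = 3)
  sts <- generate_structures(cfg)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sts[[1]], f)
  back <- read_structure(f)
  expect_equal(back$aa, sts[[1]]$aa)
  expect_equal(back$x, round(sts[[1]]$x, 3))
  expect_equal(back$plddt, round(sts[[1]]$plddt, 2))
})

test_that("contact graph equals brute-force distance thresholding", {
  # collinear residues at 0, 4, 8, 12: boundary pair (1,3) at exactly 8 A included
  st <- toy_structure(n = 4, spacing = 4)
  cg <- build_contact_graph(st, cutoff = 8)
  expect_equal(cg$edges, cbind(c(1, 1, 2, 2, 3), c(2, 3, 3, 4, 4)))
  expect_equal(nrow(build_contact_graph(toy_structure(1))$edges), 0)
  expect_equal(nrow(build_contact_graph(st, cutoff = 0)$edges), 0)
  # randomized oracle check + monotonicity in cutoff
  set.seed(13)
  for (r in 1:5) {
    n <- sample(5:25, 1)
    st <- protein_structure(sample(c("A", "C", "X"), n, TRUE),
                            matrix(runif(n * 3, 0, 20), n, 3), runif(n, 0, 100))
    xyz <- as.matrix(st[, c("x", "y", "z")])
    D <- as.matrix(dist(xyz))
    last <- -1
    for (cutoff in c(4, 8, 12)) {
      cg <- build_contact_graph(st, cutoff)
      want <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
      expect_equal(nrow(cg$edges), nrow(want))
      expect_gte(nrow(cg$edges), last)
      last <- nrow(cg$edges)
      if (nrow(cg$edges) > 0)
        expect_true(all(D[cg$edges] <= cutoff))
    }
  }
})

test_that("protein encoding is SE(3)-invariant and relabel-consistent", {
  cfg <- generator_config(n_chem = 6, n_prot = 3, mean_degree_chem = 1,
                          mean_degree_prot = 2, residue_length = c(25L, 30L), seed = 5)
  sts <- generate_structures(cfg)
  enc <- encoder_config(layers = 3, s_dim = 32, v_dim = 8)
  set.seed(21)
  for (st in sts) {
    e0 <- encode_protein(build_contact_graph(st), enc)
    expect_length(e0, 32)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    shift <- rnorm(3, sd = 10)
    xyz <- as.matrix(st[, c("x", "y", "z")]) %*% R
    xyz <- sweep(xyz, 2, shift, "+")
    e1 <- encode_protein(build_contact_graph(protein_structure(st$aa, xyz, st$plddt)), enc)
    expect_lt(max(abs(e0 - e1)), 1e-5)
    # pure translation
    xyz2 <- sweep(as.matrix(st[, c("x", "y", "z")]), 2, c(3, -7, 11), "+")
    e2 <- encode_protein(build_contact_graph(protein_structure(st$aa, xyz2, st$plddt)), enc)
    expect_lt(max(abs(e0 - e2)), 1e-5)
    # order-preserving relabel (fresh objects): exact re-run equality
    e3 <- encode_protein(build_contact_graph(protein_structure(st$aa,
            as.matrix(st[, c("x", "y", "z")]), st$plddt)), enc)
    expect_identical(as.numeric(e0), as.numeric(e3))
  }
})

test_that("plddt pooling weights residues by confidence", {
  st <- toy_structure(n = 4)
  st$plddt <- c(100, 100, 10, 10)
  cg <- build_contact_graph(st)
  e_w <- encode_protein(cg, encoder_config(layers = 1, s_dim = 16, v_dim = 4, pool = "plddt"))
  e_m <- encode_protein(cg, encoder_config(layers = 1, s_dim = 16, v_dim = 4, pool = "mean"))
  expect_false(isTRUE(all.equal(as.numeric(e_w), as.numeric(e_m))))
})

test_that("structural topology signature matches hand counts", {
  path3 <- protein_structure(rep("A", 3), cbind(c(0, 4, 8), 0, 0), rep(90, 3))
  sig <- structural_topology_signature(build_contact_graph(path3, cutoff = 5))
  expect_equal(unname(sig["mean_degree"]), 4 / 3)
  expect_equal(unname(sig["max_degree"]), 2)
  expect_equal(unname(sig["mean_betweenness"]), 1 / 3)
  # complete contact graph: single-valued degree distribution -> entropy 0
  tight <- protein_structure(rep("A", 4), matrix(runif(12), 4, 3), rep(90, 4))
  expect_equal(unname(structural_topology_signature(
    build_contact_graph(tight, cutoff = 100))["degree_entropy"]), 0)
  lone <- build_contact_graph(toy_structure(2, spacing = 50))
  expect_equal(unname(structural_topology_signature(lone)), rep(0, 4))
})
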