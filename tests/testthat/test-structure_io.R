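# reading structures and deriving per-residue sites

# a small hand-built PDB with side-chain and charged-group atoms
full_atom_pdb <- function(path) {
  lines <- c(
    # Asp 1: CA at origin, OD1 (0,0,0)+x offsets chosen for the midpoint check
    "ATOM      1  N   ASP A   1      -1.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ASP A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ASP A   1       1.000   1.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  ASP A   1       0.000   1.000   0.000  1.00  0.00           C",
    "ATOM      5  OD1 ASP A   1       0.000   2.000   0.000  1.00  0.00           O",
    "ATOM      6  OD2 ASP A   1       2.000   2.000   0.000  1.00  0.00           O",
    # Gly 2: CA only side chain fallback
    "ATOM      7  N   GLY A   2       3.000   0.000   0.000  1.00  0.00           N",
    "ATOM      8  CA  GLY A   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      9  C   GLY A   2       5.000   0.000   0.000  1.00  0.00           C",
    # Lys 3 with NZ
    "ATOM     10  CA  LYS A   3       8.000   0.000   0.000  1.00  0.00           C",
    "ATOM     11  CB  LYS A   3       8.000   1.000   0.000  1.00  0.00           C",
    "ATOM     12  NZ  LYS A   3       8.000   4.000   0.000  1.00  0.00           N",
    # water + ligand must be dropped
    "HETATM   13  O   HOH A 101      30.000  30.000  30.000  1.00  0.00           O",
    "TER", "END")
  writeLines(lines, path)
  path
}

test_that("loading keeps protein chains in deposition order and drops heteroatoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  full_atom_pdb(f)
  asm <- load_assembly(f)
  expect_length(asm, 1L)
  expect_equal(asm[[1]]$monomer_id, "A")
  expect_false(any(asm[[1]]$atoms$resid == "HOH"))
  # bitwise round-trip: loading twice gives identical coordinates
  asm2 <- load_assembly(f)
  expect_identical(asm[[1]]$atoms, asm2[[1]]$atoms)
})

test_that("residue sites implement the three conventions and their fallbacks", {
  f <- withr::local_tempfile(fileext = ".pdb")
  full_atom_pdb(f)
  m <- load_assembly(f)[[1]]

  cg <- residue_sites(m, "charged_group_centroid")
  # Asp charged group = midpoint of OD1 (0,2,0) and OD2 (2,2,0)
  expect_equal(as.numeric(cg[cg$resid == "ASP", c("x", "y", "z")]),
               c(1, 2, 0))
  # Lys charged group = NZ
  expect_equal(as.numeric(cg[cg$resid == "LYS", c("x", "y", "z")]),
               c(8, 4, 0))

  sc <- residue_sites(m, "sidechain_centroid")
  # Gly has no side chain: falls back to its CA
  expect_equal(as.numeric(sc[sc$resid == "GLY", c("x", "y", "z")]),
               c(4, 0, 0))
  # Asp side-chain heavy atoms: CB, OD1, OD2
  expect_equal(as.numeric(sc[sc$resid == "ASP", c("x", "y", "z")]),
               colMeans(rbind(c(0, 1, 0), c(0, 2, 0), c(2, 2, 0))))

  ca <- residue_sites(m, "calpha")
  expect_equal(ca$x, c(0, 4, 8))
})

test_that("chain grouping and explicit order control the monomer list", {
  tpl <- toy_monomer(hydrophobic = list(q = c(1.38, -2.53),
                                        xyz = rbind(c(0, 0, 2), c(0, 0, -2))))
  asm <- helical_assembly(tpl, 4, radius = 15, rise_per_monomer = 2,
                          twist_per_monomer = 30)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(asm, f)

  by_chain <- load_assembly(f)
  expect_length(by_chain, 4L)
  expect_equal(vapply(by_chain, `[[`, character(1), "monomer_id"),
               c("A", "B", "C", "D"))

  grouped <- load_assembly(f, groups = list(c("A", "B"), c("C", "D")))
  expect_length(grouped, 2L)
  expect_equal(grouped[[1]]$monomer_id, "A+B")
  expect_equal(vapply(grouped, `[[`, integer(1), "ordinal"), 1:2)

  reordered <- load_assembly(f, chain_order = c("C", "A", "B", "D"))
  expect_equal(vapply(reordered, `[[`, character(1), "monomer_id"),
               c("C", "A", "B", "D"))
  expect_equal(vapply(reordered, `[[`, integer(1), "ordinal"), 1:4)
})

test_that("rigid transforms of the input move every residue site equivariantly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  full_atom_pdb(f)
  m <- load_assembly(f)[[1]]
  set.seed(42)
  R <- random_rotation(); tr <- runif(3, -20, 20)
  m2 <- m
  xyz <- t(R %*% t(as.matrix(m$atoms[, c("x", "y", "z")]))) +
    matrix(tr, nrow(m$atoms), 3, byrow = TRUE)
  m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
  for (mode in c("calpha", "sidechain_centroid", "charged_group_centroid")) {
    s1 <- as.matrix(residue_sites(m, mode)[, c("x", "y", "z")])
    s2 <- as.matrix(residue_sites(m2, mode)[, c("x", "y", "z")])
    expect_equal(s2, t(R %*% t(s1)) + matrix(tr, nrow(s1), 3, byrow = TRUE),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("unusable inputs fail loudly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  O   HOH A   1       0.0     0.0     0.0  1.00  0.00           O",
               "END"), f)
  expect_error(load_assembly(f), "empty assembly")
  expect_error(load_assembly(tempfile()), "not found")
  g <- withr::local_tempfile(fileext = ".pdb")
  full_atom_pdb(g)
  expect_error(load_assembly(g, model_index = 5), "model_index")
})
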