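test_that("a minimal one-residue file parses to an identity model", {
  f <- system.file("extdata", "toy_plm.pdb", package = "fabpocket")
  s <- read_pdb(f)
  poly <- s$atoms[s$atoms$kind == "polymer", ]
  expect_equal(nrow(poly), 5)
  expect_equal(sort(poly$name), sort(c("N", "CA", "C", "O", "CB")))
  expect_equal(poly$resname, rep("ALA", 5))
  expect_equal(poly$resno, rep(1L, 5))
  # hetero routing: PLM is a ligand, water is neither chain nor ligand
  lig <- ligand_residues(s)
  expect_equal(nrow(lig), 1)
  expect_equal(lig$resname, "PLM")
  expect_equal(lig$n_atoms, 3L)
  expect_equal(nrow(s$waters), 1)
  expect_false(any(s$atoms$resname == "HOH"))
})

test_that("altloc duplicates keep the highest-occupancy conformer", {
  f <- write_fixture_pdb(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       3.000   1.000   0.000  1.00  0.00           C",
    "END"))
  s <- read_pdb(f)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 2.0)       # B has occupancy 0.60
  expect_equal(ca$altloc, "B")
  # occupancy tie goes to altloc A
  f2 <- write_fixture_pdb(c(
    "ATOM      1  CA BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "END"))
  s2 <- read_pdb(f2)
  expect_equal(s2$atoms$altloc, "A")
  expect_equal(s2$atoms$x, 1.0)
})

test_that("hydrogens are dropped and malformed records are named by line", {
  f <- write_fixture_pdb(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       0.500   0.500   0.000  1.00  0.00           H",
    "END"))
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$element, "N")
  f2 <- write_fixture_pdb(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       bad.xx   0.000   0.000  1.00  0.00           C",
    "END"))
  expect_error(read_pdb(f2), "line 2")
  f3 <- write_fixture_pdb(c("REMARK none", "END"))
  expect_error(read_pdb(f3), "no ATOM or HETATM")
})

test_that("vdW radii come from the element table with a logged default", {
  s <- make_structure(data.frame(
    element = c("C", "N", "O", "S", "P", "SE"),
    x = rnorm(6), y = rnorm(6), z = rnorm(6), resno = 1:6,
    stringsAsFactors = FALSE))
  expect_warning(s2 <- assign_vdw_radii(s), "SE")
  expect_equal(s2$atoms$vdw, c(1.70, 1.55, 1.52, 1.80, 1.80, 1.70))
  # all-carbon cage: all radii equal the carbon default, no warning
  cage <- make_cage(cage_spec(seed = 3))
  expect_silent(cage <- assign_vdw_radii(cage))
  expect_true(all(cage$atoms$vdw == 1.70))
})

test_that("pocket PDB round-trips atoms and sphere centers", {
  s <- make_cage(cage_spec(n_shell_atoms = 150, seed = 2))
  pockets <- detect_pockets(s)
  expect_gte(length(pockets), 1)
  f <- tempfile(fileext = ".pdb")
  write_pocket_pdb(s, f, pockets)
  s2 <- read_pdb(f)
  # appended HETATM pseudo-atoms: one per alpha sphere, resname STP
  stp <- s2$atoms[s2$atoms$resname == "STP", ]
  expect_equal(nrow(stp), sum(vapply(pockets, function(p) p$n_spheres,
                                     numeric(1))))
  # sphere centers recovered within PDB 3-decimal precision
  sp1 <- pockets[[1]]$spheres
  got <- stp[stp$resno == pockets[[1]]$id, ]
  expect_equal(sort(got$x), sort(sp1$cx), tolerance = 1e-3)
  # polymer content identical: parse -> write -> parse round-trip
  poly1 <- s$atoms[s$atoms$kind == "polymer",
                   c("name", "chain", "resno", "icode", "x", "y", "z")]
  poly2 <- s2$atoms[s2$atoms$kind == "polymer",
                    c("name", "chain", "resno", "icode", "x", "y", "z")]
  expect_equal(nrow(poly1), nrow(poly2))
  expect_equal(poly1$x, poly2$x, tolerance = 1e-3)
  expect_equal(poly1$resno, poly2$resno)
  # zero pockets: ATOM content identical to input
  f0 <- tempfile(fileext = ".pdb")
  write_pocket_pdb(s, f0, list())
  atom_lines <- function(p) grep("^(ATOM|HETATM)", readLines(p), value = TRUE)
  f_in <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, f_in)
  expect_identical(atom_lines(f0), atom_lines(f_in))
})

test_that("every non-water HETATM residue is routed to exactly one ligand", {
  f <- write_fixture_pdb(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C1  PLM A 101       5.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  MYR B 101       9.000   0.000   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A 201      12.000   0.000   0.000  1.00  0.00           O",
    "END"))
  s <- read_pdb(f)
  lig <- ligand_residues(s)
  expect_setequal(lig$resname, c("PLM", "MYR"))
  expect_equal(sum(s$atoms$kind == "ligand"), 2)
  # no atom appears twice across kinds
  key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$name, s$atoms$resname)
  expect_false(anyDuplicated(key) > 0)
})
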