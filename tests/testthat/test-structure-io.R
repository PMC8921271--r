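test_that("minimal mmCIF with one atom and a P1 cell parses to the identity setup", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_MINI",
    "_entry.id MINI",
    "_cell.length_a 20.000", "_cell.length_b 20.000", "_cell.length_c 20.000",
    "_cell.angle_alpha 90.00", "_cell.angle_beta 90.00", "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA . ALA A 1 ? 5.000 6.000 7.000 1.00 15.00"
  ), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1L)
  expect_length(m$cell$symops, 1L)
  expect_equal(m$cell$symops[[1]]$rotation, diag(3))
  expect_equal(m$cell$symops[[1]]$translation, c(0, 0, 0))
  expect_equal(c(m$atoms$x, m$atoms$y, m$atoms$z), c(5, 6, 7))
})

test_that("fractional coordinates convert through the orthogonalisation matrix", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_FRAC",
    "_cell.length_a 20.0", "_cell.length_b 20.0", "_cell.length_c 20.0",
    "_cell.angle_alpha 90", "_cell.angle_beta 90", "_cell.angle_gamma 90",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.fract_x", "_atom_site.fract_y", "_atom_site.fract_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA ALA A 1 0.5 0.5 0.5 1.00 10.00"
  ), path)
  m <- read_structure(path)
  expect_equal(c(m$atoms$x, m$atoms$y, m$atoms$z), c(10, 10, 10))

  # orthogonal cell: frac (fx, fy, fz) -> (fx a, fy b, fz c) exactly
  cell <- crystal_cell(11, 13, 17)
  expect_equal(frac_to_orth(cell, c(0.25, 0.5, 0.75))[1, ],
               c(0.25 * 11, 0.5 * 13, 0.75 * 17))
  # general cell: fractionalisation inverts orthogonalisation
  tric <- crystal_cell(30, 40, 50, 80, 95, 110)
  f <- matrix(runif(30), ncol = 3)
  expect_equal(orth_to_frac(tric, frac_to_orth(tric, f)), f, tolerance = 1e-12)
})

test_that("the same structure serialised as mmCIF and PDB reads back identically", {
  m <- generate_fixture(fixture_spec(n_chains = 1, residues_per_chain = 20))
  cif <- withr::local_tempfile(fileext = ".cif")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_mmcif(m, cif)
  write_pdb(m, pdb)
  mc <- read_structure(cif)
  mp <- read_structure(pdb)
  for (col in c("serial", "atom_name", "residue_name", "chain_id",
                "residue_seq", "occupancy", "b_iso")) {
    expect_equal(mc$atoms[[col]], mp$atoms[[col]], info = col)
    expect_equal(mc$atoms[[col]], m$atoms[[col]], info = col)
  }
  expect_lt(max(abs(mc$atoms$x - mp$atoms$x)), 1e-3)
  expect_lt(max(abs(mc$atoms$y - mp$atoms$y)), 1e-3)
  expect_lt(max(abs(mc$atoms$z - mp$atoms$z)), 1e-3)
  expect_equal(mc$metadata$resolution, m$metadata$resolution)
  expect_equal(mc$metadata$temperature, m$metadata$temperature)
  expect_equal(mp$metadata$r_free, m$metadata$r_free)
})

test_that("the PDB reader agrees with bio3d on generated fixtures", {
  m <- generate_fixture(fixture_spec(n_chains = 1, residues_per_chain = 15, seed = 4))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, pdb)
  ours <- read_structure(pdb)
  ref <- suppressWarnings(bio3d::read.pdb(pdb))$atom
  expect_equal(nrow(ours$atoms), nrow(ref))
  expect_equal(ours$atoms$x, ref$x, tolerance = 1e-9)
  expect_equal(ours$atoms$b_iso, ref$b, tolerance = 1e-9)
  expect_equal(ours$atoms$atom_name, ref$elety)
  expect_equal(ours$atoms$residue_name, ref$resid)
  expect_equal(ours$atoms$residue_seq, ref$resno)
})

test_that("defective files are rejected with the missing record named", {
  no_cell <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_X", "_entry.id X"), no_cell)
  expect_error(read_structure(no_cell), "_cell")

  no_atoms <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_X",
               "_cell.length_a 10", "_cell.length_b 10", "_cell.length_c 10",
               "_cell.angle_alpha 90", "_cell.angle_beta 90", "_cell.angle_gamma 90",
               "_symmetry.space_group_name_H-M 'P 1'"), no_atoms)
  expect_error(read_structure(no_atoms), "zero atoms")

  bad_sg <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 Q 9 9 9        1",
    "ATOM      1  CA  ALA A   1       5.000   5.000   5.000  1.00 15.00           C",
    "END"), bad_sg)
  expect_error(read_structure(bad_sg), "symbol table")

  no_b <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1            1",
    "ATOM      1  CA  ALA A   1       5.000   5.000   5.000  1.00                  C",
    "END"), no_b)
  expect_error(read_structure(no_b), "B-factor")
})

test_that("symmetry operators parse and the bundled table covers common groups", {
  op <- parse_symop("-X,Y+1/2,-Z")
  expect_equal(op$rotation, diag(c(-1, 1, -1)))
  expect_equal(op$translation, c(0, 0.5, 0))
  # identity returns coordinates unchanged
  f <- matrix(runif(9), ncol = 3)
  expect_equal(apply_symop(parse_symop("X,Y,Z"), f), f)
  expect_length(spacegroup_symops("P 21 21 21"), 4L)
  expect_length(spacegroup_symops("P 1 21 1"), 2L)
  expect_length(spacegroup_symops("P 43 21 2"), 8L)
  expect_null(spacegroup_symops("NOT A GROUP"))
})

test_that("B_Damage-coloured output writes the value into the B column", {
  m <- generate_fixture(fixture_spec(n_chains = 1, residues_per_chain = 12, seed = 2))
  ctx <- expand_lattice(m)
  bd <- compute_bdamage(m, packing_density(ctx))
  out <- withr::local_tempfile(fileext = ".pdb")

  # uniform case: all B_Damage exactly 1 -> every B column reads "  1.00"
  bd1 <- bd
  bd1$atoms$bdamage <- 1
  write_bdamage_coordinates(m, bd1, out)
  lines <- readLines(out)
  at <- lines[startsWith(lines, "ATOM")]
  expect_true(all(substr(at, 61, 66) == "  1.00"))

  # round-trip: B column equals B_Damage to 2 dp
  write_bdamage_coordinates(m, bd, out)
  back <- read_structure(out)
  expect_equal(back$atoms$b_iso[match(bd$atoms$serial, back$atoms$serial)],
               round(bd$atoms$bdamage, 2), tolerance = 1e-9)

  # missing atom -> error naming the serial
  bd_missing <- bd
  bd_missing$atoms <- bd_missing$atoms[-1, ]
  expect_error(write_bdamage_coordinates(m, bd_missing, out), "serial")
})
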