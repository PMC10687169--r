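test_that("a minimal PDB parses into one chain, one residue, three atoms", {
  m <- parse_structure(minimal_pdb_text(), format = "pdb")
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(length(unique(m$atoms$chain)), 1)
  expect_equal(length(unique(m$atoms$resno)), 1)
  expect_equal(m$atoms$name, c("N", "CA", "C"))
  expect_equal(m$atoms$element, c("N", "C", "C"))
})

test_that("waters and metals are retained and empty/garbage input errors", {
  txt <- paste(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, c(0, 0, 0)),
    pdb_atom_line(2, "ZN", "ZN", "A", 90, c(3, 0, 0), element = "Zn",
                  record = "HETATM"),
    pdb_atom_line(3, "O", "HOH", "A", 101, c(6, 0, 0), element = "O",
                  record = "HETATM"),
    "END"), collapse = "\n")
  m <- parse_structure(txt, format = "pdb")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(sum(toupper(m$atoms$element) == "ZN"), 1)
  expect_equal(nrow(select_atoms(m, water = TRUE)), 1)
  expect_error(parse_structure("\n\n", format = "pdb"), "empty")
  expect_error(parse_structure("not a structure at all\n", format = "pdb"))
})

test_that("altloc policy keeps the highest-occupancy conformer, ties to A", {
  two_alt <- function(occ_a, occ_b) paste(c(
    pdb_atom_line(1, "CA", "SER", "A", 1, c(0, 0, 0), occ = occ_a, alt = "A"),
    pdb_atom_line(2, "CA", "SER", "A", 1, c(5, 0, 0), occ = occ_b, alt = "B"),
    "END"), collapse = "\n")
  m1 <- parse_structure(two_alt(0.4, 0.6), format = "pdb")
  expect_equal(nrow(m1$atoms), 1)
  expect_equal(m1$atoms$x, 5)  # B wins on occupancy
  m2 <- parse_structure(two_alt(0.5, 0.5), format = "pdb")
  expect_equal(m2$atoms$x, 0)  # tie goes to altloc A
})

test_that("write -> parse round-trip preserves counts, names and coordinates", {
  m <- make_ubr_zinc_model(n_chains = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- parse_structure(path)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_equal(m2$atoms$resid, m$atoms$resid)
  expect_equal(round(m2$atoms$x, 3), round(m$atoms$x, 3))
  expect_equal(round(m2$atoms$y, 3), round(m$atoms$y, 3))
  expect_equal(round(m2$atoms$z, 3), round(m$atoms$z, 3))
})

test_that("cell and Cartesian symmetry operators survive a PDB round-trip", {
  ops <- list(cbind(diag(3), c(0, 0, 0)),
              cbind(diag(c(-1, 1, -1)), c(0, 5, 4)))
  m <- make_zinc_site("C4")
  m$unit_cell <- c(10, 10, 8, 90, 90, 90)
  m$space_group <- "P 1 21 1"
  m$sym_ops <- ops
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- parse_structure(path)
  expect_equal(unname(m2$unit_cell), c(10, 10, 8, 90, 90, 90))
  expect_equal(m2$space_group, "P 1 21 1")
  expect_equal(length(m2$sym_ops), 2)
  expect_equal(m2$sym_ops[[2]], ops[[2]], tolerance = 1e-6)
})

test_that("fractional symmetry-operator strings parse correctly", {
  op <- parse_symop_xyz("-x,y+1/2,-z+1/2")
  expect_equal(op, cbind(diag(c(-1, 1, -1)), c(0, 0.5, 0.5)))
  expect_equal(parse_symop_xyz("x,y,z"), cbind(diag(3), c(0, 0, 0)))
  expect_error(parse_symop_xyz("x,y"), "malformed")
})

test_that("identity-only symmetry leaves the atom count unchanged", {
  m <- make_zinc_site("C2H2")
  m$unit_cell <- c(100, 100, 100, 90, 90, 90)
  m$space_group <- "P 1"
  m$sym_ops <- list(cbind(diag(3), c(0, 0, 0)))
  n0 <- nrow(m$atoms)
  expect_equal(nrow(expand_symmetry(m, 5)$atoms), n0)
})

test_that("expansion without cell/operators gives an instructive error", {
  m <- make_zinc_site("C2H2")
  expect_error(expand_symmetry(m, 5), "without symmetry expansion")
})

test_that("P1 lattice translations match brute-force enumeration", {
  atoms <- data.frame(eleno = 1L, name = "CA", alt = "", resid = "GLY",
                      chain = "A", resno = 1L, x = 0, y = 0, z = 0,
                      o = 1, b = 0, element = "C", het = FALSE,
                      stringsAsFactors = FALSE)
  cell <- c(10, 11, 12, 90, 90, 90)
  m <- structure_model("p1", atoms, unit_cell = cell, space_group = "P 1",
                       sym_ops = list(cbind(diag(3), c(0, 0, 0))))
  radius <- 13
  ex <- expand_symmetry(m, radius)
  copies <- ex$atoms[ex$atoms$is_symmetry_copy, ]
  # oracle: enumerate all lattice offsets directly
  grid <- expand.grid(na = -1:1, nb = -1:1, nc = -1:1)
  grid <- grid[!(grid$na == 0 & grid$nb == 0 & grid$nc == 0), ]
  pos <- cbind(grid$na * cell[1], grid$nb * cell[2], grid$nc * cell[3])
  keep <- sqrt(rowSums(pos^2)) <= radius
  expected <- pos[keep, , drop = FALSE]
  expect_equal(nrow(copies), nrow(expected))
  got <- round(as.matrix(copies[, c("x", "y", "z")]), 9)
  got <- got[order(got[, 1], got[, 2], got[, 3]), ]
  want <- expected[order(expected[, 1], expected[, 2], expected[, 3]), ]
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("symmetry copies are exact images under the stored operators", {
  m <- make_zinc_site("C2H2")
  cell <- c(20, 22, 24, 90, 90, 90)
  m$unit_cell <- cell
  m$space_group <- "P 21 21 21"
  # Cartesian operators of an orthorhombic 2-fold screw set
  m$sym_ops <- list(
    cbind(diag(3), c(0, 0, 0)),
    cbind(diag(c(-1, -1, 1)), c(cell[1] / 2, 0, cell[3] / 2)),
    cbind(diag(c(-1, 1, -1)), c(0, cell[2] / 2, cell[3] / 2)),
    cbind(diag(c(1, -1, -1)), c(cell[1] / 2, cell[2] / 2, 0)))
  ex <- expand_symmetry(m, radius = 30)
  copies <- ex$atoms[ex$atoms$is_symmetry_copy, ]
  expect_gt(nrow(copies), 0)
  orig <- ex$atoms[!ex$atoms$is_symmetry_copy, ]
  O <- orthogonalization_matrix(cell)
  for (lab in unique(copies$sym_op)) {
    k <- as.integer(sub("op([0-9]+).*", "\\1", lab))
    shift <- as.integer(strsplit(sub(".*\\[(.*)\\]", "\\1", lab), ",")[[1]])
    op <- m$sym_ops[[k]]
    expected <- sweep(as.matrix(orig[, c("x", "y", "z")]) %*% t(op[, 1:3]),
                      2, op[, 4] + as.numeric(O %*% shift), "+")
    got <- as.matrix(copies[copies$sym_op == lab, c("x", "y", "z")])
    expect_equal(got, expected, ignore_attr = TRUE, tolerance = 1e-9)
  }
  # originals untouched, output a superset of input
  expect_equal(as.matrix(orig[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("select_atoms filters deterministically and allows empty results", {
  m <- make_ubr_zinc_model(n_chains = 3)
  zn <- select_atoms(m, element = "Zn")
  expect_equal(nrow(zn), 9)
  expect_equal(zn$chain, sort(zn$chain))
  expect_equal(nrow(select_atoms(m, selector = function(a) a$resno > 1e6)), 0)
  cys_a <- select_atoms(m, chain = "A", resid = "CYS")
  expect_true(all(diff(cys_a$resno) >= 0))
})

test_that("a minimal mmCIF parses with cell and fractional operators", {
  cif <- paste(c(
    "data_test",
    "_cell.length_a   10.000",
    "_cell.length_b   12.000",
    "_cell.length_c   14.000",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 21 21 21'",
    "loop_",
    "_symmetry_equiv.id",
    "_symmetry_equiv.pos_as_xyz",
    "1 'x,y,z'",
    "2 '-x+1/2,-y,z+1/2'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . GLY A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 GLY A CA 1",
    "#"), collapse = "\n")
  m <- suppressWarnings(parse_structure(cif, format = "mmcif"))
  expect_equal(nrow(m$atoms), 1)
  expect_equal(unname(m$unit_cell[1:3]), c(10, 12, 14))
  expect_equal(length(m$sym_ops), 2)
  # second operator in Cartesian form for an orthorhombic cell
  expect_equal(m$sym_ops[[2]],
               cbind(diag(c(-1, -1, 1)), c(5, 0, 7)), tolerance = 1e-9)
})
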