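test_that("structure reading infers molecule roles on a minimal system", {
  path <- write_three_atom_pdb(tempfile(fileext = ".pdb"))
  tr <- read_structure(path)
  expect_equal(n_atoms(tr), 3)
  expect_equal(tr$topology$atoms$role, c("protein", "ion", "ligand"))
  expect_equal(frame_coords(tr, 1)[2, ], c(3, 0, 0))
  # element-derived defaults
  expect_equal(tr$topology$atoms$mass[2], 65.38)
  expect_equal(tr$topology$atoms$charge, c(0, 0, 0))
})

test_that("parameter sidecar overrides element defaults (zinc mass and charge)", {
  path <- write_three_atom_pdb(tempfile(fileext = ".pdb"))
  sidecar <- tempfile(fileext = ".tsv")
  writeLines(c(
    "residue_name\tatom_name\tmass\tcharge\tsigma\tepsilon\tpb_radius",
    "ZN\tZN\t65.4\t2.0\t1.95\t0.0125\t1.39"
  ), sidecar)
  tr <- read_structure(path, sidecar)
  zn <- tr$topology$atoms[2, ]
  expect_equal(zn$mass, 65.4)
  expect_equal(zn$charge, 2.0)
  # atoms without sidecar rows keep defaults
  expect_equal(tr$topology$atoms$charge[c(1, 3)], c(0, 0))
})

test_that("duplicate serials are rejected with a validation error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line("ATOM", 1, "CB", "GLY", "A", 1, 1, 0, 0, "C"),
    "END"
  ), path)
  expect_error(read_structure(path), "duplicate atom serial")
})

test_that("unknown elements are reported with the offending record", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("ATOM", 7, "XX", "GLY", "A", 1, 0, 0, 0, "XQ"), "END"), path)
  expect_error(read_structure(path), "unknown element 'XQ'.*serial 7")
})

test_that("multi-model PDB trajectories read frame by frame", {
  path <- write_three_atom_pdb(tempfile(fileext = ".pdb"))
  topo <- read_structure(path)$topology
  traj_path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line("HETATM", 2, "ZN", "ZN", "A", 2, 3, 0, 0, "ZN"),
    pdb_line("HETATM", 3, "C1", "LIG", "B", 3, 0, 3, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0.5, 0, 0, "C"),
    pdb_line("HETATM", 2, "ZN", "ZN", "A", 2, 3.5, 0, 0, "ZN"),
    pdb_line("HETATM", 3, "C1", "LIG", "B", 3, 0.5, 3, 0, "C"),
    "ENDMDL", "END"
  ), traj_path)
  tr <- read_trajectory(traj_path, topo)
  expect_equal(n_frames(tr), 2)
  expect_equal(frame_coords(tr, 2)[1, 1], 0.5)
})

test_that("atom-count mismatches cite the offending frame", {
  path <- write_three_atom_pdb(tempfile(fileext = ".pdb"))
  topo <- read_structure(path)$topology
  traj_path <- tempfile(fileext = ".pdb")
  frame_lines <- c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line("HETATM", 2, "ZN", "ZN", "A", 2, 3, 0, 0, "ZN"),
    pdb_line("HETATM", 3, "C1", "LIG", "B", 3, 0, 3, 0, "C")
  )
  writeLines(c(
    "MODEL        1", frame_lines, "ENDMDL",
    "MODEL        2", frame_lines, "ENDMDL",
    "MODEL        3", frame_lines[1:2], "ENDMDL", "END"
  ), traj_path)
  expect_error(read_trajectory(traj_path, topo), "frame 3: expected 3 atoms, got 2")
})

test_that("XYZ trajectory roundtrip preserves coordinates at printed precision", {
  set.seed(42)
  topo <- toy_protein_topology()
  coords <- array(rnorm(5 * 6 * 3, sd = 5), dim = c(5, 6, 3))
  tr <- new_trajectory(topo, coords, times = seq(0, 0.4, by = 0.1))
  path <- tempfile(fileext = ".xyz")
  write_trajectory(tr, path)
  back <- read_trajectory(path, topo)
  expect_equal(n_frames(back), 5)
  expect_equal(back$coords, round(tr$coords, 6), tolerance = 1e-12)
  expect_equal(back$times, tr$times)
})

test_that("PDB trajectory roundtrip agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  topo <- toy_protein_topology()
  coords <- array(round(rnorm(2 * 6 * 3, sd = 4), 3), dim = c(2, 6, 3))
  tr <- new_trajectory(topo, coords)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(tr, path)
  ours <- read_trajectory(path, topo)
  expect_equal(ours$coords, coords)
  ref <- bio3d::read.pdb(path, multi = TRUE)
  expect_equal(matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE),
               matrix(coords[1, , ], ncol = 3))
  expect_equal(ref$atom$resid[1:2], c("ALA", "ALA"))
})

test_that("selection grammar matches roles, names and residue ranges", {
  topo <- toy_protein_topology()
  expect_equal(as.integer(select_atoms(topo, "protein and name CA")), c(1, 3, 5))
  expect_equal(as.integer(select_atoms(topo, "resid 2-3 and name CB")), c(4, 6))
  expect_equal(as.integer(select_atoms(topo, "name CA CB")), 1:6)
  expect_equal(as.integer(select_atoms(topo, "resid 1 or resid 3")), c(1, 2, 5, 6))
  toy <- gen_toy_complex(toy_complex_spec())
  expect_equal(as.integer(select_atoms(toy$topology, "ligand")), 3)
  expect_error(select_atoms(topo, "resid 999"), "matched no atoms")
  expect_error(select_atoms(topo, "frobnicate"), "unknown token")
})

test_that("selection is deterministic and order-stable under re-selection", {
  topo <- toy_protein_topology()
  s1 <- select_atoms(topo, "protein and name CA")
  # selecting over the subset topology with the same expression is identity
  sub <- new_topology(topo$atoms[as.integer(s1), ])
  s2 <- select_atoms(sub, "protein and name CA")
  expect_equal(as.integer(s2), seq_along(s1))
})

test_that("write_table emits a re-readable fixed-order TSV", {
  rows <- list(
    list(ligand = "L1", dG_pbsa = -70.084, minus_TdS = 5.839),
    list(ligand = "L2", dG_pbsa = -74.161, minus_TdS = 16.321)
  )
  path <- tempfile(fileext = ".tsv")
  write_table(rows, path)
  back <- read_table_tsv(path)
  expect_equal(names(back), c("ligand", "dG_pbsa", "minus_TdS"))
  expect_equal(back$dG_pbsa, c(-70.08, -74.16))
  # heterogeneous keys refused
  expect_error(
    write_table(list(list(a = 1), list(b = 2)), tempfile()),
    "heterogeneous keys"
  )
  # empty rows give a header-only file
  write_table(data.frame(a = numeric(0), b = numeric(0)), path)
  expect_equal(nrow(read_table_tsv(path)), 0)
})
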