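test_that("Coulomb term reproduces hand arithmetic at the fixed constant", {
  topo <- new_topology(data.frame(
    serial = 1:2, name = c("Q1", "Q2"), element = "C", resname = c("ALA", "LIG"),
    resid = 1:2, chain = c("A", "B"), mass = 12, charge = c(1, 1),
    sigma = 0, epsilon = 0, pb_radius = 1.7, stringsAsFactors = FALSE
  ))
  fr <- rbind(c(0, 0, 0), c(3.32, 0, 0))
  e <- pair_nonbonded(fr, topo, 1, 2)
  expect_equal(e[["E_elec"]], 332.0636 / 3.32, tolerance = 1e-12)
  expect_equal(e[["E_elec"]], 100.02, tolerance = 1e-4)
  expect_equal(e[["E_vdw"]], 0)
})

test_that("Lennard-Jones roots and minimum are exact", {
  mk <- function(r) {
    topo <- new_topology(data.frame(
      serial = 1:2, name = c("C1", "C2"), element = "C", resname = c("ALA", "LIG"),
      resid = 1:2, chain = c("A", "B"), mass = 12, charge = 0,
      sigma = 3.4, epsilon = 0.25, pb_radius = 1.7, stringsAsFactors = FALSE
    ))
    pair_nonbonded(rbind(c(0, 0, 0), c(r, 0, 0)), topo, 1, 2)[["E_vdw"]]
  }
  expect_equal(mk(3.4), 0, tolerance = 1e-12)
  expect_equal(mk(2^(1 / 6) * 3.4), -0.25, tolerance = 1e-12)
})

test_that("pairwise energies equal an independent brute-force double loop", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 8
    atoms <- data.frame(
      serial = 1:n, name = paste0("C", 1:n), element = "C",
      resname = c(rep("ALA", 4), rep("LIG", 4)),
      resid = c(1:4, rep(5L, 4)), chain = c(rep("A", 4), rep("B", 4)),
      mass = 12, charge = runif(n, -1, 1), sigma = runif(n, 2.5, 4),
      epsilon = runif(n, 0, 0.4), pb_radius = 1.7, stringsAsFactors = FALSE
    )
    topo <- new_topology(atoms)
    fr <- matrix(runif(3 * n, 0, 12), n, 3)
    while (min(dist(fr)) < 1) fr <- matrix(runif(3 * n, 0, 12), n, 3)
    fast <- pair_nonbonded(fr, topo, 1:4, 5:8)
    slow <- brute_force_nonbonded(fr, atoms, 1:4, 5:8)
    expect_equal(fast[["E_vdw"]], slow[["E_vdw"]], tolerance = 1e-10)
    expect_equal(fast[["E_elec"]], slow[["E_elec"]], tolerance = 1e-10)
  }
})

test_that("overlapping atoms and non-disjoint groups are rejected", {
  toy <- gen_toy_complex(toy_complex_spec())
  topo <- toy$topology
  fr <- frame_coords(toy, 1)
  expect_error(pair_nonbonded(fr, topo, 1:2, 2:3), "disjoint")
  fr2 <- fr
  fr2[3, ] <- fr2[1, ]
  expect_error(pair_nonbonded(fr2, topo, 1:2, 3), "overlapping atoms: serial 1")
})

test_that("SASA of an isolated sphere is the exact expanded-sphere area", {
  topo <- new_topology(data.frame(
    serial = 1L, name = "O1", element = "O", resname = "LIG", resid = 1L,
    chain = "A", mass = 16, charge = 0, sigma = 0, epsilon = 0,
    pb_radius = 1.6, stringsAsFactors = FALSE
  ))
  s <- sasa(matrix(0, 1, 3), topo, 1)
  expect_equal(s$total, 4 * pi * 3.0^2, tolerance = 1e-12)
  expect_equal(s$total, 113.097, tolerance = 1e-3)
})

test_that("SASA is additive at infinite separation and follows the cap formula", {
  mk_two <- function(d) {
    topo <- new_topology(data.frame(
      serial = 1:2, name = c("O1", "O2"), element = "O", resname = c("ALA", "LIG"),
      resid = 1:2, chain = c("A", "B"), mass = 16, charge = 0, sigma = 0,
      epsilon = 0, pb_radius = 1.6, stringsAsFactors = FALSE
    ))
    sasa(rbind(c(0, 0, 0), c(d, 0, 0)), topo, 1:2)
  }
  one <- 4 * pi * 3^2
  expect_equal(mk_two(100)$total, 2 * one, tolerance = 1e-12)
  # touching expanded spheres: buried area is infinitesimal
  expect_equal(mk_two(6)$total, 2 * one, tolerance = 0.005 * 2 * one)
  # oracle: spherical-cap closed form for equal spheres at distance d:
  # exposed = 2 * 2 pi R (R + d/2)
  d <- 3.5
  expect_equal(mk_two(d)$total, 2 * 2 * pi * 3 * (3 + d / 2),
               tolerance = 0.02 * 2 * one)
  # near-complete overlap leaves about one sphere's area
  expect_equal(mk_two(0.6)$total, 2 * 2 * pi * 3 * (3 + 0.3),
               tolerance = 0.02 * one)
})

test_that("SASA point-count convergence on the two-sphere cap oracle", {
  topo <- new_topology(data.frame(
    serial = 1:2, name = c("O1", "O2"), element = "O", resname = c("ALA", "LIG"),
    resid = 1:2, chain = c("A", "B"), mass = 16, charge = 0, sigma = 0,
    epsilon = 0, pb_radius = 1.6, stringsAsFactors = FALSE
  ))
  exact <- 2 * 2 * pi * 3 * (3 + 1.75)
  errs <- vapply(c(240, 960, 3840), function(np) {
    p <- solvation_params(n_sasa_points = np)
    abs(sasa(rbind(c(0, 0, 0), c(3.5, 0, 0)), topo, 1:2, p)$total - exact) / exact
  }, numeric(1))
  expect_lt(errs[2], 0.002)
  expect_lt(errs[3], errs[1])
})

test_that("zero-radius atoms in the SASA selection are refused", {
  topo <- new_topology(data.frame(
    serial = 1L, name = "X1", element = "C", resname = "LIG", resid = 1L,
    chain = "A", mass = 12, charge = 0, sigma = 0, epsilon = 0,
    pb_radius = 0, stringsAsFactors = FALSE
  ))
  expect_error(sasa(matrix(0, 1, 3), topo, 1), "zero PB radius")
})

test_that("nonpolar solvation is the affine SASA law", {
  p <- solvation_params()
  expect_equal(nonpolar_solvation(0, p), 0.92)
  expect_equal(nonpolar_solvation(113.097, p), 0.00542 * 113.097 + 0.92)
  expect_equal(nonpolar_solvation(113.097, p), 1.533, tolerance = 1e-3)
  p0 <- solvation_params(gamma = 0)
  expect_equal(nonpolar_solvation(5000, p0), 0.92)
})

test_that("single-trajectory breakdown matches brute force on the 3-bead complex", {
  toy <- gen_toy_complex(toy_complex_spec())
  p <- select_atoms(toy$topology, "protein")
  l <- select_atoms(toy$topology, "ligand")
  params <- solvation_params(grid_spacing = 0.8, grid_padding = 6)
  bd <- binding_breakdown(toy, p, l, params, window = NULL)
  oracle <- brute_force_nonbonded(frame_coords(toy, 1), toy$topology$atoms,
                                  as.integer(p), as.integer(l))
  expect_equal(bd$dE_vdw, oracle[["E_vdw"]], tolerance = 1e-10)
  expect_equal(bd$dE_elec, oracle[["E_elec"]], tolerance = 1e-10)
  expect_equal(bd$dE_bonded, 0)
  # composition identity holds on the emitted record
  expect_equal(bd$dG_pbsa,
               bd$dE_vdw + bd$dE_elec + bd$dG_polar + bd$dG_nonpolar,
               tolerance = 1e-12)
  # the net nonpolar constant is -b
  sa <- function(sel) sasa(frame_coords(toy, 1), toy$topology, sel, params)$total
  expect_equal(bd$dG_nonpolar,
               params$gamma * (sa(c(p, l)) - sa(p) - sa(l)) - params$b_const,
               tolerance = 1e-9)
})

test_that("a far-separated ligand has vanishing interaction terms", {
  spec <- toy_complex_spec(coords = rbind(c(0, 0, 0), c(4, 0, 0), c(2, 500, 0)))
  toy <- gen_toy_complex(spec)
  p <- select_atoms(toy$topology, "protein")
  l <- select_atoms(toy$topology, "ligand")
  e <- pair_nonbonded(frame_coords(toy, 1), toy$topology, p, l)
  expect_lt(abs(e[["E_vdw"]]), 1e-4)
  expect_lt(abs(e[["E_elec"]]), 1e-4)
  # polar binding term at a (computationally tractable) large separation
  spec40 <- toy_complex_spec(coords = rbind(c(0, 0, 0), c(4, 0, 0), c(2, 40, 0)))
  toy40 <- gen_toy_complex(spec40)
  params <- solvation_params(grid_spacing = 0.7, grid_padding = 5)
  bd <- binding_breakdown(toy40, p, l, params, window = NULL)
  expect_lt(abs(bd$dG_polar), 0.5)
})

test_that("window averaging is the mean of per-snapshot terms", {
  toy <- gen_toy_complex(toy_complex_spec(n_frames = 3, jitter_sd = 0.05, seed = 2))
  p <- select_atoms(toy$topology, "protein")
  l <- select_atoms(toy$topology, "ligand")
  params <- solvation_params(grid_spacing = 1.0, grid_padding = 5)
  all3 <- binding_breakdown(toy, p, l, params, window = NULL)
  singles <- lapply(1:3, function(f) {
    one <- new_trajectory(toy$topology, toy$coords[f, , , drop = FALSE])
    binding_breakdown(one, p, l, params, window = NULL)
  })
  for (term in c("dE_vdw", "dE_elec", "dG_polar", "dG_nonpolar")) {
    expect_equal(all3[[term]], mean(vapply(singles, `[[`, numeric(1), term)),
                 tolerance = 1e-12)
  }
  expect_error(binding_breakdown(toy, p, l, params, window = integer(0)),
               "empty")
})

test_that("per-residue vdW and electrostatics partition the totals exactly", {
  spec <- toy_complex_spec(
    coords = rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0), c(2, 4.5, 1)),
    n_protein_beads = 2, charges = c(1, -1, 1, -0.5),
    sigmas = rep(3.4, 4), epsilons = rep(0.1, 4), masses = rep(12, 4),
    pb_radii = rep(1.7, 4)
  )
  toy <- gen_toy_complex(spec)
  p <- select_atoms(toy$topology, "protein")
  l <- select_atoms(toy$topology, "ligand")
  params <- solvation_params(grid_spacing = 0.8, grid_padding = 5)
  bd <- binding_breakdown(toy, p, l, params, window = NULL, per_residue = TRUE)
  pr <- bd$per_residue
  expect_equal(nrow(pr), 2)
  expect_equal(sum(pr$vdw) + sum(pr$elec), bd$dE_vdw + bd$dE_elec,
               tolerance = 1e-9)
  # sign check mirrors the decomposition convention: same-sign neighbors give
  # unfavorable (positive) terms, opposite-sign favorable (negative)
  expect_gt(pr$elec[1], 0) # +1 bead vs net-positive ligand charges
  expect_lt(pr$elec[2], 0) # -1 bead
  # protein polar shares equal an independent recomputation from the solves
  fr <- frame_coords(toy, 1)
  both <- sort(c(as.integer(p), as.integer(l)))
  phi_c <- attr(pb_polar_solvation(fr, toy$topology, both, params), "per_atom")
  phi_p <- attr(pb_polar_solvation(fr, toy$topology, as.integer(p), params), "per_atom")
  pos <- match(as.integer(p), both)
  expect_equal(sum(pr$polar), sum(phi_c[pos]) - sum(phi_p), tolerance = 1e-9)
})

test_that("a residue with zero charges contributes nothing electrostatic", {
  spec <- toy_complex_spec(charges = c(0, -1, 1))
  toy <- gen_toy_complex(spec)
  pr <- per_residue_decomposition(toy, select_atoms(toy$topology, "protein"),
                                  select_atoms(toy$topology, "ligand"),
                                  solvation_params(grid_spacing = 1.0,
                                                   grid_padding = 5),
                                  window = NULL)
  expect_equal(pr$elec[1], 0, tolerance = 1e-12)
})

test_that("nonbonded terms are invariant under a global rigid motion", {
  toy <- gen_toy_complex(toy_complex_spec())
  p <- select_atoms(toy$topology, "protein")
  l <- select_atoms(toy$topology, "ligand")
  fr <- frame_coords(toy, 1)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  fr2 <- fr %*% t(R) + matrix(c(11, -4, 6), 3, 3, byrow = TRUE)
  e1 <- pair_nonbonded(fr, toy$topology, p, l)
  e2 <- pair_nonbonded(fr2, toy$topology, p, l)
  expect_equal(e1, e2, tolerance = 1e-8)
  # SASA under pure translation is exact (the point set translates rigidly)
  s1 <- sasa(fr, toy$topology, 1:3)
  s2 <- sasa(fr + matrix(c(11, -4, 6), 3, 3, byrow = TRUE), toy$topology, 1:3)
  expect_equal(s1$total, s2$total, tolerance = 1e-10)
})

test_that("assemble_total validates its inputs", {
  bd <- energy_breakdown(-10, -20, 15, -2)
  expect_error(assemble_total(bd, structure(list(minus_T_dS = NULL),
                                            class = "entropy_result")),
               "lacks minus_T_dS")
  ent <- structure(list(minus_T_dS = 3), class = "entropy_result")
  out <- assemble_total(bd, ent)
  expect_equal(out$dG_total, -17 + 3)
  zero <- assemble_total(bd, structure(list(minus_T_dS = 0),
                                       class = "entropy_result"))
  expect_equal(zero$dG_total, zero$dG_pbsa)
})
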