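# Synthetic ensembles with known ground truth. Every generator is a pure
# function of (spec, seed): the caller's RNG state is saved and restored.

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

bead_topology <- function(k, masses = NULL, role = "protein", charges = NULL) {
  if (is.null(masses)) masses <- rep(12.011, k)
  if (is.null(charges)) charges <- rep(0, k)
  if (role == "protein") {
    atoms <- data.frame(
      serial = seq_len(k), name = "CA", element = "C", resname = "ALA",
      resid = seq_len(k), chain = "A",
      mass = masses, charge = charges, stringsAsFactors = FALSE
    )
  } else {
    atoms <- data.frame(
      serial = seq_len(k), name = paste0("C", seq_len(k)), element = "C",
      resname = "LIG", resid = 1L, chain = "B",
      mass = masses, charge = charges, stringsAsFactors = FALSE
    )
  }
  new_topology(atoms)
}

#' Generate a multivariate-Gaussian coordinate ensemble
#'
#' Frames are i.i.d. draws from N(mean, covariance) over the 3K stacked
#' Cartesian coordinates of K bead atoms. The generating law's covariance is
#' the ground truth against which covariance models and entropy estimators
#' are tested.
#'
#' @param mean 3K vector (A), coordinates stacked (x1,y1,z1,x2,...)
#' @param covariance 3K x 3K symmetric positive-semidefinite matrix (A^2)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param masses optional K atomic masses (amu); default 12.011 each
#' @param topology optional `topology` for the K atoms (overrides the
#'   default one-bead protein residues; must have exactly K atoms)
#' @return `trajectory` of K one-bead protein residues
#' @export
#' @examples
#' tr <- gen_gaussian_ensemble(rep(0, 6), diag(0.04, 6), n_frames = 100, seed = 1)
gen_gaussian_ensemble <- function(mean, covariance, n_frames, seed,
                                  masses = NULL, topology = NULL) {
  d <- length(mean)
  stopifnot(d %% 3 == 0, n_frames >= 1)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(dim(covariance), c(d, d)))) {
    validation_error("covariance must be ", d, " x ", d)
  }
  if (max(abs(covariance - t(covariance))) > 1e-12) {
    validation_error("covariance not symmetric within 1e-12")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    validation_error("covariance not positive semidefinite (eigenvalue ", min(ev), ")")
  }
  draws <- with_seed(seed, MASS::mvrnorm(n_frames, mu = mean, Sigma = covariance))
  if (n_frames == 1) draws <- matrix(draws, nrow = 1)
  k <- d / 3
  coords <- array(NA_real_, dim = c(n_frames, k, 3))
  for (a in seq_len(k)) coords[, a, ] <- draws[, (3 * a - 2):(3 * a), drop = FALSE]
  if (is.null(topology)) topology <- bead_topology(k, masses = masses)
  if (n_atoms(topology) != k) validation_error("topology must have ", k, " atoms")
  new_trajectory(topology, coords)
}

random_rotation_matrix <- function(max_rot_deg) {
  if (max_rot_deg >= 180) {
    # uniform over SO(3) by quaternion sampling
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), nrow = 3, byrow = TRUE)
  } else {
    # random axis, angle uniform in [0, max_rot]
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, max_rot_deg) * pi / 180
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                nrow = 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
}

#' Contaminate an ensemble with rigid-body motion
#'
#' Each frame is composed with an independent random proper rotation (about
#' the frame centroid, angle at most `max_rot` about a random axis; uniform
#' over the rotation group when `max_rot = 180`) and a random translation
#' with components uniform in +/- `max_trans`. Internal geometry of every
#' frame is untouched, so a least-squares fit must recover the original
#' fluctuations exactly.
#'
#' @param traj input trajectory
#' @param max_rot maximum rotation angle, degrees
#' @param max_trans maximum translation component, A
#' @param seed RNG seed
#' @return trajectory with the same topology
#' @export
gen_rigid_contaminated <- function(traj, max_rot, max_trans, seed) {
  stopifnot(inherits(traj, "trajectory"), n_frames(traj) >= 1)
  coords <- traj$coords
  with_seed(seed, {
    for (f in seq_len(n_frames(traj))) {
      xyz <- frame_coords(traj, f)
      cen <- colMeans(xyz)
      R <- if (max_rot > 0) random_rotation_matrix(max_rot) else diag(3)
      tr <- if (max_trans > 0) stats::runif(3, -max_trans, max_trans) else c(0, 0, 0)
      coords[f, , ] <- sweep(xyz, 2, cen) %*% t(R) +
        matrix(cen + tr, nrow(xyz), 3, byrow = TRUE)
    }
  })
  new_trajectory(traj$topology, coords, box = traj$box, times = traj$times)
}

#' Generate an ideal-gas particle box
#'
#' Uniform i.i.d. particle positions in an orthorhombic box each frame, plus
#' one fixed probe particle at the box center (an ion bead) to serve as the
#' RDF center. The exact number density `n_particles / prod(box)` is the
#' ground truth for g(r) = 1.
#'
#' @param n_particles number of gas particles (excluding the probe)
#' @param box length-3 box lengths, A
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return `trajectory`; atom 1 is the central probe (role `ion`), the rest
#'   are gas particles
#' @export
gen_ideal_gas <- function(n_particles, box, n_frames, seed) {
  stopifnot(n_particles >= 1, length(box) == 3, all(box > 0), n_frames >= 1)
  atoms <- data.frame(
    serial = seq_len(n_particles + 1),
    name = c("ZN", paste0("G", seq_len(n_particles))),
    element = c("ZN", rep("C", n_particles)),
    resname = c("ZN", rep("GAS", n_particles)),
    resid = c(1L, rep(2L, n_particles)),
    chain = "X",
    role = c("ion", rep("ligand", n_particles)),
    stringsAsFactors = FALSE
  )
  topo <- new_topology(atoms)
  coords <- array(NA_real_, dim = c(n_frames, n_particles + 1, 3))
  center <- box / 2
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      coords[f, 1, ] <- center
      coords[f, -1, ] <- cbind(
        stats::runif(n_particles, 0, box[1]),
        stats::runif(n_particles, 0, box[2]),
        stats::runif(n_particles, 0, box[3])
      )
    }
  })
  new_trajectory(topo, coords, box = box)
}

#' Specification for a toy bead protein-ligand complex
#'
#' The default is a three-bead complex: two one-bead protein residues and a
#' one-bead ligand with charges (+1, -1, +1) e and mild Lennard-Jones
#' parameters, sized so that all energy terms are non-trivial but exactly
#' checkable by hand.
#'
#' @param coords n x 3 bead coordinates (A), protein beads first
#' @param n_protein_beads number of protein beads (leading rows of `coords`)
#' @param charges per-bead charges, e
#' @param sigmas per-bead LJ sigma, A
#' @param epsilons per-bead LJ epsilon, kcal/mol
#' @param masses per-bead masses, amu
#' @param pb_radii per-bead PB radii, A
#' @param n_frames number of frames (frames beyond the first are jittered)
#' @param jitter_sd Gaussian jitter applied per coordinate for multi-frame
#'   ensembles, A
#' @param seed RNG seed
#' @return a `toy_complex_spec` list
#' @export
toy_complex_spec <- function(coords = rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0)),
                             n_protein_beads = 2,
                             charges = c(1, -1, 1),
                             sigmas = rep(3.4, nrow(coords)),
                             epsilons = rep(0.1, nrow(coords)),
                             masses = rep(12.011, nrow(coords)),
                             pb_radii = rep(1.7, nrow(coords)),
                             n_frames = 1, jitter_sd = 0.05, seed = 1) {
  n <- nrow(coords)
  stopifnot(n_protein_beads >= 1, n_protein_beads < n)
  stopifnot(length(charges) == n, length(sigmas) == n, length(epsilons) == n,
            length(masses) == n, length(pb_radii) == n)
  structure(
    list(coords = coords, n_protein_beads = n_protein_beads, charges = charges,
         sigmas = sigmas, epsilons = epsilons, masses = masses,
         pb_radii = pb_radii, n_frames = n_frames, jitter_sd = jitter_sd,
         seed = seed),
    class = "toy_complex_spec"
  )
}

#' Generate a toy bead protein-ligand complex ensemble
#'
#' Protein beads become one-bead residues; ligand beads form a single
#' ligand residue. Charges, LJ parameters, masses and PB radii from the spec
#' are embedded in the topology, so the ensemble is directly consumable by
#' the interaction-energy module.
#'
#' @param spec a [toy_complex_spec()]
#' @return `trajectory`
#' @export
gen_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  coords <- as.matrix(spec$coords)
  n <- nrow(coords)
  dmin <- min(stats::dist(coords))
  if (dmin < 0.5) {
    validation_error("overlapping beads: minimum pair distance ", round(dmin, 3), " A < 0.5 A")
  }
  np <- spec$n_protein_beads
  nl <- n - np
  atoms <- data.frame(
    serial = seq_len(n),
    name = c(rep("CA", np), paste0("C", seq_len(nl))),
    element = "C",
    resname = c(rep("ALA", np), rep("LIG", nl)),
    resid = c(seq_len(np), rep(np + 1L, nl)),
    chain = c(rep("A", np), rep("B", nl)),
    mass = spec$masses, charge = spec$charges, sigma = spec$sigmas,
    epsilon = spec$epsilons, pb_radius = spec$pb_radii,
    stringsAsFactors = FALSE
  )
  topo <- new_topology(atoms)
  arr <- array(NA_real_, dim = c(spec$n_frames, n, 3))
  arr[1, , ] <- coords
  if (spec$n_frames > 1) {
    with_seed(spec$seed, {
      for (f in 2:spec$n_frames) {
        arr[f, , ] <- coords + matrix(stats::rnorm(3 * n, sd = spec$jitter_sd), n, 3)
      }
    })
  }
  new_trajectory(topo, arr)
}
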