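# MM/PBSA-style interaction energies: pairwise nonbonded terms, solvent
# accessible surface area (Shrake-Rupley), finite-difference Poisson polar
# solvation, binding free energy assembly and per-residue decomposition.

#' Continuum-solvation parameters
#'
#' @param eps_in solute interior dielectric (default 1)
#' @param eps_out solvent dielectric (default 80, water)
#' @param gamma surface-tension coefficient of the nonpolar term,
#'   kcal/(mol A^2) (default 0.00542)
#' @param b_const additive constant of the nonpolar term, kcal/mol
#'   (default 0.92)
#' @param probe_radius solvent probe radius, A (default 1.4)
#' @param grid_spacing Poisson grid spacing, A
#' @param grid_padding clearance between solute extent and grid boundary, A
#' @param sor_tolerance SOR relative-residual stopping criterion
#' @param max_iter SOR iteration cap
#' @param kappa inverse Debye screening length, 1/A (default 0, salt-free)
#' @param n_sasa_points sphere points per atom for SASA (default 960)
#' @return `solvation_params` list
#' @export
solvation_params <- function(eps_in = 1, eps_out = 80, gamma = 0.00542,
                             b_const = 0.92, probe_radius = 1.4,
                             grid_spacing = 0.5, grid_padding = 8,
                             sor_tolerance = 1e-7, max_iter = 20000,
                             kappa = 0, n_sasa_points = 960) {
  if (!(eps_out >= eps_in && eps_in >= 1)) {
    validation_error("dielectrics must satisfy eps_out >= eps_in >= 1")
  }
  stopifnot(probe_radius >= 0, grid_spacing > 0, grid_padding > 0,
            sor_tolerance > 0, n_sasa_points >= 12)
  structure(
    list(eps_in = eps_in, eps_out = eps_out, gamma = gamma, b_const = b_const,
         probe_radius = probe_radius, grid_spacing = grid_spacing,
         grid_padding = grid_padding, sor_tolerance = sor_tolerance,
         max_iter = max_iter, kappa = kappa, n_sasa_points = n_sasa_points),
    class = "solvation_params"
  )
}

#' Pairwise nonbonded interaction energy between two groups
#'
#' E_elec = sum k q_i q_j / r_ij over all cross pairs; E_vdw is the 12-6
#' Lennard-Jones sum with Lorentz-Berthelot combining (arithmetic-mean sigma,
#' geometric-mean epsilon). No cutoff is applied: on desk-scale systems the
#' full double sum is exact.
#'
#' @param frame n_atoms x 3 coordinates (A)
#' @param topo `topology` carrying charges and LJ parameters
#' @param group_a,group_b disjoint `selection`s
#' @param coulomb_k Coulomb constant, kcal A/(mol e^2)
#' @return named numeric: `E_vdw`, `E_elec` (kcal/mol)
#' @export
pair_nonbonded <- function(frame, topo, group_a, group_b,
                           coulomb_k = COULOMB_K) {
  a <- as.integer(group_a)
  b <- as.integer(group_b)
  if (length(intersect(a, b)) > 0) validation_error("groups must be disjoint")
  atoms <- topo$atoms
  xa <- frame[a, , drop = FALSE]
  xb <- frame[b, , drop = FALSE]
  # all-pairs distance matrix |a| x |b|
  r2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  r <- sqrt(pmax(r2, 0))
  if (any(r < 1e-6)) {
    w <- which(r < 1e-6, arr.ind = TRUE)[1, ]
    validation_error(
      "overlapping atoms: serial ", atoms$serial[a[w[1]]], " and serial ",
      atoms$serial[b[w[2]]], " at distance < 1e-6 A"
    )
  }
  qq <- outer(atoms$charge[a], atoms$charge[b])
  e_elec <- coulomb_k * sum(qq / r)
  sig <- outer(atoms$sigma[a], atoms$sigma[b], `+`) / 2
  eps <- sqrt(outer(atoms$epsilon[a], atoms$epsilon[b]))
  sr6 <- (sig / r)^6
  e_vdw <- sum(4 * eps * (sr6^2 - sr6))
  c(E_vdw = e_vdw, E_elec = e_elec)
}

# deterministic quasi-uniform unit sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each selected atom is expanded by the probe radius and covered with a
#' deterministic quasi-uniform point set; the exposed fraction (points not
#' buried inside any neighboring expanded sphere) times the expanded-sphere
#' area is the atom's SASA.
#'
#' @param frame n_atoms x 3 coordinates (A)
#' @param topo `topology` carrying PB radii
#' @param sel `selection` defining the solute whose surface is traced
#' @param params [solvation_params()]
#' @return list with `total` (A^2) and `per_atom` (named by selection order)
#' @export
sasa <- function(frame, topo, sel = seq_len(nrow(frame)),
                 params = solvation_params()) {
  sel <- as.integer(sel)
  radii <- topo$atoms$pb_radius[sel] + params$probe_radius
  if (any(topo$atoms$pb_radius[sel] <= 0)) {
    bad <- sel[which(topo$atoms$pb_radius[sel] <= 0)[1]]
    validation_error("zero PB radius for atom serial ", topo$atoms$serial[bad])
  }
  xyz <- frame[sel, , drop = FALSE]
  k <- length(sel)
  pts <- sphere_points(params$n_sasa_points)
  per_atom <- numeric(k)
  for (i in seq_len(k)) {
    surf <- sweep(pts * radii[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(surf))
    for (j in seq_len(k)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= radii[i] + radii[j]) next
      d2 <- rowSums(sweep(surf, 2, xyz[j, ])^2)
      exposed <- exposed & (d2 >= radii[j]^2)
      if (!any(exposed)) break
    }
    per_atom[i] <- mean(exposed) * 4 * pi * radii[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation free energy from SASA
#'
#' gamma * SASA + b. Note the convention: the additive constant applies per
#' species, so in a binding difference (complex minus parts) it contributes
#' -b net.
#'
#' @param sasa_total total SASA, A^2
#' @param params [solvation_params()]
#' @return kcal/mol
#' @export
nonpolar_solvation <- function(sasa_total, params = solvation_params()) {
  stopifnot(sasa_total >= 0)
  params$gamma * sasa_total + params$b_const
}

pb_solvation_detail <- function(frame, topo, sel, params) {
  sel <- as.integer(sel)
  xyz <- frame[sel, , drop = FALSE]
  qs <- topo$atoms$charge[sel]
  radii <- topo$atoms$pb_radius[sel]
  if (all(qs == 0)) {
    return(list(dG = 0, per_atom = numeric(length(sel)), iterations = 0L))
  }
  solv <- fd_poisson_solve_cpp(
    xyz, qs, radii, params$eps_in, params$eps_out,
    params$grid_spacing, params$grid_padding, COULOMB_K, params$kappa,
    params$sor_tolerance, params$max_iter
  )
  ref <- fd_poisson_solve_cpp(
    xyz, qs, radii, params$eps_in, params$eps_in,
    params$grid_spacing, params$grid_padding, COULOMB_K, 0,
    params$sor_tolerance, params$max_iter
  )
  per_atom <- 0.5 * qs * (solv$phi_at_atoms - ref$phi_at_atoms)
  list(dG = sum(per_atom), per_atom = per_atom,
       iterations = c(solv$iterations, ref$iterations))
}

#' Polar solvation free energy by finite-difference Poisson solve
#'
#' Solves the Poisson equation twice on the identical grid -- once with the
#' exterior dielectric `eps_out`, once homogeneously at `eps_in` -- and
#' reports dG_polar = 1/2 sum_i q_i (phi_solvated - phi_reference) at the
#' atom sites. The grid self-energy cancels exactly between the two solves.
#'
#' @inheritParams sasa
#' @return kcal/mol (scalar), with the per-atom contributions attached as
#'   attribute `per_atom`
#' @export
pb_polar_solvation <- function(frame, topo, sel = seq_len(nrow(frame)),
                               params = solvation_params()) {
  det <- pb_solvation_detail(frame, topo, sel, params)
  structure(det$dG, per_atom = det$per_atom)
}

#' Construct an MM/PBSA energy breakdown record
#'
#' The composition identities dG_pbsa = dE_vdw + dE_elec + dG_polar +
#' dG_nonpolar and dG_total = dG_pbsa + minus_TdS are machine-checked on
#' every record. When assembling from table values already rounded for
#' printing, pass a matching `tol`.
#'
#' @param dE_vdw,dE_elec,dG_polar,dG_nonpolar component energies, kcal/mol
#' @param dG_pbsa optional explicit sum (defaults to the component sum)
#' @param minus_TdS optional entropic term -T dS, kcal/mol
#' @param dG_total optional explicit total (defaults to dG_pbsa + minus_TdS)
#' @param n_snapshots number of snapshots averaged
#' @param per_residue optional per-residue decomposition data.frame
#' @param tol tolerance for the composition identities (default 1e-9)
#' @return `energy_breakdown` list; `dE_bonded` is identically 0 under the
#'   single-trajectory scheme
#' @export
energy_breakdown <- function(dE_vdw, dE_elec, dG_polar, dG_nonpolar,
                             dG_pbsa = NULL, minus_TdS = NULL, dG_total = NULL,
                             n_snapshots = 1L, per_residue = NULL, tol = 1e-9) {
  comp_sum <- dE_vdw + dE_elec + dG_polar + dG_nonpolar
  if (is.null(dG_pbsa)) dG_pbsa <- comp_sum
  if (abs(dG_pbsa - comp_sum) > tol) {
    validation_error(
      "dG_pbsa (", dG_pbsa, ") does not match component sum (", comp_sum,
      ") within ", tol
    )
  }
  if (!is.null(minus_TdS)) {
    if (is.null(dG_total)) dG_total <- dG_pbsa + minus_TdS
    if (abs(dG_total - (dG_pbsa + minus_TdS)) > tol) {
      validation_error("dG_total does not equal dG_pbsa + minus_TdS within ", tol)
    }
  }
  structure(
    list(dE_bonded = 0, dE_vdw = dE_vdw, dE_elec = dE_elec,
         dG_polar = dG_polar, dG_nonpolar = dG_nonpolar, dG_pbsa = dG_pbsa,
         minus_TdS = minus_TdS, dG_total = dG_total,
         per_residue = per_residue, n_snapshots = as.integer(n_snapshots)),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "energy breakdown (%d snapshots, kcal/mol):\n  dE_vdw %8.2f  dE_elec %8.2f\n  dG_polar %7.2f  dG_nonpolar %6.2f\n  dG_pbsa %8.2f",
    x$n_snapshots, x$dE_vdw, x$dE_elec, x$dG_polar, x$dG_nonpolar, x$dG_pbsa
  ))
  if (!is.null(x$minus_TdS)) {
    cat(sprintf("  -TdS %6.2f  dG_total %8.2f", x$minus_TdS, x$dG_total))
  }
  cat("\n")
  invisible(x)
}

#' Single-trajectory MM/PBSA binding energy breakdown
#'
#' For each window snapshot the complex, protein and ligand geometries are
#' all extracted from the same frame (single-trajectory scheme, so the
#' bonded term cancels identically): dE_vdw/dE_elec are the protein-ligand
#' cross terms, dG_polar = PB(complex) - PB(protein) - PB(ligand), and
#' dG_nonpolar is the SASA term of the complex minus the parts (net -b).
#' Terms are averaged over the window.
#'
#' @param traj trajectory of the complex
#' @param protein_sel,ligand_sel disjoint non-empty `selection`s
#' @param params [solvation_params()]
#' @param window frame window (see [window_frames()]); default the final
#'   10 percent of frames, the snapshot-averaging convention
#' @param per_residue also compute the per-residue decomposition
#' @return `energy_breakdown`
#' @export
binding_breakdown <- function(traj, protein_sel, ligand_sel,
                              params = solvation_params(),
                              window = c(0.9, 1), per_residue = FALSE) {
  p <- as.integer(protein_sel)
  l <- as.integer(ligand_sel)
  if (length(p) == 0 || length(l) == 0) validation_error("empty selection")
  if (length(intersect(p, l)) > 0) validation_error("selections must be disjoint")
  frames <- window_frames(traj, window)
  if (length(frames) == 0) validation_error("empty snapshot window")
  topo <- traj$topology
  both <- sort(c(p, l))

  nb <- matrix(0, length(frames), 2)
  polar <- numeric(length(frames))
  nonpolar <- numeric(length(frames))
  res_acc <- NULL
  for (w in seq_along(frames)) {
    fr <- frame_coords(traj, frames[w])
    nb[w, ] <- pair_nonbonded(fr, topo, p, l)
    pb_c <- pb_solvation_detail(fr, topo, both, params)
    pb_p <- pb_solvation_detail(fr, topo, p, params)
    pb_l <- pb_solvation_detail(fr, topo, l, params)
    polar[w] <- pb_c$dG - pb_p$dG - pb_l$dG
    sa_c <- sasa(fr, topo, both, params)
    sa_p <- sasa(fr, topo, p, params)
    sa_l <- sasa(fr, topo, l, params)
    nonpolar[w] <- nonpolar_solvation(sa_c$total, params) -
      nonpolar_solvation(sa_p$total, params) -
      nonpolar_solvation(sa_l$total, params)
    if (per_residue) {
      res_w <- residue_terms(fr, topo, p, l, both, pb_c, pb_p, pb_l,
                             sa_c, sa_p, params)
      res_acc <- if (is.null(res_acc)) res_w else {
        cbind(res_acc[, 1:3],
              res_acc[, -(1:3)] + res_w[, -(1:3)])
      }
    }
  }
  per_res <- NULL
  if (per_residue) {
    per_res <- res_acc
    per_res[, -(1:3)] <- per_res[, -(1:3)] / length(frames)
  }
  energy_breakdown(
    dE_vdw = mean(nb[, 1]), dE_elec = mean(nb[, 2]),
    dG_polar = mean(polar), dG_nonpolar = mean(nonpolar),
    n_snapshots = length(frames), per_residue = per_res
  )
}

# per-residue terms for one frame; pb_*/sa_* are precomputed details
residue_terms <- function(fr, topo, p, l, both, pb_c, pb_p, pb_l, sa_c, sa_p,
                          params) {
  atoms <- topo$atoms
  key <- paste(atoms$chain[p], atoms$resid[p], sep = "|")
  res_keys <- unique(key)
  out <- data.frame(
    chain = sub("\\|.*", "", res_keys),
    resid = as.integer(sub(".*\\|", "", res_keys)),
    resname = atoms$resname[p][match(res_keys, key)],
    vdw = 0, elec = 0, polar = 0, nonpolar = 0,
    stringsAsFactors = FALSE
  )
  # complex PB per-atom contributions indexed by position in `both`
  pos_in_both <- match(p, both)
  pos_in_prot <- seq_along(p)
  for (ri in seq_along(res_keys)) {
    sub_p <- p[key == res_keys[ri]]
    e <- pair_nonbonded(fr, topo, sub_p, l)
    out$vdw[ri] <- e[["E_vdw"]]
    out$elec[ri] <- e[["E_elec"]]
    in_res <- key == res_keys[ri]
    out$polar[ri] <- sum(pb_c$per_atom[pos_in_both[in_res]]) -
      sum(pb_p$per_atom[pos_in_prot[in_res]])
    out$nonpolar[ri] <- params$gamma *
      (sum(sa_c$per_atom[pos_in_both[in_res]]) -
       sum(sa_p$per_atom[pos_in_prot[in_res]]))
  }
  out
}

#' Per-residue decomposition of the binding energy
#'
#' Restricted pairwise sums (vdW, electrostatic) of each protein residue
#' against the ligand, plus that residue's share of the polar
#' (1/2 q dPhi from the complex-vs-parts Poisson solves) and nonpolar
#' (gamma dSASA) terms, averaged over the snapshot window. The vdW and
#' electrostatic columns sum exactly to the totals of the breakdown.
#'
#' @inheritParams binding_breakdown
#' @return data.frame: chain, resid, resname, vdw, elec, polar, nonpolar
#'   (kcal/mol)
#' @export
per_residue_decomposition <- function(traj, protein_sel, ligand_sel,
                                      params = solvation_params(),
                                      window = c(0.9, 1)) {
  binding_breakdown(traj, protein_sel, ligand_sel, params, window,
                    per_residue = TRUE)$per_residue
}

#' Assemble the total binding free energy with the entropic term
#'
#' dG_total = dG_pbsa + (-T dS): copies the entropic term of an
#' [entropy_change()] result into the breakdown.
#'
#' @param breakdown `energy_breakdown` with `dG_pbsa` set
#' @param entropy `entropy_result` with `minus_T_dS` set
#' @param tol identity-check tolerance passed through (use the printing
#'   precision when assembling from rounded table values)
#' @return updated `energy_breakdown` with `minus_TdS` and `dG_total`
#' @export
assemble_total <- function(breakdown, entropy, tol = 1e-9) {
  stopifnot(inherits(breakdown, "energy_breakdown"))
  if (is.null(breakdown$dG_pbsa)) validation_error("breakdown lacks dG_pbsa")
  mtds <- if (inherits(entropy, "entropy_result")) entropy$minus_T_dS else entropy
  if (is.null(mtds)) validation_error("entropy result lacks minus_T_dS")
  energy_breakdown(
    dE_vdw = breakdown$dE_vdw, dE_elec = breakdown$dE_elec,
    dG_polar = breakdown$dG_polar, dG_nonpolar = breakdown$dG_nonpolar,
    dG_pbsa = breakdown$dG_pbsa, minus_TdS = mtds,
    n_snapshots = breakdown$n_snapshots, per_residue = breakdown$per_residue,
    tol = tol
  )
}
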