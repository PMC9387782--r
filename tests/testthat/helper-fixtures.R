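# Shared fixtures, all built in code at test time.

pdb_line <- function(rec, serial, name, resname, chain, resid, x, y, z, element) {
  name4 <- if (nchar(element) == 2 || nchar(name) >= 4) {
    formatC(name, width = -4)
  } else {
    paste0(" ", formatC(name, width = -3))
  }
  sprintf("%-6s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, substr(name4, 1, 4), resname, chain, resid,
          x, y, z, 1, 0, element)
}

# 3-atom system: one GLY Calpha, one Zn ion, one ligand carbon
write_three_atom_pdb <- function(path) {
  writeLines(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line("HETATM", 2, "ZN", "ZN", "A", 2, 3, 0, 0, "ZN"),
    pdb_line("HETATM", 3, "C1", "LIG", "B", 3, 0, 3, 0, "C"),
    "END"
  ), path)
  path
}

# small 3-residue peptide-like topology (CA + CB per residue)
toy_protein_topology <- function() {
  new_topology(data.frame(
    serial = 1:6,
    name = rep(c("CA", "CB"), 3),
    element = "C",
    resname = rep(c("ALA", "GLY", "SER"), each = 2),
    resid = rep(1:3, each = 2),
    chain = "A",
    stringsAsFactors = FALSE
  ))
}

# independently coded double-loop nonbonded oracle (kept deliberately naive)
brute_force_nonbonded <- function(frame, atoms, ia, ib, k = 332.0636) {
  e_el <- 0
  e_vdw <- 0
  for (i in ia) {
    for (j in ib) {
      r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      e_el <- e_el + k * atoms$charge[i] * atoms$charge[j] / r
      sij <- (atoms$sigma[i] + atoms$sigma[j]) / 2
      eij <- sqrt(atoms$epsilon[i] * atoms$epsilon[j])
      e_vdw <- e_vdw + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  c(E_vdw = e_vdw, E_elec = e_el)
}

# a fake covariance model with a prescribed spectrum (for entropy formulas)
model_from_spectrum <- function(lambda, mass_weighted = TRUE) {
  d <- length(lambda)
  structure(
    list(selection = seq_len(d %/% 3), mean_coords = rep(0, d),
         covariance = diag(sort(lambda, decreasing = TRUE), d),
         mass_weighted = mass_weighted, masses = rep(1, d),
         eigenvalues = sort(lambda, decreasing = TRUE),
         eigenvectors = diag(d), n_frames_used = 2L),
    class = "covariance_model"
  )
}

# independent closed-form quantum harmonic oscillator entropy per mode,
# written from the constants (kcal, amu, A, ps unit system)
qho_mode_entropy <- function(lambda_mw, temperature = 300) {
  kB <- 0.0019872041
  hbar <- 1.054571817e-34 / 1.66053906660e-35
  kT <- kB * temperature * 418.4
  alpha <- hbar / sqrt(lambda_mw * kT)
  kB * (alpha / (exp(alpha) - 1) - log(1 - exp(-alpha)))
}
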