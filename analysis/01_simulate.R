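#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study systems with known ground truth.
#
# Real HDAC2-inhibitor trajectories are 100-ns all-atom MD runs that cannot
# be regenerated here; instead every downstream stage is exercised on
# statistical stand-ins whose true covariances, densities and energies are
# known exactly. This script materializes them on disk so the later stages
# (and a skeptical reader) can inspect the raw inputs.

suppressPackageStartupMessages(library(trajthermo))
dir.create("results", showWarnings = FALSE)
dir.create("results/ensembles", showWarnings = FALSE)

seed <- 2026

# A 20-bead apo "protein" on a helix-like curve with residue-dependent
# Gaussian fluctuations, contaminated with uniform random rigid-body motion
# the fit stage must remove. With 20 beads the 6 rigid degrees of freedom
# absorbed by the fit are a small fraction of the 60 coordinates, so the
# recovered RMSF profile tracks the generating one closely.
k_apo <- 20
t_par <- seq(0, 3 * pi, length.out = k_apo)
apo_xyz <- cbind(4 * cos(t_par), 4 * sin(t_par), 1.5 * t_par)
apo_sigmas <- rep(c(0.30, 0.20, 0.12, 0.25), length.out = k_apo) # A
apo_mean <- as.numeric(t(apo_xyz))
apo_cov <- diag(rep(apo_sigmas^2, each = 3))
apo <- gen_gaussian_ensemble(apo_mean, apo_cov, n_frames = 400, seed = seed)
apo_dirty <- gen_rigid_contaminated(apo, max_rot = 180, max_trans = 5,
                                    seed = seed + 1)
write_trajectory(apo_dirty, "results/ensembles/apo_contaminated.pdb")
write_table(data.frame(resid = seq_len(k_apo), sigma_A = apo_sigmas),
            "results/ensembles/apo_true_sigmas.tsv", digits = 3)
cat("apo ensemble: 400 frames,", k_apo, "beads, rigid-contaminated ->",
    "results/ensembles/apo_contaminated.pdb\n")

# A 3-bead toy protein-ligand complex (charges +1/-1/+1 e) jittered over
# 50 frames: the energy stage's substrate.
toy <- gen_toy_complex(toy_complex_spec(n_frames = 50, jitter_sd = 0.05,
                                        seed = seed + 2))
write_trajectory(toy, "results/ensembles/toy_complex.pdb")
cat("toy complex: 50 jittered frames, 2 protein beads + 1 ligand bead ->",
    "results/ensembles/toy_complex.pdb\n")

# An ideal-gas box around a central probe: ground truth g(r) = 1 everywhere,
# so the coordination integral has a closed form.
gas <- gen_ideal_gas(1000, box = rep((1000 / 0.01)^(1 / 3), 3),
                     n_frames = 200, seed = seed + 3)
cat(sprintf("ideal gas: 1000 particles, rho = %.4f / A^3, 200 frames (kept in memory by stage 05)\n",
            1000 / prod(gas$box)))
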