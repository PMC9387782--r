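# trajthermo

Thermodynamic post-processing of molecular dynamics trajectories of
protein–ligand complexes, built around the analysis used to dissect
inhibitor binding to HDAC2 (histone deacetylase 2, a Zn²⁺-dependent
epigenetic drug target): why do chemically diverse inhibitors with similar
interaction energies show very different potencies? A large part of the
answer is the configurational entropy lost on binding, which this package
estimates and folds into the binding free energy.

## The model

For each complex, snapshots from an MD run are combined into an end-state
(MM/PBSA) estimate of the binding free energy

```
ΔG_binding = ΔE_MM + ΔG_solvation − TΔS
ΔE_MM      = ΔE_bonded + ΔE_vdW + ΔE_elec          (single-trajectory: ΔE_bonded ≡ 0)
ΔG_solv    = ΔG_polar + ΔG_nonpolar
ΔG_nonpolar = γ·SASA + b                            (γ = 0.00542 kcal/(mol·Å²), b = 0.92 kcal/mol)
```

with ΔG_polar from a finite-difference Poisson solve (ε_in = 1, ε_out = 80,
probe 1.4 Å) and the entropic term from the quasi-harmonic approximation:
rigid-body motion is removed by Kabsch superposition, the mass-weighted
covariance C of the Cα (protein) or all-atom (ligand) fluctuations is
diagonalized, and each mode of variance λ contributes a quantum
harmonic-oscillator entropy at α = ħω/k_BT, ω = √(k_BT/λ):

```
S = k_B Σ_i [ α_i/(e^{α_i} − 1) − ln(1 − e^{−α_i}) ],   −TΔS = −T (S_complex − S_apo − S_ligand)
```

The Schlitter determinant bound and a classical Gaussian estimator are also
provided. Around the zinc site, coordination is quantified by
n = ∫ 4πr²ρ g(r) dr over the first shell (cutoff 2.7 Å), plus distance
series and geometric hydrogen-bond occupancies (3.5 Å / 30°). Finally,
pIC₅₀ = −log₁₀(IC₅₀·10⁻⁹) is correlated against ΔG_PBSA and ΔG_total.

Because regenerating 100-ns all-atom trajectories is out of scope, the
package ships generators for synthetic ensembles with exact ground truth
(Gaussian fluctuation ensembles, rigid-body-contaminated copies, ideal-gas
boxes, toy bead complexes) on which every estimator is validated against
closed forms and brute-force oracles. See the vignette
(`vignettes/trajectory-thermodynamics.Rmd`) for the assumptions and
numerical choices.

## Worked example

```r
library(trajthermo)
toy <- gen_toy_complex(toy_complex_spec(n_frames = 10, seed = 1))
p <- select_atoms(toy$topology, "protein")
l <- select_atoms(toy$topology, "ligand")
bd <- binding_breakdown(toy, p, l,
                        solvation_params(grid_spacing = 0.8, grid_padding = 6),
                        window = c(0.9, 1))
bd
#> energy breakdown (1 snapshots, kcal/mol):
#>   dE_vdw    -0.16  dE_elec     2.33
#>   dG_polar   -2.51  dG_nonpolar  -1.33
#>   dG_pbsa    -1.67
```

The three beads carry charges (+1, −1, +1) e: the like-charge pair
dominates the gas-phase electrostatics (+2.33), solvation screens most of
it back (−2.51), the net nonpolar constant is −b, and the identity
ΔG_PBSA = ΔE_vdW + ΔE_elec + ΔG_polar + ΔG_nonpolar is machine-checked on
the record. On the bundled published tables,

```r
acts <- hdac2_reference_activities()
tab  <- hdac2_reference_energies("known")
correlation_report(acts, tab, use_total = FALSE)$r  # +0.197  (ΔG_PBSA alone)
correlation_report(acts, tab, use_total = TRUE)$r   # -0.712  (with −TΔS)
```

— including the entropic term is what turns an uncorrelated energy ranking
into a trend with measured potency for these structurally diverse ligands.

## The analysis workflow

`analysis/01_simulate.R` … `06_activity_correlation.R` run the pipeline as
a narrative: generate the synthetic study systems, remove rigid-body
motion and profile RMSD/RMSF, build the essential-dynamics model and the
quasi-harmonic −TΔS, assemble the MM/PBSA breakdown with per-residue
decomposition, compute RDF/coordination/H-bond geometry, and correlate
activity with energy. Each stage prints what it found and writes TSV
tables under `results/`. The same computations are callable in one step via
`run_pipeline(pipeline_config(...))`.

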