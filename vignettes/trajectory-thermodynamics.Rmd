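---
title: "Thermodynamic analysis of protein-ligand MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic analysis of protein-ligand MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajthermo)
```

## What the package computes

`trajthermo` post-processes molecular dynamics trajectories of
protein-ligand complexes into binding thermodynamics. The workflow it
implements is the one used to study why different inhibitors of the
Zn²⁺-dependent epigenetic enzyme HDAC2 achieve different potencies:

1. **Superposition** — every frame is least-squares fitted (Kabsch) to a
   reference over a selection (Cα atoms by convention), removing rigid-body
   translation and rotation; RMSD and RMSF profiles summarize what remains.
2. **Essential dynamics** — the 3K x 3K covariance of the fitted Cartesian
   fluctuations is diagonalized; the leading eigenvectors are the concerted
   motions, and projections onto the first two span a free-energy landscape
   by Boltzmann inversion, G = −k_B T ln(P/P_max).
3. **Quasi-harmonic entropy** — the mass-weighted covariance defines
   effective harmonic modes; summing per-mode quantum-oscillator entropies
   gives the configurational entropy S, and the bound-minus-unbound
   difference gives −TΔS = −T(S_complex − S_apo − S_ligand).
4. **MM/PBSA energies** — per snapshot, protein-ligand van der Waals and
   Coulomb terms, a polar solvation term from a finite-difference Poisson
   solve, and a nonpolar term γ·SASA + b; ΔG_PBSA is their window average
   and ΔG_total = ΔG_PBSA + (−TΔS).
5. **Coordination geometry** — radial distribution functions around a
   center (the catalytic zinc in the motivating study), running
   coordination numbers n = ∫ 4πr²ρ g(r) dr over the first shell, distance
   series, and geometric hydrogen-bond detection.
6. **Reporting** — table assembly with machine-checked identities and the
   correlation of pIC₅₀ with ΔG_PBSA / ΔG_total.

All quantities use Å, kcal/mol, amu, ps, elementary charges and kelvin.

## The synthetic-data generators, and what they do (not) show

Re-running 100-ns all-atom MD is out of scope, so every stage is exercised
on synthetic ensembles whose ground truth is known exactly:

* `gen_gaussian_ensemble()` draws i.i.d. frames from a prescribed
  multivariate normal — the exact situation the quasi-harmonic
  approximation assumes. Covariance recovery and entropy convergence can
  therefore be tested against closed forms.
* `gen_rigid_contaminated()` composes each frame with a uniform random
  rotation (quaternion-sampled when the cap is 180°, so no orientation
  bias) and translation; internal geometry is untouched, making fit removal
  exactly checkable.
* `gen_ideal_gas()` gives g(r) = 1 and a closed-form coordination number
  (4/3)πR³ρ.
* `gen_toy_complex()` builds bead protein-ligand complexes with explicit
  charges and Lennard-Jones parameters, small enough that brute-force
  double loops and analytic solvation results (Born ion, spherical caps)
  serve as oracles.

Passing on these fixtures demonstrates that the estimators are implemented
correctly and converge at the expected rates. It does **not** demonstrate
that real MD fluctuations are Gaussian (they are not — anharmonicity and
multi-basin kinetics bias quasi-harmonic entropies upward), nor that the
hard-sphere dielectric boundary reproduces a molecular-surface Poisson
solver on real proteins.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| temperature | 300 | K | thermostat temperature of the target simulations; −TΔS is reported at this T regardless of metadata |
| eps_in / eps_out | 1 / 80 | — | solute and water dielectrics |
| γ (`gamma`) | 0.00542 | kcal/(mol·Å²) | nonpolar surface coefficient |
| b (`b_const`) | 0.92 | kcal/mol | nonpolar additive constant, applied per species (net −b in a binding difference) |
| probe radius | 1.4 | Å | solvent probe for SASA |
| grid spacing | 0.5 | Å | Poisson grid; 0.25 Å gives Born-ion errors near 0.1% |
| first-shell cutoff | 2.7 | Å | coordination shell bound; bin width 0.02 Å aligns it with a bin edge |
| H-bond criteria | 3.5 Å / 30° | | donor-acceptor distance and H-D-A angle |
| Coulomb constant | 332.0636 | kcal·Å/(mol·e²) | standard molecular-mechanics value |
| `eig_floor` | 1e-8 | amu·Å² | drops the ≤ 6 residual rigid-body modes before entropy summation |

## Numerical choices

**Poisson solver.** The linearized Poisson equation (zero ionic strength by
default; a Debye κ is accepted) is discretized on a cubic grid centered on
the solute centroid with an odd node count, solved by red-black successive
over-relaxation with ω = 2/(1 + sin(π/n)). The dielectric on each grid
face is the harmonic (series) average over the connecting segment, using
the exact segment-sphere intersection fractions merged across atoms; this
smoothed boundary converges monotonically for the Born ion (errors 3.0%,
0.56%, 0.11% at 1.0, 0.5, 0.25 Å here), where a binary midpoint map does
not. Charges spread trilinearly; boundary conditions are analytic screened
Coulomb potentials in the exterior dielectric. The grid self-energy is
removed by a second solve on the identical grid with the exterior set to
`eps_in`, so only the reaction-field difference is reported. Because the
grid is solute-anchored, energies are exactly translation-invariant;
rotations change the grid alignment and perturb the polar term at the
discretization level — a known property of fixed-grid solvers, not a bug.

**Single-trajectory scheme.** Complex, protein and ligand geometries are
all extracted from complex-trajectory snapshots, so the bonded term of the
molecular-mechanics energy cancels identically and `dE_bonded` is fixed at
zero. This is the convention of the end-state tools this analysis mirrors.

**Entropy estimators.** `andricioaei_karplus` (default) sums quantum
harmonic-oscillator entropies over modes of the mass-weighted covariance
with α = ħω/(k_B T), ω = sqrt(k_B T/λ); `schlitter` is the determinant
upper bound (k_B/2) Σ ln(1 + k_B T e² λ/ħ²) and is asserted ≥ the quantum
value; `classical_gaussian` is (k_B/2) ln((2πe)^d det C), whose log
argument carries units — it is only meaningful inside `entropy_change()`,
which enforces dim(complex) = dim(apo) + dim(ligand) for it. Constants are
converted once into the amu-Å-ps-kcal/mol system (1 amu·Å²/ps² = 10 J/mol
exactly, so 1 kcal/mol = 418.4 internal units; ħ = 6.3508 amu·Å²/ps).

**Covariance conventions.** The biased 1/n normalizer is the default (the
entropy formulas consume the ensemble second moment); 1/(n−1) is a flag.
The complex covariance selection is protein Cα plus all ligand atoms, the
only choice under which the entropy subtraction is dimension-consistent;
ligand models use all ligand atoms. Fitting is enforced inside
`covariance_model()` against the window's first frame (the window-start
reference convention) and can be disabled for ensembles generated without
rigid contamination.

**SASA.** Shrake-Rupley with a deterministic golden-section spiral point
set (960 points by default; isolated spheres are exact, two-sphere
configurations agree with the spherical-cap closed form to well under 2%).

**Degenerate inputs.** Collinear or < 3-atom fit selections, single-frame
fluctuation requests, empty selections, overlapping atoms (r < 1e-6 Å),
all-discarded entropy spectra, and R2 ≤ R1 shells raise validation errors
rather than returning silent nonsense. Unoccupied landscape bins are +Inf;
ties in the determinant sign of the Kabsch solution resolve to the proper
branch.

## Design choices made where the design was open

* **Fit selection / RMSD atoms.** The Cα convention is the default for
  fitting and covariance; backbone (N/CA/C/O) selections are expressible
  through the selection grammar for RMSD profiles. The reference frame is
  the window's first frame.
* **Mass weighting of the fit** is off by default (matching the common
  trajectory-fitting default); the quantum entropy methods require and
  enforce mass-weighted covariances.
* **Windows.** Energies average the final 10% of frames; entropy uses the
  final 20%. Both are arguments.
* **Eq-6 constant.** The nonpolar b is applied per species and differenced,
  contributing −b net to binding.
* **Per-residue polar shares** are ½ q_i Δφ differences between the complex
  solve and the corresponding part solve, attributed to the residue owning
  atom i; vdW/electrostatic shares are restricted pair sums and partition
  the totals exactly.
* **Ionic strength** is zero in the Poisson step by default (κ
  configurable).
* **Reference tables.** The published per-ligand energy table shipped in
  `inst/extdata` is internally consistent at printed precision for 11 of 12
  ligands; one carbamide row's components do not sum to its printed
  ΔG_PBSA (off by 3.54 kcal/mol), so the identity check is relaxed for that
  single row while the total-assembly arithmetic still runs against the
  printed ΔG_PBSA.

## Problem sizes used in tests and reports

Covariance/entropy recovery uses K = 3–5 atoms at 20,000–50,000 frames
(sampling error comfortably below the 2% assertion bands); the Born ion is
solved at 1.0/0.5/0.25 Å spacings on grids up to 81³; the ideal-gas
coordination fixture uses 1,000 particles × 1,000 frames; the end-to-end
pipeline runs three toy ligands at 1,500–3,000 frames per fluctuation
ensemble. These sizes were chosen so each statistical check sits well
inside its tolerance while the whole suite remains quick to run.

## A worked example

```{r example}
toy <- gen_toy_complex(toy_complex_spec(n_frames = 10, seed = 1))
p <- select_atoms(toy$topology, "protein")
l <- select_atoms(toy$topology, "ligand")
bd <- binding_breakdown(toy, p, l,
                        solvation_params(grid_spacing = 0.8, grid_padding = 6),
                        window = c(0.9, 1))
bd
```

The composition identity ΔG_PBSA = ΔE_vdW + ΔE_elec + ΔG_polar +
ΔG_nonpolar is machine-checked on every record, as is
ΔG_total = ΔG_PBSA + (−TΔS) once an entropy result is attached with
`assemble_total()`.

## Known limitations

* The dielectric boundary is the union of atom spheres (no reentrant
  molecular surface), a simplification relative to reference Poisson
  solvers; accurate for bead systems and the Born ion, approximate for
  tightly packed solutes.
* Quasi-harmonic entropies inherit the Gaussian assumption; solvation
  entropy is not computed.
* No periodic-boundary unwrapping is performed; frames are assumed imaged
  as whole molecules, and minimum-image distances are used only in the
  coordination module when a box is present.
* Trajectory formats are multi-model PDB and XYZ only; binary formats are
  out of scope.
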