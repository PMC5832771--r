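---
title: "Mapping a peptide binding site and its rigidifying effect: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a peptide binding site and its rigidifying effect: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptisite)
```

# Scope and model

`peptisite` implements a complete desk-scale pipeline for the question:
*where does a short basic peptide bind on a receptor dimer, and what does
binding do to the receptor?* The motivating system is the inhibitory
octapeptide NOP-1 (LKRYKRRL-NH~2~, derived from the EIN2 nuclear
localization signal) acting on the GAF-domain dimer of the ethylene
receptor ETR1, but every stage is generic: any multi-model ensemble of a
receptor plus a diffusing peptide chain can be analysed.

The pipeline has five analysis stages:

1. **Binding-site mapping** — occupancy grids of the ligand centre of mass
   over time windows, and per-residue hydrogen-bond/salt-bridge
   propensities (`occupancy_grid()`, `top_sites()`,
   `hbond_saltbridge_propensity()`).
2. **Bound-state extraction** — frames in which the peptide hydrogen-bonds
   designated anchor residues, sampled on a stride
   (`extract_bound_frames()`).
3. **Pose clustering** — Ward clustering of bound poses on pairwise
   all-atom ligand RMSD (`pairwise_ligand_rmsd()`, `ward_linkage()`,
   `cut_tree()`, `merge_clusters()`).
4. **Rigidity perturbation** — body-bar constraint networks, pebble-game
   rigid-cluster decomposition, constraint dilution, and the per-residue
   stability change upon removing the ligand's constraints
   (`build_network()`, `pebble_game_rigid_clusters()`,
   `dilution_stability()`, `delta_g_profile()`).
5. **Binding-isotherm fitting** — MST temperature-jump reduction and the
   one-site depletion fit (`delta_fnorm_from_trace()`, `fit_isotherm()`).

Because no trajectories or raw thermophoresis traces are publicly
deposited for the motivating study, the package ships a first-class
synthetic-data module whose generators plant known ground truth, so every
estimator can be validated against exact bookkeeping.

# The synthetic study system

## Receptor, peptide, trajectories

`build_toy_dimer()` constructs a C2-symmetric two-chain receptor from
ideal α-helices (φ = −57°, ψ = −47°, giving a rise of ~1.5 Å, ~100° per
residue and a C~α~ radius of ~2.3 Å). Helices are built from internal
coordinates (ideal bond lengths/angles) rather than cylindrical
parameters so that covalent geometry is realistic enough for
distance-based bond perception and hydrogen placement. Chain B is chain A
rotated by exactly 180° about the z axis, so the dimer is exactly
homomeric; planted glutamates (requested by residue number) appear on
*both* chains to preserve that symmetry.

`simulate_diffusion_runs()` emulates the study's design of 15 independent
free-diffusion simulations with frames every 0.1 ns. Kinetic realism is
deliberately not attempted: the per-frame state (free, or dwelling at one
of the planted sites) follows a two-parameter Markov chain whose
stationary distribution equals the requested dwell fractions
(self-transition weight 0.5 by default; only stationary occupancies, not
dwell-time distributions, are consumed downstream). Dwell frames place
the rigid peptide template with its centre of mass at the site centre
plus isotropic Gaussian noise, orient it by a least-squares (Kabsch) fit
of designated donor atoms onto ideal hydrogen-bond positions (or by a
single-arm alignment when fewer than three donors are designated), and
then snap each designated donor and its hydrogen to an exact
donor–acceptor distance of 2.9 Å with a linear D–H···A geometry. A final
rigid translation restores the exact centre of mass, perturbing the
snapped geometry by only a few hundredths of an Å, so detection under the
default criterion is guaranteed. Free frames are placed uniformly in a
shell starting 8 Å beyond the receptor, padded by the peptide's own
radius so that *no peptide atom* violates the 8 Å minimum distance — the
condition is molecule-to-molecule, which is what makes the generator's
truth table exact for bound-frame extraction.

What the generator does **not** emulate: receptor flexibility (the
receptor is frozen except in the dedicated RMSF fixtures), solvent,
realistic binding kinetics, peptide conformational exchange, and any
force-field energetics. Passing tests therefore demonstrate correctness
of the estimators given their stated contracts, not agreement with the
original trajectories — the study's absolute occupancy and snapshot
counts depend on 30 µs of undeposited simulation and are out of reach by
construction.

## Isotherms

`generate_isotherm()` produces 2-fold dilution series (default 16 points
from 10 µM, 3 replicates) at the study's labelled-protein concentration
of 25 nM, with responses
`ΔF_norm = offset + amplitude · f_b(c; K_d, P) + ε`,
`ε ~ N(0, (noise_sd · amplitude)²)`. The default noise of 5% of the
amplitude is a typical MST replicate scatter.

# Numerical and design choices

**Occupancy grid.** Cubic bins with a 3 Å edge, spanning the bounding box
of all contributing centres of mass plus a one-bin margin; binning is
half-open. The 3 Å edge is the only length scale consistent with the
source protocol's grid description, which is dimensionally garbled in the
original text; it is exposed as a parameter.

**Hydrogen bonds and salt bridges.** The mapping criterion is geometric
(the original analysis deferred to VMD's defaults, which are unstated):
donor–acceptor ≤ 3.5 Å and D–H···A ≥ 135°, ligand strictly as donor and
receptor as acceptor; salt bridges are ligand side-chain nitrogens (Lys
NZ, Arg NE/NH1/NH2) within 4.0 Å of receptor carboxylate oxygens. A
heavy-atom fallback (distance only) handles hydrogen-free topologies but
must be requested explicitly. All cutoffs are parameters of
`hbond_criterion()`.

**Ward heights.** Merge heights are reported as
δ = √(increase in total within-cluster sum of squares), the convention in
which two singletons a, b merge at |a−b|/√2. This equals the common
Ward.D2 linkage height divided by √2; `ward_linkage()` documents the
conversion, and the implementation is cross-checked in the tests against
a naive greedy Ward that recomputes sums of squares from raw coordinates.
Ligand poses are compared **without re-superposition** in the receptor
frame: position and orientation differences between binding modes are
the clustering signal, and re-fitting would erase them. Cluster
centroids are medoids, so a centroid is always an actual conformation.

**Constraint network.** Atoms are rigid bodies with six degrees of
freedom. Bar multiplicities follow rigidity-theory conventions: single
covalent bonds 5 bars (one dihedral left free), peptide/carbonyl/
carboxylate/guanidinium bonds 6 bars (torsionally locked by resonance),
hydrogen bonds and salt bridges 5 bars, hydrophobic tethers 2 bars.
Hydrogen-bond strengths use a Mayo-style 12-10 potential
`E = V0 [5(d0/d)^12 − 6(d0/d)^10] cos²θ` with V0 = 8 kcal/mol and
d0 = 2.8 Å, the standard form in the rigidity literature; geometries with
θ < 90° are excluded. Hydrophobic tethers join side-chain C/S atoms
closer than the sum of their van der Waals radii (C 1.7 Å, S 1.8 Å) plus
0.25 Å. Ligand-interface constraints use the same geometric rules as the
intramolecular ones; the knowledge-based pair potentials used in the
original study are proprietary to that toolchain, and the geometric rules
preserve the constraint-topology class that the perturbation analysis
depends on. All of this is configurable through `network_params()`.

**Pebble game.** The (6,6) body-bar pebble game is implemented in C++
with failed-search rigid-cluster detection; mutual rigidity of bodies is
transitive, so clusters are accumulated in a union–find structure. Bars
are processed in ascending atom-serial order, making the decomposition
deterministic; the tests additionally verify invariance under insertion
order and exact agreement (cluster partition and global degrees of
freedom) with a generic rigidity-matrix rank oracle on random networks.

**Stability and ΔG~i~.** The per-residue stability `g_i` is a dilution
integral: stepping an energy cutoff σ from 0 to −8 kcal/mol in 0.1 steps,
only hydrogen bonds with `E_HB ≤ σ` are retained, and `g_i` accumulates
`0.1 · 1[residue i's C-alpha is in the giant rigid cluster at σ]`. The
per-residue perturbation is
`ΔG_i = ⟨g_i(ground)⟩ − ⟨g_i(perturbed)⟩`
over the network ensemble, the perturbed state being the ground state
with every ligand-associated constraint (and the ligand bodies) removed.
Positive values mean the ligand stabilizes the residue; the reporting
threshold defaults to 0.1 kcal/mol. This dilution-integral definition is
this package's own concrete surrogate for the ensemble-perturbation free
energy of the CNA literature, which the source study delegates to its
references without reproducing; it has the same contract (per-residue,
kcal/mol, positive = ligand-stabilized, 0.1 threshold) but is not claimed
to be numerically identical to the original software. "Giant cluster"
means largest by atom count, ties resolved toward the cluster containing
the lowest atom serial.

**Depletion fit.** At 25 nM labelled protein and dissociation constants
near 100 nM, free and total ligand differ appreciably, so the default
one-site model solves the quadratic mass balance
`f_b = [(P + c + K_d) − √((P + c + K_d)² − 4Pc)] / (2P)`;
the pure hyperbola is available via `model = "hyperbolic"` (and is used
internally as the P → 0 limit below 10⁻⁶ nM). The fit multistarts over a
decade-spaced K~d~ grid spanning the nonzero concentration range,
reports Jacobian-based standard errors, and flags "no binding" when the
amplitude is within two standard errors of zero — mirroring how flat
(denatured-control) series behave. Whether the original curves were
fitted with or without depletion is not stated in the source; both forms
are provided, depletion by default.

**PDB input/output.** The multi-model reader/writer is deliberately
self-contained: it reports per-model atom-count mismatches by model
number, refuses coordinates outside the fixed-width field, parses CONECT
records, and reads/writes per-model `REMARK 100 TIME_NS` frame times (a
plain-text sidecar of times is also accepted). Covalent bonds are the
union of CONECT records and element-radius distance perception
(r₁ + r₂ + 0.4 Å, minimum 0.4 Å) — a perception rule rather than
per-residue template dictionaries, which would add bulk without changing
any downstream result; bond *typing* (peptide, carbonyl, carboxylate,
guanidinium → 6 bars) is by atom name. Round trips are cross-checked
against an independent reader (bio3d) in the tests.

# Problem sizes

The test suite and the acceptance script run entirely from generated
data at sizes chosen to exercise the estimators' contracts: 15 runs ×
2000 frames (the study's run count at a shorter per-run length) for
planted-site recovery; networks of a few hundred atoms and 80-rung
dilution ladders for the rigidity stage; 100-seed Monte Carlo for the
K~d~ recoveries. The three recovery targets use the study's reported
dissociation constants (88 nM full-length, 104 nM for the unmutated
TM+GAF construct, 128 nM for the acidic-patch variant at half amplitude)
as planted ground truths and ask the median fitted K~d~ over 100 noisy
synthetic isotherms to land within 10%.

# Known limitations

- The rigidity ΔG~i~ is a declared surrogate (see above); absolute
  values are comparable within this package only.
- The diffusion generator's dwell poses are geometrically idealized;
  occupancy numbers are exactly as planted, not emergent.
- A perturbation signal requires the bound ligand to *bridge* receptor
  elements with enough independent constraints; a peptide attached by a
  single hydrogen bond is, correctly, a hinge and produces ΔG ≡ 0. The
  `plant_bridge_site()` helper constructs bridging configurations for
  validation.
- No periodic-boundary handling and no binary trajectory formats;
  ensembles are assumed unwrapped, as the generators produce them.
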