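---
title: "Monte Carlo induced-fit landscape screening for polyol oxidases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo induced-fit landscape screening for polyol oxidases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Alditol oxidases (AldO, EC 1.1.3.41) are FAD-dependent enzymes that oxidize
polyols such as xylitol and glycerol at the terminal C1 hydroxyl, producing
hydrogen peroxide as the only by-product. They are attractive biocatalysts
for upgrading the glycerol surplus of biodiesel production. Candidate
enzymes can be triaged computationally before any wet-lab work: a Monte
Carlo induced-fit simulation of the enzyme-substrate complex maps, for many
thousands of ligand poses, the *interaction energy* against the *catalytic
distance* - the distance between the side-chain terminal nitrogen (PDB atom
NZ) of the conserved active-site lysine and the nearest terminal hydroxyl
proton of the substrate. If the global energy minimum of that landscape
lies within hydrogen-transfer range (a permissive 4 Å cut-off), the enzyme
is predicted to be active on the substrate; if the minimum lies well beyond
the cut-off, the candidate is discarded. The same landscapes, computed for
point mutants, drive enzyme engineering: a variant whose catalytic minimum
sits at a similar or better distance *and* at a better interaction energy
than the wild type is predicted to be an improvement.

`aldoscape` implements this entire analysis at desk scale: the sampler, the
energy model, the landscape screening and mutant-comparison rules, the
downstream enzyme-characterization mathematics (Michaelis-Menten kinetics,
catalytic efficiency, kinetic isotope effects, thermal-shift melting
temperatures, flavin extinction coefficients, pH profiles), and - crucially -
seeded synthetic generators that produce receptors with *planted, known*
landscapes and assay datasets with *planted, known* parameters, so that every
stage of the pipeline is testable without any external structure or
measurement.

## The energy model

The package deliberately uses a small, fully documented nonbonded model
rather than importing a molecular-mechanics force field:

* **Lennard-Jones 12-6** per protein-ligand atom pair, with
  Lorentz-Berthelot combining: the pair well depth is
  $\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$ (kcal/mol) and the
  pair minimum-energy distance $r^{min}_{ij} = (r^{min}_i + r^{min}_j)/2$
  (Å).
* **Coulomb with a distance-dependent dielectric** $\epsilon(r) = 4r$, i.e.
  $E_c = 332.0636\, q_i q_j / (4 r^2)$ kcal/mol, a common implicit-screening
  shortcut.
* **10 Å cut-off with potential shift**: every pair term has its value at
  the cut-off subtracted, so the energy goes to zero exactly and
  continuously at 10 Å. No solvation term.

All coordinates are in Å, energies in kcal/mol, charges in elementary
units, and residue numbering is 1-based as in PDB files. The ligand is
rigid (its internal energy is constant and set to zero); the catalytic
distance is measured to the hydroxyl *proton*, so ligand templates must
carry explicit polar hydrogens, while receptor hydrogens are optional.

Two consequences of this design matter for interpretation. First, all
planted-landscape statements (well positions, depths) are *defined relative
to this model*; its absolute energies are not comparable to energies from
any other force field, and the package never makes such comparisons.
Second, because the model is cheap and has analytic rigid-body gradients,
an *exhaustive* rigid-body grid scan (translations on a cubic grid clipped
to a sphere, times a ZYZ Euler rotation grid) is feasible and serves as the
package's docking and verification oracle. Halving either grid step
produces a superset of poses, so a refined scan can never report a higher
minimum - the property the oracle tests rely on.

## The five-phase Monte Carlo step

`run_simulation()` runs independent walkers (walker $w$ is seeded with
`seed + w`, so a report is bit-reproducible); each step applies:

1. **Ligand perturbation**: a uniform random translation of magnitude at
   most `trans_max` and a rotation about a uniform random axis by at most
   `rot_max`. Proposals whose ligand centroid leaves the spherical
   sampling box are resampled (at most 50 times, then the identity is
   proposed); the kernel is symmetric.
2. **Backbone move** (every `anm_every` steps): a random combination of
   anisotropic-network-model modes, scaled to an exact node RMSD of
   `anm_amplitude`.
3. **Side-chain relief**: residues with any atom within
   `sidechain_radius` of the ligand are scanned over a 30° chi1/chi2
   rotamer grid, keeping the lowest-energy conformation; the current
   conformation is always a candidate, so the phase never raises the
   energy and is a no-op when repeated.
4. **Rigid-body minimization** of the ligand (gradient descent with an
   Armijo backtracking line search, at most 200 iterations, stopping at a
   gradient norm of 1e-3 or when two consecutive iterations improve the
   energy by less than 1e-5 in relative terms - in the stiff
   Lennard-Jones landscape the line search can zig-zag with a large
   gradient long after the energy has converged); the energy trace is
   monotone by construction.
5. **Metropolis acceptance** on the total energy at temperature `kT`; on
   rejection the previous state (pose, protein, energies) is restored, and
   every step emits one record of the post-decision state.

Defaults (all exposed in `sampler_config()`): box radius 6 Å around the
active site, `trans_max` 1 Å, `rot_max` 20°, side-chain radius 6 Å, `kT`
1.2 kcal/mol, backbone moves of 0.5 Å every 4th step. The desk-scale
budget is 8 walkers x 200 steps; the original HPC-scale protocol
(70 walkers x 1000 steps) is available by configuration. `kT` is an
effective sampling temperature chosen for mixing, not a physical one.

Two design decisions deserve emphasis:

* **Backbone moves are fresh harmonic draws about the reference
  structure**, not cumulative displacements of the evolving structure. A
  cumulative scheme is a random walk in conformation space and was observed
  to drift a receptor by several Å over a few hundred steps, moving planted
  landscape minima with it; fresh draws keep the ensemble within
  `anm_amplitude` of the native fold, which is exactly what an elastic
  network model describes. With the backbone and side-chain phases
  disabled and minimization off, the chain is a plain Metropolis sampler
  with a symmetric kernel and satisfies detailed balance; that diagnostic
  mode is what the equilibrium tests use.
* **Minimization acts only on the ligand's six rigid-body degrees of
  freedom.** The protein relaxes only through its own two phases. This
  keeps each step cheap and the acceptance bookkeeping simple.

Walkers start, by default, at uniform random points inside the sampling box
with random orientations, which matters for landscapes with more than one
basin: started from a single point, a short chain can fail to visit a
second minimum entirely.

## The elastic network

`build_modes()` assembles the standard anisotropic network model on the
backbone nodes (Cα atoms, or every pseudo-atom in the synthetic pockets):
unit springs between nodes within a 12 Å cut-off, the 3N x 3N Hessian with
off-diagonal blocks $-\hat{d}\hat{d}^T$, and the lowest six nontrivial
modes. A connected, non-degenerate network has exactly six zero modes (the
rigid motions); degenerate geometries (collinear nodes) have more, and a
disconnected network is an error that names its components. In
`displace_backbone()` all atoms of a residue translate rigidly with their
node - side chains are carried, not deformed.

## Synthetic receptors with planted landscapes

`make_pocket_receptor()` builds a pseudo-protein whose landscape is known
by construction and then *verified* by the oracle (the generator's
acceptance gate):

* A **docked target pose** places the ligand's first labeled terminal
  hydroxyl proton at distance `d_star` from the anchor NZ atom, molecule
  pointing away.
* A **cradle** of attractor pseudo-atoms is placed at the exact combined
  Lennard-Jones minimum distance from the heavy atoms of the docked pose
  (up to two per atom, at well-separated angles). Because every cradle
  pair term is at its minimum simultaneously in the docked pose, that pose
  is (nearly) the global landscape minimum.
* A **charged proton pin** sits behind the proton on the anchor axis at
  the pair equilibrium distance (solved numerically from its LJ + Coulomb
  terms), holding the catalytic distance at the planted value. The pin is
  negatively charged so that it attracts the partially positive hydroxyl
  proton and repels the hydroxyl oxygens - a neutral Lennard-Jones pin
  cannot distinguish a proton from the larger, more polarizable heavy
  atoms, and early neutral designs produced decoy poses presenting an
  oxygen (or the internal, secondary hydroxyl) to the pin. For the same
  reason, terminal (primary) hydroxyls of the ligand templates carry a
  larger partial polarization than internal ones.
* A **wall** of wide-core, negligible-well atoms on a sphere around the
  site, plus one **backing wall atom directly behind every cradle
  attractor**, removes alternative binding poses on the outside of the
  attractor cluster (poses "hugging" the cluster from outside would
  otherwise compete with the planted minimum). Wall atoms double as
  elastic-network scaffold.
* **Depth calibration** exploits that pair energies scale linearly with
  the pair well depth at a fixed pose: the cradle epsilons are rescaled by
  solving a small linear system so the landscape minimum equals
  `-well_depth` exactly, iterating scan-and-rescale to a fixed point
  because the argmin shifts slightly as the well is rescaled.
* An optional **decoy site** (a second cradle 120° away, with its own pin
  and depth) produces two-minimum landscapes; the sampling box is then
  centred between the sites and widened to cover both. The wide
  separation prevents a single pose from bridging both attractor clusters,
  which would create a spurious intermediate minimum.

`make_mutant_variant()` rescales the well depths of *all* attractive site
atoms (cradle, pin and anchor) uniformly so the landscape minimum deepens
by `delta_e` with its position untouched - the synthetic analogue of a
tunnel-mouth mutation that improves substrate binding without moving the
catalytic geometry. Uniform scaling matters: because the site energy is a
pure attractive sum, every binding pose deepens in proportion to its own
energy, so the measured deepening does not depend on exactly which pose a
sampler or oracle identifies as the minimum (scaling only a subset of
atoms was observed to over-deepen alternative poses that engage that
subset more strongly). The calibration reference is the continuous
multi-start-minimized global minimum, and the construction is re-verified
against the same multi-start search on the mutant.

Verification runs a fine local scan around each planted site (0.25 Å
translation grid, rotations within 80-100° of the docked orientation) plus
a coarse global scan of the whole box, and errors out if the minimum is
farther than 0.3 Å from the planted distance, more than 0.5 kcal/mol from
the planted depth, or beaten by a stray minimum elsewhere.

What the generators deliberately do **not** emulate: real protein topology
and side-chain chemistry, solvent, ligand flexibility, and any
force-field-specific energetics. Passing the recovery tests therefore
shows that the pipeline's *inference machinery* (sampling, screening,
comparison, fitting) is correct and well-calibrated on landscapes whose
truth is known - it does not validate predictions on real enzymes, which
inherit all the error of the energy model and of predicted structures.

## Assay-data generators and characterization mathematics

* `make_mm_dataset()` draws initial rates
  $v = k_{cat} [S] / (K_M + [S])$ with multiplicative lognormal noise of
  coefficient of variation `noise_cv` (default 0.05; rates are positive,
  and CV-style error matches enzymology practice; the mean of the
  lognormal factor is exactly 1). `fit_mm()` refits by Levenberg-Marquardt
  nonlinear least squares with unit weights, initialized from a
  Hanes-Woolf linearization; it requires five distinct concentrations and
  warns when the data never approach saturation.
* `efficiency()` is exact arithmetic, $k_{cat}/(K_M/1000)$ in
  M$^{-1}$s$^{-1}$; `report_efficiency()` reproduces the rounding used in
  characterization tables (nearest integer below 1000, two significant
  figures above).
* `make_melt_curve()` produces a logistic flavin-fluorescence unfolding
  signal on the standard 20-95 °C, 1 °C-step thermal ramp, with
  multiplicative (CV-style) noise; the default transition width (slope
  1.5 °C, a 10-90% rise of about 6.6 °C) reflects cooperative two-state
  unfolding and is what makes a +/-1 °C derivative-peak read-out
  attainable at 2% noise. `tm_from_melt()` reads the melting temperature
  as the maximum of the 3-point moving-average-smoothed derivative and
  flags curves with no transition (a flat or uniform-slope signal) rather
  than reporting a meaningless peak.
* `make_kie_dataset()` pairs protiated/deuterated datasets sharing
  $K_M$; `kie()` reports the $k_{cat}$ ratio with propagated standard
  error and annotates ratios above one as hydrogen transfer being
  partially rate-limiting.
* `extinction_coefficient()` scales the free-FAD 450 nm reference
  (11.3 mM$^{-1}$cm$^{-1}$, the standard literature value, configurable)
  by the native/denatured absorbance ratio. `rate_from_absorbance()`
  converts peroxidase-coupled dye slopes (default
  $\varepsilon_{515}$ = 26 mM$^{-1}$cm$^{-1}$) to per-enzyme turnover
  assuming one dye per H$_2$O$_2$ - a stoichiometry the assay literature
  does not always state, so it is documented and fixed here.
* `ph_profile()` normalizes activities to the maximum (=100%); an
  all-flat profile reports the lowest pH with an explicit note.

## Screening rules and their conventions

* `catalytic_distance()` is the minimum over the labeled terminal hydroxyl
  protons - both ends of an end-symmetric polyol (glycerol, xylitol) are
  evaluated and the closer one used. Open-chain D-xylulose has a C2
  ketone and is encoded with a single reactive terminus (the C1 hydroxyl).
  The distance is measured to the *proton*; measuring to the hydroxyl
  oxygen would shift values by roughly the O-H bond length, and the proton
  convention is the operational definition used throughout. (The atom
  name is NZ: the side-chain terminal nitrogen of lysine; descriptions of
  this distance sometimes write "Nε", which lysine does not have.)
* `build_profile()` bins the scatter at 0.25 Å and takes per-bin minima
  (the lower envelope); envelope minima need at least 1 kcal/mol of
  prominence to be reported, which suppresses noise-level wiggles. The
  global minimum is taken from the raw points, not the envelope. Broad
  binding wells can legitimately report several nearby sub-basin minima;
  screening decisions depend only on the global minimum and on whether
  prominent minima exist beyond the cut-off.
* `classify_landscape()` applies the 4 Å rule to the global-minimum
  distance, boundary inclusive (the cut-off is deliberately permissive).
  Lowering the cut-off can only demote candidates, never promote them.
  Secondary envelope minima beyond the cut-off are reported; a catalytic
  landscape with a prominent non-catalytic second minimum is the pattern
  associated with substrate binding in unproductive poses, i.e. an
  elevated Michaelis constant.
* `compare_mutant()` marks a variant improved when its catalytic minimum
  is at most 0.5 Å worse in distance *and* strictly better in energy. The
  0.5 Å tolerance operationalizes "similar or better distance", which has
  no published numeric value. The density ratio (fraction of sampled
  points inside the catalytic window, computed over an identical window
  for both datasets) is reported but kept out of the boolean rule, since
  no threshold for "significantly higher density" is established.
* `rank_candidates()` orders catalytic candidates first, then by global
  minimum energy, then distance, with lexicographic id tie-breaks -
  deterministic under input permutation.

## Sequence triage

`global_align()` wraps Needleman-Wunsch global alignment (BLOSUM62, gap
open 10, extend 0.5) and computes percent identity with gap-free aligned
columns as the default denominator - the convention closest to
"identities / aligned length" for near-full-length homologs; alternative
denominators are options, since identity values are convention-sensitive
at the level of a percentage point. `homolog_filter()` retains candidates
strictly above the threshold (default 60%).

## Numerical choices and degenerate inputs

* Pair terms are computed from squared distances only (no square roots in
  the hot loops); the grid oracle uses an early exit on core-overlapping
  clashes that cannot change the argmin, and exact energies in table mode.
* The minimizer caps its initial step so no atom moves more than about
  0.5 Å per line-search trial; an exhausted line search terminates the
  minimization at the current (locally stationary) point.
* Rotamer scans prefer the current conformation on ties (within 1e-9),
  which makes the phase idempotent.
* PDB altloc records collapse to the highest-occupancy conformer (first in
  file order on ties); waters are skipped by default; malformed
  ATOM/HETATM records are reported with their line number; unparameterized
  atoms get neutral defaults with a counted warning, but a parameter table
  that misses more than half the atoms is rejected as the wrong table.
* Flat melt curves yield a flagged missing Tm, not a number; flat pH
  profiles report the lowest pH with a note; Michaelis-Menten fits that
  fail to converge withhold their parameters and say so.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to give stable statistics
on a single core: equilibrium checks on a frozen two-well toy use 1e5
total Monte Carlo steps against an exact Boltzmann quadrature of the same
pose space; archetype recovery runs 20 seeded generator+sampler+screening
pipelines at the default desk-scale budget (8 walkers x 200 steps; planted
minima can have secondary pose families within half a kcal/mol, which
smaller budgets resolve unreliably); sampler-versus-oracle optimality
uses 1e4 steps against a 0.25 Å / 30° exhaustive scan; kinetics bias is
averaged over 100 seeded datasets (10 concentrations x 3 replicates);
melting-temperature recovery over 50 seeded curves. The full-scale
sampling budget of the original protocol is a configuration choice, not a
code path difference.

## Known limitations

* The energy model is minimal by design; its landscapes are meaningful
  relative to themselves, and no quantity computed here should be compared
  numerically to published force-field energies.
* The ligand is rigid; real glycerol has rotatable bonds, and an
  induced-fit protocol with ligand flexibility could shift both distances
  and energies.
* Backbone fluctuation sampling is near-native by construction; large
  conformational changes (loop opening, domain motion) are out of scope.
* The Metropolis criterion is evaluated on the total energy as computed
  (interaction plus the side-chain self terms of optimized residues);
  with the heuristic side-chain and minimization phases enabled the chain
  is an optimizing sampler, not an equilibrium one - which is the intended
  use for landscape mapping.
* Percent identity depends on alignment conventions at the level of about
  a percentage point; the package documents its choice rather than
  claiming a canonical value.
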