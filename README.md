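# aldoscape

In-silico bioprospecting and engineering of glycerol-active alditol
oxidases (AldO, EC 1.1.3.41) by Monte Carlo induced-fit landscape
screening — as a desk-scale, fully testable R pipeline.

## Who this is for and what it does

Enzyme engineers triaging oxidase candidates for polyol (glycerol,
xylitol) oxidation, and computational people who want the screening logic
of induced-fit simulations in an inspectable, seeded, unit-tested form.
The package covers the whole workflow:

1. **Sampling.** A Monte Carlo induced-fit engine: each step perturbs the
   rigid ligand (random translation ≤ 1 Å, rotation ≤ 20° inside a 6 Å
   spherical box), applies an anisotropic-network-model backbone
   fluctuation, relieves side-chain clashes on a rotamer grid, minimizes
   the ligand's rigid-body degrees of freedom, and accepts or rejects by
   the Metropolis criterion at temperature *kT*. Energies come from a
   documented minimal nonbonded model (shifted 12-6 Lennard-Jones +
   Coulomb with distance-dependent dielectric ε(r) = 4r, 10 Å cutoff),
   with the compute-heavy kernels in C++.
2. **Screening.** Each step records the interaction energy *E* and the
   catalytic distance *d* — from the catalytic lysine's NZ atom to the
   nearest terminal hydroxyl proton of the substrate. A candidate is
   **catalytic** iff the global minimum of the (d, E) landscape satisfies
   d ≤ 4 Å (a permissive proton-transfer range); prominent secondary
   minima beyond the cutoff are flagged. A mutant **improves** on the
   wild type iff its catalytic minimum is at a similar-or-better distance
   (≤ 0.5 Å worse) with a strictly better interaction energy.
3. **Characterization.** Michaelis–Menten fitting (v = k~cat~[S]/(K~M~+[S]),
   Levenberg–Marquardt with Hanes–Woolf initialization), catalytic
   efficiency k~cat~/K~M~, kinetic isotope effects, thermal-shift melting
   temperatures (derivative-peak read-out), flavin extinction
   coefficients, pH profiles, and global-alignment percent identity for
   homolog triage.
4. **Synthetic truth.** Seeded generators build pocket receptors whose
   landscape minima are *planted* at known distances and depths (verified
   at build time by an exhaustive rigid-body grid-scan oracle), mutant
   variants with an exactly calibrated well deepening, and assay datasets
   with known kinetic parameters — so every stage is testable end to end
   with no downloads and no wet-lab data.

## Worked example

```r
library(aldoscape)

## a receptor with a landscape minimum planted at 3.0 Å / -8 kcal/mol
rec <- make_pocket_receptor(pocket_spec(d_star = 3.0, well_depth = 8, seed = 1))
glycerol <- load_ligand_template("glycerol")
traj <- run_simulation(rec, glycerol,
                       sampler_config(n_steps = 200, n_walkers = 8, seed = 1))
classify_landscape(build_profile(traj), candidate_id = "candidate_1")
#>   candidate_id global_min_distance global_min_energy catalytic
#> 1 candidate_1                 3.00             -8.76 TRUE

## a mutant with a planted 1.46 kcal/mol deepening of the catalytic well
mut <- make_mutant_variant(rec, delta_e = -1.46)
cfg <- sampler_config(n_steps = 250, n_walkers = 6, anm_every = 0, seed = 2)
compare_mutant(run_simulation(rec, glycerol, cfg),
               run_simulation(mut, glycerol, cfg))
#>   delta_min_energy delta_min_distance density_ratio improved
#> 1            -1.46            0.00142             1 TRUE

## steady-state kinetics: synthetic rates at kcat 4.0 1/s, KM 41 mM, 2% CV
fit <- fit_mm(make_mm_dataset(assay_spec(kcat = 4.0, km = 41,
                                         noise_cv = 0.02, seed = 7)))
fit
#> <mm_fit> kcat = 4.01 +/- 0.02 1/s, KM = 40.1 +/- 0.73 mM, kcat/KM = 99.8 1/(M s)

## thermal shift: melt curve generated at Tm 76 °C with 2% noise
tm_from_melt(make_melt_curve(tm = 76, noise = 0.02, seed = 3))
#>      tm has_transition max_slope
#> 1  75.5 TRUE               0.159
```

The verdict says the sampled global minimum sits at 3.00 Å (within the
4 Å proton-transfer cutoff, hence catalytic) at −8.76 kcal/mol, at the
planted well. The mutant comparison recovers the planted deepening at an
essentially unchanged catalytic distance, so the variant is flagged as an
improvement; the kinetics fit recovers the generating parameters within
their standard errors, and the melt-curve read-out returns the planted
melting temperature to within the 1 °C ramp resolution.

Results tibbles plot directly: `autoplot(traj)` draws the landscape
scatter with its lower envelope and the 4 Å line, `autoplot(fit)` the
saturation curve, `autoplot(curve)` a melt curve with its Tm. A thin
command-line wrapper (`inst/exec/aldoscape`) exposes the stages as
subcommands (`synth`, `simulate`, `screen`, `compare-mutant`, `rank`,
`kinetics-fit`, `meltfit`, `kie`, `identity`, `report`).

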