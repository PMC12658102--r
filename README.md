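# helimer

Quantitative analysis of **weak helical multimerization** — the kind of
self-association an intrinsically disordered protein region with a short,
conserved, transiently α-helical segment undergoes: dissociation constants
in the µM–mM range, multimer populations of a few percent, fast exchange.
The motivating system is the conserved region (residues 319–341) of the
TDP-43 C-terminal domain, whose helix-mediated assembly links phase
separation, nuclear retention, and toxicity, but every component is
generic.

The package is aimed at biophysicists combining sedimentation-velocity
analytical ultracentrifugation (SV-AUC), NMR, structure prediction, and
molecular-dynamics ensembles into one picture. It provides:

* **Mass-action speciation** for self-association schemes with stepwise,
  species-molar dissociation constants (`Kd1 = [M]²/[D]`,
  `Kd2 = [D]²/[T]`), plus the smooth-sphere s-ratio expectation `n^(2/3)`
  for an n-mer (`solve_speciation`, `expected_s_nmer`,
  `signal_weighted_s`).
* A conservative finite-volume **Lamm-equation solver**,
  `∂c/∂t = (1/r) ∂/∂r [ r D ∂c/∂r − s ω² r² c ]`, with exponential flux
  fitting, no-flux walls, and rapid re-equilibration of reacting species
  onto the mass-action manifold (`simulate_boundaries`).
* **c(s) distribution** inversion with one-standard-deviation F-ratio
  Tikhonov regularization and peak integration (`fit_cs`, `integrate_cs`).
* **Direct global boundary fitting** of association models across
  concentrations, with log-space constants, multistart
  Levenberg–Marquardt, error-surface-projection confidence intervals, and
  scheme comparison with physical-plausibility flags
  (`fit_association_model`, `profile_interval`, `compare_schemes`).
* **Ensemble structural statistics**: superposition-free distance RMSD
  with a 1 nm instability criterion, heavy-atom contact maps (0.6 nm
  cutoff, `|i−j| > 3` within chains), per-residue contact totals with
  replica/block SEM, Kabsch–Sander helix fractions, minimum inter-chain
  distances with dissociation episodes, GROMOS clustering, and the
  `0.8·ipTM + 0.2·pTM` model-confidence score.
* **NMR metrics**: secondary Cα shifts against a random-coil reference,
  concentration-dependent ¹⁵N chemical-shift perturbations normalized to
  wild type, solvent-PRE attenuation with exposure flags.
* **Correlation analyses** across mutant panels with named exclusion
  flags, and seeded **synthetic-data generators** for scan sets, helical
  bundles, and mutant tables, so the whole pipeline is testable offline.

## Worked example

A monomer–dimer–tetramer equilibrium with a weak monomer–dimer step
(2.4 mM) and a much tighter dimer–tetramer step (2.7 µM), solved at a
107 µM loading:

```r
library(helimer)

scheme <- association_scheme(c(1, 2, 4), stepwise_kd = c(2400, 2.7))
solve_speciation(107, scheme)
#> speciation at 107 uM monomer equivalents
#>   species molar_uM monomer_equiv_uM
#>   monomer   86.430           86.430
#>     dimer    3.112            6.225
#>  tetramer    3.587           14.350

expected_s_nmer(2)
#> [1] 1.587401
```

At 107 µM, 6.2 µM of protein sits in dimers and 14.3 µM in tetramers —
the dimer is a weakly populated intermediate on the way to a cooperative
tetramer. A dimer is expected at only ~1.59× the monomer s-value, so a
boundary component near 2× the monomer is itself evidence for species
beyond the dimer.

The forward/inverse machinery closes the loop on synthetic data:

```r
expt <- cell_experiment(times_s = seq(600, 30000, by = 600), rpm = 50000,
                        temperature_C = 25, pathlength_mm = 3)
species <- list(hydro_species(1.54, n = 1, signal_coef = 0.01),
                hydro_species(2.43, n = 2, signal_coef = 0.01),
                hydro_species(3.94, n = 4, signal_coef = 0.01))
d58  <- gen_auc_scans(expt, species, scheme = scheme, loading = 58,
                      noise_sd = 0.005, seed = 11, ncells = 300)
d107 <- gen_auc_scans(expt, species, scheme = scheme, loading = 107,
                      noise_sd = 0.005, seed = 12, ncells = 300)
fit_association_model(list(d58, d107), scheme, expt, n_starts = 2,
                      seed = 1, ncells = 300)
#> global Lamm-equation fit: monomer-dimer-tetramer model
#>   s (S): 1.538, 2.53, 3.881
#>   stepwise Kd (uM): 2427, 2.607
#>   loadings (uM): 58.02, 107
#>   rmsd: 0.004991 AU over 38100 points
```

The global refit recovers the generating constants (2.4 mM and 2.7 µM)
and s-values from 0.005 AU-noise boundaries at two concentrations, with
the rms deviation at the noise floor.

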