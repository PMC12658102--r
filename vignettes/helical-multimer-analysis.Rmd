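---
title: "Quantifying weak helical multimerization: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying weak helical multimerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helimer)
```

# The problem

Intrinsically disordered protein regions that carry a short, conserved,
transiently alpha-helical segment — the conserved region (CR, residues
319–341) of the TDP-43 C-terminal domain is the motivating case — can
self-associate through helix–helix contacts into weak, rapidly exchanging
multimers.  These assemblies sit far below the affinities that produce
stable, crystallizable complexes: dissociation constants in the high
micromolar to millimolar range, populations of a few percent at accessible
concentrations, and exchange on the chemical-shift timescale.  No single
technique resolves them.  `helimer` implements the quantitative machinery
that an integrative study of such a system needs:

* mass-action speciation and hydrodynamic scaling expectations
  (`solve_speciation`, `expected_s_nmer`);
* forward simulation of sedimentation-velocity (SV-AUC) boundaries by the
  Lamm equation, for independent and for rapidly re-equilibrating
  self-associating species (`simulate_boundaries`);
* continuous c(s) distribution inversion (`fit_cs`, `integrate_cs`);
* direct global fitting of association models to multi-concentration scan
  sets with confidence intervals and model comparison
  (`fit_association_model`, `profile_interval`, `compare_schemes`);
* structural statistics over coordinate ensembles: distance RMSD, heavy-atom
  contact maps, Kabsch–Sander helix assignment, minimum inter-chain
  distances, GROMOS conformational clustering (`drms_series`,
  `contact_map`, `helix_fraction`, `min_interchain_distance`,
  `cluster_gromos`);
* NMR-derived scalar metrics (`secondary_ca_shift`, `csp_norm`,
  `spre_attenuation`) and cross-modality correlations
  (`correlate_measures`);
* seeded synthetic-data generators (`gen_auc_scans`, `gen_helical_bundle`,
  `gen_mutant_table`) so every stage is testable without external data.

# Mass-action speciation

A self-association scheme is a list of species with stoichiometries $n_j$
and dissociation constants.  We use the **stepwise, species-molar
convention**: each step is a dimerization of the previous species, with

$$K_{d,1} = \frac{[\mathrm{M}]^2}{[\mathrm{D}]}, \qquad
  K_{d,2} = \frac{[\mathrm{D}]^2}{[\mathrm{T}]},$$

so the overall constants are $K_\mathrm{D} = K_{d,1}$ and
$K_\mathrm{T} = K_{d,1}^2 K_{d,2}$, and
$[j] = [\mathrm{M}]^{n_j} / K_j$.  This is the only convention under
which a monomer–dimer–tetramer model with $K_{d,1}$ = 2.4 mM and
$K_{d,2}$ = 2.7 µM reproduces the speciation those constants are quoted
with, and we state it prominently for that reason.  Concentrations are
µM throughout; mM is accepted at the interface and converted.  Schemes
whose stoichiometries do not double at each step (monomer–trimer, say)
are specified through overall constants instead.

Total monomer-equivalent concentration
$c_\mathrm{tot} = \sum_j n_j [\mathrm{M}]^{n_j}/K_j$ is strictly
increasing in the free monomer concentration, so speciation reduces to one
bracketed root find on $[0, c_\mathrm{tot}]$; we polish the `uniroot`
result with Newton steps and verify mass balance to a relative $10^{-9}$.
"Concentration in the dimer form" always means the monomer-equivalent
concentration $2[\mathrm{D}]$.

```{r}
scheme <- association_scheme(c(1, 2, 4), stepwise_kd = c(2400, 2.7))
solve_speciation(107, scheme)
```

The smooth-sphere expectation for an n-mer's sedimentation coefficient at
equal partial specific volume and frictional ratio is $n^{2/3}$
(`expected_s_nmer`): mass grows as $n$, the Stokes radius as $n^{1/3}$.
A dimer is expected at $2^{2/3} \approx 1.59\times$ the monomer s-value —
the yardstick against which an observed ~2x species argues for
higher-order assembly.

# The Lamm-equation solver

Boundary evolution in a sector-shaped cell follows the Lamm equation

$$\frac{\partial c}{\partial t} = \frac{1}{r}\frac{\partial}{\partial r}
  \left[ r D \frac{\partial c}{\partial r} - s\,\omega^2 r^2 c \right].$$

`simulate_boundaries` discretizes it with a conservative finite-volume
scheme in the spirit of Claverie: uniform radial cells between meniscus
and bottom, no-flux walls, and exponentially fitted (Scharfetter–Gummel)
face fluxes, which interpolate smoothly between central differencing at
low cell Peclet number and pure upwinding as $D \to 0$.  Because the
update is written in flux form, total sector mass $\int c\,r\,dr$ is
conserved to round-off — the 0.1% conservation requirement is met by
construction, and the tests verify it.  Time stepping is a theta scheme
(default $\theta = 0.5$, Crank–Nicolson) with a tridiagonal solve per
species and step; the step size follows an advective Courant number
(default `cfl = 1`) on the fastest species.  Tiny negative
concentrations from the explicit half-step are clamped; negatives beyond
$10^{-4}$ of the loading abort with a diagnostic.

**Reacting systems.**  For a self-association scheme the species are
transported independently within each step and then every cell is
projected back onto the mass-action manifold, conserving local monomer
equivalents (operator splitting).  This is the rapid-equilibrium limit —
appropriate for the fast-exchange regime that direct boundary fits of
weak self-association assume — and it removes unconstrained kinetic rate
parameters.  The local projection is a safeguarded Newton iteration with
warm starts, so the reacting solver costs little more than the
independent one.  With the constants pushed to infinity the reacting
solver reproduces the independent-species solution in the monomer
channel (a regression test).

Defaults: 500 radial cells for forward simulation, 300 for fitting
(halving the cell width changes scan signals by well under 0.2% rms at
these settings); reported radii every 0.003 cm, excluding 0.01 cm at the
meniscus and 0.05 cm at the bottom, where real fits exclude optical
artifacts and back-diffusion pile-up.  Diffusion coefficients default to
the Svedberg relation $D = sRT/(M(1-\bar v \rho))$ with the species mass
fixed at $n \times$ 16 kDa (a typical mass for the disordered domain
studied; any consistent choice works because generation and fitting share
the rule).  The partial specific volume defaults to 0.73 mL/g, a standard
protein value; solvent density and viscosity default to pure water at the
run temperature via the Kell and Korson correlations
(`water_density`, `water_viscosity`).

**Signal model.**  Every monomer unit carries the same signal
coefficient (default 0.01 AU/(µM·cm), i.e. a ~10,000 M$^{-1}$cm$^{-1}$
chromophore), so a species contributes
`signal_coef * n * molar concentration * pathlength`.  Pathlength (3 or
12 mm centerpieces) enters as a linear scale.

# c(s) inversion

`fit_cs` builds a library of noise-free single-species Lamm solutions on
an s-grid (default 100 points, 0.5–10 S), with $D(s)$ tied to a common
frictional ratio through the sphere relations, and solves the
non-negative least-squares problem with a second-difference Tikhonov
penalty.  The penalty strength is chosen by bisection so that the
penalized misfit exceeds the unpenalized minimum by the one-standard-
deviation F-ratio ($P = 0.683$) — the standard regularization criterion
in this field.  The frictional ratio defaults to 1.4 (an s of ~1.5 S at
~14–16 kDa implies an elongated, IDR-like particle) and can be scanned
(`f_f0 = "fit"`).  Early scans can be dropped (`skip_scans`) to remove
contributions from large aggregates that clear the cell quickly.
`integrate_cs` returns loading signal and weighted-average $s_w$ over a
range; `cs_peak_ranges` splits the grid at local minima (ties toward
lower s) to define per-peak integration limits.

# Direct boundary fitting

`fit_association_model` minimizes the summed squared residuals of the
reacting forward model over all scans and concentrations jointly
(Levenberg–Marquardt via `minpack.lm`).  Design choices:

* Dissociation constants are fitted as $\log_{10} K_d$ — they span µM to
  mM and must stay positive.
* Per-set loading concentrations are free nuisance parameters (exact
  loadings are never known); the signal coefficient is fixed.
* Meniscus and bottom are fixed from the cell geometry, not fitted.
* Multistart (default 5 starts): the first start uses truth-agnostic
  heuristics (boundary-midpoint motion for the monomer s, $n^{2/3}$
  scaling for the rest), later starts draw log-uniform constants; the
  seed fixes the draw.
* An optional non-participating "aggregate" species (own s, per-set
  trace amplitude) can absorb large material; off by default for
  synthetic data.
* Systematic time-invariant/radial-invariant noise elimination is not
  applied to synthetic data (which has none by construction).

`profile_interval` reports error-surface-projection intervals: the
parameter is scanned, all others re-optimized, and the interval is where
$\chi^2 \le \chi^2_\mathrm{min}\,(1 + \tfrac{p}{N-p} F(p, N-p; P))$.
This projection convention (all parameters jointly perturbed) is
deliberately conservative; it is stated here because fitting software
differs on this point.  Bounds that never cross within the scan are
reported open and flagged, as happens for parameters the data do not
constrain.  `compare_schemes` ranks candidate schemes by rmsd and flags
physically unreasonable fits — fitted s-ratios off $n^{2/3}$ by more than
1.5x, or s-values that fail to increase with stoichiometry.

# Trajectory statistics

All coordinates are nm internally; Angstrom inputs (PDB) are converted on
read.  Residue numbering is kept verbatim so UniProt-based labels match
outputs.

* **dRMS** (`drms_series`): superposition-free deviation
  $\sqrt{\tfrac{2}{N(N-1)}\sum_{i<j}(d_{ij}(t)-d_{ij}^\mathrm{ref})^2}$
  over all heavy-atom pairs of the selection (default residues 320–341,
  all chains, intra- and inter-chain pairs).  A frame with dRMS > 1 nm is
  flagged unstable — the criterion used to call a multimer model
  structurally unstable.
* **Contacts** (`contact_map`): residues i, j are in contact when any two
  heavy atoms lie within 0.6 nm.  The sequence-separation rule
  $|i-j| > 3$ applies within a chain only; inter-chain pairs are always
  eligible (for intermolecular maps the rule is moot, and this reading
  keeps intra-chain maps sensible).  Maps report per-position any-contact
  probability over retained frames (mean counts are an option — the
  choice is declared because published maps rarely say).  Equilibration
  frames can be dropped; `contact_totals` sums one axis
  ($N_\mathrm{contact}$) with SEM over replicas, or over 5 contiguous
  time blocks of a single run (`contact_blocks`).
* **Helicity** (`helix_fraction`): Kabsch–Sander hydrogen bonds,
  $E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
  kcal/mol with a −0.5 kcal/mol threshold; a minimal alpha-helix needs
  two consecutive i→i+4 turns.  Only state H counts as helix (the
  `do_dssp` convention for "helix fraction"); 3-10 and pi states are not
  folded in.  Missing amide hydrogens are placed 1.01 A from N along the
  bisector away from CA and the previous carbonyl carbon; missing
  backbone heavy atoms make a residue unassignable (`NA`), never silently
  non-helical.  The assignment is cross-checked against an independent
  DSSP implementation in the test suite.
* **Minimum inter-chain distance** (`min_interchain_distance`): per-frame
  minimum over heavy-atom pairs; dissociation episodes are maximal runs
  above a threshold (default 0.6 nm, matching the contact cutoff — our
  convention, declared because published mindist traces rarely state
  one) with a minimum dwell.
* **Clustering** (`cluster_gromos`): GROMOS greedy neighbor-count
  clustering under a pairwise Kabsch-superposition RMSD cutoff (default
  0.3 nm on the backbone of residues 320–341), ties broken toward the
  earliest frame, which makes the algorithm deterministic.
* **Model confidence** (`af2_confidence`): the weighted
  interface/global predicted-TM score $0.8\,\mathrm{ipTM} +
  0.2\,\mathrm{pTM}$ used to rank predicted multimer models.

# NMR metrics and correlations

`secondary_ca_shift` subtracts a user-supplied random-coil reference
(no scale is hardcoded — random-coil sets are a user choice and the
package does not pick one).  `csp_norm` quantifies concentration-dependent
self-assembly as the 15N shift change of a probe resonance (default
residue 328) between a high-concentration and a monomeric
low-concentration condition, normalized to wild type; 15N only, no
composite weighting, because that is how the quantity is defined.
Variants broadened beyond detection return an explicit exclusion marker,
never 0.  `spre_attenuation` normalizes paramagnet-containing intensities
to the paramagnet-free reference; ratios below 0.1 at the highest
paramagnet concentration flag solvent-exposed groups (a ratio of 0 is
complete signal loss).

`correlate_measures` computes Pearson or Spearman coefficients between
mutant-table columns with exclusions applied pairwise and reported by
name (`broadened_NMR`, `no_droplets`, `irregular_morphology` are the
conventional reasons).  Correlations use mean values; measurement SDs are
reported alongside but not used as weights, matching how plain
correlation coefficients are quoted.  WT normalization is affine and so
cannot change Pearson's r — the tests assert this rather than assume it.

# Synthetic generators: what they emulate, and what they do not

`gen_auc_scans` adds i.i.d. Gaussian noise (default 0.005 AU) to exact
forward solutions: it emulates absorbance-detection shot noise but not
time-invariant window artifacts, radial-invariant offsets, meniscus
optical artifacts, or slow aggregate formation during a run.
`gen_helical_bundle` builds ideal poly-alanine alpha-helices (textbook
1.5 A rise and 100 degrees twist per residue emerge from standard
backbone internal coordinates with phi = −57, psi = −47) on a regular
polygon with a chosen axis spacing, alternating chain direction for
antiparallel bundles, then applies Gaussian coordinate jitter and an
optional scripted chain displacement with the episode recorded as ground
truth.  It emulates the geometry and contact topology of a four-helix
assembly — not side-chain packing, solvent, or realistic conformational
kinetics.  `gen_mutant_table` draws variant pairs from a bivariate normal
with a chosen correlation and maps them affinely onto WT-normalized
scales (n = 18 by default, the number of conserved-region positions a
mutagenesis panel covers).  Passing tests on these generators therefore
demonstrate correctness of the estimators and solvers, not the realism
of any particular molecular system.

Every generator is bit-reproducible given its seed and records its ground
truth on the output object.

# Problem sizes and numerical tolerances

The package's own validation uses desk-scale problems chosen to exercise
every code path: recovery fits use two scan sets (58 and 107 µM, 50
scans each, 300 radial cells, 0.005 AU noise, three seeds) — about a
minute of compute — while unit tests use 120–200 cells and 8–12 scans.
Speciation is solved to $10^{-9}$ relative mass balance; the D = 0
boundary position matches the analytic law $r_m e^{s\omega^2 t}$ to
0.5% on a 2000-cell grid; c(s) round trips recover single-species s
within 2% at 0.005 AU noise; contact maps are checked exactly against a
brute-force $O(N^2)$ oracle up to 200 atoms.

# Known limitations

* The rapid-equilibrium assumption: kinetically limited reaction
  boundaries (finite on/off rates) are out of scope, as are flotation,
  compressible solvents, and synthetic-boundary cells.
* c(s) is the plain one-dimensional distribution with a single
  frictional ratio; size-and-shape (2D) and Bayesian variants are not
  implemented.
* The confidence-interval convention is the conservative joint-region
  projection described above; conventions differ between fitting
  programs, so intervals are comparable only within one convention.
* Helix fractions count the alpha (H) state only.
* Correlation analyses treat measurement error as reporting detail, not
  as errors-in-variables; with large, heteroscedastic SDs the plain
  coefficients are attenuated estimates.
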