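# Shared fixtures, built in code.

# monomer-dimer-tetramer scheme with the published best-fit constants
mdt_scheme <- function() association_scheme(c(1, 2, 4),
                                            stepwise_kd = c(2400, 2.7))

# the three species of the best-fit model (s in S at experimental
# conditions; masses n x 16 kDa; equal per-monomer signal coefficient)
mdt_species <- function(signal_coef = 0.01)
  list(hydro_species(1.54, n = 1, signal_coef = signal_coef),
       hydro_species(2.43, n = 2, signal_coef = signal_coef),
       hydro_species(3.94, n = 4, signal_coef = signal_coef))

# reduced-size experiment for fitting tests (keeps the suite fast while
# spanning the same boundary depletion as a full run)
small_expt <- function(n_scans = 12, pathlength_mm = 3)
  cell_experiment(times_s = seq(1200, 28800, length.out = n_scans),
                  rpm = 50000, pathlength_mm = pathlength_mm)

small_radii <- function(by = 0.008) seq(6.01, 7.15, by = by)

# full-size study conditions: 50 scans, 3 mm cells, 50 krpm
study_expt <- function()
  cell_experiment(times_s = seq(600, 30000, by = 600), rpm = 50000,
                  pathlength_mm = 3)

# strip class/attributes from a contact map for exact matrix comparison
strip_map <- function(m) {
  m <- unclass(m)
  matrix(as.numeric(m), nrow(m))
}

# tiny two-atom ensemble with one inter-"residue" distance
two_atom_traj <- function(d_ref = 1.0, d_frame = 1.5) {
  at <- data.frame(chain = "A", resno = c(1, 10), resname = "ALA",
                   name = "CA", element = "C")
  x <- array(0, c(2, 2, 3))
  x[1, 2, 1] <- d_ref
  x[2, 2, 1] <- d_frame
  traj_ensemble(at, x)
}
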