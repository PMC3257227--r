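# ribodyn

Residue-resolved stability and dynamics analysis for small globular
proteins, built around the solution-NMR and molecular-dynamics
characterisation of the monomeric derivative of bovine seminal
ribonuclease (mBS, 124 residues).  The package is aimed at protein NMR
spectroscopists and simulators who want a tested, scriptable
reimplementation of the standard residue-by-residue analyses:

- **Hydrogen/deuterium exchange** (`hx_kinetics`): first-order decay fits
  of peak intensities, intrinsic (random-coil) rate prediction from
  poly-DL-alanine reference parameters with nearest-neighbour and
  temperature corrections, protection factors `P = k_rc / k_obs`, opening
  free energies `dG_op = RT ln P`, and EX1/EX2 discrimination from a pH
  pair.
- **Lipari–Szabo model-free analysis** (`relaxation`): the spectral
  density `J(w) = 2/5 [S2 tc/(1+(w tc)^2) + (1-S2) t/(1+(w t)^2)]`,
  forward R1/R2/NOE (+ eta_xy, eta_zz) under isotropic tumbling with an
  axially symmetric -160 ppm 15N CSA and r_NH = 1.02 A, a two-stage
  global-tau_c inversion with Monte-Carlo confidence bounds, reduced
  spectral-density mapping (J(0), J(wN), J(0.87 wH)), CSA/DD-based
  exchange detection, and the empirical size formula
  `tau_c = (9.18e-3/T) exp(2416/T) N^0.93` ns.
- **Two-state urea denaturation** (`denaturation`): per-residue fits of
  the native fraction `f_N(c) = 1/(1+exp(-(dG - m c)/RT))`, midpoint
  aggregation, and chemical-shift perturbations.
- **Paramagnetic (TEMPOL) surface mapping** (`paramagnetic`): autoscaled
  diamagnetic/paramagnetic volume ratios `A_i`, hot-spot classification
  (`A_i > 1.7`), and regression against hydrogen-bond freedom.
- **Trajectory observables** (`traj_analysis`): RMSF after least-squares
  superposition, hydrogen-bond percentage lifetimes (0.35 nm / 75
  degrees), hydration-density grids with MDHS detection (0.05 nm grid,
  0.6/0.8 nm shells), and probe-sphere atom depth indexes (8 A probe,
  isolated atom = 2).
- **Synthetic data** (`synthetic`): seeded generators for every input
  type with machine-readable ground truth, defaulting to the measured
  mBS regime.
- **Reporting and CLI** (`report`, `ribodyn_run`): per-residue dossiers,
  B-factor-annotated PDB output, and a `ribodyn` command-line entry
  point (see `inst/cli/ribodyn`).

## Worked example

```r
library(ribodyn)

# H/D exchange: protection factor and opening free energy of a protected
# histidine (k_obs = 0.038/hr, P = 2.48e5)
pe <- protection_and_energy(k_obs = 0.038, k_rc = 0.038 * 2.48e5,
                            temperature_K = 300)
round(c(P = pe$P, dG_op = pe$dG_op), 3)
#>         P     dG_op
#> 2.480e+05 7.404e+00    # dG_op in kcal/mol

# model-free round trip on synthetic relaxation data
g <- gen_relaxation(n_residues = 20, tau_c_ns = 7.9, S2_mean = 0.90,
                    noise = 0.02, seed = 1)
fit <- fit_model_free(g$records, n_mc = 0)
fit
#> <model_free_result> tau_c = 7.90 ns, 20 residues (mean S2 = 0.911)
#>   back-calculation |rel err|: T1 0.8%, T2 0.8%, NOE 0.2%

# empirical tumbling-time prediction for a 124-residue protein at 300 K
round(empirical_tauc(124, 300), 1)
#> [1] 8.5   # ns
```

The fitted global correlation time (7.9 ns), mean order parameter
(~0.90) and the 8.5 ns empirical prediction are the headline dynamics of
a compact ~14 kDa monomer; a urea cohort generated at a 4.2 M midpoint
refits to `mean_C_half` within 0.1 M (see `gen_urea` /
`aggregate_midpoints`).

## Command line

```sh
ribodyn simulate hx --seed 17 --out demo/
ribodyn hx --series demo/hx_series.tsv --sequence demo/sequence.fasta \
           --ph 5.65 --temp 300 --out demo/hx.tsv
```

Subcommands: `hx`, `relax`, `denat`, `para`, `traj`, `simulate`,
`report`.  Every output embeds the tool version and a content hash, and
identical configurations reproduce byte-identical files.
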