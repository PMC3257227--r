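---
title: "Models and methods behind ribodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ribodyn` reimplements, as reusable and tested code, the residue-resolved
analyses used to characterise the stability and dynamics of a small
globular protein in solution — concretely, the monomeric derivative of
bovine seminal ribonuclease (mBS, 124 residues, four disulfides).  This
vignette explains each model, its assumptions, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generators do and do not establish.  It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Hydrogen/deuterium exchange

Amide protons exchange with solvent deuterons by transient opening
events.  `fit_exchange_decay()` fits the first-order law
$I(t) = I(0)\,e^{-k_{obs} t}$ to each residue's peak intensity versus
time.  The fit profiles the rate (the amplitude is linear and solved
analytically) and reports standard errors from the analytic Jacobian;
this is numerically robust where Gauss–Newton iterations stall on
zero-residual (noiseless) data.  Series whose total decay is below twice
the noise level, or whose fitted half-life exceeds five times the last
sampled time, are reported qualitatively (flag `too_slow`, with an upper
bound $k \le \ln 2 / (5\,t_{max})$) rather than with a meaningless rate;
negative fitted rates flag `non_exchanging`.

Intrinsic (random-coil) rates `intrinsic_rate()` use poly-DL-alanine
reference rates in D2O (log10 of 1.62, 10.05, −1.5 per minute for acid,
base and water catalysis at 293 K; pK of D2O 15.05), nearest-neighbour
side-chain factors (the residue's own "L" factor and the preceding
residue's "R" factor, shipped as a versioned data file in
`inst/extdata/exchange_reference_params.tsv`), Arrhenius corrections with
activation energies 14/17/19 kcal/mol, and the glass-electrode
correction pD = pH$_{read}$ + 0.4.  Titratable side chains (Asp, Glu,
His) mix their charged/neutral parameter sets by the protonation
fraction at the working pD.  Cysteines default to cystine parameters
(`cys_oxidized = TRUE`), appropriate for a fully disulfide-bonded
ribonuclease.  Because the exact variant of the published parameter set
used by any given web calculator is ambiguous, consistency checks
against reference products $k_{obs}\cdot P$ are held to a factor of two,
not printed precision.

Under EX2, `protection_and_energy()` computes $P = k_{rc}/k_{obs}$ and
$\Delta G_{op} = RT \ln P$ with $R = 1.987\times10^{-3}$ kcal/(mol K)
and a default $T = 300$ K (the experiment temperature; exposed as an
argument).  `classify_regime()` compares the rate ratio across a pH pair
with both limiting predictions (1 for EX1, $10^{\Delta pH}$ for EX2)
inside a multiplicative band of total width 3 — i.e. within $\sqrt 3$
either side — which cleanly separates the two limits for
$\Delta pH \approx 1$; anything matching neither (or both) is
`undetermined`.

One deliberate red test: the shipped 47-row reference table is checked
for internal thermodynamic consistency ($RT\ln P$ against the printed
$\Delta G_{op}$, ±0.1 kcal/mol at 300 K).  One row (Ser21) deviates by
0.118 kcal/mol; 46 of 47 agree within 0.05.  The discrepancy is in the
source table itself, so the test is left failing rather than widened.

## 15N relaxation and the model-free analysis

The forward model assumes a single isotropic global tumbling time
$\tau_c$, an axially symmetric 15N shielding tensor with
$\Delta\sigma = -160$ ppm, and $r_{NH} = 1.02$ Å.  With the
Lipari–Szabo spectral density
$$J(\omega) = \tfrac25\Big[\frac{S^2\tau_c}{1+(\omega\tau_c)^2}
 + \frac{(1-S^2)\tau}{1+(\omega\tau)^2}\Big],\qquad
 \tau^{-1}=\tau_c^{-1}+\tau_e^{-1},$$
`forward_rates()` assembles R1, R2, the steady-state NOE and the
CSA/DD cross-correlated rates from the standard dipolar + CSA
expressions.  Two sign conventions matter and are kept explicit:
$\gamma_N < 0$, so NOE values below one (and negative, for mobile
residues) are representable; and the zero-/double-quantum frequencies
use the *signed* $\omega_N$, so $|\omega_H+\omega_N| \approx 0.90\,
\omega_H$ — this is precisely what makes the conventional
$J(0.87\omega_H)$ high-frequency lumping of reduced spectral-density
mapping internally consistent (the package's mapping reproduces the
analytic $J$ to well under the documented 3% for
$\tau_c \in [4, 12]$ ns).  The dipole–CSA angle for the $\eta$ rates
defaults to 17° and is configurable; the data analysed here do not
constrain it.

`fit_model_free()` is a two-stage inversion: stage 1 profiles $\tau_c$
on a 2–15 ns grid at 0.05 ns resolution (evaluated coarse-to-fine for
speed: a 0.25 ns sweep locates the basin, the 0.05 ns points inside it
are then evaluated exactly as a full sweep would), with per-residue
$(S^2, \tau_e)$ re-optimised at every grid point and warm-started along
the grid; ties break toward smaller $\tau_c$ and a golden-section search
polishes the optimum.  Stage 2 refits per-residue parameters at the
fixed $\tau_c$ and, optionally, bootstraps 90% confidence intervals from
Gaussian noise replicates (5th/95th percentiles; `n_mc = 500` by
default, seeded).  A single model per residue is fitted — no five-model
selection — matching how compact, well-ordered proteins are usually
reported.  Two numerical safeguards: $\tau_e$ is capped at 1 ns because
the $(S^2\to 0,\ \tau_e\to\infty)$ ridge is observationally equivalent
to rigid tumbling and otherwise traps the optimiser; and fits that end
on the $S^2$ bound or above a small objective threshold are restarted
from neutral starting points.  Residues with negative NOE are
auto-excluded (their dynamics are outside this parameterisation), as are
caller-listed outliers.

`detect_exchange()` exploits the fact that across residues sharing the
global tumbling, R2 is essentially an affine function of the
exchange-free $\eta_{xy}$; a robust Theil–Sen line defines the
consensus, and residues with positive residuals beyond 2 robust SDs are
flagged.  A uniform exchange contribution is absorbed into the intercept
and cannot be detected residue-by-residue; the intercept is therefore
compared with the theoretical exchange-free value at the
R2/R1-implied $\tau_c$, and a >10%-of-R2 excess raises an explicit
global-offset warning.

`empirical_tauc()` implements the empirical size/temperature correlation
$\tau_c = (9.18\times10^{-3}/T)\,e^{2416/T} N^{0.93}$ ns, which gives
8.5 ns for $N = 124$ at 300 K.

## Two-state urea unfolding

In slow exchange the native cross-peak intensity tracks the native
population, so per-residue intensities normalised to the 0 M point are
fitted with
$f_N(c) = \big[1 + e^{-(\Delta G_{H_2O} - m c)/RT}\big]^{-1}$ and
$C_{1/2} = \Delta G_{H_2O}/m$.  No sloping baselines are fitted (the
inputs are normalised intensities); $T$ defaults to 300 K.  Data that
never cross the transition raise an `unbracketed` error instead of
extrapolating.  `aggregate_midpoints()` reports the unweighted cohort
mean and SD, flags dispersion above 10% of the mean, and lists >2 SD
outliers.  The two-state adequacy diagnostic is exercised in the tests:
a synthetic cohort with a hidden intermediate fits "successfully" but
leaves residuals several times the noise floor — the signature that
would contradict a two-state claim.  Chemical-shift perturbations use
the community weighting $\sqrt{\Delta\delta_H^2 + (0.154\,
\Delta\delta_N)^2}$; the 0.154 nitrogen scale is an interpretation (the
underlying report gives only a raw 0.1 ppm cutoff), and both it and the
threshold are arguments.

## Paramagnetic (TEMPOL) accessibility

The soluble nitroxide TEMPOL attenuates the amide cross peaks of
probe-accessible residues.  Because diamagnetic and paramagnetic spectra
carry arbitrary acquisition gains, volumes are first autoscaled —
$\upsilon_i = V_i/\overline V$, mean exactly 1 per spectrum (a median
variant is provided) — and attenuations are
$A_i = \upsilon^d_i/\upsilon^p_i$.  These definitions are
reconstructions: the source's displayed formulas are not recoverable
from the text, but this pair reproduces every stated behaviour (profile
centred near 1, observed range ~0.4–2.0, larger = more attenuated, and
invariance to independent spectrum gains, which the tests assert to
machine precision).  Hot spots default to $A_i > 1.7$; a 10% volume
error propagates to $A_i$ as $A\sqrt2\cdot 10\%$.  Zero paramagnetic
volumes are censored-high, not averaged.

## Trajectory observables

All analyses take a topology plus frames (multi-model PDB or in-memory
arrays); running the simulation itself is out of scope, and a toy
generator provides inputs.  RMSF superposes every frame on a reference
(Kabsch SVD; collinear selections are rejected) before computing
fluctuations.  Hydrogen bonds use 3.5 Å donor–acceptor distance and a
75° angular cutoff interpreted as the maximum deviation of the D–H···A
angle from linearity (accept when the angle at H is ≥ 105°); the
acceptor-centred `adh` convention is available as a switch, and both are
validated against a brute-force per-frame oracle.  The "percentage
lifetime" is the fraction of frames in which at least one acceptor
satisfies both criteria, and `1 − lifetime/100` feeds the TEMPOL
correlation as hydrogen-bond freedom.

The hydration grid bins water-oxygen positions (default 0.5 Å voxels)
after superposition, keeps observations within 8 Å of the protein
surface (distance to the nearest heavy atom minus its van der Waals
radius), and normalises by the mean count over bulk voxels (6–8 Å
shell).  Two numerical details: the grid origin is snapped to an
absolute lattice so voxel boundaries are reproducible and the binning is
exactly equivariant under axis-aligned rigid motions by lattice
multiples; and the bulk mean uses only voxels fully inside the counted
region, because voxels straddling the 8 Å truncation undercount and
would bias the normalisation low.  Hydration sites (MDHS) are
first-shell 26-neighbourhood local maxima at ≥2× bulk density; the 2×
factor is a documented choice (no persistence filtering), and with
sparse toy statistics individual 1-count voxels can qualify — the tests
therefore establish site detection with a pinned water and flatness with
long, dense uniform sampling, not MDHS counts on short trajectories.

Atom depth uses a probe sphere (8 Å) centred on each target atom; the
solvent-exposed volume is estimated by deterministic voxel quadrature
(0.5 Å) excluding voxels inside any atom's van der Waals sphere, and the
index is normalised so an isolated atom scores exactly 2:
$D_i = 2 V_{exposed}/V_{exposed}^{isolated}$.  This normalisation choice
(rather than dividing by the raw probe volume) pins the stated isolated
limit exactly and keeps $D_i \in [0, 2]$ monotone under crowding; it
agrees with a Monte-Carlo volume oracle to well under 1%.

## Synthetic data: what a green test establishes

The generators emulate the *statistical structure* the analyses assume,
with the measured regime as defaults: exchange rates log-uniform over
0.003–2.2 hr⁻¹, an isotropic 7.9 ns tumbler with $S^2$ from a truncated
normal (0.90 ± 0.07) and optional planted flexible dips or Rex, urea
cohorts with a 4.2 M midpoint and $m = 1.2$ kcal/(mol M) on a 0–7 M
grid, lognormal volume pairs with independent spectrum gains and exact
×2 hot spots, and jittered-template trajectories with exact planted
hydrogen-bond occupancies and a pinned hydration site.  Noise defaults:
2% fractional for relaxation, 5% for intensities and volumes (10% error
assumed for paramagnetic volumes).  They do not emulate spectral
overlap, peak-picking errors, baseline distortions, correlated noise,
anisotropic diffusion, or physically realistic water dynamics — so green
round-trip tests establish the correctness and calibration of the
estimators under their own assumptions, not the reproduction of any
experimental per-residue profile (raw spectra for those were never
deposited; the tests say so explicitly where it matters).

## Open design points resolved here

- Peak *heights* versus *volumes*: both are accepted anywhere an
  intensity is consumed; the column label is carried through, never
  interpreted.
- EX1/EX2 band semantics follow the worked example (total width 3)
  rather than the looser "factor of 3 each side" phrasing, since only
  the former classifies the example's intermediate ratio as
  undetermined.
- Missing errors default to 2% (relaxation rates) and 5% (volumes,
  intensities) of the value and are recorded in the output metadata.
- The model-free grid tie-break (smallest $\tau_c$), the closed lower
  bounds of the protection classes (`P = 1e4` is "mid"), and the 17°
  dipole–CSA angle are conventions chosen once and documented.

## Known limitations

Single-field model-free fits only (no anisotropic diffusion tensor, no
multi-field joint fits); no native-state HX under denaturant; no
back-exchange correction; the CLI `report` subcommand is a thin wrapper
and the full dossier assembly is an R-level API; hydration analysis
assumes orthorhombic (or absent) periodic boxes and superposable frames.
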