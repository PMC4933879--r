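---
title: "Models and methods: binding kinetics and structural comparison of affinity-matured repeat-protein binders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darpkin)
```

darpkin quantifies protein–protein binding the way an affinity-maturation
study of a DARPin (designed ankyrin repeat protein) against tubulin is
analysed: equilibrium titrations and stopped-flow kinetics read out by a
conjugated fluorophore, orthogonal surface plasmon resonance (SPR)
kinetics, ELISA-based off-rate ranking, comparison of the crystal
structures of the free and bound binder, and limited-proteolysis mass
assignment. This vignette records the models, their assumptions, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

All internal computation uses SI units — mol/L for concentrations, seconds
for time — and converts to the conventional reporting units (nM, s⁻¹,
M⁻¹s⁻¹, Å, Å², degrees) only at input and output, via `to_nM()` /
`from_nM()`. This removes the most common class of silent errors in
multi-module kinetics code.

## The 1:1 binding scheme and its three read-outs

Everything rests on the mass-action scheme A + B ⇌ AB with association
rate constant $k_{on}$ (M⁻¹s⁻¹) and dissociation rate constant $k_{off}$
(s⁻¹); the equilibrium dissociation constant is $K_D = k_{off}/k_{on}$.

**Equilibrium titration (tight-binding isotherm).** A fixed concentration
$D^*$ of labelled probe is titrated with ligand at total concentration
$T$. Because the probe (15–100 nM here) is comparable to or above $K_D$,
free and total ligand differ, and the bound fraction is the root of the
equilibrium quadratic:

$$\Delta F = F_{max}\,\frac{(K_D + T + D^*) - \sqrt{(K_D + T + D^*)^2 -
4\,T\,D^*}}{2\,D^*}$$

implemented in `isotherm_response()`. In the limit $D^* \ll K_D$ it
reduces to the hyperbola $F_{max}T/(K_D+T)$; the package tests verify both
this limit and agreement with an independent root-bracketing solution of
the equilibrium.

**Chase dissociation.** Pre-formed labelled complex is mixed with a large
excess of unlabelled competitor. Rebinding of the labelled probe is then
negligible and the signal decays mono-exponentially with observed rate
equal to $k_{off}$. The chase is taken at saturating competitor; no
extrapolation in competitor concentration is attempted, because under the
protocol modelled here the observed rate is already concentration
independent.

**Pseudo-first-order association.** With ligand in at least five-fold
excess over the probe, association is effectively first order with
$k_{obs} = k_{on}[T] + k_{off}$; the slope of $k_{obs}$ against $[T]$
(weighted least squares when per-trace standard errors are available) is
$k_{on}$. The intercept estimates $k_{off}$ too, but poorly; it is
reported only as a consistency note against the chase value, never
averaged into it. `sim_association_series()` warns below 5× excess and
refuses below 2×, where the approximation is meaningless.

**SPR (1:1 Langmuir).** Under flow, the free analyte concentration $C$ at
the sensor surface is constant, so occupancy follows
$R(t) = R_{eq}(1-e^{-(k_{on}C+k_{off})t})$ during injection, with
$R_{eq} = R_{max}C/(C + K_D)$, and decays as $e^{-k_{off}t}$ during the
wash. `fit_langmuir()` fits these closed forms — no ODE in the inner loop
— in a global mode (one $k_{on}, k_{off}, R_{max}$ shared across the
concentration series, one constant baseline offset per curve) and a
per-curve mode. Bulk refractive-index jumps, drift, and mass-transport
limitation are deliberately not modelled. The plateau analysis
(`extract_plateaus()` + `plateau_kd()`) is the equilibrium fallback for
data where the kinetic fit is poor: "plateau" is operationalised as the
mean response over the last 10 % of the association window, flagged when
the curve still rises by more than 1 % across that stretch.

## The ODE oracle

`ode_binding()` integrates the exact scheme
$d[AB]/dt = k_{on}[A][B] - k_{off}[AB]$ with `deSolve::lsoda`, relative
tolerance $10^{-9}$ and an absolute tolerance of
$\min(10^{-12}\,\mathrm{M},\ 10^{-9}\times$ smallest species total$)$ — the
scaling keeps the oracle sharper than every closed form it validates even
for sub-nanomolar systems, where a fixed $10^{-12}$ M floor would dominate
the solution. The oracle is used only in tests and validation: the
depletion isotherm must match its steady state, the Langmuir forms must
match it under the constant-ligand condition, and mono-exponential fits of
its association traces must return $k_{obs}$ within the pseudo-first-order
prediction. It is the package's brute-force standard, not a fitting
engine.

## Fitting: optimisation, uncertainty, degeneracies

All nonlinear fits use Levenberg–Marquardt damped least squares
(`minpack.lm`), unweighted in the residuals (the synthetic noise model is
homoscedastic Gaussian, and the experiments modelled here are analysed the
same way). Specifics worth recording:

* **Titration multi-start.** In the tight-binding regime
  ($D^* \gg K_D$) the isotherm is nearly piecewise linear and the
  likelihood in $K_D$ is flat; a single bad start silently lands in a
  local minimum. `fit_titration()` therefore starts from a crossing-point
  heuristic (ligand concentration at half-saturation minus $D^*/2$, the
  depletion correction) and from 0.1× and 10× that value, keeping the best
  converged result.
* **Exponential initialisation.** `fit_monoexponential()` initialises from
  a log-linear regression of the baseline-subtracted signal, which makes
  the refinement start within a few percent of the optimum for clean
  traces. A fitted amplitude below 3× the residual rms raises a "no
  transition" error rather than returning a meaningless rate; traces
  shorter than two half-lives of the fitted transition are flagged.
* **Positivity.** The Langmuir engine optimises $\log k_{on}$,
  $\log k_{off}$, $\log R_{max}$, which enforces positivity without active
  box constraints and makes the standard errors multiplicative (delta
  method back to the natural scale).
* **Uncertainty.** Default standard errors are asymptotic
  (covariance-based). `confint()` methods build Wald intervals with
  Student-t quantiles at the fit's residual degrees of freedom — with a
  five-point $k_{obs}$ line the normal quantile under-covers noticeably
  (≈78 % observed instead of 95 %), while the t-based interval restores
  nominal behaviour. A seeded residual-resampling bootstrap (500 refits by
  default) is available behind `bootstrap = TRUE` for the fluorescence
  fits; it is an adjunct, not the default, because the asymptotic errors
  are what the modelled analyses report.
* **Degenerate inputs.** An all-zero titration returns an object with
  `converged = FALSE` instead of raising; a flat sensorgram set and a
  plateau series linear in concentration (no curvature ⇒ $K_D$ above the
  tested range) raise explicit errors.
* **Floating point.** The isotherm discriminant
  $(K_D+T+D^*)^2 - 4TD^*$ is mathematically $\ge K_D^2 > 0$ but can round
  below zero at stoichiometric points when $K_D$ is tiny; it is clamped at
  0 when within $10^{-12}$ relative of zero.

The titration/kinetic cross-check (`kd_consistency()`) calls two $K_D$
estimates concordant when their max/min ratio is at most 2 — about the
reproducibility of such constants across methods and preparations.

## Structural comparison

`read_structure()` parses PDB-format files through `bio3d::read.pdb` and
then applies this package's policies: alternate locations collapse to the
highest-occupancy conformer (ties broken alphabetically, discards
counted), waters and heteroatoms are flagged and excluded from geometry,
hydrogens are ignored throughout (crystal structures at the relevant
resolutions do not include them).

* **Superposition** (`superpose()`) is a Kabsch SVD fit on Cα atoms paired
  by author residue numbering; unmatched residues are dropped and counted,
  which is how structures with differently modelled regions (a disordered
  cap, for instance) are compared without manual alignment. The
  reflection case is corrected to a proper rotation. The **motif
  rotation** (`motif_rotation()`) superposes on a reference selection
  (e.g. N-cap plus internal repeats, residues ≤ 149), applies that
  transform, then superposes the motif alone; the rotation angle of the
  second fit, $\arccos((\mathrm{tr}R - 1)/2)$, is the single number quoted
  for a domain motion, with the axis also reported. The default boundary
  between "body" and "cap" (residue 149) follows the subtilisin-cleavage
  boundary of this scaffold and is overridable through selections.
* **Interfaces and clashes** use all heavy atoms and a cell-list
  neighbour search that is property-tested equal to the all-pairs scan; a
  residue is an interface residue if any heavy atom is within the cutoff
  (4 Å default) of the other side. `count_close_contacts()` enumerates
  sub-threshold pairs (2 Å is the conventional "severe clash" reading for
  a docked, unrelaxed model).
* **SASA** (`compute_sasa()`) is Shrake–Rupley with a deterministic
  Fibonacci point shell (960 points/atom default, probe 1.4 Å) and a
  Bondi-style radius set (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å,
  fallback 1.70 with a warning). Determinism matters: buried surface area
  $BSA = SASA(A)+SASA(B)-SASA(AB)$ involves cancellation of large totals,
  and a stochastic point set would make regression testing tolerance
  games. The implementation is checked against an independent
  latitude–longitude quadrature oracle and the analytic isolated-sphere
  value ($4\pi(1.7+1.4)^2 = 120.76$ Å² for carbon).
* **B-factor means** are occupancy-weighted arithmetic means over a
  selection; because it is unstated whether published per-region means use
  all atoms or Cα only, both are a selection away (`atoms = "heavy"` vs
  `atoms = "CA"`).

The deposited entries for this system (4DRX, 4DUI, 5EYL, 5EYP) are
megabyte-scale and are not shipped; `load_deposited_structures()` reads
user-supplied local copies (`options(darpkin.pdb_dir=)` or
`DARPKIN_PDB_DIR`) and the acceptance suite runs the full crystallographic
comparison when they are present.

## ELISA ranking and fragment masses

The off-rate ELISA classifier uses the three published bands of
variant-to-parent signal ratio under competitor conditions: low < 2,
medium 3–6, high ≥ 8. The bands do not tile the line; ratios in [2, 3) or
(6, 8) are returned as `indeterminate` rather than forced into a
neighbour, because visual assignment of borderline wells is not an
algorithm. Buffer-condition ratios, which differentiate binders far less,
are carried as auxiliary output only.

`fragment_mass()` uses average (not monoisotopic) residue masses to
0.01 Da plus one water per fragment — appropriate for ESI-MS of intact
~16 kDa species. `match_fragments()` scans all contiguous fragments
exhaustively (prefix sums; ~14 000 candidates for a 169-mer) with a 2 Da
default tolerance: wide enough to absorb table rounding, narrow enough to
keep the single-alanine (71.08 Da) discrimination that the cleavage-site
assignment rests on. The bundled fixture
(`inst/extdata/synthetic_darpin_tm3_like.fasta`) is a **synthetic**
DARPin-like construct — the true evolved-variant sequence is not
redistributable from here — engineered so the assignment logic is exactly
reproducible: residue 149 is alanine, fragment 1–149 has mass ≈ 15.8 kDa,
fragment 11–160 matches 1–148 within 0.03 Da, and no other contiguous
fragment matches either observed mass within tolerance.

## The synthetic-data generator

Every generator is a pure function of its parameters and an integer seed,
with per-generator derived RNG streams (adding a generator never shifts
another's draws), and noise-free output lies exactly on the corresponding
model evaluator. The noise model is i.i.d. Gaussian on the signal — no
baseline drift, photobleaching, stopped-flow dead time, bulk-shift jumps,
or plate-position effects. That is a deliberate match to the unweighted
least-squares analyses being tested: parameter-recovery results stay
interpretable (any bias is the estimator's, not an artifact model's), at
the price that passing tests say nothing about robustness to instrument
artifacts in real data.

Default designs: titrations use 12 log-spaced ligand concentrations from
$D^*/10$ to $\max(20K_D, 5D^*)$ (covering depletion and saturation; the
actual spacing used in the modelled experiments is unpublished, so this is
a repository choice); association series default to 5× to 80× probe
excess; sensorgram sets use five concentrations spanning $K_D/4$ to
$4K_D$, the usual design centred on the expected $K_D$.

The toy complex (`sim_toy_complex()`) is a fully specified two-chain
miniature of the cap-rotation problem: a receptor chain, a binder whose
C-terminal cap sits on a circle of radius 5 Å about a recorded axis, an
exact designed rotation between "free" and "complexed" states, a designed
number of sub-2 Å receptor–cap contacts in the unrotated state (relieved
by rotations above ≈ 19°), and designed interface pairs at an exact
distance. Every geometric operation in the package can therefore be tested
against a constructed truth rather than a reference implementation.

## Problem sizes and reproducibility

The recovery studies use 200 seeded replicates per variant at 1 % noise —
enough for a ±3 % standard error on a coverage proportion while keeping
the whole suite interactive. The neighbour-search equivalence property
runs 100 random configurations; SASA oracles run on one- and two-atom
systems where quadrature is exact to the stated tolerance. Pipeline
reports embed the config hash, the seed, and the package version, and
identical inputs reproduce bit-identical reports.

## Known limitations

* One-site, rigid 1:1 binding only: no cooperative, multi-site, or
  conformational-selection schemes, and no mass-transport or two-state SPR
  models. Where the modelled system deviates (the parent binder's SPR fit
  is known to be imperfect), this package reports the misfit, it does not
  add parameters.
* The structural module compares deposited conformers; it does not do
  crystallographic symmetry expansion (lattice-packing clashes are out of
  scope), mmCIF parsing, or electrostatics.
* ELISA signals are treated as endpoint absorbances; no kinetic modelling
  of the readout.
* The fragment-mass module assigns contiguous unmodified fragments;
  post-translational modifications and protease specificity are the
  caller's problem.
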