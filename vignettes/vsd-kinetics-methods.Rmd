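---
title: "Models and methods behind vsdkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vsdkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdkinetics)
```

# The problem

Voltage-sensing domains (VSDs) of voltage-gated cation channels convert
membrane depolarisation into conformational motion: the positively charged
S4 helix slides outward through the domain, its gating charges hopping
between fixed countercharges ("sliding helix" mechanism). The kinetics and
thermodynamics of that motion — which resting states exist, how deep their
basins are, how high the barriers between them stand — determine the
channel's activation kinetics and voltage dependence. `vsdkinetics`
implements the standard analysis chain that turns trajectory data into those
quantities:

1. featurisation of trajectory coordinates (e.g. S4 C-alpha positions),
2. time-lagged independent component analysis (tICA) to isolate the slow
   coordinates,
3. k-means microstates and a maximum-likelihood **reversible Markov state
   model** (MSM), validated by implied timescales and the
   Chapman–Kolmogorov test,
4. PCCA+ coarse-graining into metastable macrostates,
5. mean first passage times (MFPTs) and, through transition-state theory
   (TST), one-dimensional free-energy profiles with per-transition barriers,
6. state-resolved ion-pair and hydrogen-bond occupancy tables and the axial
   S4 displacement metric,
7. Boltzmann fits of voltage-clamp activation data.

Every stage is verifiable against synthetic inputs with planted ground
truth, generated by the package itself.

# The synthetic-data generators

## Metastable Langevin trajectories

`generate_langevin()` integrates overdamped (Brownian) Euler–Maruyama
dynamics

$$x_{t+1} = x_t - \frac{\Delta t}{\gamma}\nabla U(x_t)
  + \sqrt{2\,k_BT\,\Delta t/\gamma}\;\xi_t$$

on a sum-of-inverted-Gaussians potential (wells and barriers placed
directly, analytic gradient everywhere). This diffusive surrogate reproduces
the statistical structure the MSM stages consume — metastable basins,
Boltzmann-distributed populations, barrier-controlled passage times — without
any claim to reproduce molecular force fields or microsecond-scale absolute
times of a real VSD. Positions are in nm, energies in units of $k_BT$, and
the time unit is arbitrary; the pipeline maps one trajectory time unit to
`time_unit_seconds` (default 1 µs) only when converting rates to kJ/mol
barriers.

Two numerical choices matter:

* **Confinement.** Inverted Gaussians flatten at infinity, so an unconfined
  walker eventually leaves the well region and diffuses freely, destroying
  the stationarity of well-to-well kinetics. The `gaussian_wells` form
  therefore adds a flat-bottom harmonic wall (default spring constant
  50 kT/nm², radius = outermost well + 3 widths). The wall is symmetric
  about the well centroid and leaves relative well weights — hence all
  free-energy differences — untouched.
* **Step size.** The integrator warns when a single step exceeds ten times
  the narrowest well width; the bundled conditions use
  $\Delta t = 0.005$ with well curvature $\approx 22\,kT/\text{nm}^2$,
  i.e. $\Delta t\,\kappa/\gamma \approx 0.11$.

The default double-well study conditions are wells at $\pm 1$ nm, depth
4.5 kT, width 0.45 nm (barrier $\approx 3.7\,kT$), $k_BT = 1$, $\gamma = 1$,
$5\times10^6$ steps — enough for several hundred barrier crossings, so
counting statistics (not model error) dominate at the percent level.

## The sliding-helix fixture

`default_helix_spec()` builds a coarse VSD stand-in: five gating charges
(K0, R1–R4) on a mobile axial helix, four states whose anchors descend in
5.1 Å steps (total travel 15.3 Å, three helical turns; activated state
first), and three fixed countercharges chosen so that the planted contact
map realises the two canonical patterns: a charge-transfer-centre partner
contacted hand-over-hand in *every* state, one ENC partner contacted in the
activated plus two adjacent resting states (the kinetics-slowing pattern),
and one ENC partner contacted in the activated state *only* (the
voltage-dependence pattern). Geometry is validated at construction: with
zero jitter every planted contact must fall inside the 4.0 Å cutoff and no
unplanted pair may, otherwise the spec is rejected naming the offending
pair. Gaussian positional jitter emulates thermal spread.

What the fixture does **not** emulate: real side-chain geometry and
rotamers, helix rotation or 3₁₀ transitions, solvent and membrane, or
correlated motions — so passing contact tests demonstrates correctness of
the *detection and bookkeeping*, not force-field realism.

## Voltage-clamp sweeps

`generate_sweeps()` evaluates
$I = G_{max}(V - V_{rev})\,/\,(1 + e^{-(V - V_{1/2})/k})$
per voltage and replicate and adds i.i.d. Gaussian noise (the simplest noise
model consistent with pooled patch-clamp residuals; real recordings have
voltage-dependent and temporally correlated noise the generator does not
attempt).

# Estimators

## tICA

Covariances are estimated in symmetrised form ($C_\tau \leftarrow
(\hat C_\tau + \hat C_\tau^T)/2$, with $C_0$ averaged over both pair
endpoints), which guarantees a real spectrum; $C_0$ receives a ridge of
$10^{-6}\,\mathrm{tr}(C_0)/d$ by default. The generalised problem
$C_\tau v = \lambda C_0 v$ is solved through a Cholesky whitening of
$C_0$, giving $C_0$-orthonormal eigenvectors; signs are fixed by making the
largest-magnitude loading positive so runs are reproducible. Retained
components default to the smallest set reaching 95% cumulative kinetic
variance ($\sum \lambda_i^2$). Lagged pairs never straddle trajectory
boundaries.

## Microstates and the reversible MSM

k-means uses k-means++ seeding (best of `n_init` restarts by inertia,
deterministic under the seed); for very long inputs the centres are fitted
on an evenly spaced subsample of at most 2×10⁵ frames and all frames are
then assigned to the nearest centre. The microstate count defaults to 100 —
the conventional choice for this analysis — scaled down to
`min(100, n_frames/50)` for small inputs.

Transition counting is sliding-window. Estimation is restricted to the
largest strongly connected component of the count graph (the model is only
defined on a communicating set; retained state/count fractions are logged).
The reversible maximum-likelihood transition matrix comes from the standard
self-consistent fixed-point iteration on the flux variables
$x_{ij} = \pi_i T_{ij}$, run to a relative tolerance of $10^{-10}$
(at most $10^6$ sweeps). Every estimate must satisfy row-stochasticity to
$10^{-10}$ and detailed balance and stationarity to $10^{-8}$, or it is
rejected.

The Chapman–Kolmogorov test compares set-staying probabilities under
$T(\tau)^f$ with models re-estimated at $f\tau$, using a
trajectory-resampling bootstrap band (95%, 50 draws by default; a single
long trajectory is split into blocks first). "Pass" means the prediction
lies inside the band at every factor — the conventional reading of the test,
which has no canonical hard threshold.

## PCCA+

Memberships come from the dominant right eigenvectors via the inner-simplex
construction: successive farthest-point vertex selection with orthogonal
deflation, barycentric coordinates with respect to the selected vertices,
then feasibility restoration by clipping at zero and renormalising rows to
the simplex. We deliberately stop short of the subsequent crispness
optimisation found in some implementations: on the block-structured chains
that define metastability the plain inner-simplex solution is already exact
(verified down to couplings of $10^{-3}$), and it keeps the construction
deterministic and dependency-free. A warning is issued when
$\lambda_{n}\approx\lambda_{n+1}$ (no spectral gap), in which case the
macrostate count is weakly determined.

## MFPTs, their validation, and TST barriers

`mfpt()` solves the absorbing linear system
$(I - T_{\neg B})\,m = \tau\mathbf 1$ and averages over the source set with
stationary weights. `empirical_mfpt()` is the model-free counterpart: it
counts, for every observed visit to the source, the time to the next
observation of the target.

One subtlety deserves emphasis. An MSM at lag $\tau$ models the dynamics
*observed every $\tau$*; a first-touch count at full frame resolution also
counts sub-lag excursions that graze the macrostate boundary and return —
events below the model's time resolution. The validation therefore reads
the label sequence at the model's lag (`stride = lag`). With that
like-for-like definition the double-well MSM reproduces counted passage
times to within a few percent at every lag tested, while the
frame-resolution count is systematically shorter; both numbers are available
to the user through the `stride` argument.

Barriers invert the Eyring-type relation $k = (k_BT/h)\,K^\ddagger$,
$K^\ddagger = e^{-\Delta G^\ddagger/RT}$ (no transmission prefactor), with
rates taken as $1/\text{MFPT}$ between adjacent states along the activation
ordering; both directions are reported, since either convention appears in
the literature. Physical constants are CODATA 2018 values fixed in
`physical_constants()`; 300 K is the default temperature. State levels are
$G_A = -RT\ln\Pi_A$ shifted so the most populated state (the activated
state, under depolarised-condition data) sits at zero. Because TST inversion
of finite-sample MFPTs need not close the thermodynamic cycle exactly, the
profile carries a `cycle_residual` diagnostic rather than enforcing closure.

## Contacts and displacement

An ion pair exists in a frame when the minimum distance between side-chain
heavy atoms of a (+) and a (−) group is at or below the cutoff (default
4.0 Å — a conventional salt-bridge criterion; recorded on every table).
H-bonds use 3.5 Å and a 120° D–H…A angle, with a documented heavy-atom-only
mode for coarse fixtures without hydrogens. Occupancy is the within-state
frame fraction; rows are reported at or above 0.5 by default (a
"formed in this state" call), and an `atom_pairs` column counts simultaneous
atom-level contacts because one residue pair can contribute several.
Displacement is the difference of selection centroids projected on the
membrane normal (+z extracellular; negative = inward). Representative
structures are state medoids under selection RMSD with lowest-index
tie-breaking.

## Electrophysiology fits

Both printed curve forms (I–V and conductance–voltage Boltzmann) are fitted
by Levenberg–Marquardt least squares with data-derived starts and a small
restart grid. The conductance transform keeps the source convention
$G = (-I \cdot 1000)/(V_{rev} - V)$ verbatim, so fitted $G_{max}$ carries
the factor 1000 in its units. Per-cell fitting (fit each replicate, average
parameters) is the default, pooled fitting is available; on noise-free data
the two printed equations are algebraically linked and the package verifies
the identity to $10^{-6}$. Deactivation tails are summarised by a
single-exponential fit — a model-form choice of this package, flagged in its
output.

# Problem sizes and determinism

The bundled validation uses $5\times10^6$ Langevin steps (strided to
$10^6$ frames) for kinetics recovery, $3\times10^6$ steps per asymmetry
setting for thermodynamic recovery, 50-dimensional tICA oracle problems,
and 100 seeded replicates for the noise study of the activation fits —
sizes at which counting error sits well below the validation tolerances.
All randomness flows from explicit integer seeds (one global seed derives
per-stage seeds in the pipeline), and every generator returns bit-identical
output for identical seeds.

# Known limitations

* The Langevin surrogate is one- or two-dimensional and diffusive; it
  validates the statistical machinery, not molecular realism, and no
  quantitative match to µs–ms transition times of a real VSD is attempted.
* MSMs estimated from short seeded trajectories inherit whatever bias the
  seeding distribution carries; the package estimates a plain reversible
  MSM and does not reweight.
* PCCA+ without crispness optimisation can assign boundary microstates of
  strongly overlapping basins less sharply than optimised variants.
* The state ordering of a free-energy profile is user-supplied or inferred
  from a one-dimensional coordinate; assigning structural identities
  (resting 1…activated) to macrostates of real data remains the analyst's
  judgement.
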