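---
title: "The rWAIL water potential: model, engine, estimators and critical-phenomena analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rWAIL water potential: model, engine, estimators and critical-phenomena analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwail)
```

# The model

rWAIL is a four-site water potential derived entirely from first-principles
reference forces (adaptive force matching against coupled-cluster-quality
data, with the dispersion coefficient fixed separately from
symmetry-adapted perturbation theory).  It has no empirically adjusted
parameters.  The intermolecular energy between two molecules is

$$
U_{\text{inter}} \;=\; \sum_{i,j} \frac{q_i q_j}{r_{ij}}
\;+\; A_{\mathrm{OO}}\, e^{-\alpha r_{\mathrm{OO}}}
\;-\; \frac{C_{\mathrm{OO}}}{r_{\mathrm{OO}}^{6}}
\;+\; \sum_{\mathrm{M,H}} U_{\mathrm{HB}}(r_{\mathrm{MH}}),
$$

where the Coulomb sum runs over the charged sites (two hydrogens and the
massless M site per molecule; the oxygen is uncharged), the Born--Mayer
repulsion and the $r^{-6}$ dispersion act on the oxygen--oxygen distance,
and the hydrogen-bond wall

$$
U_{\mathrm{HB}}(r) \;=\;
\begin{cases}
A_4\,(r - r_c)^4, & r < r_c\\[2pt]
0, & r \ge r_c
\end{cases}
$$

acts on every intermolecular M--H pair.  Because the contact at $r_c$ is
quartic, $U_{\mathrm{HB}}$ is three-times continuously differentiable
there.  Its role is to counter the very strong short-range M--H Coulomb
attraction that the large site charges ($q_M = -1.3464\,e$) would
otherwise produce: the net effect is a physically shaped hydrogen bond.
A scan of the hydrogen-bonded dimer gives a minimum near
$-6.2$ kcal/mol at $r_{\mathrm{OO}} \approx 2.95$ Å (computed by
`pairEnergy()`; see the acceptance report), the expected magnitude for a
condensed-phase effective pair potential.

The M site is massless and carries the negative charge.  It is placed
from the *full* O--H bond vectors,

$$
\vec r_M = \vec r_O + a\left[(\vec r_{H1}-\vec r_O) +
                            (\vec r_{H2}-\vec r_O)\right],
\qquad a = 0.2,
$$

so in the flexible model the M position responds to the instantaneous
geometry.  The rule is linear with weights summing to one, which has two
convenient consequences: the force on M redistributes onto O/H1/H2 with
constant weights $(1-2a,\,a,\,a)$ preserving molecular force and torque
exactly, and the M site contributes to the pairwise virial without any
correction term.

## Variants

Three parameter sets are shipped (`loadParameters()`): the flexible model
and two rigid *ensemble-geometry* (EG) variants whose fixed bond length
and angle equal the thermal averages of the flexible model at a reference
temperature (`EG273`, `EG298`).  All intermolecular parameters are
identical across variants; only $r_e$, $\theta_e$ and the presence of
intramolecular terms differ.  `ensembleGeometry()` is the EG constructor:
it averages the OH and HH distances over a flexible trajectory and derives
the angle from the mean *distances*,
$\theta_e = 2\arcsin(\langle HH\rangle / 2\langle OH\rangle)$ — this is
not the same as the mean angle, and the distance-based definition is the
one used here.

## Intramolecular terms and the prefactor convention

The flexible variant uses quartic bonds and a harmonic angle,

$$
U_{\text{intra}} = \sum_{i=1,2}\left[
\tfrac{k_2}{2} d_i^2 + \tfrac{k_3}{3} d_i^3 + \tfrac{k_4}{4} d_i^4
\right] + \tfrac{k_\theta}{2}(\theta-\theta_e)^2,
\qquad d_i = r_i - r_e .
$$

The $1/n$ prefactor convention (the force along a bond is
$-(k_2 d + k_3 d^2 + k_4 d^3)$) is a genuine design decision: the
tabulated coefficients do not by themselves fix it.  We adopted it on
physical grounds and locked it with a regression test: under this
convention the curvature of the bond potential at $r_e$ equals $k_2 =
1263$ kcal/(mol Å$^2$), which matches the known OH-stretch force constant
(about 8.45 mdyn/Å $\approx$ 1216 kcal/(mol Å$^2$)), and the
Morse-consistency ratio $|V'''/V''| = 2|k_3|/k_2 \approx 2.55$ Å$^{-1}$
falls in the expected range for an OH bond.  The no-prefactor reading
would double the force constant and put the stretch frequency near
5200 cm$^{-1}$, which is unphysical.  The convention lives behind the
single exported constant `intraPrefactorConvention`.

# The engine

Internal units are kcal/mol, Å, ps, amu and $e$; the user-facing
`SystemState` uses the GRO conventions (nm, nm/ps).  SI conversions
happen only in the estimators and exporters, against the constants table
`physicalConstants` (CODATA 2018).

**Electrostatics.**  Plain Ewald summation is the reference path:
real-space erfc sum, reciprocal sum with per-axis mode limits and a
spherical $k$ cutoff, self term, and analytic subtraction of the three
intramolecular charge pairs.  The splitting parameter and mode limits are
tuned automatically from a single accuracy target (`ewaldParams(tol)`,
default $10^{-5}$): $\mathrm{erfc}(\alpha r_c) = \mathrm{tol}$ and
$k_{\mathrm{cut}} = 2\alpha\sqrt{-\ln \mathrm{tol}}$.  Conducting
("tin-foil") boundary conditions are used, as in every production Ewald
code.  Correctness is pinned by two oracles in the test suite: the
rocksalt lattice energy against an Evjen-weighted direct sum (agreement
to $10^{-5}$, reproducing the Madelung constant 1.7475646), and
invariance of the total energy under a factor-of-two change of the
splitting parameter.

**Cutoffs.**  The van der Waals terms use a molecule-based cutoff on the
minimum-image O--O distance: when a molecule pair is inside the cutoff,
*all* its site--site real-space terms are evaluated with one consistent
image shift, so molecules are never split across the minimum-image
convention and no charge group is ever truncated mid-molecule.  Bulk runs
apply the uniform-fluid tail corrections
$E_{\mathrm{tail}} = -2\pi N^2 C_{\mathrm{OO}}/(3 V r_c^3)$ and
$P_{\mathrm{tail}} = -4\pi \rho^2 C_{\mathrm{OO}}/(3 r_c^3)$ (the
exponential repulsion tail decays faster than any power and is
neglected); slab runs must disable them (`slabCutoff()`: 1.75 nm cutoff,
no corrections), since the formulas assume a homogeneous fluid.  One
subtlety is documented rather than hidden: with a *fixed* cutoff the
volume-derivative of the tail energy accounts for only half of
$P_{\mathrm{tail}}$; the other half comes from pairs crossing the cutoff
under compression, which a finite frozen configuration cannot show.  The
finite-difference pressure test therefore runs with corrections off,
where the virial and thermodynamic routes agree identically.

**Pair enumeration.**  The real-space loop is a brute-force
$O(N^2_{\mathrm{mol}})$ molecule-pair sweep with early distance
rejection.  At the desk scales this package targets (tens to a few
thousand molecules) the loop is not the bottleneck, and correctness — an
enumerable, oracle-checkable path — is the contract; a neighbor list
would add state without changing any result.

**Integrators.**  Velocity Verlet throughout.  NVT uses a Nosé--Hoover
thermostat (single chain, mass
$Q = N_f k_B T (\tau_T/2\pi)^2$), with relaxation defaults matching the
simulation protocols (2 ps for NPT, 5 ps for NVT).  NPT adds isotropic
cell dynamics: a piston variable with mass
$W = (N_f{+}3) k_B T (\tau_P/2\pi)^2$ driven by
$3V(P_{\mathrm{mol}} - P_0)$ and damped on the time scale $\tau_P$, with
*molecular* (center-of-mass) scaling so rigid geometries are never
strained, and no direct kinetic coupling (the thermostat absorbs the
adiabatic heating of compression).  The damping term is what makes the
piston settle instead of ringing indefinitely; the scheme is validated
against the ideal-gas equation of state (mean density within 2% of
$P/k_BT$) and the pressure setpoint.  It samples an approximate
isothermal--isobaric ensemble adequate for equilibration and desk-scale
property estimates; production claims about fluctuation-derived
quantities at supercooled conditions should use long runs and the block
errors the estimators report.

**Pressure.**  The pressure tensor uses the molecular (group-based)
route: center-of-mass kinetic term plus the molecular virial
$\Xi_{\mathrm{mol}} = \Xi_{\mathrm{atomic}} - \sum_i (\vec r_i - \vec
R_{\mathrm{com}}) \otimes \vec F_i$.  Constraint forces then never enter
(they are internal to a molecule), and the M-site contribution is exact
because the virtual-site rule is linear.  For bulk scalar pressure and
for the slab surface-tension anisotropy the molecular and atomic routes
have identical ensemble averages.

**Constraints.**  Rigid variants are maintained by iterative
SHAKE/RATTLE on the two OH distances and the HH distance (relative
tolerance $10^{-12}$ on squared lengths, bounded iterations with an
explicit non-convergence error).  The velocity projection preserves
linear and angular momentum to $10^{-10}$; a free rigid molecule
conserves kinetic energy to $10^{-12}$ relative over 10 ps at 2 fs.

**Determinism.**  The only stochastic element of a run is the initial
Maxwell--Boltzmann draw, controlled by a seed; identical seeds give
bit-identical trajectories on one platform.  The initializer rescales the
center-of-mass and internal velocity components *separately* to the
target temperature, so systems with weak rotation--translation coupling
(notably force-free surrogates) start from the correct equipartition
rather than from a sampling fluctuation that nothing would relax.

**Degenerate inputs.**  Oxygen--oxygen distances below 0.5 Å are an
error (the Born--Mayer plus $r^{-6}$ form diverges attractively at
contact; silently returning a huge negative energy would corrupt any
downstream minimization); collinear H--O--H geometries are allowed, only
coincident sites are rejected in the M-site rule.

# Property estimators

All estimators share the same conventions: an explicit equilibration
discard fraction (default 10% — the protocols rarely state equilibration
windows, so it is a visible parameter rather than a hidden choice), block
averaging with 10 blocks for every reported error bar (at least 5 blocks
are required for an error bar to be meaningful; shorter series warn), SI
conversion at the estimator boundary, and pure-function behavior.

* `kappaT()`: $\kappa_T = \langle \delta V^2\rangle / (k_B T \langle
  V\rangle)$ from NPT volume fluctuations, in MPa$^{-1}$.
* `heatCapacityFd()`: $C_p = (\langle H\rangle_{T_2} - \langle
  H\rangle_{T_1}) / (N\,\Delta T)$, protocol pair (295, 301) K.
* `deltaHVap()`: $\Delta H_{\mathrm{vap}} = \langle V_{\mathrm{gas}}
  \rangle - \langle V_{\mathrm{liq}}\rangle/N + RT + \Delta
  E_{\mathrm{self}}$, every term reported.  The self-energy term is the
  polarization cost of the condensed-phase dipole enhancement,
  $\Delta E_{\mathrm{self}} = -(\mu_{\mathrm{model}} -
  \mu_{\mathrm{gas}})^2/(2\alpha_{\mathrm{pol}})$ with gas-phase monomer
  defaults ($\mu_{\mathrm{gas}} = 1.855$ D, $\alpha_{\mathrm{pol}} =
  1.47$ Å$^3$); it is computed by its own function (`deltaESelf()`) and
  reported separately so the convention is auditable.  The approximately
  $-6$ kJ/mol nuclear-quantum correction known from path-integral work is
  attached as an annotation, never applied.
* `dielectricConstant()`: fluctuation--dissipation route
  $\varepsilon_{\mathrm{raw}} = 1 + \langle \delta M^2\rangle/(3
  \varepsilon_0 V k_B T)$, then the electronic-continuum scaling
  $\varepsilon = \varepsilon_\infty\,\varepsilon_{\mathrm{raw}}$ with
  $\varepsilon_\infty = 1.78$.  A multiplicative scaling was adopted
  (the electronic-continuum view of nonpolarizable models); since the
  choice is debatable, **both** raw and scaled values are always
  reported.
* `diffusionEinstein()`: $D = $ slope(MSD)$/6$ over a window excluding
  the ballistic regime; the error bar comes from the dispersion of
  independent per-particle slopes (pooled-MSD residuals are strongly
  correlated and would understate it); a significant quadratic term
  flags a non-diffusive (drifting) regime; wrapped input is rejected.
  The +15% nuclear-quantum annotation is reported, never applied.
* `surfaceTension()`: $\gamma = (L_Z/2)\left[\langle P_Z\rangle -
  (\langle P_X\rangle + \langle P_Y\rangle)/2\right]$, the factor 1/2
  for the two interfaces of a periodic slab, converted from bar nm to
  mN/m.
* `rdfCalc()`: site--site $g(r)$ normalized to the uniform fluid, with
  intramolecular pairs excluded.

Each estimator is tested against synthetic series whose moments were
chosen by *inverting the estimator's own formula at generation time*
(`synthSeries()`), across 20 seeded replicates, within 3 standard errors.

# Critical-phenomena analysis

* **Coexistence densities** (`slabPhaseDensities()`): plateau means of a
  slab density profile, with an explicit interface-exclusion half-width;
  uniform profiles (coexistence lost) are an error, not a number.
* **Wegner expansion** (`wegnerFit()`):
  $\rho_l - \rho_v = B_0 \tau^{\beta}(1 + B_1 \tau^{\Delta})$ with the 3D
  Ising exponents fixed ($\beta = 0.325$, $\Delta = 0.5$),
  $\tau = 1 - T/T_c$; amplitudes and $T_c$ free; the number of correction
  amplitudes is a knob (default 1, a parsimonious truncation) and is
  echoed in the result.
* **Singular diameter** (`criticalDensityFit()`):
  $(\rho_l+\rho_v)/2 = \rho_c + a_1 \tau^{1-\alpha'} + a_2 \tau$ with
  $\alpha' = 0.11$ fixed and $T_c$ supplied; linear in its free
  parameters, solved exactly.
* **Antoine** (`antoineFit()`): least squares on $\ln P$ of
  $\ln P = A - B/(T+C)$; $P_c$ is the fitted form evaluated at $T_c$.
* **Extended IAPWS correlation** (`iapwsEFit()`):
  $$\gamma(T) = B\,\tau^{\mu}(1 + b\tau) + \gamma_s\,
  e^{\,c\,(T_e - T)}, \qquad \mu = 11/9,\ \gamma_s = 1\ \mathrm{mN/m},$$
  weighted nonlinear least squares with $T_c$ *fixed* from the
  coexistence analysis (never fitted here).  The parameterization fits
  $(B, b, c, T_e)$ directly: by construction the deviation from the
  classical term equals $\gamma_s$ at $T = T_e$, which makes $T_e$ the
  *emergence temperature* of the exponential low-temperature component.
  The fit demands supercooled points (otherwise $T_e$ is unidentifiable
  and the call errors), is invariant to point order and uniform weight
  rescaling, and flags the null case (no detectable emergence component)
  instead of reporting a meaningless $T_e$.
* **LLCP localization** (`locateLLCP()`): each isobar of a $(T,P)$ grid
  is classified as *discontinuous* (a density jump between adjacent
  temperatures exceeding 5$\times$ the pooled block error — a
  conservative threshold against supercooled noise), *continuous* (an
  interior $\kappa_T$ maximum, i.e. a Widom-line crossing) or
  *featureless*.  The critical point is bracketed between the adjacent
  continuous and discontinuous isobars; the temperature estimate is the
  midpoint between the Widom-peak temperature on the continuous side and
  the jump temperature on the discontinuous side (the true critical
  temperature lies between the binodal end and the Widom line), the
  density is the average of the jump midpoint and the continuous-side
  value, and the reported uncertainties are never smaller than the grid
  spacing.  All-continuous or all-discontinuous grids return "not
  bracketed" — never a fabricated point.  The locator is validated
  against a van-der-Waals-type equation of state with water-like
  constants, whose critical point is known analytically.
* **Melting point** (`meltingPointThreePhase()`): protocol driver for the
  NVE three-phase (ice/liquid/vapor) method — evolve the coexistence cell
  from bracketing initial temperatures, classify the end state, bisect.
  The end-state classifier uses the Errington--Debenedetti tetrahedral
  order parameter averaged over molecules (ice $\bar q \gtrsim 0.8$,
  ambient liquid $\approx 0.5$); ambiguous end states widen the bracket
  and are flagged rather than silently resolved.

**Optimizer.**  All nonlinear fits go through one multistart
Levenberg--Marquardt driver (`minpack.lm`), 8 starts from a seeded Latin
hypercube plus one physics-informed start, convergence tolerances
$10^{-12}$; every seed is an argument.  Noiseless synthetic data are
recovered to $10^{-5}$ relative or better; 1%-noise recovery is
statistically unbiased across 20 seeds.

# Fixture generators and what they do (not) emulate

Every generator is a pure function of its parameters and a seed.

* `buildWaterBox()` places molecules on a jittered body-centered lattice
  with uniformly random orientations at the box size implied by the
  target density, guaranteeing a minimum O--O distance of 2.4 Å.  It is a
  *starting* configuration, not an equilibrated liquid: tests that need
  liquid structure equilibrate it first with a short thermostatted run.
* `buildSlab()` reproduces the production slab geometries (2139 molecules
  in 3.999 Ų $\times$ 10 nm, leaving a 6 nm vacuum; 1728/3.58 for the
  ambient protocol) and warns when the vacuum gap falls below twice the
  cutoff.
* `buildIceIh()` builds the lonsdaleite oxygen lattice of hexagonal ice
  in an orthorhombic supercell (standard lattice constants $a = 4.5$ Å,
  $c = 7.32$ Å, recorded in the metadata; density 0.932 g/cm$^3$) and
  assigns protons by a seeded stochastic repair sweep until the
  Bernal--Fowler rules hold (every oxygen donates exactly two hydrogens,
  every bond carries exactly one).  The ice rules are verified in the
  tests by an independent distance-graph check, not by the builder's own
  bookkeeping.  Hydrogens are placed along the accepted bonds at $r_e$,
  so molecular angles start tetrahedral; the constraint solver snaps them
  to the variant's geometry within the first steps of a rigid run.
* `synthSeries()` and `synthCurves()` generate stationary Gaussian /
  AR(1) / random-walk observables and closed-form analysis curves with
  the exact moments or parameters the target estimator inverts, shipping
  the ground truth alongside.  They deliberately do *not* emulate the
  full correlation structure, non-Gaussian tails or slow relaxation of
  real MD observables — so passing recovery tests demonstrates estimator
  correctness, not that a given production trajectory is long enough;
  the block errors exist precisely to carry that burden on real data.

# Problem sizes used by the shipped tests

The test and acceptance suites run entirely at desk scale, as a design
choice: force/energy consistency on 32-molecule boxes; energy
conservation on 216-molecule boxes over 10 ps at the protocol time steps
(0.5 fs flexible, 2 fs rigid); thermostat/barostat validation on 64--125
molecules; estimator recovery on synthetic series of $10^3$--$10^4$
samples with 20 replicates; fitter recovery on 8--17-point curves; the
LLCP locator on an analytic equation of state.  The headline production
numbers (melting points, supercooled surface tension and its emergence
temperature, the liquid--liquid critical point near 203 K and 90 MPa)
require multi-nanosecond trajectories of 343--2139 molecules; the
protocols are encoded as runnable scripts under `inst/experiments/`,
sized for a multicore node rather than for a test suite.

# Known limitations

* Orthorhombic boxes only; no triclinic cells, no constant-surface-tension
  ensembles, no mesh (PME) acceleration — plain Ewald is exact but
  $O(N^{3/2})$-ish at fixed accuracy, which is fine up to a few thousand
  molecules and deliberate beyond that.
* The NPT cell dynamics is a damped isotropic piston, not a
  measure-exact isothermal--isobaric integrator; means are validated,
  and long-run fluctuation quantities carry block errors for a reason.
* Water only: a single molecular topology (3 physical sites + 1 virtual
  site) is hard-wired through the engine.
* No finite-size scaling: critical-point estimates are single-box, as in
  the production protocols, and inherit their finite-size shifts.
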