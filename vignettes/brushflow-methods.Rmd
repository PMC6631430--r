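---
title: "Modelling electro-osmotic flow screening by grafted polymer coatings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electro-osmotic flow screening by grafted polymer coatings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brushflow)
library(dplyr)
```

## The physical problem

A nanoslit of width $w = 20$ nm carries a 1:1 electrolyte between two
positively charged walls (surface charge density
$\sigma_s = 3.28\times 10^{-2}$ C/m²). Both walls are grafted with
PEG-like polymer chains on a square lattice of constant $a = 2.5$ nm. An
electric field $E_{ext}$ applied along the slit drags the net double-layer
charge and drives an electro-osmotic flow (EOF), which the coating screens:
each polymer bead exerts a Stokes drag on the fluid. The central quantity
is the *effective hydrodynamic (Stokes) radius* of a bead, $a_{bead}$ —
the radius of an isolated sphere with the same drag. In coatings it is far
smaller than the physical bead radius $a_0 = 0.156$ nm, because
neighbouring beads shield each bead from the flow.

brushflow implements the continuum side of this problem and everything
needed to exercise it end to end on synthetic data:

1. a one-dimensional **Navier–Stokes–Brinkman (NSB)** solver for the flow
   profile $u(z)$;
2. **radius inference** — fitting $a_{bead}$ to an observed velocity
   profile, and extracting $a_{bead}(\theta)$ from drag tables through
   Stokes' law;
3. **coating-structure statistics** — non-normalized radial distribution
   functions, planar orientation distributions, exposed far-bead counts,
   gyration radii and their scaling;
4. an additive **far-bead shielding model** for $a_{bead}(N)$;
5. **synthetic-data generators** that stand in for particle simulations:
   grafted excluded-volume chains, Gouy–Chapman double layers, parametric
   bead-density profiles, pivot-algorithm self-avoiding walks, and
   forward-solved velocity profiles with optional noise.

## The Navier–Stokes–Brinkman model

The steady, unidirectional flow across the slit obeys

$$\frac{d}{dz}\,\mu(z)\frac{du}{dz}
  \;-\; 6\pi\,\mu(z)\,n(z)\,a_{bead}\,K(\phi(z))\,u(z)
  \;+\; \rho_e(z)\,E_{ext} \;=\; 0,$$

with $\mu(z)$ the fluid viscosity, $n(z)$ the bead number density,
$\phi(z) = \tfrac{4\pi}{3}a_0^3 n(z)$ the bead volume fraction,
$\rho_e(z) = F\sum_i z_i c_i(z)$ the ionic charge density (signed
valences $z_i$, Faraday constant $F$), and $K(\phi)$ a hindered-drag
correction. The three terms are the viscous stress, the distributed
Stokes drag of the coating, and the electric body force.

Model ingredients and the choices behind them:

* **Viscosity.** The Einstein dilute-suspension relation
  $\mu = \mu_0(1 + 2.5\phi)$, with bulk solvent viscosity
  $\mu_0 = 0.85\times10^{-3}$ Pa·s by default (water-like at 300 K;
  configurable). Position-resolved solvent-density corrections are out of
  scope.
* **Hindrance $K(\phi)$.** Pairwise hydrodynamic correlations increase the
  drag per bead above the isolated-sphere value. The default is the
  Kim–Russel fixed-bed expansion
  $K(\phi) = 1 + \tfrac{3}{\sqrt 2}\phi^{1/2} + \tfrac{135}{64}\phi\ln\phi
  + 16.456\,\phi$, which has the correct dilute limit $K(0)=1$ and
  increases over the physically admissible range $[0, 0.64]$. We place
  $K$ *multiplicatively on the drag* (drag enhancement), following
  hindered-settling conventions; a `"none"` model ($K \equiv 1$) gives the
  dilute limit. The correction matters little at the volume fractions of
  the default scenarios ($\phi \lesssim 0.04$) but is exposed for denser
  coatings.
* **Driving term.** The charge density uses signed valences: a neutral
  electrolyte must not drive flow, so $\rho_e = F\sum_i z_i c_i$, not
  $F\sum_i c_i$.
* **Boundary conditions.** No slip ($u = 0$) at the wall and mirror
  symmetry ($du/dz = 0$) at mid-slit. The hydrodynamic wall position is
  not knowable from continuum arguments alone, so the no-slip plane
  defaults to $z = 0$ (the innermost wall-layer centre) with a
  configurable offset.
* **Units.** Interfaces use the natural bench units — nm, mol/L, V/nm,
  Pa·s — and all internal arithmetic is SI; velocities are returned in
  m/s.

### Discretization

`solve_nsb()` uses conservative-flux second-order finite differences on a
uniform half-slit grid: fluxes $\mu_{i\pm1/2}(u_{i\pm1}-u_i)/h$ with
*harmonic-mean* interface viscosities, a ghost-point reflection for the
mid-slit symmetry row, and a tridiagonal sparse solve. The harmonic mean
is exact for viscosity jumps located on cell interfaces and agrees with
the arithmetic mean to second order for smooth profiles. The test suite
verifies (i) agreement with an exact transfer-matrix solution for
piecewise-constant coefficients to better than $10^{-4}$ relative
$L_\infty$ over randomized instances, (ii) fourth-ordered error reduction
per grid halving (i.e. second-order convergence), (iii) exact linearity in
$E_{ext}$, and (iv) the Helmholtz–Smoluchowski plateau
$u = -\varepsilon\varepsilon_0\zeta E_{ext}/\mu_0$ in the polymer-free,
thin-double-layer limit.

## Radius inference

`fit_abead()` treats $a_{bead}$ as the single adjustable parameter and
minimizes the unweighted $L_2$ mismatch between the NSB solution and an
observed velocity profile over the half-slit grid (Brent's bounded scalar
minimization on $[0, a_0]$). The mid-slit speed decreases monotonically in
$a_{bead}$, so the objective is well behaved; if no interior minimum
beats the bounds the boundary solution is returned and flagged. An
optional near-wall mask (off by default) excludes the first few tenths of
a nm, where particle simulations show layering artifacts that the
continuum model cannot represent.

`stokes_radius_from_drag()` converts measured drag forces on a bead to
radii via $a(\theta) = F(\theta) / (6\pi\mu v(\theta))$, with forces in
the MD convention kJ/(mol·nm) (conversion through Avogadro's number,
$N_A = 6.02214076\times10^{23}$). The drag forces themselves are
*inputs*: they come from particle-level simulation and enter as CSV
tables. A synthetic, qualitatively shaped table ships in
`inst/extdata/drag_table_synthetic.csv` for demonstrations; it is not
measured data.

`average_radius_over_orientation()` averages $a(\theta)$ over
$[0°, 90°]$ by trapezoidal quadrature. Because near-bead orientations in
coatings are observed to be homogeneous, the default weight is the
hemisphere measure $\sin\theta\,d\theta$ (uniform on the sphere);
a uniform-in-$\theta$ weight is selectable since either reading of
"averaged over $\theta$" is defensible, and the two differ by only a few
percent for smooth tables.

## Coating structure

* **Non-normalized RDF.** Pair-distance histograms are divided by the
  number of reference beads and the shell volume $4\pi r^2\Delta r$, but
  *not* by a bulk density — the bead distribution across a slit is
  strongly inhomogeneous, so a bulk normalization would be arbitrary. Of
  the two readings of "non-normalized" (per shell volume vs raw counts)
  we report counts per shell volume, which keeps peak positions and makes
  densities comparable across bin widths. The first peak sits at the bond
  length $b$, the second at the fixed next-nearest distance
  $2b\sin(54.75°) \approx 0.245$ nm; the coating becomes
  chain-length-dependent only beyond the near/far split $r_0 = 0.3$ nm.
* **Orientation distributions.** Neighbour directions at shell distance
  $r$ (default $b = 0.15$ nm) are kept when their out-of-plane offset is
  within a slab of half-width $0.5a_0$, projected into the $(x,z)$ or
  $(x,y)$ plane, and histogrammed by angle to the flow direction, folded
  to $[0°, 180°]$. Normalizing by the mean makes a structureless coating
  read $f \equiv 1$; for exactly isotropic directions the projected angle
  is uniform regardless of slab width, which the tests exploit.
* **Exposed far beads.** A far bead ($r > r_0$) contributes to shielding
  only with a clear line of sight: pair $(i,j)$ is *exposed* when no third
  bead lies within one bead diameter $d_{occ} = 2a_0$ of the open segment
  $ij$, with its perpendicular foot strictly between the endpoints.
  Endpoint grazing does not occlude. The implementation is checked
  against an exhaustive $O(n^3)$ oracle; under periodic images the
  criterion is applied only to pairs shorter than half the box, where the
  minimum-image segment is unambiguous. `exposed_far_beads()` averages
  the exposed counts over reference beads in a slab (default
  $z = 1 \pm 0.25$ nm) into $n_{far}(r)$.
* **Gyration scaling.** $\gamma$ is the least-squares slope of
  $\log R_g$ against $\log N$; replicates at one $N$ are averaged first.
  On noiseless power laws the estimate is exact to numerical precision.
  `classify_conformation()` applies the brush/mushroom rule: brush when
  $R_g$ exceeds the grafting separation, mushroom below, a crossover label
  at equality. With the package's calibrated model
  $R_g(N) = 2.5\,(N/14)^{0.65}$ nm the flip occurs at $N = 14$.

## The far-bead shielding model

Assuming far-bead contributions add independently,

$$a_{bead}(N) = a^{near}_{bead}
  - \int_0^{\pi/2}\! d\theta \int_0^{\infty}\! dr\,
    \bigl[a^{near}_{bead} - a_{bead}(r, \theta)\bigr]\,
    P_{far}(r, \theta; N),
  \qquad
  P_{far} = \tfrac12\, n_{far}(r; N)\,\sin\theta .$$

Here $a_{bead}(r,\theta)$ is the tabulated central-bead radius of a
three-bead complex flanked by two far beads (a *shielding kernel*), and
$a^{near}_{bead} \approx 0.18\,a_0$ is its saturation value when far beads
are absent. The kernel is particle-simulation data in real use (CSV
ingest); for testing, `parametric_kernel()` provides the family
$a(r,\theta) = a^{near}[1 - A e^{-(r - r_0)/\lambda} g(\theta)]$ with a
decreasing angular profile $g$, reproducing the qualitative saturation
with $r$ and the weaker effect of perpendicular far beads.

Numerical notes: the double integral is a trapezoid rule on the tabulated
$(r,\theta)$ grid ($\theta$ in radians); by construction the
$\theta$-integral of $P_{far}$ is $n_{far}/2$ — we keep the model's
normalization exactly as defined rather than rescaling it, and flag that a
total weight above 1 strains the additivity assumption (warning). Negative
outputs, possible for heavy far-bead loads, are clamped to zero with a
warning instead of erroring, since the model is explicitly approximate.
Partially occluded beads carry no fractional weight. `shielding_radius()`
reports, per orientation, the distance beyond which the kernel stays
within a tolerance of saturation — for the parametric family this
reproduces the closed-form inversion $r_s = r_0 + \lambda\ln(A g/\tau)$.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* the analysis chain
consumes, not the underlying molecular dynamics:

* **Grafted coatings.** Chains carry $3N + 2$ free beads (united-atom
  counting for a PEG chain of degree $N$ whose first two backbone beads
  anchor it), bond length $b = 0.15$ nm, fixed bond angle 109.5° with
  random dihedrals, and hard-core excluded volume of one bead diameter
  $2a_0$ between all bead pairs except those within two bonds along a
  chain, whose separations are fixed by the bond geometry at 0.15 and
  ≈0.245 nm. All chains grow concurrently, one bead per chain per sweep,
  so no early mushroom can smother an ungrown grafting site; dead ends
  trigger progressively deeper backtracking, and a genuinely overcrowded
  specification fails with an error naming the chain. Everything is
  reproducible from the seed.
* **Double layers.** Closed-form Gouy–Chapman profiles for the stated
  $\sigma_s$, superposed from both walls. With the default ionic strength
  $3.4\times10^{-2}$ mol/L the Debye length is 1.65 nm, six-fold smaller
  than the half slit, so superposition is accurate and the generated
  profiles are electroneutral to a few $10^{-5}$. The solver accepts any
  tabulated $c_i(z)$, so measured profiles can be substituted directly.
  (Quoted experimental ionic strengths for comparable PEG-coated systems
  range up to 0.56 M; the value is plain configuration.)
* **Bead densities.** Either binned from a configuration
  (bead-count-conserving) or parametric: the classical parabolic brush
  $n(z) = n_0(1 - (z/h)^2)$, or a Gaussian mushroom. Forward scenarios
  use the parabolic form with height $h = 2R_g(N)$ from the calibrated
  gyration model and amplitude $n_0 = 3\Gamma/2h$ conserving the grafted
  coverage $\Gamma = (3N + 2)/a^2$ per wall — at $N = 14$:
  $h = 5$ nm, $n_0 \approx 2.1$ nm⁻³, peak $\phi \approx 0.034$.
* **Velocity profiles.** Forward NSB solves with a planted $a_{bead}$
  plus i.i.d. Gaussian noise under the scenario seed (`noise_sd = 0`
  returns the solver output bit-identically).
* **Free chains.** A pivot-algorithm sampler for cubic-lattice
  self-avoiding walks (octahedral symmetries, hash-set overlap checks,
  samples every 10 accepted pivots after $10N$ accepted equilibration
  moves from a rod start), implemented in C++ for throughput. Chain
  lengths 50–400 with 2000 samples each give the self-avoiding gyration
  exponent $\approx 0.59$–0.60; disabling exclusion yields ideal walks
  with exponent 1/2. This is an *independent physics check* of the
  gyration machinery, not a model of grafted PEG, whose measured exponent
  (0.65) reflects chain stiffness and solvent interactions the lattice
  walk does not carry.

What passing tests on synthetic data do **not** show: agreement with any
particular molecular force field, wall-layering structure of a real
solvent, charge regulation, or coupling between ion distributions and the
flow (ion profiles are inputs, not solved for). The forward/inverse
round-trip demonstrates that the inference machinery is consistent, not
that a particular $a_{bead}$ value is physically correct.

Reference values quoted for this system vary slightly across reports and
are handled as configuration: the physical bead radius appears as both
0.156 nm and 0.153 nm (we default to 0.156 everywhere), and a grafting
density of 0.164 nm⁻² is mutually inconsistent with the 2.5 nm lattice
constant (0.16 nm⁻²); the lattice constant wins.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script use: 1601–2001 grid points
across the slit (solver truncation error $\sim 10^{-5}$ relative), 50
chains for structural statistics, 2000 pivot samples per chain length at
$N \le 400$, 20 replicate ensembles for exponent round-trips, and
$10^{-8}$ nm optimizer tolerance for the radius fit. These sizes keep the
whole suite under a minute on one core while leaving each statistical
check several standard errors of headroom; all of them are arguments, not
constants.

## Known limitations

* One-dimensional, steady, linear-response hydrodynamics only; no
  electrostatics–flow coupling, no time dependence.
* Several hindrance closures circulate in the soft-particle
  electrokinetics literature; we ship the Kim–Russel expression as the
  default and keep $K(\phi)$ pluggable so alternatives can be swapped in.
* The shielding kernel family is a fixture: real kernels must come from
  particle-level drag measurements.
* The coating generator reproduces geometry and packing statistics, not
  thermodynamic ensembles — its chains are athermal growth processes, not
  Boltzmann-weighted configurations.

## A minimal session

```{r example, eval = FALSE}
sc <- synthetic_scenario(N = 14, a_bead = 0.019, seed = 1)
profiles <- scenario_profiles(sc)
observed <- synthesize_velocity(sc, profiles)
fit <- fit_abead(observed, profiles, scenario_params(sc))
glance(fit)

coating <- generate_grafted_coating(N = 14, n_chains_per_wall = 25,
                                    seed = 1)
rdf_peaks(non_normalized_rdf(coating, bin_width = 0.005, r_min = 0.05))

kern <- parametric_kernel(a_near = 0.18 * 0.156)
nf <- exposed_far_beads(coating, reference_z = 1)
effective_radius(kern, build_pfar(nf, kern))
```
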