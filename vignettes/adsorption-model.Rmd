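---
title: "Hybrid discrete-continuous Lennard-Jones adsorption on carbon nanocarriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid discrete-continuous Lennard-Jones adsorption on carbon nanocarriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosorb)
```

## The model

`nanosorb` computes and minimizes the van der Waals adsorption energy of
rigid, planar drug molecules on two idealized all-carbon nanocarriers: an
infinite flat graphene sheet and a spherical C60 fullerene. All interactions
are non-bonded 12-6 Lennard-Jones terms,

$$\Phi(\rho) = -\frac{A}{\rho^6} + \frac{B}{\rho^{12}}
  = \epsilon\left[-2\left(\frac{\sigma}{\rho}\right)^6
  + \left(\frac{\sigma}{\rho}\right)^{12}\right],
  \qquad A = 2\epsilon\sigma^6,\; B = \epsilon\sigma^{12},$$

where $\epsilon$ is the well depth (kcal/mol) and $\sigma$ the separation at
the minimum (Å). Heteroatomic pairs use the standard mixing rule
$\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}$,
$\sigma_{ij} = (\sigma_i + \sigma_j)/2$. The bundled per-element table
(H, C, N, O, F, S, Cl) follows the UFF non-bonded parameters, whose van der
Waals distance is already the minimum-energy separation; tables quoted as
zero-crossing distances must be scaled by $2^{1/6}$ before loading
(`load_lj_table()` accepts any CSV with the same columns).

Two molecules interact by the exact discrete double sum over their atom
pairs. A molecule and a carrier interact through the *hybrid
discrete-continuous* model: the drug stays atomistic while the carrier's
atoms are smeared into a uniform surface density $\eta$, so each drug atom
sees the closed-form surface integral
$E = \eta(-A I_3 + B I_6)$ with $I_n = \int_S \rho^{-2n}\,dS$:

* **plane** ($z = 0$, $I_n = \pi/((n-1)\delta^{2n-2})$):
  $E(\delta) = \eta_p \pi\left(-A/(2\delta^4) + B/(5\delta^{10})\right)$,
  with minimum at $\delta^* = \sigma/2^{1/6}$;
* **sphere** (radius $a$, probe at center distance $\delta > a$):
  $E(\delta) = \frac{a\pi\eta_s}{\delta}\left\{-\frac{A}{2}\left[
  (a-\delta)^{-4} - (a+\delta)^{-4}\right] + \frac{B}{5}\left[
  (a-\delta)^{-10} - (a+\delta)^{-10}\right]\right\}$.

Graphene's density comes from its honeycomb geometry,
$\eta_p = 4/(3\sqrt{3}\,b^2)$ with bond length $b = 1.42$ Å
(`graphene_surface_density()` evaluates to 0.38177 atoms/Å²; the value
0.3812 often quoted in the continuum-approximation literature corresponds to
$b = 1.421$ Å — the 0.16 % difference scales all plane energies by the same
factor and is far below every tolerance used here). The C60 density is
$\eta_s = 60/(4\pi a^2) = 0.3789$ atoms/Å² at the mean cage radius
$a = 3.55$ Å.

Assumptions worth stating plainly: molecules are rigid (no bond bending or
twisting, so the only degrees of freedom are rigid-body poses), there are no
electrostatic or solvent terms, carriers are perfect continuum surfaces, and
only exterior adsorption on the sphere is supported (interior points hit a
domain error; the surface itself is a non-integrable singularity).

## Verification of the closed forms

The continuum formulas are the scientific core, so they are verified against
fully independent routes rather than against themselves:

* `quad_plane_energy()` integrates the plane integrand by iterated adaptive
  quadrature over the infinite domain; the closed form agrees to better than
  $10^{-6}$ relative error over the working range of heights.
* `quad_sphere_energy()` integrates the spherical integrand in the polar
  angle; agreement is at machine precision.
* `oracle_plane_energy()` brute-force sums the pair potential over a finite
  honeycomb patch (`make_lattice_patch()`); at a patch radius of 30-40 Å the
  discrete sum matches the continuum formula to better than 1 % at the
  pair-minimum height, and the hybrid energy of a small ring molecule at
  3.4 Å matches the ring-against-patch double sum within 2 %.
* `oracle_sphere_energy()` does equal-area quadrature over a Fibonacci point
  set; with 60 points at the C60 radius it also quantifies the error of
  treating the real discrete cage as a continuum (a few percent at contact
  distances).

Two caveats uncovered during verification are documented rather than hidden.
First, the hexagonal-lattice density formula at $b = 1.42$ Å gives 0.3818,
not the often-printed 0.3812 (see above). Second, the sphere formula
converges to the plane formula at fixed surface clearance $h$ with a
leading-order relative deviation of $h/a$ — curvature, not error — so at
$a = 1000$ Å and $h = 6$ Å the two necessarily differ by about $6\times
10^{-3}$; the package's tests assert this true convergence law and the
$10^{-3}$ agreement at radii ($a \ge 10^4$ Å) where it actually holds.

## Molecules and their frames

`read_sdf()` parses the atom block of V2000 connection tables (bonds are
irrelevant to a rigid model); `read_xyz()`/`write_xyz()` handle XYZ.
Chloride counterions are stripped (`strip_counterions()`): methylene blue is
modelled as its 38-atom chromophore, the ion contributing nothing to
adsorption. Hydrogens are kept in all energy sums.

Each planar molecule carries an orthonormal frame used by the geometric
descriptors: the **normal** of the total-least-squares plane through the
*carbon* atoms only (ring planes are what stack; out-of-plane hydrogens and
substituents should not tilt the fit), a **front** vector from the center of
mass toward a designated atom projected into that plane, and the completing
**side** vector. Front-atom defaults are the unique fluorine for
fluorouracil, the central acridine nitrogen for proflavine (resolved as the
nitrogen nearest the center of mass, which cleanly separates it from the two
terminal amines), and the ring sulfur for methylene blue. All selectors are
configurable, since any consistent in-plane reference direction serves.

### Bundled geometries are synthetic

The shipped drug structures (`drug_molecule()`) are MMFF94-optimized 3D
geometries generated from the molecular graphs, not database conformers, and
their files are named `*_synthetic.sdf` accordingly. For rigid planar
chromophores a force-field geometry differs from a database conformer by a
few hundredths of an Ångström in bond lengths, which propagates to roughly
1-3 % in equilibrium energies — visible in the worked comparisons below but
small against the basin-to-basin energy differences the optimizer resolves.
Users wanting exact reference conformers can pass their own SDF files
anywhere a bundled drug name is accepted.

## Poses and the evolutionary search

A configuration of $n$ molecules is described by $5n$ variables: per
molecule a center-of-mass translation $(x, y, z)$ and two rotations
$(\theta_x, \theta_y)$ about the lab axes. The rotation convention is fixed
(first $\theta_x$, then $\theta_y$, about the molecule's default center of
mass) so poses are reproducible; two angles suffice because the third Euler
angle is degenerate with the carrier symmetry for single molecules and is
recovered through combinations of the two for stacks. Translations default
to $[-16, 16]$ Å and angles to $[-180°, 180°]$. For plane systems the $z$
lower bound is raised to $+1.5$ Å; a symmetric box would let centers of mass
start below the sheet, where the continuum formula is meaningless.

Because a rotated molecule can still dip an atom through the surface from a
legal center-of-mass position, the objective returns a large penalty that
grows with the violation whenever any atom comes within 0.2 Å of the carrier
surface (or crosses it). At 0.2 Å the repulsive $\delta^{-10}$ wall is
already astronomically positive, so the penalty only repairs the sign error
of the formula past the singularity and never shapes a feasible basin.
Everywhere feasible, the objective equals `total_energy()` exactly (this is
a tested invariant).

Minimization uses a single-objective real-coded genetic algorithm — the
configuration that unified NSGA-III reduces to for one objective: binary
tournament selection, simulated binary crossover ($p_c = 0.9$,
$\eta_c = 15$), polynomial mutation ($p_m = 1/n_{var}$, $\eta_m = 20$), and
elitist $\mu+\lambda$ truncation survival. Every run is reproducible from
its seed, the best-so-far history is non-increasing by construction, and
populations never leave the bounds. Production-scale settings
(`ga_settings_production()`: population 12000, 10000 offspring, 400-600
generations) match the published search protocol; the test-scale defaults
(population 200, 150 generations) suffice for single-molecule systems, whose
landscape is effectively low-dimensional. Population evaluation is a single
C++ kernel (about 5 µs per configuration for three 12-atom molecules), which
is what makes production-scale protocols affordable on one CPU.

Multi-molecule systems are genuinely multimodal: distinct stable
configurations (stackings, surface arrangements) live in basins separated by
large barriers, and a single GA run settles into one of them. The search
protocol is therefore multi-seed (`multi_seed_search()`, 5-12 seeds), and
`group_configurations()` merges seeds that found the same basin: two results
belong together when their energies agree within 0.1 kcal/mol *and* every
geometric descriptor agrees within 0.3 Å / 15°. Those defaults separate
configuration pairs like the two methylene-blue stackings on graphene
(energy gap ≈ 0.3 kcal/mol, rotational-angle gap ≈ 180°) while absorbing
seed-to-seed optimizer noise. Descriptors are intrinsically invariant under
the carrier symmetry (in-plane motions for the plane, global rotations for
the sphere) and are compared after sorting over molecules, which also
quotients the permutation of identical molecules; raw poses are never
compared. Group labels A, B, ... follow ascending representative energy.

## Geometric descriptors

For a pair of posed molecules (`pair_descriptors()`): $\xi$ is the distance
between centers of mass; $d$ the interplanar distance, measured along the
mean of the two carbon-plane normals after sign-aligning them (the "shortest
distance between two parallel planes" is ambiguous for almost-parallel
planes, and the sign alignment handles flipped stacks); $\alpha$ the incline
angle between the oriented normals; $\beta$ the rotational angle between the
front vectors projected into the mean plane. Frames are computed on the
default molecule and transported through the pose rotation, which keeps the
normal attached to the molecule — a flipped partner therefore reports
$\alpha$ near 180°, which is exactly what distinguishes anti-parallel from
co-parallel stacks.

$\beta$ is reported as the raw oriented angle in $[0°, 180°]$, with the
folded value $\min(\beta, 180°-\beta)$ alongside, because both conventions
appear in the stacking literature (sometimes within one table).
Classification (`classify_alignment()`) uses the raw angle: planes parallel
when $\min(\alpha, 180°-\alpha) \le 20°$, then co-parallel for
$\beta \le 30°$, anti-parallel for $\beta \ge 150°$, orthogonally parallel
between. Against the carrier (`plane_carrier_descriptors()`,
`sphere_carrier_descriptors()`): $d$ is the center-of-mass clearance above
the surface, $\gamma$ the tilt between molecular normal and surface normal
folded to $[0°, 90°]$ (only the magnitude is meaningful), and $\omega$ the
angular separation of two molecules seen from the sphere center.

## Problem sizes used by the tests

The shipped test-suite runs the full pipeline at sizes chosen to exercise
every claim while staying desk-scale: continuum-vs-quadrature sweeps over
$\delta \in [2.5, 10]$ Å; lattice patches of radius 30-40 Å (about 1-2
thousand atoms) for the hybrid-consistency checks and radius 200 Å (about
50 000 atoms, count only) for the density-convergence check; GA populations
of 200 with 100-150 generations for single-molecule systems; and populations
of 2000-6000 with up to 500 generations and 3-8 seeds for the stacked and
multi-molecule reproductions. The one genuinely hard search shipped —
three fluorouracils arranging into an equilateral triangle on the C60
surface, a 15-variable multimodal problem — uses the production protocol at
reduced population. What passing these tests shows is that the
implementation is faithful to the model and reproduces the published
equilibria from synthetic geometry; what it cannot show is anything about
flexible molecules, solvated systems, or carriers whose discreteness
matters, all of which are outside the model by construction.

## Known limitations

* Rigid bodies only; no conformational relaxation on adsorption.
* Pure van der Waals: no electrostatics (methylene blue is in reality a
  cation), no solvent, no many-body polarization.
* Continuum carriers: the atomic corrugation of graphene and the
  pentagon/hexagon structure of C60 are averaged away; the 60-point oracle
  puts that error at a few percent at contact distance.
* The GA is stochastic: with few seeds, rare basins (e.g. the three-molecule
  triangle) can be missed; the multi-seed protocol with grouping is the
  intended usage, not single runs.
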