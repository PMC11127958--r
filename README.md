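# nanosorb

Adsorption of rigid small-molecule drugs on idealized carbon nanocarriers,
computed with a hybrid discrete–continuous Lennard-Jones model and minimized
with an evolutionary rigid-body pose search.

The package is for modellers who want equilibrium adsorption energies and
geometries of planar drug molecules — fluorouracil, proflavine and methylene
blue are bundled — on an infinite flat graphene sheet or a spherical C60
fullerene, without atomistic simulation machinery: the carrier's atoms are
averaged into a uniform surface density and integrated in closed form, while
the drug stays atomistic.

## The model

Non-bonded pair interactions are 12-6 Lennard-Jones,

    Φ(ρ) = −A/ρ⁶ + B/ρ¹²,   A = 2εσ⁶,  B = εσ¹²,

with per-element (ε, σ) from a bundled UFF-style table and the standard
mixing rule ε_ij = √(ε_i ε_j), σ_ij = (σ_i + σ_j)/2. Integrating Φ over a
carrier surface with atom density η gives closed forms for one drug atom at
distance δ:

* graphene plane (η_p = 4/(3√3 b²), b = 1.42 Å):
  `E = η_p π (−A/(2δ⁴) + B/(5δ¹⁰))`
* C60 sphere of radius a = 3.55 Å (η_s = 60/(4πa²), δ from the center):
  `E = (aπη_s/δ){ −(A/2)[(a−δ)⁻⁴ − (a+δ)⁻⁴] + (B/5)[(a−δ)⁻¹⁰ − (a+δ)⁻¹⁰] }`

The total energy of n posed molecules is the exact atom–atom double sum over
all molecule pairs plus the per-atom carrier terms. Each molecule has 5 pose
variables (x, y, z, θx, θy); the 5n-dimensional landscape is minimized with
a seeded real-coded genetic algorithm (tournament selection, SBX crossover,
polynomial mutation, elitist survival) run over several seeds, and the seeds
are grouped into distinct stable configurations by their geometric
descriptors: interplanar distance d, center-of-mass separation ξ, incline
angle α, rotational angle β, surface clearance d_GP/d_C60, tilt γ, angular
separation ω.

## Worked example

One fluorouracil molecule adsorbing on graphene:

```r
library(nanosorb)

fu  <- drug_molecule("fluorouracil")      # 12 atoms, centered at its COM
gp  <- plane_carrier()                    # z = 0, eta_p = 0.3818 atoms/A^2
obj <- build_objective(fu, gp)            # 5-variable pose objective

st  <- ga_settings(default_pose_bounds(1, gp),
                   pop_size = 200, n_gen = 150, seed = 1)
res <- minimize_single_seed(obj, st)
res
#> <optimization_result> seed 1: E = -15.4975 kcal/mol (30200 evals, 1 molecules)

configuration_record(res, fu, gp, drug_front_selector("fluorouracil"))
#> <configuration_record> E = -15.4975 kcal/mol
#>   per molecule:
#>   d_surface gamma
#> 1     3.348 0.689
```

The molecule lies flat (tilt γ below one degree) with its center of mass
3.35 Å above the sheet, bound by −15.5 kcal/mol — the π-stacking geometry
expected for a planar ring on graphene. Multi-molecule systems use
`multi_seed_search()` and `group_configurations()`; `run_adsorption()` wraps
the whole pipeline (structure loading, search, grouping, CSV/XYZ/JSON
output) from a single YAML/JSON config, and `inst/cli/nanosorb.R` exposes it
as a command line (`optimize`, `energy`, `descriptors`, `validate`).

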