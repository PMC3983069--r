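---
title: "Modelling stress sensing by shallow membrane insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stress sensing by shallow membrane insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(membrins)
```

## The physical problem

Peripheral membrane proteins often attach to membranes by pushing a small
amphipathic helix sideways into the outer lipid monolayer, to roughly 40%
of the monolayer's thickness.  Because the helix occupies volume inside a
material that already carries depth-dependent lateral stresses, the work
of carving out that volume depends on the stressed state of the membrane.
`membrins` models this energetics with continuum elasticity: the insertion
is a rigid cylindrical rod (cross-section radius `r`, default 0.5 nm;
embedding depth `d`, default 0.8 nm; in-plane length `L_ins`, default
2 nm) embedded into the outer monolayer of a bilayer of two monolayers of
thickness `h = 2` nm each.

The package's central quantity is the *elastic binding energy*
`eps_el`, the stress-dependent part of the free energy of moving one
insertion from solution into the membrane.  Binding constants relative to
the unstressed flat membrane follow by Boltzmann weighting,

    K_rel = exp(-(eps_el - eps_el0)/kT) * g(R),

with a small geometric factor `g(R)` that matters only for very small
vesicles.  The strong, exponential dependence on `eps_el` is what makes
shallow insertions sensitive reporters of intra-membrane stress.

## Stress profiles and their moments

A monolayer's mechanical state is summarised by its trans-monolayer
lateral stress profile `sigma(z)` (tension-positive, kT nm^-3), with `z`
measured from the bilayer midplane outward.  Two integral moments matter:
the lateral tension `gamma = \int sigma dz` and the bending moment about
the neutral plane, here defined as `tau = -\int (z - z0) sigma dz` so that
a flat monolayer frustrated by a spontaneous curvature `J_s` carries
`tau = kappa * J_s`.  The neutral plane sits at `z0 = 2h/3`, at the
polar/apolar interface.  With this sign convention, lysolipid-like species
(`J_s > 0`) produce lateral *pressure* in the headgroup region — exactly
the stress that opposes shallow embedding.

Two kinds of profile are used, reflecting how the stress arises:

* **Composition-driven (chemical) profiles** (`build_stress_profile()`).
  The depth structure of a frustration stress is not determined by its
  moments alone, so the package uses a three-zone decomposition: a
  headgroup zone (raised-cosine bump centred 0.3 nm below the outer
  surface, width 0.6 nm), a narrow interfacial zone at the neutral plane
  (width 0.5 nm) and a broad acyl-chain zone (centred at `h/3`, width
  1.2 nm).  Zone amplitudes are solved exactly from the `(gamma, tau)`
  constraints.  By default the bending-moment modulation is carried by the
  headgroup/interface pair of zones (`w_head = 1`): lysolipids, DAG and
  PE act primarily at the headgroup/interface region.  A zero-moment
  "frustration" component (nonzero pointwise stress in an unstressed
  monolayer) is available through `frustration_amp`; its default is 0, so
  profiles measure the *deviation* from the unstressed reference state —
  the common frustration offset of a real membrane cancels from every
  emitted ratio.

* **Mechanically driven (elastic) profiles**
  (`elastic_stress_profile()`).  A monolayer strained by
  `eps(z) = eps0 + c (z - z_n)` carries `sigma = E(z)/(1-nu^2) * eps(z)`.
  Consistency with the finite element constitutive law fixes this shape;
  it is used for the external-torque and stretching protocols.

The depth-dependent Young's modulus is two-zone: a stiffer
headgroup/interface region above `h/2` and softer chains below, with the
zone ratio fixed by requiring the neutral plane (where stretching and
bending decouple) to sit at `z0`, and the overall scale calibrated so the
plane-strain bending stiffness `\int E (z-z0)^2 dz/(1-nu^2)` equals the
monolayer bending modulus `kappa` (default 10 kT; with the defaults,
`E_head/E_tail = 5` and `E_tail = 5.7 kT nm^-3 ≈ 23 MPa`).  The Poisson
ratio is 0.49 (lipid volume is nearly conserved).

## Five ways of generating stress

`scenario_state()` prepares the pre-insertion equilibrium for five
experimentally realisable protocols.  With equal monolayer rigidities and
small spontaneous curvatures:

| kind              | curvature `J`      | outer-monolayer stress                      |
|-------------------|--------------------|---------------------------------------------|
| `outer_Js`        | `J_s/2`            | chemical (`tau = kappa J_s`) + bending      |
| `inner_Js`        | `-J_s/2`           | bending only                                |
| `symmetric_Js`    | `0`                | chemical (`tau = kappa J_s`)                |
| `external_torque` | `M/(2 kappa)`      | bending only                                |
| `stretch`         | `0`                | uniform elastic tension                     |

Bilayer curvature `J > 0` bulges toward the outer monolayer.  All five
reduce to the same unstressed state at zero magnitude, and the lateral
stress averaged over the void region is compressive for `outer_Js > 0`
and `symmetric_Js > 0` but tensile for `inner_Js < 0`, positive torque
and stretching — which is why apparent "curvature sensing" has opposite
signs for different curvature-generating mechanisms.

Curved pre-insertion states are represented on the *flat* reference
domain: the curvature enters through the residual stress profiles and
through the external loads that maintain them (the lab-frame moment and
per-monolayer tensions of `sigma0`), a standard small-deformation
linearisation valid for `|J| h < 0.5`, which the package enforces.

**Monolayer coupling.**  Uncoupled monolayers exchange lipid with a
reservoir (a small patch in a large membrane): each monolayer's lateral
boundary translation is free.  Coupled monolayers (a closed liposome)
conserve their lipid numbers: the embedding solve constrains each
monolayer's integrated lateral strain exactly, and bent pre-states carry
the area-difference stress of bending at fixed leaflet populations —
bending strain referenced to the bilayer midplane, so the outer leaflet of
a small extruded liposome is under tension (`gamma_out = J gamma_A z0`,
with `gamma_A` the monolayer stretching modulus).  This leaflet tension,
not the bending moment, dominates the predicted size dependence of
binding.

## The finite element model

The cross-section `[0, L_dom] x [-h, h]` (default `L_dom = 20` nm, ten
monolayer thicknesses; doubling it changes the embedding energy by well
under 1%) is meshed with graded structured triangles (at least 1908
elements) and refined by conforming longest-edge bisection towards the
insertion until at least 5514 elements, using the strain-energy density of
the unstressed embedding as the error indicator.  Quadratic (P2)
triangles are used throughout: the uniform-tension and pure-bending
verification fixtures are then exact up to solver precision, and the
near-incompressible Poisson ratio causes no volumetric locking.  Moduli
zone breaks and the midplane coincide with mesh lines, so the
depth-dependent modulus is exact per element.

Boundary conditions follow the mirror symmetry of the rod: the left
boundary is the insertion mid-plane, where the rigid insertion imposes the
horizontal displacement `u_x(0, z) = sqrt(r^2 - (z - z_c)^2)` over the arc
(carving exactly half the void) and `u_x = 0` elsewhere; the top and
bottom surfaces are free; the far (right) boundary remains a straight
symmetry plane — its lateral displacement is affine in depth while
material slides freely along it — whose rotation is an energy-minimisation
variable.  The monolayer interface at the midplane transmits normal
displacement but no tangential traction (monolayers slide).  One vertical
pin removes the rigid vertical mode.  The assembled system is reduced by
constraint elimination and solved with a sparse Cholesky factorisation,
which is reused across all load cases sharing a geometry (scenario sweeps
and fits re-solve only the right-hand side).

## The two-step embedding decomposition

Embedding is computed in two steps.  Step 1 carves the void while the
membrane shape (the far-boundary rotation) is frozen; its energy is
`eps_V0 + delta_eps_V`, where the void energy

    eps_V0 = -L_ins * \int_void sigma0(z) dA

is evaluated by direct quadrature of the pre-insertion stress over the
void cross-section (an angular substitution removes the square-root edge
of the chord, giving ~1e-9 accuracy), never from the FEM residual.
Step 2 releases the shape relaxation; `eps_R <= 0` by construction
(nested minimisation).  The budget identity
`eps_el = eps_V0 + delta_eps_V + eps_R` is exact bookkeeping.

In this linearised model the collapse of `eps_el` onto `eps_V0` — the
universality of stress sensing — is close to exact: for laterally uniform
pre-stress, the work of the pre-stress against the void-induced
deformation reduces, by the divergence theorem, to boundary terms that the
maintaining loads cancel, so `delta_eps_V` and `eps_R` are almost
independent of the stressed state (residual cross-scenario scatter is a
few 1e-3 kT, from quadrature and the stress-stiffness difference of the
constrained arc).  The package therefore *demonstrates* the collapse
rather than assuming it: the five scenarios produce very different
profiles and maintaining loads, and the sweep verifies that the slope of
`eps_el` versus `eps_V0` is one and that `K_rel` follows
`exp(-eps_V0/kT)`.

The apparent curvature sensitivity `xi` (from
`eps_el ≈ eps_el(0) - xi J`, fitted over `|J| <= 0.1 nm^-1`) is positive
for torque- and inner-leaflet-generated curvature, negative for
outer-leaflet generation, grows with the insertion radius, and is
non-monotonic in the embedding depth — the void progressively overlaps
stress zones of opposite sign as it deepens.

## Fitting ALPS binding data

Two measured data sets are embedded as fixtures: relative binding
constants of the ArfGAP1 helices ALPS1/ALPS2 to liposomes of radii
34/42/90 nm, and of ArfGAP1 to flat liposomes of six
DOPC:DOPE:DOPS:DAG compositions (spontaneous curvatures from the
area-fraction weighted sum of lipid contributions; the default table
DOPC −0.115, DOPE −0.333, DOPS +0.068, DAG −0.985 nm^-1 reproduces all
six printed mixture curvatures to better than 0.001 nm^-1).

Size fits use coupled monolayers with torque-generated curvature
calibrated so the pre-insertion curvature equals `1/R` (one principal
curvature; the second principal curvature of a sphere is neglected — a
known bias of the 2-D kinematics).  Composition fits use coupled
symmetric spontaneous-curvature generation.  Because the elastic binding
energy is exactly linear in `L_ins`, the fit over `(L, d)` factorises:
per-unit-length energies are computed once per depth (one mesh and two
factorisations each) and scanned over lengths in closed form, followed by
golden-section refinement along the depth.

Two structural limitations surface in these fits and are worth stating
plainly.  First, the model's embedding energies are linear in `1/R`, so
the ratio `ln K(34)/ln K(42)` is fixed at 1.44 for any geometry, while the
measured pairs imply 1.57 (ALPS1) and 2.06 (ALPS2); a two-parameter fit
therefore splits residuals of 10–25% across the two ratios.  Second, the
fitted depths land at 0.8–0.9 nm: with the two-zone modulus the
mechanically generated stress grows with depth as `E(z) z`, so sensitivity
keeps rising as the void deepens.  A stress profile concentrated nearer
the outer surface would move the optimum shallower (0.4–0.5 nm); the
depth estimate is the quantity most sensitive to the profile-shape
choices above.  The composition data also contain variation the model
cannot capture: the two PE-rich mixtures bind far less than DAG mixtures
of similar spontaneous curvature, so no model in which binding depends on
composition only through `J_s` can fit all six rows closely.

## Numerical choices

* Energies in kT (T = 300 K), lengths in nm.
* Direct sparse Cholesky; reduced systems are symmetric positive
  definite, with singular reductions reported as unconstrained rigid
  modes.
* Stiffness quadrature: 3-point (exact for P2 with element-wise constant
  modulus); pre-stress loads and energy: 7-point (degree 5).
* Profile grids: 2001 points with jump-resolving nodes at the moduli zone
  break; integral moments of the piecewise-linear interpolant are
  evaluated exactly, so the `(gamma, tau)` constraints hold to 1e-9.
* Problem sizes: the default solves use ~6000 triangles (~25k unknowns,
  about a second per factorisation); sweeps use 9 magnitudes per scenario
  over `eps_V0` in [-2, 2] kT; fits scan 19 depths and 41 lengths.
* Everything is deterministic; there is no randomness anywhere in the
  computation.

## What the verification does and does not show

The analytic fixtures (uniform tension, pure bending, void quadrature,
zero load) verify the solver against closed forms to 1–2%; the scenario
sweeps verify the collapse, sign structure and geometry dependences of
stress sensing; the fits verify that the machinery reproduces measured
binding ratios at the level discussed above.  None of this validates the
continuum model's microscopic realism: depth profiles of stress and
stiffness are coarse three-zone/two-zone idealisations of what molecular
simulations would give, lipid tilt and thermal fluctuations are absent,
insertions are rigid cylinders without orientational freedom, and the
dilute-binding assumption is a documented precondition rather than a
checked one.

## A minimal session

```{r example}
library(membrins)

# one embedding in a symmetric DAG-enriched membrane
cfg <- run_config(scenario = list(kind = "symmetric_Js",
                                  magnitude = -0.1))
res <- run_simulation(cfg)
res$budget; res$K_rel

# the five-scenario collapse
sw <- embed_sweep(span = c(-2, 2), n = 9)
coef(lm(eps_el ~ eps_V0, data = sw))

# ALPS1 size fit
fit <- fit_geometry(alps_size_table("ALPS1"), L_grid = seq(3, 7, 0.1))
fit
```
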