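---
title: "Update-free identification of corneal material parameters: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Update-free identification of corneal material parameters: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Keratoconus softens the cornea by degrading its collagen fibers. A
non-contact tonometer (NCT) indents the cornea with an air pulse while
imaging its deformation, so in principle the measurement carries enough
information to identify structural material parameters in vivo. The
classical route — finite-element model updating, where a forward
simulation is re-run inside an optimization loop — takes hours per
forward solve and is unusable at the device. `egmeye` implements an
update-free alternative: the equilibrium gap method (EGM). Given a
displacement field and the external forces, the discrete residual

$$\mathbf{R}(\boldsymbol\alpha) \;=\; \mathbf{f}^{\mathrm{int}}(\hat{\mathbf u}, \boldsymbol\alpha) - \mathbf{f}^{\mathrm{ext}}$$

is *evaluated*, never solved. For the cornea model used here the
internal force vector is exactly linear in three of the four material
parameters, so minimizing $\mathbf R^\top\mathbf R$ is a convex 3x3
least-squares problem with a unique solution — identification in
fractions of a second instead of repeated multi-hour forward solves.

## Constitutive model

The corneal stroma is modeled as an anisotropic hyperelastic solid with
two dispersed collagen fiber families (nasal–temporal and
superior–inferior):

$$\psi = \underbrace{\tfrac{K}{4}\left(J^2 - 1 - 2\ln J\right)}_{\text{volumetric penalty}}
      + \underbrace{\tfrac{\mu}{2}\left(\tilde I_1 - 3\right)}_{\text{neo-Hookean matrix}}
      + \sum_{i=1}^{2}\underbrace{\tfrac{k_1}{2k_2}\left[e^{k_2 (\tilde I_{4,i}^* - 1)^2} - 1\right]}_{\text{fiber families}}$$

with the dispersed invariant
$\tilde I_4^* = \kappa \tilde I_1 + (1-3\kappa)\tilde I_4$,
$\kappa \in [0, 1/3]$. The Cauchy stress follows by push-forward of
$2\,\partial\psi/\partial \mathbf C$; its exact decomposition

$$\boldsymbol\sigma = K\,\hat{\boldsymbol\sigma}_K + \mu\,\hat{\boldsymbol\sigma}_\mu + k_1\,\hat{\boldsymbol\sigma}_{k_1}$$

at fixed $k_2$ is what `stress_decomposition()` provides and what the
whole identification rests on. The nonlinear parameter $k_2$ is found by
an outer grid search minimizing the relative scatter

$$f_{\mathrm{rel}}(k_2) = \sum_{i=1}^{3} \frac{\sigma_{\mathrm{Dev},\alpha_i}(k_2)}{\langle\alpha_i\rangle(k_2)}$$

of the state-wise linear identifications across $m \ge 3$ deformation
states: only the correct $k_2$ lets a single parameter triple explain
every deformation state at once.

Reference parameter sets (`reference_material_sets()`): healthy
$K = 10$ MPa, $\mu = 0.275$ MPa, $k_1 = 0.04$ MPa, $k_2 = 200$ (the
exponent is dimensionless), with keratoconus-like degradation modeled
purely as reduced fiber stiffness ($k_1 = 0.02, 0.01, 0$ MPa for KK-I,
KK-II, KK-III).

### Choices where the model is underdetermined

* **Variance correction.** The fiber energy admits an optional factor
  $a = 1 + K^*\sigma^2_{\tilde I_4^*}$; the reference parameter sets
  carry no values for these coefficients, so the factor defaults to 1
  and can be enabled through `material_parameters()`.
* **Fiber tension–compression.** A tension-only switch (fibers active
  only for $\tilde I_4^* > 1$) is available but **off by default**. The
  dispersed invariant makes the fiber term quadratically small around
  $\tilde I_4^* = 1$, so the smooth law is mechanically harmless under
  tonometry loading — and it is the variant that reproduces the
  characteristic shape of the $f_{\mathrm{rel}}$ curve (a secondary
  local minimum toward $k_2 \to 0$ next to the global minimum at the
  generating value). With the switch on, that secondary feature
  disappears on this fixture; the switch matters more than one would
  guess, which is why it is an explicit, documented option.
* **Small $k_2$.** Below $k_2 = 10^{-6}$ the fiber energy is evaluated
  by its series expansion, which tends continuously to the quadratic
  law $\tfrac{k_1}{2}(\tilde I_4^*-1)^2$; the $f_{\mathrm{rel}}$ curve
  is probed near $k_2 \to 0$, so the branch must be smooth there.

## The finite-element fixture

All data in this package are synthetic, generated by the package's own
reduced eye model so that generator and identifier share one
discretization and recovery can be verified to machine accuracy.

* Geometry: corneal ellipsoid of revolution (default semi-axes
  7.2/6.6 mm, apex radius $\approx 7.9$ mm), central thickness 0.545 mm
  blending smoothly (cosine) to 0.70 mm at the limbus start radius
  4.6 mm; a 2 mm wide limbus ring whose outer rim is clamped; quarter
  symmetry with floating bearings on the two symmetry planes. The
  planform uses an elliptical square-to-disc map, so the hex grid has no
  polar singularity at the apex.
* Elements: 8-node hexahedra, $2\times2\times2$ Gauss quadrature, with
  the volumetric term evaluated at the element-centroid Jacobian (mean
  dilatation) against near-incompressibility locking. The identical
  scheme is used for generation and identification — this, not mesh
  fineness, is what makes the inverse recovery exact.
* Default mesh: `n_planform = 8`, 2 layers through the thickness, 2
  limbus rings — 192 elements, 345 nodes, 1035 DOFs. This size keeps a
  full forward tonometry run at about a minute on one core while
  resolving the indentation; the vignette section on limitations
  discusses discretization error.
* Fluid cavity: the anterior chamber is a single pressure unknown with
  the linear law $p = p_0 + K_W (V_0 - V)/V_0$, volume by a
  divergence-theorem integral over the deformed wetted surface. The
  default $K_W = 0.02$ MPa is an *effective* ocular volume-response
  modulus: the fixture's rigid clamped rim replaces the compliant
  sclera/lens of a whole eye, and a literal water bulk modulus (2 GPa,
  still configurable) would seal the chamber nearly rigidly. The
  default was fixed once so that an indentation of about 1 mm raises
  the IOP by a few mmHg, the anterior-chamber response scale reported
  for NCT.
* Auxiliary components: the limbus is a quasi-incompressible
  neo-Hookean surrogate with the small-strain-equivalent moduli of
  $E = 1.4$ MPa, $\nu = 0.49$. Sclera and lens are not meshed in the
  reduced fixture (flags exist and fail loudly); their mechanical role
  at the rim is played by the clamp, their volumetric role by the
  effective cavity modulus.

## Virtual tonometry and the three deformation states

The air pulse is a rotationally symmetric Gaussian follower pressure
$p(r) = p_{\mathrm{peak}} e^{-r^2/2s^2}$ on the anterior surface
(default $p_{\mathrm{peak}} = 0.020$ MPa, $s = 1.2$ mm, 8 ramp steps),
calibrated once so the healthy fixture reaches about 1 mm apex
deflection; the device's real pressure footprint is not modeled.

Before loading, the stress-free reference geometry is recovered by the
fixed-point iteration
$\mathbf X_0 \leftarrow \mathbf X_0 - (\mathbf x(\mathbf X_0) - \mathbf X_{\mathrm{target}})$
at fixed IOP (default 17.5 mmHg), terminating when the pressurized
configuration matches the in-vivo target within 2 µm at every node
(3 iterations on the default fixture). A relaxation factor is available
for stubborn geometries but has not been needed.

Three states are extracted per record: state 1 at applanation, state 3
at peak load, state 2 halfway between on the load schedule. Applanation
is detected when the central anterior surface (disc of 1 mm radius,
widened on coarse meshes to at least 8 nodes and mirrored across the
symmetry planes) deviates from its best-fit plane by less than 5 µm,
with linear interpolation of the signed central sagitta between ramp
steps; the device's own criterion is not published, so this is a
documented package convention. Every state is a *converged equilibrium
solve* — displacements and external forces are stored as a matched
pair, which is the precondition for exact recovery.

## Numerical choices in the solver

* Newton with a finite-difference element tangent (forward differences,
  $h = 10^{-6}$ mm), sparse LU on the free DOFs, and the
  pressure–volume coupling handled as a nonsymmetric rank-one update by
  Sherman–Morrison with the exact discrete volume gradient.
* Convergence: $\lVert\mathbf R\rVert_{\mathrm{free}} \le
  10^{-8}\lVert\mathbf f^{\mathrm{ext}}\rVert + 10^{-10}$ N.
* Globalization: the dimple formation under the pulse is strongly
  nonlinear; strict monotone line search stalls there. The solver
  accepts non-monotone full steps (rejecting only element inversion or
  a tenfold residual growth), caps the step at 0.2 mm, and reuses the
  factorized tangent while the contraction is strong, rejecting
  reused-tangent steps that fail to descend.
* Degenerate inputs fail loudly: inverted elements name the elements,
  zero-area facets and non-closed wetted surfaces raise geometry
  errors, meshes with non-positive reference Jacobians are rejected at
  construction.

## The identification layer

`compute_sensitivity_vectors()` assembles each $\mathbf c_i$ as the
internal-force vector with the corresponding parameter set to one and
the others to zero — the residual a standard FE code returns when asked
for $\mathbf R(\alpha_i = 1, \alpha_{j\ne i} = 0, \mathbf f^{\mathrm{ext}} = \mathbf 0)$.
Rows at Dirichlet and symmetry DOFs carry unknown reactions and are
masked; all remaining DOFs enter (the limbus rows balance exactly
because its known-material internal forces are moved into the effective
external force, keeping the unknown vector strictly 3-dimensional).
Columns are normalized before the $3\times3$ normal equations are
solved, since $\mathbf c_K$ and $\mathbf c_{k_1}$ differ by orders of
magnitude. Negative solutions trigger an exhaustive active-set
re-solve over the $2^3$ sign patterns with non-negativity constraints
and are flagged; rank-deficient columns (e.g. $k_1$ with inactive
fibers) produce a named warning rather than a crash.

For $f_{\mathrm{rel}}$ the *population* standard deviation (divide by
$m$) is used — the convention is fixed so the documented two-state toy
example (triples $(1,1,1)$ and $(3,3,3)$ give $f_{\mathrm{rel}} = 1.5$)
is deterministic. A parameter mean below $10^{-12}$ MPa is guarded
rather than divided by; the curve is then effectively flagged through
the separate unidentifiability flag (averaged $k_1 < 10^{-3}$ MPa, the
KK-III case, where the fiber term — and with it $k_2$ — drops out of
the residual entirely).

## Mechanical morphing from 2D contours

Real devices deliver 2D section contours, not 3D full fields. The
morphing module rebuilds a representative field: contours are extruded
to axisymmetric stamps (spline in $r$ with an even extension about the
axis, so the apex curvature is captured); the corneal surface nodes are
then driven vertically onto the stamps at their *current* horizontal
positions while sliding freely in-plane, under a quasi-incompressible
isotropic surrogate material, with the cavity coupled so the IOP update
comes out of the volume change. The sliding loop re-evaluates the stamp
heights until the prescription stabilizes below 0.1 µm, with
sub-stepped updates (25 µm initially, 20 µm during sliding) because the
corrections concentrate on the steep corneal periphery.

Morph surrogate defaults: $E = 1$ MPa with effective $\nu = 0.495$. A
harder penalty ($\nu = 0.499$) made the periphery imprint solves
diverge while improving the volume constraint immaterially — the
centroid $|J - 1|$ stays below 0.003 either way, an order of magnitude
inside the 0.02 contract. The $|J-1|$ diagnostic is evaluated at the
element centroid because that is where the mean-dilatation element
enforces the constraint; full Gauss points additionally carry the
bending-parasitic volume oscillation that the element formulation
deliberately filters and that the generator's own fields exhibit
equally. The surrogate modulus is not innocuous, though: the morph
model's *own prestress* (its stress-free geometry is recovered with the
surrogate material, as the pipeline prescribes) scales roughly with
$1/E$ under the fixed IOP, so the reconstructed total field's reference
— and with it the identified absolute values — shifts when $E$ changes,
even though the imprinted final configuration is $E$-independent. What
survives, and what the test suite asserts by doubling $E$, is the
property the pathway exists for: the identified fiber-stiffness
*ordering* across degraded sets.

What to expect from contour-only identification (and what the tests
assert): the fiber-stiffness *ordering* across degraded sets is
recovered robustly; the absolute values are biased (here $K$ comes out
around 30 MPa because the surrogate enforces incompressibility harder
than the generating penalty of 10 MPa — expected, since beyond
quasi-incompressibility the penalty value hardly influences the
response; $k_2$ is underestimated). Ranges, not point values, are the
clinically meaningful output of this pathway.

## What the synthetic data do and do not show

The generator emulates: prestress from IOP, follower air-pulse loading,
cavity pressure rise, anisotropic fiber response with dispersion, the
three-state extraction, device-like 2D contours, and uniform absolute
image noise (±0.01 µm and ±0.1 µm per displacement component, 10 seeded
repetitions, no smoothing). It does not emulate: the real device's
pressure footprint and its shear component, patient-specific geometry
or fiber maps (the dispersion profile defaults to a constant 0.1 and
recovery is profile-independent because generation and identification
share it), corneal viscoelasticity and inertia, or optical segmentation
artifacts beyond white noise. Passing tests therefore demonstrate the
*method* — exact convex recovery, the scatter-based $k_2$ search, noise
sensitivity scaling, contour-only feasibility — not clinical accuracy.

The noise study reproduces the qualitative finding that motivates
smoothing: at 0.01 µm all repetitions stay within ±10% of the
generating values; at 0.1 µm the identification leaves the band in
every repetition, with the volumetric penalty $K$ *underestimated*
because uncorrelated nodal noise reads as spurious volume change.

## Known limitations

* Discretization: the default fixture carries a few percent
  displacement discretization error (refining from
  `n_planform = 4, n_layers = 1` to `8, 2` moves the inflated apex by
  about 8%). This does not touch identification accuracy — generator
  and identifier share the mesh — but absolute deflection amplitudes
  are fixture-specific, and production-scale absolute values are out of
  scope here.
* The reduced fixture has no lens and no separate vitreous cavity, so
  the anterior-chamber/vitreous pressure split is not represented; the
  single effective cavity reproduces only the anterior-chamber response
  scale.
* The $f_{\mathrm{rel}}$ landscape is non-convex; the default grid
  (10–400, step 10) brackets the physiological range, and a search from
  near zero upwards is recommended whenever the low-$k_2$ branch is of
  interest.
* Wall-clock: a full record (stress-free iteration plus tonometry ramp
  and three state solves) takes about a minute; a four-set recovery
  study with morphing runs in roughly ten minutes on one core.

## Reproducing the study numbers

`scripts/acceptance.R` regenerates the healthy, KK-I and KK-II records
from scratch, runs the linear identification and the $k_2$ grid search,
checks the stress-free reload bound, and writes the resulting values as
JSON — see the README for the exact invocation.
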