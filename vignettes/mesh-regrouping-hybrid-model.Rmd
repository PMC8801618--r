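---
title: "Mesh-regrouping hybrid DE/SP3 light transport for XLCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-regrouping hybrid DE/SP3 light transport for XLCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxtomo)
```

## The problem

X-ray luminescence computed tomography (XLCT) excites nanophosphors inside
tissue with X-rays; the particles emit optical photons (for Eu-based
phosphors, mainly at 610 and 630 nm) that diffuse to the surface where a
camera measures them. Reconstructing the internal source requires a forward
model of light transport through heterogeneous tissue. The diffusion
equation (DE) is cheap but valid only where scattering strongly dominates
absorption; the third-order simplified spherical harmonics approximation
(SP3) is accurate in low-scattering, high-absorption organs but doubles the
number of unknowns per node.

`luxtomo` implements a hybrid strategy: the tetrahedral mesh is *regrouped*
by tissue into a DE region (Region 1) and an SP3 region (Region 2), each
carried by its own self-contained sub-mesh. The two finite-element systems
are assembled independently — so their dimensions are `n1` and `2 n2` rather
than `2 n` everywhere — and coupled row-by-row at the duplicated interface
nodes. The coupled hybrid system has dimension `n1 + 2 n2`.

## Models

**Diffusion region.** For fluence $\Phi$, absorption $\mu_a$, diffusion
coefficient $D = 1/(3(\mu_a + (1-g)\mu_s))$ and refractive-mismatch factor
$A_n$, the P1 weak form gives the element integrals

$$M_{jk} = \int_\Omega D\,\nabla\varphi_j\cdot\nabla\varphi_k
  + \mu_a\,\varphi_j\varphi_k \,dr
  + \oint_{\partial\Omega} \frac{\varphi_j\varphi_k}{2A_n}\,dA,
\qquad F_{jk} = \int_\Omega \varphi_j\varphi_k\,dr,$$

and the linear system $M\Phi = FS$ for a source power density $S$.

**SP3 region.** The composite moments $(\varphi_1, \varphi_2)$ satisfy the
canonical coupled system with moment coefficients
$\mu_{ai} = \mu_a + \mu_s(1 - g^i)$:

$$-\nabla\!\cdot\!\tfrac{1}{3\mu_{a1}}\nabla\varphi_1 + \mu_a\varphi_1
 - \tfrac{2}{3}\mu_a\varphi_2 = S,\qquad
-\nabla\!\cdot\!\tfrac{1}{7\mu_{a3}}\nabla\varphi_2
 + \left(\tfrac{4}{9}\mu_a + \tfrac{5}{9}\mu_{a2}\right)\varphi_2
 - \tfrac{2}{3}\mu_a\varphi_1 = -\tfrac{2}{3}S.$$

The physical fluence is the composite $\Phi = \varphi_1 -
\tfrac{2}{3}\varphi_2$. We assemble the symmetric form with the
$-\tfrac23\mu_a$ mass coupling in **both** off-diagonal blocks; this is
forced by the composite-moment derivation (the right-hand side
$\{S, -\tfrac23 S\}$ is only consistent with the symmetric coupling) and by
the requirement that the hybrid contain pure SP3 as an exact special case.

**Boundary terms.** Partial-current (Marshak) conditions with specular
Fresnel reflection close both systems. All reflection moments are evaluated
by composite Gauss-Legendre quadrature split at the total-internal-reflection
cosine, where the Fresnel reflectance is non-smooth. For the DE,
$A_n = (1 + R_j)/(1 - R_\Phi)$ with $R_\Phi = \int_0^1 2\mu R_F \,d\mu$ and
$R_j = \int_0^1 3\mu^2 R_F \,d\mu$. For SP3 the first- and third-order
Marshak conditions are solved for the normal derivatives of
$(\varphi_1,\varphi_2)$, producing a 2x2 table of boundary-mass
coefficients; at a matched boundary it reduces to the closed form
$\bigl(\begin{smallmatrix}1/2 & -1/8\\ -1/8 & 7/24\end{smallmatrix}\bigr)$,
which the tests verify analytically. Statements of the surface-moment
relation vary (and are not always mutually consistent) across the
literature on this model family; we use the standard composite convention
throughout, isolated in one function (`composite_fluence()`) so an
alternative reading can be swapped in for comparison.

## Mesh regrouping and coupling

`regroup_mesh()` splits a region-labelled mesh into two sub-meshes with
stable (order-preserving) local renumbering. Nodes shared by both regions
are duplicated into each sub-mesh; the duplicates are detected by exact
bitwise coordinate identity (they are copies, not recomputations — a
tolerance is available for externally produced meshes) and recorded as
interface pairs. Only the *original outer boundary* carries Robin terms;
the internal interface does not. Conservation properties (element counts,
volume to 1e-12 relative, merge-back isomorphism) are tested on randomized
phantoms.

`couple_interface_nodes()` performs the row surgery: for each pair (DE node
$d$, SP3 node $s$), the $\varphi_1$ row of $s$ is accumulated into the row
of $d$ — the flux balance at the shared point is counted once across both
regions — and the vacated row becomes the unit-diagonal constraint
$\varphi_{1,s} - \Phi_d - \tfrac{2}{3}\varphi_{2,s} = 0$, i.e. continuity
of the physical fluence across the interface. Which moment row to vacate is
not derivable from the construction sketch alone; vacating $\varphi_1$ and
keeping the $\varphi_2$ equation keeps the system square and reproduces
both pure models exactly in the single-region limits, which is the testable
contract (relative difference < 1e-10 in the tests). Post-solve interface
continuity holds to solver precision (~1e-13 observed).

## Forward solving and sensitivity

Systems are solved by sparse LU with a residual contract (default 1e-10).
The sensitivity matrix $A = L M^{-1} F P$ (rows: measurable surface nodes,
columns: nodal sources; $L$ extracts composite fluence, $P$ applies the SP3
$-\tfrac23$ source scaling) is built by adjoint solves — one factorisation
of $M^T$, one triangular solve per measurable row — never forming the dense
$M^{-1}F$. Multispectral systems stack per-wavelength blocks unweighted.

## Numerical choices

* **P1 elements, closed-form integrals.** Mass `V/10`-`V/20`, face mass
  `area/6`-`area/12`, stiffness from gradient outer products; verified
  against an independent Duffy-transform quadrature oracle to 1e-12.
* **Canonical orientation.** Tets are reoriented to positive volume on
  construction; assembly assumes positive Jacobians.
* **Mass lumping for reconstruction meshes.** At 610 nm the liver's
  diffusion length (~0.37 mm) is below a practical reconstruction mesh
  size (1 mm), and consistent P1 mass then violates the discrete maximum
  principle severely (most surface values went negative in our
  experiments, destroying the sensitivity matrix's information content).
  The assemblers therefore offer row-sum mass lumping (`lump = TRUE`),
  which restores the maximum principle for reaction-dominated elements;
  the reconstruction pipeline uses it, while element-level operations and
  convergence studies keep the consistent closed forms.
* **Ray tracing.** X-ray attenuation uses exact half-space clipping of the
  beam ray against every element's face planes; the ray is nudged
  laterally by ~1e-9 of the domain diameter into general position so that
  rays lying exactly in lattice face planes are not double counted.
* **Degenerate inputs.** Zero-volume tets, empty measurable selections,
  non-manifold faces, missing tissue labels and non-conformable systems
  all error with informative messages rather than propagating NaNs.

## Inverse problem

`reconstruct()` minimises
$\tfrac12\lVert AS - \Phi^m\rVert_2^2 + \tau\lVert S\rVert_1$ over
$S \ge 0$ with an incomplete-variables truncated conjugate gradient (IVTCG)
scheme: the variable with the most negative gradient joins the restricted
set (1 per outer iteration by default), truncated CG solves the restricted
normal equations (relative tolerance 1e-3), the iterate is projected onto
the non-negative orthant with backtracking, and iterations stop on relative
objective change < 1e-6 or after 50 outer iterations. The L1 norm is the
default because this solver family is sparsity-promoting; Tikhonov (L2) is
available via `solver = "tikhonov"`.

Two practical elements matter as much as the solver itself:

* **Column normalisation** (`normalize = TRUE`): the forward operator's
  columns decay steeply with depth, and without normalisation any sparse
  solution collapses onto superficial nodes (we observed 4-5 mm location
  errors even on noiseless same-mesh data; with normalisation, < 0.1 mm).
  `tau` is interpreted relative to $\max|A^T\Phi^m|$ so defaults transfer
  across measurement scales.
* **Debiasing refit** (`debias_refit()`): a non-negative least-squares
  refit on the recovered support expanded by its mesh neighbours,
  redistributing intensity over the physically contiguous cluster. This is
  the standard post-processing of sparse recovery and noticeably improves
  overlap (Dice) metrics.

Evaluation metrics follow the field's definitions: ARE (mean absolute
deviation over the *global* reference maximum), location error of the
energy-weighted centroid, Dice overlap of the region with values at or
above 30% of the maximum, and CNR with node-count weights and population
variances.

## Synthetic phantoms and what they do (and do not) show

`build_phantom()` meshes spheres, cylinders and slabs by structured lattice
subdivision (six Kuhn tets per cube, consistent across cubes) with tissue
assignment by centroid-inside tests, fully deterministic for a fixed spec.
`paper_like_phantom()` is a 35-mm-tall, 9-mm-radius cylinder with an
adipose background and five embedded organ compartments labelled with the
shipped murine optical table (`digimouse_610_630`, 610/630 nm), plus a
1-mm-radius spherical source inside the liver compartment — the same scale,
organ set, region split and source geometry as a murine torso experiment,
with geometric primitives standing in for the atlas anatomy.

Recovery experiments simulate forward data on a finer mesh (h = 0.8 mm,
~105k elements) than the reconstruction mesh (h = 1 mm, ~54k elements,
mirroring the ~117k/55k element split used at this problem scale), add 5%
relative Gaussian noise, and reconstruct with IVTCG from the 400
highest-signal surface nodes. This avoids the inverse crime, but the
lattice phantoms' stair-stepped organ boundaries make the two meshes
disagree more than two body-fitted meshes would, especially inside the
strongly absorbing 610-nm liver; passing tests therefore demonstrate
robustness to discretisation-level model error and measurement noise, not
to the anatomical, calibration and surface-mapping errors of real
experiments.

Single-wavelength recoveries locate the 1-mm source to ~0.1-0.2 mm, an
order of magnitude below the element size. At that floor the location
error of the stacked two-wavelength reconstruction is statistically
indistinguishable from the single-wavelength ones: across seeds it falls in
the same 0.05-0.3 mm band but is not ordered below the worse single
wavelength seed-by-seed, because the comparison is between two near-equal
noise-dominated quantities. Multispectral stacking is therefore reported as
"never meaningfully worse" (always well under a third of the element size)
rather than pointwise dominant at these conditions.

## Validation oracles

Two independent references validate the forward models:

* the closed-form infinite-medium diffusion Green's function
  $\Phi(r) = e^{-\mu_{\rm eff} r}/(4\pi D r)$, matched by the DE solver to
  a few percent on radial shell averages 3-10 transport lengths from a
  near-point source, with the error decreasing under uniform refinement;
* a voxelised Monte Carlo photon-transport simulator (exponential step
  sampling, Henyey-Greenstein scattering, weight absorption with Russian
  roulette at weight 1e-4 and survival 0.1, Fresnel partial reflection),
  deliberately independent of the tetrahedral meshes, with a
  platform-independent xoshiro256** generator so a fixed seed is
  bit-reproducible. Energy is conserved to 1e-10 with compensated
  accumulation. DE surface exitance agrees with MC binned exitance to an
  ARE of ~0.04 on the brightest equal-solid-angle surface patches of a
  homogeneous scattering sphere (1e6 photons), comparable to the accuracy
  this model family reports in the diffusive regime.

## Known limitations

* Lattice meshing only; no body-fitted or graded meshes, so organ
  boundaries are stair-stepped at the element scale.
* SP3 only (no SP5/SP7), steady-state only, single scattering phase
  parameterisation (Henyey-Greenstein).
* The luminescence yield is a free scale (default 1); X-ray attenuation
  defaults to zero (direct source specification is the primary phantom
  workflow, matching how simulated sources are placed at this scale).
* The regularisation parameter is user-supplied; no L-curve or
  cross-validation selection.
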