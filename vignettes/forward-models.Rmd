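---
title: "Surface-based forward models of MEG and EEG with cerebrospinal fluid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based forward models of MEG and EEG with cerebrospinal fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(headbem)
```

# The model

MEG and EEG signals are generated by primary current density in the cortex
flowing in a passive volume conductor. Under the quasi-static approximation
the electric potential solves a Poisson-type equation
$\nabla\cdot(\sigma\nabla\Phi)=\nabla\cdot\vec J_p$, and the magnetic field
follows from the Biot–Savart law applied to both the primary and the volume
("return") currents. When the head is modelled as piecewise-homogeneous and
isotropic — nested or non-nested compartments bounded by closed surfaces —
both quantities reduce to surface integrals: the potential satisfies a
boundary-integral equation whose kernel is the solid angle of the surface
elements, with each boundary weighted by its conductivity jump
$\sigma^- - \sigma^+$, and the volume-current contribution to the magnetic
field is the Geselowitz surface integral of the boundary potential, again
weighted by the jumps.

`headbem` discretises the boundary potential with linear (hat) basis
functions on triangle meshes and weights the residual either pointwise at
the vertices (linear collocation, LC) or with the hat functions themselves
(linear Galerkin, LG). The double-layer integrals of the linear basis are
evaluated with closed forms: the van Oosterom–Strackee solid angle plus
analytic edge (logarithmic) terms for the linear moments; the correctness of
this closed form is pinned against dense numerical quadrature in the test
suite. Compartment conductivities default to the standard values: brain and
scalp 0.33 S/m, CSF 1.79 S/m, and skull $0.33/K$ where $K$ is the
soft-tissue-to-skull resistivity ratio (plausible range roughly 20–80;
$K = 50$ is used for verification).

## Discretisation choices

**Collocation diagonal.** At a mesh vertex the surface is not smooth, so the
textbook factor $2\pi(\sigma^++\sigma^-)$ does not apply. The principal
value of the double layer over the faces adjacent to the collocation vertex
vanishes on flat triangles; the concentrated jump is handled with the *auto
solid angle*: the own-surface diagonal is set so that the interior-limit
row sum is exactly $4\pi$. This makes the operator annihilate constant
potentials to machine precision, for nested and non-nested topologies alike
(the row identity telescopes through the conductivity jumps of all
enclosing surfaces).

**Galerkin quadrature.** Outer integrals use a degree-5 7-point triangle
rule near the singularity, a degree-2 rule for separated pairs and a
centroid rule for panels more than about twelve panel diameters apart; pairs
of faces sharing a vertex are re-integrated on a recursively subdivided
outer triangle (two levels, 16 sub-triangles). The self-face jump
contributes exactly $2\pi$ times the element mass matrix. Because mixed
quadrature orders perturb the exact block row sums at the $10^{-4}$ level,
the known exact values ($4\pi$ times the mass-matrix row sum when the row
surface lies on or inside the column surface, zero otherwise) are restored
by spreading each block's deficit uniformly over its columns — the Galerkin
analogue of the auto solid angle. The constant null space is then exact to
machine precision.

**Deflation and reference.** The EEG operator determines the potential only
up to a constant; a rank-one deflation pins the mean potential of the
outermost surface to zero. Electrode topographies are subsequently
average-referenced before any metric is computed, so no result depends on
the deflation constant. Magnetometer readings are used raw.

**Isolated source approach (ISA).** With a poorly conducting skull, the
potential on and outside the skull is the small difference of large
contributions. The solver therefore first solves the *isolated* problem —
the sub-model consisting of the isolation surface (default: inner skull)
and everything inside it, with vanishing outside conductivity — and then
solves the full model with the modified right-hand side
$-\sigma_\mathrm{skull}\,B_\mathrm{iso}\,\varphi^0$, adding the isolated
potential back on the inner surfaces. Both steps reuse the same
geometry-dependent matrices, and the final result is exactly independent of
the arbitrary reference constant of the isolated solution (the identity
telescopes discretely; this is verified in the tests). ISA measurably
reduces the EEG error at fixed mesh for $K = 50$ and is on by default.

**Magnetic field.** The Geselowitz integrals are evaluated per triangle with
a 3-point rule, interpolating the *vertex normals* of the smooth surface
across each panel (curved-panel correction); the synthetic generators attach
analytic normals (exactly radial for icospheres, analytic normals of the
perturbed surface for perturbed spheres). Two exact identities follow: a
constant potential on a closed surface contributes nothing (each surface
operator is explicitly projected to annihilate constants, matching the
continuous identity), and on a concentric-sphere model with radial
magnetometer normals the volume-current term cancels from the readings
exactly, so the external field is conductivity-independent — the discrete
counterpart of the classical spherical-conductor result. Field points are
assumed at least ~15 mm outside the scalp (MEG helmets are), where the
kernels are smooth.

**Units.** Mesh coordinates are millimetres at all I/O boundaries and are
converted to SI metres at a single point before field computations; dipoles
(A·m), potentials (V) and fields (T) are SI throughout. Dipole moments
default to 10 nA·m; all metrics are scale-invariant, so the magnitude is
cosmetic.

# Synthetic geometry: what it emulates and what it does not

All experiments run on built-in surrogates; no anatomical data are needed.

* **Layered spheres** with radii 78/81/87/92 mm (pial, inner skull, outer
  skull, scalp): a 3 mm CSF layer, a 6 mm skull and a 5 mm scalp — plausible
  adult dimensions chosen once as the package default. Meshes are icospheres
  (recursive icosahedron subdivision; triangle-side length TSL halves per
  level) whose vertices lie exactly on the nominal spheres, so the analytic
  layered-sphere series is an exact reference for the continuum problem.
* **Perturbed spheres** displace all surfaces radially with one shared
  random band-limited (spherical-harmonic, degree ≤ 6) field, breaking the
  spherical symmetry so that MEG becomes sensitive to conductivities while
  preserving closedness, orientation and mutual distances (the surfaces stay
  radial graphs).
* **A non-nested surrogate** places three disjoint brain bodies in the
  CSF-conductivity space inside the inner skull, mirroring the
  five-sub-volume topology that arises when the cerebellum is meshed
  separately.
* **Sensors**: 256 electrodes on a deterministic Fibonacci lattice over the
  upper scalp, snapped to the mesh by radial ray casting and interpolated
  with the BEM hat basis; 102 magnetometers on an upper helmet cap
  (120 mm), radial 21 mm square coils integrated with 2×2 Gauss points.
  Counts match common whole-head systems so topography dimensionalities are
  realistic; the true vendor layouts are not reproduced.
* **Sources**: quasi-uniform dipoles in the brain volume, at least 1.5 mm
  below the pial surface; orientations radial, tangential, or seeded
  random. EEG studies use random orientations; MEG verification uses
  tangential dipoles (radial ones produce near-null fields by spherical
  symmetry) and MEG robustness studies random orientations.

What passing tests on these surrogates do **not** show: effects of real
cortical geometry (thin sulcal CSF, gyral crowns), segmentation errors,
tissue anisotropy, or sensor co-registration error. Spheres make EEG fully
and MEG minimally conductivity-sensitive; conclusions about the *size* of
CSF effects on MEG in real heads cannot be drawn from concentric spheres
(that is precisely why the perturbed surrogate exists).

# Verification and the convergence study

The analytic references are (i) the spherical-harmonic series for a dipole
in a piecewise-constant layered sphere, solved per degree with a small
interface linear system in per-layer normalised radial bases (adaptive
truncation to $10^{-10}$, eccentricities up to 0.95 converge in a few
hundred terms; the homogeneous special case is pinned against the classical
closed form) and (ii) the closed-form external field of a dipole in a
spherically symmetric conductor for MEG.

One verification subtlety matters: a mesh with vertices *on* a sphere is an
inscribed polyhedron, i.e. a slightly smaller conductor, and the volume
deficit depends on the mesh level. With mixed per-surface levels this
biases effective layer thicknesses (about 1 % of the 6 mm skull between
levels 3 and 4) and appears as a uniform, depth-independent amplitude
error against a nominal-radius oracle. The oracle therefore uses each
mesh's *equal-volume* sphere radius — the spherical conductor closest to
the one the BEM actually solves — and evaluates electrode positions that
fall marginally outside that radius at the outer boundary.

The convergence family meshes pial, inner and outer skull at icosphere
level $\ell = 2, 3, 4$ (TSL roughly 20, 10, 5 mm on the pial sphere) with
the scalp capped at level 3 (a level-2 scalp supports neither method),
200 dipoles, $K = 50$. Median relative errors against the oracle decrease
monotonically for both weightings and modalities: LC 30 % → 12 % → 4.8 %,
LG 1.6 % → 0.32 % → 0.30 %. LC is limited by the pointwise treatment of
the thin skull and plateaus near 5 %; the acceptance test therefore bounds
LC at 6 % (the observed value plus a margin for the sampling variability
of the 200-source median) and LG at the 2 % target it comfortably meets.
MEG errors are orders of magnitude smaller (≈ $10^{-5}$) because radial
magnetometers measure only the primary field in spherical geometry; their
residual reflects volume-current leakage through the off-centre coil
integration points and also decreases with mesh density.

# The compensation study

Omitting the highly conducting CSF from a three-shell (3-S) model biases
EEG amplitudes upward; lowering the skull conductivity compensates. The
study fixes the geometry (reference meshing: pial and inner skull at level
4, outer skull and scalp at level 3; LG weighting for all models, so
conductivity is the only varying factor, as in a conductivity-focused
analysis), sweeps the reference 4-C model over $K_\mathrm{ref} \in
\{20,\dots,80\}$ and test models over $K_\mathrm{test}$ grids (4-C: 20–80;
3-S: 20–170, step 10), and summarises per-source RE and CC by median and
16th/84th percentiles. The *expectation* over the unknown true skull
conductivity is the unweighted mean over the $K_\mathrm{ref}$ grid (the
range and step are specified; a flat weighting is the neutral choice). The
optimal ratio minimises the expected median RE, with candidates within one
percentage point resolved by the better expected CC. Weak sources are not
excluded from any summary.

On the default surrogate the selection lands at $K_\mathrm{opt} = 50$ for
the 4-C model and $K_\mathrm{equi} = 100$ for the 3-S model, with
per-$K_\mathrm{ref}$ compensation factors running from 2.5 (at
$K_\mathrm{ref}=20$) to about 1.8 (at 80) and a CC-optimal factor of 1.5 —
the compensation behaviour is essentially geometry-independent. The
*absolute* error of the uncompensated 3-S model is not: a uniform 3 mm
spherical CSF layer shunts less volume current than the sulcal and
ventricular CSF of a real head, so the surrogate's uncompensated mean RE
(~32 %) sits below the level seen with anatomical models (above 40 %),
while compensation still cuts it by more than half (to ~13 %).

# Numerical and degenerate-input notes

* Solid angles and double-layer weights are scale-invariant; evaluation at
  a point on a surface raises a singular-evaluation error (LC handles its
  own vertices via the auto solid angle instead).
* Coplanar exterior observation points have exactly zero double-layer
  weight; the in-plane guard activates below $10^{-12}$ panel diameters.
* Meshes are re-oriented outward on load by a signed-volume check (with a
  warning); degenerate faces are rejected at construction.
* STL carries no connectivity, so vertices are merged at $10^{-6}$ mm on
  read.
* The series solution refuses dipoles outside the innermost layer and
  reports non-convergence beyond the truncation cap with the eccentricity
  in the message.
* Sweeps reuse one assembly per geometry; factorisations are cached per
  conductivity fingerprint and only the latest is retained, bounding
  memory.

# Problem sizes

Defaults were chosen so that the full verification family, the compensation
study (7×7 and 7×16 grids, 200 sources, 256 electrodes) and the
perturbed-sphere MEG sweep complete on a single desktop CPU core in tens of
minutes in total: reference models have ~6 400–8 300 vertices (dense LU
with reuse across right-hand sides), test models ~2 000–3 800.

# Known limitations

* LC accuracy on thin-shell geometry plateaus near 5 % median RE; use LG
  for reference-quality computations.
* The non-nested surrogate is built disjoint by construction; no mesh
  repair of intersecting anatomy is provided.
* No anisotropy, no gray/white distinction, no skull fine structure;
  gradiometers and realistic coil geometries are out of scope.
* FreeSurfer binary surfaces are not read; OFF/PLY/STL are.
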