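# headbem

Surface-based boundary-element (BEM) forward models of MEG and EEG, with
explicit support for the cerebrospinal fluid (CSF) compartment and for
*compensating* its omission.

## The problem

Interpreting MEG/EEG signals requires a forward model: the mapping from a
cortical current dipole to the signals it produces at the sensors. Routine
analysis uses three-shell (3-S) head models (brain, skull, scalp) that omit
the highly conducting CSF between brain and skull, which measurably distorts
EEG topographies. A four-compartment (4-C) model (brain, CSF, skull, scalp)
fixes this at modest cost — and when the CSF *is* omitted, its effect on EEG
can be partially compensated by lowering the skull conductivity of the 3-S
model. `headbem` implements the forward solver and the machinery to quantify
both effects, for researchers developing or validating MEG/EEG volume
conductor models.

## The model

The head is piecewise-homogeneous and isotropic: closed triangulated
surfaces \(S_l\) separate compartments with conductivities jumping by
\(\sigma^-_l - \sigma^+_l\). The potential solves the boundary-integral
equation

\[ 2\pi(\sigma^+_k+\sigma^-_k)\,\phi(\mathbf r) = g(\mathbf r) +
\sum_l (\sigma^-_l-\sigma^+_l)\int_{S_l}\phi(\mathbf r')\,
\frac{(\mathbf r'-\mathbf r)\cdot d\mathbf S'}{|\mathbf r-\mathbf r'|^3},
\qquad \mathbf r \in S_k, \]

with \(g\) the infinite-medium dipole term, and the magnetic field follows
from the Geselowitz equation (primary Biot–Savart field plus the
boundary-potential surface integrals). The solver discretises \(\phi\) with
linear basis functions — collocation (LC) or Galerkin (LG) weighting — with
closed-form double-layer integrals, deflation, and the isolated source
approach (ISA) for the high-contrast skull. Conductivities: brain/scalp
0.33 S/m, CSF 1.79 S/m, skull \(0.33/K\) with \(K\) the skull resistivity
ratio (plausible range 20–80).

Verification is against analytic oracles on synthetic geometry (no
anatomical data needed): the spherical-harmonic series for a dipole in a
layered concentric sphere (EEG) and the closed-form external field of a
spherically symmetric conductor (MEG).

## Worked example

Build a four-compartment sphere model (`K = 50`), solve it with linear
Galerkin BEM, and check the EEG leadfield against the layered-sphere series:

```r
library(headbem)

model <- build_layered_sphere_model(
  "4C", K = 50,
  mesh_levels = c(pial = 3, inner_skull = 3, outer_skull = 3, scalp = 3))
sources <- build_source_space(50, radius_range = c(0, 76.5),
                              orientation_mode = "random", seed = 1)
arrays  <- build_sensor_arrays(model)          # 256 electrodes, 102 magnetometers
system  <- assemble_system(model, method = "LG", use_isa = TRUE)

lf <- eeg_leadfield(model, system, sources, arrays$electrodes)

oracle <- multilayer_sphere_potential(as_layered_sphere_spec(model),
                                      sources, arrays$electrodes$positions)
compare_leadfields(sweep(oracle, 2, colMeans(oracle)),  # average reference
                   lf$matrix)
```

```
<metric_summary over 50 sources: median RE 0.0032, median CC 1.00000>
```

A median relative error (RE) of 0.33 % means the BEM topographies agree
with the analytic solution to a few parts in a thousand at this mesh
density; the correlation coefficient (CC) near 1 says the topography
*shapes* are essentially exact. The same pipeline with
`meg_leadfield()` verifies MEG against `sarvas_field()`.

The compensation analysis runs the skull-conductivity sweeps and selects
the optimal 4-C ratio (`K_opt`) and the equivalent 3-S ratio (`K_equi`)
that best stands in for the missing CSF:

```r
study <- compensation_study(sphere_geometry(), n_sources = 200)
study$K_opt    # 50
study$K_equi   # 100
mean(study$uncompensated$re)   # 0.323 : uncompensated 3-S EEG error (mean RE)
mean(study$compensated$re)     # 0.134 : with the compensated skull conductivity
```

Command-line wrappers (`verify-sphere`, `study`, `forward`) over the same
functions live in `inst/cli/headbem`, driven by a YAML config
(`inst/extdata/study-default.yaml` documents the schema).

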