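---
title: "Needle-electrode EIT on a resistor mesh: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needle-electrode EIT on a resistor mesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitmesh)
```

## The imaging problem

Electrical impedance tomography injects current between boundary electrodes
and infers the internal resistance distribution of a medium from the
voltages that appear on the remaining electrodes. `eitmesh` targets a
specific acquisition geometry: hollow brachytherapy needles inserted
through the standard 13×13 guide template (130 mm square) act as the
electrodes, so the "boundary" is a ring of needles placed *inside* the
tissue around the region of interest. The continuum physics is Poisson's
equation ∇·(σ∇U) = 0 with a current (Neumann) boundary condition; this
package never discretizes the PDE directly. Instead the medium is modelled
from the outset as a square resistor network — the discrete form in which
the method was conceived — and all voltages follow from circuit analysis.

## Forward model

An `s × s` node lattice carries `2(s² − s)` resistors: `z_h[k, j]` between
nodes N[k,j] and N[k,j+1], `z_v[k, j]` between N[k,j] and N[k+1,j]
(`eit_grid()`). Kirchhoff's current law at every node yields `C* V_f = I`
with `C*` the nodal conductance matrix assembled from 1/z
(`assemble_conductivity()`); resistors that would cross the lattice
boundary are simply absent, which is the infinite-resistance convention.
`C*` is a graph Laplacian — symmetric, zero row sums — and singular, so one
node is grounded: row and column `g` are zeroed and the diagonal entry
pinned to exactly 1 (`ground_conductivity()`, the Hadamard-product
construction with `G[g,g] = 1/C*[g,g]`). Assumptions worth stating:

* **Purely resistive network.** No reactive components; the injection
  frequency is carried only as a label on measurement frames. This is why
  frequency-difference imaging is a pure data-level subtraction here.
* **Ideal point electrodes.** A needle is a single mesh node; there is no
  contact impedance and no complete-electrode model.
* **2-D slice.** The mesh represents the template plane at the needles'
  insertion depth; out-of-plane current spread is not modelled.

The adjacent protocol (`adjacent_protocol()`) drives consecutive electrode
pairs (1,2), (2,3), …, (E,1) and measures differential voltages on every
consecutive pair not touching the drive pair — needles carrying current
are never used to measure. With the default eight needles: 8 patterns × 5
pairs = 40 measurements per frame.

## Inverse solver

`eit_reconstruct()` is a damped Gauss-Newton (Modified Newton-Raphson)
iteration on the resistance vector `z` minimizing
θ(z) = ½‖V(z) − V0‖². Each iteration simulates `V(z)`, forms the Jacobian
`J = ∂V/∂z`, and applies

Δz = −(JᵀJ + λI)⁻¹ Jᵀ (V − V0).

With 40 measurements against 1,300 unknowns the problem is severely
underdetermined; the Marquardt term λI is what keeps the damped Hessian
invertible and selects a small-norm update.

**Jacobian.** The default is the adjoint formulation: with `u_p` the nodal
field of the drive pattern and `u_m` the field of a unit current driven
through the measurement pair, the sensitivity of that measurement to the
resistor spanning nodes (α, β) is `z⁻² (u_p[α]−u_p[β]) (u_m[α]−u_m[β])`.
One Cholesky factorization per iteration serves all 8 drive fields and the
8 distinct measurement-pair fields, so a full 40 × 1,300 Jacobian costs 16
triangular solves. A central finite-difference Jacobian is retained purely
as an independent oracle; the test suite requires agreement to 1e-4
relative on random meshes.

## Tunable parameters

| Parameter | Unit | Default | Notes |
|---|---|---|---|
| `s` | nodes/side | 26 | even multiple of the 13 template holes; 1,300 resistors |
| `amplitude_A` | A | 0.015 | injected current per pattern |
| `z0` | Ω | scenario background | recovery is reliable when \|z0 − z_true\| < 10 Ω |
| `lambda` | – | 1e-8 | useful band ≈ 1e-9–1e-8 for this protocol; constant across iterations (no adaptive schedule) |
| `max_iter` | – | 3 | the update magnitude has stabilized by then on these protocols |
| `delta_tol` | Ω | 0 | infinity-norm threshold on Δz; no canonical value exists, so the iteration cap governs by default |
| `z_floor` | Ω | 1e-6 | positivity clamp after each update |
| `snr_db` | dB | Inf | optional Gaussian measurement noise (simulation only) |

## Numerical choices

* **Factorization, not inversion.** The grounded matrix is symmetric
  positive definite; all solves use one Cholesky factorization per mesh.
  The exact-zero structure of the grounded row/column guarantees the ground
  voltage is exactly 0 in every solution.
* **Update via the push-through identity.** (JᵀJ + λI)⁻¹Jᵀ = Jᵀ(JJᵀ + λI)⁻¹
  exactly, so the damped step is an n × n solve (n = 40) instead of a
  1,300 × 1,300 one. Tests verify both routes agree on small systems.
* **Positivity clamp.** A Gauss-Newton step can overshoot into nonphysical
  negative resistances; after each update `z` is clamped to `z_floor` so
  conductances stay finite. Highly conductive inclusions therefore
  reconstruct as floor-valued resistors, not zeros.
* **Monotonicity is checked, not guaranteed.** On noiseless synthetic
  frames the suite asserts θ is non-increasing over the default three
  iterations; Gauss-Newton offers no such guarantee with noise, so noisy
  traces are recorded and reported but not enforced.
* **Normalization convention.** Tomograms map resistance affinely to
  [0, 1]; a constant image maps to all zeros. The rasterizer assigns each
  of the (s−1)² cells the mean of its four bounding resistors — symmetric
  and orientation-agnostic; no claim is made of reproducing any specific
  published figure's interpolation.

## Design choices where the design was open

* **Ground node.** Any single node may be grounded; the package fixes the
  corner N[s, s], which can never be a template hole (holes sit on the odd
  sublattice). Simulation and reconstruction must share the ground, and do
  by default.
* **Template-to-mesh map.** Thirteen holes coincide with 26 nodes only on
  an every-other-node sublattice; hole (a, b) maps to node (2b−1, 2a−1),
  anchored so corners align. Note the physical pitch implied by the node
  lattice (10.4 mm between holes) differs slightly from 130 mm/12; the
  node lattice is the package's canonical coordinate system.
* **Measurement polarity.** Differential voltage v[a] − v[b] with `a` the
  lower electrode ordinal, rows ordered by pattern then ring position — a
  fixed convention so frames from different sources are comparable.
* **Frequency-difference reconstruction** runs the unchanged MNR machinery
  on the difference frame; no separate linearization is introduced.

## The phantom generator

`phantom_spec()` / `generate_phantom()` build a uniform background with
circular or rectangular inclusions; a resistor belongs to an inclusion if
its physical midpoint falls inside (later inclusions override earlier
ones). `scenario_phantom()` packages the bench-scenario classes the method
was validated on: a 38 mm or 16 mm conductive disc (aluminum modelled as
1e-3 Ω) in a 5 Ω saline-like background, the same disc in a 60 Ω
gelatin-like background, and a moderately conductive 20 Ω "meat" inclusion
in gelatin. The physical experiments did not record the template
coordinates of the eight needles, so `default_electrodes()` places them as
a symmetric ring of template holes around the centre hole — a package
assumption, stated here once.

What the generator deliberately does **not** emulate: electrode contact
impedance, needle-shaft conduction along the insertion axis, 3-D current
spread, electronics drift, or frequency-dependent tissue dispersion
(inclusions differ between frequency labels only if the user supplies
different phantoms). Passing recovery tests on these phantoms therefore
demonstrates correctness of the discrete model and solver — not clinical
imaging performance on real tissue.

## Problem sizes used by the test suite

Structural and oracle checks run on meshes of side 2–8 (hand-solvable
loops, finite-difference Jacobians, reciprocity); recovery and
acceptance checks run the full 26-node, eight-needle, 40-measurement,
3-iteration configuration, which completes in under a second per scenario.
The suite's random meshes are locally seeded, so every test is
reproducible in isolation.

## Known limitations

* Resolution is bounded by 40 measurements against 1,300 unknowns;
  reconstructions localize inclusions well inside the electrode ring but
  cannot recover fine structure, and sensitivity decays quickly outside
  the ring.
* Absolute imaging assumes the background resistance is roughly known
  (the |z0 − z_true| < 10 Ω guidance); a badly chosen z0 degrades
  recovery.
* No complete-electrode model: measured data from hardware with
  significant contact impedance will carry a systematic component the
  model cannot fit.
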