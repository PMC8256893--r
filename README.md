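# eitmesh

Electrical impedance tomography (EIT) with brachytherapy needles as the
electrodes. In high-dose-rate prostate brachytherapy, hollow needles are
inserted through a standard 13×13 guide template (130 mm extent); because
the needles are conductive, they can double as current-injection and
voltage-measurement electrodes deep inside the tissue, where conventional
surface-electrode EIT cannot reach. `eitmesh` implements that imaging
method end to end for researchers in biomedical image reconstruction:
forward simulation of the needle measurements on synthetic phantoms, the
inverse reconstruction, and tomogram rendering.

## The model

The medium is discretized as a square mesh of `s × s` nodes joined by
`2(s² − s)` resistors (`s = 26` → 1,300 resistors; every template hole
coincides with a mesh node). Kirchhoff's current law at each node gives the
nodal system

    C* V_f = I,

where `C*` is the `s² × s²` conductance (Laplacian) matrix and `I` carries
`+I` / `−I` at the injection pair (15 mA by default). `C*` is singular; one
node is grounded by the Hadamard-product construction `C = C* ∘ G`
(row/column of the ground zeroed, grounded diagonal pinned to 1), after
which `V_f = C⁻¹ I`.

Measurements follow the **adjacent protocol**: current through consecutive
electrode pairs (1,2), (2,3), …, (E,1); differential voltages on every other
consecutive pair not touching the drive electrodes. With E = 8 needles this
yields 8 patterns × 5 pairs = 40 unique measurements.

The inverse problem — recover the resistance vector `z` from measured
voltages `V0` — is solved by the Modified Newton-Raphson (damped
Gauss-Newton) iteration

    θ(z)  = ½ (V(z) − V0)ᵀ (V(z) − V0)
    Δz    = −(JᵀJ + λW)⁻¹ Jᵀ (V(z) − V0),      W = identity
    z     ← z + Δz,

with the Jacobian `J = ∂V/∂z` computed by exact adjoint sensitivities
(`∂V_m/∂z_i = z_i⁻² (u_p[a]−u_p[b])(u_m[a]−u_m[b])`), Marquardt damping
`λ = 1e-8` by default, and a 3-iteration termination. Absolute imaging
reconstructs a single-frequency frame; frequency-difference imaging feeds
the difference of two frames (e.g. 179 kHz − 1 kHz) to the same machinery.
Images are the `(s−1)×(s−1)` cell raster of the resistance map, normalized
to [0, 1].

## Worked example

Reconstruct a 38 mm conductive disc (an aluminum-cylinder analogue,
0.001 Ω) centred in a 5 Ω saline-like background, using the default
eight-needle ring:

```r
library(eitmesh)

sc    <- scenario_phantom("saline_large_disc")
truth <- generate_phantom(sc$spec)
prot  <- adjacent_protocol(
  map_template_to_node(sc$electrodes$a, sc$electrodes$b, 26), 26)
prot
#> Adjacent EIT protocol: 8 electrodes, 8 injection patterns, 40 measurements,
#> 15 mA on a 26 x 26 node mesh

frame <- simulate_measurements(truth, prot)
fit   <- eit_reconstruct(frame, prot, z0 = 5)
summary(fit)
#> EIT resistance reconstruction (Modified Newton-Raphson)
#>   mesh: 26 x 26 nodes (1300 resistors), 8 electrodes, 40 measurements
#>   z0 = 5 ohm, lambda = 1e-08, stopped by max_iter after 3 iteration(s)
#>   final objective: 4.068e-07 V^2, resistance range 1e-06 -- 5.546 ohm
#>
#> Iteration trace:
#>  iteration    objective update_norm
#>          1 4.667547e-05   4.1340382
#>          2 3.467237e-06   2.2819436
#>          3 4.067659e-07   0.6300218
#>
#> Reconstructed resistances (ohm):
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.000001 4.742010 4.985455 4.580339 5.019394 5.545970
#>
#> Voltage residuals: RMS 0.0001613 V, max |r| 0.0002305 V

round(peak_region_centroid(fit, "min"), 1)
#> x_mm y_mm
#> 62.4 62.4
plot(fit)   # normalized tomogram, dark = low resistance
```

The misfit θ drops two orders of magnitude over the three iterations, the
lowest-resistance region is driven towards the floor inside the disc, and
its centroid lands on the true inclusion centre (62.4, 62.4) mm.

A full pipeline (phantom → simulate → reconstruct → render, with a
manifest of all artifacts) is available as `run_pipeline(run_config(...))`
or from the shell via `inst/cli/eitmesh-cli.R`.

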