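# ehgsim

Forward simulation of electrohysterogram (EHG) surface potentials, for
researchers comparing surface-electrode designs for non-invasive uterine
monitoring.

The EHG is the electrical activity of the uterine muscle (myometrium)
recorded on the abdomen of a pregnant woman. Whether it is best recorded
with a plain monopolar disc or with Laplacian concentric-ring electrodes
is an electrode-design question that can be answered computationally.
`ehgsim` implements the full forward chain:

* **Dipole-band source** — the travelling depolarization front as an
  annular band of dipoles on a conical uterus wall (half-angle θ = 10°,
  speed c = 30 mm/s, width δ = 6 mm, moment p₀ = 2.2×10⁻¹³ C·mm),
  whose axial potential is the closed-form difference of its two
  edge-ring terms, scaled by the band density
  `D = p0 / (π sinθ [(R+δ)² − R²])`.
* **Layered volume conductor** — a hemispherical abdomen (100 mm) of
  skin / fat / muscle shells over a grounded myometrium surface, solved
  quasi-statically (`∇·(σ∇φ) = −∇·Js`) with a finite-difference operator
  (harmonic-mean face conductances; sparse Cholesky or preconditioned
  conjugate gradients).
* **Four electrode read-outs** — monopolar disc average and the bipolar
  `(4/r²)(v̄ᵣ − v₀)`, quasi-bipolar `(v̄₂ᵣ + v₀)/2 − v̄ᵣ` and tri-polar
  `(1/3r²)[16(v̄ᵣ − v₀) − (v̄₂ᵣ − v₀)]` concentric-ring Laplacian
  estimators, plus their five-point and nine-point stencil oracles.
* **Experiment drivers** — waveform recording, conduction-delay /
  propagation-speed estimation, attenuation sweeps with the 20 dB
  sensitivity distance (with or without six random noise dipoles), and
  fat/muscle thickness sweeps.

## Worked example

```r
library(ehgsim)

band <- dipole_band_params()          # the standard parameter set
round(band_traversal_time(band))
#> [1] 27

# conduction delay between axial observation points 50 mm apart
w <- simulate_round_trip(band, zetas = c(0, 50), dt = 0.1,
                         t_end = band_traversal_time(band))
est <- estimate_propagation_speed(w[[1]], w[[2]], spacing = 50,
                                  method = "onset", outbound_only = FALSE)
c(est$delay_s, est$speed_mm_s)
#> [1]  1.773026 28.200378

# local sensitivity of the four designs (10 mm outer ring)
model <- abdomen_model()
specs <- list(electrode_spec("monopolar", r = 5),
              electrode_spec("bipolar", r = 5),
              electrode_spec("quasi_bipolar", r = 5),
              electrode_spec("tripolar", r = 5))
curves <- attenuation_sweep(model, band, specs)
sapply(curves, function(cu) as.numeric(distance_at_attenuation(cu)))
#> monopolar: 30.0 (censored)   bipolar: 9.9
#> quasi_bipolar: 30.0 (censored)   tripolar: 9.6
```

Reading the numbers: the band needs 27 s for its fundus-to-cervix
traversal; the onset-latency delay of 1.77 s over 50 mm implies an
apparent conduction speed of 28 mm/s (quadratic peak timing gives
31 mm/s — see the vignette on why the estimators differ). In the
attenuation sweep, the bipolar and tri-polar rings lose 20 dB within
about 10 mm of source displacement while the monopolar and quasi-bipolar
read-outs never do within 30 mm: the true-Laplacian designs are the more
local, hence preferred, EHG electrodes.

Batch runs are driven by a YAML configuration
(`inst/extdata/example-config.yaml` documents the format) through
`run_experiment()` or the CLI wrapper:

```sh
Rscript inst/scripts/ehgsim.R sweep-attenuation --config my-config.yaml --outdir out
```

Every experiment writes CSV tables plus a JSON metadata file sufficient
to reproduce it exactly.

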