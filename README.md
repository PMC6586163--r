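# rootprobe

Quantitative analysis of radial water and solute transport in plant roots
measured with the **root pressure probe**, plus the calibrations, suberin
chemistry and statistics that accompany such experiments.

## The problem

When a root is excised and sealed to a pressure probe, it builds up a
steady root pressure. Perturbing the system — mechanically with the
probe's micrometer screw, or osmotically by changing the bathing medium —
produces pressure relaxations whose kinetics encode the root's transport
properties under the composite transport model:

* **Hydrostatic relaxations** are single exponentials with rate constant

  `kwr = ln 2 / t½w = Lpr · Ar · β`

  where `Lpr` (m s⁻¹ MPa⁻¹) is the root's hydraulic conductivity, `Ar`
  (m²) the mounted root surface area and `β` (MPa m⁻³) the elastic
  coefficient of the measuring system.

* **Osmotic responses** (e.g. adding 30 mM NaCl ≙ 60 mOsmol kg⁻¹, an
  osmotic step `Δπ°s = R·T·Cs ≈ 0.148 MPa` at 23 °C) are biphasic: a
  rapid exosmotic water phase is followed by a slower recovery as the
  solute permeates with rate constant

  `ksr = ln 2 / t½s = Ar · Psr / Vx`

  with `Psr` (m s⁻¹) the solute permeability and `Vx` the functional
  xylem volume (1.5 % of the conductive root cylinder). The reflection
  coefficient follows from the depth `ΔPr` and time `tmin` of the
  pressure minimum:

  `σsr = (ΔPr / Δπ°s) · exp(ksr · tmin)`

The package provides a deterministic forward simulator for both
experiment types, the inverse estimator `probe_fit()` with the standard
cut-test quality control, PEG-8000 osmoticum calibration
(`peg8000_water_potential()`), zone-resolved suberin monomer
quantification normalized to endodermal surface area
(`aggregate_amounts()`), one-way ANOVA with Fisher-LSD compact letter
displays, TPM expression summaries, and seeded synthetic-data generators
so the whole pipeline can be validated end to end without any
experimental data.

It is aimed at plant physiologists analyzing pressure-probe traces and at
anyone who wants a transparent, testable reference implementation of the
composite-transport-model arithmetic.

## Worked example

Simulate one root at typical control-condition parameters
(`Lpr = 8.11e-8 m s⁻¹ MPa⁻¹`, `Psr = 2.24e-9 m s⁻¹`, `σ = 0.38`) with
realistic sensor noise (sd 0.002 MPa), then recover the parameters:

```r
library(rootprobe)

pr <- probe_system(beta = 1.09e10, Ar = 1.57e-4)
ge <- root_geometry()            # 0.1 m conductive length, 0.5 mm diameter
tp <- transport_params(Lpr = 8.11e-8, Psr = 2.24e-9, sigma = 0.38)

set.seed(7)
hy  <- simulate_hydrostatic_relaxation(tp, pr, noise_sd = 0.002)
os  <- simulate_osmotic_response(tp, pr, ge, noise_sd = 0.002,
                                 delta_pi = vant_hoff_osmotic_pressure(60),
                                 duration = 2400, dt = 0.5)
fit <- probe_fit(hy, os, pr, ge)
summary(fit)
#> Transport parameters (conventional units):
#> Lpr_hydrostatic (1e-8 m/s/MPa)     Lpr_osmotic (1e-8 m/s/MPa)
#>                          8.145                          8.819
#>                 Psr (1e-9 m/s)                          sigma
#>                          2.211                          0.389
#> half-times: t1/2w = 4.97 s, t1/2s = 588 s
#> biphasic minimum: deltaPr = 0.05562 MPa at tmin = 27 s
#> QC: indeterminate
```

The true values are recovered within a few percent from a single noisy
trace pair: the water-exchange half-time of ~5 s gives the hydrostatic
`Lpr`, the solute half-time of ~10 min gives `Psr`, and the
permeation-corrected depth of the pressure minimum gives `σ`.

The PEG-8000 calibration reproduces the standard osmotic-stress recipes:

```r
peg8000_water_potential(c(0.175, 0.254, 0.316))   # % w/w at 23 °C
#> [1] -0.4078856 -0.8134050 -1.2281112             # ≈ -0.4 / -0.8 / -1.2 MPa
```

`run_pipeline(simulation_config(seed = 1))` executes the full synthetic
study — probe cohorts (n = 8 roots per group), zone-resolved suberin
tables with LSD letters, TPM summaries — and writes CSV tables plus a
`results.json` into a run directory, byte-reproducibly per seed.

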