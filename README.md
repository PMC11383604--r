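# mmwr — magnetic microwire rheometry of airway mucus gels

Airway mucus turns pathologically solid in type-2 ("asthmatic")
inflammation, and understanding that transition requires measuring the
mechanics of the thin mucus gel secreted by airway epithelial cells *in
situ*, on top of the living culture. The magnetic microwire rheometer
(MMWR) does this by laying a glass-coated ferromagnetic microwire on the
mucus surface, pulling it axially with a calibrated magnetic step force
(10 s on / 20 s off, twice, imaged every 500 ms), and reading the gel's
creep compliance from the wire's displacement.

This package is the analysis side of that experiment, for researchers
doing live-cell rheology on ALI (air–liquid interface) epithelial
cultures — plus a synthetic-data generator with known ground truth so the
entire inference chain can be validated end to end.

## The model

Creep compliance follows from wire displacement as

    J(t) = C · x(t) / F0,      C = 4πL / arccosh(h/r)

where `C` is the drag coefficient of a cylinder (radius `r`, length `L`)
translating parallel to a no-slip surface at height `h` — here the cell
layer, localized per culture from multi-channel intensity z-profiles.
The compliance curve is fitted with the four-parameter Burgers model

    J(t) = J1 + J2·(1 − exp(−t/τ)) + t/η0

yielding the steady-state compliance `Je0 = J1 + J2` (softness) and the
zero-shear viscosity `η0` (resistance to flow). Creep recovery after
force cessation classifies each gel: a viscoelastic solid recoils
(nearly) completely, a liquid only partially. Cohorts are compared per
donor with ratio paired t tests (paired t on log within-donor ratios) of
`Je0` and `η0`, after averaging transwell-insert replicates.

## Worked example

A bundled synthetic acquisition (a liquid-like gel, 2% displacement
noise, truth `Je0 = 0.15 Pa⁻¹`, `η0 = 200 Pa·s`):

```r
library(mmwr)

# 1. wire height above the cell layer, from the z-profile scan
prof <- read_zprofiles_csv(system.file("extdata", "synthetic_zprofiles.csv",
                                       package = "mmwr"))
layers <- locate_layers(prof)
#> cell surface 10.12 um, wire centre 66.96 um, wire height 56.83 um

# 2. drag coefficient for this geometry
geom <- wire_geometry(h = layers$wire_height_um * 1e-6)
geom$C
#> [1] 0.03011   # metres

# 3. displacement -> compliance -> Burgers fit
tr <- read_trace_csv(system.file("extdata", "synthetic_trace.csv",
                                 package = "mmwr"))
cc <- compliance_from_displacement(tr, F0 = max(tr$force_N), C = geom$C)
fit_burgers(cc)
#> Burgers creep fit (2 cycles)
#>   Je0  = 0.1471 1/Pa
#>   eta0 = 192.6 Pa s
#>   recovery ratio = 0.745 -> viscoelastic_liquid
#>   residual RMS = 0.00328
```

The fitted softness and viscosity land within a few percent of the
generating truth; the recovery ratio of 0.75 (only partial recoil) marks
the gel as a viscoelastic liquid. For a full cohort —
simulate, fit every trace, compare conditions — see the numbered scripts
under `analysis/` (`01_simulate.R` … `04_validate.R`), which write their
tables and report under `results/`, or call `run_experiment()` directly.

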