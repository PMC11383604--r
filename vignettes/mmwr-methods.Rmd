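---
title: "Creep compliance microrheology of mucus gels with a magnetic microwire: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Creep compliance microrheology of mucus gels with a magnetic microwire: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmwr)
```

# The measurement

Airway epithelial cells grown at air–liquid interface (ALI) secrete an
apical mucus gel whose mechanics cannot be probed by bulk rheometry without
destroying the culture. The magnetic microwire rheometer (MMWR) solves this
by laying a glass-coated ferromagnetic microwire (radius ~12.3 µm, length
5.3 mm) on the mucus surface between two electromagnetic coils in
anti-Helmholtz configuration. The coil current produces a uniform field
gradient and hence a constant axial force on the wire; the wire's
displacement is imaged every 500 ms. The standard protocol applies the
force for 10 s, releases it for 20 s, and repeats once — one minute per
measurement.

This package implements the full inference chain from that raw measurement
to cohort-level biology: displacement → creep compliance → Burgers model
parameters → liquid/solid classification → paired condition statistics. A
synthetic-data generator produces every input with known ground truth so
the chain can be validated end to end.

# From displacement to compliance

Creep compliance is strain per unit stress under a constant load,

$$J(t) = \frac{C\,x(t)}{F_0},$$

where $x(t)$ is the wire displacement, $F_0$ the applied force, and $C$ a
geometric drag coefficient with units of length that converts the wire's
force/displacement into the material's stress/strain. Treating the wire as
a cylinder translating along its axis at height $h$ above a no-slip plane
(the cell layer, far stiffer than the mucus above it), lubrication theory
gives

$$C = \frac{4\pi L}{\operatorname{arccosh}(h/r)}.$$

The arccosh form is used rather than the far-field $\ln(2h/r)$
approximation because the wire sits close to the surface ($h/r \approx
4.6$ at the typical $h$ = 57 µm); the two agree asymptotically, which the
test suite exploits as a built-in cross-check. $C$ diverges at contact
($h \to r$) and decreases monotonically with height; `wire_geometry()`
refuses $h \le r$.

The height $h$ is measured per culture from a multi-channel axial scan:
the membrane stain (647 nm) localizes the cell surface, the bright-field
channel the wire centre, and fluorescent particles (488 nm) the top of the
mucus layer. `locate_layers()` takes the dominant peak of each channel
with sub-grid precision — a three-point parabolic interpolation around the
argmax, refined by a Gaussian-plus-baseline least-squares fit of the peak
neighbourhood. The refinement matters only under noise: three samples
cannot average intensity noise, while the full peak (width ~4 µm) can.
The mucus-top channel is reported but does not enter $C$.

The applied force comes from a linear force–current calibration,
through the origin by default because the coil pair produces a
proportional force. Anchored at (0.6 A, 110 nN) — the control-condition
setting — the line predicts 458.3 nN at the 2.5 A used for stiffer
IL-13 gels, matching the instrument's nominal 460 nN to 0.4%.

# The Burgers model

A mucus gel shows three creep regimes: an instantaneous elastic jump, a
retarded elastic rise, and steady viscous flow. The four-parameter Burgers
model (a Maxwell element in series with a Kelvin–Voigt element) is the
minimal model with all three:

$$J(t) = J_1 + J_2\left(1 - e^{-t/\tau}\right) + \frac{t}{\eta_0}.$$

* $J_1$ (Pa⁻¹) — instantaneous compliance, the reciprocal of the first
  spring modulus $E_1$;
* $J_2$ (Pa⁻¹) — retarded compliance, reciprocal of the second spring
  $E_2$, with dashpot $\eta_2 = \tau/J_2$;
* $\tau$ (s) — retardation time;
* $\eta_0$ (Pa·s) — zero-shear viscosity, the first dashpot.

Two derived scalars summarize a gel: the steady-state compliance
$J_e^0 = J_1 + J_2$ (the intercept of the long-time flow asymptote; a
measure of softness) and $\eta_0$ (the reciprocal of the asymptote's
slope; resistance to flow). A viscoelastic solid is represented exactly by
the sentinel $\eta_0 = \infty$ rather than a large finite number, so the
complete-recovery limit is exact in the forward model.

The response to the on/off protocol follows by Boltzmann superposition:
each force step of sign $s_j$ at time $t_j$ contributes
$s_j (F_0/C) J(t - t_j)$. After a single 10-s on phase the gel recoils,
leaving the unrecoverable flow $(F_0/C)\,t_{\mathrm{on}}/\eta_0$ — zero
for a solid. The closed-form response is verified against independent
numerical integration of the spring–dashpot ODE network to better than
1e-9 relative in the test suite.

# Fitting

Only the force-on windows are fitted (the off phase informs recovery, not
the fit), relative to the onset of the applied force. Two numerical
choices keep the fit fast and reliable:

**Exact step history.** Later cycles start from a state still influenced
by earlier ones (residual flow, a still-relaxing Kelvin element). Fitting
each window against the superposition model with the known step times —
rather than against a bare single-step $J(t)$ with a baseline shift —
removes that bias exactly. On-phase samples then obey
$J_{\mathrm{obs}}(t) = J_1 + J_2\,b(t;\tau) + c(t)/\eta_0$ with known
basis functions $b$ (summed exponentials) and $c$ (accumulated force-on
time).

**Profile (variable projection) solve.** At fixed $\tau$ the model is
linear in $(J_1, J_2, 1/\eta_0)$, so the profiled residual sum of squares
is a smooth 1-D function of $\tau$: it is scanned on a 60-point log grid
spanning a quarter sample interval to twenty window lengths, minimized by
1-D search, and the result polished by Levenberg–Marquardt in
log-parameters (which enforces positivity for free). A seeded multi-start
(8 starts, fixed internal seed, caller's RNG untouched) runs only in the
rare case that the linear solve violates positivity and the polish stays
poor. The profile stage is immune to the $J_2$–$\eta_0$ collinearity that
traps a joint 4-parameter descent when $\tau$ is comparable to the window
length; on noiseless traces the pipeline recovers $(J_e^0, \eta_0)$ to
machine precision across three decades of parameters.

**Cycle pooling.** The two on-windows are fitted jointly with shared
parameters by default. This is deliberately not the mean of two
independent per-cycle fits: a single 10-s window barely resolves the flow
term when $\eta_0$ is large, while the flow accumulated *between* the
windows gives the joint fit a 30-s lever arm. In Monte-Carlo runs at 2%
displacement noise (see `analysis/04_validate.R`) the joint fit's median
$\eta_0$ error is ~1%, an order of magnitude below the per-cycle mean's.
Per-cycle fits are still computed and reported (`$cycles`) because their
agreement is a useful quality-control check, and `pooling = "percycle"`
restores the averaging behaviour.

**Degenerate inputs.** A pure Newtonian series drives $J_1, J_2$ to the
positivity floor and recovers $\eta$; a fitted $\eta_0$ above
$10^6\, t_{\mathrm{on}} / J_e^0$ raises a solid-limit flag instead of
reporting a meaningless huge viscosity.

# Recovery and classification

The recovery ratio of a cycle is
$R = (x_{\mathrm{end\,on}} - x_{\mathrm{end\,off}}) /
(x_{\mathrm{end\,on}} - x_{\mathrm{pre\,cycle}})$, using the last sample
of each phase (robust, and with the closed form
$1 - (t_{\mathrm{on}}/\eta_0)/J(t_{\mathrm{on}})$ as test oracle once
$t_{\mathrm{off}} \gtrsim 10\tau$). The pre-cycle baseline removes flow
accumulated in earlier cycles so both cycles give the same ratio. $R = 1$
is complete recoil.

A gel is classified `viscoelastic_solid` when $R \ge 0.9$ (configurable).
The threshold operationalizes "recoiled nearly completely" versus
"partially recoiled"; no quantitative criterion exists for it, so 0.9 is
reported alongside every result. Classification is monotone in $\eta_0$,
switching exactly once along a viscosity sweep.

A stress sweep checks the linear viscoelastic regime: fits at ≥3 forces
are declared linear when the coefficients of variation of $J_e^0$ and
$\eta_0$ stay within 0.2 and the slope of $\log J_e^0$ versus $\log F$
within 0.1 — in the linear regime compliance is force-independent by
definition.

# The synthetic cohort

`simulate_cohort()` emulates the paired experimental design: each donor's
culture is measured under control, IL-13-activated, and IL-13 + DTT
conditions, with 2–3 transwell-insert replicates per condition, and the
comparison is within donor. Choices, fixed once:

* **Donor population.** $J_e^0 \sim \mathrm{lognormal}(\log 0.15, 0.4)$
  Pa⁻¹ and $\eta_0 \sim \mathrm{lognormal}(\log 200, 0.4)$ Pa·s for
  control gels — soft, liquid-like mucus with $R \approx 0.75$ under the
  default protocol. $\tau = 2$ s and a 2:1 $J_1{:}J_2$ split are held
  fixed across donors and conditions, since condition effects are
  reported as fold changes of $(J_e^0, \eta_0)$ and nothing constrains a
  $\tau$ shift.
* **Condition effects** act multiplicatively on $(J_e^0, \eta_0)$: IL-13
  × (0.3, 20), DTT restoring control exactly. The viscosity factor is
  set to 20 because the defining qualitative feature of IL-13 mucus is
  near-complete recoil: with $t_{\mathrm{on}} = 10$ s a factor of 5
  leaves $R \approx 0.82$ — still below the 0.9 solid threshold — while
  20 gives $R \approx 0.95$. Donors in the low-viscosity tail can still
  straddle the threshold trace-by-trace, so classification is summarized
  at condition level (mean recovery ratio).
* **Replicate variability.** Inserts within a donor share the latent
  parameters up to an independent log-normal jitter of CV 0.10 on each of
  $(J_e^0, \eta_0)$ — a realistic insert-to-insert spread for replicate
  ALI cultures. Without it the paired design has essentially no residual
  variance and every power calculation saturates at 1.
* **Noise.** Additive i.i.d. Gaussian displacement noise with SD
  expressed as a fraction (default 2%) of the elastic plateau
  $(F_0/C)J_e^0$, making noise levels comparable across materials and
  forces. Real traces also contain drift, vibration spikes and
  heteroscedastic tracking error; passing tests on this generator
  validates the inference chain, not robustness to every artefact of a
  real microscope.
* **Forces** follow the experimental settings per condition (110 nN
  control/DTT, 460 nN IL-13); each trace records its own $F_0$, so
  donor-adjusted forces are explicit data rather than hidden assumptions.

All generators are pure functions of (spec, seed): identical outputs on
repeat calls, and the caller's RNG stream is never disturbed.

# Cohort statistics

Insert replicates are averaged to one value per (donor, condition)
*first*; ratios are formed *afterwards* (the two orders differ, and the
per-donor-mean order matches how replicate inserts are summarized into a
single symbol per donor). The "ratio paired t test" is constructed as a
two-sided paired Student's t test on log-transformed within-donor ratios:

$$t = \frac{\overline{\log(b/a)}}{s_{\log(b/a)}/\sqrt{n}}, \qquad
\mathrm{df} = n - 1,$$

reported with the geometric-mean ratio $e^{\overline{\log(b/a)}}$. It is
invariant to rescaling either condition and is verified against an
independent paired t test on logs to 1e-10. Zero-variance log ratios are
flagged (p = 1 when the mean is also zero, p = 0 otherwise) rather than
dividing by zero. No multiple-testing correction is applied — comparisons
are reported per pair, and the generated report says so. At n = 4–5
donors no normality testing is attempted; the log transform and the
pairing carry the inference.

The full pipeline's type-I error (simulate null cohort → fit every trace
→ test) is checked to sit in [0.03, 0.07] at nominal α = 0.05 over 500
seeds, and power is monotone in the $J_e^0$ effect on the grid
{0.9, 0.7, 0.5, 0.3}.

# Wire tracking from image stacks

`track_wire_displacement()` recovers axial wire motion from a time-lapse
stack. Pixels are projected onto the wire axis with matched weights (the
wire's own cross-section profile, estimated from the reference frame), so
rows far from the wire contribute no noise. Each frame's 1-D profile is
cross-correlated with the reference at integer lags; the peak is refined
continuously by maximizing the correlation of the spline-interpolated
profile (three-point parabolic refinement remains as the fallback when
the peak sits at the search boundary). Because a single noisy reference
frame would imprint its own noise on every estimate as a common offset, a
second pass re-tracks against an ensemble reference — the average of all
frames shifted back to the frame-1 position — and re-anchors frame 1 to
zero. Frames whose peak correlation falls below 0.5 are flagged as
failures, never silently interpolated.

The renderer used for validation draws the wire as a finite
Gaussian-profile ridge (cross-section SD 5 px, ends smoothed by a 1-px
PSF) — a scaled-down emulation of a 24.6-µm wire imaged with a 20×
objective, where the wire spans several pixels and its ends are the only
axial structure. Round-trip accuracy is quoted pooled over seeds (all
frame errors from 20 independently rendered stacks), the statistically
meaningful estimate of tracker error: at SNR 10 the pooled RMS error is
below 0.1 px with pooled bias below 0.02 px, as recomputed by
`analysis/04_validate.R` and the acceptance script.

# Validation problem sizes

The shipped validation uses: 100 log-uniform parameter draws for the
noiseless forward/inverse identity (compliances and viscosity over three
decades; $\tau$ over 0.25–25 s, the range resolvable between the 0.5-s
sampling and the 10-s window); 50 seeds for noisy recovery at 2% noise;
500 null seeds for type-I calibration and 60 seeds per effect size for
power; 20 rendered stacks for tracking. These sizes give stable Monte
Carlo estimates while keeping the whole suite comfortably interactive.

# Limitations

* The Burgers model is the simplest liquid-capable viscoelastic model; no
  generalized Maxwell/Prony series, frequency-domain conversion
  (G′/G″), or nonlinear constitutive behaviour is attempted.
* The drag model assumes a single no-slip plane: no finite-depth
  corrections, no wire rotation, no magnetics simulation.
* The tracker is 1-D (axial): rigid-body rotation of the wire is out of
  scope.
* The synthetic cohort emulates design and noise structure, not mucus
  biochemistry: cilia, transport, peroxidase chemistry and thiomer
  gelation are outside the generator; a thiomer-overlay experiment is
  representable only as another labelled condition with its own effect
  sizes.
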