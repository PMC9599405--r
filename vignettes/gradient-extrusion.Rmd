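---
title: "Modelling gradient formation in single-cartridge extrusion bioprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gradient formation in single-cartridge extrusion bioprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradink)
```

## The problem

Graded tissues such as the enthesis (the tendon-to-bone insertion) motivate
printing constructs whose composition changes continuously along a strand.
One way to obtain such gradients without a mixing head is to load two
hydrogel blocks — an *AB block system* with a flat contact interface — into a
single printer cartridge and extrude them with a piston. Laminar flow of a
shear-thinning ink develops a nonuniform velocity profile across the barrel,
so fluid elements at different radii have different residence times. The
flat interface is smeared into an axial composition gradient at the outlet
(*back-mixing*), and, when the walls enforce no slip, slow near-wall fluid of
the first material forms a shell around a core of the second (*core-shell
effect*), leaving a residual wall film that is only flushed out when the
piston crown arrives.

`gradink` reproduces this process at desk scale with a reduced-order
kinematic model — deliberately not a full Navier–Stokes solve — and
quantifies the resulting strand gradients the same way a fluorescence
sampling experiment would.

## Constitutive model

The ink follows the Ostwald–de Waele power law

$$\tau = k\,\dot\gamma^{\,n},$$

with flow consistency index $k$ (Pa·s$^n$) and flow behavior index $n$
($n<1$: shear thinning). The package's reference parameter set uses the
values fitted for a 3% w/v recombinant spider-silk (eADF4(C16)) hydrogel,
$k = 148.89$ Pa·s$^n$ and $n = 0.2025$, valid over
$\dot\gamma = 0.1\text{–}10\ \mathrm{s^{-1}}$. Fitting is ordinary least
squares in $(\log\dot\gamma, \log\tau)$ space, restricted to the validity
window: the slope is $n$, the intercept $\log k$. This closed-form choice is
exact on noiseless power-law data and unbiased in $n$ under multiplicative
(log-normal) stress noise; whether the original fit was performed on stress
or viscosity data is not documented, so stress is the package's stated
choice (viscosity-based flow curves are converted on read,
$\tau = \eta\dot\gamma$, never inside the fitter).

A Metzner–Reed generalized Reynolds number,
$Re = \rho U^{2-n} D^n / \big(k\,((3n+1)/4n)^n\, 8^{\,n-1}\big)$, is provided
as a sanity check: at cartridge conditions it is $\sim 10^{-3}$, deep
creeping flow, which justifies the quasi-steady treatment below.

## Flow model

The cartridge is a straight barrel (radius $R_b$, length $L_{bar}$) followed
by a linear conical taper to the outlet radius $R_o$; needle gauges 14/16/20
map to conventional inner diameters (1.60/1.19/0.603 mm). The piston crown
is a planar wall advancing at $v$; the volumetric flow is
$Q = v\pi R_b^2$.

Because $Re \ll 1$, the field is modelled as locally fully developed
(lubrication form): at axial position $z$ with local radius $R(z)$,

$$u_z(r,z) = U(z)\,\varphi(r/R(z)), \qquad U(z) = \frac{Q}{\pi R(z)^2},$$

where $\varphi$ is the normalized profile with unit flux-weighted mean.
Free-slip walls give a plug, $\varphi \equiv 1$; no-slip walls give the
fully developed power-law tube profile

$$\varphi(\xi) = \frac{3n+1}{n+1}\left(1-\xi^{(n+1)/n}\right),$$

which reduces to the Poiseuille parabola at $n=1$ and flattens toward a plug
as $n \to 0$. The radial velocity follows from incompressibility; in the
cone the streamlines are lines of constant normalized radius, so flux-tube
identity is preserved through the contraction.

**Piston healing zone.** A strictly steady no-slip profile is inconsistent
with the moving crown: wall fluid would be overtaken by the piston. Within a
healing length $\ell$ of the crown the profile is blended to the crown's
plug motion,

$$u_z = v + \big(U\varphi - v\big)\,w(s), \qquad w(s) = 1 - e^{-s/\ell},$$

with $s$ the distance ahead of the crown and $\ell = R_b$ by default (the
creeping-flow decay scale of end disturbances; it is an explicit argument).
The matching analytic $u_r$ keeps every cross-section flux exactly $Q$.
This term is what sweeps the near-wall film out at the end of the stroke —
the mechanism behind the experimentally observed residual first material
being extruded "at the end" — and it is the only part of the field that
depends on the piston position. Strict wall no-slip therefore holds away
from the crown; within $\sim\ell$ of the crown the wall velocity rises to
$v$.

## Transient simulation and material accounting

The A/B interface is seeded with Lagrangian markers: an equal-flux radial
grid (each interior marker represents equal volumetric throughput), refined
by equal-area markers over the outer 10% of the cross-section (the wall film
is flux-starved but volume-rich), plus explicit axis and wall contact
points. Markers are advected by vectorized RK4 with substeps of
$\Delta t/20$.

Material accounting is volumetric and exact. The in-barrel volume of
material A is the axisymmetric quadrature of the column between the marker
surface and the accounting plane, and the reported outlet concentration of a
reporting step is the flow-averaged fraction delivered during that step,

$$C_A(t_k) = \frac{V_A^{in}(t_{k-1}) - V_A^{in}(t_k)}{Q\,\Delta t}.$$

The series therefore telescopes: summed over the run it returns the initial
block-A volume to machine precision, and the extruded A:B volume ratio
equals the fill ratio exactly. An earlier design that counted "live"
equal-flux markers was abandoned because it undercuts the wall film squeezed
inward by the crown by several percent; the volumetric form has no such
leak.

**Accounting plane.** The outlet series is accounted at the cone entrance;
the conical tip is kept in the geometry (it sets the outlet radius mapping
of cross-section snapshots and the streamline contraction) but its hold-up
volume (~0.2 mL for the default geometry) is treated as a
composition-preserving delay line, reported as metadata (`cone_holdup_m3`,
`cone_delay_s`). This is the only consistent convention once the run is
declared to end when the piston reaches the cone entrance: counting the
cone's primed content as block material would distort both the fill-ratio
and the conservation balance by ~15% of a typical block A volume.

**End of extrusion** is the piston reaching the cone entrance, i.e.
$t_{end} = (L_A + L_B)/v$; material remaining in the cone is reported, not
extruded.

Cross-section snapshots aggregate flux tubes into equal-flux annuli mapped
to outlet radii; the core–shell statistic is the mean A-concentration of the
outer half-flux annuli minus the inner half (positive = A-rich shell).
`residual_wall_fraction` reports the fraction of A extruded after $C_A$
first falls below a threshold (default 0.01, a package choice). On a run
object it evaluates the engine's substep-resolution record: at the standard
reporting step of 0.1 s the final crown flush crosses the threshold and
empties within a single reporting interval, so the coarse series would alias
the metric to zero.

### The independent cross-check engine

`simulate_extrusion_fv` is a deliberately different discretisation:
first-order upwind finite volumes on a fixed axisymmetric grid (default
64×256), steady developed profile without the healing term, pure-B inflow at
the piston start plane, flux-weighted outlet average. At reference
parameters the two engines agree to a mean absolute discrepancy of about
0.01 in $C_A(t)$; the residual difference is dominated by upwind numerical
diffusion and by the crown flush, which the fixed-field oracle cannot
represent (its wall film never exits). The tested tolerance is 0.02.

### What the model does and does not capture

Captured: residence-time back-mixing and the sigmoid outlet crossover,
core–shell segregation under no-slip walls, the late residual-film flush,
exact volume balances, plug-flow limits. Not captured: the momentum-field
details of the contraction (no pressure drop, no die swell, no
viscoelasticity), any multivalued folding of the interface at the crown
corner, surface tension between the blocks, and particle or cell transport.
With free-slip walls the reduced model is an exact plug and produces a step
crossover; the smooth crossover reported by the full CFD under nominally
slip outer boundaries is therefore represented here by the no-slip mode,
which is the package default — the wall mode is an explicit setting rather
than a guess at the original solver's wall treatment.

## From outlet series to printed strand

Deposition is kinematic: arc length $s = v_{print}\,t$ (default print speed
20 mm/s), concentrations carried over, deposited volume per length
$Q/v_{print}$ attached as metadata. A 10 s extrusion printed at 20 mm/s
yields a 0.200 m strand.

## Gradient metrics

`compute_gradient_metrics` works on simulated or measured profiles. The
dominant direction comes from the rank correlation of position and value; a
monotone envelope is fitted by isotonic regression (PAVA), and the 10/50/90%
span crossings of the envelope are located by linear interpolation:
midpoint $s_{50}$ and transition width $s_{90}-s_{10}$. Measuring on the
envelope deliberately excludes a descending inner-filter tail from the
width — the decline is a measurement artifact, not a material gradient — and
the tail is instead reported via plateau detection (samples within 5% of
span of the maximum, at least two consecutive; both thresholds are package
choices, stated here once) and a terminal-decline flag. The metrics are
invariant to affine intensity rescaling, and spatial reversal flips the
direction while preserving the width.

For a logistic profile $C(s) = 1/(1+e^{-(s-s_0)/w})$ the closed forms
$s_{50}=s_0$ and width $=2\ln 9\,w \approx 4.394\,w$ are used as test
oracles.

## Fluorescence forward model

Measured intensity of labeled material follows
$F(C) = \alpha C e^{-\beta C}$: linear onset ($F'(0)=\alpha$), interior
maximum at $C = 1/\beta$ when $\beta > 1$, then decline — the inner filter
effect at high fluorophore concentration. The single-exponential form is
chosen over an absorbance-based $10^{-A}$ correction because no path length,
extinction coefficient, or calibration is available to parameterize the
latter; $\beta$ is a free parameter of the synthetic generator only
(default 1.5, giving the modest terminal decline characteristic of strand
fluorometry of fully labeled material). Composing simulation → strand →
response with $\beta > 1$ reproduces the rise–plateau–decline pattern seen
experimentally.

## Synthetic data

All pipeline inputs can be generated with seeded pure functions:

* `synth_flow_curve`: $\tau_i = k\dot\gamma_i^n e^{\varepsilon_i}$,
  $\varepsilon_i \sim N(0,\sigma^2)$, log-spaced over the fit range.
  Multiplicative noise keeps stresses positive; $\sigma$ defaults to 0.05
  (~5% of signal), an ordinary rheometer repeatability figure.
* `synth_strand_samples`: equal-distance sampling (default 3 cm) with
  $n_1 = 3$ technical × $n_2 = 3$ scaffold replicates per position, additive
  Gaussian instrument noise of 5% of the maximum response.

Defaults mirror the reference experiment: piston speed 5 mm/s, reporting
step 0.1 s, print speed 20 mm/s, 1:2 AB fill, 20G outlet, 0.1 bar pneumatic
pressure as metadata (the engine is velocity-driven). The default block
lengths, 10 mm A / 20 mm B (0.72 / 1.45 mL in the 3cc barrel), honour the
1:2 simulated ratio and sit inside the 0.5–1 mL per-block loading range used
experimentally; they were fixed once, before any acceptance measurement. A
green test on synthetic data establishes internal consistency of the model
chain, not fidelity to any particular rheometer or printer: real flow
curves have yield-stress and thixotropic signatures the generator does not
emulate, and real strand intensities include scattering and sampling-volume
variability beyond additive Gaussian noise.

## Numerical choices

* RK4 substep $\Delta t/20$, refused if it under-resolves the healing zone;
  streamline integration halves its step adaptively in the contraction and
  interpolates the outlet crossing linearly.
* Equal-flux seeding uses a monotone-spline inversion of the cumulative flux
  fraction polished by Newton steps.
* The marker quadrature is trapezoidal in $r$ over radially ordered markers
  (markers cannot cross in this field; they are re-sorted defensively).
* Degenerate inputs: constant profiles yield width 0 with an undefined,
  flagged midpoint; a series that never crosses the residual threshold
  returns 0 with a warning; CFL-violating finite-volume steps are refused
  with guidance rather than silently subdivided.

## A worked run

```{r example, eval = FALSE}
cfg <- default_run_config()                 # reference parameter set
run <- simulate_extrusion(cfg$geom, cfg$fill, cfg$settings, cfg$params)
run
strand <- outlet_to_strand(run, cfg$settings$print_speed)
compute_gradient_metrics(strand)
residual_wall_fraction(run)
core_shell_statistic(run$snapshots[[4]])    # 0.9 of the run duration
```

## Known limitations

The reduced-order field cannot predict process pressures or strand
morphology; the cone is a delay line, so any additional smearing inside the
tip is ignored; the interface is assumed to remain single-valued in radius
(the crown-corner fold is represented only through the healing sweep); and
slip-mode runs produce an idealized step rather than the partially mixed
crossover a full solver with contraction effects might show.
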