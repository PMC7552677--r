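---
title: "Modeling dysfunctional bileaflet valves with subaortic stenosis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dysfunctional bileaflet valves with subaortic stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmhvflow)
```

## The problem

A bileaflet mechanical heart valve (BMHV) in the aortic position is
routinely surveilled with Doppler echocardiography. The clinical surrogates
— transvalvular peak velocity $V_{peak}$, mean transvalvular pressure
gradient $TPG_{mean} = \overline{4 V^2}$ (mmHg, $V$ in m/s), Doppler
velocity index $DVI = V_{LVOT}/V_{peak}$ and effective orifice area
$EOA = Q/V_{peak}$ — are compared against guideline thresholds to suspect
leaflet dysfunction. A concomitant narrowing of the left ventricular
outflow tract (subaortic stenosis, SAS) accelerates the flow upstream of
the prosthesis and can mimic or mask valve dysfunction in those same
surrogates.

`bmhvflow` implements a desk-scale in-silico version of this diagnostic
problem: a parametric 2D model of the outflow tract with a tunnel-type SAS
and a 27 mm-class bileaflet prosthesis, a pulsatile incompressible flow
solver, field post-processing (vorticity, viscous and modeled turbulent
shear stress), extraction of the four Doppler surrogates per case, and
sensitivity/specificity evaluation of the guideline criteria over a
45-case grid: LVOT hydraulic diameter $\in \{27,25,23,21,19\}$ mm,
one-leaflet opening restriction $\in \{0,50,100\}\%$, and mean cardiac
output $\in \{3,5,7\}$ L/min at a fixed 70 bpm heart rate with a 0.3 s
systole. Blood is Newtonian with $\rho = 1060$ kg/m$^3$ and
$\mu = 0.0035$ Pa s.

## Study grid and derived quantities

Cases are enumerated deterministically (dysfunction outermost, diameter
descending, flow innermost) with stable ids such as `d19_f100_q7`:

```{r}
grid <- enumerate_cases()
nrow(grid)
head(grid, 3)
```

Two pieces of printed arithmetic anchor the geometry interpretation. The
hydraulic inlet diameter is read as a circular cross-section, making the
19 mm LVOT a 50% area reduction against the 27 mm annulus — a 2D width
ratio would give only 30%, so the circular reading is the one consistent
with the study's framing:

```{r}
round(100 * stenosis_area_reduction(19))
```

Restricting the opening of one of the two symmetric leaflets by 50% or
100% removes 25% or 50% of total valve area:

```{r}
100 * valve_area_restriction(c(50, 100))
```

The Womersley number with the standard definition
$\alpha = R\sqrt{\omega/\nu}$ at $R = 13.5$ mm and 70 bpm evaluates to
about 20.1 (`womersley_number(0.0135, 70)`). The value 16.2 sometimes
quoted for this configuration is not reproducible from these constants;
the characteristic length behind it is unstated, so the package implements
the standard definition and documents the discrepancy rather than
reconciling it.

## Geometry

The 2D channel is laid out along the streamwise axis: a tunnel-shaped
stenotic LVOT at the case diameter $d$ (the tunnel type is an extended
concentric narrowing, so the inlet opening itself is $d$), a conical
expansion from $d$ to the 27 mm annulus over the `stenosis_length_mm`
segment immediately upstream of the valve plane, two rigid leaflets, a
two-sided sinus bulge, and the ascending aorta. Dimension defaults
(leaflets 12 mm x 0.8 mm pivoting at hinges 4 mm off the centerline,
opening travel 25-85 degrees from the valve plane, 4 mm sinus bulge over
25 mm, segment lengths 30/20/25/80 mm) are representative published
values for a 27 mm bileaflet prosthesis; the pipeline's acceptance surface
deliberately does not depend on their exact values, and all are
configurable.

The affected leaflet interpolates linearly between the open and closed
angles with the dysfunction percentage; the functional leaflet stays fully
open and is rasterized as an exact mirror image, so a healthy valve is
cell-wise mirror-symmetric. Geometry is rasterized to a masked-cell
(stair-step) representation on a uniform Cartesian grid rather than a
body-fitted mesh: it is deterministic, desk-scale, and adequate for the
formula-level and qualitative claims the package makes. Thin structures
are inflated to at least two cells when rasterized so leaflets remain
watertight on coarse grids (with the 0.8 mm leaflet this engages whenever
the spacing exceeds 0.4 mm, including both the 0.45 mm default and the
0.9 mm grid used in the coarse studies below).

```{r}
mask <- build_geometry(case_spec(27, 0, 5),
                       geometry_params(grid_spacing_mm = 0.9))
orifice_widths(mask)  # two laterals flanking the smaller central orifice
```

A fully open valve exposes one central and two lateral orifices; full
closure of one leaflet removes the affected lateral orifice.

## Inflow and the 3D-to-2D mapping

The systolic inflow is a half-sine pulse over the 0.3 s systole and zero
in diastole, scaled so the cycle mean equals the case's cardiac output;
the peak flow is $Q_{peak} = CO \cdot (T/T_{sys}) \cdot \pi/2$, about
22.4 L/min (374 cm$^3$/s) at 5 L/min. The published inflow for this kind
of rig is experimental and available only graphically; the half-sine
substitute preserves the mean, the heart rate and the systole duration,
and its peak-flow arithmetic reproduces the expected healthy-valve EOA
scale ($\approx 374/136 \approx 2.7$ cm$^2$ at $V_{peak} = 1.36$ m/s).

Cardiac output is a 3D-equivalent quantity driving a 2D simulation. The
mapping adopted here converts $Q(t)$ to a plug inlet velocity through the
circular LVOT cross-section, $U = Q/(\pi d^2/4)$, and the 2D solver
transports that velocity scale. This makes the inlet velocity — and with
it every downstream velocity surrogate — scale as $1/d^2$ with the
stenosis diameter, which is what gives SAS its accelerating effect in the
model. A plug profile with a stated inlet turbulence intensity is standard
practice for this kind of rig.

`EOA = Q_{peak}/V_{peak}` uses the peak systolic volumetric flow: the
cycle-mean flow would give EOA values several-fold too small to be
meaningful against the clinical thresholds (about 0.6 cm$^2$ for a healthy
valve), so the peak-flow convention is the only self-consistent reading.

## Flow solver

The solver is a Chorin-type fractional-step (projection) method on a
staggered (MAC) grid, implemented in compiled code:

* explicit convection, first-order upwind by default (a 75% central blend
  is available); explicit diffusion;
* pressure Poisson solve by warm-started conjugate gradients with Neumann
  conditions at walls and inlet and a Dirichlet zero-gauge condition on
  the outlet faces; the post-projection discrete divergence of every fluid
  cell is kept below `poisson_tolerance` times $U_{ref}/h$, where
  $U_{ref}$ is the peak inlet velocity of the run;
* outlet velocity is zero-gradient with a uniform flux correction, so the
  instantaneous inlet and outlet fluxes balance exactly and cycle-integrated
  mass conservation follows from the divergence control;
* no-slip on solids via mirrored ghost values (the zero-velocity wall sits
  halfway between cell centers);
* the macro time step (0.5 ms default, matching time-step-independence
  practice for this problem class) is subdivided adaptively so that the
  advective CFL number stays below `cfl_limit` and the explicit diffusion
  limit (including the stiffer wall-ghost stencil) is respected. The
  `advance()` single-step interface instead refuses CFL violations with a
  suggested step, which keeps the step contract explicit for unit use.
* `max_inner_iterations` caps the pressure-correction rounds per time
  step; each round is one conjugate-gradient solve to tolerance. A
  non-convergent step raises an error carrying the scaled residual
  history.

Runs start from quiescent flow (no random state anywhere in the solver),
simulate `n_cycles` cardiac cycles and return the final cycle, together
with a periodicity metric: the relative L2 velocity difference between the
last two cycles at eight matched phases. Because the inflow is zero in
diastole, cycle-to-cycle memory is short; the healthy reference case
reaches a periodicity metric below 5% already between cycles one and two
on the coarse grid, and below 2% between cycles four and five.

### Turbulence closure

The optional closure is the standard Wilcox $k$-$\omega$ model
($\alpha = 5/9$, $\beta = 3/40$, $\beta^* = 0.09$,
$\sigma = \sigma^* = 1/2$) with 5% inlet turbulence intensity, upwind
transport, explicit production, semi-implicit destruction, and
$\nu_t = k/\omega$ clipped at `nut_max_ratio` (default 1000) times the
molecular viscosity. Solid-adjacent cells take the near-wall asymptote
$\omega = 6\nu/(\beta y_1^2)$ at the first-cell distance $y_1 = h/2$ — an
acknowledged approximation of low-Reynolds wall treatment. Negative $k$
after an update is floored to zero and counted in the run diagnostics.

Laminar mode is the default for the shipped studies: at the coarse
resolutions used here the first-order upwind scheme is already strongly
dissipative, and the package's quantitative claims are restricted to
quantities that do not depend on the turbulence model (the closure is
exercised by its own unit contracts, e.g. convergence of $\omega$ to the
algebraic production-dissipation balance $\omega = S\sqrt{\alpha/\beta}$
under uniform shear). Absolute turbulent-shear-stress magnitudes from
full-scale CFD (hundreds of Pa) are out of scope for this desk-scale
reimplementation and are treated as qualitative context only.

## Verification

Two analytic benchmarks gate the solver (also exposed via the `verify`
command):

* steady plane Poiseuille flow in a 64-cell-wide channel: the
  centerline-to-mean velocity ratio must match the analytic value 1.5
  within 2%;
* oscillatory channel flow at Womersley number 5 against the exact
  profile (evaluated through its complex closed form and cross-checked to
  1e-8 against an independent eigenfunction-series evaluation): RMS error
  below 5% over the final forcing period.

Both are initialized from the analytic profile — a divergence-free state —
so the benchmark measures the discrete operators rather than a slow
viscous start-up transient. Mass conservation (cycle-integrated inlet vs
outlet flux within 1%) and the per-cell divergence bound are asserted on
every stored run.

## What the coarse studies show — and what they cannot

The shipped tests and the acceptance script run a 2x2x2 corner sub-grid of
the study (27/19 mm, 0/100% dysfunction, 3/7 L/min) at `h = 0.9` mm with
two cardiac cycles per case, plus the healthy 5 L/min references — sizes
chosen so the full suite remains a desk-scale computation. At that
resolution the model reproduces the headline physics of the problem:

* a healthy valve produces three valve-plane jets; full one-leaflet
  closure leaves a dominant lateral jet on the functioning side;
* $V_{peak}$ increases monotonically with dysfunction level, SAS severity
  and cardiac output; EOA decreases with dysfunction; peak vorticity
  magnitude increases with SAS severity;
* DVI and EOA are nearly flow-independent (relative spread across cardiac
  outputs well under 15%).

What it does not do: reproduce the absolute Doppler magnitudes of
full-scale, fine-mesh CFD. A first-order 2D solver at 0.9 mm under-resolves
the jets, so simulated $V_{peak}$ runs low (about 1.0 m/s for the healthy
27 mm, 5 L/min case against the 1.3-1.4 m/s scale expected of the real
configuration), DVI runs correspondingly high, and the simulated DVI range
extends slightly above the 0.25-0.89 envelope of the full-scale study.
Consequently sensitivities of the guideline thresholds evaluated on the
coarse sub-grid are not comparable to published point estimates; the
accuracy machinery is therefore verified against exhaustive brute-force
confusion counting and hand-counted fixtures, not against any published
table. The synthetic jet-field generator (`synthetic_jet_field`), which
prescribes exact downstream and LVOT maxima, is the bridge that lets the
Doppler and accuracy stages be validated independently of solver fidelity.

## Numerical choices and degenerate inputs

* Tie-breaks: `peak_over` resolves equal maxima to the earliest snapshot
  time, then the lowest cell index, making reported peak locations
  reproducible.
* Threshold comparisons in `classify` are inclusive, matching the printed
  guideline notation; reported percentages are exact, with integer
  rounding only in the presentation table.
* Degenerate inputs raise typed errors rather than returning silent
  defaults: a fully occluded valve plane, a zero-flow Doppler series,
  single-class labels in `sensitivity_specificity`, fewer than two reports
  per diameter in the per-LVOT summary.
* The configuration file is YAML with unknown-key rejection; every run can
  write a JSON manifest with the configuration snapshot, case ids and
  solver diagnostics so grid runs are resumable and auditable.

## Known limitations

Fixed leaflets (no opening/closing kinematics, no fluid-structure
interaction), no hinge-gap microflow, 2D only, tunnel-type SAS only, heart
rates other than 70 bpm are accepted but untested, and the turbulence
closure is exercised at unit level rather than validated against
high-Reynolds data. These mirror the boundaries of the study the package
re-implements, plus the resolution compromises stated above.
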